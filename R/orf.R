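# Six-frame ORF finding and CDS selection for transcriptome contigs.

# Standard genetic code (translation table 1), keyed by codon.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# Translate a nucleotide string (length divisible by 3); codons containing N
# (or any non-ACGT base) become X; stop codons become '*'.
translate_nt <- function(nt) {
  if (nchar(nt) == 0) return("")
  tab <- codon_table()
  codons <- substring(nt, seq(1L, nchar(nt) - 2L, by = 3L),
                      seq(3L, nchar(nt), by = 3L))
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(nt) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Find open reading frames in all six frames of a nucleotide sequence
#'
#' Scans the three forward and three reverse frames of a contig for open
#' reading frames. Two conventions are supported: `atg_to_stop` reports, for
#' every maximal stop-free codon run, the ORF from its first ATG to the stop
#' (an ORF truncated by the sequence end is reported without a stop);
#' `stop_to_stop` reports every maximal stop-free codon run regardless of a
#' start codon. Coordinates are 1-based inclusive on the forward strand and
#' exclude the stop codon; `N` bases translate to `X`.
#'
#' @param sequence Nucleotide string over `ACGTN` (case-insensitive).
#' @param min_aa_length Minimum peptide length to report (default 30).
#' @param orf_mode `"atg_to_stop"` (default) or `"stop_to_stop"`.
#' @return Tibble with columns `frame` (in -3..-1, 1..3), `start`, `end`
#'   (forward-strand nucleotide coordinates), `peptide`, `aa_length`.
#' @examples
#' find_orfs("ATGAAATAA", min_aa_length = 2)
#' @export
find_orfs <- function(sequence, min_aa_length = 30L,
                      orf_mode = c("atg_to_stop", "stop_to_stop")) {
  orf_mode <- match.arg(orf_mode)
  stopifnot(min_aa_length >= 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) > 0 && grepl("[^ACGTN]", sequence)) {
    abort("sequence contains characters outside ACGTN")
  }
  empty <- tibble(frame = integer(), start = integer(), end = integer(),
                  peptide = character(), aa_length = integer())
  L <- nchar(sequence)
  if (L < 3L) return(empty)

  scan_strand <- function(nt, strand_sign) {
    out <- list()
    for (off in 0:2) {
      n_codons <- (nchar(nt) - off) %/% 3L
      if (n_codons < 1L) next
      aa <- strsplit(translate_nt(substr(nt, off + 1L, off + 3L * n_codons)),
                     "")[[1]]
      is_stop <- aa == "*"
      # maximal stop-free runs of codon indices
      run_id <- cumsum(is_stop)
      for (run in split(which(!is_stop), run_id[!is_stop])) {
        if (orf_mode == "atg_to_stop") {
          starts_codon <- run[substring(nt, off + 3L * (run - 1L) + 1L,
                                        off + 3L * (run - 1L) + 3L) == "ATG"]
          if (length(starts_codon) == 0) next
          first <- starts_codon[1]
          pep <- paste(aa[seq(first, run[length(run)])], collapse = "")
          c_start <- first
        } else {
          pep <- paste(aa[run], collapse = "")
          c_start <- run[1]
        }
        if (nchar(pep) < min_aa_length) next
        nt_start <- off + 3L * (c_start - 1L) + 1L
        nt_end <- nt_start + 3L * nchar(pep) - 1L
        out[[length(out) + 1L]] <- tibble(
          frame = strand_sign * (off + 1L),
          start = nt_start, end = nt_end, peptide = pep,
          aa_length = nchar(pep)
        )
      }
    }
    bind_rows(out)
  }

  fwd <- scan_strand(sequence, 1L)
  rev <- scan_strand(revcomp(sequence), -1L)
  if (nrow(rev) > 0) {
    # map reverse-complement coordinates back to the forward strand
    s <- L - rev$end + 1L
    e <- L - rev$start + 1L
    rev$start <- s
    rev$end <- e
  }
  res <- bind_rows(fwd, rev)
  if (nrow(res) == 0) return(empty)
  as_tibble(res[corder(res$start, res$frame), , drop = FALSE])
}

#' Find ORFs for a table of contigs
#'
#' @param contigs Tibble with columns `contig_id`, `sequence`.
#' @inheritParams find_orfs
#' @return Tibble of ORFs with `contig_id` and a unique `orf_id` per contig
#'   prepended to the [find_orfs()] columns.
#' @export
find_all_orfs <- function(contigs, min_aa_length = 30L,
                          orf_mode = c("atg_to_stop", "stop_to_stop")) {
  orf_mode <- match.arg(orf_mode)
  res <- purrr::map2(contigs$contig_id, contigs$sequence, function(id, s) {
    orfs <- find_orfs(s, min_aa_length, orf_mode)
    if (nrow(orfs) == 0) return(NULL)
    mutate(orfs, contig_id = id,
           orf_id = sprintf("%s_orf%d", id, seq_len(nrow(orfs))),
           .before = 1)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(contig_id = character(), orf_id = character(),
                  frame = integer(), start = integer(), end = integer(),
                  peptide = character(), aa_length = integer()))
  }
  out
}

#' Select one coding sequence per contig
#'
#' Mirrors the two-tier CDS selection used for transcriptome contigs: when any
#' ORF of a contig has a database best hit, the ORF with the strongest hit is
#' chosen (highest bitscore, ties broken by lowest e-value, then longest
#' peptide, then smallest start); otherwise the longest ORF is chosen (ties by
#' smallest start, then lowest absolute frame). The result partitions contigs
#' into `best_hit` and `longest` provenance classes.
#'
#' @param orfs Tibble from [find_all_orfs()].
#' @param best_hits Tibble with columns `contig_id`, `orf_id`, `hit_found`,
#'   `bitscore`, `evalue` (at most one row per ORF); may have zero rows.
#' @return Tibble with one row per contig that had at least one ORF, with a
#'   `selection` column in `{"best_hit","longest"}`. Contigs absent from
#'   `orfs` are silently absent; a zero-ORF contig cannot be represented.
#' @export
select_cds <- function(orfs, best_hits = NULL) {
  if (nrow(orfs) == 0) {
    warn("no ORFs supplied; no CDS selected")
    return(mutate(orfs, selection = character(0)))
  }
  if (is.null(best_hits) || nrow(best_hits) == 0) {
    best_hits <- tibble(contig_id = character(), orf_id = character(),
                        hit_found = logical(), bitscore = numeric(),
                        evalue = numeric())
  }
  if (anyDuplicated(best_hits[c("contig_id", "orf_id")])) {
    abort("best_hits has more than one row for some (contig, orf)")
  }
  x <- orfs |>
    left_join(select(best_hits, "contig_id", "orf_id", "hit_found",
                     "bitscore", "evalue"),
              by = c("contig_id", "orf_id")) |>
    mutate(hit_found = !is.na(.data$hit_found) & .data$hit_found)

  x |>
    group_by(.data$contig_id) |>
    group_modify(function(g, key) {
      if (any(g$hit_found)) {
        h <- g[g$hit_found, , drop = FALSE]
        h <- h[order(-h$bitscore, h$evalue, -h$aa_length, h$start), , drop = FALSE]
        cbind(h[1, , drop = FALSE], selection = "best_hit")
      } else {
        h <- g[order(-g$aa_length, g$start, abs(g$frame)), , drop = FALSE]
        cbind(h[1, , drop = FALSE], selection = "longest")
      }
    }) |>
    ungroup()
}
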