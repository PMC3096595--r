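# Readers and writers for the external formats the pipeline touches:
# FASTA, InterProScan TSV, DBD catalogs, Inparanoid sqltables, edge lists.

VALID_AA <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Read a FASTA file into a tibble of protein records
#'
#' A deliberately strict FASTA reader: sequence lines may contain only the 20
#' amino acids plus `X` and `*` (case-insensitive), and every record needs a
#' non-empty identifier. Violations are reported with the offending line
#' number, which matters when ingesting large third-party proteome dumps.
#'
#' @param path Path to a FASTA file.
#' @param species_id Species tag attached to every record. If `NULL`, the tag
#'   is extracted from each header with `header_token` (a 1-based index into
#'   the `|`-separated header fields).
#' @param header_token Integer index of the `|`-separated header field holding
#'   the species tag when `species_id` is `NULL`.
#' @param alphabet Character vector of allowed residues. Defaults to the amino
#'   acid alphabet; pass e.g. `c("A","C","G","T","N")` for nucleotide contigs.
#' @return A tibble with columns `protein_id`, `species_id`, `sequence`,
#'   `description` — one row per record. Empty files yield zero rows.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 a homeobox protein", "MKT"), tf)
#' read_fasta(tf, species_id = "AM")
#' @export
read_fasta <- function(path, species_id = NULL, header_token = 2L,
                       alphabet = VALID_AA) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, ">")
  if (length(lines) > 0 && !is_header[1] && any(nzchar(trimws(lines)))) {
    abort(sprintf("FASTA parse error at line 1 of '%s': expected '>' header", path))
  }
  if (!any(is_header)) {
    return(tibble(protein_id = character(), species_id = character(),
                  sequence = character(), description = character()))
  }
  rec_idx <- cumsum(is_header)
  headers <- lines[is_header]
  header_lines <- which(is_header)

  bad <- which(!is_header & !grepl(paste0("^[", paste(gsub("\\*", "\\\\*", alphabet), collapse = ""),
                                          tolower(paste(alphabet, collapse = "")), "]*$"),
                                   trimws(lines)))
  if (length(bad) > 0) {
    abort(sprintf("FASTA parse error at line %d of '%s': illegal residue in sequence",
                  bad[1], path))
  }

  ids <- sub("^>\\s*", "", headers)
  desc <- sub("^\\S*\\s*", "", ids)
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    abort(sprintf("FASTA parse error at line %d of '%s': empty record id",
                  header_lines[which(!nzchar(ids))[1]], path))
  }

  seqs <- vapply(split(toupper(trimws(lines[!is_header])), rec_idx[!is_header]),
                 paste0, character(1), collapse = "")
  seqs <- seqs[match(as.character(seq_along(ids)), names(seqs))]
  seqs[is.na(seqs)] <- ""

  if (is.null(species_id)) {
    sp <- vapply(strsplit(ids, "|", fixed = TRUE), function(f) {
      if (length(f) < header_token) NA_character_ else f[header_token]
    }, character(1))
    if (anyNA(sp)) {
      abort(sprintf("FASTA header at line %d lacks a '|' token %d for the species tag",
                    header_lines[which(is.na(sp))[1]], header_token))
    }
  } else {
    sp <- rep(species_id, length(ids))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate record id '%s' in '%s'", ids[duplicated(ids)][1], path))
  }
  tibble(protein_id = ids, species_id = sp, sequence = unname(seqs),
         description = desc)
}

#' Write protein records to a FASTA file
#'
#' @param proteins Tibble with `protein_id`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  hdr <- if ("description" %in% names(proteins) && any(nzchar(proteins$description))) {
    ifelse(nzchar(proteins$description),
           paste0(">", proteins$protein_id, " ", proteins$description),
           paste0(">", proteins$protein_id))
  } else paste0(">", proteins$protein_id)
  chunks <- map2(hdr, proteins$sequence, function(h, s) {
    if (!nzchar(s)) return(h)
    starts <- seq(1L, nchar(s), by = width)
    c(h, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(as.character(unlist(chunks)), path, useBytes = TRUE)
  invisible(path)
}

#' Column layout of an InterProScan-style TSV
#'
#' Column positions differ across InterProScan versions; the default maps the
#' version-5 TSV (protein accession in column 1, analysis in column 4, domain
#' accession in 5, name in 6, start in 7, end in 8, score in 9).
#'
#' @param protein_id,analysis,accession,name,start,end,score 1-based column
#'   indices.
#' @return A named integer list used by [read_interproscan_tsv()].
#' @export
ipr_columns <- function(protein_id = 1L, analysis = 4L, accession = 5L,
                        name = 6L, start = 7L, end = 8L, score = 9L) {
  list(protein_id = protein_id, analysis = analysis, accession = accession,
       name = name, start = start, end = end, score = score)
}

#' Read domain annotations from an InterProScan-style TSV
#'
#' Retains only rows whose analysis column matches `analysis_filter`
#' (default `"Pfam"`); other member databases (SUPERFAMILY, PRINTS, ...) are
#' skipped. Coordinates are validated: `1 <= start <= end`.
#'
#' @param path Path to the TSV (no header line, InterProScan convention).
#' @param analysis_filter Analyses to retain; `NULL` keeps every row.
#' @param columns Column layout, see [ipr_columns()].
#' @return Tibble with `protein_id`, `domain_accession`, `domain_name`,
#'   `start`, `end`, `score`, `is_pfam`.
#' @export
read_interproscan_tsv <- function(path, analysis_filter = "Pfam",
                                  columns = ipr_columns()) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn(sprintf("no annotation rows in '%s'", path))
    return(empty_annotations())
  }
  need <- max(unlist(columns[c("protein_id", "analysis", "accession", "start", "end")]))
  if (ncol(raw) < need) {
    abort(sprintf("'%s' has %d columns but the declared layout needs %d",
                  path, ncol(raw), need))
  }
  col <- function(i) if (i <= ncol(raw)) raw[[i]] else NA_character_
  out <- tibble(
    protein_id = col(columns$protein_id),
    analysis = col(columns$analysis),
    domain_accession = col(columns$accession),
    domain_name = col(columns$name),
    start = suppressWarnings(as.integer(col(columns$start))),
    end = suppressWarnings(as.integer(col(columns$end))),
    score = suppressWarnings(as.numeric(col(columns$score)))
  )
  if (!is.null(analysis_filter)) {
    out <- filter(out, .data$analysis %in% analysis_filter)
  }
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 1L | out$end < out$start)
  if (length(bad) > 0) {
    abort(sprintf("invalid domain coordinates in '%s' (retained row %d): start=%s end=%s",
                  path, bad[1], out$start[bad[1]], out$end[bad[1]]))
  }
  if (nrow(out) == 0) warn(sprintf("0 annotation rows retained from '%s'", path))
  out |>
    mutate(is_pfam = grepl("^PF[0-9]+$", .data$domain_accession)) |>
    select(-"analysis")
}

empty_annotations <- function() {
  tibble(protein_id = character(), domain_accession = character(),
         domain_name = character(), start = integer(), end = integer(),
         score = numeric(), is_pfam = logical())
}

#' Read a catalog of sequence-specific DNA-binding domains
#'
#' The catalog drives TF classification: a protein is called a TF when it
#' carries at least one domain listed here. One accession per line, `#`
#' comments and blank lines allowed; duplicates are collapsed.
#'
#' @param path Path to a plain-text catalog file.
#' @return Character vector of unique accessions, sorted.
#' @export
read_dbd_catalog <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  acc <- unique(lines[nzchar(lines)])
  if (length(acc) == 0) {
    abort(sprintf("DBD catalog '%s' is empty: a TF census against an empty catalog is meaningless", path))
  }
  inform(sprintf("DBD catalog '%s': %d accessions", basename(path), length(acc)))
  csort(acc)
}

#' Read an Inparanoid sqltable of pairwise ortholog groups
#'
#' The sqltable dialect has five tab-separated columns per row:
#' `group_id`, `bitscore`, `species_id`, `confidence`, `protein_id`.
#' Seed orthologs carry confidence 1.0; additional members (inparalogs,
#' duplicated after the speciation) carry confidences in (0, 1]. Every group
#' must span exactly the file's two species.
#'
#' @param path Path to the sqltable file.
#' @param col_order Character vector naming the five columns in file order
#'   (override for sqltable variants).
#' @return An ortholog map: a tibble with columns `group_id`, `bitscore`,
#'   `species_id`, `confidence`, `protein_id` and a `"species_pair"`
#'   attribute (sorted pair of species ids).
#' @export
read_inparanoid_sqltable <- function(path,
                                     col_order = c("group_id", "bitscore",
                                                   "species_id", "confidence",
                                                   "protein_id")) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = col_order,
                         col_types = readr::cols(.default = "c"), progress = FALSE)
  map <- tibble(
    group_id = as.integer(raw$group_id),
    bitscore = as.numeric(raw$bitscore),
    species_id = raw$species_id,
    confidence = as.numeric(raw$confidence),
    protein_id = raw$protein_id
  )
  validate_ortholog_map(map, path)
}

validate_ortholog_map <- function(map, origin = "ortholog map") {
  if (nrow(map) == 0) {
    attr(map, "species_pair") <- character()
    return(map)
  }
  if (any(is.na(map$confidence)) || any(map$confidence < 0 | map$confidence > 1)) {
    bad <- which(is.na(map$confidence) | map$confidence < 0 | map$confidence > 1)[1]
    abort(sprintf("%s: confidence %s outside [0,1] (row %d)",
                  origin, map$confidence[bad], bad))
  }
  n_sp <- map |> group_by(.data$group_id) |>
    summarise(k = n_distinct(.data$species_id), .groups = "drop")
  if (any(n_sp$k != 2L)) {
    g <- n_sp$group_id[n_sp$k != 2L][1]
    abort(sprintf("%s: group %s spans %d species, expected exactly 2",
                  origin, g, n_sp$k[n_sp$group_id == g]))
  }
  pair <- csort(unique(map$species_id))
  if (length(pair) != 2L) {
    abort(sprintf("%s: file references %d species, expected exactly 2",
                  origin, length(pair)))
  }
  attr(map, "species_pair") <- pair
  map
}

ortholog_map_key <- function(map) paste(attr(map, "species_pair"), collapse = "|")

# Partners of `proteins` (in species `from`) in species `to`, per protein.
# Returns a named list of character vectors (may be empty vectors).
ortholog_partners <- function(map, proteins, from, to) {
  sub <- map |> filter(.data$species_id %in% c(from, to))
  own <- sub |> filter(.data$species_id == from, .data$protein_id %in% proteins)
  other <- sub |> filter(.data$species_id == to)
  by_group <- split(other$protein_id, other$group_id)
  res <- lapply(proteins, function(p) {
    gids <- as.character(own$group_id[own$protein_id == p])
    csort(unique(unlist(by_group[gids], use.names = FALSE)))
  })
  setNames(res, proteins)
}

#' Write an interaction network as a TSV or SIF edge list
#'
#' Edges are written in a deterministic order (lexicographic by canonical
#' endpoint pair); self-loops appear with identical endpoints. The TSV format
#' carries the provenance columns; SIF is a bare
#' `node relation node` triple per edge.
#'
#' @param network Tibble with columns `protein_a`, `protein_b`, `species_id`,
#'   `provenance`, `source_edge_ids`, `evidence` (TSV); only the endpoints are
#'   required for SIF.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @param relation SIF relation label.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, format = c("tsv", "sif"),
                            relation = "tf_tf") {
  format <- match.arg(format)
  net <- as_tibble(network)
  if (nrow(net) > 0) {
    cp <- canonical_pair(net$protein_a, net$protein_b)
    net$protein_a <- cp$protein_a
    net$protein_b <- cp$protein_b
    net <- net[corder(net$protein_a, net$protein_b), , drop = FALSE]
  }
  if (format == "sif") {
    writeLines(sprintf("%s %s %s", net$protein_a, relation, net$protein_b),
               path, useBytes = TRUE)
    return(invisible(path))
  }
  cols <- c("protein_a", "protein_b", "species_id", "provenance",
            "source_edge_ids", "evidence")
  for (c0 in setdiff(cols, names(net))) net[[c0]] <- rep("", nrow(net))
  readr::write_tsv(net[cols], path, progress = FALSE)
  invisible(path)
}

#' Read an interaction network edge list written by [write_edge_list()]
#'
#' Duplicate unordered edges are collapsed on read with a logged count, and
#' endpoints are canonicalized, so a re-read network compares equal as a set
#' of unordered provenance-tagged edges.
#'
#' @param path Path to a TSV edge list.
#' @return Tibble with the canonical network columns.
#' @export
read_edge_list <- function(path) {
  stopifnot(file.exists(path))
  net <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("protein_a", "protein_b")
  if (!all(req %in% names(net))) {
    abort(sprintf("'%s' lacks protein_a/protein_b columns", path))
  }
  blank <- !nzchar(net$protein_a) | !nzchar(net$protein_b) |
    is.na(net$protein_a) | is.na(net$protein_b)
  if (any(blank)) abort(sprintf("'%s': blank endpoint id at row %d", path, which(blank)[1]))
  cp <- canonical_pair(net$protein_a, net$protein_b)
  net$protein_a <- cp$protein_a
  net$protein_b <- cp$protein_b
  n0 <- nrow(net)
  net <- distinct(net)
  if (nrow(net) < n0) {
    inform(sprintf("collapsed %d duplicate edge rows in '%s'", n0 - nrow(net), path))
  }
  as_tibble(net[corder(net$protein_a, net$protein_b), , drop = FALSE])
}

#' Read a TSV of source (experimentally verified) TF-TF interactions
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `species_id` and
#'   optionally `edge_id`, `evidence`.
#' @return Tibble with columns `edge_id`, `protein_a`, `protein_b`
#'   (canonical order), `species_id`, `evidence`; duplicate unordered edges
#'   within a species collapsed with a logged count.
#' @export
read_source_edges <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("protein_a", "protein_b", "species_id")
  if (!all(req %in% names(raw))) {
    abort(sprintf("'%s' lacks required columns %s", path,
                  paste(setdiff(req, names(raw)), collapse = ", ")))
  }
  blank <- is.na(raw$protein_a) | is.na(raw$protein_b) |
    !nzchar(raw$protein_a) | !nzchar(raw$protein_b)
  if (any(blank)) abort(sprintf("'%s': blank endpoint id at row %d", path, which(blank)[1]))
  cp <- canonical_pair(raw$protein_a, raw$protein_b)
  raw$protein_a <- cp$protein_a
  raw$protein_b <- cp$protein_b
  if (!"evidence" %in% names(raw)) raw$evidence <- ""
  n0 <- nrow(raw)
  raw <- distinct(raw, .data$protein_a, .data$protein_b, .data$species_id,
                  .keep_all = TRUE)
  if (nrow(raw) < n0) {
    inform(sprintf("collapsed %d duplicate source edges in '%s'", n0 - nrow(raw), path))
  }
  if (!"edge_id" %in% names(raw)) {
    raw$edge_id <- sprintf("%s_e%05d", raw$species_id,
                           stats::ave(seq_len(nrow(raw)), raw$species_id, FUN = seq_along))
  }
  select(as_tibble(raw), "edge_id", "protein_a", "protein_b", "species_id", "evidence")
}
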