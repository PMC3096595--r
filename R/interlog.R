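# The core computation: interolog inference by ortholog cross products.
# A source interaction (A, B) observed in species s is transferred to
# species i as the set of all unordered pairs (a, b) with a an ortholog of A
# and b an ortholog of B in i, retained only when the endpoints are TFs.

unordered_pairs <- function(ids, mode = c("full", "diagonal")) {
  mode <- match.arg(mode)
  ids <- csort(unique(ids))
  if (length(ids) == 0) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  if (mode == "diagonal") {
    return(tibble(protein_a = ids, protein_b = ids))
  }
  idx <- which(upper.tri(diag(length(ids)), diag = TRUE), arr.ind = TRUE)
  tibble(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]])
}

#' Infer interologs of source TF interactions in target species
#'
#' For every source edge (A, B) of species s and every requested target
#' species i != s, the candidate interologs are all unordered pairs from the
#' cross product of A's and B's ortholog sets in i (one-to-many and
#' many-to-many ortholog relations thus expand a single source interaction
#' into several interologs — a network expansion). A candidate is retained
#' only when its endpoints pass the DNA-binding-domain filter. Homodimeric
#' sources (A = B) expand per `homodimer_mode`: `"full"` takes all unordered
#' paralog pairs (the literal cross product), `"diagonal"` only the self
#' pairs (a redundant system of homodimers).
#'
#' @param source_edges Tibble from [read_source_edges()] (`edge_id`,
#'   `protein_a`, `protein_b`, `species_id`, `evidence`).
#' @param ortholog_maps Named list of ortholog map tibbles keyed by sorted
#'   `"A|B"` species pairs (see [read_inparanoid_sqltable()]).
#' @param tf_sets TF-set tibble covering the target species (`protein_id`,
#'   `species_id`), from [classify_tfs()].
#' @param target_species Species to infer into; defaults to every species in
#'   `tf_sets` (each source edge skips its own species).
#' @param homodimer_mode `"full"` (default) or `"diagonal"`.
#' @param dbd_filter `"both"` (default: both endpoints must be TFs) or
#'   `"either"` (at least one endpoint; sensitivity mode).
#' @return A long tibble with one row per retained (source edge, interolog):
#'   columns `source_edge_id`, `species_id` (target), `protein_a`,
#'   `protein_b` (canonical order). Collapse to per-species networks with
#'   [collapse_interlogs()] or [merge_networks()].
#' @export
infer_interlogs <- function(source_edges, ortholog_maps, tf_sets,
                            target_species = NULL,
                            homodimer_mode = c("full", "diagonal"),
                            dbd_filter = c("both", "either")) {
  homodimer_mode <- match.arg(homodimer_mode)
  dbd_filter <- match.arg(dbd_filter)
  target_species <- target_species %||% csort(unique(tf_sets$species_id))
  tf_by_species <- split(tf_sets$protein_id, tf_sets$species_id)

  out <- list()
  for (s in csort(unique(source_edges$species_id))) {
    edges_s <- filter(source_edges, .data$species_id == s)
    prots <- unique(c(edges_s$protein_a, edges_s$protein_b))
    for (i in setdiff(target_species, s)) {
      map <- get_pair_map(ortholog_maps, s, i)
      lk <- ortholog_partners(map, prots, from = s, to = i)
      tfs_i <- tf_by_species[[i]] %||% character()
      cand <- pmap(list(edges_s$edge_id, edges_s$protein_a, edges_s$protein_b),
                   function(eid, a, b) {
        if (a == b) {
          pairs <- unordered_pairs(lk[[a]], homodimer_mode)
        } else {
          oa <- lk[[a]]; ob <- lk[[b]]
          if (length(oa) == 0 || length(ob) == 0) return(NULL)
          grid <- tidyr::expand_grid(x = oa, y = ob)
          pairs <- distinct(canonical_pair(grid$x, grid$y))
        }
        if (nrow(pairs) == 0) return(NULL)
        keep <- if (dbd_filter == "both") {
          pairs$protein_a %in% tfs_i & pairs$protein_b %in% tfs_i
        } else {
          pairs$protein_a %in% tfs_i | pairs$protein_b %in% tfs_i
        }
        pairs <- pairs[keep, , drop = FALSE]
        if (nrow(pairs) == 0) return(NULL)
        mutate(pairs, source_edge_id = eid, species_id = i, .before = 1)
      })
      out[[length(out) + 1L]] <- bind_rows(cand)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(source_edge_id = character(), species_id = character(),
                  protein_a = character(), protein_b = character()))
  }
  as_tibble(res[corder(res$species_id, res$source_edge_id, res$protein_a,
                       res$protein_b), , drop = FALSE])
}

#' Collapse per-source-edge interologs into per-species networks
#'
#' An interolog reachable from several source edges is stored once, with the
#' originating edge ids merged into a sorted `;`-separated list.
#'
#' @param interlogs Long tibble from [infer_interlogs()].
#' @return Network tibble: `species_id`, `protein_a`, `protein_b`,
#'   `provenance` (`"inferred"`), `source_edge_ids`, `n_sources`.
#' @export
collapse_interlogs <- function(interlogs) {
  interlogs |>
    group_by(.data$species_id, .data$protein_a, .data$protein_b) |>
    summarise(provenance = "inferred",
              source_edge_ids = paste(csort(unique(.data$source_edge_id)),
                                      collapse = ";"),
              n_sources = n_distinct(.data$source_edge_id), .groups = "drop") |>
    arrange(.data$species_id, .data$protein_a, .data$protein_b)
}

#' Merge source and inferred interactions into per-species total networks
#'
#' Takes the union of unordered edges per species. An edge that is both
#' experimentally sourced and inferred keeps `provenance = "source"` with the
#' inferred origins appended to its `source_edge_ids`.
#'
#' @param source_edges Source-edge tibble.
#' @param interlogs Long interolog tibble from [infer_interlogs()].
#' @return List with `networks` (one tibble over all species:
#'   `species_id`, `protein_a`, `protein_b`, `provenance`,
#'   `source_edge_ids`, `n_sources`, `evidence`) and `counts` (tibble with
#'   per-species `source`, `inferred`, `total` edge counts).
#' @export
merge_networks <- function(source_edges, interlogs) {
  src <- source_edges |>
    transmute(.data$species_id, .data$protein_a, .data$protein_b,
              provenance = "source", source_edge_ids = .data$edge_id,
              n_sources = 1L, evidence = .data$evidence)
  inf <- collapse_interlogs(interlogs) |> mutate(evidence = "interolog")

  dup <- inner_join(
    select(inf, "species_id", "protein_a", "protein_b",
           inferred_ids = "source_edge_ids"),
    select(src, "species_id", "protein_a", "protein_b"),
    by = c("species_id", "protein_a", "protein_b"))
  src <- src |>
    left_join(dup, by = c("species_id", "protein_a", "protein_b")) |>
    mutate(source_edge_ids = ifelse(is.na(.data$inferred_ids),
                                    .data$source_edge_ids,
                                    paste(.data$source_edge_ids,
                                          .data$inferred_ids, sep = ";")),
           n_sources = 1L + ifelse(is.na(.data$inferred_ids), 0L,
                                   stringr::str_count(.data$inferred_ids, ";") + 1L)) |>
    select(-"inferred_ids")
  inf_only <- anti_join(inf, select(src, "species_id", "protein_a", "protein_b"),
                        by = c("species_id", "protein_a", "protein_b"))
  networks <- bind_rows(src, inf_only) |>
    arrange(.data$species_id, .data$protein_a, .data$protein_b)
  counts <- networks |>
    group_by(.data$species_id) |>
    summarise(source = sum(.data$provenance == "source"),
              inferred = sum(.data$provenance == "inferred"),
              total = n(), .groups = "drop")
  list(networks = networks, counts = counts)
}
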