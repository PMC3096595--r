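# A simplified in-package ortholog caller following the Inparanoid scheme:
# mutual-best-hit seed pairs plus same-species inparalogs scoring at least as
# high against their seed as the seed pair scores against each other.

#' Infer pairwise ortholog groups by bidirectional best hits with inparalogs
#'
#' Seeds are mutual best hits between the two species. A further protein of
#' species X joins a seed's group as an inparalog when its similarity to the
#' X-side seed is at least the seed-seed score — the signature of a
#' duplication after the speciation, which is exactly the co-orthology the
#' cross-product interolog transfer must expand over. Groups are disjoint; a
#' protein eligible for several groups joins the one whose seed it scores
#' highest against (ties by seed order).
#'
#' @param scores Symmetric non-negative similarity matrix (e.g. bitscores)
#'   over the proteins of both species; dimnames are protein ids.
#' @param species Named character vector mapping each protein id to its
#'   species; exactly two species must occur.
#' @return An ortholog map tibble (`group_id`, `bitscore`, `species_id`,
#'   `confidence`, `protein_id`) with a `"species_pair"` attribute, the same
#'   shape [read_inparanoid_sqltable()] returns. Seeds carry confidence 1.
#' @export
infer_orthologs_bbh <- function(scores, species) {
  if (length(scores) == 0 || nrow(scores) == 0) {
    m <- tibble(group_id = integer(), bitscore = numeric(),
                species_id = character(), confidence = numeric(),
                protein_id = character())
    attr(m, "species_pair") <- character()
    return(m)
  }
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            identical(rownames(scores), colnames(scores)),
            all(scores >= 0))
  ids <- rownames(scores)
  species <- species[ids]
  if (anyNA(species)) abort("every protein in `scores` needs a species assignment")
  pair <- csort(unique(species))
  if (length(pair) != 2) abort("`species` must name exactly two species")
  x_ids <- ids[species == pair[1]]
  y_ids <- ids[species == pair[2]]
  xy <- scores[x_ids, y_ids, drop = FALSE]

  best_of <- function(m) {
    # index of the best partner per row; ties broken by column order
    apply(m, 1L, function(r) which(r == max(r))[1])
  }
  bx <- best_of(xy)                 # best y for each x
  by <- best_of(t(xy))              # best x for each y
  seeds <- which(by[bx[seq_along(x_ids)]] == seq_along(x_ids))
  seeds <- seeds[xy[cbind(seeds, bx[seeds])] > 0]
  if (length(seeds) == 0) {
    m <- tibble(group_id = integer(), bitscore = numeric(),
                species_id = character(), confidence = numeric(),
                protein_id = character())
    attr(m, "species_pair") <- pair
    return(m)
  }
  seed_x <- x_ids[seeds]
  seed_y <- y_ids[bx[seeds]]
  seed_score <- xy[cbind(seeds, bx[seeds])]
  ord <- corder(-seed_score, seed_x)
  seed_x <- seed_x[ord]; seed_y <- seed_y[ord]; seed_score <- seed_score[ord]

  rows <- list()
  assign_inparalogs <- function(side_ids, seed_side) {
    # candidate inparalogs: same-species non-seed proteins; best group wins
    cand <- setdiff(side_ids, seed_side)
    if (length(cand) == 0) return(NULL)
    sc <- scores[cand, seed_side, drop = FALSE]
    elig <- sweep(sc, 2L, seed_score, `>=`)
    sc[!elig] <- -Inf
    g <- apply(sc, 1L, function(r) if (all(!is.finite(r))) NA_integer_ else which.max(r))
    keep <- !is.na(g)
    if (!any(keep)) return(NULL)
    tibble(group_id = unname(g[keep]),
           protein_id = cand[keep],
           bitscore = sc[cbind(which(keep), g[keep])],
           confidence = pmin(1, seed_score[g[keep]] / sc[cbind(which(keep), g[keep])]))
  }

  base <- bind_rows(
    tibble(group_id = seq_along(seed_x), protein_id = seed_x,
           bitscore = seed_score, confidence = 1, species_id = pair[1]),
    tibble(group_id = seq_along(seed_y), protein_id = seed_y,
           bitscore = seed_score, confidence = 1, species_id = pair[2])
  )
  inp_x <- assign_inparalogs(x_ids, seed_x)
  if (!is.null(inp_x)) inp_x$species_id <- pair[1]
  inp_y <- assign_inparalogs(y_ids, seed_y)
  if (!is.null(inp_y)) inp_y$species_id <- pair[2]
  out <- bind_rows(base, inp_x, inp_y) |>
    select("group_id", "bitscore", "species_id", "confidence", "protein_id") |>
    arrange(.data$group_id, .data$species_id, desc(.data$confidence),
            .data$protein_id)
  validate_ortholog_map(as_tibble(out), "infer_orthologs_bbh")
}

#' Write an ortholog map as an Inparanoid-style sqltable
#'
#' @param map Ortholog map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inparanoid_sqltable <- function(map, path) {
  lines <- sprintf("%d\t%s\t%s\t%s\t%s", map$group_id, fmt_num(map$bitscore),
                   map$species_id, fmt_num(map$confidence), map$protein_id)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Fetch the ortholog map for an unordered species pair from a named list
# keyed "A|B" (sorted); error naming the pair when absent.
get_pair_map <- function(ortholog_maps, s1, s2) {
  key <- paste(csort(c(s1, s2)), collapse = "|")
  m <- ortholog_maps[[key]]
  if (is.null(m)) abort(sprintf("no ortholog map for species pair %s", key))
  m
}
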