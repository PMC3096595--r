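# Domain-composition profiling of TF repertoires, the arcsine-square-root
# transform, Fisher contingency testing across species, and the
# domain-composition distance tree.

#' Arcsine-square-root transformation of a proportion
#'
#' `asin(sqrt(p))`, the classical variance-stabilizing transformation for
#' binomial proportions: transformed values are nearly normal with a variance
#' almost independent of the underlying probability, which makes domain
#' abundances comparable across repertoires of very different size.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' arcsine_transform(c(0, 0.25, 1))
#' @export
arcsine_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("proportions must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Domain-composition profile of a TF repertoire
#'
#' For each species, counts how many TFs contain each domain type. Counting
#' is presence-per-TF: a TF carrying several copies of the same domain
#' contributes 1 to that domain's count (set `count_copies = TRUE` to count
#' annotation hits instead). Proportions are counts over the species' TF
#' total, and the arcsine-square-root transform of each proportion is
#' attached.
#'
#' @param tf_set TF-set tibble from [classify_tfs()] (columns `protein_id`,
#'   `species_id`), possibly covering several species.
#' @param annotations Domain-annotation tibble (`protein_id`,
#'   `domain_accession`); typically all Pfam domains of the TFs, not only the
#'   DNA-binding ones.
#' @param count_copies Count annotation hits instead of TF presence. In
#'   this mode a proportion can exceed 1 (average copies per TF); the
#'   arcsine transform is applied to the proportion capped at 1.
#' @return Tibble with columns `species_id`, `domain_accession`, `count`,
#'   `n_tfs`, `proportion`, `transformed`.
#' @export
composition_profile <- function(tf_set, annotations, count_copies = FALSE) {
  if (nrow(tf_set) == 0) abort("empty TF set")
  ann <- annotations |>
    inner_join(distinct(tf_set, .data$protein_id, .data$species_id),
               by = "protein_id")
  if (!count_copies) {
    ann <- distinct(ann, .data$species_id, .data$protein_id, .data$domain_accession)
  }
  totals <- tf_set |> count(.data$species_id, name = "n_tfs")
  ann |>
    count(.data$species_id, .data$domain_accession, name = "count") |>
    left_join(totals, by = "species_id") |>
    mutate(proportion = .data$count / .data$n_tfs,
           transformed = arcsine_transform(pmin(.data$proportion, 1))) |>
    arrange(.data$species_id, desc(.data$count), .data$domain_accession)
}

#' Top-k domains per species and their union
#'
#' @param profiles Profile tibble from [composition_profile()].
#' @param k Number of domains per species (default 10, the usual
#'   repertoire-comparison choice). Ties are broken lexicographically by
#'   accession; species with fewer than `k` domains return all of them with a
#'   message.
#' @return List with `per_species` (named list of ordered accession vectors)
#'   and `union` (sorted union across species).
#' @export
top_k_domains <- function(profiles, k = 10L) {
  stopifnot(k >= 1L)
  per_species <- profiles |>
    group_by(.data$species_id) |>
    group_map(function(g, key) {
      g <- g[corder(-g$count, g$domain_accession), , drop = FALSE]
      if (nrow(g) < k) {
        inform(sprintf("species %s has only %d domains (< k = %d)",
                       key$species_id, nrow(g), k))
      }
      head(g$domain_accession, k)
    }) |>
    setNames(csort(unique(profiles$species_id)))
  list(per_species = per_species,
       union = csort(unique(unlist(per_species, use.names = FALSE))))
}

#' Build a species-by-domain contingency table of TF counts
#'
#' @param profiles Profile tibble from [composition_profile()].
#' @param domains Domain accessions forming the columns (typically the top-10
#'   union from [top_k_domains()]); absent domains count 0.
#' @return Integer matrix, rows = species, columns = domains.
#' @export
domain_contingency <- function(profiles, domains) {
  wide <- profiles |>
    filter(.data$domain_accession %in% domains) |>
    select("species_id", "domain_accession", "count") |>
    tidyr::pivot_wider(names_from = "domain_accession", values_from = "count",
                       values_fill = 0L)
  species <- csort(wide$species_id)
  m <- as.matrix(wide[match(species, wide$species_id),
                      setdiff(names(wide), "species_id"), drop = FALSE])
  rownames(m) <- species
  missing <- setdiff(domains, colnames(m))
  if (length(missing) > 0) {
    m <- cbind(m, matrix(0L, nrow(m), length(missing),
                         dimnames = list(NULL, missing)))
  }
  m[, csort(domains), drop = FALSE]
}

#' Fisher's test of domain-composition differences between species
#'
#' For a 2x2 table the exact two-sided hypergeometric test is used. For
#' larger tables the Freeman-Halton generalization is estimated by
#' Monte-Carlo (the exact enumeration is infeasible for a 5 x 10 table of
#' repertoire counts), with a fixed seed and the standard error of the
#' p-value estimate reported; a chi-square approximation is available as a
#' fallback.
#'
#' @param table Non-negative integer matrix (species x domains), r, c >= 2.
#'   Zero-margin rows/columns are dropped with a warning.
#' @param method `"auto"` (exact for 2x2, Monte-Carlo otherwise),
#'   `"exact"`, `"monte_carlo"` or `"chisq"`.
#' @param B Monte-Carlo replicate count.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `p_value`, `method`, `statistic` (Pearson chi-square of
#'   the same table, as a descriptive effect measure), `se` (Monte-Carlo
#'   standard error, else `NA`), `B`.
#' @export
fisher_species_test <- function(table, method = c("auto", "exact",
                                                  "monte_carlo", "chisq"),
                                B = 1e5, seed = 1L) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("contingency table must hold non-negative integer counts")
  }
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping zero-margin rows/columns from the contingency table")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    abort("contingency table needs at least 2 rows and 2 columns after margin filtering")
  }
  if (method == "auto") {
    method <- if (all(dim(table) == c(2, 2))) "exact" else "monte_carlo"
  }
  stat <- suppressWarnings(chisq.test(table, correct = FALSE)$statistic)
  if (method == "chisq") {
    p <- suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
    se <- NA_real_
  } else if (method == "exact") {
    p <- fisher.test(table)$p.value
    se <- NA_real_
  } else {
    p <- with_seed(seed, fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
    se <- sqrt(p * (1 - p) / B)
  }
  list(p_value = unname(p), method = method, statistic = unname(stat),
       se = se, B = if (method == "monte_carlo") B else NA_real_)
}

#' Pairwise species distances from domain-composition profiles
#'
#' Euclidean distance between the species' vectors of arcsine-transformed
#' domain proportions over a shared domain set (a domain absent from a
#' species contributes 0).
#'
#' @param profiles Profile tibble from [composition_profile()].
#' @param domains Domain set defining the coordinates; default: the union of
#'   all domains present in `profiles`.
#' @return Symmetric numeric matrix with zero diagonal, species as dimnames.
#' @export
species_distance_matrix <- function(profiles, domains = NULL) {
  domains <- domains %||% csort(unique(profiles$domain_accession))
  species <- csort(unique(profiles$species_id))
  if (length(species) < 2) abort("need at least two species profiles")
  m <- matrix(0, length(species), length(domains),
              dimnames = list(species, domains))
  sub <- filter(profiles, .data$domain_accession %in% domains)
  m[cbind(sub$species_id, sub$domain_accession)] <- sub$transformed
  as.matrix(dist(m))
}

#' Cluster species by domain composition into a tree
#'
#' UPGMA (average-linkage agglomeration; default) or neighbour joining on a
#' species distance matrix. Output is deterministic for a given matrix; ties
#' resolve by the (lexicographic) leaf order of the matrix.
#'
#' @param d Symmetric distance matrix (e.g. from
#'   [species_distance_matrix()]).
#' @param method `"upgma"` or `"nj"`.
#' @return An [ape::as.phylo()] tree; UPGMA trees are ultrametric.
#' @export
build_domain_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("need at least two taxa")
  if (n == 2) {
    warn("only 2 taxa: returning the single-split tree")
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rownames(d)[1],
                                        d[1, 2] / 2, rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  if (n == 3 && method == "nj") {
    warn("3 taxa: neighbour joining returns the star/resolved 3-taxon tree")
  }
  if (method == "upgma") {
    hc <- hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
  } else {
    ape::nj(stats::as.dist(d))
  }
}

#' Newick string of a domain tree
#'
#' @param tree `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_domain_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Bar chart of top-domain proportions per species
#'
#' @param profiles Profile tibble from [composition_profile()].
#' @param domains Domains to display (default: top-10 union).
#' @return A ggplot object.
#' @export
plot_domain_profiles <- function(profiles, domains = NULL) {
  domains <- domains %||% top_k_domains(profiles, 10L)$union
  dat <- filter(profiles, .data$domain_accession %in% domains)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$domain_accession,
                                    y = 100 * .data$proportion,
                                    fill = .data$species_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of TFs with domain", fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
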