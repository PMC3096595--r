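profile_fixture <- function() {
  tf <- tibble::tibble(protein_id = c("t1", "t2"), species_id = "AM")
  ann <- tibble::tibble(
    protein_id = c("t1", "t2", "t2", "t2"),
    domain_accession = c("PF00046", "PF00046", "PF00170", "PF00046"))
  composition_profile(tf, ann)
}

test_that("composition_profile counts domain presence per TF", {
  prof <- profile_fixture()
  expect_equal(prof$count[prof$domain_accession == "PF00046"], 2L)
  expect_equal(prof$count[prof$domain_accession == "PF00170"], 1L)
  expect_equal(prof$proportion[prof$domain_accession == "PF00046"], 1.0)
  expect_equal(prof$proportion[prof$domain_accession == "PF00170"], 0.5)
  # a duplicated hit on t2 contributed 1, not 2 (presence semantics)
  tf <- tibble::tibble(protein_id = "t2", species_id = "AM")
  ann <- tibble::tibble(protein_id = c("t2", "t2"),
                        domain_accession = "PF00046")
  p2 <- composition_profile(tf, ann)
  expect_equal(p2$count, 1L)
  # copy-count mode counts hits
  p3 <- composition_profile(tf, ann, count_copies = TRUE)
  expect_equal(p3$count, 2L)
})

test_that("a TF without annotations still contributes to the denominator", {
  tf <- tibble::tibble(protein_id = c("t1", "t2"), species_id = "AM")
  ann <- tibble::tibble(protein_id = "t1", domain_accession = "PF00046")
  prof <- composition_profile(tf, ann)
  expect_equal(prof$n_tfs, 2L)
  expect_equal(prof$proportion, 0.5)
})

test_that("top_k_domains orders by count with lexicographic tie-break", {
  prof <- tibble::tibble(
    species_id = "AM", domain_accession = c("C", "A", "B"),
    count = c(1L, 5L, 3L), n_tfs = 6L, proportion = c(1, 5, 3) / 6,
    transformed = arcsine_transform(c(1, 5, 3) / 6))
  expect_equal(top_k_domains(prof, 2)$per_species$AM, c("A", "B"))
  tie <- dplyr::mutate(prof, count = c(3L, 3L, 1L))
  expect_equal(top_k_domains(tie, 1)$per_species$AM, "A")
  expect_message(top_k_domains(prof, 10), "only 3")
})

test_that("arcsine transform matches its closed forms and is monotone", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(1), pi / 2)
  expect_equal(arcsine_transform(0.25), pi / 6)
  expect_error(arcsine_transform(1.2), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_transform(p)) > 0))
})

test_that("the transform stabilizes binomial variance across p", {
  set.seed(33)
  n <- 100
  ps <- seq(0.1, 0.9, by = 0.1)
  raw_var <- numeric(length(ps))
  tr_var <- numeric(length(ps))
  for (i in seq_along(ps)) {
    x <- rbinom(4000, n, ps[i]) / n
    raw_var[i] <- var(x)
    tr_var[i] <- var(arcsine_transform(x))
  }
  expect_gte(max(raw_var) / min(raw_var), 2)
  expect_lt(max(tr_var) / min(tr_var), 1.6)
})

test_that("fisher_species_test matches hypergeometric enumeration on 2x2", {
  tabs <- list(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
               matrix(c(5, 0, 0, 5), 2, byrow = TRUE),
               matrix(c(8, 2, 3, 9), 2, byrow = TRUE),
               matrix(c(1, 9, 7, 2), 2, byrow = TRUE))
  for (tab in tabs) {
    got <- fisher_species_test(tab, method = "exact")
    expect_equal(got$p_value, oracle_fisher_2x2(tab), tolerance = 1e-9)
  }
  # two enumerable reference tables
  expect_equal(fisher_species_test(matrix(c(3, 1, 1, 3), 2))$p_value,
               0.4857, tolerance = 1e-4)
  expect_equal(fisher_species_test(matrix(c(5, 0, 0, 5), 2))$p_value,
               2 / 252, tolerance = 1e-9)
})

test_that("Monte-Carlo Fisher is seeded, near 1 for identical rows", {
  tab <- matrix(rep(c(10L, 20L, 5L), 3), nrow = 3, byrow = TRUE)
  r1 <- fisher_species_test(tab, method = "monte_carlo", B = 2000, seed = 4)
  r2 <- fisher_species_test(tab, method = "monte_carlo", B = 2000, seed = 4)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 1 - 5 * r1$se - 0.05)
})

test_that("zero-margin rows are dropped with a warning", {
  tab <- matrix(c(3, 1, 0, 0, 1, 3), nrow = 3, byrow = TRUE)
  expect_warning(r <- fisher_species_test(tab, method = "exact"),
                 "zero-margin")
  expect_equal(r$p_value, oracle_fisher_2x2(matrix(c(3, 1, 1, 3), 2,
                                                   byrow = TRUE)),
               tolerance = 1e-9)
})

test_that("species_distance_matrix is a metric on transformed profiles", {
  set.seed(9)
  mkprof <- function(sp, props) {
    tibble::tibble(species_id = sp, domain_accession = sprintf("PF%02d", seq_along(props)),
                   count = NA_integer_, n_tfs = NA_integer_,
                   proportion = props, transformed = arcsine_transform(props))
  }
  p1 <- runif(6)
  prof <- dplyr::bind_rows(mkprof("A", p1), mkprof("B", p1),
                           mkprof("C", runif(6)))
  d <- species_distance_matrix(prof)
  expect_equal(d["A", "B"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  # single-coordinate perturbation gives exactly that distance
  delta <- 0.1
  p2 <- p1
  p2[3] <- p2[3] + delta
  prof2 <- dplyr::bind_rows(mkprof("A", p1), mkprof("B", p2))
  t1 <- arcsine_transform(p1[3])
  t2 <- arcsine_transform(p2[3])
  expect_equal(species_distance_matrix(prof2)["A", "B"], abs(t2 - t1))
  # triangle inequality over random triples
  for (rep in 1:20) {
    prof3 <- dplyr::bind_rows(mkprof("A", runif(5)), mkprof("B", runif(5)),
                              mkprof("C", runif(5)))
    d3 <- species_distance_matrix(prof3)
    expect_lte(d3["A", "C"], d3["A", "B"] + d3["B", "C"] + 1e-12)
  }
})

test_that("UPGMA recovers forced topologies and matches the oracle", {
  d <- matrix(c(0, 2, 10, 2, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_domain_tree(d, "upgma")
  expect_true(same_topology(tr, ape::read.tree(text = "((A,B),C);")))

  set.seed(14)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    pts <- matrix(runif(n * 4), n)
    rownames(pts) <- LETTERS[1:n]
    d <- as.matrix(dist(pts))
    tr <- build_domain_tree(d, "upgma")
    orc <- oracle_upgma(d)
    # merge heights: hclust average-linkage heights equal the oracle's
    hc_heights <- sort(ape::branching.times(tr) * 2)
    expect_equal(sort(unname(hc_heights)), sort(orc$heights), tolerance = 1e-9)
    # clades coincide
    got <- sapply(tree_clades(tr), paste, collapse = "|")
    want <- sapply(orc$clades, paste, collapse = "|")
    expect_true(all(want[lengths(orc$clades) < n] %in% got))
  }
})

test_that("NJ recovers the exact topology from additive distances", {
  # distances generated on a known 4-taxon tree are additive; NJ is
  # consistent and must recover the split
  tree <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:3):0.5);")
  d <- ape::cophenetic.phylo(tree)
  nj <- build_domain_tree(d, "nj")
  expect_true(same_topology(ape::unroot(nj), ape::unroot(tree)))
})

test_that("domain trees are deterministic and degenerate cases warn", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(tr <- build_domain_tree(d), "2 taxa")
  expect_setequal(tr$tip.label, c("A", "B"))
  d5 <- as.matrix(dist(matrix(runif(20), 5)))
  dimnames(d5) <- list(LETTERS[1:5], LETTERS[1:5])
  expect_identical(write_domain_tree(build_domain_tree(d5)),
                   write_domain_tree(build_domain_tree(d5)))
})
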