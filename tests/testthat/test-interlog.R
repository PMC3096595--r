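# Fixture: one human source edge (A, B) with configurable ortholog sets and
# TF membership in coral (AM).
tiny_instance <- function(orth_a = c("a1", "a2"), orth_b = "b1",
                          tfs_am = c(orth_a, orth_b), homodimer = FALSE) {
  src <- "HS"
  a <- "HS_A"; b <- if (homodimer) "HS_A" else "HS_B"
  edges <- tibble::tibble(edge_id = "e1", protein_a = min(a, b),
                          protein_b = max(a, b), species_id = src,
                          evidence = "")
  rows <- list()
  g <- 0L
  add_group <- function(seed, partners) {
    g <<- g + 1L
    tibble::tibble(group_id = g, bitscore = 100,
                   species_id = c(src, rep("AM", length(partners))),
                   confidence = c(1, rep(0.9, length(partners))),
                   protein_id = c(seed, partners))
  }
  if (length(orth_a) > 0) rows$a <- add_group(a, orth_a)
  if (!homodimer && length(orth_b) > 0) rows$b <- add_group(b, orth_b)
  m <- dplyr::bind_rows(rows)
  attr(m, "species_pair") <- c("AM", "HS")
  maps <- list("AM|HS" = m)
  tf <- tibble::tibble(
    protein_id = c(a, b, tfs_am),
    species_id = c(src, src, rep("AM", length(tfs_am))))
  tf <- dplyr::distinct(tf)
  list(edges = edges, maps = maps, tf = tf)
}

test_that("the cross product expands a 2x1 ortholog relation to two interologs", {
  inst <- tiny_instance()
  il <- infer_interlogs(inst$edges, inst$maps, inst$tf, target_species = "AM")
  expect_equal(nrow(il), 2L)
  expect_setequal(paste(il$protein_a, il$protein_b),
                  c("a1 b1", "a2 b1"))
})

test_that("an empty ortholog set blocks the transfer", {
  inst <- tiny_instance(orth_b = character())
  il <- infer_interlogs(inst$edges, inst$maps, inst$tf, target_species = "AM")
  expect_equal(nrow(il), 0L)
})

test_that("the DBD filter drops candidates with a non-TF endpoint", {
  inst <- tiny_instance(tfs_am = c("a1", "b1"))  # a2 is not a TF
  il <- infer_interlogs(inst$edges, inst$maps, inst$tf, target_species = "AM")
  expect_equal(paste(il$protein_a, il$protein_b), "a1 b1")
  # single-endpoint (either) mode keeps the a2 pair
  il2 <- infer_interlogs(inst$edges, inst$maps, inst$tf, target_species = "AM",
                         dbd_filter = "either")
  expect_equal(nrow(il2), 2L)
})

test_that("homodimer sources expand per mode", {
  inst <- tiny_instance(orth_a = c("a1", "a2"), homodimer = TRUE,
                        tfs_am = c("a1", "a2"))
  full <- infer_interlogs(inst$edges, inst$maps, inst$tf,
                          target_species = "AM", homodimer_mode = "full")
  expect_setequal(paste(full$protein_a, full$protein_b),
                  c("a1 a1", "a1 a2", "a2 a2"))
  diag <- infer_interlogs(inst$edges, inst$maps, inst$tf,
                          target_species = "AM", homodimer_mode = "diagonal")
  expect_setequal(paste(diag$protein_a, diag$protein_b),
                  c("a1 a1", "a2 a2"))
})

test_that("a missing ortholog map is reported with the species pair", {
  inst <- tiny_instance()
  expect_error(
    infer_interlogs(inst$edges, inst$maps,
                    dplyr::mutate(inst$tf[1, ], species_id = "SP"),
                    target_species = "SP"),
    "HS\\|SP")
})

test_that("infer_interlogs equals brute-force enumeration on random instances", {
  set.seed(77)
  n_checked <- 0L
  for (rep in 1:60) {
    inst <- random_interlog_instance()
    for (mode in c("full", "diagonal")) {
      for (filt in c("both", "either")) {
        il <- infer_interlogs(inst$edges, inst$maps, inst$tf_tbl,
                              target_species = inst$species,
                              homodimer_mode = mode, dbd_filter = filt)
        want <- oracle_interlogs(inst$edges, inst$orth, inst$tfs,
                                 homodimer_mode = mode, dbd_filter = filt)
        expect_equal(ord_interlogs(il), ord_interlogs(want),
                     info = sprintf("rep=%d mode=%s filter=%s", rep, mode, filt))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("the P x Q cardinality law holds on zero-loss synthetic data", {
  cfg <- sim_config(n_families = 60, n_source_edges = 40, loss_rate = 0,
                    duplication_rate = 0.8, seed = 13)
  sim <- simulate_dataset(cfg)
  tf <- classify_tfs(sim$proteins, sim$annotations, sim$catalog)
  il <- infer_interlogs(sim$source_edges, sim$ortholog_maps, tf)
  fams <- sim$ground_truth$families
  fam_of <- setNames(fams$family, fams$protein_id)
  counts <- dplyr::count(il, source_edge_id, species_id)
  for (r in seq_len(nrow(counts))) {
    e <- sim$source_edges[sim$source_edges$edge_id == counts$source_edge_id[r], ]
    i <- counts$species_id[r]
    fa <- fam_of[[e$protein_a]]; fb <- fam_of[[e$protein_b]]
    P <- sum(fams$family == fa & fams$species_id == i)
    Q <- sum(fams$family == fb & fams$species_id == i)
    if (e$protein_a == e$protein_b) {
      expect_equal(counts$n[r], P * (P + 1) / 2)
    } else if (fa == fb) {
      # same family at both endpoints: the unordered cross product collapses
      expect_equal(counts$n[r], P * (P + 1) / 2)
    } else {
      expect_equal(counts$n[r], P * Q)
    }
  }
})

test_that("interlog inference is monotone in the TF sets and endpoint-symmetric", {
  set.seed(123)
  for (rep in 1:10) {
    inst <- random_interlog_instance()
    il_full <- infer_interlogs(inst$edges, inst$maps, inst$tf_tbl,
                               target_species = inst$species)
    # drop one TF: counts never increase
    drop_idx <- sample(nrow(inst$tf_tbl), 1)
    tf_less <- inst$tf_tbl[-drop_idx, ]
    il_less <- infer_interlogs(inst$edges, inst$maps, tf_less,
                               target_species = inst$species)
    expect_lte(nrow(il_less), nrow(il_full))
    # swapping endpoints changes nothing
    edges_sw <- dplyr::mutate(inst$edges, tmp = protein_a,
                              protein_a = protein_b, protein_b = tmp) |>
      dplyr::select(-tmp)
    il_sw <- infer_interlogs(edges_sw, inst$maps, inst$tf_tbl,
                             target_species = inst$species)
    expect_equal(ord_interlogs(il_sw), ord_interlogs(il_full))
  }
})

test_that("merge_networks keeps source provenance and counts add up", {
  src <- tibble::tibble(edge_id = "e1", protein_a = "a", protein_b = "b",
                        species_id = "HS", evidence = "y2h")
  il <- tibble::tibble(source_edge_id = c("e1", "e1", "e1"),
                       species_id = c("HS", "HS", "AM"),
                       protein_a = c("a", "a", "x"),
                       protein_b = c("b", "c", "y"))
  m <- merge_networks(src, il)
  hs <- m$networks[m$networks$species_id == "HS", ]
  expect_equal(nrow(hs), 2L)
  ab <- hs[hs$protein_a == "a" & hs$protein_b == "b", ]
  expect_equal(ab$provenance, "source")
  expect_true(grepl("e1", ab$source_edge_ids))
  cnt <- m$counts
  expect_equal(cnt$total[cnt$species_id == "HS"], 2L)
  expect_equal(cnt$total[cnt$species_id == "AM"], 1L)
  # species with no source data: total equals the inferred count
  expect_equal(cnt$source[cnt$species_id == "AM"], 0L)
})

test_that("zero-loss totals equal source edges mapped through expansion multiplicities", {
  cfg <- sim_config(n_families = 60, n_source_edges = 40, loss_rate = 0,
                    duplication_rate = 0.5, seed = 19)
  sim <- simulate_dataset(cfg)
  tf <- classify_tfs(sim$proteins, sim$annotations, sim$catalog)
  il <- infer_interlogs(sim$source_edges, sim$ortholog_maps, tf)
  truth <- sim$ground_truth$true_interlogs
  expect_equal(
    as.data.frame(dplyr::arrange(il, source_edge_id, species_id, protein_a, protein_b)),
    as.data.frame(dplyr::arrange(truth, source_edge_id, species_id, protein_a,
                                 protein_b))[, c("source_edge_id", "species_id",
                                                 "protein_a", "protein_b")])
})
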