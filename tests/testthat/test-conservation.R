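five_sp <- c("AM", "DM", "HS", "MM", "SP")

# small hand-built class setup: e1 everywhere, e2 missing AM, e3 only HS
toy_classes <- function() {
  src <- tibble::tibble(edge_id = c("e1", "e2", "e3"),
                        protein_a = c("h1", "h3", "h5"),
                        protein_b = c("h2", "h4", "h6"),
                        species_id = "HS", evidence = "")
  il <- dplyr::bind_rows(
    tidyr::expand_grid(source_edge_id = "e1",
                       species_id = setdiff(five_sp, "HS")) |>
      dplyr::mutate(protein_a = paste0(tolower(species_id), "_x"),
                    protein_b = paste0(tolower(species_id), "_y")),
    tibble::tibble(source_edge_id = "e2",
                   species_id = c("DM", "MM", "SP"),
                   protein_a = c("dm_a", "mm_a", "sp_a"),
                   protein_b = c("dm_b", "mm_b", "sp_b")))
  build_interaction_classes(src, il, species = five_sp)
}

test_that("interaction classes carry multiplicities and presence patterns", {
  cl <- toy_classes()
  expect_equal(nrow(cl), 15L)  # 3 classes x 5 species
  pats <- conserved_classes(cl, required_species = "HS")
  expect_equal(pats$n_present, c(5L, 4L, 1L))
  # source species present by construction
  expect_true(all(cl$present[cl$species_id == "HS"]))
})

test_that("unknown source edge ids are rejected", {
  src <- tibble::tibble(edge_id = "e1", protein_a = "a", protein_b = "b",
                        species_id = "HS", evidence = "")
  il <- tibble::tibble(source_edge_id = "ghost", species_id = "AM",
                       protein_a = "x", protein_b = "y")
  expect_error(build_interaction_classes(src, il), "ghost")
})

test_that("conservation follows subset semantics of the required species", {
  cl <- toy_classes()
  expect_equal(conserved_classes(cl)$class_id, "e1")
  expect_equal(conserved_classes(cl, c("HS", "MM"))$class_id, c("e1", "e2"))
  # shrinking the requirement never shrinks the conserved set
  full <- conserved_classes(cl)$class_id
  sub <- conserved_classes(cl, c("HS", "SP"))$class_id
  expect_true(all(full %in% sub))
})

test_that("every class is exactly one of conserved, TRI with the rest", {
  cl <- toy_classes()
  conserved <- conserved_classes(cl)$class_id
  tris <- detect_tris(cl)$class_id
  all_ids <- unique(cl$class_id)
  expect_setequal(c(conserved, tris), all_ids)
  expect_length(intersect(conserved, tris), 0L)
  # the source-only class counts as a TRI with |pattern| = 1
  expect_true("e3" %in% tris)
})

test_that("TRI records carry the restriction pattern and missing species", {
  cl <- toy_classes()
  tris <- detect_tris(cl)
  e2 <- tris[tris$class_id == "e2", ]
  expect_equal(e2$missing_species, "AM")
  expect_equal(e2$presence_pattern, "DM;HS;MM;SP")
  expect_equal(e2$restricted_to, e2$presence_pattern)
  # a fully conserved set yields no records
  none <- detect_tris(dplyr::filter(cl, class_id == "e1"))
  expect_equal(nrow(none), 0L)
})

test_that("planted TRIs are recovered exactly, with causes, on synthetic data", {
  cfg <- sim_config(n_families = 150, n_source_edges = 60, loss_rate = 0,
                    tri_loss_rate = 0.12, seed = 31)
  sim <- simulate_dataset(cfg)
  tf <- classify_tfs(sim$proteins, sim$annotations, sim$catalog)
  il <- infer_interlogs(sim$source_edges, sim$ortholog_maps, tf)
  cl <- build_interaction_classes(sim$source_edges, il, species = sim$species)
  tris <- detect_tris(cl, sim$ortholog_maps, tf)
  planted <- sim$ground_truth$planted_tris
  expect_setequal(tris$class_id, planted$edge_id)
  m <- merge(tris, planted, by.x = "class_id", by.y = "edge_id")
  expect_equal(m$presence_pattern.x, m$presence_pattern.y)
  expect_equal(m$cause.x, m$cause.y)
  expect_true(all(c("ortholog_loss", "dbd_loss") %in% m$cause.x))
})

test_that("expansions report multiplicities above the threshold, sorted", {
  src <- tibble::tibble(edge_id = "e1", protein_a = "h1", protein_b = "h2",
                        species_id = "HS", evidence = "")
  # 2x3 ortholog expansion in AM -> multiplicity 6
  il <- tidyr::expand_grid(a = c("am1", "am2"), b = c("am3", "am4", "am5")) |>
    dplyr::transmute(source_edge_id = "e1", species_id = "AM",
                     protein_a = a, protein_b = b)
  cl <- build_interaction_classes(src, il, species = c("AM", "HS"))
  ex <- detect_expansions(cl)
  expect_equal(ex$multiplicity, 6L)
  expect_equal(ex$species_id, "AM")
  # all one-to-one: empty table
  il1 <- il[1, ]
  cl1 <- build_interaction_classes(src, il1, species = c("AM", "HS"))
  expect_equal(nrow(detect_expansions(cl1)), 0L)
})

test_that("homodimer expansion multiplicities differ by mode as 3 vs 2", {
  inst_edges <- tibble::tibble(edge_id = "e1", protein_a = "HS_A",
                               protein_b = "HS_A", species_id = "HS",
                               evidence = "")
  m <- tibble::tibble(group_id = 1L, bitscore = 100,
                      species_id = c("HS", "AM", "AM"),
                      confidence = c(1, 0.9, 0.8),
                      protein_id = c("HS_A", "am1", "am2"))
  attr(m, "species_pair") <- c("AM", "HS")
  maps <- list("AM|HS" = m)
  tf <- tibble::tibble(protein_id = c("HS_A", "am1", "am2"),
                       species_id = c("HS", "AM", "AM"))
  for (mode in c("full", "diagonal")) {
    il <- infer_interlogs(inst_edges, maps, tf, target_species = "AM",
                          homodimer_mode = mode)
    cl <- build_interaction_classes(inst_edges, il, species = c("AM", "HS"))
    ex <- detect_expansions(cl)
    expect_equal(ex$multiplicity, if (mode == "full") 3L else 2L)
  }
})

test_that("conserved subnetworks are the components of the reference graph", {
  src <- tibble::tibble(edge_id = c("e1", "e2", "e3"),
                        protein_a = c("a", "b", "d"),
                        protein_b = c("b", "c", "e"),
                        species_id = "HS", evidence = "")
  il <- tidyr::expand_grid(source_edge_id = c("e1", "e2", "e3"),
                           species_id = "AM") |>
    dplyr::mutate(protein_a = paste0("am_", source_edge_id, "_1"),
                  protein_b = paste0("am_", source_edge_id, "_2"))
  cl <- build_interaction_classes(src, il, species = c("AM", "HS"))
  conserved <- conserved_classes(cl)
  sub <- conserved_subnetworks(conserved, src, il, reference_species = "HS",
                               species_order = c("HS", "AM"))
  comp_sizes <- table(unique(sub$components)$component_id)
  expect_equal(sort(as.integer(comp_sizes)), c(1L, 2L))  # {a,b,c} and {d,e}
  # each species' edges reported per component
  expect_setequal(unique(sub$edges$species_id), c("AM", "HS"))
})

test_that("two planted modules come back as two components", {
  # two disjoint triangles in the source network, fully conserved
  mk_edges <- function(prefix, eoff) {
    tibble::tibble(edge_id = sprintf("e%d", eoff + 1:3),
                   protein_a = paste0(prefix, c("1", "1", "2")),
                   protein_b = paste0(prefix, c("2", "3", "3")),
                   species_id = "HS", evidence = "")
  }
  src <- dplyr::bind_rows(mk_edges("HS_m1_", 0), mk_edges("HS_m2_", 3))
  il <- src |>
    dplyr::transmute(source_edge_id = edge_id, species_id = "AM",
                     protein_a = sub("HS", "AM", protein_a),
                     protein_b = sub("HS", "AM", protein_b))
  cl <- build_interaction_classes(src, il, species = c("AM", "HS"))
  sub <- conserved_subnetworks(conserved_classes(cl), src, il, "HS",
                               species_order = c("HS", "AM"))
  expect_equal(length(unique(sub$components$component_id)), 2L)
})
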