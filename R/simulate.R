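# Ground-truthed synthetic data: a 5-species tree, gene families with
# post-speciation duplications and losses, DBD-bearing domain architectures,
# a preferential-attachment source interaction network in the assayed
# species, and planted interaction losses as TRI ground truth. Every
# downstream stage of the pipeline can be tested against the generator's own
# brute-force bookkeeping.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the data regime the pipeline is built for: five species
#' related by the tree `((((HS,MM),SP),DM),AM)` (human, mouse, sea urchin,
#' fruit fly, coral); a few hundred ancestral gene families expanded by
#' post-speciation duplications (pure inparalogs, the co-orthology the
#' cross-product transfer must handle); about a third of families carrying a
#' sequence-specific DNA-binding domain; and a scale-free source interaction
#' network assayed in the two mammals.
#'
#' @param species_tree Newick string, rooted, 5 leaves.
#' @param n_families Number of ancestral gene families.
#' @param duplication_rate Poisson mean of extra post-speciation copies per
#'   family per lineage (copies per lineage ~ 1 + Poisson).
#' @param loss_rate Probability a family is lost in a lineage.
#' @param dbd_fraction Probability a family carries a DNA-binding domain.
#' @param n_source_edges Total source-network size, split over
#'   `source_species`.
#' @param source_species The "assayed" species holding experimental
#'   interactions.
#' @param attachment_exponent Preferential-attachment exponent (edge
#'   endpoints drawn with probability proportional to `degree^gamma`).
#' @param homodimer_fraction Fraction of source edges that are self-loops.
#' @param tri_loss_rate Probability a family is knocked out in one
#'   non-assayed lineage (ortholog deletion or DBD stripping, 50/50) to
#'   plant a taxonomically restricted interaction.
#' @param seed Integer driving all randomness through one stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(species_tree = "((((HS,MM),SP),DM),AM);",
                       n_families = 500L,
                       duplication_rate = 0.3,
                       loss_rate = 0.05,
                       dbd_fraction = 0.35,
                       n_source_edges = 300L,
                       source_species = c("HS", "MM"),
                       attachment_exponent = 1,
                       homodimer_fraction = 0.05,
                       tri_loss_rate = 0,
                       seed = 1L) {
  tree <- ape::read.tree(text = species_tree)
  if (is.null(tree)) abort("species_tree is not a valid Newick string")
  species <- tree$tip.label
  rates <- c(loss_rate = loss_rate, dbd_fraction = dbd_fraction,
             homodimer_fraction = homodimer_fraction,
             tri_loss_rate = tri_loss_rate)
  if (any(rates < 0 | rates > 1)) {
    abort(sprintf("rate outside [0,1]: %s",
                  paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")))
  }
  stopifnot(duplication_rate >= 0, n_families >= 0, n_source_edges >= 0,
            attachment_exponent >= 0)
  if (!all(source_species %in% species)) {
    abort("source_species must be leaves of the species tree")
  }
  structure(list(species_tree = species_tree, tree = tree, species = species,
                 n_families = as.integer(n_families),
                 duplication_rate = duplication_rate, loss_rate = loss_rate,
                 dbd_fraction = dbd_fraction,
                 n_source_edges = as.integer(n_source_edges),
                 source_species = source_species,
                 attachment_exponent = attachment_exponent,
                 homodimer_fraction = homodimer_fraction,
                 tri_loss_rate = tri_loss_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Domain pools. DBD accessions form the synthetic catalog; generic
# accessions are never in the catalog.
sim_dbd_pool <- function() sprintf("PF9%04d", 1:25)
sim_generic_pool <- function() sprintf("PF8%04d", 1:40)

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Simulate gene families across the species tree
#'
#' Each ancestral family survives in a lineage with probability
#' `1 - loss_rate`; a surviving lineage holds `1 + Poisson(duplication_rate)`
#' copies (the extra copies are inparalogs: duplications after the terminal
#' speciation, so every cross-species member pair of a family is
#' co-orthologous). Families carry a domain architecture inherited by every
#' member: DBD families one catalog accession (plus, half the time, a
#' generic domain), other families one or two generic domains.
#'
#' Operates on the current RNG stream; [simulate_dataset()] seeds it.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (tibble `protein_id`, `species_id`,
#'   `sequence`, `description`, `family`), `annotations` (InterProScan-style
#'   tibble), `families` (tibble `family`, `species_id`, `protein_id`,
#'   `copy`, `has_dbd`) and `catalog`.
#' @export
simulate_gene_families <- function(config) {
  sp <- config$species
  nf <- config$n_families
  catalog <- sim_dbd_pool()
  fam_rows <- list()
  if (nf > 0) {
    fam_dbd <- runif(nf) < config$dbd_fraction
    fam_domain <- ifelse(fam_dbd, sample(catalog, nf, replace = TRUE),
                         sample(sim_generic_pool(), nf, replace = TRUE))
    fam_extra <- ifelse(runif(nf) < 0.5,
                        sample(sim_generic_pool(), nf, replace = TRUE),
                        NA_character_)
    for (f in seq_len(nf)) {
      for (s in sp) {
        if (runif(1) < config$loss_rate) next
        n_copies <- 1L + rpois(1, config$duplication_rate)
        fam_rows[[length(fam_rows) + 1L]] <- tibble(
          family = f, species_id = s, copy = seq_len(n_copies),
          protein_id = sprintf("%s_f%04d_p%d", s, f, seq_len(n_copies)),
          has_dbd = fam_dbd[f], domain = fam_domain[f], extra = fam_extra[f])
      }
    }
  }
  families <- bind_rows(fam_rows)
  if (nrow(families) == 0) {
    families <- tibble(family = integer(), species_id = character(),
                       copy = integer(), protein_id = character(),
                       has_dbd = logical(), domain = character(),
                       extra = character())
  }
  lens <- if (nrow(families) > 0) {
    as.integer(round(runif(nrow(families), 100, 1500)))
  } else integer()
  proteins <- tibble(
    protein_id = families$protein_id, species_id = families$species_id,
    sequence = vapply(lens, random_peptide, character(1)),
    description = sprintf("synthetic family %d", families$family),
    family = families$family)
  ann_main <- tibble(protein_id = families$protein_id,
                     domain_accession = families$domain,
                     start = 10L)
  has_extra <- !is.na(families$extra)
  ann_extra <- tibble(protein_id = families$protein_id[has_extra],
                      domain_accession = families$extra[has_extra],
                      start = 80L)
  annotations <- bind_rows(ann_main, ann_extra)
  annotations <- tibble(
    protein_id = annotations$protein_id,
    domain_accession = annotations$domain_accession,
    domain_name = paste0("dom_", annotations$domain_accession),
    start = annotations$start,
    end = annotations$start + 49L,
    score = 1e-10,
    is_pfam = TRUE)
  list(proteins = proteins,
       annotations = arrange(annotations, .data$protein_id, .data$start),
       families = select(families, "family", "species_id", "protein_id",
                         "copy", "has_dbd"),
       catalog = catalog)
}

#' Plant lineage-specific interaction losses
#'
#' Each family is, with probability `tri_loss_rate`, knocked out in one
#' lineage drawn uniformly from the non-assayed species: either its members
#' there are deleted outright (`ortholog_loss`) or only their DNA-binding
#' domain annotations are stripped (`dbd_loss`), 50/50. Any source
#' interaction touching a knocked-out family then cannot be transferred to
#' that lineage, planting a taxonomically restricted interaction with a
#' known cause.
#'
#' @param gf Output of [simulate_gene_families()].
#' @param config A [sim_config()].
#' @return `gf` with losses applied, plus `planted_losses` (tibble `family`,
#'   `species_id`, `cause`).
#' @export
plant_losses <- function(gf, config) {
  lineages <- setdiff(config$species, config$source_species)
  planted <- tibble(family = integer(), species_id = character(),
                    cause = character())
  if (config$tri_loss_rate > 0 && length(lineages) > 0 &&
      nrow(gf$families) > 0) {
    fams <- unique(gf$families$family)
    hit <- fams[runif(length(fams)) < config$tri_loss_rate]
    if (length(hit) > 0) {
      planted <- tibble(
        family = hit,
        species_id = sample(lineages, length(hit), replace = TRUE),
        cause = sample(c("ortholog_loss", "dbd_loss"), length(hit),
                       replace = TRUE))
    }
  }
  for (r in seq_len(nrow(planted))) {
    idx <- gf$families$family == planted$family[r] &
      gf$families$species_id == planted$species_id[r]
    victims <- gf$families$protein_id[idx]
    if (planted$cause[r] == "ortholog_loss") {
      gf$families <- gf$families[!idx, , drop = FALSE]
      gf$proteins <- filter(gf$proteins, !(.data$protein_id %in% victims))
      gf$annotations <- filter(gf$annotations,
                               !(.data$protein_id %in% victims))
    } else {
      gf$annotations <- filter(gf$annotations,
                               !(.data$protein_id %in% victims &
                                   .data$domain_accession %in% gf$catalog))
      gf$families$has_dbd[idx] <- FALSE
    }
  }
  gf$planted_losses <- planted
  gf
}

# Pairwise Inparanoid-style ortholog maps from the (post-loss) families:
# every family with members on both sides of a pair is one group; the
# first copy is the seed (confidence 1), later copies are inparalogs.
build_true_ortholog_maps <- function(families, species) {
  maps <- list()
  pairs <- utils::combn(csort(species), 2, simplify = FALSE)
  for (pr in pairs) {
    sub <- families |> filter(.data$species_id %in% pr)
    both <- sub |>
      group_by(.data$family) |>
      filter(n_distinct(.data$species_id) == 2L) |>
      ungroup()
    if (nrow(both) == 0) {
      m <- tibble(group_id = integer(), bitscore = numeric(),
                  species_id = character(), confidence = numeric(),
                  protein_id = character())
    } else {
      fams <- sort(unique(both$family))
      both <- both |>
        mutate(group_id = match(.data$family, fams),
               bitscore = round(150 + 5 * .data$family %% 200 +
                                  runif(n(), 0, 10), 1),
               confidence = ifelse(.data$copy == 1L, 1,
                                   round(runif(n(), 0.3, 0.99), 3)))
      m <- both |>
        select("group_id", "bitscore", "species_id", "confidence",
               "protein_id") |>
        arrange(.data$group_id, .data$species_id, desc(.data$confidence),
                .data$protein_id)
    }
    attr(m, "species_pair") <- pr
    maps[[paste(pr, collapse = "|")]] <- m
  }
  maps
}

#' Simulate a scale-free source interaction network
#'
#' Grows `n_source_edges` edges by preferential attachment among the
#' DBD-bearing proteins of the assayed species: nodes activate one at a
#' time, each attaching to an active node drawn with probability
#' proportional to `degree^attachment_exponent`; once every eligible node is
#' active both endpoints are drawn preferentially. A `homodimer_fraction`
#' of edges are self-loops. Edges are split evenly over the source species.
#'
#' @param config A [sim_config()].
#' @param families Family tibble (post-losses) with `has_dbd`.
#' @return Source-edge tibble (`edge_id`, `protein_a`, `protein_b`,
#'   `species_id`, `evidence`).
#' @export
simulate_source_network <- function(config, families) {
  n_total <- config$n_source_edges
  srcs <- config$source_species
  out <- list()
  if (n_total == 0) {
    return(tibble(edge_id = character(), protein_a = character(),
                  protein_b = character(), species_id = character(),
                  evidence = character()))
  }
  quota <- diff(round(seq(0, n_total, length.out = length(srcs) + 1)))
  for (si in seq_along(srcs)) {
    s <- srcs[si]
    nodes <- families |>
      filter(.data$species_id == s, .data$has_dbd) |>
      pull("protein_id") |> csort()
    if (length(nodes) < 10) {
      abort(sprintf("species %s has only %d DBD-bearing proteins (need >= 10)",
                    s, length(nodes)))
    }
    # growth process: nodes activate in random order, each new node
    # attaching preferentially to the active network (degree-proportional),
    # which is what makes the degree sequence heavy-tailed; once every node
    # is active, both endpoints are drawn preferentially
    nodes <- sample(nodes)
    deg <- setNames(numeric(length(nodes)), nodes)
    active <- nodes[1]
    next_new <- 2L
    seen <- character()
    edges <- vector("list", quota[si])
    e <- 0L
    guard <- 0L
    while (e < quota[si] && guard < 50L * quota[si] + 1000L) {
      guard <- guard + 1L
      # linear preferential kernel; degree-0 nodes (the seed node before its
      # first edge) keep weight 1 so the process can start
      w <- pmax(deg[active], 1)^config$attachment_exponent
      if (runif(1) < config$homodimer_fraction) {
        v <- sample(active, 1, prob = w)
        a <- v; b <- v
      } else if (next_new <= length(nodes)) {
        a <- nodes[next_new]
        b <- sample(active, 1, prob = w)
      } else {
        a <- sample(active, 1, prob = w)
        b <- sample(setdiff(active, a), 1, prob = w[setdiff(active, a)])
      }
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      key <- paste(a, b, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (next_new <= length(nodes) && !(nodes[next_new] %in% active) &&
          nodes[next_new] %in% c(a, b)) {
        active <- c(active, nodes[next_new])
        next_new <- next_new + 1L
      }
      e <- e + 1L
      edges[[e]] <- c(a, b)
      deg[a] <- deg[a] + 1
      deg[b] <- deg[b] + 1
    }
    if (e < quota[si]) {
      warn(sprintf("source network for %s saturated at %d of %d edges",
                   s, e, quota[si]))
      edges <- edges[seq_len(e)]
    }
    em <- do.call(rbind, edges)
    out[[s]] <- tibble(edge_id = sprintf("%s_e%05d", s, seq_len(nrow(em))),
                       protein_a = em[, 1], protein_b = em[, 2],
                       species_id = s, evidence = "synthetic_assay")
  }
  bind_rows(out)
}

# Brute-force ground-truth interologs: plain nested loops over family
# members, independent of the join-based infer_interlogs() implementation.
brute_force_true_interlogs <- function(source_edges, families, species) {
  fam_of <- setNames(families$family, families$protein_id)
  dbd_members <- function(f, s) {
    sort(families$protein_id[families$family == f &
                               families$species_id == s & families$has_dbd])
  }
  rows <- list()
  for (r in seq_len(nrow(source_edges))) {
    a <- source_edges$protein_a[r]; b <- source_edges$protein_b[r]
    s <- source_edges$species_id[r]; eid <- source_edges$edge_id[r]
    fa <- fam_of[[a]]; fb <- fam_of[[b]]
    for (i in setdiff(species, s)) {
      ma <- dbd_members(fa, i)
      mb <- dbd_members(fb, i)
      if (length(ma) == 0 || length(mb) == 0) next
      seen <- character()
      for (x in ma) for (y in mb) {
        p <- sort(c(x, y))
        key <- paste(p, collapse = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- tibble(
          source_edge_id = eid, species_id = i,
          protein_a = p[1], protein_b = p[2])
      }
    }
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(source_edge_id = character(), species_id = character(),
                  protein_a = character(), protein_b = character())
  }
  res
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs the full generator under one seeded RNG stream: gene families,
#' planted losses, pairwise ortholog maps, the source network, and the
#' ground truth (true ortholog groups, exact expected interolog sets per
#' source edge and species computed by the brute-force cross-product rule,
#' expected presence patterns, planted TRIs with causes, and expected
#' expansions). Ground-truth interologs follow the default inference
#' settings (`homodimer_mode = "full"`, both endpoints TF).
#'
#' @param config A [sim_config()].
#' @return List with `config`, `species`, `proteins`, `annotations`,
#'   `catalog`, `ortholog_maps`, `source_edges` and `ground_truth` (list:
#'   `families`, `planted_losses`, `true_interlogs`, `expected_patterns`,
#'   `planted_tris`, `planted_expansions`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  with_seed(config$seed, {
    gf <- simulate_gene_families(config)
    gf <- plant_losses(gf, config)
    maps <- build_true_ortholog_maps(gf$families, config$species)
    source_edges <- simulate_source_network(config, gf$families)
    truth_il <- brute_force_true_interlogs(source_edges, gf$families,
                                           config$species)
    pat <- expected_patterns(source_edges, truth_il, config$species)
    tris <- pat |>
      filter(.data$n_present < length(config$species)) |>
      left_join(planted_causes(source_edges, gf$families, config$species),
                by = "edge_id")
    expansions <- truth_il |>
      count(.data$source_edge_id, .data$species_id, name = "multiplicity") |>
      filter(.data$multiplicity >= 2L) |>
      rename(edge_id = "source_edge_id")
    list(config = config, species = config$species,
         proteins = select(gf$proteins, -"family"),
         annotations = gf$annotations, catalog = gf$catalog,
         ortholog_maps = maps, source_edges = source_edges,
         ground_truth = list(families = gf$families,
                             planted_losses = gf$planted_losses,
                             true_interlogs = truth_il,
                             expected_patterns = pat,
                             planted_tris = tris,
                             planted_expansions = expansions))
  })
}

expected_patterns <- function(source_edges, true_interlogs, species) {
  present <- true_interlogs |> distinct(.data$source_edge_id, .data$species_id)
  source_edges |>
    transmute(edge_id = .data$edge_id, src = .data$species_id) |>
    left_join(present |> rename(edge_id = "source_edge_id"),
              by = "edge_id") |>
    group_by(.data$edge_id) |>
    summarise(presence_pattern = paste(csort(unique(c(.data$src[1],
                                                      stats::na.omit(.data$species_id)))),
                                       collapse = ";"),
              n_present = length(unique(c(.data$src[1],
                                          stats::na.omit(.data$species_id)))),
              .groups = "drop")
}

# For edges missing some species, decide (from truth) whether the loss is an
# ortholog deletion or only a DBD knock-out in each missing species.
planted_causes <- function(source_edges, families, species) {
  fam_of <- setNames(families$family, families$protein_id)
  rows <- map(seq_len(nrow(source_edges)), function(r) {
    eid <- source_edges$edge_id[r]
    fa <- fam_of[[source_edges$protein_a[r]]]
    fb <- fam_of[[source_edges$protein_b[r]]]
    s <- source_edges$species_id[r]
    miss <- character(); causes <- character()
    for (i in setdiff(species, s)) {
      present_a <- any(families$family == fa & families$species_id == i)
      present_b <- any(families$family == fb & families$species_id == i)
      dbd_a <- any(families$family == fa & families$species_id == i &
                     families$has_dbd)
      dbd_b <- any(families$family == fb & families$species_id == i &
                     families$has_dbd)
      if (dbd_a && dbd_b) next
      miss <- c(miss, i)
      causes <- c(causes,
                  if (!present_a || !present_b) "ortholog_loss" else "dbd_loss")
    }
    if (length(miss) == 0) return(NULL)
    tibble(edge_id = eid, missing_species = paste(csort(miss), collapse = ";"),
           cause = if (length(unique(causes)) == 1) causes[1] else "mixed")
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(edge_id = character(), missing_species = character(),
                  cause = character())
  }
  res
}

#' Write a simulated dataset to disk
#'
#' Emits every input file the pipeline reads — per-species FASTA,
#' per-species InterProScan-style TSV, the DBD catalog, pairwise
#' Inparanoid-style sqltables, the source-edge TSV — plus the ground truth
#' and config as JSON. Re-running with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return The `simulate_dataset()` result, invisibly, with `$paths`
#'   attached.
#' @export
emit_dataset <- function(dir, config = sim_config()) {
  sim <- simulate_dataset(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (s in sim$species) {
    p <- filter(sim$proteins, .data$species_id == s)
    paths[[paste0("fasta_", s)]] <- file.path(dir, sprintf("proteins_%s.fasta", s))
    write_fasta(p, paths[[paste0("fasta_", s)]])
    ann <- semi_join(sim$annotations, p, by = "protein_id")
    ipr <- tibble(c1 = ann$protein_id, c2 = "-",
                  c3 = nchar(p$sequence[match(ann$protein_id, p$protein_id)]),
                  c4 = "Pfam", c5 = ann$domain_accession, c6 = ann$domain_name,
                  c7 = ann$start, c8 = ann$end, c9 = fmt_num(ann$score))
    paths[[paste0("domains_", s)]] <- file.path(dir, sprintf("domains_%s.tsv", s))
    readr::write_tsv(ipr, paths[[paste0("domains_", s)]], col_names = FALSE,
                     progress = FALSE)
  }
  paths$catalog <- file.path(dir, "dbd_catalog.txt")
  writeLines(c("# synthetic sequence-specific DNA-binding domain catalog",
               sim$catalog), paths$catalog, useBytes = TRUE)
  for (key in names(sim$ortholog_maps)) {
    pr <- strsplit(key, "|", fixed = TRUE)[[1]]
    f <- file.path(dir, sprintf("sqltable.%s-%s", pr[1], pr[2]))
    paths[[paste0("sqltable_", key)]] <- f
    write_inparanoid_sqltable(sim$ortholog_maps[[key]], f)
  }
  paths$source_edges <- file.path(dir, "source_edges.tsv")
  readr::write_tsv(sim$source_edges, paths$source_edges, progress = FALSE)
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$ground_truth, paths$ground_truth, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  paths$config <- file.path(dir, "config.json")
  cfg <- sim$config[setdiff(names(sim$config), "tree")]
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}

#' Simulate domain-composition profiles along a species tree
#'
#' Evolves arcsine-transformed domain proportions by Brownian motion down a
#' given tree (ancestral values drawn uniformly in the middle of the
#' transformed range, Gaussian increments with variance
#' `sd_per_unit^2 * branch length`, clipped to `[0, pi/2]`). On an
#' ultrametric tree the expected pairwise distances are ultrametric with the
#' tree's own topology. Used to test that
#' the domain-composition tree recovers a known generating topology under
#' small perturbation.
#'
#' @param tree A rooted `phylo` object (or Newick string) with branch
#'   lengths.
#' @param n_domains Number of domain coordinates.
#' @param sd_per_unit Brownian standard deviation per square root of unit
#'   branch length.
#' @param n_tfs Nominal repertoire size used to back-transform counts.
#' @return A profile tibble compatible with [species_distance_matrix()].
#' @export
simulate_domain_profiles <- function(tree, n_domains = 12L, sd_per_unit = 0.05,
                                     n_tfs = 200L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  vals <- matrix(NA_real_, n_tip + tree$Nnode, n_domains)
  vals[root, ] <- runif(n_domains, 0.4, 1.1)
  # walk edges from the root downward (preorder)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (r in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[r, 1]; child <- ord$edge[r, 2]
    step <- stats::rnorm(n_domains, 0, sd_per_unit * sqrt(ord$edge.length[r]))
    vals[child, ] <- pmin(pi / 2, pmax(0, vals[parent, ] + step))
  }
  out <- list()
  for (i in seq_len(n_tip)) {
    tr <- vals[i, ]
    prop <- sin(tr)^2
    out[[i]] <- tibble(species_id = tree$tip.label[i],
                       domain_accession = sprintf("PF7%04d", seq_len(n_domains)),
                       count = as.integer(round(prop * n_tfs)),
                       n_tfs = as.integer(n_tfs),
                       proportion = prop, transformed = tr)
  }
  bind_rows(out)
}
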