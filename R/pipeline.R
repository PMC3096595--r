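# End-to-end orchestration: read inputs, classify TFs, infer interologs,
# merge networks, align into classes, extract conserved/TRI/expansion sets,
# degree statistics and the domain-composition phylogeny; write every table
# plus a JSON manifest (input checksums, seed, per-stage counts).

#' Assemble a pipeline run configuration
#'
#' @param proteins Named character vector: species id -> FASTA path.
#' @param annotations Named character vector: species id -> InterProScan-style
#'   TSV path.
#' @param dbd_catalog Path to the DBD catalog.
#' @param ortholog_maps Character vector of Inparanoid sqltable paths (one
#'   per species pair).
#' @param source_edges Path to the source-interaction TSV.
#' @param out_dir Output directory.
#' @param species_order Display/adjacency order of species (default: sorted
#'   names of `proteins`).
#' @param homodimer_mode,dbd_filter Passed to [infer_interlogs()].
#' @param required_species Conservation requirement
#'   (default: all species).
#' @param top_k Top domains per species for the contingency table and tree.
#' @param tree_method `"upgma"` or `"nj"`.
#' @param fisher_B Monte-Carlo replicates for the Fisher test.
#' @param seed Seed recorded in the manifest and used for the Fisher draw.
#' @return A `run_config` list (validated lazily by [run_pipeline()]).
#' @export
run_config <- function(proteins, annotations, dbd_catalog, ortholog_maps,
                       source_edges, out_dir, species_order = NULL,
                       homodimer_mode = "full", dbd_filter = "both",
                       required_species = NULL, top_k = 10L,
                       tree_method = "upgma", fisher_B = 1e5, seed = 1L) {
  structure(list(proteins = proteins, annotations = annotations,
                 dbd_catalog = dbd_catalog, ortholog_maps = ortholog_maps,
                 source_edges = source_edges, out_dir = out_dir,
                 species_order = species_order %||% csort(names(proteins)),
                 homodimer_mode = homodimer_mode, dbd_filter = dbd_filter,
                 required_species = required_species, top_k = as.integer(top_k),
                 tree_method = tree_method, fisher_B = fisher_B,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Path to a YAML/JSON run config.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    vapply(p, function(x) if (file.exists(x)) x else file.path(base, x),
           character(1))
  }
  run_config(proteins = resolve(unlist(cfg$proteins)),
             annotations = resolve(unlist(cfg$annotations)),
             dbd_catalog = resolve(cfg$dbd_catalog),
             ortholog_maps = unname(resolve(unlist(cfg$ortholog_maps))),
             source_edges = resolve(cfg$source_edges),
             out_dir = cfg$out_dir %||% "netfootprint_out",
             species_order = cfg$species_order,
             homodimer_mode = cfg$homodimer_mode %||% "full",
             dbd_filter = cfg$dbd_filter %||% "both",
             required_species = cfg$required_species,
             top_k = cfg$top_k %||% 10L,
             tree_method = cfg$tree_method %||% "upgma",
             fisher_B = cfg$fisher_B %||% 1e5,
             seed = cfg$seed %||% 1L)
}

#' Run the full footprinting pipeline
#'
#' Stages: `read` -> `classify` -> `interlogs` -> `merge` -> `classes` ->
#' `conservation` -> `stats` -> `domains`. Any stage failure aborts with the
#' stage name after writing a partial manifest, so a fixed input can resume
#' from the written stage outputs.
#'
#' @param config A [run_config()] or path to a YAML/JSON config.
#' @return The manifest list, invisibly; all tables are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   inputs = lapply(
                     c(config$proteins, config$annotations,
                       dbd_catalog = unname(config$dbd_catalog),
                       setNames(config$ortholog_maps,
                                paste0("map", seq_along(config$ortholog_maps))),
                       source_edges = unname(config$source_edges)),
                     function(p) if (file.exists(p))
                       unname(tools::md5sum(p)) else NA_character_))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  dat <- stage("read", {
    species <- config$species_order
    proteins <- bind_rows(lapply(species, function(s) {
      read_fasta(config$proteins[[s]], species_id = s)
    }))
    annotations <- bind_rows(lapply(species, function(s) {
      read_interproscan_tsv(config$annotations[[s]])
    }))
    catalog <- read_dbd_catalog(config$dbd_catalog)
    maps <- list()
    for (p in config$ortholog_maps) {
      m <- read_inparanoid_sqltable(p)
      maps[[ortholog_map_key(m)]] <- m
    }
    source_edges <- read_source_edges(config$source_edges)
    list(species = species, proteins = proteins, annotations = annotations,
         catalog = catalog, maps = maps, source_edges = source_edges)
  })
  manifest$stages$read <- list(n_proteins = nrow(dat$proteins),
                               n_annotations = nrow(dat$annotations),
                               n_catalog = length(dat$catalog),
                               n_source_edges = nrow(dat$source_edges))

  tf_sets <- stage("classify", {
    tf <- classify_tfs(dat$proteins, dat$annotations, dat$catalog)
    for (s in dat$species) {
      readr::write_tsv(filter(tf, .data$species_id == s),
                       file.path(out, sprintf("tf_%s.tsv", s)),
                       progress = FALSE)
    }
    tf
  })
  manifest$stages$classify <- as.list(
    setNames(as.integer(table(factor(tf_sets$species_id,
                                     levels = dat$species))), dat$species))

  interlogs <- stage("interlogs", {
    infer_interlogs(dat$source_edges, dat$maps, tf_sets,
                    target_species = dat$species,
                    homodimer_mode = config$homodimer_mode,
                    dbd_filter = config$dbd_filter)
  })
  manifest$stages$interlogs <- list(
    n_interlog_rows = nrow(interlogs),
    n_distinct_interlogs = nrow(distinct(interlogs, .data$species_id,
                                         .data$protein_a, .data$protein_b)))

  merged <- stage("merge", {
    m <- merge_networks(dat$source_edges, interlogs)
    for (s in dat$species) {
      write_edge_list(filter(m$networks, .data$species_id == s),
                      file.path(out, sprintf("interactions_%s.tsv", s)))
    }
    readr::write_tsv(m$counts, file.path(out, "network_counts.tsv"),
                     progress = FALSE)
    m
  })
  manifest$stages$merge <- setNames(as.list(merged$counts$total),
                                    merged$counts$species_id)

  classes <- stage("classes", {
    cl <- build_interaction_classes(dat$source_edges, interlogs,
                                    species = dat$species)
    readr::write_tsv(cl, file.path(out, "interaction_classes.tsv"),
                     progress = FALSE)
    cl
  })

  cons <- stage("conservation", {
    conserved <- conserved_classes(classes, config$required_species)
    tris <- detect_tris(classes, dat$maps, tf_sets)
    expansions <- detect_expansions(classes)
    readr::write_tsv(conserved, file.path(out, "conserved_classes.tsv"),
                     progress = FALSE)
    readr::write_tsv(tris, file.path(out, "tris.tsv"), progress = FALSE)
    readr::write_tsv(expansions, file.path(out, "expansions.tsv"),
                     progress = FALSE)
    for (s in dat$species) {
      keep <- bind_rows(
        dat$source_edges |>
          filter(.data$species_id == s,
                 .data$edge_id %in% conserved$class_id) |>
          select("protein_a", "protein_b"),
        interlogs |>
          filter(.data$species_id == s,
                 .data$source_edge_id %in% conserved$class_id) |>
          select("protein_a", "protein_b")) |> distinct()
      write_edge_list(mutate(keep, species_id = s),
                      file.path(out, sprintf("conserved_%s.sif", s)),
                      format = "sif")
    }
    list(conserved = conserved, tris = tris, expansions = expansions)
  })
  manifest$stages$conservation <- list(n_conserved = nrow(cons$conserved),
                                       n_tris = nrow(cons$tris),
                                       n_expansions = nrow(cons$expansions))

  stats_out <- stage("stats", {
    rows <- list()
    fits <- list()
    for (s in dat$species) {
      net <- filter(merged$networks, .data$species_id == s)
      if (nrow(net) == 0) next
      rows[[s]] <- mutate(network_summary(net), species_id = s, .before = 1)
      deg <- degree_distribution(net)
      fit <- tryCatch(fit_power_law(deg), error = function(e) NULL)
      if (!is.null(fit)) fits[[s]] <- mutate(glance(fit), species_id = s,
                                             .before = 1)
    }
    summaries <- bind_rows(rows)
    readr::write_tsv(summaries, file.path(out, "network_summary.tsv"),
                     progress = FALSE)
    fits <- bind_rows(fits)
    if (nrow(fits) > 0) {
      readr::write_tsv(fits, file.path(out, "powerlaw_fits.tsv"),
                       progress = FALSE)
    }
    list(summaries = summaries, fits = fits)
  })
  manifest$stages$stats <- list(n_species_summarised = nrow(stats_out$summaries),
                                n_powerlaw_fits = nrow(stats_out$fits))

  domains_out <- stage("domains", {
    profiles <- composition_profile(tf_sets, dat$annotations)
    topk <- top_k_domains(profiles, config$top_k)
    ct <- domain_contingency(profiles, topk$union)
    ft <- fisher_species_test(ct, method = "monte_carlo", B = config$fisher_B,
                              seed = config$seed)
    dmat <- species_distance_matrix(profiles, topk$union)
    tree <- build_domain_tree(dmat, config$tree_method)
    readr::write_tsv(profiles, file.path(out, "domain_profiles.tsv"),
                     progress = FALSE)
    readr::write_tsv(as_tibble(ct, rownames = "species_id"),
                     file.path(out, "domain_contingency.tsv"), progress = FALSE)
    write_domain_tree(tree, file.path(out, "domain_tree.nwk"))
    list(profiles = profiles, fisher = ft, tree = tree)
  })
  manifest$stages$domains <- list(
    n_domain_types = length(unique(domains_out$profiles$domain_accession)),
    fisher_p = domains_out$fisher$p_value,
    fisher_se = domains_out$fisher$se)

  manifest$outputs <- as.list(tools::md5sum(
    csort(list.files(out, full.names = TRUE,
                     pattern = "[.](tsv|sif|nwk)$"))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
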