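# Cross-species network alignment via interaction classes: one class per
# source edge, holding its interologs in every species. Classes are the unit
# of conservation, taxonomic restriction (TRI) and expansion analysis.

#' Align networks into interaction classes
#'
#' One class per source edge; the class collects the edge itself (in its
#' source species) and its interologs per species. The result is a long
#' tibble with one row per (class, species) over all `species`, with
#' `multiplicity` = number of distinct interologs there (the source edge
#' counts 1 in its own species), so a class' presence pattern is
#' `{species : multiplicity >= 1}`.
#'
#' @param source_edges Source-edge tibble.
#' @param interlogs Long interolog tibble from [infer_interlogs()]; every
#'   `source_edge_id` must reference a source edge.
#' @param species Species universe; default: source species plus every
#'   species occurring in `interlogs`.
#' @return Tibble with columns `class_id`, `source_species`, `source_a`,
#'   `source_b`, `species_id`, `multiplicity`, `present`.
#' @export
build_interaction_classes <- function(source_edges, interlogs,
                                      species = NULL) {
  unknown <- setdiff(interlogs$source_edge_id, source_edges$edge_id)
  if (length(unknown) > 0) {
    abort(sprintf("interologs reference unknown source edge id(s), e.g. '%s'",
                  unknown[1]))
  }
  species <- species %||% csort(unique(c(source_edges$species_id,
                                         interlogs$species_id)))
  mult <- interlogs |>
    distinct(.data$source_edge_id, .data$species_id, .data$protein_a,
             .data$protein_b) |>
    count(.data$source_edge_id, .data$species_id, name = "multiplicity")
  base <- source_edges |>
    transmute(class_id = .data$edge_id, source_species = .data$species_id,
              source_a = .data$protein_a, source_b = .data$protein_b)
  grid <- tidyr::expand_grid(base, species_id = species) |>
    left_join(mult, by = c(class_id = "source_edge_id", "species_id")) |>
    mutate(multiplicity = tidyr::replace_na(.data$multiplicity, 0L),
           multiplicity = ifelse(.data$species_id == .data$source_species,
                                 .data$multiplicity + 1L, .data$multiplicity),
           present = .data$multiplicity >= 1L) |>
    arrange(.data$class_id, .data$species_id)
  as_tibble(grid)
}

# presence pattern per class as a sorted ";"-joined string
class_patterns <- function(classes) {
  classes |>
    group_by(.data$class_id, .data$source_species, .data$source_a,
             .data$source_b) |>
    summarise(n_present = sum(.data$present),
              n_species = n(),
              presence_pattern = paste(csort(.data$species_id[.data$present]),
                                       collapse = ";"),
              .groups = "drop")
}

#' Classes conserved across a required species set
#'
#' @param classes Class tibble from [build_interaction_classes()].
#' @param required_species Species that must all be present; default: every
#'   species in `classes` (full five-way conservation).
#' @return One row per conserved class with its presence pattern.
#' @export
conserved_classes <- function(classes, required_species = NULL) {
  required_species <- required_species %||% csort(unique(classes$species_id))
  pat <- class_patterns(classes)
  ok <- classes |>
    filter(.data$species_id %in% required_species) |>
    group_by(.data$class_id) |>
    summarise(conserved = all(.data$present), .groups = "drop") |>
    filter(.data$conserved)
  pat |> semi_join(ok, by = "class_id") |> arrange(.data$class_id)
}

#' Detect taxonomically restricted interactions (TRIs)
#'
#' A TRI is an interaction class whose presence pattern is a proper,
#' non-empty subset of the analyzed species — the interaction-level analogue
#' of taxonomically restricted genes: gained or lost in specific lineages.
#' When ortholog maps and TF sets are supplied, each missing species is
#' diagnosed: `ortholog_loss` (an endpoint has no ortholog there) or
#' `dbd_loss` (orthologs exist but none passes the DNA-binding-domain
#' filter); a class missing species for different reasons is tagged
#' `mixed`.
#'
#' @param classes Class tibble from [build_interaction_classes()].
#' @param ortholog_maps,tf_sets Optional: the inputs the interologs were
#'   inferred from, enabling cause annotation.
#' @return Tibble with `class_id`, `presence_pattern`, `restricted_to`,
#'   `n_present`, `missing_species`, `cause`.
#' @export
detect_tris <- function(classes, ortholog_maps = NULL, tf_sets = NULL) {
  species <- csort(unique(classes$species_id))
  if (length(species) < 2) abort("need at least 2 analyzed species")
  pat <- class_patterns(classes)
  tri <- pat |>
    filter(.data$n_present >= 1, .data$n_present < .data$n_species) |>
    mutate(restricted_to = .data$presence_pattern)
  if (nrow(tri) == 0) {
    return(mutate(tri, missing_species = character(0), cause = character(0)))
  }
  missing <- map_chr(strsplit(tri$presence_pattern, ";", fixed = TRUE),
                     function(p) paste(setdiff(species, p), collapse = ";"))
  tri$missing_species <- missing

  annotate_cause <- function(row) {
    if (is.null(ortholog_maps) || is.null(tf_sets)) return(NA_character_)
    miss <- strsplit(row$missing_species, ";", fixed = TRUE)[[1]]
    causes <- map_chr(miss, function(i) {
      map <- tryCatch(get_pair_map(ortholog_maps, row$source_species, i),
                      error = function(e) NULL)
      if (is.null(map)) return("unknown")
      lk <- ortholog_partners(map, unique(c(row$source_a, row$source_b)),
                              from = row$source_species, to = i)
      if (any(lengths(lk) == 0)) return("ortholog_loss")
      tfs_i <- tf_sets$protein_id[tf_sets$species_id == i]
      lost_tf <- map_lgl(lk, function(o) !any(o %in% tfs_i))
      if (any(lost_tf)) "dbd_loss" else "unknown"
    })
    if (length(unique(causes)) == 1) causes[1] else "mixed"
  }
  tri$cause <- map_chr(seq_len(nrow(tri)), function(r) annotate_cause(tri[r, ]))
  tri |>
    select("class_id", "presence_pattern", "restricted_to", "n_present",
           "missing_species", "cause") |>
    arrange(.data$class_id)
}

#' Detect lineage-specific network expansions
#'
#' One-to-many and many-to-many ortholog relations expand a single source
#' interaction into several interologs in a species; rows with multiplicity
#' at or above `threshold` are reported, largest first.
#'
#' @param classes Class tibble from [build_interaction_classes()].
#' @param threshold Minimum multiplicity (default 2).
#' @return Tibble `class_id`, `species_id`, `multiplicity`, sorted by
#'   multiplicity descending.
#' @export
detect_expansions <- function(classes, threshold = 2L) {
  stopifnot(threshold >= 2L)
  classes |>
    filter(.data$species_id != .data$source_species,
           .data$multiplicity >= threshold) |>
    select("class_id", "species_id", "multiplicity") |>
    arrange(desc(.data$multiplicity), .data$class_id, .data$species_id)
}

#' Conserved subnetworks across species
#'
#' Projects the conserved classes onto a reference species, takes the
#' connected components of that graph, and reports every component with the
#' corresponding edges in each species plus the orthology links between
#' species adjacent in `species_order` (the display convention: dashed
#' orthology lines only between neighbouring rows).
#'
#' @param conserved One row per conserved class
#'   (from [conserved_classes()]).
#' @param source_edges,interlogs The edge data the classes were built from.
#' @param reference_species Species whose graph defines the components.
#' @param species_order Display order of species; default: sorted.
#' @param ortholog_maps Optional named list of ortholog maps for the
#'   orthology links between adjacent species.
#' @return List with `components` (tibble `component_id`, `class_id`),
#'   `edges` (tibble `component_id`, `species_id`, `protein_a`, `protein_b`,
#'   `class_id`) and `ortholog_links` (tibble `component_id`,
#'   `species_from`, `species_to`, `protein_from`, `protein_to`; empty
#'   without `ortholog_maps`).
#' @export
conserved_subnetworks <- function(conserved, source_edges, interlogs,
                                  reference_species, species_order = NULL,
                                  ortholog_maps = NULL) {
  edges_of <- function(cls, sp) {
    src <- source_edges |>
      filter(.data$edge_id %in% cls, .data$species_id == sp) |>
      transmute(class_id = .data$edge_id, .data$protein_a, .data$protein_b)
    inf <- interlogs |>
      filter(.data$source_edge_id %in% cls, .data$species_id == sp) |>
      transmute(class_id = .data$source_edge_id, .data$protein_a,
                .data$protein_b)
    distinct(bind_rows(src, inf))
  }
  cls <- conserved$class_id
  ref <- edges_of(cls, reference_species)
  if (nrow(ref) == 0) {
    return(list(components = tibble(component_id = integer(),
                                    class_id = character()),
                edges = tibble(component_id = integer(), species_id = character(),
                               protein_a = character(), protein_b = character(),
                               class_id = character()),
                ortholog_links = tibble(component_id = integer(),
                                        species_from = character(),
                                        species_to = character(),
                                        protein_from = character(),
                                        protein_to = character())))
  }
  g <- igraph::graph_from_data_frame(ref[c("protein_a", "protein_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  ref$component_id <- unname(pmin(comp[ref$protein_a], comp[ref$protein_b]))
  comp_of_class <- ref |> distinct(.data$class_id, .data$component_id)

  species_order <- species_order %||%
    csort(unique(c(source_edges$species_id, interlogs$species_id)))
  all_edges <- bind_rows(lapply(species_order, function(sp) {
    e <- edges_of(cls, sp)
    if (nrow(e) == 0) return(NULL)
    mutate(e, species_id = sp)
  })) |>
    inner_join(comp_of_class, by = "class_id",
               relationship = "many-to-many") |>
    distinct(.data$component_id, .data$species_id, .data$protein_a,
             .data$protein_b, .data$class_id) |>
    arrange(.data$component_id, .data$species_id, .data$protein_a,
            .data$protein_b)

  links <- tibble(component_id = integer(), species_from = character(),
                  species_to = character(), protein_from = character(),
                  protein_to = character())
  if (!is.null(ortholog_maps) && length(species_order) > 1) {
    link_rows <- list()
    for (j in seq_len(length(species_order) - 1)) {
      s1 <- species_order[j]; s2 <- species_order[j + 1]
      map <- tryCatch(get_pair_map(ortholog_maps, s1, s2),
                      error = function(e) NULL)
      if (is.null(map)) next
      n1 <- all_edges |> filter(.data$species_id == s1)
      nodes1 <- unique(c(n1$protein_a, n1$protein_b))
      comp1 <- all_edges |>
        filter(.data$species_id == s1) |>
        tidyr::pivot_longer(c("protein_a", "protein_b"),
                            values_to = "protein") |>
        distinct(.data$component_id, .data$protein)
      nodes2 <- all_edges |> filter(.data$species_id == s2)
      nodes2 <- unique(c(nodes2$protein_a, nodes2$protein_b))
      lk <- ortholog_partners(map, nodes1, from = s1, to = s2)
      for (r in seq_len(nrow(comp1))) {
        partners <- intersect(lk[[comp1$protein[r]]], nodes2)
        if (length(partners) == 0) next
        link_rows[[length(link_rows) + 1L]] <- tibble(
          component_id = comp1$component_id[r], species_from = s1,
          species_to = s2, protein_from = comp1$protein[r],
          protein_to = partners)
      }
    }
    if (length(link_rows) > 0) links <- bind_rows(link_rows)
  }
  list(components = arrange(comp_of_class, .data$component_id, .data$class_id) |>
         select("component_id", "class_id"),
       edges = all_edges,
       ortholog_links = links)
}
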