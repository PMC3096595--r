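# TF classification by DNA-binding-domain content, and validation of the
# predicted repertoire against a curated known set.

#' Classify proteins as transcription factors by DNA-binding-domain content
#'
#' A protein is regarded as a TF when it carries at least one domain from the
#' catalog of sequence-specific DNA-binding Pfam domains. The accessions that
#' triggered the call are recorded per member.
#'
#' @param proteins Tibble with `protein_id` and `species_id` columns (one row
#'   per protein; sequence not required).
#' @param annotations Tibble of domain annotations with `protein_id` and
#'   `domain_accession` columns (e.g. from [read_interproscan_tsv()]).
#' @param catalog Character vector of DBD accessions
#'   (from [read_dbd_catalog()]).
#' @param strict If `TRUE` (default), an annotation referencing a protein
#'   absent from `proteins` is an error; if `FALSE` it is dropped with a
#'   warning.
#' @return A TF set: tibble with one row per TF — `protein_id`, `species_id`,
#'   `dbd_accessions` (`;`-separated sorted accessions), `n_dbd`.
#' @export
classify_tfs <- function(proteins, annotations, catalog, strict = TRUE) {
  if (length(catalog) == 0) abort("empty DBD catalog")
  unknown <- setdiff(annotations$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    msg <- sprintf("%d annotation(s) reference unknown proteins (e.g. '%s')",
                   length(unknown), unknown[1])
    if (strict) abort(msg) else warn(msg)
    annotations <- filter(annotations, .data$protein_id %in% proteins$protein_id)
  }
  hits <- annotations |>
    filter(.data$domain_accession %in% catalog) |>
    distinct(.data$protein_id, .data$domain_accession) |>
    group_by(.data$protein_id) |>
    summarise(dbd_accessions = paste(csort(.data$domain_accession), collapse = ";"),
              n_dbd = n(), .groups = "drop")
  proteins |>
    distinct(.data$protein_id, .data$species_id) |>
    inner_join(hits, by = "protein_id") |>
    arrange(.data$species_id, .data$protein_id)
}

#' Validate a predicted TF set against a curated known set
#'
#' Computes true positives (predicted and known), false positives (predicted
#' only), false negatives (known only) and the positive predictive value
#' PPV = 100 * TP / (TP + FP), reported as a percentage rounded half-up to
#' two decimals.
#'
#' @param predicted Character vector of predicted TF ids (or a TF-set tibble
#'   with a `protein_id` column).
#' @param known Character vector of known TF ids.
#' @return A `tf_validation` object: list with `n_known`, `n_predicted`,
#'   `tp`, `fp`, `fn`, `ppv` (percent, 2 decimals; `NA` and a flag when the
#'   predicted set is empty). Has [tidy()] and [glance()] methods.
#' @examples
#' validate_against_known(c("a", "b", "c"), c("b", "c", "d"))
#' @export
validate_against_known <- function(predicted, known) {
  if (is.data.frame(predicted)) predicted <- predicted$protein_id
  if (is.data.frame(known)) known <- known$protein_id
  predicted <- unique(predicted)
  known <- unique(known)
  tp <- length(intersect(predicted, known))
  fp <- length(setdiff(predicted, known))
  fn <- length(setdiff(known, predicted))
  undefined <- length(predicted) == 0
  if (undefined) warn("empty predicted set: PPV undefined")
  out <- list(
    n_known = length(known), n_predicted = length(predicted),
    tp = tp, fp = fp, fn = fn,
    ppv = if (undefined) NA_real_ else round_half_up(100 * tp / (tp + fp), 2),
    ppv_undefined = undefined
  )
  structure(out, class = "tf_validation")
}

#' @export
print.tf_validation <- function(x, ...) {
  cat(sprintf(
    "TF validation: %d predicted vs %d known\n  TP %d  FP %d  FN %d  PPV %s%%\n",
    x$n_predicted, x$n_known, x$tp, x$fp, x$fn,
    if (is.na(x$ppv)) "NA" else sprintf("%.2f", x$ppv)))
  invisible(x)
}

#' @rdname validate_against_known
#' @param x A `tf_validation` object.
#' @param ... Unused.
#' @export
tidy.tf_validation <- function(x, ...) {
  tibble(metric = c("tp", "fp", "fn", "ppv"),
         value = c(x$tp, x$fp, x$fn, x$ppv))
}

#' @rdname validate_against_known
#' @export
glance.tf_validation <- function(x, ...) {
  tibble(n_known = x$n_known, n_predicted = x$n_predicted,
         tp = x$tp, fp = x$fp, fn = x$fn, ppv = x$ppv)
}
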