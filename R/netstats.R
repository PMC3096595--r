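# Degree-distribution summaries and discrete power-law fitting for the
# per-species TF networks.

#' Degree distribution of an interaction network
#'
#' Degree is the number of distinct interaction partners. Under the default
#' `partner_count` policy a self-loop (homodimer) contributes 1 — the TF is
#' its own partner; under `graph_degree` it contributes 2 (the graph-theoretic
#' convention, used by the handshake identity).
#'
#' @param network Edge tibble with `protein_a`, `protein_b` (and optionally
#'   `species_id`, carried through).
#' @param self_loop_policy `"partner_count"` (default) or `"graph_degree"`.
#' @return A `degree_distribution` tibble: one row per node with columns
#'   `protein_id`, `degree` (plus `species_id` when present in `network`).
#' @export
degree_distribution <- function(network,
                                self_loop_policy = c("partner_count",
                                                     "graph_degree")) {
  self_loop_policy <- match.arg(self_loop_policy)
  if (nrow(network) == 0) abort("empty network")
  by_species <- "species_id" %in% names(network)
  grp <- if (by_species) list(network$species_id) else list(rep("", nrow(network)))
  parts <- lapply(split(seq_len(nrow(network)), grp[[1]]), function(idx) {
    e <- network[idx, , drop = FALSE]
    long <- tibble(protein_id = c(e$protein_a, e$protein_b),
                   partner = c(e$protein_b, e$protein_a))
    deg <- long |>
      distinct(.data$protein_id, .data$partner) |>
      count(.data$protein_id, name = "degree")
    if (self_loop_policy == "graph_degree") {
      loops <- e |>
        filter(.data$protein_a == .data$protein_b) |>
        distinct(.data$protein_a)
      deg$degree <- deg$degree + as.integer(deg$protein_id %in% loops$protein_a)
    }
    if (by_species) deg$species_id <- e$species_id[1]
    deg
  })
  out <- bind_rows(parts) |> arrange(.data$protein_id)
  attr(out, "self_loop_policy") <- self_loop_policy
  class(out) <- c("degree_distribution", class(out))
  out
}

#' Degree histogram
#'
#' @param degrees A [degree_distribution()] tibble or numeric vector.
#' @return Tibble `degree`, `n_nodes`.
#' @export
degree_histogram <- function(degrees) {
  d <- if (is.data.frame(degrees)) degrees$degree else degrees
  tibble(degree = as.integer(names(table(d))),
         n_nodes = as.integer(table(d))) |>
    arrange(.data$degree)
}

# Hurwitz zeta sum_{k>=xmin} k^-a, by direct summation plus an
# Euler-Maclaurin tail correction; accurate to ~1e-10 for a > 1.
hurwitz_zeta <- function(a, xmin, n_terms = 2e4) {
  k <- seq(xmin, xmin + n_terms - 1)
  head_sum <- sum(k^(-a))
  N <- xmin + n_terms - 1
  tail <- (N + 0.5)^(1 - a) / (a - 1)
  head_sum + tail
}

mle_alpha <- function(tail_degrees, xmin) {
  slog <- sum(log(tail_degrees))
  n <- length(tail_degrees)
  opt <- optimize(function(a) n * log(hurwitz_zeta(a, xmin)) + a * slog,
                  interval = c(1.0001, 8))
  list(alpha = opt$minimum, loglik = -opt$objective)
}

ks_stat_discrete <- function(tail_degrees, alpha, xmin) {
  ks <- sort(unique(tail_degrees))
  z <- hurwitz_zeta(alpha, xmin)
  pk <- vapply(ks, function(k) k^(-alpha), numeric(1)) / z
  # theoretical CDF at each observed k (cumulative over xmin..k)
  all_k <- seq(xmin, max(ks))
  cdf_all <- cumsum(all_k^(-alpha) / z)
  th <- cdf_all[match(ks, all_k)]
  emp <- cumsum(as.integer(table(factor(tail_degrees, levels = ks)))) /
    length(tail_degrees)
  max(abs(emp - th))
}

#' Fit a power law to a degree sequence
#'
#' Discrete maximum-likelihood fit of `p(k) ~ k^-alpha` for `k >= xmin`
#' (Clauset-style): for each candidate cutoff, alpha maximizes the
#' Hurwitz-zeta likelihood and the cutoff minimizing the Kolmogorov-Smirnov
#' distance between the empirical and fitted tail is chosen. A least-squares
#' fit of the log-log degree histogram is available for comparison
#' (`method = "ols"`); it is the historical approach but statistically
#' biased, and is flagged as such.
#'
#' @param degrees Numeric vector of degrees, or a [degree_distribution()]
#'   tibble. Zeros are excluded from the fit.
#' @param method `"mle"` (default) or `"ols"`.
#' @param xmin `"auto"` (KS-minimizing scan) or a fixed integer cutoff.
#' @param min_tail Minimum number of tail observations a candidate cutoff
#'   must retain (default 10).
#' @return A `powerlaw_fit`: list with `alpha`, `xmin`, `ks_statistic`,
#'   `method`, `n_tail`, `loglik`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_power_law <- function(degrees, method = c("mle", "ols"), xmin = "auto",
                          min_tail = 10L) {
  method <- match.arg(method)
  d <- if (is.data.frame(degrees)) degrees$degree else degrees
  d <- d[d >= 1]
  if (length(d) < min_tail) abort("too few positive degrees to fit")
  if (length(unique(d)) == 1) {
    abort("degenerate input: all degrees equal; no power law is identifiable")
  }
  if (method == "ols") {
    hist <- degree_histogram(d)
    fitlm <- stats::lm(log(n_nodes) ~ log(degree), data = hist)
    alpha <- -unname(stats::coef(fitlm)[2])
    xm <- min(d)
    tail_d <- d[d >= xm]
    fit <- list(alpha = alpha, xmin = xm,
                ks_statistic = ks_stat_discrete(tail_d, alpha, xm),
                method = "ols (log-log least squares; biased)",
                n_tail = length(tail_d),
                loglik = NA_real_)
    class(fit) <- "powerlaw_fit"
    return(fit)
  }
  candidates <- if (identical(xmin, "auto")) {
    xs <- sort(unique(d))
    xs[vapply(xs, function(x) sum(d >= x), integer(1)) >= min_tail &
         xs <= stats::quantile(d, 0.99)]
  } else as.integer(xmin)
  if (length(candidates) == 0) candidates <- min(d)
  best <- NULL
  for (xm in candidates) {
    tail_d <- d[d >= xm]
    if (length(unique(tail_d)) < 2) next
    m <- mle_alpha(tail_d, xm)
    ks <- ks_stat_discrete(tail_d, m$alpha, xm)
    if (is.null(best) || ks < best$ks_statistic) {
      best <- list(alpha = m$alpha, xmin = xm, ks_statistic = ks,
                   method = "mle (discrete, KS-selected xmin)",
                   n_tail = length(tail_d), loglik = m$loglik)
    }
  }
  if (is.null(best)) abort("no admissible xmin candidate")
  structure(best, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s)\n  alpha = %.4f, xmin = %d, KS = %.4f, n_tail = %d\n",
              x$method, x$alpha, x$xmin, x$ks_statistic, x$n_tail))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `powerlaw_fit` object.
#' @param ... Unused.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("alpha", "xmin"), estimate = c(x$alpha, x$xmin))
}

#' @rdname fit_power_law
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, ks_statistic = x$ks_statistic,
         n_tail = x$n_tail, loglik = x$loglik, method = x$method)
}

#' Log-log degree histogram with the fitted power law
#'
#' @param object A `powerlaw_fit`.
#' @param degrees The degree data the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.powerlaw_fit <- function(object, degrees, ...) {
  hist <- degree_histogram(degrees) |> filter(.data$degree >= 1)
  hist$frequency <- hist$n_nodes / sum(hist$n_nodes)
  z <- hurwitz_zeta(object$alpha, object$xmin)
  p_tail <- sum(hist$frequency[hist$degree >= object$xmin])
  line <- tibble(degree = seq(object$xmin, max(hist$degree)))
  line$frequency <- p_tail * line$degree^(-object$alpha) / z
  ggplot2::ggplot(hist, ggplot2::aes(.data$degree, .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)",
                  title = sprintf("alpha = %.2f, xmin = %d",
                                  object$alpha, object$xmin)) +
    ggplot2::theme_minimal()
}

#' Sample from a discrete power-law distribution
#'
#' `P(K = k) ~ k^-alpha` for `k = xmin, ..., kmax` (the truncation mass above
#' `kmax` is negligible for the exponents of interest). Used by the
#' synthetic-data generator and for fitter calibration.
#'
#' @param n Sample size.
#' @param alpha Scaling exponent (> 1).
#' @param xmin Lower cutoff.
#' @param kmax Upper truncation.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1L, kmax = 1e5L) {
  stopifnot(alpha > 1, xmin >= 1)
  k <- seq(xmin, kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Summary statistics of an interaction network
#'
#' @param network Edge tibble with `protein_a`, `protein_b`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_self_loops`,
#'   `mean_degree`, `max_degree`, `n_components`.
#' @export
network_summary <- function(network) {
  if (nrow(network) == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, n_self_loops = 0L,
                  mean_degree = NA_real_, max_degree = NA_integer_,
                  n_components = 0L))
  }
  net <- distinct(canonical_pair(network$protein_a, network$protein_b))
  deg <- degree_distribution(net)
  g <- igraph::graph_from_data_frame(net, directed = FALSE)
  tibble(n_nodes = length(unique(c(net$protein_a, net$protein_b))),
         n_edges = nrow(net),
         n_self_loops = sum(net$protein_a == net$protein_b),
         mean_degree = mean(deg$degree),
         max_degree = max(deg$degree),
         n_components = igraph::components(g)$no)
}
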