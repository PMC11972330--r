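#' Empirical tail probabilities for a vector of distances
#'
#' Converts observed distances into self-inclusive empirical tail
#' probabilities: `p(g) = #{g' : d(g') >= d(g)} / N`. The gene with the
#' single largest distance gets `p = 1/N`, tied distances share the same
#' `p`, and if every distance is identical every `p` is 1 (nothing is
#' selectable). This is the rank-based equivalent of deriving the density of
#' the observed distances empirically and selecting its upper tail.
#'
#' @param d Numeric vector of distances (length >= 2). `NA` entries
#'   propagate to `NA` p-values and are excluded from the ranking.
#' @return Numeric vector of p-values in `[1/N, 1]`, `N` the number of
#'   non-missing distances.
#' @export
#' @examples
#' empirical_pvalues(c(3, 2, 1))  # 1/3, 2/3, 1
empirical_pvalues <- function(d) {
  if (!is.numeric(d)) stop_data("`d` must be numeric.")
  ok <- !is.na(d)
  n <- sum(ok)
  if (n < 2) stop_data("need at least two non-missing distances.")
  if (any(!is.finite(d[ok]))) stop_data("distances must be finite.")
  p <- rep(NA_real_, length(d))
  # #{d' >= d} = N - #{d' < d} = N - (min-rank - 1)
  p[ok] <- (n - rank(d[ok], ties.method = "min") + 1) / n
  p
}

#' Select genes in the empirical upper tail
#'
#' Flags p-values at or below `alpha`. With tie-free continuous distances
#' over `N` genes this selects exactly `floor(alpha * N)` genes — the
#' "alpha * 100 % most divergent". A tie group spanning the cutoff is
#' selected or rejected as a whole, because its members share one p-value.
#'
#' @param p Numeric vector of empirical p-values (`NA` allowed; never
#'   selected).
#' @param alpha Selection level in (0, 1). Default 0.01.
#' @return Logical vector, `TRUE` for selected entries.
#' @export
select_significant <- function(p, alpha = 0.01) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("`alpha` must lie in (0, 1).")
  !is.na(p) & p <= alpha
}

#' Cross-metric consensus of per-metric selections
#'
#' Combines the per-metric distances, p-values and significance flags into
#' the compiled screen table: one row per gene that is significant in at
#' least one metric, with the count of significant metrics and the mean
#' p-value, sorted by `n_metrics_significant` (descending), then `mean_p`
#' (ascending), then `gene_id` — a deterministic total order.
#'
#' @param distances Tibble `gene_id` + one column per metric (from
#'   [compute_distances()]).
#' @param pvalues,flags Tibbles of matching shape holding per-metric
#'   empirical p-values and significance flags.
#' @return A tibble with columns `gene_id`, `n_metrics_significant`,
#'   `mean_p`, then `d_<metric>`, `p_<metric>`, `sig_<metric>` triplets.
#' @export
consensus_rank <- function(distances, pvalues, flags) {
  metrics <- setdiff(names(distances), "gene_id")
  if (length(metrics) == 0) stop_config("no metric columns in `distances`.")
  if (!identical(names(pvalues), names(distances)) ||
      !identical(names(flags), names(distances)) ||
      !identical(pvalues$gene_id, distances$gene_id) ||
      !identical(flags$gene_id, distances$gene_id))
    stop_config("`distances`, `pvalues` and `flags` must align.")

  fl <- as.matrix(flags[, metrics, drop = FALSE])
  fl[is.na(fl)] <- FALSE          # inapplicable metric => not significant
  pm <- as.matrix(pvalues[, metrics, drop = FALSE])
  out <- tibble::tibble(
    gene_id = distances$gene_id,
    n_metrics_significant = as.integer(rowSums(fl)),
    mean_p = rowMeans(pm, na.rm = TRUE))
  for (mm in metrics) {
    out[[paste0("d_", mm)]] <- distances[[mm]]
    out[[paste0("p_", mm)]] <- pvalues[[mm]]
    out[[paste0("sig_", mm)]] <- fl[, mm]
  }
  out <- out[out$n_metrics_significant > 0, , drop = FALSE]
  out[order(-out$n_metrics_significant, out$mean_p, out$gene_id), ]
}

#' Run the multi-metric divergence screen
#'
#' The full screening stage: computes every requested dissimilarity on every
#' scaled profile pair, converts each metric's distances into empirical tail
#' probabilities, selects the genes with `p <= alpha` per metric (the
#' `alpha * 100` % most divergent), and compiles the cross-metric consensus
#' table. Everything is deterministic given the inputs and parameters.
#'
#' @param pairs Scaled, variance-filtered `tempo_profiles` (see
#'   [build_profile_pairs()], [filter_by_variance()],
#'   [scale_profile_pairs()]).
#' @param metrics Metric names; default all of [tempo_metrics()].
#' @param params A [metric_params()] object.
#' @param alpha Per-metric empirical selection level. Default 0.01.
#' @return An object of class `"tempo_screen"` with elements `result` (the
#'   compiled consensus tibble), `distances`, `pvalues`, `flags`, `alpha`,
#'   `metrics`, `params`, `time_vector`, `n_screened` and
#'   `n_degenerate`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_screen <- function(pairs, metrics = tempo_metrics(),
                       params = metric_params(), alpha = 0.01) {
  check_profiles(pairs)
  metrics <- check_metric_names(unique(metrics))
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("`alpha` must lie in (0, 1).")
  n_degenerate <- if (isTRUE(attr(pairs, "scaled")))
    sum(pairs$degenerate) else 0L
  distances <- compute_distances(pairs, metrics, params)

  pvalues <- distances
  flags <- distances
  all_tied <- character(0)
  for (mm in metrics) {
    p <- empirical_pvalues(distances[[mm]])
    if (all(p == 1, na.rm = TRUE)) all_tied <- c(all_tied, mm)
    pvalues[[mm]] <- p
    flags[[mm]] <- select_significant(p, alpha)
  }
  if (length(all_tied) > 0)
    inform(paste0("metric(s) with all distances identical ",
                  "(nothing selectable): ",
                  paste(all_tied, collapse = ", ")))

  structure(
    list(result = consensus_rank(distances, pvalues, flags),
         distances = distances,
         pvalues = pvalues,
         flags = flags,
         alpha = alpha,
         metrics = metrics,
         params = attr(distances, "metric_params"),
         time_vector = attr(distances, "time_vector"),
         n_screened = nrow(distances),
         n_degenerate = as.integer(n_degenerate)),
    class = "tempo_screen")
}

#' @export
print.tempo_screen <- function(x, ...) {
  cat(sprintf(
    "Temporal divergence screen: %d genes x %d metrics, alpha = %g\n",
    x$n_screened, length(x$metrics), x$alpha))
  cat(sprintf("  genes significant in >= 1 metric: %d\n", nrow(x$result)))
  if (nrow(x$result) > 0) {
    cat("  top of the consensus table:\n")
    print(head(x$result[, c("gene_id", "n_metrics_significant", "mean_p")],
               5))
  }
  invisible(x)
}

#' @describeIn run_screen Tidy the compiled consensus table (one row per
#'   selected gene).
#' @param x A `tempo_screen` object.
#' @param ... Unused.
#' @export
tidy.tempo_screen <- function(x, ...) x$result

#' @describeIn run_screen One-row summary: genes screened, genes selected,
#'   selection level, metric count, and the size of the largest consensus.
#' @export
glance.tempo_screen <- function(x, ...) {
  tibble::tibble(
    n_screened = x$n_screened,
    n_degenerate = x$n_degenerate,
    n_selected = nrow(x$result),
    max_metrics_significant =
      if (nrow(x$result) > 0) max(x$result$n_metrics_significant) else 0L,
    n_metrics = length(x$metrics),
    alpha = x$alpha)
}

#' @describeIn run_screen Bar chart of how many selected genes reach each
#'   consensus level (number of metrics significant).
#' @param object A `tempo_screen` object.
#' @export
autoplot.tempo_screen <- function(object, ...) {
  df <- dplyr::count(object$result, .data$n_metrics_significant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_metrics_significant,
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq_len(length(object$metrics))) +
    ggplot2::labs(x = "metrics calling the gene significant",
                  y = "genes",
                  title = "Cross-metric consensus of divergent trajectories") +
    ggplot2::theme_minimal()
}

#' Plot unscaled expression profiles for chosen genes
#'
#' Draws each gene's per-condition expression series on the `log2(TPM+1)`
#' scale (the unscaled values), one facet per gene — the standard way to
#' inspect genes flagged by the screen.
#'
#' @param pairs A `tempo_profiles` object (scaled or not; the raw series are
#'   used).
#' @param genes Character vector of gene ids to plot.
#' @return A ggplot object.
#' @export
plot_profiles <- function(pairs, genes) {
  check_profiles(pairs)
  idx <- match(genes, pairs$gene_id)
  if (any(is.na(idx)))
    stop_data(paste0("gene id(s) not found: ",
                     paste(genes[is.na(idx)], collapse = ", ")))
  scaled <- isTRUE(attr(pairs, "scaled"))
  w <- if (scaled) pairs$wt_raw else pairs$wt
  k <- if (scaled) pairs$ko_raw else pairs$ko
  tv <- attr(pairs, "time_vector")
  conds <- attr(pairs, "conditions")
  df <- purrr::map_dfr(idx, function(i) {
    tibble::tibble(
      gene_id = pairs$gene_id[i],
      time = rep(tv, 2),
      condition = rep(conds, each = length(tv)),
      expression = c(w[i, ], k[i, ]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$expression,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "log2(TPM + 1)") +
    ggplot2::theme_minimal()
}
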