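#' Run the whole screen from raw counts
#'
#' Chains every stage of the analysis: TPM normalization, `log2(TPM+1)`
#' transformation, profile-pair construction, variance filtering, joint
#' minmax scaling, the twelve dissimilarity measures, per-metric empirical
#' tail selection and the cross-metric consensus. Per-stage gene counts (the
#' funnel: input, post-variance-filter, selected) are reported via messages
#' and returned in the result.
#'
#' @param counts Count tibble (`gene_id` + one column per sample), or an
#'   expression tibble already on the `log2(TPM+1)` scale if
#'   `counts_are_expression = TRUE`.
#' @param gene_lengths Tibble `gene_id`, `length_bp`; ignored when
#'   `counts_are_expression = TRUE`.
#' @param sample_sheet Tibble `sample_id`, `condition`, `timepoint`,
#'   `replicate`.
#' @param conditions Length-2 character vector (reference, alternative).
#' @param variance_threshold Strict lower bound on pooled profile variance.
#'   Default 0.1.
#' @param alpha Per-metric empirical selection level. Default 0.01.
#' @param metrics Metric names, default all 12; see [tempo_metrics()].
#' @param params [metric_params()] object.
#' @param aggregate Replicate aggregation, `"mean"` or `"median"`.
#' @param counts_are_expression Set `TRUE` when `counts` already holds
#'   `log2(TPM+1)` values (skips TPM normalization).
#' @return A `tempo_screen` object (see [run_screen()]) with an extra
#'   `funnel` element: a tibble of per-stage gene counts.
#' @export
run_pipeline <- function(counts, gene_lengths = NULL, sample_sheet,
                         conditions = c("WT", "KO"),
                         variance_threshold = 0.1,
                         alpha = 0.01,
                         metrics = tempo_metrics(),
                         params = metric_params(),
                         aggregate = c("mean", "median"),
                         counts_are_expression = FALSE) {
  aggregate <- match.arg(aggregate)
  metrics <- check_metric_names(unique(metrics))   # fail fast, before any work
  expr <- if (counts_are_expression) {
    counts
  } else {
    if (is.null(gene_lengths))
      stop_config("`gene_lengths` is required for count input.")
    log_tpm(counts_to_tpm(counts, gene_lengths))
  }
  pairs <- build_profile_pairs(expr, sample_sheet,
                               aggregate = aggregate,
                               conditions = conditions)
  n_input <- nrow(pairs)
  kept <- filter_by_variance(pairs, variance_threshold)
  n_kept <- nrow(kept)
  inform(sprintf("profiles: %d input, %d pass the variance filter (> %g)",
                 n_input, n_kept, variance_threshold))
  scaled <- scale_profile_pairs(kept)
  screen <- run_screen(scaled, metrics = metrics, params = params,
                       alpha = alpha)
  inform(sprintf("selected: %d genes significant in >= 1 of %d metrics",
                 nrow(screen$result), length(screen$metrics)))
  screen$funnel <- tibble::tibble(
    stage = c("input", "variance_filtered", "screened", "selected"),
    n_genes = c(n_input, n_kept, screen$n_screened,
                nrow(screen$result)))
  screen$pairs <- scaled
  screen
}
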