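#' Convert raw read counts to transcripts per million (TPM)
#'
#' For each sample, reads are first rated per kilobase of transcript
#' (`count / (length_bp / 1000)`), then rescaled so the rates in that sample
#' sum to one million:
#' `tpm_g = rate_g / sum(rate) * 1e6`. Column sums of the result are 1e6 by
#' construction, making the values comparable across samples of different
#' sequencing depth.
#'
#' @param counts Tibble with a `gene_id` column followed by one numeric
#'   column of non-negative counts per sample.
#' @param gene_lengths Tibble with columns `gene_id` and `length_bp`
#'   (positive transcript lengths in base pairs) covering every gene in
#'   `counts`.
#' @return A tibble of the same shape as `counts` holding TPM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10, 20))
#' lens <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000, 2000))
#' counts_to_tpm(counts, lens)  # both genes at 5e5 TPM
counts_to_tpm <- function(counts, gene_lengths) {
  check_counts_frame(counts)
  if (!is.data.frame(gene_lengths) ||
      !all(c("gene_id", "length_bp") %in% names(gene_lengths)))
    stop_data("`gene_lengths` needs columns gene_id and length_bp.")
  len <- gene_lengths$length_bp[match(counts$gene_id, gene_lengths$gene_id)]
  missing <- counts$gene_id[is.na(len)]
  if (length(missing) > 0)
    stop_data(paste0("no gene length for: ",
                     paste(head(missing, 5), collapse = ", ")))
  if (any(len <= 0))
    stop_data("gene lengths must be positive.")

  m <- as.matrix(counts[, -1, drop = FALSE])
  if (any(m < 0)) stop_data("counts must be non-negative.")
  rate <- m / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop_data(paste0("sample(s) with all-zero counts: ",
                     paste(colnames(m)[tot == 0], collapse = ", ")))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  dplyr::bind_cols(counts[, 1], tibble::as_tibble(as.data.frame(tpm)))
}

#' Log-transform an expression matrix
#'
#' Applies `log2(x + 1)` elementwise, the standard compression of TPM values
#' onto an approximately additive scale; zero maps to zero.
#'
#' @param tpm Tibble with a `gene_id` column followed by non-negative
#'   numeric columns.
#' @return Tibble of the same shape with `log2(tpm + 1)` values.
#' @export
log_tpm <- function(tpm) {
  check_counts_frame(tpm, what = "expression")
  m <- as.matrix(tpm[, -1, drop = FALSE])
  if (any(m < 0)) stop_data("expression values must be non-negative.")
  dplyr::bind_cols(tpm[, 1], tibble::as_tibble(as.data.frame(log2(m + 1))))
}

check_counts_frame <- function(x, what = "count") {
  if (!is.data.frame(x) || names(x)[1] != "gene_id" || ncol(x) < 2)
    stop_data(paste0("a ", what,
                     " table must have gene_id as its first column, ",
                     "followed by one column per sample."))
  if (anyDuplicated(x$gene_id))
    stop_data("duplicate gene_id values.")
  m <- x[, -1, drop = FALSE]
  if (!all(vapply(m, is.numeric, logical(1))))
    stop_data(paste0("non-numeric ", what, " column."))
  if (any(!is.finite(as.matrix(m))))
    stop_data(paste0("non-finite ", what, " values."))
  invisible(x)
}

new_tempo_profiles <- function(df, time_vector, conditions, aggregate,
                               scaled = FALSE) {
  structure(df,
            time_vector = time_vector,
            conditions = conditions,
            aggregate = aggregate,
            scaled = scaled,
            class = c("tempo_profiles", class(tibble::tibble())))
}

restore_profile_attrs <- function(df, template, scaled = NULL) {
  new_tempo_profiles(df,
                     time_vector = attr(template, "time_vector"),
                     conditions = attr(template, "conditions"),
                     aggregate = attr(template, "aggregate"),
                     scaled = scaled %||% attr(template, "scaled"))
}

#' Build per-gene condition profile pairs from an expression table
#'
#' Collapses replicate samples to one expression series per gene and
#' condition: for every condition and time point the replicate `log2(TPM+1)`
#' values are aggregated (arithmetic mean by default), producing a pair of
#' length-`T` series per gene, ordered by time. The pooled variance of the
#' `2T` aggregated values is recorded per gene and drives
#' [filter_by_variance()].
#'
#' @param expression Tibble with a `gene_id` column followed by one numeric
#'   column per sample, on the `log2(TPM+1)` scale (see [log_tpm()]).
#' @param sample_sheet Tibble with columns `sample_id`, `condition`,
#'   `timepoint` describing every expression column. Both conditions must be
#'   observed at every time point.
#' @param aggregate `"mean"` (default) or `"median"` collapse of replicates.
#' @param conditions Length-2 character vector naming the reference and
#'   alternative condition labels, in that order. Default `c("WT", "KO")`.
#' @param var_type `"sample"` (denominator `2T - 1`, default) or
#'   `"population"` (`2T`) for the pooled variance.
#' @return A `tempo_profiles` tibble with columns `gene_id`, matrix columns
#'   `wt` and `ko` (genes x T), and `variance`; the time vector and condition
#'   labels travel as attributes.
#' @export
build_profile_pairs <- function(expression, sample_sheet,
                                aggregate = c("mean", "median"),
                                conditions = c("WT", "KO"),
                                var_type = c("sample", "population")) {
  aggregate <- match.arg(aggregate)
  var_type <- match.arg(var_type)
  check_counts_frame(expression, what = "expression")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop_config("`conditions` must be two distinct labels.")
  need <- c("sample_id", "condition", "timepoint")
  if (!is.data.frame(sample_sheet) || !all(need %in% names(sample_sheet)))
    stop_design("`sample_sheet` needs columns sample_id, condition, timepoint.")
  samples <- names(expression)[-1]
  unknown <- setdiff(samples, sample_sheet$sample_id)
  if (length(unknown) > 0)
    stop_design(paste0("expression columns missing from the sample sheet: ",
                       paste(unknown, collapse = ", ")))
  sheet <- sample_sheet[match(samples, sample_sheet$sample_id), ]
  bad <- setdiff(unique(sheet$condition), conditions)
  if (length(bad) > 0)
    stop_design(paste0("condition label(s) outside {",
                       paste(conditions, collapse = ", "), "}: ",
                       paste(bad, collapse = ", ")))
  tp_by_cond <- lapply(conditions, function(cc)
    sort(unique(sheet$timepoint[sheet$condition == cc])))
  if (!identical(tp_by_cond[[1]], tp_by_cond[[2]]))
    stop_design(paste0(
      "time points must be observed in both conditions; present in one only: ",
      paste(union(setdiff(tp_by_cond[[1]], tp_by_cond[[2]]),
                  setdiff(tp_by_cond[[2]], tp_by_cond[[1]])),
            collapse = ", ")))
  time_vector <- tp_by_cond[[1]]
  tt <- length(time_vector)
  if (tt < 2) stop_design("need at least two time points.")

  m <- as.matrix(expression[, -1, drop = FALSE])
  agg_series <- function(cond) {
    out <- matrix(0, nrow(m), tt)
    for (i in seq_len(tt)) {
      cols <- which(sheet$condition == cond &
                      sheet$timepoint == time_vector[i])
      block <- m[, cols, drop = FALSE]
      out[, i] <- if (aggregate == "mean") {
        rowMeans(block)
      } else {
        apply(block, 1, median)
      }
    }
    out
  }
  wt <- agg_series(conditions[1])
  ko <- agg_series(conditions[2])
  variance <- row_vars(cbind(wt, ko), population = var_type == "population")

  df <- tibble::tibble(gene_id = expression$gene_id,
                       wt = wt, ko = ko, variance = variance)
  new_tempo_profiles(df, time_vector, conditions, aggregate, scaled = FALSE)
}

#' Filter profile pairs by pooled variance
#'
#' Retains genes whose pooled variance across the `2T` aggregated expression
#' values is strictly greater than `threshold`. The default threshold 0.1 on
#' the `log2(TPM+1)` scale removes genes that are essentially flat in both
#' conditions and therefore uninformative for trajectory comparison.
#'
#' @param pairs A `tempo_profiles` tibble from [build_profile_pairs()].
#' @param threshold Strict lower bound on the pooled variance. Default 0.1.
#' @return The retained subset, attributes preserved.
#' @export
filter_by_variance <- function(pairs, threshold = 0.1) {
  check_profiles(pairs)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop_config("`threshold` must be a single number.")
  keep <- pairs$variance > threshold
  restore_profile_attrs(pairs[keep, , drop = FALSE], pairs)
}

#' Jointly minmax-scale each gene's condition pair
#'
#' Rescales both of a gene's series with the extrema of the pooled `2T`
#' values: `E' = (E - E_min) / (E_max - E_min)`, so that after scaling the
#' highest pooled value is exactly 1 and the lowest exactly 0. Because one
#' shared range is used for both conditions, the relationship between the
#' two series (which one is higher, and by how much, relatively) is
#' preserved — the property every downstream dissimilarity relies on.
#' Constant pairs (`E_max == E_min`) cannot be scaled; they are set to zero
#' and flagged `degenerate`, and are skipped by [compute_distances()].
#'
#' @param pairs Unscaled `tempo_profiles` from [build_profile_pairs()] (or
#'   [filter_by_variance()]).
#' @return A `tempo_profiles` tibble with `wt`/`ko` replaced by their scaled
#'   versions, the raw series kept as `wt_raw`/`ko_raw`, and new columns
#'   `e_min`, `e_max`, `degenerate`.
#' @export
scale_profile_pairs <- function(pairs) {
  check_profiles(pairs)
  if (isTRUE(attr(pairs, "scaled")))
    stop_config("profile pairs are already scaled.")
  pooled <- cbind(pairs$wt, pairs$ko)
  e_min <- do.call(pmin, as.data.frame(pooled))
  e_max <- do.call(pmax, as.data.frame(pooled))
  if (nrow(pairs) == 0) {
    e_min <- numeric(0)
    e_max <- numeric(0)
  }
  rng <- e_max - e_min
  degenerate <- rng == 0
  safe <- ifelse(degenerate, 1, rng)
  wt_s <- (pairs$wt - e_min) / safe
  ko_s <- (pairs$ko - e_min) / safe
  if (any(degenerate)) {
    wt_s[degenerate, ] <- 0
    ko_s[degenerate, ] <- 0
  }
  df <- tibble::tibble(gene_id = pairs$gene_id,
                       wt = wt_s, ko = ko_s,
                       wt_raw = pairs$wt, ko_raw = pairs$ko,
                       variance = pairs$variance,
                       e_min = e_min, e_max = e_max,
                       degenerate = degenerate)
  restore_profile_attrs(df, pairs, scaled = TRUE)
}

check_profiles <- function(pairs) {
  if (!inherits(pairs, "tempo_profiles"))
    stop_config("expected a `tempo_profiles` object from build_profile_pairs().")
  invisible(pairs)
}

#' @export
print.tempo_profiles <- function(x, ...) {
  tv <- attr(x, "time_vector")
  cat(sprintf("Profile pairs: %d genes x %d time points (%s vs %s), %s\n",
              nrow(x), length(tv),
              attr(x, "conditions")[1], attr(x, "conditions")[2],
              if (isTRUE(attr(x, "scaled"))) "jointly minmax-scaled"
              else "unscaled"))
  NextMethod()
}
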