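#' The twelve profile dissimilarity measures
#'
#' Returns the canonical metric names accepted by [compute_distances()],
#' [profile_distance()] and [run_screen()]:
#' `euclidean` (pointwise L2), `sts` (short time series: L2 between the
#' piecewise slopes), `dtw` (dynamic time warping), `tam` (time alignment
#' measurement), `acf` (L2 between autocorrelation vectors), `fourier`
#' (L2 between leading DFT coefficients), `cdm` (compression-based
#' dissimilarity), `cid` (complexity-invariant distance), `cor`
#' (Pearson-correlation dissimilarity), `per` (periodogram distance),
#' `int.per` (integrated-periodogram distance), and `frechet` (discrete
#' Frechet distance).
#'
#' @return Character vector of the 12 metric names.
#' @export
tempo_metrics <- function() {
  c("euclidean", "sts", "dtw", "tam", "acf", "fourier",
    "cdm", "cid", "cor", "per", "int.per", "frechet")
}

#' Tuning parameters for the dissimilarity measures
#'
#' Bundles the free parameters of the metric family. Defaults depending on
#' the series length `T` are resolved when a computation runs and are
#' recorded in the distance-table metadata.
#'
#' @param acf_max_lag Largest autocorrelation lag compared. Default `T - 2`.
#' @param fourier_n_coef Number of leading DFT coefficients compared
#'   (including the DC term). Default `floor(T/2) + 1`.
#' @param cdm_alphabet_size Number of uniform quantization bins over `[0, 1]`
#'   for the compression-based measure. Default 8.
#' @param cdm_compressor `"lzma"` (default) or `"deflate"`.
#' @param cid_epsilon Regularizer added to both complexity estimates in the
#'   complexity-invariant ratio. Default 1e-12.
#' @param per_n_freq Number of non-zero Fourier frequencies in the
#'   periodogram distances. Default `floor(T/2)`.
#' @param frechet_embedding `"value_only"` (default) compares values alone;
#'   `"time_value"` embeds each series as a curve in the (time, value)
#'   plane. The default avoids letting the time axis (days) dominate the
#'   minmax-scaled values, which span `[0, 1]`.
#' @return A list of class `"tempo_metric_params"`.
#' @export
metric_params <- function(acf_max_lag = NULL,
                          fourier_n_coef = NULL,
                          cdm_alphabet_size = 8L,
                          cdm_compressor = c("lzma", "deflate"),
                          cid_epsilon = 1e-12,
                          per_n_freq = NULL,
                          frechet_embedding = c("value_only", "time_value")) {
  cdm_compressor <- match.arg(cdm_compressor)
  frechet_embedding <- match.arg(frechet_embedding)
  if (!is.null(acf_max_lag) && (!is_count(acf_max_lag) || acf_max_lag < 1))
    stop_config("`acf_max_lag` must be a positive integer.")
  if (!is.null(fourier_n_coef) &&
      (!is_count(fourier_n_coef) || fourier_n_coef < 1))
    stop_config("`fourier_n_coef` must be a positive integer.")
  if (!is_count(cdm_alphabet_size) || cdm_alphabet_size < 2)
    stop_config("`cdm_alphabet_size` must be an integer >= 2.")
  if (!is_scalar_number(cid_epsilon) || cid_epsilon < 0)
    stop_config("`cid_epsilon` must be non-negative.")
  if (!is.null(per_n_freq) && (!is_count(per_n_freq) || per_n_freq < 1))
    stop_config("`per_n_freq` must be a positive integer.")
  structure(list(acf_max_lag = acf_max_lag,
                 fourier_n_coef = fourier_n_coef,
                 cdm_alphabet_size = as.integer(cdm_alphabet_size),
                 cdm_compressor = cdm_compressor,
                 cid_epsilon = cid_epsilon,
                 per_n_freq = per_n_freq,
                 frechet_embedding = frechet_embedding),
            class = "tempo_metric_params")
}

resolve_params <- function(params, tt) {
  if (!inherits(params, "tempo_metric_params"))
    stop_config("`params` must come from metric_params().")
  params$acf_max_lag <- as.integer(params$acf_max_lag %||% max(1L, tt - 2L))
  params$fourier_n_coef <-
    as.integer(params$fourier_n_coef %||% (tt %/% 2L + 1L))
  params$per_n_freq <- as.integer(params$per_n_freq %||% max(1L, tt %/% 2L))
  if (params$acf_max_lag > tt - 1L)
    stop_config("`acf_max_lag` must be at most T - 1.")
  if (params$fourier_n_coef > tt)
    stop_config("`fourier_n_coef` must be at most T.")
  if (params$per_n_freq > tt - 1L)
    stop_config("`per_n_freq` must be at most T - 1.")
  params
}

# --- vectorized metric kernels -------------------------------------------
# Each kernel maps two genes x T matrices to one value per gene. The
# per-pair interface profile_distance() funnels through the same kernels
# with 1-row matrices, so a single code path is tested.

metric_euclidean <- function(w, k, time, p) sqrt(rowSums((w - k)^2))

row_slopes <- function(m, time) {
  dt <- diff(time)
  (m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]) /
    rep(dt, each = nrow(m))
}

metric_sts <- function(w, k, time, p) {
  sqrt(rowSums((row_slopes(k, time) - row_slopes(w, time))^2))
}

metric_dtw <- function(w, k, time, p) cpp_dtw(w, k)

metric_tam <- function(w, k, time, p) cpp_tam(w, k)

metric_frechet <- function(w, k, time, p) {
  cpp_frechet(w, k,
              if (p$frechet_embedding == "time_value") time else NULL)
}

# Biased sample autocorrelation out to lag L; a constant series has all
# autocorrelations defined as zero.
acf_matrix <- function(m, max_lag) {
  tt <- ncol(m)
  c0 <- m - rowMeans(m)
  denom <- rowSums(c0^2)
  out <- matrix(0, nrow(m), max_lag)
  ok <- denom > 0
  for (lag in seq_len(max_lag)) {
    num <- rowSums(c0[, seq_len(tt - lag), drop = FALSE] *
                     c0[, seq_len(tt - lag) + lag, drop = FALSE])
    out[ok, lag] <- num[ok] / denom[ok]
  }
  out
}

metric_acf <- function(w, k, time, p) {
  sqrt(rowSums((acf_matrix(w, p$acf_max_lag) -
                  acf_matrix(k, p$acf_max_lag))^2))
}

# Unnormalized DFT, series along rows; returns genes x T complex matrix.
row_fft <- function(m) t(stats::mvfft(t(m)))

metric_fourier <- function(w, k, time, p) {
  nc <- p$fourier_n_coef
  d <- (row_fft(w) - row_fft(k))[, seq_len(nc), drop = FALSE]
  sqrt(rowSums(Mod(d)^2))
}

periodogram <- function(m, n_freq) {
  X <- row_fft(m)
  (Mod(X[, 1L + seq_len(n_freq), drop = FALSE])^2) / ncol(m)
}

metric_per <- function(w, k, time, p) {
  sqrt(rowSums((periodogram(w, p$per_n_freq) -
                  periodogram(k, p$per_n_freq))^2))
}

# Normalized cumulative periodogram; zero-power series fall back to the
# uniform ramp k/K so that two constant series are at distance zero. "Zero"
# power is detected up to the DFT's rounding noise (a constant series leaves
# O(T * eps) residuals in its nonzero-frequency coefficients).
cum_periodogram <- function(m, n_freq) {
  P <- periodogram(m, n_freq)
  tot <- rowSums(P)
  zero <- tot <= ncol(m)^2 * .Machine$double.eps
  out <- t(apply(P, 1, cumsum)) / ifelse(zero, 1, tot)
  if (n_freq == 1L) out <- matrix(out, ncol = 1L)
  if (any(zero))
    out[zero, ] <- rep(seq_len(n_freq) / n_freq, each = sum(zero))
  out
}

metric_intper <- function(w, k, time, p) {
  rowSums(abs(cum_periodogram(w, p$per_n_freq) -
                cum_periodogram(k, p$per_n_freq)))
}

metric_cid <- function(w, k, time, p) {
  ce <- function(m) sqrt(rowSums((m[, -1, drop = FALSE] -
                                    m[, -ncol(m), drop = FALSE])^2))
  cw <- ce(w); ck <- ce(k)
  eps <- p$cid_epsilon
  metric_euclidean(w, k, time, p) *
    (pmax(cw, ck) + eps) / (pmin(cw, ck) + eps)
}

# sqrt(2 (1 - rho)); a constant series gets rho := 0, hence distance sqrt(2).
metric_cor <- function(w, k, time, p) {
  cw <- w - rowMeans(w)
  ck <- k - rowMeans(k)
  sw <- rowSums(cw^2)
  sk <- rowSums(ck^2)
  rho <- ifelse(sw > 0 & sk > 0, rowSums(cw * ck) / sqrt(sw * sk), 0)
  sqrt(pmax(2 * (1 - rho), 0))
}

quantize_series <- function(z, alphabet) {
  z <- pmin(pmax(z, 0), 1)
  as.raw(pmin(floor(z * alphabet), alphabet - 1L))
}

compressed_size <- function(bytes, compressor) {
  type <- if (compressor == "lzma") "xz" else "gzip"
  length(memCompress(bytes, type = type))
}

cdm_pair <- function(x, y, p) {
  bx <- quantize_series(x, p$cdm_alphabet_size)
  by <- quantize_series(y, p$cdm_alphabet_size)
  cx <- compressed_size(bx, p$cdm_compressor)
  cy <- compressed_size(by, p$cdm_compressor)
  cxy <- compressed_size(c(bx, by), p$cdm_compressor)
  cyx <- compressed_size(c(by, bx), p$cdm_compressor)
  (cxy + cyx) / (2 * (cx + cy))
}

metric_cdm <- function(w, k, time, p) {
  vapply(seq_len(nrow(w)),
         function(g) cdm_pair(w[g, ], k[g, ], p),
         numeric(1))
}

metric_kernels <- function() {
  list(euclidean = metric_euclidean, sts = metric_sts, dtw = metric_dtw,
       tam = metric_tam, acf = metric_acf, fourier = metric_fourier,
       cdm = metric_cdm, cid = metric_cid, cor = metric_cor,
       per = metric_per, `int.per` = metric_intper, frechet = metric_frechet)
}

check_metric_names <- function(metrics) {
  valid <- tempo_metrics()
  bad <- setdiff(metrics, valid)
  if (length(bad) > 0)
    stop_config(paste0("unknown metric(s): ", paste(bad, collapse = ", "),
                       ". Valid names: ", paste(valid, collapse = ", ")))
  if (length(metrics) == 0) stop_config("at least one metric is required.")
  metrics
}

#' Dissimilarity between one pair of series
#'
#' Computes a single named dissimilarity between two equal-length series,
#' typically a gene's jointly scaled condition profiles. See
#' [tempo_metrics()] for the available measures and [metric_params()] for
#' their tuning parameters.
#'
#' @param x,y Numeric vectors of equal length `T >= 2`, finite.
#' @param metric One of [tempo_metrics()].
#' @param time Sampling times (strictly increasing, length `T`); used by the
#'   slope-based `sts` measure and the `time_value` Frechet embedding.
#'   Defaults to `0, 1, ..., T - 1`.
#' @param params A [metric_params()] object.
#' @return A single non-negative number.
#' @export
#' @examples
#' profile_distance(c(0, 0, 1), c(0, 1, 1), metric = "dtw")  # 0
profile_distance <- function(x, y, metric,
                             time = seq_along(x) - 1,
                             params = metric_params()) {
  metric <- check_metric_names(metric)
  if (length(metric) != 1L) stop_config("`metric` must be a single name.")
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_data("`x` and `y` must be numeric vectors of equal length.")
  if (length(x) < 2) stop_data("series must have at least two points.")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_data("series contain non-finite values.")
  if (length(time) != length(x) || any(diff(time) <= 0))
    stop_data("`time` must be strictly increasing and match the series length.")
  p <- resolve_params(params, length(x))
  kernel <- metric_kernels()[[metric]]
  as.numeric(kernel(matrix(x, 1), matrix(y, 1), as.numeric(time), p))
}

#' Compute the gene-by-metric distance table
#'
#' Evaluates each requested dissimilarity between every gene's scaled WT and
#' KO series. Degenerate (constant) pairs flagged by
#' [scale_profile_pairs()] are excluded with a message, since no dissimilarity
#' is meaningful for them.
#'
#' @param pairs Scaled `tempo_profiles` from [scale_profile_pairs()].
#' @param metrics Character vector of metric names; default all 12.
#' @param params A [metric_params()] object.
#' @return A tibble with `gene_id` and one non-negative numeric column per
#'   metric; the resolved parameters and time vector travel as attributes
#'   (`metric_params`, `time_vector`).
#' @export
compute_distances <- function(pairs, metrics = tempo_metrics(),
                              params = metric_params()) {
  check_profiles(pairs)
  if (!isTRUE(attr(pairs, "scaled")))
    stop_config("profile pairs must be scaled first; see scale_profile_pairs().")
  metrics <- check_metric_names(unique(metrics))
  if (any(pairs$degenerate)) {
    inform(sprintf("excluding %d degenerate (constant) profile pair(s).",
                   sum(pairs$degenerate)))
    pairs <- restore_profile_attrs(
      pairs[!pairs$degenerate, , drop = FALSE], pairs)
  }
  time <- as.numeric(attr(pairs, "time_vector"))
  p <- resolve_params(params, length(time))
  w <- pairs$wt
  k <- pairs$ko
  kernels <- metric_kernels()
  cols <- lapply(metrics, function(mm) kernels[[mm]](w, k, time, p))
  names(cols) <- metrics
  out <- dplyr::bind_cols(tibble::tibble(gene_id = pairs$gene_id),
                          tibble::as_tibble(cols))
  attr(out, "metric_params") <- p
  attr(out, "time_vector") <- time
  out
}
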