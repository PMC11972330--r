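#' Configure a synthetic two-condition expression time course
#'
#' Builds the configuration object consumed by [simulate_timecourse()]. The
#' generator emulates a bulk RNA-seq time course observed in two conditions
#' (by default a wild-type `WT` arm with 4 replicate clones and a knockout
#' `KO` arm with 2), sampled at 7 time points across a two-week
#' differentiation window. Most genes share one latent trajectory between the
#' two arms (the null population); a chosen number of genes receive a
#' condition-divergent trajectory in the `KO` arm, mimicking the delayed or
#' attenuated activation seen for sequentially induced developmental genes.
#'
#' Latent trajectories are drawn on the linear TPM scale from four template
#' families: `flat` (constant housekeeping-like level), `ramp` (monotone
#' increase), `pulse` (transient bump), and `sigmoid` (switch-like activation
#' `baseline + plateau / (1 + exp(-k (t - t0)))`, the shape of a gene turning
#' on mid-course). Differential genes are built on the sigmoid template and
#' the knockout arm is perturbed according to `effect_kinds`:
#'
#' * `delay` — the activation midpoint `t0` is shifted later by `delay_shift`
#'   time units,
#' * `attenuation` — the plateau is multiplied by `attenuation_factor` on the
#'   linear scale,
#' * `suppression` — the knockout trajectory is flattened to the baseline,
#' * `ectopic` — the gene is flat in the reference arm but activates in the
#'   knockout arm.
#'
#' Two emission modes are supported. `"counts"` draws negative-binomial read
#' counts around TPM-proportional means scaled by lognormal per-sample
#' library sizes (coefficient of variation 0.2), exercising the full
#' normalization path. `"expression"` emits `log2(TPM+1)` values with
#' Gaussian noise of standard deviation `noise_sd_log` directly, exercising
#' the screen in isolation.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_timepoints Number of time points per condition. Default 7.
#' @param time_vector Strictly increasing sampling times (days). Default
#'   `c(0, 2, 4, 6, 9, 11, 14)`.
#' @param replicates_per_condition Named integer vector of replicates per
#'   condition. Default `c(WT = 4, KO = 2)`.
#' @param n_differential Number of genes planted with a condition-divergent
#'   trajectory. Must not exceed `n_genes`.
#' @param effect_kinds Character subset of
#'   `c("delay", "attenuation", "suppression", "ectopic")`; planted genes
#'   cycle through these kinds.
#' @param delay_shift Later shift (same units as `time_vector`) of the
#'   activation midpoint for `delay` genes. Default 4 (two grid steps).
#' @param attenuation_factor Multiplier in (0, 1) applied to the plateau of
#'   `attenuation` genes on the linear TPM scale. Default 0.3.
#' @param noise_sd_log Gaussian noise standard deviation on the
#'   `log2(TPM+1)` scale. Default 0.1.
#' @param nb_dispersion Negative-binomial dispersion for count emission
#'   (variance `mu + dispersion * mu^2`). Default 0.05.
#' @param mean_library_size Mean sequencing depth per sample. Default 5e6.
#' @param gene_length_log_mean,gene_length_log_sd Natural-log mean and sd of
#'   the lognormal gene-length distribution (bp). Defaults `log(1500)` / 0.6.
#' @param emission `"counts"` or `"expression"` (see Details).
#' @param seed Integer RNG seed; the simulation is fully deterministic given
#'   the configuration.
#'
#' @return A list of class `"tempo_sim_config"`.
#' @seealso [simulate_timecourse()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_differential = 10, seed = 42)
#' sim <- simulate_timecourse(cfg)
#' sim$truth
sim_config <- function(n_genes,
                       n_timepoints = 7L,
                       time_vector = c(0, 2, 4, 6, 9, 11, 14),
                       replicates_per_condition = c(WT = 4L, KO = 2L),
                       n_differential = 0L,
                       effect_kinds = c("delay", "attenuation",
                                        "suppression", "ectopic"),
                       delay_shift = 4,
                       attenuation_factor = 0.3,
                       noise_sd_log = 0.1,
                       nb_dispersion = 0.05,
                       mean_library_size = 5e6,
                       gene_length_log_mean = log(1500),
                       gene_length_log_sd = 0.6,
                       emission = c("counts", "expression"),
                       seed = 1L) {
  emission <- match.arg(emission)
  if (!is_count(n_genes) || n_genes < 1)
    stop_config("`n_genes` must be a positive integer.")
  if (!is_count(n_timepoints) || n_timepoints < 2)
    stop_config("`n_timepoints` must be an integer >= 2.")
  if (length(time_vector) != n_timepoints)
    stop_config("`time_vector` must have length `n_timepoints`.")
  if (any(!is.finite(time_vector)) || any(diff(time_vector) <= 0))
    stop_config("`time_vector` must be strictly increasing.")
  if (length(replicates_per_condition) != 2L ||
      is.null(names(replicates_per_condition)) ||
      anyDuplicated(names(replicates_per_condition)) ||
      any(replicates_per_condition < 1) ||
      any(replicates_per_condition != floor(replicates_per_condition)))
    stop_config(
      "`replicates_per_condition` must be two named positive integers, e.g. c(WT = 4, KO = 2).")
  if (!is_count(n_differential) || n_differential > n_genes)
    stop_config("`n_differential` must be an integer in [0, n_genes].")
  kinds_ok <- c("delay", "attenuation", "suppression", "ectopic")
  effect_kinds <- unique(effect_kinds)
  if (n_differential > 0 &&
      (length(effect_kinds) == 0 || !all(effect_kinds %in% kinds_ok)))
    stop_config(paste0("`effect_kinds` must be a non-empty subset of: ",
                       paste(kinds_ok, collapse = ", ")))
  if (!is_scalar_number(delay_shift) || delay_shift < 0)
    stop_config("`delay_shift` must be a non-negative number.")
  if (!is_scalar_number(attenuation_factor) ||
      attenuation_factor <= 0 || attenuation_factor >= 1)
    stop_config("`attenuation_factor` must lie in (0, 1).")
  if (!is_scalar_number(noise_sd_log) || noise_sd_log < 0)
    stop_config("`noise_sd_log` must be non-negative.")
  if (!is_scalar_number(nb_dispersion) || nb_dispersion <= 0)
    stop_config("`nb_dispersion` must be positive.")
  if (!is_scalar_number(mean_library_size) || mean_library_size <= 0)
    stop_config("`mean_library_size` must be positive.")
  if (!is_scalar_number(gene_length_log_mean) ||
      !is_scalar_number(gene_length_log_sd) || gene_length_log_sd < 0)
    stop_config("Gene-length lognormal parameters are invalid.")
  if (!is_scalar_number(seed))
    stop_config("`seed` must be a single integer.")

  structure(
    list(n_genes = as.integer(n_genes),
         n_timepoints = as.integer(n_timepoints),
         time_vector = as.numeric(time_vector),
         replicates_per_condition = replicates_per_condition,
         n_differential = as.integer(n_differential),
         effect_kinds = effect_kinds,
         delay_shift = delay_shift,
         attenuation_factor = attenuation_factor,
         noise_sd_log = noise_sd_log,
         nb_dispersion = nb_dispersion,
         mean_library_size = mean_library_size,
         gene_length_log_mean = gene_length_log_mean,
         gene_length_log_sd = gene_length_log_sd,
         emission = emission,
         seed = as.integer(seed)),
    class = "tempo_sim_config")
}

# Latent linear-TPM trajectory templates. All return a length-T vector.
template_trajectory <- function(template, time, p) {
  switch(template,
    flat = rep(p$baseline, length(time)),
    ramp = {
      span <- diff(range(time))
      p$baseline + (p$plateau - p$baseline) * (time - time[1]) / span
    },
    pulse = p$baseline +
      (p$plateau - p$baseline) *
        exp(-(time - p$midpoint)^2 / (2 * p$width^2)),
    sigmoid = p$baseline + p$plateau / (1 + exp(-p$rate * (time - p$midpoint))),
    stop_config(paste0("unknown template: ", template))
  )
}

draw_template_params <- function(template, time) {
  span <- diff(range(time))
  list(
    baseline = switch(template,
                      flat = loguniform(1, 0.5, 200),
                      loguniform(1, 0.1, 5)),
    plateau = loguniform(1, 10, 1000),
    midpoint = runif(1, time[1] + 1, time[length(time)] - 1),
    rate = 1,
    width = span / 6)
}

#' Simulate a two-condition expression time course with ground truth
#'
#' Generates a gene-by-sample data set according to a [sim_config()]: raw
#' negative-binomial read counts (or, in expression mode, `log2(TPM+1)`
#' values), gene lengths, a sample sheet, and a truth table recording which
#' genes were planted with a divergent knockout trajectory and how. Null
#' genes share an identical latent trajectory in both conditions, so any
#' divergence measured on them downstream is attributable to noise alone.
#'
#' @param config A `"tempo_sim_config"` from [sim_config()].
#' @return A list of class `"tempo_sim"` with elements:
#'   \describe{
#'     \item{counts}{tibble `gene_id` + one integer column per sample
#'       (emission `"counts"` only).}
#'     \item{expression}{tibble of `log2(TPM+1)` values per sample
#'       (emission `"expression"` only).}
#'     \item{gene_lengths}{tibble `gene_id`, `length_bp`.}
#'     \item{sample_sheet}{tibble `sample_id`, `condition`, `timepoint`,
#'       `replicate`.}
#'     \item{truth}{tibble `gene_id`, `is_differential`, `effect_kind`,
#'       `template` and template parameters.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_timecourse <- function(config) {
  if (!inherits(config, "tempo_sim_config"))
    stop_config("`config` must be created with sim_config().")
  with_seed(config$seed, simulate_timecourse_impl(config))
}

simulate_timecourse_impl <- function(cfg) {
  n <- cfg$n_genes
  time <- cfg$time_vector
  tt <- cfg$n_timepoints
  conds <- names(cfg$replicates_per_condition)
  gene_id <- sprintf("gene_%06d", seq_len(n))

  length_bp <- pmax(200L, as.integer(round(
    rlnorm(n, cfg$gene_length_log_mean, cfg$gene_length_log_sd))))

  diff_idx <- if (cfg$n_differential > 0) {
    sort(sample.int(n, cfg$n_differential))
  } else integer(0)
  is_differential <- seq_len(n) %in% diff_idx
  effect_kind <- rep(NA_character_, n)
  if (length(diff_idx) > 0) {
    effect_kind[diff_idx] <-
      rep_len(cfg$effect_kinds, length(diff_idx))
  }

  # Null genes draw one of four template families; planted genes are built on
  # the switch-like activation template (flat in WT for the ectopic kind).
  templates <- c("flat", "ramp", "pulse", "sigmoid")
  template <- sample(templates, n, replace = TRUE,
                     prob = c(0.55, 0.15, 0.15, 0.15))
  template[is_differential] <-
    ifelse(effect_kind[is_differential] == "ectopic", "flat", "sigmoid")

  params <- vector("list", n)
  wt <- matrix(0, n, tt)
  ko <- matrix(0, n, tt)
  for (g in seq_len(n)) {
    p <- draw_template_params(template[g], time)
    params[[g]] <- p
    if (!is_differential[g]) {
      wt[g, ] <- ko[g, ] <- template_trajectory(template[g], time, p)
      next
    }
    kind <- effect_kind[g]
    if (kind == "ectopic") {
      # flat reference arm at a low baseline; knockout activates
      wt[g, ] <- rep(p$baseline, tt)
      ko[g, ] <- template_trajectory("sigmoid", time, p)
    } else {
      wt[g, ] <- template_trajectory("sigmoid", time, p)
      pk <- p
      if (kind == "delay") pk$midpoint <- p$midpoint + cfg$delay_shift
      if (kind == "attenuation") pk$plateau <- p$plateau * cfg$attenuation_factor
      ko[g, ] <- if (kind == "suppression") {
        rep(p$baseline, tt)
      } else {
        template_trajectory("sigmoid", time, pk)
      }
    }
  }

  sample_sheet <- tidyr::expand_grid(
    condition = conds,
    replicate = seq_len(max(cfg$replicates_per_condition)),
    timepoint = time)
  sample_sheet <- sample_sheet[
    sample_sheet$replicate <=
      cfg$replicates_per_condition[sample_sheet$condition], ]
  sample_sheet$sample_id <- sprintf(
    "%s_T%02d_R%d", sample_sheet$condition,
    match(sample_sheet$timepoint, time), sample_sheet$replicate)
  sample_sheet <- tibble::as_tibble(
    sample_sheet[, c("sample_id", "condition", "timepoint", "replicate")])

  n_samples <- nrow(sample_sheet)
  latent_for <- function(cond) if (cond == conds[1]) wt else ko

  out <- list(gene_lengths = tibble::tibble(gene_id = gene_id,
                                            length_bp = length_bp),
              sample_sheet = sample_sheet,
              config = cfg)

  if (cfg$emission == "counts") {
    lib_sdlog <- sqrt(log(1 + 0.2^2))
    lib <- rlnorm(n_samples, log(cfg$mean_library_size) - lib_sdlog^2 / 2,
                  lib_sdlog)
    cnt <- matrix(0L, n, n_samples)
    for (s in seq_len(n_samples)) {
      ti <- match(sample_sheet$timepoint[s], time)
      tpm <- latent_for(sample_sheet$condition[s])[, ti]
      if (cfg$noise_sd_log > 0)
        tpm <- tpm * 2^rnorm(n, 0, cfg$noise_sd_log)
      rate <- tpm * length_bp
      mu <- lib[s] * rate / sum(rate)
      cnt[, s] <- rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    counts <- tibble::as_tibble(as.data.frame(cnt))
    names(counts) <- sample_sheet$sample_id
    out$counts <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), counts)
  } else {
    expr <- matrix(0, n, n_samples)
    for (s in seq_len(n_samples)) {
      ti <- match(sample_sheet$timepoint[s], time)
      tpm <- latent_for(sample_sheet$condition[s])[, ti]
      e <- log2(tpm + 1)
      if (cfg$noise_sd_log > 0) e <- e + rnorm(n, 0, cfg$noise_sd_log)
      expr[, s] <- e
    }
    em <- tibble::as_tibble(as.data.frame(expr))
    names(em) <- sample_sheet$sample_id
    out$expression <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), em)
  }

  out$truth <- tibble::tibble(
    gene_id = gene_id,
    is_differential = is_differential,
    effect_kind = effect_kind,
    template = template,
    baseline = vapply(params, `[[`, numeric(1), "baseline"),
    plateau = vapply(params, `[[`, numeric(1), "plateau"),
    midpoint = vapply(params, `[[`, numeric(1), "midpoint"),
    rate = vapply(params, `[[`, numeric(1), "rate"))

  structure(out, class = "tempo_sim")
}

#' @export
print.tempo_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic two-condition time course\n")
  cat(sprintf("  %d genes x %d samples (%s emission), %d time points\n",
              cfg$n_genes, nrow(x$sample_sheet), cfg$emission,
              cfg$n_timepoints))
  cat(sprintf("  planted differential genes: %d (%s)\n",
              cfg$n_differential,
              if (cfg$n_differential > 0)
                paste(cfg$effect_kinds, collapse = ", ") else "none"))
  invisible(x)
}
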