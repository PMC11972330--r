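# TSV readers with validation. Error messages carry 1-based file line
# numbers (header = line 1) so problems can be located in the input.

read_tsv_quiet <- function(path) {
  if (!file.exists(path))
    stop_parse(paste0("input file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a raw count table
#'
#' Expects a tab-separated file whose header starts with `gene_id` followed
#' by one column per sample; entries must be non-negative finite numbers and
#' gene ids unique.
#'
#' @param path Path to the TSV file.
#' @return A tibble (`gene_id` + one numeric column per sample).
#' @export
read_counts <- function(path) {
  x <- read_tsv_quiet(path)
  if (names(x)[1] != "gene_id" || ncol(x) < 2)
    stop_parse(paste0(path, ": header must be gene_id followed by sample ids."))
  dup <- which(duplicated(x$gene_id))
  if (length(dup) > 0)
    stop_parse(sprintf("%s: duplicate gene_id '%s' at line %d.",
                       path, x$gene_id[dup[1]], dup[1] + 1L))
  m <- x[, -1, drop = FALSE]
  if (!all(vapply(m, is.numeric, logical(1))))
    stop_parse(paste0(path, ": non-numeric count column."))
  mm <- as.matrix(m)
  bad <- which(!is.finite(mm) | mm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_parse(sprintf(
      "%s: negative or non-finite count at line %d, column '%s'.",
      path, bad[1, 1] + 1L, colnames(mm)[bad[1, 2]]))
  x
}

#' Read a gene-length table
#'
#' Tab-separated file with columns `gene_id` and `length_bp` (positive
#' transcript length in base pairs).
#'
#' @inheritParams read_counts
#' @return A tibble with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  x <- read_tsv_quiet(path)
  if (!all(c("gene_id", "length_bp") %in% names(x)))
    stop_parse(paste0(path, ": header must contain gene_id and length_bp."))
  dup <- which(duplicated(x$gene_id))
  if (length(dup) > 0)
    stop_parse(sprintf("%s: duplicate gene_id '%s' at line %d.",
                       path, x$gene_id[dup[1]], dup[1] + 1L))
  bad <- which(!is.finite(x$length_bp) | x$length_bp <= 0)
  if (length(bad) > 0)
    stop_parse(sprintf("%s: non-positive gene length at line %d.",
                       path, bad[1] + 1L))
  x
}

#' Read and validate a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `condition`, `timepoint`,
#' `replicate`. Sample ids must be unique, condition labels must come from
#' `conditions`, and both conditions must be observed at the same set of
#' time points.
#'
#' @inheritParams read_counts
#' @param conditions Length-2 character vector of allowed condition labels
#'   (reference first). Default `c("WT", "KO")`.
#' @return A tibble with the four columns above.
#' @export
read_sample_sheet <- function(path, conditions = c("WT", "KO")) {
  x <- read_tsv_quiet(path)
  need <- c("sample_id", "condition", "timepoint", "replicate")
  if (!all(need %in% names(x)))
    stop_parse(paste0(path, ": header must contain ",
                      paste(need, collapse = ", "), "."))
  dup <- which(duplicated(x$sample_id))
  if (length(dup) > 0)
    stop_parse(sprintf("%s: duplicate sample_id '%s' at line %d.",
                       path, x$sample_id[dup[1]], dup[1] + 1L))
  bad <- which(!(x$condition %in% conditions))
  if (length(bad) > 0)
    stop_parse(sprintf(
      "%s: condition '%s' at line %d is outside {%s}.",
      path, x$condition[bad[1]], bad[1] + 1L,
      paste(conditions, collapse = ", ")))
  if (!is.numeric(x$timepoint))
    stop_parse(paste0(path, ": timepoint column must be numeric."))
  tps <- lapply(conditions, function(cc)
    sort(unique(x$timepoint[x$condition == cc])))
  if (!identical(tps[[1]], tps[[2]]))
    stop_design(paste0(
      path, ": time point(s) present in one condition only: ",
      paste(union(setdiff(tps[[1]], tps[[2]]),
                  setdiff(tps[[2]], tps[[1]])), collapse = ", ")))
  x
}

#' Write the files of a simulated data set
#'
#' Writes the count (or expression) table, gene lengths, sample sheet and
#' truth table of a [simulate_timecourse()] result as TSV files into a
#' directory.
#'
#' @param sim A `tempo_sim` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim <- function(sim, dir) {
  if (!inherits(sim, "tempo_sim")) stop_config("`sim` must be a tempo_sim.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  main <- if (sim$config$emission == "counts") "counts" else "expression"
  paths[main] <- file.path(dir, paste0(main, ".tsv"))
  readr::write_tsv(sim[[main]], paths[main])
  paths["gene_lengths"] <- file.path(dir, "gene_lengths.tsv")
  readr::write_tsv(sim$gene_lengths, paths["gene_lengths"])
  paths["sample_sheet"] <- file.path(dir, "sample_sheet.tsv")
  readr::write_tsv(sim$sample_sheet, paths["sample_sheet"])
  paths["truth"] <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}

meta_header <- function(kv) {
  vapply(names(kv), function(k)
    sprintf("# %s=%s", k, paste(kv[[k]], collapse = ",")),
    character(1))
}

parse_meta_header <- function(lines) {
  kv <- sub("^# ", "", lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Write profile pairs to a TSV with a metadata header
#'
#' Long format: two rows per gene (one per condition) with the raw and, if
#' available, scaled values at each time point, the pooled variance and the
#' degenerate flag. `# key=value` comment lines carry the time vector,
#' condition labels and scaling state so [read_profiles()] can reconstruct
#' the object.
#'
#' @param pairs A `tempo_profiles` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(pairs, path) {
  check_profiles(pairs)
  tv <- attr(pairs, "time_vector")
  scaled <- isTRUE(attr(pairs, "scaled"))
  conds <- attr(pairs, "conditions")
  n <- nrow(pairs)
  raw_w <- if (scaled) pairs$wt_raw else pairs$wt
  raw_k <- if (scaled) pairs$ko_raw else pairs$ko
  long <- tibble::tibble(
    gene_id = rep(pairs$gene_id, each = 2),
    condition = rep(conds, times = n))
  raw <- matrix(NA_real_, 2 * n, length(tv))
  raw[seq(1, 2 * n, by = 2), ] <- raw_w
  raw[seq(2, 2 * n, by = 2), ] <- raw_k
  colnames(raw) <- paste0("raw_", seq_along(tv))
  long <- dplyr::bind_cols(long, tibble::as_tibble(as.data.frame(raw)))
  if (scaled) {
    sc <- matrix(NA_real_, 2 * n, length(tv))
    sc[seq(1, 2 * n, by = 2), ] <- pairs$wt
    sc[seq(2, 2 * n, by = 2), ] <- pairs$ko
    colnames(sc) <- paste0("scaled_", seq_along(tv))
    long <- dplyr::bind_cols(long, tibble::as_tibble(as.data.frame(sc)))
  }
  long$variance <- rep(pairs$variance, each = 2)
  long$degenerate <- if (scaled) rep(pairs$degenerate, each = 2) else FALSE
  header <- meta_header(list(
    time_vector = tv,
    conditions = conds,
    aggregate = attr(pairs, "aggregate"),
    scaled = scaled))
  writeLines(header, path)
  readr::write_tsv(long, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read profile pairs written by [write_profiles()]
#'
#' @param path Path to a profiles TSV.
#' @return A `tempo_profiles` object.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("input file not found: ", path))
  all_lines <- readLines(path)
  meta_lines <- all_lines[startsWith(all_lines, "# ")]
  meta <- parse_meta_header(meta_lines)
  for (key in c("time_vector", "conditions", "scaled"))
    if (is.null(meta[[key]]))
      stop_parse(paste0(path, ": missing '# ", key, "=' metadata line."))
  tv <- as.numeric(strsplit(meta$time_vector, ",")[[1]])
  conds <- strsplit(meta$conditions, ",")[[1]]
  scaled <- identical(meta$scaled, "TRUE")
  x <- readr::read_tsv(path, comment = "# ", show_col_types = FALSE,
                       progress = FALSE)
  wt_rows <- x$condition == conds[1]
  pick <- function(prefix, rows) {
    as.matrix(x[rows, paste0(prefix, seq_along(tv)), drop = FALSE])
  }
  raw_w <- unname(pick("raw_", wt_rows))
  raw_k <- unname(pick("raw_", !wt_rows))
  df <- tibble::tibble(gene_id = x$gene_id[wt_rows])
  if (scaled) {
    df$wt <- unname(pick("scaled_", wt_rows))
    df$ko <- unname(pick("scaled_", !wt_rows))
    df$wt_raw <- raw_w
    df$ko_raw <- raw_k
  } else {
    df$wt <- raw_w
    df$ko <- raw_k
  }
  df$variance <- x$variance[wt_rows]
  if (scaled) {
    pooled <- cbind(raw_w, raw_k)
    df$e_min <- do.call(pmin, as.data.frame(pooled))
    df$e_max <- do.call(pmax, as.data.frame(pooled))
    df$degenerate <- x$degenerate[wt_rows]
  }
  new_tempo_profiles(df, tv, conds, meta$aggregate %||% "mean",
                     scaled = scaled)
}

#' Write a distance table with its parameter metadata
#'
#' The gene-by-metric table from [compute_distances()] is written as TSV
#' preceded by `# key=value` lines recording the resolved metric parameters,
#' the compressor behind the compression-based measure, and the time vector
#' — everything needed to reproduce the values.
#'
#' @param distances Tibble from [compute_distances()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_distance_table <- function(distances, path) {
  p <- attr(distances, "metric_params")
  kv <- list(time_vector = attr(distances, "time_vector"))
  if (!is.null(p)) {
    kv <- c(kv, unclass(p))
    kv$compressor_backend <- paste0(
      "R memCompress ",
      if (p$cdm_compressor == "lzma") "xz" else "gzip",
      " (R ", getRversion(), ")")
  }
  writeLines(meta_header(kv), path)
  readr::write_tsv(distances, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write the compiled screen table
#'
#' @param screen A `tempo_screen` object from [run_screen()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_screen <- function(screen, path) {
  if (!inherits(screen, "tempo_screen"))
    stop_config("`screen` must be a tempo_screen.")
  readr::write_tsv(screen$result, path)
  invisible(path)
}
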