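# Independent oracle implementations used to verify the package kernels.
# Everything here is deliberately naive (path enumeration, direct formula
# loops) and shares no code with the package internals.

# All monotone warping paths from (1,1) to (n,m); steps down/right/diagonal.
# Returned as two-column index matrices including both endpoints.
enum_warping_paths <- local({
  cache <- new.env(parent = emptyenv())
  function(n, m) {
    key <- paste(n, m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    recurse <- function(i, j) {
      if (i == n && j == m) return(list(matrix(c(i, j), 1)))
      out <- list()
      for (step in list(c(0, 1), c(1, 0), c(1, 1))) {
        ni <- i + step[1]; nj <- j + step[2]
        if (ni <= n && nj <= m)
          for (p in recurse(ni, nj))
            out <- c(out, list(rbind(c(i, j), p)))
      }
      out
    }
    cache[[key]] <- recurse(1, 1)
    cache[[key]]
  }
})

oracle_dtw <- function(x, y) {
  paths <- enum_warping_paths(length(x), length(y))
  min(vapply(paths, function(p) sum(abs(x[p[, 1]] - y[p[, 2]])), numeric(1)))
}

oracle_frechet <- function(x, y) {
  paths <- enum_warping_paths(length(x), length(y))
  min(vapply(paths, function(p) max(abs(x[p[, 1]] - y[p[, 2]])), numeric(1)))
}

# Brute-force cumulative DTW cost to each cell (minimum over enumerated
# partial paths), then the diagonal-preferred backtrack (diagonal, then
# horizontal, then vertical on ties) and the TAM step-count summary.
oracle_tam <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- enum_warping_paths(i, j)
    D[i, j] <- min(vapply(sub, function(p) sum(abs(x[p[, 1]] - y[p[, 2]])),
                          numeric(1)))
  }
  i <- n; j <- m; nd <- nh <- nv <- 0
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1; nh <- nh + 1; next }
    if (j == 1) { i <- i - 1; nv <- nv + 1; next }
    dg <- D[i - 1, j - 1]; lf <- D[i, j - 1]; up <- D[i - 1, j]
    best <- min(dg, lf, up)
    if (dg == best) { i <- i - 1; j <- j - 1; nd <- nd + 1 }
    else if (lf == best) { j <- j - 1; nh <- nh + 1 }
    else { i <- i - 1; nv <- nv + 1 }
  }
  p <- nd + nh + nv
  if (p == 0) 0 else nh / p + nv / p + (1 - nd / p)
}

# Direct-formula oracles.
oracle_euclidean <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s)
}

oracle_sts <- function(x, y, tv) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    sx <- (x[i + 1] - x[i]) / (tv[i + 1] - tv[i])
    sy <- (y[i + 1] - y[i]) / (tv[i + 1] - tv[i])
    s <- s + (sy - sx)^2
  }
  sqrt(s)
}

oracle_acf_vec <- function(z, max_lag) {
  n <- length(z); mu <- mean(z)
  den <- sum((z - mu)^2)
  if (den == 0) return(rep(0, max_lag))
  vapply(seq_len(max_lag), function(k)
    sum((z[1:(n - k)] - mu) * (z[(k + 1):n] - mu)) / den, numeric(1))
}

oracle_dft <- function(z) {
  n <- length(z)
  vapply(0:(n - 1), function(k)
    sum(z * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

oracle_periodogram <- function(z, n_freq) {
  X <- oracle_dft(z)
  Mod(X[1 + seq_len(n_freq)])^2 / length(z)
}

oracle_per <- function(x, y, n_freq) {
  sqrt(sum((oracle_periodogram(x, n_freq) -
              oracle_periodogram(y, n_freq))^2))
}

# Independent end-to-end screen: aggregation, variance filter, joint minmax
# scaling, all 12 metrics by direct formulas, rank p-values and flags.
oracle_metric_row <- function(x, y, tv) {
  n <- length(x)
  K <- floor(n / 2)
  Px <- oracle_periodogram(x, K); Py <- oracle_periodogram(y, K)
  Fx <- if (sum(Px) > 49 * .Machine$double.eps) cumsum(Px) / sum(Px) else seq_len(K) / K
  Fy <- if (sum(Py) > 49 * .Machine$double.eps) cumsum(Py) / sum(Py) else seq_len(K) / K
  ce <- function(z) sqrt(sum(diff(z)^2))
  rho <- if (sd(x) > 0 && sd(y) > 0) cor(x, y) else 0
  qz <- function(z) as.raw(pmin(floor(pmin(pmax(z, 0), 1) * 8), 7))
  cs <- function(b) length(memCompress(b, "xz"))
  bx <- qz(x); by <- qz(y)
  eu <- oracle_euclidean(x, y)
  c(euclidean = eu,
    sts = oracle_sts(x, y, tv),
    dtw = {  # naive DP written out again, independent of src/
      D <- matrix(Inf, n, n)
      for (i in 1:n) for (j in 1:n) {
        cc <- abs(x[i] - y[j])
        pr <- if (i == 1 && j == 1) 0 else
          min(if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf,
              if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
        D[i, j] <- cc + pr
      }
      D[n, n]
    },
    tam = {
      D <- matrix(Inf, n, n)
      for (i in 1:n) for (j in 1:n) {
        cc <- abs(x[i] - y[j])
        pr <- if (i == 1 && j == 1) 0 else
          min(if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf,
              if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
        D[i, j] <- cc + pr
      }
      i <- n; j <- n; nd <- nh <- nv <- 0
      while (i > 1 || j > 1) {
        if (i == 1) { j <- j - 1; nh <- nh + 1; next }
        if (j == 1) { i <- i - 1; nv <- nv + 1; next }
        b <- min(D[i - 1, j - 1], D[i, j - 1], D[i - 1, j])
        if (D[i - 1, j - 1] == b) { i <- i - 1; j <- j - 1; nd <- nd + 1 }
        else if (D[i, j - 1] == b) { j <- j - 1; nh <- nh + 1 }
        else { i <- i - 1; nv <- nv + 1 }
      }
      p <- nd + nh + nv
      nh / p + nv / p + (1 - nd / p)
    },
    acf = sqrt(sum((oracle_acf_vec(x, n - 2) -
                      oracle_acf_vec(y, n - 2))^2)),
    fourier = sqrt(sum(Mod(oracle_dft(x)[1:(K + 1)] -
                             oracle_dft(y)[1:(K + 1)])^2)),
    cdm = (cs(c(bx, by)) + cs(c(by, bx))) / (2 * (cs(bx) + cs(by))),
    cid = eu * (max(ce(x), ce(y)) + 1e-12) / (min(ce(x), ce(y)) + 1e-12),
    cor = sqrt(max(0, 2 * (1 - rho))),
    per = oracle_per(x, y, K),
    int.per = sum(abs(Fx - Fy)),
    frechet = {
      D <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) {
        cc <- abs(x[i] - y[j])
        pr <- if (i == 1 && j == 1) 0 else
          min(if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf,
              if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
        D[i, j] <- max(cc, pr)
      }
      D[n, n]
    })
}

oracle_screen <- function(expression, sheet, alpha = 0.01, threshold = 0.1) {
  genes <- expression$gene_id
  m <- as.matrix(expression[, -1])
  tv <- sort(unique(sheet$timepoint))
  agg <- function(cond) vapply(tv, function(t) {
    cols <- sheet$sample_id[sheet$condition == cond & sheet$timepoint == t]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  W <- agg("WT"); K <- agg("KO")
  v <- apply(cbind(W, K), 1, var)
  keep <- v > threshold
  W <- W[keep, , drop = FALSE]; K <- K[keep, , drop = FALSE]
  lo <- pmin(apply(W, 1, min), apply(K, 1, min))
  hi <- pmax(apply(W, 1, max), apply(K, 1, max))
  Ws <- (W - lo) / (hi - lo); Ks <- (K - lo) / (hi - lo)
  D <- t(vapply(seq_len(nrow(Ws)),
                function(g) oracle_metric_row(Ws[g, ], Ks[g, ], tv),
                numeric(12)))
  P <- apply(D, 2, function(d) vapply(d, function(x) mean(d >= x),
                                      numeric(1)))
  flags <- P <= alpha
  list(gene_id = genes[keep], distances = D, pvalues = P, flags = flags,
       n_sig = rowSums(flags))
}

random_pair <- function(t_len) {
  list(x = runif(t_len), y = runif(t_len))
}
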