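# Residual autocorrelation diagnostics: per-bird temporal ACF and a
# distance-binned (Moran-type) spatial correlogram with permutation
# envelopes.

#' Per-bird temporal autocorrelation of model residuals
#'
#' Standard sample autocorrelation ([stats::acf()]) computed per bird on
#' chronologically ordered residuals and averaged across birds with weights
#' proportional to series length. Lags are in fix index, not wall-clock
#' time. Series shorter than 3 or with zero variance are skipped and
#' counted. The null envelope is +/- 1.96/sqrt(n) with n the total length of
#' the usable series.
#'
#' @param residuals Numeric residual vector.
#' @param bird_id Bird identifier per residual.
#' @param max_lag Largest lag; default 20.
#' @return Data frame with `lag`, `acf`, `n_series`; attributes `envelope`
#'   (numeric) and `n_skipped`.
#' @export
temporal_acf <- function(residuals, bird_id, max_lag = 20) {
  stopifnot(length(residuals) == length(bird_id))
  by_bird <- split(residuals, bird_id)
  usable <- list()
  n_skipped <- 0L
  for (s in by_bird) {
    if (length(s) < 3 || stats::sd(s) == 0) {
      n_skipped <- n_skipped + 1L
    } else {
      usable[[length(usable) + 1]] <- s
    }
  }
  if (length(usable) == 0) {
    stop("no usable residual series (all shorter than 3 or constant)",
         call. = FALSE)
  }
  n_total <- sum(lengths(usable))
  acc <- matrix(NA_real_, nrow = length(usable), ncol = max_lag)
  w <- lengths(usable)
  for (i in seq_along(usable)) {
    s <- usable[[i]]
    ml <- min(max_lag, length(s) - 1)
    a <- stats::acf(s, lag.max = ml, plot = FALSE)$acf[-1]
    acc[i, seq_len(ml)] <- a
  }
  avg <- vapply(seq_len(max_lag), function(l) {
    ok <- !is.na(acc[, l])
    if (!any(ok)) return(NA_real_)
    sum(acc[ok, l] * w[ok]) / sum(w[ok])
  }, numeric(1))
  nser <- vapply(seq_len(max_lag), function(l) sum(!is.na(acc[, l])),
                 integer(1))
  out <- data.frame(lag = seq_len(max_lag), acf = avg, n_series = nser)
  attr(out, "envelope") <- 1.96 / sqrt(n_total)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Distance-binned spatial correlogram of model residuals
#'
#' Moran-type correlation of residual pairs per distance class: with
#' centered residuals `z`, the bin statistic is
#' `mean(z_i * z_j over pairs in the bin) / (sum(z^2)/n)`. Pair distances
#' are great-circle. The 95% null envelope per bin comes from permutations
#' of the residuals over the locations (199 by default). Bins with fewer
#' than 30 pairs are flagged low-count.
#'
#' @param residuals Numeric residual vector.
#' @param lon,lat Locations, degrees.
#' @param bin_width Bin width in meters; default 250.
#' @param max_distance Largest pair distance considered, meters; default
#'   3000.
#' @param n_perm Number of permutations for the envelope; default 199.
#' @param seed Seed for the permutations (mandatory).
#' @return Data frame of class `spatial_correlogram` with `bin_center`,
#'   `correlation`, `n_pairs`, `lower`, `upper`, `low_count`.
#' @export
spatial_correlogram <- function(residuals, lon, lat, bin_width = 250,
                                max_distance = 3000, n_perm = 199, seed) {
  n <- length(residuals)
  stopifnot(length(lon) == n, length(lat) == n)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(seed)
  # all pairs i < j within max_distance
  ii <- jj <- integer(0)
  dd <- numeric(0)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    d <- great_circle_distance(lat[i], lon[i], lat[js], lon[js])
    keep <- d <= max_distance
    ii <- c(ii, rep.int(i, sum(keep)))
    jj <- c(jj, js[keep])
    dd <- c(dd, d[keep])
  }
  if (length(dd) == 0) {
    stop("no point pairs within 'max_distance'", call. = FALSE)
  }
  bin <- pmin(floor(dd / bin_width), ceiling(max_distance / bin_width) - 1)
  bins <- sort(unique(bin))
  z <- residuals - mean(residuals)
  denom <- sum(z^2) / n
  if (denom == 0) stop("residuals have zero variance", call. = FALSE)
  cross <- z[ii] * z[jj]
  obs <- rowsum(cross, bin)[, 1] / tabulate(bin + 1L)[bins + 1L] / denom
  counts <- as.integer(tabulate(bin + 1L)[bins + 1L])
  perm <- matrix(NA_real_, n_perm, length(bins))
  for (p in seq_len(n_perm)) {
    zp <- sample(z)
    cr <- zp[ii] * zp[jj]
    perm[p, ] <- rowsum(cr, bin)[, 1] / counts / denom
  }
  env <- apply(perm, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(
    bin_center = (bins + 0.5) * bin_width,
    correlation = as.numeric(obs),
    n_pairs = counts,
    lower = env[1, ],
    upper = env[2, ],
    low_count = counts < 30
  )
  class(out) <- c("spatial_correlogram", "data.frame")
  out
}
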