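#' Sobol sensitivity indices by Saltelli sampling
#'
#' First-order (S1) and total-order (ST) variance-based sensitivity
#' indices of a scalar model over independent uniformly distributed
#' inputs, using the Saltelli design (A, B and the k radial A_B^(i)
#' matrices; `base_n * (k + 2)` model evaluations) with the Saltelli-2010
#' S1 estimator and the Jansen ST estimator, plus bootstrap confidence
#' intervals over the base sample.
#'
#' @param parameter_ranges named list of `c(min, max)` ranges.
#' @param model function taking a named numeric vector (one point) and
#'   returning a scalar; or, if `vectorized = TRUE`, a function of a
#'   matrix (rows = points) returning a vector.
#' @param base_n base sample size (>= 64 recommended).
#' @param seed RNG seed.
#' @param n_boot bootstrap replicates for the CIs.
#' @param conf confidence level.
#' @param vectorized whether `model` accepts a matrix of points.
#' @return object of class `sobol_result`: data.frame `indices` with
#'   columns `parameter`, `S1`, `S1_lo`, `S1_hi`, `ST`, `ST_lo`, `ST_hi`,
#'   plus `base_n` and total evaluations `n_eval`.
#' @export
sobol_sensitivity <- function(parameter_ranges, model, base_n = 256, seed = 1,
                              n_boot = 200, conf = 0.95, vectorized = FALSE) {
  k <- length(parameter_ranges)
  stopifnot(k >= 2, base_n >= 8)
  pn <- names(parameter_ranges)
  if (is.null(pn) || any(pn == "")) stop("parameter_ranges must be named")
  set.seed(seed)
  lo <- vapply(parameter_ranges, `[`, numeric(1), 1)
  hi <- vapply(parameter_ranges, `[`, numeric(1), 2)
  scale_mat <- function(u) sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  A <- scale_mat(matrix(stats::runif(base_n * k), base_n, k,
                        dimnames = list(NULL, pn)))
  B <- scale_mat(matrix(stats::runif(base_n * k), base_n, k,
                        dimnames = list(NULL, pn)))
  evalm <- function(m) {
    if (vectorized) as.numeric(model(m))
    else apply(m, 1, function(row) model(stats::setNames(row, pn)))
  }
  fA <- evalm(A)
  fB <- evalm(B)
  fAB <- matrix(NA_real_, base_n, k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fAB[, i] <- evalm(ABi)
  }
  est <- function(idx) {
    fa <- fA[idx]; fb <- fB[idx]; fab <- fAB[idx, , drop = FALSE]
    v <- stats::var(c(fa, fb))
    s1 <- vapply(seq_len(k), function(i) mean(fb * (fab[, i] - fa)) / v,
                 numeric(1))
    st <- vapply(seq_len(k), function(i) 0.5 * mean((fa - fab[, i])^2) / v,
                 numeric(1))
    c(s1, st)
  }
  full <- est(seq_len(base_n))
  boot <- replicate(n_boot, est(sample.int(base_n, base_n, replace = TRUE)))
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  indices <- data.frame(parameter = pn,
                        S1 = full[seq_len(k)],
                        S1_lo = ci[1, seq_len(k)], S1_hi = ci[2, seq_len(k)],
                        ST = full[k + seq_len(k)],
                        ST_lo = ci[1, k + seq_len(k)],
                        ST_hi = ci[2, k + seq_len(k)],
                        stringsAsFactors = FALSE)
  structure(list(indices = indices, base_n = base_n,
                 n_eval = base_n * (k + 2), conf = conf),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> %d parameters, base n = %d (%d evaluations)\n",
              nrow(x$indices), x$base_n, x$n_eval))
  print(x$indices, digits = 3)
  invisible(x)
}
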