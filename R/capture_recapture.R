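# Capture-recapture population-size estimators over the merged-peak
# frequency spectrum. Peak callers play the role of capture occasions: a
# true binding site "captured" k times appears as a merged peak of
# frequency k, and the unseen mass f0 (sites no caller found) is estimated
# from the low-order frequencies f1, f2, f3. The expected true peak count
# is the mean of the estimators that are defined on a given spectrum.

pop_estimate <- function(estimator, S, f0_hat = NA_real_, lambda_hat = NA_real_,
                         N_hat = NULL, defined = TRUE) {
  if (is.null(N_hat)) N_hat <- S + f0_hat
  structure(list(estimator = estimator, N_hat = N_hat, f0_hat = f0_hat,
                 lambda_hat = lambda_hat, S = S, defined = defined),
            class = "pop_estimate")
}

undefined_estimate <- function(estimator, S, reason) {
  out <- pop_estimate(estimator, S, N_hat = NA_real_, defined = FALSE)
  out$reason <- reason
  out
}

#' @export
print.pop_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("%s: N_hat = %.4f (S = %d, f0_hat = %.4f)\n",
                x$estimator, x$N_hat, x$S, x$f0_hat))
  else
    cat(sprintf("%s: undefined (%s)\n", x$estimator, x$reason))
  invisible(x)
}

#' Chao's lower-bound population-size estimator
#'
#' `f0_hat = f1^2 / (2 f2)`; when `f2 = 0` the bias-corrected form
#' `f1 (f1 - 1) / (2 (f2 + 1))` is used. `N_hat = S + f0_hat`.
#'
#' @param spectrum A `freq_spectrum`.
#' @return A `pop_estimate`.
#' @export
chao_estimate <- function(spectrum) {
  S <- spectrum$S
  stopifnot(S >= 1)
  f1 <- spectrum_f(spectrum, 1)
  f2 <- spectrum_f(spectrum, 2)
  f0 <- if (f2 > 0) f1^2 / (2 * f2) else f1 * (f1 - 1) / (2 * (f2 + 1))
  pop_estimate("chao", S, f0_hat = f0)
}

#' Zelterman's estimator
#'
#' Poisson rate from the ratio of doubletons to singletons,
#' `lambda_hat = 2 f2 / f1`, then `N_hat = S / (1 - exp(-lambda_hat))`.
#' Undefined when `f1 = 0` or `f2 = 0`.
#'
#' @inheritParams chao_estimate
#' @return A `pop_estimate`.
#' @export
zelterman_estimate <- function(spectrum) {
  S <- spectrum$S
  stopifnot(S >= 1)
  f1 <- spectrum_f(spectrum, 1)
  f2 <- spectrum_f(spectrum, 2)
  if (f1 == 0 || f2 == 0)
    return(undefined_estimate("zelterman", S, "requires f1 > 0 and f2 > 0"))
  lam <- 2 * f2 / f1
  N <- S / (1 - exp(-lam))
  pop_estimate("zelterman", S, f0_hat = N - S, lambda_hat = lam, N_hat = N)
}

#' Zero-truncated-Poisson maximum-likelihood estimator
#'
#' Solves `lambda / (1 - exp(-lambda)) = mean capture count` by bisection on
#' `(1e-8, 50]` to absolute tolerance `1e-9`, then
#' `N_hat = S / (1 - exp(-lambda_hat))`. Undefined when the mean capture
#' count is <= 1 (all singletons: lambda -> 0, N unbounded).
#'
#' @inheritParams chao_estimate
#' @return A `pop_estimate`.
#' @export
mle_ztp_estimate <- function(spectrum) {
  S <- spectrum$S
  stopifnot(S >= 1)
  mbar <- spectrum$total / S
  if (mbar <= 1)
    return(undefined_estimate("mle_ztp", S, "mean capture count <= 1"))
  g <- function(lam) lam / (1 - exp(-lam))   # strictly increasing, g(0+) = 1
  lo <- 1e-8; hi <- 50
  if (g(hi) < mbar)
    return(undefined_estimate("mle_ztp", S, "mean capture count out of range"))
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (g(mid) < mbar) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  N <- S / (1 - exp(-lam))
  pop_estimate("mle_ztp", S, f0_hat = N - S, lambda_hat = lam, N_hat = N)
}

#' Chapman's two-source population-size estimator
#'
#' `N_hat = (n1 + 1)(n2 + 1)/(m + 1) - 1` for two capture sources with
#' `n1`, `n2` captures and `m` recaptures (seen by both).
#'
#' @param n1,n2 Number of peaks from each of the two callers (merged-peak
#'   presence counts).
#' @param m Number of merged peaks both callers contributed to.
#' @return A `pop_estimate`.
#' @export
chapman_estimate <- function(n1, n2, m) {
  stopifnot(n1 >= 0, n2 >= 0, m >= 0, m <= min(n1, n2))
  N <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
  S <- n1 + n2 - m
  pop_estimate("chapman", S, f0_hat = N - S, N_hat = N)
}

#' Chapman estimate generalised to more than two callers
#'
#' For K callers, the unweighted mean of the two-source Chapman estimates
#' over all K(K-1)/2 caller pairs, computed from a merged-peak presence
#' matrix.
#'
#' @param presence Logical matrix (merged peaks x callers) from
#'   [caller_presence()].
#' @return A `pop_estimate` (estimator `"chapman"`).
#' @export
chapman_from_presence <- function(presence) {
  K <- ncol(presence)
  S <- nrow(presence)
  if (K < 2)
    return(undefined_estimate("chapman", S, "requires >= 2 callers"))
  pairs <- combn(K, 2)
  ests <- apply(pairs, 2, function(p) {
    n1 <- sum(presence[, p[1]])
    n2 <- sum(presence[, p[2]])
    m <- sum(presence[, p[1]] & presence[, p[2]])
    chapman_estimate(n1, n2, m)$N_hat
  })
  pop_estimate("chapman", S, f0_hat = mean(ests) - S, N_hat = mean(ests))
}

#' Lanumteang-Boehning estimator
#'
#' Third-order extension of Chao's estimator using the first three frequency
#' counts: `f0_hat = f1^2/(2 f2) * (3 f1 f3)/(2 f2^2) = 3 f1^3 f3 / (4 f2^3)`.
#' The correction factor equals 1 under homogeneous Poisson captures (where
#' it reduces to Chao) and exceeds 1 under heterogeneity. Undefined when
#' `f1`, `f2` or `f3` is 0.
#'
#' @inheritParams chao_estimate
#' @return A `pop_estimate`.
#' @export
lanumteang_bohning_estimate <- function(spectrum) {
  S <- spectrum$S
  stopifnot(S >= 1)
  f1 <- spectrum_f(spectrum, 1)
  f2 <- spectrum_f(spectrum, 2)
  f3 <- spectrum_f(spectrum, 3)
  if (f1 == 0 || f2 == 0 || f3 == 0)
    return(undefined_estimate("lanumteang_bohning", S,
                              "requires f1, f2, f3 > 0"))
  f0 <- 3 * f1^3 * f3 / (4 * f2^3)
  pop_estimate("lanumteang_bohning", S, f0_hat = f0)
}

#' Expected true peak count: mean of the defined estimators
#'
#' Runs Chao, Lanumteang-Boehning, Zelterman and the zero-truncated-Poisson
#' MLE on the spectrum (plus Chapman when a presence matrix is supplied)
#' and averages the `N_hat` of those that are defined; undefined estimators
#' are excluded rather than imputed.
#'
#' @param spectrum A `freq_spectrum` with `S >= 1`.
#' @param presence Optional logical presence matrix for the Chapman
#'   estimator; see [caller_presence()].
#' @return List with `mean` (the expected peak count) and `estimates`
#'   (named list of `pop_estimate` objects, including undefined ones).
#' @export
expected_peak_count <- function(spectrum, presence = NULL) {
  stopifnot(spectrum$S >= 1)
  ests <- list(
    chao = chao_estimate(spectrum),
    lanumteang_bohning = lanumteang_bohning_estimate(spectrum),
    zelterman = zelterman_estimate(spectrum),
    mle_ztp = mle_ztp_estimate(spectrum))
  if (!is.null(presence))
    ests$chapman <- chapman_from_presence(presence)
  vals <- vapply(ests, function(e) if (e$defined) e$N_hat else NA_real_,
                 numeric(1))
  if (all(is.na(vals)))
    stop("all population-size estimators are undefined on this spectrum; ",
         "fall back to the observed merged-peak count S = ", spectrum$S)
  list(mean = mean(vals, na.rm = TRUE), estimates = ests)
}
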