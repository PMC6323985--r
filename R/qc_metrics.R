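# ENCODE-standard ChIP-seq quality metrics (NRF, PBC1/2, NSC, RSC, FRiP)
# plus the capture-recapture control metrics FNCM and FPCM.

#' False Negative Control Metric
#'
#' Ratio of the number of peaks a caller reported to the capture-recapture
#' expected number of true peaks. Values well below 1 indicate the caller
#' missed peaks.
#'
#' @param observed_peaks Number of peaks in the caller's set (>= 0).
#' @param expected_n Expected true peak count (> 0), e.g. from
#'   [expected_peak_count()].
#' @return `observed_peaks / expected_n`.
#' @export
fncm <- function(observed_peaks, expected_n) {
  stopifnot(observed_peaks >= 0)
  if (!is.finite(expected_n) || expected_n <= 0)
    stop("expected peak count must be positive and finite")
  observed_peaks / expected_n
}

#' False Positive Control Metric
#'
#' Under homogeneous Poisson captures with rate `lambda_hat` and population
#' size `N_hat`, the expected number of unit-frequency merged peaks is
#' `N_hat * lambda_hat * exp(-lambda_hat)` (Poisson pmf at 1 times the
#' population size). FPCM is the observed f1 over this expectation; values
#' well above 1 flag an excess of caller-specific singletons (false
#' positives).
#'
#' @param spectrum A `freq_spectrum` (supplies the observed f1).
#' @param lambda_hat Poisson capture rate (> 0), typically Zelterman's.
#' @param n_hat Estimated population size (> 0).
#' @return Observed over expected unit-frequency merged peak count.
#' @export
fpcm <- function(spectrum, lambda_hat, n_hat) {
  stopifnot(lambda_hat > 0, n_hat > 0)
  f1_obs <- spectrum_f(spectrum, 1)
  expected_f1 <- n_hat * lambda_hat * exp(-lambda_hat)
  if (expected_f1 <= 0) stop("expected unit-frequency count is zero")
  f1_obs / expected_f1
}

tag_keys <- function(tags) paste(tags$chrom, tags$pos5, tags$strand)

#' Non-Redundancy Fraction
#'
#' Distinct (chrom, pos5, strand) triples over total tags.
#'
#' @param tags Tag data frame (`chrom`, `pos5`, `strand`).
#' @return Real in `(0, 1]`.
#' @export
nrf <- function(tags) {
  validate_tags(tags)
  if (nrow(tags) == 0) stop("no tags")
  length(unique(tag_keys(tags))) / nrow(tags)
}

#' PCR Bottlenecking Coefficients 1 and 2
#'
#' With M1 the number of genomic positions carrying exactly one tag and M2
#' exactly two: `PBC1 = M1 / M_distinct`, `PBC2 = M1 / M2` (`Inf` when
#' `M2 = 0`).
#'
#' @inheritParams nrf
#' @return Named list `pbc1`, `pbc2`.
#' @export
pbc <- function(tags) {
  validate_tags(tags)
  if (nrow(tags) == 0) stop("no tags")
  counts <- table(tag_keys(tags))
  m1 <- sum(counts == 1)
  m2 <- sum(counts == 2)
  list(pbc1 = m1 / length(counts),
       pbc2 = if (m2 == 0) Inf else m1 / m2)
}

#' Fraction of Reads in Peaks
#'
#' A tag is "in peaks" when its 5' position lies inside any peak interval
#' (half-open containment).
#'
#' @inheritParams nrf
#' @param peaks Interval data frame (`chrom`, `start`, `end`).
#' @return Real in `[0, 1]`.
#' @export
frip <- function(tags, peaks) {
  validate_tags(tags)
  if (nrow(tags) == 0) stop("no tags")
  if (nrow(peaks) == 0) return(0)
  tag_gr <- GenomicRanges::GRanges(tags$chrom,
                                   IRanges::IRanges(tags$pos5 + 1L, tags$pos5 + 1L))
  peak_gr <- peaks_to_granges(peaks)
  hit <- IRanges::overlapsAny(tag_gr, peak_gr)
  mean(hit)
}

#' Strand cross-correlation profile, NSC and RSC
#'
#' For each shift d in `0..max_shift`, the Pearson correlation between the
#' per-position 5'-start count vectors of the + strand and the - strand
#' shifted left by d, computed per chromosome over the span covered by tags
#' and combined across chromosomes by a span-length-weighted average. The
#' profile peaks near the fragment length; a secondary "phantom" peak sits
#' at the read length.
#'
#' `cc_frag` is the profile maximum outside a +/- 5 bp exclusion zone around
#' the read length; `cc_read` the value at the read length; `cc_min` the
#' profile minimum. `NSC = cc_frag / cc_min`;
#' `RSC = (cc_frag - cc_min) / (cc_read - cc_min)`.
#'
#' @inheritParams nrf
#' @param max_shift Largest shift evaluated (>= read_length).
#' @param read_length Read length in bp (location of the phantom peak).
#' @return List with `profile` (data frame `shift`, `cc`), `nsc`, `rsc`,
#'   `cc_frag`, `cc_read`, `cc_min`, and `fragment_length` (argmax shift
#'   outside the exclusion zone).
#' @export
cross_correlation <- function(tags, max_shift = 400L, read_length = 36L) {
  validate_tags(tags)
  if (!all(c("+", "-") %in% tags$strand))
    stop("cross-correlation requires tags on both strands")
  if (max_shift < read_length) stop("max_shift must be >= read_length")
  shifts <- 0:max_shift
  total <- numeric(length(shifts))
  wsum <- 0
  for (chrom in unique(tags$chrom)) {
    t <- tags[tags$chrom == chrom, ]
    if (!all(c("+", "-") %in% t$strand)) next
    lo <- min(t$pos5); hi <- max(t$pos5)
    n <- hi - lo + 1L
    if (n <= max_shift + 2L) next
    plus <- tabulate(t$pos5[t$strand == "+"] - lo + 1L, nbins = n)
    minus <- tabulate(t$pos5[t$strand == "-"] - lo + 1L, nbins = n)
    cc <- vapply(shifts, function(d) {
      a <- plus[1:(n - d)]
      b <- minus[(1 + d):n]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    if (all(is.na(cc))) next
    cc[is.na(cc)] <- 0
    total <- total + n * cc
    wsum <- wsum + n
  }
  if (wsum == 0) stop("no chromosome with usable two-strand coverage")
  cc <- total / wsum
  if (all(cc == cc[1])) stop("constant cross-correlation profile (zero variance)")
  excl <- abs(shifts - read_length) <= 5L
  cc_frag <- max(cc[!excl])
  frag_len <- shifts[!excl][which.max(cc[!excl])]
  cc_read <- cc[shifts == read_length]
  cc_min <- min(cc)
  list(profile = data.frame(shift = shifts, cc = cc),
       nsc = cc_frag / cc_min,
       rsc = (cc_frag - cc_min) / (cc_read - cc_min),
       cc_frag = cc_frag, cc_read = cc_read, cc_min = cc_min,
       fragment_length = frag_len)
}

#' Assemble the full QC report for one experiment
#'
#' Combines the ENCODE metrics with the capture-recapture controls: peaks
#' from all callers are merged, the frequency spectrum feeds the
#' population-size estimators, FNCM is computed per caller against the
#' averaged expected peak count, and FPCM uses Zelterman's lambda (falling
#' back to the zero-truncated-Poisson MLE when Zelterman is undefined).
#' FRiP is computed against the merged peak intervals.
#'
#' @param tags Tag data frame; `NULL` skips the tag-based metrics.
#' @param peak_sets Named list of per-caller peak data frames.
#' @param read_length,max_shift Passed to [cross_correlation()].
#' @return List of class `qc_report` with fields `nrf`, `pbc1`, `pbc2`,
#'   `nsc`, `rsc`, `frip`, `fncm` (named per caller), `fpcm`,
#'   `expected_peaks`, `estimates`, `spectrum`.
#' @export
qc_report <- function(tags, peak_sets, read_length = 36L, max_shift = 400L) {
  merged <- merge_peaks(peak_sets)
  spectrum <- frequency_spectrum(merged)
  presence <- caller_presence(merged)
  exp_pk <- expected_peak_count(spectrum, presence)
  fncm_by_caller <- vapply(names(peak_sets), function(cl)
    fncm(nrow(peak_sets[[cl]]), exp_pk$mean), numeric(1))
  lam_src <- exp_pk$estimates$zelterman
  if (!lam_src$defined) lam_src <- exp_pk$estimates$mle_ztp
  fpcm_val <- if (lam_src$defined)
    fpcm(spectrum, lam_src$lambda_hat, exp_pk$mean) else NA_real_
  rep <- list(nrf = NA_real_, pbc1 = NA_real_, pbc2 = NA_real_,
              nsc = NA_real_, rsc = NA_real_, frip = NA_real_,
              fncm = fncm_by_caller, fpcm = fpcm_val,
              expected_peaks = exp_pk$mean,
              estimates = exp_pk$estimates, spectrum = spectrum)
  if (!is.null(tags) && nrow(tags) > 0) {
    rep$nrf <- nrf(tags)
    p <- pbc(tags)
    rep$pbc1 <- p$pbc1; rep$pbc2 <- p$pbc2
    rep$frip <- frip(tags, merged)
    if (all(c("+", "-") %in% tags$strand)) {
      cc <- try(cross_correlation(tags, max_shift = max_shift,
                                  read_length = read_length), silent = TRUE)
      if (!inherits(cc, "try-error")) {
        rep$nsc <- cc$nsc; rep$rsc <- cc$rsc
        rep$fragment_length <- cc$fragment_length
      } else warning("cross-correlation failed: ", attr(cc, "condition")$message)
    } else warning("tags on one strand only; NSC/RSC not computed")
  }
  class(rep) <- "qc_report"
  rep
}

#' Serialise a QC report to JSON
#' @param report A `qc_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report_json <- function(report, path = NULL) {
  est <- lapply(report$estimates, function(e)
    list(estimator = e$estimator, defined = e$defined,
         N_hat = if (e$defined) e$N_hat else NULL,
         lambda_hat = if (is.finite(e$lambda_hat %||% NA_real_)) e$lambda_hat else NULL))
  x <- list(nrf = report$nrf, pbc1 = report$pbc1,
            pbc2 = if (is.infinite(report$pbc2)) "Inf" else report$pbc2,
            nsc = report$nsc, rsc = report$rsc, frip = report$frip,
            fncm = as.list(report$fncm), fpcm = report$fpcm,
            expected_peaks = report$expected_peaks,
            spectrum = list(S = report$spectrum$S,
                            f = as.list(report$spectrum$f)),
            estimators = est)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

`%||%` <- function(a, b) if (is.null(a)) b else a
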