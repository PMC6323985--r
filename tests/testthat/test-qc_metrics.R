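make_tags <- function(pos, strand = NULL, chrom = "chr1") {
  if (is.null(strand)) strand <- rep("+", length(pos))
  data.frame(chrom = rep(chrom, length(pos)), pos5 = as.integer(pos),
             strand = strand, stringsAsFactors = FALSE)
}

test_that("FNCM is the observed/expected peak-count ratio", {
  expect_equal(fncm(80, 100), 0.8)
  expect_equal(fncm(100, 100), 1)
  expect_error(fncm(10, 0), "positive")
  expect_error(fncm(10, -5), "positive")
})

test_that("FPCM compares observed f1 with the Poisson-expected count", {
  sp <- spectrum_from_counts(c("1" = 40, "2" = 30))
  # E[f1] = N * lambda * exp(-lambda) = 100 * 1 * e^-1 = 36.788
  expect_equal(fpcm(sp, lambda_hat = 1, n_hat = 100), 40 / (100 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(round(fpcm(sp, 1, 100), 4), 1.0873)

  # f1 equal to its expectation gives exactly 1
  lam <- 0.7; N <- 200
  f1 <- N * lam * exp(-lam)
  sp2 <- spectrum_from_counts(setNames(c(round(f1), 10), 1:2))
  expect_equal(fpcm(sp2, lam, N), round(f1) / f1)
  expect_error(fpcm(sp, 0, 100))
})

test_that("NRF counts distinct (chrom, pos5, strand) triples", {
  t1 <- make_tags(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2))
  expect_equal(nrf(t1), 0.8)
  expect_equal(nrf(make_tags(1:5)), 1)
  expect_equal(nrf(make_tags(rep(7, 4))), 1 / 4)
  # same position, opposite strands are distinct
  expect_equal(nrf(make_tags(c(5, 5), c("+", "-"))), 1)
  expect_error(nrf(make_tags(integer(0))), "no tags")
})

test_that("PBC1/PBC2 follow the position-multiplicity histogram", {
  # multiset {a x1, b x1, c x2, d x2, e x4}
  t1 <- make_tags(c(1, 2, 3, 3, 4, 4, 5, 5, 5, 5))
  p <- pbc(t1)
  expect_equal(p$pbc1, 2 / 5)
  expect_equal(p$pbc2, 1)

  p_all_single <- pbc(make_tags(1:6))
  expect_equal(p_all_single$pbc1, 1)
  expect_true(is.infinite(p_all_single$pbc2))

  p_all_double <- pbc(make_tags(rep(1:3, each = 2)))
  expect_equal(p_all_double$pbc1, 0)
})

test_that("FRiP counts tags whose 5' position falls inside peaks", {
  peaks <- data.frame(chrom = "chr1", start = c(10L, 50L), end = c(20L, 60L))
  tags <- make_tags(c(10, 15, 19, 55, 20, 49, 60, 100, 3, 70))
  expect_equal(frip(tags, peaks), 0.4)   # 10,15,19,55 in; 20,49,60 out (half-open)
  expect_equal(frip(tags, peaks[0, ]), 0)
  genome_wide <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(frip(tags, genome_wide), 1)
})

test_that("cross-correlation peaks near the fragment length", {
  cfg <- sim_config(seed = 7, genome_length = 60000L, n_true_sites = 60L,
                    fragment_length = 147L, read_length = 36L,
                    frags_per_site = 60L, background_frac = 0.2)
  sim <- simulate_peak_sets(cfg)
  tags <- simulate_tags(cfg, sim$sites)
  cc <- cross_correlation(tags, max_shift = 300L, read_length = 36L)
  expect_lt(abs(cc$fragment_length - 147L), 10.5)
  # the fragment-length peak stands far above the profile noise floor
  expect_gt(cc$cc_frag, 0.05)
  expect_gt(cc$cc_frag, cc$cc_min + 0.05)

  # invariant to tag order and chromosome order
  cc2 <- cross_correlation(tags[rev(seq_len(nrow(tags))), ],
                           max_shift = 300L, read_length = 36L)
  expect_equal(cc2$profile$cc, cc$profile$cc)

  expect_error(cross_correlation(make_tags(1:50)), "both strands")
})

test_that("a phantom population at the read-length shift inflates cc_read", {
  set.seed(8)
  rl <- 36L
  pos <- sort(sample.int(20000, 600))
  base <- rbind(make_tags(pos, rep("+", 600)),
                make_tags(sample.int(20000, 600), rep("-", 600)))
  cc0 <- cross_correlation(base, max_shift = 200L, read_length = rl)
  # duplicate every + tag on the - strand shifted by the read length
  phantom <- rbind(base, make_tags(pos + rl, rep("-", 600)))
  cc1 <- cross_correlation(phantom, max_shift = 200L, read_length = rl)
  expect_gt(cc1$cc_read, cc0$cc_read + 0.1)
})

test_that("binding signal raises the fragment-length cross-correlation peak", {
  # NSC = cc_frag/cc_min is numerically unstable on synthetic data because
  # cc_min sits at the noise floor around zero and can change sign; the
  # robust signal-strength readout compared here is cc_frag itself.
  cfg_sig <- sim_config(seed = 9, genome_length = 50000L, n_true_sites = 50L,
                        frags_per_site = 80L, background_frac = 0.1)
  sim <- simulate_peak_sets(cfg_sig)
  tags_sig <- simulate_tags(cfg_sig, sim$sites)
  cc_sig <- cross_correlation(tags_sig, max_shift = 300L, read_length = 36L)

  # no-signal data: the two strands are completely independent
  set.seed(10)
  tags_bg <- rbind(make_tags(sample.int(49000, 3000), rep("+", 3000)),
                   make_tags(sample.int(49000, 3000), rep("-", 3000)))
  cc_bg <- cross_correlation(tags_bg, max_shift = 300L, read_length = 36L)
  expect_gt(cc_sig$cc_frag, cc_bg$cc_frag)
  expect_gt(cc_sig$rsc, 1)
})

test_that("qc_report assembles all metrics end to end", {
  cfg <- sim_config(seed = 11, genome_length = 200000L, n_true_sites = 150L,
                    duplicate_rate = 0.2, frags_per_site = 40L)
  sim <- simulate_peak_sets(cfg)
  tags <- simulate_tags(cfg, sim$sites)
  rep <- qc_report(tags, sim$peaks, read_length = 36L, max_shift = 300L)

  for (field in c("nrf", "pbc1", "frip", "fpcm", "expected_peaks"))
    expect_true(is.finite(rep[[field]]), info = field)
  expect_true(is.finite(rep$pbc2) || is.infinite(rep$pbc2))
  expect_length(rep$fncm, 4)
  expect_true(all(is.finite(rep$fncm)))
  expect_true(rep$nrf >= 0 && rep$nrf <= 1)
  expect_true(rep$pbc1 >= 0 && rep$pbc1 <= 1)
  expect_true(rep$frip >= 0 && rep$frip <= 1)

  js <- qc_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$nrf, rep$nrf, tolerance = 1e-12)
  expect_equal(parsed$fpcm, rep$fpcm, tolerance = 1e-12)
  expect_equal(sort(names(parsed$fncm)), sort(names(rep$fncm)))

  # single-strand tags: NSC/RSC absent with a warning, other metrics present
  plus_only <- tags[tags$strand == "+", ]
  expect_warning(rep2 <- qc_report(plus_only, sim$peaks), "one strand")
  expect_true(is.na(rep2$nsc))
  expect_true(is.finite(rep2$nrf))
})
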