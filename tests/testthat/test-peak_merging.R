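test_that("merge_peaks performs single-linkage union of overlaps", {
  sets <- list(A = data.frame(chrom = "chr1", start = 0L, end = 100L),
               B = data.frame(chrom = "chr1", start = 50L, end = 150L),
               C = data.frame(chrom = "chr1", start = 200L, end = 300L))
  m <- merge_peaks(sets)
  expect_equal(m$start, c(0L, 200L))
  expect_equal(m$end, c(150L, 300L))
  expect_equal(m$frequency, c(2L, 1L))
  expect_equal(m$callers[[1]], c("A", "B"))
  expect_equal(m$callers[[2]], "C")

  # frequency counts peaks, not callers: same-caller overlap gives freq 2
  m2 <- merge_peaks(list(A = data.frame(chrom = "chr1",
                                        start = c(0L, 5L), end = c(10L, 15L))))
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$frequency, 2L)
  expect_equal(m2$callers[[1]], "A")
  expect_equal(m2$n_callers, 1L)

  # abutting half-open intervals do NOT merge
  m3 <- merge_peaks(list(A = data.frame(chrom = "chr1", start = 0L, end = 10L),
                         B = data.frame(chrom = "chr1", start = 10L, end = 20L)))
  expect_equal(nrow(m3), 2L)
  expect_true(all(m3$frequency == 1L))

  # chained overlap collapses to one merged peak
  m4 <- merge_peaks(list(A = data.frame(chrom = "chr1", start = 0L, end = 10L),
                         B = data.frame(chrom = "chr1", start = 8L, end = 20L),
                         C = data.frame(chrom = "chr1", start = 18L, end = 30L)))
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$frequency, 3L)
})

test_that("merging equals the connected-components oracle on random inputs", {
  set.seed(11)
  for (i in 1:30) {
    p <- random_peaks(sample(c(5, 40, 200), 1))
    m <- merge_peaks(p)
    o <- brute_merge(p)
    got <- m[, c("chrom", "start", "end", "frequency")]
    rownames(got) <- NULL
    class(got) <- "data.frame"
    expect_equal(got, o)
  }
})

test_that("merging is idempotent, order-invariant and conserves peak count", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_peaks(100)
    m <- merge_peaks(p)
    # idempotence on geometry
    m2 <- merge_peaks(m[, c("chrom", "start", "end")])
    expect_equal(m2[, c("chrom", "start", "end")],
                 m[, c("chrom", "start", "end")], ignore_attr = TRUE)
    # order invariance
    mp <- merge_peaks(p[sample.int(nrow(p)), ])
    expect_equal(mp[, c("chrom", "start", "end", "frequency")],
                 m[, c("chrom", "start", "end", "frequency")],
                 ignore_attr = TRUE)
    # conservation: sum k * f_k equals number of input peaks
    sp <- frequency_spectrum(m)
    expect_equal(sp$total, nrow(p))
    expect_equal(sum(sp$f), sp$S)
  }
})

test_that("frequency spectrum counts merged peaks by constituent frequency", {
  sets <- list(A = data.frame(chrom = "chr1", start = 0L, end = 100L),
               B = data.frame(chrom = "chr1", start = 50L, end = 150L),
               C = data.frame(chrom = "chr1", start = 200L, end = 300L))
  sp <- frequency_spectrum(merge_peaks(sets))
  expect_equal(sp$S, 2L)
  expect_equal(sp$f, c("1" = 1L, "2" = 1L))
  expect_equal(sp$total, 3L)

  # n disjoint singletons
  n <- 7L
  sp1 <- frequency_spectrum(merge_peaks(data.frame(
    chrom = "chr1", start = seq(0, by = 100, length.out = n),
    end = seq(50, by = 100, length.out = n), caller = "A")))
  expect_equal(sp1$f, c("1" = n))

  expect_equal(frequency_spectrum(
    merge_peaks(data.frame(chrom = character(0), start = integer(0),
                           end = integer(0))))$S, 0L)
})

test_that("clusters merge one TF/caller across experiments with provenance", {
  p <- data.frame(chrom = "chr1", start = c(0L, 40L), end = c(100L, 140L),
                  caller = "MACS", experiment_id = c("EXP1", "EXP2"),
                  tf = "CTCF")
  cl <- build_clusters(p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$experiments[[1]], c("EXP1", "EXP2"))

  # single experiment: clusters are the self-merged peaks
  cl1 <- build_clusters(p[1, ])
  expect_equal(cl1$start, 0L)

  p_bad <- p; p_bad$caller <- c("MACS", "GEM")
  expect_error(build_clusters(p_bad), "single caller")
  p_bad2 <- p; p_bad2$tf <- c("CTCF", "MAX")
  expect_error(build_clusters(p_bad2), "single TF")
})

test_that("meta-clusters merge clusters across callers with support filter", {
  macs <- build_clusters(data.frame(chrom = "chr1", start = 0L, end = 100L,
                                    caller = "MACS", experiment_id = "E1",
                                    tf = "CTCF"))
  gem <- build_clusters(data.frame(chrom = "chr1", start = 80L, end = 180L,
                                   caller = "GEM", experiment_id = "E2",
                                   tf = "CTCF"))
  mc <- build_metaclusters(list(MACS = macs, GEM = gem))
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$start, 0L)
  expect_equal(mc$end, 180L)
  expect_equal(mc$callers[[1]], c("GEM", "MACS"))
  expect_equal(mc$experiments[[1]], c("E1", "E2"))

  # min_callers filter drops single-caller meta-clusters
  far <- build_clusters(data.frame(chrom = "chr2", start = 0L, end = 50L,
                                   caller = "GEM", experiment_id = "E3",
                                   tf = "CTCF"))
  mc2 <- build_metaclusters(list(MACS = macs, GEM = far), min_callers = 2)
  expect_equal(nrow(mc2), 0L)

  # identical cluster geometry from four callers
  four <- lapply(1:4, function(i) macs)
  names(four) <- c("MACS", "GEM", "SISSRs", "PICS")
  mc4 <- build_metaclusters(four)
  expect_equal(nrow(mc4), 1L)
  expect_equal(mc4$n_callers, 4L)
  expect_equal(mc4[, c("start", "end")], macs[, c("start", "end")],
               ignore_attr = TRUE)
})

test_that("caller presence matrix reflects contributing callers", {
  sets <- list(A = data.frame(chrom = "chr1", start = c(0L, 200L),
                              end = c(100L, 300L)),
               B = data.frame(chrom = "chr1", start = 50L, end = 150L))
  pres <- caller_presence(merge_peaks(sets))
  expect_equal(dim(pres), c(2L, 2L))
  expect_equal(pres[1, ], c(A = TRUE, B = TRUE))
  expect_equal(pres[2, ], c(A = TRUE, B = FALSE))
})

test_that("merged peaks round-trip to BED with frequency in the score column", {
  sets <- list(A = data.frame(chrom = "chr1", start = 0L, end = 100L),
               B = data.frame(chrom = "chr1", start = 50L, end = 150L))
  f <- withr::local_tempfile(fileext = ".bed")
  write_merged_bed(merge_peaks(sets), f)
  back <- read_bed(f)
  expect_equal(back$score, 2)
  expect_equal(back$name, "A,B")
})
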