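# Synthetic-data generators with the statistical structure the QC
# mathematics assumes: true binding sites captured by callers under a
# homogeneous Poisson (or per-caller Bernoulli) model, caller-specific
# noise peaks, and 5'-start tags whose strand cross-correlation peaks at
# the fragment length. Everything is deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults describe the stated simulation world: four peak callers (MACS,
#' GEM, SISSRs, PICS), 1000 true sites of width 200 bp on a 1 Mb
#' chromosome, Poisson(1.5) capture counts split across callers, 10 bp
#' positional jitter, 180 bp fragments sequenced as 36 bp reads from both
#' ends, 30 fragments per site with a 50% uniform-background fragment
#' fraction.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param genome_length Chromosome length in bp.
#' @param n_true_sites Number of non-overlapping true binding sites.
#' @param capture_model `list(type = "poisson", lambda = ...)` (per-site
#'   capture count, each capture assigned to a random caller) or
#'   `list(type = "bernoulli", p = c(...))` (per-caller detection
#'   probabilities, one peak per detecting caller).
#' @param callers Caller labels.
#' @param noise_rate Per-caller false-peak rate: each caller emits
#'   `Poisson(noise_rate * n_true_sites)` noise peaks at random positions.
#' @param jitter_sd SD (bp) of the Normal positional jitter on detected
#'   peak starts and of the width noise.
#' @param peak_width True site / peak width in bp.
#' @param fragment_length,read_length Fragment and read lengths in bp
#'   (fragment must exceed read).
#' @param duplicate_rate Fraction of tags duplicated (PCR duplicates).
#' @param frags_per_site Sequenced fragments per true site.
#' @param background_frac Background fragments as a fraction of signal
#'   fragments.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6L,
                       n_true_sites = 1000L,
                       capture_model = list(type = "poisson", lambda = 1.5),
                       callers = c("MACS", "GEM", "SISSRs", "PICS"),
                       noise_rate = 0,
                       jitter_sd = 10,
                       peak_width = 200L,
                       fragment_length = 180L,
                       read_length = 36L,
                       duplicate_rate = 0,
                       frags_per_site = 30L,
                       background_frac = 0.5) {
  stopifnot(genome_length >= 100, n_true_sites >= 1, noise_rate >= 0,
            jitter_sd >= 0, fragment_length > read_length,
            duplicate_rate >= 0, duplicate_rate <= 1)
  if (capture_model$type == "bernoulli" &&
      length(capture_model$p) != length(callers))
    stop("bernoulli capture model needs one probability per caller")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome sequence
#'
#' I.i.d. ACGT, with optional planted exact repeats (a segment copied
#' elsewhere, creating long minimal-unique-lengths) and an optional N run.
#'
#' @param config A `sim_config` (supplies seed and genome_length).
#' @param repeat_length Length of the planted repeat (0 = none); the
#'   segment at one random location is copied to a second.
#' @param n_run_length Length of a planted N run (0 = none).
#' @param chrom Chromosome name.
#' @return Named character vector of length 1 (the genome).
#' @export
simulate_genome <- function(config, repeat_length = 0L, n_run_length = 0L,
                            chrom = "chrSim") {
  set.seed(config$seed)
  n <- as.integer(config$genome_length)
  bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (repeat_length > 0) {
    if (2L * repeat_length + 2L > n) stop("repeat too long for genome")
    src <- sample.int(n %/% 2L - repeat_length, 1L)
    dst <- n %/% 2L + sample.int(n %/% 2L - repeat_length, 1L)
    bases[dst:(dst + repeat_length - 1L)] <- bases[src:(src + repeat_length - 1L)]
  }
  if (n_run_length > 0) {
    at <- sample.int(n - n_run_length, 1L)
    bases[at:(at + n_run_length - 1L)] <- "N"
  }
  setNames(paste(bases, collapse = ""), chrom)
}

place_sites <- function(config) {
  w <- config$peak_width
  gap <- w            # inter-site gap >> jitter keeps detections cluster-pure
  n <- config$n_true_sites
  slack <- config$genome_length - n * (w + gap)
  if (slack < 0)
    stop("cannot place ", n, " non-overlapping sites; use a larger genome")
  starts <- sort(runif(n, 0, slack)) + (seq_len(n) - 1L) * (w + gap)
  starts <- as.integer(floor(starts))
  data.frame(chrom = "chrSim", start = starts, end = starts + w,
             stringsAsFactors = FALSE)
}

#' Simulate true sites and per-caller peak sets
#'
#' True sites are placed without overlap; each is "captured" under the
#' configured model. Under the Poisson model a site's capture count is
#' Poisson(lambda) and each capture becomes one peak assigned to a caller
#' uniformly at random, so the merged-peak frequency of a detected site is
#' exactly its Poisson count. Detected peaks get Normal positional jitter
#' and width noise; each caller additionally emits
#' Poisson(noise_rate * n_true_sites) false peaks at uniform positions.
#'
#' @param config A `sim_config`.
#' @return List: `sites` (truth intervals), `peaks` (named list of
#'   per-caller peak data frames), `capture_counts` (per-site counts).
#' @export
simulate_peak_sets <- function(config) {
  set.seed(config$seed)
  sites <- place_sites(config)
  n <- nrow(sites)
  K <- length(config$callers)
  cm <- config$capture_model
  site_idx <- integer(0)
  caller_idx <- integer(0)
  if (cm$type == "poisson") {
    counts <- rpois(n, cm$lambda)
    site_idx <- rep(seq_len(n), counts)
    caller_idx <- sample.int(K, length(site_idx), replace = TRUE)
  } else if (cm$type == "bernoulli") {
    for (k in seq_len(K)) {
      det <- which(runif(n) < cm$p[k])
      site_idx <- c(site_idx, det)
      caller_idx <- c(caller_idx, rep(k, length(det)))
    }
    counts <- tabulate(site_idx, nbins = n)
  } else stop("unknown capture model: ", cm$type)
  w <- config$peak_width
  starts <- sites$start[site_idx] +
    as.integer(round(rnorm(length(site_idx), 0, config$jitter_sd)))
  widths <- pmax(20L, w + as.integer(round(rnorm(length(site_idx), 0,
                                                 config$jitter_sd))))
  starts <- pmax(0L, pmin(starts, config$genome_length - widths))
  peaks_all <- data.frame(chrom = "chrSim", start = starts,
                          end = starts + widths,
                          caller = config$callers[caller_idx],
                          stringsAsFactors = FALSE)
  # caller-specific noise peaks (mostly singletons in the merged spectrum)
  if (config$noise_rate > 0) {
    for (k in seq_len(K)) {
      nn <- rpois(1, config$noise_rate * n)
      if (nn == 0) next
      ns <- as.integer(floor(runif(nn, 0, config$genome_length - w)))
      peaks_all <- rbind(peaks_all, data.frame(
        chrom = "chrSim", start = ns, end = ns + w,
        caller = config$callers[k], stringsAsFactors = FALSE))
    }
  }
  peaks <- lapply(config$callers, function(cl) {
    p <- peaks_all[peaks_all$caller == cl, , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  names(peaks) <- config$callers
  list(sites = sites, peaks = peaks, capture_counts = counts)
}

#' Simulate 5'-start tag records
#'
#' Fragments of the configured length are centred on true sites (with a
#' little spread) plus a uniform background component; each fragment yields
#' a + strand tag at its start and a - strand tag whose 5' position is the
#' fragment's last base, so the strand cross-correlation peaks near the
#' fragment length. PCR duplicates are injected at `duplicate_rate`.
#'
#' @param config A `sim_config`.
#' @param sites Truth intervals from [simulate_peak_sets()].
#' @return Tag data frame (`chrom`, `pos5`, `strand`).
#' @export
simulate_tags <- function(config, sites) {
  set.seed(config$seed + 1L)       # distinct stream from the peak generator
  fl <- config$fragment_length
  centers_sig <- rep((sites$start + sites$end) %/% 2L, config$frags_per_site) +
    as.integer(round(rnorm(nrow(sites) * config$frags_per_site, 0, 20)))
  n_bg <- as.integer(round(config$background_frac * length(centers_sig)))
  centers_bg <- as.integer(floor(runif(n_bg, fl, config$genome_length - fl)))
  centers <- c(centers_sig, centers_bg)
  fs <- centers - fl %/% 2L
  fs <- pmax(0L, pmin(fs, config$genome_length - fl))
  tags <- data.frame(chrom = "chrSim",
                     pos5 = c(fs, fs + fl - 1L),
                     strand = rep(c("+", "-"), each = length(fs)),
                     stringsAsFactors = FALSE)
  if (config$duplicate_rate > 0) {
    ndup <- as.integer(round(config$duplicate_rate * nrow(tags)))
    dup <- tags[sample.int(nrow(tags), ndup, replace = TRUE), , drop = FALSE]
    tags <- rbind(tags, dup)
  }
  rownames(tags) <- NULL
  tags
}
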