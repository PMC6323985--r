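# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: suffix arrays by naive substring sort, LCP by pairwise
# character comparison, MUL by direct occurrence counting, merging by
# connected components of the pairwise-overlap graph, PWM thresholds by
# exhaustive 4^L enumeration, the zero-truncated-Poisson MLE by grid search.

# --- suffix array / LCP ------------------------------------------------------

naive_sa <- function(text) {
  n <- nchar(text)
  suf <- substring(text, 1:n, n)
  order(suf, method = "radix") - 1L
}

# naive SA over integer codes: map codes to Unicode characters (UTF-8 byte
# order is monotone in code point, so radix sort matches integer order)
naive_sa_codes <- function(codes) {
  n <- length(codes)
  chars <- vapply(codes, function(cc) intToUtf8(cc + 64L), character(1))
  suf <- vapply(1:n, function(i) paste(chars[i:n], collapse = ""), character(1))
  order(suf, method = "radix") - 1L
}

naive_lcp_codes <- function(codes, sa) {
  n <- length(codes)
  lcp <- integer(n)
  for (i in 2:n) {
    a <- sa[i - 1] + 1L; b <- sa[i] + 1L
    h <- 0L
    while (a + h <= n && b + h <= n && codes[a + h] == codes[b + h]) h <- h + 1L
    lcp[i] <- h
  }
  lcp
}

naive_lcp <- function(text, sa) {
  naive_lcp_codes(utf8ToInt(text), sa)
}

# --- MUL ---------------------------------------------------------------------

revcomp_chr <- function(s) {
  x <- rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]])
  x[!x %in% c("A", "C", "G", "T")] <- "N"
  paste(x, collapse = "")
}

# MUL[i] = smallest m such that the m-mer at forward position i (1-based
# here) contains only ACGT and occurs exactly once among all ACGT-only
# windows of the forward + reverse-complement sequence collection; -1 if no
# such m exists before the window runs into a non-base or the sequence end.
brute_mul <- function(genome) {
  seqs <- c(unname(genome), vapply(unname(genome), revcomp_chr, character(1)))
  kmer_tab <- new.env(parent = emptyenv())
  all_kmers <- function(m) {
    key <- as.character(m)
    if (!is.null(kmer_tab[[key]])) return(kmer_tab[[key]])
    km <- unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < m) return(character(0))
      w <- substring(s, 1:(n - m + 1), m:n)
      w[!grepl("[^ACGT]", w)]
    }))
    tab <- table(km)
    kmer_tab[[key]] <- tab
    tab
  }
  out <- lapply(names(genome), function(chrom) {
    s <- toupper(genome[[chrom]])
    n <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    vapply(1:n, function(i) {
      m <- 1L
      repeat {
        if (i + m - 1L > n) return(-1L)
        if (chars[i + m - 1L] %in% c("A", "C", "G", "T") == FALSE) return(-1L)
        q <- substr(s, i, i + m - 1L)
        if (as.integer(all_kmers(m)[q]) == 1L) return(m)
        m <- m + 1L
      }
    }, integer(1))
  })
  names(out) <- names(genome)
  out
}

random_genome <- function(len, n_chrom = 1, with_repeat = FALSE, with_n = FALSE) {
  g <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  names(g) <- paste0("chr", seq_len(n_chrom))
  if (with_repeat && len >= 80) {
    # copy a 30-mer from the first half into the second half of chr1
    src <- sample.int(len %/% 2 - 30, 1)
    dst <- len %/% 2 + sample.int(len %/% 2 - 30, 1)
    ch <- strsplit(g[[1]], "", fixed = TRUE)[[1]]
    ch[dst:(dst + 29)] <- ch[src:(src + 29)]
    g[[1]] <- paste(ch, collapse = "")
  }
  if (with_n && len >= 40) {
    at <- sample.int(len - 10, 1)
    ch <- strsplit(g[[1]], "", fixed = TRUE)[[1]]
    ch[at:(at + 4)] <- "N"
    g[[1]] <- paste(ch, collapse = "")
  }
  g
}

# --- peak merging ------------------------------------------------------------

# connected components of the interval-overlap graph (same chrom, >= 1
# shared base under half-open coordinates)
brute_merge <- function(peaks) {
  n <- nrow(peaks)
  if (n == 0) return(peaks[0, c("chrom", "start", "end")])
  same <- outer(peaks$chrom, peaks$chrom, "==")
  ov <- same & outer(peaks$start, peaks$end, "<") & outer(peaks$end, peaks$start, ">")
  comp <- seq_len(n)
  repeat {  # label propagation until fixpoint
    new <- vapply(seq_len(n), function(i) min(comp[ov[i, ]]), integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix)
    data.frame(chrom = peaks$chrom[ix[1]], start = min(peaks$start[ix]),
               end = max(peaks$end[ix]), frequency = length(ix),
               stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_peaks <- function(n, genome_len = 5000, callers = c("A", "B", "C")) {
  start <- sample.int(genome_len, n, replace = TRUE) - 1L
  width <- sample(10:120, n, replace = TRUE)
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + width,
             caller = sample(callers, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# --- capture-recapture -------------------------------------------------------

# two-stage grid search for lambda/(1 - exp(-lambda)) = mbar at 1e-6
# resolution
grid_ztp_lambda <- function(mbar) {
  g <- function(l) l / (1 - exp(-l))
  coarse <- seq(1e-6, 50, by = 1e-3)
  i <- which.min(abs(g(coarse) - mbar))
  fine <- seq(max(1e-6, coarse[i] - 1e-3), coarse[i] + 1e-3, by = 1e-6)
  fine[which.min(abs(g(fine) - mbar))]
}

random_spectrum <- function() {
  k <- 1:sample(3:6, 1)
  f <- sapply(k, function(kk) sample.int(50, 1))
  # ensure mean capture count > 1 so the MLE is defined
  f <- c(f[1], f[-1] + 1L)
  spectrum_from_counts(setNames(f, k))
}

# --- PWM ---------------------------------------------------------------------

random_pwm <- function(L, seed = NULL) {
  counts <- matrix(sample.int(50, L * 4, replace = TRUE), nrow = L)
  pcm_to_pwm(counts)
}

# exhaustive threshold over the same discretised integer weights the DP
# uses: enumerate all 4^L words, tail probability from word probabilities
enum_threshold_int <- function(pwm, pvalue, n_bins = 1000L) {
  d <- cistromeqc:::discretize_pwm(pwm, n_bins)
  iw <- d$iw
  L <- nrow(iw)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in 1:L) {
    scores <- scores + iw[j, words[, j]]
    probs <- probs * pwm$background[words[, j]]
  }
  agg <- tapply(probs, scores, sum)
  sc <- as.numeric(names(agg))
  o <- order(sc)
  sc <- sc[o]; p <- as.numeric(agg[o])
  tail_p <- rev(cumsum(rev(p)))
  ok <- which(tail_p <= pvalue + 1e-15)
  t_int <- if (length(ok) == 0) max(sc) + 1 else sc[ok[1]]
  list(t_int = t_int, binw = d$binw, achievable = sc)
}
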