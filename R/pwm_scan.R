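# Position-weight-matrix site prediction with exact p-value -> score
# threshold computation. Scores are log2 odds against an i.i.d. background;
# the score distribution of a random word is obtained by exact dynamic-
# programming convolution of the per-position score distributions after
# discretising weights to bins of 1e-3 of the matrix score range.

#' Read position count matrices in HOCOMOCO plain-text layout
#'
#' Each record is a `>name` header followed by L rows of 4 whitespace-
#' separated counts (columns A, C, G, T).
#'
#' @param path Input path.
#' @return Named list of `pcm` objects (`tf_name`, `counts` L x 4 matrix).
#' @export
read_pcm <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no '>' records in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (any(lengths(rows) != 4) || any(vapply(rows, anyNA, logical(1))))
      stop("malformed count row in record ", name)
    counts <- do.call(rbind, rows)
    colnames(counts) <- c("A", "C", "G", "T")
    out[[name]] <- new_pcm(name, counts)
  }
  out
}

new_pcm <- function(tf_name, counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, nrow(counts) >= 1, all(counts >= 0))
  if (any(rowSums(counts) == 0))
    stop("PCM has a position with no positive count")
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, counts = counts), class = "pcm")
}

#' Convert a position count matrix to a log-odds scoring matrix
#'
#' `w[j, b] = log2( (c[j, b] + pseudocount * background[b]) /
#' (N_j + pseudocount) / background[b] )` with `N_j` the column sum at
#' position j.
#'
#' @param pcm A `pcm` object or bare L x 4 count matrix.
#' @param background Base composition (A, C, G, T), summing to 1. Default
#'   uniform.
#' @param pseudocount Total pseudocount mass distributed by background
#'   (> 0, default 1).
#' @return A `pwm` object: list with `weights` (L x 4), `background`,
#'   `tf_name`.
#' @export
pcm_to_pwm <- function(pcm, background = rep(0.25, 4), pseudocount = 1) {
  if (inherits(pcm, "pcm")) {
    counts <- pcm$counts; name <- pcm$tf_name
  } else {
    counts <- as.matrix(pcm); name <- NA_character_
  }
  stopifnot(pseudocount > 0, length(background) == 4, all(background > 0))
  if (abs(sum(background) - 1) > 1e-12) stop("background must sum to 1")
  if (any(rowSums(counts) == 0)) stop("PCM has an all-zero position")
  nj <- rowSums(counts)
  w <- log2(sweep(counts + outer(rep(pseudocount, nrow(counts)), background),
                  1, nj + pseudocount, "/"))
  w <- sweep(w, 2, log2(background), "-")
  colnames(w) <- c("A", "C", "G", "T")
  structure(list(weights = w, background = background, tf_name = name),
            class = "pwm")
}

# Integer-discretised weights shared by the threshold DP and its exhaustive
# oracle: bins of (score range)/n_bins.
discretize_pwm <- function(pwm, n_bins = 1000L) {
  w <- pwm$weights
  rng <- sum(apply(w, 1, max)) - sum(apply(w, 1, min))
  binw <- max(rng / n_bins, 1e-12)
  list(iw = round(w / binw), binw = binw)
}

#' Score threshold for a target p-value
#'
#' Smallest score t such that `P(score(random word) >= t) <= pvalue` under
#' the i.i.d. background model. The distribution of the word score is
#' computed exactly by convolving the per-position score distributions over
#' weights discretised to bins of `1/n_bins` of the matrix score range.
#'
#' @param pwm A `pwm` object.
#' @param pvalue Target p-value in `(0, 1]`.
#' @param n_bins Number of discretisation bins across the score range
#'   (default 1000).
#' @return The threshold score (numeric), with attributes `pvalue_actual`
#'   (the achieved tail probability) and `binw` (bin width).
#' @export
score_threshold <- function(pwm, pvalue, n_bins = 1000L) {
  if (!is.numeric(pvalue) || pvalue <= 0 || pvalue > 1)
    stop("pvalue must be in (0, 1]")
  d <- discretize_pwm(pwm, n_bins)
  iw <- d$iw
  L <- nrow(iw)
  # dist[k] = P(integer score == cur_lo + k - 1), grown position by position
  cur_lo <- 0L
  cur_len <- 1L
  dist <- 1
  bg <- pwm$background
  for (j in seq_len(L)) {
    wj <- iw[j, ]
    new_lo <- cur_lo + min(wj)
    new_len <- cur_len + (max(wj) - min(wj))
    nd <- numeric(new_len)
    for (b in 1:4) {
      off <- wj[b] - min(wj)
      idx <- seq_len(cur_len) + off
      nd[idx] <- nd[idx] + bg[b] * dist[seq_len(cur_len)]
    }
    dist <- nd
    cur_lo <- new_lo
    cur_len <- new_len
  }
  scores_int <- cur_lo + seq_len(cur_len) - 1L
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= pvalue + 1e-15)
  if (length(ok) == 0) {
    # no achievable score has tail <= pvalue; threshold above the maximum
    t_int <- scores_int[cur_len] + 1L
    p_act <- 0
  } else {
    t_int <- scores_int[ok[1]]
    p_act <- tail_p[ok[1]]
  }
  structure(t_int * d$binw, pvalue_actual = p_act, binw = d$binw,
            threshold_int = t_int)
}

#' Scan a sequence for PWM hits above a threshold
#'
#' Both strands are scanned; windows containing any non-ACGT base are
#' skipped. Minus-strand hits are reported in forward-strand coordinates
#' (0-based half-open).
#'
#' @param sequence Character string over ACGT/N (case folded).
#' @param pwm A `pwm` object.
#' @param threshold Score threshold, typically from [score_threshold()].
#' @return Data frame `start`, `end`, `strand`, `score`, sorted by start.
#' @export
scan_sequence <- function(sequence, pwm, threshold) {
  w <- pwm$weights
  L <- nrow(w)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  codes <- match(chars, c("A", "C", "G", "T"))   # NA for N etc.
  nw <- n - L + 1L
  # reverse-complement matrix scans the minus strand in forward coordinates
  w_rc <- w[L:1, 4:1, drop = FALSE]
  s_fwd <- numeric(nw)
  s_rev <- numeric(nw)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + nw - 1L)]
    s_fwd <- s_fwd + w[j, ][cj]    # NA propagates through N windows
    s_rev <- s_rev + w_rc[j, ][cj]
  }
  hit_f <- which(!is.na(s_fwd) & s_fwd >= threshold)
  hit_r <- which(!is.na(s_rev) & s_rev >= threshold)
  out <- data.frame(
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(s_fwd[hit_f], s_rev[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Score a single word with a PWM
#' @param word Character string of length L over ACGT.
#' @param pwm A `pwm` object.
#' @return Numeric score (sum of per-position weights).
#' @export
score_word <- function(word, pwm) {
  w <- pwm$weights
  codes <- match(strsplit(toupper(word), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  if (length(codes) != nrow(w)) stop("word length must equal matrix length")
  if (anyNA(codes)) stop("word must be over ACGT")
  sum(w[cbind(seq_len(nrow(w)), codes)])
}

#' Write PWM hits as BED6
#' @param hits Data frame from [scan_sequence()].
#' @param chrom Chromosome name to attach.
#' @param name Feature name for the name column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, chrom, name, path) {
  x <- data.frame(chrom = chrom, start = hits$start, end = hits$end,
                  name = name, score = hits$score, strand = hits$strand,
                  stringsAsFactors = FALSE)
  write_bed(x, path)
}
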