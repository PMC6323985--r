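# Minimal-unique-length (MUL) mappability tracks.
#
# The genome and its reverse complement are concatenated into one symbol
# sequence, every chromosome copy followed by a separator. Each separator is
# a DISTINCT symbol ordered below A < C < G < T: two suffixes can therefore
# never share a prefix across a separator, which is what makes the
# L = max(LCP[i], LCP[i+1]) formula sound. Non-ACGT bases (N and IUPAC
# ambiguity codes) also become separators, so k-mers containing them never
# map and MUL there is -1.

BASE_ALPHABET <- c("A", "C", "G", "T")

#' Build the concatenated forward + reverse-complement text of a genome
#'
#' Produces the integer-coded string `chr1 | sep | revcomp(chr1) | sep |
#' chr2 | ...` over which the suffix array is built. Separator symbols take
#' codes `1..n_sep` (each distinct, below all bases); bases take codes
#' `n_sep+1 .. n_sep+4` in A < C < G < T order.
#'
#' @param genome Named character vector of chromosome sequences (ACGT plus
#'   ambiguity codes; case is folded).
#' @return An object of class `concat_text`: list with `codes` (integer
#'   vector), `n_sep` (number of separator symbols), and `boundaries`
#'   (data frame mapping text offsets back to chrom/strand/position).
#' @export
build_concatenated_text <- function(genome) {
  if (length(genome) == 0) stop("empty genome")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named")
  chunks <- list()
  bnd <- list()
  offset <- 0L
  for (chrom in names(genome)) {
    fwd <- strsplit(toupper(genome[[chrom]]), "", fixed = TRUE)[[1]]
    if (length(fwd) == 0) stop("zero-length chromosome: ", chrom)
    rc <- rev(chartr("ACGT", "TGCA", fwd))
    rc[!rc %in% BASE_ALPHABET] <- "N"
    bnd[[length(bnd) + 1L]] <- data.frame(
      chrom = chrom, strand = "+", offset = offset, length = length(fwd),
      stringsAsFactors = FALSE)
    chunks[[length(chunks) + 1L]] <- fwd
    chunks[[length(chunks) + 1L]] <- "."          # separator slot
    offset <- offset + length(fwd) + 1L
    bnd[[length(bnd) + 1L]] <- data.frame(
      chrom = chrom, strand = "-", offset = offset, length = length(rc),
      stringsAsFactors = FALSE)
    chunks[[length(chunks) + 1L]] <- rc
    chunks[[length(chunks) + 1L]] <- "."
    offset <- offset + length(rc) + 1L
  }
  chars <- unlist(chunks, use.names = FALSE)
  base_idx <- match(chars, BASE_ALPHABET)          # NA for separators/ambiguity
  is_sep <- is.na(base_idx)
  n_sep <- sum(is_sep)
  codes <- integer(length(chars))
  codes[is_sep] <- seq_len(n_sep)                  # distinct, below all bases
  codes[!is_sep] <- base_idx[!is_sep] + n_sep
  structure(list(codes = codes, n_sep = n_sep,
                 boundaries = do.call(rbind, bnd)),
            class = "concat_text")
}

#' Suffix array of a text (SA-IS, linear time)
#'
#' @param text A character string, or an integer code vector (values >= 1),
#'   or a `concat_text` object.
#' @return Integer vector of 0-based suffix start positions in strictly
#'   increasing lexicographic order of suffixes.
#' @export
build_suffix_array <- function(text) {
  .sais_sa(text_codes(text))
}

#' LCP array from a text and its suffix array (Kasai, linear time)
#'
#' `LCP[i]` is the longest-common-prefix length of the suffixes ranked
#' `i - 1` and `i`; `LCP[1] = 0` (R indexing; rank 0 has no predecessor).
#'
#' @param text As in [build_suffix_array()].
#' @param sa Suffix array of `text`.
#' @return Integer vector, same length as the text.
#' @export
build_lcp <- function(text, sa) {
  .kasai_lcp(text_codes(text), as.integer(sa))
}

text_codes <- function(text) {
  if (inherits(text, "concat_text")) return(text$codes)
  if (is.character(text)) {
    stopifnot(length(text) == 1, nzchar(text))
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    return(as.integer(factor(chars, levels = sort(unique(chars)))))
  }
  codes <- as.integer(text)
  if (length(codes) == 0) stop("empty text")
  codes
}

#' Minimal unique length array from SA and LCP
#'
#' For the suffix at rank `i`, with `L = max(LCP[i], LCP[i+1])` (LCP beyond
#' the last rank taken as 0), the shortest uniquely mapping read at that
#' text position has length `L + 1` provided the symbol at offset `L` is a
#' base; if it is a separator no read of any length maps uniquely there and
#' MUL is -1. Only forward-strand genome positions are reported.
#'
#' @param ctext A `concat_text` object.
#' @param sa,lcp Suffix array and LCP array of `ctext` (computed when
#'   missing).
#' @return Named list, one integer vector per chromosome (class
#'   `mul_array`); values are read lengths (>= 1) or -1.
#' @export
compute_mul <- function(ctext, sa = NULL, lcp = NULL) {
  stopifnot(inherits(ctext, "concat_text"))
  if (is.null(sa)) sa <- build_suffix_array(ctext)
  if (is.null(lcp)) lcp <- build_lcp(ctext, sa)
  codes <- ctext$codes
  n <- length(codes)
  L <- pmax(lcp, c(lcp[-1], 0L))
  nxt <- sa + L                                  # 0-based offset of symbol L
  ok <- nxt < n
  ok[ok] <- codes[nxt[ok] + 1L] > ctext$n_sep    # symbol at offset L is a base
  mul_by_rank <- ifelse(ok, L + 1L, -1L)
  mul_text <- integer(n)
  mul_text[sa + 1L] <- mul_by_rank
  fwd <- ctext$boundaries[ctext$boundaries$strand == "+", , drop = FALSE]
  out <- lapply(seq_len(nrow(fwd)), function(i) {
    idx <- fwd$offset[i] + seq_len(fwd$length[i])    # 1-based text indices
    mul_text[idx]
  })
  names(out) <- fwd$chrom
  structure(out, class = "mul_array")
}

#' Compute MUL arrays for a genome
#'
#' Convenience wrapper: concatenated text, SA-IS, Kasai LCP, MUL.
#'
#' @param genome Named character vector of chromosome sequences.
#' @return A `mul_array` (named list of per-chromosome integer vectors).
#' @export
mul_array <- function(genome) {
  ctext <- build_concatenated_text(genome)
  compute_mul(ctext)
}

#' Unmappable regions for a given read length
#'
#' Position `i` is unmappable for read length `k` iff `MUL[i] = -1` or
#' `MUL[i] > k`.
#'
#' @param mul A `mul_array`.
#' @param k Read length (>= 1).
#' @return Interval data frame (`chrom`, `start`, `end`), maximal runs,
#'   sorted.
#' @export
unmappable_regions <- function(mul, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("read length k must be >= 1")
  res <- lapply(names(mul), function(chrom) {
    bad <- mul[[chrom]] == -1L | mul[[chrom]] > k
    if (!any(bad)) return(NULL)
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths       # 0-based starts
    keep <- r$values
    data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Fraction of the genome unmappable at read length k
#'
#' @inheritParams unmappable_regions
#' @return Real in `[0, 1]`: total unmappable length over total genome
#'   length (N positions count in both numerator and denominator).
#' @export
unmappable_fraction <- function(mul, k) {
  total <- sum(lengths(mul))
  if (total == 0) stop("empty genome")
  reg <- unmappable_regions(mul, k)
  sum(reg$end - reg$start) / total
}
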