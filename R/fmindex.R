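# BWT / FM-index over the concatesome: suffix-array construction by prefix
# doubling, backward search for exact substring queries, and the LF walk.

FM_ALPHABET <- c("$", "A", "C", "G", "T")

# suffix array (1-based start positions, lexicographic order) by prefix
# doubling; O(n log^2 n) using radix order()
suffix_array <- function(chars) {
  n <- length(chars)
  rank <- match(chars, sort.int(unique(chars), method = "radix"))
  h <- 1L
  while (max(rank) < n) {
    key2 <- c(rank[-seq_len(min(h, n))], rep(0L, min(h, n)))
    ord <- order(rank, key2, method = "radix")
    r <- rank[ord]
    k2 <- key2[ord]
    newrank <- integer(n)
    newrank[ord] <- cumsum(c(1L, (r[-1L] != r[-n]) | (k2[-1L] != k2[-n])))
    rank <- newrank
    h <- h * 2L
  }
  sa <- integer(n)
  sa[rank] <- seq_len(n)
  sa
}

#' Build an FM-index over a concatesome
#'
#' Appends a sentinel, builds the suffix array and Burrows-Wheeler
#' transform, and precomputes the rank (occurrence) structure used by
#' backward search. IUPAC ambiguity codes cannot be carried by the 2-bit-style
#' BWT alphabet, so they are replaced by `A` inside the index text only; any
#' candidate hit found through the index is re-scored against the original
#' sequence by the percent-identity dynamic program, where ambiguity matches
#' are free.
#'
#' @param x A `concatesome` or a single DNA string.
#' @return An `fm_index`: list with `text` (index text, no sentinel), `sa`
#'   (1-based suffix starts), `bwt`, `occ` (cumulative per-character ranks),
#'   and `char_starts`.
#' @export
build_fm_index <- function(x) {
  text <- if (inherits(x, "concatesome")) x$sequence else x
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) abort("cannot index an empty sequence")
  text <- toupper(text)
  text <- gsub("[^ACGT]", "A", text)
  chars <- c(strsplit(text, "", fixed = TRUE)[[1L]], "$")
  n <- length(chars)
  sa <- suffix_array(chars)
  bwt <- chars[ifelse(sa == 1L, n, sa - 1L)]
  occ <- vapply(FM_ALPHABET, function(a) cumsum(bwt == a),
                integer(n))  # n x 5, occ[i, a] = count of a in bwt[1..i]
  totals <- occ[n, ]
  char_starts <- setNames(
    cumsum(c(0L, totals[-length(totals)])), FM_ALPHABET
  )
  structure(
    list(text = text, sa = sa, bwt = bwt, occ = occ,
         char_starts = char_starts),
    class = "fm_index"
  )
}

#' @export
print.fm_index <- function(x, ...) {
  cat("<fm_index> ", nchar(x$text), " bp\n", sep = "")
  invisible(x)
}

#' Exact substring search via FM-index backward search
#'
#' @param idx An `fm_index`.
#' @param pattern A single ACGT string.
#' @return Sorted integer vector of 0-based occurrence positions in the
#'   index text (empty when the pattern is absent).
#' @export
backward_search <- function(idx, pattern) {
  stopifnot(inherits(idx, "fm_index"), is.character(pattern),
            length(pattern) == 1L, nchar(pattern) >= 1L)
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1L]])
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    return(integer(0))  # index alphabet cannot contain other characters
  }
  lo <- 1L
  hi <- length(idx$bwt)
  for (ch in chars) {
    cs <- idx$char_starts[[ch]]
    occ_lo <- if (lo > 1L) idx$occ[lo - 1L, ch] else 0L
    lo <- cs + occ_lo + 1L
    hi <- cs + idx$occ[hi, ch]
    if (lo > hi) return(integer(0))
  }
  sort.int(idx$sa[lo:hi] - 1L)
}

#' Invert the BWT with the LF walk
#'
#' Reconstructs the original text from the transform alone, the defining
#' reversibility property of the BWT (used as a structural self-check).
#'
#' @param idx An `fm_index`.
#' @return The reconstructed text (sentinel removed).
#' @export
bwt_invert <- function(idx) {
  n <- length(idx$bwt)
  out <- character(n - 1L)
  i <- 1L  # first row starts with the sentinel; bwt[1] is the text's last char
  for (j in (n - 1L):1L) {
    ch <- idx$bwt[i]
    out[j] <- ch
    i <- idx$char_starts[[ch]] + idx$occ[i, ch]
  }
  paste(out, collapse = "")
}
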