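# K-mer frequency profiling for read denoising. Each k-mer is packed into
# 2k bits (A=00, C=01, G=10, T=11, leftmost base most significant) and used
# to index a counter array of length 4^k; the resulting empirical k-mer
# frequency distribution flags reads carrying rare (likely erroneous) k-mers.

#' Encode k-mers as 2-bit-packed integers
#'
#' @param kmer Character vector of equal-length ACGT strings.
#' @return Integer vector in `[0, 4^k)`; the leftmost base occupies the most
#'   significant bit pair.
#' @examples
#' encode_kmer("ACGT")  # 27, binary 00 01 10 11
#' @export
encode_kmer <- function(kmer) {
  k <- unique(nchar(kmer))
  if (length(k) != 1L) abort("all k-mers must have the same length")
  if (k > 15L) abort("k-mers longer than 15 cannot be packed")
  chars <- matrix(unlist(strsplit(kmer, "", fixed = TRUE)),
                  ncol = k, byrow = TRUE)
  codes <- matrix(match(chars, c("A", "C", "G", "T")) - 1, ncol = k)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort(paste0("k-mer contains non-ACGT base(s): ",
                 paste(bad, collapse = ", ")))
  }
  as.integer(codes %*% 4^((k - 1):0))
}

# 0..3 base codes for one sequence; NA for anything outside ACGT
base_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T")) - 1
}

# packed values of all length-k windows of one coded read; windows touching
# a non-ACGT base are dropped (the 2-bit code has no slot for them)
window_codes <- function(codes, k) {
  if (length(codes) < k) return(integer(0))
  e <- embed(codes, k)  # row i = codes[(i+k-1):i]
  v <- e %*% 4^(0:(k - 1))
  as.integer(v[!is.na(v)])
}

#' Build the empirical k-mer counter over a read set
#'
#' Slides a k-wide window across every read, incrementing the counter
#' indexed by each window's 2-bit packed value. Windows containing non-ACGT
#' characters are skipped entirely. With the default k = 8 the counter array
#' has length 2^16 = 65536.
#'
#' @param reads Character vector of sequences, or a data frame with a
#'   `sequence` column.
#' @param k Word size; the operational range for 16S data is 8 to 14
#'   (smaller values are accepted, mainly for testing). Memory is 4 bytes
#'   per counter, i.e. `4 * 4^k` bytes.
#' @return A `kmer_counter`: list with `k`, `counts` (integer vector of
#'   length `4^k`), `total_kmers`, and `n_reads` (reads profiled, the
#'   denominator of the denoising prevalence threshold).
#' @export
build_kmer_counter <- function(reads, k = 8L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  stopifnot(k >= 1L, k <= 14L)
  all_windows <- unlist(lapply(reads, function(s) {
    window_codes(base_codes(s), k)
  }))
  counts <- tabulate(all_windows + 1L, nbins = 4L^k)
  structure(
    list(k = as.integer(k), counts = counts,
         total_kmers = length(all_windows), n_reads = length(reads)),
    class = "kmer_counter"
  )
}

#' @export
print.kmer_counter <- function(x, ...) {
  cat("<kmer_counter> k=", x$k, ", ", x$total_kmers, " k-mers over ",
      x$n_reads, " reads (", sum(x$counts > 0L), " distinct)\n", sep = "")
  invisible(x)
}

#' Discard reads carrying rare k-mers
#'
#' A read is discarded when any of its valid k-mer windows occurs fewer than
#' `denoise_fraction * n_reads` times in the empirical counter — i.e. the
#' k-mer's prevalence across the profiled read set falls below the chosen
#' fraction, marking it as a probable sequencing error. Both partitions are
#' returned so discards are auditable.
#'
#' @param reads A data frame of reads (with a `sequence` column) or a
#'   character vector.
#' @param counter A [build_kmer_counter()] result over the same read set.
#' @param denoise_fraction Prevalence threshold in (0, 1); e.g. `1e-4`
#'   discards reads with a k-mer seen in fewer than 0.01% of reads.
#' @return A list with elements `kept` and `discarded`, each the same type
#'   as `reads`.
#' @export
denoise_reads <- function(reads, counter, denoise_fraction) {
  stopifnot(inherits(counter, "kmer_counter"),
            denoise_fraction > 0, denoise_fraction < 1)
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  cutoff <- denoise_fraction * counter$n_reads
  bad <- vapply(seqs, function(s) {
    w <- window_codes(base_codes(s), counter$k)
    length(w) > 0L && any(counter$counts[w + 1L] < cutoff)
  }, logical(1L), USE.NAMES = FALSE)
  if (is.data.frame(reads)) {
    list(kept = reads[!bad, , drop = FALSE],
         discarded = reads[bad, , drop = FALSE])
  } else {
    list(kept = reads[!bad], discarded = reads[bad])
  }
}
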