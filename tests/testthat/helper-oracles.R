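# Independent oracles used to check the package's optimized paths.
# Each deliberately takes the simplest possible route: linear scans,
# hash maps, rotation sorts, exhaustive enumeration.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# linear-scan version of concatesome coordinate resolution
locate_hit_linear <- function(cs, start, ref_span) {
  total <- nchar(cs$sequence)
  ends <- c(cs$offsets[-1L], total)
  vapply(seq_along(start), function(r) {
    i <- max(which(cs$offsets <= start[r]))
    if (start[r] + ref_span[r] > ends[i]) NA_character_ else cs$otu_ids[i]
  }, character(1L))
}

# hash-map deduplication: count (sequence, sample) pairs in an environment
dedup_naive <- function(reads) {
  env <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(reads))) {
    key <- paste0(reads$sequence[r], "\r", reads$sample_id[r])
    env[[key]] <- (env[[key]] %||% 0L) + 1L
  }
  keys <- ls(env)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble::tibble(
    sequence = vapply(parts, `[[`, "", 1L),
    sample_id = vapply(parts, `[[`, "", 2L),
    count = vapply(keys, function(k) env[[k]], integer(1L),
                   USE.NAMES = FALSE)
  )
  dplyr::arrange(out, sequence, sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# every occurrence of pattern in text, 0-based, by direct substring scan
naive_scan <- function(text, pattern) {
  n <- nchar(text)
  l <- nchar(pattern)
  if (l > n) return(integer(0))
  starts <- 1:(n - l + 1L)
  which(substring(text, starts, starts + l - 1L) == pattern) - 1L
}

# BWT by brute force: sort all rotations of text + sentinel, take the last column
bwt_rotations <- function(text) {
  s <- paste0(text, "$")
  n <- nchar(s)
  rot <- vapply(seq_len(n), function(i) {
    paste0(substring(s, i, n), substring(s, 1L, i - 1L))
  }, character(1L))
  rot <- stringr::str_sort(rot, locale = "C")
  paste(substring(rot, n, n), collapse = "")
}

# exhaustive semi-global identity: stratify alignments by deletion count d,
# take the best matches for each d by direct recurrence over all partial
# alignments, and maximize matches / (m + d) at the end
enum_identity <- function(query, ref) {
  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  m <- length(qc)
  n <- length(rc)
  h <- array(-Inf, dim = c(m + 1L, n + 1L, n + 1L))
  h[1L, , 1L] <- 0  # free reference prefix, no deletions yet
  for (i in 1:m) {
    for (j in 0:n) {
      for (d in 0:n) {
        best <- -Inf
        if (j > 0L) {
          v <- h[i, j, d + 1L] + (qc[i] == rc[j])
          if (v > best) best <- v
        }
        v <- h[i, j + 1L, d + 1L]  # insertion
        if (v > best) best <- v
        if (j > 0L && d > 0L) {
          v <- h[i + 1L, j, d]  # deletion
          if (v > best) best <- v
        }
        h[i + 1L, j + 1L, d + 1L] <- best
      }
    }
  }
  best_id <- 0
  for (j in 0:n) {
    for (d in 0:n) {
      v <- h[m + 1L, j + 1L, d + 1L]
      if (is.finite(v)) best_id <- max(best_id, v / (m + d))
    }
  }
  best_id
}

# small ready-made concatesome fixtures
toy_concatesome <- function() {
  build_concatesome(tibble::tibble(
    otu_id = c("A", "B"),
    sequence = c("ACGT", "GGCC")
  ))
}

random_concatesome <- function(n_refs, len_range = c(30L, 80L)) {
  build_concatesome(tibble::tibble(
    otu_id = paste0("R", seq_len(n_refs)),
    sequence = vapply(
      sample(len_range[1L]:len_range[2L], n_refs, replace = TRUE),
      random_seq, character(1L)
    )
  ))
}
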