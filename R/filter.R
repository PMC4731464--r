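# Read parsing, trimming, deduplication into the sample dictionary,
# read compaction, and multiplicity (singleton/doubleton/...) filtering.

#' Parse demultiplexed amplicon reads from FASTA
#'
#' Read identifiers are expected in the demultiplexed convention
#' `SampleID_ReadNumber`: the sample id is everything before the *last*
#' underscore of the first whitespace-delimited header token. Headers with
#' no underscore fall back to the whole token as the sample id (with a
#' warning). Records with empty sequences are skipped with a warning.
#'
#' @param path Path to a FASTA file of reads.
#' @return A tibble with columns `sample_id`, `read_id`, `sequence`
#'   (uppercased), one row per surviving record.
#' @export
parse_reads <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warn(paste0("skipped ", sum(empty), " record(s) with empty sequences"))
    ids <- ids[!empty]
    seqs <- seqs[!empty]
  }
  no_us <- !grepl("_", ids)
  if (any(no_us)) {
    warn(paste0(sum(no_us), " header(s) contain no '_'; ",
                "using the whole identifier as the sample id"))
  }
  tibble(
    sample_id = ifelse(no_us, ids, sub("_[^_]*$", "", ids)),
    read_id = ids,
    sequence = seqs
  )
}

#' Trim reads to a fixed length
#'
#' Keeps the first `trim_length` bases of each sequence; shorter sequences
#' pass through unchanged. Trimming is applied before deduplication so that
#' uniformly trimmed reads collapse together.
#'
#' @param seq Character vector of sequences.
#' @param trim_length Positive integer, or `NULL` for no trimming.
#' @return Character vector of trimmed sequences.
#' @export
trim_read <- function(seq, trim_length) {
  if (is.null(trim_length)) return(seq)
  stopifnot(trim_length >= 1L)
  substr(seq, 1L, trim_length)
}

#' Reverse-complement sequences (IUPAC-aware)
#'
#' @param seq Character vector over the IUPAC nucleotide alphabet.
#' @return Character vector of reverse complements (N stays N, R becomes Y,
#'   and so on).
#' @export
reverse_complement <- function(seq) {
  bad <- regmatches(seq, regexpr("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv]", seq))
  bad <- unlist(bad)
  if (length(bad) > 0L) {
    abort(paste0("non-IUPAC character(s) in sequence: ",
                 paste(unique(bad), collapse = ", ")))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Dictionary tags are the 0-based ordinal of each distinct sequence in
# lexicographic order -- the contractually fixed output order.
retag_dict <- function(d) {
  seqs <- stringr::str_sort(unique(d$sequence), locale = "C")
  d$tag <- as.character(match(d$sequence, seqs) - 1L)
  d <- arrange(d, match(.data$sequence, seqs), .data$sample_id)
  d <- d[, c("tag", "sequence", "sample_id", "count")]
  class(d) <- c("dedup_dict", class(tibble()))
  d
}

#' Deduplicate reads into a sample dictionary
#'
#' Collapses identical sequences into one entry each, tracking the number of
#' occurrences of each sequence in each sample so that deduplication is
#' lossless: the dictionary can be expanded back to the full read multiset.
#' Entries are ordered lexicographically by sequence (byte order), and each
#' distinct sequence receives a `tag`, its 0-based ordinal in that order.
#'
#' @param reads A data frame with columns `sample_id` and `sequence`
#'   (already trimmed as desired), e.g. from [parse_reads()].
#' @return A `dedup_dict`: a tibble with columns `tag`, `sequence`,
#'   `sample_id`, `count`, one row per (sequence, sample) pair.
#' @examples
#' reads <- tibble::tibble(
#'   sample_id = c("S1", "S1", "S2"),
#'   sequence = c("ACGT", "ACGT", "ACGT")
#' )
#' deduplicate(reads)  # one entry, counts S1:2 S2:1
#' @export
deduplicate <- function(reads) {
  reads <- as_tibble(reads)
  stopifnot(all(c("sample_id", "sequence") %in% names(reads)))
  d <- reads |>
    group_by(.data$sequence, .data$sample_id) |>
    summarise(count = dplyr::n(), .groups = "drop")
  retag_dict(d[, c("sequence", "sample_id", "count")])
}

#' Per-entry totals of a sample dictionary
#'
#' @param d A `dedup_dict`.
#' @return A tibble with columns `tag`, `sequence`, `total`, one row per
#'   distinct sequence, in dictionary (lexicographic) order.
#' @export
dict_entries <- function(d) {
  d |>
    group_by(.data$tag, .data$sequence) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(as.integer(.data$tag))
}

#' Merge reads that are prefixes of longer reads (read compaction)
#'
#' Amplicon reads start at a common primer site, so a shorter read is often
#' just a length-truncated copy of a longer one. Compaction normalizes this
#' variation by treating every entry whose sequence is a prefix of another
#' entry's sequence as copies of the longest containing entry, adding its
#' per-sample counts to that entry. When two containing entries tie for
#' length the lexicographically smallest wins (a determinism tie-break).
#'
#' @param d A `dedup_dict`.
#' @return A compacted `dedup_dict`; total counts are conserved.
#' @export
compact_reads <- function(d) {
  ent <- dict_entries(d)
  seqs <- ent$sequence  # already lexicographic
  n <- length(seqs)
  target <- seq_len(n)
  if (n > 1L) {
    lens <- nchar(seqs)
    for (i in seq_len(n - 1L)) {
      # entries having seqs[i] as a prefix form a contiguous lexicographic run
      best <- i
      j <- i + 1L
      while (j <= n && startsWith(seqs[j], seqs[i])) {
        if (lens[j] > lens[best]) best <- j
        j <- j + 1L
      }
      target[i] <- best
    }
  }
  map <- tibble(sequence = seqs, merged = seqs[target])
  d |>
    left_join(map, by = "sequence") |>
    group_by(sequence = .data$merged, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    retag_dict()
}

#' Drop low-multiplicity sequences (singleton/doubleton filtering)
#'
#' A sequence observed only once in the whole dataset is likely to carry a
#' sequencing error; one observed twice or more rarely is. The `d_level`
#' knob selects how aggressive this is: levels 0 and 1 keep everything
#' (level 1 conventionally marks that read compaction was applied), level 2
#' drops entries with total count 1 (singletons), level 3 also drops total
#' count 2, and so on — entries with total count `< d_level` are removed.
#'
#' @param d A `dedup_dict`.
#' @param d_level Non-negative integer.
#' @return A filtered `dedup_dict` (retagged over the survivors).
#' @export
filter_by_count <- function(d, d_level) {
  stopifnot(d_level >= 0L)
  if (d_level <= 1L) return(d)
  keep <- dict_entries(d)
  keep <- keep$sequence[keep$total >= d_level]
  retag_dict(filter(d, .data$sequence %in% keep))
}

#' Write the filtered FASTA and sample dictionary
#'
#' The FASTA contains one record per dictionary entry, headed by the entry's
#' tag, in tag order; this is the reduced read set handed to the aligner.
#' The dictionary file is a TSV with one row per entry: tag, sequence, then
#' `sample:count` pairs. Reverse-complementing, when requested, is applied
#' only to the FASTA sequences at write time — the dictionary keeps the
#' original orientation.
#'
#' @param d A `dedup_dict`.
#' @param fasta_path,dict_path Output paths.
#' @param rc Reverse-complement FASTA sequences at write time?
#' @return Invisibly, `d`.
#' @export
write_filtered <- function(d, fasta_path, dict_path, rc = FALSE) {
  ent <- dict_entries(d)
  out_seq <- ent$sequence
  if (isTRUE(rc)) out_seq <- reverse_complement(out_seq)
  writeLines(paste0(">", ent$tag, "\n", out_seq), fasta_path)
  rows <- d |>
    group_by(.data$tag, .data$sequence) |>
    summarise(
      pairs = paste(paste0(.data$sample_id, ":", .data$count),
                    collapse = "\t"),
      .groups = "drop"
    ) |>
    arrange(as.integer(.data$tag))
  writeLines(paste(rows$tag, rows$sequence, rows$pairs, sep = "\t"), dict_path)
  invisible(d)
}

#' Read a sample dictionary written by [write_filtered()]
#'
#' @param dict_path Path to the dictionary TSV.
#' @return A `dedup_dict` tibble (`tag`, `sequence`, `sample_id`, `count`).
#' @export
read_dedup_dictionary <- function(dict_path) {
  lines <- readLines(dict_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  d <- purrr::map_dfr(parts, function(p) {
    if (length(p) < 3L) abort("malformed dictionary row")
    sc <- strsplit(p[-(1:2)], ":", fixed = TRUE)
    tibble(
      tag = p[[1L]],
      sequence = p[[2L]],
      sample_id = vapply(sc, `[[`, "", 1L),
      count = as.integer(vapply(sc, `[[`, "", 2L))
    )
  })
  class(d) <- c("dedup_dict", class(tibble()))
  d
}
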