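# Concatenated reference chromosome ("concatesome") and coordinate resolution.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

#' Read a multi-FASTA of reference marker genes
#'
#' Headers may contain descriptions; the first whitespace-delimited token is
#' taken as the OTU identifier. Sequences are uppercased. Wrapped and
#' single-line FASTA are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `otu_id` and `sequence`, in file order.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(
    otu_id = sub("\\s.*$", "", names(set)),
    sequence = toupper(as.character(set))
  )
}

#' Build a concatesome from a reference set
#'
#' Joins reference marker-gene sequences end to end into one artificial
#' chromosome, with no separator characters, recording the 0-based start
#' offset of each reference so that alignment coordinates can be resolved
#' back to individual OTUs.
#'
#' @param refs A data frame with columns `otu_id` and `sequence` (uppercase
#'   DNA, IUPAC alphabet), e.g. from [read_reference_fasta()].
#' @return An object of class `concatesome`: a list with `sequence` (single
#'   string), `offsets` (0-based integer starts), and `otu_ids`.
#' @examples
#' cs <- build_concatesome(
#'   tibble::tibble(otu_id = c("A", "B"), sequence = c("ACGT", "GGCC"))
#' )
#' cs$offsets  # 0 4
#' @export
build_concatesome <- function(refs) {
  refs <- as_tibble(refs)
  stopifnot(all(c("otu_id", "sequence") %in% names(refs)))
  if (nrow(refs) == 0L) {
    abort("reference set is empty; cannot build a concatesome")
  }
  dup <- refs$otu_id[duplicated(refs$otu_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate OTU id(s) in reference set: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(refs$otu_id))) abort("empty OTU id in reference set")
  empty <- which(!nzchar(refs$sequence))
  if (length(empty) > 0L) {
    abort(paste0("empty sequence for reference record(s): ",
                 paste(refs$otu_id[empty], collapse = ", ")))
  }
  bad <- !grepl(paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]+$"),
                refs$sequence)
  if (any(bad)) {
    abort(paste0("non-IUPAC characters in reference(s): ",
                 paste(refs$otu_id[bad], collapse = ", ")))
  }
  lens <- nchar(refs$sequence)
  structure(
    list(
      sequence = paste(refs$sequence, collapse = ""),
      offsets = as.integer(cumsum(c(0L, lens[-length(lens)]))),
      otu_ids = refs$otu_id
    ),
    class = "concatesome"
  )
}

#' @export
print.concatesome <- function(x, ...) {
  cat("<concatesome> ", length(x$otu_ids), " references, ",
      nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

#' @export
length.concatesome <- function(x) nchar(x$sequence)

#' Write a concatesome as single-line FASTA plus an offset index
#'
#' The FASTA holds exactly one record whose sequence is on a single line
#' (the form a BWT database builder consumes); the index is a headerless
#' two-column TSV of `otu_id` and 0-based start offset, in concatesome order.
#'
#' @param cs A `concatesome`.
#' @param fasta_path,index_path Output paths.
#' @param record_id FASTA record name (default `"concatesome"`).
#' @return Invisibly, `cs`.
#' @export
write_concatesome <- function(cs, fasta_path, index_path,
                              record_id = "concatesome") {
  stopifnot(inherits(cs, "concatesome"))
  if (nchar(cs$sequence) == 0L || length(cs$otu_ids) == 0L) {
    abort("refusing to write an empty concatesome")
  }
  writeLines(c(paste0(">", record_id), cs$sequence), fasta_path)
  writeLines(paste(cs$otu_ids, cs$offsets, sep = "\t"), index_path)
  invisible(cs)
}

#' Read a concatesome back from FASTA + index files
#'
#' @param fasta_path,index_path Paths written by [write_concatesome()].
#' @return A `concatesome`.
#' @export
read_concatesome <- function(fasta_path, index_path) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1L) {
    abort("concatesome FASTA must contain exactly one record")
  }
  idx <- read_concatesome_index(index_path)
  structure(
    list(
      sequence = toupper(as.character(set[[1L]])),
      offsets = idx$offset,
      otu_ids = idx$otu_id
    ),
    class = "concatesome"
  )
}

#' Read a concatesome offset index
#'
#' @param index_path Two-column headerless TSV (otu_id, 0-based offset).
#' @return A tibble with columns `otu_id` and `offset`.
#' @export
read_concatesome_index <- function(index_path) {
  raw <- utils::read.delim(index_path, header = FALSE,
                           colClasses = c("character", "integer"),
                           col.names = c("otu_id", "offset"))
  as_tibble(raw)
}

#' Resolve a concatesome alignment to an OTU, rejecting junction hits
#'
#' Maps a 0-based half-open reference interval `[start, start + ref_span)` on
#' the concatesome to the OTU whose slice contains it. An alignment whose end
#' extends past the start of the next concatenated gene spans a junction and
#' is biologically meaningless; it is rejected. An alignment ending flush at
#' the next gene's start (half-open end equal to the next offset) is a
#' legitimate full-length match and is kept.
#'
#' @param cs A `concatesome`.
#' @param start 0-based start position(s) on the concatesome.
#' @param ref_span Number of reference bases consumed (positive).
#' @return A tibble with one row per input: `start`, `ref_span`, `otu_id`
#'   (NA when rejected), and `status` (`"ok"` or `"junction"`).
#' @export
locate_hit <- function(cs, start, ref_span) {
  stopifnot(inherits(cs, "concatesome"))
  n <- length(start)
  stopifnot(length(ref_span) == n)
  total <- nchar(cs$sequence)
  if (any(start < 0L) || any(ref_span < 1L) || any(start + ref_span > total)) {
    abort("alignment coordinates out of concatesome bounds")
  }
  # findInterval is a binary search over the ascending offsets
  i <- findInterval(start, cs$offsets)
  nxt <- c(cs$offsets[-1L], total)
  junction <- (start + ref_span) > nxt[i]
  tibble(
    start = as.integer(start),
    ref_span = as.integer(ref_span),
    otu_id = ifelse(junction, NA_character_, cs$otu_ids[i]),
    status = ifelse(junction, "junction", "ok")
  )
}
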