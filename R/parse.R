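# SAM parsing and OTU table assembly: alignment coordinates are resolved to
# OTUs through the concatesome index, junction-spanning hits discarded, and
# dictionary entries expanded back to per-sample read counts.

#' Reference span consumed by a CIGAR string
#'
#' Operations M, =, X, D, and N consume reference; I, S, H, and P do not.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference bases consumed.
#' @export
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
    if (length(lens) != length(ops)) abort(paste0("malformed CIGAR: ", cg))
    sum(lens[ops %in% c("M", "=", "X", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Parse a headerless SAM file of concatesome alignments
#'
#' Consumes the mandatory SAM columns only. Records flagged unmapped
#' (FLAG bit 0x4) are skipped silently; unparseable lines are skipped with
#' one summary warning. The 1-based SAM POS is converted to a 0-based
#' concatesome coordinate here — the single conversion point in the
#' pipeline.
#'
#' @param path Path to a (headerless) SAM file; header lines (`@`) are
#'   tolerated and ignored.
#' @return A tibble: `query_tag`, `concat_start` (0-based), `cigar`,
#'   `ref_span`.
#' @export
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 6L && !is.na(suppressWarnings(as.integer(f[[2L]]))) &&
      !is.na(suppressWarnings(as.integer(f[[4L]])))
  }, logical(1L))
  if (any(!ok)) {
    warn(paste0("skipped ", sum(!ok), " unparseable SAM line(s)"))
    fields <- fields[ok]
  }
  if (length(fields) == 0L) {
    return(tibble(query_tag = character(0), concat_start = integer(0),
                  cigar = character(0), ref_span = integer(0)))
  }
  flag <- vapply(fields, function(f) as.integer(f[[2L]]), integer(1L))
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]
  tibble(
    query_tag = vapply(fields, `[[`, "", 1L),
    concat_start = vapply(fields, function(f)
      as.integer(f[[4L]]) - 1L, integer(1L)),
    cigar = vapply(fields, `[[`, "", 6L)
  ) |>
    mutate(ref_span = cigar_ref_span(.data$cigar))
}

#' Assemble the sample-by-OTU table from hits, dictionary, and taxonomy
#'
#' Each surviving hit assigns its dictionary entry's full per-sample counts
#' to the matched OTU; hits whose alignment crosses a junction between
#' concatenated marker genes are discarded and tallied. Row order is first
#' appearance in the hit stream; columns are sample ids in sorted order.
#' When several hits share one tag (possible only with an externally
#' produced SAM) the first line wins and later ones are warned about.
#'
#' @param hits Tibble from [parse_sam()] or [align_reads()] (only rows with
#'   `aligned = TRUE` are used when that column is present).
#' @param cs The `concatesome` the alignments refer to.
#' @param dict The `dedup_dict` covering every hit tag.
#' @param tax Optional taxonomy map (tibble `otu_id`, `taxonomy`); OTUs
#'   absent from the map are annotated `"Unassigned"`.
#' @return An `otu_table`; junction statistics and the assigned/junction tag
#'   sets ride along for accounting (see [glance.otu_table()]).
#' @export
assemble_table <- function(hits, cs, dict, tax = NULL) {
  stopifnot(inherits(cs, "concatesome"))
  if ("aligned" %in% names(hits)) hits <- filter(hits, .data$aligned)
  if (anyDuplicated(hits$query_tag)) {
    dups <- unique(hits$query_tag[duplicated(hits$query_tag)])
    warn(paste0("multiple hits for ", length(dups),
                " tag(s); keeping the first of each"))
    hits <- hits[!duplicated(hits$query_tag), , drop = FALSE]
  }
  missing <- setdiff(hits$query_tag, dict$tag)
  if (length(missing) > 0L) {
    abort(paste0("hit tag(s) absent from the sample dictionary: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  totals <- dict |>
    group_by(.data$tag) |>
    summarise(total = sum(.data$count), .groups = "drop")

  if (nrow(hits) > 0L) {
    loc <- locate_hit(cs, hits$concat_start, hits$ref_span)
    hits$otu_id <- loc$otu_id
    junction_tags <- hits$query_tag[loc$status == "junction"]
    kept <- hits[loc$status == "ok", , drop = FALSE]
  } else {
    hits$otu_id <- character(0)
    junction_tags <- character(0)
    kept <- hits
  }
  junction_reads <- sum(totals$total[totals$tag %in% junction_tags])

  expanded <- kept |>
    select("query_tag", "otu_id") |>
    left_join(dict, by = c(query_tag = "tag"),
              relationship = "one-to-many") |>
    group_by(.data$otu_id, .data$sample_id) |>
    summarise(count = sum(.data$count), .groups = "drop")

  otu_ids <- unique(kept$otu_id)  # first appearance in hit stream
  sample_ids <- stringr::str_sort(unique(expanded$sample_id), locale = "C")
  taxonomy <- NULL
  if (!is.null(tax)) {
    taxonomy <- tax$taxonomy[match(otu_ids, tax$otu_id)]
    taxonomy[is.na(taxonomy)] <- "Unassigned"
    taxonomy <- normalize_taxonomy(taxonomy)
  }
  new_otu_table(
    otu_ids, sample_ids,
    expanded[, c("otu_id", "sample_id", "count")],
    taxonomy = taxonomy,
    junction_hits = length(junction_tags),
    junction_reads = as.integer(junction_reads),
    assigned_tags = kept$query_tag,
    junction_tags = junction_tags
  )
}

#' Write the dictionary sequences that failed to match the database
#'
#' Entries with no surviving hit — neither assigned to an OTU nor dropped at
#' a junction — are written as FASTA, headed by their dictionary tags, e.g.
#' as input for a subsequent de novo clustering step.
#'
#' @param dict The `dedup_dict`.
#' @param t The assembled `otu_table` (carries the assigned/junction tags).
#' @param path Output FASTA path.
#' @return Invisibly, a tibble of the unmatched entries (`tag`, `sequence`,
#'   `total`).
#' @export
collect_unmatched <- function(dict, t, path) {
  stopifnot(inherits(t, "otu_table"))
  ent <- dict_entries(dict)
  un <- filter(ent, !.data$tag %in% c(t$assigned_tags, t$junction_tags))
  writeLines(
    if (nrow(un) > 0L) paste0(">", un$tag, "\n", un$sequence) else character(0),
    path
  )
  invisible(un)
}
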