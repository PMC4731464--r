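# The sparse sample-by-OTU count table and its serializations.

BIOM_FORMAT <- "Biological Observation Matrix 1.0.0"
BIOM_URL <- "http://biom-format.org"

# taxonomy strings are normalized to "; "-joined ranks so that all writers
# and readers agree byte-for-byte
normalize_taxonomy <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(trimws(strsplit(s, ";", fixed = TRUE)[[1L]]), collapse = "; ")
  }, character(1L), USE.NAMES = FALSE)
}

#' Read an OTU-to-taxonomy map
#'
#' @param path Two-column TSV (otu_id, semicolon-delimited taxonomy string),
#'   no header.
#' @return A tibble with columns `otu_id` and `taxonomy` (normalized to
#'   `"; "`-joined ranks).
#' @export
read_taxonomy_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("otu_id", "taxonomy"),
                           quote = "")
  tibble(otu_id = raw$otu_id, taxonomy = normalize_taxonomy(raw$taxonomy))
}

new_otu_table <- function(otu_ids, sample_ids, counts, taxonomy = NULL,
                          junction_hits = 0L, junction_reads = 0L,
                          assigned_tags = character(0),
                          junction_tags = character(0)) {
  stopifnot(is.data.frame(counts),
            all(c("otu_id", "sample_id", "count") %in% names(counts)))
  if (nrow(counts) > 0L) {
    stopifnot(all(counts$count >= 1L),
              all(counts$otu_id %in% otu_ids),
              all(counts$sample_id %in% sample_ids),
              !anyDuplicated(counts[c("otu_id", "sample_id")]))
  }
  if (!is.null(taxonomy)) stopifnot(length(taxonomy) == length(otu_ids))
  structure(
    list(otu_ids = otu_ids, sample_ids = sample_ids,
         counts = as_tibble(counts), taxonomy = taxonomy,
         junction_hits = junction_hits, junction_reads = junction_reads,
         assigned_tags = assigned_tags, junction_tags = junction_tags),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", length(x$otu_ids), " OTUs x ", length(x$sample_ids),
      " samples, ", sum(x$counts$count), " reads",
      if (!is.null(x$taxonomy)) ", taxonomy-annotated" else "",
      "\n", sep = "")
  if (x$junction_hits > 0L) {
    cat("  junction hits discarded: ", x$junction_hits, " (",
        x$junction_reads, " reads)\n", sep = "")
  }
  invisible(x)
}

#' Tidy an OTU table into a long tibble
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A tibble with columns `otu_id`, `sample_id`, `count`, and
#'   `taxonomy` when present; only nonzero cells, in table order.
#' @method tidy otu_table
#' @export
tidy.otu_table <- function(x, ...) {
  out <- x$counts |>
    mutate(
      otu_id = factor(.data$otu_id, levels = x$otu_ids),
      sample_id = factor(.data$sample_id, levels = x$sample_ids)
    ) |>
    arrange(.data$otu_id, .data$sample_id) |>
    mutate(otu_id = as.character(.data$otu_id),
           sample_id = as.character(.data$sample_id))
  if (!is.null(x$taxonomy)) {
    out$taxonomy <- x$taxonomy[match(out$otu_id, x$otu_ids)]
  }
  out
}

#' One-row summary of an OTU table
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A one-row tibble: `n_otus`, `n_samples`, `total_count`,
#'   `density` (filled fraction of the matrix), `junction_hits`,
#'   `junction_reads`.
#' @method glance otu_table
#' @export
glance.otu_table <- function(x, ...) {
  cells <- length(x$otu_ids) * length(x$sample_ids)
  tibble(
    n_otus = length(x$otu_ids),
    n_samples = length(x$sample_ids),
    total_count = sum(x$counts$count),
    density = if (cells > 0L) nrow(x$counts) / cells else NA_real_,
    junction_hits = x$junction_hits,
    junction_reads = x$junction_reads
  )
}

#' @export
as.matrix.otu_table <- function(x, ...) {
  m <- matrix(0L, length(x$otu_ids), length(x$sample_ids),
              dimnames = list(x$otu_ids, x$sample_ids))
  if (nrow(x$counts) > 0L) {
    m[cbind(match(x$counts$otu_id, x$otu_ids),
            match(x$counts$sample_id, x$sample_ids))] <- x$counts$count
  }
  m
}

#' Heatmap of an OTU table
#'
#' @param object An `otu_table`.
#' @param ... Unused.
#' @return A ggplot: samples by OTUs, tile fill = log10(count + 1).
#' @method autoplot otu_table
#' @export
autoplot.otu_table <- function(object, ...) {
  td <- tidy(object)
  td$otu_id <- factor(td$otu_id, levels = rev(object$otu_ids))
  td$sample_id <- factor(td$sample_id, levels = object$sample_ids)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$sample_id, y = .data$otu_id,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count+1)") +
    ggplot2::labs(x = "Sample", y = "OTU") +
    ggplot2::theme_minimal()
}

#' Write an OTU table as sparse BIOM 1.0 JSON
#'
#' A single JSON document with the required BIOM 1.0 keys (`id`, `format`,
#' `format_url`, `type`, `generated_by`, `date`, `matrix_type` "sparse",
#' `matrix_element_type` "int", `shape`, `rows`, `columns`, `data`).
#' Taxonomy, when present, is stored per row as a list of ranks under
#' `metadata$taxonomy`.
#'
#' @param t An `otu_table`.
#' @param path Output path.
#' @param table_id Value of the BIOM `id` key.
#' @param date Timestamp string for the `date` key; pass a fixed value for
#'   byte-reproducible output, or `NULL` for the current time.
#' @return Invisibly, `path`.
#' @export
write_biom <- function(t, path, table_id = "otupick OTU table",
                       date = NULL) {
  stopifnot(inherits(t, "otu_table"))
  if (is.null(date)) date <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  rows <- purrr::map(seq_along(t$otu_ids), function(i) {
    md <- if (is.null(t$taxonomy)) NULL else
      list(taxonomy = as.list(strsplit(t$taxonomy[i], "; ",
                                       fixed = TRUE)[[1L]]))
    list(id = t$otu_ids[i], metadata = md)
  })
  cols <- purrr::map(t$sample_ids, function(s) list(id = s, metadata = NULL))
  data <- purrr::pmap(
    list(match(t$counts$otu_id, t$otu_ids) - 1L,
         match(t$counts$sample_id, t$sample_ids) - 1L,
         t$counts$count),
    function(r, c, v) list(r, c, v)
  )
  doc <- list(
    id = table_id,
    format = BIOM_FORMAT,
    format_url = BIOM_URL,
    type = "OTU table",
    generated_by = paste0("otupick ",
                          as.character(utils::packageVersion("otupick"))),
    date = date,
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = c(length(t$otu_ids), length(t$sample_ids)),
    rows = rows,
    columns = cols,
    data = data
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a sparse BIOM 1.0 JSON file back into an OTU table
#'
#' @param path Path to a BIOM 1.0 JSON document.
#' @return An `otu_table`.
#' @export
read_biom_table <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$matrix_type, "sparse")) {
    abort("only sparse BIOM 1.0 documents are supported")
  }
  otu_ids <- vapply(doc$rows, function(r) r$id, character(1L))
  sample_ids <- vapply(doc$columns, function(s) s$id, character(1L))
  tax <- NULL
  has_tax <- any(vapply(doc$rows, function(r)
    !is.null(r$metadata$taxonomy), logical(1L)))
  if (has_tax) {
    tax <- vapply(doc$rows, function(r) {
      tx <- r$metadata$taxonomy
      if (is.null(tx)) NA_character_ else
        paste(unlist(tx), collapse = "; ")
    }, character(1L))
  }
  if (length(doc$data) > 0L) {
    counts <- tibble(
      otu_id = otu_ids[vapply(doc$data, function(d) d[[1L]],
                              numeric(1L)) + 1L],
      sample_id = sample_ids[vapply(doc$data, function(d) d[[2L]],
                                    numeric(1L)) + 1L],
      count = as.integer(vapply(doc$data, function(d) d[[3L]], numeric(1L)))
    )
  } else {
    counts <- tibble(otu_id = character(0), sample_id = character(0),
                     count = integer(0))
  }
  new_otu_table(otu_ids, sample_ids, counts, taxonomy = tax)
}

#' Write an OTU table in legacy tab-delimited format
#'
#' Header line `#OTU ID<TAB>sample...<TAB>taxonomy` (taxonomy column present
#' only when the table is annotated), then one dense integer row per OTU.
#'
#' @param t An `otu_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_legacy <- function(t, path) {
  stopifnot(inherits(t, "otu_table"))
  m <- as.matrix(t)
  header <- paste(c("#OTU ID", t$sample_ids,
                    if (!is.null(t$taxonomy)) "taxonomy"), collapse = "\t")
  body <- vapply(seq_along(t$otu_ids), function(i) {
    paste(c(t$otu_ids[i], m[i, ],
            if (!is.null(t$taxonomy)) t$taxonomy[i]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a legacy tab-delimited OTU table
#'
#' @param path Path written by [write_legacy()].
#' @return An `otu_table`.
#' @export
read_legacy_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#OTU ID")) {
    abort("not a legacy OTU table (missing '#OTU ID' header)")
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_tax <- identical(tail(header, 1L), "taxonomy")
  sample_ids <- header[-1L]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  body <- lines[-1L]
  otu_ids <- character(0)
  tax <- if (has_tax) character(0) else NULL
  cells <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    otu_ids <- c(otu_ids, f[1L])
    vals <- as.integer(f[seq_along(sample_ids) + 1L])
    if (has_tax) tax <- c(tax, f[length(f)])
    nz <- which(vals > 0L)
    if (length(nz) > 0L) {
      cells[[length(cells) + 1L]] <- tibble(
        otu_id = f[1L], sample_id = sample_ids[nz], count = vals[nz]
      )
    }
  }
  counts <- if (length(cells) > 0L) bind_rows(cells) else
    tibble(otu_id = character(0), sample_id = character(0),
           count = integer(0))
  new_otu_table(otu_ids, sample_ids, counts, taxonomy = tax)
}
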