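# One-command orchestration: prep (concatesome) -> filter -> align -> parse.

#' Configure a pipeline run
#'
#' @param refs Path to the multi-FASTA of reference marker genes.
#' @param reads Path to the demultiplexed reads FASTA.
#' @param out_dir Output directory; all intermediates and results are
#'   written here (auditable stages over opaque in-memory hand-off).
#' @param trim_length Optional fixed trim length applied before
#'   deduplication.
#' @param rc Reverse-complement filtered reads at output (use when reads
#'   are sequenced antisense to the reference database).
#' @param d_level Dedup stringency: 0 = plain dedup, 1 = + read compaction
#'   (default), 2 = + drop singletons, 3 = + drop doubletons, ...
#' @param k K-mer size for denoising (default 8).
#' @param denoise_fraction Optional k-mer prevalence threshold in (0, 1);
#'   `NULL` (default) disables k-mer denoising.
#' @param min_identity Percent-identity threshold for alignment (0.97).
#' @param preset Aligner effort: `"fast"`, `"default"`, or `"max"`.
#' @param aligner `"embedded"` to align with the package's FM-index
#'   aligner, or `"external"` to consume a SAM file produced by an external
#'   BWT aligner (see [external_aligner_command()]).
#' @param sam Path to the externally produced headerless SAM
#'   (`aligner = "external"` only).
#' @param taxonomy Optional path to an OTU-to-taxonomy TSV.
#' @param format Output table format, `"biom"` or `"legacy"`.
#' @param unmatched Also write a FASTA of sequences that failed to match?
#' @param biom_date Timestamp written into the BIOM `date` field; fixed by
#'   default so identical inputs give byte-identical outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(refs, reads, out_dir,
                            trim_length = NULL, rc = FALSE, d_level = 1L,
                            k = 8L, denoise_fraction = NULL,
                            min_identity = 0.97, preset = "default",
                            aligner = c("embedded", "external"),
                            sam = NULL, taxonomy = NULL,
                            format = c("biom", "legacy"),
                            unmatched = FALSE,
                            biom_date = "1970-01-01T00:00:00") {
  aligner <- match.arg(aligner)
  format <- match.arg(format)
  for (p in c(refs, reads, sam, taxonomy)) {
    if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
  }
  if (aligner == "external" && is.null(sam)) {
    abort("external aligner mode requires a 'sam' path")
  }
  structure(
    list(refs = refs, reads = reads, out_dir = out_dir,
         trim_length = trim_length, rc = rc, d_level = as.integer(d_level),
         k = as.integer(k), denoise_fraction = denoise_fraction,
         min_identity = min_identity, preset = preset, aligner = aligner,
         sam = sam, taxonomy = taxonomy, format = format,
         unmatched = unmatched, biom_date = biom_date),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full closed-reference OTU-picking pipeline
#'
#' Stages: build and write the concatesome; parse, trim, deduplicate,
#' optionally denoise and multiplicity-filter the reads into the sample
#' dictionary; align the dictionary sequences (embedded FM-index aligner,
#' or an externally supplied SAM); resolve hits to OTUs, discard junction
#' hits, expand to per-sample counts, and write the OTU table. Identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return An `otupick_run` summary; the assembled `otu_table` is in
#'   `$table` and all output paths in `$paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    concat_fasta = file.path(cfg$out_dir, "concatesome.fna"),
    concat_index = file.path(cfg$out_dir, "concatesome.idx"),
    filtered = file.path(cfg$out_dir, "filtered.fna"),
    dict = file.path(cfg$out_dir, "samples.tsv"),
    sam = if (cfg$aligner == "embedded")
      file.path(cfg$out_dir, "hits.sam") else cfg$sam,
    table = file.path(cfg$out_dir,
                      if (cfg$format == "biom") "table.biom" else "table.txt"),
    unmatched = if (cfg$unmatched)
      file.path(cfg$out_dir, "unmatched.fna") else NULL
  )

  cs <- run_stage("prep", {
    refs <- read_reference_fasta(cfg$refs)
    cs <- build_concatesome(refs)
    write_concatesome(cs, paths$concat_fasta, paths$concat_index)
    cs
  })

  filt <- run_stage("filter", {
    reads <- parse_reads(cfg$reads)
    n_in <- nrow(reads)
    reads$sequence <- trim_read(reads$sequence, cfg$trim_length)
    n_denoised <- 0L
    if (!is.null(cfg$denoise_fraction)) {
      counter <- build_kmer_counter(reads, cfg$k)
      parts <- denoise_reads(reads, counter, cfg$denoise_fraction)
      n_denoised <- nrow(parts$discarded)
      reads <- parts$kept
    }
    d <- deduplicate(reads)
    n_unique_raw <- nrow(dict_entries(d))
    if (cfg$d_level >= 1L) d <- compact_reads(d)
    if (cfg$d_level >= 2L) d <- filter_by_count(d, cfg$d_level)
    write_filtered(d, paths$filtered, paths$dict, rc = cfg$rc)
    list(dict = d, n_in = n_in, n_denoised = n_denoised,
         n_unique_raw = n_unique_raw)
  })

  run_stage("align", {
    if (cfg$aligner == "embedded") {
      idx <- build_fm_index(cs)
      queries <- dict_entries(filt$dict)
      if (cfg$rc) queries$sequence <- reverse_complement(queries$sequence)
      hits <- align_reads(queries, idx, cs,
                          scoring_contract(cfg$min_identity), cfg$preset)
      write_sam(hits, paths$sam,
                sequences = setNames(queries$sequence, queries$tag))
    }
    invisible(NULL)
  })

  result <- run_stage("parse", {
    hits <- parse_sam(paths$sam)
    tax <- if (!is.null(cfg$taxonomy)) read_taxonomy_map(cfg$taxonomy)
    t <- assemble_table(hits, cs, filt$dict, tax)
    if (cfg$format == "biom") {
      write_biom(t, paths$table, date = cfg$biom_date)
    } else {
      write_legacy(t, paths$table)
    }
    un <- NULL
    if (cfg$unmatched) un <- collect_unmatched(filt$dict, t, paths$unmatched)
    list(table = t, unmatched = un)
  })

  t <- result$table
  ent <- dict_entries(filt$dict)
  structure(
    list(
      table = t,
      paths = paths,
      config = cfg,
      counts = list(
        reads_in = filt$n_in,
        reads_denoised = filt$n_denoised,
        unique_sequences = filt$n_unique_raw,
        duplicates_removed = filt$n_in - filt$n_denoised - filt$n_unique_raw,
        entries_aligned = nrow(ent),
        dict_reads = sum(ent$total),
        reads_tabled = sum(t$counts$count),
        junction_hits = t$junction_hits,
        junction_reads = t$junction_reads,
        unmatched_entries = nrow(ent) -
          length(t$assigned_tags) - length(t$junction_tags),
        otus_observed = length(t$otu_ids)
      )
    ),
    class = "otupick_run"
  )
}

#' @export
print.otupick_run <- function(x, ...) {
  cnt <- x$counts
  cat("<otupick_run>\n")
  cat("  reads in:            ", cnt$reads_in, "\n", sep = "")
  cat("  denoised (discarded):", cnt$reads_denoised, "\n", sep = " ")
  cat("  unique sequences:    ", cnt$unique_sequences, "\n", sep = "")
  cat("  entries aligned:     ", cnt$entries_aligned, "\n", sep = "")
  cat("  reads in table:      ", cnt$reads_tabled, "\n", sep = "")
  cat("  junction discards:   ", cnt$junction_hits, " hits / ",
      cnt$junction_reads, " reads\n", sep = "")
  cat("  unmatched entries:   ", cnt$unmatched_entries, "\n", sep = "")
  cat("  OTUs observed:       ", cnt$otus_observed, "\n", sep = "")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `otupick_run`.
#' @param ... Unused.
#' @return A one-row tibble of the run's counters.
#' @method glance otupick_run
#' @export
glance.otupick_run <- function(x, ...) {
  as_tibble(x$counts)
}

#' Read-fate bar chart for a pipeline run
#'
#' @param object An `otupick_run`.
#' @param ... Unused.
#' @return A ggplot showing how many input reads were tabled, dropped at
#'   junctions, unmatched, or discarded by denoising.
#' @method autoplot otupick_run
#' @export
autoplot.otupick_run <- function(object, ...) {
  cnt <- object$counts
  unmatched_reads <- cnt$dict_reads - cnt$reads_tabled - cnt$junction_reads
  count_filtered <- cnt$reads_in - cnt$reads_denoised - cnt$dict_reads
  lv <- c("tabled", "junction", "unmatched", "count-filtered", "denoised")
  df <- tibble(
    fate = factor(lv, levels = lv),
    reads = c(cnt$reads_tabled, cnt$junction_reads, unmatched_reads,
              count_filtered, cnt$reads_denoised)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fate, y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Reads") +
    ggplot2::theme_minimal()
}
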