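# Synthetic marker-gene references, taxonomy, and multi-sample amplicon
# reads with controlled error, so the whole pipeline is testable without
# any external database.

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Specify a synthetic amplicon simulation
#'
#' Defaults describe a small but realistic marker-gene study: a handful of
#' references a few hundred bases long, three samples of 100 reads each with
#' geometrically decaying (few-taxa-dominated) abundances, error-free
#' 150-base amplicon reads. All randomness is fixed by `seed`.
#'
#' @param n_references Number of reference marker genes.
#' @param reference_length Length range (min, max) of references, in bases.
#' @param n_samples Number of samples.
#' @param reads_per_sample Reads drawn per sample.
#' @param abundance_ratio Geometric decay of per-sample reference
#'   abundances; each sample gets its own random preference order.
#' @param substitution_rate Per-base substitution probability in reads.
#' @param indel_rate Per-base probability of a 1-base insertion or deletion.
#' @param read_length Amplicon read length (reads are reference prefixes,
#'   uniform start, as for primer-anchored amplicons).
#' @param length_jitter Maximum uniform shortening of each read, in bases
#'   (emulates variable trimming).
#' @param mode `"amplicon"` (prefix reads) or `"shotgun"` (uniform random
#'   start positions on the concatenated reference — exists to manufacture
#'   junction-spanning alignments for testing).
#' @param seed Integer RNG seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_references = 5L,
                            reference_length = c(200L, 280L),
                            n_samples = 3L,
                            reads_per_sample = 100L,
                            abundance_ratio = 0.5,
                            substitution_rate = 0,
                            indel_rate = 0,
                            read_length = 150L,
                            length_jitter = 0L,
                            mode = c("amplicon", "shotgun"),
                            seed = 1L) {
  stopifnot(n_references >= 1L, n_samples >= 1L, reads_per_sample >= 0L,
            substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            read_length >= 1L, length_jitter >= 0L,
            min(reference_length) >= read_length)
  structure(
    list(n_references = n_references,
         reference_length = as.integer(reference_length),
         n_samples = n_samples, reads_per_sample = reads_per_sample,
         abundance_ratio = abundance_ratio,
         substitution_rate = substitution_rate, indel_rate = indel_rate,
         read_length = as.integer(read_length),
         length_jitter = as.integer(length_jitter),
         mode = match.arg(mode), seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

mutate_read <- function(seq, sub_rate, indel_rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  subs <- which(stats::runif(n) < sub_rate)
  for (i in subs) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  n_ins <- 0L
  n_del <- 0L
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_len(n)) {
      if (stats::runif(1L) < indel_rate) {
        if (stats::runif(1L) < 0.5) {
          n_del <- n_del + 1L
          next  # deletion: drop this base
        }
        out <- c(out, sample(c("A", "C", "G", "T"), 1L))
        n_ins <- n_ins + 1L
      }
      out <- c(out, bases[i])
    }
    bases <- out
  }
  list(sequence = paste(bases, collapse = ""),
       n_sub = length(subs), n_ins = n_ins, n_del = n_del)
}

#' Simulate a synthetic reference set, taxonomy, and amplicon reads
#'
#' References are rejection-sampled until all pairs fall below 97% identity
#' (checked with the package's own semi-global scorer over read-length
#' prefixes), so closed-reference assignment of simulated reads is
#' unambiguous. A manifest records every read's true reference, sample, and
#' introduced edits.
#'
#' @param spec A [simulation_spec()].
#' @param max_attempts Rejection-sampling attempts before giving up.
#' @return A list: `refs` (tibble `otu_id`, `sequence`), `reads` (tibble
#'   `sample_id`, `read_id`, `sequence`), `taxonomy` (tibble `otu_id`,
#'   `taxonomy`), `manifest` (tibble with one row per read: `read_id`,
#'   `sample_id`, `otu_id`, `start`, `n_sub`, `n_ins`, `n_del`, `length`).
#' @export
simulate_community <- function(spec, max_attempts = 20L) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_fixed_seed(spec$seed, {
    refs <- NULL
    for (attempt in seq_len(max_attempts)) {
      lens <- sample(seq(spec$reference_length[1L], spec$reference_length[2L]),
                     spec$n_references, replace = TRUE)
      seqs <- vapply(lens, random_dna, character(1L))
      ok <- TRUE
      if (spec$n_references > 1L) {
        w <- spec$read_length
        for (a in seq_len(spec$n_references - 1L)) {
          for (b in (a + 1L):spec$n_references) {
            id <- semi_global_identity(substr(seqs[a], 1L, w),
                                       seqs[b])$identity
            if (id >= 0.97) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (ok) {
        refs <- tibble(otu_id = paste0("OTU", seq_len(spec$n_references)),
                       sequence = seqs)
        break
      }
    }
    if (is.null(refs)) {
      abort("could not sample sufficiently distinct references")
    }

    taxonomy <- tibble(
      otu_id = refs$otu_id,
      taxonomy = paste0("k__Bacteria; p__Phylum", seq_len(spec$n_references),
                        "; g__Genus", seq_len(spec$n_references),
                        "; s__species", seq_len(spec$n_references))
    )

    concat <- paste(refs$sequence, collapse = "")
    reflens <- nchar(refs$sequence)
    rows <- vector("list", spec$n_samples)
    for (s in seq_len(spec$n_samples)) {
      pref <- sample(spec$n_references)  # sample-specific preference order
      probs <- spec$abundance_ratio^(order(pref) - 1L)
      probs <- probs / sum(probs)
      picks <- sample(spec$n_references, spec$reads_per_sample,
                      replace = TRUE, prob = probs)
      out <- vector("list", spec$reads_per_sample)
      for (r in seq_along(picks)) {
        ref_i <- picks[r]
        len <- spec$read_length -
          if (spec$length_jitter > 0L)
            sample(0:spec$length_jitter, 1L) else 0L
        if (spec$mode == "amplicon") {
          start <- 0L
          raw <- substr(refs$sequence[ref_i], 1L, len)
        } else {
          start <- sample(0:(nchar(concat) - len), 1L)
          raw <- substr(concat, start + 1L, start + len)
          ref_i <- findInterval(start, cumsum(c(0L, reflens))[-length(reflens) - 1L])
        }
        mut <- mutate_read(raw, spec$substitution_rate, spec$indel_rate)
        out[[r]] <- tibble(
          read_id = paste0("S", s, "_", r - 1L),
          sample_id = paste0("S", s),
          otu_id = refs$otu_id[ref_i],
          start = start,
          sequence = mut$sequence,
          n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del,
          length = nchar(mut$sequence)
        )
      }
      rows[[s]] <- bind_rows(out)
    }
    manifest <- bind_rows(rows)
    list(
      refs = refs,
      reads = manifest[, c("sample_id", "read_id", "sequence")],
      taxonomy = taxonomy,
      manifest = manifest[, c("read_id", "sample_id", "otu_id", "start",
                              "n_sub", "n_ins", "n_del", "length")]
    )
  })
}

#' Write a simulated community to disk
#'
#' Emits `refs.fna`, `reads.fna` (headers `SampleID_ReadNumber`),
#' `taxonomy.tsv`, and `manifest.json` under `dir`.
#'
#' @param sim A [simulate_community()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    refs = file.path(dir, "refs.fna"),
    reads = file.path(dir, "reads.fna"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  writeLines(paste0(">", sim$refs$otu_id, "\n", sim$refs$sequence),
             paths$refs)
  writeLines(paste0(">", sim$reads$read_id, "\n", sim$reads$sequence),
             paths$reads)
  writeLines(paste(sim$taxonomy$otu_id, sim$taxonomy$taxonomy, sep = "\t"),
             paths$taxonomy)
  jsonlite::write_json(sim$manifest, paths$manifest, digits = NA)
  invisible(paths)
}
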