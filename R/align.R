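# Percent-identity alignment: the scoring contract, the semi-global dynamic
# program that defines %ID, the embedded seed-and-extend aligner over the
# FM-index, and the external (bowtie2-style) command parameterization.

# IUPAC nucleotide bitmasks; two characters "match" when their base sets
# intersect, so matches to ambiguity codes are never penalized
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

iupac_codes <- function(seq) {
  m <- IUPAC_MASK[strsplit(seq, "", fixed = TRUE)[[1L]]]
  if (anyNA(m)) abort("sequence contains non-IUPAC characters")
  unname(m)
}

#' Percent-identity scoring contract
#'
#' The matching criterion: every match in an alignment weighs 1 and every
#' mismatch 0; matches to ambiguous bases are not penalized; sequential gaps
#' weigh no differently than single gaps (no affine penalty). Identity is
#' the summed match score divided by the total alignment length spanning the
#' query, and a hit is acceptable when identity reaches `min_identity`.
#'
#' @param min_identity Minimum acceptable identity, in (0, 1].
#' @return A `scoring_contract` list.
#' @export
scoring_contract <- function(min_identity = 0.97) {
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 1) {
    abort("min_identity must be in (0, 1]")
  }
  structure(
    list(match_weight = 1, mismatch_weight = 0, ambiguous_weight = 1,
         gap_open_extra = 0, min_identity = min_identity),
    class = "scoring_contract"
  )
}

# one banded-free semi-global DP maximizing (matches - lambda * ref_gap_bases)
# over alignments of the whole query against any window of the reference;
# returns score matrix for traceback
sg_dp <- function(qm, rm, lambda) {
  m <- length(qm)
  n <- length(rm)
  S <- matrix(0, m + 1L, n + 1L)
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    mt <- as.numeric(bitwAnd(qm[i], rm) > 0L)           # match indicator row
    cand <- pmax(S[i, jj] + mt,                          # diagonal
                 S[i, jj + 1L])                          # insertion (query base vs gap)
    cand <- c(S[i + 1L, 1L], cand)
    # deletions decay by lambda along j: running max of cand[j'] - lambda (j - j')
    S[i + 1L, ] <- cummax(cand + lambda * (0:n)) - lambda * (0:n)
  }
  S
}

# traceback from S at the best end column; prefers diagonal, then insertion,
# then deletion (deterministic, minimizes reference gaps among optima)
sg_traceback <- function(S, qm, rm, lambda) {
  m <- length(qm)
  n <- length(rm)
  final <- S[m + 1L, ]
  j <- which.max(final) - 1L  # smallest maximizing end (0-based ref consumed)
  i <- m
  ops <- character(0)
  matches <- 0L
  dels <- 0L
  end_j <- j
  eps <- 1e-9
  while (i > 0L) {
    mt <- if (j > 0L) as.numeric(bitwAnd(qm[i], rm[j]) > 0L) else NA_real_
    if (j > 0L && abs(S[i + 1L, j + 1L] - (S[i, j] + mt)) < eps) {
      ops <- c(ops, "M")
      matches <- matches + (mt > 0)
      i <- i - 1L
      j <- j - 1L
    } else if (abs(S[i + 1L, j + 1L] - S[i, j + 1L]) < eps) {
      ops <- c(ops, "I")
      i <- i - 1L
    } else {
      ops <- c(ops, "D")
      dels <- dels + 1L
      j <- j - 1L
    }
  }
  list(matches = as.integer(matches), dels = dels,
       ref_start = j, ref_span = end_j - j, ops = rev(ops))
}

compress_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Semi-global percent-identity alignment (the %ID oracle)
#'
#' Computes the optimal alignment of the full query against a reference
#' segment with free end gaps on the reference side, under unit cost per
#' mismatch and per gap base (no affine component), and reports the identity
#' of that alignment: matching columns divided by total alignment length.
#' Ambiguity codes in the reference match any compatible base for free.
#'
#' Identity is a ratio of two alignment-dependent quantities, so the optimum
#' is found by Dinkelbach iteration: repeatedly maximize
#' `matches - lambda * ref_gap_bases` and update `lambda` with the achieved
#' identity until it stabilizes (a handful of iterations).
#'
#' @param query,reference Single DNA strings; the query must be fully
#'   covered, the reference may overhang freely on both sides.
#' @param contract A [scoring_contract()] (only used for its conventions;
#'   the identity returned is threshold-free).
#' @return A list: `identity`, `cigar` (M/I/D, M covering both matches and
#'   mismatches), `ref_start` (0-based within `reference`), `ref_span`,
#'   `matches`, `align_length`.
#' @examples
#' semi_global_identity("ACGTACGT", "ACGTACGT")$identity  # 1
#' @export
semi_global_identity <- function(query, reference,
                                 contract = scoring_contract()) {
  stopifnot(nchar(query) >= 1L, nchar(reference) >= 1L)
  qm <- iupac_codes(query)
  rm_ <- iupac_codes(reference)
  m <- length(qm)
  lambda <- 0
  best <- NULL
  for (iter in 1:25) {
    S <- sg_dp(qm, rm_, lambda)
    tb <- sg_traceback(S, qm, rm_, lambda)
    id <- tb$matches / (m + tb$dels)
    if (!is.null(best) && id <= best$identity + 1e-12) break
    best <- list(identity = id, tb = tb)
    lambda <- id
  }
  tb <- best$tb
  list(
    identity = best$identity,
    cigar = compress_cigar(tb$ops),
    ref_start = tb$ref_start,
    ref_span = tb$ref_span,
    matches = tb$matches,
    align_length = m + tb$dels
  )
}

# effort presets for the embedded seed-and-extend aligner; the preset names
# mirror the conventional fast / default / very-sensitive trade-off, the
# parameter values are this package's own
ALIGN_PRESETS <- list(
  fast    = list(seed_len = 24L, n_seed_pos = 4L,  pad = 8L,  max_cand = 16L),
  default = list(seed_len = 20L, n_seed_pos = 8L,  pad = 12L, max_cand = 32L),
  max     = list(seed_len = 16L, n_seed_pos = 16L, pad = 20L, max_cand = 64L)
)

#' Align one read against the concatesome through the FM-index
#'
#' Strategy: try an exact backward search of the whole read first (the
#' common case for amplicon data against a well-populated database); on
#' failure, take fixed-length seeds spread across the read, backward-search
#' each, and extend every candidate location with the semi-global dynamic
#' program against a padded reference window. The first candidate meeting
#' `min_identity` — in seed order, then by leftmost concatesome position —
#' wins and the search terminates, so results are deterministic. Forward
#' strand only; reads are expected already in reference orientation.
#'
#' Every returned hit is scored by [semi_global_identity()] against the
#' original concatesome text, so ambiguity-code replacements inside the
#' index never affect acceptance.
#'
#' @param idx An `fm_index` built over `cs`.
#' @param cs The `concatesome`.
#' @param read A single read sequence.
#' @param contract A [scoring_contract()].
#' @param preset `"fast"`, `"default"`, or `"max"`.
#' @return A one-row tibble: `concat_start` (0-based), `ref_span`, `cigar`,
#'   `identity`, `aligned` (logical); `aligned = FALSE` with NA fields when
#'   no acceptable hit exists.
#' @export
align_read <- function(idx, cs, read, contract = scoring_contract(),
                       preset = "default") {
  stopifnot(inherits(idx, "fm_index"), inherits(cs, "concatesome"),
            nchar(read) >= 1L)
  p <- ALIGN_PRESETS[[match.arg(preset, names(ALIGN_PRESETS))]]
  m <- nchar(read)
  no_hit <- tibble(concat_start = NA_integer_, ref_span = NA_integer_,
                   cigar = NA_character_, identity = NA_real_,
                   aligned = FALSE)
  total <- nchar(cs$sequence)

  score_window <- function(win_start, win_end) {
    segment <- substr(cs$sequence, win_start + 1L, win_end)
    res <- semi_global_identity(read, segment, contract)
    if (res$identity >= contract$min_identity) {
      tibble(concat_start = win_start + res$ref_start,
             ref_span = res$ref_span, cigar = res$cigar,
             identity = res$identity, aligned = TRUE)
    } else NULL
  }

  # stage 1: whole-read exact match
  exact <- backward_search(idx, read)
  for (pos in exact) {
    hit <- score_window(pos, min(pos + m, total))
    if (!is.null(hit)) return(hit)
  }

  # stage 2: seed and extend
  seed_len <- min(p$seed_len, m)
  starts <- unique(pmin(
    as.integer(round(seq(0L, m - seed_len, length.out = p$n_seed_pos))),
    m - seed_len
  ))
  tried <- integer(0)
  for (off in starts) {
    seed <- substr(read, off + 1L, off + seed_len)
    hits <- backward_search(idx, seed)
    if (length(hits) == 0L) next
    cand <- sort.int(unique(pmax(hits - off, 0L)))
    cand <- setdiff(cand, tried)
    cand <- head(cand, p$max_cand)
    tried <- c(tried, cand)
    for (ws in cand) {
      win_start <- max(0L, ws - p$pad)
      win_end <- min(total, ws + m + p$pad)
      hit <- score_window(win_start, win_end)
      if (!is.null(hit)) return(hit)
    }
  }
  no_hit
}

#' Align a filtered read set against the concatesome
#'
#' Applies [align_read()] to each dictionary entry (or any table of tagged
#' sequences), preserving tag order.
#'
#' @param queries A data frame with columns `tag` and `sequence` (e.g.
#'   [dict_entries()] output), or a `dedup_dict`.
#' @param idx,cs,contract,preset As in [align_read()].
#' @return A tibble with one row per query: `query_tag`, `concat_start`,
#'   `ref_span`, `cigar`, `identity`, `aligned`.
#' @export
align_reads <- function(queries, idx, cs, contract = scoring_contract(),
                        preset = "default") {
  if (inherits(queries, "dedup_dict")) queries <- dict_entries(queries)
  stopifnot(all(c("tag", "sequence") %in% names(queries)))
  if (nrow(queries) == 0L) {
    return(tibble(query_tag = character(0), concat_start = integer(0),
                  ref_span = integer(0), cigar = character(0),
                  identity = numeric(0), aligned = logical(0)))
  }
  purrr::map2_dfr(queries$tag, queries$sequence, function(tag, seq) {
    mutate(align_read(idx, cs, seq, contract, preset),
           query_tag = tag, .before = 1L)
  })
}

#' Emit the external BWT aligner's argument set for a %ID threshold
#'
#' Produces the full option set that makes a bowtie2-compatible aligner
#' implement the percent-identity criterion: no ambiguous-base penalty
#' (`--np 0`), unit mismatch cost (`--mp "1,1"`), unit per-base gap cost
#' with no affine opening cost (`--rdg "0,1" --rfg "0,1"`), a minimum score
#' function whose third argument is `min_identity - 1` (so a read of length
#' L may lose at most `L * (1 - min_identity)` points), first-acceptable-hit
#' termination (`-k 1`), forward strand only (`--norc`), plus headerless SAM
#' output and suppression of unaligned reads.
#'
#' @param min_identity Identity threshold in (0, 1]; 0.97 yields
#'   `--score-min "L,0,-0.03"`.
#' @param effort `"default"` (no extra flag), `"fast"`, or `"max"`
#'   (very sensitive).
#' @return Character vector of arguments.
#' @examples
#' external_aligner_args(0.97)
#' @export
external_aligner_args <- function(min_identity = 0.97, effort = "default") {
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 1) {
    abort("min_identity must be in (0, 1]")
  }
  effort <- match.arg(effort, c("default", "fast", "max"))
  score_min <- sprintf("L,0,%.2f", min_identity - 1)
  args <- c(
    "--np", "0",
    "--mp", "1,1",
    "--rdg", "0,1",
    "--rfg", "0,1",
    "--score-min", score_min,
    "-k", "1",
    "--norc",
    "--no-hd", "--no-unal"
  )
  c(args, switch(effort,
                 fast = "--fast",
                 max = "--very-sensitive",
                 default = character(0)))
}

#' Print the complete external aligner command line
#'
#' @param index_base Path prefix of the externally built BWT database.
#' @param reads_fasta Filtered reads FASTA (from [write_filtered()]).
#' @param sam_out Output SAM path.
#' @param min_identity,effort As in [external_aligner_args()].
#' @return The command as a single string (invisibly also printed).
#' @export
external_aligner_command <- function(index_base, reads_fasta, sam_out,
                                     min_identity = 0.97,
                                     effort = "default") {
  args <- external_aligner_args(min_identity, effort)
  cmd <- paste(c("bowtie2", args, "-x", shQuote(index_base),
                 "-f", "-U", shQuote(reads_fasta),
                 "-S", shQuote(sam_out)), collapse = " ")
  cmd
}

#' Write alignment hits as headerless SAM
#'
#' One line per aligned query, mandatory SAM columns only; unaligned
#' queries are suppressed.
#'
#' @param hits Tibble from [align_reads()].
#' @param path Output path.
#' @param sequences Optional named character vector (tag -> sequence) to
#'   fill the SEQ column; `*` otherwise.
#' @param rname Reference name (default `"concatesome"`).
#' @return Invisibly, the number of lines written.
#' @export
write_sam <- function(hits, path, sequences = NULL, rname = "concatesome") {
  h <- filter(hits, .data$aligned)
  if (nrow(h) == 0L) {
    writeLines(character(0), path)
    return(invisible(0L))
  }
  seqcol <- if (is.null(sequences)) rep("*", nrow(h)) else
    unname(sequences[h$query_tag])
  lines <- paste(h$query_tag, 0L, rname, h$concat_start + 1L, 255L,
                 h$cigar, "*", 0L, 0L, seqcol, "*", sep = "\t")
  writeLines(lines, path)
  invisible(length(lines))
}
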