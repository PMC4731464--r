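write_fasta_tmp <- function(headers, seqs) {
  f <- withr::local_tempfile(fileext = ".fna", .local_envir = parent.frame())
  writeLines(paste0(">", headers, "\n", seqs), f)
  f
}

test_that("read parsing applies the SampleID_ReadNumber convention", {
  f <- write_fasta_tmp(c("S1_0", "S2_10 extra words"), c("acgt", "GGGG"))
  reads <- parse_reads(f)
  expect_equal(reads$sample_id, c("S1", "S2"))
  expect_equal(reads$read_id, c("S1_0", "S2_10"))
  expect_equal(reads$sequence, c("ACGT", "GGGG"))  # uppercased

  # multi-underscore ids split at the last underscore
  f2 <- write_fasta_tmp("subject_A_42", "ACGT")
  expect_equal(parse_reads(f2)$sample_id, "subject_A")

  f3 <- write_fasta_tmp("noseparator", "ACGT")
  expect_warning(r3 <- parse_reads(f3), "no '_'")
  expect_equal(r3$sample_id, "noseparator")
})

test_that("parsed per-sample counts match the simulation manifest", {
  sim <- simulate_community(simulation_spec(
    n_samples = 3L, reads_per_sample = 50L, seed = 11L
  ))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  reads <- parse_reads(paths$reads)
  got <- dplyr::count(reads, sample_id)
  want <- dplyr::count(sim$manifest, sample_id)
  expect_equal(got, want)
})

test_that("trimming keeps a prefix and never lengthens", {
  expect_equal(trim_read("ACGTACGT", 4L), "ACGT")
  expect_equal(trim_read("ACG", 10L), "ACG")
  expect_equal(trim_read("ACG", NULL), "ACG")
  set.seed(5)
  seqs <- vapply(sample(1:40, 50, replace = TRUE), random_seq, character(1L))
  out <- trim_read(seqs, 15L)
  expect_true(all(nchar(out) <= 15L))
  expect_true(all(startsWith(seqs, out)))
})

test_that("reverse complement follows the IUPAC table and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement("AACG"), "CGTT")  # hand computation
  expect_equal(reverse_complement("ANRY"), "RYNT")  # ambiguity codes
  expect_error(reverse_complement("ACZ"), "Z")
  set.seed(6)
  seqs <- vapply(rep(30L, 25L), random_seq, character(1L))
  expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("deduplication tracks per-sample multiplicity losslessly", {
  reads <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    sequence = c("ACGT", "ACGT", "ACGT")
  )
  d <- deduplicate(reads)
  expect_equal(nrow(dict_entries(d)), 1L)
  expect_equal(d$count[d$sample_id == "S1"], 2L)
  expect_equal(d$count[d$sample_id == "S2"], 1L)
  expect_equal(sum(d$count), nrow(reads))  # conservation

  three <- tibble::tibble(sample_id = "S1",
                          sequence = c("AA", "CC", "GG"))
  d3 <- deduplicate(three)
  expect_equal(nrow(dict_entries(d3)), 3L)
  expect_true(all(d3$count == 1L))
  # lexicographic entry order and ordinal tags
  expect_equal(dict_entries(d3)$sequence, c("AA", "CC", "GG"))
  expect_equal(dict_entries(d3)$tag, c("0", "1", "2"))
})

test_that("sorted-path dedup equals the naive hash-map oracle", {
  set.seed(303)
  for (trial in 1:25) {
    reads <- tibble::tibble(
      sample_id = sample(paste0("S", 1:4), 400L, replace = TRUE),
      sequence = vapply(rep(8L, 400L), function(n)
        random_seq(n, c("A", "C")), character(1L))
    )
    got <- dplyr::arrange(deduplicate(reads)[, c("sequence", "sample_id",
                                                 "count")],
                          sequence, sample_id)
    expect_equal(as.data.frame(got), as.data.frame(dedup_naive(reads)))
  }
})

test_that("compaction merges prefixes into the longest container", {
  d <- deduplicate(tibble::tibble(
    sample_id = c("S1", "S2", "S2", "S2"),
    sequence = c("ACGTAC", "ACGT", "ACGT", "ACGT")
  ))
  cd <- compact_reads(d)
  ent <- dict_entries(cd)
  expect_equal(ent$sequence, "ACGTAC")
  expect_equal(sum(cd$count), 4L)
  expect_equal(cd$count[cd$sample_id == "S2"], 3L)

  # no containment: identity
  d2 <- deduplicate(tibble::tibble(sample_id = "S1",
                                   sequence = c("AAA", "CCC")))
  expect_equal(dict_entries(compact_reads(d2))$sequence, c("AAA", "CCC"))

  # chain AC < ACG < ACGT merges transitively
  d3 <- deduplicate(tibble::tibble(sample_id = c("S1", "S1", "S2"),
                                   sequence = c("AC", "ACG", "ACGT")))
  cd3 <- compact_reads(d3)
  expect_equal(dict_entries(cd3)$sequence, "ACGT")
  expect_equal(sum(cd3$count), 3L)
})

test_that("compaction conserves totals and never increases entries", {
  set.seed(404)
  for (trial in 1:10) {
    base <- vapply(rep(12L, 10L), random_seq, character(1L))
    # generate reads as random-length prefixes of a few templates
    reads <- tibble::tibble(
      sample_id = sample(c("S1", "S2"), 120L, replace = TRUE),
      sequence = vapply(sample(base, 120L, replace = TRUE), function(s) {
        substr(s, 1L, sample(4:12, 1L))
      }, character(1L), USE.NAMES = FALSE)
    )
    d <- deduplicate(reads)
    cd <- compact_reads(d)
    expect_equal(sum(cd$count), sum(d$count))
    expect_lte(nrow(dict_entries(cd)), nrow(dict_entries(d)))
    # no surviving entry is a prefix of another
    seqs <- dict_entries(cd)$sequence
    for (s in seqs) {
      expect_equal(sum(startsWith(seqs, s)), 1L)
    }
  }
})

test_that("multiplicity filtering drops below-threshold entries, nested in level", {
  reads <- tibble::tibble(
    sample_id = c(rep("S1", 5), "S1", "S2", "S2"),
    sequence = c(rep("AAAA", 5), "CCCC", "CCCC", "GGGG")
  )
  d <- deduplicate(reads)  # totals: AAAA 5, CCCC 2, GGGG 1
  lvl2 <- dict_entries(filter_by_count(d, 2L))
  expect_setequal(lvl2$sequence, c("AAAA", "CCCC"))
  lvl3 <- dict_entries(filter_by_count(d, 3L))
  expect_equal(lvl3$sequence, "AAAA")
  expect_equal(filter_by_count(d, 0L), d)
  expect_equal(filter_by_count(d, 1L), d)

  # survivors nested as d_level rises
  set.seed(7)
  reads <- tibble::tibble(
    sample_id = sample(c("S1", "S2"), 200L, replace = TRUE),
    sequence = vapply(rep(4L, 200L), function(n)
      random_seq(n, c("A", "C")), character(1L))
  )
  d <- deduplicate(reads)
  prev <- dict_entries(d)$sequence
  for (lvl in 2:6) {
    cur <- dict_entries(filter_by_count(d, lvl))$sequence
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("filtered FASTA and dictionary round-trip; RC applies only to FASTA", {
  d <- deduplicate(tibble::tibble(
    sample_id = c("S1", "S2", "S1"),
    sequence = c("AACG", "AACG", "GGTT")
  ))
  fa <- withr::local_tempfile(fileext = ".fna")
  dc <- withr::local_tempfile(fileext = ".tsv")
  write_filtered(d, fa, dc)
  expect_length(readLines(fa), 4L)  # 2 entries
  back <- read_dedup_dictionary(dc)
  expect_equal(as.data.frame(back), as.data.frame(d))

  write_filtered(d, fa, dc, rc = TRUE)
  set <- Biostrings::readDNAStringSet(fa)
  ent <- dict_entries(d)
  expect_equal(as.character(set), setNames(reverse_complement(ent$sequence),
                                           ent$tag))
  # dictionary keeps the original orientation
  expect_equal(read_dedup_dictionary(dc)$sequence[1], "AACG")
})

test_that("lossless mode accounts for every parsed read", {
  sim <- simulate_community(simulation_spec(
    reads_per_sample = 60L, length_jitter = 20L, seed = 21L
  ))
  d <- deduplicate(sim$reads)
  expect_equal(sum(d$count), nrow(sim$reads))
  cd <- compact_reads(d)
  expect_equal(sum(cd$count), nrow(sim$reads))
  # every read is accounted for by an entry that contains it as a prefix
  ent <- dict_entries(cd)
  covered <- vapply(sim$reads$sequence, function(s) {
    any(startsWith(ent$sequence, s))
  }, logical(1L), USE.NAMES = FALSE)
  expect_true(all(covered))
})
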