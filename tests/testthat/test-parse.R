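sam_line <- function(tag, pos, cigar, flag = 0L) {
  paste(tag, flag, "concatesome", pos, 255, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}

test_that("CIGAR reference consumption follows the SAM rules", {
  expect_equal(cigar_ref_span("8M"), 8L)
  expect_equal(cigar_ref_span("4M1D3M"), 8L)
  expect_equal(cigar_ref_span("4M1I3M"), 7L)
  expect_equal(cigar_ref_span("2S5M3H"), 5L)
  expect_equal(cigar_ref_span(c("10M", "5M2N5M")), c(10L, 12L))
})

test_that("headerless SAM parsing converts POS once and skips unmapped", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    sam_line("tag0", 5L, "8M"),
    sam_line("tag1", 1L, "4M1D3M"),
    sam_line("unmapped", 0L, "*", flag = 4L),
    "not a sam line"
  ), f)
  expect_warning(hits <- parse_sam(f), "1 unparseable")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$concat_start, c(4L, 0L))  # 1-based -> 0-based
  expect_equal(hits$ref_span, c(8L, 8L))

  empty <- withr::local_tempfile(fileext = ".sam")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_sam(empty)), 0L)
})

test_that("hits expand to full per-sample dictionary counts", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    sequence = c("ACGT", "ACGT", "ACGT")
  ))
  hits <- tibble::tibble(query_tag = "0", concat_start = 0L, ref_span = 4L)
  t <- assemble_table(hits, cs, d)
  td <- tidy(t)
  expect_equal(td$count[td$sample_id == "S1"], 2L)
  expect_equal(td$count[td$sample_id == "S2"], 1L)
  expect_equal(sum(td$count), 3L)
  expect_equal(t$otu_ids, "A")
})

test_that("junction hits produce an empty table and are tallied", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(sample_id = "S1", sequence = "GTGG"))
  hits <- tibble::tibble(query_tag = "0", concat_start = 2L, ref_span = 4L)
  t <- assemble_table(hits, cs, d)
  expect_equal(length(t$otu_ids), 0L)
  expect_equal(t$junction_hits, 1L)
  expect_equal(t$junction_reads, 1L)
  expect_equal(glance(t)$total_count, 0L)
})

test_that("entries hitting the same OTU sum into one row", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(
    sample_id = c("S1", "S2"),
    sequence = c("ACG", "CGT")
  ))
  hits <- tibble::tibble(query_tag = c("0", "1"),
                         concat_start = c(0L, 1L), ref_span = c(3L, 3L))
  t <- assemble_table(hits, cs, d)
  expect_equal(t$otu_ids, "A")
  expect_equal(sum(t$counts$count), 2L)
})

test_that("a hit tag missing from the dictionary is a hard error", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(sample_id = "S1", sequence = "ACGT"))
  hits <- tibble::tibble(query_tag = "99", concat_start = 0L, ref_span = 4L)
  expect_error(assemble_table(hits, cs, d), "absent from the sample dictionary")
})

test_that("duplicate tags keep the first hit with a warning", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(sample_id = "S1", sequence = "ACGT"))
  hits <- tibble::tibble(query_tag = c("0", "0"),
                         concat_start = c(0L, 4L), ref_span = c(4L, 4L))
  expect_warning(t <- assemble_table(hits, cs, d), "multiple hits")
  expect_equal(t$otu_ids, "A")
})

test_that("table assembly is order-independent up to the ordering rule", {
  set.seed(55)
  cs <- random_concatesome(6L, c(40L, 60L))
  reads <- tibble::tibble(
    sample_id = sample(c("S1", "S2", "S3"), 60L, replace = TRUE),
    sequence = vapply(sample(seq_along(cs$otu_ids), 60L, replace = TRUE),
                      function(i) {
                        ends <- c(cs$offsets[-1L], nchar(cs$sequence))
                        substring(cs$sequence, cs$offsets[i] + 1L, ends[i])
                      }, character(1L))
  )
  d <- deduplicate(reads)
  ent <- dict_entries(d)
  starts <- vapply(ent$sequence, function(s)
    naive_scan(cs$sequence, s)[1L], integer(1L), USE.NAMES = FALSE)
  hits <- tibble::tibble(query_tag = ent$tag, concat_start = starts,
                         ref_span = nchar(ent$sequence))
  t1 <- assemble_table(hits, cs, d)
  t2 <- assemble_table(hits[sample(nrow(hits)), ], cs, d)
  expect_equal(dplyr::arrange(tidy(t1), otu_id, sample_id),
               dplyr::arrange(tidy(t2), otu_id, sample_id))
})

test_that("taxonomy is attached when supplied; absent ids are Unassigned", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(sample_id = c("S1", "S1"),
                                  sequence = c("ACGT", "GGCC")))
  hits <- tibble::tibble(query_tag = c("0", "1"),
                         concat_start = c(0L, 4L), ref_span = c(4L, 4L))
  tax <- tibble::tibble(otu_id = "A", taxonomy = "k__Bacteria;p__Firmicutes")
  t <- assemble_table(hits, cs, d, tax)
  expect_equal(t$taxonomy[match("A", t$otu_ids)],
               "k__Bacteria; p__Firmicutes")
  expect_equal(t$taxonomy[match("B", t$otu_ids)], "Unassigned")
  t_untaxed <- assemble_table(hits, cs, d)
  expect_null(t_untaxed$taxonomy)
})

test_that("unmatched collection partitions the dictionary exactly", {
  cs <- toy_concatesome()
  d <- deduplicate(tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    sequence = c("ACGT", "TTTT", "GTGG")
  ))
  ent <- dict_entries(d)
  # ACGT matches, GTGG is a junction, TTTT has no hit
  hits <- tibble::tibble(
    query_tag = ent$tag[match(c("ACGT", "GTGG"), ent$sequence)],
    concat_start = c(0L, 2L), ref_span = c(4L, 4L)
  )
  t <- assemble_table(hits, cs, d)
  f <- withr::local_tempfile(fileext = ".fna")
  un <- collect_unmatched(d, t, f)
  expect_equal(un$sequence, "TTTT")
  expect_length(readLines(f), 2L)
  # the three groups partition the dictionary
  expect_setequal(c(t$assigned_tags, t$junction_tags, un$tag), ent$tag)
  # count conservation across the partition
  expect_equal(sum(t$counts$count) + t$junction_reads + sum(un$total),
               sum(d$count))

  # all matched -> empty unmatched file
  t2 <- assemble_table(hits[1, ],
                       cs, deduplicate(tibble::tibble(sample_id = "S1",
                                                      sequence = "ACGT")))
  f2 <- withr::local_tempfile(fileext = ".fna")
  un2 <- collect_unmatched(deduplicate(tibble::tibble(sample_id = "S1",
                                                      sequence = "ACGT")),
                           t2, f2)
  expect_equal(nrow(un2), 0L)
  expect_length(readLines(f2), 0L)
})
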