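mk_contigs <- function(ids, lens, bins) {
  tibble::tibble(contig_id = ids, length = lens, bin_id = bins,
                 sequence = NA_character_)
}

test_that("length filter is strictly greater-than", {
  contigs <- mk_contigs(c("a", "b", "c"), c(5001L, 5000L, 4999L), "bin1")
  kept <- filter_contigs_by_length(contigs)
  expect_equal(kept$contig_id, "a")
  expect_equal(nrow(filter_contigs_by_length(contigs[0, ])), 0L)
})

test_that("representative selection keeps the longest contig per bin", {
  contigs <- mk_contigs(
    c("c1", "c2", "solo", "cB", "cA"),
    c(8000L, 6000L, 7000L, 7000L, 7000L),
    c("b1", "b1", "b2", "b3", "b3")
  )
  reps <- suppressMessages(select_representative_contigs(contigs))
  expect_equal(sort(reps$contig_id), c("c1", "cA", "solo"))
  # tie in b3 resolved to lexicographically smallest id
  expect_true("cA" %in% reps$contig_id)

  with_unbinned <- dplyr::bind_rows(
    contigs, mk_contigs("loose", 9000L, NA_character_)
  )
  expect_message(reps2 <- select_representative_contigs(with_unbinned),
                 "unbinned")
  expect_false("loose" %in% reps2$contig_id)
  expect_equal(nrow(reps2), dplyr::n_distinct(contigs$bin_id))
})

test_that("reference-sample selection is deterministic and uniform", {
  ids <- sprintf("s%02d", 1:10)
  expect_equal(sort(select_reference_samples(ids, 10, seed = 1)), ids)
  expect_identical(
    select_reference_samples(ids, 3, seed = 7),
    select_reference_samples(ids, 3, seed = 7)
  )
  expect_error(select_reference_samples(ids, 11, seed = 1), "n_refs")

  withr::with_seed(123, {
    hits <- table(unlist(lapply(1:4000, function(i) {
      select_reference_samples(ids, 2, seed = sample.int(1e8, 1))
    })))
    freqs <- as.numeric(hits) / 4000
    expect_true(all(abs(freqs - 0.2) < 0.03))
  })
})

test_that("mapping summaries count distinct primary reads and union coverage", {
  contigs <- mk_contigs("c1", 1000L, "b1")
  aln <- tibble::tibble(
    read_id = c("r1", "r2", "r2dup", "rsec", "runmap"),
    contig_id = c("c1", "c1", "c1", "c1", NA),
    mapped = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    primary = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    ref_spans = list(
      cbind(start = 0L, end = 50L),
      cbind(start = 25L, end = 75L),
      cbind(start = 25L, end = 75L),
      cbind(start = 900L, end = 950L),
      matrix(integer(0), ncol = 2)
    )
  )
  s <- summarize_mapping(aln, contigs, "sampleA", total_sample_reads = 100L)
  expect_equal(s$mapped_read_count, 3L)
  expect_equal(s$covered_bases, 75L)  # secondary alignment not counted

  none <- summarize_mapping(aln[5, ], contigs, "sampleA", 100L)
  expect_equal(none$mapped_read_count, 0L)
  expect_equal(none$covered_bases, 0L)

  bad <- dplyr::mutate(aln[1, ], contig_id = "ghost")
  expect_error(summarize_mapping(bad, contigs, "s", 10L), "not in the representative")
})

test_that("rpkm and coverage follow the printed formulas", {
  s <- tibble::tibble(
    sample_id = "s", contig_id = "c",
    mapped_read_count = c(4, 0, 1e6),
    covered_bases = c(700, 0, 1000),
    total_sample_reads = c(1000, 1000, 1e6),
    contig_length = c(2000, 2000, 1000)
  )
  expect_equal(rpkm(s), c(2000, 0, 1e6))
  expect_equal(coverage(s), c(0.35, 0, 1))
  expect_equal(coverage(dplyr::mutate(s[1, ], contig_length = 1000)), 0.7)
  expect_error(rpkm(dplyr::mutate(s, total_sample_reads = 0)), "positive")

  # scale invariance: doubling counts and totals leaves rpkm unchanged
  withr::with_seed(21, {
    r <- tibble::tibble(
      sample_id = "s", contig_id = "c",
      mapped_read_count = sample(1:1000, 50),
      covered_bases = 0,
      total_sample_reads = sample(1e4:1e6, 50),
      contig_length = sample(5000:20000, 50)
    )
    doubled <- dplyr::mutate(
      r, mapped_read_count = mapped_read_count * 2,
      total_sample_reads = total_sample_reads * 2
    )
    expect_equal(rpkm(doubled), rpkm(r))
  })
})

test_that("the genomic matrix zeroes sub-threshold coverage cells", {
  summaries <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    contig_id = rep(c("cA", "cB"), 2),
    mapped_read_count = c(100L, 100L, 100L, 100L),
    covered_bases = c(700L, 699L, 1000L, 0L),
    total_sample_reads = 1000L,
    contig_length = 1000L
  )
  m <- build_genomic_matrix(summaries, coverage_threshold = 0.70, log = FALSE)
  v <- fm_values(m)
  expect_equal(v["s1", "cA"], 1e5)  # coverage exactly 0.70 kept
  expect_equal(v["s1", "cB"], 0)    # 0.699 zeroed
  expect_equal(v["s2", "cB"], 0)
  expect_equal(fm_modality(m), "genomic")

  logged <- build_genomic_matrix(summaries, coverage_threshold = 0)
  expect_equal(fm_values(logged), log10(fm_values(
    build_genomic_matrix(summaries, coverage_threshold = 0, log = FALSE)
  ) + 1e-6))

  expect_error(build_genomic_matrix(summaries[-1, ]), "exactly once")
})
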