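test_that("feature datasets are reproducible and carry the class signal", {
  spec <- synthetic_spec(n_samples_per_class = 10, seed = 5)
  d1 <- generate_feature_dataset(spec)
  d2 <- generate_feature_dataset(spec)
  expect_identical(
    lapply(d1$features, fm_values),
    lapply(d2$features, fm_values)
  )
  expect_equal(names(d1$features), c("taxonomic", "genomic", "functional"))
  expect_equal(nrow(d1$labels), 20L)
  expect_equal(d1$positive, "case")
  expect_true(all(fm_values(d1$features$taxonomic) >= 0))

  # log transform recovers the Gaussian scale exactly up to the pseudocount
  lt <- log_transform(d1$features$taxonomic, pseudocount = 0)
  expect_true(all(is.finite(fm_values(lt))))

  # strongly separable data admits a perfect linear separator
  spec5 <- synthetic_spec(
    n_samples_per_class = 30, seed = 6,
    modalities = list(taxonomic = list(
      n_features = 50, n_informative = 10, effect_size = 5, noise_sd = 1
    ))
  )
  d5 <- generate_feature_dataset(spec5)
  X <- fm_values(log_transform(d5$features$taxonomic))
  y <- as.integer(d5$labels$label) - 1
  fit <- suppressWarnings(glm(y ~ X[, 1:10], family = binomial))
  expect_equal(mean((fitted(fit) > 0.5) == y), 1)
})

test_that("a zero effect size yields exchangeable classes", {
  spec0 <- synthetic_spec(
    n_samples_per_class = 25, seed = 9,
    modalities = list(taxonomic = list(
      n_features = 40, n_informative = 10, effect_size = 0, noise_sd = 1
    ))
  )
  d0 <- generate_feature_dataset(spec0)
  X <- fm_values(log_transform(d0$features$taxonomic, pseudocount = 0))
  y <- d0$labels$label
  pvals <- apply(X, 2, function(col) t.test(col ~ y)$p.value)
  # p-values approximately uniform: no feature separates the classes
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("sequence generation conserves reads and matches its bookkeeping", {
  spec <- synthetic_spec(
    n_samples_per_class = 2, seed = 13,
    seq = list(n_contigs = 6, n_bins = 3, reads_per_sample = 400L,
               contig_length_range = c(5500L, 7000L))
  )
  dir <- withr::local_tempdir()
  ds <- generate_sequence_dataset(spec, dir)

  per_sample <- dplyr::summarise(
    dplyr::group_by(ds$ground_truth, sample_id),
    total = sum(true_count)
  )
  expect_true(all(per_sample$total == 400L))

  reps <- ds$representatives
  expect_equal(nrow(reps), 3L)
  lens <- setNames(reps$length, reps$contig_id)
  for (sid in ds$labels$sample_id) {
    aln <- read_sam(file.path(dir, "sam", paste0(sid, ".sam")),
                    contig_lengths = lens)
    s <- summarize_mapping(
      aln, reps, sid,
      total_sample_reads = 400L
    )
    gt <- ds$ground_truth[ds$ground_truth$sample_id == sid, ]
    merged <- dplyr::left_join(s, gt, by = c("sample_id", "contig_id"))
    expect_identical(merged$mapped_read_count, merged$true_count)
    expect_identical(merged$covered_bases, merged$true_covered_bases)
  }
})

test_that("contigs with zero class abundance receive no reads", {
  ab <- rbind(c(0, 0.5, 0.5), c(0.4, 0.3, 0.3))
  spec <- synthetic_spec(
    n_samples_per_class = 2, seed = 17,
    seq = list(n_contigs = 3, n_bins = 3, reads_per_sample = 300L,
               abundance = ab)
  )
  dir <- withr::local_tempdir()
  ds <- generate_sequence_dataset(spec, dir)
  gt <- ds$ground_truth
  first_rep <- sort(ds$representatives$contig_id)[1]
  controls <- ds$labels$sample_id[ds$labels$label == "control"]
  zero_rows <- gt[gt$contig_id == first_rep & gt$sample_id %in% controls, ]
  expect_true(all(zero_rows$true_count == 0L))
  expect_true(all(zero_rows$true_covered_bases == 0L))
})

test_that("reads longer than the shortest contig are refused", {
  spec <- synthetic_spec(
    n_samples_per_class = 2, seed = 1,
    seq = list(contig_length_range = c(150L, 200L), read_length = 300L,
               n_contigs = 4, n_bins = 2)
  )
  expect_error(generate_sequence_dataset(spec, withr::local_tempdir()),
               "read_length exceeds")
})

test_that("generated profiles and KO hits feed the feature pipelines", {
  spec <- synthetic_spec(
    n_samples_per_class = 2, seed = 19,
    seq = list(n_contigs = 4, n_bins = 2, reads_per_sample = 200L,
               ko_reads_per_sample = 120L, n_kos = 10L, n_species = 8L)
  )
  dir <- withr::local_tempdir()
  ds <- generate_sequence_dataset(spec, dir)
  sids <- ds$labels$sample_id

  prof_paths <- setNames(
    file.path(dir, "profiles", paste0(sids, ".tsv")), sids
  )
  taxo <- build_taxonomic_from_files(prof_paths, "species",
                                     prevalence_filter = FALSE, log = FALSE)
  v <- fm_values(taxo)
  expect_equal(nrow(v), 4L)
  expect_equal(ncol(v), 8L)
  expect_equal(unname(rowSums(v)), rep(100, 4), tolerance = 1e-6)

  qlen <- readr::read_tsv(file.path(dir, "query_lengths.tsv"),
                          col_names = c("query_id", "length"),
                          col_types = "cn", progress = FALSE)
  hits_paths <- setNames(file.path(dir, "hits", paste0(sids, ".tsv")), sids)
  fun <- build_functional_from_files(
    hits_paths, qlen, read_ko_lengths(file.path(dir, "ko_lengths.tsv")),
    total_reads = setNames(rep(120, 4), sids), log = FALSE
  )
  ko_lens <- read_ko_lengths(file.path(dir, "ko_lengths.tsv"))
  vt <- fm_values(fun)
  truth <- ds$ko_truth
  for (sid in sids) {
    for (ko in colnames(vt)) {
      cnt <- truth$true_count[truth$sample_id == sid & truth$ko_id == ko]
      expect_equal(
        vt[sid, ko], cnt * 1e3 * 1e6 / (120 * ko_lens[[ko]])
      )
    }
  }
})
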