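#' Read contigs and bin assignments
#'
#' @param fasta_path Contig FASTA.
#' @param bins_path Two-column TSV (`contig_id`, `bin_id`); contigs absent
#'   from the table are treated as unbinned.
#' @return A tibble (class `contig_tbl`) with columns `contig_id`, `length`,
#'   `bin_id` (`NA` = unbinned), `sequence`.
#' @export
read_contigs <- function(fasta_path, bins_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- tibble(
    contig_id = ids,
    length = Biostrings::width(seqs),
    bin_id = NA_character_,
    sequence = as.character(seqs)
  )
  if (!is.null(bins_path)) {
    bins <- readr::read_tsv(
      bins_path,
      col_names = c("contig_id", "bin_id"), col_types = "cc", progress = FALSE
    )
    out$bin_id <- bins$bin_id[match(out$contig_id, bins$contig_id)]
  }
  contig_tbl(out)
}

contig_tbl <- function(x) {
  if (any(x$length < 1L)) abort("contig length must be >= 1")
  has_seq <- !is.na(x$sequence) & nzchar(x$sequence)
  if (any(has_seq & nchar(x$sequence) != x$length)) {
    abort("contig length disagrees with sequence length")
  }
  structure(as_tibble(x), class = c("contig_tbl", class(as_tibble(x))))
}

#' Randomly select reference samples
#'
#' Reference samples are the random subset of training samples whose
#' assembled contigs define the genomic feature space. The draw is uniform
#' without replacement and reproducible given `seed`.
#'
#' @param sample_ids Candidate (training) sample ids.
#' @param n_refs Number of reference samples to draw.
#' @param seed Integer seed.
#' @return Character vector of selected sample ids.
#' @export
select_reference_samples <- function(sample_ids, n_refs, seed) {
  if (n_refs < 1 || n_refs > length(sample_ids)) {
    abort(sprintf(
      "n_refs must be in [1, %d], got %s", length(sample_ids), n_refs
    ))
  }
  withr::with_seed(seed, sample(sample_ids, n_refs))
}

#' Length-filter contigs
#'
#' Keeps contigs strictly longer than `min_len` (default 5000 bp); short
#' contigs carry too little signal for genome-level abundance features.
#'
#' @param contigs A contig tibble.
#' @param min_len Length threshold in bases; contigs of exactly this length
#'   are removed.
#' @return The filtered contig tibble.
#' @export
filter_contigs_by_length <- function(contigs, min_len = 5000) {
  contig_tbl(contigs[contigs$length > min_len, , drop = FALSE])
}

#' Select one representative contig per bin
#'
#' The longest contig of each bin stands for the bin's non-redundant
#' genomic fragment; length ties break to the lexicographically smallest
#' `contig_id`. Unbinned contigs are excluded (with a message).
#'
#' @param contigs A contig tibble with bin assignments.
#' @return A contig tibble with one row per bin.
#' @export
select_representative_contigs <- function(contigs) {
  unbinned <- is.na(contigs$bin_id)
  if (any(unbinned)) {
    inform(sprintf("excluding %d unbinned contig(s)", sum(unbinned)))
  }
  binned <- contigs[!unbinned, , drop = FALSE]
  out <- binned |>
    group_by(.data$bin_id) |>
    arrange(desc(.data$length), .data$contig_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$contig_id)
  contig_tbl(out)
}

#' Summarise read mapping per (sample, contig)
#'
#' Counts distinct mapped reads (primary alignments only) and the breadth
#' of coverage (bases covered by at least one aligned interval, via
#' interval union) for every representative contig, including contigs with
#' no alignments.
#'
#' @param alignments An alignment tibble ([read_sam()]) of one sample's
#'   reads vs. the representative contigs.
#' @param contigs Contig tibble of the representative contigs.
#' @param sample_id Sample identifier for the output rows.
#' @param total_sample_reads Number of reads in the sample (RPKM
#'   denominator).
#' @return A tibble (class `mapping_summary`) with columns `sample_id`,
#'   `contig_id`, `mapped_read_count`, `covered_bases`,
#'   `total_sample_reads`, `contig_length`.
#' @export
summarize_mapping <- function(alignments, contigs, sample_id,
                              total_sample_reads) {
  used <- alignments[alignments$mapped & alignments$primary, , drop = FALSE]
  unknown <- setdiff(unique(used$contig_id), contigs$contig_id)
  if (length(unknown)) {
    abort(paste0("alignment to contig not in the representative set: ", unknown[1]))
  }
  by_contig <- split(seq_len(nrow(used)), used$contig_id)
  stats <- map(by_contig, function(idx) {
    spans <- do.call(rbind, used$ref_spans[idx])
    ir <- IRanges::reduce(IRanges::IRanges(
      start = spans[, 1] + 1L, end = spans[, 2]
    ))
    list(
      count = length(unique(used$read_id[idx])),
      covered = sum(IRanges::width(ir))
    )
  })
  out <- tibble(
    sample_id = sample_id,
    contig_id = contigs$contig_id,
    mapped_read_count = vapply(
      contigs$contig_id,
      function(cid) if (cid %in% names(stats)) stats[[cid]]$count else 0L,
      integer(1), USE.NAMES = FALSE
    ),
    covered_bases = vapply(
      contigs$contig_id,
      function(cid) if (cid %in% names(stats)) stats[[cid]]$covered else 0L,
      integer(1), USE.NAMES = FALSE
    ),
    total_sample_reads = total_sample_reads,
    contig_length = contigs$length
  )
  if (any(out$covered_bases > out$contig_length)) {
    abort("covered bases exceed contig length")
  }
  mapping_summary(out)
}

mapping_summary <- function(x) {
  structure(as_tibble(x), class = c("mapping_summary", class(as_tibble(x))))
}

#' RPKM of a contig in a sample
#'
#' Reads per kilobase per million:
#' `mapped_read_count * 1e3 * 1e6 / (total_sample_reads * contig_length)`.
#'
#' @param summaries A mapping-summary tibble ([summarize_mapping()]).
#' @return Numeric vector of RPKM values, one per row.
#' @export
rpkm <- function(summaries) {
  if (any(summaries$total_sample_reads <= 0)) {
    abort("total_sample_reads must be positive")
  }
  if (any(summaries$contig_length <= 0)) {
    abort("contig_length must be positive")
  }
  as.numeric(summaries$mapped_read_count) * 1e3 * 1e6 /
    (as.numeric(summaries$total_sample_reads) * as.numeric(summaries$contig_length))
}

#' Breadth of coverage of a contig in a sample
#'
#' Fraction of the contig's bases covered by at least one read:
#' `covered_bases / contig_length`, in `[0, 1]`.
#'
#' @inheritParams rpkm
#' @return Numeric vector of coverage fractions.
#' @export
coverage <- function(summaries) {
  if (any(summaries$contig_length <= 0)) {
    abort("contig_length must be positive")
  }
  summaries$covered_bases / summaries$contig_length
}

#' Assemble the genome-level abundance feature matrix
#'
#' Builds the samples x representative-contigs matrix of RPKM values,
#' zeroing cells whose breadth of coverage falls under
#' `coverage_threshold` (a fragment that is mostly uncovered is taken to be
#' absent from the sample), then log-transforms.
#'
#' @param summaries Row-bound mapping summaries covering the full
#'   sample x contig grid.
#' @param coverage_threshold Coverage below this fraction zeroes the cell
#'   (default 0.70); cells at exactly the threshold are kept.
#' @param pseudocount Passed to [log_transform()].
#' @param log Apply the log transform (default `TRUE`).
#' @return A `feature_matrix` (modality `"genomic"`).
#' @export
build_genomic_matrix <- function(summaries, coverage_threshold = 0.70,
                                 pseudocount = 1e-6, log = TRUE) {
  samples <- unique(summaries$sample_id)
  contigs <- unique(summaries$contig_id)
  if (nrow(summaries) != length(samples) * length(contigs) ||
      anyDuplicated(summaries[c("sample_id", "contig_id")])) {
    abort("summaries must cover each (sample, contig) pair exactly once")
  }
  vals <- summaries |>
    mutate(
      value = ifelse(coverage(summaries) >= coverage_threshold, rpkm(summaries), 0)
    ) |>
    select("sample_id", "contig_id", "value") |>
    pivot_wider(names_from = "contig_id", values_from = "value")
  vals <- vals[match(samples, vals$sample_id), c("sample_id", sort(contigs))]
  m <- feature_matrix(vals, modality = "genomic", transform = "raw")
  if (log) log_transform(m, pseudocount) else m
}
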