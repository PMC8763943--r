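#' Build the genomic feature matrix from files
#'
#' End-to-end genomic-modality pipeline: read contigs and bin assignments,
#' drop contigs not longer than `min_len`, pick the longest contig per bin
#' as representative, summarise each sample's SAM alignments against the
#' representatives, and assemble the coverage-filtered RPKM matrix.
#'
#' @param contig_fasta Contig FASTA path.
#' @param bins_tsv Two-column contig-to-bin TSV path.
#' @param sam_paths Named character vector of SAM paths, names = sample
#'   ids.
#' @param total_reads Named numeric vector of per-sample read counts (the
#'   RPKM denominator), or a data frame `sample_id`, `total_reads`.
#' @inheritParams filter_contigs_by_length
#' @inheritParams build_genomic_matrix
#' @return A `feature_matrix` (modality `"genomic"`).
#' @export
build_genomic_from_files <- function(contig_fasta, bins_tsv, sam_paths,
                                     total_reads, min_len = 5000,
                                     coverage_threshold = 0.70,
                                     pseudocount = 1e-6, log = TRUE) {
  if (is.data.frame(total_reads)) {
    total_reads <- setNames(total_reads$total_reads, total_reads$sample_id)
  }
  stopifnot(!is.null(names(sam_paths)))
  contigs <- read_contigs(contig_fasta, bins_tsv)
  reps <- select_representative_contigs(filter_contigs_by_length(contigs, min_len))
  rep_lens <- setNames(reps$length, reps$contig_id)
  summaries <- map(names(sam_paths), function(sid) {
    aln <- read_sam(sam_paths[[sid]], contig_lengths = rep_lens)
    summarize_mapping(aln, reps, sid, unname(total_reads[sid]))
  }) |> list_rbind()
  build_genomic_matrix(summaries, coverage_threshold, pseudocount, log)
}

#' Build the functional feature matrix from files
#'
#' Reads each sample's 12-column tabular KO hits, applies the
#' identity/coverage/e-value filter, resolves multi-hit reads to their best
#' hit, and assembles the gene-length-normalised RPKM matrix.
#'
#' @param hits_paths Named character vector of hit-file paths, names =
#'   sample ids.
#' @param query_lengths Named numeric vector (or data frame) of query
#'   lengths for all reads in the hit files.
#' @param ko_lengths Named numeric vector of KO gene lengths
#'   ([read_ko_lengths()]).
#' @param total_reads Named numeric vector of per-sample read counts.
#' @inheritParams filter_hits
#' @inheritParams build_functional_matrix
#' @return A `feature_matrix` (modality `"functional"`).
#' @export
build_functional_from_files <- function(hits_paths, query_lengths, ko_lengths,
                                        total_reads, min_identity = 50,
                                        min_qcov = 50, max_evalue = 1e-10,
                                        pseudocount = 1e-6, log = TRUE) {
  stopifnot(!is.null(names(hits_paths)))
  if (is.data.frame(total_reads)) {
    total_reads <- setNames(total_reads[[2]], total_reads[[1]])
  }
  assigned <- map(names(hits_paths), function(sid) {
    hits <- read_diamond_hits(hits_paths[[sid]], query_lengths)
    best <- assign_best_hit(filter_hits(hits, min_identity, min_qcov, max_evalue))
    if (!nrow(best)) return(NULL)
    mutate(best, sample_id = sid)[c("sample_id", "read_id", "ko_id")]
  }) |> list_rbind()
  build_functional_matrix(
    assigned, ko_lengths, total_reads[names(hits_paths)],
    pseudocount, log
  )
}

#' Build per-rank taxonomic feature matrices from profile files
#'
#' @param profile_paths Named character vector of MetaPhlAn-style profile
#'   paths, names = sample ids.
#' @param rank One of [taxon_ranks()].
#' @param prevalence_filter Apply [filter_single_sample_taxa()]; defaults
#'   to `TRUE` at genus and species rank, `FALSE` above.
#' @inheritParams log_transform
#' @param log Apply the log transform (default `TRUE`).
#' @return A `feature_matrix` (modality `"taxonomic"`).
#' @export
build_taxonomic_from_files <- function(profile_paths, rank,
                                       prevalence_filter = rank %in% c("genus", "species"),
                                       pseudocount = 1e-6, log = TRUE) {
  stopifnot(!is.null(names(profile_paths)))
  profiles <- imap(
    as.list(profile_paths),
    function(p, sid) read_metaphlan_profile(p, sample_id = sid)
  )
  m <- build_rank_table(unname(profiles), rank)
  if (prevalence_filter) m <- filter_single_sample_taxa(m)
  if (log) log_transform(m, pseudocount) else m
}
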