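# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-base bitmaps, brute-force recounts) and never reuse package code.

make_fm <- function(values, modality = "taxonomic", transform = "raw",
                    sample_ids = sprintf("s%02d", seq_len(nrow(values)))) {
  rownames(values) <- sample_ids
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  }
  feature_matrix(values, modality = modality, transform = transform)
}

random_fm <- function(n = 5, p = 7, modality = "genomic", seed = 1) {
  withr::with_seed(seed, {
    make_fm(matrix(round(runif(n * p, 0, 50), 6), n, p), modality = modality)
  })
}

# one-line SAM record builder
sam_line <- function(qname, flag, rname, pos1, cigar, seq = NULL,
                     tags = character(0)) {
  if (is.null(seq)) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    qlen <- sum(as.integer(sub("[A-Z=]$", "", ops))[
      grepl("[MIS=X]$", ops)
    ])
    seq <- strrep("A", max(qlen, 1))
  }
  paste(c(qname, flag, rname, pos1, "60", cigar, "*", "0", "0", seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}

write_sam <- function(path, contig_lengths, records) {
  writeLines(
    c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
              as.integer(contig_lengths)),
      records
    ),
    path
  )
  path
}

# per-base bitmap coverage oracle over 0-based half-open intervals
bitmap_covered <- function(spans, contig_length) {
  hit <- logical(contig_length)
  for (k in seq_len(nrow(spans))) {
    if (spans[k, 2] > spans[k, 1]) {
      hit[(spans[k, 1] + 1):spans[k, 2]] <- TRUE
    }
  }
  sum(hit)
}

# brute-force RPKM from the printed formula, computed digit by digit
naive_rpkm <- function(count, total, len) {
  count * 1000 * 1000000 / (as.numeric(total) * as.numeric(len))
}

# read tibble builder for preprocessing tests
make_reads <- function(quals, seqs = NULL, ids = NULL) {
  n <- length(quals)
  seqs <- seqs %||% vapply(quals, function(q) strrep("A", length(q)), character(1))
  tibble::tibble(
    read_id = ids %||% sprintf("r%02d", seq_len(n)),
    sequence = seqs,
    qualities = quals,
    mate = "unpaired"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small log-scale labelled dataset for model tests
tiny_model_data <- function(n_per_class = 12, p = 20, shift = 5, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    Z <- matrix(rnorm(n * p), n, p)
    Z[(n_per_class + 1):n, 1:4] <- Z[(n_per_class + 1):n, 1:4] + shift
    labels <- factor(rep(c("control", "case"), each = n_per_class),
                     levels = c("control", "case"))
    m <- make_fm(Z, modality = "taxonomic", transform = "log")
    list(m = m, labels = labels)
  })
}

fast_cfg <- function(hidden = c(16, 8), epochs = 30, seed = 1) {
  encoder_config(hidden, epochs = epochs, batch_size = 8, seed = seed)
}
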