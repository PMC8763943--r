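#' Read / write FASTQ (Phred+33)
#'
#' @param path FASTQ path (may be gzipped on read).
#' @param mate Mate tag to attach to every read: `"R1"`, `"R2"` or
#'   `"unpaired"`.
#' @return A tibble (class `read_tbl`) with columns `read_id`, `sequence`,
#'   `qualities` (list of integer Phred scores), `mate`.
#' @export
read_fastq <- function(path, mate = "unpaired") {
  mate <- match.arg(mate, c("R1", "R2", "unpaired"))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual_strings <- as.character(S4Vectors::mcols(x)$qualities)
  read_tbl(tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x)),
    qualities = lapply(unname(qual_strings), function(s) utf8ToInt(s) - 33L),
    mate = mate
  ))
}

#' @rdname read_fastq
#' @param reads A read tibble as returned by [read_fastq()].
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  qual <- Biostrings::PhredQuality(vapply(
    reads$qualities,
    function(q) rawToChar(as.raw(q + 33L)),
    character(1)
  ))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  invisible(path)
}

read_tbl <- function(x) {
  structure(as_tibble(x), class = c("read_tbl", class(as_tibble(x))))
}

#' Sliding-window quality trimming
#'
#' Trims each read from both ends with a sliding-window mean-quality rule:
#' the retained region runs from the first to the last window (of `window`
#' bases) whose mean Phred score reaches `q_threshold`; remaining
#' sub-threshold bases at the edges of that region are then clipped.
#' Reads whose retained region is shorter than `window`, or with no passing
#' window at all, are rejected.
#'
#' @param reads A read tibble ([read_fastq()]).
#' @param q_threshold Minimum window mean Phred score (default 20).
#' @param window Window width in bases (default 10).
#' @return The kept reads, trimmed, with a `rejected` attribute holding a
#'   tibble of dropped `read_id`s and reasons.
#' @export
quality_filter <- function(reads, q_threshold = 20, window = 10) {
  res <- map(seq_len(nrow(reads)), function(i) {
    q <- reads$qualities[[i]]
    n <- length(q)
    if (n == 0L) {
      return(list(keep = FALSE, reason = "empty"))
    }
    if (n < window) {
      return(list(keep = FALSE, reason = "shorter_than_window"))
    }
    cs <- cumsum(c(0, q))
    win_mean <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
    pass <- which(win_mean >= q_threshold)
    if (!length(pass)) {
      return(list(keep = FALSE, reason = "low_quality"))
    }
    from <- pass[1]
    to <- pass[length(pass)] + window - 1L
    # clip residual sub-threshold bases at the region edges
    while (from <= to && q[from] < q_threshold) from <- from + 1L
    while (to >= from && q[to] < q_threshold) to <- to - 1L
    if (to - from + 1L < window) {
      return(list(keep = FALSE, reason = "trimmed_too_short"))
    }
    list(keep = TRUE, from = from, to = to)
  })
  keep <- vapply(res, `[[`, logical(1), "keep")
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    idx <- which(keep)
    out$sequence <- vapply(seq_along(idx), function(k) {
      substring(out$sequence[k], res[[idx[k]]]$from, res[[idx[k]]]$to)
    }, character(1))
    out$qualities <- map(seq_along(idx), function(k) {
      reads$qualities[[idx[k]]][res[[idx[k]]]$from:res[[idx[k]]]$to]
    })
  }
  attr(out, "rejected") <- tibble(
    read_id = reads$read_id[!keep],
    reason = vapply(res[!keep], `[[`, character(1), "reason")
  )
  read_tbl(out)
}

#' Remove reads containing ambiguous bases
#'
#' Drops every read whose sequence contains one or more `N`.
#'
#' @param reads A read tibble.
#' @return The kept reads, with a `rejected` attribute as in
#'   [quality_filter()].
#' @export
drop_n_reads <- function(reads) {
  keep <- !grepl("N", reads$sequence, fixed = TRUE)
  out <- reads[keep, , drop = FALSE]
  attr(out, "rejected") <- tibble(
    read_id = reads$read_id[!keep],
    reason = rep("contains_N", sum(!keep))
  )
  read_tbl(out)
}

#' Classify reads as host contamination from host-reference alignments
#'
#' A read is called host when it is mapped to the host reference with a
#' mismatch count under 10% and a soft-clip length under 30% of the read
#' length (both strict inequalities); boundary reads and unmapped reads are
#' non-host.
#'
#' @param alignments An alignment tibble ([read_sam()]) of reads vs. the
#'   host reference.
#' @param max_mismatch_frac Mismatch fraction bound (default 0.10).
#' @param max_softclip_frac Soft-clip fraction bound (default 0.30).
#' @return A tibble with columns `read_id`, `status` (`"host"` /
#'   `"non_host"`).
#' @export
classify_host_read <- function(alignments, max_mismatch_frac = 0.10,
                               max_softclip_frac = 0.30) {
  need_mm <- alignments$mapped & is.na(alignments$mismatch_count)
  if (any(need_mm)) {
    abort(sprintf(
      "read '%s': mapped but mismatch count unavailable (no NM or MD tag)",
      alignments$read_id[which(need_mm)[1]]
    ))
  }
  host <- alignments$mapped &
    alignments$mismatch_count < max_mismatch_frac * alignments$read_length &
    alignments$softclip_length < max_softclip_frac * alignments$read_length
  tibble(
    read_id = alignments$read_id,
    status = ifelse(host, "host", "non_host")
  )
}

#' Preprocess paired-end reads: quality trim, drop Ns, remove host reads
#'
#' Applies [quality_filter()] and [drop_n_reads()] to both mates and removes
#' host-classified reads using alignments against the host reference.
#' Pair consistency is enforced: if either mate of a pair is rejected or
#' host, both mates are dropped.
#'
#' @param r1,r2 Read tibbles for the two mates (`r2` may be `NULL` for
#'   single-end data).
#' @param host_alignments Optional alignment tibble of all reads vs. the
#'   host reference ([read_sam()]); reads absent from it are kept.
#' @inheritParams quality_filter
#' @return A list with elements `r1`, `r2` (filtered read tibbles) and
#'   `n_removed`.
#' @export
preprocess_reads <- function(r1, r2 = NULL, host_alignments = NULL,
                             q_threshold = 20, window = 10) {
  clean <- function(x) drop_n_reads(quality_filter(x, q_threshold, window))
  k1 <- clean(r1)
  k2 <- if (!is.null(r2)) clean(r2) else NULL
  host_ids <- character(0)
  if (!is.null(host_alignments) && nrow(host_alignments)) {
    st <- classify_host_read(host_alignments)
    host_ids <- st$read_id[st$status == "host"]
  }
  keep_ids <- setdiff(k1$read_id, host_ids)
  if (!is.null(k2)) {
    keep_ids <- setdiff(intersect(keep_ids, k2$read_id), host_ids)
    k2 <- k2[k2$read_id %in% keep_ids, , drop = FALSE]
  }
  k1 <- k1[k1$read_id %in% keep_ids, , drop = FALSE]
  list(
    r1 = read_tbl(k1), r2 = if (is.null(k2)) NULL else read_tbl(k2),
    n_removed = nrow(r1) - nrow(k1)
  )
}
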