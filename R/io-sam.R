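#' Read a SAM file into alignment records
#'
#' Parses SAM (v1.6) text into a tibble of alignment records, one row per
#' alignment line. Reference spans are derived from the CIGAR string
#' (reference-consuming ops `M`, `=`, `X`, `D`; `N` skips split a span into
#' separate intervals) and stored 0-based half-open. The mismatch count is
#' taken from the `NM` tag minus inserted/deleted bases when `NM` is
#' present, otherwise re-derived from the `MD` tag, otherwise `NA`.
#'
#' @param path Path to a SAM file.
#' @param contig_lengths Optional named integer vector of reference lengths.
#'   When supplied it is checked against the `@SQ` headers; when absent the
#'   `@SQ` headers are used.
#' @return A tibble (class `alignment_tbl`) with columns `read_id`,
#'   `contig_id` (`NA` for unmapped reads), `flag`, `mapped`, `primary`,
#'   `ref_start` (0-based), `ref_spans` (list of two-column matrices of
#'   0-based half-open intervals), `span_length`, `read_length`,
#'   `mismatch_count` (may be `NA`), `softclip_length`.
#' @export
read_sam <- function(path, contig_lengths = NULL) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr][grepl("^@SQ\t", lines[hdr])]
  sq_len <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    sq_len <- setNames(ln, sn)
  }
  if (is.null(contig_lengths)) {
    if (!length(sq_len)) abort("no @SQ headers and no contig_lengths given")
    contig_lengths <- sq_len
  } else if (length(sq_len)) {
    common <- intersect(names(sq_len), names(contig_lengths))
    if (length(common) && any(sq_len[common] != contig_lengths[common])) {
      abort("@SQ lengths disagree with contig_lengths")
    }
    missing_sq <- setdiff(names(sq_len), names(contig_lengths))
    if (length(missing_sq)) {
      abort(paste0("@SQ reference not in contig_lengths: ", missing_sq[1]))
    }
  }

  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(alignment_tbl(tibble(
      read_id = character(), contig_id = character(), flag = integer(),
      mapped = logical(), primary = logical(), ref_start = integer(),
      ref_spans = list(), span_length = integer(), read_length = integer(),
      mismatch_count = integer(), softclip_length = integer()
    )))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- lengths(fields) < 11L
  if (any(short)) {
    abort(sprintf("SAM line %d: fewer than 11 fields", which(short)[1]))
  }
  fld <- function(k) vapply(fields, `[[`, character(1), k)
  read_id <- fld(1)
  flag <- as.integer(fld(2))
  rname <- fld(3)
  pos0 <- as.integer(fld(4)) - 1L
  cigar <- fld(6)
  seq_str <- fld(10)
  tags <- map(fields, function(f) if (length(f) > 11L) f[12:length(f)] else character(0))

  mapped <- bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 2304L) == 0L

  unknown <- mapped & !(rname %in% names(contig_lengths))
  if (any(unknown)) {
    abort(sprintf(
      "read '%s': alignment to unknown reference '%s'",
      read_id[which(unknown)[1]], rname[which(unknown)[1]]
    ))
  }

  cig <- map(seq_along(cigar), function(i) {
    if (!mapped[i]) list(op = character(0), len = integer(0)) else parse_cigar(cigar[i])
  })
  qlen_cigar <- vapply(cig, function(cg) {
    sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
  has_seq <- seq_str != "*"
  bad_len <- mapped & has_seq & nchar(seq_str) != qlen_cigar
  if (any(bad_len)) {
    i <- which(bad_len)[1]
    abort(sprintf(
      "read '%s': CIGAR query length %d != sequence length %d",
      read_id[i], qlen_cigar[i], nchar(seq_str[i])
    ))
  }
  read_length <- ifelse(has_seq, nchar(seq_str), ifelse(mapped, qlen_cigar, NA_integer_))

  spans <- map(seq_along(cig), function(i) {
    if (!mapped[i]) empty_span() else cigar_ref_spans(cig[[i]], pos0[i])
  })
  span_length <- vapply(spans, function(s) {
    if (nrow(s)) sum(s[, 2] - s[, 1]) else 0L
  }, integer(1))
  out_of_range <- vapply(seq_along(spans), function(i) {
    s <- spans[[i]]
    mapped[i] && nrow(s) > 0 &&
      (s[1, 1] < 0 || s[nrow(s), 2] > unname(contig_lengths[rname[i]]))
  }, logical(1))
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    abort(sprintf(
      "read '%s': alignment outside [0, %d) on '%s'",
      read_id[i], unname(contig_lengths[rname[i]]), rname[i]
    ))
  }

  softclip <- vapply(cig, function(cg) sum(cg$len[cg$op == "S"]), integer(1))
  ins <- vapply(cig, function(cg) sum(cg$len[cg$op == "I"]), integer(1))
  del <- vapply(cig, function(cg) sum(cg$len[cg$op == "D"]), integer(1))
  mismatch <- vapply(seq_along(tags), function(i) {
    if (!mapped[i]) return(NA_integer_)
    nm <- tag_value(tags[[i]], "NM", "i")
    if (!is.na(nm)) return(as.integer(nm) - ins[i] - del[i])
    md <- tag_value(tags[[i]], "MD", "Z")
    if (!is.na(md)) return(md_mismatches(md))
    NA_integer_
  }, integer(1))

  alignment_tbl(tibble(
    read_id = read_id,
    contig_id = ifelse(mapped, rname, NA_character_),
    flag = flag,
    mapped = mapped,
    primary = primary,
    ref_start = ifelse(mapped, pos0, NA_integer_),
    ref_spans = spans,
    span_length = span_length,
    read_length = as.integer(read_length),
    mismatch_count = mismatch,
    softclip_length = softclip
  ))
}

alignment_tbl <- function(x) {
  structure(as_tibble(x), class = c("alignment_tbl", class(as_tibble(x))))
}

empty_span <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

parse_cigar <- function(cigar) {
  if (cigar == "*") return(list(op = character(0), len = integer(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    abort(paste0("malformed CIGAR: ", cigar))
  }
  list(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

# reference intervals consumed by an alignment, split at N skips
cigar_ref_spans <- function(cig, pos0) {
  pos <- pos0
  cur_start <- NA_integer_
  spans <- list()
  for (i in seq_along(cig$op)) {
    op <- cig$op[i]
    len <- cig$len[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- pos
      pos <- pos + len
    } else if (op == "N") {
      if (!is.na(cur_start)) {
        spans[[length(spans) + 1L]] <- c(cur_start, pos)
        cur_start <- NA_integer_
      }
      pos <- pos + len
    }
    # I, S, H, P consume no reference
  }
  if (!is.na(cur_start)) spans[[length(spans) + 1L]] <- c(cur_start, pos)
  if (!length(spans)) return(empty_span())
  m <- do.call(rbind, spans)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

tag_value <- function(tags, tag, type) {
  pref <- paste0(tag, ":", type, ":")
  hit <- tags[startsWith(tags, pref)]
  if (!length(hit)) return(NA_character_)
  substring(hit[1], nchar(pref) + 1L)
}

# mismatch bases encoded in an MD:Z tag: letters outside ^-deletion runs
md_mismatches <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  sum(grepl("^[A-Za-z]$", toks))
}
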