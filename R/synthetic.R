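#' Specification for synthetic datasets
#'
#' Controls class structure, per-modality Gaussian feature signal, and the
#' sequence-level generator (contigs, reads, clade profiles, KO hits).
#' Defaults describe a small two-class study with 10 of 100 features per
#' modality informative at a two-standard-deviation between-class shift.
#'
#' @param n_samples_per_class Samples per class (default 30).
#' @param n_classes Number of classes (default 2; labels are
#'   `control`/`case` for two classes, the disease class last).
#' @param modalities Named list (taxonomic/genomic/functional), each a list
#'   with `n_features`, `n_informative`, `effect_size` (between-class mean
#'   shift in units of the within-class SD) and `noise_sd`.
#' @param seq List of sequence-level parameters: `n_contigs`, `n_bins`,
#'   `contig_length_range` (bp), `read_length` (bp), `reads_per_sample`,
#'   `n_diff_contigs` (contigs with class-differential abundance),
#'   `abundance` (optional classes x representative-contigs matrix of
#'   sampling weights; rows need not be normalised), `n_species`,
#'   `n_diff_species`, `n_kos`, `n_diff_kos`, `ko_reads_per_sample`,
#'   `ko_length_range`.
#' @param seed Integer seed; every draw the generator makes descends from
#'   it.
#' @param preset `"custom"` (use the arguments as given), `"small"`
#'   (20 samples, 30 contigs, 50k reads total; seconds) or `"paperlike"`
#'   (200 samples and larger feature spaces; minutes).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples_per_class = 30L, n_classes = 2L,
                           modalities = NULL, seq = NULL, seed = 1L,
                           preset = c("custom", "small", "paperlike")) {
  preset <- match.arg(preset)
  def_mod <- function(p, inf, es = 2, sd = 1) {
    list(n_features = p, n_informative = inf, effect_size = es, noise_sd = sd)
  }
  base_seq <- list(
    n_contigs = 30L, n_bins = 10L, contig_length_range = c(6000L, 9000L),
    read_length = 100L, reads_per_sample = 2500L, n_diff_contigs = 4L,
    abundance = NULL, n_species = 20L, n_diff_species = 6L,
    n_kos = 40L, n_diff_kos = 8L, ko_reads_per_sample = 500L,
    ko_length_range = c(300L, 1500L)
  )
  if (preset == "small") {
    n_samples_per_class <- 10L
    n_classes <- 2L
    modalities <- NULL
  } else if (preset == "paperlike") {
    n_samples_per_class <- 100L
    n_classes <- 2L
    modalities <- list(
      taxonomic = def_mod(330L, 30L), genomic = def_mod(280L, 25L),
      functional = def_mod(6000L, 100L)
    )
    base_seq$n_contigs <- 300L
    base_seq$n_bins <- 100L
    base_seq$reads_per_sample <- 20000L
    base_seq$n_kos <- 400L
  }
  modalities <- modalities %||% list(
    taxonomic = def_mod(100L, 10L),
    genomic = def_mod(100L, 10L),
    functional = def_mod(100L, 10L)
  )
  sq <- utils::modifyList(base_seq, seq %||% list())
  stopifnot(
    n_samples_per_class >= 1, n_classes >= 2,
    sq$n_bins <= sq$n_contigs
  )
  for (m in modalities) {
    if (m$n_informative > m$n_features || m$effect_size < 0) {
      abort("modality spec: need n_informative <= n_features and effect_size >= 0")
    }
  }
  structure(
    list(
      n_samples_per_class = as.integer(n_samples_per_class),
      n_classes = as.integer(n_classes),
      modalities = modalities, seq = sq, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

synth_labels <- function(spec) {
  n <- spec$n_samples_per_class * spec$n_classes
  class_names <- if (spec$n_classes == 2L) {
    c("control", "case")
  } else {
    sprintf("class%02d", seq_len(spec$n_classes))
  }
  tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    label = factor(
      rep(class_names, each = spec$n_samples_per_class),
      levels = class_names
    )
  )
}

#' Generate labelled multi-modality feature matrices
#'
#' Draws class-conditional Gaussian log-abundances per modality:
#' informative features are shifted between classes by
#' `effect_size * noise_sd`, the rest are pure noise. Values are
#' exponentiated (base 10) into non-negative raw abundances so that
#' [log_transform()] recovers the Gaussian scale.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `features` (named list of raw `feature_matrix`
#'   objects), `labels` (tibble `sample_id`, `label`) and `positive` (the
#'   disease class).
#' @export
generate_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- synth_labels(spec)
  n <- nrow(labels)
  cls <- as.integer(labels$label)
  withr::with_seed(spec$seed, {
    features <- imap(spec$modalities, function(mo, mod_name) {
      Z <- matrix(
        rnorm(n * mo$n_features, sd = mo$noise_sd),
        nrow = n, ncol = mo$n_features
      )
      if (mo$n_informative > 0 && mo$effect_size > 0) {
        shift <- (cls - 1) * mo$effect_size * mo$noise_sd
        Z[, seq_len(mo$n_informative)] <-
          Z[, seq_len(mo$n_informative), drop = FALSE] + shift
      }
      vals <- 10^Z
      colnames(vals) <- sprintf("%s_f%03d", mod_name, seq_len(mo$n_features))
      rownames(vals) <- labels$sample_id
      feature_matrix(vals, modality = mod_name, transform = "raw")
    })
    list(
      features = features, labels = labels,
      positive = levels(labels$label)[nlevels(labels$label)]
    )
  })
}

#' Generate a dataset with complementary modality signals
#'
#' Builds a two-class dataset in which each modality carries class signal
#' for only one disjoint subset of the samples: modality `m`'s informative
#' features separate the classes (at `effect_size` within-class SDs) only
#' for the samples of group `m`, and are pure noise elsewhere. No single
#' modality can classify every sample, but their combination can — the
#' construction that motivates fusing modalities at all.
#'
#' @param n_per_group Samples per group; there are as many groups as
#'   modalities, class-balanced within each group.
#' @param n_modalities Number of modalities/groups (default 3, named
#'   taxonomic/genomic/functional).
#' @param n_features,n_informative,effect_size,noise_sd Per-modality feature
#'   geometry, as in [synthetic_spec()].
#' @param seed Integer seed.
#' @return As [generate_feature_dataset()]: raw `feature_matrix` objects,
#'   labels and the positive class, plus `group` membership in the labels
#'   tibble.
#' @export
generate_complementary_dataset <- function(n_per_group = 10, n_modalities = 3,
                                           n_features = 60, n_informative = 6,
                                           effect_size = 5, noise_sd = 1,
                                           seed = 1L) {
  stopifnot(n_per_group %% 2 == 0, n_modalities >= 2)
  mods <- c("taxonomic", "genomic", "functional")[seq_len(min(n_modalities, 3))]
  if (n_modalities > 3) mods <- c(mods, sprintf("modality%d", 4:n_modalities))
  n <- n_per_group * n_modalities
  labels <- tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    label = factor(rep(rep(c("control", "case"), each = n_per_group / 2),
                       n_modalities),
                   levels = c("control", "case")),
    group = rep(mods, each = n_per_group)
  )
  cls <- as.integer(labels$label) - 1L
  withr::with_seed(seed, {
    features <- setNames(map(seq_along(mods), function(m) {
      Z <- matrix(rnorm(n * n_features, sd = noise_sd), n, n_features)
      in_group <- labels$group == mods[m]
      Z[in_group, seq_len(n_informative)] <-
        Z[in_group, seq_len(n_informative), drop = FALSE] +
        cls[in_group] * effect_size * noise_sd
      vals <- 10^Z
      colnames(vals) <- sprintf("%s_f%03d", mods[m], seq_len(n_features))
      rownames(vals) <- labels$sample_id
      feature_matrix(
        vals,
        modality = if (mods[m] %in% fm_modalities()) mods[m] else "fused",
        transform = "raw"
      )
    }), mods)
    list(features = features, labels = labels, positive = "case")
  })
}

# class-specific sampling weights: gamma base, differential units scaled
# up in the disease class and down in the control class
class_weights <- function(n_units, n_diff, n_classes, fold = 6) {
  base <- rgamma(n_units, shape = 2, rate = 1) + 0.05
  t(vapply(seq_len(n_classes), function(k) {
    w <- base
    if (n_diff > 0) {
      idx <- seq_len(n_diff)
      # alternate direction across units so every class has markers
      up <- idx[(idx + k) %% n_classes == 0]
      down <- setdiff(idx, up)
      w[up] <- w[up] * fold
      w[down] <- w[down] / fold
    }
    w / sum(w)
  }, numeric(n_units)))
}

random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a full sequence-level synthetic dataset on disk
#'
#' Writes every file the pipeline consumes: random DNA contigs with bin
#' assignments, per-sample SAM alignments of error-free reads drawn with
#' class-dependent contig abundances, MetaPhlAn-style clade profiles, KO
#' hit tables with a query-length table and KO gene lengths, a read-count
#' manifest and labels. Reads are drawn only from the representative
#' (longest-per-bin) contigs, emulating mapping against the non-redundant
#' reference set. A ground-truth table of true per-(sample, contig) read
#' counts and covered bases (tracked with a per-base bitmap while reads are
#' placed) is returned for oracle tests.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file/dir paths), `labels`,
#'   `ground_truth` (tibble: `sample_id`, `contig_id`, `true_count`,
#'   `true_covered_bases`, `total_reads`, `contig_length`), `ko_truth`
#'   (tibble: `sample_id`, `ko_id`, `true_count`), `abundance` (the
#'   class x contig weight matrix) and `representatives`.
#' @export
generate_sequence_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sq <- spec$seq
  labels <- synth_labels(spec)
  cls <- as.integer(labels$label)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("sam", "profiles", "hits")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }

  withr::with_seed(spec$seed, {
    # --- contigs and bins ---------------------------------------------------
    lens <- sample(sq$contig_length_range[1]:sq$contig_length_range[2],
                   sq$n_contigs, replace = TRUE)
    if (sq$read_length > min(lens)) {
      abort("read_length exceeds the shortest contig")
    }
    contig_ids <- sprintf("contig%03d", seq_len(sq$n_contigs))
    bin_ids <- sprintf("bin%02d", rep_len(seq_len(sq$n_bins), sq$n_contigs))
    seqs <- random_dna(lens)

    fasta_path <- file.path(dir, "contigs.fasta")
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- contig_ids
    Biostrings::writeXStringSet(dna, fasta_path, width = 80L)
    bins_path <- file.path(dir, "bins.tsv")
    readr::write_tsv(tibble(contig_id = contig_ids, bin_id = bin_ids),
                     bins_path, col_names = FALSE)

    # representatives: longest per bin, ties to smallest id (generator-side
    # bookkeeping, computed independently of the pipeline helpers)
    rep_idx <- vapply(split(seq_len(sq$n_contigs), bin_ids), function(ix) {
      ix[order(-lens[ix], contig_ids[ix])][1]
    }, integer(1))
    rep_idx <- rep_idx[order(contig_ids[rep_idx])]
    rep_ids <- contig_ids[rep_idx]
    rep_lens <- lens[rep_idx]
    n_rep <- length(rep_ids)

    ab <- sq$abundance %||%
      class_weights(n_rep, min(sq$n_diff_contigs, n_rep), spec$n_classes)
    if (!is.matrix(ab) || nrow(ab) != spec$n_classes || ncol(ab) != n_rep) {
      abort("abundance must be a classes x representative-contigs matrix")
    }

    # --- per-sample reads and SAM ------------------------------------------
    hdr <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", rep_ids, rep_lens)
    )
    rl <- sq$read_length
    qual <- strrep("I", rl)
    truth <- vector("list", nrow(labels))
    for (i in seq_len(nrow(labels))) {
      sid <- labels$sample_id[i]
      w <- ab[cls[i], ]
      counts <- as.integer(rmultinom(1, sq$reads_per_sample, prob = w))
      lines <- vector("list", n_rep)
      covered <- integer(n_rep)
      read_no <- 0L
      for (j in seq_len(n_rep)) {
        cj <- counts[j]
        if (cj > 0L) {
          starts <- sample.int(rep_lens[j] - rl + 1L, cj, replace = TRUE) - 1L
          bitmap <- logical(rep_lens[j])
          for (s0 in starts) bitmap[(s0 + 1L):(s0 + rl)] <- TRUE
          covered[j] <- sum(bitmap)
          ids <- sprintf("%s_r%05d", sid, read_no + seq_len(cj))
          read_no <- read_no + cj
          lines[[j]] <- sprintf(
            "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:0",
            ids, rep_ids[j], starts + 1L, rl,
            substring(seqs[rep_idx[j]], starts + 1L, starts + rl), qual
          )
        }
      }
      writeLines(c(hdr, unlist(lines)),
                 file.path(dir, "sam", paste0(sid, ".sam")))
      truth[[i]] <- tibble(
        sample_id = sid, contig_id = rep_ids, true_count = counts,
        true_covered_bases = covered,
        total_reads = sq$reads_per_sample, contig_length = rep_lens
      )
    }
    truth <- list_rbind(truth)

    # --- clade profiles -----------------------------------------------------
    n_sp <- sq$n_species
    lineage <- tibble(
      species = sprintf("Species%02d", seq_len(n_sp)),
      genus = sprintf("Genus%02d", ceiling(seq_len(n_sp) / 2)),
      family = sprintf("Family%02d", ceiling(seq_len(n_sp) / 4)),
      order = sprintf("Order%02d", ceiling(seq_len(n_sp) / 8)),
      class = sprintf("Class%02d", ceiling(seq_len(n_sp) / 12)),
      phylum = sprintf("Phylum%02d", ceiling(seq_len(n_sp) / 16))
    )
    sp_w <- class_weights(n_sp, min(sq$n_diff_species, n_sp), spec$n_classes)
    for (i in seq_len(nrow(labels))) {
      sid <- labels$sample_id[i]
      g <- rgamma(n_sp, shape = 25 * n_sp * sp_w[cls[i], ], rate = 1)
      prop <- 100 * g / sum(g)
      lines <- c("#SampleID\tclade_abundance", "k__Bacteria\t100")
      for (rk in c("phylum", "class", "order", "family", "genus", "species")) {
        pieces <- c("phylum", "class", "order", "family", "genus", "species")
        upto <- pieces[seq_len(match(rk, pieces))]
        pref <- c(phylum = "p", class = "c", order = "o", family = "f",
                  genus = "g", species = "s")
        clade_str <- apply(lineage[upto], 1L, function(row) {
          paste0("k__Bacteria|",
                 paste(paste0(pref[upto], "__", row), collapse = "|"))
        })
        agg <- rowsum(prop, clade_str)
        lines <- c(lines, sprintf(
          "%s\t%s", rownames(agg),
          formatC(agg[, 1], digits = 17, format = "g")
        ))
      }
      writeLines(lines, file.path(dir, "profiles", paste0(sid, ".tsv")))
    }

    # --- KO hits ------------------------------------------------------------
    ko_ids <- sprintf("K%05d", seq_len(sq$n_kos))
    ko_len <- sample(sq$ko_length_range[1]:sq$ko_length_range[2],
                     sq$n_kos, replace = TRUE)
    readr::write_tsv(tibble(ko_id = ko_ids, gene_length = ko_len),
                     file.path(dir, "ko_lengths.tsv"), col_names = FALSE)
    ko_w <- class_weights(sq$n_kos, min(sq$n_diff_kos, sq$n_kos),
                          spec$n_classes)
    ko_truth <- vector("list", nrow(labels))
    qlen_rows <- vector("list", nrow(labels))
    for (i in seq_len(nrow(labels))) {
      sid <- labels$sample_id[i]
      counts <- as.integer(rmultinom(1, sq$ko_reads_per_sample,
                                     prob = ko_w[cls[i], ]))
      read_ids <- sprintf("%s_kr%05d", sid, seq_len(sum(counts)))
      ko_of_read <- rep(ko_ids, counts)
      hits <- tibble(
        read_id = read_ids, ko_id = ko_of_read,
        percent_identity = round(runif(length(read_ids), 80, 100), 1),
        align_length = rl, mismatches = 0L, gap_openings = 0L,
        qstart = 1L, qend = rl, sstart = 1L, send = rl,
        e_value = 10^-round(runif(length(read_ids), 20, 60), 1),
        bit_score = round(runif(length(read_ids), 150, 400), 1)
      )
      readr::write_tsv(hits, file.path(dir, "hits", paste0(sid, ".tsv")),
                       col_names = FALSE)
      qlen_rows[[i]] <- tibble(query_id = read_ids, length = rl)
      ko_truth[[i]] <- tibble(sample_id = sid, ko_id = ko_ids,
                              true_count = counts)
    }
    readr::write_tsv(list_rbind(qlen_rows),
                     file.path(dir, "query_lengths.tsv"), col_names = FALSE)
    ko_truth <- list_rbind(ko_truth)

    manifest <- tibble(
      sample_id = labels$sample_id,
      total_reads = sq$reads_per_sample,
      ko_total_reads = sq$ko_reads_per_sample
    )
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    readr::write_tsv(labels, file.path(dir, "labels.tsv"))

    invisible(list(
      paths = list(
        contigs = fasta_path, bins = bins_path,
        sam_dir = file.path(dir, "sam"),
        profiles_dir = file.path(dir, "profiles"),
        hits_dir = file.path(dir, "hits"),
        query_lengths = file.path(dir, "query_lengths.tsv"),
        ko_lengths = file.path(dir, "ko_lengths.tsv"),
        manifest = file.path(dir, "manifest.tsv"),
        labels = file.path(dir, "labels.tsv")
      ),
      labels = labels, ground_truth = truth, ko_truth = ko_truth,
      abundance = ab, representatives = tibble(
        contig_id = rep_ids, length = rep_lens, bin_id = bin_ids[rep_idx]
      )
    ))
  })
}
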