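---
title: "Multimodal classification of host phenotype from metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal classification of host phenotype from metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromodal)
```

## The problem

Shotgun metagenomes of the human gut carry several complementary signals of
host disease status: which taxa are present and in what proportions, how
abundant particular genomic fragments are (including fragments from
unannotated organisms), and which metabolic functions the community
encodes. micromodal turns each of these into a feature matrix — a
**modality** — and classifies disease status with a two-stage multimodal
feedforward network evaluated by leave-one-out cross-validation (LOOCV).

The three modalities are:

1. **Taxonomic composition.** Per-sample clade proportion profiles
   (MetaPhlAn-style TSVs) are assembled into one matrix per rank from
   phylum to species. Genus- and species-level taxa seen in only one
   sample are removed as likely sample-specific.
2. **Genome-level abundance.** Contigs assembled from a random subset of
   *reference samples* are length-filtered (strictly longer than 5000 bp),
   and the longest contig of each bin represents its bin as a
   non-redundant genomic fragment. Every sample's reads are mapped against
   these representatives, and each (sample, contig) cell holds

   $$\mathrm{RPKM}(s_i, c_j) = \frac{\#\text{mapped reads in } s_i \times 10^3 \times 10^6}
        {\#\text{reads in } s_i \times \mathrm{length}(c_j)}$$

   A cell is zeroed when the breadth of coverage
   $\mathrm{Coverage}(s_i, c_j) = \text{covered bases}/\text{length}(c_j)$
   falls below 0.70 — a fragment most of whose bases are never touched by
   a read is taken to be absent from that sample, not merely rare.
3. **Functional abundance.** Protein-level hits of reads against KEGG
   orthologs (DIAMOND 12-column tabular) are filtered at percent identity
   ≥ 50, query coverage ≥ 50 and e-value ≤ 1e−10, each read keeps its
   best hit (highest bit score; ties by lowest e-value, then smallest KO
   id), and per-KO counts become gene-length-normalised RPKM values.

All matrices are log10-transformed (with a pseudocount, below) before they
reach a network.

## The model

Each modality is fed to its own supervised encoder: a fully connected
feedforward network with ReLU hidden layers and a softmax output, trained
with categorical cross-entropy and Adam (learning rate 0.001, moment
decays 0.9/0.999). The taxonomic and genomic encoders use 200-100-50
hidden nodes; the functional encoder, built for wider inputs, uses
500-100-50. The activations of each encoder's **last hidden layer** are
the modality's embedded representation. Stage two freezes the encoders,
concatenates the embeddings into a shared representation (3 × 50 = 150
dimensions for three modalities) and trains a final 50-25 classifier on
it. Freezing is structural: fusion training simply never touches encoder
weights, and a test asserts bitwise equality before and after.

Training details the architecture does not pin down were fixed as
defaults and are configurable through `encoder_config()`: 100 epochs,
minibatches of 16, Glorot-uniform initialisation, no dropout or early
stopping. The canonical loss for a softmax output is categorical
cross-entropy, so that is the loss. An end-to-end fine-tuning mode is
deliberately absent: two-stage training with frozen encoders is the
contract, which keeps the embedding stage reusable and the fusion stage
cheap.

Determinism is part of the API: all weight initialisation and batch
shuffling derives from R's RNG under the caller's seed, and the compiled
training loop is deterministic in its inputs, so the same seed reproduces
the same weights bit for bit. The loop itself runs in single precision —
minibatch gradient noise dwarfs float rounding — while everything outside
training is double precision.

## Evaluation protocol

`loocv()` runs one fold per sample; the held-out sample takes part in
neither training stage. Feature steps that depend on the training set —
the prevalence filter, reference-sample selection — would leak information
if computed globally, so `loocv()` accepts a per-fold `prep` hook that
recomputes them from the training rows only; the fold receives raw
inputs, never globally precomputed summaries. `repeat_eval()` repeats the
whole LOOCV under derived seeds (five times by default) and averages
accuracy, precision, recall and AUC.

Accuracy, precision and recall are the usual confusion-count ratios with
the disease class as positive; undefined ratios (zero denominators) are
reported as `NA`, never coerced to 0. Both one-vs-positive and
macro-averaged precision/recall are reported; for class-balanced designs
they coincide. ROC curves use thresholds at the midpoints between
consecutive distinct scores (with sentinels beyond both extremes), and
AUC is the trapezoid area — equal to the tie-corrected Mann–Whitney U
statistic over $n_1 n_0$, which a test asserts. `ensemble_vote()`
majority-votes several classifiers' predictions, breaking ties by highest
mean predicted probability and then by label order.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| quality threshold | Q20 | `quality_filter()` | standard quality floor for Illumina gut metagenomes |
| trim window | 10 bases | `quality_filter()` | window-mean trimming; per-base edge clipping afterwards |
| host mismatch / soft-clip bounds | < 10% / < 30% of read length | `classify_host_read()` | reads aligning that cleanly to the host genome are contamination; both bounds strict |
| contig length filter | > 5000 bp | `filter_contigs_by_length()` | short contigs carry unstable abundance estimates |
| coverage threshold | ≥ 0.70 | `build_genomic_matrix()` | breadth below this marks the fragment absent; boundary kept |
| hit filter | ≥ 50% id, ≥ 50% qcov, ≤ 1e−10 | `filter_hits()` | cutoffs read as inclusive, the conventional meaning of "cutoff" |
| pseudocount | 1e−6 | `log_transform()` | maps zero abundance to −6 on the log10 scale, well below any observed value |
| epochs / batch | 100 / 16 | `encoder_config()` | small-cohort defaults; no early stopping |

## The synthetic-data generator

Real accession-scale datasets are hundreds of gigabytes; the package
instead ships a generator that emulates **every** input the pipeline
consumes, with known ground truth, so each stage can be verified
end-to-end:

* `generate_feature_dataset()` draws class-conditional Gaussian
  log-abundances (informative features shifted between classes by
  `effect_size` within-class SDs, the rest pure noise) and exponentiates
  them into raw abundances, so `log_transform()` recovers the Gaussian
  scale.
* `generate_sequence_dataset()` writes random DNA contigs with bin
  assignments, draws per-sample reads from the representative contigs
  with class-specific Dirichlet-derived abundance weights, and emits
  error-free end-to-end SAM alignments, clade profiles, KO hit tables and
  manifests. While placing reads it tracks true per-(sample, contig)
  counts and covered bases with a per-base bitmap; this bookkeeping is
  the oracle against which the SAM-parsing route is compared cell for
  cell.
* `generate_complementary_dataset()` builds the construction that
  motivates fusion: each modality separates the classes only within one
  disjoint third of the samples (5 SD shift there, pure noise elsewhere),
  so no single modality can classify everyone but their combination can.

Reads are error-free by design — the point is to isolate the pipeline's
arithmetic from aligner noise, not to emulate a sequencer. The generator
therefore says nothing about robustness to sequencing error, chimeras,
uneven coverage biases or real taxonomies, and passing tests on synthetic
data do not certify accuracy on real cohorts; they certify that the
bookkeeping, formulas, filters and protocol are implemented exactly.

Class-differential abundances are drawn by scaling a shared
gamma(shape 2) weight vector up or down 6-fold on the differential units,
alternating direction so every class has markers, then normalising. The
gamma base gives realistic order-of-magnitude spread between contigs, so
some (sample, contig) pairs genuinely fall below the 70% breadth
threshold and the filter is exercised.

## Numerical and design choices

* **Boundary readings.** "Longer than 5000 bp" and "under 10%/30%/70%"
  are read strictly: 5000 bp contigs are dropped, a read at exactly 10%
  mismatches is not host, a cell at exactly 0.70 coverage is kept.
* **Zeroed, not missing.** Sub-threshold coverage cells become 0 before
  the log transform, since the network needs dense input and "absent from
  this sample" is exactly what 0 abundance encodes.
* **Counting.** Mapped reads are counted as distinct read ids over
  primary alignments only; duplicates are not removed. Covered bases are
  the size of the interval union of aligned reference spans (deletions
  consume reference; `N` skips split spans).
* **Mismatch counts.** From the `NM` tag minus inserted/deleted bases
  when present, else re-derived from `MD`; a mapped read with neither is
  an error at host-classification time rather than silently non-host.
* **Tie-breaks** are total and documented everywhere: longest contig ties
  by smallest id, best hit by bit score / e-value / KO id, argmax by first
  class in label order, vote ties by mean probability then label order.
* **Per-rank profiles.** Each profile line contributes one entry at its
  terminal rank; kingdom lines vanish after the bacteria-only filter and
  strain-level lines are skipped, leaving the six ranks phylum–species.
* **Degenerate inputs.** Empty profiles warn and yield empty matrices;
  empty hit files yield zero-width matrices; a class missing from a
  training fold downgrades that fold to a warning plus a trivial
  prediction instead of aborting the whole evaluation.

## Validation scale

The shipped tests and the acceptance script validate at sizes chosen to
finish comfortably on a single CPU: formula oracles at 1,000 random
inputs each; end-to-end bookkeeping on the `small` sequence preset
(20 samples, 30 contigs, 50,000 reads); leakage checks on a 12-sample
set; signal recovery on 60 samples with 100 features per modality
(10 informative at a 2 SD shift) over five LOOCV repetitions with a
three-permutation label-shuffled control; complementarity on 30 samples
over three repetitions. The `paperlike` preset (200 samples, larger
feature spaces) exists for heavier experiments and runs in minutes rather
than seconds.

## A worked example

```{r example, eval = FALSE}
library(micromodal)

spec <- synthetic_spec(n_samples_per_class = 30, seed = 7)
ds <- generate_feature_dataset(spec)
mats <- lapply(ds$features, log_transform)

res <- repeat_eval(mats, ds$labels$label, runs = 5, base_seed = 7,
                   positive = "case")
glance(res)
autoplot(res$runs[[1]])   # ROC curve of the first run
```

## Known limitations

* The package consumes assemblies, bins, alignments and hit tables as
  files; it does not run assemblers, binners, aligners or profilers.
* LOOCV is the only cross-validation scheme; k-fold would be a small
  extension but is untested and therefore not offered.
* The encoders are plain dense networks without regularisation; on very
  wide real datasets some form of early stopping or weight decay may be
  worth adding before trusting single-run numbers.
* Single-precision training means third-party reimplementations in double
  precision will match to ~1e−5 per step, not bitwise; the package's own
  determinism contract (same seed, same platform, same bits) still holds.
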