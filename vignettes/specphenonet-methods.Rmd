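---
title: "Identification-free phenotype classification of tandem-MS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identification-free phenotype classification of tandem-MS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specphenonet)
```

## The problem

In shotgun proteomics and metabolomics, most acquired tandem spectra are
never assigned to a peptide or metabolite: database-search engines disagree
with each other, isobaric metabolites are degenerate, and up to ~70% of the
signal — the "dark" proteome and metabolome — is discarded before any
biological question is asked. `specphenonet` takes the opposite route: it
classifies cancer phenotypes (healthy control `CNT`, ovarian `OVC`, kidney
`RNC`, prostate `PRC`) **directly from the raw peak lists** in Mascot
Generic Format, using only the three descriptors every mgf file carries —
retention time (RT), mass-to-charge ratio (m/z), and intensity — and never
identifying a single molecule.

Two classifiers are provided:

* a **4-channel 1D residual CNN** consuming parallel streams of
  (m/z, intensity) for the proteomic and metabolomic layers of one subject;
* a **3D CNN** consuming a volume built from a sequence of RT x m/z
  intensity images of a single layer.

## Preprocessing model

Noise reduction follows four stages, each a pure function of its input and
configuration:

1. **Feature extraction.** Every fragment peak of every scan becomes an
   (rt, m/z, intensity) triple; RT is snapped to a 0.1 s grid
   (`rt_step`), and triples are ordered by (rt, m/z).
2. **ppm quantization.** m/z values are binned multiplicatively with ratio
   `1 + ppm * 1e-6` — 10 ppm for proteomic, 100 ppm for metabolomic data —
   so the bin width is proportional to mass at every mass, which is what a
   ppm tolerance means. The bin center deviates from any member by at most
   half the tolerance. Quantization runs before the frequency filter:
   frequencies of continuous m/z values are undefined, so the filter must
   count quantized bins (the stage list (a)-(d) is preserved
   semantically).
3. **Rare-feature elimination.** A bin's frequency is the number of
   distinct files containing it (not a within-file peak count); bins with
   frequency `<= 2` are dropped (a strict "greater than" rule,
   configurable). The filter is idempotent. By default the vocabulary is
   counted on the **training split** and applied unchanged to
   test/validation (`vocab_source = "train_only"`): an absolute threshold
   applied separately to splits of different sizes passes systematically
   different amounts of background through each split, which both leaks
   split identity into the features and shifts the test distribution away
   from the training one. A `per_dataset` mode counts within each split
   for pipelines that want strictly independent processing.
4. **Min-max scaling and elliptic envelope.** m/z and intensity are mapped
   to [0, 1]. By default statistics are fitted on the training split only
   and applied to test/validation (leakage-safe); a `per_dataset` mode
   scales each split by its own range. The elliptic envelope fits a robust
   location/scatter (minimum covariance determinant, via `MASS::cov.rob`)
   to each file's (m/z, intensity) cloud and removes the `outlier_fraction`
   (default 0.2, an upper bound — reflecting an assumed measurement error
   below 20%) of points with the largest Mahalanobis distance. For large
   files the MCD is fitted on a capped random subsample (2000 points) and
   all points are scored; streams shorter than 25 points pass through
   untouched, as do degenerate constant clouds (with a warning). The
   feature space and per-file application are our choices — (m/z,
   intensity) is the only 2D space both omics layers share.

The four model channels are `(prot_mz, prot_intensity, met_mz,
met_intensity)`, each of a fixed `channel_length` (default 2^15; the
architecture itself never dictates this, so it is configuration). Longer
streams are uniformly subsampled preserving RT order; shorter ones are
right-padded with zeros. RT orders the data but is *not* an input channel.

## Splits and augmentation

Splits are stratified per class over **subjects**, so the proteomic and
metabolomic files of one subject always land in the same split; 300
labeled files at a 0.6 train fraction give the canonical 180/120
partition. Augmentation extracts the first and last 5% of scans of every
file into a per-split database; replicates are synthesized by re-inserting
randomly drawn same-split elements at uniform random RT positions within
the middle 90% of the run (the "meaningful part"), re-stamping their RT.
Elements are whole scans, since they are extracted from file sections and
re-inserted at scan positions. `audit_leakage()` verifies that no
augmented file contains an element sourced from another split. The
replicate multiplicity and per-replicate insert fraction (default 0.10,
mirroring the extracted fraction) are configuration: the published dataset
sizes imply roughly a 6x enlargement of the training pool but are not
internally consistent enough to pin a single multiplier, so the cohort
scale is parameterized throughout.

## Image representation

For the 3D model, the RT axis is cut into consecutive 96.7 s windows
starting at 0; each window becomes a 512 x 512 raster with RT within the
window on one axis and m/z (within a per-layer axis range, proteomic
100-2000 Th, metabolomic 50-1000 Th — configurable, as no canonical limits
exist) on the other. A full 0-9476.6 s run yields exactly 98 frames.
Multiple peaks landing on one pixel aggregate by max (robust and
monotone; sum is available), and intensity is encoded to [0, 1] grayscale
by `log1p` then max-normalization over the file. Sequences are padded with
blank frames or truncated to exactly 98 so every file yields a fixed-shape
volume. Image augmentation transforms a uniformly chosen 30% of frames
with one of \{shift, rectangle zeroing, crop-and-rescale\}; magnitudes
(shift up to 10% of the side, zeroed area up to 10%, crop to 90%) are
configurable because only the transform family is canonical. Frames are
then reduced to 256 x 256 by area averaging and stacked into a
256 x 256 x 98 volume.

## Architectures

**1D residual CNN.** A stem convolution (kernel 32, 64 filters, stride 2)
is followed by four stages of (4, 3, 3, 4) residual blocks with kernel 7
and filters 64/128/256/512; each block is conv-BN-GELU-conv-BN with a
GELU after the skip addition, the skip path using a kernel-1
stride-matched projection exactly when shape changes. Stride 2 is applied
on the first convolution of each stage. That is 1 + 2(4+3+3+4) = 29
convolutions. GELU uses the tanh approximation
`0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3)))`. The head is average
pooling (kernel 3), global average pooling, dropout (p = 0.3), and a
dense 512 -> 4 softmax. A kernel-3 pooling alone cannot produce a
512-wide flatten for any plausible input length, while the dense layer is
unambiguously 512 x 4; global average pooling honors both, and dropout
sits between pooling and the dense head. Two desk-scale variants exist
alongside the full-width default. The `reduced = TRUE` preset (one block
per stage, 8-32 filters, 512-long channels) keeps the topology at minimal
cost for engine-level tests. The *recovery* preset used in the worked
examples (one block per stage, 128 filters, a kernel-1 stem of 256
filters, channels long enough that no stream is subsampled) reflects
what the desk-scale data demand: the full model's large stem kernel is
motivated by smooth, non-stationary spectral signal, whereas at desk
scale each channel position holds one discrete peak, and class identity
lives in *which m/z values recur*. A kernel-1 stem builds per-peak value
ramps that the kernel-7 residual stages assemble into narrow value
detectors; global average pooling then counts their occurrences — a
learned, soft histogram. Empirically this preset generalizes where
large-stem narrow variants memorize the training files. Keeping channels
at full stream length matters for the same reason: uniform subsampling
of variable-length streams decouples positions from retention time
across files and discards most occurrences of each marker.

**3D CNN.** Eight valid (unpadded) 3D convolutions with kernels
(7,9,9)x16, (5,7,7)x16, (5,7,7)x32, (2,5,5)x32, (2,5,5)x64, (1,3,3)x128,
(1,3,3)x256, (1,3,3)x512, batch normalization after every convolution,
PReLU activations, and three max-pools of kernels (3,3,3), (2,2,2),
(2,2,2). Max-pool strides equal their kernels: unit strides (as the layer
table literally lists) cannot reduce a 256 x 256 x 98 volume to a
4096-wide flatten, whereas kernel-strided pooling with valid convolutions
lands exactly on 512 channels x (2,2,2) = 4096 features entering the
dense 4096 -> 64 -> 4 head. An adaptive average pool to (2,2,2) before
the flatten guarantees that width for any admissible input and is the
identity under defaults.

Both models are built on an internal neural-network engine (im2col +
GEMM convolutions in C++/Armadillo, batch normalization, dropout,
Adam); every layer's analytic gradient is verified against central finite
differences in the test suite, and evaluation-mode forwards run through a
cache-free single-pass path so a full-size 3D forward stays under ~2 GB.
Weights use variance-scaling (He) initialization, seeded per model.

## Training and evaluation

Training minimizes multiclass cross-entropy (natural log; a one-hot truth
gives `-log p_true`, with zero probabilities clamped at 1e-12) with Adam
(framework-default moments), 25 epochs, initial learning rate 1e-3, and a
plateau schedule: when test accuracy has not improved for 2 consecutive
epochs (the patience is our choice; only the trigger and the 0.5 factor
are canonical), the rate halves. `evaluate_model()` reports accuracy,
macro recall and macro F1 plus per-class precision/recall/F1 and the 4x4
confusion matrix in the fixed order CNT, OVC, RNC, PRC.

The inter-phenotype distance matrix is the single most consequential open
design point: no canonical definition exists for how such distances are
computed from a trained classifier. We define `d(a, b)` as the Euclidean
distance between the per-class centroids of penultimate-layer embeddings
(512-d for the default 1D model, 64-d for the 3D model) over the test
set, with a cosine option, isolated behind `class_distance_matrix()`.
The matrix is symmetric with a zero diagonal by construction; only its
*ordinal* structure (which phenotypes are closer) is claimed, never the
published numeric values, which belong to the 240 GB real cohort.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` plants per-class marker m/z values (Gaussian elution
envelopes, ppm-scale m/z jitter, log-normal intensity noise) on a shared
background of common peaks and uniform decoys, with a configurable
fraction of pure-noise scans. Elution times are treated as analyte
properties: a marker's elution center and width are deterministic
functions of its m/z, shared by every file, with a small per-file
chromatographic drift (`rt_drift_fraction`, default 2% of the run). This
mirrors real LC reproducibility and is what makes an RT-aligned positional
representation meaningful at all — with run-random elution times the
channels would carry class information only in value space, not position
space. Inter-class similarity is controlled by
marker sharing: by default the three cancers share a common marker pool
absent from the control, RNC/OVC share the most pairwise markers and
OVC/PRC the fewest, so the control is constructed to be the most distant
phenotype and RNC/OVC the closest pair — the geometry the distance matrix
is expected to recover. Defaults are desk-scale: 30 subjects per class,
200 scans per file over a 967 s run (ten image windows; the full
9476.6 s span is exercised in the frame-count contract), ~30 decoy peaks
per scan, 5/50 ppm jitter, and a seed hierarchy (master seed ->
counter-derived per-file seeds) that makes cohorts reproducible file by
file.

What passing on synthetic cohorts shows: the pipeline is
information-preserving end to end, the models can learn class structure
expressed as recurring m/z features, and the distance matrix recovers
planted similarity geometry. What it does not show: performance on real
HPLC-MS/MS data, whose peak density, correlation structure, isotope
envelopes, and batch effects the generator deliberately does not emulate.

## Numerical choices and degenerate inputs

* Quantization bins are indexed by `round(log(mz) / log1p(ppm * 1e-6))`;
  the representative is the bin center, making quantization idempotent.
* Ties at the elliptic-envelope cut distance are broken first-come so the
  removed count never exceeds `floor(fraction * n)`.
* Subsampling indices for overlong channels are
  `floor((0:(L-1)) * n / L) + 1`: exactly every other element at n = 2L,
  always RT-ordered.
* Empty files render as blank (warned) frame sequences; empty streams
  min-max scale to empty streams; a constant scaling channel maps to 0.
* `read_mgf` fails hard on a block without RT (the pipeline is RT-driven,
  so silent defaults are unsafe) and names the offending block; an
  optional minutes dialect converts header values < 200 under an explicit
  flag only.
* Problem sizes in the test suite are chosen for a single desktop CPU:
  reduced-width 1D models, one full-size 3D forward, and cohorts of 120
  subjects (the recovery experiment trains 72 and evaluates 48 subjects
  at channel length 3584 for 20 epochs); the full-width 1D model is
  built and audited structurally but trained only in reduced form.
* The classifier head is initialized near zero so an untrained model
  answers with a near-uniform distribution (mean cross-entropy ~ ln 4),
  the standard sanity property for a softmax classifier.

## Known limitations

* No mzML or vendor-format ingestion; mgf only, by design.
* The 3D model trains only at full input size in principle (its
  convolution cascade admits no much smaller input); training it
  end-to-end on CPU is impractical, so its training path is validated at
  the layer level (finite-difference gradients) and the model is
  exercised forward at full size.
* Min-max scaling and envelope filtering semantics on real cohorts
  (global vs per-file) are genuinely underdetermined; both modes exist,
  defaults documented above.
* The published per-layer image totals are not integer multiples of 98;
  the fixed-98 frame policy is a deliberate simplification that keeps
  every volume the same shape.
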