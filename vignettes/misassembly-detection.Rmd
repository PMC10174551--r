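---
title: "Detecting misassembled contigs from read alignments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting misassembled contigs from read alignments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contiguard)
```

## The detection problem

A misassembled contig — a relocation, inversion, translocation or
interspecies chimera — carries a junction that no read pair in the
underlying community truly spans. When the sequencing reads are aligned
back to such a contig, the neighborhood of the junction looks wrong in
several correlated ways: aligned bases disagree with the contig past the
junction (SNV pileups), mates of pairs that straddle the junction either
fail to map (orphans) or map in implausible orientation or at implausible
distance (discordant pairs), alignment scores dip, and the proper-pair
insert-size statistics drift. None of these signals requires a reference
genome; they are all functions of the contig and its own reads. The package
turns them into per-position feature channels and trains a convolutional
classifier to map a contig's feature matrix to a probability of
misassembly.

## Per-position features and preprocessing

`compute_pileup()` produces 23 channels per contig position. Count channels
(`num_query_{A,C,G,T}`, `num_SNPs`, `num_proper`, `num_orphan`,
`num_proper_SNP`, `num_discordant`, `num_pairs`) count covering reads with
a property and are later divided by coverage, which both bounds them in
`[0, 1]` and removes the overall sequencing-depth scale. The remaining
channels are numeric (coverage; min/mean/stdev of mapping quality,
alignment score, and — over proper pairs only — insert size; local sequence
entropy and GC in a 50 bp window; an integer code of the contig base) and
are standardized to zero mean and unit variance using statistics fitted on
training data only (`fit_normalization()`). Uncovered positions have no
defined statistics; after preprocessing they are exactly zero — the
post-standardization mean — so they are maximally uninformative rather than
out-of-distribution. The standard deviation over a single covering read is
defined as 0, and a channel with zero variance in training stores `sd = 1`
so constants standardize to 0 instead of dividing by zero.

Fourteen of the 23 channels form the default model input: base
composition, SNV counts, pairing counts, the three alignment-score
statistics, mean mapping quality, coverage, and the minimum insert size —
at least one channel from each signal family. The catalog is configuration,
not code: `feature_catalog(selected = ...)` changes the input set, and the
model width follows it.

Mean coverage is capped at 20 by `subsample_to_coverage()` (whole pairs
dropped at random), which keeps high-depth datasets inside the regime the
model was trained on.

## The network

`model_config()` describes the architecture; `build_model()` realizes it.
The data path is: input batch normalization over the 14 channels → an
initial convolution (kernel 10, 16 filters, batch-normalized, ReLU) → four
residual groups of 2, 5, 5 and 2 blocks with 16, 32, 64 and 128 filters —
the first convolution of groups 2–4 has stride 2 and doubles the filters —
→ masked global average pooling → dense 128×50 (ReLU) → dense 50×1
(sigmoid). A residual block is two batch-normalized kernel-5 convolutions
with ReLU between, an element-wise skip addition and a final ReLU.
Convolutions are unpadded, so a stride-1 block's skip path crops the last
`2*(K-1) = 8` positions of the block input to match the body; a
downsampling block replaces the skip identity with a kernel-1, stride-2
convolution (with bias, not batch-normalized). All convolutions carry
biases; batch-normalization contributes a scale and shift (trainable) and
moving mean and variance (not trainable) per channel. Under the defaults
this comes to 562,573 parameters, 559,441 trainable; the difference —
3,132 — is exactly twice the 1,566 batch-normalized channels. The kernel
sizes (10 initial, 5 in blocks) are the unique small integers for which
this architecture family reproduces those totals, and the parameter count
is a pure function of the configuration (`count_parameters()`).

Variable-length input is handled by zero-padding every contig in a batch to
the longest one and propagating a validity mask through the same
length-arithmetic as the data: after every convolution, positions whose
receptive field would touch padding are marked invalid and zeroed, batch
statistics are computed over valid positions only, and the global average
pool divides by each contig's own valid length. A contig's score is
therefore invariant to the amount of batch padding to within floating-point
noise (tested at 1e-6). The shortest input the stack of unpadded
convolutions admits is 366 positions (`min_input_length()`); shorter
contigs are zero-padded up to it and the pad counts as input, exactly as a
short contig is padded to a fixed network length in practice.

Masked batch statistics are a deliberate choice: with padding included,
batch statistics would depend on the length composition of a batch. The
moving-average momentum is 0.9 rather than a slower default so that
inference statistics are usable after the short trainings this package
targets; both are configurable.

The forward and backward passes are written in R on top of BLAS
matrix-multiplication, with the convolution lowered to K shifted GEMMs over
the concatenated batch axis in a small C++ layer (`src/conv1d.cpp`) —
batches are `channels x (length * batch)` matrices, so one GEMM per kernel
tap covers the whole batch without an im2col copy. Gradients are verified
against central finite differences in the test suite.

## Training protocol

`train_model()` minimizes binary cross-entropy with Adam at an initial
learning rate of 1e-4, batch size 200, gradients clipped per tensor to norm
1 and element-wise to 0.5. Misassembled contigs are rare, so every epoch
keeps all positives and redraws a fresh 10% subsample of negatives without
replacement; the realized positive fraction is exactly
`P / (P + round(0.1 N))`. Contigs shorter than the 20,000 bp window are
used whole; longer positives contribute a window chosen uniformly among
those containing a uniformly chosen breakpoint (each junction of a
multi-junction contig is equally likely); longer negatives contribute a
uniform window. Validation contigs (10%, disjoint) get their windows once,
from a fixed seed, so the validation AUPRC is comparable across epochs; it
is computed every second epoch, the model is checkpointed whenever it
improves, and after two evaluations without improvement the learning rate
is multiplied by 0.8. The returned model is the checkpoint with the best
validation AUPRC, which the tests assert equals the running maximum of the
history.

## Inference, evaluation, and assembly QC

`predict_contigs()` scores contigs at most 20,000 bp long in one window and
splits longer ones into 20,000 bp chunks that advance by 19,500 bp — an
overlap of 500 bp so a junction at a chunk boundary is interior to the next
chunk — with the final chunk anchored at the contig end (it may overlap its
predecessor by more; full coverage is guaranteed). The contig score is the
maximum over chunks: a superset of windows can only raise it.

`auprc()` uses step-wise (average-precision) integration over distinct
score thresholds; its value under uninformative scores equals the positive
prevalence, which the suite checks at n = 100,000. `auroc()` is the
mid-rank Mann–Whitney statistic and is cross-checked against an independent
implementation. `filter_assembly()` drops contigs scoring strictly above
0.8 and reports contig counts, total bases, N50 (sort descending,
accumulate to half the total), mean and median lengths, and with truth
labels the misassembly rate and misassembled-bases fraction before and
after. `estimate_misassembly_rate()` is the fraction of contigs above the
threshold; ranking assemblies by it recovers the true quality ordering
(`rank_assemblies()` reports Pearson and Spearman correlations against
known rates). `insert_size_guard()` passes a dataset whose proper-pair
insert quantiles q05 and q95 lie inside the closed interval [117, 493] and
otherwise warns that predictions may be less accurate; boundary values
pass.

## The synthetic-data pipeline and what it does (not) emulate

`simulate_contig_dataset()` is the desk-scale stand-in for a
community-simulation, assembly, re-alignment and truth-labeling chain. It
generates random reference genomes (i.i.d. bases at a configurable GC),
draws a lognormal community profile (`sample_community()`; sigma controls
evenness, the location parameter is free because only relative abundances
survive normalization), and builds each contig either as a clean substring
of one genome or with an injected misassembly of one of the four classes,
recording every junction as a breakpoint ("bases before the junction", so a
5000+5000 chimera has breakpoint 5000). Reads are simulated from the
*source genome regions* of each contig — fragment starts uniform, fragment
lengths Normal(insert mean, sd) truncated at the read length, substitution
errors rising linearly across the read per a named profile, no indels — and
`truth_align()` places each mate on the contig through the source segment
with maximal overlap, full-length with an all-match CIGAR, deriving
mismatches by direct base comparison. Pairs are proper iff both mates map
in FR orientation with an observed insert within mean ± 3 sd; single
mapped mates are orphans; mapped non-proper pairs are discordant. The
mapping-quality surrogate is a constant 42 (1 for segments marked
repetitive) and the alignment-score surrogate is −6 per mismatch, monotone
in mismatch count like an end-to-end aligner's score. Coordinates are
1-based closed internally (the R idiom); SAM output is 1-based as required.

This construction reproduces the *signal structure* the classifier relies
on: SNV pileups past junctions, orphan/discordant enrichment around them
(and, realistically, at contig ends, where mates fall off the assembly),
coverage irregularities, and insert-size anomalies. It does not emulate
real assembler behavior (graph artifacts, collapsed repeats), empirical
error profiles with indels, mapping ambiguity between similar genomes, or
GC-dependent coverage bias. A model trained here demonstrates that the
architecture and pipeline learn these signals; it says nothing about
accuracy on real sequencing data, which requires the full-scale chain.

## Problem sizes used by the shipped experiments

The test-suite experiment uses 2,000 contigs of 400–700 bp (so most
contigs are a single window), 25% misassembled with equal probability over
the four classes, mean coverage 10 with a cap of 20, read length 100,
insert 270 ± 50, a flat 0.5% substitution rate, and 4 training epochs at
batch size 100 (half the protocol default, bounding the activation memory
of backpropagation) — three full pipeline replicates under different seeds, each
required to reach a validation AUPRC of at least twice the 0.25 prevalence
(they reach ≈0.95 or better). The assembler-ranking experiment scores six
independently simulated 250-contig assemblies with injected misassembly
fractions from 0.01 to 0.30 and checks that the estimated rates rank them
with positive Spearman correlation. Contig lengths are far below the real
median of assembled contigs; they were chosen so a full training run is a
matter of minutes on one CPU while every component — windowing, padding,
masking, chunking — still executes on its nontrivial path.

## Numerical choices and degenerate inputs

Batch-normalization uses variance epsilon 1e-3. Fragment-length sampling
resamples until the length is at least the read length (and at most the
source region), avoiding degenerate fragments when the insert mean is
close to the read length. Zero-coverage contigs produce all-zero feature
rows rather than errors; an all-zero window still scores (input batch
normalization recenters it). Ties in breakpoint choice and anchor segments
resolve uniformly and to the earlier segment respectively. All generators,
training loops and predictions are deterministic given their seeds;
per-stage seeds derive from a single run seed by hashing the stage name.

## Known limitations

The classifier shares the known failure modes of its design: inversions are
the hardest class (their junctions preserve pairing distance better),
short contigs carry little evidence, and the model is sensitive to
insert-size distributions outside its training range — hence the guard.
Training here is CPU-bound and desk-scale; the package deliberately does
not attempt distributed or GPU training, indel-aware simulation, breakpoint
localization, or per-class misassembly prediction.
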