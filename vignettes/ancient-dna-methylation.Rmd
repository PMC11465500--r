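---
title: "Simulating and quality-controlling direct methylation detection in ancient DNA"
author: "paleometh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quality-controlling direct methylation detection in ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleometh)
```

## The problem

DNA methylation in ancient bone can now be read *directly*, by converting
the extracted DNA with bisulfite or enzymatic methyl-seq (EM-seq) chemistry
and sequencing it, rather than inferred indirectly from the accumulation of
post-mortem damage. Direct conversion of degraded DNA raises questions that
do not exist for modern samples: conversion chemistry destroys part of an
already tiny endogenous fraction, it selects for longer fragments, enzymatic
conversion can fail to deaminate unmethylated cytosines (inflating apparent
non-CpG methylation), and — most insidiously — post-mortem deamination of
*methylated* cytosines produces genuine thymines that no uracil-excision
treatment can remove, deflating apparent methylation in exactly the regions
that are most methylated.

`paleometh` makes the entire measurement chain testable at desk scale. A
forward simulator produces ancient-DNA sequencing libraries whose every
molecule has a known methylation state and damage history; the analysis
half of the package (three-letter alignment, methylation calling, QC
metrics, segmentation and beta-track comparison) then re-measures those
libraries, so each analysis can be validated against the simulator's
ground truth — and the biases above can be exhibited and quantified on
demand.

## The forward model

A simulated library is built in stages, each mirroring one laboratory step.

**Toy genome and truth methylome.** A single random chromosome (default
100 kb) is CpG-depleted to the vertebrate-like background density of about
one CpG per 50 bp, with `cgi_count` planted CpG islands in which the CG
dinucleotide recurs every 6 bp (several-fold the background density). The
truth methylome assigns one beta value (percent methylation, 0–100,
strand-symmetric) to every CpG site. Real methylomes are regionally
organised, so betas are drawn *per block*: runs of consecutive background
CpGs (geometric length, mean 10 sites) share a single draw from a bimodal
mixture, and each CpG island is one hypomethylated block
(Beta(0.6, 15) · 100). The background mixture combines a hypomethylated
component Beta(0.8, 10) and a methylated component Beta(16, 4) (mean 80%),
and the mixture weight is solved in closed form so that the probability
mass below beta 20 plus the mass inside [71, 90] is exactly 0.80 — the
bimodal shape characteristic of an osteoblast methylome. With at least
10,000 background CpGs the realised fraction lands within a percentage
point or two of 80%.

**Fragments and overhangs.** Molecule lengths are lognormal
(`length_mean_log = log(65)`, `length_sd_log = 0.35`) truncated to
[20, 250] bp — the short-fragment regime of ancient DNA — and placed
uniformly. Each duplex carries two single-stranded 5' overhangs with
independent geometric lengths (`overhang_geom_p = 0.45`, mean ≈ 1.2 bp,
matching the 1–2 bp overhangs typical of ancient molecules): the left
overhang on the top strand, the right on the bottom strand.

**Deamination damage.** Each cytosine deaminates independently:
with probability `d_ss` (default 0.5) on single-stranded overhang
positions, and with probability `d_ds + (d_ss − d_ds)·exp(−d_decay·x)` at
double-stranded positions at distance `x` from the nearest strand end
(`d_ds = 0.02`, `d_decay = 0.3`/bp) — the canonical end-biased damage
profile. Chemistry is respected: an unmethylated C becomes uracil (read as
T after amplification), a methylated C loses its amine directly to
thymine. The `d_ss`/`d_ds` defaults are illustrative magnitudes, not
values fitted to any particular sample; what the analyses depend on is the
end bias and the mC→T asymmetry, not the absolute rates.

**Enzymatic pretreatments.** Exonuclease VII trims single-stranded
overhangs, but incompletely: an overhang of length L is reduced to
`min(L, r)` with `r` drawn uniformly from 3–5 bp, reproducing the observed
residual overhangs of treated control constructs. USER treatment cuts each
strand at every uracil and re-emits the pieces (< 20 bp dropped); in
`partial` mode a *terminal* uracil escapes excision with probability
`terminal_retain_prob` (default 0.5), since UDG acts poorly at strand ends
— partial-UDG libraries therefore keep a reduced, but not absent, damage
signal at the first and last base. Setting the probability to 1 gives
fully deterministic terminal retention.

**Conversion.** Each surviving strand is emitted independently.
Bisulfite: unmethylated C → T with probability `conv_eff` (0.99),
methylated C → T with probability `overconv` (0.01). EM-seq: methylated
C → T with probability `p_protect_fail` (0.01), unmethylated C *retained*
with probability `p_deam_fail` (0.05) — the deamination-failure mode that
inflates apparent non-CpG methylation downstream. Both conversions expose
strands to a harsh treatment, modelled as logistic length-dependent
survival `plogis((L − survival_L50)/survival_k)` (L50 = 50 bp, k = 15), so
converted libraries are biased toward longer fragments. The `none` model
only reads uracils as thymine, with no survival filter.

**Sequencing.** Reads are drawn *with replacement* from the pool of
converted strands (the source of PCR duplicates and the basis of the
complexity analysis), mixed with exogenous decoy reads (uniform random
sequence; default 40% endogenous) and spiked control oligos (default 2%),
and subjected to uniform per-base substitution error (`seq_error = 0.001`).
Everything is deterministic given the configuration seed.

**Spike-in controls.** The methylation controls are 60-bp duplexes with
exactly 15 cytosines per strand, one fully methylated and one fully
unmethylated. Published control designs fix the length and the 15-C
constraint but not the base sequence, so the shipped sequences are
synthetic stand-ins built from 4-bp units each holding one C and one G in
mixed CpG/non-CpG contexts; they are overridable. The exonuclease controls
hybridise a 60-bp strand to the reverse complement of its middle 40 bp,
leaving a 10-bp overhang at each end, with plain, uracil or methylated
overhang variants.

## What the simulator does not emulate

No PCR-cycle-explicit amplification (duplicates are an idealised uniform
resampling), no indels, no quality-score modelling, no capture-bait or
GC-amplification bias, no microbial genomes behind the decoy reads (they
are uniform random sequence, so they essentially never map), and no
5hmC/5mC distinction. Passing tests therefore demonstrate the *logic* of
the analyses — context classification, strand accounting, duplicate
handling, the direction and rough magnitude of each bias — not their
calibration on any real instrument's error profile.

## The analysis chain

**Three-letter alignment.** The reference is converted in silico into an
original-top view (C→T) and an original-bottom view (reverse complement,
then C→T); reads are collapsed the same way, so conversion state cannot
prevent mapping. Candidate positions come from a k-mer seed table and are
verified by full Hamming comparison; the best hit within `max_mismatch = 2`
maps the read, uniquely best → MAPQ 37, tied → MAPQ 0 (the pipeline's
MAPQ ≥ 30 filter then keeps exactly the unique alignments — a binary MAPQ
is all the downstream analyses use). The seed length default is `k = 10`
so that three disjoint seeds fit in the 30-bp minimum read: by pigeonhole,
any alignment with at most two mismatches retains one exact seed, which
makes the seeded search provably equivalent to an exhaustive scan — a
property the test suite checks against an independent `Biostrings`
brute-force oracle. There is no indel alignment: the simulator emits none.

**Duplicate removal** keys on (start, end, strand view); one record per
key survives, chosen as the lexicographically smallest read identifier so
the operation is deterministic and idempotent. **Percent endogenous** is
mapped MAPQ ≥ 30 reads over all raw reads, controls and decoys included.

**Methylation calling.** Each deduplicated MAPQ ≥ 30 read contributes one
call per covered reference cytosine on its strand of origin: read C →
methylated, read T → unmethylated, any other base (sequencing error) is
ignored rather than counted. Strand assignment comes from the alignment
view, never from base composition. Contexts are CpG/CHG/CHH (H ≠ G) on
the strand carrying the C; positions too close to the 3' genome end to
classify are CHH with a truncation flag. Context percentages pool both
strands. The beta value of a position is simply its percent of methylated
calls; the default `min_coverage` is 1, since segment-level averaging, not
per-position filtering, is the smoothing step of the workflow.

**QC metrics** reproduce the study's control analyses: CGI contrast
(methylation percentage inside vs outside island intervals), length
frequency distributions and their across-sample mean ± SD, the doubling
subsample ladder of unique reads (checked against the closed form
`M·(1−(1−1/M)^n)` for uniform amplification), positive-control scoring
(reads matched by wildcarding every template C to C/T with at most one
other mismatch — conversion state is unknown at match time and one
mismatch absorbs sequencing error), exoVII-control length distributions,
and the damage-by-methylation profile described below. The damage profile
refuses converted libraries outright, since conversion chemistry writes
C→T everywhere and would confound the damage signal.

**Segmentation and comparison.** The reference track is segmented by
recursive binary segmentation on the ordered betas; a split must reduce
the within-segment SSE by more than `penalty_lambda · log(n) · σ²`, where
σ² is the *noise* variance estimated robustly from the median absolute
successive difference. The penalty is deliberately scaled to noise rather
than to the track variance: methylomes are bimodal, so the track variance
is dominated by the block structure the segmentation is supposed to find,
and a variance-scaled threshold rejects genuine boundaries wholesale on
alternating hypo-/hyper-methylated stretches. Segment means are then
grouped by one-dimensional k-means (`n_groups = 4`, 20 seeded restarts,
groups relabelled by ascending centre for determinism) and adjacent
same-group segments are joined — the neighbour-joining convention of
methylation-profile segmentation. Sample tracks are averaged per segment
(unweighted over covered positions; uncovered segments are NA), binned
into ten right-closed decile bins ((0,10], …, (90,100], beta 0 into the
first bin — the bin convention is a choice, fixed here once), and
clustered by Euclidean distance over segments complete in every sample
with average linkage, samples pre-sorted by name so distance ties break
deterministically.

## The damage/methylation confound

The analysis most worth spelling out: in a *non-converted*, partial-UDG
library, the C→T rate at the 5'-most read positions rises with the
methylation level of the surrounding region. Three signal sources add up:
at original strand termini, deaminated methylated Cs read T and retained
terminal uracils read T; at the 5' ends created by USER cutting, only
mC-derived Ts remain (any deaminated unmethylated C there was itself the
cut site); and both the mC channels scale with beta while the uracil
channel shrinks with beta. With full terminal retention the two terminal
channels would cancel exactly and the position-1 rate would be flat in
beta; with partial retention (the default, and the behaviour of real
partial-UDG protocols, which show a *reduced* terminal signal) the rate
increases across beta bins — the confound that makes highly methylated
regions look less methylated after conversion, quantified here by binning
reads by the beta decile of the truth segment they overlap.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally and in BED output; printed
reports are 1-based where labelled. Geometric overhangs have support 0, 1,
2, …, so `overhang_geom_p = 1` means blunt ends. A fragment whose
overhangs consume it entirely keeps only its top strand. Empty inputs are
contract errors where silence would mislead (empty length sets, empty
rank-sum samples, constant x in the regression) and graceful where a valid
degenerate answer exists (zero fragments → empty library; a track shorter
than `min_size` → one segment; an all-duplicate library → a flat
complexity curve). `expected_unique` guards M ≥ 1; the histogram flags —
rather than invents — an empty input. Segmentation, k-means grouping and
the whole simulator consume seeds explicitly, so identical configurations
give byte-identical outputs.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to give each statistical
assertion real power while staying desk-scale: 50,000-fragment libraries
for the analytic conversion-error checks (Monte-Carlo standard errors of a
few hundredths of a percentage point), 1.5-Mb genomes (~30,000 background
CpGs) for the methylome calibration, 20 seeds of 15,000-fragment
partial-UDG libraries for the damage confound, 1,000 oracle-checked reads
against a 50-kb genome for the aligner, and 20 paired-seed replicates for
each direction-of-bias claim. These are the package's own choices of
simulation size.

## Known limitations

The aligner is Hamming-only and single-end; repetitive toy genomes can
produce MAPQ-0 reads but there is no rescue by paired ends or soft
clipping. Percent endogenous is pinned by the configured read mixture, so
conversion-induced loss of endogenous molecules shows up as reduced
library complexity (a smaller unique-molecule pool), not as a reduced
endogenous percentage across arms. The damage model uses a single elevated single-stranded rate
rather than a measured per-position profile. Conversion survival is the
same logistic for bisulfite and EM-seq unless configured otherwise.
Decile bins and the segmentation penalty are conventions — sensible, but
other conventions would shift segment boundaries and histogram masses
slightly. None of the defaults are fitted to a specific ancient sample;
they are magnitudes a practitioner would recognise, intended for testing
analysis logic, not for forecasting any particular excavation's yield.
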