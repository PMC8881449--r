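---
title: "equimeta: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{equimeta: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter, what the synthetic
data does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## What the pipeline estimates

Shotgun metagenomics of horse feces yields hundreds of millions of
150-bp read pairs per cohort. The pipeline turns those reads into four
kinds of quantity per sample: a species-level relative abundance vector,
a CAZy-family functional abundance vector, an antimicrobial-resistance
profile with a phenotype-by-genome interaction network, and the summary
statistics used to compare cohorts (alpha diversity, ordination,
rank-based tests, per-feature associations). At desk scale every stage
runs on synthetic communities whose truth is known exactly, which is how
the package tests itself.

## Read quality control

Five rules, applied trim-first: the maximal run of trailing bases below
Q20 is removed, capped at 29 bases (a read is never discarded by
trimming alone); the trimmed read is then discarded if it has two or
more ambiguous bases, thirty or more sub-Q20 bases, an adapter match, or
a host-genome alignment. Adapter and host discards co-remove the mate;
ambiguous/low-quality discards orphan the mate into a singleton stream
that is excluded from paired profiling — a conservative choice that
keeps the pairing contract simple.

The rules are listed without an order in the field's descriptions of
such filters; trimming first matches the intent of rescuing 3'-degraded
reads, and the ≥30-low-quality-bases test is evaluated *after* trimming
(both choices are configurable in `qc_params()`). Adapter detection is a
suffix/prefix overlap search (minimum overlap 8, ≤10% mismatches)
preceded by removal of the first six bases — the literal effect of a
Cutadapt `-u 6` pre-clip; whether the original tooling hard-clipped all
reads or candidates only is not knowable from the outside, so the clip
applies to the candidate test only. Host removal uses the pluggable
alignment contract below with a 50-bit score threshold; externally
computed SAM alignments can be substituted.

One corner case deserves a note: a read whose trailing low-quality run
exceeds the 29-base cap but whose residual low-quality count stays below
30 keeps a low-quality tail, and re-running QC would trim again. On
generator output this never happens (defects are planted away from the
3' end precisely so that labels predict decisions), and the idempotence
property is tested on that data.

## The desk-scale aligner

All stages consume one contract: "every qualified alignment above
thresholds". The internal implementation is exact k-mer seeding (k = 16
for DNA, 4 for protein) with ungapped extension along the seed diagonal
under +1/−2 match/mismatch scoring, keeping the best local segment per
read × target (Kadane's rule on the diagonal). Bit scores and E-values
use Karlin–Altschul statistics, `bit = (λS − ln K)/ln 2` and
`E = K·m·n·e^{−λS}`, with λ = 1.28 and K = 0.46 — the classic constants
for +1/−2 ungapped DNA scoring; protein mode reuses them, which makes
protein scores "bit-score-like" rather than BLOSUM-calibrated. This is a
deliberate desk-scale replacement for production aligners; equivalence
with bowtie2 or DIAMOND is not claimed, and their outputs (SAM, BLAST
m8) can be imported via `read_external_hits()`. Thresholds are strict
(`score > s`, `E < e`), matching the downstream merge rule, with
identity ≥ 0.9 as the stated default for genome-mode mapping. Tests pin
the aligner to a brute-force sliding-window oracle on small instances
and to a Monte-Carlo false-positive bound on random reads.

## Reference database curation

Within each species, complete and draft genomes are processed separately
and recombined. Genome length and GC content each pass through Tukey's
fences with coefficient 2 (keep v iff Q1 − 2·IQR ≤ v ≤ Q3 + 2·IQR);
failing either discards the genome. Quartiles use linear interpolation
between order statistics (the common type-7 rule) — the method is not
dictated by the procedure's description, so it is configurable. The
three longest survivors per completeness class are kept. Unnamed
"Genus sp." genomes are pooled per genus and clustered at distance 0.9;
the distance is 1 − Jaccard similarity of canonical k-mer sets (k = 12
for desk-scale genomes, configurable to 21), the linkage is complete
(the phrase "single complete clustering" reads most naturally as
complete linkage; single linkage is available), and the longest genome
per cluster represents it, ties broken lexicographically by accession.
Plasmid records never enter the filters; they follow their parent
replicon's fate, since length/GC outlier logic is meaningless for a
5-kb plasmid sitting in a chromosome distribution. Determinism is a
contract: inputs are sorted by accession before processing.

## Taxonomic profiling

The estimator is subsample-and-average: draw N pairs without
replacement, align in all-hits mode, build a profile, repeat R times,
average. Field-scale values are N = 15 million (4.5 Gb of sequence at
2 × 150 bp) and R = 100; the desk defaults are N = 50,000 and R = 10 so
the full recovery experiment runs in seconds to minutes.

The per-subsample profile uses two-pass fractional assignment. Pass 1
counts pairs whose hit set is a single species. Pass 2 gives each
multi-species pair unit weight split across its hit species
proportionally to the pass-1 counts, uniformly if all are zero. The
published description of the original profile construction is a citation
without formulas, so this unique-then-proportional scheme is a
documented stand-in; `redistribute_iters` = 1 reproduces a single
reassignment pass, larger values iterate it EM-style. A pair counts as
one unit and its hit set is the union over both mates.

Species weights are divided by the mean representative genome span
(chromosome plus attached plasmids) before relative scaling — read
sampling is length-weighted, so length normalization is required for
unbiasedness; it can be toggled off. The `unassigned` fraction (pairs
with no hits) is an explicit column, so per-read weight is conserved:
assigned weight plus unassigned equals the pair count. After averaging,
species detected in at most `rare_sample_threshold = 2` samples across
the run are removed and rows renormalized; the filter is applied after
averaging and across the full sample set, which makes it
order-independent.

## CAZy and resistome profiling

Mates are aligned separately against the gene catalog and merged per
pair with score > 60 and E-value < 1e-5 (strict inequalities). A pair
hitting g genes contributes 1/g to each; per-gene weights are divided by
gene length in kilo-amino-acids. The direction of the length adjustment
("adjusted by related gene length") is ambiguous in prose; division —
the standard RPK-style correction for long genes accruing more reads —
is implemented. Weights split across two genes of one family re-sum
within the family; there is no family-level deduplication, consistent
with the per-gene wording. Family counts are distinct families with
positive abundance; pathway groups (starch/glycogen vs cellulose) are
sums over a user-supplied family map, with unmapped families logged and
counted as other.

ARG profiling reuses the same fractional machinery with phenotype-level
aggregation. The co-assignment network counts, per sample, read pairs
assigned to both a resistance phenotype and a reference genome; the
frequency denominator is the sample's subsampled pair count (the
original's "mean frequency" names no denominator; raw counts are a
configuration switch). A pair co-assigned to several genomes splits its
weight equally, mirroring the fractional convention elsewhere. Pairs are
the co-assignment unit (single-read counting would double-count
fragments). Cohort edge weight is the arithmetic mean over all cohort
samples, zeros included — so an interaction seen in one of two samples
at frequency 0.01 weighs 0.005. Genome nodes carry replicon labels, and
the network exports to TSV and GraphML with styling carried as
attributes.

## Statistics layer

Diversity: observed species; Shannon −Σp ln p and Simpson 1 − Σp² (via
vegan); Chao1 = S + f1²/(2 f2), with the f1(f1−1)/2 correction when
doubletons are absent — the classic formula is implemented directly
because the commonly packaged variant is the bias-corrected one, which
gives different values; an abundance-based coverage estimator in the
Chao & Lee form with rare cutoff 10 (listed as ICE in the report); the
Gini *inequality* coefficient of the nonzero abundances, a deliberately
distinct column from Simpson — "Gini diversity index" is ambiguous, and
since Simpson is reported separately the inequality reading is
implemented, with Gini–Simpson available as `gini_simpson()`; Faith's PD
as the total branch length spanning observed tips and the root (via
picante), erroring with the offending names when features are missing
from the tree.

Ordination: d(i, j) = 1 − Spearman correlation of the two samples'
feature vectors (ties mid-ranked; a constant vector has no rank
correlation and raises an error naming the sample), classical PCoA by
double-centering −D²/2 and eigendecomposition, coordinates scaled by
√eigenvalue. Spearman distances are generally non-Euclidean, so negative
eigenvalues occur; they are dropped with a warning and explained
variance is reported over the positive spectrum.

The one-sided Wilcoxon rank-sum test enumerates all C(n+m, n) group
assignments when n + m ≤ 12 — valid under ties and exact by
construction — and otherwise uses the normal approximation with tie and
continuity corrections. The association layer replaces an external
multivariate-association tool with an in-package equivalent: per
feature, OLS of log(abundance + pc) on the target variable plus
adjustment covariates, where pc is half the smallest nonzero value of
the matrix; t-test p-values for two-level targets, joint F-tests
otherwise; Benjamini–Hochberg q-values across features. TransCo is
|coefficient| × (±1 by sign) — numerically the coefficient itself; the
printed formula is applied as stated and the identity is asserted in
tests. Collinear target/adjustment designs are rejected up front.

## The synthetic community generator

The generator defines the conditions every test runs under. Species
abundances are log-normal: species-level log-means N(0, σ = 1), sample
level noise N(0, σ = 0.5) on top, renormalized per sample — no
distribution is prescribed anywhere for such communities, and log-normal
is the field's default assumption. Signal species receive a
multiplicative fold change in a designated habitat or site; an optional
`baseline_share` pins a signal species' expected share, which keeps the
compositional shift on null species negligible — without it, a 4-fold
effect on a randomly large species visibly breaks the null features'
p-value validity (renormalization moves every other species), which is a
property of compositional data, not of the test.

Each species has a primary chromosome (20–60 kb by default — toy scale,
about two orders of magnitude below real bacterial genomes), an optional 5–15 kb plasmid,
and up to three variant records: mutated copies (3% substitutions,
97–100% length) that are mostly drafts, plus diverged plasmid copies
when the species carries one, so that every strain record represents a
whole genome. That last point matters: length normalization divides by
the mean representative genome span, and if variant strains lacked the
plasmid the estimator would inherit a systematic bias for
plasmid-bearing species. Unnamed species ("Genus sp.") exercise the
clustering path. Spiked ARG/CAZy genes are stop-free ORF-like sequences
written into non-overlapping genome positions, so each catalog entry is
a verbatim substring of its host replicon and CAZy proteins translate
cleanly.

Reads are 2 × 150 bp pairs drawn from source strains with weight
abundance × replicon length, fragment lengths 250–450 bp, uniform
substitution errors (0.2% default), and per-read quality strings drawn
from a pre-generated pool of high-quality (≥ Q26) patterns. Defective
reads violate exactly one QC rule: 2–4 planted Ns; ≥ 32 sub-Q20 bases
scattered over the read interior with the 3' end left intact (tail-
concentrated low quality would be rescued by trimming and the label
would stop predicting the decision); an exact adapter prefix of ≥ 12 bp
replacing the 3' tail; or both mates drawn from a designated host
genome. Clean reads are rejection-sampled against the adapter rule so a
chance suffix match cannot mislabel them — the generator's contract is
that labels are an exact QC oracle.

What the generator does *not* emulate: indel errors, quality-by-cycle
decay, GC-coverage bias, strain mixtures within a species, real CAZy/ARG
sequence families (genes are random ORFs, so cross-gene homology is
absent), and realistic genome sizes. Passing tests therefore demonstrate
the correctness of the computational chain under its stated model, not
robustness to every artifact of real sequencing data.

## Numerical and engineering choices

Alignment and QC hot loops are in C++ (Rcpp); everything else is base R
over Biostrings/ape/picante/vegan/igraph. Seeds: every stochastic
function takes an explicit seed, child streams are derived
deterministically and kept below 2³¹, and the caller's RNG state is
never disturbed. Tie-breaks are lexicographic by accession throughout.
The pipeline orchestrator hashes each stage's parameters and records
output checksums in a JSON manifest; a rerun skips stages whose hash and
outputs are intact. The resume logic tracks parameters, not data
lineage — editing an upstream stage's *outputs* by hand re-triggers that
stage (checksums), but a stage whose inputs changed while its own
parameters did not is not re-run; deleting downstream directories is the
supported way to force recomputation.

Problem sizes in the shipped tests and acceptance script were chosen so
the full suite completes in a few minutes on a single core: QC oracle at
10,000 pairs, taxonomic recovery at 50,000-pair subsamples × 10 repeats
from a 62,500-pair pool (L1 error vs truth ≈ 0.01, bound 0.05),
dispersion scaling at 1,500-pair subsamples with 48 independent runs per
R ∈ {1, 4, 16} (successive SD ratios expected 2, accepted in
[1.3, 3.1]), association power/FDR at 20 + 20 samples × 60 species × 50
replicates (power ≥ 0.9, FDR ≤ 0.10 against the nominal 0.05).

## Known limitations

The aligner is ungapped and single-threaded; indel-containing reads
align as split segments and may fall below thresholds. The ICE
implementation is the abundance-based coverage form; incidence-based
variants across sample groups are not provided. The association model is
fixed-effects OLS on log abundances — no zero-inflation, no random
effects, no compositional transforms beyond the log. Field-scale inputs
(15 million pairs × 100 repeats) are supported by the same code paths
but are not desk-scale; the subsample-once-align-once optimization in
`profile_sample()` keeps repeats cheap, but alignment of the full pool
is still the dominant cost.
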