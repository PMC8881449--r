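# equimeta

Desk-scale, fully testable shotgun-metagenomics profiling for horse gut
microbiome studies — and for anyone who wants the statistical machinery of
such a pipeline reproducible on a laptop. The package implements the
complete computational chain used to compare domestic and feral horse
fecal microbiomes: paired-end read quality control, reference genome
database curation, subsample-and-average taxonomic profiling,
carbohydrate-active enzyme (CAZy) family profiling, antimicrobial
resistance gene (ARG) co-assignment networks, and the downstream
statistics (alpha diversity, Spearman-distance PCoA, one-sided Wilcoxon
comparisons, covariate-adjusted per-feature association). A synthetic
community generator with complete ground truth makes every stage
verifiable end to end.

## The methods in brief

**Read QC.** A read is trimmed of at most 29 trailing bases below Q20,
then discarded if it (1) contains ≥ 2 ambiguous bases, (2) contains ≥ 30
bases below Q20, (3) matches the adapter (suffix/prefix overlap search
after a 6-base 5' clip), or (4) aligns to the host genome. Adapter and
host discards remove the mate as well; other discards orphan the mate
into a singleton stream.

**Reference curation.** Within each species (complete and draft genomes
handled separately, then combined), genomes with abnormal length or GC
content are discarded by Tukey's fences with coefficient k = 2, i.e. a
genome is kept iff its value lies in [Q1 − 2·IQR, Q3 + 2·IQR]; the three
longest survivors are retained. Genomes without a binomial species name
("Genus sp.") are pooled per genus, clustered by complete linkage on
1 − k-mer-Jaccard distance with a 0.9 cut, and the longest genome per
cluster becomes its representative.

**Taxonomic profiling.** From each sample, N read pairs are drawn without
replacement (field scale: 15 million pairs = 4.5 Gb; desk default:
50,000) and aligned in all-hits mode. Read pairs hitting exactly one
species are counted first; each multi-species pair's unit weight is then
split across its hit species proportionally to those unique counts
(uniformly when no unique evidence exists). Species weights are divided
by mean representative genome length, scaled to relative abundance with
an explicit `unassigned` fraction, the subsample repeated R times (field
scale 100, desk 10) and the profiles averaged. Species detected in ≤ 2
samples are removed and rows renormalized.

**CAZy profiling.** Mates are aligned separately against the protein
catalog (six-frame translation at desk scale; DIAMOND m8 accepted as a
drop-in); alignments are merged per pair with score > 60 and
E-value < 1e-5. Each pair's unit weight is split equally over its mapped
genes, divided by gene length (kilo-amino-acids, RPK-style) and summed
per family; starch/glycogen vs cellulose pathway groups are sums of
member families.

**Resistome network.** A read pair assigned to both an ARG phenotype and
a reference genome lets that genome contribute to the phenotype. Per
sample, frequency(phenotype, genome) = co-assigned pairs / subsampled
pairs (multi-genome pairs split equally); the cohort edge weight is the
arithmetic mean of this frequency over all samples of the cohort. Nodes
carry replicon labels (chromosome / plasmid / contig), and the network
exports as edge/node TSV and GraphML.

**Statistics.** Observed species, Shannon, Simpson, Chao1
(S + f1²/2f2), an ICE-style coverage estimator (rare cutoff 10), the
Gini inequality coefficient, and Faith's phylogenetic diversity; PCoA on
d = 1 − Spearman's rho with classical double-centering; one-sided
Wilcoxon rank-sum tests (exact by enumeration for n + m ≤ 12); and
per-feature OLS association of log abundances on habitat/site with
Benjamini–Hochberg q-values and the signed-coefficient transform
TransCo = |coef| × sign(coef).

## Worked example

```r
library(equimeta)

genomes <- generate_genomes(n_species = 5, length_range = c(20000, 40000),
                            plasmid_prob = 0.3, seed = 7)
spiked  <- spike_genes(genomes, arg_catalog_size = 4,
                       cazy_catalog_size = 8, seed = 7)
truth   <- c(0.35, 0.25, 0.18, 0.14, 0.08)
names(truth) <- unique(genomes$metadata$species[genomes$metadata$source])

reads <- simulate_reads(spiked$genomes, truth, n_pairs = 20000, seed = 7)
db    <- curate_genomes(spiked$genomes)
prof  <- profile_sample(reads$pairs, db$kept,
                        profiler_config(n_pairs_per_subsample = 15000,
                                        n_repeats = 10), seed = 7)
round(prof$profile, 4)
#>   Equigenus02 species01   Equigenus02 species02 Equigenus03 sp. SYN0007
#>                  0.3480                  0.2497                  0.1772
#> Equigenus03 sp. SYN0023   Equigenus03 species04              unassigned
#>                  0.0815                  0.1437                  0.0000
```

The estimated relative abundances sit within an L1 distance of 0.0103 of
the planted truth (`sum(abs(est - truth))` after dropping `unassigned`),
with a mapped-read ratio of 1.00 — every subsampled pair found its source
genome. The same reads profiled against the spiked CAZy catalog recover
all 8 spiked families:

```r
caz <- cazy_profile_sample(reads$pairs, spiked$cazy_catalog)
round(caz$family_abundance, 3)
#>   GH2  GH29   GH3  GH31   GT2  GT35   GT4  GT78
#> 0.090 0.079 0.203 0.054 0.046 0.186 0.112 0.229
caz$n_families
#> [1] 8
```

The whole chain (simulate → qc → build-db → profile → cazy → resistome →
diversity → associate) runs from one configuration:

```r
cfg <- default_run_config(out_dir = "equimeta_run", seed = 1)
run_pipeline(cfg)   # resumable; writes a manifest with stage checksums
```

or from a shell via the wrapper script and a YAML config
(`inst/scripts/equimeta.R`, `inst/extdata/example-config.yaml`).

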