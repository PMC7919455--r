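---
title: "Measuring evolutionary pressure on protein-coding genes with omegaGC"
author: "omegaGC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring evolutionary pressure on protein-coding genes with omegaGC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegaGC)
```

# The problem

The ratio of nonsynonymous to synonymous substitution rates, dN/dS (omega),
is the workhorse measurement of selective pressure on protein-coding
sequences: values below 1 indicate purifying selection, values above 1 an
excess of amino-acid change suggestive of positive selection.  Estimated
genome-wide from pairwise alignments of modern human, archaic hominin and
chimpanzee coding sequences against a reconstructed ancestral primate
genome, per-gene omega supports two derived analyses:

* a genome partition into selectively constrained genes (SCGs) and more
  divergent, putatively positively selected genes (PSGs), and
* gene-set screens asking whether genes expressed in a tissue, belonging to
  a pathway, or implicated in a disease are under unusual pressure.

Raw omega is confounded by base composition: mutation rates in primates vary
with local GC content, and amino-acid-changing positions are concentrated at
codon positions 1-2.  omegaGC therefore works on **omega_GC12**: raw dN/dS
regressed on the gene's GC fraction at codon positions 1 and 2 (GC12), the
residuals Z-standardized per taxon across the analyzed gene universe.  A
score of +2 means "two genome-wide standard deviations more divergent than
expected for a gene of this GC12 content".

Because the real inputs (genome-scale ancestral alignments, population VCFs,
expression atlases) are external resources, the package ships a full
synthetic-data generator with known ground truth; every stage of the
pipeline is validated against that ground truth rather than against any
external dataset.

# Divergence estimation

`estimatePair()` implements counting estimation in the Nei-Gojobori family:

* **Sites.** Each sense codon contributes 3 sites, split fractionally into
  synonymous and nonsynonymous parts by classifying its nine
  single-nucleotide neighbours under the standard genetic code.  Neighbours
  that are stop codons are excluded and the affected position rescaled over
  its remaining neighbours.  Site counts are averaged between the two
  aligned sequences.  With `kappa != 1` neighbours are weighted by the
  transition/transversion ratio; the default `kappa = 1` is the classic
  equal-weight scheme.
* **Differences.** Codon pairs differing at 2 or 3 positions are scored by
  averaging synonymous/nonsynonymous step counts over all mutational
  pathways that avoid stop-codon intermediates, with equal pathway weights.
  If every pathway passes through a stop (possible only at 3 differences),
  all pathways are used and the codon flagged.
* **Multiple hits.** Jukes-Cantor correction, d = -3/4 log(1 - 4p/3),
  applied to the per-site proportions of both classes.  p >= 3/4 is outside
  the domain and fails with a diagnostic naming the gene.
* **The zero rule.** A gene with zero synonymous differences would have an
  infinite ratio; following the screen's protection rule, Sd = 0 is replaced
  by 1 (recorded in `SdCorrected`) before computing dS, so omega is always
  finite.  Identical sequences thus give omega = 0, not 0/0.
* Codons containing gaps, ambiguous bases, or stops in either sequence are
  skipped whole and reported.

The reference estimator for this analysis family is PAML's yn00.  This
package deliberately reimplements the counting estimator in a fully
specified, oracle-testable form: the 61x61 pathway table is checked
exhaustively against independent enumeration in the test suite, and
correctness at pipeline level is established by parameter recovery on
simulations rather than by bit-matching external software.  Scale
differences between counting variants are absorbed by the per-taxon
Z-standardization downstream.

# GC12 correction and standardization

"Correcting with a generalized linear model" is implemented as its simplest
member: a Gaussian identity-link fit (ordinary least squares) of raw omega
on a single linear GC12 term, per taxon.  Residuals are standardized to mean
0, SD 1 over the genes entering the fit (the analyzed universe, i.e. after
any ortholog filtering, which is an input assumption here).  Coefficients
are retained in `correctionFits()` for audit.  No log-transform is applied
to raw omega, and no higher-order GC terms are fitted; both would change the
score's meaning and neither is needed to remove the linear confound the
generator (and, mechanistically, GC-biased mutation) produces.  OLS
residuals are exactly orthogonal to the regressor, so the post-correction
|cor(omega_GC12, GC12)| is zero up to floating point by construction; the
scientifically substantive check, done by simulation, is that a strong
pre-correction correlation does not leak into downstream classification.

GC12 itself is computed on the ancestral CDS (one value per gene, shared
across taxa); N bases are excluded from numerator and denominator.

# Fixation statistics

Polymorphism enters as a pre-annotated table of segregating sites (gene,
consequence class, minor allele frequency); variant calling and annotation
are out of scope.  `countPolymorphism()` applies strict MAF cutoffs (all
SNPs, < 1%, < 5% being the conventional screens).  Then, per gene:

* **Neutrality index** NI = (Pn/Ps) / (Dn/Ds), computed on raw counts (site
  normalizations cancel within a gene).  Zero-valued Ps, Dn or Ds are
  replaced by 1 — mirroring the divergence zero rule — so NI is finite;
  Pn = 0 gives NI = 0; all four counts zero is undefined (NA).  NI < 1
  marks divergence fixed in the modern population.
* **Direction of Selection** DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps), exact, with no
  zero replacement because its denominators are sums; a zero denominator
  yields NA.  On strictly positive counts, NI < 1 and DoS > 0 are
  mathematically equivalent, which the suite verifies exhaustively on the
  1..20 count grid.

# Expression specificity

Expression matrices are log-transformed as log(1+x) (base e; downstream
Z-scores are invariant to the base, and the pseudo-count handles zeros) and
standardized per gene across tissues.  Genes with zero cross-tissue variance
get Z = 0 everywhere — neutral rather than dropped, so the gene universe is
stable.  The dual axis (Z across genes within a tissue, an expression-level
score) is available via `axis = "genes"` but unused downstream.  Tissue gene
sets are genes with specificity Z > 2 in that tissue.  The tau index,
tau = sum(1 - x_i/x_max) / (T-1), is computed on the untransformed profile
and reported alongside.  A per-tissue batch effect shifts that tissue's
Z-scores uniformly; this is documented, not corrected.

# Gene-set statistics

Each gene set's omega_GC12 values are tested against 0 (the genome mean
after standardization) with the one-sample Wilcoxon signed-rank test: zeros
dropped, ties mid-ranked, exact p for n <= 25 without ties, normal
approximation with continuity and tie correction otherwise.  The effect
size is the matched-pairs rank-biserial correlation
rc = (sum r+ - sum r-) / (sum r+ + sum r-), the difference between the
proportions of signed-rank mass above and below zero; rc < 0 means the set
is more constrained than the genome.

Because gene sets are biased in GC content and coding length, empirical
p-values come from a covariate-matched bootstrap: `nDraws` random sets of
the same size are drawn from the universe, stratified on a joint quantile
grid of (GC12, log CDS length) so that each draw reproduces the observed
set's covariate distribution.  With observed statistic m (the set's rc by
default; the mean score optionally) and draw values B_i,

p = 2 min( (1 + #{B_i >= m}) / (N+1), (1 + #{B_i <= m}) / (N+1) ),

capped at 1 (the two-tailed formula can reach 2 when the observed value
sits at the centre of the draw distribution).  The smallest attainable p is
2/(N+1).  Strata containing set members but too few universe candidates
borrow from the nearest grid bin, with a warning.

Two deliberate parameter choices:

* **Grid resolution: 10 x 10 deciles** (configurable).  A coarser 5 x 5
  grid leaves residual within-bin confounding when a set concentrates in a
  covariate tail — e.g. a set drawn from the top GC12 decile sits in the
  upper half of the top quintile bin, and its matched draws are still
  systematically GC-poorer, inflating rejection above nominal.  Decile bins
  make tail-decile sets exactly matchable while leaving ~20 genes per
  stratum even at a 2000-gene universe.  The test suite demonstrates both
  halves: matched resampling stays calibrated on GC-biased null sets where
  naive resampling rejects almost always.
* **Bonferroni families**: one family per screen (one call to
  `enrichGeneSets()`), matching the per-dataset corrections of this kind of
  analysis.

Set-vs-set association (e.g. extreme genes vs brain-related annotation) uses
Fisher's exact test on the 2x2 membership table over the analyzed universe,
reporting the sample odds ratio, the exact conditional odds ratio, and a
95% CI from the log-OR normal approximation with Haldane 0.5 correction
when a cell is empty.

# Classification

`clusterGenes()` performs agglomerative hierarchical clustering (Euclidean
distance, Ward linkage) on the gene x taxon omega_GC12 matrix.  The number
of clusters is chosen by majority vote of three internal indices — mean
silhouette width, Calinski-Harabasz, Davies-Bouldin — over k = 2..6, ties
going to the smaller k.  This is a deliberately reduced version of the
"vote of 30 indices" approach (NbClust-style): the decision logic is the
same and the index list pluggable, without the dependency surface.  When
even the winning partition has mean silhouette below 0.25 the tool warns
that the data do not support a strong partition (a single Gaussian blob
produces exactly this).

`extremeGenes()` extracts the tails of the omega_GC12 distribution on the
human taxon at the 2 SD threshold (the score is already standardized, so
">2 SD" is simply score > 2): PSGs are upper-tail genes additionally
required to have NI < 1 (divergence fixed in the modern population); SCGs
are the lower tail, with no fixation filter — constraint needs no fixation
evidence.  Upper-tail genes lacking an NI are excluded from the PSG list
and reported.  The default NI uses all SNPs; the MAF cutoff is
configurable.  `partitionBrainRelated()` then counts each list's overlap
with annotation sets (tissue-specific, synaptic, disease; categories may
overlap) and tests enrichment against the annotation union by Fisher's
exact test.

# The synthetic world

`simulationConfig()` fixes the ground-truth world; the defaults are chosen
once, as a realistic deep-primate-ancestor regime, and the test suite runs
against them:

* **Star phylogeny.**  Four taxa (hs, neanderthal, denisovan, chimp)
  diverge independently from one ancestor.  The analysis is strictly
  pairwise ancestor-vs-taxon, so shared internal branches would only
  correlate the taxa without changing any per-taxon property under test.
* **Gene lengths 100-600 codons**, uniform; CDS have an ATG initiator, no
  internal or terminal stop.
* **GC12 targets uniform on 0.3-0.7**, the bulk of the human coding range;
  placement of G/C at positions 1-2 hits the rounded target exactly.
* **branchSubsPerCodon = 0.35** substitution proposals per codon per
  branch, about 0.1 expected synonymous substitutions per synonymous site —
  the divergence depth of a comparison against a deep primate ancestor.
  This depth also keeps the per-gene ratio-estimator bias (of order
  1/E[Sd], from the reciprocal of a noisy synonymous count) at the
  few-percent level for 300-codon genes.
* **True omega mixture**: 65% of genes at 0.2, 25% at 0.5, 8% at 1.0, 2% at
  2.5 — a purifying-dominated genome with a small adaptively evolving tail
  (genome-wide mean ~0.35).
* **kappa = 1.** The equal-weight NG86-family estimator assumes no
  transition/transversion bias; the generator's default matches that
  assumption so recovery tests measure implementation correctness, not
  model mismatch.  Both the generator and the estimator expose `kappa` for
  exploring biased-mutation worlds (with kappa > 1 and the equal-weight
  estimator, omega is underestimated — the classic NG86 behaviour).
* **gcBiasSlope = 2**: the realized omega of a gene is distorted
  multiplicatively by 1 + slope*(GC12 - 0.5), i.e. +/-40% across the GC12
  range, emulating how GC-linked mutational and repair biases contaminate
  the measured ratio.  A pure rate multiplier would scale dN and dS equally
  and leave the ratio clean, which is precisely not what genome data show;
  the distortion is therefore placed on the ratio itself, which is the
  signal the GC12 regression is designed to remove.  The effect is centred
  (mean 1 over the GC12 range), so cohort means remain unbiased.
* **Substitution process.**  Proposals are Poisson with rate
  branchSubsPerCodon x codons x max(1, omega_eff); each picks a uniform
  site and a kappa-weighted alternative base among those not creating a
  stop codon (stop-creating changes are rejected and redrawn at the same
  site, the same convention as the estimator's stop-rescaled sites).
  Synonymous changes are accepted with probability min(1, 1/omega_eff),
  nonsynonymous with min(1, omega_eff).  For omega <= 1 this is the plain
  "accept synonymous always, nonsynonymous with probability omega" rule;
  for omega > 1 the rate scaling keeps the synonymous rate constant across
  genes — selection on the protein should not suppress dS — and the
  realized nonsynonymous/synonymous rate ratio equals omega_eff exactly for
  all omega >= 0.  Every accepted change is logged with position and class,
  so the simulator's own record can be recounted independently.
* **Polymorphism**: per-gene synonymous segregating sites are Poisson with
  mean 0.03 per synonymous site (a 1000-Genomes-like density); the
  nonsynonymous/synonymous count ratio and frequency spectrum follow the
  gene's selection regime — purifying genes carry reduced, rare-shifted
  nonsynonymous variation (neutral folded spectrum damped by
  exp(-MAF/0.005)), positively selected genes carry neutral-like
  polymorphism, because their signature is an excess of fixed differences,
  not of segregating ones.  That is what drives NI below 1 for true PSGs.
  MAF values live on a 1/5000 grid (5000 chromosomes).
* **Expression**: log-normal baseline (per-gene level sd 1, per-tissue
  noise sd 0.5 on the log scale) over 16 tissues; 10% of genes are spiked
  32-fold in exactly one tissue.  A 32-fold spike sits ~3.3 SD above the
  gene's own profile, comfortably above the Z > 2 calling threshold.

**What the generator does not emulate** — and hence what a green test does
not establish: alignment and orthology error, ancestral-state
misreconstruction, indels, recombination and linked selection, demography
(the frequency spectra are stylized), codon-usage bias, lineage-specific
rates on a real tree, and sequencing coverage.  Recovery results certify
the implementation against its own stated model, not the biology of any
particular dataset.

# Numerical conventions

* Determinism: every generator is a pure function of (config, seed);
  `simulateDataset()` and `runPipeline()` re-seed from their config, and
  repeated runs are byte-identical.
* Jukes-Cantor is undefined at p >= 3/4; the estimator fails loudly rather
  than clamping.
* Wilcoxon zeros are dropped, ties mid-ranked; rank-biserial uses the same
  ranks as the test.
* The empirical bootstrap p is capped at 1 and bounded below by 2/(N+1).
* Cluster labels for k = 2 are "SCG-like"/"PSG-like", ordered by the mean
  human-taxon score; other k get ordered neutral labels.
* All tables are TSV (tab, '.' decimal, header, UTF-8); gene sets are GMT;
  alignments are FASTA with `<gene>|<taxon>` record ids and one
  `ancestor` record per gene.

# Limitations

The counting estimator is a pairwise method: it is not suited to resolving
differences between very closely related taxa (archaic hominins vs modern
humans) gene by gene — at those distances most genes have a handful of
substitutions and the per-gene scores are noise-dominated; the genome-wide
and set-level statistics are the intended use.  The GC correction is linear
and per-taxon; residual nonlinear composition effects would require a
richer model.  The NI zero-replacement rule, like all such conventions,
biases per-gene NI for genes with very few counts; it is used only as a
binary fixation filter (NI < 1) here.
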