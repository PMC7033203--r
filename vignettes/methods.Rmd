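---
title: "Methods: candidate funnels, correlation networks and WGT dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate funnels, correlation networks and WGT dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models and procedures the package
implements, the parameters that matter and why their defaults were chosen,
what the synthetic-data generator does and does not emulate, and the
numerical conventions adopted where the underlying screening practice
leaves a choice open.

## The screening problem

Triptolide-type diterpenoids are made by cytochrome P450s (CYPs) that are
unknown a priori and numerous: a plant genome carries hundreds of CYPs.
The screen couples three independent lines of evidence:

1. **metabolite response** — LC-MS features in the diterpenoid mass range
   whose intensities respond to methyl-jasmonate (MeJA) elicitation of
   suspension cells;
2. **co-expression** — CYPs whose expression tracks those features across
   the elicitation time course and a tissue panel, and resembles the
   profiles of known upstream pathway genes (the diterpene synthases used
   as baits);
3. **lineage specificity** — CYP subfamilies restricted to the focal
   species, as the metabolite itself is.

Each line is a filter with explicit thresholds; the funnel composes them
in a fixed order and records survivors per stage, so a result is always
an auditable list of (rule, set) pairs rather than a single opaque score.

## Peak filtering

A feature table (m/z, retention time, fragment count, per-sample
intensities) passes three filters:

* **Mass window**, default 295–400 Da, both bounds inclusive. The bounds
  are conventionally quoted without stating open/closed; inclusive ends
  are this package's documented convention, tested at the boundary.
* **Responsiveness**: one-way ANOVA across sample groups on
  `log2(x + 1)` intensities, with a raw-scale max-fold
  (max group mean / min group mean, pseudocount 1). A peak is retained
  when `p < 0.01` **and** max-fold `> 2`. The practice this reproduces
  describes the ANOVA as identifying metabolites that did *not* change;
  since the downstream correlation analysis needs the changing peaks, the
  default retains responders, and `keep = "unresponsive"` selects the
  complement for readers who prefer the literal reading. The grouping
  factor is configurable; the default groups time-course samples by
  condition x time.
* **Fragments**: features with `fragment_count == 0` are removed —
  fragmentless features cannot be structurally followed up.

Zero within-group variance is mapped to `p = 0` when group means differ
and `p = 1` when they do not, so degenerate rows behave like their
limits. The filters commute as set operations; the funnel order is fixed
only so that stage counts are comparable across runs.

## Expression processing

RPKM is the standard `1e9 * count / (length_bp * library_size)`. The
expression floor "well-expressed" is RPKM > 1 in at least one sample.

Differential expression is a two-sided **pooled-variance Student's t**
per gene per time point on `log2(x + 1)` values — pooled rather than
Welch because that is the test named by the screening practice this
package reproduces. Fold change is the ratio of arithmetic means on the
raw scale with pseudocount 1. Significance requires `p < alpha`
(default 0.05) **and** `max(fold, 1/fold) >= 2`; a gene is "DE" when
significant at any of the configured elicitation windows (default 4, 12,
24, 48, 72 h — the early-to-mid response, excluding time 0 and the late
points where induction saturates). No multiple-testing correction is
applied, matching the raw-threshold screening usage; `build_network()`
exposes a Benjamini-Hochberg flag for users who want it.

**Tissue dominance** operationalizes "highly expressed in root bark",
which is otherwise informal: the focal tissue must be the strict maximum
across tissues *and* at least `min_ratio` (default 2) times the median
of the other tissues (pseudocount 1). Both parts matter: argmax alone
flags genes with flat profiles; the ratio alone can be won by a tissue
that is not even the maximum.

## The correlation network

Profiles are per-row z-scores of `log2(x + 1)` values (constant rows
become all-zero and are flagged, and are excluded from correlation).
Pearson r between every gene and metabolite pair over shared samples is
tested with the classical `t = r sqrt((n-2)/(1-r^2))` approximation,
two-sided. An edge requires `r > 0.7` and `p < 0.05`, both strict, on
signed r — the cutoffs are quoted as strict inequalities, and the
positive-correlation reading is the default because a biosynthetic gene
is expected to rise with its product. `positive_only = FALSE` switches
the cutoff to `|r|`. The cell time course and the tissue panel give two
networks built separately (they measure different contrasts); the edge
union is used downstream, keeping the larger r for duplicated edges.

## CYP classification by identity

All identity computations use true global (Needleman-Wunsch) alignment
with BLOSUM62 and affine gaps (open 10, extend 1). **Percent identity is
matches over aligned columns excluding terminal-gap columns** — stated
explicitly because the screening literature rarely defines the
denominator; this BLAST-like convention is robust for near-global
homologs of unequal length. Coverage is the fraction of query residues
inside the non-terminal alignment. Identity is symmetric; coverage is
role-specific.

* homologs: seed coverage >= 50% and identity > 50% (strict);
* species-specific: best cross-species identity < 55% (strict) — the
  conventional CYP subfamily boundary;
* near-duplicates: single-linkage clusters at identity >= 97%, one
  representative per cluster (longest sequence, ties by smallest id).

The exhaustive-alignment approach is deterministic and database-free; it
deliberately replaces heuristic database search plus tree inspection,
which is a faithful substitution at panel scale (hundreds of proteins)
but would not scale to full proteomes.

## The candidate funnel

Stages, in order: (1) CYPs linked to a target metabolite in the network;
(2) restricted to RPKM > 1; (3) **union** with species-specific CYPs
that are MeJA-induced or focal-tissue dominant — specificity is an
independent evidence line, so it widens rather than narrows the pool;
(4) restricted to genes that are DE or tissue-dominant *and* have
Pearson r above the network cutoff to at least one bait profile ("highly
similar expression to the diterpene synthases" has no canonical formula;
bait-r-above-cutoff is this package's operationalization and is
configurable); (5) minus a user-supplied exclusion list (genes with
known, irrelevant function), then 97% duplicate collapse. The exact
Boolean structure of stage 3/4 cannot be reconstructed uniquely from the
narrative screening description; the one implemented here follows its
order of presentation and is validated on planted synthetic truth rather
than on any claim to reproduce historical candidate counts.

## Paralog divergence and WGT dating

**4DTv** is the proportion of fourfold-degenerate third-codon sites
(prefix in TC, CT, CC, CG, AC, GT, GC, GG, identical in both sequences)
whose third bases differ by a transversion. It is reported uncorrected;
the raw proportion is what is conventionally plotted, and at the
divergences of interest (4DTv < 0.5) saturation is mild.

**Ks** uses the Nei-Gojobori (1986) counting estimator with
Jukes-Cantor correction: synonymous site counts per codon average the
two sequences; observed differences are classified by averaging over
minimal mutational pathways; pathways through stop codons are excluded,
and codon pairs whose every pathway is blocked are skipped with a
warning. Changes *to* stop codons count as nonsynonymous in site
counting (the per-position denominator stays 3), matching the common
MEGA/Biopython convention. `Ks = -(3/4) ln(1 - 4 pS / 3)`; `pS >= 3/4`
flags saturation. NG86 replaces maximum-likelihood codon models
(codeml): it is closed-form, deterministic, and accurate for Ks below
~1, which covers the WGT signal (~0.27); for deeper divergences it
underestimates relative to ML, a documented limitation.

The molecular clock is `T = Ks / (2 r)` with the eudicot rate
`r = 6.5e-9` substitutions/site/year, so Ks 0.273 corresponds to 21 MYA
and Ks 0.13 to exactly 10 MYA.

**Collinearity blocks** are maximal monotone chains of homolog pairs
(reference ranks strictly increasing; query ranks strictly increasing or
decreasing) with rank gaps of at most 10 on both genomes, extracted
greedily by descending length and kept at >= 5 gene pairs. Greedy
longest-first chaining replaces MCScanX's scored dynamic programming; at
the block sizes relevant here the chains are unambiguous, and the greedy
rule is deterministic (ties break to the leftmost start, `+` orientation
first). Ranks are 1-based; block intervals are inclusive.

**Syntenic depth** of a reference gene is the number of distinct query
blocks covering its rank; the modal depth over covered genes is the
multiplication signature (3 for a WGT). Interval coverage rather than
per-gene homolog counting makes the statistic robust to individual gene
losses inside a conserved block.

## The synthetic-data generator

One latent logistic induction trajectory (midpoint 48 h, scale 20 h,
rescaled to 0 at the first and 1 at the last sampled time) is shared by
the planted pathway CYPs, the tandem duplicate pair, the bait synthases
and the target metabolite peaks — the minimal structure under which
network recovery is meaningful. Treated-condition means follow
`baseline * (1 + (fold - 1) * latent(t))`, with the target fold
defaulting to 3.6, the observed induction of triptolide in elicited
cells; pathway-gene amplitudes draw from [3.6, 6.1] so genes are at
least as responsive as the metabolite. Planted genes are root-bark
dominant (8x baseline, other tissues 0.15-0.6x); background genes get
mild log-normal tissue preferences so the panel is not artificially
flat. Counts are integer-rounded log-normal draws (log-scale sd 0.25);
no count-model claim is made beyond that convention.

Proteins evolve from family roots by point substitution: shared families
at ~12% per-copy divergence (cross-species identity ~75-80%, safely
above the 55% cutoff), the planted specific subfamily from its own
unrelated root (cross-species identity ~20-40%, safely below), and the
tandem pair by rejection-adjusted mutation counts that land measured
identity in [97, 98] — at or just above the collapse cutoff, so the
planted pair always collapses; tolerance is one identity point,
reflecting length quantization.

Paralog pairs evolve from stop-free random ancestors down two lineages
under per-site Jukes-Cantor for T years at rate r, rejecting
substitutions that create in-frame stops. The expected raw difference is
`3/4 (1 - exp(-8 T r / 3))`; stop rejection depresses realized
divergence by a small deterministic amount (order 1e-3 at the default
divergences), visible in the generator's own calibration test. The
triplicated map places the three post-WGT copies on three homeologous
query chromosomes — what a genome multiplication physically produces —
then erodes each copy by independent per-gene loss (default 40%) and
inverts local six-gene windows at rate 0.05.

What the generator does **not** emulate: read-level sequencing noise,
raw spectra/chromatograms, indel evolution, rate variation across sites
or lineages, correlated gene loss (fractionation bias), and
tandem-array expansion beyond the single planted pair. Passing tests
therefore demonstrate correctness of the estimators and the funnel
logic under the declared generative model, not robustness to every
failure mode of real multi-omics data.

## Problem sizes and numerical conventions

Validation runs use 500 pairs x 1,000 codons for date recovery (median
recovered T 21.1 MYA at a planted 21) and a 3,000-gene, 19-chromosome
map for depth recovery (modal depth 3 at 40% loss) — sizes at which the
sampling error of the median is well inside the +/- 6 MYA band while a
full run stays interactive. Unit suites use smaller instances (120-240
genes, 20-100 pairs). Other conventions: pseudocount 1 before every log
and raw-scale ratio; correlation p-values from the t approximation
(exact under bivariate normality); KDE mode detection uses Silverman's
rule bandwidth and a 5% relative prominence floor; all generator
randomness derives deterministically from one integer seed via fixed
per-generator stream offsets, so identical configurations are
byte-identical across runs.

## Known limitations

NG86 vs ML discrepancy grows with divergence; 4DTv is uncorrected; the
funnel's stage-3/4 Boolean structure is one defensible reading of an
under-specified screen; exhaustive global alignment limits the
classifier to curated panels; and tissue "replicates" default to one
sample per tissue, so tissue-network p-values lean on the sample count
of the panel, not on biological replication.
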