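---
title: "Methods: models, parameters and design choices in droughtseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in droughtseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtseq)
```

droughtseq implements the downstream analysis of a two-tissue,
two-contrast, three-replicate bulk RNA-seq stress experiment: shoots and
roots treated with abscisic acid (ABA) versus its NaOH solvent control,
and PEG osmoticum versus water, profiled in three biological replicate
sequencing runs. This vignette documents the statistical models, the
tunable parameters, the synthetic-data generator, and the numerical and
design decisions, in enough detail that a maintainer can judge every
choice.

## Count model and normalization

Raw per-gene, per-lane counts are modelled as negative binomial (NB) with
a gene-specific mean and a single **common dispersion** $\varphi$ shared
across genes: $\mathrm{Var}(Y) = \mu + \varphi\mu^2$. $\varphi = 0$
reduces to Poisson. A common dispersion is the right level of complexity
for three replicates; genewise (tagwise/trended) dispersions are out of
scope.

Because one sequencing run produced systematically higher counts (the
generator emulates this with a ×1.3 library scale on the last run), all
lanes are **quantile normalized jointly, once**: every lane's sorted value
vector is replaced by the mean of the cross-lane order statistics. Ties
within a lane receive the interpolated reference value at their average
rank (so a two-way tie gets the midpoint of the two spanned reference
quantiles). This is the standard dialect implemented by
`limma::normalizeQuantiles(ties = TRUE)`, which backs
`quantile_normalize()`; the test suite checks it against an independent
rank-average implementation. Note a structural consequence of any
tie-averaging rule: when lanes have different tie patterns (heavy ties at
low counts), the post-normalization sorted vectors agree only up to those
tie groups; for tie-free data they are identical across lanes.

Normalization equalizes library sizes, which is what makes the exact
test's conditioning valid. The pipeline therefore always normalizes before
testing; the exact test itself assumes equalized sizes and performs no
pseudo-count machinery of its own. Normalized values are rounded to
integers for the likelihood computations.

## Common-dispersion estimation

`estimate_common_dispersion()` maximizes the **conditional log-likelihood**
summed over genes and over the two groups of the contrast. For $n$ iid
NB lanes with size $r = 1/\varphi$, the counts given their group total
follow a Dirichlet-multinomial law that is free of the mean, so the
profile over $\varphi$ is well posed with no mean nuisance parameters.
The search is a 1-D bounded optimization (Brent) on the shrunken scale
$\delta = \varphi/(1+\varphi) \in [10^{-6}, 1-10^{-6}]$, tolerance
$10^{-8}$. Genes with zero total in a group contribute nothing. If the
boundary value attains the optimum (flat likelihood, e.g. identical
lanes), the estimator returns the boundary $\delta$, i.e. effectively
Poisson — a finite answer rather than an error. Parameter-recovery tests
confirm $\hat\varphi < 0.01$ on Poisson data and
$\hat\varphi \in [0.15, 0.25]$ at a true 0.2 with 5000 genes, and the
estimate agrees with edgeR's conditional-ML estimator on shared fixtures.

## The exact test

For each gene, the two group sums $S_1, S_2$ (over $n_1$, $n_2$ lanes)
are NB with sizes $n_i/\varphi$. Under the null of a common mean and
equal library sizes, the conditional distribution of $S_1$ given
$T = S_1 + S_2$ does not depend on the mean. The two-sided p-value sums
the probabilities of **all partitions of $T$ at most as probable as the
observed one** (the same dialect as edgeR's `exactTest`); a relative tie
tolerance of $10^{-10}$ keeps exactly-equal mirror outcomes in the
rejection set despite floating-point noise. $\varphi = 0$ degenerates to
the conditional binomial test. Zero-total genes get $p = 1$ and
$\log_2\mathrm{FC} = 0$ by convention.

The log2 fold change is computed from per-lane group means of normalized
counts with a pseudo-count of 0.5 added to each group mean, so zero
groups give finite values.

Calibration is verified two ways: the raw-p false-positive rate at 0.05
on a $10^4$-gene null lies in $[0.04, 0.06]$, and the **randomized
p-values** $p - U \cdot \Pr(\text{tie class of the observed partition})$
are uniform by Kolmogorov–Smirnov. The tie class matters: in a symmetric
conditional distribution the mirror partition has *exactly* the observed
probability, so randomizing over the single outcome's mass leaves a
detectable non-uniformity at $n = 10^4$; randomizing over the tie class
is exact. The Monte-Carlo oracle for individual p-values uses a bracketing
comparison, because outcomes whose true probability sits within
Monte-Carlo noise of the observed outcome's cannot be classified from
finite draws: clearly-less-probable outcomes bound p from below,
possibly-less-probable ones from above, and the exact p must fall in the
bracket.

## The filter cascade

A gene is differentially expressed iff all three hold:

* **Depth**: median sequencing depth ≥ 2X in at least one of the two
  compared groups. Depth is `count × read_length / exonic_length` — the
  only reading under which "sequencing depth" is dimensionally a coverage;
  a raw-count mode is available (`depth_mode`). The median is taken across
  the biological replicates of a tissue/condition group.
* **Effect**: $|\log_2\mathrm{FC}| \ge 1$.
* **Significance**: BH-adjusted p < 0.05. An optional raw-p pre-filter
  (`p_prefilter`, default off) mirrors workflows that shortlist at raw
  p < 0.01 before adjusting; with the adjusted threshold in place it is
  redundant in effect and is provided without asserting intent.

"Transcriptionally active" is a separate, weaker notion: ≥ 2 uniquely
mapped raw counts **summed across all lanes of the experiment** (the
all-samples-all-runs reading), not per-lane.

Overlap percentages between DE lists are ambiguous in their denominator,
so `overlap_sets()` reports both conventions: shared over the union, and
shared over each list separately.

## Enrichment: the Z-score engine

For a DE list of size $n$ (after intersecting with the database universe)
against a category of size $K$ in a universe of $N$ unique genes:
$E = nK/N$ and $Z = (O-E)/\sqrt{V}$. The variance phrase that motivates
this engine is read as "square root of the **variance** of the expected
counts"; the default variance is hypergeometric,
$V = n\frac{K}{N}(1-\frac{K}{N})\frac{N-n}{N-1}$ (sampling without
replacement, which makes $Z$ exactly standardized — empirical mean 0, sd
1 over random draws), with Poisson $V = E$ as a configurable alternative
since either reading of the phrase is defensible. The p accompanying $Z$
is the one-sided upper-tail normal probability, because all significance
criteria are one-directional ($Z \ge 2$). The exact central
hypergeometric p is always computed alongside (via `phyper`; an
enumeration oracle checks it at small $N$).

Significance is the three-part criterion: $Z \ge 2$, $p \le 0.05$,
$E > 1$. For cis-element runs the criterion's p is the **BH-adjusted
exact hypergeometric** p (`p_source = "hypergeometric"`,
`adjust = "BH"`); for pathway and TF runs it is the normal p unadjusted,
matching the respective published conventions; the adjustment method used
is recorded in the result's attributes. Gene models on unassembled
scaffolds (ids shaped `Sb###s######`) are removed when the database
loads; the universe is the set of unique genes across categories, never
the sum of category sizes, and DE genes outside the universe are dropped
before computing $n$. When TF families overlap, each gene counts once per
family and $n$ remains $|DE \cap \text{universe}|$.

## GO enrichment with length-bias correction

Long genes collect more reads and are more likely to be called DE at a
fixed effect size. `go_enrich()` corrects this with the **Wallenius
noncentral hypergeometric** distribution: category genes are drawn with
odds $\omega$ relative to the rest, where $\omega$ is the mean of a
fitted **probability weighting function** (PWF) over member genes divided
by its mean over non-members.

* PWF fit: genes are split into 20 equal-occupancy length bins (fewer if
  lengths tie), the DE proportion per bin is smoothed by isotonic
  (non-decreasing) regression, evaluated by linear interpolation between
  bin centers, and clamped to $(10^{-6}, 1-10^{-6})$. Degenerate inputs
  (all/no DE, all lengths equal) give a constant PWF with a warning.
* Wallenius pmf: evaluated through the integral representation after the
  substitution $u = t^{1/D}$, which turns the integrand into a beta-like
  kernel; the log-integrand is maximized on a grid and the integral is
  computed on the rescaled exponential with `integrate` (rel.tol
  $10^{-10}$), falling back to Simpson's rule on a fixed mesh if adaptive
  integration fails. This evaluation is stable for draws in the hundreds,
  where the naive integrand underflows. $\omega = 1$ routes to the exact
  central pmf. Checks: mass sums to 1 within $10^{-8}$, the
  complement-swap symmetry $(K,k,\omega) \to (N-K, n-k, 1/\omega)$ holds,
  and the pmf matches a sequential biased-urn simulation within
  Monte-Carlo error.

Gene-GO pairs are deduplicated on load, gene-model suffixes (the number
after the final `.`) are collapsed, and scaffold ids dropped — so each
unique gene contributes at most once per category. No propagation up the
GO graph is performed; annotations are used as given (flat pairs).
Significance is flagged on the **raw** Wallenius p at 0.05 to match the
flat-annotation GO convention; BH-adjusted values are reported alongside
for readers who want them.

## Pathways, reaction coverage and the cross-talk network

The pathway database is a pathway → reaction → gene table with an
optional collapse map merging closely related variants (members become
unions; chained or cyclic maps are rejected). The **reaction coverage
ratio** is the fraction of a pathway's reactions containing ≥ 1 DE gene;
pathways with fewer than 3 reactions are excluded from that report as
uninformative.

The **cross-talk network** has collapsed pathways as nodes, scored by
(up-regulated − down-regulated) DE genes they contain (zero renders
neutral); an edge joins two pathways exactly when they share ≥ 1 DE gene,
weighted by the number of shared DE genes — counted once per pair no
matter how many reactions carry them — and classed at ≤5 / 6–9 / ≥10.
The hormone subnetwork takes, for every pair of hormone-flagged pathways,
**all** nodes on any unweighted shortest path between them (hop count;
the only structure the construction defines — edge weights are evidence
counts, not distances), with ties included and isolated hormone pathways
retained; a 1-hop-neighborhood mode is provided as the alternative
reading of "neighbor pathways". Direction for node scores always comes
from one contrast at a time; genes DE in opposite directions in different
contrasts are never pooled. Export is GraphML + SIF + node/edge TSVs for
Cytoscape, and round-trips losslessly.

## Promoter extraction and motif scanning

`extract_upstream()` cuts the 1000 bp immediately upstream of each gene
feature's start — `[start-1000, start-1]` for plus-strand genes, the
reverse complement of `[end+1, end+1000]` for minus-strand genes —
truncating at contig boundaries (recorded per gene) and skipping genes on
missing contigs or without strand. The window anchors on the *gene*
feature start by default (`feature` is configurable); with unrefined
annotations the window may contain 5'-UTR, so positions are reported as
offsets from the window's 5' end rather than distances to a TSS.

`scan_motifs()` reports **every** (overlapping) match of each IUPAC
degenerate pattern, on both strands by default (cis-element databases are
orientation-ambiguous; single-strand mode exists for the literal
forward-only reading). Reverse-strand hits are matches of the
reverse-complement pattern, positioned by their 5'-most base in the
forward window; palindromic patterns therefore report each site on both
strands, which is immaterial for enrichment because presence is
gene-level. An `N` in the promoter never satisfies any motif symbol —
including `N` in the motif — so masked regions cannot generate hits;
matching is delegated to `Biostrings::vmatchPattern` with literal
subjects, plus a post-filter dropping any hit spanning a subject `N`.
Motifs with identical sequences are collapsed on load (aliases kept).
Enrichment uses gene-level presence over the universe of all genes with
extracted promoters, under the three-part criterion with BH-adjusted
hypergeometric p.

## Ortholog triage

Descriptions are matched **case-insensitively and whole-word** against
{hypothetical, expressed, predicted, uncharacterized} — whole-word so
"overexpressed" does not count as "expressed". The decision tree runs
once per non-focal species: a focal DE gene of unknown function is kept
for a species iff it has ≥ 1 ortholog there, *all* its orthologs in that
species are unknown-function, and ≥ 1 of them is in that species'
drought-responsive list. Expression direction is deliberately ignored
(published drought lists mix severities and platforms). Branch (b) is
evaluated per species — orthologs elsewhere do not affect the call — with
a stricter all-species mode behind `require_all_species`. The focal
drought-responsiveness is the pipeline's own DE union across contrasts by
default, or an external list.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults are the
generator's definition of the experiment, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| design | 2 tissues × (ABA/NaOH, PEG/H2O) × 3 replicates | the emulated design (24 lanes) |
| baseline means | log-normal, median 50 counts/lane, sdlog 1 | deep bulk RNA-seq dynamic range |
| dispersion $\varphi$ | 0.1 | typical bulk biological replicates |
| silent fraction | 0.17 | the observed share of never-detected gene models |
| spike fraction / values | 5% per contrast at ±1.5, ±2 | detectable but not trivial effects |
| gene lengths | log-normal, median 1000 bp, sdlog 0.35, min 200 | cereal exonic lengths |
| read length | 50 bp | the trimmed read length |
| library imbalance | last run ×1.3 | the base-caller-upgrade effect QN must remove |

Counts are drawn gene-by-lane NB (Poisson at $\varphi=0$); spiked sets
per tissue/contrast are drawn from a shared pool 1.5× the spike count so
cross-contrast overlaps are non-trivial. Annotations plant two enriched
pathways, two GO terms, one TF family and one motif, each preferring
true-DE genes at configurable odds (odds 1 is an exact null
construction); promoters carry planted IUPAC instances at recorded
positions inside a synthetic genome written as FASTA + GFF3; the ortholog
table plants a conserved-unknown set passing every branch of the tree
plus distractors failing each branch individually. One global seed drives
everything through deterministic child seeds; outputs are bit-identical
under a fixed seed.

What the generator does **not** emulate: read-level errors and alignment
ambiguity (counts are generated directly), splice structure, GC or
positional bias, correlated gene-gene expression, batch structure beyond
the single library-size scale, and realistic genome composition (promoter
background is iid uniform ACGT). Passing tests therefore demonstrate the
correctness and calibration of the algorithms under the stated model, not
robustness to artifacts the model excludes.

## Problem sizes used by tests and the acceptance script

Chosen once as the package's study sizes: null calibration at $10^4$
genes, 3 vs 3, $\varphi = 0.1$, mean 50; Monte-Carlo p oracle from a
$10^6$-draw pool at mean 4, $\varphi = 0.15$, 50 observed partitions;
spike-in recovery with 200 genes at $|\log_2\mathrm{FC}| = 2$, baseline
mean 50, $\varphi = 0.1$, $n = 3$, in a 1000-gene universe, with
sensitivity and observed FDR pooled over 10 replicate simulations —
pooling because a single run's observed FDR at ~200 discoveries has
Monte-Carlo noise comparable to the distance between the BH target
(0.05·π₀ = 0.04 here) and the 0.05 bound; Z calibration over $10^4$
hypergeometric draws at $(n,K,N) = (100, 200, 2000)$; Wallenius urn
oracle with $10^6$ sequential draws at $(N,K,n,\omega) = (20,5,10,2)$;
scanner oracle on $10^3$ random 1-kb promoters × 20 random motifs;
network oracle up to 50 pathways; end-to-end determinism at 800 genes.

## Known limitations

Common dispersion only; no GLM designs or batch covariates. The exact
test requires equalized library sizes and integer counts (rounded
normalized values). Quantile normalization can distort extreme tails when
a large fraction of top-ranked genes is differentially expressed in some
lanes only. The Wallenius evaluation targets the parameter ranges of
category enrichment (draws up to a few thousand); it is not a
general-purpose extreme-tail implementation. The PWF is monotone
non-decreasing by construction; a genuinely decreasing length bias would
be flattened. Promoter extraction anchors on annotated feature starts and
cannot recover unannotated TSSs.
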