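---
title: "Methods: pan-cancer eRNA quantification, regulation and clinical association"
author: "ernascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer eRNA quantification, regulation and clinical association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Enhancer RNAs (eRNAs) are noncoding transcripts produced at active
enhancers. Their expression tracks enhancer activity, which makes them
usable as a transcriptome-level readout of regulatory state across tumor
cohorts: which enhancers are active where, which transcription factors
plausibly drive them, which nearby genes they plausibly regulate, and
whether their expression carries pharmacogenomic or clinical signal.
`ernascape` implements that chain of analyses as a tested pipeline over
standard file formats, together with a synthetic-cohort generator that
plants every effect the pipeline is meant to detect. This vignette is the
package's account of the methods: the procedures, the tunable parameters
and their defaults, the numerical choices, and what the synthetic results
do and do not establish about real data.

## Region construction

Enhancer annotations disagree between catalogues, so the pipeline starts
from a consensus: intervals from three sources are pooled, and a maximal
merged interval is kept when at least one of its bases is covered by
intervals from at least `min_sources = 2` distinct sources. "Annotated in
at least two datasets" has no unique operational reading; one base of
multi-source overlap is the most permissive defensible rule, and it is
isolated in `consensus_enhancers()` so a stricter rule (reciprocal
overlap, midpoint distance) can be swapped in without touching anything
else.

Because eRNA transcription extends beyond the enhancer peak itself, each
consensus enhancer contributes one candidate region of `flank_bp = 3000`
bp on either side of its midpoint (`floor((start + end) / 2)`; odd widths
round down). Regions are clamped at chromosome ends rather than dropped.
Overlapping surviving regions are *not* merged — one region per consensus
enhancer, so counts of eRNAs correspond to counts of enhancers — with a
`merge_regions` switch for the other convention.

Transcription from known genes must not be mistaken for eRNA signal, so a
region is removed entirely (never trimmed) when it overlaps, by even one
base, the exclusion mask: gene and lncRNA bodies extended by
`gene_extension_bp = 1000` beyond both TSS and TES; a
`uaRNA_window_bp = 500` window for upstream-antisense transcription; and
blacklist intervals (rRNA repeats and similar artefact-prone regions).
The uaRNA window is placed strand-aware immediately upstream of the
*extended* TSS — a window anchored at the TSS itself would sit inside the
1 kb extension and exclude nothing, so the only reading under which the
parameter does any work is upstream of the extension. Gene *bodies* (not
exons only) are masked: an eRNA region inside an intron would otherwise
pick up pre-mRNA signal. All coordinates are BED-style 0-based half-open
internally; strand is carried but ignored by all overlap logic except the
uaRNA window.

The whole interval engine is checked exactly — not statistically —
against per-base brute-force oracles on seeded random toy genomes.

## Quantification and classification

A read contributes to a region when it overlaps it by at least one base;
a read overlapping several regions counts toward each — the simplest
auditable rule, given that no rescue scheme is defensible without isoform
information. Expression is reads per million (RPM): the count divided by
the sample's *total mapped reads* over 10^6 (not reads-in-regions, which
would make the denominator depend on the region set). RPM is exactly
invariant under joint scaling of counts and library size.

An eRNA is *detectable* in a cohort when its mean RPM over the cohort's
tumor samples is at least `rpm_detect = 1` (inclusive); normal samples
enter only the paired differential test, since cohort labels are tumor
types. A stricter `rpm_strict = 5` cutoff is carried as a robustness
check and is provably nested. Detectability counts over cohorts classify
each eRNA as ubiquitous (>= 10 cohorts), intermediately specific (2–9),
cancer-type specific (exactly 1) or undetected; the classes partition the
detectable set by construction. Sample-to-sample expression similarity is
pairwise Spearman correlation over the detectable eRNAs; the matrix is
emitted as-is (embedding and clustering of it are left to the user).

## Correlation machinery

One Spearman implementation serves every stage: mid-ranks for ties,
pairwise-complete observations, and a two-sided p-value from the
large-sample t approximation `t = r * sqrt((n - 2) / (1 - r^2))`. Pairs
with fewer than `min_pairs_n = 10` complete observations are skipped —
rank tests below that size are degenerate and the threshold is explicit
rather than silent. False-discovery control is Benjamini–Hochberg
throughout (via `p.adjust`), and the *scope* of each adjustment is fixed
and documented per stage: all TF x eRNA tests jointly within a cohort for
regulators; all candidate pairs within a cohort for target links; all
eRNA x drug pairs within a drug-response source; eRNAs within a cohort
for differential expression and survival; eRNAs within (cohort, clinical
feature) for group tests. Joint-within-cohort is the most conservative
scope consistent with testing "in each cancer type".

Regulator and target-link edges require `Rs >= rs_min = 0.3` **and**
`q < fdr_max = 0.05`. The sign matters: the rule is positive-only, taken
literally from the convention that a regulator or target relationship is
evidenced by co-expression, not anti-correlation. A `regulator_absolute`
switch provides the |Rs| variant. A TF correlated with at least
`master_fraction = 25%` of a cohort's detectable eRNAs is a putative
master regulator; masters in at least `general_master_min_types = 10`
cohorts are general masters. Both boundaries are inclusive (the source
conventions waver between "≥" and "more than"; inclusive is the default,
both are reachable by config).

## Target network, Hi-C support, permutation test

Candidate eRNA–gene pairs require the same chromosome and a
midpoint-to-TSS distance of at most `max_link_distance_bp = 1` Mb
(inclusive). TSS anchoring matches enhancer–promoter interaction
semantics; the region midpoint is the natural anchor on the eRNA side. A
region lying entirely inside an intron of a candidate gene disqualifies
that pair (its signal is confounded with the host pre-mRNA). Links are
candidate pairs passing the co-expression gate above.

Hi-C support is looked up per tissue at the (region-midpoint bin, TSS
bin) key — unordered, since contact matrices are symmetric — at
`hic_bin_bp = 10000` (the bin size of the source matrices is a config
knob, not an assumption). A tissue supports a link when its
observed/expected value is at least `hic_oe_min = 1.0`, i.e. observed
contact exceeding the distance-expected background; "remarkable
interaction" is otherwise undefined, and the threshold is exposed.
Missing bin pairs count as unsupported.

Enrichment of support is tested by permutation: `n_permutations = 10000`
draws of equally many uniform random (region, gene) pairs genome-wide —
any chromosome, no distance constraint, distinct pairs within one draw —
each scored for its supported-in-any-tissue fraction. The empirical
p-value uses the add-one correction `p = (b + 1) / (n + 1)`, which can
never reach zero and reproduces the conventional "p < 0.0001" floor at
10,000 permutations. Genome-wide background is the default because the
background is described as random pairs throughout the genome; a
distance-matched mode (`permutation_distance_matched`) restricts the draw
to the <= 1 Mb universe for sensitivity analysis. Under the null the
p-value is uniform on its grid; this is tested, not assumed.

Correlations across subgroups (e.g. disease subtypes) are combined by
Fisher's variance-stabilizing transform: `z = atanh(Rs)` averaged with
weights `n - 3` (the inverse variance of z), mapped back with `tanh`, and
the combined two-sided p from `Z = zbar * sqrt(sum(n - 3))`. With one
group the combination is the identity.

## Drug response and clinical association

Across cell lines, eRNA expression is correlated with drug-response AUC.
Higher AUC means more drug needed — a more resistant line — so a
significant *negative* correlation is labelled `sensitive` (high
expression goes with low AUC) and a positive one `resistant`. The
convention is stated here prominently because nothing in the data format
enforces it. Each drug-response source is screened and FDR-controlled
separately. An association is `within`-pathway when the eRNA has a
putative target gene in the drug's target pathway, `cross` when it has
annotated targets but none there, `unassigned` otherwise; the three
labels partition every association.

Differential expression uses cohorts with at least 5 tumor–normal pairs:
fold change is the ratio of tumor to normal mean RPM with a pseudocount
`de_pseudocount = 0.1` on both (avoiding division by zero while barely
perturbing detectable-scale values), and the test is a paired two-sided
t-test on `log2(RPM + 0.1)` — the log scale matches the fold-change
semantics, and "tumor and paired normal samples" is read as a paired
design. Calls are `up` when `FC >= 1.5` and `q < 0.05`, `down` when
`FC <= 1/1.5`, else `ns`; swapping the condition labels maps FC to 1/FC
and exchanges up and down exactly.

Group comparisons (subtype, stage, grade, smoking history) drop groups
below `min_group_size = 5`; two surviving groups give a Welch t-test,
more give one-way ANOVA on expression. Stage and grade are treated as
unordered categories — no trend tests. Survival association defaults to a
univariate Cox model on z-scored `log2(RPM + 0.1)` (the log scale keeps
the lognormal tail from dominating the fit; the Wald p is reported), with
a log-rank comparison of the top versus bottom expression quartile as the
secondary mode. Cohorts need at least 20 subjects and 10 events. An eRNA
is *clinically relevant* when at least one of survival, subtype, stage,
grade or smoking reaches `q < 0.05` in any cohort — by definition the
union of the per-category sets.

## The synthetic cohort

No public inputs are required anywhere: `simulate_all()` generates every
file the pipeline reads, from one seed, with a truth ledger. What it
emulates, and how:

* **Genome and annotations.** Non-overlapping genes (2–5 exons),
  lncRNAs, and a small blacklist on four 10 Mb chromosomes; three
  enhancer sources in which a controllable fraction
  (`cross_source_overlap_frac = 0.6`) of base enhancers recurs in a
  second or third source with a jitter small enough to guarantee
  overlap. Base enhancers are separated by a gap larger than the jitter,
  so the expected consensus set is known *exactly* from the ledger.
* **Expression.** A Gaussian copula on latent standard normals: a
  planted (driver, target, rho) pair correlates the latents at rho, and
  each latent maps monotonically to a log-normal negative-binomial mean
  (`latent_sd = 1.2` on the natural-log scale, library sizes log-normal
  around `mean_library_size = 5e6`). Because the transform is monotone,
  the Spearman correlation of a planted pair is analytically
  `6/pi * asin(rho/2)` before counting noise. The NB dispersion default
  (`nb_dispersion = 0.02`) is deliberately low: the generator is
  required to reproduce that analytic value to within 0.1 at rho = 0.9,
  and a dispersion much above 0.05 attenuates rank correlations out of
  that band. This is a calibration of the generator, not a claim about
  TCGA-scale dispersion.
* **Cohort structure.** Each eRNA is "on" in a cohort with probability
  `erna_on_prob = 0.7` (off means a 200-fold baseline reduction), every
  feature gets a per-cohort log-normal program multiplier
  (`cohort_program_sd = 0.5`) — giving within-cohort expression
  similarity exceeding between-cohort similarity, the testable form of
  the cohort-clustering claim — and paired tumor/normal samples share a
  patient latent (`patient_rho = 0.4`), so paired tests face real
  pairing structure.
* **Planted effects.** One master TF driving 40% of eRNAs at rho 0.6;
  40 eRNA–gene links at rho 0.5 drawn from the *candidate-pair universe*
  (so the network stage can in principle find them); tumor fold changes
  of 4 on 30 eRNAs; drug correlations of |rho| = 0.6 with alternating
  sign; exponential survival with log-hazard log(2) per SD of planted
  eRNA log-expression and ~30% independent exponential censoring; and a
  2-SD subtype mean shift. Hi-C O/E values are log-normal with median 1
  over all same-chromosome bin pairs within 2 Mb (mirroring the
  short-range coverage of real O/E matrices — a random genome-wide pair
  is usually missing, i.e. unsupported), and bins of planted links are
  multiplied by `hic_enrichment = 10` in the enriched tissues.

What the generator does **not** emulate: sequencing-depth and
read-length batch effects, isoform structure and polyadenylation bias,
copy-number confounding of expression, realistic linkage between
clinical covariates, or Hi-C distance decay beyond the presence/absence
of short-range bins. Passing the planted-recovery tests therefore shows
the pipeline detects the effects it targets at realistic sizes and
sample counts under a faithful null; it does not certify performance on
real cohorts with those additional artefacts.

## Test and acceptance problem sizes

The packaged tests run the interval oracles on 50 random toy genomes
(chromosomes <= 100 kb), the statistics oracles on 1000 random vectors,
null calibration on 20 seeds of 3 cohorts x 60 tumor samples (all six
statistical stages held at or below a 5% discovery rate at q < 0.05,
with regulator/link discovery essentially zero under the Rs >= 0.3
gate), permutation-null uniformity on 200 seeds (Kolmogorov–Smirnov at
alpha 0.01), and planted recovery at the effect sizes above (master TF
at n = 100 in >= 90% of 20 seeds; links at n = 80 against
precision/recall bounds of 0.90/0.70 fixed in advance by an independent
copula simulation oracle; DE "up" calls at >= 95% with 30 pairs; Cox
sign and significance at n = 200 in >= 95% of 50 seeds; drug direction
labels at >= 95% over 50 seeds; planted Hi-C enrichment at the
permutation floor p = 1/(n+1)). These sizes were chosen so the whole
suite exercises every claim in minutes on one CPU while keeping
Monte-Carlo slack wide of each bound.

## Known limitations

* The consensus rule, uaRNA placement, Hi-C support threshold and
  permutation background each encode one defensible reading of an
  under-specified published procedure; all are config-switchable, and
  absolute counts (regions, links) shift under the alternatives.
* BH scopes are fixed per stage; a global-across-cohorts FDR would be
  stricter and is not provided.
* The survival module is univariate only — no adjustment, no competing
  risks.
* BAM input is out of scope: alignments enter as intervals (BED); a
  region x sample count matrix from any external counter is accepted
  directly.
* Liftover between genome builds is the user's responsibility; all
  inputs must share one coordinate system.
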