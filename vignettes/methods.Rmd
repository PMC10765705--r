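---
title: "Methods: co-evolution and phenotype-similarity based candidate-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-evolution and phenotype-similarity based candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`evoranker` links a patient's candidate genes (the survivors of routine
variant filtering) to the patient's phenotype through guilt-by-association:
the causal gene's functional neighborhood — the genes it co-evolved with and
the genes it interacts with — should be enriched for genes already known to
cause phenotypes like the patient's. The package makes this operational in
three layers.

### Normalized phylogenetic profiles

The conservation of gene *g* in species *s* is the bitscore of *g*'s best
BLAST hit in *s* divided by *g*'s self-hit bitscore, log2-transformed. The
ratio is clipped at 1 in the rare case a cross-species hit outscores the
self-alignment (counted in the output metadata); log2 ratios are therefore
non-positive, with 0 meaning "as conserved as the query itself".

Each species column is then z-scored so that phylogenetic distance does not
dominate: a yeast column and a chimp column contribute on the same scale. We
use the sample standard deviation (n − 1), the convention of standard scaling
routines, recorded in the matrix metadata. A column that is constant after
imputation is an error — it cannot be scaled and carries no signal.

**Missing hits.** When no ortholog is detected, the log2 ratio is undefined.
Two imputation policies are offered, applied *before* z-scoring:
`floor_epsilon` (default) sets the value to the column minimum − 1, keeping
"absent" strictly below every observed value; `column_min` ties it to the
least-conserved observed gene. The default preserves the ordering
interpretation that absence is the strongest form of non-conservation.

### Clade-wise co-evolution

Co-evolution of two genes is the Pearson correlation of their profile rows.
Correlations are computed within species subsets (clades) as well as across
all Eukaryota, because a pair of genes can co-evolve tightly inside plants or
fungi while looking uncorrelated globally. The package ships the 16 reference
clade names spanning the eukaryotic tree; any user-supplied clade map works.

Per clade, the query's top *k* partners are ranked 1..k (default *k* = 50,
the cutoff that benchmarked best among 10/25/50/75/100) and clade lists are
merged into a unique partner set keeping each partner's best rank and the
clade achieving it. Design choices where more than one convention is
defensible:

* **Which columns enter the correlation** — always the clade's full column
  set of the single imputed matrix, not pairwise-complete columns, so every
  gene pair is compared over identical coordinates.
* **Ortholog presence** — a clade participates when the query has an observed
  (pre-imputation) hit in at least `min_species` of its species, default
  `max(3, 10%)`: Pearson needs three points, and the 10% rule avoids clades
  supported by a single stray hit.
* **Ties in r** — broken lexicographically by gene id, making rankings
  reproducible across platforms; smaller *k* is always a prefix of larger
  *k*.

### Phenotype ranking

Information content is annotation-frequency based: `IC(t) = -ln(n_t / N)`
with `n_t` the genes annotated to *t* or any descendant (annotations
propagate to ancestors) and *N* the annotated-gene total. The root has IC 0;
a term annotating a single gene has IC `ln N`. Terms annotating no gene get
the maximum observed IC by default (they are real ontology terms, just
unused; dropping them is available). Pairwise term similarity is Lin's
measure, `2 IC(MICA) / (IC(t1) + IC(t2))`, with the 0/0 case defined as 0;
set similarity is the *symmetric* best-match average, so patient and gene are
interchangeable. A Resnik-product scorer is included as an opt-in robustness
check; on toy universes it agrees on the top gene.

No similarity threshold defines "phenotype-related": thresholds proved
impossible to set consistently across HPO term sets of very different
specificity, so the entire ranked list is used as the reference distribution
and enrichment is assessed against it.

### Enrichment and combination

For each candidate and each evidence channel (co-evolved partners,
interaction partners), the channel genes' similarity scores are compared to
the scores of *all* ranked genes with a one-sided two-sample KS statistic
`D- = max(0, sup_x(Fj - Fi))` (reference ECDF minus sample ECDF, both
right-continuous step functions evaluated at the pooled unique values).
Channel genes outside the annotated universe are dropped — both ECDFs must
live on the same scale — and duplicate partners across clades count once.
A channel with fewer than `min_overlap = 3` usable genes is skipped; KS with
fewer points is uninformative.

The p-value is exact for small problems (full enumeration of all
`C(n+m, n)` label assignments, default cap n + m ≤ 12) and asymptotic
otherwise, using `exp(-2 nm/(n+m) D²)` — the same approximation R's
`ks.test` uses for one-sided two-sample alternatives, which our tests verify
term by term. The exact mode is the reference implementation for the
approximation.

Channel p-values are combined by Fisher's method (`-2 Σ ln p ~ χ²(2k)`), with
k adapting to the channels actually available, or by Simes' method. P-values
are clamped at 1e-300 before the log. Candidates are ranked by combined
p-value, ties broken by gene id; candidates with no usable channel are
flagged `no_evidence` and placed last rather than dropped. No
multiple-testing correction is applied to the ranking itself — the method
ranks by raw combined p — but a Benjamini–Hochberg column is exposed for
reference.

### Variant filtering

The filter mirrors routine exome practice. Class: keep nonsense, frameshift,
nonsynonymous, splice-site; rescue synonymous variants any splicing predictor
(dbscSNV RF/ADA, SpliceAI) calls at ≥ 0.5; drop intronic/UTR/ncRNA.
Frequency: all *present* sources (gnomAD, AF_popmax, in-house) must pass
≤ 0.02 (recessive) or < 0.001 (dominant); a missing frequency is a novel
variant and passes. Deleteriousness: truncating variants pass outright;
nonsynonymous variants need PolyPhen-2 ≥ 0.5 or REVEL ≥ 0.5 or SIFT ≤ 0.5,
and pass when all three predictors are missing (a variant is excluded only
when affirmatively predicted benign — otherwise every truncating variant
lacking missense scores would vanish). The SIFT cutoff of 0.5 is the value
the routine filter table states; it is unusually permissive (the conventional
deleterious cutoff is 0.05), so `sift_cutoff` is exposed for users who prefer
the stricter convention. Gene-level rules: recessive needs a passing
hom/hemizygous variant or ≥ 2 distinct passing heterozygous variants (an
unphased compound-het proxy — single-proband exomes have no phase); dominant
accepts any passing variant.

## The synthetic generator

Real inputs at production scale (a thousand-genome profile matrix, the full
HPO, population exomes) cannot ship with a package, and patient exomes are
restricted data. The generator therefore builds inputs with the statistical
structure the method assumes:

* **Matrix** — standard-normal background; each planted module shares a
  per-species latent factor inside its clades
  (`value = sqrt(ρ)·factor + sqrt(1-ρ)·noise`), giving expected pairwise
  correlation ρ, exactly 1 at ρ = 1. Latents map to a raw bitscore table
  (`best = self · 2^(v−8)`) that round-trips through the normalizer.
  Per-species z-scoring attenuates module correlations slightly (the shared
  factor leaks into the column mean and sd), which the generator tests
  measure on the latent scale.
* **Ontology** — a random rooted DAG built in levels, annotations weighted
  towards deeper terms so ICs span 0 to `ln(n_genes)` (one single-gene leaf
  is always pinned).
* **Patient** — one passing homozygous novel truncating variant in the causal
  gene, one passing variant per decoy gene, and noise variants built to fail
  each filter stage, so the recessive candidate set is exactly causal +
  decoys.
* **Network** — random medium/high-confidence edges distributed identically
  for causal and decoy genes. The network channel deliberately carries *no*
  planted signal: recovery must come from co-evolution, mirroring real cases
  where a novel gene has no curated interactions, and keeping null scenarios
  exactly candidate-symmetric.

Defaults, chosen once as the study conditions: 500 genes × 120 species, 4
clades + Eukaryota; module of 50 genes (matching the top-50 partner cutoff,
i.e. a pathway-sized functional module); ρ = 0.9 within-module; 80% of module
partners annotated with the 3-term query; 20 decoys, giving 21 recessive
candidates — inside the 11–80 range typical of filtered recessive exomes.
These scales keep the full test suite and benchmark in the low minutes on one
CPU while leaving every statistical decision (ECDFs over hundreds of genes,
KS asymptotics, clade merging over 5 clades) in its intended regime.

**What passing benchmarks do and do not show.** The generator's background is
i.i.d. normal post-normalization — real conservation scores have phylogenetic
autocorrelation, block structure from lineage-specific losses, and heavier
tails; real ontologies have far deeper hierarchies and annotation biases; the
planted module is cleaner than real pathways. Spike-in recovery here
demonstrates that the pipeline's statistics are wired correctly and calibrated
under the null (top-1 at chance when ρ = 0 and the annotation overlap is
removed), not that real-world accuracy reaches any particular level.

## Numerical and degenerate-input choices

* z-score denominator: sample sd (n − 1), recorded in metadata.
* Bitscore ratio > 1: clipped to 1 and counted.
* KS exact/asymptotic switch at n + m ≤ 12 (enumeration is `C(n+m, n)`).
* p-value floor 1e-300 before `ln`; p = 0 input is an error, not silently
  floored.
* Empty KS sample is an error distinct from "insufficient overlap" (flagged,
  channel skipped).
* Candidate absent from matrix *and* network: flagged `no_evidence`, ranked
  last with p = 1, never dropped.
* Obsolete/alt ontology ids resolve to primary ids at load; unresolvable ids
  error listing the offenders.
* STRING 0–1000 integer scores auto-detected (any value > 1) and divided by
  1000; duplicate edges keep the max; the 0.5 threshold is inclusive
  ("at least" medium confidence).

## Limitations

* The asymptotic one-sided KS p-value is approximate for moderate samples
  (slightly conservative in our null simulations); the exact mode bounds it
  but is only feasible for small samples.
* Compound-heterozygous detection is unphased; two passing variants on the
  same haplotype will be miscounted as biallelic.
* Semantic similarity inherits HPO annotation bias: well-studied genes score
  higher; the enrichment test against the full ranked universe mitigates but
  does not remove this.
* Fisher's method assumes independent channels; co-evolution and interaction
  evidence are positively correlated for well-annotated genes, making the
  combined p anti-conservative there. Simes' method, valid under positive
  dependence, is provided and produced near-identical orderings in our
  benchmarks.
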