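---
title: "Models and methods behind cytgrn"
author: "cytgrn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytgrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytgrn)
```

`cytgrn` treats the regulation of cytokine genes as a bipartite network:
transcription factors (TFs) on one side, cytokine genes on the other, an
edge for every curated protein–DNA interaction (PDI). This vignette
documents the underlying models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions that were
genuinely open — in enough detail that a reader can audit or re-derive
every number the package produces.

## The curated network model

An interaction record is the triple (TF, cytokine, species) plus its
annotations: the set of assay categories that support it, the regulatory
activity, and the article identifiers. Three assay categories are
distinguished — chromatin immunoprecipitation (`chip`), in vitro binding
such as EMSA or pull-down (`binding_in_vitro`), and functional assays
such as reporters, knockdowns and knockouts (`functional`). Input tables
may use free-text assay names; `default_assay_map()` maps them onto the
three categories and is user-editable, because curation vocabularies
differ between groups.

Duplicate rows for the same (TF, cytokine, species) are merged: assay
categories and article IDs are unioned, and conflicting annotated
activities collapse to `bifunctional`. Degree therefore counts distinct
partners, never citations. **Evidence levels** follow a conjunction rule:
a PDI is `high` evidence only when a functional assay *and* at least one
direct-binding assay support it; in particular `{chip, binding_in_vitro}`
without a functional assay is `low`, because binding without a functional
read-out does not establish regulation.

Two conventions make the connectivity statistics reproducible:

* `degree_rank_coverage()` breaks degree ties lexicographically by
  symbol, so the "fraction of TFs carrying more than half of the PDIs"
  is deterministic.
* Cross-species comparison defaults to case-insensitive symbol identity
  as the ortholog map. Genes without a counterpart under the map (or
  under a user-supplied two-column mapping) count as species-specific.
  Curated orthology resources would shift the species-specific fractions
  slightly; symbol identity was chosen because curated tables are keyed
  by gene name.

## Per-TF scores

**Tissue-specificity (TSPS).** For a non-negative expression profile over
$T$ tissues, with $p_i$ the tissue's share of the gene's total expression
and $p = 1/T$,

$$\mathrm{TSPS} = \sum_i p_i \log_2 \frac{p_i}{p},$$

the Kullback–Leibler divergence from uniform, in bits; equivalently
$\log_2 T$ minus the Shannon entropy of $(p_i)$ — the test suite checks
this identity against an independent entropy computation. Conventions:
$0 \log 0 := 0$ (standard entropy limit); an all-zero profile has no
defined score and raises an error rather than returning 0, mirroring the
exclusion of genes without usable expression. The score is invariant
under positive scaling of the profile, so TPM versus any rescaled unit is
immaterial. The TS call threshold defaults to 0.7 bits, a value
originally motivated by the bimodal score distribution over TF panels;
it is exposed as a parameter.

**Expression enrichment (EES).** A pseudocount of 1 TPM is added to every
value *first* (damping ratios from near-zero transcripts), each tissue's
pseudocounted value is divided by the gene's pseudocounted mean, and the
per-tissue enrichments are averaged within the immune and non-immune
tissue sets. The count-weighted mean of the two group scores is exactly 1
by construction, a property the tests assert. Because of the pseudocount
the score is deliberately *not* scale-equivariant.

**Inflammatory score (IS).** Over a TF's distinct cytokine targets,
$\mathrm{IS} = n_\text{pro}/n - n_\text{anti}/n \in [-1, 1]$, with the
canonical 10-gene pro-inflammatory and 13-gene anti-inflammatory panels
as defaults (`pro_inflammatory_cytokines`,
`anti_inflammatory_cytokines`). The fraction scale (not percent) is used
so the pro/anti bands sit at $\pm 0.5$.

**Degree bins.** Summaries by connectivity default to bins
$\{0, 1, 2\text{–}4, 5\text{–}9, \ge 10\}$. The bin edges are
configurable; these defaults give a roughly geometric progression that
keeps each bin populated at curated-network sizes, and the degree-0 bin
exists so TFs absent from the network can be compared against network
members.

## Enrichment tests

* **Cell-type enrichment** uses a pooled two-proportion z-test comparing
  a TF's share of targets in a cell type against the pooled share among
  all other TFs' PDIs. The pooled-z variant (rather than chi-square with
  continuity correction) was an open choice; the pooled z is the direct
  large-sample test for equality of two proportions and its square equals
  the uncorrected chi-square statistic, which the tests verify. TFs with
  fewer than 2 targets are skipped: a one-target proportion is
  degenerate.
* **Disease enrichment** builds, per (TF, disease), a 2×2 table over the
  *configured cytokine universe* — not merely cytokines with PDIs — so
  that untargeted cytokines contribute to the margins. Enrichment is
  directional, hence a one-sided (greater) Fisher test by default, with
  the two-sided variant available. The odds ratio is reported as the
  sample cross-product $ad/bc$ ($\infty$ when $bc = 0 < ad$).
* **Multiple testing** uses Benjamini–Hochberg step-up adjustment with an
  FDR threshold of 0.1, applied jointly across the full TF × context
  family (the family structure is not dictated by the analysis, and the
  joint family is the conservative choice). Note the BH transform is not
  idempotent — re-adjusting adjusted values inflates them — so adjusted
  p-values must never be fed back through `bh_adjust()`.

## The degree-preserving null model

`edge_switch_randomize()` repeatedly selects two edges
$(t_1, c_1), (t_2, c_2)$ and rewires them to $(t_1, c_2), (t_2, c_1)$,
rejecting proposals that collide with an existing edge or share an
endpoint. Every node's degree is preserved exactly. The attempt budget
defaults to $10 \times |E|$; on small toy networks the resulting state
distribution is statistically indistinguishable from uniform over the
degree-preserving support (verified against exhaustive enumeration), so
the budget mixes adequately at the network sizes involved. The inner
loop is compiled (Rcpp) and draws from R's RNG, so `set.seed()` governs
replicate-for-replicate reproducibility.

The triplet statistic counts (TF, cytokine, disease) triples where the
edge exists and both partners carry the disease annotation; a pair
sharing $k$ diseases contributes $k$. A pair-level variant (each pair
counts at most once) is available via `count = "pairs"`, since either
reading of a "shared-disease set" is defensible; the triple count is the
default because it weights multi-disease sharing. Significance is the
one-sided upper-tail normal probability of the z-score against the
randomized replicates (1000 by default), with the empirical tail fraction
reported alongside; when the null is degenerate (zero variance) the
empirical fraction is reported as the p-value with a warning.

## Motif scanning

A PWM is stored as per-position base probabilities; loading applies a
pseudocount (default 0.01 per cell) and renormalizes, which avoids
$-\infty$ log-odds from zero counts while barely moving informative
positions. The window score is

$$s = \sum_{i} \log_2 \frac{p_i(b_i)}{q(b_i)}$$

with a uniform background $q = 0.25$ by default (both the log base and
the background are parameters and are recorded in the object). Both
strands are scanned; minus-strand hits are reported at their
forward-strand 0-based offset with half-open windows. Windows containing
`N` have undefined likelihood and are skipped. The reporting threshold
defaults to 10 bits — a stringent cut-off under which only sites within
about one mismatch of a sharp motif's consensus score — and promoters are
expected as 2 kb of sequence upstream of the transcription start site,
supplied 5'→3' on the coding strand.

## Predicting novel PDIs

The co-expression step is a provider abstraction: a function from a query
gene set to a ranked gene list. The default provider emulates a
co-expression search engine over a user-supplied compendium, scoring each
candidate by its Fisher-z-averaged Pearson correlation with the query
genes; it queries all known targets jointly (per-target rank aggregation
would be an alternative; the joint query is the default because the known
targets jointly define the TF's regulatory context). For each TF with at
least two known targets and an available PWM, the top 100 co-expressed
genes are intersected with the cytokine universe, already-known targets
are removed, and candidates are retained when the TF has at least one
binding site at threshold 10 in the candidate's 2 kb promoter.

Confidence tiers combine the site count with mouse evidence: `high` =
≥ 2 sites and the orthologous interaction present in the mouse network;
`medium` = ≥ 2 sites without mouse evidence or exactly 1 site with it;
`low` = 1 site and no mouse evidence. ("Fewer than two sites" can only
mean exactly one here, because zero-site candidates were filtered out.)
Prediction quality is summarized by the 2×2 enrichment of predictions
among mouse-reported pairs over the candidate universe, with the
cross-product odds ratio and an uncorrected chi-square p-value (Yates
correction available). The Haldane–Anscombe (+0.5) odds ratio is also
returned: on synthetic worlds where every false prediction can land
inside the mouse network, the raw cross-product is infinite, and the
+0.5 estimator keeps the summary finite without changing its meaning.

## The synthetic world

`generate_world()` produces every input with known ground truth from one
master seed, which fans out into independent child seeds (drawn once,
below $2^{31}$) so each generator is a pure function of its parameters.
The defaults define the study conditions used throughout the tests and
the acceptance script:

| quantity | default | rationale |
|---|---|---|
| TFs × cytokines | 40 × 60 | curated-network scale, seconds of compute |
| TF degree law | truncated power law, exponent 2 | hub-dominated degrees seen in curated GRNs |
| tissues | 34 (5 immune) | typical expression-atlas panel shape |
| TS planting | 90% of expression mass in one tissue | puts planted genes far above the 0.7-bit call |
| promoters | 2000 bp, uniform composition | matches the 2 kb scanning convention |
| PWMs | length 12, dominant base 0.99 | at threshold 10 admits ≤ 1 mismatch; ~1% of random 2 kb promoters contain a spurious site |
| compendium | 60 samples, module loading 2 | module members rank top-of-list reliably |
| corpus | 100 abstracts, 20 planted triples | decoys include embedded-symbol near-misses |

Planted novel PDIs receive all three signals the predictor looks for — a
co-expression module membership, two promoter sites, and a mouse edge —
so end-to-end recovery as high-confidence calls is the designed outcome,
and the recovery rate measures pipeline correctness, not biological
performance.

What the generator deliberately does **not** emulate: real gene
identities and symbol synonymy beyond the variant grammar, literature
bias (publication-count-driven degree inflation), GC content and
repeat structure of real promoters, correlated assay annotations, or
batch structure in expression compendia. Green synthetic tests therefore
certify the algorithms and their calibration under the stated conditions;
they do not certify recovery rates on real curated data, where signal
strengths are weaker and confounded.

## Numerical and degenerate-input conventions

* $0 \log 0 := 0$ in all entropy-like sums.
* Degenerate pooled proportions (all successes or all failures) return
  $z = 0$, $p = 1$ with a warning rather than `NaN`.
* Odds ratios report $\infty$ when only the concordant product is
  non-zero and `NaN` when both products vanish.
* Edge switching on a network admitting no legal swap (e.g. complete
  bipartite) returns the input topology with a warning.
* Tie-breaks in rankings are lexicographic; all list-valued fields are
  kept sorted, so equal inputs produce byte-identical outputs.
* Scanning a sequence shorter than the motif returns an empty hit table
  with a warning; a `+∞` threshold yields zero sites everywhere.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run at the generator defaults
above: 1000-replicate degree-preservation checks, 200 synthetic nulls at
100 randomizations each for the type-I-error calibration of the triplet
z-test (acceptance band 5% ± Monte-Carlo error, fixed beforehand),
exhaustive Fisher enumeration up to table total 30, and one full
synthetic world per end-to-end check. These sizes were chosen so a
complete run takes a few minutes on a single core while every stochastic
assertion retains comfortable margins.

## Known limitations

* Symbol-identity orthology under-counts cross-species overlap for genes
  without same-name orthologs; supply an explicit mapping table for
  rigorous comparisons.
* The co-expression provider is a stand-in contract: rankings from a
  production co-expression service over thousands of datasets will
  differ from any single-compendium correlation ranking.
* The motif threshold of 10 bits is a convention; PWM scales differ
  between motif databases, so thresholds should be revisited when
  importing models whose scores are not log₂ odds against a uniform
  background.
* Literature triage is co-mention screening, not relation extraction;
  its output is a curation queue, not an interaction list.
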