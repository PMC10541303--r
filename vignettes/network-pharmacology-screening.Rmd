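---
title: "Methods: network-pharmacology screening with npscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology screening with npscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscreen)
```

# The model

`npscreen` implements a five-stage screening funnel for multi-herb compound
libraries, entirely offline and file-based. Each stage is a pure function of
its inputs, so a run is completely described by its input files and a
`pipeline_config()` object; `run_pipeline()` chains the stages and writes
every intermediate table.

1. **Drug-likeness screen.** Each compound is scored with QED, the weighted
   geometric mean of eight asymmetric double-sigmoidal (ADS) desirability
   functions of the descriptors MW, ALOGP, HBA, HBD, PSA, ROTB, AROM and
   ALERTS. A compound passes if QED is at or above the cutoff and (by
   default) its oral-bioavailability flag is set. Multi-herb duplicates are
   then merged into one record carrying the union of source herbs.
2. **Target intersection.** Predicted targets of the surviving compounds are
   intersected with a disease gene table; common genes at or above a
   relevance-score cut become the *potential targets*.
3. **PPI topology.** The interaction network (STRING-style weighted edge
   list, combined score on the 0–1000 scale) is restricted to the potential
   targets; nodes passing the degree, betweenness and closeness thresholds
   simultaneously become *key targets*.
4. **Over-representation.** Key targets are tested against a GMT collection
   with the exact hypergeometric upper tail, optionally Benjamini–Hochberg
   adjusted.
5. **C-T-P assembly.** A tripartite compound–target–pathway network is
   assembled over all screened compounds, the key targets and the top
   enriched pathways; compounds are ranked by their degree toward key
   targets and *key compounds* selected by a degree floor or a top-*k* rule.

A companion module does exact-mass arithmetic for mass-spectrometric
identity checks: monoisotopic masses from a CODATA/IUPAC isotope table,
protonated-adduct m/z with optional neutral losses, and signed ppm errors.

# Assumptions

* Gene identity is by symbol after canonicalization (upper case, whitespace
  stripped); no alias resolution is attempted.
* PPI edges are undirected and unweighted for topology: centralities are
  computed on unit-length edges, with the score used only as an inclusion
  cut.
* The hypergeometric test treats the annotation universe as the frame; by
  default the universe is the union of all term members, and query genes
  outside it are dropped with a warning.
* Descriptor tables are trusted as given; QED is computed from the supplied
  descriptors, not from structures.

# Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `qed_cutoff` | 0.4 | conventional "drug-like" floor for QED |
| `require_ob` | `TRUE` | oral formulations; both gates must pass |
| `qed_weights` | `"unweighted"` | QED's weightings are near-equivalent in rank; unweighted is the simplest defensible default, `"mo"` (maximum-information weights) is available |
| `relevance_min` | 9 | keeps roughly the upper tail of a heavy-tailed relevance distribution |
| `score_min` | 700 | STRING "high confidence" |
| `deg_min`, `bc_min`, `cc_min` | 10, 0.001, 0.6 | joint hub criterion: locally well-connected, on shortest paths, and globally central |
| `p_max`, `adjust` | 0.05, `"none"` | screening-stage convention; BH available and recommended for confirmatory use |
| `top_pathways` | 20 | network readability, not inference |
| `compound_rule` | `degree_min = 3` | a compound correlating with three or more key targets is unlikely to do so by chance in sparse C-T edge sets |

All thresholds are inclusive (`>=`), and every stage sorts its output
deterministically, so reruns are byte-identical.

# Numerical choices

**QED.** The ADS coefficients are the published maximum-likelihood fits; each
desirability is normalized by its own maximum and clipped into (0, 1] so the
geometric mean is defined even at extreme descriptor values. The
implementation is checked against a frozen reference oracle of 100
descriptor vectors to below 1e-6 (observed agreement ~1e-10).

**Centralities.** Degree and betweenness come from igraph, with betweenness
normalized by `(n-1)(n-2)/2`. Closeness is computed in-package with the
Wasserman–Faust component scaling,
`((n_c - 1) / sum d) * ((n_c - 1) / (n - 1))`, because igraph's default
closeness is undefined on disconnected graphs, which routinely occur after
restricting to potential targets. Both are validated against an exhaustive
shortest-path-enumeration oracle on 1000 random graphs of up to 10 nodes.

**Hypergeometric tail.** `hypergeom_p(k, K, n, N)` is
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`; tests compare it to direct
rational enumeration with binomial coefficients for every configuration with
`N <= 12`.

**Type-I calibration.** The null design used to check the enrichment test's
level was fixed analytically before any test was run: universe 1000, query
80, seventeen term sizes from 40 to 200. For that design the exact attained
level of the nominal 0.05 test (accounting for the discreteness of the
hypergeometric p-value) is 0.0412, comfortably inside the 0.05 ± 0.02
acceptance band; small queries or small terms would make the attained level
collapse far below nominal and the check uninformative.

**Exact masses.** The isotope table uses CODATA/IUPAC monoisotopic masses
(proton 1.00727646 u, H2O 18.0105646 u). Adduct m/z is
`(M - losses + protons * 1.00727646) / charge`; ppm error is
`(measured - theoretical) / theoretical * 1e6`, signed.

# The synthetic-data generator

`write_synthetic_inputs()` emulates every database input with planted ground
truth, all derived deterministically from one seed:

* **Compound descriptors** from simple parametric families (log-normal MW,
  normal ALOGP, Poisson counts, gamma PSA); the oral-bioavailability flag is
  Bernoulli with a high success probability for Lipinski/Veber-passing
  compounds and a low one otherwise, so the screen has real work to do.
  A configurable fraction of rows are duplicates of earlier compounds under
  a different herb, exercising deduplication.
* **Relevance scores** are Pareto-tailed (scale 3), so a relevance cut of 9
  keeps a predictable upper-tail fraction — e.g. shape 0.834 gives
  `P(score >= 9) = (1/3)^0.834 ≈ 0.40`.
* **Planted potential targets**: a chosen number of disease genes are
  guaranteed to be predicted targets, and a chosen subset of those is
  guaranteed relevance >= 9 while the rest stay below; non-planted disease
  genes are excluded from the prediction pool so the intersection is exact.
* **Planted PPI hubs** form a clique plus exactly `hub_degree_boost` spokes
  each, so hub degree is deterministic (`n_hubs - 1 + boost`) and sits above
  any non-hub under Erdős–Rényi background; with a saturated boost (spokes
  to every non-hub) a degree floor between the two separates hubs
  near-deterministically.
* **Planted enriched terms** are composed mostly of key genes
  (`planted_overlap`), with background terms drawn uniformly from the
  universe.

`synth_preset_study_scale()` is a convenience configuration at realistic
study scale: a ten-herb library of 2419 rows, 196 disease genes, 52 planted
common genes of which 22 are planted potential targets, 9 planted hubs, and
20 planted enriched terms among 40. These sizes are the package's own
defaults for a large-screen demonstration; every one of them is a
constructor argument.

**Realism limits.** Descriptors are drawn independently (real descriptors
correlate: MW with PSA, HBA with PSA), prediction edges are exchangeable
rather than promiscuity-skewed, and the PPI background is Erdős–Rényi
rather than scale-free. The generator is designed for *recovery testing* —
known truth in, known truth out — not for benchmarking method power on
realistic networks.

# Known limitations

* Published identification tables are not always internally consistent:
  printed "calculated" masses can mix round-half-up and truncation in the
  final digit, and the sign convention of reported ppm errors varies between
  sources. `mass_table()` therefore recomputes everything from the formula
  and reports its own signed ppm; comparisons to printed values should allow
  one unit in the last printed place.
* In synthetic libraries with predictions spread over a large target
  universe, few compounds reach the default key-compound floor of 3 key
  targets; the rule is meant for real prediction sets, which are far more
  concentrated. Use `compound_rule = "top_k"` for synthetic data if a
  non-empty selection is needed.
* Closeness on very small components is dominated by the component-size
  scaling; thresholds tuned on large networks should be revisited when the
  potential-target set is tiny.
* The enrichment test assumes a fixed universe; with `adjust = "none"` the
  stage is a screen, not a confirmatory analysis.
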