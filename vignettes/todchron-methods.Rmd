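---
title: "Methods: trees of domains, chronologies and Venn-group timelines"
author: "todchron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trees of domains, chronologies and Venn-group timelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(todchron)
```

# The model

`todchron` infers the history of protein structural domains from their
abundance profile across proteomes. The central assumptions, in the order the
pipeline uses them:

1. **Abundance and spread carry memory.** The genomic abundance of a domain
   family grows over evolutionary time and its occupancy spreads across
   lineages; both are robust to moderate horizontal transfer and loss. A
   family that is abundant and near-universal is old; one that is sparse and
   restricted is young.
2. **Ordered (Wagner) characters.** Each proteome is one multistate character
   over the domain-family taxa. Because the states are binned abundance
   levels, state changes are serial: going from abundance level 3 to level 7
   passes through the intermediate levels, so the cost of a change is
   `|i − j|` on the linear 0..S−1 state graph, and changes are reversible.
   Tree length is minimized by Sankoff dynamic programming; for the linear
   cost the per-node min-plus convolution collapses to a two-pass distance
   transform, making scoring O(nodes × S × characters).
3. **Generality-criterion rooting.** With symmetric costs, unrooted length is
   invariant to root placement, so rooting needs an external polarity
   statement. The package implements the "ancestor" variant of Lundberg
   rooting: a hypothetical ancestor carrying each character's observed
   maximum state (default; the ancestral condition is the most general,
   abundant one) — or minimum state — is attached to every edge in turn, and
   the most parsimonious attachment receives the root. The "standard"
   nested-pattern implementation of the generality criterion is not
   reproduced; with Wagner characters only ancestor attachment yields a
   non-arbitrary most-parsimonious root, which is why the ancestor variant is
   the package default and the only one offered.
4. **Node-distance chronology.** The relative age of a leaf is the number of
   internal nodes (equivalently edges, i.e. cladogenic events) on its path
   from the root, min-max normalized to `nd ∈ [0, 1]`; 0 is the oldest leaf.
   Normalizing by the (min, max) range rather than by the maximum alone
   makes the most basal family sit exactly at nd 0, matching the convention
   that the most ancient family anchors the timeline. An affine "clock of
   folds" maps nd to geological time; the default anchors (0 → 3.6 Gya,
   1 → 0 Gya) reproduce the published pairing nd ≈ 0.5 ↔ 1.8 Gya and are
   fully configurable, since any serious calibration is external input.
5. **Venn groups and phases.** The non-empty subsets of {A, B, E, V} that
   contain a family partition the census into 15 groups, 8 "unique to or
   shared with viruses" and 7 "unique to cells". Phase boundaries are the
   first-appearance nd values of marker groups; the default marker map
   (I ← ABE, II ← BEV, III ← earliest bacterial-side group, IV ← V,
   V ← earliest eukaryal-side group) encodes the published order of
   appearance. Phases are half-open `[b_k, b_{k+1})`: a feature exactly on a
   boundary belongs to the later phase, a deterministic convention.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_states` | 24 | ordered bins | NEXUS single-symbol alphabet limit; finer bins add resolution but no signal beyond Poisson noise |
| coding formula | `round((S−1)·ln(a+1)/ln(m_j+1))`, per-proteome `m_j` | states | satisfies the stated endpoints (0 → 0, max → S−1), is monotone in abundance, and normalizes unequal proteome sizes; a global-maximum variant is selectable (`rescale = "global"`) |
| rounding | half-up | — | deterministic, matches common implementations (base R `round()` is banker's rounding and is not used) |
| `moves` | NNI | — | SPR is available; on the censuses this package targets NNI converges in seconds while SPR costs quadratically more per sweep |
| clock anchors | (0, 3.6), (1, 0) | (nd, Gya) | see above |
| e-value cutoff | strict `< 0.001` | — | prototype-to-family mapping filter |
| `nd_window` | 0 | nd | non-modular criterion: 0 reproduces the strict "maps exclusively to a single family" reading; a positive window generalizes to "families of similar time of origin" |
| rank-sum switch | exact ≤ 12, else normal | pooled n | exact enumeration handles ties correctly at small n (and returns p = 1 for identical samples); the tie-corrected, continuity-corrected normal approximation takes over beyond it |

Numerical choices: parsimony tie-breaks (stepwise insertion edge, Lundberg
attachment, NNI acceptance) always prefer the lowest edge index in a
deterministic traversal, so seeded runs are bit-reproducible. NeighborNet
split weights come from a Lawson–Hanson non-negative least squares over all
splits compatible with the circular ordering; splits below `1e-8` weight are
dropped, trivial (singleton) splits are always retained. Bootstrap support
matching requires exact bipartition identity — with ≤ 4 network taxa the
split space is tiny and nearest-split matching would only blur it.

# The synthetic generator

There is no deposited census, so validation rests on `simulate_census()`,
which realizes the coupling the chronology method assumes:

* **Birth times** are uniform on [0, 1) (or stated design points).
* **Vertical descent.** Within each supergroup the proteomes stand in a fixed
  lineage order with divergence quantiles `q`; a family born at `t`
  colonizes lineages with `q ≤ base + slope·(1 − t)`. Older families
  therefore occupy nested supersets of the lineages carrying younger ones —
  the shared-and-derived structure that ordered parsimony reads. An early
  independent-Bernoulli version of this model produced censuses whose
  maximum-parsimony trees carried *no* recoverable chronology (shorter trees
  scored worse against the truth); nestedness, not mean occupancy, is what
  makes node distances meaningful.
* **Noise.** Each presence/absence flips with `flip_rate` (sporadic transfer
  and loss); `hgt_rate·t` adds late extra spread (the f-value rise in the
  second half of the timeline); a `parasite_fraction` of each code's
  proteomes loses presences with `loss_rate` (reductive evolution).
* **Viral sharing.** Virus-shared families get `viral_boost` extra spread in
  cellular codes — viruses help spread domain wealth — which is what the
  rank-sum dominance tests detect.
* **Abundance.** A present cell holds `1 + Poisson(growth_rate·(1 − t)·c)`
  copies, `c` a per-code factor (viral proteomes are small).

`default_fixture()` states a concrete world: 77 families over
36 proteomes (A 6, B 14, E 10, V 6), universal-heavy composition, ground
truth appearance order ABEV < ABE < BEV < BE < bacterial-side groups, a
virus-specific cohort born at 0.47–0.53, eukaryal-side groups from 0.62 on,
and seed 42. Two dimensioning choices deserve explanation:

* The census is universal-heavy and the viral/archaeal codes contribute few
  characters. Because the per-proteome rescaling gives every character the
  full 0..23 range, a supergroup's weight in the parsimony criterion is its
  proteome count; when a restricted Venn group faces a large block of
  characters from codes it is absent from, its families collapse into a
  clade at an arbitrary depth and node distances decouple from age. At desk
  scale, chronology identifiability requires the universal backbone to
  dominate.
* For the same reason, virus-specific families — zero in every cellular
  character — necessarily attach near the crown of a desk-scale tree. In the
  real census, 74% of proteomes are viral and virus-specific families carry
  enough character mass to sit mid-timeline; 6 viral characters cannot
  reproduce that. Phase accounting on the fixture is therefore validated
  against the generator's truth chronology, while tree-based recovery is
  validated on what the tree can identify (the birth ranking and the
  ABEV → ABE → BEV → BE group order).

Hence, a green test establishes that the pipeline recovers a stated world
whose spread model is nested vertical descent with moderate noise; it does
not establish robustness to block-structured occupancy, nor the absolute
placement of virus-specific families, nor anything about the real 3892 ×
8127 census, whose published tree statistics (2,083,556 steps, RI 0.704,
g1 0.0004) are far beyond desk-scale searches.

# Degenerate inputs and edge policies

* All-zero proteomes encode as constant state 0, are flagged, and fall to the
  informative filter; all-zero families are retained in the census but
  excluded from Venn analysis as orphans (dropping them silently would
  corrupt the Venn accounting).
* Missing states (`?`) get zero-cost initialization over all states in the
  Sankoff pass (the standard treatment).
* A tree whose leaves are all equidistant from the root has no chronology:
  all nd are set to 0 with a warning.
* `run_pipeline()` falls back to an evenly spaced six-phase timeline (and
  records the fact in its manifest) when the configured markers do not
  delimit increasing boundaries on a recovered chronology — on small or
  noisy censuses marker inversions are expected, and a pipeline that aborts
  there would hide every downstream artifact.
* Cumulative accumulation counts use strictly-before-boundary membership, so
  the cumulative count at a boundary equals the sum of the completed phases'
  counts (the convention consistent with the published cumulative totals);
  the curve also reports the inclusive endpoint at nd = 1.

# Known limitations

* Heuristic search offers stepwise addition plus NNI/SPR hill-climbing; no
  ratchet, no tree fusing. For ≤ 7 taxa it provably attains the exhaustive
  optimum (tested); beyond that it is a local search.
* The rank-sum normal approximation deviates from exact enumeration by up to
  ~0.15 under heavy ties near p = 1 (harmless but real; the property test
  documents the envelope).
* NeighborNet is implemented for the small taxon sets this analysis needs
  (the four supergroups; tested to 6 taxa against tree metrics); it is not
  tuned for large distance matrices.
* The loop-prototype machinery starts from a prototype → family mapping
  table; deriving prototypes from structures (density-search clustering,
  profile scanning) is upstream and out of scope.
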