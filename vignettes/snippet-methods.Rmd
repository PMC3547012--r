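---
title: "Methods: snippet discovery, haplotype networks, and the synthetic world"
author: "snippetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snippet discovery, haplotype networks, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snippetr)
```

## The model in brief

A *snippet* is a very short hyper-variable window of the mitochondrial
control region that can be amplified as a sub-100 bp product from heavily
degraded bone and still resolve species and, often, populations. `snippetr`
operationalises the idea in four linked models:

* a **variation profile**: per-column minimum-mutation counts on a tree,
  calibrated into %/Myr rates;
* a **window score** for candidate snippets;
* **exact-string haplotypes** over the chosen window, with per-species label
  series, spanning networks, and a locality-based diversity ratio;
* a **three-step sexing decision** exploiting avian ZW genetics.

This vignette explains each model's assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## Variation profiling

Change counts are reconstructed by parsimony over the 5-state alphabet
{A, C, G, T, gap}. We use the unit-cost Sankoff recursion rather than
textbook two-child Fitch so that the trifurcating root of an unrooted
neighbour-joining tree (and any polytomy) is handled exactly; on binary
trees the two are identical. The per-column *total* is the parsimony
minimum and is independent of which optimal ancestral labelling is chosen.
The split into transitions, transversions, insertions (gap→base along the
root-to-tip direction) and deletions (base→gap) requires one concrete
labelling; we make it deterministic by rooting at the tree's first internal
node and breaking ties towards the state earliest in the fixed order
A < C < G < T < gap. The type split is therefore reproducible but
approximate — a caveat inherent to any single-labelling classification.

Guide trees are neighbour joining on p-distances with pairwise deletion
(sites with a gap or N in either sequence are skipped; an optional
gap-as-fifth-state mode exists, but that convention is reserved for the
network module where it is part of the method). Ties in the Q criterion join
the lowest-index pair; negative branch lengths are clamped to zero with the
deficit moved to the sister branch so the pair's patristic distance is
preserved. Runs of adjacent gap columns are counted per column, not merged
into indel events: the profile is a per-site plot and event merging would
need an indel model we do not have.

Rates are relative quantities: a bin's rate is
`calibration_rate * density(bin) / mean density`, so the length-weighted
mean over bins equals the user-supplied calibration rate by construction
(checked to 1e-9 relative in the tests). No calibration value is built in —
published control-region rate estimates differ, and the package should not
launder one particular number as a default. All examples in the
documentation use 24 %/Myr, a magnitude typical of published ratite
control-region hotspot estimates, purely for illustration.

Parsimony undercounts when the same site is hit repeatedly along one
lineage. At the simulator's default divergences this biases a planted 4x
rate contrast down to a recovered ~3.3x; the recovery test bands
(±30%) account for exactly this known compression, not for tuning slack.

## Window scoring

Two groups are *separated* by a window iff no exact window string (gaps
included) occurs in both. This is deliberately string-based, not
distance-based: the downstream assay types fragments by exact sequence, so a
window that "almost" separates two populations is not useful. The composite
score is

```
discrimination x min(left flank conservation, right flank conservation)
```

with the distinct-string count as a tie-break (higher first) and then the
leftmost start. Flank conservation is the mean, over primer-length columns,
of the modal non-N symbol frequency (gaps count: a primer cannot anneal over
an indel polymorphism either). The product form is an artifact decision —
no scoring formula exists in the literature for this construction, only the
requirement that a usable snippet be both discriminating and flankable — so
the scan exposes every component column and users can re-rank. `primer_len`
defaults to 20, the middle of the 18–26 nt range of typical assay primers;
`window_len` defaults to 30 and `max_amplicon` to 70 (insert plus two
primers), the design envelope for degraded-template PCR.

## Haplotypes, networks, localities

Haplotype catalogs are per-species: the same window string in two species
keeps both labels, matching the field's per-species label series (D*, Dr*,
E*, A*, P* in moa). Catalog entries keep the *aligned* window string so the
gap-as-fifth-state distance stays meaningful; fragment matching degaps the
entry, and N in a fragment matches anything. A fragment whose Ns make it
compatible with several entries is an error (the assay must be repeated),
and a fragment matching nothing mints the next unused label — so typing is
idempotent.

Networks are minimum spanning networks: Kruskal growth over fifth-state
distances in which, at the moment two components join, *every* edge of that
minimal weight joining them is retained; the extras are flagged
`alternative` (the "possible additional linkages" of published network
figures). Edges are processed in (weight, label, label) order, so output is
deterministic. Edge steps above 1 stand for intermediate, undetected
haplotypes. The statistical-parsimony connection limit of TCS is *not*
reproduced: `parsimony_limit()` offers a Jukes–Cantor single-hit heuristic,
clearly marked experimental, and `apply_step_limit()` takes a user-fixed
cap (default: none — published moa networks include multi-step links).

Localities closer than 25 km are merged by single linkage under haversine
distance, with a strict `<` at the threshold ("less than ~25 km" is the
field convention); records without coordinates group by exact name. The
diversity ratio — distinct haplotypes over distinct occupied locality
groups — is a deliberately assumption-light index for datasets where most
locations carry one or two samples; it is invariant to duplicating records
and is not a rarefaction-corrected estimator.

## Sexing

In birds, the W chromosome is female-limited. Step 1 tests for a short
W-specific product (58 bp); positives are female. Step 2 tests W-negative
samples for a 72 bp autosomal product; negatives are "unknown" (no
amplifiable nuclear DNA — absence of W is uninformative). Step 3 retests
autosomal-positive samples with the W primers; a late positive is female,
a second negative is male. Male calls are therefore conservative: a female
whose W assay dropped out twice is miscalled male, with probability
`dropout_w^2` when the autosomal assay is reliable. The simulator exposes
the dropout parameters; the caller does not, because real assays do not
know their own dropout rate — the package records evidence strings instead.

## The synthetic world

`sim_config()` describes the world the pipeline assumes, and its defaults
are fixed, not tuned per test:

| parameter | default | why |
|---|---|---|
| `n_samples`, `seq_len` | 100, 683 | the scale of the reference control-region alignment |
| `hot_window`, `hot_factor` | (554, 583), 4 | the reported hotspot position (30 columns anchored at 554) and its ~4x rate contrast |
| `flank_len`, `flank_factor` | 20, 0.05 | conserved blocks bracketing the hotspot, emulating the TAS and F-box motifs between which the real snippet sits — the reason conserved flanking primers exist at all |
| `titv_ratio` | 10 | transition dominance typical of control-region data |
| `indel_prob` | 5e-4 | sparse single-column indels (~10% of the substitution rate) |
| `n_species` | 9 | all recognised moa species, as in the reference alignment |
| `species_depth` | 10 | stem length per species; with `background_rate` this gives ~10% interspecific p-distance and makes a typical background window separate only a minority of species pairs while the hotspot separates essentially all — the defining property of a usable snippet |
| `background_rate` | 0.0045 | ~1.5% intraspecific p-distance, typical of HVRI |
| `n_localities`, `geo_structure` | 12, 0.8 | localities laid out >25 km apart; strong but imperfect haplotype–locality fidelity |
| `frag_len_logmean`, `frag_len_logsd` | 4.0, 0.6 | lognormal fragment lengths, median ~55 nt, as in degraded bone |

Each species evolves down a stem from one ancestral sequence and then
through a Kingman coalescent (`ape::rcoal`); mutations are Poisson along
branches, indels toggle single columns to/from the gap state, and samples
are placed at their haplotype's home locality with probability
`geo_structure`. The generator deliberately omits several features of real
ancient DNA: cytosine-deamination miscoding (terminal C→T damage),
alignment error, heterogeneous background site rates, migration between
populations, and multi-column indel events. A green recovery test therefore
establishes that the *method* works in a world with the stated statistical
structure — not that any particular empirical rate or haplotype count is
reproduced. The reported per-species haplotype totals and diversity ratios
of the motivating moa dataset depend on previously published samples that
are not packaged here, and the package makes no attempt to reproduce them.

Two numerical notes on the recovery tests. First, the 30-column rate bins
tile from column 1, while the default hotspot (554–583) straddles two bins;
no single bin can exhibit the full 4x contrast, so hotspot location is
asserted as *overlap* of the hottest bin, and the 4x-recovery check plants
a bin-aligned window (541–570). Second, single-run contrast ratios carry
Poisson noise of roughly ±0.8, so recovery is asserted on means over seeds.

## Degenerate inputs and edge rules

Ragged alignments, unknown alphabet characters, duplicate sample ids, and
sequence/metadata orphans are hard errors naming the culprit — ancient-DNA
miscalls should fail loudly, not be coerced. A sample whose window is all
gaps is excluded from discrimination with a warning. A pair of sequences
with zero comparable sites is an error naming the pair. Zero total changes
make rate calibration impossible and say so. Museum-table missing values
("–" or empty) map to NA, and the one printed source-column typo
("reservior") is canonicalised on load.

## Known limitations

* The transition/transversion/indel split depends on the deterministic
  labelling tie-break; only totals are labelling-invariant.
* The NJ guide tree is a point estimate; counting changes on a fixed tree
  ignores topological uncertainty (no bootstrap is attempted).
* `parsimony_limit()` is a heuristic stand-in for statistical parsimony.
* Exact-string discrimination is sensitive to alignment quality inside the
  window; a realigned dataset can shift window coordinates.
* The sex-ratio text reduces by the male count and reports computed counts
  only; it does not attempt to match any externally reported ratio.
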