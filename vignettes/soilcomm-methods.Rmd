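---
title: "soilcomm: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{soilcomm: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcomm)
```

`soilcomm` analyses the community structure of soil fungal and bacterial
OTU tables sampled across land-use strata — the typical design contrasts
orchard management regimes (IPM vs organic, crop row vs drive row) with a
semi-natural grassland benchmark. This vignette documents the statistical
conventions the package commits to, why each was chosen where a genuine
choice existed, and what its synthetic benchmark can and cannot tell you
about real data.

## Rarefaction

Library sizes in amplicon surveys differ by orders of magnitude, and
richness-type statistics and presence-driven correlations respond to depth
rather than biology if depths are uneven. `rarefy_counts()` subsamples each
sample **without replacement** to a common depth — the multivariate
hypergeometric model, which is what "rarefaction" means in the ecological
literature (resampling *reads actually present* in the library, not a
multinomial re-draw). Conventional depths for soil data are exposed as
`default_rarefaction_depth()`: 10,000 reads for fungal ITS and 20,000 for
bacterial 16S libraries.

Two deliberate conventions:

* **Per-sample RNG streams.** Each sample's draw is seeded from
  `(seed, sample_id)` via a deterministic string hash, never from the
  global RNG sequence. Reordering columns therefore cannot change any
  sample's rarefied counts, and a fixed seed gives bit-identical output.
* **Shallow samples are an error by default.** A sample below the target
  depth usually signals an upstream QC problem; silently dropping it would
  change the design. `drop_shallow = TRUE` opts into dropping (with a
  warning), which the simulator's stress tests use.

The package rarefies **once per seed**. Averaging over repeated
rarefactions is left to the caller: the calibration tests show the single
draw is unbiased (mean rarefied count of taxon *i* equals
`depth * count_i / total`; mean richness equals the closed-form
hypergeometric expectation implemented in `expected_rarefied_richness()`),
so averaging only reduces Monte-Carlo noise, it does not move the target.

## Hill and Faith diversity

`hill_diversity()` implements orders 0 (richness) and 1
(`exp(-sum(p_i * log(p_i)))`, the effective number of equally common
taxa). Natural logarithms are used; the exponential cancels the base so
the choice is immaterial, but it is stated here for the record. ¹D ≤ ⁰D
always, with equality exactly for perfectly even communities — this
monotonicity is enforced by a property test.

`faith_pd()` is **root-inclusive**: the branch set is the union of
leaf-to-root paths of the observed taxa, the dominant convention (and the
one `picante::pd(include.root = TRUE)` uses, which serves as an
independent cross-check in the test suite — the implementation itself is a
direct tree traversal, not a wrapper). `include_root = FALSE` switches to
the minimal spanning subtree by subtracting the root-to-MRCA chain; a
single observed leaf then has PD 0. Faith's PD is presence-only by
definition; abundances beyond presence are deliberately ignored. The
provenance of the phylogeny is the caller's concern — any rooted newick
tree with branch lengths over the observed taxa is accepted, and the
simulator supplies a random bifurcating tree with exponential branch
lengths for testing.

## Co-occurrence networks

Within each stratum, `spearman_matrix()` rank-correlates all taxon pairs
across that stratum's samples (mid-ranks on ties). P-values use the
t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n-2` df — standard
and accurate at the n ≈ 90 samples per stratum these designs provide. An
exact enumeration (`spearman_p_exact()`) exists for n ≤ 8, where the
approximation is at its weakest; it is a diagnostic, not the default.
Zero-variance taxa cannot be ranked and are excluded with a warning.

`build_network()` keeps an edge iff `rho > 0.6` **and** `p < 0.05`, both
inequalities strict, positive correlations only. Strictness matters: a
correlation exactly at the threshold yields no edge, and the test suite
pins this. No multiple-testing correction is applied by default — the
convention in this literature is raw p beside a high correlation floor —
but `adjust = "BH"` is available, and raising `rho_min` or lowering
`alpha` is guaranteed (and property-tested) never to add an edge.

Topology metrics (`node_centrality()`, `topology_summary()`) follow these
conventions, each chosen to match the scale on which the keystone
thresholds below are meaningful:

* **Closeness** is *unnormalized*: `1 / sum(d(u, v))` over the vertices
  reachable from `u`, 0 for isolated nodes. On a network of a few hundred
  nodes this puts closeness in the 10⁻³–10⁻¹ range, where a cutoff like
  0.005 discriminates; size-normalized closeness would saturate above any
  such cutoff.
* **Betweenness** is unnormalized with each unordered pair counted once,
  again matching the magnitude of cutoffs like 40 or 50.
* **Diameter and average path length** are computed over connected pairs
  only; an edgeless graph reports them as `NA`, never 0.
* **Modularity** is Newman's Q of a Louvain partition at resolution 1.
  Louvain is stochastic and a single run can stall in a local optimum on
  small graphs, so the package runs 20 seeded restarts and keeps the
  best-Q partition; the seed and the membership are returned with the
  summary. On exhaustive small-graph benchmarks (all partitions of up to
  8 nodes) this reaches the global optimum.

All of degree, closeness, betweenness, diameter and path length are
verified *exactly* against an independent brute-force oracle (all-pairs
BFS plus explicit shortest-path enumeration) on hundreds of random small
graphs in the acceptance tests.

`identify_keystones()` applies joint strict thresholds — degree above,
closeness above, betweenness below — so a keystone is a highly connected
taxon embedded in a well-knit neighbourhood rather than a bridge between
clusters. The presets (`fungi`: 5 / 0.005 / 40; `bacteria`: 15 / 0.03 /
50) are the conventional cutoffs for ITS and 16S soil networks of this
size; they are parameters, not constants, and `keystone_criteria()`
accepts arbitrary values.

`per_stratum_networks()` builds each stratum's network from that
stratum's samples only, with identical settings everywhere, and refuses
strata below 4 samples (a correlation on fewer points is noise). Networks
are exported as GraphML (node attributes: centralities and keystone flag;
edge attributes: rho, p) or edge-list TSV.

## Indicator (association) analysis

The statistic is the **group-equalized point-biserial correlation r.g**:
the Pearson correlation between a taxon's abundance and the 0/1 membership
indicator of a stratum combination, computed after reweighting sites so
every stratum contributes total weight N/K. With equal stratum sizes this
*is* the plain point-biserial correlation (the test suite checks the
identity), and with unequal sizes it removes group-size bias; the plain
statistic is available with `equalize = FALSE`.

`best_combination()` searches all nonempty proper subsets of strata
(2^K − 2 combinations; 30 at the design's K = 5), breaking ties toward
smaller combinations and then lexicographically, so results are
deterministic. The permutation test shuffles whole samples and **repeats
the combination search inside every permutation** — maximizing only in
the observed data would bias p downward. p = (1 + #{perm ≥ obs}) /
(n_perm + 1), so the floor is 1/(n_perm + 1); the default 999
permutations follows the package-wide permutation convention. Calibration
is tested directly: under an exchangeable null (2,000 simulated taxa,
999 permutations, 30 sites) the empirical type-I error at α = 0.05 must
land in [0.035, 0.065].

Permutations are unrestricted whole-sample shuffles. Designs with strong
plot-level autocorrelation may want restricted permutation within blocks;
that is a caller-level extension, and the nested plot identifiers carried
in the metadata make it possible.

`association_network()` renders the significant associations as a
bipartite stratum–taxon graph and summarizes specialist fractions
(cardinality-1 combinations) and pairwise sharing between strata.

## Guild aggregation

`guild_read_counts()` uses a **single-label** guild model: each taxon
contributes to exactly one guild, `unassigned` to none, and guild totals
plus the unassigned remainder reproduce each sample's depth exactly (a
conservation law the tests enforce). Annotation sources often emit
multi-guild assignments; those must be collapsed to one label upstream,
and the reader rejects multi-label rows with an explicit message rather
than guessing a collapse rule. Statistical modelling of the guild counts
(e.g. Poisson GLMMs over the nested design) is out of scope by design;
the module stops at the response-variable table.

## The synthetic benchmark

`simulate_community()` generates the full artifact set (counts, nested
metadata, tree, guilds, ground truth) from a latent-factor model: taxon
log-abundance = base + stratum indicator effects + λ·Z_module +
√(1−λ²)·ε, softmaxed to relative abundances, with counts drawn
Dirichlet-multinomial at a log-normal depth (truncated at 1,000 reads).
The latent-factor construction was chosen over a direct multivariate
normal because it is rank-correlation-friendly and each module's
within-group latent correlation is simply λ².

The `orchard_benchmark` preset mirrors the five-stratum field design
(90 samples per stratum, 450 total; three plots per site) and plants:

* **10 hub groups in the grassland stratum** (hub + 9 partners, loading
  0.95): each group becomes a 10-clique in the grassland network, giving
  hub degree ≈ 9 and near-zero betweenness — keystones by construction.
* **One 6-taxon module per orchard stratum** (loading 0.88): a 6-clique
  has degree 5, *deliberately at but not above* the fungal keystone degree
  cutoff, so orchard strata have edges but no keystones — the sparse
  orchard vs connected grassland contrast is constructible, not assumed.
* **20 indicator taxa** (15 single-stratum, 5 two-stratum combinations)
  at log-fold-change 2 — about 2 latent SDs, strong but not degenerate.

Two calibration decisions deserve a note. The Dirichlet-multinomial
concentration defaults to 10,000 (mild overdispersion): at low
concentrations the Dirichlet noise alone attenuates within-module Spearman
correlations below the 0.6 edge threshold, i.e. the generator would not
plant what it claims to plant. Likewise, module and hub taxa draw their
base log-abundance from N(1, 0.5) against an N(0, 1) background: rank
correlation is only estimable for taxa sampled with adequate counts, and
planting "correlated" structure on near-singleton taxa would be planting
nothing. Both parameters were fixed while calibrating the generator
against its own planting contract (within-module pairwise ρ > 0.6 for
loading 0.95 at 90 samples), which is itself a property test. The
monotone counterpart — increasing overdispersion never strengthens planted
correlations — is also tested.

What the benchmark does **not** emulate: real taxonomies and phylogenetic
signal in abundances, sequencing-error and chimera processes, multi-guild
annotations, spatial autocorrelation between sites, and compositional
coupling beyond what softmax induces. Passing the recovery tests therefore
shows the pipeline's inference machinery is correct and calibrated on data
whose generating process is known; it does not certify performance on real
tables, where correlation structure is weaker and confounded.

`null_community` (no planted structure) verifies the false-positive side:
at ρ > 0.6 and p < 0.05 with 60 samples, spurious edges are essentially
absent (< 1% of pairs, and typically zero). `tiny_fixture` (12 taxa, 10
samples) exercises the full pipeline in seconds and backs the end-to-end
and determinism tests.

## The pipeline and reproducibility

`run_pipeline()` chains the stages in the field's canonical order with
two stratification presets: `management` (orchards only: IPM/organic ×
crop/drive row) and `land_use` (crop rows omitted — the conservative
comparison of drive rows against the grassland benchmark) plus `all`.
Every output directory carries a `manifest.json` with parameters, seeds,
package and R versions, and MD5 checksums of inputs and outputs; the
manifest is written with status `incomplete` before computation starts and
rewritten as `complete` at the end, so interrupted runs are always
detectable. Reruns with the same config and seed are byte-identical, and a
test asserts stage-for-stage equality between the pipeline and the
standalone functions.

## Problem sizes used in validation

The test and acceptance suites run at: 200 random graphs of ≤ 7 nodes and
30 of ≤ 8 nodes for the exact graph-metric and modularity oracles; 2,000
replicate rarefactions of a 46-read toy sample; 2,000 null taxa × 999
permutations for type-I calibration; and one full `orchard_benchmark`
simulation (200 taxa × 450 samples, five networks, 999-permutation
indicator analysis) for planted-structure recovery. These sizes make the
Monte-Carlo bands in the assertions meaningful while keeping a full run in
the low minutes on a single core.

## Known limitations

* Spearman co-occurrence on rarefied counts ignores compositionality;
  SparCC/SPIEC-EASI-style estimators are out of scope, and negative
  associations are excluded by the positive-only convention.
* The t approximation for Spearman p is asymptotic; below ~10 samples per
  stratum use the exact mode or distrust the edges (the package refuses
  < 4 outright).
* Keystone identification is threshold-based and inherits the
  arbitrariness of its cutoffs; treat the presets as conventions to be
  reported, not estimated quantities.
* The permutation test treats samples as exchangeable; nested designs
  with strong plot effects need restricted permutations, which the
  package does not yet provide.
* Guild aggregation trusts the annotation table; no confidence filtering
  is applied.
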