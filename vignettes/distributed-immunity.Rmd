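---
title: "Quantifying distributed immunity in CRISPR host-phage communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying distributed immunity in CRISPR host-phage communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdi)
```

## The problem

Microbes with an active CRISPR-Cas system acquire heritable, sequence-specific
immunity against their phages by copying short stretches of phage genome
(protospacers) into a genomic array of spacers. Because a phage genome offers
many acquirable protospacers, different cells in one population can become
immune to the *same* phage through *different* spacers. We call this
many-genotypes-to-one-phenotype configuration **distributed immunity**: the
population is phenotypically uniform (everyone is immune) but genetically
diverse, and no single phage escape mutation can re-open the whole host
population. This package provides

1. metrics that quantify distributed immunity in a strain-resolved community
   snapshot (PDI, IDI, HVI),
2. a stochastic eco-evolutionary simulator of spacer acquisition and phage
   escape on Lotka-Volterra community dynamics,
3. replicate-sweep analysis tools (final-window medians, host-peak detection,
   stability/extinction bookkeeping, rank correlations, linear-vs-quadratic
   model choice, subsampled bin comparisons), and
4. an empirical pipeline that estimates the same metrics from sequencing
   products: spacer-per-read tables for the host side and escape-SNP
   frequencies for the phage side.

## The metrics

A *community* holds host strains (ordered spacer arrays `G_i`, proportions
`N_i`) and viral strains (protospacer vectors `H_k`, proportions `V_k`).
Matching is identifier equality: a spacer matches a protospacer if and only
if they carry the same allele identifier, because a spacer is a copy of the
protospacer it was acquired from. Sequence-level matching, PAM recognition
and partial (seed) matching are deliberately out of scope.

**Population-wide distributed immunity** scans every triplet of two host
strains and one viral strain. A triplet contributes if and only if the two
hosts match the virus at *different* protospacer positions; immunity through
one shared protospacer is not distributed, since a single escape mutation
voids it in both hosts. Contributions are abundance-weighted and scaled by
the evenness factor
`sigma(N_i, N_j) = 1 - |N_i - N_j| / max(N_i, N_j)`,
so a pair of equally abundant strains counts fully and a pair dominated by
one strain counts little:

\[
\mathrm{PDI} = \sum_{i \ne j} \sum_k N_i N_j V_k\,
  \sigma(N_i, N_j)\, D(G_i, G_j, H_k),
\]

where `D` is the 0/1 distributed-pair indicator and the sum runs over
*ordered* host pairs. The ordered-pair convention is deliberate: with `n`
equally abundant strains, all immune to all viruses via distinct
protospacers, it yields exactly the ceiling `1 - 1/n` (an unordered sum
would halve it). `max_pdi()` evaluates that ceiling for any abundance
profile — viral proportions drop out of it because they sum to one.

Two details are worth making explicit:

* `D` is an indicator, not a count. The count variant (how many distinct
  position pairs distribute a host pair) is exposed as
  `distributed_count()` but unused: a triplet either survives a
  single-protospacer escape or it does not.
* The evenness factor divides by the *pair* maximum. A variant dividing by
  the population-wide maximum proportion is available through
  `sigma = "population"` in every metric entry point; it never down-weights
  a pair relative to the default, and it is the designated sensitivity knob
  if a published value computed under the other convention needs to be
  reproduced.

**Individual distributed immunity** is the abundance-weighted mean number of
distinct protospacers of a viral strain matched by a host,
`IDI = sum_ik N_i V_k R(G_i, H_k)`. Values above one mean the average host
targets the viral population at several genomic positions, the within-host
analogue of PDI. `R` counts matched *positions*: if one allele occupies two
positions of an empirical protospacer vector, a single spacer matching it
counts twice, consistent with "distinct attack points on this strain".

**HVI** is the abundance-weighted proportion of host-virus encounters with
no matching spacer, `sum_ik N_i V_k (1 - M(G_i, H_k))` — the fraction of the
host population that viruses can infect. Full susceptibility gives 1, full
immunity 0.

Strains are never abundance-filtered before metric evaluation; display
thresholds in figures are presentation choices, not analysis ones. Viral
strains with no matches still enter every sum (contributing zero), keeping
the metrics continuous in composition.

```{r metrics-example}
comm <- make_community(n_hosts = 4, n_viruses = 2)
di_metrics(comm) # fully distributed, equal abundances: pdi = 1 - 1/4
```

## The simulator

`simulate_coevolution()` implements a hybrid scheme: deterministic ecology,
stochastic evolution.

**Ecology.** With `m_ik` the match indicator and
`s_ik = (1 - m_ik) + m_ik f` the effective susceptibility (immunity fails
with a small probability `f`), strain densities follow

\[
\frac{dN_i}{dt} = r N_i \Big(1 - \frac{\sum_j N_j}{K}\Big)
  - (1 - q)\,\varphi N_i \sum_k V_k s_{ik}, \qquad
\frac{dV_k}{dt} = \beta (1 - q)\, \varphi V_k \sum_i N_i s_{ik}
  - \varphi V_k \sum_i N_i - m_v V_k .
\]

Every adsorption removes the virion, whatever its outcome; only adsorptions
onto vulnerable hosts that do not trigger spacer acquisition lyse the cell
and release a burst of `beta` new virions. Integration is fixed-step RK4
with `dt = 0.05` h. One hour equals the inverse host growth rate, i.e. a
typical host generation.

**Evolution.** After each step, strain-creating events are drawn from
Poisson thinning of the corresponding fluxes (the culture volume is fixed at
1 mL, so densities double as expected individual counts):

* *Spacer acquisition* at total rate `q phi sumN sumV`: a host copies a
  uniformly chosen protospacer allele of an attacking virus to the leader
  end of its locus; when the locus already holds `S` spacers the trailer-end
  spacer is dropped (leader-proximal acquisition with first-in-first-out
  loss). Acquiring an allele already present is a no-op, and an acquisition
  reproducing an existing strain's locus merges into it. One founder
  individual moves from parent to product.
* *Escape mutation* at rate `mu P beta (1-q) phi V_k sum_i N_i s_ik` per
  viral strain: one uniformly chosen protospacer position is replaced by a
  globally novel allele (infinite-alleles model, no back mutation; double
  mutants are `O(mu^2)` and ignored). The mutant is seeded with one founder
  virion taken from the parent.

Strains falling below the extinction cutoff of 0.1 individuals per mL are
pruned; identifiers are never reused, so a pruned genotype that re-evolves
is a new strain. A run ends at `t_end` or when a side's total density falls
below the cutoff (viral or host extinction).

### Parameters and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `S` | max spacers per locus | 10 | — |
| `P` | protospacers per phage genome | 10 | — |
| `q` | acquisition probability per adsorption | 1e-5 | — |
| `mu` | escape probability per protospacer per virion | 5e-7 | — |
| `r` | host growth rate | 1 | 1/h |
| `K` | carrying capacity | 3.158e5 | cells/mL |
| `phi` | adsorption rate constant | 1e-7 | mL/h |
| `beta` | burst size | 50 | virions |
| `m_v` | free-virion decay | 0.1 | 1/h |
| `f` | immunity failure probability | 1e-5 | — |
| `dt` | RK4 step | 0.05 | h |
| `cutoff` | extinction density | 0.1 | 1/mL |

`S`, `P`, `q` and `mu` are the biological knobs the sweep analyses vary.
The ecological constants are standard phage-host modelling choices: an
adsorption constant of 1e-7 mL/h, burst sizes of tens, and decay around
0.1/h are textbook ranges for lytic phage on fast-growing hosts. `K` is
chosen so that the stability threshold of 3e5 cells/mL used by the analysis
layer sits at approximately 95% of carrying capacity (3e5 / 0.95). Initial
densities default to one naive host strain (empty locus) at 1e5 cells/mL
and one ancestral viral strain at 1e6 virions/mL. All of these are
`sim_params()` fields, so none is baked in.

### Numerical choices

* RK4 at `dt = 0.05` resolves the fastest default rate (host growth, 1/h)
  with 20 steps per characteristic time; in the decoupled limit
  (`phi = 0`) the recorded virion decay matches the closed form to better
  than 1e-6 relative error, which is the accuracy the test suite enforces.
* Negative densities produced by an overly coarse step are clipped to zero
  and counted; the count is surfaced as a warning, never silently ignored.
* Event sampling draws one Poisson count from the summed rate and then
  assigns events categorically — distributionally identical to independent
  per-pair draws, and much cheaper when thousands of viral strains are
  alive.
* With a fixed seed the trajectory is bit-reproducible; replicate seeds in
  `run_sweep()` are derived deterministically from the sweep seed.
* The susceptibility matrix is maintained incrementally in compiled code;
  per-snapshot metric evaluation uses an inverted spacer-to-host index so
  that communities with thousands of viral strains remain tractable.

## Sweep analysis

The analysis layer mirrors how replicate simulations are condensed in the
distributed-immunity literature:

* **Final-window medians** (`window_median()`, default last 500 h of the
  horizon) summarize each replicate after transients; replicates that end
  early have no defined window and are flagged `NA`.
* **Host peaks** (`find_host_peaks()`): strict local maxima of total host
  density, filtered by topographic prominence (default 5% of `K`) and a
  10 h minimum separation, with ties resolved toward the earlier peak.
  "Peak" is not otherwise defined operationally in this literature, so the
  prominence and separation defaults are package choices, exposed as
  arguments.
* **Stability** (`is_stable()`): the host population strictly exceeds
  3e5 cells/mL (about 95% of `K`) over a stretch of consecutive recorded
  points spanning at least 100 h. The boundary convention is strict on
  density and inclusive on the span.
* **Outcome bookkeeping** (`classify_outcomes()`): `complete` runs reach
  the horizon with every locus full throughout the final window;
  `viral_extinction` runs lose their phage; `unfilled_locus` runs reach the
  horizon without a full locus. Runs whose locus never filled — including
  extinctions that struck pre-fill — form the exclusion set for population
  averages.
* **Statistics**: Spearman rank correlations between replicate summaries;
  one-way ANOVA fitted as a linear model (valid for unbalanced group
  sizes) with Holm-adjusted pairwise t tests (the adjustment choice is the
  package's; unadjusted comparisons are recoverable from the fit);
  linear-vs-quadratic model choice by `AIC = n log(RSS/n) + 2k`, which
  differs from R's `AIC()` only by an additive constant that cancels in
  the comparison; and `subsample_compare()`, which draws repeated
  subsamples, bins them by PDI (width 0.1) or IDI (width 0.6), and
  compares per-bin stability and extinction proportions.

Replicates are binned by DI measured at all recorded time points of the
final window (its median); binning by peak values is available by
summarizing the `peaks` table instead — the qualitative conclusions do not
depend on the choice.

## The empirical pipeline

Estimating distributed immunity from a sequenced co-culture needs
strain-resolved tables for both sides.

**Host side.** Reads covering the CRISPR locus are reduced to a
spacer-per-read table. Reads are usable when they carry at least two novel
spacers, or one novel spacer anchored by ancestral spacers or by visible
leader sequence (`filter_reads()`). `reconstruct_loci()` then groups reads
by spacer content; a read truncated before the trailer inherits the
trailer-end spacers of the complete group whose leader-end content extends
it — "extends" operationalized as: the read's spacer list is a prefix of
the group's list, the conservative reading of similar leader-end content.
Best-supported candidate wins; residual ties break deterministically toward
the lexicographically smallest completed locus (with a warning). Reads
matching no group are completed with the spacers fixed in the population.
Strain proportions are read fractions. Merging truncated reads into
existing types prevents truncation artifacts from inflating apparent strain
diversity — and thereby PDI, which grows with the number of even,
distinctly-matching strains. (Merging does not *bound* PDI from above in
every configuration: splitting off rare duplicate types can also lower the
evenness weights. The test suite documents both directions.)

Reads truncated at the *leader* end cannot be anchored this way and are
kept as-is; the synthetic read generator therefore defaults to trailer-end
truncation, which is also the common failure mode when loci are sequenced
inward from the leader.

**Phage side.** Escape SNPs in protospacers or PAMs are taken as
independent events: `viral_strains_from_snps()` enumerates every SNP
combination as a strain with proportion given by the product of carried-SNP
frequencies and absent-SNP complements (fixed SNPs are carried by all). A
SNP removes its protospacer from the match set of strains carrying it; PAM
and protospacer mutations are treated identically, since both abolish
interference.

`estimate_di()` translates host spacers to the protospacers they target (a
spacer-to-protospacer map is the third input; unannotated spacers are
matchless and reported) and evaluates the same metrics as for simulated
communities.

```{r empirical-example}
extdata <- system.file("extdata", package = "crisprdi")
reads <- filter_reads(read_reads_tsv(
  file.path(extdata, "synthetic_coculture_reads.tsv")))
hosts <- reconstruct_loci(reads, fixed_spacers = 1:3)
viruses <- viral_strains_from_snps(read_snps_tsv(
  file.path(extdata, "synthetic_phage_snps.tsv")))
estimate_di(hosts, viruses,
            read_spacer_map_tsv(file.path(extdata,
                                          "synthetic_spacer_map.tsv")))
```

The bundled tables are *synthetic*: they emulate the structure of a
one-week host-phage co-culture experiment (partially truncated reads over
evolved loci; one fixed and two segregating escape SNPs) so that the
pipeline is demonstrable and testable offline. They are not derived from
any sequencing archive.

## What the synthetic generators do and do not emulate

`make_community()` produces the canonical immunity structures (fully
distributed, shared-spacer, clonal, mixed) with equal or Dirichlet
abundances — the configurations that pin the metrics' exact values and
exercise the evenness factor. `make_reads()` samples reads from true loci
with per-end truncation and novelty flags. Neither emulates sequencing
error, chimeric reads, within-locus deletions, or abundance estimation bias
from locus-length-dependent coverage; conclusions from passing tests
therefore concern the reconstruction and metric algebra, not those
upstream artifacts. Likewise the simulator omits spatial structure,
multiple loci per host, CRISPR-lacking competitors and latent-period
modelling.

## Problem sizes used by the checks

The packaged checks run the simulator at a reduced scale chosen as a
sensible desk-scale experiment: 20 replicates per condition and a 3000 h
horizon for the directional sweep comparisons (protospacer number 5 vs 20,
mutation rate 1e-7 vs 1e-6), with final-500-h medians; the acceptance
script reruns six sweep arms at 10 replicates each. Published full-scale
analyses of this model family average hundreds of replicates over 10000 h
horizons, so quantitative sweep statistics at the reduced scale are
order-of-magnitude reproductions, while the metric algebra, the simulator
limits and the reconstruction round trips are exact at any scale.

## Known limitations

* The ecological constants (`phi`, `beta`, `m_v`, `f`, initial densities)
  are standard-range defaults, not fitted values; sweep statistics shift
  quantitatively with them, though the directional responses to `P` and
  `mu` are robust in our checks.
* Viral strain counts can reach the thousands under the defaults; memory
  for full per-strain recording grows accordingly (about 100 MB per
  10000 h trajectory at that diversity). `record_every` thins it.
* Acquisition copying a protospacer already present in the locus is a
  no-op rather than a locus reordering; the alternative would make strain
  identity depend on acquisition order in ways the data cannot resolve.
* The empirical reconstruction assumes novel spacers accumulate at the
  leader end and that trailer content is shared when leader content
  matches; populations with internal deletions violate this and will be
  merged too aggressively.
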