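# crisprdi

Distributed immunity in CRISPR host–phage communities: metrics, an
eco-evolutionary simulator, sweep analytics, and an empirical estimation
pipeline.

## The problem

When a microbial population defends itself with CRISPR-Cas, different cells
can become immune to the *same* phage through *different* spacers, because a
phage genome offers many acquirable protospacers. The population is then
phenotypically uniform but genetically diverse — *distributed immunity* — and
no single phage escape mutation re-opens the whole host population. This
package quantifies that configuration and simulates the coevolutionary
dynamics that produce it. It is aimed at microbial ecologists and modellers
working with strain-resolved host/phage community data (simulated or
sequenced).

## The metrics

For host strains with spacer sets `G_i` and proportions `N_i`, and viral
strains with protospacer vectors `H_k` and proportions `V_k`
(spacer–protospacer matching is identifier equality):

- **PDI** (population-wide distributed immunity) sums over ordered host
  pairs and viruses
  `PDI = Σ_{i≠j} Σ_k N_i N_j V_k σ(N_i,N_j) D(G_i,G_j,H_k)`,
  where `D = 1` iff the two hosts match the virus at *different*
  protospacers and `σ(N_i,N_j) = 1 − |N_i−N_j|/max(N_i,N_j)` is an evenness
  weight. With `n` equal, fully distributed strains, `PDI = 1 − 1/n`
  (its ceiling, `max_pdi()`).
- **IDI** (individual distributed immunity) is the abundance-weighted mean
  number of distinct protospacer matches per host–virus pair,
  `Σ_ik N_i V_k R(G_i,H_k)`.
- **HVI** is the abundance-weighted proportion of host–virus encounters
  with no match — the hosts that viruses can infect.

The simulator couples Lotka–Volterra ecology (logistic hosts, adsorption,
bursts, virion decay, RK4 integration) with stochastic leader-end spacer
acquisition and infinite-alleles protospacer escape, strain-level pruning
at a 0.1/mL extinction cutoff, and full per-hour strain recording.

## Worked example

Metrics on a designed community, then a full empirical estimate from the
bundled synthetic sequencing tables:

```r
library(crisprdi)

di_metrics(make_community(n_hosts = 4, n_viruses = 2))
#> # A tibble: 1 × 6
#>     pdi   idi   hvi max_pdi n_host_strains n_viral_strains
#>   <dbl> <dbl> <dbl>   <dbl>          <int>           <int>
#> 1  0.75     1     0    0.75              4               2
```

Four equally abundant host strains, each immune to both viruses via its own
protospacer: PDI sits at its ceiling `1 − 1/4`; every host carries exactly
one matching spacer (IDI = 1); no encounter is susceptible (HVI = 0).

```r
extdata <- system.file("extdata", package = "crisprdi")
reads   <- filter_reads(read_reads_tsv(file.path(extdata, "synthetic_coculture_reads.tsv")))
hosts   <- reconstruct_loci(reads, fixed_spacers = 1:3)
viruses <- viral_strains_from_snps(read_snps_tsv(file.path(extdata, "synthetic_phage_snps.tsv")))
estimate_di(hosts, viruses, read_spacer_map_tsv(file.path(extdata, "synthetic_spacer_map.tsv")))
#> spacer(s) without protospacer annotation treated as matchless: 1, 2, 3
#> # A tibble: 1 × 6
#>     pdi   idi   hvi max_pdi n_host_strains n_viral_strains
#>   <dbl> <dbl> <dbl>   <dbl>          <int>           <int>
#> 1 0.147 0.866 0.222   0.313              5               4
```

The reconstruction groups 80 partially truncated reads into 5 host strains;
the three escape SNPs (one fixed, two segregating) expand to 4 phage
strains by independence. The host population realizes PDI 0.147 of an
attainable 0.313 given its (uneven) strain abundances; the average host
matches the phage population 0.87 times; 22% of encounters find no
matching spacer. Ancestral spacers target nothing in this phage and are
reported as matchless.

Simulation and sweeps:

```r
traj <- simulate_coevolution(sim_params(P = 20, t_end = 3000), seed = 1)
glance(traj)                      # outcome, final densities, event counts
trajectory_metrics(traj) |> plot_di_series()
sw <- run_sweep(tibble::tibble(P = c(5, 20)), replicates = 20,
                base_params = sim_params(t_end = 3000), seed = 1)
classify_outcomes(sw)
```

A thin CLI over the same functions is installed at
`system.file("scripts", "crispr-di", package = "crisprdi")` with
subcommands `simulate`, `sweep`, `metrics`, `analyze`, `empirical`,
`fixtures`.

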