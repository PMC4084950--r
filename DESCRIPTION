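Package: crisprdi
Title: Distributed Immunity in CRISPR Host-Phage Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies distributed immunity in microbial communities with
    CRISPR-Cas adaptive immunity. Provides the population-wide (PDI) and
    individual (IDI) distributed-immunity metrics and the
    hosts-viruses-can-infect (HVI) susceptibility index for strain-resolved
    host and phage abundance tables; a hybrid deterministic/stochastic
    eco-evolutionary simulator of spacer acquisition and protospacer escape
    on Lotka-Volterra community dynamics; replicate-sweep analysis tools
    (final-window medians, host-peak detection, stability and extinction
    classification, rank correlations, linear-vs-quadratic model choice);
    and an empirical pipeline that reconstructs host CRISPR arrays from
    spacer-per-read tables and phage strain mixtures from SNP frequencies
    to estimate distributed immunity in sequenced communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
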