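# Independent brute-force oracles used to validate the optimized metric
# kernel, plus random community generators for property-style tests.

# triple-loop evaluation of PDI/IDI/HVI/max-PDI straight from the
# definitions, using only base R
oracle_metrics <- function(comm, sigma = "pairwise") {
  h <- comm$hosts
  v <- comm$viruses
  nh <- nrow(h)
  nv <- nrow(v)
  n_max <- max(h$proportion)
  sig <- function(ni, nj) {
    d <- if (sigma == "population") n_max else max(ni, nj)
    1 - abs(ni - nj) / d
  }
  pdi <- 0
  idi <- 0
  hvi <- 0
  mp <- 0
  for (i in seq_len(nh)) {
    for (k in seq_len(nv)) {
      mc <- sum(v$protospacers[[k]] %in% h$spacers[[i]])
      idi <- idi + h$proportion[i] * v$proportion[k] * mc
      if (mc == 0) hvi <- hvi + h$proportion[i] * v$proportion[k]
    }
    for (j in seq_len(nh)) {
      if (i == j) next
      mp <- mp + h$proportion[i] * h$proportion[j] *
        sig(h$proportion[i], h$proportion[j])
      for (k in seq_len(nv)) {
        hk <- v$protospacers[[k]]
        mi <- which(hk %in% h$spacers[[i]])
        mj <- which(hk %in% h$spacers[[j]])
        dist_ok <- length(mi) > 0 && length(mj) > 0 &&
          !(length(mi) == 1 && length(mj) == 1 && mi == mj)
        if (dist_ok) {
          pdi <- pdi + h$proportion[i] * h$proportion[j] *
            v$proportion[k] * sig(h$proportion[i], h$proportion[j])
        }
      }
    }
  }
  c(pdi = pdi, idi = idi, hvi = hvi, max_pdi = mp)
}

# random community with arbitrary spacer/protospacer overlap
random_community <- function(seed, max_hosts = 6, max_viruses = 5,
                             n_alleles = 8, max_spacers = 4, P = 5) {
  set.seed(seed)
  nh <- sample(2:max_hosts, 1)
  nv <- sample(1:max_viruses, 1)
  hosts <- tibble::tibble(
    strain_id = seq_len(nh),
    spacers = lapply(seq_len(nh), function(i) {
      sample.int(n_alleles, sample(0:max_spacers, 1))
    }),
    abundance = runif(nh, 0.05, 1)
  )
  viruses <- tibble::tibble(
    strain_id = seq_len(nv),
    protospacers = lapply(seq_len(nv), function(k) {
      sample.int(n_alleles, P, replace = TRUE)
    }),
    abundance = runif(nv, 0.05, 1)
  )
  as_community(hosts, viruses)
}
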