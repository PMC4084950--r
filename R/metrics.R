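#' Distributed-immunity metrics for a community
#'
#' Computes the population-wide distributed immunity (PDI), individual
#' distributed immunity (IDI), the proportion of hosts that viruses can
#' infect (HVI), and the attainable PDI ceiling (`max_pdi`) for one
#' community snapshot.
#'
#' PDI sums, over all ordered pairs of distinct host strains `i != j` and
#' every viral strain `k`, the triplet contribution
#' `N_i N_j V_k sigma(N_i, N_j) D(G_i, G_j, H_k)`, where `D` is
#' [distributed_indicator()] (1 when the two hosts match the virus at
#' different protospacers) and `sigma(N_i, N_j) = 1 - |N_i - N_j| /
#' max(N_i, N_j)` is the evenness weight ([evenness_factor()]). With `n`
#' equally abundant host strains all immune to all viruses via distinct
#' protospacers, PDI attains its ceiling `1 - 1/n`.
#'
#' IDI is the abundance-weighted average number of distinct protospacer
#' matches per host-virus pair, `sum_ik N_i V_k R(G_i, H_k)`; values above
#' 1 mean the average host targets the viral population at several
#' genomic positions. HVI is `sum_ik N_i V_k (1 - M(G_i, H_k))`, the
#' abundance-weighted proportion of host-virus encounters with no matching
#' spacer (fully susceptible hosts give HVI = 1).
#'
#' @param comm A [community()].
#' @param sigma Evenness-weight variant: `"pairwise"` (default) scales the
#'   abundance difference of a host pair by the pair maximum; `"population"`
#'   scales it by the maximum proportion of any host strain in the
#'   population. The pairwise form is the primary definition; the
#'   population form is a sensitivity variant.
#' @return A one-row tibble with columns `pdi`, `idi`, `hvi`, `max_pdi`,
#'   `n_host_strains`, `n_viral_strains` (and `time` when the community
#'   carries one).
#' @examples
#' comm <- make_community(n_hosts = 4, n_viruses = 2,
#'                        structure = "fully_distributed")
#' di_metrics(comm) # pdi = 1 - 1/4
#' @seealso [pdi()], [idi()], [hvi()], [max_pdi()], [trajectory_metrics()]
#' @export
di_metrics <- function(comm, sigma = c("pairwise", "population")) {
  stopifnot(inherits(comm, "crispr_community"))
  sigma <- match.arg(sigma)
  v <- di_metrics_cpp(comm$hosts$spacers, comm$hosts$proportion,
                      comm$viruses$protospacers, comm$viruses$proportion,
                      identical(sigma, "population"))
  out <- tibble(
    pdi = v[["pdi"]], idi = v[["idi"]], hvi = v[["hvi"]],
    max_pdi = v[["max_pdi"]],
    n_host_strains = nrow(comm$hosts),
    n_viral_strains = nrow(comm$viruses)
  )
  if (!is.null(comm$time)) out <- add_column(out, time = comm$time,
                                             .before = 1)
  out
}

#' @rdname di_metrics
#' @export
pdi <- function(comm, sigma = c("pairwise", "population")) {
  di_metrics(comm, sigma)$pdi
}

#' @rdname di_metrics
#' @export
idi <- function(comm) di_metrics(comm)$idi

#' @rdname di_metrics
#' @export
hvi <- function(comm) di_metrics(comm)$hvi

#' Evenness weight of a host strain pair
#'
#' The factor `1 - |N_i - N_j| / max(N_i, N_j)` that scales a triplet's
#' contribution to PDI: 1 for equally abundant strains, approaching 0 as
#' one strain dominates the pair. The `"population"` variant divides the
#' difference by the maximum host proportion in the whole community
#' instead of the pair maximum.
#'
#' @param ni,nj Positive host strain proportions (vectorized).
#' @param n_max Population maximum proportion, only used by
#'   `sigma = "population"`.
#' @param sigma Variant, as in [di_metrics()].
#' @return Numeric in `[0, 1]` (pairwise variant).
#' @examples
#' evenness_factor(0.6, 0.4) # 2/3
#' @export
evenness_factor <- function(ni, nj, sigma = c("pairwise", "population"),
                            n_max = NULL) {
  sigma <- match.arg(sigma)
  if (any(ni <= 0) || any(nj <= 0)) {
    abort("proportions must be positive")
  }
  denom <- if (sigma == "population") {
    if (is.null(n_max)) abort("n_max is required for sigma = \"population\"")
    n_max
  } else {
    pmax(ni, nj)
  }
  1 - abs(ni - nj) / denom
}

#' Maximum attainable PDI for a host abundance profile
#'
#' The PDI ceiling is reached when every host strain is immune to every
#' viral strain through distinct protospacers, so that every triplet
#' contributes; viral proportions then sum out and the ceiling depends only
#' on the host abundance profile:
#' `sum over ordered pairs i != j of N_i N_j sigma(N_i, N_j)`.
#' For `n` equally abundant strains this equals `1 - 1/n`.
#'
#' @param proportions Positive host strain proportions summing to 1.
#' @inheritParams evenness_factor
#' @return A number in `[0, 1)`.
#' @examples
#' max_pdi(rep(0.1, 10)) # 0.9
#' @export
max_pdi <- function(proportions, sigma = c("pairwise", "population")) {
  sigma <- match.arg(sigma)
  if (any(proportions <= 0)) abort("proportions must be positive")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  n <- length(proportions)
  if (n < 2) return(0)
  nm <- max(proportions)
  acc <- 0
  for (i in seq_len(n - 1)) {
    nj <- proportions[(i + 1):n]
    sig <- evenness_factor(rep(proportions[i], length(nj)), nj,
                           sigma = sigma, n_max = nm)
    acc <- acc + sum(proportions[i] * nj * sig)
  }
  2 * acc
}
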