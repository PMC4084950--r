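#' Generate a synthetic community with a prescribed immunity structure
#'
#' Deterministic, seeded community generators covering the canonical
#' immunity configurations: `"fully_distributed"` (every host carries a
#' unique spacer matching a distinct protospacer of every virus — the
#' maximum-PDI configuration), `"shared_spacer"` (every host is immune via
#' the same single spacer, so PDI is 0 despite full immunity), `"clonal"`
#' (a single host strain) and `"mixed"` (random spacer draws, some
#' matchless).
#'
#' @param n_hosts,n_viruses Strain counts.
#' @param S,P Maximum spacers per host and protospacers per virus.
#' @param structure Immunity structure, see above.
#' @param abundance `"equal"` or `"dirichlet"` (symmetric, concentration
#'   `alpha`) strain abundances, applied to both sides.
#' @param alpha Dirichlet concentration parameter.
#' @param host_matches For `structure = "clonal"`: whether the single host
#'   carries a matching spacer.
#' @param seed Optional integer seed.
#' @return A [community()].
#' @examples
#' pdi(make_community(n_hosts = 4, n_viruses = 2)) # 1 - 1/4
#' pdi(make_community(n_hosts = 4, structure = "shared_spacer")) # 0
#' @export
make_community <- function(n_hosts, n_viruses = 1,
                           S = 10, P = max(10, n_hosts),
                           structure = c("fully_distributed",
                                         "shared_spacer", "clonal",
                                         "mixed"),
                           abundance = c("equal", "dirichlet"),
                           alpha = 1, host_matches = TRUE, seed = NULL) {
  structure <- match.arg(structure)
  abundance <- match.arg(abundance)
  if (!is.null(seed)) set.seed(seed)
  if (structure == "clonal") n_hosts <- 1L
  if (structure == "fully_distributed" && n_hosts > P) {
    abort("fully_distributed needs n_hosts <= P distinct protospacers")
  }
  props <- function(n) {
    if (abundance == "equal") return(rep(1 / n, n))
    g <- stats::rgamma(n, shape = alpha)
    while (any(g == 0)) g <- stats::rgamma(n, shape = alpha)
    g / sum(g)
  }
  base_protos <- lapply(seq_len(n_viruses), function(k) seq_len(P))
  host_spacers <- switch(
    structure,
    fully_distributed = lapply(seq_len(n_hosts), function(i) i),
    shared_spacer = rep(list(1L), n_hosts),
    clonal = list(if (host_matches) 1L else integer()),
    mixed = lapply(seq_len(n_hosts), function(i) {
      k <- sample.int(min(3L, S), 1)
      sample.int(P + 2L, k) # alleles P+1, P+2 match no virus
    })
  )
  if (structure == "mixed") {
    base_protos <- lapply(seq_len(n_viruses), function(k) {
      sample.int(P, P, replace = TRUE)
    })
  }
  community(
    hosts = tibble(strain_id = seq_len(n_hosts),
                   spacers = lapply(host_spacers, as.integer),
                   proportion = props(n_hosts)),
    viruses = tibble(strain_id = seq_len(n_viruses),
                     protospacers = lapply(base_protos, as.integer),
                     proportion = props(n_viruses))
  )
}

#' Generate synthetic spacer-bearing reads from true loci
#'
#' Emulates shotgun reads over CRISPR loci: each read samples a host
#' strain proportional to abundance and shows its spacer array, possibly
#' truncated at the leader and/or trailer end (at least one spacer always
#' remains visible). Truncation at an end hides that end's flanking
#' sequence and a uniform number of its spacers.
#'
#' @param loci True host strains: a tibble with `strain_id`, `spacers`
#'   (list-column, leader first) and `proportion`.
#' @param depth Number of reads.
#' @param truncation Probability that a read is truncated at the trailer
#'   end; `truncation_leader` likewise for the leader end (default 0,
#'   since leader-truncated reads cannot be anchored by the
#'   reconstruction).
#' @param truncation_leader Leader-end truncation probability.
#' @param ancestral Integer identifiers of ancestral spacers (everything
#'   else is flagged novel).
#' @param seed Optional integer seed.
#' @return A read table suitable for [filter_reads()] /
#'   [reconstruct_loci()], with a `true_strain` column recording the
#'   ground truth.
#' @examples
#' loci <- tibble::tibble(strain_id = 1:2,
#'                        spacers = list(c(101L, 1L), c(102L, 1L)),
#'                        proportion = c(0.5, 0.5))
#' make_reads(loci, depth = 20, truncation = 0, ancestral = 1L, seed = 1)
#' @export
make_reads <- function(loci, depth, truncation = 0,
                       truncation_leader = 0, ancestral = integer(),
                       seed = NULL) {
  loci <- as_tibble(loci)
  stopifnot(depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  ancestral <- as.integer(ancestral)
  picks <- sample.int(nrow(loci), depth, replace = TRUE,
                      prob = loci$proportion)
  rows <- lapply(seq_len(depth), function(rix) {
    sp <- as.integer(loci$spacers[[picks[rix]]])
    has_leader <- TRUE
    has_trailer <- TRUE
    if (length(sp) > 1 && runif(1) < truncation_leader) {
      k <- sample.int(length(sp) - 1L, 1)
      sp <- sp[-seq_len(k)]
      has_leader <- FALSE
    }
    if (length(sp) > 1 && runif(1) < truncation) {
      k <- sample.int(length(sp) - 1L, 1)
      sp <- sp[seq_len(length(sp) - k)]
      has_trailer <- FALSE
    }
    tibble(read_id = rix, spacers = list(sp), has_leader = has_leader,
           has_trailer = has_trailer,
           novel = list(!(sp %in% ancestral)),
           true_strain = loci$strain_id[picks[rix]])
  })
  dplyr::bind_rows(rows)
}
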