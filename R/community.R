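#' Build a host-virus community snapshot
#'
#' A community is the unit on which all distributed-immunity metrics are
#' evaluated: a set of host strains, each with an ordered CRISPR spacer
#' array (leader end first) and a population proportion, and a set of viral
#' strains, each with a protospacer allele vector and a proportion. Spacers
#' and protospacers share an integer identifier space; a spacer matches a
#' protospacer if and only if their identifiers are equal.
#'
#' @param hosts A data frame with columns `strain_id`, `spacers` (a
#'   list-column of integer vectors, leader end first) and `proportion`
#'   (and optionally `density` in cells/mL).
#' @param viruses A data frame with columns `strain_id`, `protospacers`
#'   (a list-column of integer vectors) and `proportion` (optionally
#'   `density` in virions/mL).
#' @param time Optional time point in hours.
#'
#' @return An object of class `crispr_community`: a list with tibbles
#'   `hosts` and `viruses` and the `time` attribute.
#'
#' @details Proportions must sum to 1 (within 1e-9) on each side, strain
#' identifiers must be unique within a side, and a host locus may not carry
#' duplicate spacer identifiers. Use [as_community()] to build a community
#' from raw (unnormalized) abundances.
#'
#' @examples
#' comm <- community(
#'   hosts = tibble::tibble(strain_id = 1:2, spacers = list(1L, 2L),
#'                          proportion = c(0.5, 0.5)),
#'   viruses = tibble::tibble(strain_id = 1L, protospacers = list(1:3),
#'                            proportion = 1)
#' )
#' di_metrics(comm)
#' @export
community <- function(hosts, viruses, time = NULL) {
  hosts <- as_side_tbl(hosts, "spacers", "host")
  viruses <- as_side_tbl(viruses, "protospacers", "virus")
  check_proportions(hosts$proportion, "host")
  check_proportions(viruses$proportion, "virus")
  for (g in hosts$spacers) {
    if (anyDuplicated(g)) {
      abort("duplicate spacer identifiers within one host locus")
    }
  }
  structure(list(hosts = hosts, viruses = viruses, time = time),
            class = "crispr_community")
}

as_side_tbl <- function(x, allele_col, side) {
  x <- as_tibble(x)
  needed <- c("strain_id", allele_col, "proportion")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0(side, " table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) abort(paste0("empty population: no ", side, " strains"))
  if (anyDuplicated(x$strain_id)) {
    abort(paste0("duplicate ", side, " strain_id"))
  }
  x[[allele_col]] <- lapply(x[[allele_col]], function(v) {
    as.integer(v[!is.na(v)])
  })
  x
}

check_proportions <- function(p, side) {
  if (any(p < 0) || any(p > 1)) {
    abort(paste0(side, " proportions must lie in [0, 1]"))
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort(paste0(side, " proportions must sum to 1 (got ",
                 format(sum(p)), ")"))
  }
  invisible(p)
}

#' Normalize raw strain abundance tables into a community
#'
#' Rescales nonnegative abundances to proportions on each side and drops
#' zero-abundance strains. Either a `density`/`abundance` column or a
#' `proportion` column may be supplied as the abundance measure.
#'
#' @inheritParams community
#' @param abundance_col Name of the abundance column; defaults to the first
#'   of `density`, `abundance`, `proportion` present.
#' @return A [community()] object; densities are preserved when supplied.
#' @examples
#' hosts <- tibble::tibble(strain_id = 1:3, spacers = list(1L, 2L, 3L),
#'                         abundance = c(3, 1, 0))
#' viruses <- tibble::tibble(strain_id = 1L, protospacers = list(1:3),
#'                           abundance = 5)
#' as_community(hosts, viruses)$hosts$proportion
#' @export
as_community <- function(hosts, viruses, time = NULL, abundance_col = NULL) {
  norm_side <- function(x, allele_col, side) {
    x <- as_tibble(x)
    col <- abundance_col %||%
      intersect(c("density", "abundance", "proportion"), names(x))[1]
    if (is.na(col) || is.null(col) || !col %in% names(x)) {
      abort(paste0("no abundance column found in ", side, " table"))
    }
    ab <- x[[col]]
    if (any(ab < 0)) abort("abundances must be >= 0")
    if (sum(ab) <= 0) abort(paste0("empty population: all ", side,
                                   " abundances are zero"))
    x <- x[ab > 0, , drop = FALSE]
    x$proportion <- x[[col]] / sum(ab)
    x
  }
  community(norm_side(hosts, "spacers", "host"),
            norm_side(viruses, "protospacers", "virus"),
            time = time)
}

#' @export
print.crispr_community <- function(x, ...) {
  cat("<crispr_community>",
      if (!is.null(x$time)) paste0(" t = ", x$time, " h"), "\n", sep = "")
  cat("  hosts:  ", nrow(x$hosts), " strain(s), ",
      format(round(average_spacers_per_host(x), 3)),
      " spacers/host (abundance-weighted)\n", sep = "")
  cat("  viruses:", nrow(x$viruses), "strain(s)\n")
  invisible(x)
}

#' Spacer-protospacer matching primitives
#'
#' `match_count()` returns the number of distinct protospacer positions of a
#' viral strain whose allele identifier equals some spacer identifier of the
#' host (an allele occupying several positions is counted at each position).
#' `match_presence()` is its 0/1 truncation: whether the host is immune to
#' the virus at all. `distributed_indicator()` is the triplet test at the
#' heart of population-wide distributed immunity: 1 iff two protospacer
#' positions `p != p'` of the virus exist such that `p` is matched by a
#' spacer of the first host and `p'` by a spacer of the second.
#' `distributed_count()` is the count variant (number of such ordered
#' position pairs); it is exposed for sensitivity work but unused by the
#' metrics, which follow the indicator semantics.
#'
#' @param spacers,spacers_i,spacers_j Integer vectors of spacer identifiers
#'   carried by a host strain.
#' @param protospacers Integer vector of protospacer alleles of a viral
#'   strain (one entry per position).
#' @return An integer count, or 0/1 for the presence/indicator forms.
#' @examples
#' match_count(c(1L, 2L, 9L), c(1L, 2L, 2L)) # 3: allele 2 at two positions
#' distributed_indicator(1L, 2L, c(1L, 2L, 3L)) # different protospacers
#' distributed_indicator(1L, 1L, c(1L, 2L, 3L)) # same spacer: 0
#' @export
match_count <- function(spacers, protospacers) {
  sum(protospacers %in% spacers)
}

#' @rdname match_count
#' @export
match_presence <- function(spacers, protospacers) {
  as.integer(match_count(spacers, protospacers) >= 1L)
}

#' @rdname match_count
#' @export
distributed_indicator <- function(spacers_i, spacers_j, protospacers) {
  mi <- which(protospacers %in% spacers_i)
  mj <- which(protospacers %in% spacers_j)
  if (length(mi) == 0L || length(mj) == 0L) return(0L)
  if (length(mi) == 1L && length(mj) == 1L && mi == mj) return(0L)
  1L
}

#' @rdname match_count
#' @export
distributed_count <- function(spacers_i, spacers_j, protospacers) {
  mi <- which(protospacers %in% spacers_i)
  mj <- which(protospacers %in% spacers_j)
  sum(outer(mi, mj, `!=`))
}

#' Abundance-weighted mean spacers per host
#'
#' @param comm A [community()].
#' @return `sum_i N_i |G_i|`, the expected CRISPR locus length of a host
#'   drawn at random from the population.
#' @examples
#' comm <- make_community(n_hosts = 3, n_viruses = 1)
#' average_spacers_per_host(comm)
#' @export
average_spacers_per_host <- function(comm) {
  stopifnot(inherits(comm, "crispr_community"))
  sum(comm$hosts$proportion * lengths(comm$hosts$spacers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
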