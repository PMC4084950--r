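#' Filter spacer-bearing reads for locus reconstruction
#'
#' Keeps reads that can be assigned to an evolved CRISPR genotype: reads
#' containing at least two novel spacers, or at least one novel spacer
#' together with ancestral spacers or visible leader sequence. Reads
#' showing a single novel spacer with nothing to anchor it are dropped.
#'
#' @param reads A tibble of read observations with columns `read_id`,
#'   `spacers` (list-column of integer spacer identifiers in
#'   leader-to-trailer order), `has_leader`, `has_trailer` (logical), and
#'   `novel` (list-column of logicals aligned with `spacers`, novel vs
#'   ancestral).
#' @return The kept rows.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = 1:2,
#'   spacers = list(c(101L, 102L), 103L),
#'   has_leader = c(FALSE, FALSE), has_trailer = c(TRUE, FALSE),
#'   novel = list(c(TRUE, TRUE), TRUE)
#' )
#' filter_reads(reads) # second read dropped: lone unanchored novel spacer
#' @export
filter_reads <- function(reads) {
  reads <- validate_reads(reads)
  n_novel <- vapply(reads$novel, sum, 1L)
  n_anc <- lengths(reads$novel) - n_novel
  keep <- n_novel >= 2L |
    (n_novel >= 1L & (n_anc >= 1L | reads$has_leader))
  reads[keep, , drop = FALSE]
}

validate_reads <- function(reads) {
  reads <- as_tibble(reads)
  needed <- c("read_id", "spacers", "has_leader", "has_trailer", "novel")
  missing <- setdiff(needed, names(reads))
  if (length(missing) > 0) {
    abort(paste0("reads table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  reads$spacers <- lapply(reads$spacers, as.integer)
  reads$novel <- lapply(reads$novel, as.logical)
  if (any(lengths(reads$spacers) == 0)) {
    abort("reads must carry at least one spacer")
  }
  if (any(lengths(reads$spacers) != lengths(reads$novel))) {
    abort("'novel' flags must align with 'spacers'")
  }
  reads
}

#' Reconstruct host CRISPR loci from reads
#'
#' Groups reads by spacer content and completes truncated loci. Reads with
#' visible trailer sequence define complete loci. A read lacking trailer
#' information inherits the trailer-end spacers of the complete group
#' whose leader-end content extends it (the read's spacer list is a prefix
#' of the group's); when several groups qualify, the best-supported one
#' wins, with remaining ties broken deterministically toward the
#' lexicographically smallest completed locus (with a warning). A
#' truncated read matching no group is completed with the spacers fixed in
#' the population. Each unique completed spacer set is one host strain
#' whose proportion is its read fraction.
#'
#' @param reads A (typically [filter_reads()]-filtered) read table.
#' @param fixed_spacers Integer identifiers of spacers fixed in the
#'   population (the assumed trailer-end content when no group matches).
#' @param merge_truncated When `FALSE`, truncated reads are never merged
#'   into complete groups and are completed with `fixed_spacers` only;
#'   exposed to quantify how merging guards against PDI overestimation.
#' @return A tibble of host strains: `strain_id`, `spacers` (list-column),
#'   `n_reads`, `proportion`.
#' @examples
#' reads <- tibble::tibble(
#'   read_id = 1:3,
#'   spacers = list(c(7L, 8L), c(7L, 8L, 1L, 2L), c(7L, 8L, 1L, 2L)),
#'   has_leader = c(TRUE, TRUE, TRUE),
#'   has_trailer = c(FALSE, TRUE, TRUE),
#'   novel = list(c(TRUE, TRUE), c(TRUE, TRUE, FALSE, FALSE),
#'                c(TRUE, TRUE, FALSE, FALSE))
#' )
#' reconstruct_loci(reads, fixed_spacers = c(1L, 2L))
#' @export
reconstruct_loci <- function(reads, fixed_spacers = integer(),
                             merge_truncated = TRUE) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0) abort("no reads to reconstruct from")
  fixed_spacers <- as.integer(fixed_spacers)

  complete <- reads[reads$has_trailer, , drop = FALSE]
  truncated <- reads[!reads$has_trailer, , drop = FALSE]

  key <- function(v) paste(v, collapse = ",")
  group_keys <- vapply(complete$spacers, key, "")
  groups <- unique(group_keys)
  group_loci <- complete$spacers[match(groups, group_keys)]
  group_support <- as.integer(table(factor(group_keys, levels = groups)))

  complete_locus <- function(sp) {
    if (merge_truncated && length(group_loci) > 0) {
      is_prefix <- vapply(group_loci, function(g) {
        length(g) >= length(sp) && identical(g[seq_along(sp)], sp)
      }, TRUE)
      if (any(is_prefix)) {
        cand <- which(is_prefix)
        best <- cand[group_support[cand] == max(group_support[cand])]
        if (length(best) > 1) {
          warn("tied candidate groups for a truncated read; taking the lexicographically smallest completed locus")
          best <- best[order_lex(group_loci[best])[1]]
        }
        return(group_loci[[best[1]]])
      }
    }
    c(sp, setdiff(fixed_spacers, sp))
  }

  completed <- c(complete$spacers,
                 lapply(truncated$spacers, complete_locus))
  ckeys <- vapply(completed, key, "")
  strains <- unique(ckeys)
  counts <- as.integer(table(factor(ckeys, levels = strains)))
  tibble(
    strain_id = seq_along(strains),
    spacers = completed[match(strains, ckeys)],
    n_reads = counts,
    proportion = counts / sum(counts)
  )
}

# order integer-vector list lexicographically (element-wise, shorter first
# on shared prefix)
order_lex <- function(lst) {
  maxlen <- max(lengths(lst))
  padded <- lapply(lst, function(v) c(v, rep(-Inf, maxlen - length(v))))
  do.call(order, lapply(seq_len(maxlen), function(i) {
    vapply(padded, `[[`, 1.0, i)
  }))
}

#' Enumerate viral strains from independent SNP frequencies
#'
#' Treats each segregating escape SNP as an independent event and
#' enumerates every combination of SNPs as a viral strain, with proportion
#' equal to the product of carried-SNP frequencies and absent-SNP
#' complements. SNPs flagged as fixed are carried by every strain.
#'
#' @param snps A tibble with columns `snp_id`, `frequency` (fraction of
#'   reads carrying the mutation, in `[0, 1]`), `escaped_protospacer`
#'   (integer identifier of the protospacer or PAM the SNP disrupts) and
#'   optionally `fixed` (logical; defaults to `FALSE`).
#' @return A tibble of viral strains: `strain_id`, `snps` (list-column of
#'   carried `snp_id`s), `escaped` (list-column of escaped protospacer
#'   identifiers) and `proportion`. Zero-probability combinations are
#'   dropped; proportions sum to 1.
#' @examples
#' snps <- tibble::tibble(snp_id = c("i", "ii", "iii"),
#'                        frequency = c(1, 0.5, 0.2),
#'                        escaped_protospacer = c(11L, 12L, 13L),
#'                        fixed = c(TRUE, FALSE, FALSE))
#' viral_strains_from_snps(snps) # proportions 0.4 / 0.4 / 0.1 / 0.1
#' @export
viral_strains_from_snps <- function(snps) {
  snps <- as_tibble(snps)
  needed <- c("snp_id", "frequency", "escaped_protospacer")
  missing <- setdiff(needed, names(snps))
  if (length(missing) > 0) {
    abort(paste0("snps table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"fixed" %in% names(snps)) snps$fixed <- FALSE
  if (any(snps$frequency < 0 | snps$frequency > 1)) {
    abort("SNP frequencies must lie in [0, 1]")
  }
  fixed <- snps[snps$fixed, , drop = FALSE]
  seg <- snps[!snps$fixed, , drop = FALSE]
  s <- nrow(seg)
  combos <- if (s == 0) {
    matrix(logical(0), nrow = 1, ncol = 0)
  } else {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), s)))
  }
  rows <- lapply(seq_len(nrow(combos)), function(ci) {
    carried <- combos[ci, ]
    pr <- prod(ifelse(carried, seg$frequency, 1 - seg$frequency))
    tibble(
      snps = list(c(fixed$snp_id, seg$snp_id[carried])),
      escaped = list(as.integer(c(fixed$escaped_protospacer,
                                  seg$escaped_protospacer[carried]))),
      proportion = pr
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$proportion > 0, , drop = FALSE]
  out$proportion <- out$proportion / sum(out$proportion)
  add_column(out, strain_id = seq_len(nrow(out)), .before = 1)
}

#' Build a community from reconstructed hosts and SNP-derived viruses
#'
#' Translates reconstructed host strains and SNP-combination viral strains
#' into a [community()] on the protospacer identifier space: each host
#' spacer is mapped to the protospacer it targets, and a viral strain's
#' protospacer vector is the full annotated protospacer set minus the
#' positions escaped by its SNPs, so a spacer matches a viral strain iff
#' its target protospacer is present and un-escaped there.
#'
#' @param hosts Host strains from [reconstruct_loci()].
#' @param viruses Viral strains from [viral_strains_from_snps()].
#' @param spacer_map A tibble with columns `spacer` and `protospacer`
#'   (integer identifiers). Spacers without an annotation are treated as
#'   matchless (a message reports them).
#' @return A [community()]; host spacer identities are target protospacer
#'   identifiers. Read counts and SNP content are kept in the
#'   `provenance` attribute.
#' @export
empirical_community <- function(hosts, viruses, spacer_map) {
  hosts <- as_tibble(hosts)
  viruses <- as_tibble(viruses)
  spacer_map <- as_tibble(spacer_map)
  if (!all(c("spacer", "protospacer") %in% names(spacer_map))) {
    abort("spacer_map needs columns 'spacer' and 'protospacer'")
  }
  all_protos <- sort(unique(as.integer(spacer_map$protospacer)))
  unmapped <- integer()
  host_targets <- lapply(hosts$spacers, function(sp) {
    hit <- match(as.integer(sp), spacer_map$spacer)
    if (anyNA(hit)) {
      unmapped <<- union(unmapped, as.integer(sp)[is.na(hit)])
    }
    unique(as.integer(spacer_map$protospacer[hit[!is.na(hit)]]))
  })
  if (length(unmapped) > 0) {
    message("spacer(s) without protospacer annotation treated as matchless: ",
            paste(sort(unmapped), collapse = ", "))
  }
  virus_protos <- lapply(viruses$escaped, function(e) {
    setdiff(all_protos, as.integer(e))
  })
  comm <- community(
    hosts = tibble(strain_id = hosts$strain_id, spacers = host_targets,
                   proportion = hosts$proportion),
    viruses = tibble(strain_id = viruses$strain_id,
                     protospacers = virus_protos,
                     proportion = viruses$proportion)
  )
  attr(comm, "provenance") <- list(
    n_reads = if ("n_reads" %in% names(hosts)) hosts$n_reads else NULL,
    snps = if ("snps" %in% names(viruses)) viruses$snps else NULL,
    unmapped_spacers = sort(unmapped)
  )
  comm
}

#' Estimate distributed immunity from sequencing-derived tables
#'
#' End-to-end empirical estimate: builds the community with
#' [empirical_community()] and evaluates [di_metrics()] on it, exactly as
#' for simulated populations.
#'
#' @inheritParams empirical_community
#' @inheritParams di_metrics
#' @return The [di_metrics()] tibble, with the community attached as
#'   attribute `"community"`.
#' @examples
#' hosts <- tibble::tibble(strain_id = 1:2, spacers = list(101L, 102L),
#'                         proportion = c(0.5, 0.5))
#' viruses <- tibble::tibble(strain_id = 1L, snps = list(character()),
#'                           escaped = list(integer()), proportion = 1)
#' map <- tibble::tibble(spacer = c(101L, 102L), protospacer = c(11L, 12L))
#' estimate_di(hosts, viruses, map)$pdi # two even hosts, distinct targets
#' @export
estimate_di <- function(hosts, viruses, spacer_map,
                        sigma = c("pairwise", "population")) {
  comm <- empirical_community(hosts, viruses, spacer_map)
  out <- di_metrics(comm, sigma = sigma)
  attr(out, "community") <- comm
  out
}
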