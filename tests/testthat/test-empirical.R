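mk_reads <- function(spacer_sets, leader, trailer, novel_sets,
                     ids = seq_along(spacer_sets)) {
  tibble::tibble(read_id = ids,
                 spacers = lapply(spacer_sets, as.integer),
                 has_leader = leader, has_trailer = trailer,
                 novel = novel_sets)
}

test_that("read filtering keeps only anchorable evolved reads", {
  reads <- mk_reads(
    spacer_sets = list(c(101, 102), 103, 104, c(105, 1)),
    leader = c(FALSE, FALSE, TRUE, FALSE),
    trailer = c(TRUE, FALSE, FALSE, TRUE),
    novel_sets = list(c(TRUE, TRUE), TRUE, TRUE, c(TRUE, FALSE)))
  kept <- filter_reads(reads)
  # two novel spacers: kept; lone novel spacer: dropped;
  # leader + novel: kept; novel + ancestral: kept
  expect_equal(kept$read_id, c(1L, 3L, 4L))
  # purely ancestral reads carry no evolved information
  anc <- mk_reads(list(c(1, 2)), FALSE, TRUE, list(c(FALSE, FALSE)))
  expect_equal(nrow(filter_reads(anc)), 0)
})

test_that("truncated reads inherit trailer spacers from extending groups", {
  reads <- mk_reads(
    spacer_sets = list(c(7, 8), c(7, 8, 1, 2), c(7, 8, 1, 2)),
    leader = c(TRUE, TRUE, TRUE),
    trailer = c(FALSE, TRUE, TRUE),
    novel_sets = list(c(TRUE, TRUE), c(TRUE, TRUE, FALSE, FALSE),
                      c(TRUE, TRUE, FALSE, FALSE)))
  strains <- reconstruct_loci(reads, fixed_spacers = c(1L, 2L))
  expect_equal(nrow(strains), 1L)
  expect_equal(strains$spacers[[1]], c(7L, 8L, 1L, 2L))
  expect_equal(strains$n_reads, 3L)
  expect_equal(strains$proportion, 1)
})

test_that("unmatched truncated reads fall back to fixed trailer spacers", {
  reads <- mk_reads(
    spacer_sets = list(9),
    leader = TRUE, trailer = FALSE, novel_sets = list(TRUE))
  strains <- reconstruct_loci(reads, fixed_spacers = c(1L, 2L))
  expect_equal(strains$spacers[[1]], c(9L, 1L, 2L))
  # identical reads collapse to a single strain of proportion 1
  same <- mk_reads(rep(list(c(5, 1)), 4), rep(TRUE, 4), rep(TRUE, 4),
                   rep(list(c(TRUE, FALSE)), 4))
  expect_equal(nrow(reconstruct_loci(same, integer())), 1L)
})

test_that("ties between candidate groups break deterministically", {
  reads <- mk_reads(
    spacer_sets = list(c(7), c(7, 1, 3), c(7, 1, 2)),
    leader = c(TRUE, TRUE, TRUE),
    trailer = c(FALSE, TRUE, TRUE),
    novel_sets = list(TRUE, c(TRUE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE)))
  expect_warning(strains <- reconstruct_loci(reads, integer()), "tie")
  # the truncated read joins the lexicographically smaller locus (7,1,2)
  n <- strains$n_reads[vapply(strains$spacers, function(s) {
    identical(s, c(7L, 1L, 2L))
  }, TRUE)]
  expect_equal(n, 2L)
})

test_that("the better-supported extension wins over lexicographic order", {
  reads <- mk_reads(
    spacer_sets = list(c(7), c(7, 1, 3), c(7, 1, 3), c(7, 1, 2)),
    leader = rep(TRUE, 4),
    trailer = c(FALSE, TRUE, TRUE, TRUE),
    novel_sets = list(TRUE, c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                      c(TRUE, FALSE, FALSE)))
  strains <- reconstruct_loci(reads, integer())
  n <- strains$n_reads[vapply(strains$spacers, function(s) {
    identical(s, c(7L, 1L, 3L))
  }, TRUE)]
  expect_equal(n, 3L)
})

test_that("SNP combinations follow independence products", {
  snps <- tibble::tibble(snp_id = c("i", "ii", "iii"),
                         frequency = c(1, 0.5, 0.2),
                         escaped_protospacer = c(11L, 12L, 13L),
                         fixed = c(TRUE, FALSE, FALSE))
  v <- viral_strains_from_snps(snps)
  key <- vapply(v$snps, paste, "", collapse = "+")
  props <- setNames(v$proportion, key)
  expect_equal(unname(props["i"]), 0.4)
  expect_equal(unname(props["i+ii"]), 0.4)
  expect_equal(unname(props["i+iii"]), 0.1)
  expect_equal(unname(props["i+ii+iii"]), 0.1)
  expect_equal(sum(v$proportion), 1)

  none <- viral_strains_from_snps(snps[snps$fixed, ])
  expect_equal(nrow(none), 1L)
  expect_equal(none$proportion, 1)

  # a frequency-1 segregating SNP appears in every surviving combination
  snps2 <- snps
  snps2$frequency[2] <- 1
  v2 <- viral_strains_from_snps(snps2)
  expect_true(all(vapply(v2$snps, function(s) "ii" %in% s, TRUE)))
  expect_equal(sum(v2$proportion), 1)
  expect_error(
    viral_strains_from_snps(dplyr::mutate(snps, frequency = c(1, 2, 0.2))),
    "\\[0, 1\\]")
})

test_that("empirical DI estimates follow the match/escape semantics", {
  map <- tibble::tibble(spacer = c(101L, 102L, 103L),
                        protospacer = c(11L, 12L, 13L))
  # clonal host population: no pairs, pdi = 0
  clonal <- tibble::tibble(strain_id = 1L, spacers = list(101L),
                           proportion = 1)
  v0 <- tibble::tibble(strain_id = 1L, snps = list(character()),
                       escaped = list(integer()), proportion = 1)
  expect_equal(estimate_di(clonal, v0, map)$pdi, 0)

  # two even hosts targeting distinct un-escaped protospacers: pdi = 1/2
  two <- tibble::tibble(strain_id = 1:2, spacers = list(101L, 102L),
                        proportion = c(0.5, 0.5))
  m2 <- estimate_di(two, v0, map)
  expect_equal(m2$pdi, 0.5)
  expect_equal(m2$hvi, 0)

  # an escape SNP disables the only spacer of a host against that strain
  vesc <- tibble::tibble(strain_id = 1:2,
                         snps = list(character(), "e1"),
                         escaped = list(integer(), 11L),
                         proportion = c(0.5, 0.5))
  single <- tibble::tibble(strain_id = 1L, spacers = list(101L),
                           proportion = 1)
  mesc <- estimate_di(single, vesc, map)
  expect_equal(mesc$idi, 0.5) # only the un-escaped strain is matched
  expect_equal(mesc$hvi, 0.5)

  # unannotated spacers are matchless and logged
  odd <- tibble::tibble(strain_id = 1L, spacers = list(c(101L, 999L)),
                        proportion = 1)
  expect_message(m_odd <- estimate_di(odd, v0, map), "999")
  expect_equal(m_odd$idi, 1)
})

test_that("reconstruction recovers truth exactly with full visibility", {
  loci <- tibble::tibble(
    strain_id = 1:3,
    spacers = list(c(101L, 102L, 1L, 2L), c(103L, 1L, 2L),
                   c(104L, 105L, 1L, 2L)),
    proportion = c(0.5, 0.3, 0.2))
  reads <- make_reads(loci, depth = 400, truncation = 0,
                      ancestral = c(1L, 2L), seed = 9)
  strains <- reconstruct_loci(filter_reads(reads),
                              fixed_spacers = c(1L, 2L))
  expect_equal(nrow(strains), 3L)
  key <- vapply(strains$spacers, paste, "", collapse = ",")
  truth <- vapply(loci$spacers, paste, "", collapse = ",")
  expect_setequal(key, truth)
  # proportions match the read draw exactly (no reads dropped)
  tab <- table(factor(vapply(reads$spacers, paste, "", collapse = ","),
                      levels = truth))
  expect_equal(strains$proportion[match(truth, key)],
               as.vector(tab) / sum(tab))
})

test_that("trailer truncation merges reads without inflating strains", {
  loci <- tibble::tibble(
    strain_id = 1:2,
    spacers = list(c(101L, 102L, 1L, 2L), c(103L, 104L, 1L, 2L)),
    proportion = c(0.6, 0.4))
  reads <- filter_reads(make_reads(loci, depth = 600, truncation = 0.3,
                                   ancestral = c(1L, 2L), seed = 4))
  strains <- reconstruct_loci(reads, fixed_spacers = c(1L, 2L))
  expect_lte(nrow(strains), 2L)
  key <- vapply(strains$spacers, paste, "", collapse = ",")
  p1 <- strains$proportion[key == "101,102,1,2"]
  # recovered proportion within 3 binomial SE of the truth
  expect_lt(abs(p1 - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(reads)))
})

test_that("merging truncated reads guards against inflated diversity", {
  # ancestral spacers 1 and 2 target nothing in the phage (the ancestor
  # was susceptible), so only novel spacers carry annotations
  map <- tibble::tibble(spacer = 101:104, protospacer = 11:14)
  v0 <- tibble::tibble(strain_id = 1L, snps = list(character()),
                       escaped = list(integer()), proportion = 1)
  # two even true strains; half of each strain's reads are truncated to
  # their leader-most spacer: treating those reads as distinct strains
  # doubles the apparent diversity and inflates PDI; merging restores the
  # true value
  reads <- mk_reads(
    spacer_sets = list(c(101, 102, 1), c(101), c(103, 104, 1), c(103)),
    leader = rep(TRUE, 4),
    trailer = c(TRUE, FALSE, TRUE, FALSE),
    novel_sets = list(c(TRUE, TRUE, FALSE), TRUE, c(TRUE, TRUE, FALSE),
                      TRUE))
  merged <- reconstruct_loci(reads, fixed_spacers = 1L)
  split <- reconstruct_loci(reads, fixed_spacers = 1L,
                            merge_truncated = FALSE)
  pdi_m <- suppressMessages(estimate_di(merged, v0, map)$pdi)
  pdi_s <- suppressMessages(estimate_di(split, v0, map)$pdi)
  expect_equal(pdi_m, 0.5)      # the true two-strain value
  expect_equal(pdi_s, 0.75)     # four apparent strains: 1 - 1/4
  expect_lt(pdi_m, pdi_s)

  # merging never infers more strains than treating reads as distinct
  for (seed in 1:10) {
    set.seed(seed)
    loci <- tibble::tibble(
      strain_id = 1:3,
      spacers = list(c(101L, 102L, 1L, 2L), c(103L, 104L, 1L, 2L),
                     c(105L, 106L, 1L, 2L)),
      proportion = as.vector(prop.table(runif(3, 0.2, 1))))
    rds <- filter_reads(make_reads(loci, depth = 200, truncation = 0.4,
                                   ancestral = c(1L, 2L), seed = seed))
    n_m <- nrow(reconstruct_loci(rds, fixed_spacers = c(1L, 2L)))
    n_s <- nrow(reconstruct_loci(rds, fixed_spacers = c(1L, 2L),
                                 merge_truncated = FALSE))
    expect_lte(n_m, n_s)
    expect_lte(n_m, nrow(loci))
  }
})
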