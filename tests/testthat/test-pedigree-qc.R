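test_that("true parent-offspring duos have zero Mendelian error", {
  sim <- desk_sim()
  pop <- sim$founders$pop
  withr::with_seed(71, {
    kids <- make_cross(pop, "MR5like", "DOM01", 3, generation = "F1")
  })
  all_pop <- bind_pops(pop, kids)
  for (i in pop_ids(kids)) {
    d <- mendelian_error_rate(all_pop, "MR5like", i)
    expect_equal(d$error_rate, 0)
    expect_equal(d$verdict, "parent_offspring_candidate")
  }
})

test_that("the duo statistic is symmetric and flags duplicates", {
  sim <- desk_sim()
  pop <- sim$founders$pop
  d1 <- mendelian_error_rate(pop, "DOM01", "DOM02")
  d2 <- mendelian_error_rate(pop, "DOM02", "DOM01")
  expect_equal(d1$error_rate, d2$error_rate)
  expect_equal(d1$n_compared, d2$n_compared)

  dup <- mendelian_error_rate(pop, "DOM01", "DOM01")
  expect_equal(dup$error_rate, 0)
  expect_true(dup$identical_genotypes)
})

test_that("unrelated pairs exceed the duo threshold", {
  # unrelated domestic founders share no parental haplotypes, so opposing
  # homozygotes occur at a rate far above 0.5%
  withr::with_seed(72, {
    for (k in 1:5) {
      map <- make_apple_map(5, 80, 100, seed = sample.int(1e6, 1))
      f <- make_founders(map, founder_spec("D", 0.5), n_domestic = 2,
                         seed = sample.int(1e6, 1))
      d <- mendelian_error_rate(f$pop, "DOM01", "DOM02")
      expect_equal(d$verdict, "excluded")
    }
  })
})

test_that("pairwise inference recovers true pairs with no false exclusions", {
  sim <- desk_sim()
  pop <- sim$founders$pop
  withr::with_seed(73, {
    f1 <- make_cross(pop, "MR5like", "DOM01", 2, generation = "F1")
    all_pop <- bind_pops(pop, f1)
    k1 <- pop_ids(f1)[1]
    pbc1 <- make_cross(all_pop, k1, "DOM02", 2, generation = "pBC1")
    all_pop <- bind_pops(all_pop, pbc1)
  })
  res <- infer_parent_offspring(all_pop, pedigree = all_pop$meta)
  true_pairs <- all_pop$meta |>
    tidyr::pivot_longer(c("mother", "father"), values_to = "parent") |>
    dplyr::filter(!is.na(parent), parent %in% pop_ids(all_pop))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cand_keys <- key(res$candidates$id_a, res$candidates$id_b)
  expect_true(all(key(true_pairs$id, true_pairs$parent) %in% cand_keys))
  expect_equal(nrow(res$conflicts), 0)
  # a single individual yields an empty result
  solo <- infer_parent_offspring(subset_pop(pop, "DOM01"))
  expect_equal(nrow(solo$duos), 0)
})

test_that("null-allele adjustment restores a corrupted duo verdict", {
  sim <- desk_sim()
  pop <- sim$founders$pop
  withr::with_seed(74, {
    kids <- make_cross(pop, "MR5like", "DOM01", 3, generation = "F1")
  })
  all_pop <- bind_pops(pop, kids)
  noisy <- inject_null_alleles(all_pop, null_allele_rate = 0.02,
                               seed = 75)$pop
  kid <- pop_ids(kids)[1]
  before <- mendelian_error_rate(noisy, "MR5like", kid)
  expect_gt(before$error_rate, 0)

  adj <- adjust_null_allele_calls(noisy, "MR5like", pop_ids(kids))
  adj2 <- adjust_null_allele_calls(adj$pop, "DOM01", pop_ids(kids))
  after <- mendelian_error_rate(adj2$pop, "MR5like", kid)
  expect_equal(after$error_rate, 0)
  expect_equal(after$verdict, "parent_offspring_candidate")
  expect_gt(nrow(adj$changes), 0)
})

test_that("adjustment modes follow the replication threshold", {
  map <- even_map(n = 20)
  # parent homozygous A at site 3; offspring homozygous B there
  parent <- rbind(rep(1L, 20), rep(1L, 20))
  off <- rbind(rep(2L, 20), rep(2L, 20))
  make3 <- function() phased_pop(map, list(P = list(LG01 = parent),
                                           O1 = list(LG01 = off),
                                           O2 = list(LG01 = off),
                                           O3 = list(LG01 = off)))
  # conservative: both sides go missing
  cons <- adjust_null_allele_calls(make3(), "P", "O1")
  expect_true(all(is.na(cons$pop$obs$P$LG01)))
  expect_true(all(is.na(cons$pop$obs$O1$LG01)))
  expect_true(all(cons$changes$action == "set_missing"))
  # replicated in 3 offspring: parent recoded het-with-null
  rec <- adjust_null_allele_calls(make3(), "P", c("O1", "O2", "O3"),
                                  mode = "recode")
  expect_true(all(sort(rec$pop$obs$P$LG01[, 1]) == c(1L, 2L)))
  expect_true(all(rec$changes$action == "recoded_het_with_null"))
  # no conflicts: zero changes
  none <- adjust_null_allele_calls(
    phased_pop(map, list(P = list(LG01 = parent),
                         O1 = list(LG01 = parent))), "P", "O1")
  expect_equal(nrow(none$changes), 0)
})

test_that("adjustment never raises the error rate of a true duo", {
  sim <- desk_sim()
  pop <- sim$founders$pop
  withr::with_seed(76, {
    kids <- make_cross(pop, "MR5like", "DOM01", 4, generation = "F1")
  })
  all_pop <- bind_pops(pop, kids)
  noisy <- inject_null_alleles(all_pop, null_allele_rate = 0.05,
                               seed = 77)$pop
  adj <- adjust_null_allele_calls(noisy, "MR5like", pop_ids(kids))$pop
  for (i in pop_ids(kids)) {
    before <- mendelian_error_rate(noisy, "MR5like", i)$error_rate
    after <- mendelian_error_rate(adj, "MR5like", i)$error_rate
    expect_lte(after, before)
  }
})

test_that("genome-wide sharing matches relatedness expectations", {
  map <- make_apple_map(seed = 79)
  pop <- make_founders(map, founder_spec("D", 0.5), n_domestic = 3,
                       seed = 80)$pop
  # identical individuals share everything
  self <- genomewide_sharing_fraction(pop, "DOM01", "DOM01")
  expect_equal(self$share_pct, 100, tolerance = 0.01)
  expect_equal(self$max_pairing_pct, 100, tolerance = 0.01)

  withr::with_seed(78, {
    kids <- make_cross(pop, "DOM01", "DOM02", 1, generation = "F1")
    all_pop <- bind_pops(pop, kids)
    kid <- pop_ids(kids)[1]
    po <- genomewide_sharing_fraction(all_pop, "DOM01", kid)
    # the maternal homolog partitions between the mother's two homologs
    expect_gte(max(po$pairings$shared_pct[po$pairings$homolog_b == 1]), 45)
    expect_equal(po$share_pct, 50, tolerance = 0.2)

    # grandparent vs grandchild: about 25% over replicates
    shares <- vapply(1:30, function(k) {
      f1 <- make_cross(pop, "DOM01", "DOM02", 1, generation = "F1",
                       prefix = paste0("f", k))
      p2 <- bind_pops(pop, f1)
      gc <- make_cross(p2, pop_ids(f1)[1], "DOM03", 1,
                       generation = "F2", prefix = paste0("g", k))
      p3 <- bind_pops(p2, gc)
      genomewide_sharing_fraction(p3, "DOM01", pop_ids(gc)[1])$share_pct
    }, numeric(1))
  })
  se <- stats::sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - 25), 3 * se + 1)
})
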