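test_that("identical haplotypes give one whole-chromosome segment", {
  map <- even_map(n = 20)
  h <- rep(c(1L, 2L), 10)
  segs <- find_shared_segments(h, h, map, "LG01")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_shared_snps, 20L)
  expect_equal(segs$start_cM, 0)
  expect_equal(segs$end_cM, 10)
})

test_that("a single mismatch splits a run at the offending SNP", {
  map <- even_map(n = 20)
  a <- rep(1L, 20)
  b <- a; b[10] <- 2L
  segs <- find_shared_segments(a, b, map, "LG01")
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start_index, c(1L, 11L))
  expect_equal(segs$end_index, c(9L, 20L))
  expect_equal(segs$n_shared_snps, c(9L, 10L))
})

test_that("missing sites neither break runs nor count as shared", {
  map <- even_map(n = 20)
  a <- rep(1L, 20)
  b <- a
  b[c(5, 6)] <- NA
  a[15] <- NA
  segs <- find_shared_segments(a, b, map, "LG01")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_shared_snps, 17L)
  expect_equal(segs$n_missing_spanned, 3L)
  # runs are trimmed to informative shared SNPs at both ends
  b2 <- rep(1L, 20); b2[c(1, 2, 20)] <- NA
  segs2 <- find_shared_segments(rep(1L, 20), b2, map, "LG01")
  expect_equal(segs2$start_index, 3L)
  expect_equal(segs2$end_index, 19L)
})

test_that("the segment caller matches the naive oracle on random instances", {
  withr::with_seed(101, {
    for (k in 1:100) {
      n <- sample(20:200, 1)
      map <- even_map(len = n / 2, n = n)
      mode <- sample(c("unrelated", "mosaic"), 1)
      a <- sample(c(1L, 2L), n, replace = TRUE)
      b <- if (mode == "unrelated") {
        sample(c(1L, 2L), n, replace = TRUE)
      } else {
        x <- a
        flips <- sample(n, rbinom(1, n, 0.1))
        x[flips] <- 3L - x[flips]
        x
      }
      a[sample(n, rbinom(1, n, 0.05))] <- NA
      b[sample(n, rbinom(1, n, 0.05))] <- NA
      got <- find_shared_segments(a, b, map, "LG01")
      want <- naive_shared_segments(a, b, map, "LG01")
      expect_equal(got$start_index, want$start_index)
      expect_equal(got$end_index, want$end_index)
      expect_equal(got$n_shared_snps, want$n_shared_snps)
    }
  })
})

test_that("subtraction labels a copied homolog domestic, the rest unadapted", {
  map <- even_map(n_chrom = 2, len = 40, n = 50)
  withr::with_seed(7, {
    anc1 <- lapply(1:2, function(i)
      rbind(sample(1:2, 50, TRUE), sample(1:2, 50, TRUE)))
  })
  names(anc1) <- c("LG01", "LG02")
  donor <- lapply(c("LG01", "LG02"), function(chr) {
    rbind(anc1[[chr]][1, ],                        # homolog 1: ancestor copy
          withr::with_seed(8, sample(1:2, 50, TRUE)))  # homolog 2: unrelated
  })
  names(donor) <- c("LG01", "LG02")
  pop <- phased_pop(map, list(ANC = anc1, DON = donor))
  res <- define_unadapted_haplotypes(pop, "DON", "ANC", min_snps = 16)
  h1 <- res$intervals[res$intervals$homolog == 1, ]
  expect_true(all(h1$origin == "domestic"))
  # vacuous subtraction: everything unadapted
  res0 <- define_unadapted_haplotypes(pop, "DON", character(), min_snps = 16)
  expect_true(all(res0$intervals$origin == "unadapted"))
  expect_equal(res0$summary$unadapted_pct, 100)
})

test_that("an Evereste-like donor subtracts to about half unadapted", {
  map <- make_apple_map(17, 80, 100, seed = 51)
  f <- make_founders(map, founder_spec("EVR", 0.50), n_domestic = 2,
                     seed = 52)
  res <- define_unadapted_haplotypes(f$pop, "EVR", f$domestic_ancestors)
  expect_equal(res$summary$unadapted_pct, 50, tolerance = 0.04)
  # the donor traced against itself returns its own unadapted percent
  rep_self <- trace_unadapted(f$pop, "EVR", "EVR", res)
  expect_equal(rep_self$percent_diploid, res$summary$unadapted_pct,
               tolerance = 0.01)
})

test_that("the >15-SNP rule and the parent filter behave at the boundary", {
  map <- even_map(n = 60)
  donor <- rep(1L, 60)
  parent <- rep(2L, 60)

  # 16 informative shared SNPs: retained; 15: dropped
  for (n_shared in c(15, 16)) {
    desc <- rep(2L, 60)
    desc[1:n_shared] <- 1L
    segs <- find_shared_segments(donor, desc, map, "LG01")
    kept <- filter_candidate_segments(segs, donor, desc,
                                      list(parent, parent), min_snps = 16)
    expect_equal(nrow(kept), as.integer(n_shared == 16))
    if (nrow(kept) > 0) expect_equal(kept$disposition, "donor_exclusive")
  }

  # a segment carried identically by the parent with no differential
  # extension is dropped
  desc <- rep(2L, 60); desc[10:40] <- 1L
  parent_same <- rep(2L, 60); parent_same[10:40] <- 1L
  segs <- find_shared_segments(donor, desc, map, "LG01")
  kept <- filter_candidate_segments(segs, donor, desc,
                                    list(parent_same, rep(2L, 60)))
  expect_equal(nrow(kept), 0)
})

test_that("the extended-region exception retains differentially extending segments", {
  map <- even_map(n = 60)
  donor <- rep(1L, 60)
  # descendant matches donor on SNPs 10..45; parent carries the same core
  # 20..45 but mismatches donor and descendant on 10..19 (the left
  # extension is donor-specific by 10 SNPs)
  desc <- rep(2L, 60); desc[10:45] <- 1L
  parent_a <- rep(2L, 60); parent_a[20:45] <- 1L
  # the candidate segment under scrutiny: restrict donor to the core
  donor_masked <- rep(NA_integer_, 60); donor_masked[20:45] <- 1L
  segs <- find_shared_segments(donor_masked, desc, map, "LG01")
  expect_equal(nrow(segs), 1)
  kept <- filter_candidate_segments(segs, donor, desc,
                                    list(parent_a, rep(2L, 60)))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$disposition, "exception_retained")
})

test_that("raising min_snps never increases retained centimorgans", {
  sim <- desk_sim()
  founders <- sim$founders
  withr::with_seed(61, {
    kids <- make_cross(founders$pop, "MR5like", "DOM01", 4,
                       generation = "F1")
  })
  pop <- bind_pops(founders$pop, kids)
  def <- define_unadapted_haplotypes(pop, "MR5like",
                                     founders$domestic_ancestors)
  for (i in pop_ids(kids)) {
    tot <- vapply(c(8, 16, 30, 60), function(ms) {
      trace_unadapted(pop, i, "MR5like", def, parent_id = "DOM01",
                      min_snps = ms)$total_unadapted_cM
    }, numeric(1))
    expect_true(all(diff(tot) <= 1e-9))
  }
})

test_that("an absurd min_snps yields an empty but well-formed report", {
  sim <- desk_sim()
  founders <- sim$founders
  withr::with_seed(62, {
    kids <- make_cross(founders$pop, "MR5like", "DOM01", 1,
                       generation = "F1")
  })
  pop <- bind_pops(founders$pop, kids)
  def <- define_unadapted_haplotypes(pop, "MR5like",
                                     founders$domestic_ancestors)
  rep0 <- trace_unadapted(pop, pop_ids(kids)[1], "MR5like", def,
                          min_snps = 1e6)
  expect_equal(nrow(rep0$segments), 0)
  expect_equal(rep0$total_unadapted_cM, 0)
  expect_equal(rgene_only_classifier(rep0), "no_rgene_segment")
})

test_that("traced segments recover truth with high precision and recall", {
  sim <- desk_sim()
  founders <- sim$founders
  cfg <- program_config(n_generations = 2, offspring_per_cross = 30,
                        required_rgenes = "FB_MR5", n_parents_per_gen = 1,
                        seed = 63)
  run <- run_pbc_series(founders, cfg)
  pop <- run$pop
  def <- define_unadapted_haplotypes(pop, "MR5like",
                                     founders$domestic_ancestors)
  meta <- pop$meta
  ids <- meta$id[meta$generation == "pBC1"]
  ids <- utils::head(ids, 12)
  prec_num <- prec_den <- rec_num <- rec_den <- 0
  for (i in ids) {
    parent <- meta$father[meta$id == i]
    rep <- trace_unadapted(pop, i, "MR5like", def, parent_id = parent,
                           rgene_loci = sim$rg)
    for (hom in 1:2) {
      for (chr in unique(sim$map$chrom)) {
        traced <- rep$segments[rep$segments$homolog == hom &
                                 rep$segments$chrom == chr, ]
        tr <- pop$truth[pop$truth$id == i & pop$truth$homolog == hom &
                          pop$truth$chrom == chr &
                          pop$truth$origin == "exotic", ]
        # only truth segments spanning >= 16 SNPs enter the recall
        if (nrow(tr) > 0) {
          n_snps <- vapply(seq_len(nrow(tr)), function(k) {
            sum(sim$map$chrom == chr & sim$map$cM >= tr$start_cM[k] &
                  sim$map$cM <= tr$end_cM[k])
          }, numeric(1))
          tr_big <- tr[n_snps >= 16, ]
          rec_den <- rec_den + sum(tr_big$end_cM - tr_big$start_cM)
          rec_num <- rec_num + overlap_cM(traced, tr_big)
        }
        prec_den <- prec_den + sum(traced$end_cM - traced$start_cM)
        prec_num <- prec_num + overlap_cM(traced, tr)
      }
    }
  }
  expect_gt(rec_num / rec_den, 0.95)
  expect_gt(prec_num / prec_den, 0.95)
})

test_that("foreground-selected carriers retain an R-gene-linked segment", {
  sim <- desk_sim()
  founders <- sim$founders
  withr::with_seed(64, {
    kids <- make_cross(founders$pop, "MR5like", "DOM01", 40,
                       generation = "F1")
  })
  scr <- screen_population(kids, founders$panel, "FB_MR5")
  carriers <- scr$id[scr$status == "selected"]
  pop <- bind_pops(founders$pop, kids)
  def <- define_unadapted_haplotypes(pop, "MR5like",
                                     founders$domestic_ancestors)
  cohort <- trace_cohort(pop, carriers, "MR5like", def,
                         parent_ids = "DOM01", rgene_loci = sim$rg)
  expect_true(all(cohort$n_rgene_linked >= 1))
  expect_true(all(cohort$class %in% c("rgene_only", "rgene_plus_extra")))
})

test_that("genotype-mode tracing tolerates null-allele corruption", {
  sim <- desk_sim()
  founders <- sim$founders
  cfg <- program_config(n_generations = 2, offspring_per_cross = 30,
                        required_rgenes = "FB_MR5", n_parents_per_gen = 1,
                        seed = 63)
  run <- run_pbc_series(founders, cfg)
  pop <- run$pop
  map <- sim$map
  def <- define_unadapted_haplotypes(pop, "MR5like",
                                     founders$domestic_ancestors)
  meta <- pop$meta
  ids <- utils::head(meta$id[meta$generation == "pBC1"], 10)

  recall_of <- function(p, genotype_mode) {
    rec_num <- rec_den <- 0
    for (i in ids) {
      parent <- meta$father[meta$id == i]
      rep <- trace_unadapted(p, i, "MR5like", def, parent_id = parent,
                             genotype_mode = genotype_mode)
      for (chr in unique(map$chrom)) {
        tr <- p$truth[p$truth$id == i & p$truth$chrom == chr &
                        p$truth$origin == "exotic", ]
        if (nrow(tr) == 0) next
        n_snps <- vapply(seq_len(nrow(tr)), function(k) {
          sum(map$chrom == chr & map$cM >= tr$start_cM[k] &
                map$cM <= tr$end_cM[k])
        }, numeric(1))
        tr <- tr[n_snps >= 16, ]
        if (nrow(tr) == 0) next
        traced <- rep$segments[rep$segments$chrom == chr, ]
        rec_den <- rec_den + sum(tr$end_cM - tr$start_cM)
        rec_num <- rec_num + overlap_cM(traced, tr)
      }
    }
    rec_num / rec_den
  }

  clean <- recall_of(pop, genotype_mode = TRUE)
  expect_gt(clean, 0.95)

  noisy <- inject_null_alleles(pop, null_allele_rate = 0.02, seed = 99)$pop
  for (i in ids) {
    noisy <- adjust_null_allele_calls(noisy, meta$father[meta$id == i], i)$pop
    noisy <- adjust_null_allele_calls(noisy, meta$mother[meta$id == i], i)$pop
  }
  corrupted <- recall_of(noisy, genotype_mode = TRUE)
  expect_gt(corrupted, clean - 0.05)
})
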