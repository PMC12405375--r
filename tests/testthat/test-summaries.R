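test_that("the expectation calculator reproduces the published values", {
  expect_equal(expected_unadapted_fraction(50, 1), 25.0)
  expect_equal(expected_unadapted_fraction(75, 0), 75.0)
  expect_equal(expected_unadapted_fraction(75, 1), 37.5)
  expect_equal(expected_unadapted_fraction(75, 5), 2.3)
  expect_equal(expected_unadapted_fraction(50, 4), 3.1)
  expect_error(expected_unadapted_fraction(-1, 2), "non-negative")
  expect_error(expected_unadapted_fraction(50, -1), "non-negative")
})

test_that("the expectation halves exactly per added meiosis", {
  for (f in c(30, 50, 75, 100)) {
    raw <- f * 2^-(0:8)
    expect_equal(expected_unadapted_fraction(f, 0:8), round(raw, 1))
    expect_equal(raw[-1] / raw[-9], rep(0.5, 8))
  }
})

test_that("generation summaries attach explicit-meiosis expectations", {
  d <- tibble::tibble(
    generation = c("pBC4", "pBC4", "pBC5"),
    percent_diploid = c(3.0, 5.0, 2.0)
  )
  s <- unadapted_generation_summary(
    d, meioses = c(pBC4 = 4, pBC5 = 5), donor_fraction = 50)
  expect_equal(s$mean_pct[s$generation == "pBC4"], 4.0)
  expect_equal(s$expected_pct, c(3.1, 1.6))
  # single report: mean = min = max
  s1 <- unadapted_generation_summary(
    tibble::tibble(generation = "g", percent_diploid = 2.0))
  expect_equal(unlist(s1[, c("mean_pct", "min_pct", "max_pct")]),
               c(mean_pct = 2, min_pct = 2, max_pct = 2))
})

test_that("the packaged funnel fixture reproduces the published statistics", {
  rec <- fbe_cross_records()
  # column totals the published table prints
  tot <- rec |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum))
  expect_equal(tot$pollinated_flowers, 6624)
  expect_equal(tot$fruits, 973)
  expect_equal(tot$mas_tested, 2370)
  expect_equal(tot$rgene_carriers, 1126)
  expect_equal(tot$crosses, 116)
  expect_equal(tot$seeds, 5033)

  fs <- funnel_statistics(rec)
  val <- function(loc, stat, met = NA) {
    v <- fs$value[fs$location == loc & fs$statistic == stat &
                    (is.na(met) & is.na(fs$metric) |
                       !is.na(fs$metric) & fs$metric %in% met)]
    v
  }
  expect_equal(val("LIFT", "fruits_per_flower"), 0.18)
  expect_equal(val("field", "fruits_per_flower"), 0.14)
  expect_equal(val("LIFT", "share_pct", "pollinated_flowers"), 27.4)
  expect_equal(val("LIFT", "per_generation_avg", "crosses"), 19.2)
  expect_equal(val("field", "per_generation_avg", "crosses"), 4.0)
  expect_equal(val("LIFT", "total", "pollinated_flowers"), 1813)

  # second series: field fruits per flower higher than fast-track
  fs3 <- funnel_statistics(fbmr5_cross_records())
  v3 <- function(loc, stat) {
    fs3$value[fs3$location == loc & fs3$statistic == stat &
                is.na(fs3$metric)]
  }
  expect_equal(v3("field", "fruits_per_flower"), 0.20)
  expect_equal(v3("LIFT", "fruits_per_flower"), 0.12)
})

test_that("an all-zero funnel reports undefined ratios without errors", {
  rec <- fbe_cross_records()
  rec[, vapply(rec, is.numeric, logical(1))] <- 0
  fs <- funnel_statistics(rec)
  expect_true(all(is.na(fs$value[fs$statistic == "fruits_per_flower"])))
  expect_true(all(is.na(fs$value[fs$statistic == "seeds_per_fruit"])))
})

test_that("seed planning inverts the funnel rates", {
  expect_equal(plan_seed_requirement(39, 0.65, 0.5, 0.2), 600)
  expect_equal(plan_seed_requirement(10, 1, 1, 1), 10)
  expect_equal(expected_flowering_carriers(800, 0.65, 0.5, 0.2), 52)
  expect_error(plan_seed_requirement(10, 0, 0.5, 0.2), "rates")
  # the recommended 600-800 seed window brackets 30-40 flowering carriers
  expect_equal(expected_flowering_carriers(600, 0.65, 0.5, 0.2), 39)
})

test_that("relative lesion length is scaled to the susceptible control", {
  expect_equal(relative_lesion_length(10, 40, 50, 100), 50)
  expect_equal(relative_lesion_length(5, 10, 5, 10), 100)
  expect_equal(relative_lesion_length(0, 30, 50, 100), 0)
  expect_warning(v <- relative_lesion_length(10, 40, 0, 100), "undefined")
  expect_true(is.na(v))
})

test_that("compact letters separate and join groups correctly", {
  withr::with_seed(91, {
    d_same <- tibble::tibble(
      g = rep(c("a", "b", "c"), each = 10),
      y = rep(rnorm(10), 3)
    )
  })
  same <- anova_tukey_letters(d_same, y, g)
  expect_equal(unique(tidy(same)$letters), "a")

  withr::with_seed(92, {
    d_far <- tibble::tibble(
      g = rep(c("lo", "hi"), each = 10),
      y = c(rnorm(10, 0, 1), rnorm(10, 10, 1))
    )
  })
  far <- anova_tukey_letters(d_far, y, g)
  expect_equal(length(unique(tidy(far)$letters)), 2)
  expect_lt(glance(far)$p_value, 0.001)

  # extremes differ, the middle group straddles: letters like a / ab / b
  withr::with_seed(93, {
    d_mid <- tibble::tibble(
      g = rep(c("low", "mid", "high"), each = 8),
      y = c(rnorm(8, 0, 1), rnorm(8, 1.4, 1), rnorm(8, 2.8, 1))
    )
  })
  mid <- anova_tukey_letters(d_mid, y, g)
  lt <- tidy(mid)
  sig <- mid$pairs[mid$pairs$p_adj < 0.05, ]
  shares <- function(a, b) {
    la <- strsplit(lt$letters[lt$group == a], "")[[1]]
    lb <- strsplit(lt$letters[lt$group == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (k in seq_len(nrow(mid$pairs))) {
    a <- mid$pairs$group_a[k]; b <- mid$pairs$group_b[k]
    expect_equal(shares(a, b), mid$pairs$p_adj[k] >= 0.05)
  }

  expect_error(anova_tukey_letters(
    tibble::tibble(g = c("a", "a", "b"), y = 1:3), y, g), "at least 2")
})

test_that("letters agree with direct pairwise Tukey decisions on random instances", {
  withr::with_seed(94, {
    for (k in 1:300) {
      ng <- sample(2:5, 1)
      spread <- runif(1, 0, 3)
      d <- purrr::map_dfr(seq_len(ng), function(i) {
        tibble::tibble(g = letters[i],
                       y = rnorm(sample(3:8, 1), mean = i * spread))
      })
      res <- anova_tukey_letters(d, y, g)
      lt <- res$letters
      for (j in seq_len(nrow(res$pairs))) {
        a <- res$pairs$group_a[j]; b <- res$pairs$group_b[j]
        la <- strsplit(lt$letters[lt$group == a], "")[[1]]
        lb <- strsplit(lt$letters[lt$group == b], "")[[1]]
        expect_equal(length(intersect(la, lb)) > 0,
                     res$pairs$p_adj[j] >= 0.05)
      }
    }
  })
})
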