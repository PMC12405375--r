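#' Expected unadapted genome fraction after repeated backcrossing
#'
#' Under Mendelian expectation, every cross to a fully adapted parent
#' halves the donor genome fraction: `donor_fraction * 2^-n_meioses`,
#' reported to one decimal, the convention used for published
#' expectations (50% donor, 1 meiosis -> 25.0; 75%, 5 -> 2.3;
#' 50%, 4 -> 3.1). The meiosis count is always explicit, never inferred
#' from generation labels, because labeling conventions differ by one
#' between introgression series.
#'
#' @param donor_fraction donor unadapted fraction in percent (0-100).
#' @param n_meioses number of meioses separating the individual from the
#'   donor (>= 0).
#' @return Expected percentage, rounded to one decimal.
#' @examples
#' expected_unadapted_fraction(50, 1)  # 25
#' expected_unadapted_fraction(75, 5)  # 2.3
#' @export
expected_unadapted_fraction <- function(donor_fraction, n_meioses) {
  if (any(donor_fraction < 0) || any(n_meioses < 0)) {
    stop("donor_fraction and n_meioses must be non-negative", call. = FALSE)
  }
  round(donor_fraction * 2^(-n_meioses), 1)
}

#' Per-generation summary of traced unadapted fractions
#'
#' @param data a tibble with columns `generation` and `percent_diploid`
#'   (e.g. [trace_cohort()] output joined to generation labels).
#' @param meioses optional named numeric vector mapping generation label
#'   to meiosis count (must be supplied explicitly; labels are never
#'   parsed).
#' @param donor_fraction donor unadapted percentage used for the
#'   expectation column (required when `meioses` is given).
#' @return A tibble per generation: `generation`, `n`, `mean_pct`,
#'   `min_pct`, `max_pct` and, when meioses are supplied, `n_meioses`
#'   and `expected_pct`.
#' @export
unadapted_generation_summary <- function(data, meioses = NULL,
                                         donor_fraction = NULL) {
  out <- data |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = mean(.data$percent_diploid),
      min_pct = min(.data$percent_diploid),
      max_pct = max(.data$percent_diploid),
      .groups = "drop"
    )
  if (!is.null(meioses)) {
    stopifnot(!is.null(donor_fraction), !is.null(names(meioses)),
              all(out$generation %in% names(meioses)))
    out <- out |>
      dplyr::mutate(
        n_meioses = unname(meioses[.data$generation]),
        expected_pct = expected_unadapted_fraction(donor_fraction,
                                                   .data$n_meioses)
      )
  }
  out
}

#' Read breeding-funnel cross records
#'
#' CSV with columns `series`, `generation`, `location` (`field` or
#' `LIFT`) and the per-generation counts (`crosses`,
#' `pollinated_flowers`, `fruits`, `seeds`, `sown`, `scab_eliminated`,
#' `pre_mas_losses`, `mas_tested`, `rgene_carriers`,
#' `selected_for_lift`, `parents_next_gen`). Only raw counts are stored;
#' every ratio is derived by [funnel_statistics()].
#'
#' @param path file path; the packaged fixtures hold the published
#'   per-generation counts of the two apple fire blight introgression
#'   series (see [fbe_cross_records()]).
#' @return A tibble.
#' @export
read_cross_records <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    series = readr::col_character(),
    generation = readr::col_character(),
    location = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname read_cross_records
#' @export
fbe_cross_records <- function() {
  read_cross_records(system.file("extdata", "fbE_table2.csv",
                                 package = "pbctrace"))
}

#' @rdname read_cross_records
#' @export
fbmr5_cross_records <- function() {
  read_cross_records(system.file("extdata", "fbMR5_table3.csv",
                                 package = "pbctrace"))
}

#' Breeding-funnel statistics
#'
#' Per location: totals across generations for every count column,
#' the location's share of the grand total (percent, 1 decimal),
#' per-generation averages computed over the generations with a nonzero
#' count of that metric at that location (1 decimal; the convention that
#' reproduces the published per-generation averages), fruits per
#' pollinated flower (2 decimals) and seeds per fruit (1 decimal).
#' Ratios with zero denominators are reported as `NA` (undefined), never
#' as zero.
#'
#' @param records a cross-record tibble (see [read_cross_records()]).
#' @return A tidy tibble with columns `location`, `statistic`, `metric`,
#'   `value`. Statistics are `total`, `share_pct`, `per_generation_avg`
#'   and the derived ratios (`metric = NA` for ratios).
#' @export
funnel_statistics <- function(records) {
  metrics <- names(records)[vapply(records, is.numeric, logical(1))]
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "count")
  totals <- long |>
    dplyr::group_by(.data$location, .data$metric) |>
    dplyr::summarise(
      total = sum(.data$count),
      n_nonzero = sum(.data$count > 0),
      .groups = "drop"
    )
  grand <- totals |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(grand = sum(.data$total), .groups = "drop")
  per_loc <- totals |>
    dplyr::left_join(grand, by = "metric") |>
    dplyr::mutate(
      share_pct = ifelse(.data$grand > 0,
                         round(.data$total / .data$grand * 100, 1), NA),
      per_generation_avg = ifelse(.data$n_nonzero > 0,
                                  round(.data$total / .data$n_nonzero, 1),
                                  NA)
    )
  stats_long <- per_loc |>
    dplyr::select("location", "metric", "total", "share_pct",
                  "per_generation_avg") |>
    tidyr::pivot_longer(c("total", "share_pct", "per_generation_avg"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::select("location", "statistic", "metric", "value")
  ratio_of <- function(num, den) {
    ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  }
  wide <- per_loc |>
    dplyr::select("location", "metric", "total") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "total")
  ratios <- list()
  if (all(c("fruits", "pollinated_flowers") %in% names(wide))) {
    ratios[[length(ratios) + 1]] <- tibble::tibble(
      location = wide$location, statistic = "fruits_per_flower",
      metric = NA_character_,
      value = round(ratio_of(wide$fruits, wide$pollinated_flowers), 2)
    )
  }
  if (all(c("seeds", "fruits") %in% names(wide))) {
    ratios[[length(ratios) + 1]] <- tibble::tibble(
      location = wide$location, statistic = "seeds_per_fruit",
      metric = NA_character_,
      value = round(ratio_of(wide$seeds, wide$fruits), 1)
    )
  }
  dplyr::bind_rows(stats_long, !!!ratios) |>
    dplyr::arrange(.data$location, .data$statistic, .data$metric)
}

#' Plan seed numbers for a target of flowering carriers
#'
#' Inverts the breeding funnel: `seeds = ceiling(target / (survival *
#' carrier * flowering))`. With the funnel rates observed in fast-track
#' apple introgression (about 65% of sown seeds reaching marker testing,
#' 50% carrying the R-gene, and 20% flowering by the second
#' vernalization), a target of 30-40 flowering carriers lands in the
#' recommended 600-800 seeds per generation.
#'
#' @param target_flowering_carriers desired number of flowering
#'   carriers.
#' @param survival_rate fraction of seeds that survive to marker
#'   testing, in (0, 1].
#' @param carrier_rate fraction carrying the R-gene (0.5 for a single
#'   heterozygous locus), in (0, 1].
#' @param flowering_rate fraction of carriers that flower in time, in
#'   (0, 1].
#' @return Number of seeds needed (integer).
#' @examples
#' plan_seed_requirement(39, 0.65, 0.5, 0.2)  # 600
#' @export
plan_seed_requirement <- function(target_flowering_carriers, survival_rate,
                                  carrier_rate = 0.5, flowering_rate = 0.2) {
  rates <- c(survival_rate, carrier_rate, flowering_rate)
  if (any(rates <= 0) || any(rates > 1)) {
    stop("rates must be in (0, 1]", call. = FALSE)
  }
  stopifnot(target_flowering_carriers > 0)
  ceiling(target_flowering_carriers / prod(rates))
}

#' @rdname plan_seed_requirement
#' @param seeds number of seeds sown.
#' @return `expected_flowering_carriers()`: the expected number of
#'   flowering carriers from `seeds`.
#' @export
expected_flowering_carriers <- function(seeds, survival_rate,
                                        carrier_rate = 0.5,
                                        flowering_rate = 0.2) {
  rates <- c(survival_rate, carrier_rate, flowering_rate)
  if (any(rates <= 0) || any(rates > 1)) {
    stop("rates must be in (0, 1]", call. = FALSE)
  }
  seeds * prod(rates)
}

#' Relative lesion length (percent of susceptible control)
#'
#' Fire blight severity is scored as lesion length divided by total
#' shoot length, expressed relative to the percent lesion length of the
#' susceptible control in the same trial:
#' `(lesion/shoot) / (control_lesion/control_shoot) * 100`.
#'
#' @param lesion_cm,shoot_cm lesion and total shoot length of the tested
#'   plant (shoot > 0).
#' @param control_lesion_cm,control_shoot_cm the susceptible control's
#'   lesion and shoot length (shoot > 0); a control lesion of zero makes
#'   the statistic undefined (`NA` with a warning).
#' @return Percent of the control's percent lesion length (vectorized).
#' @export
relative_lesion_length <- function(lesion_cm, shoot_cm, control_lesion_cm,
                                   control_shoot_cm) {
  stopifnot(all(shoot_cm > 0), all(control_shoot_cm > 0),
            all(lesion_cm >= 0))
  ctrl <- control_lesion_cm / control_shoot_cm
  if (any(ctrl == 0)) {
    warning("control lesion length is zero: relative value undefined",
            call. = FALSE)
  }
  ifelse(ctrl > 0, (lesion_cm / shoot_cm) / ctrl * 100, NA_real_)
}

#' One-way ANOVA with compact-letter Tukey groups
#'
#' Fits a one-way ANOVA of `value` on `group`, runs Tukey's HSD on all
#' pairs, and assigns a compact letter display by insert-and-absorb:
#' groups sharing any letter are not significantly different at `alpha`.
#'
#' @param data a data frame.
#' @param value,group column names (tidy evaluation) of the response and
#'   the grouping factor.
#' @param alpha significance level (default 0.05).
#' @return An object of class `anova_cld` with [tidy()] (letters and
#'   group means) and [glance()] (F statistic, degrees of freedom,
#'   p value) methods.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 5),
#'                 y = c(rnorm(5), rnorm(5, 10)))
#' tidy(anova_tukey_letters(d, y, g))
#' @export
anova_tukey_letters <- function(data, value, group, alpha = 0.05) {
  d <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  counts <- table(d$group)
  if (length(counts) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs at least 2 values; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  d$group <- factor(d$group)
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- tibble::tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"])
  ) |>
    tidyr::separate_wider_delim("contrast", "-",
                                names = c("group_a", "group_b"))
  means <- d |>
    dplyr::group_by(group = as.character(.data$group)) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  sig <- pairs[pairs$p_adj < alpha, c("group_a", "group_b")]
  letters_tbl <- cld_insert_absorb(as.character(means$group), sig)
  structure(list(
    letters = dplyr::left_join(means, letters_tbl, by = "group") |>
      dplyr::mutate(group = as.character(.data$group)),
    pairs = pairs,
    f_statistic = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p_value = an[["Pr(>F)"]][1],
    alpha = alpha
  ), class = "anova_cld")
}

# insert-and-absorb compact letter display. `groups` ordered (letters are
# assigned in this order); `sig` is a tibble of significantly different
# pairs (group_a, group_b). Guarantees: significant pairs never share a
# letter; non-significant pairs always share at least one.
cld_insert_absorb <- function(groups, sig) {
  cols <- list(groups)
  for (k in seq_len(nrow(sig))) {
    a <- sig$group_a[k]; b <- sig$group_b[k]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        nxt <- c(nxt, list(col))
      }
    }
    # absorb columns that are subsets of another column
    nxt <- nxt[lengths(nxt) > 0]
    keep <- vapply(seq_along(nxt), function(i) {
      !any(vapply(seq_along(nxt), function(j) {
        j != i && all(nxt[[i]] %in% nxt[[j]]) &&
          (length(nxt[[j]]) > length(nxt[[i]]) || j < i)
      }, logical(1)))
    }, logical(1))
    cols <- nxt[keep]
  }
  ord <- order(vapply(cols, function(col) min(match(col, groups)), numeric(1)))
  cols <- cols[ord]
  lab <- letters[seq_along(cols)]
  tibble::tibble(
    group = groups,
    letters = vapply(groups, function(g) {
      paste(lab[vapply(cols, function(col) g %in% col, logical(1))],
            collapse = "")
    }, character(1))
  )
}

#' @method print anova_cld
#' @export
print.anova_cld <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$f_statistic, 4), ", p = ", signif(x$p_value, 3),
      "\nTukey compact letter display (alpha = ", x$alpha, "):\n", sep = "")
  print(x$letters)
  invisible(x)
}

#' @export
tidy.anova_cld <- function(x, ...) x$letters

#' @export
glance.anova_cld <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, df_between = x$df_between,
    df_within = x$df_within, p_value = x$p_value
  )
}
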