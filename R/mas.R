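#' Marker panels
#'
#' A marker panel is a tibble mirroring the published MAS table layout:
#' columns `rgene`, `linkage_group`, `marker`, `marker_type`
#' (`SSR`/`SCAR`/`SNP`), `coupling_allele` (the allele linked in cis to
#' the resistance allele in the donor: an SSR fragment size, a SCAR band
#' size with `(0)` denoting band presence in coupling, or a SNP base) and
#' `gala_ref` (the reference genotype of the susceptible control,
#' where reported). `read_marker_panel()` reads the TSV form;
#' `apple_mas_panel()` returns the panel of fire blight, scab and mildew
#' R-gene markers shipped with the package.
#'
#' @param path file path to a panel TSV.
#' @return A tibble.
#' @export
read_marker_panel <- function(path) {
  panel <- readr::read_tsv(path, col_types = readr::cols(
    rgene = readr::col_character(),
    linkage_group = readr::col_character(),
    marker = readr::col_character(),
    marker_type = readr::col_character(),
    coupling_allele = readr::col_character(),
    gala_ref = readr::col_character()
  ))
  stopifnot(all(nzchar(panel$coupling_allele)))
  panel
}

#' @rdname read_marker_panel
#' @export
apple_mas_panel <- function() {
  read_marker_panel(system.file("extdata", "mas_panel.tsv",
                                package = "pbctrace"))
}

#' Call R-gene presence from marker genotypes
#'
#' A marker supports presence iff its coupling allele is observed in the
#' genotype (SSR and SNP genotypes are unordered allele pairs; SCAR
#' genotypes report the band size or `0` for no band). Markers with
#' missing genotypes are uninformative. Under the default `"all"` rule
#' the gene is called present iff every informative marker supports it;
#' under `"majority"`, iff more than half do. Zero informative markers
#' yield an undetermined call (`NA`), never `FALSE`.
#'
#' @param genotypes a data frame with columns `marker`, `allele1`,
#'   `allele2` (character; `NA` = missing).
#' @param panel panel rows for a single R-gene (see [read_marker_panel()]).
#' @param rule combination rule, `"all"` (default) or `"majority"`.
#' @return A one-row tibble: `rgene`, `present` (logical, `NA` =
#'   undetermined), `n_informative`, `n_supporting`, `discordant`, and a
#'   list-column `evidence` with the per-marker table.
#' @examples
#' panel <- tibble::tibble(rgene = "Fb_E", linkage_group = "LG12",
#'   marker = "ChFbE06", marker_type = "SSR", coupling_allele = "260",
#'   gala_ref = "243/243")
#' g <- tibble::tibble(marker = "ChFbE06", allele1 = "243", allele2 = "260")
#' call_rgene_presence(g, panel)
#' @export
call_rgene_presence <- function(genotypes, panel, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  stopifnot(length(unique(panel$rgene)) == 1)
  genotypes <- tibble::as_tibble(genotypes)
  ev <- panel |>
    dplyr::left_join(genotypes, by = "marker") |>
    dplyr::mutate(
      informative = !is.na(.data$allele1) | !is.na(.data$allele2),
      supports = .data$informative &
        (coupling_value(.data$coupling_allele) == .data$allele1 |
           coupling_value(.data$coupling_allele) == .data$allele2),
      supports = dplyr::coalesce(.data$supports, FALSE)
    ) |>
    dplyr::select("marker", "marker_type", "coupling_allele",
                  "allele1", "allele2", "informative", "supports")
  n_inf <- sum(ev$informative)
  n_sup <- sum(ev$supports)
  present <- if (n_inf == 0) {
    NA
  } else if (rule == "all") {
    n_sup == n_inf
  } else {
    n_sup > n_inf / 2
  }
  tibble::tibble(
    rgene = panel$rgene[1],
    present = present,
    n_informative = n_inf,
    n_supporting = n_sup,
    discordant = n_inf > 0 && n_sup > 0 && n_sup < n_inf,
    evidence = list(ev)
  )
}

# the allele value a marker must show to support presence; SCAR coupling
# written "375 (0)"-style in published tables reduces to the band size
coupling_value <- function(x) sub("\\s*\\(.*\\)$", "", x)

#' Screen a population for required R-genes
#'
#' Calls every required gene for every individual from the observed
#' genotypes at the panel markers and partitions the population into
#' `selected` (all required genes present), `rejected` (at least one
#' called absent) and `undetermined` (no absence call but at least one
#' undetermined gene). The partition is exhaustive and disjoint. With
#' zero required genes everything is selected.
#'
#' @param pop a [phased_pop()].
#' @param panel a marker panel whose `marker` values are map SNPs (as
#'   produced by [make_founders()]), or any panel whose markers appear in
#'   the map.
#' @param required_rgenes character vector of gene names to require.
#' @param rule combination rule passed to [call_rgene_presence()].
#' @return A tibble with `id`, `status`, and one logical column per
#'   required gene (`NA` = undetermined).
#' @export
screen_population <- function(pop, panel, required_rgenes,
                              rule = c("all", "majority")) {
  rule <- match.arg(rule)
  ids <- pop_ids(pop)
  if (length(required_rgenes) == 0) {
    return(tibble::tibble(id = ids, status = "selected"))
  }
  stopifnot(all(required_rgenes %in% panel$rgene))
  panel <- dplyr::filter(panel, .data$rgene %in% required_rgenes)
  midx <- match(panel$marker, pop$map$marker)
  if (anyNA(midx)) {
    stop("panel markers absent from map: ",
         paste(panel$marker[is.na(midx)], collapse = ", "), call. = FALSE)
  }
  chrom_of <- pop$map$chrom[midx]
  # index within chromosome
  within_idx <- stats::ave(seq_len(nrow(pop$map)), pop$map$chrom,
                           FUN = seq_along)[midx]
  # vectorized evaluation of the same support rule as
  # call_rgene_presence(): coupling allele observed among the genotype's
  # alleles; missing genotypes uninformative
  n_m <- nrow(panel)
  coup <- coupling_value(panel$coupling_allele)
  informative <- supports <- matrix(FALSE, n_m, length(ids),
                                    dimnames = list(NULL, ids))
  for (r in seq_len(n_m)) {
    for (i in ids) {
      a <- get_geno(pop, i, chrom_of[r])[, within_idx[r]]
      inf <- !all(is.na(a))
      informative[r, i] <- inf
      supports[r, i] <- inf && any(allele_chr[a[!is.na(a)]] == coup[r])
    }
  }
  present_one <- function(rows, i) {
    n_inf <- sum(informative[rows, i])
    if (n_inf == 0) return(NA)
    n_sup <- sum(supports[rows, i])
    if (rule == "all") n_sup == n_inf else n_sup > n_inf / 2
  }
  wide <- tibble::tibble(id = ids)
  for (g in required_rgenes) {
    rows <- which(panel$rgene == g)
    wide[[g]] <- vapply(ids, function(i) present_one(rows, i), logical(1))
  }
  gene_cols <- as.matrix(wide[required_rgenes])
  status <- dplyr::case_when(
    apply(gene_cols, 1, function(x) any(!x, na.rm = TRUE)) ~ "rejected",
    apply(gene_cols, 1, function(x) anyNA(x)) ~ "undetermined",
    TRUE ~ "selected"
  )
  dplyr::mutate(wide, status = status, .after = "id")
}

#' Segregation ratio with exact binomial confidence interval
#'
#' Carrier fraction among determinately tested individuals, with an
#' exact (Clopper-Pearson) 95% confidence interval and a flag raised
#' when the interval excludes the Mendelian expectation.
#'
#' @param x either a screening result from [screen_population()] (counts
#'   are taken as `selected` over `selected + rejected`) or the number of
#'   carriers.
#' @param n number of tested individuals (when `x` is a count).
#' @param expected expected carrier fraction (default 0.5 for a
#'   heterozygous-by-noncarrier cross).
#' @return A tibble: `n_tested`, `n_carriers`, `fraction`, `conf_low`,
#'   `conf_high`, `deviates` (TRUE when the CI excludes `expected`).
#' @examples
#' segregation_ratio(1126, 2370)
#' @export
segregation_ratio <- function(x, n = NULL, expected = 0.5) {
  if (is.data.frame(x)) {
    carriers <- sum(x$status == "selected")
    tested <- sum(x$status %in% c("selected", "rejected"))
  } else {
    carriers <- x
    tested <- n
  }
  if (is.null(tested) || tested < 1) {
    stop("zero tested individuals", call. = FALSE)
  }
  bt <- binom.test(carriers, tested)
  tibble::tibble(
    n_tested = tested,
    n_carriers = carriers,
    fraction = carriers / tested,
    conf_low = bt$conf.int[1],
    conf_high = bt$conf.int[2],
    deviates = expected < bt$conf.int[1] | expected > bt$conf.int[2]
  )
}
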