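#' Phased populations
#'
#' A `phased_pop` holds a collection of phased diploid individuals on a
#' shared genetic map. Alleles are biallelic, array-style `"A"`/`"B"`
#' (stored internally as integers 1/2 with `NA` for missing), two homologs
#' per chromosome per individual, always in map order. The object
#' optionally carries ground-truth ancestry segments (simulator output)
#' and an observed-genotype view that may differ from the true haplotypes
#' after null-allele or missingness injection.
#'
#' Haplotypes live in an efficient list-of-matrices core; use
#' [tidy_haplotypes()] (or `as_tibble()`) for a long tibble view.
#'
#' @param map a [genetic_map()].
#' @param haplo named list: individual id -> named list of chromosomes ->
#'   2 x n_loci integer matrix (rows = homologs, values 1, 2 or `NA`).
#' @param meta tibble with columns `id`, `mother`, `father`, `generation`
#'   (`NA` for unknown parents). Defaults to founders with unknown parents.
#' @param truth optional tibble of ancestry segments with columns
#'   `id`, `homolog`, `chrom`, `start_cM`, `end_cM`, `origin`.
#' @param obs optional observed-genotype view, same shape as `haplo`
#'   (unordered allele pairs; row order carries no phase meaning).
#' @return An object of class `phased_pop`.
#' @export
phased_pop <- function(map, haplo, meta = NULL, truth = NULL, obs = NULL) {
  map <- validate_genetic_map(map)
  chroms <- unique(map$chrom)
  n_loci <- table(factor(map$chrom, levels = chroms))
  for (id in names(haplo)) {
    h <- haplo[[id]]
    if (!setequal(names(h), chroms)) {
      stop("individual ", id, " does not cover the map chromosomes",
           call. = FALSE)
    }
    for (chr in chroms) {
      if (!is.matrix(h[[chr]]) || nrow(h[[chr]]) != 2 ||
          ncol(h[[chr]]) != n_loci[[chr]]) {
        stop("individual ", id, ", chromosome ", chr,
             ": haplotype matrix must be 2 x ", n_loci[[chr]], call. = FALSE)
      }
    }
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(
      id = names(haplo), mother = NA_character_, father = NA_character_,
      generation = "founder"
    )
  }
  stopifnot(all(names(haplo) %in% meta$id), all(meta$id %in% names(haplo)))
  if (is.null(truth)) truth <- empty_truth()
  structure(
    list(map = map, haplo = haplo, meta = meta, truth = truth, obs = obs),
    class = "phased_pop"
  )
}

empty_truth <- function() {
  tibble::tibble(
    id = character(), homolog = integer(), chrom = character(),
    start_cM = numeric(), end_cM = numeric(), origin = character()
  )
}

#' @method print phased_pop
#' @export
print.phased_pop <- function(x, ...) {
  cat("<phased_pop> ", length(x$haplo), " individuals, ",
      nrow(x$map), " SNPs on ", length(unique(x$map$chrom)),
      " chromosomes (", round(map_total_length(x$map), 1), " cM)\n", sep = "")
  if (nrow(x$truth) > 0) cat("  with truth ancestry segments\n")
  if (!is.null(x$obs)) cat("  with observed-genotype view\n")
  invisible(x)
}

#' @export
length.phased_pop <- function(x) length(x$haplo)

#' Individual ids of a phased population
#' @param pop a `phased_pop`.
#' @return Character vector of ids.
#' @export
pop_ids <- function(pop) names(pop$haplo)

# internal accessors ---------------------------------------------------------

get_hap <- function(pop, id, chrom, homolog) {
  pop$haplo[[id]][[chrom]][homolog, ]
}

# observed genotype view: obs if present, else the true haplotypes
get_geno <- function(pop, id, chrom) {
  if (!is.null(pop$obs)) pop$obs[[id]][[chrom]] else pop$haplo[[id]][[chrom]]
}

# subset a population by id (keeps map, meta rows, truth rows, obs)
subset_pop <- function(pop, ids) {
  stopifnot(all(ids %in% pop_ids(pop)))
  phased_pop(
    pop$map, pop$haplo[ids],
    meta = dplyr::filter(pop$meta, .data$id %in% ids),
    truth = dplyr::filter(pop$truth, .data$id %in% ids),
    obs = if (!is.null(pop$obs)) pop$obs[ids]
  )
}

# merge two populations on the same map
bind_pops <- function(a, b) {
  stopifnot(identical(a$map$marker, b$map$marker))
  obs <- if (!is.null(a$obs) || !is.null(b$obs)) {
    c(a$obs %||% a$haplo, b$obs %||% b$haplo)
  }
  phased_pop(a$map, c(a$haplo, b$haplo),
    meta = dplyr::bind_rows(a$meta, b$meta),
    truth = dplyr::bind_rows(a$truth, b$truth),
    obs = obs
  )
}

allele_chr <- c("A", "B")

#' Long tibble view of phased haplotypes
#'
#' @param pop a `phased_pop`.
#' @param ids optional subset of individual ids.
#' @return A tibble with columns `id`, `marker`, `chrom`, `cM`, `homolog`,
#'   `allele` (`"A"`, `"B"` or `NA`).
#' @export
tidy_haplotypes <- function(pop, ids = pop_ids(pop)) {
  purrr::map_dfr(ids, function(i) {
    # column-major unlisting of a 2 x L matrix alternates homologs per locus
    tibble::tibble(
      id = i,
      marker = rep(pop$map$marker, each = 2),
      chrom = rep(pop$map$chrom, each = 2),
      cM = rep(pop$map$cM, each = 2),
      homolog = rep(1:2, times = nrow(pop$map)),
      allele = allele_chr[unlist(
        lapply(pop$haplo[[i]], function(m) as.vector(m)), use.names = FALSE)]
    )
  })
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.phased_pop <- function(x, ...) tidy_haplotypes(x)

#' True unadapted genome fraction per individual
#'
#' Uses the simulator's ground-truth ancestry segments: summed cM of
#' exotic-origin segments over both homologs divided by twice the map
#' length, as a percentage of the diploid genome.
#'
#' @param pop a `phased_pop` carrying truth segments.
#' @param origin label counted as unadapted (default `"exotic"`).
#' @return A tibble with `id`, `unadapted_cM`, `unadapted_pct`.
#' @export
truth_unadapted_fraction <- function(pop, origin = "exotic") {
  total <- 2 * map_total_length(pop$map)
  base <- tibble::tibble(id = pop_ids(pop))
  agg <- pop$truth |>
    dplyr::filter(.data$origin == !!origin) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(unadapted_cM = sum(.data$end_cM - .data$start_cM),
                     .groups = "drop")
  base |>
    dplyr::left_join(agg, by = "id") |>
    dplyr::mutate(
      unadapted_cM = dplyr::coalesce(.data$unadapted_cM, 0),
      unadapted_pct = .data$unadapted_cM / total * 100
    )
}
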