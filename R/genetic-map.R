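#' Genetic maps
#'
#' A genetic map is a tibble with one row per SNP locus and columns
#' `marker` (character, unique), `chrom` (character, e.g. `"LG01"`) and
#' `cM` (numeric map position). Positions must be strictly increasing
#' within a chromosome and every chromosome must carry at least two loci.
#' All coordinates in this package are genetic (centimorgan); there are no
#' base-pair coordinates anywhere.
#'
#' @param marker character vector of marker names.
#' @param chrom character vector of chromosome (linkage group) names.
#' @param cM numeric vector of map positions in centimorgans.
#' @return A tibble of class `genetic_map`.
#' @examples
#' genetic_map(c("m1", "m2", "m3"), rep("LG01", 3), c(0, 1.5, 3))
#' @export
genetic_map <- function(marker, chrom, cM) {
  map <- tibble::tibble(
    marker = as.character(marker),
    chrom = as.character(chrom),
    cM = as.numeric(cM)
  )
  validate_genetic_map(map)
}

#' @rdname genetic_map
#' @param map a data frame with columns `marker`, `chrom`, `cM`.
#' @export
validate_genetic_map <- function(map) {
  req <- c("marker", "chrom", "cM")
  if (!all(req %in% names(map))) {
    stop("genetic map needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(map$cM) || any(map$cM < 0)) {
    stop("map positions must be non-negative and non-missing", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) {
    dup <- unique(map$marker[duplicated(map$marker)])
    stop("duplicate marker ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  # map order is the coordinate authority: keep input order, demand that it
  # is already sorted strictly within chromosome
  bad <- map |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::n() >= 2, c(FALSE, diff(.data$cM) <= 0)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    stop("positions not strictly increasing within chromosome at marker(s): ",
         paste(utils::head(bad$marker, 5), collapse = ", "), call. = FALSE)
  }
  n_per <- table(map$chrom)
  if (any(n_per < 2)) {
    stop("every chromosome needs >= 2 loci; offending: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), call. = FALSE)
  }
  class(map) <- unique(c("genetic_map", class(map)))
  map
}

#' Total map length in centimorgans
#'
#' Sum over chromosomes of (last - first) position.
#'
#' @param map a `genetic_map`.
#' @return A single numeric value (cM).
#' @export
map_total_length <- function(map) {
  sum(chrom_lengths(map)$length_cM)
}

#' Per-chromosome span of a genetic map
#'
#' @param map a `genetic_map`.
#' @return A tibble with `chrom`, `start_cM`, `end_cM`, `length_cM`, `n_loci`.
#' @export
chrom_lengths <- function(map) {
  map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      start_cM = dplyr::first(.data$cM),
      end_cM = dplyr::last(.data$cM),
      length_cM = dplyr::last(.data$cM) - dplyr::first(.data$cM),
      n_loci = dplyr::n(),
      .groups = "drop"
    )
}

# internal: named list chrom -> numeric vector of positions (map order)
map_positions <- function(map) {
  split(map$cM, factor(map$chrom, levels = unique(map$chrom)))
}

# internal: named list chrom -> character vector of marker ids
map_markers <- function(map) {
  split(map$marker, factor(map$chrom, levels = unique(map$chrom)))
}

#' Read / write a genetic map
#'
#' The on-disk format is a tab-separated file with columns
#' `marker`, `chrom`, `cM`. `read_genetic_map()` validates the result;
#' malformed rows or non-monotone positions raise errors naming the
#' offender. Round-tripping a map through `write_genetic_map()` and
#' `read_genetic_map()` is byte-stable.
#'
#' @param path file path.
#' @return `read_genetic_map()` returns a `genetic_map` tibble;
#'   `write_genetic_map()` returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(),
    chrom = readr::col_character(),
    cM = readr::col_double()
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed map row at line ", probs$row[1] + 1L, " of ", path,
         call. = FALSE)
  }
  validate_genetic_map(raw)
}

#' @rdname read_genetic_map
#' @param map a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  map <- validate_genetic_map(map)
  out <- dplyr::mutate(map, cM = format_cM(.data$cM))
  readr::write_tsv(out, path)
  invisible(path)
}

# fixed-width decimal so write -> read -> write is byte-stable
format_cM <- function(x) formatC(x, format = "f", digits = 4)
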