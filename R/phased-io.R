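#' Read and write phased genotypes
#'
#' Two on-disk formats are supported. (1) A minimal phased VCF: one line
#' per map SNP with `REF=A`, `ALT=B`, `POS` equal to the locus rank within
#' its chromosome (genetic-map coordinates are the single authority and
#' live in the map file) and `|`-phased `GT` fields. (2) A wide
#' tab-separated haplotype table with a `marker` column plus two columns
#' per individual, `<id>_h1` and `<id>_h2`, holding `A`/`B`/`NA`.
#'
#' On reading, unphased (`/`-separated) or half-missing VCF genotypes are
#' set to missing on both homologs and a warning reports how many sites
#' were affected. Markers present in the file but absent from the map are
#' an error; loci are always returned in map order.
#'
#' @param path file path.
#' @param map a [genetic_map()].
#' @return A [phased_pop()] (readers) or `path`, invisibly (writers).
#' @name phased_io
NULL

#' @rdname phased_io
#' @export
read_phased_vcf <- function(path, map) {
  map <- validate_genetic_map(map)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(vcf)
  missing_in_map <- setdiff(ids, map$marker)
  if (length(missing_in_map) > 0) {
    stop("markers absent from map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF contains no samples", call. = FALSE)
  rownames(gt) <- ids
  ploidy_sep <- gsub("[0-9.]", "", gt[!is.na(gt)])
  if (any(nchar(ploidy_sep) > 1)) {
    stop("mixed or non-diploid ploidy in GT field", call. = FALSE)
  }
  parse_one <- function(g) {
    # returns c(h1, h2) in 1/2/NA coding
    if (is.na(g) || g %in% c(".", ".|.", "./.")) return(c(NA_integer_, NA_integer_))
    if (grepl("/", g, fixed = TRUE)) return(c(NA_integer_, NA_integer_))  # unphased
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2 || any(parts == ".")) return(c(NA_integer_, NA_integer_))
    as.integer(parts) + 1L
  }
  gtv <- gt[!is.na(gt)]
  n_bad <- sum(grepl("/", gtv, fixed = TRUE) |
                 grepl("^\\.\\|[0-9]$|^[0-9]\\|\\.$", gtv))
  if (n_bad > 0) {
    warning(n_bad, " unphased or half-missing genotype(s) set to missing",
            call. = FALSE)
  }
  chroms <- unique(map$chrom)
  markers_by_chrom <- map_markers(map)
  haplo <- lapply(colnames(gt), function(sample) {
    calls <- vapply(gt[, sample], parse_one, integer(2))  # 2 x n_sites
    colnames(calls) <- ids
    setNames(lapply(chroms, function(chr) {
      mk <- markers_by_chrom[[chr]]
      m <- matrix(NA_integer_, nrow = 2, ncol = length(mk))
      present <- mk %in% ids
      m[, present] <- calls[, mk[present], drop = FALSE]
      m
    }), chroms)
  })
  names(haplo) <- colnames(gt)
  phased_pop(map, haplo)
}

#' @rdname phased_io
#' @param pop a [phased_pop()].
#' @export
write_phased_vcf <- function(pop, path) {
  map <- pop$map
  pos_rank <- stats::ave(seq_len(nrow(map)), map$chrom, FUN = seq_along)
  ids <- pop_ids(pop)
  gt_code <- function(m, j) {
    h1 <- m[1, j]; h2 <- m[2, j]
    paste0(ifelse(is.na(h1), ".", h1 - 1L), "|", ifelse(is.na(h2), ".", h2 - 1L))
  }
  chroms <- unique(map$chrom)
  body <- character(nrow(map))
  row <- 0L
  for (chr in chroms) {
    mk <- map$marker[map$chrom == chr]
    for (j in seq_along(mk)) {
      row <- row + 1L
      gts <- vapply(ids, function(i) gt_code(pop$haplo[[i]][[chr]], j),
                    character(1))
      body[row] <- paste(c(chr, pos_rank[row], mk[j], "A", "B", ".", "PASS",
                           ".", "GT", gts), collapse = "\t")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", chroms, ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname phased_io
#' @export
read_phased_table <- function(path, map) {
  map <- validate_genetic_map(map)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), .default = readr::col_character()
  ))
  missing_in_map <- setdiff(raw$marker, map$marker)
  if (length(missing_in_map) > 0) {
    stop("markers absent from map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "),
         call. = FALSE)
  }
  hap_cols <- setdiff(names(raw), "marker")
  ids <- unique(sub("_h[12]$", "", hap_cols))
  need <- c(paste0(ids, "_h1"), paste0(ids, "_h2"))
  if (!setequal(hap_cols, need)) {
    stop("haplotype table needs <id>_h1 and <id>_h2 columns per individual",
         call. = FALSE)
  }
  idx <- match(raw$marker, map$marker)
  chroms <- unique(map$chrom)
  markers_by_chrom <- map_markers(map)
  to_code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "A"] <- 1L
    out[x == "B"] <- 2L
    out
  }
  haplo <- setNames(lapply(ids, function(i) {
    full1 <- rep(NA_integer_, nrow(map))
    full2 <- rep(NA_integer_, nrow(map))
    full1[idx] <- to_code(raw[[paste0(i, "_h1")]])
    full2[idx] <- to_code(raw[[paste0(i, "_h2")]])
    setNames(lapply(chroms, function(chr) {
      sel <- map$chrom == chr
      rbind(full1[sel], full2[sel])
    }), chroms)
  }), ids)
  phased_pop(map, haplo)
}

#' @rdname phased_io
#' @export
write_phased_table <- function(pop, path) {
  map <- pop$map
  cols <- list(marker = map$marker)
  to_chr <- function(v) ifelse(is.na(v), NA_character_, allele_chr[v])
  for (i in pop_ids(pop)) {
    h1 <- unlist(lapply(pop$haplo[[i]], function(m) m[1, ]), use.names = FALSE)
    h2 <- unlist(lapply(pop$haplo[[i]], function(m) m[2, ]), use.names = FALSE)
    cols[[paste0(i, "_h1")]] <- to_chr(h1)
    cols[[paste0(i, "_h2")]] <- to_chr(h2)
  }
  readr::write_tsv(tibble::as_tibble(cols), path)
  invisible(path)
}

#' Read and write simulator truth ancestry segments
#'
#' Tab-separated: `id  homolog  chrom  start_cM  end_cM  origin`.
#'
#' @param path file path.
#' @return A tibble (reader) or `path`, invisibly (writer).
#' @export
read_truth_segments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), homolog = readr::col_integer(),
    chrom = readr::col_character(), start_cM = readr::col_double(),
    end_cM = readr::col_double(), origin = readr::col_character()
  ))
}

#' @rdname read_truth_segments
#' @param truth a truth-segment tibble (see [phased_pop()]).
#' @export
write_truth_segments <- function(truth, path) {
  out <- dplyr::mutate(truth,
    start_cM = format_cM(.data$start_cM), end_cM = format_cM(.data$end_cM))
  readr::write_tsv(out, path)
  invisible(path)
}
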