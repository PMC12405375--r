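#' Find shared haplotype segments between two haplotypes
#'
#' A shared segment is a maximal run of matching informative SNPs: a
#' mismatching informative SNP breaks a run; SNPs missing on either
#' haplotype neither break a run nor count toward its SNP total. Runs
#' start and stop at shared informative SNPs (equivalently, at
#' chromosome ends or at shared SNPs adjacent to SNPs that are not
#' shared), and segment bounds in cM are the positions of the first and
#' last shared SNP.
#'
#' @param hap_a,hap_b integer haplotype vectors (1/2/`NA`) in map order
#'   for one chromosome.
#' @param map a [genetic_map()].
#' @param chrom chromosome name (for positions and output labels).
#' @return A tibble with one row per segment: `chrom`, `start_cM`,
#'   `end_cM`, `start_index`, `end_index`, `n_shared_snps`,
#'   `n_missing_spanned`.
#' @export
find_shared_segments <- function(hap_a, hap_b, map, chrom) {
  pos <- map$cM[map$chrom == chrom]
  stopifnot(length(hap_a) == length(pos), length(hap_b) == length(pos))
  informative <- !is.na(hap_a) & !is.na(hap_b)
  idx <- which(informative)
  if (length(idx) == 0) return(empty_segments())
  m <- hap_a[idx] == hap_b[idx]
  # run-length encode the match flags over informative sites
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) return(empty_segments())
  si <- idx[starts[keep]]
  ei <- idx[ends[keep]]
  n_snps <- r$lengths[keep]
  tibble::tibble(
    chrom = chrom,
    start_cM = pos[si],
    end_cM = pos[ei],
    start_index = si,
    end_index = ei,
    n_shared_snps = n_snps,
    n_missing_spanned = (ei - si + 1L) - n_snps
  )
}

empty_segments <- function() {
  tibble::tibble(
    chrom = character(), start_cM = numeric(), end_cM = numeric(),
    start_index = integer(), end_index = integer(),
    n_shared_snps = integer(), n_missing_spanned = integer()
  )
}

#' Define a donor's unadapted haplotypes by subtraction
#'
#' Donor homolog intervals that share a segment of at least `min_snps`
#' informative SNPs with any homolog of any identified domestic ancestor
#' are labeled `domestic`; the complement is labeled `unadapted`. With no
#' ancestors supplied the whole genome is labeled unadapted (vacuous
#' subtraction).
#'
#' @param pop a [phased_pop()] containing the donor and the ancestors.
#' @param donor_id donor individual id.
#' @param ancestor_ids character vector of identified domestic ancestor
#'   ids (possibly empty).
#' @param min_snps minimum informative shared SNPs for a domestic match
#'   (default 16, i.e. "more than 15").
#' @param max_missing_rate refuse chromosomes whose donor missing rate
#'   exceeds this (data-quality guard, default 0.5).
#' @return A list with `intervals` (tibble `homolog`, `chrom`,
#'   `start_index`, `end_index`, `start_cM`, `end_cM`, `origin`) and
#'   `summary` (tibble with `unadapted_cM`, `unadapted_pct` of the
#'   diploid genome).
#' @export
define_unadapted_haplotypes <- function(pop, donor_id, ancestor_ids,
                                        min_snps = 16,
                                        max_missing_rate = 0.5) {
  map <- pop$map
  chroms <- unique(map$chrom)
  out <- list()
  for (chr in chroms) {
    pos <- map$cM[map$chrom == chr]
    for (hom in 1:2) {
      hap <- get_hap(pop, donor_id, chr, hom)
      if (mean(is.na(hap)) > max_missing_rate) {
        stop("donor missing rate above ", max_missing_rate, " on ", chr,
             "; refusing to subtract", call. = FALSE)
      }
      covered <- rep(FALSE, length(hap))
      for (anc in ancestor_ids) {
        for (ahom in 1:2) {
          segs <- find_shared_segments(hap, get_hap(pop, anc, chr, ahom),
                                       map, chr)
          segs <- segs[segs$n_shared_snps >= min_snps, ]
          for (k in seq_len(nrow(segs))) {
            covered[segs$start_index[k]:segs$end_index[k]] <- TRUE
          }
        }
      }
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      out[[length(out) + 1]] <- tibble::tibble(
        homolog = hom, chrom = chr,
        start_index = starts, end_index = ends,
        start_cM = pos[starts], end_cM = pos[ends],
        origin = ifelse(r$values, "domestic", "unadapted")
      )
    }
  }
  intervals <- dplyr::bind_rows(out)
  un <- dplyr::filter(intervals, .data$origin == "unadapted")
  total <- 2 * map_total_length(map)
  list(
    intervals = intervals,
    summary = tibble::tibble(
      id = donor_id,
      unadapted_cM = sum(un$end_cM - un$start_cM),
      unadapted_pct = sum(un$end_cM - un$start_cM) / total * 100
    )
  )
}

#' Filter candidate shared segments
#'
#' Implements the published retention rules for donor-descendant shared
#' haplotypes: a segment must contain at least `min_snps` informative
#' shared SNPs (default 16, i.e. "more than 15") and must not be present
#' in the descendant's non-admixed parent. A segment carried by the
#' parent as well survives only through the extended-region exception:
#' extending outward SNP-by-SNP from the segment on each side, the
#' descendant's haplotype must keep matching the donor strictly further
#' than it matches the parent on at least one side (by at least
#' `min_extension` informative SNPs).
#'
#' @param segments output of [find_shared_segments()] for one
#'   donor-homolog / descendant-homolog pair on one chromosome.
#' @param donor_hap,desc_hap the donor and descendant haplotype vectors
#'   the segments came from.
#' @param parent_haps list of the non-admixed parent's two haplotype
#'   vectors for this chromosome (may be `NULL`: no parent filter).
#' @param min_snps minimum informative shared SNPs (default 16).
#' @param min_extension minimum strict extension (informative SNPs) for
#'   the exception (default 1).
#' @return The retained rows of `segments` with a `disposition` column
#'   (`donor_exclusive` or `exception_retained`).
#' @export
filter_candidate_segments <- function(segments, donor_hap, desc_hap,
                                      parent_haps = NULL, min_snps = 16,
                                      min_extension = 1) {
  segments <- segments[segments$n_shared_snps >= min_snps, ]
  if (nrow(segments) == 0 || is.null(parent_haps)) {
    segments$disposition <- rep("donor_exclusive", nrow(segments))
    return(segments)
  }
  keep <- logical(nrow(segments))
  disposition <- character(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    si <- segments$start_index[k]; ei <- segments$end_index[k]
    in_parent <- any(vapply(parent_haps, function(ph) {
      span_matches(desc_hap, ph, si, ei)
    }, logical(1)))
    if (!in_parent) {
      keep[k] <- TRUE
      disposition[k] <- "donor_exclusive"
    } else {
      # extended-region exception, tested on each side
      left_d <- extension_length(desc_hap, donor_hap, si, -1L)
      left_p <- max(vapply(parent_haps, function(ph)
        extension_length(desc_hap, ph, si, -1L), numeric(1)))
      right_d <- extension_length(desc_hap, donor_hap, ei, +1L)
      right_p <- max(vapply(parent_haps, function(ph)
        extension_length(desc_hap, ph, ei, +1L), numeric(1)))
      if (left_d >= left_p + min_extension ||
          right_d >= right_p + min_extension) {
        keep[k] <- TRUE
        disposition[k] <- "exception_retained"
      }
    }
  }
  out <- segments[keep, ]
  out$disposition <- disposition[keep]
  out
}

# collapse an unphased genotype (2 x L matrix) against a reference
# haplotype: the reference allele where it is observed in the genotype,
# the other allele on an informative mismatch, NA where untyped
geno_pseudo_hap <- function(ref_hap, geno) {
  has_ref <- (!is.na(geno[1, ]) & geno[1, ] == ref_hap) |
    (!is.na(geno[2, ]) & geno[2, ] == ref_hap)
  out <- ifelse(has_ref, ref_hap, 3L - ref_hap)
  out[is.na(geno[1, ]) & is.na(geno[2, ])] <- NA_integer_
  out[is.na(ref_hap)] <- NA_integer_
  as.integer(out)
}

# does hap_b carry the haplotype of hap_a over [si, ei]? missing-tolerant:
# no informative mismatch and at least one informative match
span_matches <- function(hap_a, hap_b, si, ei) {
  a <- hap_a[si:ei]; b <- hap_b[si:ei]
  inf <- !is.na(a) & !is.na(b)
  sum(inf) > 0 && all(a[inf] == b[inf])
}

# number of consecutive informative matching SNPs walking outward from
# `from` (exclusive) in direction `dir` (+1/-1); missing sites are skipped
extension_length <- function(hap_a, hap_b, from, dir) {
  n <- length(hap_a)
  i <- from + dir
  matched <- 0L
  while (i >= 1 && i <= n) {
    if (!is.na(hap_a[i]) && !is.na(hap_b[i])) {
      if (hap_a[i] == hap_b[i]) matched <- matched + 1L else break
    }
    i <- i + dir
  }
  matched
}

#' Trace unadapted donor genome in a descendant
#'
#' Compares each unadapted donor homolog interval (from
#' [define_unadapted_haplotypes()]) against both descendant homologs
#' with [find_shared_segments()], applies the retention rules of
#' [filter_candidate_segments()] against the descendant's non-admixed
#' parent, merges retained segments per descendant homolog, and reports
#' centimorgan totals and the percentage of the diploid genome. Retained
#' segments overlapping an R-gene window are labeled R-gene-linked.
#'
#' @param pop a [phased_pop()] containing donor, descendant and parent.
#' @param descendant_id,donor_id,parent_id individual ids; `parent_id`
#'   (the non-admixed parent) may be `NULL` to skip the parent filter.
#' @param donor_unadapted result of [define_unadapted_haplotypes()] (its
#'   `intervals` element, or the list itself).
#' @param rgene_loci optional tibble of [rgene_locus()] rows.
#' @param min_snps minimum informative shared SNPs (default 16).
#' @param min_extension see [filter_candidate_segments()].
#' @param genotype_mode compare the donor haplotype against the
#'   descendant's (and parent's) unphased observed genotypes instead of
#'   phased homologs: a site matches when the donor allele is among the
#'   observed alleles. Use for null-allele-corrupted data where phase
#'   cannot be trusted; segments then carry `homolog = 0`.
#' @return An `unadapted_report`: list with `id`, `segments` (tibble
#'   `id`, `homolog`, `chrom`, `start_cM`, `end_cM`, `n_snps`,
#'   `disposition`, `rgene_linked`), `total_unadapted_cM`,
#'   `percent_diploid` and `per_chromosome` breakdown.
#' @export
trace_unadapted <- function(pop, descendant_id, donor_id, donor_unadapted,
                            parent_id = NULL, rgene_loci = NULL,
                            min_snps = 16, min_extension = 1,
                            genotype_mode = FALSE) {
  if (is.list(donor_unadapted) && !is.data.frame(donor_unadapted) &&
      "intervals" %in% names(donor_unadapted)) {
    donor_unadapted <- donor_unadapted$intervals
  }
  un <- dplyr::filter(donor_unadapted, .data$origin == "unadapted")
  map <- pop$map
  res <- list()
  for (chr in unique(un$chrom)) {
    un_chr <- un[un$chrom == chr, ]
    n_loci <- sum(map$chrom == chr)
    for (dhom in unique(un_chr$homolog)) {
      ivals <- un_chr[un_chr$homolog == dhom, ]
      donor_hap <- get_hap(pop, donor_id, chr, dhom)
      masked <- rep(NA_integer_, n_loci)
      for (k in seq_len(nrow(ivals))) {
        sel <- ivals$start_index[k]:ivals$end_index[k]
        masked[sel] <- donor_hap[sel]
      }
      if (genotype_mode) {
        # unphased comparison: a site matches when the donor allele is
        # among the descendant's observed alleles
        desc_haps <- list(geno_pseudo_hap(donor_hap,
                                          get_geno(pop, descendant_id, chr)))
        parent_haps <- if (!is.null(parent_id)) {
          list(geno_pseudo_hap(donor_hap, get_geno(pop, parent_id, chr)))
        }
        thoms <- 0L
      } else {
        desc_haps <- list(get_hap(pop, descendant_id, chr, 1),
                          get_hap(pop, descendant_id, chr, 2))
        parent_haps <- if (!is.null(parent_id)) {
          list(get_hap(pop, parent_id, chr, 1),
               get_hap(pop, parent_id, chr, 2))
        }
        thoms <- 1:2
      }
      for (ti in seq_along(desc_haps)) {
        desc_hap <- desc_haps[[ti]]
        segs <- find_shared_segments(masked, desc_hap, map, chr)
        segs <- filter_candidate_segments(segs, masked, desc_hap,
                                          parent_haps, min_snps,
                                          min_extension)
        if (nrow(segs) > 0) {
          segs$target_homolog <- thoms[ti]
          segs$source_homolog <- dhom
          res[[length(res) + 1]] <- segs
        }
      }
    }
  }
  segs_all <- if (length(res)) dplyr::bind_rows(res) else {
    x <- empty_segments()
    x$disposition <- character()
    x$target_homolog <- integer(); x$source_homolog <- integer()
    x
  }
  # merge overlaps per descendant homolog so nothing is double counted
  merged <- if (nrow(segs_all) == 0) {
    tibble::tibble(
      id = character(), chrom = character(), homolog = integer(),
      start_cM = numeric(), end_cM = numeric(), n_snps = integer(),
      disposition = character()
    )
  } else segs_all |>
    dplyr::group_by(.data$chrom, homolog = .data$target_homolog) |>
    dplyr::group_modify(function(d, g) {
      m <- merge_intervals(d$start_cM, d$end_cM)
      m$n_snps <- vapply(seq_len(nrow(m)), function(j) {
        max(d$n_shared_snps[d$start_cM <= m$end_cM[j] &
                              d$end_cM >= m$start_cM[j]])
      }, integer(1))
      m$disposition <- vapply(seq_len(nrow(m)), function(j) {
        dd <- d$disposition[d$start_cM <= m$end_cM[j] &
                              d$end_cM >= m$start_cM[j]]
        if (any(dd == "exception_retained")) "exception_retained"
        else "donor_exclusive"
      }, character(1))
      m
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(id = descendant_id, .before = 1)
  merged$rgene_linked <- FALSE
  if (!is.null(rgene_loci) && nrow(merged) > 0) {
    for (k in seq_len(nrow(rgene_loci))) {
      hit <- merged$chrom == rgene_loci$chrom[k] &
        intervals_overlap(merged$start_cM, merged$end_cM,
                          rgene_loci$window_start_cM[k],
                          rgene_loci$window_end_cM[k])
      merged$rgene_linked <- merged$rgene_linked | hit
    }
  }
  total_cM <- sum(merged$end_cM - merged$start_cM)
  per_chrom <- merged |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(unadapted_cM = sum(.data$end_cM - .data$start_cM),
                     .groups = "drop")
  structure(list(
    id = descendant_id,
    segments = merged[, c("id", "homolog", "chrom", "start_cM", "end_cM",
                          "n_snps", "disposition", "rgene_linked")],
    total_unadapted_cM = total_cM,
    percent_diploid = total_cM / (2 * map_total_length(map)) * 100,
    per_chromosome = per_chrom
  ), class = "unadapted_report")
}

#' @method print unadapted_report
#' @export
print.unadapted_report <- function(x, ...) {
  cat("<unadapted_report> ", x$id, ": ",
      round(x$total_unadapted_cM, 2), " cM unadapted (",
      round(x$percent_diploid, 2), "% of diploid genome), ",
      nrow(x$segments), " segment(s)\n", sep = "")
  if (any(x$segments$disposition == "exception_retained")) {
    cat("  note: extended-region exception fired for ",
        sum(x$segments$disposition == "exception_retained"),
        " segment(s)\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.unadapted_report <- function(x, ...) x$segments

#' @export
glance.unadapted_report <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_segments = nrow(x$segments),
    n_rgene_linked = sum(x$segments$rgene_linked),
    total_unadapted_cM = x$total_unadapted_cM,
    percent_diploid = x$percent_diploid
  )
}

#' Classify a traced descendant by its retained segments
#'
#' `rgene_only` when every retained unadapted segment is R-gene-linked
#' and at least one exists; `rgene_plus_extra` when R-gene-linked and
#' other segments coexist; `no_rgene_segment` otherwise (for a
#' MAS-selected carrier this flags a tracer/MAS conflict).
#'
#' @param report an `unadapted_report` from [trace_unadapted()].
#' @return A length-1 character vector.
#' @export
rgene_only_classifier <- function(report) {
  segs <- report$segments
  if (nrow(segs) == 0 || !any(segs$rgene_linked)) return("no_rgene_segment")
  if (all(segs$rgene_linked)) "rgene_only" else "rgene_plus_extra"
}

#' Trace a cohort of descendants
#'
#' Convenience wrapper running [trace_unadapted()] over many descendants
#' and returning a tidy per-individual summary.
#'
#' @inheritParams trace_unadapted
#' @param descendant_ids character vector of descendant ids.
#' @param parent_ids single id, or named vector mapping descendant id ->
#'   non-admixed parent id, or `NULL`.
#' @return A tibble: `id`, `n_segments`, `n_rgene_linked`,
#'   `total_unadapted_cM`, `percent_diploid`, `class`.
#' @export
trace_cohort <- function(pop, descendant_ids, donor_id, donor_unadapted,
                         parent_ids = NULL, rgene_loci = NULL,
                         min_snps = 16, min_extension = 1,
                         genotype_mode = FALSE) {
  purrr::map_dfr(descendant_ids, function(d) {
    pid <- if (is.null(parent_ids)) NULL
           else if (length(parent_ids) == 1 && is.null(names(parent_ids)))
             parent_ids
           else unname(parent_ids[d])
    rep <- trace_unadapted(pop, d, donor_id, donor_unadapted,
                           parent_id = pid, rgene_loci = rgene_loci,
                           min_snps = min_snps,
                           min_extension = min_extension,
                           genotype_mode = genotype_mode)
    dplyr::mutate(glance(rep), class = rgene_only_classifier(rep))
  })
}
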