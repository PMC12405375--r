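#' Mendelian error rate between two individuals
#'
#' Counts opposing homozygotes (AA vs BB) over jointly non-missing sites
#' of the observed-genotype view. A true parent-offspring duo has rate
#' zero in error-free data; null alleles inflate the rate by making
#' heterozygotes read as homozygotes. The verdict applies a configurable
#' threshold (default 0.5%).
#'
#' @param pop a [phased_pop()].
#' @param id_a,id_b individual ids.
#' @param threshold error-rate threshold for the parent-offspring
#'   verdict.
#' @return A one-row tibble: `id_a`, `id_b`, `n_compared`,
#'   `n_opposing_homozygous`, `error_rate`, `identical_genotypes`,
#'   `verdict` (`parent_offspring_candidate` or `excluded`).
#' @export
mendelian_error_rate <- function(pop, id_a, id_b, threshold = 0.005) {
  n_comp <- 0L
  n_opp <- 0L
  n_same <- 0L
  for (chr in unique(pop$map$chrom)) {
    ga <- get_geno(pop, id_a, chr)
    gb <- get_geno(pop, id_b, chr)
    ok <- !is.na(ga[1, ]) & !is.na(ga[2, ]) & !is.na(gb[1, ]) & !is.na(gb[2, ])
    n_comp <- n_comp + sum(ok)
    hom_a <- ga[1, ] == ga[2, ]
    hom_b <- gb[1, ] == gb[2, ]
    opp <- ok & hom_a & hom_b & ga[1, ] != gb[1, ]
    n_opp <- n_opp + sum(opp)
    same <- ok & (pmin(ga[1, ], ga[2, ]) == pmin(gb[1, ], gb[2, ])) &
      (pmax(ga[1, ], ga[2, ]) == pmax(gb[1, ], gb[2, ]))
    n_same <- n_same + sum(same)
  }
  if (n_comp == 0) stop("zero jointly typed sites", call. = FALSE)
  rate <- n_opp / n_comp
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    n_compared = n_comp,
    n_opposing_homozygous = n_opp,
    error_rate = rate,
    identical_genotypes = n_same == n_comp,
    verdict = ifelse(rate <= threshold, "parent_offspring_candidate",
                     "excluded")
  )
}

#' Infer parent-offspring candidate pairs
#'
#' Computes the duo Mendelian error rate for all pairs and lists those
#' below the threshold. When a recorded pedigree is supplied, recorded
#' parent-offspring pairs whose duo statistic excludes them are reported
#' as conflicts.
#'
#' @param pop a [phased_pop()].
#' @param pedigree optional recorded pedigree tibble (`id`, `mother`,
#'   `father`, ...).
#' @param threshold duo error-rate threshold (default 0.005).
#' @return A list with `duos` (all pairwise summaries), `candidates`
#'   (pairs below threshold) and `conflicts` (recorded parent-offspring
#'   pairs that the data exclude; empty tibble when no pedigree given).
#' @export
infer_parent_offspring <- function(pop, pedigree = NULL, threshold = 0.005) {
  ids <- pop_ids(pop)
  if (length(ids) < 2) {
    empty <- tibble::tibble(
      id_a = character(), id_b = character(), n_compared = integer(),
      n_opposing_homozygous = integer(), error_rate = numeric(),
      identical_genotypes = logical(), verdict = character()
    )
    return(list(duos = empty, candidates = empty,
                conflicts = empty[, c("id_a", "id_b")]))
  }
  pairs <- utils::combn(ids, 2)
  duos <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    mendelian_error_rate(pop, pairs[1, k], pairs[2, k], threshold)
  })
  candidates <- dplyr::filter(duos,
                              .data$verdict == "parent_offspring_candidate")
  conflicts <- tibble::tibble(id_a = character(), id_b = character())
  if (!is.null(pedigree)) {
    rec <- dplyr::bind_rows(
      tibble::tibble(id_a = pedigree$id, id_b = pedigree$mother),
      tibble::tibble(id_a = pedigree$id, id_b = pedigree$father)
    ) |>
      dplyr::filter(!is.na(.data$id_b), .data$id_a %in% ids,
                    .data$id_b %in% ids)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    excluded <- duos[duos$verdict == "excluded", ]
    conflicts <- rec[key(rec$id_a, rec$id_b) %in%
                       key(excluded$id_a, excluded$id_b), ]
  }
  list(duos = duos, candidates = candidates, conflicts = conflicts)
}

#' Adjust genotype calls at null-allele sites
#'
#' Sites showing the opposing-homozygote pattern between a parent and
#' its offspring are treated as null-allele artifacts. In the
#' conservative default mode every conflicting genotype (parent and
#' offspring) is set to missing. In `"recode"` mode, a parent conflict
#' replicated in at least `min_offspring` independent offspring recodes
#' the parent to a heterozygote (its visible allele plus the opposing
#' allele, i.e. heterozygous-with-null); with fewer replicates the site
#' falls back to the conservative rule. Every change is logged.
#'
#' @param pop a [phased_pop()].
#' @param parent_id the parent whose calls are audited.
#' @param offspring_ids offspring used as evidence.
#' @param mode `"missing"` (conservative default) or `"recode"`.
#' @param min_offspring replicates required to recode (default 2).
#' @return A list with `pop` (adjusted observed-genotype view) and
#'   `changes` (tibble: `id`, `marker`, `chrom`, `action`, `from`, `to`).
#' @export
adjust_null_allele_calls <- function(pop, parent_id, offspring_ids,
                                     mode = c("missing", "recode"),
                                     min_offspring = 2) {
  mode <- match.arg(mode)
  obs <- pop$obs %||% pop$haplo
  changes <- list()
  geno_str <- function(g) {
    if (anyNA(g)) "NA/NA" else paste(allele_chr[sort(g)], collapse = "/")
  }
  for (chr in unique(pop$map$chrom)) {
    mk <- pop$map$marker[pop$map$chrom == chr]
    gp <- obs[[parent_id]][[chr]]
    hom_p <- !is.na(gp[1, ]) & !is.na(gp[2, ]) & gp[1, ] == gp[2, ]
    conf <- matrix(FALSE, nrow = length(offspring_ids), ncol = ncol(gp))
    for (oi in seq_along(offspring_ids)) {
      go <- obs[[offspring_ids[oi]]][[chr]]
      hom_o <- !is.na(go[1, ]) & !is.na(go[2, ]) & go[1, ] == go[2, ]
      conf[oi, ] <- hom_p & hom_o & gp[1, ] != go[1, ]
    }
    n_conf <- colSums(conf)
    for (j in which(n_conf > 0)) {
      if (mode == "recode" && n_conf[j] >= min_offspring) {
        old <- gp[, j]
        other <- 3L - old[1]
        obs[[parent_id]][[chr]][, j] <- c(old[1], other)
        changes[[length(changes) + 1]] <- tibble::tibble(
          id = parent_id, marker = mk[j], chrom = chr,
          action = "recoded_het_with_null",
          from = geno_str(old), to = geno_str(c(old[1], other))
        )
      } else {
        for (who in c(parent_id, offspring_ids[conf[, j]])) {
          old <- obs[[who]][[chr]][, j]
          obs[[who]][[chr]][, j] <- NA_integer_
          changes[[length(changes) + 1]] <- tibble::tibble(
            id = who, marker = mk[j], chrom = chr,
            action = "set_missing", from = geno_str(old), to = "NA/NA"
          )
        }
      }
    }
  }
  pop$obs <- obs
  list(pop = pop,
       changes = if (length(changes)) dplyr::bind_rows(changes)
                 else tibble::tibble(id = character(), marker = character(),
                                     chrom = character(), action = character(),
                                     from = character(), to = character()))
}

#' Genome-wide haplotype sharing between two individuals
#'
#' Runs the shared-segment caller over every homolog pairing and reports
#' the percentage of the map covered by shared segments of at least
#' `min_segment_snps` SNPs: per pairing, the maximum over pairings, and
#' a per-individual sharing score (`share_pct`) defined as the mean over
#' the target's two homologs of the fraction covered by sharing with
#' either source homolog. The score is approximately 100% for
#' duplicates, 50% for parent-offspring and 25% for
#' grandparent-grandchild; it screens for distant relatives.
#'
#' @param pop a [phased_pop()].
#' @param id_a source individual.
#' @param id_b target individual.
#' @param min_segment_snps minimum SNPs per counted segment (default 16).
#' @return A list with `pairings` (tibble `homolog_a`, `homolog_b`,
#'   `shared_cM`, `shared_pct`), `max_pairing_pct` and `share_pct`.
#' @export
genomewide_sharing_fraction <- function(pop, id_a, id_b,
                                        min_segment_snps = 16) {
  map <- pop$map
  L <- map_total_length(map)
  chroms <- unique(map$chrom)
  seg_list <- list()
  for (ha in 1:2) for (hb in 1:2) {
    for (chr in chroms) {
      segs <- find_shared_segments(get_hap(pop, id_a, chr, ha),
                                   get_hap(pop, id_b, chr, hb), map, chr)
      segs <- segs[segs$n_shared_snps >= min_segment_snps, ]
      if (nrow(segs) > 0) {
        seg_list[[length(seg_list) + 1]] <-
          dplyr::mutate(segs, homolog_a = ha, homolog_b = hb)
      }
    }
  }
  segs_all <- if (length(seg_list)) dplyr::bind_rows(seg_list) else {
    dplyr::mutate(empty_segments(), homolog_a = integer(),
                  homolog_b = integer())
  }
  pairings <- tidyr::expand_grid(homolog_a = 1:2, homolog_b = 1:2) |>
    dplyr::left_join(
      segs_all |>
        dplyr::group_by(.data$homolog_a, .data$homolog_b, .data$chrom) |>
        dplyr::summarise(
          cM = interval_union_length(.data$start_cM, .data$end_cM),
          .groups = "drop") |>
        dplyr::group_by(.data$homolog_a, .data$homolog_b) |>
        dplyr::summarise(shared_cM = sum(.data$cM), .groups = "drop"),
      by = c("homolog_a", "homolog_b")
    ) |>
    dplyr::mutate(shared_cM = dplyr::coalesce(.data$shared_cM, 0),
                  shared_pct = .data$shared_cM / L * 100)
  # per target homolog: union over source homologs
  by_target <- vapply(1:2, function(hb) {
    d <- segs_all[segs_all$homolog_b == hb, ]
    if (nrow(d) == 0) return(0)
    sum(vapply(split(d, d$chrom), function(dc)
      interval_union_length(dc$start_cM, dc$end_cM), numeric(1))) / L * 100
  }, numeric(1))
  list(
    pairings = pairings,
    max_pairing_pct = max(pairings$shared_pct),
    share_pct = mean(by_target)
  )
}
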