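#' Generate an apple-like genetic map
#'
#' Deterministic for a fixed seed. Each chromosome carries its first SNP
#' at 0 cM and its last at `chrom_length_cM`; interior positions are
#' sorted uniform draws. The default desk-scale map (17 linkage groups
#' named `LG01..LG17`, 100 SNPs each, 80 cM each) mirrors the shape of a
#' dense curated apple array map at a size that keeps simulations fast;
#' scale `snps_per_chrom` up for higher resolution.
#'
#' @param n_chrom number of linkage groups (named `LG01`, `LG02`, ...).
#' @param chrom_length_cM length of every chromosome in centimorgans.
#' @param snps_per_chrom number of SNP loci per chromosome (>= 2).
#' @param seed integer seed; the map is a pure function of its arguments.
#' @return A [genetic_map()].
#' @examples
#' make_apple_map(1, 10, 2, seed = 1)
#' @export
make_apple_map <- function(n_chrom = 17, chrom_length_cM = 80,
                           snps_per_chrom = 100, seed = 1) {
  stopifnot(snps_per_chrom >= 2, n_chrom >= 1, chrom_length_cM > 0)
  withr::with_seed(seed, {
    chroms <- sprintf("LG%02d", seq_len(n_chrom))
    purrr::map_dfr(chroms, function(chr) {
      pos <- c(0, sort(runif(snps_per_chrom - 2, 0, chrom_length_cM)),
               chrom_length_cM)
      pos <- round(pos, 4)
      while (anyDuplicated(pos)) {  # ties after rounding: redraw offenders
        k <- which(duplicated(pos))
        pos[k] <- round(runif(length(k), 0, chrom_length_cM), 4)
        pos <- sort(pos)
        pos[1] <- 0; pos[length(pos)] <- chrom_length_cM
      }
      tibble::tibble(
        marker = sprintf("%s_%05d", chr, seq_len(snps_per_chrom)),
        chrom = chr, cM = pos
      )
    }) |>
      validate_genetic_map()
  })
}

#' Describe an R-gene locus
#'
#' A named resistance locus with a point position and a closed window
#' (in cM) that contains the gene; tracing labels retained segments that
#' overlap the window as R-gene-linked, and marker-assisted selection
#' places its diagnostic markers inside the window.
#'
#' @param name gene name (e.g. `"Fb_E"`, `"FB_MR5"`).
#' @param chrom chromosome name.
#' @param position_cM point position of the gene.
#' @param window_cM length-2 numeric, closed window containing the gene.
#' @return A one-row tibble with columns `rgene`, `chrom`, `position_cM`,
#'   `window_start_cM`, `window_end_cM`.
#' @export
rgene_locus <- function(name, chrom, position_cM, window_cM) {
  stopifnot(length(window_cM) == 2, window_cM[1] <= position_cM,
            position_cM <= window_cM[2])
  tibble::tibble(
    rgene = name, chrom = chrom, position_cM = position_cM,
    window_start_cM = window_cM[1], window_end_cM = window_cM[2]
  )
}

#' Founder specification for the synthetic donor
#'
#' @param id donor id.
#' @param unadapted_fraction target fraction of the donor's diploid genome
#'   of unadapted exotic origin (e.g. 0.75 for an MR5-like donor, 0.50 for
#'   an 'Evereste'-like donor).
#' @param rgenes optional tibble of [rgene_locus()] rows carried (in
#'   coupling) on the donor's exotic homolog.
#' @return A list of class `founder_spec`.
#' @export
founder_spec <- function(id, unadapted_fraction, rgenes = NULL) {
  stopifnot(unadapted_fraction >= 0, unadapted_fraction <= 1)
  structure(list(id = id, unadapted_fraction = unadapted_fraction,
                 rgenes = rgenes), class = "founder_spec")
}

#' Simulate founders with labeled unadapted genome
#'
#' Builds a donor whose diploid genome carries the requested fraction of
#' unadapted exotic origin, the donor's domestic pseudo-parent (the
#' identified ancestor used later for subtraction), and a pool of
#' unrelated domestic founders. The donor follows the admixed-parent
#' construction: homolog 1 is fully exotic (or a mosaic for fractions
#' below one half), homolog 2 is a copy of the domestic pseudo-parent's
#' first homolog with one exotic block per chromosome overwritten so the
#' diploid exotic fraction hits the target exactly (in cM, up to map
#' resolution at segment edges).
#'
#' Exotic and domestic allele-frequency profiles are drawn independently
#' (Uniform(0, 1) per SNP), so exotic haplotypes share no extended runs
#' with domestic material. At the diagnostic marker SNPs of any supplied
#' R-gene (the loci inside its window), the domestic pool is fixed for
#' `A` and the exotic profile for `B`, so the coupling allele `B` is
#' donor-exclusive, as real MAS markers are.
#'
#' @param map a [genetic_map()].
#' @param donor a [founder_spec()].
#' @param n_domestic number of unrelated domestic founders to simulate.
#' @param seed integer seed.
#' @param n_panel_snps diagnostic SNPs per R-gene window (default 3).
#' @return A list with elements `pop` (a [phased_pop()] carrying truth
#'   ancestry segments), `panel` (a marker-panel tibble for
#'   [screen_population()]; `NULL` when the donor has no R-genes),
#'   `domestic_ancestors` (ids of the donor's identified domestic
#'   pseudo-parent) and `freqs` (the per-SNP domestic and exotic allele
#'   frequency profiles, used to draw fresh recurrent parents).
#' @export
make_founders <- function(map, donor, n_domestic = 4, seed = 1,
                          n_panel_snps = 3) {
  stopifnot(inherits(donor, "founder_spec"))
  map <- validate_genetic_map(map)
  withr::with_seed(seed, {
    chroms <- unique(map$chrom)
    pos <- map_positions(map)
    spans <- chrom_lengths(map)
    f <- donor$unadapted_fraction

    # per-homolog exotic fractions (admixed-parent construction)
    if (f >= 0.5) {
      p1 <- 1; p2 <- 2 * f - 1
    } else {
      p1 <- 2 * f; p2 <- 0
    }
    # feasibility: a partial exotic block must be guaranteed to contain at
    # least one SNP wherever it lands, i.e. be longer than the widest
    # inter-SNP gap on every chromosome
    max_gap <- purrr::map_dbl(pos, ~ max(diff(.x)))
    for (p in c(p1, p2)) {
      if (p > 0 && p < 1 &&
          any(p * spans$length_cM <= max_gap[spans$chrom])) {
        stop("unadapted_fraction ", f,
             " is not attainable at this map resolution", call. = FALSE)
      }
    }

    dom_freq <- runif(nrow(map))   # frequency of allele B, domestic pool
    exo_freq <- runif(nrow(map))   # frequency of allele B, exotic pool

    panel <- NULL
    if (!is.null(donor$rgenes)) {
      panel <- purrr::pmap_dfr(donor$rgenes, function(rgene, chrom,
                                                      position_cM,
                                                      window_start_cM,
                                                      window_end_cM) {
        in_win <- which(map$chrom == chrom & map$cM >= window_start_cM &
                          map$cM <= window_end_cM)
        if (length(in_win) == 0) {
          stop("R-gene window for ", rgene, " contains no map SNP",
               call. = FALSE)
        }
        take <- in_win[order(abs(map$cM[in_win] - position_cM))]
        take <- sort(utils::head(take, n_panel_snps))
        tibble::tibble(
          rgene = rgene, linkage_group = chrom, marker = map$marker[take],
          marker_type = "SNP", coupling_allele = "B", gala_ref = "A/A"
        )
      })
      fixed <- match(panel$marker, map$marker)
      dom_freq[fixed] <- 0   # domestic pool never carries the coupling allele
      exo_freq[fixed] <- 1   # exotic haplotypes always do
    }

    draw_hap <- function(freq_by_chrom) {
      setNames(lapply(chroms, function(chr) {
        fr <- freq_by_chrom[[chr]]
        1L + rbinom(length(fr), 1, fr)
      }), chroms)
    }
    dom_by_chrom <- split(dom_freq, factor(map$chrom, levels = chroms))
    exo_by_chrom <- split(exo_freq, factor(map$chrom, levels = chroms))

    # unrelated domestic founders + the donor's domestic pseudo-parent
    dom_ids <- sprintf("DOM%02d", seq_len(n_domestic))
    anc_id <- paste0(donor$id, "_domparent")
    haplo <- list()
    truth <- list()
    for (i in c(dom_ids, anc_id)) {
      h1 <- draw_hap(dom_by_chrom)
      h2 <- draw_hap(dom_by_chrom)
      haplo[[i]] <- setNames(
        lapply(chroms, function(chr) rbind(h1[[chr]], h2[[chr]])), chroms)
      truth[[i]] <- domestic_tiles(i, spans)
    }

    # donor homologs: exotic blocks overwrite a domestic background copy.
    # The donor must be heterozygous at its R-gene loci, so the
    # non-carrier homolog carries no exotic material on R-gene
    # chromosomes; its per-chromosome fraction elsewhere is scaled up to
    # keep the diploid total exact.
    rgene_tbl <- donor$rgenes
    frac_for <- function(hom, chr) {
      p <- if (hom == 1) p1 else p2
      if (is.null(rgene_tbl) || p == 0) return(p)
      rg_chrom <- unique(rgene_tbl$chrom)
      if (hom == 1) return(p)
      if (chr %in% rg_chrom) return(0)
      L_tot <- sum(spans$length_cM)
      L_rg <- sum(spans$length_cM[spans$chrom %in% rg_chrom])
      p_scaled <- p * L_tot / (L_tot - L_rg)
      if (p_scaled > 1) {
        stop("unadapted_fraction ", f, " cannot keep the R-gene loci ",
             "heterozygous on this map", call. = FALSE)
      }
      p_scaled
    }
    exotic_block <- function(chr, p, carrier) {
      # returns c(start, end) of the exotic block on this chromosome, or
      # NULL when p == 0; covers the R-gene window when carrier is TRUE
      sp <- spans[spans$chrom == chr, ]
      if (p <= 0) return(NULL)
      if (p >= 1) return(c(sp$start_cM, sp$end_cM))
      len <- p * sp$length_cM
      lo <- sp$start_cM; hi <- sp$end_cM - len
      if (carrier) {
        win <- rgene_tbl[rgene_tbl$chrom == chr, ]
        # block must contain [window_start, window_end]
        lo <- max(lo, max(win$window_end_cM) - len)
        hi <- min(hi, min(win$window_start_cM))
        if (lo > hi) {
          stop("R-gene window on ", chr,
               " does not fit inside the exotic block", call. = FALSE)
        }
      }
      s <- runif(1, lo, hi)
      c(s, s + len)
    }

    donor_hap <- setNames(vector("list", length(chroms)), chroms)
    donor_truth <- list()
    anc <- haplo[[anc_id]]
    for (chr in chroms) {
      sp <- spans[spans$chrom == chr, ]
      p <- pos[[chr]]
      carrier_here <- !is.null(rgene_tbl) && chr %in% rgene_tbl$chrom
      h <- matrix(NA_integer_, 2, length(p))
      for (hom in 1:2) {
        ph <- frac_for(hom, chr)
        base <- anc[[chr]][hom, ]           # domestic background
        blk <- exotic_block(chr, ph, carrier_here && hom == 1)
        if (is.null(blk)) {
          h[hom, ] <- base
          donor_truth[[length(donor_truth) + 1]] <- tibble::tibble(
            id = donor$id, homolog = hom, chrom = chr,
            start_cM = sp$start_cM, end_cM = sp$end_cM, origin = "domestic")
        } else {
          inside <- p >= blk[1] & p <= blk[2]
          hap <- base
          hap[inside] <- 1L + rbinom(sum(inside), 1, exo_by_chrom[[chr]][inside])
          h[hom, ] <- hap
          segs <- tibble::tibble(
            id = donor$id, homolog = hom, chrom = chr,
            start_cM = c(sp$start_cM, blk[1], blk[2]),
            end_cM = c(blk[1], blk[2], sp$end_cM),
            origin = c("domestic", "exotic", "domestic"))
          donor_truth[[length(donor_truth) + 1]] <-
            segs[segs$end_cM > segs$start_cM | segs$origin == "exotic", ]
        }
      }
      donor_hap[[chr]] <- h
    }
    haplo[[donor$id]] <- donor_hap
    truth[[donor$id]] <- dplyr::bind_rows(donor_truth)

    # the pseudo-parent is a genetic parent only when the donor's second
    # homolog is an intact copy of it (Evereste-like, p2 = 0); with a
    # partially overwritten homolog (MR5-like) it is a more distant
    # identified ancestor and is not recorded as a pedigree parent
    donor_mother <- if (p2 == 0) anc_id else NA_character_
    meta <- tibble::tibble(
      id = names(haplo),
      mother = ifelse(names(haplo) == donor$id, donor_mother, NA_character_),
      father = NA_character_,
      generation = ifelse(names(haplo) == donor$id, "donor", "founder")
    )
    pop <- phased_pop(map, haplo, meta = meta,
                      truth = dplyr::bind_rows(truth))
    list(pop = pop, panel = panel, domestic_ancestors = anc_id,
         freqs = tibble::tibble(marker = map$marker, dom_freq = dom_freq,
                                exo_freq = exo_freq))
  })
}

# one all-domestic tile per homolog per chromosome
domestic_tiles <- function(id, spans) {
  tidyr::expand_grid(homolog = 1:2, chrom = spans$chrom) |>
    dplyr::left_join(spans, by = "chrom") |>
    dplyr::transmute(id = id, homolog = .data$homolog, chrom = .data$chrom,
                     start_cM = .data$start_cM, end_cM = .data$end_cM,
                     origin = "domestic")
}

#' Inject null-allele and missingness noise
#'
#' A null allele makes a true heterozygote read as homozygous for the
#' visible allele in the observed-genotype view; the true haplotypes are
#' retained untouched, so tracing accuracy can be measured against truth.
#' Missingness sets both observed alleles to `NA`.
#'
#' @param pop a [phased_pop()].
#' @param null_allele_rate per-SNP probability that a true heterozygote is
#'   read as homozygous for the visible allele.
#' @param missing_rate per-SNP probability that a genotype is read as
#'   missing.
#' @param seed integer seed.
#' @param null_which which allele drops out at a selected heterozygous
#'   site: `"random"` (default), `"A"` or `"B"`.
#' @return A list with `pop` (the population with an updated
#'   observed-genotype view) and `n_injected` (count of null-allele
#'   sites injected).
#' @export
inject_null_alleles <- function(pop, null_allele_rate = 0.02,
                                missing_rate = 0, seed = 1,
                                null_which = c("random", "A", "B")) {
  stopifnot(null_allele_rate >= 0, null_allele_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  null_which <- match.arg(null_which)
  withr::with_seed(seed, {
    obs <- pop$obs %||% pop$haplo
    n_injected <- 0L
    for (i in names(obs)) {
      for (chr in names(obs[[i]])) {
        m <- obs[[i]][[chr]]
        het <- which(!is.na(m[1, ]) & !is.na(m[2, ]) & m[1, ] != m[2, ])
        if (null_allele_rate > 0 && length(het) > 0) {
          hit <- het[runif(length(het)) < null_allele_rate]
          if (length(hit) > 0) {
            dropped <- switch(null_which,
              random = ifelse(runif(length(hit)) < 0.5, 1L, 2L),
              A = 1L, B = 2L)
            visible <- 3L - dropped
            m[1, hit] <- visible
            m[2, hit] <- visible
            n_injected <- n_injected + length(hit)
          }
        }
        if (missing_rate > 0) {
          gone <- which(runif(ncol(m)) < missing_rate)
          m[, gone] <- NA_integer_
        }
        obs[[i]][[chr]] <- m
      }
    }
    pop$obs <- obs
    list(pop = pop, n_injected = n_injected)
  })
}
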