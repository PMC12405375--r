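#' Simulate a single gamete
#'
#' Haldane model: per chromosome the crossover count is Poisson with mean
#' equal to the chromosome length in Morgans (cM / 100), breakpoints are
#' uniform on the chromosome span, there is no interference and no
#' obligate chiasma. Ancestry labels, when the parent carries truth
#' segments, are spliced at the same breakpoints.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] (or call via
#' [run_pbc_series()], which seeds once) for reproducibility.
#'
#' @param pop a [phased_pop()].
#' @param id parent individual id.
#' @return A list with `alleles` (named list chrom -> integer vector) and
#'   `truth` (tibble `chrom`, `start_cM`, `end_cM`, `origin`; empty when
#'   the parent carries no truth labels).
#' @export
simulate_gamete <- function(pop, id) {
  stopifnot(id %in% pop_ids(pop))
  g <- gamete_raw(pop$haplo[[id]], truth_split(pop$truth, id),
                  map_positions(pop$map), chrom_lengths(pop$map))
  list(alleles = g$alleles,
       truth = tibble::tibble(chrom = g$chrom, start_cM = g$start,
                              end_cM = g$end, origin = g$origin))
}

# per-chromosome list of base-R truth columns for one individual
truth_split <- function(truth, id) {
  tr <- truth[truth$id == id, ]
  if (nrow(tr) == 0) return(NULL)
  lapply(split(seq_len(nrow(tr)), tr$chrom), function(i) {
    list(homolog = tr$homolog[i], start = tr$start_cM[i],
         end = tr$end_cM[i], origin = tr$origin[i])
  })
}

# core gamete draw on pre-extracted structures (hot path: base R only);
# truth comes back as parallel vectors, not a tibble
gamete_raw <- function(hap_ind, tr_ind, pos, spans) {
  alleles <- list()
  t_chr <- t_s <- t_e <- t_o <- list()
  for (k in seq_len(nrow(spans))) {
    chr <- spans$chrom[k]
    p <- pos[[chr]]
    lo <- spans$start_cM[k]; hi <- spans$end_cM[k]
    n_xo <- rpois(1, (hi - lo) / 100)
    bp <- sort(runif(n_xo, lo, hi))
    h0 <- sample(1:2, 1)
    nsw <- findInterval(p, bp)
    hom <- ifelse(nsw %% 2 == 0, h0, 3L - h0)
    m <- hap_ind[[chr]]
    alleles[[chr]] <- m[cbind(hom, seq_along(p))]
    ct <- if (is.null(tr_ind)) NULL else tr_ind[[chr]]
    if (!is.null(ct)) {
      sp <- splice_truth(ct, bp, h0, lo, hi)
      if (length(sp$start)) {
        t_chr[[chr]] <- rep(chr, length(sp$start))
        t_s[[chr]] <- sp$start; t_e[[chr]] <- sp$end; t_o[[chr]] <- sp$origin
      }
    }
  }
  list(alleles = alleles,
       chrom = unlist(t_chr, use.names = FALSE) %||% character(),
       start = unlist(t_s, use.names = FALSE) %||% numeric(),
       end = unlist(t_e, use.names = FALSE) %||% numeric(),
       origin = unlist(t_o, use.names = FALSE) %||% character())
}

# splice parent truth segments at crossover breakpoints (base R)
splice_truth <- function(ct, bp, h0, lo, hi) {
  cuts <- c(lo, bp, hi)
  n_int <- length(cuts) - 1L
  s <- e <- numeric(0)
  o <- character(0)
  for (j in seq_len(n_int)) {
    a <- cuts[j]; b <- cuts[j + 1]
    hom <- if (j %% 2 == 1) h0 else 3L - h0
    sel <- which(ct$homolog == hom & ct$start < b & ct$end > a)
    if (length(sel)) {
      s <- c(s, pmax(ct$start[sel], a))
      e <- c(e, pmin(ct$end[sel], b))
      o <- c(o, ct$origin[sel])
    }
  }
  if (length(s) > 1) {
    ord <- order(s)
    s <- s[ord]; e <- e[ord]; o <- o[ord]
    n <- length(s)
    # merge adjacent pieces with the same origin
    new_run <- c(TRUE, o[-1] != o[-n] | s[-1] - e[-n] > 1e-9)
    run_id <- cumsum(new_run)
    first <- which(new_run)
    last <- c(first[-1] - 1L, n)
    s <- s[first]; e <- e[last]; o <- o[first]
  }
  list(start = s, end = e, origin = o)
}

#' Cross two individuals
#'
#' Each offspring combines one maternal gamete (homolog 1) and one
#' paternal gamete (homolog 2); truth ancestry is inherited with the
#' gametes. Uses the current RNG state.
#'
#' @param pop a [phased_pop()] containing both parents.
#' @param mother,father parent ids.
#' @param n_offspring number of offspring.
#' @param prefix id prefix for offspring (default `"<mother>x<father>"`).
#' @param generation generation label recorded in the offspring metadata.
#' @param track_ancestry splice truth ancestry labels into the offspring
#'   (default `TRUE`); disable for very large crosses where only
#'   genotypes are needed.
#' @return A [phased_pop()] of the offspring only.
#' @export
make_cross <- function(pop, mother, father, n_offspring,
                       prefix = NULL, generation = "offspring",
                       track_ancestry = TRUE) {
  stopifnot(mother %in% pop_ids(pop), father %in% pop_ids(pop))
  prefix <- prefix %||% paste0(mother, "x", father)
  chroms <- unique(pop$map$chrom)
  ids <- if (n_offspring > 0) sprintf("%s_%03d", prefix, seq_len(n_offspring))
         else character()
  meta <- tibble::tibble(id = ids, mother = mother, father = father,
                         generation = generation)
  if (n_offspring == 0) {
    return(phased_pop(pop$map, structure(list(), names = character()),
                      meta = meta[0, ], truth = empty_truth()))
  }
  pos <- map_positions(pop$map)
  spans <- chrom_lengths(pop$map)
  tr_m <- if (track_ancestry) truth_split(pop$truth, mother)
  tr_f <- if (track_ancestry) truth_split(pop$truth, father)
  haplo <- vector("list", length(ids))
  names(haplo) <- ids
  t_id <- t_hom <- t_chr <- t_s <- t_e <- t_o <- vector("list", 2 * length(ids))
  for (j in seq_along(ids)) {
    i <- ids[j]
    gm <- gamete_raw(pop$haplo[[mother]], tr_m, pos, spans)
    gf <- gamete_raw(pop$haplo[[father]], tr_f, pos, spans)
    haplo[[j]] <- setNames(lapply(chroms, function(chr) {
      rbind(gm$alleles[[chr]], gf$alleles[[chr]])
    }), chroms)
    if (track_ancestry) {
      k <- 2 * j - 1
      t_id[[k]] <- rep(i, length(gm$chrom))
      t_hom[[k]] <- rep(1L, length(gm$chrom))
      t_chr[[k]] <- gm$chrom; t_s[[k]] <- gm$start
      t_e[[k]] <- gm$end; t_o[[k]] <- gm$origin
      t_id[[k + 1]] <- rep(i, length(gf$chrom))
      t_hom[[k + 1]] <- rep(2L, length(gf$chrom))
      t_chr[[k + 1]] <- gf$chrom; t_s[[k + 1]] <- gf$start
      t_e[[k + 1]] <- gf$end; t_o[[k + 1]] <- gf$origin
    }
  }
  truth <- if (track_ancestry) {
    tibble::tibble(
      id = unlist(t_id, use.names = FALSE),
      homolog = unlist(t_hom, use.names = FALSE),
      chrom = unlist(t_chr, use.names = FALSE),
      start_cM = unlist(t_s, use.names = FALSE),
      end_cM = unlist(t_e, use.names = FALSE),
      origin = unlist(t_o, use.names = FALSE)
    )
  } else empty_truth()
  phased_pop(pop$map, haplo, meta = meta, truth = truth)
}

#' Flowering attrition over vernalization cycles
#'
#' Each individual flowers at cycle `k` with probability `p_k`
#' conditional on not having flowered before; at most four cycles are
#' allowed (individuals that never flowered within the supplied cycles
#' are discarded from the program).
#'
#' @param data a data frame with an `id` column (e.g. the `meta` of a
#'   [phased_pop()]).
#' @param flowering_probs numeric vector (length 1-4) of per-cycle
#'   conditional flowering probabilities.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return The input tibble with added `flowered` (logical) and
#'   `flowering_cycle` (integer, `NA` if never flowered).
#' @export
apply_flowering_attrition <- function(data, flowering_probs, seed = NULL) {
  if (length(flowering_probs) > 4) {
    stop("at most 4 vernalization cycles are supported", call. = FALSE)
  }
  stopifnot(all(flowering_probs >= 0), all(flowering_probs <= 1),
            "id" %in% names(data))
  run <- function() {
    n <- nrow(data)
    cycle <- rep(NA_integer_, n)
    alive <- rep(TRUE, n)
    for (k in seq_along(flowering_probs)) {
      fl <- alive & runif(n) < flowering_probs[k]
      cycle[fl] <- k
      alive <- alive & !fl
    }
    dplyr::mutate(tibble::as_tibble(data),
                  flowered = !is.na(cycle), flowering_cycle = cycle)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Configure a pseudo-backcross program
#'
#' @param n_generations number of crossing generations (= meioses from
#'   the donor; generation labels run F1, pBC1, pBC2, ...).
#' @param offspring_per_cross offspring produced per cross.
#' @param required_rgenes character vector of R-genes that foreground
#'   MAS must retain; `NULL` disables foreground selection (all offspring
#'   are eligible), as in a drift-only halving-law run.
#' @param flowering_probs per-cycle flowering probabilities (max 4), or
#'   `NULL` for no attrition.
#' @param background_selection `"off"` or `"min_donor_fraction"` (rank
#'   eligible carriers by true unadapted fraction, keep the lowest).
#' @param n_parents_per_gen carriers used as parents for the next
#'   generation.
#' @param seed integer seed for the whole program run.
#' @return A list of class `program_config`.
#' @export
program_config <- function(n_generations, offspring_per_cross = 60,
                           required_rgenes = NULL, flowering_probs = NULL,
                           background_selection = c("off", "min_donor_fraction"),
                           n_parents_per_gen = 2, seed = 1) {
  stopifnot(n_generations >= 1, offspring_per_cross >= 0)
  if (!is.null(flowering_probs)) {
    stopifnot(length(flowering_probs) <= 4,
              all(flowering_probs >= 0), all(flowering_probs <= 1))
  }
  structure(list(
    n_generations = n_generations,
    offspring_per_cross = offspring_per_cross,
    required_rgenes = required_rgenes,
    flowering_probs = flowering_probs,
    background_selection = match.arg(background_selection),
    n_parents_per_gen = n_parents_per_gen,
    seed = seed
  ), class = "program_config")
}

#' Run a multi-generation marker-assisted pseudo-backcross program
#'
#' Starting from a donor founder, each generation crosses the current
#' carrier parents to fresh, unrelated domestic recurrent parents (drawn
#' from the domestic allele-frequency profile, mimicking the use of many
#' distinct elite cultivars), retains offspring that carry all required
#' R-genes (via [screen_population()]), optionally applies flowering
#' attrition and background selection, and promotes surviving carriers
#' to parents of the next generation.
#'
#' @param founders the list returned by [make_founders()].
#' @param config a [program_config()].
#' @return A list with `pop` (all simulated individuals with metadata and
#'   truth ancestry), `summary` (per-generation tibble: label, meiosis
#'   count, offspring, carriers, flowered, parents used) and `pedigree`
#'   (tibble view of the metadata).
#' @export
run_pbc_series <- function(founders, config) {
  stopifnot(inherits(config, "program_config"))
  pop <- founders$pop
  panel <- founders$panel
  donor_id <- pop$meta$id[pop$meta$generation == "donor"]
  stopifnot(length(donor_id) == 1)
  if (!is.null(config$required_rgenes)) {
    if (is.null(panel) ||
        !all(config$required_rgenes %in% panel$rgene)) {
      stop("panel does not cover the required R-genes", call. = FALSE)
    }
  }
  withr::with_seed(config$seed, {
    parents <- donor_id
    all_pop <- pop
    summaries <- list()
    for (g in seq_len(config$n_generations)) {
      label <- if (g == 1) "F1" else paste0("pBC", g - 1)
      offspring <- NULL
      for (pi in seq_along(parents)) {
        rp_id <- sprintf("RP_g%d_%d", g, pi)
        rp <- make_domestic_founders(pop$map, founders$freqs, rp_id)
        all_pop <- bind_pops(all_pop, rp)
        cr <- make_cross(all_pop, parents[pi], rp_id,
                         config$offspring_per_cross,
                         prefix = sprintf("G%d_P%d", g, pi),
                         generation = label)
        offspring <- if (is.null(offspring)) cr else bind_pops(offspring, cr)
      }
      if (length(offspring) == 0) {
        stop("program extinct at generation ", label, ": no offspring",
             call. = FALSE)
      }
      if (!is.null(config$required_rgenes)) {
        scr <- screen_population(offspring, panel, config$required_rgenes)
        carriers <- scr$id[scr$status == "selected"]
      } else {
        carriers <- pop_ids(offspring)
      }
      if (length(carriers) == 0) {
        stop("program extinct at generation ", label,
             ": no surviving carriers", call. = FALSE)
      }
      eligible <- carriers
      n_flowered <- NA_integer_
      if (!is.null(config$flowering_probs)) {
        att <- apply_flowering_attrition(
          tibble::tibble(id = carriers), config$flowering_probs)
        eligible <- att$id[att$flowered]
        n_flowered <- length(eligible)
        if (length(eligible) == 0) {
          stop("program extinct at generation ", label,
               ": no carrier flowered", call. = FALSE)
        }
      }
      if (config$background_selection == "min_donor_fraction") {
        fr <- truth_unadapted_fraction(subset_pop(offspring, eligible))
        eligible <- fr$id[order(fr$unadapted_pct)]
      } else {
        eligible <- sample(eligible)  # random order among equals
      }
      next_parents <- utils::head(eligible, config$n_parents_per_gen)
      all_pop <- bind_pops(all_pop, offspring)
      summaries[[g]] <- tibble::tibble(
        generation = label, n_meioses = g,
        n_offspring = length(offspring),
        n_carriers = length(carriers),
        n_flowered = n_flowered,
        parents = list(next_parents)
      )
      parents <- next_parents
    }
    list(pop = all_pop, summary = dplyr::bind_rows(summaries),
         pedigree = all_pop$meta)
  })
}

# fresh unrelated domestic individuals from a stored frequency profile
make_domestic_founders <- function(map, freqs, ids) {
  chroms <- unique(map$chrom)
  spans <- chrom_lengths(map)
  fr_by_chrom <- split(freqs$dom_freq, factor(map$chrom, levels = chroms))
  haplo <- setNames(lapply(ids, function(i) {
    setNames(lapply(chroms, function(chr) {
      fr <- fr_by_chrom[[chr]]
      rbind(1L + rbinom(length(fr), 1, fr), 1L + rbinom(length(fr), 1, fr))
    }), chroms)
  }), ids)
  truth <- dplyr::bind_rows(lapply(ids, domestic_tiles, spans = spans))
  meta <- tibble::tibble(id = ids, mother = NA_character_,
                         father = NA_character_, generation = "recurrent")
  phased_pop(map, haplo, meta = meta, truth = truth)
}
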