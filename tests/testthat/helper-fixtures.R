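# Shared test fixtures and independent oracles. Everything is generated in
# code; no binary fixtures.

# evenly spaced deterministic map (unit tests)
even_map <- function(n_chrom = 1, len = 10, n = 20) {
  chroms <- sprintf("LG%02d", seq_len(n_chrom))
  purrr::map_dfr(chroms, function(chr) {
    tibble::tibble(
      marker = sprintf("%s_m%03d", chr, seq_len(n)),
      chrom = chr,
      cM = seq(0, len, length.out = n)
    )
  }) |> validate_genetic_map()
}

# build a phased_pop from per-individual lists of per-chromosome 2 x L
# integer matrices, or from plain vectors (duplicated onto both homologs)
pop_from_haps <- function(map, ...) {
  inds <- list(...)
  chroms <- unique(map$chrom)
  haplo <- lapply(inds, function(h) {
    if (is.matrix(h)) h <- list(h)
    if (!is.list(h)) h <- list(rbind(h, h))
    setNames(h, chroms[seq_along(h)])
  })
  phased_pop(map, haplo)
}

# Independent quadratic-style oracle for the shared-segment caller.
# Enumerates candidate (start, end) pairs over informative matching sites
# using mismatch prefix sums, then keeps non-contained pairs.
naive_shared_segments <- function(hap_a, hap_b, map, chrom) {
  pos <- map$cM[map$chrom == chrom]
  n <- length(pos)
  inf <- !is.na(hap_a) & !is.na(hap_b)
  match_at <- inf & !is.na(hap_a == hap_b) & hap_a == hap_b
  mism_at <- inf & hap_a != hap_b
  mism_at[is.na(mism_at)] <- FALSE
  cmism <- cumsum(mism_at)
  starts <- which(match_at)
  if (length(starts) == 0) {
    return(tibble::tibble(start_index = integer(), end_index = integer(),
                          n_shared_snps = integer()))
  }
  # widest valid end for every matching start
  maxj <- vapply(starts, function(i) {
    js <- which(match_at & seq_len(n) >= i & (cmism - cmism[i]) == 0)
    max(js)
  }, integer(1))
  cand <- tibble::tibble(start_index = starts, end_index = maxj)
  # drop pairs contained in another candidate
  keep <- vapply(seq_len(nrow(cand)), function(k) {
    !any(cand$start_index <= cand$start_index[k] &
           cand$end_index >= cand$end_index[k] &
           (cand$start_index != cand$start_index[k] |
              cand$end_index != cand$end_index[k]))
  }, logical(1))
  out <- unique(cand[keep, ])
  out$n_shared_snps <- vapply(seq_len(nrow(out)), function(k) {
    sum(match_at[out$start_index[k]:out$end_index[k]])
  }, integer(1))
  out[order(out$start_index), ]
}

# interval overlap length between two segment tables (start_cM/end_cM)
overlap_cM <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- max(a$start_cM[i], b$start_cM[j])
      hi <- min(a$end_cM[i], b$end_cM[j])
      if (hi > lo) tot <- tot + (hi - lo)
    }
  }
  tot
}

# default desk-scale simulation shared by several tests (built once)
desk_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      map <- make_apple_map(seed = 11)
      rg <- rgene_locus("FB_MR5", "LG03", 40, c(35, 45))
      founders <- make_founders(map, founder_spec("MR5like", 0.75, rg),
                                n_domestic = 2, seed = 12)
      cache <<- list(map = map, rg = rg, founders = founders)
    }
    cache
  }
})
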