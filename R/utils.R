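#' @importFrom rlang .data %||%
#' @importFrom stats setNames rpois runif rbinom aov TukeyHSD binom.test
#' @importFrom utils head
NULL

# interval utilities (closed cM intervals) -----------------------------------

# merge overlapping/adjacent intervals; x is a tibble with start_cM, end_cM
merge_intervals <- function(start, end, tol = 1e-9) {
  if (length(start) == 0) {
    return(tibble::tibble(start_cM = numeric(), end_cM = numeric()))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + tol) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start_cM = c(out_s, ms), end_cM = c(out_e, me))
}

# total length covered by a set of (possibly overlapping) intervals
interval_union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end_cM - m$start_cM)
}

# do two closed intervals overlap?
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
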