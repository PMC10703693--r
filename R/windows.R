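#' VAF windows used by the barcode method
#'
#' The barcode caller partitions the variant-allele-fraction (VAF) axis into
#' three closed windows: `LOW` (the somatic indicator window), `MID` and
#' `HIGH` (both dominated by germline heterozygotes).  Germline symmetry about
#' VAF 0.5 makes the expected germline content of `LOW` equal to that of
#' `HIGH`, which is what turns the HIGH/MID ratio into an estimate of the
#' germline contamination of `LOW`.
#'
#' All bounds are inclusive: a variant with VAF exactly 0.25 belongs to `LOW`.
#'
#' @param low,mid,high Length-2 numeric vectors giving the closed
#'   `[lower, upper]` VAF bounds of each window.
#' @return A tibble with columns `window`, `lo`, `hi`, one row per window.
#' @examples
#' vaf_windows()
#' @export
vaf_windows <- function(low = c(0.10, 0.25),
                        mid = c(0.35, 0.65),
                        high = c(0.75, 0.90)) {
  w <- tibble(
    window = c("LOW", "MID", "HIGH"),
    lo = c(low[1], mid[1], high[1]),
    hi = c(low[2], mid[2], high[2])
  )
  if (any(w$lo > w$hi) || any(w$lo < 0) || any(w$hi > 1)) {
    abort("VAF window bounds must satisfy 0 <= lo <= hi <= 1.")
  }
  # overlap would let one variant fall in two windows
  ord <- order(w$lo)
  if (any(w$hi[ord][-3] >= w$lo[ord][-1])) {
    abort("VAF windows must be disjoint.")
  }
  w
}

# Assign each (alt_reads, depth) pair to a window label (NA when outside all
# windows).  Membership is decided on vaf = alt/depth with a small tolerance
# so that bounds printed to two decimals behave as exact closed bounds even
# when lo * depth is not representable in binary floating point.
window_of <- function(alt_reads, depth, windows = vaf_windows(), tol = 1e-9) {
  vaf <- alt_reads / depth
  out <- rep(NA_character_, length(vaf))
  for (i in seq_len(nrow(windows))) {
    inside <- vaf >= windows$lo[i] - tol & vaf <= windows$hi[i] + tol
    out[inside] <- windows$window[i]
  }
  out
}

# Exact P(VAF in [lo, hi]) for alt ~ Binomial(depth, p), used by the
# ratio-model oracle and by sensitivity calculations.
binom_window_prob <- function(depth, p, lo, hi, tol = 1e-9) {
  k_lo <- ceiling(depth * (lo - tol))
  k_hi <- floor(depth * (hi + tol))
  if (k_hi < k_lo) return(0)
  pbinom(k_hi, depth, p) - pbinom(k_lo - 1, depth, p)
}
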