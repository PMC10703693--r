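#' Indicator-mutation filter settings
#'
#' Per-variant quality bounds applied to cohort singletons before they are
#' counted as barcode indicator mutations.  Defaults are the hard-filter
#' constants of the barcode method: genotype quality at least 90, FILTER in
#' `PASS`/`Low_QD`, depth between 15 and 60 (inclusive) and at least 3 alt
#' reads (which removes the spurious 1-2-read low-VAF bump).
#'
#' @param gq_min Minimum genotype quality.
#' @param filters_keep FILTER labels admitted.
#' @param depth_min,depth_max Inclusive read-depth bounds.
#' @param alt_min Minimum alt (minor allele) read count.
#' @param snv_only Restrict to single-nucleotide variants (one-base ref and
#'   alt); indels are excluded by default.
#' @return A list of class `ch_filter_config`.
#' @export
filter_config <- function(gq_min = 90,
                          filters_keep = c("PASS", "Low_QD"),
                          depth_min = 15, depth_max = 60,
                          alt_min = 3, snv_only = TRUE) {
  stopifnot(depth_min <= depth_max, depth_min >= 1, alt_min >= 0)
  structure(list(gq_min = gq_min, filters_keep = filters_keep,
                 depth_min = depth_min, depth_max = depth_max,
                 alt_min = alt_min, snv_only = snv_only),
            class = "ch_filter_config")
}

#' Per-variant indicator filter predicate
#'
#' Vectorized test of whether each variant record passes the indicator
#' filters: `gq >= gq_min`, FILTER in `filters_keep`,
#' `depth_min <= depth <= depth_max` and `alt_reads >= alt_min` (all bounds
#' inclusive).  Records with a missing gq, depth or alt-read field fail with
#' a warning reporting how many were unusable.
#'
#' @param variants Variant tibble with columns `gq`, `filter_status`,
#'   `depth`, `alt_reads` (and `ref`/`alt` when `snv_only`).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per row of `variants`.
#' @export
indicator_pass <- function(variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "ch_filter_config"))
  bad <- is.na(variants$gq) | is.na(variants$depth) | is.na(variants$alt_reads)
  if (any(bad)) {
    warn(sprintf("%d record(s) with missing GQ/DP/AD excluded from filtering.",
                 sum(bad)))
  }
  ok <- !bad &
    variants$gq >= cfg$gq_min &
    variants$filter_status %in% cfg$filters_keep &
    variants$depth >= cfg$depth_min & variants$depth <= cfg$depth_max &
    variants$alt_reads >= cfg$alt_min
  if (isTRUE(cfg$snv_only) && all(c("ref", "alt") %in% names(variants))) {
    ok <- ok & nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  }
  ok
}

#' Apply the indicator filter, returning the retained records
#'
#' @inheritParams indicator_pass
#' @return The rows of `variants` passing [indicator_pass()], as a tibble.
#' @export
indicator_filter <- function(variants, cfg = filter_config()) {
  as_tibble(variants[indicator_pass(variants, cfg), , drop = FALSE])
}

#' Restrict a cohort variant table to cohort singletons
#'
#' A barcode indicator mutation must be private to one sample: this keeps
#' exactly those variant keys carried by a single sample in the cohort.  The
#' default key is allele-level, `(chrom, pos, alt)` — a barcode mutation is
#' an allele event — so two samples carrying different alt alleles at the
#' same position each retain their variant.  Position-level keying
#' (`(chrom, pos)`) is available via `key`.
#'
#' Singleton status is decided on the table as given, before any quality
#' filtering: the operation is idempotent.
#'
#' @param variants Cohort-wide variant tibble with `sample_id`, `chrom`,
#'   `pos`, `alt` columns.
#' @param key `"allele"` (default) or `"position"`.
#' @return The singleton rows, as a tibble.
#' @export
find_singletons <- function(variants, key = c("allele", "position")) {
  key <- match.arg(key)
  if (nrow(variants) == 0) return(as_tibble(variants))
  # encode the variant key as one double (exact below 2^53) so carrier
  # counting is hash-based rather than string-sort-based
  chrom_lv <- unique(variants$chrom)
  k <- (match(variants$chrom, chrom_lv) - 1) *
    (max(variants$pos) + 1) + variants$pos
  if (key == "allele") {
    alt_lv <- unique(variants$alt)
    k <- k * length(alt_lv) + (match(variants$alt, alt_lv) - 1)
  }
  samp_lv <- unique(variants$sample_id)
  if (max(k) * (length(samp_lv) + 1) < 2^53) {
    pair <- k * length(samp_lv) + (match(variants$sample_id, samp_lv) - 1)
    # a site re-emitted within one sample still counts as one carrier
    ku <- k[!duplicated(pair)]
    multi <- unique(ku[duplicated(ku)])
    keep_row <- !(k %in% multi)
  } else {
    cols <- if (key == "allele") c("chrom", "pos", "alt") else c("chrom", "pos")
    dt <- data.table::as.data.table(variants[, c(cols, "sample_id")])
    carriers <- dt[, list(n = data.table::uniqueN(sample_id)), by = cols]
    multi <- carriers[carriers$n > 1L]
    keep_row <- !(do.call(paste, variants[cols]) %in%
                    do.call(paste, multi[, cols, with = FALSE]))
  }
  as_tibble(variants[keep_row, , drop = FALSE])
}

#' Tabulate per-sample indicator counts by depth and VAF window
#'
#' Builds the per-sample barcode profile: counts of (filtered, singleton)
#' variants in each (integer read depth, VAF window) cell.  Window
#' membership uses the closed intervals of [vaf_windows()]; variants outside
#' all three windows are counted nowhere.
#'
#' @param variants Filtered singleton tibble with `sample_id`, `depth`,
#'   `alt_reads`, `center`, `platform` columns.
#' @param windows Window table from [vaf_windows()].
#' @return Tibble with columns `sample_id`, `center`, `platform`, `depth`,
#'   `window`, `n` (cells with zero count are absent).
#' @export
profile_cohort <- function(variants, windows = vaf_windows()) {
  if (nrow(variants) == 0) {
    return(tibble(sample_id = character(0), center = character(0),
                  platform = character(0), depth = integer(0),
                  window = character(0), n = integer(0)))
  }
  win <- window_of(variants$alt_reads, variants$depth, windows)
  dt <- data.table::data.table(
    sample_id = variants$sample_id,
    center = variants$center,
    platform = variants$platform,
    depth = as.integer(variants$depth),
    window = win
  )[!is.na(win)]
  out <- dt[, list(n = .N),
            by = c("sample_id", "center", "platform", "depth", "window")]
  data.table::setorderv(out, c("sample_id", "depth", "window"))
  as_tibble(out)
}

#' @rdname profile_cohort
#' @param sample_variants Variant records belonging to a single sample.
#' @export
profile_sample <- function(sample_variants, windows = vaf_windows()) {
  if (nrow(sample_variants) > 0 &&
      length(unique(sample_variants$sample_id)) > 1) {
    abort("profile_sample() expects records from a single sample.")
  }
  profile_cohort(sample_variants, windows)
}
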