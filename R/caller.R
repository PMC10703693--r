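#' Fit the cohort germline-contamination ratio model
#'
#' The germline contamination of the somatic indicator window (VAF
#' 0.10-0.25) is estimated from the symmetric high-VAF window: for germline
#' heterozygotes the expected counts in VAF 0.10-0.25 and 0.75-0.90 are
#' equal, and the ratio of HIGH-window to MID-window (VAF 0.35-0.65) counts
#' is approximately constant given read depth and sequencing center.  This
#' fits r(center, depth) = (cohort HIGH total) / (cohort MID total) for each
#' integer depth from `min_depth` to `max_depth`, separately per center.
#'
#' Cells whose MID denominator is zero fall back to the ratio pooled over
#' depth neighbours within `pool_window`, then to the center-wide pooled
#' ratio, keeping downstream expectations finite and smooth.
#'
#' @param profiles Per-sample profile tibble from [profile_cohort()].
#' @param min_depth Smallest per-variant depth entering the model
#'   (default 21).
#' @param max_depth Largest depth entering the model (default 60).
#' @param pool_window Depth half-width of the first fallback pool.
#' @return An object of class `germline_ratio_model` with a `ratios` tibble
#'   (center, depth, ratio, n_high, n_mid, source), per-center and overall
#'   pooled ratios, and the depth bounds.
#' @seealso [expected_germline()], [estimate_somatic()]
#' @export
fit_germline_ratio <- function(profiles, min_depth = 21, max_depth = 60,
                               pool_window = 2) {
  if (nrow(profiles) == 0) abort("cannot fit a ratio model on an empty cohort.")
  depths_kept <- profiles$depth >= min_depth & profiles$depth <= max_depth
  prof <- profiles[depths_kept, , drop = FALSE]

  totals <- prof |>
    dplyr::filter(.data$window %in% c("MID", "HIGH")) |>
    dplyr::count(.data$center, .data$depth, .data$window, wt = .data$n) |>
    tidyr::pivot_wider(names_from = "window", values_from = "n",
                       values_fill = 0L)
  for (col in c("MID", "HIGH")) {
    if (!col %in% names(totals)) totals[[col]] <- 0L
  }
  totals <- dplyr::arrange(totals, .data$center, .data$depth)

  center_pooled <- totals |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(n_high = sum(.data$HIGH), n_mid = sum(.data$MID)) |>
    dplyr::mutate(ratio = ifelse(.data$n_mid > 0,
                                 .data$n_high / .data$n_mid, 0))
  overall <- if (sum(center_pooled$n_mid) > 0) {
    sum(center_pooled$n_high) / sum(center_pooled$n_mid)
  } else 0

  neighbour_ratio <- function(center, depth) {
    near <- totals[totals$center == center &
                     abs(totals$depth - depth) <= pool_window, , drop = FALSE]
    if (sum(near$MID) > 0) sum(near$HIGH) / sum(near$MID) else NA_real_
  }

  ratios <- totals |>
    dplyr::mutate(
      ratio = ifelse(.data$MID > 0, .data$HIGH / .data$MID, NA_real_),
      source = ifelse(.data$MID > 0, "cell", NA_character_)
    )
  need <- which(is.na(ratios$ratio))
  for (i in need) {
    r <- neighbour_ratio(ratios$center[i], ratios$depth[i])
    if (!is.na(r)) {
      ratios$ratio[i] <- r
      ratios$source[i] <- "depth_pool"
    } else {
      cp <- center_pooled$ratio[center_pooled$center == ratios$center[i]]
      ratios$ratio[i] <- cp
      ratios$source[i] <- "center_pool"
    }
  }

  structure(
    list(
      ratios = tibble(center = ratios$center, depth = ratios$depth,
                      ratio = ratios$ratio, n_high = ratios$HIGH,
                      n_mid = ratios$MID, source = ratios$source),
      center_pooled = tibble(center = center_pooled$center,
                             ratio = center_pooled$ratio),
      overall_pooled = overall,
      min_depth = min_depth, max_depth = max_depth,
      pool_window = pool_window
    ),
    class = "germline_ratio_model"
  )
}

#' @exportS3Method base::print
print.germline_ratio_model <- function(x, ...) {
  cat("Germline ratio model (HIGH/MID VAF windows)\n")
  cat(sprintf("  depths %d-%d, %d center(s), %d fitted cells\n",
              x$min_depth, x$max_depth,
              length(unique(x$ratios$center)), nrow(x$ratios)))
  cat(sprintf("  overall pooled ratio: %.4g\n", x$overall_pooled))
  invisible(x)
}

#' @export
tidy.germline_ratio_model <- function(x, ...) x$ratios

#' @export
glance.germline_ratio_model <- function(x, ...) {
  tibble(
    n_centers = length(unique(x$ratios$center)),
    n_cells = nrow(x$ratios),
    n_fallback = sum(x$ratios$source != "cell"),
    min_depth = x$min_depth, max_depth = x$max_depth,
    overall_ratio = x$overall_pooled
  )
}

# resolve r(center, depth) for arbitrary (center, depth) pairs, applying the
# fallback chain for unseen cells
lookup_ratio <- function(model, center, depth) {
  key_model <- paste(model$ratios$center, model$ratios$depth)
  r <- model$ratios$ratio[match(paste(center, depth), key_model)]
  miss <- which(is.na(r))
  for (i in miss) {
    near <- model$ratios$center == center[i] &
      abs(model$ratios$depth - depth[i]) <= model$pool_window
    if (any(near) && isTRUE(sum(model$ratios$n_mid[near]) > 0)) {
      r[i] <- sum(model$ratios$n_high[near]) / sum(model$ratios$n_mid[near])
    } else {
      cp <- model$center_pooled$ratio[model$center_pooled$center == center[i]]
      r[i] <- if (length(cp)) cp else model$overall_pooled
    }
  }
  r
}

#' Expected germline contamination of the indicator window
#'
#' For each sample, E = sum over depths d in the model range of
#' r(center, d) x MID(d): the sample's observed MID-window counts scaled by
#' the cohort ratio, which under germline VAF symmetry equals the expected
#' germline count in the LOW window.
#'
#' @param profiles Per-sample profile tibble from [profile_cohort()].
#' @param model A fitted [fit_germline_ratio()] model.
#' @return Tibble with `sample_id`, `center`, `platform`,
#'   `expected_germline`.
#' @export
expected_germline <- function(profiles, model) {
  stopifnot(inherits(model, "germline_ratio_model"))
  samples <- dplyr::distinct(profiles, .data$sample_id, .data$center,
                             .data$platform)
  mid <- profiles |>
    dplyr::filter(.data$window == "MID",
                  .data$depth >= model$min_depth,
                  .data$depth <= model$max_depth)
  if (nrow(mid) == 0) {
    return(dplyr::mutate(samples, expected_germline = 0))
  }
  mid$ratio <- lookup_ratio(model, mid$center, mid$depth)
  e <- mid |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(expected_germline = sum(.data$ratio * .data$n))
  samples |>
    dplyr::left_join(e, by = "sample_id") |>
    dplyr::mutate(expected_germline =
                    dplyr::coalesce(.data$expected_germline, 0))
}

#' Estimate per-sample somatic singleton counts in the indicator window
#'
#' S = (observed LOW-window count over the model depth range) minus the
#' expected germline contamination from [expected_germline()].  S may be
#' negative; it is reported as-is (clamping would bias null calibration).
#'
#' @inheritParams expected_germline
#' @param manifest Optional manifest tibble (`sample_id`, `center`,
#'   `platform`); when supplied, samples with no profiled variants are
#'   included with S = 0.
#' @return Tibble with `sample_id`, `center`, `platform`, `observed_low`,
#'   `expected_germline`, `estimated_somatic`.
#' @export
estimate_somatic <- function(profiles, model, manifest = NULL) {
  e <- expected_germline(profiles, model)
  low <- profiles |>
    dplyr::filter(.data$window == "LOW",
                  .data$depth >= model$min_depth,
                  .data$depth <= model$max_depth) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(observed_low = sum(.data$n))
  out <- e |>
    dplyr::left_join(low, by = "sample_id") |>
    dplyr::mutate(
      observed_low = dplyr::coalesce(.data$observed_low, 0L),
      estimated_somatic = .data$observed_low - .data$expected_germline
    ) |>
    dplyr::select("sample_id", "center", "platform", "observed_low",
                  "expected_germline", "estimated_somatic")
  if (!is.null(manifest)) {
    missing <- manifest[!manifest$sample_id %in% out$sample_id, , drop = FALSE]
    if (nrow(missing)) {
      out <- dplyr::bind_rows(
        out,
        tibble(sample_id = missing$sample_id, center = missing$center,
               platform = missing$platform, observed_low = 0L,
               expected_germline = 0, estimated_somatic = 0)
      )
    }
    out <- out[match(manifest$sample_id, out$sample_id), , drop = FALSE]
  }
  out
}

#' Threshold configuration for the CH call
#'
#' The CH decision compares the estimated somatic count S with an effective
#' threshold T.  T is the platform-specific absolute threshold when one is
#' defined for the sample's platform (46 for `WGS NoPCR Nova`, 32 for
#' `NEB WGS`); otherwise T = `base` plus the signed center adjustment
#' (+1 for Vanguard, -2.2 for Sanger; `default_adjustment`, normally 0, for
#' centers not listed).  The base of 20 indicator mutations was calibrated
#' to an expected CH fraction of about 1% at age 40.
#'
#' @param base Base threshold in indicator-mutation counts.
#' @param center_adjustments Named numeric vector of signed adjustments.
#' @param platform_thresholds Named numeric vector of absolute overrides.
#' @param default_adjustment Adjustment for centers absent from
#'   `center_adjustments`; set to `NULL` to make unknown centers an error.
#' @return A list of class `ch_threshold_config`.
#' @export
threshold_config <- function(base = 20,
                             center_adjustments = c(Vanguard = 1,
                                                    Sanger = -2.2),
                             platform_thresholds = c("WGS NoPCR Nova" = 46,
                                                     "NEB WGS" = 32),
                             default_adjustment = 0) {
  structure(list(base = base,
                 center_adjustments = center_adjustments,
                 platform_thresholds = platform_thresholds,
                 default_adjustment = default_adjustment),
            class = "ch_threshold_config")
}

#' Resolve the effective CH threshold for (center, platform) pairs
#'
#' @param center,platform Character vectors (recycled to a common length).
#' @param cfg A [threshold_config()].
#' @return Numeric vector of effective thresholds.
#' @export
resolve_threshold <- function(center, platform, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "ch_threshold_config"))
  n <- max(length(center), length(platform))
  center <- rep_len(center, n)
  platform <- rep_len(platform, n)
  t_platform <- unname(cfg$platform_thresholds[platform])
  adj <- unname(cfg$center_adjustments[center])
  if (any(is.na(adj) & is.na(t_platform))) {
    if (is.null(cfg$default_adjustment)) {
      unknown <- unique(center[is.na(adj) & is.na(t_platform)])
      abort(paste0(
        "no threshold adjustment for center(s) ",
        paste(unknown, collapse = ", "),
        "; known centers: ",
        paste(names(cfg$center_adjustments), collapse = ", ")
      ))
    }
    adj[is.na(adj)] <- cfg$default_adjustment
  }
  ifelse(!is.na(t_platform), t_platform, cfg$base + adj)
}

#' Call clonal hematopoiesis from estimated somatic counts
#'
#' A sample is CH when its estimated somatic singleton count S reaches the
#' effective threshold T for its center/platform: `is_ch = (S >= T)`.
#' Neither S nor T is rounded.
#'
#' @param estimates Tibble from [estimate_somatic()].
#' @param cfg A [threshold_config()].
#' @return `estimates` with `threshold` and `is_ch` columns appended.
#' @export
call_ch <- function(estimates, cfg = threshold_config()) {
  estimates |>
    dplyr::mutate(
      threshold = resolve_threshold(.data$center, .data$platform, cfg),
      is_ch = .data$estimated_somatic >= .data$threshold
    )
}

#' Run the complete barcode-calling pipeline
#'
#' Composes the method end to end: cohort singleton extraction, indicator
#' filtering, per-sample profiling, germline ratio-model fitting, somatic
#' estimation and thresholded CH calling.  Input is either an in-memory
#' cohort variant tibble or a directory of per-sample VCFs (read with
#' [read_cohort()]).
#'
#' @param variants Cohort variant tibble, or `NULL` when `vcf_dir` is given.
#' @param manifest Manifest tibble with `sample_id`, `center`, `platform`.
#' @param vcf_dir Directory of per-sample `.vcf` files.
#' @param filter_cfg A [filter_config()].
#' @param threshold_cfg A [threshold_config()].
#' @param windows A [vaf_windows()] table.
#' @param min_depth,max_depth Depth range of the ratio model.
#' @param singleton_key Passed to [find_singletons()].
#' @return The CH call tibble from [call_ch()], with attributes `model`
#'   (the fitted ratio model) and `attrition` (a tibble of record counts
#'   after each stage).
#' @export
run_barcode_pipeline <- function(variants = NULL, manifest,
                                 vcf_dir = NULL,
                                 filter_cfg = filter_config(),
                                 threshold_cfg = threshold_config(),
                                 windows = vaf_windows(),
                                 min_depth = 21, max_depth = 60,
                                 singleton_key = "allele") {
  if (is.null(variants)) {
    if (is.null(vcf_dir)) abort("supply `variants` or `vcf_dir`.")
    paths <- sort(list.files(vcf_dir, pattern = "\\.vcf$", full.names = TRUE))
    variants <- read_cohort(paths, manifest)
  }
  n_input <- nrow(variants)
  singles <- find_singletons(variants, key = singleton_key)
  n_singletons <- nrow(singles)
  filtered <- indicator_filter(singles, filter_cfg)
  n_filtered <- nrow(filtered)
  profiles <- profile_cohort(filtered, windows)
  n_in_window <- sum(profiles$n)

  if (n_in_window == 0) {
    calls <- tibble(sample_id = manifest$sample_id,
                    center = manifest$center, platform = manifest$platform,
                    observed_low = 0L, expected_germline = 0,
                    estimated_somatic = 0) |>
      call_ch(threshold_cfg)
    model <- NULL
  } else {
    model <- fit_germline_ratio(profiles, min_depth = min_depth,
                                max_depth = max_depth)
    calls <- estimate_somatic(profiles, model, manifest = manifest) |>
      call_ch(threshold_cfg)
  }
  attr(calls, "model") <- model
  attr(calls, "attrition") <- tibble(
    stage = c("input", "cohort_singletons", "indicator_filter", "in_window"),
    n = c(n_input, n_singletons, n_filtered, n_in_window)
  )
  calls
}

#' Write / read a fitted ratio model as YAML
#'
#' Serializes the model as center -> depth -> ratio, plus the depth bounds,
#' so a fit can be inspected or reused outside R.
#'
#' @param model A `germline_ratio_model`.
#' @param path Output path.
#' @return `path`, invisibly (writer); the model (reader).
#' @export
write_ratio_model <- function(model, path) {
  stopifnot(inherits(model, "germline_ratio_model"))
  by_center <- split(model$ratios, model$ratios$center)
  obj <- list(
    min_depth = model$min_depth, max_depth = model$max_depth,
    pool_window = model$pool_window,
    overall_pooled = model$overall_pooled,
    centers = lapply(by_center, function(df) {
      as.list(setNames(df$ratio, as.character(df$depth)))
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_ratio_model
#' @export
read_ratio_model <- function(path) {
  obj <- yaml::read_yaml(path)
  ratios <- purrr::imap_dfr(obj$centers, function(depths, center) {
    tibble(center = center, depth = as.integer(names(depths)),
           ratio = as.numeric(unlist(depths)),
           n_high = NA_integer_, n_mid = NA_integer_,
           source = "loaded")
  })
  center_pooled <- ratios |>
    dplyr::group_by(.data$center) |>
    dplyr::summarise(ratio = mean(.data$ratio))
  structure(
    list(ratios = ratios, center_pooled = center_pooled,
         overall_pooled = obj$overall_pooled,
         min_depth = obj$min_depth, max_depth = obj$max_depth,
         pool_window = obj$pool_window),
    class = "germline_ratio_model"
  )
}
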