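#' Bundled driver-gene resources
#'
#' The candidate-driver cascades consume two plain-text resources: a gene
#' panel for the CHIP definition and a published variant list (gene +
#' protein change) that rescues recurrent MODERATE-impact drivers in the
#' CPLD cascade.  The copies bundled with the package are small synthetic
#' fixtures assembled from genes commonly mutated in myeloid/lymphoid
#' neoplasia; production analyses should supply their own curated files via
#' `path`.
#'
#' @param path TSV path; default is the bundled synthetic fixture.
#' @return A tibble (`gene` for the panel; `gene`, `hgvsp` for the list).
#' @export
chip_gene_panel <- function(path = system.file("extdata",
                                               "synthetic_chip_gene_panel.tsv",
                                               package = "chbarcode")) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' @rdname chip_gene_panel
#' @export
cpld_published_list <- function(path = system.file(
                                  "extdata",
                                  "synthetic_cpld_published_list.tsv",
                                  package = "chbarcode")) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Exact binomial test of a call against germline expectation
#'
#' A germline heterozygote has alt reads distributed Binomial(depth, 0.5);
#' a call that is not inconsistent with that model (two-sided exact p
#' strictly greater than `alpha`) is classified as a potential germline
#' call.  Vectorized over calls.
#'
#' @param alt_reads,depth Integer vectors, `0 <= alt_reads <= depth`,
#'   `depth >= 1`.
#' @param alpha Classification level (strict: `p > alpha` is potential
#'   germline).
#' @return Tibble with `p_value` and `potential_germline`.
#' @examples
#' binomial_germline_test(c(20, 3), c(40, 30))
#' @export
binomial_germline_test <- function(alt_reads, depth, alpha = 0.05) {
  n <- max(length(alt_reads), length(depth))
  alt_reads <- rep_len(as.integer(alt_reads), n)
  depth <- rep_len(as.integer(depth), n)
  if (any(is.na(depth)) || any(depth < 1)) {
    abort("depth must be a positive integer for the binomial germline test.")
  }
  if (any(alt_reads < 0 | alt_reads > depth)) {
    abort("alt_reads must lie in [0, depth].")
  }
  pairs <- paste(alt_reads, depth)
  uniq <- !duplicated(pairs)
  p_uniq <- vapply(which(uniq), function(i) {
    binom.test(alt_reads[i], depth[i], p = 0.5)$p.value
  }, numeric(1))
  p <- p_uniq[match(pairs, pairs[uniq])]
  tibble(p_value = p, potential_germline = p > alpha)
}

normalize_candidates <- function(candidates) {
  if (!"filter_status" %in% names(candidates) &&
      "filter" %in% names(candidates)) {
    candidates <- dplyr::rename(candidates, filter_status = "filter")
  }
  required <- c("sample_id", "chrom", "pos", "ref", "alt", "depth",
                "alt_reads", "gene", "hgvsp", "impact", "filter_status")
  missing <- setdiff(required, names(candidates))
  if (length(missing)) {
    abort(paste("candidate table lacks columns:",
                paste(missing, collapse = ", ")))
  }
  dplyr::mutate(as_tibble(candidates),
                vaf = .data$alt_reads / .data$depth,
                .variant_key = paste(.data$chrom, .data$pos, .data$ref,
                                     .data$alt))
}

log_step <- function(log, step, before, after) {
  dplyr::bind_rows(log, tibble(step = step,
                               n_removed = as.integer(before - after),
                               n_remaining = as.integer(after)))
}

#' CPLD candidate filter cascade
#'
#' Filters somatic-caller output down to retained candidate preleukemic
#' driver (CPLD) mutations, in this fixed order:
#'
#' 1. call-level quality: depth > 10 (strict), FILTER = `PASS`,
#'    0.01 <= VAF <= 0.99;
#' 2. classify each surviving call as potential germline via
#'    [binomial_germline_test()] (p > `alpha`), and tabulate per variant key
#'    the number of carrier samples and the potential-germline fraction;
#' 3. remove variant keys with more than `max_occurrences` carriers AND a
#'    potential-germline fraction above `germline_fraction` (both strict);
#' 4. keep only moderate/high-impact candidates that are HIGH impact in a
#'    gene outside `excluded_high_impact_genes`, or appear in the published
#'    driver list (matched on gene + protein change).
#'
#' Candidates lacking an impact annotation are dropped up front with a
#' logged count.  The attrition log (attribute `"attrition"`) attributes
#' every removal to exactly one step.
#'
#' @param candidates Tibble with columns sample_id, chrom, pos, ref, alt,
#'   depth, alt_reads, gene, hgvsp, impact, filter_status (or filter).
#' @param published_list Tibble (`gene`, `hgvsp`) of published driver
#'   variants; default the bundled synthetic fixture.
#' @param excluded_high_impact_genes HIGH-impact genes whose truncating
#'   variants are artifact-prone in this assay and need published-list
#'   support.
#' @param alpha Germline classification level.
#' @param max_occurrences,germline_fraction Recurrence-removal bounds.
#' @return Retained candidates with `vaf`, `p_germline`,
#'   `potential_germline`, `cohort_occurrences`,
#'   `potential_germline_fraction`, `in_published_list` columns and an
#'   `"attrition"` attribute.
#' @export
cpld_filter_cascade <- function(candidates,
                                published_list = cpld_published_list(),
                                excluded_high_impact_genes =
                                  c("GNAS", "JAK2", "SRSF2", "SF3B1"),
                                alpha = 0.05,
                                max_occurrences = 5,
                                germline_fraction = 0.75) {
  x <- normalize_candidates(candidates)
  log <- tibble(step = character(0), n_removed = integer(0),
                n_remaining = integer(0))

  n0 <- nrow(x)
  x <- dplyr::filter(x, !is.na(.data$impact))
  if (nrow(x) < n0) {
    inform(sprintf("%d candidate(s) dropped for missing impact annotation.",
                   n0 - nrow(x)))
  }
  log <- log_step(log, "missing_impact", n0, nrow(x))

  n1 <- nrow(x)
  x <- dplyr::filter(x, .data$depth > 10,
                     .data$filter_status == "PASS",
                     .data$vaf >= 0.01 - 1e-12, .data$vaf <= 0.99 + 1e-12)
  log <- log_step(log, "call_quality", n1, nrow(x))

  if (nrow(x)) {
    gt <- binomial_germline_test(x$alt_reads, x$depth, alpha = alpha)
    x$p_germline <- gt$p_value
    x$potential_germline <- gt$potential_germline
    keystats <- x |>
      dplyr::group_by(.data$.variant_key) |>
      dplyr::summarise(
        cohort_occurrences = dplyr::n_distinct(.data$sample_id),
        potential_germline_fraction = mean(.data$potential_germline)
      )
    x <- dplyr::left_join(x, keystats, by = ".variant_key")
  } else {
    x$p_germline <- numeric(0)
    x$potential_germline <- logical(0)
    x$cohort_occurrences <- integer(0)
    x$potential_germline_fraction <- numeric(0)
  }

  n2 <- nrow(x)
  x <- dplyr::filter(x, !(.data$cohort_occurrences > max_occurrences &
                            .data$potential_germline_fraction >
                              germline_fraction))
  log <- log_step(log, "recurrent_germline", n2, nrow(x))

  n3 <- nrow(x)
  in_list <- paste(x$gene, x$hgvsp) %in%
    paste(published_list$gene, published_list$hgvsp)
  x$in_published_list <- in_list
  x <- dplyr::filter(
    x,
    .data$impact %in% c("HIGH", "MODERATE") &
      ((.data$impact == "HIGH" &
          !.data$gene %in% excluded_high_impact_genes) |
         .data$in_published_list)
  )
  log <- log_step(log, "impact_rules", n3, nrow(x))

  out <- dplyr::select(x, -".variant_key")
  attr(out, "attrition") <- log
  out
}

#' Default exempt sites for the CHIP binomial removal
#'
#' Three TET2 hotspot substitutions are retained even when their aggregate
#' VAF is consistent with germline, because they recur as true somatic
#' drivers at near-heterozygous clone sizes.
#'
#' @return Character vector of `"GENE hgvsp"` keys.
#' @export
chip_exempt_sites <- function() {
  c("TET2 H1904R", "TET2 I1873T", "TET2 T1884A")
}

#' CHIP candidate filter cascade
#'
#' Adapted CHIP definition over a fixed gene panel:
#'
#' 1. restrict to panel genes (`U2AF1` is excluded from the panel:
#'    pseudogene-duplication mapping problems make its calls unreliable in
#'    this assay) and require depth >= `min_depth` and alt reads >=
#'    `min_alt` ("minAD");
#' 2. variant keys carried by at least `min_carriers` samples are tested for
#'    association of carrier status with age and rs7705526 dosage (logistic
#'    regression over the cohort); keys for which BOTH covariates have
#'    p > `alpha_recur` or a negative estimate are removed (keys below the
#'    carrier count are not tested and are kept);
#' 3. per variant key, an exact binomial test of the summed alt reads
#'    against half the summed depth removes keys with p > `alpha_binom`
#'    (germline-like), except the exempt sites.
#'
#' @param candidates Candidate tibble as in [cpld_filter_cascade()].
#' @param covariates Cohort covariate tibble: `sample_id`, `age`,
#'   `rs7705526` (dosage 0-2), one row per sample in the cohort.
#' @param gene_panel Tibble with a `gene` column; default bundled fixture.
#' @param exempt_sites `"GENE hgvsp"` keys bypassing step 3.
#' @param min_depth,min_alt Step-1 bounds.
#' @param min_carriers Carrier count at which the recurrence regression
#'   applies.
#' @param alpha_recur,alpha_binom Step-2 and step-3 levels.
#' @return Retained candidates with an `"attrition"` attribute.
#' @export
chip_filter_cascade <- function(candidates, covariates,
                                gene_panel = chip_gene_panel(),
                                exempt_sites = chip_exempt_sites(),
                                min_depth = 20, min_alt = 3,
                                min_carriers = 15,
                                alpha_recur = 0.1, alpha_binom = 0.01) {
  x <- normalize_candidates(candidates)
  log <- tibble(step = character(0), n_removed = integer(0),
                n_remaining = integer(0))

  panel_genes <- setdiff(gene_panel$gene, "U2AF1")
  n0 <- nrow(x)
  x <- dplyr::filter(x, .data$gene %in% panel_genes)
  log <- log_step(log, "gene_panel", n0, nrow(x))

  n1 <- nrow(x)
  x <- dplyr::filter(x, .data$depth >= min_depth, .data$alt_reads >= min_alt)
  log <- log_step(log, "depth_minAD", n1, nrow(x))

  n2 <- nrow(x)
  if (nrow(x)) {
    carriers_by_key <- split(unique(x[, c(".variant_key", "sample_id")]),
                             unique(x[, c(".variant_key", "sample_id")])$.variant_key)
    drop_keys <- character(0)
    for (key in names(carriers_by_key)) {
      carr <- carriers_by_key[[key]]$sample_id
      if (length(carr) < min_carriers) next
      cov <- covariates
      cov$carrier <- as.integer(cov$sample_id %in% carr)
      fit <- suppressWarnings(
        glm(carrier ~ age + rs7705526, data = cov, family = binomial())
      )
      sm <- summary(fit)$coefficients
      fails <- function(term) {
        if (!term %in% rownames(sm)) return(TRUE)
        sm[term, "Pr(>|z|)"] > alpha_recur || sm[term, "Estimate"] < 0
      }
      if (fails("age") && fails("rs7705526")) drop_keys <- c(drop_keys, key)
    }
    x <- dplyr::filter(x, !.data$.variant_key %in% drop_keys)
  }
  log <- log_step(log, "recurrence_regression", n2, nrow(x))

  n3 <- nrow(x)
  if (nrow(x)) {
    agg <- x |>
      dplyr::group_by(.data$.variant_key, .data$gene, .data$hgvsp) |>
      dplyr::summarise(total_alt = sum(.data$alt_reads),
                       total_depth = sum(.data$depth), .groups = "drop")
    gt <- binomial_germline_test(agg$total_alt, agg$total_depth,
                                 alpha = alpha_binom)
    agg$germline_like <- gt$potential_germline
    agg$exempt <- paste(agg$gene, agg$hgvsp) %in% exempt_sites
    drop_keys <- agg$.variant_key[agg$germline_like & !agg$exempt]
    x <- dplyr::filter(x, !.data$.variant_key %in% drop_keys)
  }
  log <- log_step(log, "binomial_germline", n3, nrow(x))

  out <- dplyr::select(x, -".variant_key")
  attr(out, "attrition") <- log
  out
}

#' Classify samples into CH subtypes
#'
#' Combines barcode CH calls with retained driver mutations:
#' `CPLD-CH` = barcode-positive with a retained driver, `CPLDneg-CH` =
#' barcode-positive without one, `CPLD-only` = driver carrier without a
#' barcode (seen particularly in younger individuals, where a driver clone
#' is present but too few indicator mutations have accumulated), `none` =
#' neither.  Samples outside `evaluated_samples` could not be assessed for
#' drivers and are marked `unevaluable` (they never enter CPLDneg counts).
#'
#' @param ch_calls Tibble from [call_ch()] (unique `sample_id`, `is_ch`).
#' @param drivers Retained driver tibble (`sample_id`, `gene`).
#' @param evaluated_samples Sample ids assessed for driver mutations;
#'   default: all samples in `ch_calls`.
#' @return Tibble with `sample_id`, `barcode_ch`, `cpld_ch`, `subtype`,
#'   `driver_genes` (comma-separated labels, `""` when none).
#' @export
classify_subtypes <- function(ch_calls, drivers,
                              evaluated_samples = ch_calls$sample_id) {
  if (anyDuplicated(ch_calls$sample_id)) {
    abort("duplicated sample_id in ch_calls.")
  }
  per_sample <- drivers |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(driver_genes =
                       paste(sort(unique(.data$gene)), collapse = ","))
  out <- ch_calls |>
    dplyr::select("sample_id", barcode_ch = "is_ch") |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      evaluated = .data$sample_id %in% evaluated_samples,
      driver_genes = dplyr::coalesce(.data$driver_genes, ""),
      cpld_ch = ifelse(.data$evaluated, .data$driver_genes != "", NA),
      subtype = dplyr::case_when(
        !.data$evaluated ~ "unevaluable",
        .data$barcode_ch & .data$cpld_ch ~ "CPLD-CH",
        .data$barcode_ch & !.data$cpld_ch ~ "CPLDneg-CH",
        !.data$barcode_ch & .data$cpld_ch ~ "CPLD-only",
        .default = "none"
      )
    ) |>
    dplyr::select("sample_id", "barcode_ch", "cpld_ch", "subtype",
                  "driver_genes")
  out
}
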