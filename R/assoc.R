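#' Apply the study exclusion criteria
#'
#' A CH study must exclude participants whose blood already reflects an
#' overt hematological disease: (a) any diagnosis in the ICD10 blocks
#' C81-C96 or D45-D47 before, or within `window_days` after, blood draw;
#' (b) white cell count below 1.5 or above 35 (10^9 cells/l);
#' (c) hemoglobin below 8 g/dl; (d) platelets below 50 (10^9/l).  All
#' bounds are strict; a missing hematology value never excludes on that
#' measure.  ICD10 codes are normalized to dotless uppercase and matched at
#' the three-character block level with subcode inheritance (C91 matches
#' C91.1); malformed codes are logged and treated as non-matching.
#'
#' The criteria are independent, so the operation is order-independent and
#' idempotent.
#'
#' @param manifest Participant tibble with `sample_id`, `wbc`, `hgb`, `plt`.
#' @param diagnoses Tibble with `sample_id`, `icd10`,
#'   `date_offset_days` (days relative to blood draw, negative = before).
#' @param window_days Post-draw exclusion window (183 days ~ 6 months).
#' @param code_blocks Character vector of ICD10 block ranges,
#'   `"C81-C96"`-style or single blocks.
#' @param wbc_min,wbc_max,hgb_min,plt_min Hematology bounds.
#' @return `manifest` with logical `excluded` and character
#'   `exclusion_reasons` (comma-separated) columns appended.
#' @export
apply_exclusions <- function(manifest, diagnoses,
                             window_days = 183,
                             code_blocks = c("C81-C96", "D45-D47"),
                             wbc_min = 1.5, wbc_max = 35,
                             hgb_min = 8, plt_min = 50) {
  blocks <- expand_icd10_blocks(code_blocks)

  heme_samples <- character(0)
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    code <- toupper(gsub("\\.", "", diagnoses$icd10))
    ok <- grepl("^[A-Z][0-9]{2}", code)
    if (any(!ok)) {
      warn(sprintf("%d malformed ICD10 code(s) treated as non-matching.",
                   sum(!ok)))
    }
    block3 <- substr(code, 1, 3)
    hit <- ok & block3 %in% blocks &
      diagnoses$date_offset_days <= window_days
    heme_samples <- unique(diagnoses$sample_id[hit])
  }

  na_false <- function(x) !is.na(x) & x
  reasons <- list(
    heme_diagnosis = manifest$sample_id %in% heme_samples,
    wbc = na_false(manifest$wbc < wbc_min | manifest$wbc > wbc_max),
    hgb = na_false(manifest$hgb < hgb_min),
    plt = na_false(manifest$plt < plt_min)
  )
  mat <- do.call(cbind, reasons)
  manifest |>
    dplyr::mutate(
      excluded = rowSums(mat) > 0,
      exclusion_reasons = apply(mat, 1, function(r) {
        paste(names(reasons)[r], collapse = ",")
      })
    )
}

# "C81-C96" -> c("C81", ..., "C96"); single blocks pass through
expand_icd10_blocks <- function(code_blocks) {
  unlist(lapply(code_blocks, function(b) {
    if (grepl("-", b)) {
      parts <- strsplit(b, "-")[[1]]
      letter <- substr(parts[1], 1, 1)
      if (letter != substr(parts[2], 1, 1)) {
        abort("ICD10 block ranges must stay within one letter.")
      }
      nums <- as.integer(substr(parts, 2, 3))
      sprintf("%s%02d", letter, seq(nums[1], nums[2]))
    } else {
      toupper(gsub("\\.", "", b))
    }
  }))
}

#' Per-variant Fisher's exact test
#'
#' Two-sided exact test of carrier status against CH status on a 2x2 table:
#' the p-value sums hypergeometric probabilities of tables no more likely
#' than the observed one (the convention of [stats::fisher.test()], which
#' computes the p here).  The reported odds ratio is the sample OR
#' `ad / bc` (the conditional-MLE OR from `fisher.test` is also returned).
#' Vectorized over tables.
#'
#' @param a Carriers among CH cases.
#' @param b Non-carriers among cases.
#' @param c Carriers among controls.
#' @param d Non-carriers among controls.
#' @return Tibble with `odds_ratio`, `odds_ratio_cmle`, `p_value`.
#' @examples
#' fisher_variant_test(2, 0, 0, 2)
#' @export
fisher_variant_test <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative.")
  if (any(a + b + c + d == 0)) {
    abort("all-zero 2x2 table: Fisher's test undefined.")
  }
  fits <- lapply(seq_len(n), function(i) {
    fisher.test(matrix(c(a[i], b[i], c[i], d[i]), nrow = 2, byrow = TRUE))
  })
  or <- (a * d) / (b * c)
  or[b * c == 0 & a * d > 0] <- Inf
  or[b * c == 0 & a * d == 0] <- NaN
  tibble(
    odds_ratio = or,
    odds_ratio_cmle = vapply(fits, function(f) unname(f$estimate),
                             numeric(1)),
    p_value = vapply(fits, function(f) f$p.value, numeric(1))
  )
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of `outcome` on `exposure` with
#' sex and age (linear and quadratic) as covariates, optionally adding the
#' smoking variables (status, pack years, years since quitting).  The
#' reported odds ratio is `exp` of the exposure coefficient with its Wald
#' p-value.  Complete (quasi-)separation is detected from enormous
#' coefficients or non-convergence and flagged rather than silently
#' reported.
#'
#' @param data Participant tibble; complete cases on the model variables
#'   are used.
#' @param outcome,exposure Names of binary 0/1 (or logical) columns.
#' @param covariates Additional covariate column names; `"age"` also enters
#'   quadratically.
#' @param adjust_smoking Add `smoking_status` (or `smoking`), `pack_years`,
#'   `years_quit` when present in `data`.
#' @return One-row `assoc_result` tibble: `phenotype`, `n_cases`,
#'   `n_controls` (counted on the exposure), `odds_ratio`, `std_error`
#'   (log-odds scale), `p_value`, `covariate_set`, `model`, `converged`,
#'   `separation`.
#' @export
logistic_assoc <- function(data, outcome, exposure,
                           covariates = c("age", "sex"),
                           adjust_smoking = FALSE) {
  smoking_vars <- character(0)
  if (adjust_smoking) {
    smoking_vars <- intersect(c("smoking_status", "smoking", "pack_years",
                                "years_quit"), names(data))
    if (!length(smoking_vars)) abort("no smoking columns found in `data`.")
  }
  vars <- unique(c(outcome, exposure, covariates, smoking_vars))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  df <- data[complete.cases(data[vars]), vars, drop = FALSE]
  y <- as.integer(as.logical(df[[outcome]]))
  if (length(unique(y)) < 2) abort("outcome has a single level.")

  terms <- c(bt(exposure), bt(setdiff(covariates, "age")))
  if ("age" %in% covariates) terms <- c(terms, "age", "I(age^2)")
  terms <- c(terms, bt(smoking_vars))
  fml <- stats::reformulate(terms, response = bt(outcome))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial(),
                              control = list(maxit = 100, epsilon = 1e-10)))
  sm <- summary(fit)$coefficients
  row <- grep(paste0("^`?", exposure), rownames(sm))[1]
  if (is.na(row)) abort("exposure term dropped from the fit (degenerate).")
  est <- sm[row, "Estimate"]
  se <- sm[row, "Std. Error"]
  sep <- !fit$converged || abs(est) > 15 ||
    any(fit$fitted.values < 1e-10) && any(fit$fitted.values > 1 - 1e-10)
  if (sep) warn("possible complete separation in logistic fit.")
  exposure_val <- as.integer(as.logical(df[[exposure]]))
  tibble(
    phenotype = exposure,
    n_cases = sum(exposure_val == 1), n_controls = sum(exposure_val == 0),
    odds_ratio = exp(est), std_error = se,
    p_value = sm[row, "Pr(>|z|)"],
    covariate_set = paste(c(covariates, smoking_vars), collapse = "+"),
    model = "logistic", converged = fit$converged, separation = sep
  )
}

bt <- function(x) if (length(x)) paste0("`", x, "`") else character(0)

#' Dose-dependent smoking model for CH risk
#'
#' Logistic fit of CH on smoking status, pack years and years since
#' quitting, with sex and age (linear and quadratic) terms, returning one
#' row per smoking covariate.  A cohort of never-smokers has no smoking
#' contrast to estimate: degenerate columns are dropped with a warning.
#'
#' @param data Participant tibble with `smoking_status` (current / previous
#'   / never), `pack_years`, `years_quit`, `age`, `sex` and the CH flag.
#' @param ch_col Name of the CH flag column.
#' @return Tibble with `term`, `estimate` (log-odds), `odds_ratio`,
#'   `std_error`, `p_value`.
#' @export
smoking_dose_model <- function(data, ch_col = "ch") {
  df <- data[complete.cases(data[c(ch_col, "smoking_status", "pack_years",
                                   "years_quit", "age", "sex")]), ]
  df$smoking_status <- factor(df$smoking_status,
                              levels = c("never", "previous", "current"))
  keep <- c("smoking_status", "pack_years", "years_quit")
  degenerate <- vapply(keep, function(v) {
    length(unique(df[[v]])) < 2
  }, logical(1))
  if (any(degenerate)) {
    warn(paste("degenerate smoking covariate(s) dropped:",
               paste(keep[degenerate], collapse = ", ")))
    keep <- keep[!degenerate]
  }
  if (!length(keep)) abort("no estimable smoking covariate.")
  fml <- stats::reformulate(c(keep, "age", "I(age^2)", "sex"),
                            response = bt(ch_col))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  rows <- grep("^(smoking_status|pack_years|years_quit)", rownames(sm))
  tibble(
    term = rownames(sm)[rows],
    estimate = sm[rows, "Estimate"],
    odds_ratio = exp(sm[rows, "Estimate"]),
    std_error = sm[rows, "Std. Error"],
    p_value = sm[rows, "Pr(>|z|)"]
  )
}

#' Inverse-variance-weighted effect-on-effect regression
#'
#' Regresses outcome effects on exposure effects across genetic
#' instruments, without an intercept, weighting each instrument by the
#' inverse variance of its outcome association: slope =
#' sum(w bx by) / sum(w bx^2) with w = 1 / se_y^2, the closed-form
#' weighted-least-squares solution.  The standard error is
#' sqrt(1 / sum(w bx^2)) (fixed-effect) and the p-value is Wald.
#'
#' @param effects Tibble with columns `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @return An object of class `ivw_fit`; see [tidy.ivw_fit()].
#' @examples
#' ivw_regression(tibble::tibble(beta_exposure = c(0.1, 0.2),
#'                               se_exposure = 0.01,
#'                               beta_outcome = c(0.05, 0.1),
#'                               se_outcome = 0.02))
#' @export
ivw_regression <- function(effects) {
  needed <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(needed %in% names(effects))) {
    abort(paste("`effects` must have columns:",
                paste(needed, collapse = ", ")))
  }
  bx <- effects$beta_exposure
  by <- effects$beta_outcome
  sy <- effects$se_outcome
  if (any(sy <= 0)) abort("se_outcome must be positive.")
  if (all(bx == 0)) abort("all exposure effects are zero; slope undefined.")
  w <- 1 / sy^2
  slope <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  z <- slope / se
  structure(
    list(slope = slope, se = se, p_value = 2 * pnorm(-abs(z)),
         n_instruments = length(bx), effects = as_tibble(effects)),
    class = "ivw_fit"
  )
}

#' @exportS3Method base::print
print.ivw_fit <- function(x, ...) {
  cat(sprintf("IVW regression (no intercept), %d instruments\n",
              x$n_instruments))
  cat(sprintf("  slope %.4g (se %.3g), p = %.3g\n", x$slope, x$se,
              x$p_value))
  invisible(x)
}

#' Broom-style accessors for IVW fits
#'
#' @param x An `ivw_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per term; `glance()`: one-row model summary.
#' @export
tidy.ivw_fit <- function(x, ...) {
  tibble(term = "beta_exposure", estimate = x$slope, std.error = x$se,
         statistic = x$slope / x$se, p.value = x$p_value)
}

#' @rdname tidy.ivw_fit
#' @export
glance.ivw_fit <- function(x, ...) {
  tibble(n_instruments = x$n_instruments, slope = x$slope,
         std.error = x$se, p.value = x$p_value)
}
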