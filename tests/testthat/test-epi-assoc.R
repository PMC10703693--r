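base_manifest <- function(wbc = 7, hgb = 14, plt = 250) {
  tibble::tibble(sample_id = "S1", wbc = wbc, hgb = hgb, plt = plt)
}

no_dx <- tibble::tibble(sample_id = character(0), icd10 = character(0),
                        date_offset_days = numeric(0))

test_that("hematology exclusion bounds are strict as printed", {
  cases <- list(
    list(m = base_manifest(wbc = 1.4), out = TRUE),
    list(m = base_manifest(wbc = 1.5), out = FALSE),
    list(m = base_manifest(wbc = 35.01), out = TRUE),
    list(m = base_manifest(wbc = 35), out = FALSE),
    list(m = base_manifest(hgb = 8), out = FALSE),
    list(m = base_manifest(hgb = 7.99), out = TRUE),
    list(m = base_manifest(plt = 50), out = FALSE),
    list(m = base_manifest(plt = 49.9), out = TRUE),
    list(m = base_manifest(wbc = NA_real_), out = FALSE)
  )
  for (cs in cases) {
    res <- apply_exclusions(cs$m, no_dx)
    expect_identical(res$excluded, cs$out)
  }
})

test_that("hematological diagnoses exclude inside the 6-month window", {
  m <- base_manifest()
  dx_at <- function(code, days) {
    tibble::tibble(sample_id = "S1", icd10 = code, date_offset_days = days)
  }
  expect_true(apply_exclusions(m, dx_at("C91.1", 100))$excluded)
  expect_false(apply_exclusions(m, dx_at("C91.1", 200))$excluded)
  expect_true(apply_exclusions(m, dx_at("C91.1", -2000))$excluded)  # prior
  expect_true(apply_exclusions(m, dx_at("D47", 0))$excluded)
  expect_true(apply_exclusions(m, dx_at("D469", 10))$excluded)  # subcode
  expect_false(apply_exclusions(m, dx_at("C80", 0))$excluded)   # outside blocks
  expect_false(apply_exclusions(m, dx_at("J44", 0))$excluded)
  expect_warning(res <- apply_exclusions(m, dx_at("banana", 0)), "malformed")
  expect_false(res$excluded)
})

test_that("exclusion is idempotent and criteria-order independent", {
  set.seed(111)
  m <- tibble::tibble(
    sample_id = sprintf("S%d", 1:200),
    wbc = rlnorm(200, log(7), 1), hgb = rnorm(200, 12, 3),
    plt = rnorm(200, 200, 120)
  )
  dx <- tibble::tibble(sample_id = sample(m$sample_id, 40),
                       icd10 = sample(c("C92", "D45", "J44", "I50"), 40,
                                      replace = TRUE),
                       date_offset_days = runif(40, -1000, 1000))
  res <- apply_exclusions(m, dx)
  eligible <- dplyr::filter(res, !excluded)[names(m)]
  res2 <- apply_exclusions(eligible, dx)
  expect_false(any(res2$excluded))
  # each reason is attributed: excluded rows carry at least one reason
  expect_true(all(nchar(res$exclusion_reasons[res$excluded]) > 0))
  expect_true(all(res$exclusion_reasons[!res$excluded] == ""))
})

test_that("Fisher test matches hand-enumerated tables", {
  res <- fisher_variant_test(2, 0, 0, 2)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$odds_ratio, Inf)

  res <- fisher_variant_test(5, 5, 5, 5)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)

  res <- fisher_variant_test(10, 0, 0, 10)
  expect_equal(res$p_value, 2 / choose(20, 10))
  expect_equal(res$odds_ratio, Inf)

  expect_equal(fisher_variant_test(0, 10, 10, 0)$odds_ratio, 0)
  expect_error(fisher_variant_test(0, 0, 0, 0), "all-zero")
  expect_error(fisher_variant_test(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p equals independent enumeration on an exhaustive grid", {
  # all tables with row margins <= 8, plus random larger tables
  grid <- expand.grid(r1 = 0:8, r2 = 0:8)
  for (i in seq_len(nrow(grid))) {
    r1 <- grid$r1[i]; r2 <- grid$r2[i]
    if (r1 + r2 == 0) next
    for (a in 0:r1) for (c in 0:r2) {
      expect_equal(fisher_variant_test(a, r1 - a, c, r2 - c)$p_value,
                   enum_fisher_p(a, r1 - a, c, r2 - c), tolerance = 1e-9)
    }
  }
  set.seed(7)
  for (j in 1:50) {
    tab <- as.integer(rmultinom(1, sample(20:60, 1), rep(0.25, 4)))
    expect_equal(fisher_variant_test(tab[1], tab[2], tab[3], tab[4])$p_value,
                 enum_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("logistic association recovers a planted odds ratio", {
  set.seed(211)
  dat <- simulate_case_control(20000, log_or_ch = log(2))
  res <- logistic_assoc(dat, outcome = "phenotype", exposure = "ch")
  expect_false(res$separation)
  expect_lt(abs(log(res$odds_ratio) - log(2)), 2 * res$std_error)
  expect_lt(res$p_value, 1e-4)
})

test_that("a null phenotype gives OR near 1", {
  set.seed(212)
  dat <- simulate_case_control(8000, log_or_ch = 0)
  res <- logistic_assoc(dat, outcome = "phenotype", exposure = "ch")
  expect_lt(abs(log(res$odds_ratio)), 3 * res$std_error)
})

test_that("adjusting for a planted confounder attenuates the CH OR", {
  set.seed(213)
  dat <- simulate_case_control(30000, log_or_ch = 0,
                               log_or_smoking_pheno = 1.2,
                               log_or_smoking_ch = 1.2)
  unadj <- logistic_assoc(dat, outcome = "phenotype", exposure = "ch")
  adj <- logistic_assoc(dat, outcome = "phenotype", exposure = "ch",
                        adjust_smoking = TRUE)
  expect_gt(unadj$odds_ratio, 1.1)
  expect_lt(abs(log(adj$odds_ratio)), abs(log(unadj$odds_ratio)))
})

test_that("complete separation is flagged, not silently reported", {
  dat <- tibble::tibble(
    y = rep(c(0, 1), each = 30),
    x = rep(c(0, 1), each = 30),
    age = runif(60, 40, 80), sex = rep(c("F", "M"), 30)
  )
  expect_warning(
    res <- logistic_assoc(dat, outcome = "y", exposure = "x"),
    "separation"
  )
  expect_true(res$separation)
})

test_that("logistic p-values are uniform under the null", {
  set.seed(214)
  pvals <- replicate(500, {
    y <- rbinom(2000, 1, 0.2)
    x <- rbinom(2000, 1, 0.3)
    age <- runif(2000, 40, 80)
    sex <- sample(c("F", "M"), 2000, replace = TRUE)
    dat <- tibble::tibble(y = y, x = x, age = age, sex = sex)
    logistic_assoc(dat, outcome = "y", exposure = "x")$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("smoking dose model recovers planted pack-year risk", {
  set.seed(215)
  n <- 15000
  status <- sample(c("never", "previous", "current"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  pack_years <- ifelse(status == "never", 0, rgamma(n, 2, scale = 10))
  years_quit <- ifelse(status == "previous", runif(n, 0, 30), 0)
  age <- runif(n, 40, 85)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  lp <- -2.5 + 0.03 * pack_years - 0.02 * years_quit + 0.02 * (age - 60)
  ch <- rbinom(n, 1, plogis(lp))
  dat <- tibble::tibble(ch = ch, smoking_status = status,
                        pack_years = pack_years, years_quit = years_quit,
                        age = age, sex = sex)
  res <- smoking_dose_model(dat)
  py <- res[res$term == "pack_years", ]
  yq <- res[res$term == "years_quit", ]
  expect_lt(abs(py$estimate - 0.03), 2 * py$std_error)
  expect_lt(py$p_value, 1e-4)
  expect_lt(yq$estimate, 0)  # protective direction

  never <- dplyr::mutate(dat, smoking_status = "never", pack_years = 0,
                         years_quit = 0)
  expect_error(expect_warning(smoking_dose_model(never), "degenerate"),
               "no estimable")
})

test_that("IVW slope equals the closed-form WLS solution", {
  eff <- tibble::tibble(
    beta_exposure = c(0.10, 0.25, -0.08, 0.31),
    se_exposure = c(0.02, 0.03, 0.02, 0.04),
    beta_outcome = c(0.031, 0.070, -0.020, 0.095),
    se_outcome = c(0.011, 0.013, 0.012, 0.017)
  )
  fit <- ivw_regression(eff)
  w <- 1 / eff$se_outcome^2
  expect_identical(fit$slope,
                   sum(w * eff$beta_exposure * eff$beta_outcome) /
                     sum(w * eff$beta_exposure^2))
  # independent route: weighted no-intercept least squares via lm/QR
  lmfit <- stats::lm(beta_outcome ~ 0 + beta_exposure, data = eff,
                     weights = w)
  expect_equal(fit$slope, unname(coef(lmfit)), tolerance = 1e-12)

  # exact proportionality
  prop <- tibble::tibble(beta_exposure = c(0.1, 0.2, 0.3),
                         se_exposure = 0.01,
                         beta_outcome = c(0.2, 0.4, 0.6),
                         se_outcome = 0.02)
  expect_equal(ivw_regression(prop)$slope, 2)
  # single-instrument ratio
  one <- tibble::tibble(beta_exposure = 0.1, se_exposure = 0.01,
                        beta_outcome = 0.05, se_outcome = 0.02)
  expect_equal(ivw_regression(one)$slope, 0.5)
  expect_error(ivw_regression(dplyr::mutate(one, beta_exposure = 0)),
               "zero")
  expect_error(ivw_regression(dplyr::mutate(one, se_outcome = 0)),
               "positive")
})

test_that("IVW recovers a noisy planted slope within 2 se", {
  set.seed(216)
  bx <- runif(40, 0.05, 0.3)
  sy <- runif(40, 0.01, 0.05)
  by <- 0.3 * bx + rnorm(40, 0, sy)
  eff <- tibble::tibble(beta_exposure = bx, se_exposure = 0.01,
                        beta_outcome = by, se_outcome = sy)
  fit <- ivw_regression(eff)
  expect_lt(abs(fit$slope - 0.3), 2 * fit$se)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$n_instruments, 40L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
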