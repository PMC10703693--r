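test_that("binomial germline test matches the exact CDF computation", {
  res <- binomial_germline_test(c(20, 3, 0), c(40, 30, 1))
  expect_equal(res$p_value[1], 1.0)
  expect_true(res$potential_germline[1])
  # exact CDF oracle: 2 * P(X <= 3 | Binomial(30, 0.5)) ~ 8.43e-6
  expect_equal(res$p_value[2], 2 * pbinom(3, 30, 0.5), tolerance = 1e-12)
  expect_false(res$potential_germline[2])
  expect_equal(res$p_value[3], 1.0)   # degenerate depth 1

  # oracle sweep: symmetric null makes the two-sided p equal the folded CDF
  for (depth in c(7, 20, 41)) {
    k <- 0:depth
    oracle <- ifelse(k == depth - k, 1,
                     pmin(1, 2 * pbinom(pmin(k, depth - k), depth, 0.5)))
    expect_equal(binomial_germline_test(k, depth)$p_value, oracle,
                 tolerance = 1e-10)
  }
  expect_error(binomial_germline_test(0, 0), "depth")
  expect_error(binomial_germline_test(5, 4), "alt_reads")
})

test_that("cpld cascade applies its rule table in the stated order", {
  cands <- dplyr::bind_rows(
    make_candidate("S1", pos = 1, depth = 10L, alt_reads = 3L),  # depth >10 strict
    make_candidate("S2", pos = 2, filter = "Low_QD"),            # not PASS
    make_candidate("S3", pos = 3, depth = 1000L, alt_reads = 9L),  # vaf < 0.01
    make_candidate("S4", pos = 4, gene = "JAK2", hgvsp = "Q501X",
                   impact = "HIGH", depth = 40L, alt_reads = 8L),  # excluded gene
    make_candidate("S5", pos = 5, gene = "JAK2", hgvsp = "V617F",
                   impact = "MODERATE", depth = 40L, alt_reads = 8L),  # in list
    make_candidate("S6", pos = 6, gene = "TP53", hgvsp = "R175X",
                   impact = "HIGH", depth = 40L, alt_reads = 8L),  # kept
    make_candidate("S7", pos = 7, gene = "TP53", hgvsp = "X1Y",
                   impact = "LOW", depth = 40L, alt_reads = 8L),   # low impact
    make_candidate("S8", pos = 8, gene = "TP53", hgvsp = "M1L",
                   impact = NA_character_)                         # unannotated
  )
  out <- cpld_filter_cascade(cands)
  expect_setequal(out$sample_id, c("S5", "S6"))
  att <- attr(out, "attrition")
  expect_identical(sum(att$n_removed), nrow(cands) - nrow(out))
  expect_identical(att$n_removed[att$step == "missing_impact"], 1L)
})

test_that("recurrent germline-like variants are removed at >5 and >75%", {
  # one variant key carried by 6 samples, 5 of them germline-like (20/40),
  # one clearly somatic (5/40): fraction 0.833 > 0.75 -> whole key removed
  carriers <- lapply(1:6, function(i) {
    make_candidate(sprintf("R%d", i), pos = 99, gene = "TP53",
                   hgvsp = "R175X", impact = "HIGH", depth = 40L,
                   alt_reads = if (i <= 5) 20L else 5L)
  })
  # control key: 5 carriers (not >5), all germline-like -> kept
  controls <- lapply(1:5, function(i) {
    make_candidate(sprintf("C%d", i), pos = 55, gene = "RUNX1",
                   hgvsp = "R204Q", impact = "HIGH", depth = 40L,
                   alt_reads = 20L)
  })
  out <- cpld_filter_cascade(dplyr::bind_rows(c(carriers, controls)))
  expect_false(any(out$pos == 99))
  expect_identical(sum(out$pos == 55), 5L)
  expect_true(all(out$cohort_occurrences[out$pos == 55] == 5))
})

test_that("cascade step order matters and is pinned", {
  # a published-list variant key with 6 germline-like carriers: recurrence
  # removal (step 3) fires before the published list could rescue it (step 4)
  carriers <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_candidate(sprintf("S%d", i), pos = 7, gene = "JAK2",
                   hgvsp = "V617F", impact = "MODERATE", depth = 40L,
                   alt_reads = 20L)
  }))
  out <- cpld_filter_cascade(carriers)
  expect_identical(nrow(out), 0L)
  att <- attr(out, "attrition")
  expect_identical(att$n_remaining[att$step == "recurrent_germline"], 0L)
})

test_that("chip cascade enforces depth/minAD and the binomial removal", {
  covars <- tibble::tibble(sample_id = sprintf("S%d", 1:40),
                           age = runif(40, 40, 80),
                           rs7705526 = sample(0:2, 40, replace = TRUE))
  cands <- dplyr::bind_rows(
    make_candidate("S1", pos = 1, gene = "DNMT3A", depth = 19L,
                   alt_reads = 5L),                        # depth < 20
    make_candidate("S2", pos = 2, gene = "DNMT3A", depth = 20L,
                   alt_reads = 2L),                        # minAD < 3
    make_candidate("S3", pos = 3, gene = "DNMT3A", depth = 40L,
                   alt_reads = 8L),                        # somatic-like, kept
    make_candidate("S4", pos = 4, gene = "TET2", hgvsp = "H1904R",
                   depth = 40L, alt_reads = 20L),          # germline-like, exempt
    make_candidate("S5", pos = 5, gene = "TET2", hgvsp = "Q999X",
                   depth = 40L, alt_reads = 20L),          # germline-like
    make_candidate("S6", pos = 6, gene = "NOTINPANEL", depth = 40L,
                   alt_reads = 8L)
  )
  out <- chip_filter_cascade(cands, covars)
  expect_setequal(out$sample_id, c("S3", "S4"))
  att <- attr(out, "attrition")
  expect_identical(sum(att$n_removed), nrow(cands) - nrow(out))
})

test_that("recurrence regression only fires at >= 15 carriers", {
  set.seed(71)
  n <- 400
  covars <- tibble::tibble(sample_id = sprintf("S%d", 1:n),
                           age = runif(n, 40, 80),
                           rs7705526 = sample(0:2, n, replace = TRUE))
  # artifact key: 20 carriers drawn independently of age and dosage, with
  # somatic-like VAF (passes the binomial step); regression must remove it
  art_carriers <- sample(covars$sample_id, 20)
  artifact <- dplyr::bind_rows(lapply(art_carriers, function(s) {
    make_candidate(s, pos = 11, gene = "ASXL1", hgvsp = "G646Wfs",
                   depth = 40L, alt_reads = 6L)
  }))
  # true driver key: carriage probability rises smoothly with age (a hard
  # age cutoff would separate the logistic fit)
  old <- sample(covars$sample_id, 25, prob = plogis((covars$age - 65) / 4))
  driver <- dplyr::bind_rows(lapply(old, function(s) {
    make_candidate(s, pos = 22, gene = "DNMT3A", hgvsp = "R882H",
                   depth = 40L, alt_reads = 6L)
  }))
  # 14-carrier key, also age-flat: below the carrier bound, never tested
  small <- dplyr::bind_rows(lapply(sample(covars$sample_id, 14), function(s) {
    make_candidate(s, pos = 33, gene = "TET2", hgvsp = "Q1000X",
                   depth = 40L, alt_reads = 6L)
  }))
  out <- chip_filter_cascade(dplyr::bind_rows(artifact, driver, small),
                             covars)
  expect_false(any(out$pos == 11))
  expect_true(all(c(22, 33) %in% out$pos))
})

test_that("germline misclassification of spiked drivers matches the exact test", {
  # clone fraction 0.5 at depth 40: alt ~ Binomial(40, 0.25); the chance the
  # exact test calls it potential germline is computable by enumeration
  depth <- 40L
  f <- 0.5
  k <- 0:depth
  p_two <- binomial_germline_test(k, depth)$p_value
  accept_prob <- sum(dbinom(k, depth, f / 2)[p_two > 0.05])
  set.seed(97)
  alt <- rbinom(4000, depth, f / 2)
  observed <- mean(binomial_germline_test(alt, depth)$potential_germline)
  mc_se <- sqrt(accept_prob * (1 - accept_prob) / 4000)
  expect_lt(abs(observed - accept_prob), 3.5 * mc_se)
})

test_that("subtype classification covers all four states plus unevaluable", {
  calls <- tibble::tibble(
    sample_id = c("A", "B", "C", "D", "E"),
    is_ch = c(TRUE, TRUE, FALSE, FALSE, TRUE)
  )
  drivers <- tibble::tibble(sample_id = c("A", "C", "C"),
                            gene = c("DNMT3A", "JAK2", "TET2"))
  out <- classify_subtypes(calls, drivers,
                           evaluated_samples = c("A", "B", "C", "D"))
  expect_identical(out$subtype,
                   c("CPLD-CH", "CPLDneg-CH", "CPLD-only", "none",
                     "unevaluable"))
  expect_identical(out$driver_genes[out$sample_id == "C"], "JAK2,TET2")
  # invariants from the definition
  expect_true(all(out$barcode_ch[out$subtype == "CPLDneg-CH"] &
                    !out$cpld_ch[out$subtype == "CPLDneg-CH"]))
  expect_true(all(!out$barcode_ch[out$subtype == "CPLD-only"] &
                    out$cpld_ch[out$subtype == "CPLD-only"]))
  expect_error(classify_subtypes(calls[c(1, 1), ], drivers), "duplicated")
})

test_that("bundled resources load and exclude U2AF1 from the panel", {
  panel <- chip_gene_panel()
  expect_true(all(c("DNMT3A", "TET2", "ASXL1") %in% panel$gene))
  pub <- cpld_published_list()
  expect_true("V617F" %in% pub$hgvsp)
  expect_identical(chip_exempt_sites(),
                   c("TET2 H1904R", "TET2 I1873T", "TET2 T1884A"))
})
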