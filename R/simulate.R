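#' Logistic clone-prevalence curve anchored at two ages
#'
#' Default age model for the probability that a sample harbours an expanded
#' hematopoietic clone: a two-parameter logistic fixed by its values at two
#' anchor ages.  The defaults place prevalence at 1% at age 40 and 50% at
#' age 80, the range over which clonal hematopoiesis rises from rare to
#' near-ubiquitous in population sequencing cohorts.
#'
#' @param p1,p2 Prevalences at the anchor ages.
#' @param age1,age2 Anchor ages in years.
#' @return A function mapping a numeric age vector to probabilities.
#' @examples
#' f <- clone_prevalence_logistic()
#' f(c(40, 60, 80))
#' @export
clone_prevalence_logistic <- function(p1 = 0.01, age1 = 40,
                                      p2 = 0.50, age2 = 80) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, age2 != age1)
  slope <- (qlogis(p2) - qlogis(p1)) / (age2 - age1)
  intercept <- qlogis(p1) - slope * age1
  function(age) plogis(intercept + slope * age)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the generator.  The defaults describe
#' the data-generating process the barcode caller assumes: germline
#' heterozygote alt reads are Binomial(depth, 0.5), clone-private somatic
#' sites are Binomial(depth, f/2) for clone cell fraction f, and a low-VAF
#' artifact "bump" contributes records with only 1-2 alt reads.  Per-variant
#' depth follows a center-specific Poisson (or negative binomial when
#' `depth_dispersion` is finite; a dispersion of 0 fixes depth at the mean),
#' truncated to at least 1 read.
#'
#' @param n_samples Number of samples in the cohort.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param centers Data frame with columns `center`, `platform`, `fraction`
#'   (sample fractions, summing to 1), `mean_depth` and `depth_dispersion`.
#' @param n_germline_het Expected number of private germline heterozygous
#'   sites per sample (realized counts are Poisson).
#' @param shared_pool_size Number of cohort-shared germline sites; each
#'   sample carries a shared site with that site's population frequency,
#'   drawn uniformly on `[0.05, 0.5]`.  Shared sites are never cohort
#'   singletons.
#' @param clone_prevalence_fn Function age -> probability of carrying a
#'   clone, before smoking adjustment.
#' @param clone_vaf_dist Function n -> clone cell fractions in (0, 1];
#'   per-site VAF of a clone mutation is fraction / 2.
#' @param n_clone_mutations_dist Function n -> number of clone-private
#'   somatic mutations per clone-positive sample.
#' @param error_bump_rate Expected number of artifact records per sample.
#' @param driver_spike_prob Probability that a clone-positive sample carries
#'   a named driver mutation (see [spike_driver()]).
#' @param age_dist Function n -> ages at blood draw, years.
#' @param sex_ratio Probability of sex `"F"`.
#' @param smoking List of smoking-model parameters: status probabilities
#'   `p_current`, `p_previous`; clone-odds multipliers `or_current`,
#'   `or_previous`, `or_pack_year` (per pack-year, ever-smokers) and
#'   `or_year_quit` (per year since quitting, previous smokers).
#' @param gq_fail_frac Fraction of emitted records failing the genotype
#'   quality filter (GQ below 90).
#' @param low_qd_frac Fraction of records flagged `Low_QD` (admitted by the
#'   default indicator filter).
#' @param filter_fail_frac Fraction of records with a disqualifying FILTER
#'   (`LowQual`).
#' @return A validated list of class `ch_sim_config`.
#' @examples
#' cfg <- sim_config(n_samples = 50, seed = 7)
#' cfg$centers
#' @export
sim_config <- function(n_samples,
                       seed = 1L,
                       centers = default_centers(),
                       n_germline_het = 30000,
                       shared_pool_size = 500,
                       clone_prevalence_fn = clone_prevalence_logistic(),
                       clone_vaf_dist = function(n) runif(n, 0.2, 0.6),
                       n_clone_mutations_dist = function(n) rpois(n, 300),
                       error_bump_rate = 50,
                       driver_spike_prob = 0,
                       age_dist = function(n) runif(n, 40, 85),
                       sex_ratio = 0.5,
                       smoking = list(p_current = 0.10, p_previous = 0.35,
                                      or_current = 1.8, or_previous = 1.3,
                                      or_pack_year = 1.01,
                                      or_year_quit = 0.98),
                       gq_fail_frac = 0.02,
                       low_qd_frac = 0.02,
                       filter_fail_frac = 0.01) {
  centers <- as_tibble(centers)
  needed <- c("center", "platform", "fraction", "mean_depth",
              "depth_dispersion")
  if (!all(needed %in% names(centers))) {
    abort(paste("`centers` must have columns:", paste(needed, collapse = ", ")))
  }
  if (abs(sum(centers$fraction) - 1) > 1e-8 || any(centers$fraction < 0)) {
    abort("center sample fractions must be non-negative and sum to 1.")
  }
  if (any(centers$mean_depth <= 0)) abort("mean depths must be positive.")
  probs <- c(sex_ratio, gq_fail_frac, low_qd_frac, filter_fail_frac,
             driver_spike_prob, smoking$p_current, smoking$p_previous)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1].")
  if (smoking$p_current + smoking$p_previous > 1) {
    abort("smoking status probabilities exceed 1.")
  }
  if (n_samples < 1) abort("n_samples must be at least 1.")
  if (error_bump_rate < 0 || shared_pool_size < 0 || n_germline_het < 0) {
    abort("rates and counts must be non-negative.")
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         centers = centers, n_germline_het = n_germline_het,
         shared_pool_size = as.integer(shared_pool_size),
         clone_prevalence_fn = clone_prevalence_fn,
         clone_vaf_dist = clone_vaf_dist,
         n_clone_mutations_dist = n_clone_mutations_dist,
         error_bump_rate = error_bump_rate,
         driver_spike_prob = driver_spike_prob,
         age_dist = age_dist, sex_ratio = sex_ratio, smoking = smoking,
         gq_fail_frac = gq_fail_frac, low_qd_frac = low_qd_frac,
         filter_fail_frac = filter_fail_frac),
    class = "ch_sim_config"
  )
}

#' Default sequencing-center table for simulations
#'
#' Two centers on one platform, differing slightly in mean depth, mirroring
#' a multi-center cohort whose germline ratio model must be stratified by
#' center.
#'
#' @param mean_depth Baseline mean depth.
#' @return Tibble usable as the `centers` argument of [sim_config()].
#' @export
default_centers <- function(mean_depth = 35) {
  tibble(
    center = c("CenterA", "CenterB"),
    platform = c("WGS", "WGS"),
    fraction = c(0.6, 0.4),
    mean_depth = c(mean_depth, mean_depth - 3),
    depth_dispersion = c(Inf, Inf)
  )
}

# genome coordinate space: 22 autosomes of 1.2e8 bp laid out linearly
.GENOME_CHROM_LEN <- 1.2e8
.GENOME_N_CHROM <- 22L

linear_to_chrompos <- function(x) {
  chrom_i <- ((x - 1) %/% .GENOME_CHROM_LEN) + 1
  list(chrom = paste0("chr", as.integer(chrom_i)),
       pos = as.numeric((x - 1) %% .GENOME_CHROM_LEN + 1))
}

# depth law: dispersion 0 -> fixed; Inf/NA -> Poisson; else NB(mu, size)
draw_depth <- function(n, mean_depth, dispersion) {
  if (n == 0) return(integer(0))
  if (length(mean_depth) == 1) mean_depth <- rep(mean_depth, n)
  if (length(dispersion) == 1) dispersion <- rep(dispersion, n)
  d <- integer(n)
  fixed <- dispersion == 0
  pois <- !fixed & (!is.finite(dispersion))
  nb <- !fixed & !pois
  if (any(fixed)) d[fixed] <- as.integer(round(mean_depth[fixed]))
  if (any(pois)) d[pois] <- rpois(sum(pois), mean_depth[pois])
  if (any(nb)) {
    d[nb] <- rnbinom(sum(nb), mu = mean_depth[nb], size = dispersion[nb])
  }
  pmax(d, 1L)
}

BASES <- c("A", "C", "G", "T")

draw_alleles <- function(n) {
  ref_i <- sample.int(4L, n, replace = TRUE)
  # alt drawn uniformly among the three non-ref bases
  off <- sample.int(3L, n, replace = TRUE)
  alt_i <- ((ref_i - 1L + off) %% 4L) + 1L
  list(ref = BASES[ref_i], alt = BASES[alt_i])
}

draw_quality <- function(n, config) {
  gq <- ifelse(runif(n) < config$gq_fail_frac,
               sample(30:89, n, replace = TRUE),
               sample(90:99, n, replace = TRUE))
  u <- runif(n)
  filter_status <- rep("PASS", n)
  filter_status[u < config$low_qd_frac + config$filter_fail_frac] <- "Low_QD"
  filter_status[u < config$filter_fail_frac] <- "LowQual"
  list(gq = as.integer(gq), filter_status = filter_status)
}

#' Simulate a whole cohort of per-sample variant calls with known truth
#'
#' Generates the cohort manifest, every sample's variant records and a truth
#' table recording clone carriage, clone cell fraction and the number of
#' emitted clone mutations whose realized VAF falls in the somatic indicator
#' window `[0.10, 0.25]`.  Private germline and clone sites occupy disjoint
#' genomic positions across samples (so each is a cohort singleton by
#' construction), while shared-pool sites recur across samples.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `variants` (one row per called variant per
#'   sample: sample_id, chrom, pos, ref, alt, depth, alt_reads, gq,
#'   filter_status, center, platform, origin), `manifest` (sample metadata:
#'   center, platform, age, sex, smoking and hematology fields) and `truth`
#'   (sample_id, has_clone, clone_fraction, true_somatic_singletons_in_window,
#'   driver_gene).
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 4, seed = 1,
#'                                   n_germline_het = 200,
#'                                   shared_pool_size = 20))
#' dplyr::count(sim$variants, origin)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ch_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples

  manifest <- sim_manifest(config)
  truth0 <- sim_clone_truth(config, manifest)

  # realized per-sample site counts
  n_germ <- rpois(n, config$n_germline_het)
  n_clone <- integer(n)
  if (any(truth0$has_clone)) {
    n_clone[truth0$has_clone] <-
      as.integer(config$n_clone_mutations_dist(sum(truth0$has_clone)))
  }
  n_err <- rpois(n, config$error_bump_rate)

  total_private <- sum(n_germ) + sum(n_clone) + sum(n_err)
  genome_size <- .GENOME_CHROM_LEN * .GENOME_N_CHROM
  coords <- sample(genome_size, total_private + config$shared_pool_size)
  shared_coords <- coords[seq_len(config$shared_pool_size)]
  private_coords <- coords[-seq_len(config$shared_pool_size)]
  if (config$shared_pool_size == 0) private_coords <- coords

  center_row <- match(manifest$center, config$centers$center)
  mean_d <- config$centers$mean_depth[center_row]
  disp_d <- config$centers$depth_dispersion[center_row]

  piece <- function(sample_idx, coord, origin, alt_fun) {
    m <- length(sample_idx)
    depth <- draw_depth(m, mean_d[sample_idx], disp_d[sample_idx])
    alt_reads <- alt_fun(m, depth, sample_idx)
    al <- draw_alleles(m)
    qual <- draw_quality(m, config)
    cp <- linear_to_chrompos(coord)
    tibble(
      sample_id = manifest$sample_id[sample_idx],
      chrom = cp$chrom, pos = cp$pos, ref = al$ref, alt = al$alt,
      depth = depth, alt_reads = as.integer(alt_reads),
      gq = qual$gq, filter_status = qual$filter_status,
      center = manifest$center[sample_idx],
      platform = manifest$platform[sample_idx],
      origin = origin
    )
  }

  off <- 0L
  take <- function(k) {
    out <- private_coords[seq_len(k) + off]
    off <<- off + k
    out
  }

  germ_idx <- rep(seq_len(n), n_germ)
  germ <- piece(germ_idx, take(length(germ_idx)), "germline_private",
                function(m, depth, i) rbinom(m, depth, 0.5))

  clone_idx <- rep(seq_len(n), n_clone)
  clone <- piece(clone_idx, take(length(clone_idx)), "clone",
                 function(m, depth, i) {
                   rbinom(m, depth, truth0$clone_fraction[i] / 2)
                 })
  # a somatic site with no alt reads is never called
  clone <- dplyr::filter(clone, .data$alt_reads >= 1L)

  err_idx <- rep(seq_len(n), n_err)
  err <- piece(err_idx, take(length(err_idx)), "artifact",
               function(m, depth, i) {
                 pmin(sample(1:2, m, replace = TRUE), depth)
               })

  shared <- sim_shared_pool(config, manifest, shared_coords, mean_d, disp_d)

  variants <- dplyr::bind_rows(germ, shared, clone, err)
  # drop uncalled (0 alt read) germline records
  variants <- dplyr::filter(variants, .data$alt_reads >= 1L)

  windows <- vaf_windows()
  in_low <- clone$alt_reads / clone$depth >= windows$lo[1] - 1e-9 &
    clone$alt_reads / clone$depth <= windows$hi[1] + 1e-9
  low_counts <- tapply(in_low, factor(clone$sample_id,
                                      levels = manifest$sample_id), sum)
  truth <- truth0
  truth$true_somatic_singletons_in_window <-
    as.integer(ifelse(is.na(low_counts), 0L, low_counts))

  # spike named drivers into a fraction of clone-positive samples
  if (config$driver_spike_prob > 0 && any(truth$has_clone)) {
    spike_in <- truth$has_clone & runif(n) < config$driver_spike_prob
    panel <- chip_gene_panel()$gene
    for (i in which(spike_in)) {
      gene <- sample(panel, 1)
      truth$driver_gene[i] <- gene
      dep <- draw_depth(1L, mean_d[i], disp_d[i])
      spiked <- spike_driver(
        dplyr::filter(variants, .data$sample_id == manifest$sample_id[i]),
        gene = gene, protein_change = "p.Sim1X",
        clone_fraction = truth$clone_fraction[i], depth = dep
      )
      variants <- dplyr::bind_rows(
        dplyr::filter(variants, .data$sample_id != manifest$sample_id[i]),
        spiked
      )
    }
  }

  list(variants = variants, manifest = manifest, truth = truth)
}

sim_manifest <- function(config) {
  n <- config$n_samples
  center_i <- sample.int(nrow(config$centers), n, replace = TRUE,
                         prob = config$centers$fraction)
  age <- config$age_dist(n)
  sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")
  sm <- config$smoking
  u <- runif(n)
  smoking_status <- rep("never", n)
  smoking_status[u < sm$p_current + sm$p_previous] <- "previous"
  smoking_status[u < sm$p_current] <- "current"
  ever <- smoking_status != "never"
  pack_years <- ifelse(ever, stats::rgamma(n, shape = 2, scale = 10), 0)
  years_quit <- ifelse(smoking_status == "previous", runif(n, 0, 30), 0)
  tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    center = config$centers$center[center_i],
    platform = config$centers$platform[center_i],
    age = age, sex = sex,
    smoking_status = smoking_status,
    pack_years = pack_years, years_quit = years_quit,
    wbc = rlnorm(n, log(6.8), 0.25),
    hgb = rnorm(n, 14, 1.3),
    plt = pmax(rnorm(n, 250, 60), 1)
  )
}

sim_clone_truth <- function(config, manifest) {
  n <- nrow(manifest)
  p <- config$clone_prevalence_fn(manifest$age)
  sm <- config$smoking
  or <- rep(1, n)
  or[manifest$smoking_status == "current"] <- sm$or_current
  prev <- manifest$smoking_status == "previous"
  or[prev] <- sm$or_previous * sm$or_year_quit^manifest$years_quit[prev]
  ever <- manifest$smoking_status != "never"
  or[ever] <- or[ever] * sm$or_pack_year^manifest$pack_years[ever]
  p_adj <- plogis(qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + log(or))
  has_clone <- runif(n) < p_adj
  frac <- rep(0, n)
  if (any(has_clone)) frac[has_clone] <- config$clone_vaf_dist(sum(has_clone))
  tibble(
    sample_id = manifest$sample_id,
    has_clone = has_clone,
    clone_fraction = frac,
    true_somatic_singletons_in_window = 0L,
    driver_gene = NA_character_
  )
}

sim_shared_pool <- function(config, manifest, shared_coords, mean_d, disp_d) {
  k <- config$shared_pool_size
  n <- nrow(manifest)
  if (k == 0) {
    return(tibble(sample_id = character(0), chrom = character(0),
                  pos = numeric(0), ref = character(0), alt = character(0),
                  depth = integer(0), alt_reads = integer(0), gq = integer(0),
                  filter_status = character(0), center = character(0),
                  platform = character(0), origin = character(0)))
  }
  freq <- runif(k, 0.05, 0.5)
  al <- draw_alleles(k)
  cp <- linear_to_chrompos(shared_coords)
  # carriage: Bernoulli(site frequency) per sample, vectorized over the grid
  carry <- runif(k * n) < rep(freq, each = n)
  site_i <- rep(seq_len(k), each = n)[carry]
  samp_i <- rep(seq_len(n), times = k)[carry]
  m <- length(site_i)
  depth <- draw_depth(m, mean_d[samp_i], disp_d[samp_i])
  qual <- draw_quality(m, config)
  tibble(
    sample_id = manifest$sample_id[samp_i],
    chrom = cp$chrom[site_i], pos = cp$pos[site_i],
    ref = al$ref[site_i], alt = al$alt[site_i],
    depth = depth, alt_reads = rbinom(m, depth, 0.5),
    gq = qual$gq, filter_status = qual$filter_status,
    center = manifest$center[samp_i], platform = manifest$platform[samp_i],
    origin = "germline_shared"
  )
}

#' Simulate one sample's variant records
#'
#' Single-sample counterpart of [simulate_cohort()]: germline heterozygote
#' sites draw alt reads from Binomial(depth, 0.5), clone sites (when a clone
#' is present) from Binomial(depth, clone_fraction / 2), and artifact records
#' carry 1-2 alt reads.  Cohort-level structure (shared sites, singleton
#' status) does not apply to a single sample.
#'
#' @param config A [sim_config()] object.
#' @param age Age at blood draw, years.
#' @param center Center label, one of `config$centers$center`.
#' @param has_clone Force clone presence; `NULL` draws it from the
#'   age-dependent prevalence.
#' @param clone_fraction Clone cell fraction; `NULL` draws from
#'   `config$clone_vaf_dist` when a clone is present.
#' @param sample_id Sample label for the emitted records.
#' @return List with tibbles `variants` and `truth` (one row).
#' @examples
#' s <- simulate_sample(sim_config(10, seed = 3, n_germline_het = 100),
#'                      age = 70, center = "CenterA")
#' s$truth
#' @export
simulate_sample <- function(config, age, center, has_clone = NULL,
                            clone_fraction = NULL, sample_id = "S00001") {
  stopifnot(inherits(config, "ch_sim_config"), age >= 0)
  ci <- match(center, config$centers$center)
  if (is.na(ci)) {
    abort(paste0("unknown center '", center, "'; known: ",
                 paste(config$centers$center, collapse = ", ")))
  }
  single <- config
  single$n_samples <- 1L
  single$shared_pool_size <- 0L
  single$driver_spike_prob <- 0
  single$age_dist <- function(n) rep(age, n)
  keep <- config$centers[ci, ]
  keep$fraction <- 1
  single$centers <- keep
  if (!is.null(has_clone)) {
    single$clone_prevalence_fn <- function(a) rep(as.numeric(has_clone),
                                                  length(a))
  }
  if (!is.null(clone_fraction)) {
    single$clone_vaf_dist <- function(n) rep(clone_fraction, n)
  }
  sim <- simulate_cohort_noseed(single)
  sim$variants$sample_id <- sample_id
  sim$truth$sample_id <- sample_id
  list(variants = sim$variants, truth = sim$truth)
}

# simulate_cohort without touching the RNG seed: used by simulate_sample so
# that repeated calls advance the caller's RNG stream naturally
simulate_cohort_noseed <- function(config) {
  seed_save <- config$seed
  cfg2 <- config
  # re-seed from the current stream so the cohort path can be reused verbatim
  cfg2$seed <- sample.int(.Machine$integer.max, 1)
  simulate_cohort(cfg2)
}

#' Spike a named driver mutation into a sample's variant records
#'
#' Appends one annotated somatic record whose alt reads are drawn from
#' Binomial(depth, clone_fraction / 2), carrying `gene`, `hgvsp` and
#' `impact` columns as a somatic caller plus annotator would export.  A gene
#' outside the bundled panel raises a warning but the record is still
#' emitted; a zero-depth site is never emitted.
#'
#' @param variants A sample's variant tibble (may be empty).
#' @param gene Gene symbol.
#' @param protein_change HGVS-p label.
#' @param clone_fraction Clone cell fraction in (0, 1].
#' @param depth Read depth at the spiked site; default resamples one of the
#'   sample's observed depths.
#' @param impact VEP-style impact class for the record.
#' @param chrom,pos Coordinates of the spiked site.
#' @return `variants` with one extra row (or unchanged if `depth` is 0).
#' @examples
#' v <- tibble::tibble(sample_id = "S1", chrom = "chr9", pos = 1, ref = "A",
#'                     alt = "T", depth = 40L, alt_reads = 20L, gq = 99L,
#'                     filter_status = "PASS", center = "CenterA",
#'                     platform = "WGS", origin = "germline_private")
#' spike_driver(v, "JAK2", "p.Val617Phe", clone_fraction = 0.2, depth = 50)
#' @export
spike_driver <- function(variants, gene, protein_change, clone_fraction,
                         depth = NULL, impact = "MODERATE",
                         chrom = "chr9", pos = 5073770) {
  if (clone_fraction <= 0 || clone_fraction > 1) {
    abort("clone_fraction must lie in (0, 1].")
  }
  if (!gene %in% chip_gene_panel()$gene) {
    warn(paste0("gene '", gene, "' is not in the bundled driver panel; ",
                "record emitted anyway."))
  }
  if (is.null(depth)) {
    depth <- if (nrow(variants)) sample(variants$depth, 1) else 40L
  }
  depth <- as.integer(depth)
  if (depth == 0L) return(variants)
  rec <- tibble(
    sample_id = if (nrow(variants)) variants$sample_id[1] else "S00001",
    chrom = chrom, pos = as.numeric(pos), ref = "G", alt = "T",
    depth = depth,
    alt_reads = rbinom(1, depth, clone_fraction / 2),
    gq = 99L, filter_status = "PASS",
    center = if (nrow(variants)) variants$center[1] else NA_character_,
    platform = if (nrow(variants)) variants$platform[1] else NA_character_,
    origin = "driver",
    gene = gene, hgvsp = protein_change, impact = impact
  )
  dplyr::bind_rows(variants, rec)
}

#' Simulate a case-control table with a planted CH-phenotype effect
#'
#' Generates participant-level data for exercising the association layer: a
#' CH flag with age/smoking-dependent prevalence, and a binary phenotype
#' whose log-odds contain a planted CH effect plus (optionally) a smoking
#' effect, allowing confounding structures to be built deliberately.
#'
#' @param n Number of participants.
#' @param log_or_ch Planted log odds ratio of phenotype given CH.
#' @param baseline_logit Phenotype log-odds in an unexposed participant.
#' @param log_or_smoking_pheno Direct smoking effect on the phenotype
#'   log-odds (a nonzero value with `log_or_smoking_ch > 0` plants
#'   confounding).
#' @param log_or_smoking_ch Smoking effect on CH log-odds.
#' @param ch_baseline_logit CH log-odds at the mean age.
#' @param beta_age_ch CH log-odds slope per year of (centered) age.
#' @return Tibble with sample_id, age, sex, smoking (0/1), pack_years,
#'   years_quit, ch and phenotype columns.
#' @export
simulate_case_control <- function(n, log_or_ch,
                                  baseline_logit = -3,
                                  log_or_smoking_pheno = 0,
                                  log_or_smoking_ch = 0,
                                  ch_baseline_logit = -2.2,
                                  beta_age_ch = 0.06) {
  age <- runif(n, 40, 85)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  smoking <- as.integer(runif(n) < 0.3)
  pack_years <- ifelse(smoking == 1, stats::rgamma(n, 2, scale = 10), 0)
  years_quit <- ifelse(smoking == 1 & runif(n) < 0.6, runif(n, 0, 30), 0)
  ch <- as.integer(runif(n) < plogis(ch_baseline_logit +
                                       beta_age_ch * (age - 62) +
                                       log_or_smoking_ch * smoking))
  phenotype <- as.integer(runif(n) < plogis(baseline_logit +
                                              log_or_ch * ch +
                                              log_or_smoking_pheno * smoking))
  tibble(sample_id = sprintf("P%06d", seq_len(n)), age = age, sex = sex,
         smoking = smoking, pack_years = pack_years, years_quit = years_quit,
         ch = ch, phenotype = phenotype)
}
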