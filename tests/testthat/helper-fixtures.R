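# in-code fixture builders shared across test files

# one variant record with overridable fields
make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 100,
                         ref = "A", alt = "T", depth = 40L, alt_reads = 20L,
                         gq = 99L, filter_status = "PASS",
                         center = "CenterA", platform = "WGS",
                         origin = "germline_private") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, depth = as.integer(depth),
                 alt_reads = as.integer(alt_reads), gq = as.integer(gq),
                 filter_status = filter_status, center = center,
                 platform = platform, origin = origin)
}

make_variants <- function(...) dplyr::bind_rows(...)

# driver-candidate row in the schema a somatic caller + annotator exports
make_candidate <- function(sample_id = "S1", chrom = "chr2", pos = 1000,
                           ref = "C", alt = "T", depth = 40L,
                           alt_reads = 8L, gene = "DNMT3A",
                           hgvsp = "R882H", impact = "MODERATE",
                           filter = "PASS") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, depth = as.integer(depth),
                 alt_reads = as.integer(alt_reads), gene = gene,
                 hgvsp = hgvsp, impact = impact, filter = filter)
}

# germline-only configuration: no clones, no artifacts, clean quality fields
germline_only_config <- function(n_samples, seed, n_het = 2000,
                                 mean_depth = 35, dispersion = Inf,
                                 centers = NULL, shared_pool = 0) {
  if (is.null(centers)) {
    centers <- tibble::tibble(center = "C1", platform = "WGS", fraction = 1,
                              mean_depth = mean_depth,
                              depth_dispersion = dispersion)
  }
  sim_config(
    n_samples = n_samples, seed = seed, centers = centers,
    n_germline_het = n_het, shared_pool_size = shared_pool,
    clone_prevalence_fn = function(a) rep(0, length(a)),
    error_bump_rate = 0, gq_fail_frac = 0, low_qd_frac = 0,
    filter_fail_frac = 0
  )
}

# exact Binomial(depth, p) probability of VAF falling inside [lo, hi]
exact_window_prob <- function(depth, p, lo, hi) {
  k <- 0:depth
  sum(stats::dbinom(k[k / depth >= lo - 1e-9 & k / depth <= hi + 1e-9],
                    depth, p))
}

# independent exact two-sided Fisher p: enumerate the hypergeometric support
# from first principles (lchoose arithmetic, not dhyper/fisher.test)
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(n - r1, c1 - support) -
    lchoose(n, c1)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}
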