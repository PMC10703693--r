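#' Write a cohort as per-sample VCF files
#'
#' Emits one minimal VCF 4.2 per sample (CHROM, POS, ID, REF, ALT, QUAL,
#' FILTER, INFO, FORMAT with GT:AD:DP:GQ), the interchange format
#' [read_cohort()] consumes.
#'
#' @param variants Cohort variant tibble (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort_vcf <- function(variants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=Low_QD,Description=\"Low quality by depth\">",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  paths <- vapply(split(variants, variants$sample_id), function(v) {
    sid <- v$sample_id[1]
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    ref_reads <- v$depth - v$alt_reads
    body <- sprintf("%s\t%s\t.\t%s\t%s\t.\t%s\t.\tGT:AD:DP:GQ\t0/1:%d,%d:%d:%d",
                    v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                    v$ref, v$alt, v$filter_status,
                    ref_reads, v$alt_reads, v$depth, v$gq)
    path <- file.path(dir, paste0(sid, ".vcf"))
    writeLines(c(header,
                 paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                        "\tFORMAT\t", sid),
                 body),
               path)
    path
  }, character(1))
  invisible(unname(paths))
}

#' Read per-sample VCFs into a cohort variant table
#'
#' Parses each file with vcfR, decomposes multiallelic records into one row
#' per ALT allele (allelic depths follow the allele), and annotates each
#' record with the sample's center and platform from the manifest.  Records
#' lacking AD, DP or GQ keep `NA` in those fields and are excluded later by
#' the indicator filter, with a logged count here.  A VCF whose sample is
#' absent from the manifest is a hard error.
#'
#' @param paths VCF file paths, one sample per file.
#' @param manifest Tibble with `sample_id`, `center`, `platform`.
#' @return Cohort variant tibble matching the [simulate_cohort()] schema
#'   (without `origin`).
#' @export
read_cohort <- function(paths, manifest) {
  out <- purrr::map(paths, read_sample_vcf, manifest = manifest)
  dplyr::bind_rows(out)
}

read_sample_vcf <- function(path, manifest) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sid <- colnames(v@gt)[2]
  if (is.null(sid) || is.na(sid)) {
    sid <- sub("\\.vcf$", "", basename(path))
  }
  mrow <- match(sid, manifest$sample_id)
  if (is.na(mrow)) {
    abort(paste0("sample '", sid, "' in ", basename(path),
                 " is absent from the manifest."))
  }
  if (nrow(v@fix) == 0) {
    return(tibble(sample_id = character(0), chrom = character(0),
                  pos = numeric(0), ref = character(0), alt = character(0),
                  depth = integer(0), alt_reads = integer(0),
                  gq = integer(0), filter_status = character(0),
                  center = character(0), platform = character(0)))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")))
  gq <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "GQ")))

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  which_alt <- sequence(n_alt)

  alt_reads <- rep(NA_integer_, length(idx))
  ad_split <- strsplit(as.character(ad[, 1]), ",", fixed = TRUE)
  for (k in seq_along(idx)) {
    fields <- ad_split[[idx[k]]]
    if (length(fields) >= which_alt[k] + 1 && !anyNA(fields)) {
      alt_reads[k] <- suppressWarnings(as.integer(fields[which_alt[k] + 1]))
    }
  }
  incomplete <- is.na(alt_reads) | is.na(dp[idx]) | is.na(gq[idx])
  if (any(incomplete)) {
    inform(sprintf(
      "%s: %d record(s) with missing AD/DP/GQ flagged (excluded by filters).",
      basename(path), sum(incomplete)))
  }
  tibble(
    sample_id = sid,
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alts),
    depth = dp[idx],
    alt_reads = alt_reads,
    gq = gq[idx],
    filter_status = fix$FILTER[idx],
    center = manifest$center[mrow],
    platform = manifest$platform[mrow]
  )
}

#' Tab-separated writers and readers for pipeline tables
#'
#' Thin readr wrappers fixing the on-disk schema of the pipeline artifacts:
#' the manifest, diagnoses, truth, per-sample profile and CH call tables.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", center = "c", platform = "c", age = "d", sex = "c",
    smoking_status = "c", pack_years = "d", years_quit = "d",
    wbc = "d", hgb = "d", plt = "d"
  ), progress = FALSE)
}

#' @rdname tsv_io
#' @export
read_diagnoses <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", icd10 = "c", date_offset_days = "d"
  ), progress = FALSE)
}

#' Phenotype definitions from YAML
#'
#' A phenotype definition file maps a phenotype label to a set of ICD10
#' codes (or code prefixes).  [phenotype_flags()] turns diagnoses into
#' per-sample logical flags by dotless prefix matching, so `C91` matches
#' `C91.1` and `C911`.
#'
#' @param path YAML file: `label: [code, code, ...]`.
#' @return Named list of character code vectors.
#' @export
read_phenotype_defs <- function(path) {
  defs <- yaml::read_yaml(path)
  lapply(defs, function(codes) toupper(gsub("\\.", "", unlist(codes))))
}

#' @rdname read_phenotype_defs
#' @param manifest Tibble with `sample_id`.
#' @param diagnoses Diagnoses tibble (`sample_id`, `icd10`,
#'   `date_offset_days`).
#' @param defs Named list from [read_phenotype_defs()] (or built in code).
#' @param min_days Only count diagnoses dated at least this many days
#'   relative to blood draw (`-Inf` keeps all).
#' @return `manifest` with one logical column per phenotype label.
#' @export
phenotype_flags <- function(manifest, diagnoses, defs, min_days = -Inf) {
  code <- toupper(gsub("\\.", "", diagnoses$icd10))
  keep <- diagnoses$date_offset_days >= min_days
  out <- manifest
  for (label in names(defs)) {
    pat <- paste0("^(", paste(defs[[label]], collapse = "|"), ")")
    hit <- keep & grepl(pat, code)
    out[[label]] <- out$sample_id %in% unique(diagnoses$sample_id[hit])
  }
  out
}
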