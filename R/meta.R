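# Fixed-effect inverse-variance meta-analysis across cohorts and sex strata,
# exact leave-one-cohort-out subtraction, variance-explained accounting and
# the genomic-control lambda.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-cohort association records with weights `1/SE^2`
#' (fixed-effect, standard-error scheme):
#' `beta_meta = sum(beta_i/SE_i^2) / sum(1/SE_i^2)`,
#' `SE_meta = sum(1/SE_i^2)^(-1/2)`, `Z = beta_meta/SE_meta`,
#' `P = 2 pnorm(-|Z|)`. Records are combined within each (variant, stratum)
#' cell; alleles are first aligned to the orientation of the first cohort
#' carrying the variant (records that cannot be harmonized are dropped).
#' Variants carried by a single cohort pass through with `k_cohorts = 1`.
#' Cochran's Q heterogeneity statistic is reported but never used to switch
#' models. The effect-allele frequency of the meta record is the
#' sample-size-weighted mean, and a minor-allele-frequency filter is applied
#' to it.
#'
#' @param tables List of `sumstats` objects (one per cohort).
#' @param maf_min Variants whose meta effect-allele frequency has minor
#'   allele frequency at or below this value are removed (default 0.01).
#' @return A `sumstats` data frame of meta records with additional columns
#'   `z`, `k_cohorts` and `het_q`.
#' @export
ivw_meta <- function(tables, maf_min = 0.01) {
  stopifnot(length(tables) >= 1)
  core_cols <- c("chrom", "pos", "id", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n", "stratum")
  dt <- data.table::rbindlist(lapply(seq_along(tables), function(i) {
    x <- as.data.frame(tables[[i]])[, core_cols]
    x$cohort_idx <- i
    x
  }))
  dt[, vkey := paste(chrom, pos, sep = ":")]
  data.table::setorder(dt, cohort_idx)

  # reference orientation: first record observed per variant
  ref <- dt[!duplicated(vkey),
            .(vkey, ref_ea = effect_allele, ref_oa = other_allele,
              ref_eaf = eaf, ref_id = id)]
  dt <- merge(dt, ref, by = "vkey", sort = FALSE)
  al <- align_alleles(dt$ref_ea, dt$ref_oa, dt$effect_allele, dt$other_allele,
                      dt$beta, dt$eaf, ref_eaf = dt$ref_eaf)
  dt[, `:=`(beta = al$beta, eaf = al$eaf, status = al$status)]
  dt <- dt[status != "drop"]

  meta <- dt[, {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    .(chrom = chrom[1], pos = pos[1], id = ref_id[1],
      effect_allele = ref_ea[1], other_allele = ref_oa[1],
      eaf = sum(eaf * n) / sum(n), beta = b, se = s,
      z = b / s, pval = 2 * stats::pnorm(-abs(b / s)),
      n = sum(n), k_cohorts = .N, het_q = sum(w * (beta - b)^2))
  }, by = .(vkey, stratum)]

  meta <- meta[pmin(eaf, 1 - eaf) > maf_min]
  out <- as.data.frame(meta[, !"vkey"])
  extra <- out[, c("z", "k_cohorts", "het_q")]
  core <- sumstats(out[, setdiff(names(out), c("z", "k_cohorts", "het_q"))],
                   cohort = "meta")
  # sumstats() sorts; re-attach extras in the sorted order
  key_in <- paste(out$chrom, out$pos, out$stratum)
  key_out <- paste(core$chrom, core$pos, core$stratum)
  core$z <- extra$z[match(key_out, key_in)]
  core$k_cohorts <- extra$k_cohorts[match(key_out, key_in)]
  core$het_q <- extra$het_q[match(key_out, key_in)]
  core
}

#' Combine male and female X-chromosome strata
#'
#' Inverse-variance combination of the sex-stratified X-chromosome records
#' (males analysed under 0/1 dosage coding) into a single `combined` record
#' per variant. Variants present in only one stratum pass through with
#' `k_strata = 1` and are flagged. Stratum-specific records are retained in
#' the `"strata"` attribute.
#'
#' @param male,female `sumstats` objects (single-stratum X records).
#' @return A `sumstats` data frame of combined records (stratum
#'   `"combined"`), with columns `z`, `k_strata` and attribute `strata`.
#' @export
x_chrom_meta <- function(male, female) {
  m <- as.data.frame(male)
  f <- as.data.frame(female)
  m$stratum <- "male"
  f$stratum <- "female"
  dt <- data.table::as.data.table(rbind(m, f))
  ref <- dt[!duplicated(paste(chrom, pos)),
            .(vkey = paste(chrom, pos, sep = ":"), ref_ea = effect_allele,
              ref_oa = other_allele, ref_eaf = eaf, ref_id = id)]
  dt[, vkey := paste(chrom, pos, sep = ":")]
  dt <- merge(dt, ref, by = "vkey", sort = FALSE)
  al <- align_alleles(dt$ref_ea, dt$ref_oa, dt$effect_allele,
                      dt$other_allele, dt$beta, dt$eaf, ref_eaf = dt$ref_eaf)
  dt[, `:=`(beta = al$beta, eaf = al$eaf, status = al$status)]
  dt <- dt[status != "drop"]
  res <- dt[, {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    .(chrom = chrom[1], pos = pos[1], id = ref_id[1],
      effect_allele = ref_ea[1], other_allele = ref_oa[1],
      eaf = sum(eaf * n) / sum(n), beta = b, se = s, z = b / s,
      pval = 2 * stats::pnorm(-abs(b / s)), n = sum(n), k_strata = .N)
  }, by = vkey]
  out <- as.data.frame(res[, !"vkey"])
  out$stratum <- "combined"
  extra <- out[, c("z", "k_strata")]
  key_in <- paste(out$chrom, out$pos)
  core <- sumstats(out[, setdiff(names(out), c("z", "k_strata"))],
                   cohort = "x_meta")
  key_out <- paste(core$chrom, core$pos)
  core$z <- extra$z[match(key_out, key_in)]
  core$k_strata <- extra$k_strata[match(key_out, key_in)]
  attr(core, "strata") <- list(male = male, female = female)
  core
}

#' Exact subtraction of one cohort from an inverse-variance meta-analysis
#'
#' Removes a contributing cohort from a fixed-effect IVW meta-analysis
#' algebraically: with weights `w = 1/SE^2`,
#' `w_rem = w_meta - w_cohort`,
#' `beta_rem = (w_meta beta_meta - w_cohort beta_cohort) / w_rem` and
#' `SE_rem = w_rem^(-1/2)`. This is the exact inverse of adding the cohort,
#' used to build overlap-free replication datasets when an outcome GWAS
#' contains a cohort that also contributed to a meta-analysis. Sample sizes
#' subtract directly; no genomic-control scaling is applied.
#'
#' @param meta Meta-analysed `sumstats` (see [ivw_meta()]).
#' @param cohort The contributing cohort's `sumstats` to remove.
#' @return A `sumstats` data frame of the remaining meta-analysis, restricted
#'   to variants present in both inputs.
#' @export
meta_subtract <- function(meta, cohort) {
  m <- as.data.frame(meta)
  cdf <- as.data.frame(cohort)
  key_m <- paste(m$chrom, m$pos, m$stratum)
  key_c <- paste(cdf$chrom, cdf$pos, cdf$stratum)
  i <- match(key_m, key_c)
  keep <- !is.na(i)
  m2 <- m[keep, , drop = FALSE]
  c2 <- cdf[i[keep], , drop = FALSE]
  al <- align_alleles(m2$effect_allele, m2$other_allele,
                      c2$effect_allele, c2$other_allele,
                      c2$beta, c2$eaf, ref_eaf = m2$eaf)
  ok <- al$status != "drop"
  m2 <- m2[ok, , drop = FALSE]
  beta_c <- al$beta[ok]
  se_c <- c2$se[ok]
  n_c <- c2$n[ok]
  eaf_c <- al$eaf[ok]

  w_meta <- 1 / m2$se^2
  w_c <- 1 / se_c^2
  w_rem <- w_meta - w_c
  if (any(w_rem <= 0)) {
    stop("cohort not a proper subset of meta: non-positive remaining weight ",
         "at ", sum(w_rem <= 0), " variant(s)")
  }
  beta_rem <- (w_meta * m2$beta - w_c * beta_c) / w_rem
  se_rem <- 1 / sqrt(w_rem)
  n_rem <- m2$n - n_c
  eaf_rem <- ifelse(n_rem > 0, (m2$eaf * m2$n - eaf_c * n_c) / n_rem, m2$eaf)
  out <- data.frame(
    chrom = m2$chrom, pos = m2$pos, id = m2$id,
    effect_allele = m2$effect_allele, other_allele = m2$other_allele,
    eaf = pmin(pmax(eaf_rem, 1e-6), 1 - 1e-6),
    beta = beta_rem, se = se_rem,
    pval = 2 * stats::pnorm(-abs(beta_rem / se_rem)),
    n = pmax(n_rem, 1), stratum = m2$stratum, stringsAsFactors = FALSE
  )
  res <- sumstats(out, cohort = "meta_minus_cohort")
  res$z <- res$beta / res$se
  res
}

#' Variance explained by lead pQTL and fraction of heritability
#'
#' Under Hardy-Weinberg equilibrium, a biallelic additive variant with
#' allele frequency `f` and per-allele effect `beta` on a unit-variance
#' phenotype explains `2 f (1 - f) beta^2` of the phenotypic variance. The
#' sum of this quantity over the lead variants gives the variance captured
#' by the discovered pQTL, and its ratio to an externally estimated
#' heritability gives the proportion of heritability explained. Both the
#' total and the input heritability are always reported alongside the ratio.
#'
#' @param leads Data frame with columns `f` (allele frequency) and `beta`
#'   (per-allele effect estimate); an `id` column is carried through if
#'   present.
#' @param h2_input Externally estimated heritability (proportion), or `NA`
#'   if no ratio is wanted.
#' @return A `variance_explained` list: `per_variant` (with `v = 2f(1-f)b^2`),
#'   `total`, `h2_input` and `fraction` (`total / h2_input`).
#' @examples
#' variance_explained(data.frame(f = 0.1, beta = 0.3), h2_input = 0.16)
#' @export
variance_explained <- function(leads, h2_input = NA_real_) {
  stopifnot(all(leads$f > 0), all(leads$f < 1))
  v <- 2 * leads$f * (1 - leads$f) * leads$beta^2
  per <- data.frame(leads, v = v)
  total <- sum(v)
  fraction <- NA_real_
  if (!is.na(h2_input)) {
    if (h2_input <= 0) stop("h2_input must be positive to report a fraction")
    fraction <- total / h2_input
  }
  structure(list(per_variant = per, total = total,
                 h2_input = h2_input, fraction = fraction),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  cat("Variance explained by", nrow(x$per_variant), "lead variant(s):",
      sprintf("%.4f", x$total), "\n")
  if (!is.na(x$h2_input)) {
    cat("Input heritability:", x$h2_input, "-> fraction explained:",
        sprintf("%.3f", x$fraction), "\n")
  }
  invisible(x)
}

#' Genomic-control lambda
#'
#' Ratio of the median association chi-square, `(beta/se)^2`, to its null
#' expectation `qchisq(0.5, 1) = 0.4549`.
#'
#' @param table A `sumstats` object with at least 100 records.
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(table) {
  if (nrow(table) < 100) stop("need at least 100 variants for lambda")
  chisq <- (table$beta / table$se)^2
  stats::median(chisq) / stats::qchisq(0.5, 1)
}
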