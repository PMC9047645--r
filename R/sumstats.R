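# Core summary-statistics container: GWAS-SSF I/O, per-record validation,
# allele harmonisation and the rank-based inverse-normal transform.

VALID_CHROMS <- c(as.character(1:22), "X")
VALID_STRATA <- c("all", "male", "female", "combined")

# canonical GWAS-SSF column names, internal name -> file column
SSF_COLUMNS <- c(
  chrom         = "chromosome",
  pos           = "base_pair_location",
  effect_allele = "effect_allele",
  other_allele  = "other_allele",
  eaf           = "effect_allele_frequency",
  beta          = "beta",
  se            = "standard_error",
  pval          = "p_value",
  n             = "n",
  stratum       = "stratum",
  id            = "variant_id"
)

#' Build a validated summary-statistics table
#'
#' Takes a data frame of per-variant association records and returns a
#' validated, position-sorted `sumstats` object. Records violating the
#' container invariants (positive SE, allele frequency strictly inside (0,1),
#' p-value in (0,1], positive sample size, single-nucleotide A/C/G/T alleles,
#' recognised chromosome and stratum labels) are dropped and tallied in a QC
#' report attached as the `"qc"` attribute. X-chromosome records must arrive
#' sex-stratified: stratum `"all"` on X is rejected, since pooling sexes over
#' hemizygous male genotypes is not meaningful under 0/1 male dosage coding.
#'
#' @param df Data frame with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` and optionally
#'   `stratum` (default `"all"`) and `id`.
#' @param cohort Optional cohort label stored in the table metadata.
#' @param phenotype Optional phenotype label stored in the table metadata.
#' @return A `sumstats` data frame sorted by chromosome and position with
#'   attributes `meta` (provenance list) and `qc` (named rejection counts).
#' @examples
#' ss <- sumstats(data.frame(
#'   chrom = "1", pos = 1000L, effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.1, se = 0.05, pval = 0.045, n = 5000
#' ))
#' attr(ss, "qc")
#' @export
sumstats <- function(df, cohort = NULL, phenotype = NULL) {
  req <- c("chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing required sumstats column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$stratum)) df$stratum <- "all"
  if (is.null(df$id)) df$id <- NA_character_
  df$chrom <- toupper(sub("^chr", "", as.character(df$chrom)))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$stratum <- as.character(df$stratum)

  num_cols <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    }
  }

  qc <- c(
    unparsable_numeric = 0L, bad_chrom = 0L, bad_pos = 0L, bad_allele = 0L,
    nonpositive_se = 0L, eaf_out_of_range = 0L, bad_pval = 0L,
    nonpositive_n = 0L, bad_stratum = 0L, x_not_stratified = 0L,
    duplicate_key = 0L
  )
  bad_num <- rowSums(is.na(df[, num_cols, drop = FALSE])) > 0
  qc["unparsable_numeric"] <- sum(bad_num)
  keep <- !bad_num
  flag <- function(cond, reason) {
    cond <- keep & !is.na(cond) & cond
    qc[reason] <<- qc[reason] + sum(cond)
    keep <<- keep & !cond
  }
  flag(!(df$chrom %in% VALID_CHROMS), "bad_chrom")
  flag(df$pos < 1 | df$pos != floor(df$pos), "bad_pos")
  ok_nt <- function(a) a %in% c("A", "C", "G", "T")
  flag(!ok_nt(df$effect_allele) | !ok_nt(df$other_allele) |
         df$effect_allele == df$other_allele, "bad_allele")
  flag(df$se <= 0, "nonpositive_se")
  flag(df$eaf <= 0 | df$eaf >= 1, "eaf_out_of_range")
  flag(df$pval <= 0 | df$pval > 1, "bad_pval")
  flag(df$n <= 0, "nonpositive_n")
  flag(!(df$stratum %in% VALID_STRATA), "bad_stratum")
  flag(df$chrom == "X" & df$stratum == "all", "x_not_stratified")

  df <- df[keep, , drop = FALSE]
  dup <- duplicated(paste(df$chrom, df$pos, df$stratum))
  qc["duplicate_key"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]

  ord <- order(match(df$chrom, VALID_CHROMS), df$pos, df$stratum)
  df <- df[ord, c("chrom", "pos", "id", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n", "stratum")]
  rownames(df) <- NULL
  structure(df,
            meta = list(cohort = cohort, phenotype = phenotype),
            qc = qc,
            class = c("sumstats", "data.frame"))
}

#' Read a GWAS-SSF style summary-statistics file
#'
#' Reads a tab-delimited summary-statistics table with a header row. By
#' default the GWAS-SSF column names are expected (`chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`,
#' `stratum`); foreign dialects are handled by passing a column map. Rows
#' failing record-level validation are dropped and counted (see
#' [sumstats()]); a missing required column is a fatal configuration error.
#'
#' @param path Path to a tab-delimited file with header.
#' @param dialect Optional named character vector mapping internal names
#'   (`chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, and optionally `stratum`, `id`) to the file's column names.
#'   May also be the path of a YAML file holding that mapping.
#' @param cohort,phenotype Optional provenance labels.
#' @return A `sumstats` object; QC rejection counts in `attr(x, "qc")`.
#' @seealso [write_sumstats()], [qc_report()]
#' @export
read_sumstats <- function(path, dialect = NULL, cohort = NULL,
                          phenotype = NULL) {
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
    dialect <- unlist(yaml::read_yaml(dialect))
  }
  map <- SSF_COLUMNS
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  out <- list()
  for (internal in names(map)) {
    src <- map[[internal]]
    if (src %in% names(raw)) {
      out[[internal]] <- raw[[src]]
    } else if (internal %in% names(raw)) {
      out[[internal]] <- raw[[internal]]  # already internal naming
    } else if (!internal %in% c("stratum", "id")) {
      stop("required column '", src, "' (", internal, ") not found in ", path)
    }
  }
  sumstats(as.data.frame(out, stringsAsFactors = FALSE),
           cohort = cohort, phenotype = phenotype)
}

#' Write a summary-statistics table as GWAS-SSF TSV
#'
#' @param x A `sumstats` object (or conforming data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)[, names(SSF_COLUMNS)]
  names(out) <- unname(SSF_COLUMNS)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Retrieve or export the QC report of a summary-statistics table
#'
#' @param x A `sumstats` object.
#' @param json_path Optional path; when given, the report is also written as
#'   JSON.
#' @return Named integer vector of rejection counts by reason.
#' @export
qc_report <- function(x, json_path = NULL) {
  qc <- attr(x, "qc")
  if (is.null(qc)) qc <- integer(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(qc), json_path, auto_unbox = TRUE)
  }
  qc
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Align allele orientation of association records to a reference
#'
#' Vectorised allele alignment used when joining tables (meta-analysis,
#' exposure-outcome harmonisation in MR). Each record is re-expressed on the
#' reference effect allele: identical orientation is kept; swapped alleles
#' flip the sign of beta and replace the frequency by its complement; when
#' the allele pair only matches after strand complementation the complement
#' is applied first. Palindromic variants (A/T or C/G) are resolved by
#' comparing allele frequencies, and only when both frequencies are
#' informative (minor allele frequency below `eaf_limit` on both sides);
#' otherwise they are flagged non-harmonizable, as are irreconcilable allele
#' sets.
#'
#' @param ref_ea,ref_oa Reference effect/other alleles (character vectors).
#' @param ea,oa Alleles of the records to align.
#' @param beta,eaf Effect sizes and effect-allele frequencies to align.
#' @param ref_eaf Reference effect-allele frequencies (used only for
#'   palindromic resolution; may be `NA` to force exclusion of palindromes).
#' @param eaf_limit Palindromic variants with minor allele frequency above
#'   this value on either side are dropped (default 0.42).
#' @return A list with `beta`, `eaf` (aligned values) and `status`, one of
#'   `"ok"`, `"flipped"` (sign flip applied) or `"drop"`.
#' @export
align_alleles <- function(ref_ea, ref_oa, ea, oa, beta, eaf,
                          ref_eaf = NA_real_, eaf_limit = 0.42) {
  m <- length(ea)
  ref_eaf <- rep_len(ref_eaf, m)
  comp_ea <- unname(COMPLEMENT[ea])
  comp_oa <- unname(COMPLEMENT[oa])
  same  <- ea == ref_ea & oa == ref_oa
  swap  <- ea == ref_oa & oa == ref_ea
  csame <- comp_ea == ref_ea & comp_oa == ref_oa
  cswap <- comp_ea == ref_oa & comp_oa == ref_ea
  pal   <- is_palindromic(ea, oa)

  status <- rep("drop", m)
  flip <- rep(FALSE, m)
  ok_plain <- !pal & (same | swap | csame | cswap)
  status[ok_plain] <- "ok"
  flip[ok_plain] <- (swap | cswap)[ok_plain]

  # palindromic: orientation is ambiguous between 'same' and 'swapped
  # complement'; decide by frequency only when both sides are informative
  pal_cand <- pal & (same | swap)
  maf <- pmin(eaf, 1 - eaf)
  ref_maf <- pmin(ref_eaf, 1 - ref_eaf)
  informative <- pal_cand & !is.na(ref_maf) &
    maf <= eaf_limit & ref_maf <= eaf_limit
  # treat record as already oriented if its EAF is closer to the reference
  # EAF than its complement is
  pal_keep <- informative & (abs(eaf - ref_eaf) <= abs((1 - eaf) - ref_eaf))
  pal_flip <- informative & !pal_keep
  status[informative] <- "ok"
  flip[pal_flip] <- TRUE

  beta_out <- ifelse(flip, -beta, beta)
  eaf_out <- ifelse(flip, 1 - eaf, eaf)
  status[status == "ok" & flip] <- "flipped"
  list(beta = beta_out, eaf = eaf_out, status = status)
}

#' Harmonize one association record onto another's allele orientation
#'
#' Re-expresses record `b` on record `a`'s effect allele (see
#' [align_alleles()] for the rules). The two records must refer to the same
#' chromosome and position.
#'
#' @param a,b Single-row data frames (or lists) with at least
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `eaf`.
#' @return A list with elements `a` (unchanged), `b` (aligned copy) and
#'   `status` (`"ok"`, `"flipped"` or `"drop"`).
#' @examples
#' a <- list(chrom = "1", pos = 100, effect_allele = "A", other_allele = "G",
#'           beta = 0.2, eaf = 0.3)
#' b <- list(chrom = "1", pos = 100, effect_allele = "G", other_allele = "A",
#'           beta = 0.1, eaf = 0.7)
#' harmonize_alleles(a, b)$b$beta  # -0.1
#' @export
harmonize_alleles <- function(a, b) {
  if (a$chrom != b$chrom || a$pos != b$pos) {
    stop("records refer to different positions: ",
         a$chrom, ":", a$pos, " vs ", b$chrom, ":", b$pos)
  }
  al <- align_alleles(a$effect_allele, a$other_allele,
                      b$effect_allele, b$other_allele,
                      b$beta, b$eaf, ref_eaf = a$eaf)
  b_out <- b
  b_out$beta <- al$beta
  b_out$eaf <- al$eaf
  if (al$status != "drop") {
    b_out$effect_allele <- a$effect_allele
    b_out$other_allele <- a$other_allele
  }
  list(a = a, b = b_out, status = al$status)
}

#' Rank-based inverse-normal transform
#'
#' Transforms a numeric vector to normal scores via
#' `qnorm((r - c) / (n - 2c + 1))` with the Blom offset `c = 3/8`, where `r`
#' are the ranks (ties receive their average rank). The result has
#' approximately zero mean and unit variance for large `n`, and is invariant
#' to any strictly monotone transformation of the input.
#'
#' @param values Numeric vector, length at least 2, not constant.
#' @param offset Rank offset constant (default Blom's 3/8).
#' @return Numeric vector of normal scores.
#' @examples
#' round(rank_inverse_normal(c(1.2, 3.4, 2.2)), 3)  # -0.869 0.869 0.000
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (length(values) < 2) stop("need at least 2 values")
  if (anyNA(values)) stop("missing values not supported")
  if (diff(range(values)) == 0) {
    stop("inverse-normal transform undefined for constant input")
  }
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' @export
print.sumstats <- function(x, ...) {
  meta <- attr(x, "meta")
  qc <- attr(x, "qc")
  cat("GWAS summary statistics: ", nrow(x), " records",
      if (!is.null(meta$cohort)) paste0(" [", meta$cohort, "]"), "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$chrom), collapse = " "),
      "; strata: ", paste(unique(x$stratum), collapse = " "), "\n", sep = "")
  if (!is.null(qc) && sum(qc) > 0) {
    cat("  QC rejects: ", sum(qc), "\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}
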