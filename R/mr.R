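# Two-sample Mendelian randomization: instrument selection (cis or
# genome-wide), Wald ratios, fixed-effect IVW estimation with odds-ratio
# reporting, and the bidirectional driver.

#' Select and harmonize MR instruments
#'
#' Restricts the exposure records to genome-wide significant variants
#' (optionally within a cis gene window), clumps them against the LD
#' reference at the mode-specific `r^2` threshold (0.001 cis, 0.05
#' genome-wide by default), joins the outcome records by position, and
#' harmonizes the outcome onto the exposure's allele orientation.
#' Instruments missing from the outcome or failing harmonization
#' (irreconcilable or ambiguous palindromic alleles) are dropped and
#' counted.
#'
#' @param exposure Exposure summary statistics (meta-analysed `sumstats`);
#'   only strata `all`/`combined` are used.
#' @param outcome Outcome summary statistics.
#' @param ref An `ld_ref` panel.
#' @param mode `"cis"` or `"genomewide"`.
#' @param cis_window For cis mode, a list with `chrom`, `start`, `end`
#'   delimiting the gene region (typically gene body plus a flank).
#' @param p_threshold Exposure significance threshold (default 5e-8).
#' @param r2_threshold Clumping threshold; defaults to 0.001 (cis) or 0.05
#'   (genome-wide).
#' @param window_kb Clumping window; defaults to 10000 (cis) or 1000 kb.
#' @return An `instrument_set` data frame (exposure and outcome effects per
#'   instrument) with a `dropped` attribute of diagnostic counts.
#' @export
select_instruments <- function(exposure, outcome, ref,
                               mode = c("cis", "genomewide"),
                               cis_window = NULL,
                               p_threshold = 5e-8,
                               r2_threshold = NULL,
                               window_kb = NULL) {
  mode <- match.arg(mode)
  if (is.null(r2_threshold)) {
    r2_threshold <- if (mode == "cis") 0.001 else 0.05
  }
  if (is.null(window_kb)) window_kb <- if (mode == "cis") 10000 else 1000
  exp_df <- as.data.frame(exposure)
  exp_df <- exp_df[exp_df$stratum %in% c("all", "combined"), , drop = FALSE]
  if (mode == "cis") {
    if (is.null(cis_window)) stop("cis mode requires a cis_window")
    exp_df <- exp_df[exp_df$chrom == cis_window$chrom &
                       exp_df$pos >= cis_window$start &
                       exp_df$pos <= cis_window$end, , drop = FALSE]
  }
  n_sig <- sum(exp_df$pval < p_threshold)
  if (!n_sig) {
    stop("no genome-wide significant exposure variant",
         if (mode == "cis") " in the cis window")
  }
  cl <- clump(exp_df, ref, p_threshold = p_threshold,
              r2_threshold = r2_threshold, window_kb = window_kb)
  idx <- cl$index

  out_df <- as.data.frame(outcome)
  out_df <- out_df[out_df$stratum %in% c("all", "combined"), , drop = FALSE]
  j <- match(paste(idx$chrom, idx$pos), paste(out_df$chrom, out_df$pos))
  dropped <- c(missing_in_outcome = sum(is.na(j)), non_harmonizable = 0L)
  keep <- !is.na(j)
  idx <- idx[keep, , drop = FALSE]
  outm <- out_df[j[keep], , drop = FALSE]
  if (nrow(idx)) {
    al <- align_alleles(idx$effect_allele, idx$other_allele,
                        outm$effect_allele, outm$other_allele,
                        outm$beta, outm$eaf, ref_eaf = idx$eaf)
    ok <- al$status != "drop"
    dropped["non_harmonizable"] <- sum(!ok)
    instruments <- data.frame(
      chrom = idx$chrom[ok], pos = idx$pos[ok], id = idx$id[ok],
      effect_allele = idx$effect_allele[ok],
      other_allele = idx$other_allele[ok],
      eaf_exposure = idx$eaf[ok],
      beta_exposure = idx$beta[ok], se_exposure = idx$se[ok],
      pval_exposure = idx$pval[ok],
      beta_outcome = al$beta[ok], se_outcome = outm$se[ok],
      eaf_outcome = al$eaf[ok], stringsAsFactors = FALSE
    )
  } else {
    instruments <- data.frame()
  }
  if (!nrow(instruments)) {
    stop("zero instruments survive selection (significant: ", n_sig,
         ", clumped: ", nrow(cl$index),
         ", missing in outcome: ", dropped["missing_in_outcome"],
         ", non-harmonizable: ", dropped["non_harmonizable"], ")")
  }
  structure(instruments, dropped = dropped, mode = mode,
            class = c("instrument_set", "data.frame"))
}

#' Wald ratio for a single instrument
#'
#' Single-instrument causal estimate `beta_y / beta_x` with first-order
#' standard error `|SE_y / beta_x|` (exposure uncertainty ignored, the
#' convention of two-sample MR with strong instruments).
#'
#' @param beta_x,beta_y Exposure and outcome effects of the instrument.
#' @param se_y Outcome standard error.
#' @return List with `beta` and `se`.
#' @examples
#' wald_ratio(0.5, 0.25, 0.1)  # beta 0.5, se 0.2
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (any(beta_x == 0)) stop("Wald ratio undefined for zero exposure effect")
  list(beta = beta_y / beta_x, se = abs(se_y / beta_x))
}

#' Fixed-effect inverse-variance-weighted MR estimate
#'
#' Combines instruments as
#' `beta_MR = sum(bx by / sy^2) / sum(bx^2 / sy^2)` with
#' `SE = (sum(bx^2/sy^2))^(-1/2)` — algebraically the inverse-variance-
#' weighted mean of the per-instrument Wald ratios with first-order weights.
#' When the outcome is binary (log-odds records), the estimate exponentiates
#' to an odds ratio with a 95% Wald confidence interval. Cochran's Q across
#' Wald ratios is reported; with `random_effects = TRUE` the standard error
#' is additionally inflated by `max(1, sqrt(Q/(k-1)))` (multiplicative
#' random-effects scaling).
#'
#' @param instruments An `instrument_set` (or data frame with columns
#'   `beta_exposure`, `beta_outcome`, `se_outcome`).
#' @param random_effects Apply multiplicative random-effects SE scaling
#'   (default `FALSE`, plain fixed-effect).
#' @return An `mr_result` list: `beta`, `se`, `pval`, `or`, `ci_lower`,
#'   `ci_upper`, `n_instruments`, `q`, `wald_ratios`.
#' @export
ivw_mr <- function(instruments, random_effects = FALSE) {
  df <- as.data.frame(instruments)
  stopifnot(nrow(df) >= 1)
  bx <- df$beta_exposure
  by <- df$beta_outcome
  sy <- df$se_outcome
  w <- bx^2 / sy^2
  beta <- sum(bx * by / sy^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  ratios <- by / bx
  k <- nrow(df)
  q <- sum(w * (ratios - beta)^2)
  if (random_effects && k > 1) se <- se * max(1, sqrt(q / (k - 1)))
  z <- beta / se
  structure(list(
    beta = beta, se = se, pval = 2 * stats::pnorm(-abs(z)),
    or = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    n_instruments = k, q = q,
    wald_ratios = data.frame(id = df$id, beta = ratios, se = abs(sy / bx)),
    random_effects = random_effects
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "IVW MR: beta = %.4f (SE %.4f), OR = %.3f [95%% CI %.3f-%.3f], P = %.3g\n",
    x$beta, x$se, x$or, x$ci_lower, x$ci_upper, x$pval))
  cat("  instruments:", x$n_instruments,
      " Cochran's Q:", sprintf("%.2f", x$q), "\n")
  invisible(x)
}

#' Bidirectional two-sample MR driver
#'
#' Runs instrument selection and IVW estimation in both directions
#' (A on B, then B on A) with direction-appropriate exposures. A direction
#' without eligible instruments is reported as not estimable rather than an
#' error.
#'
#' @param traitA,traitB Summary statistics of the two traits.
#' @param ref An `ld_ref` panel.
#' @param mode,p_threshold,r2_threshold,window_kb Passed to
#'   [select_instruments()].
#' @return List with elements `forward` (A on B) and `reverse` (B on A);
#'   each is either an `mr_result` or a list with `status = "not_estimable"`
#'   and the reason.
#' @export
bidirectional_mr <- function(traitA, traitB, ref, mode = "genomewide",
                             p_threshold = 5e-8, r2_threshold = NULL,
                             window_kb = NULL) {
  one_way <- function(exposure, outcome) {
    tryCatch({
      inst <- select_instruments(exposure, outcome, ref, mode = mode,
                                 p_threshold = p_threshold,
                                 r2_threshold = r2_threshold,
                                 window_kb = window_kb)
      ivw_mr(inst)
    }, error = function(e) {
      list(status = "not_estimable", reason = conditionMessage(e))
    })
  }
  list(forward = one_way(traitA, traitB),
       reverse = one_way(traitB, traitA))
}
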