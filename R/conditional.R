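# Approximate conditional and joint multi-SNP analysis from marginal
# summary statistics and an LD reference panel, for secondary-signal
# discovery within a locus.

# Solve the joint model on the standardized scale: b_J = R^-1 b_m with
# Var(b_J) = sigma2_J * diag(R^-1) / n, sigma2_J = 1 - b_J' b_m (floored).
cojo_solve <- function(b_std, R, n, ridge = 1e-6, sigma2_floor = 1e-6,
                       kappa_max = 1e6) {
  k <- length(b_std)
  Rr <- R + diag(ridge, k)
  if (kappa(Rr, exact = FALSE) > kappa_max) {
    stop("LD matrix near-singular; pre-prune the variant set at r2 < 0.9")
  }
  Rinv <- solve(Rr)
  b_joint <- as.vector(Rinv %*% b_std)
  sigma2 <- max(1 - sum(b_joint * b_std), sigma2_floor)
  se_joint <- sqrt(sigma2 * diag(Rinv) / n)
  list(b_joint = b_joint, se_joint = se_joint, sigma2 = sigma2)
}

#' Joint multi-SNP model from marginal summary statistics
#'
#' Re-estimates the joint (mutually adjusted) effects of a set of variants
#' from their marginal effects and the LD correlation matrix of a reference
#' panel. Marginal per-allele effects are moved to the standardized scale
#' (`b_std = beta * sqrt(2 f (1 - f))`, valid for a unit-variance
#' phenotype), solved as `b_J = R^-1 b_std`, and mapped back to the
#' per-allele scale. Joint standard errors use the residual variance
#' `sigma2_J = 1 - b_J' b_std` (floored at a small positive constant to
#' guard against panel/sample LD mismatch) via
#' `Var(b_J) = sigma2_J diag(R^-1)/n`. With a single variant the joint model
#' equals the marginal record. A small ridge (1e-6) stabilises the solve; a
#' near-singular LD matrix is an error instructing pre-pruning.
#'
#' @param marginals Data frame of marginal records for the variant set
#'   (columns `chrom`, `pos`, `id`, `eaf`, `beta`, `se`, `pval`).
#' @param ref An `ld_ref` panel containing the variants.
#' @param n Effective sample size of the marginal analysis.
#' @return A `joint_model` list: `table` (per-variant marginal and joint
#'   estimates with Wald p-values), `sigma2`, `n`.
#' @export
joint_fit <- function(marginals, ref, n) {
  df <- as.data.frame(marginals)
  stopifnot(nrow(df) >= 1)
  scale <- sqrt(2 * df$eaf * (1 - df$eaf))
  b_std <- df$beta * scale
  R <- ld_matrix(ref, list(chrom = df$chrom, pos = df$pos))
  sol <- cojo_solve(b_std, R, n)
  beta_joint <- sol$b_joint / scale
  se_joint <- sol$se_joint / scale
  z <- beta_joint / se_joint
  table <- data.frame(
    chrom = df$chrom, pos = df$pos, id = df$id, eaf = df$eaf,
    beta_marginal = df$beta, se_marginal = df$se, pval_marginal = df$pval,
    beta_joint = beta_joint, se_joint = se_joint,
    pval_joint = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
  )
  structure(list(table = table, sigma2 = sol$sigma2, n = n),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("Joint multi-SNP model (", nrow(x$table), " variants, n = ", x$n,
      ", residual variance ", sprintf("%.4f", x$sigma2), ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Stepwise conditional scan of a locus for secondary signals
#'
#' Forward selection seeded at the locus lead (smallest marginal p):
#' at each step every remaining variant is evaluated by fitting the joint
#' model on the current selection plus that candidate; the candidate with
#' the smallest conditional p-value is admitted if it passes `p_enter`,
#' otherwise the scan stops. Candidates in strong LD (`r^2 > collinear_r2`)
#' with the current selection are skipped. A variant's conditional p may
#' fall below its marginal p when signals mask each other through negative
#' LD; the scan records each admitted variant's conditional trajectory so
#' this can be inspected.
#'
#' @param locus Data frame of marginal records for the locus.
#' @param ref An `ld_ref` panel.
#' @param n Effective sample size.
#' @param p_enter Conditional p-value required to admit a signal (default
#'   5e-8).
#' @param collinear_r2 Candidates above this `r^2` with any selected variant
#'   are skipped (default 0.9).
#' @return A `conditional_scan` list: `model` (final [joint_fit()] result),
#'   `selected` (per-signal marginal and admission-time conditional
#'   statistics), `skipped_collinear` (variant keys).
#' @export
conditional_scan <- function(locus, ref, n, p_enter = 5e-8,
                             collinear_r2 = 0.9) {
  df <- as.data.frame(locus)
  df <- df[order(df$pval, df$pos, df$effect_allele), , drop = FALSE]
  stopifnot(nrow(df) >= 1)
  sel <- 1L
  traj <- list(data.frame(step = 1L, key = key_of(df[1, , drop = FALSE]),
                          pval_marginal = df$pval[1],
                          pval_conditional = df$pval[1]))
  skipped <- character(0)
  if (p_enter > 0) {
    repeat {
      remaining <- setdiff(seq_len(nrow(df)), sel)
      if (!length(remaining)) break
      Rfull <- ld_matrix(ref, list(chrom = df$chrom, pos = df$pos))
      usable <- remaining[apply(
        Rfull[remaining, sel, drop = FALSE]^2, 1,
        function(r2) all(r2 <= collinear_r2))]
      skipped <- union(skipped,
                       key_of(df[setdiff(remaining, usable), , drop = FALSE]))
      if (!length(usable)) break
      cond_p <- vapply(usable, function(cand) {
        fit <- joint_fit(df[c(sel, cand), , drop = FALSE], ref, n)
        fit$table$pval_joint[length(sel) + 1L]
      }, numeric(1))
      best <- which.min(cond_p)
      if (cond_p[best] >= p_enter) break
      cand <- usable[best]
      traj[[length(traj) + 1]] <- data.frame(
        step = length(sel) + 1L, key = key_of(df[cand, , drop = FALSE]),
        pval_marginal = df$pval[cand], pval_conditional = cond_p[best]
      )
      sel <- c(sel, cand)
    }
  }
  model <- joint_fit(df[sel, , drop = FALSE], ref, n)
  structure(list(model = model, selected = do.call(rbind, traj),
                 skipped_collinear = skipped),
            class = "conditional_scan")
}

#' @export
print.conditional_scan <- function(x, ...) {
  cat("Conditional scan: ", nrow(x$selected), " signal(s) selected\n",
      sep = "")
  print(x$selected)
  invisible(x)
}
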