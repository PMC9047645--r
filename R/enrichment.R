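# LD-score-corrected annotation enrichment: per-SNP logistic regression of
# genome-wide significance on LD score and annotation membership, plus the
# multi-track scan with Benjamini-Hochberg FDR control.

#' Attach annotation membership and LD scores to variants
#'
#' Builds the design data for the enrichment regression. BED intervals are
#' 0-based half-open; summary statistics are 1-based, so a variant at
#' position `pos` is annotated iff `pos - 1` falls inside an interval.
#' Import goes through `rtracklayer`/`GenomicRanges`, which performs that
#' coordinate conversion. Variants without an LD score are dropped and
#' counted. An optional mask removes the extended MHC region
#' (chr6:25-34 Mb), whose LD structure distorts enrichment fits on real
#' data; it is off by default, which suits simulated data.
#'
#' @param table Variant records (`sumstats` or data frame with `chrom`,
#'   `pos`, `id`, `pval`).
#' @param bed BED file path, data frame (`chrom`, `start`, `end`) in BED
#'   coordinates, or a `GRanges` object (1-based).
#' @param scores LD scores as returned by [ld_scores()].
#' @param exclude_mhc Drop variants in chr6:25-34 Mb (default `FALSE`).
#' @return Data frame `chrom`, `pos`, `id`, `pval`, `ldscore`, `annotated`
#'   (0/1), with a `dropped_no_score` attribute.
#' @export
annotate_snps <- function(table, bed, scores, exclude_mhc = FALSE) {
  df <- as.data.frame(table)
  if (is.character(bed)) {
    gr <- rtracklayer::import(bed, format = "BED")
  } else if (methods::is(bed, "GRanges")) {
    gr <- bed
  } else {
    bed <- as.data.frame(bed)
    if (nrow(bed)) {
      gr <- GenomicRanges::GRanges(
        seqnames = as.character(bed$chrom),
        ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
      )
    } else {
      gr <- GenomicRanges::GRanges()
    }
  }
  snps <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$pos, width = 1L)
  )
  # differing chromosome sets between SNPs and track are expected (a track
  # need not touch every chromosome); the seqlevels warning is noise here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snps, gr))
  annotated <- integer(nrow(df))
  annotated[unique(S4Vectors::queryHits(hits))] <- 1L

  i <- match(paste(df$chrom, df$pos), paste(scores$chrom, scores$pos))
  out <- data.frame(
    chrom = df$chrom, pos = df$pos, id = df$id, pval = df$pval,
    ldscore = scores$ldscore[i], annotated = annotated,
    stringsAsFactors = FALSE
  )
  dropped <- sum(is.na(out$ldscore))
  out <- out[!is.na(out$ldscore), , drop = FALSE]
  if (exclude_mhc) {
    out <- out[!(out$chrom == "6" & out$pos >= 25e6 & out$pos <= 34e6), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "dropped_no_score") <- dropped
  out
}

# Firth-penalized logistic regression (Jeffreys prior), used as fallback
# under complete separation.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  k <- ncol(X)
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * (X * w))
    u <- as.vector(t(X) %*% (y - p + h * (0.5 - p)))
    delta <- as.vector(info_inv %*% u)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  se <- sqrt(diag(solve(t(X * w) %*% X)))
  list(coef = beta, se = se, converged = it < max_iter)
}

#' Fit the LD-corrected enrichment logistic regression
#'
#' Models the log-odds that a variant is genome-wide significant as
#' `mu + delta * l_j + beta * C_j`, where `l_j` is the variant's LD score
#' and `C_j` the 0/1 annotation indicator; `beta` is the log odds ratio of
#' significant associations inside the annotation relative to outside,
#' corrected for LD. Fitted by maximum likelihood (iteratively reweighted
#' least squares via `glm`, convergence 1e-8, 100 iterations max). If the
#' fit separates completely, a Firth-penalized fit is substituted with a
#' warning. Requires both outcome classes to be present.
#'
#' @param matrix Design data as returned by [annotate_snps()].
#' @param pvals Optional per-SNP p-values overriding `matrix$pval`.
#' @param alpha_gw Significance threshold defining the outcome (default
#'   5e-8).
#' @param ld_correction Include the LD-score covariate (default `TRUE`).
#' @return An `enrichment_model` list: `mu`, `delta`, `beta`, `se_beta`,
#'   `z`, `pval`, `n_snps`, `n_significant`, `method`, `converged`.
#' @export
fit_enrichment <- function(matrix, pvals = NULL, alpha_gw = 5e-8,
                           ld_correction = TRUE) {
  df <- as.data.frame(matrix)
  if (!is.null(pvals)) df$pval <- pvals
  y <- as.integer(df$pval < alpha_gw)
  if (all(y == 0) || all(y == 1)) {
    stop("outcome degenerate: need both significant and non-significant SNPs")
  }
  use_ld <- ld_correction && stats::sd(df$ldscore) > 0
  form <- if (use_ld) y ~ ldscore + annotated else y ~ annotated
  dat <- data.frame(y = y, ldscore = df$ldscore, annotated = df$annotated)
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  co <- summary(fit)$coefficients
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  method <- "irls"
  if (separated) {
    warning("possible separation in enrichment fit; ",
            "using Firth-penalized likelihood")
    X <- stats::model.matrix(form, dat)
    ff <- firth_logistic(X, y)
    co <- cbind(Estimate = ff$coef, `Std. Error` = ff$se)
    rownames(co) <- colnames(X)
    method <- "firth"
  }
  get <- function(name, col) if (name %in% rownames(co)) co[name, col] else NA_real_
  beta <- get("annotated", 1)
  se_beta <- get("annotated", 2)
  z <- beta / se_beta
  structure(list(
    mu = get("(Intercept)", 1),
    delta = get("ldscore", 1),
    beta = beta, se_beta = se_beta, z = z,
    pval = 2 * stats::pnorm(-abs(z)),
    n_snps = length(y), n_significant = sum(y),
    method = method,
    converged = if (method == "irls") fit$converged else TRUE
  ), class = "enrichment_model")
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat(sprintf(
    "Enrichment fit (%d SNPs, %d significant): beta = %.4f (SE %.4f), z = %.2f, P = %.3g\n",
    x$n_snps, x$n_significant, x$beta, x$se_beta, x$z, x$pval))
  invisible(x)
}

#' Enrichment scan across annotation tracks
#'
#' Fits the enrichment regression for each track and applies
#' Benjamini-Hochberg false-discovery-rate adjustment across the fitted
#' tracks. Tracks whose fit fails (e.g. degenerate membership) are reported
#' with a status instead of estimates.
#'
#' @param matrices Named list of [annotate_snps()] outputs, one per track.
#' @param pvals Optional shared per-SNP p-values (otherwise each matrix's
#'   own `pval` column is used).
#' @param alpha_gw,ld_correction Passed to [fit_enrichment()].
#' @return Data frame with one row per track: `track`, `mu`, `delta`,
#'   `beta`, `se_beta`, `z`, `pval`, `qval`, `n_snps`, `n_significant`,
#'   `status`.
#' @export
enrichment_scan <- function(matrices, pvals = NULL, alpha_gw = 5e-8,
                            ld_correction = TRUE) {
  if (is.null(names(matrices))) {
    names(matrices) <- paste0("track", seq_along(matrices))
  }
  rows <- lapply(names(matrices), function(tr) {
    res <- tryCatch(
      fit_enrichment(matrices[[tr]], pvals = pvals, alpha_gw = alpha_gw,
                     ld_correction = ld_correction),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(track = tr, mu = NA_real_, delta = NA_real_,
                 beta = NA_real_, se_beta = NA_real_, z = NA_real_,
                 pval = NA_real_, n_snps = NA_integer_,
                 n_significant = NA_integer_,
                 status = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(track = tr, mu = res$mu, delta = res$delta,
                 beta = res$beta, se_beta = res$se_beta, z = res$z,
                 pval = res$pval, n_snps = res$n_snps,
                 n_significant = res$n_significant,
                 status = res$method, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$qval <- NA_real_
  fitted <- !is.na(out$pval)
  out$qval[fitted] <- stats::p.adjust(out$pval[fitted], method = "BH")
  out
}
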