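# Internal vectorised single-variant association engines used by the
# synthetic-data generator: marginal OLS for quantitative phenotypes and
# chunked Newton-Raphson logistic regression for binary outcomes.

# Marginal one-SNP-at-a-time OLS of y on each column of G.
# Returns beta, se, pval (normal approximation), eaf, n.
marginal_ols_gwas <- function(G, y, ploidy = 2) {
  n <- length(y)
  stopifnot(nrow(G) == n)
  gbar <- colMeans(G)
  Sxx <- colSums(G^2) - n * gbar^2
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sxy <- as.vector(crossprod(G, yc))
  beta <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- Syy - beta^2 * Sxx
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(ifelse(Sxx > 0, sigma2 / Sxx, NA_real_))
  z <- beta / se
  data.frame(
    beta = beta, se = se,
    pval = 2 * stats::pnorm(-abs(z)),
    eaf = gbar / ploidy, n = n
  )
}

# Per-SNP logistic regression of binary d on intercept + dosage, fitted by
# Newton-Raphson simultaneously for a chunk of SNPs (closed-form 2x2
# information inversion per SNP).
logistic_gwas <- function(G, d, ploidy = 2, max_iter = 25, tol = 1e-8,
                          chunk = 256) {
  n <- length(d)
  stopifnot(nrow(G) == n)
  m <- ncol(G)
  out <- data.frame(beta = rep(NA_real_, m), se = NA_real_, pval = NA_real_,
                    eaf = colMeans(G) / ploidy, n = n)
  a0 <- stats::qlogis(mean(d))
  for (start in seq(1, m, by = chunk)) {
    idx <- start:min(start + chunk - 1, m)
    Gc <- G[, idx, drop = FALSE]
    k <- length(idx)
    a <- rep(a0, k)
    b <- rep(0, k)
    for (it in seq_len(max_iter)) {
      eta <- sweep(Gc * rep(b, each = n), 2, a, "+")
      p <- stats::plogis(eta)
      w <- p * (1 - p)
      r <- d - p
      g1 <- colSums(r)
      g2 <- colSums(r * Gc)
      i11 <- colSums(w)
      i12 <- colSums(w * Gc)
      i22 <- colSums(w * Gc^2)
      det <- i11 * i22 - i12^2
      det[det <= 0] <- NA_real_
      da <- (i22 * g1 - i12 * g2) / det
      db <- (i11 * g2 - i12 * g1) / det
      da[is.na(da)] <- 0
      db[is.na(db)] <- 0
      # dampen huge steps (quasi-separation)
      da <- pmin(pmax(da, -5), 5)
      db <- pmin(pmax(db, -5), 5)
      a <- a + da
      b <- b + db
      if (max(abs(da), abs(db)) < tol) break
    }
    eta <- sweep(Gc * rep(b, each = n), 2, a, "+")
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    i11 <- colSums(w)
    i12 <- colSums(w * Gc)
    i22 <- colSums(w * Gc^2)
    det <- i11 * i22 - i12^2
    se <- sqrt(ifelse(det > 0, i11 / det, NA_real_))
    out$beta[idx] <- b
    out$se[idx] <- se
    out$pval[idx] <- 2 * stats::pnorm(-abs(b / se))
  }
  out
}
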