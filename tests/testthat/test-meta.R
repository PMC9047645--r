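# Inverse-variance meta-analysis, X-stratum combination, exact cohort
# subtraction, variance-explained accounting and genomic-control lambda.

meta_pair <- function(b1, s1, b2, s2) {
  t1 <- toy_sumstats_df(1); t1$beta <- b1; t1$se <- s1
  t2 <- toy_sumstats_df(1); t2$beta <- b2; t2$se <- s2
  ivw_meta(list(sumstats(t1), sumstats(t2)))
}

test_that("IVW combination reproduces hand-computed weights", {
  # symmetric case
  m1 <- meta_pair(0.5, 0.1, 0.5, 0.1)
  expect_equal(m1$beta, 0.5)
  expect_equal(m1$se, 0.1 / sqrt(2))
  # asymmetric: weights 100 and 25
  m2 <- meta_pair(0.2, 0.1, 0.4, 0.2)
  expect_equal(m2$beta, 0.24)
  expect_equal(m2$se, 1 / sqrt(125))
  expect_equal(m2$z, 0.24 * sqrt(125), tolerance = 1e-12)
  expect_equal(round(m2$z, 3), 2.683)
  expect_equal(m2$k_cohorts, 2L)
})

test_that("IVW is order-invariant and associative", {
  set.seed(7)
  tabs <- lapply(1:3, function(i) {
    df <- toy_sumstats_df(4)
    df$beta <- rnorm(4, 0.1, 0.05)
    df$se <- runif(4, 0.05, 0.2)
    sumstats(df, cohort = paste0("c", i))
  })
  m123 <- ivw_meta(tabs)
  m321 <- ivw_meta(rev(tabs))
  expect_equal(m123$beta, m321$beta, tolerance = 1e-14)
  expect_equal(m123$se, m321$se, tolerance = 1e-14)
  staged <- ivw_meta(list(ivw_meta(tabs[1:2]), tabs[[3]]))
  expect_equal(staged$beta, m123$beta, tolerance = 1e-14)
  expect_equal(staged$se, m123$se, tolerance = 1e-14)
})

test_that("variants carried by one cohort pass through; MAF filter applies", {
  t1 <- toy_sumstats_df(2)
  t2 <- toy_sumstats_df(1)  # lacks the second variant
  m <- ivw_meta(list(sumstats(t1), sumstats(t2)))
  expect_equal(m$k_cohorts[match(2000, m$pos)], 1L)
  expect_equal(m$beta[match(2000, m$pos)], 0.1)
  t3 <- toy_sumstats_df(2)
  t3$eaf <- c(0.005, 0.3)
  expect_equal(nrow(ivw_meta(list(sumstats(t3)))), 1)
})

test_that("X-stratum combination pools males and females by IVW", {
  xm <- toy_sumstats_df(1); xm$chrom <- "X"; xm$stratum <- "male"
  xf <- toy_sumstats_df(1); xf$chrom <- "X"; xf$stratum <- "female"
  xm$beta <- 0.3; xm$se <- 0.1
  xf$beta <- 0.1; xf$se <- 0.1
  comb <- x_chrom_meta(sumstats(xm), sumstats(xf))
  expect_equal(comb$beta, 0.2)
  expect_equal(comb$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(comb$stratum, "combined")
  expect_equal(comb$k_strata, 2L)
  # missing stratum: pass-through, flagged by k_strata = 1
  xf2 <- toy_sumstats_df(2); xf2$chrom <- "X"; xf2$stratum <- "female"
  comb2 <- x_chrom_meta(sumstats(xm), sumstats(xf2))
  expect_equal(comb2$k_strata[match(2000, comb2$pos)], 1L)
})

test_that("meta_subtract is the exact inverse of adding a cohort", {
  tA <- toy_sumstats_df(3); tA$beta <- c(0.2, -0.1, 0.05); tA$se <- 0.1
  tB <- toy_sumstats_df(3); tB$beta <- c(0.4, 0.0, 0.1); tB$se <- 0.2
  m <- ivw_meta(list(sumstats(tA), sumstats(tB)))
  back <- meta_subtract(m, sumstats(tB))
  expect_equal(back$beta, sumstats(tA)$beta, tolerance = 1e-12)
  expect_equal(back$se, sumstats(tA)$se, tolerance = 1e-12)
  # hand-computed: (0.24, 1/sqrt(125)) minus (0.4, 0.2) -> (0.2, 0.1)
  m1 <- meta_pair(0.2, 0.1, 0.4, 0.2)
  t2 <- toy_sumstats_df(1); t2$beta <- 0.4; t2$se <- 0.2
  rem <- meta_subtract(m1, sumstats(t2))
  expect_equal(rem$beta, 0.2, tolerance = 1e-12)
  expect_equal(rem$se, 0.1, tolerance = 1e-12)
  # subtract then re-add restores the meta to machine precision
  readd <- ivw_meta(list(rem, sumstats(t2)))
  expect_equal(readd$beta, m1$beta, tolerance = 1e-14)
  expect_equal(readd$se, m1$se, tolerance = 1e-14)
  # subtracting something that was not a proper subset fails
  big <- toy_sumstats_df(1); big$beta <- 0.1; big$se <- 0.01
  expect_error(meta_subtract(m1, sumstats(big)), "proper subset")
})

test_that("variance explained follows 2f(1-f)beta^2 with explicit ratio", {
  expect_equal(variance_explained(data.frame(f = 0.5, beta = 0))$total, 0)
  ve <- variance_explained(data.frame(f = 0.1, beta = 0.3), h2_input = 0.16)
  expect_equal(ve$per_variant$v, 2 * 0.1 * 0.9 * 0.09)
  expect_equal(ve$total, 0.0162)
  expect_equal(ve$fraction, 0.0162 / 0.16)
  expect_error(variance_explained(data.frame(f = 0.1, beta = 0.3),
                                  h2_input = 0), "positive")
  multi <- variance_explained(data.frame(f = c(0.2, 0.4), beta = c(0.1, -0.2)))
  expect_equal(multi$total, 2 * .2 * .8 * .01 + 2 * .4 * .6 * .04)
})

test_that("genomic lambda scales quadratically in Z and handles degenerate input", {
  df <- toy_sumstats_df(150)
  set.seed(3)
  df$pos <- seq_len(150) * 1000
  df$beta <- rnorm(150, 0, 0.05)
  df$se <- 0.05
  ss <- sumstats(df)
  lam <- genomic_lambda(ss)
  ss2 <- ss
  ss2$se <- ss2$se / 2  # doubles every Z
  expect_equal(genomic_lambda(ss2), 4 * lam, tolerance = 1e-12)
  # identical statistics: lambda is that chi-square over 0.4549
  df3 <- df
  df3$beta <- 0.1
  df3$se <- 0.05
  expect_equal(genomic_lambda(sumstats(df3)), 4 / qchisq(0.5, 1))
  expect_error(genomic_lambda(sumstats(toy_sumstats_df(10))), "at least 100")
})

test_that("meta equals pooled individual-level OLS on a split dataset", {
  cfg <- sim_config(seed = 21, n_cohorts = 3, n_per_cohort = 700,
                    m_autosomal = 200, m_x = 20, n_ref = 200)
  map <- pqtlmeta:::build_variant_map(cfg)
  eff <- pqtlmeta:::build_effect_vectors(cfg, map)
  tabs <- list(); Gs <- list(); ys <- list()
  for (i in 1:3) {
    pqtlmeta:::seed_for(cfg, 100L + i)
    dat <- pqtlmeta:::sim_individuals(cfg, cfg$n_per_cohort[i], map, eff)
    y <- rank_inverse_normal(dat$y)
    Gs[[i]] <- dat$G_auto
    ys[[i]] <- y
    tabs[[i]] <- simulate_cohort_gwas(cfg, i)
  }
  m <- ivw_meta(tabs)
  m <- m[m$stratum == "all", ]
  G <- do.call(rbind, Gs)
  y <- unlist(ys)
  # pooled-OLS oracle from first principles
  idx <- match(paste(m$chrom, m$pos),
               paste(map$chrom, map$pos)[!map$is_x])
  for (j in sample(seq_len(nrow(m)), 25)) {
    g <- G[, idx[j]]
    fit <- lm(y ~ g)
    expect_lt(abs(m$beta[j] - coef(fit)[["g"]]), 0.02)
  }
})
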