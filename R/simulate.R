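# Synthetic multi-cohort pQTL study generator with full ground truth:
# block-LD genotypes via a Gaussian-copula haplotype model, a sex-stratified
# X-chromosome cis locus, autosomal trans loci, a polygenic background, a
# downstream binary outcome and annotation tracks enriched for causal
# variants.

#' Configuration for the synthetic study generator
#'
#' Defines the generative model every other module is validated against:
#' `n_cohorts` independent cohorts measure a rank-inverse-normal protein
#' phenotype with additive genetic architecture; haplotypes follow a
#' block-diagonal AR(1) Gaussian-copula LD structure; a strong X-chromosome
#' cis locus (three independent signals) and several autosomal trans loci
#' are planted on a polygenic background filling the target heritability; a
#' binary outcome is causally downstream of the protein with additional
#' direct (protein-independent) risk loci; annotation intervals are drawn so
#' causal variants are enriched at a declared odds ratio.
#'
#' Effect sizes `beta` are on the standardized-phenotype / standardized-
#' genotype scale, so one variant's explained variance is simply `beta^2`
#' (equal to `2f(1-f)b^2` with `b` the per-allele effect). Defaults plant a
#' cis architecture explaining about 1.7% of phenotypic variance, five trans
#' loci explaining 3.2%, and a total heritability of 0.16.
#'
#' @param seed Integer seed; every simulation artifact is a deterministic
#'   function of the configuration including this seed.
#' @param n_cohorts Number of independent cohorts.
#' @param n_per_cohort Integer vector of cohort sample sizes (recycled to
#'   `n_cohorts`).
#' @param male_fraction Proportion of males per cohort.
#' @param m_autosomal,m_x Number of autosomal / X-chromosome variants.
#' @param n_ref Diploid sample size of the LD reference panel.
#' @param ld_block_size Variants per independent LD block.
#' @param ld_rho AR(1) correlation of the latent Gaussian haplotype process
#'   within a block, in [0, 1).
#' @param maf_range Interval the minor allele frequencies are drawn from.
#' @param trans_effects Data frame (`index`, `f`, `beta`) of autosomal causal
#'   variants; `index` counts within the autosomal variant sequence, `f` is
#'   the allele frequency, `beta` the standardized effect.
#' @param cis_x_effects Data frame (`index`, `f`, `beta`) of X-chromosome
#'   causal variants; `index` counts within the X variant sequence.
#' @param h2_target Total narrow-sense heritability of the protein;
#'   the gap above the declared effects is filled by a polygenic background
#'   of tiny effects outside the declared LD blocks.
#' @param theta_causal Log-odds effect of the (transformed) protein level on
#'   the binary outcome.
#' @param outcome_prevalence Target outcome prevalence; the logistic
#'   intercept is solved numerically to achieve it.
#' @param n_outcome Sample size of the outcome GWAS (a sample independent of
#'   all cohorts, as two-sample MR assumes).
#' @param outcome_direct_effects Data frame (`index`, `f`, `gamma`) of
#'   autosomal variants with a direct per-allele log-odds effect on the
#'   outcome, not mediated by the protein (these are the loci a reverse MR
#'   instruments on).
#' @param annotation_enrichment_or Odds ratio at which causal variants are
#'   enriched in the annotated state.
#' @param annotation_base_rate Annotation membership probability for
#'   non-causal variants.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(seed = 1,
                       n_cohorts = 3,
                       n_per_cohort = 5000,
                       male_fraction = 0.5,
                       m_autosomal = 1200,
                       m_x = 240,
                       n_ref = 4000,
                       ld_block_size = 20,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       trans_effects = NULL,
                       cis_x_effects = NULL,
                       h2_target = 0.16,
                       theta_causal = 0.4,
                       outcome_prevalence = 0.1,
                       n_outcome = 20000,
                       outcome_direct_effects = NULL,
                       annotation_enrichment_or = 5,
                       annotation_base_rate = 0.1) {
  n_per_cohort <- rep_len(as.integer(n_per_cohort), n_cohorts)
  bs <- ld_block_size
  n_blocks_a <- ceiling(m_autosomal / bs)
  n_blocks_x <- ceiling(m_x / bs)
  mid <- function(block) pmin((block - 1L) * bs + ceiling(bs / 2), m_autosomal)

  if (is.null(trans_effects)) {
    k <- 5L
    blocks <- unique(round(seq(2, max(n_blocks_a - 1, 2), length.out = k)))
    trans_effects <- data.frame(
      index = mid(blocks),
      f = rep_len(c(0.15, 0.2, 0.25, 0.3, 0.35), length(blocks)),
      beta = rep_len(0.08, length(blocks))
    )
    # a weaker second causal variant inside the last trans locus, so the
    # conditional scan has a genuine secondary signal to discover
    sec <- mid(blocks[length(blocks)]) + 3L
    if (sec <= m_autosomal) {
      trans_effects <- rbind(trans_effects,
                             data.frame(index = sec, f = 0.35, beta = 0.06))
    }
  }
  if (is.null(cis_x_effects)) {
    xb <- unique(pmax(1, round(c(1, n_blocks_x / 2, n_blocks_x))))
    xmid <- pmin((xb - 1L) * bs + ceiling(bs / 2), m_x)
    cis_x_effects <- data.frame(
      index = xmid,
      f = rep_len(c(0.25, 0.2, 0.3), length(xmid)),
      beta = rep_len(c(0.11, 0.06, 0.06), length(xmid))
    )
  }
  if (is.null(outcome_direct_effects)) {
    used <- unique((trans_effects$index - 1L) %/% bs + 1L)
    free <- setdiff(seq_len(n_blocks_a), used)
    db <- free[unique(round(seq(1, length(free), length.out = 2)))]
    outcome_direct_effects <- data.frame(
      index = mid(db), f = 0.3, gamma = 0.3
    )
  }

  cfg <- structure(list(
    seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
    n_per_cohort = n_per_cohort, male_fraction = male_fraction,
    m_autosomal = as.integer(m_autosomal), m_x = as.integer(m_x),
    n_ref = as.integer(n_ref), ld_block_size = as.integer(bs),
    ld_rho = ld_rho, maf_range = maf_range,
    trans_effects = trans_effects, cis_x_effects = cis_x_effects,
    h2_target = h2_target, theta_causal = theta_causal,
    outcome_prevalence = outcome_prevalence,
    n_outcome = as.integer(n_outcome),
    outcome_direct_effects = outcome_direct_effects,
    annotation_enrichment_or = annotation_enrichment_or,
    annotation_base_rate = annotation_base_rate
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$ld_rho >= 0, cfg$ld_rho < 1,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$h2_target >= 0, cfg$h2_target <= 1,
    cfg$male_fraction > 0, cfg$male_fraction < 1,
    cfg$outcome_prevalence > 0, cfg$outcome_prevalence < 1
  )
  declared <- sum(cfg$trans_effects$beta^2) + sum(cfg$cis_x_effects$beta^2)
  if (declared > cfg$h2_target + 1e-12) {
    stop("declared effect variance (", signif(declared, 3),
         ") exceeds h2_target (", cfg$h2_target, ")")
  }
  eff_f <- c(cfg$trans_effects$f, cfg$cis_x_effects$f)
  if (any(eff_f < cfg$maf_range[1] - 1e-12 | eff_f > cfg$maf_range[2] + 1e-12)) {
    stop("declared effect allele frequencies must lie within maf_range")
  }
  if (any(cfg$trans_effects$index > cfg$m_autosomal) ||
      any(cfg$cis_x_effects$index > cfg$m_x)) {
    stop("effect index outside the simulated variant range")
  }
  invisible(cfg)
}

# deterministic per-stage RNG seeding so stages can be re-run in isolation
seed_for <- function(cfg, offset) {
  set.seed((abs(cfg$seed) * 7919 + offset) %% 2147483629L)
}

# Variant map shared by the panel, every cohort and the outcome sample.
# Allele pairs are drawn non-palindromic so simulated tables never hit the
# palindromic-exclusion rule (that rule is exercised by unit tests instead).
build_variant_map <- function(cfg) {
  seed_for(cfg, 7L)
  bs <- cfg$ld_block_size
  build_side <- function(m, chroms, is_x) {
    n_blocks <- ceiling(m / bs)
    block <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
    if (is_x) {
      chrom <- rep("X", m)
      block_on_chrom <- block
    } else {
      chrom_of_block <- chroms[((seq_len(n_blocks) - 1L) %% length(chroms)) + 1L]
      rank_on_chrom <- stats::ave(seq_len(n_blocks), chrom_of_block,
                                  FUN = seq_along)
      chrom <- chrom_of_block[block]
      block_on_chrom <- rank_on_chrom[block]
    }
    within <- stats::ave(seq_len(m), block, FUN = seq_along)
    pos <- 1e6 + (block_on_chrom - 1) * 3e6 + (within - 1) * 2500
    f <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                   c("G", "T"), c("C", "T"), c("T", "G"), c("T", "C"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    data.frame(chrom = chrom, pos = as.integer(pos),
               effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
               f = f, block = block, stringsAsFactors = FALSE)
  }
  auto <- build_side(cfg$m_autosomal, as.character(1:22), FALSE)
  xmap <- build_side(cfg$m_x, NULL, TRUE)
  xmap$block <- xmap$block + max(auto$block)
  map <- rbind(auto, xmap)
  map$f[seq_len(cfg$m_autosomal)][cfg$trans_effects$index] <- cfg$trans_effects$f
  map$f[cfg$m_autosomal + cfg$cis_x_effects$index] <- cfg$cis_x_effects$f
  odf <- cfg$outcome_direct_effects
  if (!is.null(odf) && nrow(odf)) {
    map$f[seq_len(cfg$m_autosomal)][odf$index] <- odf$f
  }
  map$id <- sprintf("rs%06d", seq_len(nrow(map)))
  map$is_x <- map$chrom == "X"
  map
}

# Haplotypes from the Gaussian copula: per block, a latent AR(1) process is
# thresholded at qnorm(1 - f) so carrier probability equals f.
gen_haplotypes <- function(map, n_hap, rho) {
  m <- nrow(map)
  H <- matrix(0L, n_hap, m)
  thr <- stats::qnorm(1 - map$f)
  for (b in unique(map$block)) {
    cols <- which(map$block == b)
    z <- matrix(0, n_hap, length(cols))
    z[, 1] <- stats::rnorm(n_hap)
    if (length(cols) > 1) {
      for (j in 2:length(cols)) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n_hap)
      }
    }
    H[, cols] <- (z > rep(thr[cols], each = n_hap)) + 0L
  }
  H
}

#' Simulate the LD reference panel
#'
#' Generates a phased haplotype panel of `n_ref` diploid individuals over
#' the configuration's variant map, with block-diagonal AR(1)
#' Gaussian-copula LD. This panel stands in for an external genotype
#' reference and feeds all LD computations (r-squared, D-prime, LD scores,
#' clumping, conditional analysis).
#'
#' @param cfg A [sim_config()] object.
#' @return An `ld_ref` object: list with `map` (variant data frame), `H`
#'   (2 `n_ref` x m phased haplotype matrix), `G` (n_ref x m dosage matrix),
#'   `n_ref` and `phased = TRUE`.
#' @export
simulate_ld_panel <- function(cfg) {
  map <- build_variant_map(cfg)
  seed_for(cfg, 11L)
  H <- gen_haplotypes(map, 2L * cfg$n_ref, cfg$ld_rho)
  G <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
    H[seq(2, nrow(H), by = 2), , drop = FALSE]
  structure(list(map = map, H = H, G = G, n_ref = cfg$n_ref, phased = TRUE),
            class = "ld_ref")
}

# per-allele effect vector over the whole map (autosomes then X), plus the
# polygenic background outside declared blocks
build_effect_vectors <- function(cfg, map) {
  m <- nrow(map)
  b <- numeric(m)  # per-allele scale
  te <- cfg$trans_effects
  b[te$index] <- te$beta / sqrt(2 * te$f * (1 - te$f))
  ce <- cfg$cis_x_effects
  xi <- cfg$m_autosomal + ce$index
  b[xi] <- ce$beta / sqrt(2 * ce$f * (1 - ce$f))
  declared_idx <- c(te$index, xi)
  h2_poly <- cfg$h2_target - sum(te$beta^2) - sum(ce$beta^2)
  poly_idx <- integer(0)
  if (h2_poly > 1e-12) {
    # keep the background clear of the declared protein loci and of the
    # outcome's direct risk loci (so the latter stay protein-null)
    excl_idx <- declared_idx
    odf <- cfg$outcome_direct_effects
    if (!is.null(odf) && nrow(odf)) excl_idx <- c(excl_idx, odf$index)
    declared_blocks <- unique(map$block[excl_idx])
    poly_idx <- which(!map$is_x & !(map$block %in% declared_blocks))
    if (length(poly_idx)) {
      seed_for(cfg, 13L)
      beta_std <- sqrt(h2_poly / length(poly_idx)) *
        sample(c(-1, 1), length(poly_idx), replace = TRUE)
      b[poly_idx] <- beta_std / sqrt(2 * map$f[poly_idx] * (1 - map$f[poly_idx]))
    }
  }
  list(b_allele = b, declared_idx = declared_idx, poly_idx = poly_idx,
       h2_poly = h2_poly)
}

# Draw one sample of individuals: sex, autosomal genotypes, X dosages
# (females sum two haplotypes, hemizygous males carry one, coded 0/1) and
# the raw protein phenotype y with Var(y) ~ 1.
sim_individuals <- function(cfg, n, map, eff) {
  sex_male <- stats::runif(n) < cfg$male_fraction
  auto_cols <- which(!map$is_x)
  x_cols <- which(map$is_x)
  Ha <- gen_haplotypes(map[auto_cols, , drop = FALSE], 2L * n, cfg$ld_rho)
  G_auto <- Ha[seq(1, 2 * n, 2), , drop = FALSE] +
    Ha[seq(2, 2 * n, 2), , drop = FALSE]
  Hx <- gen_haplotypes(map[x_cols, , drop = FALSE], 2L * n, cfg$ld_rho)
  G_x <- Hx[seq(1, 2 * n, 2), , drop = FALSE] +
    Hx[seq(2, 2 * n, 2), , drop = FALSE]
  G_x[sex_male, ] <- Hx[seq(1, 2 * n, 2), , drop = FALSE][sex_male, ]

  g_value <- as.vector(G_auto %*% eff$b_allele[auto_cols]) +
    as.vector(G_x %*% eff$b_allele[x_cols])
  e_sd <- sqrt(max(1 - cfg$h2_target, 1e-8))
  y <- g_value + stats::rnorm(n, 0, e_sd)
  list(sex_male = sex_male, G_auto = G_auto, G_x = G_x, y = y)
}

sumstats_from_engine <- function(map_rows, fit, stratum, cohort = NULL) {
  df <- data.frame(
    chrom = map_rows$chrom, pos = map_rows$pos, id = map_rows$id,
    effect_allele = map_rows$effect_allele,
    other_allele = map_rows$other_allele,
    eaf = fit$eaf, beta = fit$beta, se = fit$se, pval = fit$pval,
    n = fit$n, stratum = stratum, stringsAsFactors = FALSE
  )
  df[!is.na(df$beta) & !is.na(df$se) & df$se > 0 &
       df$eaf > 0 & df$eaf < 1, , drop = FALSE]
}

#' Simulate one cohort's protein GWAS
#'
#' Generates an independent cohort of individuals under the configured
#' genetic architecture, rank-inverse-normal transforms the protein
#' phenotype, and runs one marginal OLS regression per variant. Autosomal
#' variants are analysed in the full cohort (stratum `"all"`); X-chromosome
#' variants are analysed separately in males (0/1 dosage coding) and females
#' (0/1/2), as the container requires.
#'
#' @param cfg A [sim_config()] object.
#' @param cohort Cohort index in `1:cfg$n_cohorts`.
#' @return A `sumstats` object with strata `all`, `male` and `female`.
#' @export
simulate_cohort_gwas <- function(cfg, cohort) {
  stopifnot(cohort >= 1, cohort <= cfg$n_cohorts)
  map <- build_variant_map(cfg)
  eff <- build_effect_vectors(cfg, map)
  seed_for(cfg, 100L + cohort)
  dat <- sim_individuals(cfg, cfg$n_per_cohort[cohort], map, eff)
  y <- rank_inverse_normal(dat$y)
  auto <- map[!map$is_x, , drop = FALSE]
  xmap <- map[map$is_x, , drop = FALSE]

  parts <- list(
    sumstats_from_engine(auto, marginal_ols_gwas(dat$G_auto, y), "all")
  )
  for (sx in c("male", "female")) {
    sel <- if (sx == "male") dat$sex_male else !dat$sex_male
    if (sum(sel) >= 10) {
      fit <- marginal_ols_gwas(dat$G_x[sel, , drop = FALSE], y[sel],
                               ploidy = if (sx == "male") 1 else 2)
      parts[[length(parts) + 1]] <- sumstats_from_engine(xmap, fit, sx)
    }
  }
  sumstats(do.call(rbind, parts), cohort = paste0("cohort", cohort),
           phenotype = "protein")
}

#' Simulate the binary-outcome GWAS
#'
#' Draws an outcome sample independent of all protein cohorts. Case status
#' follows `Bernoulli(plogis(alpha + theta * y + direct))` where `y` is the
#' transformed protein value, `direct` collects the configured
#' protein-independent risk loci, and `alpha` is solved so the expected
#' prevalence matches the configuration. One logistic regression per variant
#' yields log-odds-ratio records; X-chromosome variants are fitted per sex
#' and combined by inverse-variance weighting (stratum `"combined"`).
#'
#' @param cfg A [sim_config()] object.
#' @param variants Optional integer vector of variant indices (into the
#'   combined autosome+X map) to test; default all.
#' @return A `sumstats` object of log-odds-ratio association records.
#' @export
simulate_outcome_gwas <- function(cfg, variants = NULL) {
  map <- build_variant_map(cfg)
  eff <- build_effect_vectors(cfg, map)
  seed_for(cfg, 17L)
  dat <- sim_individuals(cfg, cfg$n_outcome, map, eff)
  y <- rank_inverse_normal(dat$y)

  auto_cols <- which(!map$is_x)
  direct <- rep(0, cfg$n_outcome)
  odf <- cfg$outcome_direct_effects
  if (!is.null(odf) && nrow(odf)) {
    direct <- as.vector(dat$G_auto[, odf$index, drop = FALSE] %*% odf$gamma)
  }
  lin <- cfg$theta_causal * y + direct
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lin)) - cfg$outcome_prevalence,
    interval = c(-30, 30)
  )$root
  d <- stats::rbinom(cfg$n_outcome, 1, stats::plogis(alpha + lin))

  if (is.null(variants)) variants <- seq_len(nrow(map))
  a_test <- intersect(variants, auto_cols)
  x_test <- intersect(variants, which(map$is_x))

  parts <- list()
  if (length(a_test)) {
    ai <- match(a_test, auto_cols)
    fit <- logistic_gwas(dat$G_auto[, ai, drop = FALSE], d)
    parts[[length(parts) + 1]] <-
      sumstats_from_engine(map[a_test, , drop = FALSE], fit, "all")
  }
  if (length(x_test)) {
    xi <- match(x_test, which(map$is_x))
    fits <- lapply(c(TRUE, FALSE), function(male) {
      sel <- dat$sex_male == male
      logistic_gwas(dat$G_x[sel, xi, drop = FALSE], d[sel],
                    ploidy = if (male) 1 else 2)
    })
    # IVW combination of the sex strata into one per-allele record
    w1 <- 1 / fits[[1]]$se^2; w2 <- 1 / fits[[2]]$se^2
    beta <- (fits[[1]]$beta * w1 + fits[[2]]$beta * w2) / (w1 + w2)
    se <- 1 / sqrt(w1 + w2)
    nm <- fits[[1]]$n; nf <- fits[[2]]$n
    comb <- data.frame(
      beta = beta, se = se, pval = 2 * stats::pnorm(-abs(beta / se)),
      eaf = (fits[[1]]$eaf * nm + fits[[2]]$eaf * nf) / (nm + nf),
      n = nm + nf
    )
    parts[[length(parts) + 1]] <-
      sumstats_from_engine(map[x_test, , drop = FALSE], comb, "combined")
  }
  sumstats(do.call(rbind, parts), cohort = "outcome", phenotype = "disease")
}

#' Simulate an annotation track enriched for causal variants
#'
#' Draws per-variant annotation membership so that causal variants (the
#' declared cis and trans effects) lie in the annotated state at the
#' configured odds ratio relative to non-causal variants, then materialises
#' membership as BED-style intervals (0-based half-open) around the
#' annotated positions.
#'
#' @param cfg A [sim_config()] object.
#' @param track Name of the annotation track.
#' @return A list with `bed` (data frame `chrom`, `start`, `end`, `name`),
#'   `membership` (logical vector over the variant map) and `map`.
#' @export
simulate_annotations <- function(cfg, track = "state1") {
  map <- build_variant_map(cfg)
  causal <- rep(FALSE, nrow(map))
  causal[cfg$trans_effects$index] <- TRUE
  causal[cfg$m_autosomal + cfg$cis_x_effects$index] <- TRUE
  p0 <- cfg$annotation_base_rate
  odds1 <- cfg$annotation_enrichment_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  seed_for(cfg, 23L)
  member <- stats::runif(nrow(map)) < ifelse(causal, p1, p0)
  bed <- data.frame(
    chrom = map$chrom[member],
    start = map$pos[member] - 1L,  # 1-based position -> 0-based half-open
    end = map$pos[member],
    name = rep_len(track, sum(member)),
    stringsAsFactors = FALSE
  )
  list(bed = bed, membership = member, map = map)
}

#' Write a BED track (0-based half-open intervals)
#'
#' @param bed Data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a complete synthetic study
#'
#' Convenience driver: LD panel, per-cohort protein GWAS tables, the binary
#' outcome GWAS, an enriched annotation track, and the ground truth needed
#' to validate downstream inference.
#'
#' @param cfg A [sim_config()] object.
#' @param outcome_variants Optional variant subset passed to
#'   [simulate_outcome_gwas()].
#' @return A list of class `sim_study` with elements `config`, `map`,
#'   `panel`, `cohorts`, `outcome`, `annotation` and `truth`.
#' @export
simulate_study <- function(cfg, outcome_variants = NULL) {
  panel <- simulate_ld_panel(cfg)
  map <- panel$map
  eff <- build_effect_vectors(cfg, map)
  cohorts <- lapply(seq_len(cfg$n_cohorts),
                    function(i) simulate_cohort_gwas(cfg, i))
  outcome <- simulate_outcome_gwas(cfg, variants = outcome_variants)
  annotation <- simulate_annotations(cfg)

  ci <- eff$declared_idx
  truth <- list(
    causal = data.frame(
      chrom = map$chrom[ci], pos = map$pos[ci], id = map$id[ci],
      f = map$f[ci], beta_allele = eff$b_allele[ci],
      beta_std = eff$b_allele[ci] * sqrt(2 * map$f[ci] * (1 - map$f[ci])),
      type = ifelse(map$is_x[ci], "cis_x", "trans"),
      annotated = annotation$membership[ci],
      stringsAsFactors = FALSE
    ),
    h2 = cfg$h2_target,
    theta = cfg$theta_causal,
    outcome_direct = cfg$outcome_direct_effects,
    cis_window = list(chrom = "X",
                      start = min(map$pos[map$is_x]),
                      end = max(map$pos[map$is_x]))
  )
  structure(list(config = cfg, map = map, panel = panel, cohorts = cohorts,
                 outcome = outcome, annotation = annotation, truth = truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic pQTL study (seed ", cfg$seed, ")\n", sep = "")
  cat("  cohorts: ", cfg$n_cohorts, " (n = ",
      paste(cfg$n_per_cohort, collapse = ", "), ")\n", sep = "")
  cat("  variants: ", cfg$m_autosomal, " autosomal + ", cfg$m_x, " X\n",
      sep = "")
  cat("  declared causal: ", nrow(x$truth$causal), " (h2 target ",
      cfg$h2_target, ")\n", sep = "")
  invisible(x)
}
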