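# Shared fixtures: toy LD panels with exact correlation structure, small
# summary-statistics tables, and reduced simulation configurations.

# Panel whose dosage correlations are exactly those of the supplied
# haplotype matrix: each haplotype is duplicated into a homozygous diploid,
# so cor(dosages) == cor(haplotypes) and haplotype frequencies are
# preserved for D' counting.
panel_from_haplotypes <- function(haps, chrom = "1",
                                  pos = seq_len(ncol(haps)) * 1000) {
  m <- ncol(haps)
  map <- data.frame(
    chrom = chrom, pos = as.integer(pos),
    effect_allele = "A", other_allele = "G",
    id = sprintf("s%d", seq_len(m)), stringsAsFactors = FALSE
  )
  n <- nrow(haps)
  H <- matrix(0L, 2L * n, m)
  H[seq(1, 2 * n, 2), ] <- haps
  H[seq(2, 2 * n, 2), ] <- haps
  ld_ref(map, G = 2L * haps, H = H)
}

# Panel of continuous "dosages" with an exact sample correlation matrix,
# built from an orthonormal basis; used where a hand-specified R matrix is
# needed (clumping and joint-fit oracles). D' is not meaningful here.
panel_with_correlation <- function(R, n = 200, chrom = "1",
                                   pos = seq_len(ncol(R)) * 1000) {
  m <- ncol(R)
  # orthonormal columns, each orthogonal to the intercept, so the sample
  # correlation matrix of G equals R exactly
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * m), n, m))))[, -1]
  L <- chol(R)
  G <- Q %*% L
  map <- data.frame(
    chrom = chrom, pos = as.integer(pos),
    effect_allele = "A", other_allele = "G",
    id = sprintf("s%d", seq_len(m)), stringsAsFactors = FALSE
  )
  ld_ref(map, G = G)
}

# haplotype matrix realising given two-locus haplotype counts
haps_from_counts <- function(nAB, nAb, naB, nab) {
  rbind(
    matrix(rep(c(1L, 1L), nAB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), nAb), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), naB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 0L), nab), ncol = 2, byrow = TRUE)
  )
}

toy_sumstats_df <- function(n = 3) {
  data.frame(
    chrom = "1", pos = seq_len(n) * 1000,
    effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.05, pval = 0.01, n = 1000,
    stringsAsFactors = FALSE
  )
}

# small null configuration: no causal effects, no heritability
null_sim_config <- function(seed, m_autosomal = 400, m_x = 40,
                            n_per_cohort = 1000, n_cohorts = 1, ...) {
  no_eff <- data.frame(index = integer(0), f = numeric(0), beta = numeric(0))
  sim_config(seed = seed, n_cohorts = n_cohorts,
             n_per_cohort = n_per_cohort,
             m_autosomal = m_autosomal, m_x = m_x,
             trans_effects = no_eff, cis_x_effects = no_eff,
             outcome_direct_effects = data.frame(index = integer(0),
                                                 f = numeric(0),
                                                 gamma = numeric(0)),
             h2_target = 0, ...)
}
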