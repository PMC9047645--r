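# End-to-end orchestration over a synthetic study: meta-analysis, QC,
# clumping, conditional scans, variance-explained accounting, cis and
# genome-wide MR with meta-subtraction replication, and the enrichment
# scan. Produces a machine-readable report plus a human summary.

#' Pipeline configuration
#'
#' Collects the analysis thresholds and the simulation configuration for
#' the end-to-end driver. Defaults mirror the conventional genome-wide
#' analysis settings: significance 5e-8, minor-allele-frequency filter
#' 0.01, clumping r-squared 0.001 (cis) and 0.05 (genome-wide).
#'
#' @param sim A [sim_config()] object describing the synthetic study.
#' @param p_gw Genome-wide significance threshold.
#' @param maf_min Minor-allele-frequency filter applied to the meta EAF.
#' @param clump_r2_cis,clump_r2_gw LD clumping thresholds.
#' @param h2_input Heritability used as the denominator of the
#'   variance-explained report (defaults to the simulation's target).
#' @param out_dir Output directory for the report files, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_gw = 5e-8,
                            maf_min = 0.01,
                            clump_r2_cis = 0.001,
                            clump_r2_gw = 0.05,
                            h2_input = NULL,
                            out_dir = NULL) {
  stopifnot(p_gw > 0, p_gw <= 1, maf_min >= 0, maf_min < 0.5,
            clump_r2_cis > 0, clump_r2_cis < 1,
            clump_r2_gw > 0, clump_r2_gw < 1)
  structure(list(sim = sim, p_gw = p_gw, maf_min = maf_min,
                 clump_r2_cis = clump_r2_cis, clump_r2_gw = clump_r2_gw,
                 h2_input = if (is.null(h2_input)) sim$h2_target else h2_input,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full synthetic-study analysis pipeline
#'
#' Simulates the configured study and runs every analysis stage in order:
#' per-stratum inverse-variance meta-analysis across cohorts and combination
#' of the X-chromosome sex strata; genomic-control lambda; genome-wide LD
#' clumping to define loci; a conditional scan per locus for secondary
#' signals; the variance-explained / heritability-fraction report for the
#' lead variants; cis MR of the protein on the binary outcome plus a
#' replication on the outcome GWAS with one cohort's contribution removed
#' by meta-subtraction (emulating an overlap-free replication dataset);
#' reverse MR instrumenting on the outcome's own loci; and the annotation
#' enrichment fit. Row counts are logged per stage; any stage error halts
#' with the stage name.
#'
#' @param cfg A [pipeline_config()] object.
#' @param study Optional pre-simulated [simulate_study()] bundle (must match
#'   `cfg$sim`); simulated fresh when omitted.
#' @return A `pipeline_report` list; when `cfg$out_dir` is set, also writes
#'   `report.json` and `report.md` there.
#' @export
run_pipeline <- function(cfg, study = NULL) {
  stage <- "simulate"
  report <- list(config = list(p_gw = cfg$p_gw, maf_min = cfg$maf_min,
                               clump_r2_cis = cfg$clump_r2_cis,
                               clump_r2_gw = cfg$clump_r2_gw,
                               seed = cfg$sim$seed))
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(study)) {
    study <- run_stage("simulate", simulate_study(cfg$sim))
  }
  panel <- study$panel

  meta <- run_stage("meta", {
    m <- ivw_meta(study$cohorts, maf_min = cfg$maf_min)
    message("meta: ", nrow(m), " records from ", length(study$cohorts),
            " cohorts")
    m
  })
  xmeta <- run_stage("x_meta", {
    x_chrom_meta(meta[meta$stratum == "male", , drop = FALSE],
                 meta[meta$stratum == "female", , drop = FALSE])
  })
  combined <- rbind(
    as.data.frame(meta[meta$stratum == "all",
                       c("chrom", "pos", "id", "effect_allele",
                         "other_allele", "eaf", "beta", "se", "pval", "n",
                         "stratum")]),
    as.data.frame(xmeta[, c("chrom", "pos", "id", "effect_allele",
                            "other_allele", "eaf", "beta", "se", "pval",
                            "n", "stratum")])
  )
  report$counts <- list(
    variants_in = sum(vapply(study$cohorts, nrow, 0L)),
    meta_records = nrow(meta),
    n_all = sum(meta$stratum == "all"),
    n_male = sum(meta$stratum == "male"),
    n_female = sum(meta$stratum == "female"),
    n_x_combined = nrow(xmeta),
    analyzed = nrow(combined)
  )

  report$lambda <- run_stage("lambda", {
    genomic_lambda(meta[meta$stratum == "all", , drop = FALSE])
  })

  loci <- run_stage("define_loci", {
    li <- define_loci(combined, p_threshold = cfg$p_gw, window_kb = 1000)
    message("loci: ", nrow(li), " genome-wide significant loci")
    li
  })
  report$n_loci <- nrow(loci)
  report$loci <- loci

  report$conditional <- run_stage("conditional", {
    lapply(seq_len(nrow(loci)), function(i) {
      lead <- loci[i, ]
      win <- 5e5
      loc <- combined[combined$chrom == lead$chrom &
                        abs(combined$pos - lead$pos) <= win, , drop = FALSE]
      sc <- conditional_scan(loc, panel, n = max(loc$n), p_enter = cfg$p_gw)
      list(lead = key_of(lead), n_signals = nrow(sc$selected),
           selected = sc$selected)
    })
  })
  report$n_secondary <- sum(vapply(report$conditional,
                                   function(x) x$n_signals - 1L, 0L))

  report$variance_explained <- run_stage("h2part", {
    leads <- loci
    ve <- variance_explained(
      data.frame(id = leads$id, f = pmin(leads$eaf, 1 - leads$eaf),
                 beta = leads$beta),
      h2_input = cfg$h2_input
    )
    cis_leads <- leads[leads$chrom == "X", , drop = FALSE]
    ve_cis <- if (nrow(cis_leads)) {
      variance_explained(
        data.frame(id = cis_leads$id, f = pmin(cis_leads$eaf, 1 - cis_leads$eaf),
                   beta = cis_leads$beta),
        h2_input = cfg$h2_input
      )
    } else NULL
    list(all = ve, cis = ve_cis)
  })

  report$mr_cis <- run_stage("mr_cis", {
    inst <- select_instruments(combined, study$outcome, panel, mode = "cis",
                               cis_window = study$truth$cis_window,
                               p_threshold = cfg$p_gw,
                               r2_threshold = cfg$clump_r2_cis)
    message("mr_cis: ", nrow(inst), " instruments")
    list(result = ivw_mr(inst), n_instruments = nrow(inst))
  })

  report$mr_replication <- run_stage("mr_replication", {
    # emulate replication against an overlap-free outcome: remove one
    # cohort's share from the protein meta-analysis before instrumenting
    reduced <- meta_subtract(meta, study$cohorts[[1]])
    xr <- x_chrom_meta(reduced[reduced$stratum == "male", , drop = FALSE],
                       reduced[reduced$stratum == "female", , drop = FALSE])
    red_comb <- rbind(
      as.data.frame(reduced[reduced$stratum == "all",
                            c("chrom", "pos", "id", "effect_allele",
                              "other_allele", "eaf", "beta", "se", "pval",
                              "n", "stratum")]),
      as.data.frame(xr[, c("chrom", "pos", "id", "effect_allele",
                           "other_allele", "eaf", "beta", "se", "pval", "n",
                           "stratum")])
    )
    tryCatch({
      inst <- select_instruments(red_comb, study$outcome, panel,
                                 mode = "cis",
                                 cis_window = study$truth$cis_window,
                                 p_threshold = cfg$p_gw,
                                 r2_threshold = cfg$clump_r2_cis)
      list(result = ivw_mr(inst), n_instruments = nrow(inst))
    }, error = function(e) list(status = "not_estimable",
                                reason = conditionMessage(e)))
  })

  report$mr_bidirectional <- run_stage("mr_bidirectional", {
    bidirectional_mr(combined, study$outcome, panel, mode = "genomewide",
                     p_threshold = cfg$p_gw,
                     r2_threshold = cfg$clump_r2_gw)
  })

  report$enrichment <- run_stage("enrich", {
    scores <- ld_scores(panel)
    ann <- annotate_snps(combined, study$annotation$bed, scores)
    fit_enrichment(ann, alpha_gw = cfg$p_gw)
  })

  report$truth_check <- run_stage("truth_check", {
    tr <- study$truth$causal
    i <- match(paste(tr$chrom, tr$pos), paste(combined$chrom, combined$pos))
    found <- !is.na(i) & combined$pval[i] < cfg$p_gw
    # a marginal estimator's target at a causal variant is the LD-convolved
    # effect: sum over causal partners of r_jk times their standardized
    # effect, mapped back to the per-allele scale
    R <- ld_matrix(panel, list(chrom = tr$chrom, pos = tr$pos))
    b_std <- tr$beta_std
    scale <- sqrt(2 * tr$f * (1 - tr$f))
    expected_marginal <- as.vector(R %*% b_std) / scale
    covered <- !is.na(i) &
      abs(combined$beta[i] - expected_marginal) <= 3 * combined$se[i]
    list(n_causal = nrow(tr), n_recovered = sum(found),
         n_within_3se = sum(covered))
  })

  out <- structure(report, class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(out, cfg$out_dir)
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- report
  js$loci <- as.data.frame(js$loci)
  js$variance_explained$all <- unclass(js$variance_explained$all)
  if (!is.null(js$variance_explained$cis)) {
    js$variance_explained$cis <- unclass(js$variance_explained$cis)
  }
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(js), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c(
    "# Synthetic pQTL pipeline report", "",
    sprintf("- genomic-control lambda: %.3f", report$lambda),
    sprintf("- independent loci (P < %.1g): %d", report$config$p_gw,
            report$n_loci),
    sprintf("- secondary signals from conditional scans: %d",
            report$n_secondary),
    sprintf("- variance explained by lead variants: %.4f (h2 input %.3f, fraction %.3f)",
            report$variance_explained$all$total,
            report$variance_explained$all$h2_input,
            report$variance_explained$all$fraction),
    if (!is.null(report$mr_cis$result)) {
      sprintf("- cis MR: OR %.3f [%.3f-%.3f], P = %.3g (%d instruments)",
              report$mr_cis$result$or, report$mr_cis$result$ci_lower,
              report$mr_cis$result$ci_upper, report$mr_cis$result$pval,
              report$mr_cis$n_instruments)
    },
    sprintf("- enrichment log-OR: %.3f (P = %.3g)",
            report$enrichment$beta, report$enrichment$pval),
    sprintf("- truth check: %d/%d causal variants genome-wide significant, %d within 3 SE",
            report$truth_check$n_recovered, report$truth_check$n_causal,
            report$truth_check$n_within_3se)
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  lambda:", sprintf("%.3f", x$lambda), "\n")
  cat("  loci:", x$n_loci, " secondary signals:", x$n_secondary, "\n")
  if (!is.null(x$mr_cis$result)) {
    cat(sprintf("  cis MR OR: %.3f [%.3f-%.3f] P=%.3g\n",
                x$mr_cis$result$or, x$mr_cis$result$ci_lower,
                x$mr_cis$result$ci_upper, x$mr_cis$result$pval))
  }
  cat(sprintf("  enrichment beta: %.3f (P=%.3g)\n",
              x$enrichment$beta, x$enrichment$pval))
  invisible(x)
}
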