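# LD statistics from a genotype reference panel: pairwise r-squared and
# D-prime (haplotype counting when phased, two-locus EM otherwise), bias-
# adjusted LD scores, and greedy p-value clumping.

#' Construct an LD reference panel object
#'
#' @param map Variant data frame with columns `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and optionally `id`.
#' @param G Dosage matrix (samples x variants, values 0/1/2).
#' @param H Optional phased haplotype matrix (2n x variants, values 0/1);
#'   when present, D-prime is computed by direct haplotype counting.
#' @return An `ld_ref` object.
#' @export
ld_ref <- function(map, G, H = NULL) {
  stopifnot(ncol(G) == nrow(map))
  if (is.null(map$id)) map$id <- paste0(map$chrom, ":", map$pos)
  structure(list(map = map, G = G, H = H, n_ref = nrow(G),
                 phased = !is.null(H)),
            class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat("LD reference panel: ", x$n_ref, " samples x ", nrow(x$map),
      " variants (", if (x$phased) "phased" else "unphased", ")\n", sep = "")
  invisible(x)
}

# locate variants in the panel by id, "chrom:pos" string, or (chrom, pos) row
panel_index <- function(ref, key) {
  map <- ref$map
  if (is.list(key) && !is.null(key$chrom)) {
    return(match(paste(key$chrom, key$pos), paste(map$chrom, map$pos)))
  }
  i <- match(key, map$id)
  miss <- is.na(i)
  if (any(miss)) {
    i[miss] <- match(key[miss], paste0(map$chrom, ":", map$pos))
  }
  i
}

dprime_from_freqs <- function(pAB, pA, pB) {
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NA_real_)
  abs(D) / dmax
}

# Two-locus haplotype-frequency EM on unphased genotypes. Only the double
# heterozygote is phase-ambiguous; iterate its expected split.
em_haplotype_freq <- function(gA, gB, max_iter = 100, tol = 1e-10) {
  n <- length(gA)
  pA <- mean(gA) / 2
  pB <- mean(gB) / 2
  pAB <- pA * pB  # start at linkage equilibrium
  n_dh <- sum(gA == 1 & gB == 1)
  # expected haplotype counts from unambiguous configurations
  base_AB <- sum((gA == 2) * (gB == 2) * 2 + (gA == 2) * (gB == 1) +
                   (gA == 1) * (gB == 2))
  base_Ab <- sum((gA == 2) * (gB == 0) * 2 + (gA == 2) * (gB == 1) +
                   (gA == 1) * (gB == 0))
  base_aB <- sum((gA == 0) * (gB == 2) * 2 + (gA == 0) * (gB == 1) +
                   (gA == 1) * (gB == 2))
  base_ab <- sum((gA == 0) * (gB == 0) * 2 + (gA == 0) * (gB == 1) +
                   (gA == 1) * (gB == 0))
  for (it in seq_len(max_iter)) {
    pAb <- pA - pAB
    paB <- pB - pAB
    pab <- 1 - pA - pB + pAB
    cis <- pAB * pab
    tr <- pAb * paB
    frac <- if (cis + tr > 0) cis / (cis + tr) else 0.5
    nAB <- base_AB + n_dh * frac
    nab <- base_ab + n_dh * frac
    nAb <- base_Ab + n_dh * (1 - frac)
    naB <- base_aB + n_dh * (1 - frac)
    tot <- nAB + nab + nAb + naB
    new_pAB <- nAB / tot
    pA <- (nAB + nAb) / tot
    pB <- (nAB + naB) / tot
    if (abs(new_pAB - pAB) < tol) {
      pAB <- new_pAB
      break
    }
    pAB <- new_pAB
  }
  list(pAB = pAB, pA = pA, pB = pB)
}

#' Pairwise LD between two variants
#'
#' `r^2` is the squared Pearson correlation of dosages. `D'` is computed
#' from haplotype frequencies — by direct counting when the panel is phased,
#' otherwise from the two-locus EM haplotype-frequency estimate.
#'
#' @param ref An `ld_ref` panel.
#' @param a,b Variant identifiers (panel `id`, `"chrom:pos"` string, or a
#'   list with `chrom` and `pos`).
#' @return List with elements `r2` and `dprime`, both between 0 and 1.
#' @export
ld_pair <- function(ref, a, b) {
  i <- panel_index(ref, a)
  j <- panel_index(ref, b)
  if (is.na(i) || is.na(j)) stop("variant not found in LD panel")
  gA <- ref$G[, i]
  gB <- ref$G[, j]
  if (stats::var(gA) == 0 || stats::var(gB) == 0) {
    stop("monomorphic variant in panel: LD undefined")
  }
  r2 <- stats::cor(gA, gB)^2
  if (isTRUE(ref$phased) && !is.null(ref$H)) {
    hA <- ref$H[, i]
    hB <- ref$H[, j]
    pAB <- mean(hA == 1 & hB == 1)
    dprime <- dprime_from_freqs(pAB, mean(hA), mean(hB))
  } else {
    em <- em_haplotype_freq(gA, gB)
    dprime <- dprime_from_freqs(em$pAB, em$pA, em$pB)
  }
  list(r2 = r2, dprime = dprime)
}

#' Per-variant LD scores
#'
#' For each variant `j`, `l_j = 1 + sum_k adj(r2_jk)` over the other
#' variants `k` on the same chromosome within the window, where
#' `adj(r2) = r2 - (1 - r2)/(n_ref - 2)` is the standard finite-sample bias
#' adjustment; the self term contributes 1 unadjusted.
#'
#' @param ref An `ld_ref` panel.
#' @param window_kb Window half-width in kilobases (default 1000, a 1 Mb
#'   proxy for 1 cM).
#' @return Data frame `chrom`, `pos`, `id`, `ldscore`.
#' @export
ld_scores <- function(ref, window_kb = 1000) {
  map <- ref$map
  n <- ref$n_ref
  if (n < 50) stop("LD score estimation needs a panel of at least 50 samples")
  win <- window_kb * 1000
  ell <- rep(1, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    R2 <- stats::cor(ref$G[, idx, drop = FALSE])^2
    adj <- R2 - (1 - R2) / (n - 2)
    pos <- map$pos[idx]
    close <- abs(outer(pos, pos, "-")) <= win
    diag(close) <- FALSE
    ell[idx] <- 1 + rowSums(adj * close)
  }
  data.frame(chrom = map$chrom, pos = map$pos, id = map$id, ldscore = ell,
             stringsAsFactors = FALSE)
}

#' Greedy p-value LD clumping
#'
#' Classic index-variant selection: among records below the p-value
#' threshold, repeatedly take the most significant remaining variant as an
#' index and absorb every remaining variant on the same chromosome within
#' the window whose `r^2` with the index exceeds the threshold. Ties in p
#' are broken by position, then by effect-allele lexicographic order, so the
#' result is invariant to input row order. Variants absent from the panel
#' are treated as unlinked (with a warning).
#'
#' @param table A `sumstats` or meta-analysis data frame.
#' @param ref An `ld_ref` panel.
#' @param p_threshold Significance threshold for eligibility (default
#'   5e-8).
#' @param r2_threshold LD threshold above which a variant is absorbed by an
#'   index (e.g. 0.001 for cis-instrument selection, 0.05 genome-wide).
#' @param window_kb Clumping window half-width in kb (default 1000; use a
#'   generous window such as 10000 for a cis region).
#' @return A `clump_result` list: `index` (retained records) and
#'   `assignments` (data frame of removed variant, absorbing index, r2).
#' @export
clump <- function(table, ref, p_threshold = 5e-8, r2_threshold = 0.001,
                  window_kb = 1000) {
  df <- as.data.frame(table)
  qual <- df[df$pval < p_threshold, , drop = FALSE]
  if (!nrow(qual)) {
    return(structure(list(index = qual,
                          assignments = data.frame(removed = character(0),
                                                   index = character(0),
                                                   r2 = numeric(0))),
                     class = "clump_result"))
  }
  ord <- order(qual$pval, qual$pos, qual$effect_allele)
  qual <- qual[ord, , drop = FALSE]
  pidx <- panel_index(ref, list(chrom = qual$chrom, pos = qual$pos))
  if (anyNA(pidx)) {
    warning(sum(is.na(pidx)), " variant(s) absent from LD panel; ",
            "treated as unlinked")
  }
  win <- window_kb * 1000
  remaining <- seq_len(nrow(qual))
  kept <- integer(0)
  rem_list <- list()
  while (length(remaining)) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    cand <- remaining[qual$chrom[remaining] == qual$chrom[lead] &
                        abs(qual$pos[remaining] - qual$pos[lead]) <= win]
    cand <- cand[!is.na(pidx[cand])]
    if (length(cand) && !is.na(pidx[lead])) {
      g0 <- ref$G[, pidx[lead]]
      r2 <- as.vector(stats::cor(g0, ref$G[, pidx[cand], drop = FALSE]))^2
      absorb <- cand[!is.na(r2) & r2 > r2_threshold]
      if (length(absorb)) {
        rem_list[[length(rem_list) + 1]] <- data.frame(
          removed = key_of(qual[absorb, , drop = FALSE]),
          index = key_of(qual[lead, , drop = FALSE]),
          r2 = r2[match(absorb, cand)], stringsAsFactors = FALSE
        )
        remaining <- setdiff(remaining, absorb)
      }
    }
  }
  index <- qual[sort(kept), , drop = FALSE]
  rownames(index) <- NULL
  assignments <- if (length(rem_list)) do.call(rbind, rem_list) else
    data.frame(removed = character(0), index = character(0), r2 = numeric(0))
  structure(list(index = index, assignments = assignments),
            class = "clump_result")
}

#' Distance-based locus definition from a genome-wide scan
#'
#' Reduces the genome-wide significant records to physically distinct loci:
#' records below the p-value threshold are taken in order of increasing p,
#' and each new lead absorbs every remaining significant variant on the
#' same chromosome within the window. This is the conventional way of
#' counting "independent loci" in a GWAS report; r-squared-based clumping
#' ([clump()]) serves instrument selection instead.
#'
#' @param table A `sumstats` or meta-analysis data frame.
#' @param p_threshold Significance threshold (default 5e-8).
#' @param window_kb Merging window half-width in kb (default 1000).
#' @return Data frame of lead records, one per locus, sorted by position.
#' @export
define_loci <- function(table, p_threshold = 5e-8, window_kb = 1000) {
  df <- as.data.frame(table)
  qual <- df[df$pval < p_threshold, , drop = FALSE]
  if (!nrow(qual)) return(qual)
  qual <- qual[order(qual$pval, qual$pos, qual$effect_allele), , drop = FALSE]
  win <- window_kb * 1000
  keep <- logical(nrow(qual))
  remaining <- seq_len(nrow(qual))
  while (length(remaining)) {
    lead <- remaining[1]
    keep[lead] <- TRUE
    remaining <- remaining[!(qual$chrom[remaining] == qual$chrom[lead] &
                               abs(qual$pos[remaining] - qual$pos[lead]) <= win)]
  }
  out <- qual[keep, , drop = FALSE]
  out <- out[order(match(out$chrom, VALID_CHROMS), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

key_of <- function(rows) {
  ifelse(!is.na(rows$id) & rows$id != "", rows$id,
         paste0(rows$chrom, ":", rows$pos))
}

#' @export
print.clump_result <- function(x, ...) {
  cat("LD clumping: ", nrow(x$index), " index variant(s), ",
      nrow(x$assignments), " absorbed\n", sep = "")
  invisible(x)
}

#' Dosage correlation matrix for a set of variants
#'
#' @param ref An `ld_ref` panel.
#' @param keys Variant identifiers (see [ld_pair()]).
#' @return Correlation matrix of panel dosages.
#' @export
ld_matrix <- function(ref, keys) {
  i <- panel_index(ref, keys)
  if (anyNA(i)) stop("variant(s) not found in LD panel")
  R <- stats::cor(ref$G[, i, drop = FALSE])
  lab <- ref$map$id[i]
  dimnames(R) <- list(lab, lab)
  R
}
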