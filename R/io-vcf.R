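# VCF import/export for the LD reference panel (phased GT hard calls).

#' Write an LD reference panel as a VCF file
#'
#' Emits a minimal VCFv4.2 file with phased GT fields; the panel's effect
#' allele is written as ALT so dosages count the effect allele.
#'
#' @param ref An `ld_ref` object with phased haplotypes.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_ld_vcf <- function(ref, path) {
  stopifnot(!is.null(ref$H))
  map <- ref$map
  n <- ref$n_ref
  h1 <- t(ref$H[seq(1, 2 * n, by = 2), , drop = FALSE])
  h2 <- t(ref$H[seq(2, 2 * n, by = 2), , drop = FALSE])
  gt <- matrix(paste0(h1, "|", h2), nrow = nrow(map))
  samples <- sprintf("S%04d", seq_len(n))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- cbind(map$chrom, map$pos, map$id, map$other_allele,
                map$effect_allele, ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an LD reference panel from a VCF file
#'
#' Reads hard-called GT genotypes with `vcfR` and builds an [ld_ref()]
#' panel. The ALT allele is taken as the effect (counted) allele. Phased
#' genotypes yield a haplotype matrix (enabling haplotype-counting D');
#' unphased genotypes yield dosages only, and D' falls back to the EM
#' estimate.
#'
#' @param path Path to a VCF file.
#' @return An `ld_ref` object.
#' @export
read_ld_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    effect_allele = fix$ALT, other_allele = fix$REF,
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- all(grepl("|", gt[1, ], fixed = TRUE))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  G <- t(matrix(as.integer(a1) + as.integer(a2), nrow = nrow(gt)))
  H <- NULL
  if (phased) {
    n <- ncol(gt)
    H <- matrix(0L, 2L * n, nrow(gt))
    H[seq(1, 2 * n, by = 2), ] <- t(matrix(as.integer(a1), nrow = nrow(gt)))
    H[seq(2, 2 * n, by = 2), ] <- t(matrix(as.integer(a2), nrow = nrow(gt)))
  }
  ld_ref(map, G, H)
}
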