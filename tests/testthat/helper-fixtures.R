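# Shared fixtures: tiny in-code VCFs, small datasets, and independent
# oracles used to cross-check the package's estimators.

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# 2-breed, hand-specified dataset built directly from matrices
make_dataset <- function(geno, breed, chrom = NULL, pos = NULL,
                         polarity = NULL, annot = NULL) {
  S <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = rep("A", S), alt = rep("G", S), vtype = "SNV",
                      site_id = seq_len(S), allele_index = 1L,
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(geno))),
                        breed = breed, stringsAsFactors = FALSE)
  polarized_dataset(sites, geno, samples, polarity = polarity,
                    annot = annot)
}

# --- independent oracles -------------------------------------------------

# Weir & Cockerham (1984) two-population theta, coded directly from the
# textbook component formulas for a biallelic site
oracle_wc_theta <- function(n1, p1, het1, n2, p2, het2) {
  r <- 2
  h1 <- het1 / n1; h2 <- het2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  one_allele <- function(p1, p2, h1, h2) {
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a = a, d = a + b + hbar / 2)
  }
  comp <- one_allele(p1, p2, h1, h2) + one_allele(1 - p1, 1 - p2, h1, h2)
  unname(comp["a"] / comp["d"])
}

# V_ST by explicit variance decomposition (population variances)
oracle_vst <- function(xa, xb) {
  pv <- function(x) sum((x - mean(x))^2) / length(x)
  vt <- pv(c(xa, xb))
  vs <- (length(xa) * pv(xa) + length(xb) * pv(xb)) / (length(xa) + length(xb))
  (vt - vs) / vt
}

# haplotype counting for two loci when no double heterozygote is present:
# every individual's phase is forced
oracle_hap_count <- function(ga, gb) {
  stopifnot(!any(ga == 1 & gb == 1))
  hap <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_along(ga)) {
    a <- ga[i]; b <- gb[i]
    hap <- hap + switch(paste(a, b),
                        "0 0" = c(0, 0, 0, 2), "0 1" = c(0, 0, 1, 1),
                        "0 2" = c(0, 0, 2, 0), "1 0" = c(0, 1, 0, 1),
                        "1 2" = c(1, 0, 1, 0), "2 0" = c(0, 2, 0, 0),
                        "2 1" = c(1, 1, 0, 0), "2 2" = c(2, 0, 0, 0))
  }
  hap / (2 * length(ga))
}
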