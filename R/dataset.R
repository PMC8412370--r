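#' @keywords internal
"_PACKAGE"

#' Construct a polarized multi-breed genotype dataset
#'
#' The central container of the package: per-site genotypes for one or more
#' breed panels, with optional ancestral/derived orientation (polarity) and
#' per-site annotations.  Multi-allelic sites are decomposed into one record
#' per ALT allele for frequency and load work; the joint allele-index
#' genotypes are retained so that multi-allelic F_ST can be computed over all
#' alleles at once.
#'
#' @param sites data.frame with one row per (site, ALT allele): columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `vtype` (`"SNV"` or `"INDEL"`),
#'   `site_id` (integer index of the underlying VCF record) and
#'   `allele_index` (which ALT allele, 1-based).
#' @param geno integer matrix, `nrow(sites)` x number of samples; entries are
#'   counts of the record's ALT allele per diploid individual (0, 1, 2 or NA).
#' @param samples data.frame with columns `sample_id` and `breed`.
#' @param joint list with matrices `a1`, `a2` (allele indices, 0 = REF) with
#'   one row per underlying site record, used for multi-allelic F_ST; may be
#'   NULL.
#' @param polarity character vector along `sites`: `"alt"` (derived allele is
#'   ALT), `"ref"` (derived allele is REF) or `"unpolarized"`; NA when
#'   polarity has not been set yet.
#' @param annot optional data.frame along `sites` with columns
#'   `effect_class`, `phylop100`, `phylop46`, `phastcon_hit`.
#'
#' @return An object of class `polarized_dataset`.
#' @export
polarized_dataset <- function(sites, geno, samples, joint = NULL,
                              polarity = NULL, annot = NULL) {
  stopifnot(is.data.frame(sites), is.matrix(geno),
            nrow(sites) == nrow(geno),
            nrow(samples) == ncol(geno))
  if (any(sites$pos < 1L)) stop("site positions must be >= 1 (VCF convention)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be in {0, 1, 2, NA}")
  if (is.null(polarity)) polarity <- rep(NA_character_, nrow(sites))
  structure(
    list(sites = sites, geno = geno, samples = samples, joint = joint,
         polarity = polarity, annot = annot),
    class = "polarized_dataset")
}

#' @export
print.polarized_dataset <- function(x, ...) {
  np <- sum(!is.na(x$polarity) & x$polarity != "unpolarized")
  cat("polarized_dataset:",
      nrow(x$sites), "site records,",
      nrow(x$samples), "samples in",
      length(unique(x$samples$breed)), "breed(s)\n")
  cat("  polarity:",
      if (all(is.na(x$polarity))) "unset"
      else sprintf("%d polarized / %d unpolarized", np,
                   sum(x$polarity == "unpolarized", na.rm = TRUE)), "\n")
  cat("  annotations:", if (is.null(x$annot)) "none" else "attached", "\n")
  invisible(x)
}

#' Breeds present in a dataset
#' @param dataset a `polarized_dataset`.
#' @return character vector of breed labels.
#' @export
breeds <- function(dataset) unique(as.character(dataset$samples$breed))

# columns of the genotype matrix belonging to one breed; errors on unknown
.breed_cols <- function(dataset, breed) {
  cols <- which(dataset$samples$breed == breed)
  if (!length(cols))
    stop("unknown breed: ", breed)
  cols
}

# derived-allele count per individual given ALT counts and polarity flag
.derived_counts <- function(g, polarity) {
  if (is.na(polarity) || polarity == "unpolarized")
    return(rep(NA_integer_, length(g)))
  if (polarity == "alt") g else 2L - g
}
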