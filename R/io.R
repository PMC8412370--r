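# Reading genotypes and annotations; polarization against an outgroup;
# per-breed frequency, heterozygosity and SFS summaries.

#' Read a multi-sample VCF into a polarized_dataset
#'
#' Parses a (plain or bgzipped) VCF and assigns each retained sample to a
#' breed via `breed_map`.  Genotypes are coded as ALT-allele counts; missing
#' genotypes are preserved as NA.  Multi-allelic records are decomposed into
#' one row per ALT allele (the joint allele-index genotypes are kept for
#' multi-allelic F_ST).  Polarity is left unset; see [polarize()].
#'
#' @param vcf_source path to a VCF file.
#' @param breed_map data.frame with columns `sample_id` and `breed`, or path
#'   to a TSV with those columns.  Every sample in the VCF must appear.
#' @return A [polarized_dataset()] with polarity unset.
#' @export
read_genotypes <- function(vcf_source, breed_map) {
  if (is.character(breed_map))
    breed_map <- utils::read.table(breed_map, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "breed") %in% names(breed_map)))
    stop("breed_map needs columns sample_id and breed")
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samp <- colnames(gt)
  missing_samp <- setdiff(samp, breed_map$sample_id)
  if (length(missing_samp))
    stop("sample(s) absent from breed_map: ",
         paste(missing_samp, collapse = ", "))
  breed <- breed_map$breed[match(samp, breed_map$sample_id)]

  n_site <- nrow(gt)
  # parse GT strings into two allele-index matrices (0 = REF)
  a1 <- matrix(NA_integer_, n_site, length(samp))
  a2 <- matrix(NA_integer_, n_site, length(samp))
  gtv <- gsub("\\|", "/", as.vector(gt))
  parts <- strsplit(gtv, "/", fixed = TRUE)
  p1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  p2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, "")))
  a1[] <- p1
  a2[] <- p2

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (any(n_alt == 0L) || any(is.na(alt)))
    stop("malformed VCF: record without ALT allele at row ",
         which(n_alt == 0L | is.na(alt))[1L])

  site_id <- rep(seq_len(n_site), n_alt)
  allele_index <- unlist(lapply(n_alt, seq_len))
  alt_vec <- unlist(alt_list)
  ref_vec <- ref[site_id]
  if (any(alt_vec == ref_vec))
    stop("malformed VCF: ALT identical to REF at record ",
         site_id[which(alt_vec == ref_vec)[1L]])
  vtype <- ifelse(nchar(ref_vec) == 1L & nchar(alt_vec) == 1L &
                    alt_vec != "*", "SNV", "INDEL")
  sites <- data.frame(chrom = fix[site_id, "CHROM"],
                      pos = as.integer(fix[site_id, "POS"]),
                      ref = ref_vec, alt = alt_vec, vtype = vtype,
                      site_id = site_id, allele_index = allele_index,
                      stringsAsFactors = FALSE)

  geno <- matrix(NA_integer_, nrow(sites), length(samp))
  for (k in seq_len(nrow(sites))) {
    s <- sites$site_id[k]; ai <- sites$allele_index[k]
    geno[k, ] <- (a1[s, ] == ai) + (a2[s, ] == ai)
  }
  storage.mode(geno) <- "integer"

  polarized_dataset(
    sites = sites, geno = geno,
    samples = data.frame(sample_id = samp, breed = breed,
                         stringsAsFactors = FALSE),
    joint = list(a1 = a1, a2 = a2))
}

#' Polarize a dataset against an outgroup
#'
#' Assigns each site record a derived-allele orientation from a single
#' outgroup individual genotyped at the same sites: outgroup homozygous REF
#' means the ALT allele is derived; homozygous for the record's ALT means the
#' REF allele is derived; heterozygous or missing outgroup genotypes leave
#' the record unpolarized (excluded from load statistics).  Idempotent.
#'
#' @param dataset a [polarized_dataset()].
#' @param outgroup either a path to a single-sample VCF covering the same
#'   sites, or an integer vector along `dataset$sites` of outgroup ALT-allele
#'   counts (0, 1, 2 or NA).
#' @return The dataset with `polarity` set.
#' @export
polarize <- function(dataset, outgroup) {
  if (is.character(outgroup)) {
    og <- read_genotypes(outgroup,
                         data.frame(sample_id = .vcf_samples(outgroup),
                                    breed = "outgroup"))
    key_in <- paste(dataset$sites$chrom, dataset$sites$pos,
                    dataset$sites$ref, dataset$sites$alt)
    key_og <- paste(og$sites$chrom, og$sites$pos, og$sites$ref, og$sites$alt)
    outgroup <- og$geno[match(key_in, key_og), 1L]
  }
  stopifnot(length(outgroup) == nrow(dataset$sites))
  pol <- rep("unpolarized", nrow(dataset$sites))
  pol[!is.na(outgroup) & outgroup == 0L] <- "alt"
  pol[!is.na(outgroup) & outgroup == 2L] <- "ref"
  dataset$polarity <- pol
  dataset
}

.vcf_samples <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE, nrows = 1)
  colnames(v@gt)[-1L]
}

#' Attach a per-site annotation table
#'
#' @param dataset a [polarized_dataset()].
#' @param annot data.frame or TSV path with columns `chrom`, `pos`, `ref`,
#'   `alt`, `effect_category`, `phylop100`, `phylop46`, `phastcon_hit`.
#'   Matched to site records by (chrom, pos, ref, alt).
#' @return The dataset with `annot` attached (raw SNPeff-style categories;
#'   see [classify_sites()] for derived class labels).
#' @export
attach_annotations <- function(dataset, annot) {
  if (is.character(annot))
    annot <- utils::read.table(annot, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "effect_category",
            "phylop100", "phylop46", "phastcon_hit")
  miss <- setdiff(need, names(annot))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  key_in <- paste(dataset$sites$chrom, dataset$sites$pos,
                  dataset$sites$ref, dataset$sites$alt)
  key_an <- paste(annot$chrom, annot$pos, annot$ref, annot$alt)
  dataset$annot <- annot[match(key_in, key_an),
                         c("effect_category", "phylop100", "phylop46",
                           "phastcon_hit")]
  rownames(dataset$annot) <- NULL
  dataset
}

#' Per-breed derived-allele frequency summaries
#'
#' @param dataset a polarized [polarized_dataset()].
#' @param breed breed label.
#' @param min_called minimum number of called alleles for a site to be
#'   usable; defaults to all `2n` alleles of the panel (complete-case rule,
#'   matching the SFS convention).
#' @return data.frame along site records: `derived_freq` (derived-allele
#'   count over called alleles), `n_called` (called alleles),
#'   `hom_derived_fraction` (homozygous-derived individuals over called
#'   individuals) and `usable` (polarized and enough calls).  Frequencies at
#'   unpolarized sites are NA.
#' @export
derived_frequencies <- function(dataset, breed, min_called = NULL) {
  cols <- .breed_cols(dataset, breed)
  if (is.null(min_called)) min_called <- 2L * length(cols)
  if (all(is.na(dataset$polarity))) stop("polarity not set; run polarize()")
  g <- dataset$geno[, cols, drop = FALSE]
  n_called_ind <- rowSums(!is.na(g))
  n_called <- 2L * n_called_ind
  flip <- dataset$polarity == "ref"
  unpol <- dataset$polarity == "unpolarized"
  der_sum <- rowSums(g, na.rm = TRUE)
  der_sum[flip] <- n_called[flip] - der_sum[flip]
  hom_der <- rowSums(g == 2L, na.rm = TRUE)
  hom_der[flip] <- rowSums(g[flip, , drop = FALSE] == 0L, na.rm = TRUE)
  freq <- ifelse(n_called > 0L, der_sum / n_called, NA_real_)
  homf <- ifelse(n_called_ind > 0L, hom_der / n_called_ind, NA_real_)
  freq[unpol] <- NA_real_
  homf[unpol] <- NA_real_
  data.frame(derived_freq = freq, n_called = n_called,
             hom_derived_fraction = homf,
             usable = !unpol & n_called >= min_called)
}

# SNPeff categories constituting loss-of-function variants
LOF_CATEGORIES <- c(
  "CODON_CHANGE_PLUS_CODON_DELETION", "CODON_CHANGE_PLUS_CODON_INSERTION",
  "CODON_DELETION", "CODON_INSERTION", "EXON_DELETED", "FRAME_SHIFT",
  "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_DONOR", "START_LOST", "STOP_GAINED")

#' Classify site records into effect and conservation classes
#'
#' Effect classes `synonymous`, `nonsynonymous` and `LoF` are derived from
#' SNPeff-style categories (LoF is a fixed 10-category list); conservation
#' classes `moderate` and `high` are cut from the 100-vertebrate PhyloP
#' score.  Two published cutoff conventions are supported: `"methods"`
#' (moderate: 2 <= pp < 5; high: pp >= 5, the default) and `"results"`
#' (moderate: 2 < pp <= 5; high: pp > 5).
#'
#' @param annot data.frame with columns `effect_category` and `phylop100`
#'   (e.g. `dataset$annot`), or a `polarized_dataset` with annotations.
#' @param convention `"methods"` or `"results"`.
#' @return data.frame with `effect_class` (one of synonymous, nonsynonymous,
#'   LoF, other) and logical `moderate`, `high` columns.
#' @export
classify_sites <- function(annot, convention = c("methods", "results")) {
  convention <- match.arg(convention)
  if (inherits(annot, "polarized_dataset")) annot <- annot$annot
  if (is.null(annot)) stop("no annotations attached")
  cat_ <- annot$effect_category
  effect <- rep("other", length(cat_))
  effect[cat_ %in% c("SYNONYMOUS_CODING", "SYNONYMOUS_STOP", "synonymous")] <-
    "synonymous"
  effect[cat_ %in% c("NON_SYNONYMOUS_CODING", "nonsynonymous")] <-
    "nonsynonymous"
  effect[cat_ %in% LOF_CATEGORIES] <- "LoF"
  pp <- annot$phylop100
  if (convention == "methods") {
    moderate <- !is.na(pp) & pp >= 2 & pp < 5
    high <- !is.na(pp) & pp >= 5
  } else {
    moderate <- !is.na(pp) & pp > 2 & pp <= 5
    high <- !is.na(pp) & pp > 5
  }
  data.frame(effect_class = effect, moderate = moderate, high = high,
             stringsAsFactors = FALSE)
}

# logical index of site records in a named class
.class_index <- function(dataset, site_class, convention = "methods") {
  if (is.null(site_class)) return(rep(TRUE, nrow(dataset$sites)))
  if (is.logical(site_class)) return(site_class)
  cls <- classify_sites(dataset$annot, convention)
  switch(site_class,
         synonymous = cls$effect_class == "synonymous",
         nonsynonymous = cls$effect_class == "nonsynonymous",
         LoF = cls$effect_class == "LoF",
         moderate = cls$moderate,
         high = cls$high,
         stop("unknown site class: ", site_class))
}

#' Observed heterozygosity of a breed panel
#'
#' Mean fraction of called genotypes that are heterozygous, averaged over
#' biallelic sites segregating in the full dataset.  Observed (not
#' HWE-expected) heterozygosity is used, which is robust under inbreeding.
#'
#' @param dataset a [polarized_dataset()].
#' @param breed breed label.
#' @return a single fraction in [0, 1].
#' @export
heterozygosity <- function(dataset, breed) {
  cols <- .breed_cols(dataset, breed)
  # biallelic: underlying VCF record contributed exactly one ALT record
  biallelic <- stats::ave(dataset$sites$site_id, dataset$sites$site_id,
                          FUN = length) == 1L
  ac <- rowSums(dataset$geno, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(dataset$geno))
  segregating <- ac > 0L & ac < an
  keep <- biallelic & segregating
  g <- dataset$geno[keep, cols, drop = FALSE]
  called <- sum(!is.na(g))
  if (!called) stop("no usable sites for heterozygosity in breed ", breed)
  sum(g == 1L, na.rm = TRUE) / called
}

#' Unfolded site-frequency spectrum of a breed panel
#'
#' Counts of site records by derived-allele count 0..2n.  With
#' `require_complete` (the default, matching the convention that spectra are
#' built from sites sequenced in all individuals) only fully called sites
#' contribute.
#'
#' @param dataset a polarized [polarized_dataset()].
#' @param breed breed label.
#' @param require_complete require all individuals called at a site.
#' @return list with `counts` (length 2n+1 vector indexed 0..2n) and
#'   `n_chromosomes`.
#' @export
compute_sfs <- function(dataset, breed, require_complete = TRUE) {
  cols <- .breed_cols(dataset, breed)
  if (all(is.na(dataset$polarity))) stop("polarity not set; run polarize()")
  n_chrom <- 2L * length(cols)
  g <- dataset$geno[, cols, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  pol <- !is.na(dataset$polarity) & dataset$polarity != "unpolarized"
  keep <- pol & (!require_complete | complete)
  der <- rowSums(g[keep, , drop = FALSE], na.rm = TRUE)
  flip <- dataset$polarity[keep] == "ref"
  ncall <- 2L * rowSums(!is.na(g[keep, , drop = FALSE]))
  der[flip] <- ncall[flip] - der[flip]
  counts <- tabulate(der + 1L, nbins = n_chrom + 1L)
  list(counts = stats::setNames(counts, 0:n_chrom), n_chromosomes = n_chrom)
}

#' Variant-detection concordance between sequencing and array calls
#'
#' @param wgs_calls,array_calls integer genotype matrices (sites x samples,
#'   ALT counts, NA missing) with matching dimnames; rows are sites
#'   interrogated on the array.
#' @return list with `power` (fraction of array-variable sites variable in
#'   the sequencing calls), `accuracy` (fraction of overlapping called
#'   genotypes identical) and `fdr` (fraction of array-interrogated sites
#'   variable in sequencing but not on the array).
#' @export
concordance_metrics <- function(wgs_calls, array_calls) {
  common <- intersect(rownames(wgs_calls), rownames(array_calls))
  if (!length(common)) stop("no overlapping sites between call sets")
  w <- wgs_calls[common, , drop = FALSE]
  a <- array_calls[common, , drop = FALSE]
  variable <- function(m) {
    ac <- rowSums(m, na.rm = TRUE)
    an <- 2L * rowSums(!is.na(m))
    ac > 0L & ac < an
  }
  va <- variable(a); vw <- variable(w)
  if (!any(va)) stop("no variable array sites")
  power <- sum(va & vw) / sum(va)
  both <- !is.na(w) & !is.na(a)
  accuracy <- sum(w[both] == a[both]) / sum(both)
  fdr <- sum(vw & !va) / nrow(array_calls)
  list(power = power, accuracy = accuracy, fdr = fdr)
}
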