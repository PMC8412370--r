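# Seed-reproducible generators for breed genotype panels (frequency-level
# Wright-Fisher with per-class selection), late-onset disease cohorts and
# copy-number matrices, plus plain-text writers so every analysis stage can
# be exercised without external data.

#' Build a simulation configuration
#'
#' Defaults describe two breed panels of 20 diploids drawn from a common
#' ancestral population whose derived-allele frequencies follow a
#' discretized neutral (1/x) spectrum, then evolved independently through a
#' breed-formation bottleneck of 75 generations at effective size 500
#' (frequency-level Wright-Fisher: deterministic selection update, then
#' binomial resampling at 2Ne).  Selection coefficients are per site class;
#' the bundled scenarios set `s = 0.01` (additive) at "high"-class sites
#' and shrink one breed's Ne tenfold.  The cohort generator draws a
#' late-onset disease cohort with logistic risk
#' `alpha + beta_g g + beta_a age + beta_ga g age + beta_s sex`.
#'
#' @param seed integer seed (mandatory; all generators derive their streams
#'   from it).
#' @param n_sites named integer vector of site counts per class.
#' @param breeds named list: breed -> list of epochs, each
#'   `list(Ne =, generations =)`.
#' @param selection named numeric vector of selection coefficients per site
#'   class (cost of the derived allele).
#' @param dominance `"additive"` or `"recessive"`.
#' @param polarization_error probability the emitted outgroup carries the
#'   derived rather than the ancestral allele (default 0).
#' @param samples_per_breed diploid individuals sampled per breed.
#' @param sfs_grid grid size of the discretized ancestral spectrum.
#' @param n_chrom,site_spacing genome layout: sites are tiled across
#'   `n_chrom` chromosomes every `site_spacing` bp.
#' @param cohort list of cohort parameters: `n`, `age_range`,
#'   `marker_freqs` (named), `risk_marker`, `alpha`, `beta_g`, `beta_a`,
#'   `beta_ga`, `beta_s`, `grade_props` (proportions of severity grades 1-3
#'   among affected).
#' @param cnv list: `n_variants`, `n_shifted`, `baseline`, `shift`, `sigma`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_sites = c(synonymous = 25000, high = 25000),
                       breeds = list(
                         breedA = list(list(Ne = 500, generations = 75)),
                         breedB = list(list(Ne = 500, generations = 75))),
                       selection = c(synonymous = 0, nonsynonymous = 0,
                                     LoF = 0, moderate = 0, high = 0),
                       dominance = c("additive", "recessive"),
                       polarization_error = 0,
                       samples_per_breed = 20,
                       sfs_grid = 100,
                       n_chrom = 10, site_spacing = 1000,
                       cohort = list(), cnv = list()) {
  if (missing(seed)) stop("seed is mandatory")
  dominance <- match.arg(dominance)
  stopifnot(all(n_sites >= 0), polarization_error >= 0,
            polarization_error <= 1)
  for (b in breeds) for (ep in b)
    if (ep$Ne < 2) stop("Ne must be >= 2")
  cohort_defaults <- list(
    n = 122, age_range = c(4.8, 15.9),
    marker_freqs = c(NEBL_1 = 0.40, NEBL_2 = 0.35, NEBL_3 = 0.30,
                     NEBL_4 = 0.30, NEBL_5 = 0.25, NEBL_6 = 0.25,
                     SORBS2 = 0.00, LPHN2 = 0.03, HDGFL1 = 0.13,
                     HTR1F = 0.03),
    risk_marker = "NEBL_2",
    alpha = -5.5, beta_g = -1.2, beta_a = 0.6, beta_ga = 0.15,
    beta_s = 0.2,
    grade_props = c(55, 18, 6) / 79)
  cohort <- utils::modifyList(cohort_defaults, cohort)
  cnv_defaults <- list(n_variants = 50, n_shifted = 10, baseline = 2,
                       shift = 2, sigma = 0.3)
  cnv <- utils::modifyList(cnv_defaults, cnv)
  structure(list(seed = as.integer(seed), n_sites = n_sites,
                 breeds = breeds, selection = selection,
                 dominance = dominance,
                 polarization_error = polarization_error,
                 samples_per_breed = samples_per_breed,
                 sfs_grid = sfs_grid, n_chrom = n_chrom,
                 site_spacing = site_spacing, cohort = cohort, cnv = cnv),
            class = "sim_config")
}

#' Relaxed-selection scenario configuration
#'
#' Convenience preset: breedB's bottleneck is 10 times tighter (Ne 50 vs
#' 500) and "high"-class sites carry additive selection `s = 0.01` against
#' the derived allele; synonymous sites stay neutral.  Under these
#' conditions selection is less efficient in the small breed, which
#' therefore retains more derived alleles at constrained sites (R > 1 for
#' the bottlenecked breed at high sites) while the neutral class stays at
#' R = 1.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_bottleneck <- function(seed, ...) {
  sim_config(seed,
             breeds = list(
               breedA = list(list(Ne = 500, generations = 75)),
               breedB = list(list(Ne = 50, generations = 75))),
             selection = c(synonymous = 0, nonsynonymous = 0, LoF = 0,
                           moderate = 0, high = 0.01),
             ...)
}

#' Simulate breed genotype panels (and cohort + copy numbers)
#'
#' Draws ancestral derived-allele frequencies from a discretized 1/x
#' spectrum, evolves each breed independently (per generation: deterministic
#' selection update `dp = -(s/2) p (1-p)` for additive or `-s p^2 (1-p)` for
#' recessive effects, then binomial resampling at 2Ne), samples diploid
#' individuals by binomial draws from the final frequencies, and emits the
#' outgroup's ancestral-state genotypes (flipped with probability
#' `polarization_error`).  REF/ALT orientation is randomized per site so
#' that polarization is genuinely exercised.  Conservation scores are
#' assigned so that [classify_sites()] reproduces the true class labels.
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_study`: `dataset` (unpolarized
#'   [polarized_dataset()]), `outgroup` (ALT-count vector for
#'   [polarize()]), `truth` (per-site class, ancestral and final
#'   frequencies, orientation), `cohort` (see [simulate_cohort()]), `cnv`
#'   (see [simulate_cnv()]) and `config`.
#' @export
simulate_breed_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- rep(names(config$n_sites), config$n_sites)
  S <- length(classes)
  if (!S) stop("no sites configured")
  classes <- sample(classes)  # interleave classes along the genome
  K <- config$sfs_grid
  p0 <- sample(seq_len(K - 1) / K, S, replace = TRUE,
               prob = 1 / seq_len(K - 1))
  s_site <- config$selection[classes]
  s_site[is.na(s_site)] <- 0

  freqs <- list()
  for (b in names(config$breeds)) {
    p <- p0
    for (ep in config$breeds[[b]]) {
      two_ne <- 2L * ep$Ne
      for (g in seq_len(ep$generations)) {
        dp <- if (config$dominance == "additive")
          -(s_site / 2) * p * (1 - p)
        else -s_site * p^2 * (1 - p)
        p <- pmin(1, pmax(0, p + dp))
        p <- stats::rbinom(S, two_ne, p) / two_ne
      }
    }
    freqs[[b]] <- p
  }

  n_ind <- config$samples_per_breed
  derived <- do.call(cbind, lapply(names(config$breeds), function(b) {
    matrix(stats::rbinom(S * n_ind, 2L, rep(freqs[[b]], n_ind)), S, n_ind)
  }))
  samples <- data.frame(
    sample_id = unlist(lapply(names(config$breeds), function(b)
      paste0(b, "_", seq_len(n_ind)))),
    breed = rep(names(config$breeds), each = n_ind),
    stringsAsFactors = FALSE)

  # genome layout and REF/ALT orientation
  chrom <- paste0("chr", rep_len(seq_len(config$n_chrom), S))
  chrom <- chrom[order(rep_len(seq_len(config$n_chrom), S))]
  pos <- unlist(lapply(table(factor(chrom, unique(chrom))), function(k)
    seq_len(k) * config$site_spacing))
  derived_is_alt <- stats::runif(S) < 0.5
  base_pairs <- cbind(c("A", "C", "G", "T")[sample.int(4, S, replace = TRUE)],
                      NA)
  base_pairs[, 2] <- c("A", "C", "G", "T")[
    (match(base_pairs[, 1], c("A", "C", "G", "T")) +
       sample.int(3, S, replace = TRUE) - 1L) %% 4L + 1L]
  geno <- derived
  geno[!derived_is_alt, ] <- 2L - geno[!derived_is_alt, ]
  storage.mode(geno) <- "integer"
  outgroup <- ifelse(derived_is_alt, 0L, 2L)
  flip <- stats::runif(S) < config$polarization_error
  outgroup[flip] <- 2L - outgroup[flip]

  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = base_pairs[, 1], alt = base_pairs[, 2],
                      vtype = "SNV", site_id = seq_len(S),
                      allele_index = 1L, stringsAsFactors = FALSE)
  annot <- .simulated_annotations(classes)
  ds <- polarized_dataset(sites, geno, samples, annot = annot)
  truth <- data.frame(chrom = chrom, pos = as.integer(pos),
                      class = classes, ancestral_freq = p0,
                      derived_is_alt = derived_is_alt,
                      stringsAsFactors = FALSE)
  for (b in names(freqs)) truth[[paste0("freq_", b)]] <- freqs[[b]]

  structure(list(dataset = ds, outgroup = as.integer(outgroup),
                 truth = truth,
                 cohort = simulate_cohort(config),
                 cnv = simulate_cnv(config),
                 config = config),
            class = "simulated_study")
}

# annotation table whose classify_sites() output reproduces `classes`
.simulated_annotations <- function(classes) {
  S <- length(classes)
  cat_ <- rep("INTERGENIC", S)
  pp <- stats::runif(S, -3, 1.9)
  cat_[classes == "synonymous"] <- "SYNONYMOUS_CODING"
  cat_[classes == "nonsynonymous"] <- "NON_SYNONYMOUS_CODING"
  lof <- classes == "LoF"
  cat_[lof] <- sample(LOF_CATEGORIES, sum(lof), replace = TRUE)
  pp[classes == "moderate"] <- stats::runif(sum(classes == "moderate"),
                                            2, 4.99)
  pp[classes == "high"] <- stats::runif(sum(classes == "high"), 5, 10)
  data.frame(effect_category = cat_, phylop100 = pp,
             phylop46 = pp + stats::rnorm(S, 0, 0.5),
             phastcon_hit = FALSE, stringsAsFactors = FALSE)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$truth), "sites,",
      length(unique(x$dataset$samples$breed)), "breeds,",
      nrow(x$cohort), "cohort records,",
      nrow(x$cnv$matrix), "copy-number variants\n")
  invisible(x)
}

#' Simulate a late-onset disease cohort
#'
#' Ages are uniform on the configured range, sex is Bernoulli(0.5),
#' genotypes are binomial(2, f) at the configured marker frequencies, and
#' affection is Bernoulli with probability
#' `plogis(alpha + beta_g g + beta_a age + beta_ga g age + beta_s sex)`
#' where `g` is the risk-marker genotype.  Severity grades 1-3 among
#' affected are assigned by ordered thresholds on the linear predictor,
#' placed at the empirical quantiles implied by `grade_props`.
#'
#' @param config a [sim_config()]; uses `config$cohort` and the seed
#'   (offset so panel and cohort draws are independent).
#' @return cohort data.frame in the standard schema (`Id`, `breed`,
#'   `nationality`, `sex`, `MMVD_status`, `graded_MMVD_status`, `age`,
#'   marker columns).
#' @export
simulate_cohort <- function(config) {
  cc <- config$cohort
  set.seed(config$seed + 1L)
  n <- cc$n
  if (n == 0)
    return(read_cohort(data.frame(Id = character(0), breed = character(0),
                                  nationality = character(0),
                                  sex = integer(0), MMVD_status = integer(0),
                                  graded_MMVD_status = integer(0),
                                  age = numeric(0)), markers = character(0)))
  age <- stats::runif(n, cc$age_range[1], cc$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  markers <- names(cc$marker_freqs)
  geno <- sapply(markers, function(m)
    stats::rbinom(n, 2L, cc$marker_freqs[[m]]))
  geno <- matrix(geno, nrow = n, dimnames = list(NULL, markers))
  g <- geno[, cc$risk_marker]
  eta <- cc$alpha + cc$beta_g * g + cc$beta_a * age +
    cc$beta_ga * g * age + cc$beta_s * sex
  status <- stats::rbinom(n, 1L, stats::plogis(eta))
  graded <- integer(n)
  aff <- which(status == 1L)
  if (length(aff)) {
    cum <- cumsum(cc$grade_props)[1:2] / sum(cc$grade_props)
    thr <- stats::quantile(eta[aff], probs = cum, names = FALSE)
    graded[aff] <- 1L + (eta[aff] > thr[1]) + (eta[aff] > thr[2])
  }
  out <- data.frame(Id = sprintf("dog%03d", seq_len(n)),
                    breed = "dachshund", nationality = "Swedish",
                    sex = sex, MMVD_status = status,
                    graded_MMVD_status = graded,
                    age = round(age, 1), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(geno))
  attr(out, "markers") <- markers
  out
}

#' Simulate a diploid copy-number matrix
#'
#' Gaussian within-breed noise around breed means; the first `n_shifted`
#' variants carry a planted between-breed mean shift (so that V_ST exceeds
#' 0.7 with the default shift of 2 copies at sigma 0.3), the remainder are
#' undifferentiated.  Negative draws are truncated at zero.
#'
#' @param config a [sim_config()]; uses `config$cnv`, the breed names and
#'   `samples_per_breed`.
#' @return list with `matrix` (variants x individuals), `breed` (per
#'   column) and `shifted` (logical per variant).
#' @export
simulate_cnv <- function(config) {
  cv <- config$cnv
  set.seed(config$seed + 2L)
  brds <- names(config$breeds)
  n_ind <- config$samples_per_breed
  nv <- cv$n_variants
  breed_col <- rep(brds, each = n_ind)
  means <- matrix(cv$baseline, nv, length(brds),
                  dimnames = list(NULL, brds))
  shifted <- seq_len(nv) <= cv$n_shifted
  if (length(brds) > 1) means[shifted, 2] <- cv$baseline + cv$shift
  m <- matrix(0, nv, length(breed_col))
  for (j in seq_along(breed_col))
    m[, j] <- pmax(0, stats::rnorm(nv, means[, breed_col[j]], cv$sigma))
  colnames(m) <- paste0(breed_col, "_", rep(seq_len(n_ind),
                                            times = length(brds)))
  list(matrix = m, breed = breed_col, shifted = shifted)
}

#' Write a simulated study to plain-text files
#'
#' Emits `panel.vcf` (all breed samples), `outgroup.vcf`, `breeds.tsv`
#' (sample -> breed), `annotations.tsv`, `cohort.tsv`, `cnv.tsv` and
#' `truth.tsv` under `dir`.  Rerunning with the same study produces
#' byte-identical files.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- study$dataset
  paths <- c(panel = file.path(dir, "panel.vcf"),
             outgroup = file.path(dir, "outgroup.vcf"),
             breeds = file.path(dir, "breeds.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             cohort = file.path(dir, "cohort.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             truth = file.path(dir, "truth.tsv"))
  .write_vcf(paths["panel"], ds$sites, ds$geno, ds$samples$sample_id)
  og <- matrix(study$outgroup, ncol = 1)
  .write_vcf(paths["outgroup"], ds$sites, og, "outgroup")
  utils::write.table(ds$samples, paths["breeds"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  annot_out <- cbind(ds$sites[, c("chrom", "pos", "ref", "alt")], ds$annot)
  utils::write.table(annot_out, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$cohort, paths["cohort"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cnv_out <- cbind(data.frame(variant = paste0("cnv", seq_len(nrow(study$cnv$matrix)))),
                   as.data.frame(study$cnv$matrix))
  utils::write.table(cnv_out, paths["cnv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# minimal VCF 4.2 writer for biallelic SNV records and diploid GTs
.write_vcf <- function(path, sites, geno, sample_ids) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno))
  gt_str[is.na(geno)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
}
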