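# Case-control association of candidate markers with late-onset disease:
# OLS model families (linear probability models for binary outcomes),
# age-stratified subsampling, group allele frequencies, two-locus LD by EM
# and breed-incidence regression.

#' Read a cohort phenotype/genotype table
#'
#' Expects the supplementary-data schema: columns `Id`, `breed`,
#' `nationality`, `sex` (0 female / 1 male), `MMVD_status` (0 healthy / 1
#' affected), `graded_MMVD_status` (0=A, 1=B1, 2=B2, 3=C), `age` and one
#' column per candidate marker.  Marker genotypes may be numeric derived-
#' allele counts (0/1/2) or letter pairs (e.g. "AG"), converted via
#' `marker_defs`.  Invariant violations (graded status inconsistent with
#' binary status, non-positive ages) are reported as warnings per row, not
#' errors.
#'
#' @param tsv_source path to a TSV, or a data.frame.
#' @param markers character vector of marker column names; defaults to all
#'   columns after `age`.
#' @param marker_defs optional data.frame with columns `marker`,
#'   `ancestral`, `derived` for converting letter-pair genotypes to derived-
#'   allele counts.
#' @return data.frame of validated cohort records with numeric marker
#'   columns.
#' @export
read_cohort <- function(tsv_source, markers = NULL, marker_defs = NULL) {
  d <- if (is.character(tsv_source))
    utils::read.table(tsv_source, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else tsv_source
  need <- c("Id", "breed", "nationality", "sex", "MMVD_status",
            "graded_MMVD_status", "age")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(markers)) {
    i_age <- match("age", names(d))
    markers <- if (i_age < length(names(d)))
      names(d)[seq(i_age + 1L, length(names(d)))] else character(0)
  }
  for (m in markers) {
    if (is.character(d[[m]])) {
      if (is.null(marker_defs) || !m %in% marker_defs$marker)
        stop("letter genotypes for marker ", m,
             " need a marker_defs entry")
      def <- marker_defs[marker_defs$marker == m, ][1L, ]
      gt <- toupper(trimws(d[[m]]))
      counts <- vapply(strsplit(gt, ""), function(a) {
        if (!length(a) || any(a %in% c(".", "N", "")))
          return(NA_integer_)
        bad <- setdiff(a, c(def$ancestral, def$derived))
        if (length(bad)) return(NA_integer_)
        sum(a == def$derived)
      }, 0L)
      d[[m]] <- counts
    }
  }
  bad_grade <- which((d$MMVD_status == 0 & d$graded_MMVD_status > 0) |
                       (d$MMVD_status == 1 & d$graded_MMVD_status == 0))
  if (length(bad_grade))
    warning("graded status inconsistent with binary status in row(s): ",
            paste(bad_grade, collapse = ", "))
  bad_age <- which(!(d$age > 0))
  if (length(bad_age))
    warning("non-positive age in row(s): ", paste(bad_age, collapse = ", "))
  attr(d, "markers") <- markers
  d
}

# tidy per-term coefficient table out of an lm fit
.fit_result <- function(fit, outcome) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(outcome = outcome,
         terms = rownames(co),
         coefficients = co[, "Estimate"],
         se = co[, "Std. Error"],
         t = co[, "t value"],
         p = co[, "Pr(>|t|)"],
         adj_r2 = sm$adj.r.squared,
         r2 = sm$r.squared,
         n = length(fit$residuals),
         fit = fit),
    class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat("Linear model for", x$outcome, sprintf("(n = %d)\n", x$n))
  tab <- data.frame(beta = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  cat(sprintf("adj. R^2 = %.4f\n", x$adj_r2))
  invisible(x)
}

#' @export
coef.assoc_fit <- function(object, ...) object$coefficients

#' @export
summary.assoc_fit <- function(object, ...) {
  data.frame(outcome = object$outcome, term = object$terms,
             beta = object$coefficients, se = object$se, t = object$t,
             p = object$p, adj_r2 = object$adj_r2, n = object$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinary least squares association fit
#'
#' Fits `lm(outcome ~ term1 + term2 + ...)` on complete cases.  Binary
#' outcomes are fitted by OLS as linear probability models (not logistic),
#' mirroring the classical lm() usage for case-control screens; genotype
#' terms are additive derived-allele counts.
#'
#' @param records cohort data.frame from [read_cohort()].
#' @param outcome `"status"` (binary) or `"graded_status"`, or any column
#'   name present in `records` (`MMVD_status`/`graded_MMVD_status` aliases
#'   accepted).
#' @param terms character vector of predictor column names (markers, `age`,
#'   `sex`), possibly containing interaction operators (`*`, `:`).
#' @return object of class `assoc_fit` with per-term coefficients, standard
#'   errors, t statistics, p-values, adjusted R-squared and n.
#' @export
ols_fit <- function(records, outcome, terms) {
  ocol <- .outcome_col(records, outcome)
  fml <- stats::reformulate(terms, response = ocol)
  used <- all.vars(fml)
  cc <- stats::complete.cases(records[, used, drop = FALSE])
  dat <- records[cc, , drop = FALSE]
  k <- length(attr(stats::terms(fml), "term.labels"))
  if (nrow(dat) <= k + 1L)
    stop("too few complete cases (", nrow(dat), ") for ", k, " term(s)")
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design: ", paste(
      names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  .fit_result(fit, ocol)
}

.outcome_col <- function(records, outcome) {
  map <- c(status = "MMVD_status", graded_status = "graded_MMVD_status")
  if (outcome %in% names(map)) outcome <- map[[outcome]]
  if (!outcome %in% names(records)) stop("unknown outcome: ", outcome)
  outcome
}

#' Genotype-by-age (and sex) interaction model for graded disease status
#'
#' Fits the full factorial expansion `lm(graded_status ~ genotype*age)` or
#' `lm(graded_status ~ genotype*age*sex)` with additive 0/1/2 genotype
#' coding.  Errors if the marker is not segregating among complete cases.
#'
#' @param records cohort data.frame.
#' @param marker marker column name.
#' @param include_sex also expand by sex (default FALSE).
#' @param outcome outcome column (default graded status).
#' @return object of class `assoc_fit`.
#' @export
interaction_models <- function(records, marker, include_sex = FALSE,
                               outcome = "graded_status") {
  ocol <- .outcome_col(records, outcome)
  g <- records[[marker]]
  used <- stats::complete.cases(records[, c(ocol, marker, "age",
                                            if (include_sex) "sex")])
  if (length(unique(g[used & !is.na(g)])) < 2L)
    stop("marker ", marker, " not segregating in these records")
  terms <- if (include_sex) paste0(marker, " * age * sex")
  else paste0(marker, " * age")
  ols_fit(records, outcome, terms)
}

#' Young-case / old-control subsample association
#'
#' Builds the subset of cases younger than `case_age_max` plus controls
#' older than `control_age_min` (strict inequalities) and fits the
#' univariate linear probability model `status ~ genotype` on it.
#' Tightening both thresholds never adds records.
#'
#' @param records cohort data.frame.
#' @param case_age_max cases must have `age < case_age_max`.
#' @param control_age_min controls must have `age > control_age_min`.
#' @param marker marker column name.
#' @return list with `subset` (the records used), `n_cases`, `n_controls`
#'   and `fit` (an `assoc_fit`).
#' @export
young_case_old_control <- function(records, case_age_max, control_age_min,
                                   marker) {
  stopifnot(case_age_max > 0, control_age_min >= 0)
  is_case <- records$MMVD_status == 1 & records$age < case_age_max
  is_ctrl <- records$MMVD_status == 0 & records$age > control_age_min
  if (!any(is_case)) stop("no cases younger than ", case_age_max)
  if (!any(is_ctrl)) stop("no controls older than ", control_age_min)
  sub <- records[is_case | is_ctrl, , drop = FALSE]
  list(subset = sub, n_cases = sum(is_case), n_controls = sum(is_ctrl),
       fit = ols_fit(sub, "status", marker))
}

#' Derived-allele frequency within a filtered group
#'
#' @param records cohort data.frame.
#' @param marker marker column name (numeric derived-allele counts).
#' @param group_filter logical vector along records, or NULL for all.
#' @return derived-allele count over twice the called individuals.
#' @export
group_allele_freq <- function(records, marker, group_filter = NULL) {
  g <- records[[marker]]
  if (!is.null(group_filter)) g <- g[group_filter]
  g <- g[!is.na(g)]
  if (!length(g)) stop("no called genotypes in group")
  sum(g) / (2 * length(g))
}

#' Two-locus linkage disequilibrium from unphased genotypes by EM
#'
#' Estimates the four haplotype frequencies for a pair of biallelic markers
#' from unphased diploid genotypes by expectation-maximization: only double
#' heterozygotes are phase-ambiguous and are split between the two phase
#' configurations in proportion to the current haplotype-frequency products.
#' Initialization is at linkage equilibrium, making the estimate
#' deterministic.  Convergence: maximum haplotype-frequency change below
#' `tol`.
#'
#' @param records cohort data.frame (or any data.frame of 0/1/2 counts).
#' @param marker_a,marker_b marker column names.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000; exceeding it is an error).
#' @return object of class `ld_pair` with haplotype frequencies `hap`
#'   (AB, Ab, aB, ab where A/B are derived alleles), `d`, `d_prime` (|D'|),
#'   `r2` and `n` (individuals used).
#' @export
ld_em <- function(records, marker_a, marker_b, tol = 1e-8,
                  max_iter = 1000L) {
  ga <- records[[marker_a]]; gb <- records[[marker_b]]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L)
    stop("both markers must be segregating")
  n <- length(ga)
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  # haplotype counts fully determined except for double heterozygotes
  dh <- ga == 1L & gb == 1L
  n_dh <- sum(dh)
  # fixed haplotype contributions from unambiguous genotypes:
  # individual with counts (ga, gb) not both 1 contributes haplotypes
  # deterministically
  fixed <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in which(!dh)) {
    a <- ga[i]; b <- gb[i]
    # allocate b copies of B among the a derived-A haplotypes: without
    # double heterozygosity the phase is forced
    ab_pairs <- switch(paste(a, b),
                       "0 0" = c(0, 0, 0, 2), "0 1" = c(0, 0, 1, 1),
                       "0 2" = c(0, 0, 2, 0), "1 0" = c(0, 1, 0, 1),
                       "1 2" = c(1, 0, 1, 0), "2 0" = c(0, 2, 0, 0),
                       "2 1" = c(1, 1, 0, 0), "2 2" = c(2, 0, 0, 0))
    fixed <- fixed + ab_pairs
  }
  hap <- c(AB = pA * pB, Ab = pA * (1 - pB),
           aB = (1 - pA) * pB, ab = (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("EM did not converge in ", max_iter,
                              " iterations")
    denom <- hap["AB"] * hap["ab"] + hap["Ab"] * hap["aB"]
    w <- if (denom > 0) hap["AB"] * hap["ab"] / denom else 0.5
    counts <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    new_hap <- counts / (2 * n)
    delta <- max(abs(new_hap - hap))
    hap <- new_hap
    if (delta < tol) break
  }
  d <- hap["AB"] - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(d) / dmax else NA_real_
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 hap = hap, d = unname(d), d_prime = unname(d_prime),
                 r2 = unname(r2), n = n, iterations = iter),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("LD %s x %s (n = %d): |D'| = %.3f, r2 = %.3f\n",
              x$marker_a, x$marker_b, x$n, x$d_prime, x$r2))
  cat("haplotype frequencies:",
      paste(sprintf("%s %.3f", names(x$hap), x$hap), collapse = ", "), "\n")
  invisible(x)
}

#' Average pairwise LD over a marker set
#'
#' @param records cohort data.frame.
#' @param markers character vector of marker columns.
#' @return list with `d_prime` and `r2` means over all unordered pairs and
#'   the per-pair table.
#' @export
ld_summary <- function(records, markers) {
  pairs <- utils::combn(markers, 2, simplify = FALSE)
  tab <- do.call(rbind, lapply(pairs, function(pr) {
    x <- ld_em(records, pr[1], pr[2])
    data.frame(marker_a = pr[1], marker_b = pr[2], d_prime = x$d_prime,
               r2 = x$r2, stringsAsFactors = FALSE)
  }))
  list(d_prime = mean(tab$d_prime), r2 = mean(tab$r2), pairs = tab)
}

#' Disease incidence per 10,000 animal-years at risk
#'
#' Per-dog exposure accrues from the later of insurance start and window
#' start to the earliest of first claim, withdrawal and window end; only
#' the first claim per dog is counted.  Incidence per breed is
#' `10000 * first claims / total exposure`.
#'
#' @param claims_table data.frame with `dog_id` and `claim_date` (numeric
#'   time, e.g. decimal years; repeat claims allowed).
#' @param exposure_table data.frame with `dog_id`, `breed`,
#'   `insurance_start`, `insurance_end` (same time scale; `insurance_end`
#'   NA means still insured at window end).
#' @param window_start,window_end observation window.
#' @return data.frame per breed: `first_claims`, `dyar`, `incidence`.
#' @export
incidence_rate <- function(claims_table, exposure_table,
                           window_start, window_end) {
  first_claim <- tapply(claims_table$claim_date, claims_table$dog_id, min)
  ex <- exposure_table
  ex$first_claim <- unname(first_claim[as.character(ex$dog_id)])
  ex$insurance_end[is.na(ex$insurance_end)] <- window_end
  t0 <- pmax(ex$insurance_start, window_start)
  t1 <- pmin(ex$insurance_end, window_end)
  t1 <- pmin(t1, ifelse(is.na(ex$first_claim), Inf, ex$first_claim))
  exposure <- t1 - t0
  neg <- which(exposure < 0 & ex$insurance_start <= window_end &
                 ex$insurance_end >= window_start)
  if (length(neg))
    stop("negative exposure interval for dog(s): ",
         paste(ex$dog_id[neg], collapse = ", "))
  exposure[exposure < 0] <- 0   # insured entirely outside the window
  counted <- !is.na(ex$first_claim) & ex$first_claim >= t0 &
    ex$first_claim <= window_end & exposure > 0
  agg <- function(x, f) tapply(x, ex$breed, f)
  out <- data.frame(breed = names(agg(exposure, sum)),
                    first_claims = as.integer(agg(counted, sum)),
                    dyar = as.numeric(agg(exposure, sum)),
                    stringsAsFactors = FALSE)
  out$incidence <- 10000 * out$first_claims / out$dyar
  rownames(out) <- NULL
  out
}

#' Across-breed incidence on allele-frequency regression
#'
#' Univariate OLS of breed disease incidence on breed allele frequency at a
#' candidate marker, with optional leave-one-breed-out re-fits to gauge the
#' influence of single breeds.
#'
#' @param incidence_by_breed named numeric vector (breed -> incidence) or
#'   data.frame with `breed` and `incidence`.
#' @param allele_freq_by_breed named numeric vector (breed -> derived
#'   allele frequency).
#' @param leave_one_out also fit dropping each breed in turn (default
#'   FALSE).
#' @return an `assoc_fit`; with `leave_one_out`, a list with `fit` and
#'   `loo` (data.frame of slope and p per dropped breed).
#' @export
incidence_regression <- function(incidence_by_breed, allele_freq_by_breed,
                                 leave_one_out = FALSE) {
  if (is.data.frame(incidence_by_breed))
    incidence_by_breed <- stats::setNames(incidence_by_breed$incidence,
                                          incidence_by_breed$breed)
  common <- intersect(names(incidence_by_breed),
                      names(allele_freq_by_breed))
  if (length(common) < 3) stop("need at least 3 breeds with both values")
  d <- data.frame(incidence = incidence_by_breed[common],
                  freq = allele_freq_by_breed[common])
  fit <- .fit_result(stats::lm(incidence ~ freq, data = d), "incidence")
  if (!leave_one_out) return(fit)
  loo <- do.call(rbind, lapply(common, function(b) {
    di <- d[rownames(d) != b, , drop = FALSE]
    if (nrow(di) < 3) return(NULL)
    f <- summary(stats::lm(incidence ~ freq, data = di))$coefficients
    data.frame(dropped = b, beta = f["freq", "Estimate"],
               p = f["freq", "Pr(>|t|)"], stringsAsFactors = FALSE)
  }))
  list(fit = fit, loo = loo)
}
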