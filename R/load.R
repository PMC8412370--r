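# Derived-allele load statistics: sharing sums, R and R^2 ratios with
# weighted block-jackknife inference, Bonferroni correction and
# region-masked re-estimation.

#' Derived-allele sharing sums between two breeds
#'
#' For derived-allele frequency vectors `f_A`, `f_B` over a shared set of
#' sites, the frequency-form sums are `L_{A not B} = sum f_A (1 - f_B)` and
#' `L_{B not A} = sum f_B (1 - f_A)` — the expected numbers of sites at
#' which one chromosome drawn from each breed carries the derived allele in
#' the first breed but the ancestral allele in the second.  A strict
#' presence/absence mode (indicator `f > 0`) is available for sensitivity
#' analysis.
#'
#' @param freqs_a,freqs_b numeric vectors of derived-allele frequencies.
#' @param site_subset optional logical or integer index of sites to include.
#' @param mode `"frequency"` (default) or `"presence"`.
#' @return list with `L_a_not_b`, `L_b_not_a`, `n_sites`.
#' @export
sharing_sums <- function(freqs_a, freqs_b, site_subset = NULL,
                         mode = c("frequency", "presence")) {
  mode <- match.arg(mode)
  stopifnot(length(freqs_a) == length(freqs_b))
  if (!is.null(site_subset)) {
    freqs_a <- freqs_a[site_subset]
    freqs_b <- freqs_b[site_subset]
  }
  if (!length(freqs_a)) stop("empty site subset")
  if (mode == "presence") {
    freqs_a <- as.numeric(freqs_a > 0)
    freqs_b <- as.numeric(freqs_b > 0)
  }
  list(L_a_not_b = sum(freqs_a * (1 - freqs_b)),
       L_b_not_a = sum(freqs_b * (1 - freqs_a)),
       n_sites = length(freqs_a))
}

#' Weighted block jackknife over contiguous genomic blocks
#'
#' Splits sites (in genomic order) into `n_blocks` contiguous blocks of
#' approximately equal numbers of contributing sites, recomputes the
#' statistic leaving out one block at a time, and combines the replicates
#' with weights proportional to the number of sites removed (weighted
#' delete-one jackknife of Busing et al. 1999).
#'
#' @param statistic_fn function taking an integer index vector of retained
#'   sites and returning a scalar.
#' @param n_sites total number of contributing sites, assumed already in
#'   genomic order.
#' @param n_blocks number of contiguous blocks (default 50).
#' @return list with `point`, `leave_one_out`, `block_sizes`, `se`, `ci95`.
#' @export
weighted_block_jackknife <- function(statistic_fn, n_sites, n_blocks = 50) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (n_sites < n_blocks)
    stop("fewer usable sites (", n_sites, ") than blocks (", n_blocks, ")")
  block <- .contiguous_blocks(n_sites, n_blocks)
  m <- tabulate(block, nbins = n_blocks)
  theta <- statistic_fn(seq_len(n_sites))
  loo <- vapply(seq_len(n_blocks),
                function(j) statistic_fn(which(block != j)), 0)
  g <- n_blocks; n <- n_sites; h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  tau <- h * theta - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  se <- sqrt(var_j)
  list(point = theta, leave_one_out = loo, block_sizes = m, se = se,
       ci95 = c(theta - 1.959963984540054 * se,
                theta + 1.959963984540054 * se))
}

# assign n sites (already ordered) to k contiguous blocks of ~equal size
.contiguous_blocks <- function(n, k) {
  as.integer(ceiling(seq_len(n) / n * k))
}

#' Relative derived-allele load ratio R between two breeds
#'
#' `R_{A/B} = L_{A not B} / L_{B not A}` compares the relative number of
#' derived (potentially deleterious) alleles accumulated in breed A versus
#' breed B since their split; under equal accumulation R = 1.  Standard
#' errors come from a 50-block weighted jackknife over the genome;
#' significance is the two-sided normal p for the Z-score `(R - 1)/se`.
#'
#' Sites are used pairwise complete-case: both breeds must satisfy the
#' `min_called` rule (default: all alleles called) and the record must be
#' polarized.
#'
#' @param dataset a polarized, annotated [polarized_dataset()].
#' @param breed_a,breed_b breed labels.
#' @param site_class one of `"synonymous"`, `"nonsynonymous"`, `"LoF"`,
#'   `"moderate"`, `"high"`, a logical vector along site records, or NULL
#'   for all polarized sites.
#' @param n_blocks jackknife blocks (default 50).
#' @param statistic `"R"` (frequency form) or `"R2"` (ratio of
#'   homozygous-derived sharing sums, the recessive-load proxy).
#' @param mode sharing-sum mode, see [sharing_sums()].
#' @param min_called per-breed minimum called alleles, see
#'   [derived_frequencies()].
#' @param family_size Bonferroni family for the corrected p (default:
#'   number of breed pairs in the dataset within one site class).
#' @param mask optional mask intervals (data.frame `chrom`, `start`, `end`,
#'   0-based half-open); overlapping sites are removed before estimation.
#' @return object of class `load_ratio`.
#' @export
r_ab <- function(dataset, breed_a, breed_b, site_class = NULL,
                 n_blocks = 50, statistic = c("R", "R2"),
                 mode = c("frequency", "presence"), min_called = NULL,
                 family_size = NULL, mask = NULL) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  fa <- derived_frequencies(dataset, breed_a, min_called)
  fb <- derived_frequencies(dataset, breed_b, min_called)
  keep <- fa$usable & fb$usable & .class_index(dataset, site_class)
  if (!is.null(mask))
    keep <- keep & !.in_intervals(dataset$sites$chrom, dataset$sites$pos,
                                  normalize_mask(mask))
  if (!any(keep)) stop("no usable sites for this comparison")
  ord <- order(dataset$sites$chrom[keep], dataset$sites$pos[keep])
  if (statistic == "R") {
    xa <- fa$derived_freq[keep][ord]
    xb <- fb$derived_freq[keep][ord]
  } else {
    xa <- fa$hom_derived_fraction[keep][ord]
    xb <- fb$hom_derived_fraction[keep][ord]
  }
  ratio_fn <- function(idx) {
    s <- sharing_sums(xa, xb, idx, mode)
    if (s$L_b_not_a == 0) stop("ratio undefined: L_b_not_a = 0")
    s$L_a_not_b / s$L_b_not_a
  }
  jk <- weighted_block_jackknife(ratio_fn, length(xa), n_blocks)
  sums <- sharing_sums(xa, xb, NULL, mode)
  value <- jk$point
  z <- if (jk$se > 0) (value - 1) / jk$se else if (value == 1) 0 else
    sign(value - 1) * Inf
  p <- 2 * stats::pnorm(-abs(z))
  if (is.null(family_size)) {
    nb <- length(breeds(dataset))
    family_size <- max(1L, nb * (nb - 1L) / 2L)
  }
  structure(
    list(breed_a = breed_a, breed_b = breed_b,
         site_class = if (is.character(site_class)) site_class else "custom",
         statistic_kind = statistic, mode = mode,
         L_a_not_b = sums$L_a_not_b, L_b_not_a = sums$L_b_not_a,
         value = value, se = jk$se, ci95 = jk$ci95, z = z, p = p,
         p_bonf = bonferroni_adjust(p, family_size),
         family_size = family_size, n_sites = sums$n_sites,
         jackknife = jk),
    class = "load_ratio")
}

#' Homozygous derived-allele load ratio R^2 between two breeds
#'
#' Convenience wrapper for [r_ab()] with `statistic = "R2"`: the sharing
#' sums use observed homozygous-derived individual fractions instead of
#' allele frequencies, contrasting the relative probability that one breed
#' is homozygous for the derived allele while the other is not — a proxy
#' for recessive load.  Observed (not HWE-expected) homozygote fractions are
#' used because breed panels are inbred.
#'
#' @inheritParams r_ab
#' @return object of class `load_ratio`.
#' @export
r2_ab <- function(dataset, breed_a, breed_b, site_class = NULL,
                  n_blocks = 50, min_called = NULL, family_size = NULL,
                  mask = NULL) {
  r_ab(dataset, breed_a, breed_b, site_class, n_blocks, statistic = "R2",
       min_called = min_called, family_size = family_size, mask = mask)
}

#' Re-estimate R after masking genomic regions
#'
#' Removes site records overlapping the mask (e.g. regions under recent
#' selection) and re-runs [r_ab()], including a fresh jackknife partition of
#' the remaining sites.
#'
#' @inheritParams r_ab
#' @param mask data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   or a BED path.
#' @return object of class `load_ratio`.
#' @export
masked_r_ab <- function(dataset, breed_a, breed_b, site_class = NULL,
                        mask, n_blocks = 50, ...) {
  if (is.character(mask)) mask <- read_bed(mask)
  r_ab(dataset, breed_a, breed_b, site_class, n_blocks, mask = mask, ...)
}

#' @export
print.load_ratio <- function(x, ...) {
  cat(sprintf("%s_{%s/%s} at %s sites (n = %d)\n",
              if (x$statistic_kind == "R") "R" else "R2",
              x$breed_a, x$breed_b, x$site_class, x$n_sites))
  cat(sprintf("  value = %.4f  (95%% CI %.4f-%.4f)  se = %.4g\n",
              x$value, x$ci95[1], x$ci95[2], x$se))
  cat(sprintf("  Z = %.3f  p = %.3g  Bonferroni (family %d) p = %.3g\n",
              x$z, x$p, x$family_size, x$p_bonf))
  invisible(x)
}

#' @export
summary.load_ratio <- function(object, ...) {
  data.frame(breed_a = object$breed_a, breed_b = object$breed_b,
             site_class = object$site_class,
             statistic = object$statistic_kind,
             L_a_not_b = object$L_a_not_b, L_b_not_a = object$L_b_not_a,
             value = object$value, se = object$se,
             ci_lo = object$ci95[1], ci_hi = object$ci95[2],
             z = object$z, p = object$p, p_bonf = object$p_bonf,
             n_sites = object$n_sites, stringsAsFactors = FALSE)
}

#' @export
confint.load_ratio <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$value - q * object$se, object$value + q * object$se),
              nrow = 1,
              dimnames = list("value",
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

#' Bonferroni correction with an explicit family size
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param family_size number of tests in the family; must be at least
#'   `length(p_values)`.
#' @return corrected p-values, `min(1, p * family_size)`.
#' @export
bonferroni_adjust <- function(p_values, family_size) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (family_size < length(p_values))
    stop("family_size must be >= number of tests")
  stats::p.adjust(p_values, method = "bonferroni", n = family_size)
}

#' All-pairs load table for one or more site classes
#'
#' Runs [r_ab()] (or the R^2 variant) for every unordered breed pair and
#' each requested site class; Bonferroni family defaults to the number of
#' pairs within one class.
#'
#' @inheritParams r_ab
#' @param site_classes character vector of class labels.
#' @return data.frame, one row per (pair, class).
#' @export
load_table <- function(dataset, site_classes = "high", statistic = "R",
                       n_blocks = 50, min_called = NULL, mask = NULL) {
  brds <- breeds(dataset)
  pairs <- utils::combn(brds, 2, simplify = FALSE)
  fam <- length(pairs)
  rows <- lapply(site_classes, function(cl) {
    do.call(rbind, lapply(pairs, function(pr) {
      summary(r_ab(dataset, pr[1], pr[2], cl, n_blocks, statistic,
                   min_called = min_called, family_size = fam, mask = mask))
    }))
  })
  do.call(rbind, rows)
}

#' Normalize mask intervals
#'
#' Sorts 0-based half-open intervals and merges overlapping or touching
#' ones per chromosome.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return normalized data.frame.
#' @export
normalize_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!nrow(intervals)) return(intervals)
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  out <- list()
  cur <- intervals[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(intervals))[-1]) {
    r <- intervals[i, ]
    if (r$chrom == cur$chrom && r$start <= cur$end) {
      cur$end <- max(cur$end, r$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- r[, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# membership of 1-based positions in 0-based half-open intervals
.in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  if (is.null(intervals) || !nrow(intervals)) return(hit)
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    (pos - 1L) >= intervals$start[i] &
                    (pos - 1L) < intervals$end[i])
  }
  hit
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open; first three columns used, an
#'   optional fourth column is kept as `name`).
#' @return data.frame with `chrom`, `start`, `end` and possibly `name`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  bed[, seq_len(min(4L, ncol(bed))), drop = FALSE]
}
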