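# Per-site differentiation (Weir-Cockerham F_ST, copy-number V_ST),
# multi-stage candidate-variant prioritization and selection-window merging.

#' Weir & Cockerham's two-population F_ST estimator from counts
#'
#' The 1984 theta estimator computed from per-breed allele counts and
#' per-allele heterozygote counts.  For multi-allelic sites the variance
#' components are summed over alleles before forming the ratio.  Negative
#' estimates are retained (they carry information when averaged); the
#' estimator is undefined (NA) when both breeds are monomorphic for the
#' same allele.
#'
#' @param counts_a,counts_b lists with elements `alleles` (vector of allele
#'   counts, one entry per allele, summing to 2n), `het` (per-allele counts
#'   of individuals carrying exactly one copy) and `n` (called diploid
#'   individuals).
#' @return a single value (possibly negative), or NA when undefined.
#' @export
wc_fst <- function(counts_a, counts_b) {
  stopifnot(length(counts_a$alleles) == length(counts_b$alleles))
  n1 <- counts_a$n; n2 <- counts_b$n
  if (n1 < 1 || n2 < 1) return(NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  a_sum <- 0; d_sum <- 0
  for (u in seq_along(counts_a$alleles)) {
    p1 <- counts_a$alleles[u] / (2 * n1)
    p2 <- counts_b$alleles[u] / (2 * n2)
    h1 <- counts_a$het[u] / n1
    h2 <- counts_b$het[u] / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    d_sum <- d_sum + a + b + cc
  }
  if (d_sum == 0) return(NA_real_)
  a_sum / d_sum
}

# per-breed biallelic counts for one genotype row (ALT counts)
.site_counts <- function(g) {
  n <- sum(!is.na(g))
  ac_alt <- sum(g, na.rm = TRUE)
  het <- sum(g == 1L, na.rm = TRUE)
  list(alleles = c(2 * n - ac_alt, ac_alt), het = c(het, het), n = n)
}

#' Per-site pairwise and average pairwise F_ST across breed panels
#'
#' Computes Weir-Cockerham F_ST for every unordered breed pair at every
#' underlying site (multi-allelic sites use all alleles jointly), plus each
#' breed's average over its pairwise values (the mean over defined pairs;
#' NA when no pair is defined).
#'
#' @param dataset a [polarized_dataset()].
#' @return list of class `diff_records` with `pairwise` (matrix site
#'   records x pair labels "A|B") and `avg_pairwise_fst` (matrix site
#'   records x breeds).  Rows follow `dataset$sites` (per-ALT records of the
#'   same underlying site share values).
#' @export
fst_scan <- function(dataset) {
  brds <- breeds(dataset)
  pairs <- utils::combn(brds, 2, simplify = FALSE)
  pair_lab <- vapply(pairs, paste, "", collapse = "|")
  site_ids <- unique(dataset$sites$site_id)
  n_alt <- table(dataset$sites$site_id)
  pw <- matrix(NA_real_, length(site_ids), length(pairs),
               dimnames = list(NULL, pair_lab))
  cols_by_breed <- lapply(brds, function(b) .breed_cols(dataset, b))
  names(cols_by_breed) <- brds

  bi <- n_alt[as.character(site_ids)] == 1L
  rec_of_site <- match(site_ids, dataset$sites$site_id)
  for (k in seq_along(pairs)) {
    ca <- cols_by_breed[[pairs[[k]][1]]]
    cb <- cols_by_breed[[pairs[[k]][2]]]
    # fast vectorized path for biallelic sites
    gbA <- dataset$geno[rec_of_site[bi], ca, drop = FALSE]
    gbB <- dataset$geno[rec_of_site[bi], cb, drop = FALSE]
    pw[bi, k] <- .wc_fst_vec(gbA, gbB)
    for (si in which(!bi)) {
      s <- site_ids[si]
      rows <- which(dataset$sites$site_id == s)
      k_all <- max(dataset$sites$allele_index[rows]) + 1L
      cnt <- function(cols) {
        a1 <- dataset$joint$a1[s, cols]; a2 <- dataset$joint$a2[s, cols]
        ok <- !is.na(a1) & !is.na(a2)
        alleles <- tabulate(c(a1[ok], a2[ok]) + 1L, nbins = k_all)
        het <- vapply(seq_len(k_all) - 1L, function(u)
          sum((a1[ok] == u) != (a2[ok] == u)), 0L)
        list(alleles = alleles, het = het, n = sum(ok))
      }
      pw[si, k] <- wc_fst(cnt(ca), cnt(cb))
    }
  }
  avg <- matrix(NA_real_, length(site_ids), length(brds),
                dimnames = list(NULL, brds))
  for (b in brds) {
    inpair <- vapply(pairs, function(pr) b %in% pr, TRUE)
    avg[, b] <- rowMeans(pw[, inpair, drop = FALSE], na.rm = TRUE)
    avg[rowSums(!is.na(pw[, inpair, drop = FALSE])) == 0L, b] <- NA_real_
  }
  # expand from underlying sites to per-ALT records
  expand <- match(dataset$sites$site_id, site_ids)
  structure(list(pairwise = pw[expand, , drop = FALSE],
                 avg_pairwise_fst = avg[expand, , drop = FALSE]),
            class = "diff_records")
}

# vectorized biallelic Weir-Cockerham theta over rows of ALT-count matrices
.wc_fst_vec <- function(gA, gB) {
  n1 <- rowSums(!is.na(gA)); n2 <- rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gB == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  comp <- function(p1, p2, h1, h2) {
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    list(a = a, d = a + b + cc)
  }
  cref <- comp(1 - p1, 1 - p2, h1, h2)
  calt <- comp(p1, p2, h1, h2)
  num <- cref$a + calt$a
  den <- cref$d + calt$d
  out <- num / den
  out[den == 0 | n1 < 1 | n2 < 1] <- NA_real_
  out
}

#' Average pairwise F_ST for a focal breed
#'
#' @param records a `diff_records` object from [fst_scan()].
#' @param focal_breed breed label.
#' @return numeric vector along site records (mean over defined pairs
#'   involving the focal breed; NA when none defined).
#' @export
avg_pairwise_fst <- function(records, focal_breed) {
  if (!focal_breed %in% colnames(records$avg_pairwise_fst))
    stop("unknown breed: ", focal_breed)
  records$avg_pairwise_fst[, focal_breed]
}

#' V_ST copy-number differentiation between two breeds
#'
#' `V_ST = (V_T - V_S) / V_T` where `V_T` is the variance of diploid copy
#' number pooled over the pair and `V_S` the size-weighted mean of the
#' within-breed variances.  Population (denominator N) variances are used so
#' that identical within- and pooled distributions give exactly zero.
#'
#' @param copy_numbers numeric vector (or one row of a copy-number matrix).
#' @param breed_labels breed label per individual.
#' @param pair character vector of the two breeds to compare.
#' @return a single value, or NA when the total variance is zero.
#' @export
vst <- function(copy_numbers, breed_labels, pair) {
  stopifnot(length(pair) == 2)
  xa <- copy_numbers[breed_labels == pair[1]]
  xb <- copy_numbers[breed_labels == pair[2]]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) < 2 || length(xb) < 2)
    stop("V_ST needs at least 2 individuals per breed")
  popvar <- function(x) mean((x - mean(x))^2)
  vt <- popvar(c(xa, xb))
  if (vt == 0) return(NA_real_)
  vs <- (length(xa) * popvar(xa) + length(xb) * popvar(xb)) /
    (length(xa) + length(xb))
  (vt - vs) / vt
}

#' Per-variant average pairwise V_ST across breeds
#'
#' @param cnv numeric matrix, variants x individuals, of diploid copy
#'   numbers.
#' @param breed_labels breed per column.
#' @param focal_breed breed whose pairwise average is wanted.
#' @return numeric vector of mean V_ST over defined pairs per variant.
#' @export
avg_pairwise_vst <- function(cnv, breed_labels, focal_breed) {
  others <- setdiff(unique(breed_labels), focal_breed)
  if (!length(others)) stop("need at least two breeds")
  vals <- sapply(others, function(b)
    apply(cnv, 1L, function(x) vst(x, breed_labels, c(focal_breed, b))))
  vals <- matrix(vals, nrow = nrow(cnv))
  out <- rowMeans(vals, na.rm = TRUE)
  out[rowSums(!is.na(vals)) == 0L] <- NA_real_
  out
}

#' Stage-1 candidate variants: high-frequency derived, differentiated,
#' conserved
#'
#' Keeps site records where (i) the derived allele is at high frequency in
#' the focal breed (at least `freq_min`) and strictly highest among all
#' breeds, (ii) the focal breed's average pairwise F_ST is at least
#' `fst_min`, and (iii) the site is conserved (PhyloP 100-vertebrate score
#' at least `phylop_min` for SNVs and indels).  Idempotent: re-filtering the
#' output changes nothing.
#'
#' @param dataset a polarized, annotated [polarized_dataset()].
#' @param records a `diff_records` from [fst_scan()].
#' @param focal_breed breed label.
#' @param fst_min average pairwise F_ST cutoff (default 0.7).
#' @param freq_min derived-allele frequency cutoff in the focal breed
#'   (default 0.7).
#' @param phylop_min conservation cutoff (default 2).
#' @return data.frame of candidate variants: site coordinates, per-breed
#'   derived frequencies, `avg_pairwise_fst`, conservation scores,
#'   `effect_class` and a `provenance` column of applied rule labels.
#' @export
stage1_candidates <- function(dataset, records, focal_breed,
                              fst_min = 0.7, freq_min = 0.7,
                              phylop_min = 2) {
  brds <- breeds(dataset)
  freqs <- sapply(brds, function(b)
    derived_frequencies(dataset, b)$derived_freq)
  freqs <- matrix(freqs, ncol = length(brds),
                  dimnames = list(NULL, brds))
  f_focal <- freqs[, focal_breed]
  others <- freqs[, setdiff(brds, focal_breed), drop = FALSE]
  highest <- f_focal > apply(others, 1L, max)
  afst <- avg_pairwise_fst(records, focal_breed)
  pp100 <- if (!is.null(dataset$annot)) dataset$annot$phylop100 else
    rep(NA_real_, nrow(dataset$sites))
  keep <- !is.na(f_focal) & f_focal >= freq_min & highest &
    !is.na(afst) & afst >= fst_min &
    !is.na(pp100) & pp100 >= phylop_min
  keep[is.na(keep)] <- FALSE
  out <- data.frame(dataset$sites[keep, c("chrom", "pos", "ref", "alt",
                                          "vtype", "site_id"),
                                  drop = FALSE],
                    derived_freq = f_focal[keep],
                    avg_pairwise_fst = afst[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, freqs[keep, , drop = FALSE])
  if (!is.null(dataset$annot)) {
    out$phylop100 <- dataset$annot$phylop100[keep]
    out$phylop46 <- dataset$annot$phylop46[keep]
    cls <- classify_sites(dataset$annot)
    out$effect_class <- cls$effect_class[keep]
  }
  out$focal_breed <- rep(focal_breed, nrow(out))
  out$provenance <- rep("stage1", nrow(out))
  rownames(out) <- NULL
  out
}

#' Prioritize candidates by gene proximity and conservation
#'
#' `mode = "coding"` keeps candidates at highly conserved sites (100-
#' vertebrate PhyloP above 5) within 5 kb of a curated heart-function gene;
#' `mode = "regulatory"` keeps candidates at moderately or highly conserved
#' sites (100-vertebrate or 46-mammal PhyloP at least 2) within 5 kb of a
#' gene from a disease-downregulated list.  Gene spans are extended by
#' `flank` bp on both sides with half-open arithmetic.  Output rows are a
#' subset of the input; provenance grows by "mode:gene".
#'
#' @param candidates data.frame from [stage1_candidates()].
#' @param gene_intervals data.frame `chrom`, `start`, `end` (0-based
#'   half-open), `name`, or a BED path.
#' @param mode `"coding"` or `"regulatory"`.
#' @param gene_list character vector of gene names to consider (the curated
#'   heart-function list or the downregulated-gene list); must be non-empty.
#' @param flank proximity window in bp (default 5000).
#' @return filtered candidate data.frame with `gene` and `gene_distance`
#'   columns appended.
#' @export
prioritize_by_gene <- function(candidates, gene_intervals,
                               mode = c("coding", "regulatory"),
                               gene_list, flank = 5000L) {
  mode <- match.arg(mode)
  if (missing(gene_list) || !length(gene_list)) stop("empty gene list")
  if (is.character(gene_intervals)) gene_intervals <- read_bed(gene_intervals)
  genes <- gene_intervals[gene_intervals$name %in% gene_list, , drop = FALSE]
  if (!nrow(candidates)) return(cbind(candidates, gene = character(0),
                                      gene_distance = integer(0)))
  cons <- if (mode == "coding") {
    !is.na(candidates$phylop100) & candidates$phylop100 > 5
  } else {
    (!is.na(candidates$phylop100) & candidates$phylop100 >= 2) |
      (!is.na(candidates$phylop46) & candidates$phylop46 >= 2)
  }
  gene <- rep(NA_character_, nrow(candidates))
  dist <- rep(NA_integer_, nrow(candidates))
  p0 <- candidates$pos - 1L  # 0-based position
  for (i in seq_len(nrow(genes))) {
    lo <- genes$start[i] - flank
    hi <- genes$end[i] + flank
    hit <- candidates$chrom == genes$chrom[i] & p0 >= lo & p0 < hi &
      is.na(gene)
    if (!any(hit)) next
    d <- pmax(0L, pmax(genes$start[i] - p0[hit],
                       p0[hit] - (genes$end[i] - 1L)))
    gene[hit] <- genes$name[i]
    dist[hit] <- d
  }
  keep <- cons & !is.na(gene)
  out <- candidates[keep, , drop = FALSE]
  out$gene <- gene[keep]
  out$gene_distance <- dist[keep]
  out$provenance <- paste(out$provenance, paste0(mode, ":", out$gene),
                          sep = ";")
  rownames(out) <- NULL
  out
}

#' Scan a genomic interval for conserved non-coding candidates
#'
#' Restricts stage-1 candidates to conserved non-coding records inside a
#' single interval (1-based start, half-open end: a variant whose position
#' equals `end` is excluded).
#'
#' @param candidates data.frame from [stage1_candidates()].
#' @param chrom,start,end the interval.
#' @return filtered candidate data.frame with provenance grown by "region".
#' @export
region_scan <- function(candidates, chrom, start, end) {
  if (!nrow(candidates)) return(candidates)
  noncoding <- !candidates$effect_class %in%
    c("synonymous", "nonsynonymous", "LoF")
  keep <- candidates$chrom == chrom & candidates$pos >= start &
    candidates$pos < end & noncoding
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out))
    out$provenance <- paste(out$provenance,
                            sprintf("region:%s:%d-%d", chrom, start, end),
                            sep = ";")
  rownames(out) <- NULL
  out
}

#' Merge top-scoring selection-scan windows into regions
#'
#' Selects the top fraction of tiled composite-likelihood-ratio windows
#' (ties at the threshold all included), concatenates adjacent selected
#' windows, then aggregates concatenated runs whose gap is at most
#' `join_dist`.  Output regions are sorted, non-overlapping and carry the
#' maximum score of their member windows.
#'
#' @param window_scores data.frame with `chrom`, `start` (0-based window
#'   start) and `clr` score; windows are assumed tiled and non-overlapping.
#' @param top_frac fraction of windows to select (default 0.05).
#' @param window_size window width in bp (default 10000).
#' @param join_dist maximum gap between concatenated runs to aggregate
#'   (default 100000).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `max_clr`.
#' @export
merge_selection_windows <- function(window_scores, top_frac = 0.05,
                                    window_size = 10000L,
                                    join_dist = 100000L) {
  if (!nrow(window_scores)) stop("empty window score table")
  k <- ceiling(top_frac * nrow(window_scores))
  thr <- sort(window_scores$clr, decreasing = TRUE)[k]
  sel <- window_scores[window_scores$clr >= thr, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  sel$end <- sel$start + window_size
  # concatenate adjacent windows, then aggregate runs within join_dist
  runs <- aggregate_regions(sel[, c("chrom", "start", "end")], 0L,
                            sel$clr)
  aggregate_regions(runs[, c("chrom", "start", "end")], join_dist,
                    runs$max_clr)
}

#' Aggregate sorted regions whose gap does not exceed a join distance
#'
#' Idempotent once all remaining gaps exceed `join_dist`.
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param join_dist maximum gap to bridge (0 joins only touching regions).
#' @param scores optional per-region score carried as `max_clr`.
#' @return aggregated data.frame `chrom`, `start`, `end`, `max_clr`.
#' @export
aggregate_regions <- function(regions, join_dist = 0L, scores = NULL) {
  if (is.null(scores)) {
    scores <- if ("max_clr" %in% names(regions)) regions$max_clr else
      rep(NA_real_, nrow(regions))
  }
  o <- order(regions$chrom, regions$start)
  regions <- regions[o, , drop = FALSE]
  scores <- scores[o]
  out_c <- character(0); out_s <- numeric(0); out_e <- numeric(0)
  out_m <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    if (length(out_c) &&
        regions$chrom[i] == out_c[length(out_c)] &&
        regions$start[i] - out_e[length(out_e)] <= join_dist) {
      j <- length(out_c)
      out_e[j] <- max(out_e[j], regions$end[i])
      out_m[j] <- max(out_m[j], scores[i], na.rm = TRUE)
    } else {
      out_c <- c(out_c, regions$chrom[i])
      out_s <- c(out_s, regions$start[i])
      out_e <- c(out_e, regions$end[i])
      out_m <- c(out_m, scores[i])
    }
  }
  data.frame(chrom = out_c, start = out_s, end = out_e, max_clr = out_m,
             stringsAsFactors = FALSE)
}
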