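# Weir-Cockerham F_ST, V_ST, candidate prioritization and selection-window
# merging.

test_that("wc_fst matches the component-formula oracle and its fixed
           points", {
  # fixed difference, 20 diploids each, no heterozygotes
  ca <- list(alleles = c(40, 0), het = c(0, 0), n = 20)
  cb <- list(alleles = c(0, 40), het = c(0, 0), n = 20)
  expect_equal(wc_fst(ca, cb), 1.0)
  # equal frequencies and het counts -> no between component, value <= 0
  ce <- list(alleles = c(20, 20), het = c(8, 8), n = 20)
  expect_lte(wc_fst(ce, ce), 0)
  # textbook-formula oracle on an asymmetric configuration
  ca2 <- list(alleles = c(30, 10), het = c(8, 8), n = 20)
  cb2 <- list(alleles = c(10, 30), het = c(8, 8), n = 20)
  expect_equal(wc_fst(ca2, cb2),
               oracle_wc_theta(20, 10 / 40, 8, 20, 30 / 40, 8),
               tolerance = 1e-12)
  # symmetric in its arguments
  expect_equal(wc_fst(ca2, cb2), wc_fst(cb2, ca2), tolerance = 1e-12)
  # invariant to swapping allele labels
  swap <- function(cn) list(alleles = rev(cn$alleles), het = rev(cn$het),
                            n = cn$n)
  expect_equal(wc_fst(swap(ca2), swap(cb2)), wc_fst(ca2, cb2),
               tolerance = 1e-12)
  # both monomorphic for the same allele -> undefined
  cm <- list(alleles = c(40, 0), het = c(0, 0), n = 20)
  expect_true(is.na(wc_fst(cm, cm)))
})

test_that("fst_scan agrees with wc_fst per site and averages pairs", {
  set.seed(31)
  g <- matrix(sample(0:2, 5 * 30, replace = TRUE), 5, 30)
  ds <- make_dataset(g, breed = rep(c("a", "b", "c"), each = 10))
  rec <- fst_scan(ds)
  expect_equal(colnames(rec$pairwise), c("a|b", "a|c", "b|c"))
  for (i in 1:5) {
    cnt <- function(cols) {
      gg <- g[i, cols]
      list(alleles = c(2 * length(gg) - sum(gg), sum(gg)),
           het = rep(sum(gg == 1), 2), n = length(gg))
    }
    expect_equal(unname(rec$pairwise[i, "a|b"]),
                 wc_fst(cnt(1:10), cnt(11:20)), tolerance = 1e-12)
  }
  # average over the focal breed's pairs only
  expect_equal(avg_pairwise_fst(rec, "a"),
               rowMeans(rec$pairwise[, c("a|b", "a|c")]))
  expect_error(avg_pairwise_fst(rec, "zz"), "unknown breed")
})

test_that("multi-allelic F_ST sums variance components over alleles", {
  # 3 alleles, clean differentiation between two panels of 10
  ca <- list(alleles = c(10, 10, 0), het = c(4, 4, 0), n = 10)
  cb <- list(alleles = c(0, 10, 10), het = c(0, 4, 4), n = 10)
  v <- wc_fst(ca, cb)
  expect_true(is.finite(v))
  expect_lte(v, 1)
  # equals the sum-of-components computed per allele by hand
  comp <- function(p1, p2, h1, h2, n1 = 10, n2 = 10) {
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, a + b + hbar / 2)
  }
  cs <- comp(0.5, 0, 0.4, 0) + comp(0.5, 0.5, 0.4, 0.4) +
    comp(0, 0.5, 0, 0.4)
  expect_equal(v, cs[1] / cs[2], tolerance = 1e-12)
})

test_that("vst matches the variance-decomposition oracle", {
  expect_equal(vst(c(rep(2, 5), rep(4, 5)), rep(c("a", "b"), each = 5),
                   c("a", "b")), 1.0)
  same <- c(1, 2, 3, 4)
  expect_equal(vst(c(same, same), rep(c("a", "b"), each = 4),
                   c("a", "b")), 0, tolerance = 1e-12)
  xa <- c(2, 2, 3); xb <- c(4, 5, 5)
  got <- vst(c(xa, xb), c("a", "a", "a", "b", "b", "b"), c("a", "b"))
  expect_equal(got, oracle_vst(xa, xb), tolerance = 1e-12)
  expect_true(is.na(vst(rep(2, 6), rep(c("a", "b"), each = 3),
                        c("a", "b"))))
  expect_error(vst(c(2, 3), c("a", "b"), c("a", "b")), "at least 2")
})

make_candidate_dataset <- function() {
  # 4 sites x 2 breeds of 10: site 1 = near-fixed derived in focal,
  # conserved; site 2 = high freq but low F_ST; site 3 = ancestral-high;
  # site 4 = high freq derived but unconserved
  gA <- rbind(rep(2L, 10),
              c(rep(2L, 7), rep(1L, 3)),
              rep(0L, 10),
              rep(2L, 10))
  gB <- rbind(rep(0L, 10),
              c(rep(2L, 6), rep(1L, 4)),
              rep(2L, 10),
              rep(0L, 10))
  an <- data.frame(effect_category = c("INTERGENIC", "INTERGENIC",
                                       "INTERGENIC", "INTERGENIC"),
                   phylop100 = c(6.0, 6.0, 6.0, 0.5),
                   phylop46 = c(6.0, 6.0, 6.0, 0.5),
                   phastcon_hit = FALSE)
  ds <- make_dataset(cbind(gA, gB), breed = rep(c("A", "B"), each = 10),
                     annot = an)
  polarize(ds, rep(0L, 4))
}

test_that("stage1 keeps differentiated high-frequency derived conserved
           sites and is idempotent", {
  ds <- make_candidate_dataset()
  rec <- fst_scan(ds)
  cand <- stage1_candidates(ds, rec, "A")
  expect_equal(cand$pos, 100L)   # only the engineered site survives
  expect_equal(cand$provenance, "stage1")
  # boundary: avg F_ST below 0.7 excluded (site 2), ancestral-high
  # excluded (site 3), unconserved excluded (site 4)
  expect_false(200L %in% cand$pos)
  expect_false(300L %in% cand$pos)
  expect_false(400L %in% cand$pos)
  # idempotence: the kept record still passes every rule
  expect_gte(cand$derived_freq, 0.7)
  expect_gte(cand$avg_pairwise_fst, 0.7)
  expect_gte(cand$phylop100, 2)
})

test_that("gene-proximity prioritization respects the 5 kb half-open
           window and both modes", {
  cand <- data.frame(chrom = "chr2", pos = c(11816535L, 11811001L,
                                             11805999L, 11816535L),
                     ref = "A", alt = "G", vtype = "SNV", site_id = 1:4,
                     derived_freq = 0.9, avg_pairwise_fst = 0.9,
                     phylop100 = c(5.2, 5.2, 5.2, 1.5),
                     phylop46 = c(0, 0, 0, 2.3),
                     effect_class = "other", focal_breed = "A",
                     provenance = "stage1", stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr2", start = 11816000L, end = 11900000L,
                      name = "NEBL", stringsAsFactors = FALSE)
  # 0-based gene start 11816000: variant at pos 11811001 (0-based 11811000)
  # is 5000 bp upstream -> inside half-open window; 11805999 is outside
  kept <- prioritize_by_gene(cand, genes, "coding", gene_list = "NEBL")
  expect_setequal(kept$pos, c(11816535L, 11811001L))
  expect_true(all(grepl("coding:NEBL", kept$provenance)))
  expect_true(all(kept$gene_distance <= 5000))
  # regulatory mode accepts the 46-mammal score route
  reg <- prioritize_by_gene(cand, genes, "regulatory", gene_list = "NEBL")
  expect_true(11816535L %in% reg$pos)
  expect_equal(sum(reg$pos == 11816535L), 2)  # both records at that pos
  expect_error(prioritize_by_gene(cand, genes, "coding",
                                  gene_list = character(0)), "empty")
  # output is a subset of input and provenance grows monotonically
  expect_true(all(kept$site_id %in% cand$site_id))
  expect_true(all(nchar(kept$provenance) >
                    nchar(cand$provenance[match(kept$site_id,
                                                cand$site_id)])))
})

test_that("region scan keeps conserved non-coding candidates inside a
           half-open interval", {
  cand <- data.frame(chrom = "chr2",
                     pos = c(11816535L, 12650000L, 12000000L),
                     effect_class = c("other", "other", "nonsynonymous"),
                     provenance = "stage1", stringsAsFactors = FALSE)
  got <- region_scan(cand, "chr2", 11650000L, 12650000L)
  expect_equal(got$pos, 11816535L)  # end coordinate and coding excluded
  expect_match(got$provenance, "region:chr2")
  expect_equal(nrow(region_scan(cand[0, ], "chr2", 1L, 10L)), 0)
})

test_that("selection-window merging selects the top fraction and joins
           regions by distance", {
  # 100 windows of 10 kb; the top five are adjacent
  ws <- data.frame(chrom = "chr1",
                   start = seq(0L, by = 10000L, length.out = 100),
                   clr = c(rep(1, 40), 10, 11, 12, 13, 14, rep(1, 55)))
  reg <- merge_selection_windows(ws)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$end - reg$start, 50000)
  expect_equal(reg$max_clr, 14)
  # two selected singletons 150 kb apart stay separate
  ws2 <- ws
  ws2$clr <- 1; ws2$clr[c(10, 26)] <- c(10, 10)
  ws2$clr[96:98] <- c(9, 8, 7)  # fill remaining top-5 slots far away
  reg2 <- merge_selection_windows(ws2)
  gap <- ws2$start[26] - (ws2$start[10] + 10000)   # 150 kb
  expect_equal(gap, 150000)
  expect_true(sum(reg2$start == ws2$start[10]) == 1 &&
                sum(reg2$start == ws2$start[26]) == 1)
  # 90 kb apart joins into one region
  ws3 <- ws
  ws3$clr <- 1; ws3$clr[c(10, 20)] <- 10
  ws3$clr[c(50, 60, 70)] <- c(9, 8, 7)
  reg3 <- merge_selection_windows(ws3)
  expect_equal(ws3$start[20] - (ws3$start[10] + 10000), 90000)
  joined <- reg3[reg3$start == ws3$start[10], ]
  expect_equal(joined$end, ws3$start[20] + 10000)
  # output sorted, non-overlapping, idempotent under re-aggregation
  expect_true(all(diff(reg3$start) > 0))
  expect_true(all(reg3$end[-nrow(reg3)] <= reg3$start[-1] |
                    reg3$chrom[-nrow(reg3)] != reg3$chrom[-1]))
  again <- aggregate_regions(reg3, 100000L)
  expect_equal(again[, c("chrom", "start", "end")],
               reg3[, c("chrom", "start", "end")])
  expect_error(merge_selection_windows(ws[0, ]), "empty")
})

test_that("the full prioritization recovers an engineered causal site", {
  st <- simulate_breed_panels(sim_config(
    seed = 17, n_sites = c(synonymous = 2000, high = 2000)))
  ds <- polarize(st$dataset, st$outgroup)
  # engineer one high-class conserved site: near-fixed derived in breedA,
  # absent in breedB
  hi <- which(breedload:::.class_index(ds, "high") & ds$polarity == "alt")
  target <- hi[1]
  acols <- which(ds$samples$breed == "breedA")
  bcols <- which(ds$samples$breed == "breedB")
  ds$geno[target, acols] <- 2L
  ds$geno[target, bcols] <- 0L
  # make every other site undifferentiated by copying breedA onto breedB
  ds$geno[-target, bcols] <- ds$geno[-target, acols]
  rec <- fst_scan(ds)
  cand <- stage1_candidates(ds, rec, "breedA")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$pos, ds$sites$pos[target])
})
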