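# Cohort reading, OLS association models, age-stratified subsampling,
# group allele frequencies, two-locus EM LD and incidence regression.

make_cohort <- function(n = 120, seed = 2) {
  cfg <- sim_config(seed = seed, cohort = list(n = n))
  simulate_cohort(cfg)
}

test_that("read_cohort validates the schema and converts letter
           genotypes", {
  d <- data.frame(Id = c("a", "b", "c"), breed = "dachshund",
                  nationality = "Swedish", sex = c(0L, 1L, 0L),
                  MMVD_status = c(0L, 1L, 0L),
                  graded_MMVD_status = c(0L, 2L, 2L),
                  age = c(8.0, 10.0, 9.0),
                  NEBL_1 = c("AA", "AG", "GG"), stringsAsFactors = FALSE)
  defs <- data.frame(marker = "NEBL_1", ancestral = "A", derived = "G",
                     stringsAsFactors = FALSE)
  expect_warning(got <- read_cohort(d, marker_defs = defs),
                 "inconsistent")
  expect_equal(got$NEBL_1, c(0L, 1L, 2L))
  expect_error(read_cohort(d[, -2]), "breed")
  expect_error(read_cohort(d), "marker_defs")
})

test_that("ols_fit is a linear probability model with exact closed-form
           behaviour", {
  # 4 points on an exact line y = 2x
  d <- data.frame(Id = 1:4, breed = "b", nationality = "s", sex = 0L,
                  MMVD_status = c(2, 4, 6, 8), graded_MMVD_status = 0L,
                  age = c(1, 2, 3, 4))
  f <- suppressWarnings(ols_fit(d, "MMVD_status", "age"))
  expect_equal(unname(f$coefficients["age"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["(Intercept)"]), 0, tolerance = 1e-10)
  # binary outcome treated as plain numbers: same fit either way
  co <- make_cohort()
  f1 <- ols_fit(co, "status", "age")
  co2 <- co; co2$MMVD_status <- as.numeric(co2$MMVD_status)
  f2 <- ols_fit(co2, "status", "age")
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$p, f2$p)
  # constant outcome: slope 0 and no explained variance
  co3 <- co; co3$MMVD_status <- 1
  f3 <- suppressWarnings(ols_fit(co3, "status", "age"))
  expect_equal(unname(f3$coefficients["age"]), 0)
  expect_error(ols_fit(co[1:2, ], "status", c("age", "sex")), "few")
})

test_that("an age-progressive cohort shows the expected age effect", {
  co <- make_cohort(n = 122, seed = 4)
  f <- ols_fit(co, "status", "age")
  expect_gt(unname(f$coefficients["age"]), 0)
  expect_lt(unname(f$p["age"]), 0.01)
  # graded outcome is predicted at least as well by age (disease
  # progresses with age)
  fg <- ols_fit(co, "graded_status", "age")
  expect_gt(unname(fg$coefficients["age"]), 0)
})

test_that("interaction models expand factorially and demand segregation", {
  co <- make_cohort(n = 200, seed = 5)
  f <- interaction_models(co, "NEBL_2")
  expect_setequal(f$terms, c("(Intercept)", "NEBL_2", "age", "NEBL_2:age"))
  fs <- interaction_models(co, "NEBL_2", include_sex = TRUE)
  expect_length(fs$terms, 8)  # full three-way factorial
  expect_true("NEBL_2:age:sex" %in% fs$terms)
  expect_error(interaction_models(co, "SORBS2"), "not segregating")
})

test_that("a planted genotype-by-age interaction is recovered within 2 SE
           in most replicates", {
  # reference estimand: the large-sample OLS interaction coefficient on
  # the probability scale, obtained from one very large cohort
  big <- simulate_cohort(sim_config(seed = 999,
                                    cohort = list(n = 200000)))
  ref <- unname(interaction_models(big, "NEBL_2", outcome = "status"
  )$coefficients["NEBL_2:age"])
  expect_gt(ref, 0)   # the planted interaction is positive
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    co <- simulate_cohort(sim_config(seed = 1000 + s,
                                     cohort = list(n = 400)))
    f <- interaction_models(co, "NEBL_2", outcome = "status")
    est <- unname(f$coefficients["NEBL_2:age"])
    se <- unname(f$se["NEBL_2:age"])
    if (abs(est - ref) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("young-case/old-control subsets nest and reduce to the full fit
           at extreme thresholds", {
  co <- make_cohort(n = 200, seed = 6)
  a <- young_case_old_control(co, 10, 8, "NEBL_2")
  b <- young_case_old_control(co, 9, 9, "NEBL_2")
  expect_true(all(b$subset$Id %in% a$subset$Id))
  expect_lte(nrow(b$subset), nrow(a$subset))
  full <- young_case_old_control(co, Inf, 0, "NEBL_2")
  plain <- ols_fit(co, "status", "NEBL_2")
  expect_equal(full$fit$coefficients, plain$coefficients)
  expect_error(young_case_old_control(co, min(co$age) - 1, 8, "NEBL_2"),
               "no cases")
})

test_that("group allele frequencies count derived alleles over called
           individuals", {
  d <- data.frame(Id = 1:10, breed = "b", nationality = "s", sex = 0L,
                  MMVD_status = rep(c(1L, 0L), each = 5),
                  graded_MMVD_status = rep(c(1L, 0L), each = 5), age = 9,
                  m = c(2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(group_allele_freq(d, "m"), 8 / 20)
  expect_equal(group_allele_freq(d, "m", d$MMVD_status == 1), 0.8)
  expect_equal(group_allele_freq(d, "m", d$MMVD_status == 0), 0.0)
  expect_error(group_allele_freq(d, "m", rep(FALSE, 10)), "no called")
})

test_that("two-locus EM equals the counting oracle without double
           heterozygotes and respects LD identities", {
  # no double heterozygote: phase is forced, EM must match direct counting
  d <- data.frame(m1 = c(2L, 2L, 0L, 0L, 1L, 0L, 2L, 1L),
                  m2 = c(2L, 1L, 0L, 0L, 0L, 1L, 2L, 2L))
  got <- ld_em(d, "m1", "m2")
  expect_equal(unname(got$hap), unname(oracle_hap_count(d$m1, d$m2)),
               tolerance = 1e-10)
  expect_true(sum(got$hap) == 1)
  # a marker against itself: perfect association
  d2 <- data.frame(a = c(0L, 1L, 2L, 1L, 0L, 2L),
                   b = c(0L, 1L, 2L, 1L, 0L, 2L))
  self <- ld_em(d2, "a", "b")
  expect_equal(self$d_prime, 1, tolerance = 1e-6)
  expect_equal(self$r2, 1, tolerance = 1e-6)
  # independent markers in a large sample: r2 near zero
  set.seed(12)
  d3 <- data.frame(x = rbinom(500, 2, 0.4), y = rbinom(500, 2, 0.3))
  ind <- ld_em(d3, "x", "y")
  expect_lt(ind$r2, 0.02)
  # allele-label swap invariance
  d4 <- data.frame(x = 2L - d3$x, y = 2L - d3$y)
  sw <- ld_em(d4, "x", "y")
  expect_equal(sw$r2, ind$r2, tolerance = 1e-8)
  expect_equal(sw$d_prime, ind$d_prime, tolerance = 1e-8)
  expect_error(ld_em(data.frame(x = c(0L, 0L), y = c(0L, 1L)), "x", "y"),
               "segregating")
})

test_that("ld_summary averages over unordered pairs", {
  set.seed(14)
  h <- rbinom(300, 1, 0.5)  # shared haplotype backbone -> correlated loci
  d <- data.frame(m1 = h + rbinom(300, 1, 0.5),
                  m2 = h + rbinom(300, 1, 0.5),
                  m3 = rbinom(300, 2, 0.5))
  s <- ld_summary(d, c("m1", "m2", "m3"))
  expect_equal(nrow(s$pairs), 3)
  expect_equal(s$r2, mean(s$pairs$r2))
  expect_equal(s$d_prime, mean(s$pairs$d_prime))
})

test_that("incidence rates accrue exposure to the first claim only", {
  claims <- data.frame(dog_id = c("d1", "d1", "d2"),
                       claim_date = c(2013.0, 2015.0, 2014.0))
  expo <- data.frame(dog_id = c("d1", "d2", "d3", "d4"),
                     breed = c("ckcs", "ckcs", "ckcs", "beagle"),
                     insurance_start = c(2011, 2012, 2011, 2017),
                     insurance_end = c(2016, NA, 2016, 2018))
  got <- incidence_rate(claims, expo, 2011, 2016)
  ck <- got[got$breed == "ckcs", ]
  # d1: 2011-2013 (2 y, second claim ignored); d2: 2012-2014 (2 y);
  # d3: full 5 y uneventful
  expect_equal(ck$first_claims, 2L)
  expect_equal(ck$dyar, 2 + 2 + 5)
  expect_equal(ck$incidence, 10000 * 2 / 9)
  # dog insured after the window contributes nothing
  bg <- got[got$breed == "beagle", ]
  expect_equal(bg$dyar, 0)
})

test_that("incidence regression recovers exact slopes and flags
           influential breeds", {
  freq <- c(a = 0.1, b = 0.3, c = 0.5, d = 0.7, e = 0.9)
  inc <- 10 + 100 * freq
  f <- suppressWarnings(incidence_regression(inc, freq))
  expect_equal(unname(f$coefficients["freq"]), 100, tolerance = 1e-9)
  # constant incidence: zero slope
  f0 <- suppressWarnings(
    incidence_regression(stats::setNames(rep(5, 5), names(freq)), freq))
  expect_equal(unname(f0$coefficients["freq"]), 0, tolerance = 1e-9)
  # planted single outlier drives significance; dropping it flips the call
  set.seed(3)
  freq2 <- c(a = 0.10, b = 0.12, c = 0.14, d = 0.16, e = 0.18, ckcs = 0.95)
  inc2 <- c(rnorm(5, 20, 3), 200)
  names(inc2) <- names(freq2)
  r <- incidence_regression(inc2, freq2, leave_one_out = TRUE)
  expect_lt(unname(r$fit$p["freq"]), 0.01)
  expect_gt(r$loo$p[r$loo$dropped == "ckcs"], 0.05)
  expect_error(incidence_regression(inc2[1:2], freq2[1:2]), "3 breeds")
})
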