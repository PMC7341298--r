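test_that("allele model encodes the repeat-unit arithmetic", {
  m <- allele_model()
  refs <- m$reference_lengths
  expect_equal(unname(refs["E"] - refs["F"]), 31)
  # one lost unit plus a single-nucleotide deletion
  expect_equal(unname(refs["F"] - refs["G"]), 32)
  expect_equal(unname(refs["G"]), 557 - 31 - 1)
})

test_that("fragment lengths are called to alleles, order-invariantly", {
  expect_identical(call_alleles(c(557, 525))$genotype, "FG")
  expect_identical(call_alleles(c(525, 557))$genotype, "FG")
  expect_identical(call_alleles(557)$genotype, "FF")
  expect_identical(call_alleles(c(586, 559))$genotype, "EF")  # within tolerance
  expect_error(call_alleles(540), "matches no reference")
  # idempotence through re-derived lengths
  m <- allele_model()
  g <- call_alleles(c(557, 525), m)
  again <- call_alleles(m$reference_lengths[g$alleles], m)
  expect_identical(again$genotype, g$genotype)
})

test_that("Hardy-Weinberg randomization: exact proportions, extreme deficit, reproducibility", {
  # counts exactly at random-mating proportions have zero deviation
  h <- hwe_randomization_test(c(FF = 25, FG = 50, GG = 25), seed = 1)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  # complete heterozygote deficit is essentially impossible under the null
  h2 <- hwe_randomization_test(c(FF = 50, FG = 0, GG = 50), seed = 1)
  expect_lt(h2$p_value, 0.001)
  # seed-reproducible
  a <- hwe_randomization_test(c(FF = 20, FG = 18, GG = 12), seed = 33)
  b <- hwe_randomization_test(c(FF = 20, FG = 18, GG = 12), seed = 33)
  expect_identical(a$p_value, b$p_value)
  # monomorphic sample: undefined, not an error
  expect_true(is.na(hwe_randomization_test(c(FF = 30))$p_value))
  expect_error(hwe_randomization_test(c(FF = 2, GG = 2)), "at least 5")
})

test_that("Hardy-Weinberg randomization agrees with exact pairing enumeration", {
  # 5 birds, alleles F x5 and G x5; under random re-pairing the number of
  # heterozygous pairs j has the perfect-matching distribution
  # P(j) = C(5,j)^2 j! M(5-j)^2 / M(10) with M(2m) = (2m)!/(m! 2^m)
  M <- function(x) if (x %% 2 == 1) 0 else factorial(x) / (factorial(x / 2) * 2^(x / 2))
  pj <- vapply(0:5, function(j)
    choose(5, j)^2 * factorial(j) * M(5 - j)^2 / M(10), numeric(1))
  pj <- pj / sum(pj)
  counts <- c(FF = 2, FG = 1, GG = 2)   # het_obs = 0.2, het_exp = 0.5
  stat_of <- function(j) abs(j / 5 - 0.5)
  exact_p <- sum(pj[stat_of(0:5) >= stat_of(1) - 1e-12])
  h <- hwe_randomization_test(counts, n_rand = 4000, seed = 2)
  mc_se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(h$p_value - exact_p), 4 * mc_se)
})

test_that("Weir-Cockerham theta: boundary cases, oracle arithmetic, label invariance", {
  # identical allele frequencies: essentially zero (slightly negative allowed)
  x_eq <- matrix(c(120, 80, 120, 80), 2, 2, dimnames = list(c("F", "G"), NULL))
  expect_lt(abs(fst_between(x_eq)), 0.01)
  # fixation for alternative alleles: complete differentiation
  x_fix <- matrix(c(100, 0, 0, 100), 2, 2, dimnames = list(c("F", "G"), NULL))
  expect_equal(as.numeric(fst_between(x_fix)), 1, tolerance = 1e-12)
  # spreadsheet-style evaluation of the variance components for two breeds
  # of 100 birds with F frequencies 0.65 and 0.55
  n1 <- 100; n2 <- 100; p1 <- 0.65; p2 <- 0.55; r <- 2
  nbar <- 100; nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  oracle_allele <- function(p1, p2) {
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c(a, b, hbar / 2)
  }
  comp <- oracle_allele(p1, p2) + oracle_allele(1 - p1, 1 - p2)
  theta_oracle <- comp[1] / sum(comp)
  x <- matrix(c(130, 70, 110, 90), 2, 2, dimnames = list(c("F", "G"), c("BS", "BP")))
  expect_equal(as.numeric(fst_between(x)), theta_oracle, tolerance = 1e-12)
  expect_gt(theta_oracle, 0)
  expect_lt(theta_oracle, 0.05)
  # invariant to population labelling
  expect_equal(as.numeric(fst_between(x[, 2:1])), as.numeric(fst_between(x)),
               tolerance = 1e-12)
  expect_error(fst_between(matrix(c(10, 10, 0, 0), 2, 2)), "no sampled alleles")
})

test_that("genotype association at one age: nulls, guards, letters", {
  set.seed(201)
  g <- rep(c("FF", "FG", "GG"), times = c(18, 24, 12))
  w0 <- rnorm(length(g), 1000, 80)
  res0 <- lm2_assoc(w0, g)
  expect_true(res0$p > 0.001)  # no injected effect; extreme p would be a fluke
  # strong additive effect separates the homozygotes
  w1 <- w0 + 400 * (g == "GG") + 200 * (g == "FG")
  res1 <- lm2_assoc(w1, g)
  expect_lt(res1$p, 0.001)
  lett <- setNames(res1$means$letters, res1$means$group)
  expect_false(lett[["FF"]] == lett[["GG"]])
  expect_error(lm2_assoc(w0, rep("FF", length(w0))), "at least 2")
  expect_error(lm2_assoc(w0[1:3], c("FF", "FF", "GG")), "at least 2")
})

test_that("per-age association scan produces a coherent trajectory", {
  fl <- simulate_flock(small_design(n = 20), seed = 41, with_markers = FALSE)
  scan <- pax7_assoc_scan(fl$data, fl$genotypes, breed = "BP", sex = "F")
  expect_identical(scan$age_days, sort(unique(fl$data$age_days)))
  expect_true(all(is.na(scan$p) | (scan$p >= 0 & scan$p <= 1)))
  expect_true(all(scan$p_adj >= scan$p, na.rm = TRUE) ||
                all(scan$p_adj == scan$p, na.rm = TRUE))
})
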