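make_factors <- function(n_per = 10) {
  expand.grid(breed = c("BS", "BP"), sex = c("F", "M"), rep = seq_len(n_per))
}

test_that("ANOVA with identity relationship equals ordinary two-way ANOVA", {
  set.seed(101)
  d <- make_factors(12)
  y <- 100 + 8 * (d$breed == "BP") + 15 * (d$sex == "M") + rnorm(nrow(d), 0, 6)
  plain <- lm1_anova(y, d$breed, d$sex)
  with_id <- lm1_anova(y, d$breed, d$sex, relationship = diag(nrow(d)))
  expect_lt(max(abs(plain$table$F - with_id$table$F)), 1e-8)
  # cross-check against the standard ANOVA fit (balanced design)
  ref <- summary(stats::aov(y ~ breed * sex, data = cbind(d, y)))[[1]]
  expect_equal(plain$table$F, ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(plain$table$p, ref$`Pr(>F)`[1:3], tolerance = 1e-8)
})

test_that("large injected sex effect is declared highly significant", {
  set.seed(102)
  d <- make_factors(50)  # n = 200
  y <- 100 + rnorm(nrow(d), 0, 5)
  y[d$sex == "M"] <- y[d$sex == "M"] + 10  # two within-group SDs
  res <- lm1_anova(y, d$breed, d$sex)
  expect_lt(res$table$p[res$table$term == "sex"], 0.001)
  expect_equal(res$table$code[res$table$term == "sex"], "***")
})

test_that("relationship random effect: validation and structured fit", {
  set.seed(103)
  d <- make_factors(15)
  n <- nrow(d)
  K <- relationship_from_markers(simulate_markers(n, 15, 5, n_families = 10))
  y <- 100 + 12 * (d$sex == "M") + rnorm(n, 0, 5)
  res <- lm1_anova(y, d$breed, d$sex, relationship = K)
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  expect_lt(res$table$p[res$table$term == "sex"], 0.001)
  bad <- K; bad[1, 2] <- 2
  expect_error(lm1_anova(y, d$breed, d$sex, relationship = bad), "symmetric")
  expect_error(lm1_anova(y, d$breed, d$sex, relationship = K[-1, -1]),
               "dimension")
  expect_error(lm1_anova(rep(1, n), d$breed, d$sex), "zero variance")
})

test_that("backward elimination respects marginality and thresholds", {
  set.seed(104)
  d <- make_factors(30)
  # strong mains, null interaction
  y <- 100 + 10 * (d$breed == "BP") + 12 * (d$sex == "M") + rnorm(nrow(d), 0, 5)
  res <- backward_eliminate(y, d$breed, d$sex)
  expect_identical(res$eliminated, "breed:sex")
  expect_setequal(res$table$term, c("breed", "sex"))
  # alpha = 1 removes nothing (p >= 1 never attained)
  res1 <- backward_eliminate(y, d$breed, d$sex, alpha = 1)
  expect_identical(res1$eliminated, character(0))
  # under a pure null most datasets lose every term
  retained <- vapply(1:60, function(i) {
    yy <- rnorm(nrow(d))
    nrow(backward_eliminate(yy, d$breed, d$sex)$table)
  }, numeric(1))
  expect_lt(mean(retained > 0), 0.3)
})

test_that("Waller-Duncan letters separate and join means as the risk rule dictates", {
  # all equal means share one letter
  eq <- waller_duncan(c(a = 100, b = 100, c = 100), c(10, 10, 10),
                      mse = 25, df_error = 27)
  expect_true(all(eq$letters == "a"))
  # groups 10 pooled SEs apart must all separate
  se <- sqrt(25 * 2 / 10)
  far <- waller_duncan(c(g1 = 100, g2 = 100 + 10 * se, g3 = 100 + 20 * se,
                         g4 = 100 + 30 * se), rep(10, 4), 25, 36)
  expect_equal(length(unique(far$letters)), 4L)
  # the early-growth pattern: two close high means share, the others separate
  wk2 <- waller_duncan(c(`BS F` = 138, `BS M` = 159, `BP F` = 186, `BP M` = 184),
                       c(46, 47, 54, 54), mse = (7.5 * sqrt(50))^2,
                       df_error = 197)
  lett <- setNames(wk2$letters, wk2$group)
  expect_identical(lett[["BP F"]], lett[["BP M"]])
  expect_false(lett[["BS F"]] == lett[["BS M"]])
  expect_false(lett[["BS M"]] %in% lett[c("BP F", "BP M")])
  # invariant to group ordering
  perm <- waller_duncan(c(`BP M` = 184, `BS F` = 138, `BP F` = 186, `BS M` = 159),
                        c(54, 46, 54, 47), mse = (7.5 * sqrt(50))^2,
                        df_error = 197)
  expect_identical(setNames(perm$letters, perm$group)[names(lett)], lett)
  expect_error(waller_duncan(c(a = 1), 5, 1, 10), "at least 2")
  expect_error(waller_duncan(c(a = 1, b = 2), c(5, 5), 1, 0.5), "df_error")
})

test_that("Waller-Duncan critical t shrinks with evidence and bottoms out near 1.72", {
  ts <- vapply(c(0.2, 1.5, 3, 10, 1e5),
               function(F) flockgrowth:::waller_tcrit(100, F, 3, 100),
               numeric(1))
  expect_true(all(diff(ts) < 0))
  expect_equal(ts[5], 1.75, tolerance = 0.02)
  # a zero F statistic (identical means) declares nothing
  expect_identical(flockgrowth:::waller_tcrit(100, 0, 3, 30), Inf)
})

test_that("dimorphism percentage: published checks and algebraic identity", {
  expect_equal(round(dimorphism_delta(2184, 3074)), 41)
  expect_equal(round(dimorphism_delta(1733, 2307)), 33)
  expect_equal(dimorphism_delta(5, 5), 0)
  # antisymmetry up to the change of baseline: delta(f,m)*f = -delta(m,f)*m
  f <- 1733; m <- 2307
  expect_equal(dimorphism_delta(f, m) * f, -dimorphism_delta(m, f) * m,
               tolerance = 1e-9)
  expect_error(dimorphism_delta(0, 10), "positive")
})

test_that("allele-sharing relationship matrix matches its definition", {
  g <- array(NA_integer_, c(3, 1, 2))
  g[1, 1, ] <- c(1, 2)  # AB
  g[2, 1, ] <- c(3, 4)  # CD
  g[3, 1, ] <- c(1, 3)  # AC
  K <- relationship_from_markers(g)
  expect_equal(K[1, 2], 0)
  expect_equal(K[1, 3], 0.5)
  expect_equal(diag(K), rep(1, 3))
  # identical multi-marker genotypes are fully similar
  g2 <- simulate_markers(2, 10, 4, seed = 5)
  g2[2, , ] <- g2[1, , ]
  expect_equal(relationship_from_markers(g2)[1, 2], 1)
  # mean off-diagonal similarity matches the enumeration expectation for
  # uniform alleles: E[shared]/2 over all ordered genotype pairs
  a <- 5
  combos <- expand.grid(a1 = 1:a, a2 = 1:a, b1 = 1:a, b2 = 1:a)
  shared <- with(combos, pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1)))
  expected <- mean(shared) / 2
  gg <- simulate_markers(60, 40, a, seed = 6)
  K3 <- relationship_from_markers(gg)
  expect_equal(mean(K3[upper.tri(K3)]), expected, tolerance = 0.02)
  # all-missing pair errors
  gm <- simulate_markers(3, 2, 3, seed = 7)
  gm[2, , ] <- NA
  expect_error(relationship_from_markers(gm), "jointly typed")
})
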