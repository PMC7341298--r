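## Significance codes used throughout: n.s. (p > 0.05), * (<0.05),
## ** (<0.01), *** (<0.001).
signif_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

check_relationship <- function(K, n) {
  K <- as.matrix(K)
  if (nrow(K) != n || ncol(K) != n)
    stop("relationship matrix dimension does not match the number of birds", call. = FALSE)
  if (max(abs(K - t(K))) > 1e-8)
    stop("relationship matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(K) - 1)) > 1e-8)
    stop("relationship matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev)))
    stop("relationship matrix is not positive semi-definite", call. = FALSE)
  K
}

## Core fixed-effect F machinery shared by lm1_anova() and
## backward_eliminate(): y = X beta + u + e with u ~ N(0, sigma_u^2 K),
## e ~ N(0, sigma_e^2 I). The single variance ratio lambda = sigma_u^2 /
## sigma_e^2 is profiled by restricted likelihood on a 1-D grid (with a
## local refinement), after which the model is whitened and each term is
## tested by a marginal F against the full-model residual.
anova_terms <- function(y, fdat, terms, K = NULL, grid = NULL) {
  n <- length(y)
  if (stats::var(y) == 0)
    stop("response has zero variance: F statistics undefined", call. = FALSE)
  lambda <- 0
  U <- NULL; d <- NULL
  if (!is.null(K)) {
    K <- check_relationship(K, n)
    eg <- eigen(K, symmetric = TRUE)
    U <- eg$vectors
    d <- pmax(eg$values, 0)
    Xfull <- stats::model.matrix(stats::reformulate(terms), fdat)
    if (qr(Xfull)$rank < ncol(Xfull)) stop("singular design", call. = FALSE)
    Uy <- crossprod(U, y); UX <- crossprod(U, Xfull)
    reml <- function(lam) {
      v <- 1 + lam * d
      sv <- sqrt(v)
      qrX <- qr(UX / sv)
      rss <- sum(qr.resid(qrX, Uy / sv)^2)
      p <- qrX$rank
      ldXX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
      -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) + ldXX)
    }
    if (is.null(grid)) grid <- c(0, 10^seq(-2, 2, length.out = 13))
    ll <- vapply(grid, reml, numeric(1))
    best <- which.max(ll)
    lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
    lambda <- if (hi > lo)
      stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
    else grid[best]
    if (reml(0) >= reml(lambda)) lambda <- 0
  }
  whiten <- function(M) {
    if (is.null(K) || lambda == 0) return(M)
    crossprod(U, M) / sqrt(1 + lambda * d)
  }
  yw <- drop(whiten(cbind(y)))
  rss_of <- function(trms) {
    X <- if (length(trms))
      stats::model.matrix(stats::reformulate(trms), fdat)
    else matrix(1, n, 1)
    Xw <- whiten(X)
    qrX <- qr(Xw)
    if (qrX$rank < ncol(X)) stop("singular design", call. = FALSE)
    list(rss = sum(qr.resid(qrX, yw)^2), rank = qrX$rank)
  }
  full <- rss_of(terms)
  df_res <- n - full$rank
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  mse <- full$rss / df_res
  tab <- lapply(terms, function(tm) {
    if (removable(tm, terms)) {
      red <- rss_of(setdiff(terms, tm))
      bigger <- full
    } else {
      # marginality: a main effect is tested within the additive sub-model,
      # with the error taken from the full model
      base <- setdiff(terms, c(tm, terms[grepl(":", terms)]))
      bigger <- rss_of(c(base, tm))
      red <- rss_of(base)
    }
    df_t <- bigger$rank - red$rank
    Fv <- ((red$rss - bigger$rss) / df_t) / mse
    data.frame(term = tm, df = df_t, F = Fv,
               p = stats::pf(Fv, df_t, df_res, lower.tail = FALSE))
  })
  tab <- do.call(rbind, tab)
  tab$code <- signif_code(tab$p)
  list(table = tab, df_res = df_res, mse = mse, lambda = lambda, terms = terms)
}

removable <- function(term, terms) {
  # a term is removable if no retained higher-order term contains it
  higher <- terms[grepl(":", terms) & terms != term]
  !any(vapply(higher, function(h) all(strsplit(term, ":")[[1]] %in% strsplit(h, ":")[[1]]),
              logical(1)))
}

#' Two-way ANOVA of a trait with a relationship random effect
#'
#' Tests the fixed effects of breed, sex and their interaction on a trait
#' (actual weight at one age, or a fitted growth parameter) with an
#' optional random effect whose covariance is proportional to a bird-by-bird
#' relationship (allele-sharing) matrix — an animal-model style term that
#' substitutes for unavailable pedigree information. The single variance
#' ratio is estimated by profiled restricted likelihood over a 1-D grid;
#' with no relationship matrix (or an identity one) the analysis reduces
#' exactly to ordinary two-way ANOVA.
#'
#' @param response numeric trait vector, one value per bird.
#' @param breed,sex factors (or coercible) of the same length.
#' @param relationship optional symmetric positive semi-definite matrix with
#'   unit diagonal, entries in `[0, 1]`.
#' @param terms model terms to include.
#' @return An object of class `"lm1_anova"`: a per-term table of F, p and
#'   significance code, the residual degrees of freedom, the residual mean
#'   square and the estimated variance ratio.
#' @examples
#' set.seed(1)
#' d <- expand.grid(breed = c("BS", "BP"), sex = c("F", "M"), rep = 1:10)
#' y <- 100 + 20 * (d$sex == "M") + rnorm(40, 0, 5)
#' lm1_anova(y, d$breed, d$sex)
#' @export
lm1_anova <- function(response, breed, sex, relationship = NULL,
                      terms = c("breed", "sex", "breed:sex")) {
  fdat <- data.frame(breed = factor(breed), sex = factor(sex))
  if (length(response) != nrow(fdat))
    stop("response and factors differ in length", call. = FALSE)
  if (nlevels(fdat$breed) < 2 || nlevels(fdat$sex) < 2)
    stop("each factor needs at least 2 levels", call. = FALSE)
  res <- anova_terms(as.numeric(response), fdat, terms, K = relationship)
  structure(c(res, list(eliminated = character(0))), class = "lm1_anova")
}

#' @export
print.lm1_anova <- function(x, digits = 4, ...) {
  cat("ANOVA (breed/sex fixed effects",
      if (x$lambda > 0) sprintf(", relationship variance ratio %.3g", x$lambda) else "",
      ")\n", sep = "")
  tab <- x$table
  tab$F <- round(tab$F, digits); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat("Residual df:", x$df_res, "\n")
  if (length(x$eliminated))
    cat("Eliminated terms:", paste(x$eliminated, collapse = ", "), "\n")
  invisible(x)
}

#' Backward elimination of non-significant model terms
#'
#' Starting from the full breed + sex + breed:sex model, iteratively removes
#' the least significant removable term (the interaction before its main
#' effects) whose p-value is at or above `alpha`, refitting after each
#' removal. Returns the final model together with the elimination trail.
#'
#' @inheritParams lm1_anova
#' @param alpha retention threshold (default 0.05).
#' @return An `"lm1_anova"` object whose `eliminated` element lists removed
#'   terms in order and whose `trail` records the p-value at removal.
#' @export
backward_eliminate <- function(response, breed, sex, relationship = NULL,
                               alpha = 0.05,
                               terms = c("breed", "sex", "breed:sex")) {
  fdat <- data.frame(breed = factor(breed), sex = factor(sex))
  y <- as.numeric(response)
  eliminated <- character(0)
  trail <- data.frame(step = integer(0), term = character(0), p = numeric(0))
  current <- terms
  repeat {
    res <- anova_terms(y, fdat, current, K = relationship)
    tab <- res$table
    cand <- tab[vapply(tab$term, removable, logical(1), terms = current) &
                  tab$p >= alpha, , drop = FALSE]
    if (nrow(cand) == 0L) break
    worst <- cand$term[which.max(cand$p)]
    eliminated <- c(eliminated, worst)
    trail <- rbind(trail, data.frame(step = length(eliminated), term = worst,
                                     p = cand$p[which.max(cand$p)]))
    current <- setdiff(current, worst)
    if (length(current) == 0L) break
  }
  if (length(current) == 0L) {
    out <- list(table = res$table[0, ], df_res = length(y) - 1, mse = stats::var(y),
                lambda = res$lambda, terms = character(0))
  } else {
    out <- anova_terms(y, fdat, current, K = relationship)
  }
  structure(c(out, list(eliminated = eliminated, trail = trail)),
            class = "lm1_anova")
}

#' Waller-Duncan k-ratio t-test letter groupings
#'
#' Multiple comparison of group means using the minimum-average-risk Bayes
#' rule of Waller and Duncan (1969). The critical t depends on the k-ratio
#' (the ratio of the two linear error-loss weights; 100 corresponds roughly
#' to a 5 percent test), on the ANOVA F statistic for the groups, and on
#' both degrees of freedom: large F values shrink the critical value toward
#' its lower limit (about 1.72 at k = 100), small F values inflate it so
#' that few or no differences are declared. The critical value is computed
#' numerically by integrating the linear-loss ratio over the posterior of
#' the between-to-within variance ratio implied by F (see the methods
#' vignette for the construction) and solving the resulting monotone
#' equation.
#'
#' Means closer than the least significant difference
#' `t_crit * sqrt(mse * (1/n_i + 1/n_j))` share a letter; letters are
#' assigned by a sweep from the largest mean and the result is invariant to
#' the input ordering of groups.
#'
#' @param group_means named numeric vector of group means.
#' @param group_ns group sizes (same order).
#' @param mse residual mean square from the ANOVA.
#' @param df_error residual degrees of freedom (must exceed 1).
#' @param f_stat ANOVA F statistic for the group factor; computed from the
#'   summaries when omitted.
#' @param k_ratio error-weight ratio (50, 100 or 500 conventional; 100
#'   default).
#' @return data frame `group`, `mean`, `n`, `letters`, ordered by
#'   decreasing mean, with the critical t as attribute `t_crit`.
#' @export
waller_duncan <- function(group_means, group_ns, mse, df_error, f_stat = NULL,
                          k_ratio = 100) {
  g <- length(group_means)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(group_ns) != g) stop("group_ns length mismatch", call. = FALSE)
  if (!is.finite(mse) || mse <= 0) stop("'mse' must be positive", call. = FALSE)
  if (df_error < 1) stop("'df_error' must be at least 1", call. = FALSE)
  if (is.null(names(group_means))) names(group_means) <- paste0("g", seq_len(g))
  if (is.null(f_stat)) {
    gm <- sum(group_ns * group_means) / sum(group_ns)
    f_stat <- sum(group_ns * (group_means - gm)^2) / (g - 1) / mse
  }
  tB <- waller_tcrit(k_ratio, f_stat, g - 1, df_error)
  o <- order(group_means, decreasing = TRUE)
  m <- group_means[o]; nn <- group_ns[o]
  nsd <- function(i, j) {
    if (!is.finite(tB)) return(TRUE)
    abs(m[i] - m[j]) < tB * sqrt(mse * (1 / nn[i] + 1 / nn[j]))
  }
  # maximal runs of mutually non-separated (by the sweep) groups
  ends <- integer(g)
  for (i in seq_len(g)) {
    j <- i
    while (j < g && nsd(i, j + 1L)) j <- j + 1L
    ends[i] <- j
  }
  letters_out <- rep("", g)
  li <- 0L
  last_end <- 0L
  for (i in seq_len(g)) {
    if (i > 1L && ends[i] <= last_end) next  # run contained in the previous one
    li <- li + 1L
    rng <- i:ends[i]
    letters_out[rng] <- paste0(letters_out[rng], letters[li])
    last_end <- ends[i]
  }
  out <- data.frame(group = names(m), mean = as.numeric(m), n = as.numeric(nn),
                    letters = letters_out, stringsAsFactors = FALSE)
  attr(out, "t_crit") <- tB
  attr(out, "f_stat") <- f_stat
  out
}

## Minimum-average-risk critical t. psi_f(m) = E[max(T_f + m, 0)] is the
## expected linear loss for a t-distributed posterior; the Bayes rule
## declares a difference when the ratio of losses exceeds the k-ratio,
## averaged over the posterior of gamma = (sigma_e^2 + n sigma_tau^2) /
## sigma_e^2 given the observed F (scale-invariant prior on gamma >= 1).
## The shrinkage factor is b = 1 - 1/gamma. As F -> infinity the posterior
## concentrates at b = 1 and t_B tends to the known-variance solution
## (about 1.72 for k = 100); as F -> 1 no finite t satisfies the equation
## and +Inf is returned (no differences declared).
waller_tcrit <- function(k_ratio, f_stat, df_num, df_err) {
  if (df_err <= 1) stop("error df must exceed 1 for the loss integral", call. = FALSE)
  if (!is.finite(f_stat) || f_stat <= 0) return(Inf)
  psi <- function(m) m * stats::pt(m, df_err) +
    ((df_err + m^2) / (df_err - 1)) * stats::dt(m, df_err)
  post <- function(gam) stats::df(f_stat / gam, df_num, df_err) / gam^2
  side <- function(t, sgn) {
    integrand <- function(gam) {
      b <- 1 - 1 / gam
      sqrt(b) * psi(sgn * sqrt(b) * t) * post(gam)
    }
    stats::integrate(integrand, 1, Inf, rel.tol = 1e-8,
                     stop.on.error = FALSE)$value
  }
  lratio <- function(t) log(side(t, 1)) - log(side(t, -1))
  lk <- log(k_ratio)
  if (lratio(80) < lk) return(Inf)
  stats::uniroot(function(t) lratio(t) - lk, c(1e-3, 80), tol = 1e-7)$root
}

#' Sexual dimorphism percentage
#'
#' `((male mean - female mean) / female mean) * 100`; rounding is left to
#' display time.
#'
#' @param female_mean,male_mean group means (female mean must be positive).
#' @return dimorphism percentage.
#' @examples
#' dimorphism_delta(2184, 3074)  # +40.75 -> prints as +41
#' @export
dimorphism_delta <- function(female_mean, male_mean) {
  if (!is.numeric(female_mean) || any(female_mean <= 0))
    stop("'female_mean' must be positive", call. = FALSE)
  (male_mean - female_mean) / female_mean * 100
}

#' Allele-sharing relationship matrix from marker genotypes
#'
#' Entry (i, j) is the proportion of shared alleles averaged over markers:
#' per marker, the number of alleles the two diploid genotypes share (0, 1
#' or 2) divided by 2. Markers with a missing genotype in either bird are
#' excluded pairwise; a pair with no jointly typed marker is an error.
#'
#' @param genotypes integer/character array `n_birds x n_markers x 2` (two
#'   allele slots per marker), as produced by [simulate_markers()].
#' @return symmetric matrix with unit diagonal, entries in `[0, 1]`.
#' @export
relationship_from_markers <- function(genotypes) {
  stopifnot(length(dim(genotypes)) == 3L, dim(genotypes)[3] == 2L)
  n <- dim(genotypes)[1]; m <- dim(genotypes)[2]
  if (m < 1L) stop("at least one marker required", call. = FALSE)
  ids <- dimnames(genotypes)[[1]]
  S <- matrix(0, n, n)     # summed shared-allele proportions
  W <- matrix(0, n, n)     # markers jointly typed
  eqm <- function(x, y) outer(x, y, "==") & !is.na(outer(x, y, "=="))
  for (l in seq_len(m)) {
    a1 <- genotypes[, l, 1]; a2 <- genotypes[, l, 2]
    ok <- !(is.na(a1) | is.na(a2))
    # shared alleles of two diploid genotypes = best of the two pairings
    m11 <- eqm(a1, a1); m22 <- eqm(a2, a2)
    m12 <- eqm(a1, a2); m21 <- eqm(a2, a1)
    s <- pmax(m11 + m22, m12 + m21)
    valid <- outer(ok, ok, "&")
    s[!valid] <- 0
    S <- S + s / 2
    W <- W + valid
  }
  if (any(W == 0))
    stop("some pair of birds has no jointly typed marker", call. = FALSE)
  K <- S / W
  diag(K) <- 1
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  K
}
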