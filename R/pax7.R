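#' Minisatellite allele model for the PAX7 intron-3 repeat
#'
#' The polymorphism is a tandem repeat of a 31-bp unit inside a PCR
#' amplicon: three units give the E allele (588 bp on the reference
#' amplicon), two units the F allele (557 bp), and one unit plus a single
#' nucleotide deletion the G allele (525 bp = 557 - 31 - 1). The E allele
#' is retained in the model even where only F and G segregate, so the
#' caller generalizes to populations carrying all three.
#'
#' @param unit_length repeat-unit length in bp.
#' @param f_length amplicon length of the two-unit (F) allele in bp.
#' @param g_deletion extra single-nucleotide deletion of the G allele, bp.
#' @param tolerance matching tolerance in bp for fragment-length calling.
#' @return object of class `"allele_model"` with the reference lengths.
#' @examples
#' allele_model()$reference_lengths
#' @export
allele_model <- function(unit_length = 31, f_length = 557, g_deletion = 1,
                         tolerance = 3) {
  refs <- c(E = f_length + unit_length,
            F = f_length,
            G = f_length - unit_length - g_deletion)
  structure(list(unit_length = unit_length, reference_lengths = refs,
                 tolerance = tolerance), class = "allele_model")
}

#' Call minisatellite alleles from fragment lengths
#'
#' Each measured fragment length is matched to the nearest reference allele
#' length within the model tolerance; a single length is interpreted as a
#' homozygote. Calling is idempotent and invariant to the input order of
#' the lengths.
#'
#' @param lengths one or two fragment lengths in bp.
#' @param model an [allele_model()].
#' @return list with `alleles` (sorted pair, e.g. `c("F","G")`) and
#'   `genotype` (label, e.g. `"FG"`).
#' @examples
#' call_alleles(c(557, 525))  # F/G heterozygote
#' @export
call_alleles <- function(lengths, model = allele_model()) {
  stopifnot(inherits(model, "allele_model"))
  lengths <- as.numeric(lengths)
  if (!length(lengths) %in% 1:2 || any(!is.finite(lengths)))
    stop("provide one or two finite fragment lengths", call. = FALSE)
  refs <- model$reference_lengths
  al <- vapply(lengths, function(x) {
    d <- abs(refs - x)
    if (min(d) > model$tolerance)
      stop(sprintf("fragment length %g bp matches no reference allele (within %g bp of %s)",
                   x, model$tolerance,
                   paste(sprintf("%s=%g", names(refs), refs), collapse = ", ")),
           call. = FALSE)
    names(refs)[which.min(d)]
  }, character(1))
  if (length(al) == 1L) al <- rep(al, 2L)
  al <- sort(al)
  list(alleles = al, genotype = paste(al, collapse = ""))
}

parse_genotype_names <- function(gn) {
  # accepts "FG", "F/G" or "F:G" labels
  lapply(gn, function(s) {
    if (grepl("[/:]", s)) strsplit(s, "[/:]")[[1]] else strsplit(s, "")[[1]]
  })
}

#' Hardy-Weinberg randomization test
#'
#' Permutation test of agreement with random-mating genotype proportions.
#' Alleles are pooled over individuals, shuffled `n_rand` times and
#' re-paired into genotypes; the deviation statistic is the absolute
#' difference between observed and expected (from the allele frequencies)
#' heterozygosity, and the p-value is the proportion of randomized datasets
#' whose statistic is at least as extreme as the observed one.
#'
#' @param genotype_counts named counts, e.g. `c(FF = 25, FG = 50, GG = 25)`.
#' @param n_rand number of randomizations (default 2000).
#' @param seed optional seed for reproducibility.
#' @return object of class `"hwe_test"`: observed statistic, p-value, the
#'   observed and expected heterozygosity and the number of randomizations.
#'   A monomorphic sample yields an `NA` p-value (test undefined).
#' @export
hwe_randomization_test <- function(genotype_counts, n_rand = 2000, seed = NULL) {
  stopifnot(!is.null(names(genotype_counts)), all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n < 5) stop("need at least 5 individuals", call. = FALSE)
  pairs <- parse_genotype_names(names(genotype_counts))
  if (any(lengths(pairs) != 2L))
    stop("genotype labels must name two alleles", call. = FALSE)
  alleles <- unlist(mapply(function(p, c) rep(p, c), pairs, genotype_counts,
                           SIMPLIFY = FALSE))
  uall <- unique(alleles)
  if (length(uall) < 2L) {
    out <- list(statistic = NA_real_, p_value = NA_real_, het_obs = 0,
                het_exp = 0, n_rand = n_rand, defined = FALSE)
    class(out) <- "hwe_test"
    return(out)
  }
  het <- vapply(pairs, function(p) p[1] != p[2], logical(1))
  het_obs <- sum(genotype_counts[het]) / n
  p_freq <- table(alleles) / (2 * n)
  het_exp <- 1 - sum(p_freq^2)
  obs_stat <- abs(het_obs - het_exp)
  if (!is.null(seed)) set.seed(seed)
  av <- match(alleles, uall)  # integer alleles, length 2n
  odd <- seq(1, 2 * n, by = 2)
  perm <- vapply(seq_len(n_rand), function(i) {
    s <- sample(av)
    h <- mean(s[odd] != s[odd + 1L])
    abs(h - het_exp)
  }, numeric(1))
  out <- list(statistic = obs_stat, p_value = mean(perm >= obs_stat - 1e-12),
              het_obs = het_obs, het_exp = het_exp, n_rand = n_rand,
              defined = TRUE)
  class(out) <- "hwe_test"
  out
}

#' @export
print.hwe_test <- function(x, ...) {
  if (!x$defined) {
    cat("Hardy-Weinberg randomization test: undefined (monomorphic sample)\n")
    return(invisible(x))
  }
  cat(sprintf("Hardy-Weinberg randomization test (%d randomizations)\n", x$n_rand))
  cat(sprintf("  het obs %.4f  het exp %.4f  |diff| %.4f  p = %.4g\n",
              x$het_obs, x$het_exp, x$statistic, x$p_value))
  invisible(x)
}

#' Weir-Cockerham Fst between populations
#'
#' The theta estimator of Weir and Cockerham (1984) for one multi-allelic
#' locus: per-allele variance components a (between populations),
#' b (between individuals within populations) and c (within individuals)
#' are summed over alleles and theta = sum(a) / sum(a + b + c). With allele
#' counts only, the within-population heterozygosity entering b and c is
#' the Hardy-Weinberg expectation `2p(1-p)` unless observed heterozygote
#' proportions are supplied. The estimator is invariant to population
#' labelling and can be slightly negative around zero differentiation.
#'
#' @param allele_counts matrix of allele copy counts, alleles in rows,
#'   populations in columns.
#' @param het_obs optional matrix (same shape) of observed proportions of
#'   individuals heterozygous *for* each allele in each population.
#' @return theta estimate (scalar) with the per-allele components as
#'   attribute `"components"`.
#' @export
fst_between <- function(allele_counts, het_obs = NULL) {
  x <- as.matrix(allele_counts)
  if (ncol(x) < 2L) stop("need at least 2 populations", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 alleles", call. = FALSE)
  tot <- colSums(x)
  if (any(tot <= 0)) stop("a population has no sampled alleles", call. = FALSE)
  r <- ncol(x)
  ni <- tot / 2                      # individuals per population
  p <- sweep(x, 2, tot, "/")         # allele freq per pop
  if (is.null(het_obs)) het_obs <- 2 * p * (1 - p)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  comp <- t(vapply(seq_len(nrow(x)), function(a) {
    pa <- p[a, ]
    pbar <- sum(ni * pa) / (r * nbar)
    s2 <- sum(ni * (pa - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * het_obs[a, ]) / (r * nbar)
    aa <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    bb <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                   ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a = aa, b = bb, c = cc)
  }, numeric(3)))
  rownames(comp) <- rownames(x)
  theta <- sum(comp[, "a"]) / sum(comp)
  attr(theta, "components") <- comp
  theta
}

#' Genotype association with body weight at one age
#'
#' One-way ANOVA of weight on genotype within a breed-sex group, with
#' Waller-Duncan letter groupings of the genotype means.
#'
#' @param weights numeric vector of weights at one age.
#' @param genotypes genotype labels (factor or character), one per bird.
#' @param k_ratio Waller-Duncan k-ratio.
#' @return list of class `"lm2_assoc"`: `F`, `p`, `code`, `df`, the genotype
#'   means table with letters, and the residual mean square.
#' @export
lm2_assoc <- function(weights, genotypes, k_ratio = 100) {
  g <- factor(as.character(genotypes))
  if (length(weights) != length(g)) stop("length mismatch", call. = FALSE)
  tabn <- table(g)
  if (sum(tabn >= 2L) < 2L || nlevels(g) < 2L)
    stop("need at least 2 genotype classes with at least 2 birds each", call. = FALSE)
  fit <- stats::lm(weights ~ g)
  an <- stats::anova(fit)
  Fv <- an$`F value`[1]; p <- an$`Pr(>F)`[1]
  mse <- an$`Mean Sq`[2]; dfe <- an$Df[2]
  means <- tapply(weights, g, mean)
  wd <- waller_duncan(means, as.numeric(tabn), mse, dfe, f_stat = Fv,
                      k_ratio = k_ratio)
  structure(list(F = Fv, p = p, code = signif_code(p), df = c(an$Df[1], dfe),
                 means = wd, mse = mse), class = "lm2_assoc")
}

#' @export
print.lm2_assoc <- function(x, ...) {
  cat(sprintf("Genotype association: F(%d, %d) = %.3f, p = %.4g %s\n",
              x$df[1], x$df[2], x$F, x$p, x$code))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Per-age genotype association scan
#'
#' Applies [lm2_assoc()] at every recorded age within one breed-sex group,
#' producing the association trajectory (no multiplicity correction by
#' default, with an optional Bonferroni flag).
#'
#' @param data long-format weight table (`bird_id`, `breed`, `sex`,
#'   `age_days`, `weight_g`).
#' @param genotypes data frame with `bird_id` and `genotype` columns.
#' @param breed,sex optional single values to subset one group.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data frame: `age_days`, `F`, `p`, `p_adj`, `code`, `letters`
#'   (letters of the genotype means, largest first).
#' @export
pax7_assoc_scan <- function(data, genotypes, breed = NULL, sex = NULL,
                            adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!is.null(breed)) data <- data[data$breed == breed, ]
  if (!is.null(sex)) data <- data[data$sex == sex, ]
  if (!nrow(data)) stop("no records in the selected group", call. = FALSE)
  gmap <- stats::setNames(as.character(genotypes$genotype),
                          as.character(genotypes$bird_id))
  ages <- sort(unique(data$age_days))
  rows <- lapply(ages, function(a) {
    d <- data[data$age_days == a, ]
    gg <- gmap[as.character(d$bird_id)]
    res <- tryCatch(lm2_assoc(d$weight_g, gg), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(age_days = a, F = NA_real_, p = NA_real_,
                        code = NA_character_, letters = NA_character_))
    data.frame(age_days = a, F = res$F, p = res$p, code = res$code,
               letters = paste(sprintf("%s:%s", res$means$group, res$means$letters),
                               collapse = " "))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = if (adjust == "none") "none" else "bonferroni")
  out[c("age_days", "F", "p", "p_adj", "code", "letters")]
}
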