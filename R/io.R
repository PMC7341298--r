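#' Read a long-format body-weight table
#'
#' Expects a delimited text file (comma or tab, detected from the header)
#' with columns `bird_id`, `breed`, `sex`, `weight_g` and either `age_days`
#' or `week` (weeks are converted to days as `7 * week`; hatch is day 0).
#' Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @return data frame with columns `bird_id`, `breed`, `sex`, `age_days`,
#'   `weight_g`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need_any <- c("age_days", "week")
  need <- c("bird_id", "breed", "sex", "weight_g")
  miss <- setdiff(need, names(d))
  if (length(miss) || !any(need_any %in% names(d)))
    stop("header must provide bird_id, breed, sex, weight_g and age_days or week",
         call. = FALSE)
  if (!"age_days" %in% names(d)) d$age_days <- 7 * d$week
  bad <- which(!is.finite(d$weight_g) | d$weight_g < 0)
  if (length(bad))
    stop("invalid weight on data line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  key <- paste(d$bird_id, d$age_days)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate bird x age record at data line %d (%s)",
                 dup + 1L, key[dup]), call. = FALSE)
  }
  d[c("bird_id", "breed", "sex", "age_days", "weight_g")]
}

#' Write a long-format body-weight table
#'
#' @param data long weight table or a `"synthetic_flock"` object (its
#'   `$data` is written).
#' @param path output path; tab-separated for `.tsv`, comma otherwise.
#' @return the path, invisibly. Writing then reading restores identical
#'   values.
#' @export
write_weights <- function(data, path) {
  if (inherits(data, "synthetic_flock")) data <- data$data
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group summary of fitted growth parameters
#'
#' For each parameterization present in the fit table and each direct or
#' derived parameter: breed-sex group means, a pooled standard error,
#' ANOVA significance codes for breed, sex and their interaction, and
#' Waller-Duncan letters. The degree of maturity is averaged per bird
#' (mean of per-bird BWs/BWa), not computed from ratio of group means; mean
#' adjusted r-squared and AIC per group are appended.
#'
#' @param fits a `"flock_fits"` table from [fit_flock()].
#' @param relationship optional relationship matrix (bird order must match
#'   the per-model bird order of `fits`).
#' @param k_ratio Waller-Duncan k-ratio.
#' @param params which columns to summarize.
#' @return a list of class `"growth_report"`, one element per model, each a
#'   data frame with one row per parameter: group mean columns, `SEM`, `B`,
#'   `S`, `BxS` codes and letter strings.
#' @export
report_growth <- function(fits, relationship = NULL, k_ratio = 100,
                          params = c("BWa", "b", "k", "mu", "lam", "BWip",
                                     "Tip", "MGR", "BWs", "Dm")) {
  stopifnot(is.data.frame(fits))
  out <- list()
  for (m in unique(fits$model)) {
    sub <- fits[fits$model == m & fits$converged, , drop = FALSE]
    grp <- interaction(sub$breed, sub$sex, sep = " ", drop = TRUE)
    if (any(table(grp) == 0) || nlevels(grp) < 2)
      stop("every breed-sex group needs at least one converged fit", call. = FALSE)
    rows <- list()
    for (p in params) {
      y <- sub[[p]]
      an <- lm1_anova(y, sub$breed, sub$sex, relationship = relationship)
      means <- tapply(y, grp, mean)
      ns <- as.numeric(table(grp))
      # pooled standard error of a group mean, harmonic-mean group size
      sem <- sqrt(an$mse / (length(ns) / sum(1 / ns)))
      fb <- an$table
      wd <- waller_duncan(means, ns, an$mse, an$df_res, k_ratio = k_ratio)
      lett <- stats::setNames(wd$letters, wd$group)[levels(grp)]
      row <- as.data.frame(as.list(round_report(p, means)),
                           check.names = FALSE)
      names(row) <- levels(grp)
      row$SEM <- signif(sem, 3)
      row$B <- fb$code[fb$term == "breed"]
      row$S <- fb$code[fb$term == "sex"]
      row$BxS <- fb$code[fb$term == "breed:sex"]
      row$letters <- paste(lett, collapse = "/")
      rows[[p]] <- cbind(parameter = p, row)
    }
    gof <- do.call(rbind, lapply(c("r2_adj", "aic"), function(p) {
      means <- tapply(sub[[p]], grp, mean)
      row <- as.data.frame(as.list(round(means, 3)), check.names = FALSE)
      names(row) <- levels(grp)
      row$SEM <- NA; row$B <- ""; row$S <- ""; row$BxS <- ""; row$letters <- ""
      cbind(parameter = p, row)
    }))
    tab <- rbind(do.call(rbind, rows), gof)
    rownames(tab) <- NULL
    out[[m]] <- tab
  }
  class(out) <- "growth_report"
  out
}

## display rounding mirrors the published convention: weights to integers,
## rates to 1 decimal, k to 3 decimals, shape/lag to 2, Dm to 2
round_report <- function(param, x) {
  switch(param,
         BWa = , BWip = , BWs = round(x),
         MGR = , mu = round(x, 1),
         k = round(x, 3),
         Tip = round(x, 1),
         b = , lam = round(x, 2),
         Dm = round(x, 2),
         signif(x, 4))
}

#' @export
print.growth_report <- function(x, ...) {
  for (m in names(x)) {
    cat("Model", m, "\n")
    print(x[[m]], row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Catalog of published Gompertz parameters for reference breeds/hybrids
#'
#' Bundled literature constants for cross-breed comparison: classical-form
#' Gompertz parameters (female and male) for two fast-growing hybrids
#' (Ross 308 as RS1, Ross 708 as RS2), the medium Hubbard JA57 x Redbro
#' cross (HUB), the Berlanda (B), Padovana Argentata (PA) and Padovana
#' Camosciata (PC) local breeds, and the two Piedmontese breeds Bianca di
#' Saluzzo (BS) and Bionda Piemontese (BP) as published. Values are stored
#' as printed in their sources (the BS/BP MGR row is stored as printed
#' there even though it disagrees slightly with the unrounded group means;
#' see `provenance`).
#'
#' @return data frame: `breed_code`, `description`, `parameter`, `female`,
#'   `male`, `provenance`.
#' @export
comparison_catalog <- function() {
  rows <- list(
    c("RS1", "Ross 308 broiler", "BWa", 6401, 6949),
    c("RS1", "Ross 308 broiler", "b", 4.44, 4.79),
    c("RS1", "Ross 308 broiler", "k", 0.039, 0.042),
    c("RS1", "Ross 308 broiler", "BWip", 2356, 2557),
    c("RS1", "Ross 308 broiler", "Tip", 39, 37),
    c("RS1", "Ross 308 broiler", "MGR", 92, 107),
    c("RS2", "Ross 708 broiler", "BWa", 4664, 5475),
    c("RS2", "Ross 708 broiler", "b", 4.20, 4.62),
    c("RS2", "Ross 708 broiler", "k", 0.036, 0.036),
    c("RS2", "Ross 708 broiler", "BWip", 1716, 2015),
    c("RS2", "Ross 708 broiler", "Tip", 43, 43),
    c("RS2", "Ross 708 broiler", "MGR", 62, 73),
    c("HUB", "Hubbard JA57 x Redbro", "BWa", 3657, 4362),
    c("HUB", "Hubbard JA57 x Redbro", "b", 4.14, 4.37),
    c("HUB", "Hubbard JA57 x Redbro", "k", 0.031, 0.031),
    c("HUB", "Hubbard JA57 x Redbro", "BWip", 1345, 1605),
    c("HUB", "Hubbard JA57 x Redbro", "Tip", 46, 48),
    c("HUB", "Hubbard JA57 x Redbro", "MGR", 42, 50),
    c("B", "Berlanda", "BWa", 2697, 3880),
    c("B", "Berlanda", "b", 4.03, 4.39),
    c("B", "Berlanda", "k", 0.021, 0.019),
    c("B", "Berlanda", "BWip", 992, 1427),
    c("B", "Berlanda", "Tip", 69, 82),
    c("B", "Berlanda", "MGR", 21, 27),
    c("BS", "Bianca di Saluzzo", "BWa", 2184, 3074),
    c("BS", "Bianca di Saluzzo", "b", 3.32, 3.55),
    c("BS", "Bianca di Saluzzo", "k", 0.014, 0.014),
    c("BS", "Bianca di Saluzzo", "BWip", 804, 1131),
    c("BS", "Bianca di Saluzzo", "Tip", 86, 96),
    c("BS", "Bianca di Saluzzo", "MGR", 11, 16),
    c("PA", "Padovana Argentata", "BWa", 2022, 2245),
    c("PA", "Padovana Argentata", "b", 4.35, 4.77),
    c("PA", "Padovana Argentata", "k", 0.021, 0.020),
    c("PA", "Padovana Argentata", "BWip", 744, 826),
    c("PA", "Padovana Argentata", "Tip", 75, 81),
    c("PA", "Padovana Argentata", "MGR", 16, 17),
    c("BP", "Bionda Piemontese", "BWa", 2012, 2745),
    c("BP", "Bionda Piemontese", "b", 3.00, 3.25),
    c("BP", "Bionda Piemontese", "k", 0.016, 0.015),
    c("BP", "Bionda Piemontese", "BWip", 740, 1010),
    c("BP", "Bionda Piemontese", "Tip", 72, 80),
    c("BP", "Bionda Piemontese", "MGR", 12, 15),
    c("PC", "Padovana Camosciata", "BWa", 1979, 2558),
    c("PC", "Padovana Camosciata", "b", 4.01, 4.16),
    c("PC", "Padovana Camosciata", "k", 0.020, 0.019),
    c("PC", "Padovana Camosciata", "BWip", 728, 941),
    c("PC", "Padovana Camosciata", "Tip", 72, 76),
    c("PC", "Padovana Camosciata", "MGR", 15, 18))
  out <- data.frame(
    breed_code = vapply(rows, `[[`, "", 1),
    description = vapply(rows, `[[`, "", 2),
    parameter = vapply(rows, `[[`, "", 3),
    female = as.numeric(vapply(rows, `[[`, "", 4)),
    male = as.numeric(vapply(rows, `[[`, "", 5)),
    stringsAsFactors = FALSE)
  out$provenance <- "published growth-curve comparison, values as printed"
  out
}

#' Catalog of published actual body weights at reference ages
#'
#' Average actual weights (both sexes pooled) of reference populations at
#' standard ages, for positioning a flock between heavy, medium and light
#' types. `NA` marks ages not reported for a population.
#'
#' @return data frame: `breed_code`, `age_days`, `weight_g`.
#' @export
actual_weight_catalog <- function() {
  codes <- c("RS", "SA", "RM", "ER", "MIL", "CN", "BS", "BP", "BR", "PD", "MO", "RO", "PE")
  ages <- c(42, 84, 108, 140, 150, 168, 175, 180, 190, 210)
  w <- rbind(
    c(2936, NA, NA, NA, NA, 396, 385, 448, NA, NA, NA, NA, NA),
    c(NA, 2300, NA, NA, NA, 1095, 1000, 1086, NA, NA, NA, NA, NA),
    c(NA, NA, NA, NA, NA, NA, NA, NA, 1300, NA, NA, NA, NA),
    c(NA, NA, NA, 2186, NA, 1812, 1623, 1632, 1800, NA, NA, NA, NA),
    c(NA, NA, NA, NA, 2381, NA, NA, NA, NA, 1536, NA, NA, NA),
    c(NA, NA, NA, 2395, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    c(NA, NA, 2250, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    c(NA, NA, NA, NA, 2541, NA, 2068, 2020, NA, 1800, NA, NA, NA),
    c(NA, NA, NA, 2900, NA, NA, NA, NA, NA, 2100, NA, NA, 1500),
    c(NA, NA, NA, NA, NA, NA, 2220, 2147, NA, NA, 2142, 2175, NA))
  idx <- which(!is.na(w), arr.ind = TRUE)
  data.frame(breed_code = codes[idx[, 2]],
             age_days = ages[idx[, 1]],
             weight_g = w[idx],
             stringsAsFactors = FALSE)
}

#' Cross-breed comparison table with dimorphism statistics
#'
#' Appends the user's fitted breed rows (per-sex group means of the
#' classical-form parameters) to the bundled literature catalog and adds
#' the sexual-dimorphism percentage computed by [dimorphism_delta()]
#' (rounded to integers for display, as customary).
#'
#' @param fits optional `"flock_fits"` table; its G1 rows are summarized by
#'   breed and sex. Breeds missing one sex get `NA` markers.
#' @param catalog the literature catalog (default [comparison_catalog()]).
#' @param params parameters to include.
#' @return data frame: `breed_code`, `parameter`, `female`, `male`, `delta`.
#' @export
compare_breeds <- function(fits = NULL, catalog = comparison_catalog(),
                           params = c("BWa", "b", "k", "BWip", "Tip", "MGR")) {
  out <- catalog[catalog$parameter %in% params,
                 c("breed_code", "parameter", "female", "male")]
  if (!is.null(fits)) {
    sub <- fits[fits$model == "G1" & fits$converged, , drop = FALSE]
    for (br in unique(sub$breed)) {
      for (p in params) {
        fm <- mean(sub[[p]][sub$breed == br & sub$sex == "F"])
        mm <- mean(sub[[p]][sub$breed == br & sub$sex == "M"])
        out <- rbind(out, data.frame(
          breed_code = paste0(br, "*"), parameter = p,
          female = ifelse(is.nan(fm), NA, fm),
          male = ifelse(is.nan(mm), NA, mm)))
      }
    }
  }
  out$delta <- ifelse(is.na(out$female) | is.na(out$male), NA,
                      round(dimorphism_delta(out$female, out$male)))
  rownames(out) <- NULL
  out
}

#' Published group-mean growth parameters of the two Piedmontese breeds
#'
#' The study-level group means (both parameterizations, by breed and sex)
#' that the synthetic generator uses as truth and the acceptance checks use
#' as inputs. The classical-form female asymptote of the Bionda Piemontese
#' is stored as 2012 g (the per-sex comparison-table value; the group table
#' prints a typographic "201").
#'
#' @return data frame: `model`, `breed`, `sex`, and parameter columns
#'   (`BWa`, `b`, `k` for G1; `BWa`, `mu`, `lam` for G2).
#' @export
reference_growth_params <- function() {
  g1 <- data.frame(model = "G1",
                   breed = c("BS", "BS", "BP", "BP"),
                   sex = c("F", "M", "F", "M"),
                   BWa = c(2184, 3074, 2012, 2745),
                   b = c(3.32, 3.55, 2.99, 3.25),
                   k = c(0.014, 0.014, 0.016, 0.015),
                   mu = NA, lam = NA, stringsAsFactors = FALSE)
  g2 <- data.frame(model = "G2",
                   breed = c("BS", "BS", "BP", "BP"),
                   sex = c("F", "M", "F", "M"),
                   BWa = c(2508, 3383, 2193, 2819),
                   b = NA, k = NA,
                   mu = c(11.84, 15.83, 11.78, 15.65),
                   lam = c(14.35, 20.63, 7.47, 12.58),
                   stringsAsFactors = FALSE)
  rbind(g1, g2)
}
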