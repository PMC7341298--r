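#' Fit Gompertz curves to every bird in a long-format weight table
#'
#' Per-bird fits only: group-level curves are summarized as means of
#' per-bird parameters, never as pooled fits, so printed group means can
#' differ slightly from algebra on rounded group-mean parameters.
#'
#' @param data long-format data frame with columns `bird_id`, `breed`,
#'   `sex`, `age_days`, `weight_g` (as produced by [simulate_flock()] or
#'   [read_weights()]).
#' @param model `"G1"`, `"G2"` or `"both"`.
#' @param t_slaughter slaughter age (days) for derived traits.
#' @param control a [gompertz_control()] list.
#' @return A data frame of class `c("flock_fits", "data.frame")`, one row
#'   per bird and model, carrying both parameterizations (the unfitted one
#'   obtained by exact conversion), the derived traits, and goodness of
#'   fit (`rss`, `r2_adj`, `aic`, `converged`).
#' @export
fit_flock <- function(data, model = c("both", "G1", "G2"), t_slaughter = 180,
                      control = gompertz_control()) {
  model <- match.arg(model)
  models <- if (model == "both") c("G1", "G2") else model
  need <- c("bird_id", "breed", "sex", "age_days", "weight_g")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  birds <- split(data[c("age_days", "weight_g")], data$bird_id)
  meta <- data[!duplicated(data$bird_id), c("bird_id", "breed", "sex")]
  rownames(meta) <- as.character(meta$bird_id)
  rows <- vector("list", length(birds) * length(models))
  i <- 0L
  for (id in names(birds)) {
    tr <- validate_trajectory(birds[[id]]$age_days, birds[[id]]$weight_g,
                              min_obs = control$min_obs)
    engs <- list()
    for (m in models) {
      init <- default_init(tr$t, tr$w, m)
      engs[[m]] <- fit_gompertz_engine(tr$t, tr$w, m, init, control)
    }
    if (length(models) == 2L && engs$G1$converged && engs$G2$converged) {
      # multi-start across parameterizations: the better optimum seeds a
      # refit of the other form, so both describe the same best curve
      for (r in 1:10) {
        if (engs$G1$rss > engs$G2$rss * (1 + 1e-12)) {
          ini <- suppressWarnings(convert_g2_to_g1(
            g2_params(engs$G2$par[1], engs$G2$par[2], engs$G2$par[3])))
          cand <- fit_gompertz_engine(tr$t, tr$w, "G1", ini, control)
          if (cand$converged && cand$rss < engs$G1$rss) engs$G1 <- cand else break
        } else if (engs$G2$rss > engs$G1$rss * (1 + 1e-12)) {
          ini <- suppressWarnings(convert_g1_to_g2(
            g1_params(engs$G1$par[1], engs$G1$par[2], engs$G1$par[3])))
          cand <- fit_gompertz_engine(tr$t, tr$w, "G2", ini, control)
          if (cand$converged && cand$rss < engs$G2$rss) engs$G2 <- cand else break
        } else break
      }
    }
    for (m in models) {
      fit <- build_gompertz_fit(engs[[m]], tr, m, t_slaughter)
      i <- i + 1L
      rows[[i]] <- flock_fit_row(id, meta[id, ], fit)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flock_fits", "data.frame")
  out
}

flock_fit_row <- function(id, meta, fit) {
  na <- NA_real_
  row <- data.frame(bird_id = id, breed = as.character(meta$breed),
                    sex = as.character(meta$sex), model = fit$model,
                    BWa = na, b = na, k = na, mu = na, lam = na,
                    BWip = na, Tip = na, MGR = na, BWs = na, Dm = na,
                    BW0_implied = na,
                    rss = fit$rss, r2_adj = fit$r2_adj, aic = fit$aic,
                    converged = fit$converged, stringsAsFactors = FALSE)
  if (fit$converged) {
    p1 <- if (fit$model == "G1") fit$params else suppressWarnings(convert_g2_to_g1(fit$params))
    p2 <- if (fit$model == "G2") fit$params else suppressWarnings(convert_g1_to_g2(fit$params))
    row$BWa <- fit$params$BWa
    row$b <- p1$b; row$k <- p1$k; row$mu <- p2$mu; row$lam <- p2$lam
    row[c("BWip", "Tip", "MGR", "BWs", "Dm", "BW0_implied")] <- unlist(fit$derived)
  }
  row
}

#' Per-age correlation between actual and fitted weights
#'
#' Pearson correlation computed column-wise across birds. Columns with zero
#' variance (e.g. hatch weight recorded identically for every bird) return
#' `NA` rather than raising an error, mirroring the absence of a defined
#' correlation at hatching.
#'
#' @param actual,fitted numeric matrices, birds in rows, ages in columns,
#'   identical dimensions.
#' @return named numeric vector of per-column correlations.
#' @export
weekly_correlation <- function(actual, fitted) {
  actual <- as.matrix(actual); fitted <- as.matrix(fitted)
  if (!all(dim(actual) == dim(fitted)))
    stop("actual and fitted matrices must have identical dimensions", call. = FALSE)
  out <- vapply(seq_len(ncol(actual)), function(j) {
    a <- actual[, j]; f <- fitted[, j]
    if (stats::sd(a) == 0 || stats::sd(f) == 0) return(NA_real_)
    stats::cor(a, f)
  }, numeric(1))
  names(out) <- colnames(actual)
  out
}

#' Correlation matrix of fitted and derived growth parameters
#'
#' Pearson correlations across birds between the direct parameters of the
#' chosen parameterization and the derived traits. The inflection weight is
#' a fixed multiple (1/e) of the asymptote, so their correlation is exactly 1.
#'
#' @param fits a `"flock_fits"` table from [fit_flock()].
#' @param model which model's rows to use when both are present.
#' @param vars columns to correlate.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(fits, model = "G1",
                                   vars = c("BWa", "b", "k", "mu", "lam",
                                            "BWip", "Tip", "MGR", "BWs", "Dm")) {
  stopifnot(is.data.frame(fits))
  sub <- fits[fits$model == model & fits$converged, vars, drop = FALSE]
  if (nrow(sub) < 3L)
    stop("at least 3 converged fits are required", call. = FALSE)
  stats::cor(as.matrix(sub))
}

#' Reshape a long weight table to a bird-by-age matrix
#'
#' @param data long-format weight table (see [fit_flock()]).
#' @param value column to spread (default `weight_g`).
#' @return numeric matrix, birds in rows (named), ages in columns (named by
#'   age in days).
#' @export
weights_matrix <- function(data, value = "weight_g") {
  ages <- sort(unique(data$age_days))
  ids <- unique(data$bird_id)
  m <- matrix(NA_real_, length(ids), length(ages),
              dimnames = list(as.character(ids), as.character(ages)))
  m[cbind(match(data$bird_id, ids), match(data$age_days, ages))] <- data[[value]]
  m
}
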