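#' Control settings for Gompertz fitting
#'
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol relative tolerances on the residual sum of squares and
#'   on the parameters; convergence is declared when either is met.
#' @param bwa_upper_factor upper bound on the asymptote as a multiple of the
#'   largest observed weight (prevents asymptote run-away on flat data).
#' @param min_obs minimum number of observations accepted (default 5; three
#'   points exactly determine the three parameters, so lowering this is only
#'   sensible for interpolation checks).
#' @return A list of class `"gompertz_control"`.
#' @export
gompertz_control <- function(maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                             bwa_upper_factor = 10, min_obs = 5L) {
  structure(list(maxiter = maxiter, ftol = ftol, ptol = ptol,
                 bwa_upper_factor = bwa_upper_factor, min_obs = min_obs),
            class = "gompertz_control")
}

validate_trajectory <- function(t, w, min_obs = 5L) {
  if (length(t) != length(w)) stop("ages and weights differ in length", call. = FALSE)
  keep <- is.finite(t) & is.finite(w)
  t <- t[keep]; w <- w[keep]
  if (length(t) < min_obs)
    stop(sprintf("at least %d observations are required to fit a 3-parameter growth curve",
                 min_obs), call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  o <- order(t)
  t <- t[o]; w <- w[o]
  if (anyDuplicated(t)) stop("duplicate ages in trajectory", call. = FALSE)
  if (stats::sd(w) < 1e-8 * mean(w))
    stop("degenerate trajectory: no growth signal (constant weights)", call. = FALSE)
  list(t = t, w = w)
}

#' Starting values for a Gompertz fit
#'
#' Self-starting heuristic: the asymptote is initialised at 1.2 times the
#' largest observed weight, the shape parameter at `ln(BWa0/first weight)`,
#' and the rate constant from an ordinary regression of
#' `ln(-ln(w/BWa0))` on age (the classical Gompertz linearization). The
#' lag-time form is initialised by converting the classical starting values.
#' Degenerate inputs fall back to fixed defaults (BWa 2500 g, b 3.5,
#' k 0.015/day), typical of a medium slow-growing chicken.
#'
#' @param t ages in days.
#' @param w weights in g.
#' @param model `"G1"` or `"G2"`.
#' @return A [g1_params()] or [g2_params()] object.
#' @export
default_init <- function(t, w, model = c("G1", "G2")) {
  model <- match.arg(model)
  init <- tryCatch({
    BWa0 <- 1.2 * max(w)
    if (w[1] >= BWa0) stop("degenerate")
    b0 <- log(BWa0 / w[1])
    ok <- w < BWa0 & w > 0
    y <- log(-log(w[ok] / BWa0))
    sl <- stats::coef(stats::lm(y ~ t[ok]))[2]
    k0 <- -as.numeric(sl)
    if (!is.finite(k0) || k0 <= 0) stop("degenerate")
    g1_params(BWa = BWa0, b = b0, k = min(k0, 0.9))
  }, error = function(e) g1_params(BWa = 2500, b = 3.5, k = 0.015))
  if (model == "G2") suppressWarnings(convert_g1_to_g2(init)) else init
}

## Fast internal fitting path: residuals + analytic Jacobian through
## minpack.lm::nls.lm with box bounds. Used by both gompertz_fit() and
## fit_flock(); keeps per-bird overhead low for simulation studies.
fit_gompertz_engine <- function(t, w, model, init, control) {
  maxw <- max(w)
  eps <- 1e-8
  if (model == "G1") {
    lower <- c(BWa = maxw * (1 + 1e-9), b = 0.1, k = 1e-4)
    upper <- c(BWa = control$bwa_upper_factor * maxw, b = 20, k = 1)
    start <- c(BWa = init$BWa, b = init$b, k = init$k)
    resid_fn <- function(p) w - p[1] * exp(-p[2] * exp(-p[3] * t))
    jac_fn <- function(p) {
      ekt <- exp(-p[3] * t)
      core <- exp(-p[2] * ekt)
      cbind(-core, p[1] * core * ekt, -p[1] * core * p[2] * t * ekt)
    }
  } else {
    lower <- c(BWa = maxw * (1 + 1e-9), mu = 1e-3, lam = -200)
    upper <- c(BWa = control$bwa_upper_factor * maxw, mu = 1e3, lam = 400)
    start <- c(BWa = init$BWa, mu = init$mu, lam = init$lam)
    resid_fn <- function(p) {
      eta <- (exp(1) * p[2] / p[1]) * (p[3] - t) + 1
      w - p[1] * exp(-exp(eta))
    }
    jac_fn <- function(p) {
      eta <- (exp(1) * p[2] / p[1]) * (p[3] - t) + 1
      ee <- exp(eta)
      core <- exp(-ee)
      dBWa <- core * (1 + ee * (exp(1) * p[2] / p[1]) * (p[3] - t))
      dmu <- -core * ee * exp(1) * (p[3] - t)
      dlam <- -core * ee * exp(1) * p[2]
      cbind(-dBWa, -dmu, -dlam)
    }
  }
  start <- pmin(pmax(start, lower + eps), upper - eps)
  ctl <- minpack.lm::nls.lm.control(maxiter = control$maxiter,
                                    ftol = control$ftol, ptol = control$ptol)
  run_lm <- function(st) tryCatch(
    minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                       fn = resid_fn, jac = jac_fn, control = ctl),
    error = function(e) NULL)
  res <- run_lm(start)
  # restart-polish: restarting resets the trust region, which matters when a
  # box constraint (typically the asymptote floor) is active at the optimum
  if (!is.null(res)) {
    for (r in 1:4) {
      rss_prev <- res$deviance
      res2 <- run_lm(res$par)
      if (is.null(res2)) break
      res <- res2
      if (rss_prev - res$deviance <= 1e-10 * max(rss_prev, 1e-30)) break
    }
  }
  if (is.null(res)) {
    return(list(par = start, converged = FALSE, fitted = rep(NA_real_, length(w)),
                rss = NA_real_, message = "optimizer error"))
  }
  par <- res$par
  converged <- res$info %in% 1:4 && all(is.finite(par))
  fitted <- w - resid_fn(par)
  list(par = par, converged = converged, fitted = fitted,
       rss = sum((w - fitted)^2), message = res$message)
}

#' Fit a Gompertz growth curve to one bird's trajectory
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt with box bounds)
#' of either Gompertz parameterization to a longitudinal weight record.
#' Bounds keep the asymptote above the largest observed weight and below
#' ten times it, the shape in (0.1, 20] and the rate in (1e-4, 1), which
#' prevents asymptote collapse on trajectories with a biphasic slowdown.
#'
#' @param formula a two-sided formula `weight ~ age` with weight in g and
#'   age in days.
#' @param data a data frame in which the formula is evaluated.
#' @param model which parameterization to fit: `"G1"` (classical) or
#'   `"G2"` (lag-time form).
#' @param init optional starting parameters ([g1_params()]/[g2_params()]);
#'   [default_init()] is used when absent.
#' @param t_slaughter slaughter age in days for the derived traits.
#' @param control a [gompertz_control()] list.
#' @return An object of class `"gompertz_fit"`: parameters, derived traits,
#'   residual sum of squares, adjusted r-squared, AIC, convergence flag and
#'   fitted weights. Non-convergence is reported through the `converged`
#'   flag, never silently.
#' @examples
#' d <- data.frame(age = seq(0, 224, 14))
#' d$weight <- predict_g1(g1_params(2500, 3.4, 0.015), d$age)
#' f <- gompertz_fit(weight ~ age, d)
#' coef(f)
#' @export
gompertz_fit <- function(formula, data, model = c("G1", "G2"), init = NULL,
                         t_slaughter = 180, control = gompertz_control()) {
  model <- match.arg(model)
  mf <- stats::model.frame(formula, data)
  w <- as.numeric(stats::model.response(mf))
  t <- as.numeric(mf[[2L]])
  tr <- validate_trajectory(t, w, min_obs = control$min_obs)
  if (is.null(init)) init <- default_init(tr$t, tr$w, model)
  if (model == "G1" && !inherits(init, "g1_params"))
    stop("'init' must be a g1_params object for model G1", call. = FALSE)
  if (model == "G2" && !inherits(init, "g2_params"))
    stop("'init' must be a g2_params object for model G2", call. = FALSE)
  eng <- fit_gompertz_engine(tr$t, tr$w, model, init, control)
  build_gompertz_fit(eng, tr, model, t_slaughter, match.call())
}

build_gompertz_fit <- function(eng, tr, model, t_slaughter, call = NULL) {
  n <- length(tr$w)
  params <- NULL
  derived <- NULL
  gof <- list(r2_adj = NA_real_, aic = NA_real_)
  if (eng$converged) {
    params <- if (model == "G1")
      g1_params(eng$par[1], eng$par[2], eng$par[3])
    else
      suppressWarnings(g2_params(eng$par[1], eng$par[2], eng$par[3]))
    derived <- suppressWarnings(derive_traits(params, t_slaughter = t_slaughter))
  }
  out <- structure(list(
    model = model,
    params = params,
    coefficients = eng$par,
    derived = derived,
    rss = eng$rss,
    n_obs = n,
    n_params = 3L,
    converged = eng$converged,
    fitted_weights = eng$fitted,
    data = list(t = tr$t, w = tr$w),
    t_slaughter = t_slaughter,
    message = eng$message,
    call = call), class = "gompertz_fit")
  out$r2_adj <- NA_real_
  out$aic <- NA_real_
  if (eng$converged) {
    gof <- tryCatch(goodness(out), error = function(e) NULL)
    if (!is.null(gof)) {
      out$r2_adj <- gof$r2_adj
      out$aic <- gof$aic
    }
  }
  out
}

#' Goodness of fit of a Gompertz fit
#'
#' Adjusted coefficient of determination
#' `r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)` and Akaike's information
#' criterion computed as `n*ln(rss/n) + 2*(p + 1)` (the residual variance
#' counted as an estimated parameter). Only AIC *orderings* between the two
#' parameterizations are meaningful, not absolute values. A perfect fit
#' returns `r2_adj = 1` and an `-Inf` AIC sentinel.
#'
#' @param fit a converged `"gompertz_fit"`.
#' @return list with `r2_adj` and `aic`.
#' @export
goodness <- function(fit) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!isTRUE(fit$converged)) stop("goodness() requires a converged fit", call. = FALSE)
  n <- fit$n_obs; p <- fit$n_params
  if (n <= p + 1L)
    stop("adjusted r-squared undefined: need more observations than parameters + 1",
         call. = FALSE)
  tss <- sum((fit$data$w - mean(fit$data$w))^2)
  if (fit$rss <= .Machine$double.eps * tss)
    return(list(r2_adj = 1, aic = -Inf))
  r2 <- 1 - fit$rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2_adj = r2_adj, aic = n * log(fit$rss / n) + 2 * (p + 1))
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Gompertz fit (%s form), %d observations\n", x$model, x$n_obs))
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  print(round(x$coefficients, digits))
  cat(sprintf("  rss %.4g g^2   adj r2 %.4f   AIC %.2f\n", x$rss, x$r2_adj, x$aic))
  invisible(x)
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  out <- object
  class(out) <- "summary.gompertz_fit"
  out
}

#' @export
print.summary.gompertz_fit <- function(x, digits = 4, ...) {
  class(x) <- "gompertz_fit"
  print(x, digits = digits)
  if (x$converged) {
    cat("Derived traits (slaughter age", x$t_slaughter, "d):\n")
    print(round(unlist(x$derived), digits))
  }
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) object$coefficients

#' @export
fitted.gompertz_fit <- function(object, ...) object$fitted_weights

#' @export
residuals.gompertz_fit <- function(object, ...) object$data$w - object$fitted_weights

#' @export
predict.gompertz_fit <- function(object, newdata = NULL, t = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit", call. = FALSE)
  if (is.null(t)) {
    t <- if (is.null(newdata)) object$data$t else {
      stopifnot(is.list(newdata))
      as.numeric(newdata[[1L]])
    }
  }
  if (object$model == "G1") predict_g1(object$params, t) else predict_g2(object$params, t)
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$w, xlab = "age (d)", ylab = "body weight (g)",
                 main = sprintf("Gompertz %s fit", x$model), ...)
  if (x$converged) {
    tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
    graphics::lines(tt, predict(x, t = tt), col = "steelblue", lwd = 2)
    graphics::abline(v = x$derived$Tip, lty = 3)
  }
  invisible(x)
}

#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cv <- stats::sd(residuals(object) / fitted(object))
  f <- fitted(object)
  out <- as.data.frame(replicate(nsim, f * (1 + stats::rnorm(length(f), 0, cv))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
AIC.gompertz_fit <- function(object, ..., k = 2) object$aic
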