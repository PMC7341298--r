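#' Design of a synthetic flock
#'
#' Encodes the longitudinal study structure the generator emulates: four
#' breed-by-sex groups (46 and 47 Bianca di Saluzzo females and males, 54
#' Bionda Piemontese of each sex), biweekly weighings from hatch to 224
#' days (17 ages), group-level Gompertz truth taken from the published
#' group means, log-normal between-bird parameter variation, multiplicative
#' measurement noise, an optional biphasic slowdown window, a two-allele
#' minisatellite genotype model and unlinked markers for the relationship
#' matrix.
#'
#' Default between-bird coefficients of variation are back-calculated from
#' published standard errors of the group means (SEM times sqrt(n) over the
#' mean): 0.16 for the asymptote and 0.11 for the shape; the rate constant's
#' SEM prints as 0.000 at the published precision, so its CV is set to 0.10,
#' the same order as the shape.
#'
#' @param groups data frame with columns `breed`, `sex`, `n`, `BWa`, `b`,
#'   `k` (classical-form truth per group).
#' @param schedule weighing ages in days, strictly increasing from 0.
#' @param noise_cv multiplicative measurement noise (weight is multiplied
#'   by `1 + N(0, noise_cv)`).
#' @param cv named between-bird CVs for `BWa`, `b`, `k`.
#' @param biphasic `NULL`, or `list(window = c(start, end) days,
#'   multiplier)` applied to growth increments inside the window.
#' @param genotype list with `freq` (per-breed named allele frequency
#'   vectors, or one vector for all), `effect` (g added per G allele from
#'   `onset`), `onset` (days).
#' @param n_markers,alleles_per_marker unlinked markers simulated for the
#'   allele-sharing relationship matrix.
#' @return object of class `"flock_design"`.
#' @export
flock_design <- function(groups = default_groups(),
                         schedule = seq(0, 224, by = 14),
                         noise_cv = 0.05,
                         cv = c(BWa = 0.16, b = 0.11, k = 0.10),
                         biphasic = NULL,
                         genotype = list(freq = list(BS = c(F = 0.65, G = 0.35),
                                                     BP = c(F = 0.55, G = 0.45)),
                                         effect = 0, onset = 98),
                         n_markers = 20, alleles_per_marker = 5) {
  stopifnot(is.data.frame(groups),
            all(c("breed", "sex", "n", "BWa", "b", "k") %in% names(groups)))
  if (any(groups$n <= 0)) stop("group sizes must be positive", call. = FALSE)
  if (any(groups$BWa <= 0 | groups$b <= 0 | groups$k <= 0))
    stop("group Gompertz parameters must be positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (length(schedule) < 2L || any(diff(schedule) <= 0) || schedule[1] != 0)
    stop("schedule must be strictly increasing and start at day 0", call. = FALSE)
  if (!all(c("BWa", "b", "k") %in% names(cv)) || any(cv < 0))
    stop("cv must name non-negative BWa, b, k entries", call. = FALSE)
  if (!is.null(biphasic)) {
    if (!is.list(biphasic) || is.null(biphasic$window) || is.null(biphasic$multiplier))
      stop("biphasic must be list(window=, multiplier=)", call. = FALSE)
    if (biphasic$multiplier < 0) stop("biphasic multiplier must be >= 0", call. = FALSE)
    if (biphasic$window[1] < min(schedule) || biphasic$window[2] > max(schedule))
      stop("biphasic window lies outside the weighing schedule", call. = FALSE)
  }
  structure(list(groups = groups, schedule = schedule, noise_cv = noise_cv,
                 cv = cv, biphasic = biphasic, genotype = genotype,
                 n_markers = n_markers, alleles_per_marker = alleles_per_marker),
            class = "flock_design")
}

#' @rdname flock_design
#' @export
default_groups <- function() {
  data.frame(breed = c("BS", "BS", "BP", "BP"),
             sex = c("F", "M", "F", "M"),
             n = c(46L, 47L, 54L, 54L),
             BWa = c(2184, 3074, 2012, 2745),
             b = c(3.32, 3.55, 2.99, 3.25),
             k = c(0.014, 0.014, 0.016, 0.015),
             stringsAsFactors = FALSE)
}

#' @export
print.flock_design <- function(x, ...) {
  cat("Synthetic flock design:", sum(x$groups$n), "birds,",
      length(x$schedule), "weighing ages (0 to", max(x$schedule), "d)\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("noise CV %.3f; between-bird CVs BWa %.2f b %.2f k %.2f\n",
              x$noise_cv, x$cv["BWa"], x$cv["b"], x$cv["k"]))
  invisible(x)
}

## mean-preserving log-normal draw around m with coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s <- sqrt(log(1 + cv^2))
  m * exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate a flock with known ground truth
#'
#' Per bird, true classical-form parameters are drawn log-normally
#' (mean-preserving) around the group truth with the design CVs; noiseless
#' weights follow the Gompertz curve at the schedule ages; the optional
#' biphasic slowdown rescales growth increments inside its window; a
#' genotype is drawn under random mating from the breed allele frequencies
#' and its additive effect (grams per G allele) is added from the onset age
#' onwards; finally multiplicative measurement noise is applied. Marker
#' genotypes for the relationship matrix are simulated independently. The
#' whole dataset is a deterministic function of the seed.
#'
#' @param design a [flock_design()].
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param with_markers simulate marker genotypes and the allele-sharing
#'   relationship matrix (default `TRUE`; marker simulation happens after
#'   the weight records, so turning it off does not change them).
#' @return object of class `"synthetic_flock"`: `data` (long weight table),
#'   `genotypes` (with fragment lengths), `markers`, `relationship`,
#'   `truth` (per-bird true parameters and genotype effect) and the design.
#' @examples
#' flock <- simulate_flock(flock_design(), seed = 1)
#' nrow(flock$data)  # 201 birds x 17 ages
#' @export
simulate_flock <- function(design = flock_design(), seed = NULL,
                           with_markers = TRUE) {
  stopifnot(inherits(design, "flock_design"))
  if (!is.null(seed)) set.seed(seed)
  sched <- design$schedule
  groups <- design$groups
  amod <- allele_model()
  data_rows <- list(); truth_rows <- list(); geno_rows <- list()
  bird_no <- 0L
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    BWa_i <- rlnorm_cv(g$n, g$BWa, design$cv["BWa"])
    b_i <- rlnorm_cv(g$n, g$b, design$cv["b"])
    k_i <- rlnorm_cv(g$n, g$k, design$cv["k"])
    freqs <- design$genotype$freq
    fr <- if (is.list(freqs)) {
      if (!is.null(freqs[[g$breed]])) freqs[[g$breed]] else freqs[[1]]
    } else freqs
    for (bi in seq_len(g$n)) {
      bird_no <- bird_no + 1L
      id <- sprintf("%s_%s_%03d", g$breed, g$sex, bi)
      pars <- g1_params(BWa_i[bi], b_i[bi], k_i[bi])
      w <- predict_g1(pars, sched)
      if (!is.null(design$biphasic))
        w <- apply_biphasic(w, sched, design$biphasic$window,
                            design$biphasic$multiplier)
      al <- sample(names(fr), 2L, replace = TRUE, prob = fr)
      n_g <- sum(al == "G")
      if (design$genotype$effect != 0)
        w <- w + n_g * design$genotype$effect * (sched >= design$genotype$onset)
      if (design$noise_cv > 0)
        w <- pmax(w * (1 + stats::rnorm(length(w), 0, design$noise_cv)), 1e-6)
      data_rows[[bird_no]] <- data.frame(
        bird_id = id, breed = g$breed, sex = g$sex,
        age_days = sched, weight_g = w, stringsAsFactors = FALSE)
      al <- sort(al)
      geno_rows[[bird_no]] <- data.frame(
        bird_id = id,
        length1 = as.numeric(amod$reference_lengths[al[1]]),
        length2 = as.numeric(amod$reference_lengths[al[2]]),
        allele1 = al[1], allele2 = al[2],
        genotype = paste(al, collapse = ""), stringsAsFactors = FALSE)
      truth_rows[[bird_no]] <- data.frame(
        bird_id = id, breed = g$breed, sex = g$sex,
        BWa = BWa_i[bi], b = b_i[bi], k = k_i[bi],
        n_g_alleles = n_g, stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, data_rows)
  truth <- do.call(rbind, truth_rows)
  genotypes <- do.call(rbind, geno_rows)
  markers <- NULL; relationship <- NULL
  if (with_markers) {
    markers <- simulate_markers(bird_no, design$n_markers,
                                design$alleles_per_marker)
    dimnames(markers)[[1]] <- truth$bird_id
    relationship <- relationship_from_markers(markers)
  }
  structure(list(data = data, genotypes = genotypes, markers = markers,
                 relationship = relationship, truth = truth,
                 design = design, seed = seed),
            class = "synthetic_flock")
}

#' @export
print.synthetic_flock <- function(x, ...) {
  cat("Synthetic flock:", nrow(x$truth), "birds,",
      length(unique(x$data$age_days)), "ages,",
      nrow(x$data), "weight records\n")
  print(table(x$truth$breed, x$truth$sex))
  invisible(x)
}

#' Apply a biphasic growth slowdown to a trajectory
#'
#' Growth increments between consecutive weighings whose interval overlaps
#' the window are scaled by the multiplier (values below 1 flatten the
#' curve); increments outside are untouched, so trajectories stay
#' non-decreasing for any non-negative multiplier. This reproduces, on
#' synthetic data, the temporary slowdown at 13-21 weeks that a single
#' sigmoid underfits.
#'
#' @param weights weights at the schedule ages.
#' @param times schedule ages in days.
#' @param window `c(start, end)` in days, inside the schedule span.
#' @param multiplier non-negative increment scale factor.
#' @return modified weight vector.
#' @export
apply_biphasic <- function(weights, times, window = c(91, 147), multiplier = 0.4) {
  stopifnot(length(weights) == length(times))
  if (multiplier < 0) stop("multiplier must be >= 0", call. = FALSE)
  if (window[1] < min(times) || window[2] > max(times))
    stop("window lies outside the schedule span", call. = FALSE)
  inc <- diff(weights)
  lo <- times[-length(times)]; hi <- times[-1]
  inside <- hi > window[1] & lo < window[2]
  inc[inside] <- inc[inside] * multiplier
  cumsum(c(weights[1], inc))
}

#' Simulate unlinked marker genotypes
#'
#' Independent diploid genotypes at `n_markers` loci with
#' `alleles_per_marker` equifrequent alleles, optionally organised in
#' full-sib family blocks (each family has two simulated parents and the
#' children sample one parental allele from each), which creates the
#' within-family excess similarity an allele-sharing relationship matrix
#' should detect.
#'
#' @param n_birds number of birds.
#' @param n_markers number of loci.
#' @param alleles_per_marker alleles per locus.
#' @param n_families 0 for unrelated birds; otherwise birds are split into
#'   this many full-sib families.
#' @param seed optional seed.
#' @return integer array `n_birds x n_markers x 2`.
#' @export
simulate_markers <- function(n_birds, n_markers, alleles_per_marker = 5,
                             n_families = 0, seed = NULL) {
  if (n_birds < 1 || n_markers < 1 || alleles_per_marker < 2)
    stop("counts must be positive (and at least 2 alleles per marker)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- array(NA_integer_, c(n_birds, n_markers, 2))
  if (n_families <= 0) {
    g[] <- sample.int(alleles_per_marker, n_birds * n_markers * 2, replace = TRUE)
  } else {
    fam <- rep(seq_len(n_families), length.out = n_birds)
    for (f in seq_len(n_families)) {
      kids <- which(fam == f)
      sire <- matrix(sample.int(alleles_per_marker, n_markers * 2, TRUE), n_markers, 2)
      dam <- matrix(sample.int(alleles_per_marker, n_markers * 2, TRUE), n_markers, 2)
      for (kid in kids) {
        g[kid, , 1] <- sire[cbind(seq_len(n_markers),
                                  sample(1:2, n_markers, TRUE))]
        g[kid, , 2] <- dam[cbind(seq_len(n_markers),
                                 sample(1:2, n_markers, TRUE))]
      }
    }
  }
  g
}
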