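#' Analytic fractal dimension of a generator family
#'
#' @param family one of `"uniform_hypercube"`, `"line"`, `"plane"`,
#'   `"cantor_product"`, `"sierpinski_carpet_extrusion"`.
#' @param dim embedding dimension (3 or 4).
#' @return the exact Minkowski-Bouligand dimension of the generated set.
#' @export
analytic_dimension <- function(family, dim) {
  switch(family,
         uniform_hypercube = dim,
         line = 1,
         plane = 2,
         cantor_product = dim * log(2) / log(3),
         sierpinski_carpet_extrusion = log(8) / log(3) + 1,
         stop_fd4d("unknown fractal family '%s'", family))
}

#' Generate a point cloud of analytically known fractal dimension
#'
#' Validation fixtures for the box-counting estimator.  Families:
#' \describe{
#'   \item{line}{`n_points` evenly spaced points on the main diagonal
#'     (deterministic); dimension 1.}
#'   \item{plane}{a regular `g x g` grid (`g = round(sqrt(n_points))`) on the
#'     first two axes, remaining axes 0 (deterministic); dimension 2.}
#'   \item{uniform_hypercube}{`n_points` i.i.d. uniform points, or, with
#'     `lattice = TRUE`, a regular lattice of `g = round(n_points^(1/dim))`
#'     points per axis (cell centers).  The lattice is the right
#'     representation of a *filled* cube for box counting: a lattice with
#'     `g >= r` gives exactly `r^dim` occupied boxes, whereas i.i.d. sampling
#'     needs many points per box to saturate; dimension `dim`.}
#'   \item{cantor_product}{`n_points` i.i.d. draws from the natural measure
#'     of the `dim`-fold product of middle-thirds Cantor sets, truncated at
#'     `level` ternary digits; dimension `dim * log(2)/log(3)`.}
#'   \item{sierpinski_carpet_extrusion}{(dim 3 only) i.i.d. draws from the
#'     Sierpinski-carpet measure on axes 1-2 (base-3 digit pairs excluding
#'     the center), uniform on axis 3; dimension `log(8)/log(3) + 1`.}
#' }
#'
#' @param family fractal family (see above).
#' @param dim 3 or 4.
#' @param n_points target point count (before lattice/grid rounding and
#'   deduplication).
#' @param level digit depth for the base-3 families; the default 12 resolves
#'   structure far below the finest counting grid (3^-12 << 1/128).
#' @param lattice for `uniform_hypercube`: regular lattice instead of
#'   i.i.d. sampling.
#' @param seed RNG seed (stochastic families are deterministic given it).
#' @return list with `cloud` (a [point_cloud()]), `analytic_dimension`,
#'   `family`, `dim`, `seed`.
#' @examples
#' fr <- make_fractal("cantor_product", dim = 3, n_points = 5000, seed = 1)
#' fr$analytic_dimension            # 3 log2 / log3 ~ 1.89
#' @export
make_fractal <- function(family = c("uniform_hypercube", "line", "plane",
                                    "cantor_product",
                                    "sierpinski_carpet_extrusion"),
                         dim = 3, n_points = 2e5, level = 12, lattice = FALSE,
                         seed = 1) {
  family <- match.arg(family)
  stopifnot(dim %in% c(3L, 4L), n_points >= 1, level >= 1)
  if (family == "sierpinski_carpet_extrusion" && dim != 3L)
    stop_fd4d("sierpinski_carpet_extrusion is defined for dim = 3 only")
  top <- 1 - 2^-53
  pts <- withr::with_seed(seed, {
    switch(family,
      line = {
        t <- (seq_len(n_points) - 1) / n_points
        matrix(rep(t, dim), ncol = dim)
      },
      plane = {
        g <- max(2L, round(sqrt(n_points)))
        xy <- as.matrix(expand.grid((seq_len(g) - 0.5) / g,
                                    (seq_len(g) - 0.5) / g))
        cbind(xy, matrix(0, nrow(xy), dim - 2L))
      },
      uniform_hypercube = {
        if (lattice) {
          g <- max(2L, round(n_points^(1 / dim)))
          idx <- seq_len(g^dim) - 1
          m <- matrix(0, length(idx), dim)
          for (j in seq_len(dim))
            m[, j] <- ((idx %/% g^(j - 1)) %% g + 0.5) / g
          m
        } else {
          matrix(runif(n_points * dim), ncol = dim)
        }
      },
      cantor_product = {
        w <- 3^-(seq_len(level))
        m <- matrix(0, n_points, dim)
        for (j in seq_len(dim)) {
          digits <- matrix(sample(c(0, 2), n_points * level, replace = TRUE),
                           ncol = level)
          m[, j] <- as.vector(digits %*% w)
        }
        m
      },
      sierpinski_carpet_extrusion = {
        # 8 allowed base-3 digit pairs: all but the center (1, 1)
        pairs <- cbind(c(0, 0, 0, 1, 1, 2, 2, 2), c(0, 1, 2, 0, 2, 0, 1, 2))
        w <- 3^-(seq_len(level))
        pick <- matrix(sample.int(8L, n_points * level, replace = TRUE),
                       ncol = level)
        x <- matrix(pairs[pick, 1], ncol = level) %*% w
        y <- matrix(pairs[pick, 2], ncol = level) %*% w
        cbind(as.vector(x), as.vector(y), runif(n_points))
      })
  })
  pts[pts >= 1] <- top
  list(cloud = point_cloud(pts, dim = dim, provenance = family,
                           dedupe = family %in% c("cantor_product",
                                                  "sierpinski_carpet_extrusion")),
       analytic_dimension = analytic_dimension(family, dim),
       family = family, dim = as.integer(dim), seed = seed)
}

# Synthetic cortical shell: n points on a radially deformed sphere (mm).
# Not an anatomical cortex; just a curved 2D support for source positions.
synthetic_cortex <- function(n_sources, radius = 80) {
  z <- runif(n_sources, -1, 1)
  phi <- runif(n_sources, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  theta <- acos(z)
  r <- radius * (1 + 0.08 * sin(3 * theta) * cos(2 * phi))
  dirs * r
}

#' Simulate a two-condition source epoch
#'
#' Generates a source-space epoch with the statistical structure the 4DFD
#' analysis is sensitive to: `n_clusters` Gaussian activation bumps of
#' spatial scale `dispersion` (mm) travel over a synthetic cortical shell,
#' their amplitudes smoothed in time by an Ornstein-Uhlenbeck process,
#' relocating to a random new center with probability `temporal_jump_rate`
#' per sample, on top of i.i.d. Gaussian sensor-like noise.  Larger
#' `dispersion` and `temporal_jump_rate` produce more spatially diffuse,
#' faster-changing supra-threshold sets and hence a higher 4DFD.
#'
#' @param n_sources number of sources on the shell.
#' @param fs sampling rate (Hz).
#' @param epoch_seconds epoch duration (s).
#' @param dispersion spatial scale of the activation bumps (mm).
#' @param n_clusters number of simultaneously active bumps.
#' @param temporal_jump_rate per-sample probability that a bump relocates.
#' @param noise_sd SD of the additive Gaussian noise (bump peak amplitude
#'   has mean 1).
#' @param amplitude mean bump peak amplitude.
#' @param ou_tau OU time constant of the amplitude fluctuations (s).
#' @param ou_sd stationary SD of the amplitude fluctuations.
#' @param seed RNG seed; identical arguments give an identical epoch.
#' @param subject_id,group metadata passed to [source_epoch()].
#' @return a [source_epoch()].
#' @export
simulate_epoch <- function(n_sources = 2000, fs = 100, epoch_seconds = 20,
                           dispersion = 30, n_clusters = 3,
                           temporal_jump_rate = 0.02, noise_sd = 0.25,
                           amplitude = 1, ou_tau = 0.2, ou_sd = 0.3,
                           seed = 1, subject_id = "sim",
                           group = NA_character_) {
  stopifnot(n_sources >= 1, fs > 0, epoch_seconds > 0, dispersion > 0,
            n_clusters >= 1, temporal_jump_rate >= 0, temporal_jump_rate <= 1,
            noise_sd >= 0)
  n_t <- as.integer(round(fs * epoch_seconds))
  withr::with_seed(seed, {
    coords <- synthetic_cortex(n_sources)
    kern_for <- function(center_idx) {
      d2 <- rowSums(sweep(coords, 2, coords[center_idx, ])^2)
      exp(-d2 / (2 * dispersion^2))
    }
    centers0 <- centers <- sample.int(n_sources, n_clusters, replace = TRUE)
    K <- vapply(centers, kern_for, numeric(n_sources))
    alpha <- exp(-1 / (ou_tau * fs))
    innov_sd <- ou_sd * sqrt(1 - alpha^2)
    amp <- rnorm(n_clusters, amplitude, ou_sd)
    values <- matrix(rnorm(n_sources * n_t, 0, noise_sd), n_sources, n_t)
    for (t in seq_len(n_t)) {
      jump <- runif(n_clusters) < temporal_jump_rate
      if (any(jump)) {
        centers[jump] <- sample.int(n_sources, sum(jump), replace = TRUE)
        K[, jump] <- vapply(centers[jump], kern_for,
                            numeric(n_sources))
      }
      amp <- amplitude + alpha * (amp - amplitude) +
        rnorm(n_clusters, 0, innov_sd)
      values[, t] <- values[, t] + as.vector(K %*% pmax(amp, 0))
    }
    ep <- source_epoch(values, coords, fs = fs, subject_id = subject_id,
                       group = group)
    attr(ep, "initial_centers") <- centers0
    ep
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Holds the cohort sizes and generator parameters for a full synthetic
#' study.  Defaults are "desk scale" (2,000 sources, 100 Hz, 20 s per
#' subject) so the whole pipeline runs in minutes; `paper_scale = TRUE`
#' restores the full-study scale (15,002 sources, 500 Hz, 120 s).  Group A
#' (patient-like) has a larger spatial dispersion than group B, encoding the
#' hypothesis that its activations are more spatio-temporally diffuse.
#'
#' @param n_groupA,n_groupB subject counts (defaults 27 and 15).
#' @param n_sources,fs,epoch_seconds per-subject epoch geometry.
#' @param dispersion_A,dispersion_B group bump scales (mm);
#'   `dispersion_A > dispersion_B`.
#' @param n_clusters,temporal_jump_rate,noise_sd passed to
#'   [simulate_epoch()].
#' @param seed master seed; per-subject seeds are derived with
#'   [derive_seed()].
#' @param paper_scale use the full-study epoch geometry.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_groupA = 27, n_groupB = 15, n_sources = 2000,
                        fs = 100, epoch_seconds = 20, dispersion_A = 30,
                        dispersion_B = 15, n_clusters = 3,
                        temporal_jump_rate = 0.02, noise_sd = 0.25,
                        seed = 1, paper_scale = FALSE) {
  if (paper_scale) {
    n_sources <- 15002; fs <- 500; epoch_seconds <- 120
  }
  stopifnot(n_groupA >= 1, n_groupB >= 1, dispersion_A > 0, dispersion_B > 0)
  structure(list(n_groupA = n_groupA, n_groupB = n_groupB,
                 n_sources = n_sources, fs = fs,
                 epoch_seconds = epoch_seconds, dispersion_A = dispersion_A,
                 dispersion_B = dispersion_B, n_clusters = n_clusters,
                 temporal_jump_rate = temporal_jump_rate, noise_sd = noise_sd,
                 seed = seed, paper_scale = paper_scale),
            class = "cohort_spec")
}

#' Enumerate the subjects of a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `subject_id`, `group`, `dispersion`, `seed`, one
#'   row per subject; feed rows to [cohort_subject_epoch()].
#' @export
cohort_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_groupA + spec$n_groupB
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("groupA", "groupB"), c(spec$n_groupA, spec$n_groupB)),
    dispersion = rep(c(spec$dispersion_A, spec$dispersion_B),
                     c(spec$n_groupA, spec$n_groupB)),
    seed = vapply(seq_len(n), function(i) derive_seed(spec$seed, i),
                  integer(1)),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_subjects
#' @param i subject row index in `cohort_subjects(spec)`.
#' @export
cohort_subject_epoch <- function(spec, i) {
  subj <- cohort_subjects(spec)[i, ]
  simulate_epoch(n_sources = spec$n_sources, fs = spec$fs,
                 epoch_seconds = spec$epoch_seconds,
                 dispersion = subj$dispersion, n_clusters = spec$n_clusters,
                 temporal_jump_rate = spec$temporal_jump_rate,
                 noise_sd = spec$noise_sd, seed = subj$seed,
                 subject_id = subj$subject_id, group = subj$group)
}

#' Simulate clinical score columns for a cohort table
#'
#' Latent-factor model for Parkinsonian clinical instruments: a common
#' severity factor (optionally correlated with the subjects' mean 4DFD)
#' drives UPDRS-III-, MoCA-, MMP- and Hoehn-and-Yahr-like columns with
#' loading `loading`; residual noise is independent per instrument.  Values
#' are clipped to instrument bounds.  Cognitive instruments (MoCA, MMP) load
#' negatively on severity.  With `correlation_with_fd = 0` (default) the
#' scores are unrelated to the fractal measure, mirroring a null correlation
#' structure.
#'
#' @param table data.frame with `subject_id` and `mean_fd` columns.
#' @param correlation_with_fd target correlation between the latent factor
#'   and `mean_fd` (in `[-1, 1]`).
#' @param loading factor loading shared by all instruments (in `(0, 1)`).
#' @param seed RNG seed.
#' @return `table` with columns `updrs3`, `moca`, `mmp`, `hoehn_yahr` added.
#' @export
simulate_scores <- function(table, correlation_with_fd = 0, loading = 0.95,
                            seed = 1) {
  stopifnot(is.data.frame(table), "mean_fd" %in% names(table),
            abs(correlation_with_fd) <= 1, loading > 0, loading < 1)
  n <- nrow(table)
  instruments <- list(
    updrs3     = list(mean = 39.0, sd = 9.8,  lo = 0, hi = 132, sign = +1),
    moca       = list(mean = 25.0, sd = 2.65, lo = 0, hi = 30,  sign = -1),
    mmp        = list(mean = 28.6, sd = 2.45, lo = 0, hi = 32,  sign = -1),
    hoehn_yahr = list(mean = 2.4,  sd = 0.42, lo = 1, hi = 5,   sign = +1))
  withr::with_seed(seed, {
    zfd <- if (sd(table$mean_fd) > 0) {
      as.vector(scale(table$mean_fd))
    } else {
      rep(0, n)
    }
    factor <- correlation_with_fd * zfd +
      sqrt(1 - correlation_with_fd^2) * rnorm(n)
    for (nm in names(instruments)) {
      ins <- instruments[[nm]]
      z <- ins$sign * (loading * factor) + sqrt(1 - loading^2) * rnorm(n)
      table[[nm]] <- pmin(pmax(ins$mean + ins$sd * z, ins$lo), ins$hi)
    }
  })
  table
}
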