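#' Synthetic cortical-shell mask
#'
#' Generates a 26-connected hollow-ellipsoid shell of gray-matter-like
#' voxels, optionally folded by a smooth sinusoidal perturbation of the
#' shell surface so that local voxel density varies as it does on
#' cortex. The ellipsoid scale is searched so that the final voxel count
#' (after keeping the largest connected component) lands within 5% of
#' `target_voxels`.
#'
#' @param target_voxels requested mask size.
#' @param thickness shell thickness as a fraction of the outer radius.
#' @param fold_amp amplitude of the sinusoidal surface perturbation
#'   (fraction of the radius; 0 disables folding).
#' @param fold_freq angular frequency of the folding pattern.
#' @param rng_seed seed for the folding phases.
#' @return a [gm_mask()].
#' @export
synth_mask <- function(target_voxels, thickness = 0.30, fold_amp = 0.08,
                       fold_freq = 4, rng_seed = 1) {
  if (target_voxels < 10) stop("target_voxels too small")
  set.seed(as.integer(rng_seed))
  ph <- runif(4, 0, 2 * pi)
  ratios <- c(1.0, 1.25, 0.85)

  shell_flags <- function(s) {
    ab <- s * ratios
    half <- ceiling(ab) + 2L
    dm <- 2L * half + 1L
    x <- (seq_len(dm[1]) - half[1] - 1) / ab[1]
    y <- (seq_len(dm[2]) - half[2] - 1) / ab[2]
    z <- (seq_len(dm[3]) - half[3] - 1) / ab[3]
    X <- array(x, dm)
    Y <- aperm(array(y, dm[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(z, dm[c(3, 1, 2)]), c(2, 3, 1))
    r <- sqrt(X^2 + Y^2 + Z^2)
    theta <- atan2(Y, X)
    phi <- acos(pmin(pmax(ifelse(r > 0, Z / r, 1), -1), 1))
    fold <- fold_amp * (sin(fold_freq * theta + ph[1]) *
                          sin(fold_freq * phi + ph[2]) +
                        0.5 * sin((fold_freq + 1) * phi + ph[3]) *
                          cos((fold_freq - 1) * theta + ph[4]))
    outer_r <- 1 + fold
    r <= outer_r & r >= outer_r * (1 - thickness)
  }
  count_at <- function(s) {
    fl <- shell_flags(s)
    idx0 <- which(fl) - 1L
    if (length(idx0) == 0L) return(0L)
    comp <- cpp_components(dim(fl), idx0)
    max(tabulate(comp))
  }
  # voxel count scales ~ s^2 for a thin shell: bracket then bisect
  lo <- 2; hi <- 4
  while (count_at(hi) < target_voxels) { lo <- hi; hi <- hi * 1.6 }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    cnt <- count_at(mid)
    if (abs(cnt - target_voxels) / target_voxels <= 0.02) { lo <- hi <- mid; break }
    if (cnt < target_voxels) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  m <- suppressWarnings(gm_mask(shell_flags(s), connect = TRUE))
  if (abs(length(m$idx0) - target_voxels) / target_voxels > 0.05)
    stop("could not reach the target voxel count within 5%")
  m
}

#' Specification of a synthetic two-scan structural cohort
#'
#' Parameters of the latent-connectome generator behind
#' [synth_streamline_cohort()]: a shared backbone of fiber-count means,
#' multiplicative log-normal subject effects (stable across scans),
#' multiplicative log-normal scan effects, and Poisson sampling of the
#' per-pair fiber counts.
#'
#' @param n_subjects subjects in the cohort.
#' @param n_scans scans per subject.
#' @param edge_density mean fraction of node pairs with nonzero
#'   backbone; the probability of a connection decays exponentially with
#'   the Euclidean distance between parcel centroids (length scale
#'   `dist_scale` times the mask diameter), as in real connectomes where
#'   short-range connections dominate.
#' @param mean_fibers mean backbone fiber count per connected pair.
#' @param subject_sd SD of the log-normal subject effect: a global
#'   per-subject scale plus an independent per-pair pattern (the
#'   subject's connectomic identity), both stable across scans.
#' @param scan_sd SD of the log-normal scan effect (a global per-scan
#'   scale, e.g. session-to-session tractography yield, plus an
#'   independent per-pair component), on top of Poisson sampling noise.
#' @param dist_scale connection-probability decay length as a fraction
#'   of the mask diameter.
#' @return list of class `structural_spec`.
#' @export
synth_structural_spec <- function(n_subjects = 20, n_scans = 2,
                                  edge_density = 0.3, mean_fibers = 60,
                                  subject_sd = 0.4, scan_sd = 0.15,
                                  dist_scale = 0.2) {
  stopifnot(n_subjects >= 1, n_scans >= 1, edge_density > 0,
            mean_fibers > 0, subject_sd >= 0, scan_sd >= 0,
            dist_scale > 0)
  structure(as.list(environment()), class = "structural_spec")
}

#' Synthetic streamline cohort over a reference parcellation
#'
#' Each subject owns a latent symmetric connectome (backbone times a
#' subject effect); each scan draws per-pair fiber counts Poisson around
#' the latent value times a scan effect. Streamlines are straight
#' two-point polylines whose endpoints sit on voxel centres drawn
#' uniformly inside the two parcels, so endpoint lookup maps each fiber
#' back to its generating pair exactly; fiber length is the endpoint
#' distance.
#'
#' @param spec a [synth_structural_spec()].
#' @param p a reference `parcellation` whose parcels carry the latent
#'   connectome.
#' @param rng_seed integer; the cohort is fully reproducible from
#'   (spec, p, rng_seed).
#' @return nested list `cohort[[subject]][[scan]]` of
#'   [streamline_set()] objects, with the latent backbone matrix in
#'   attribute `backbone`.
#' @export
synth_streamline_cohort <- function(spec, p, rng_seed = 1) {
  stopifnot(inherits(spec, "structural_spec"), inherits(p, "parcellation"))
  set.seed(as.integer(rng_seed))
  N <- p$N
  coords <- cbind(p$idx0 %% p$dim[1],
                  (p$idx0 %/% p$dim[1]) %% p$dim[2],
                  p$idx0 %/% (p$dim[1] * p$dim[2]))
  members <- split(seq_along(p$labels), p$labels)
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  # distance-dependent backbone: short-range pairs connect more often,
  # so any similar-resolution parcellation sees a similar geometry
  cent <- rowsum(coords, p$labels) / as.vector(table(p$labels))
  d <- sqrt(rowSums((cent[pairs[, 1], ] - cent[pairs[, 2], ])^2))
  diam <- max(d)
  pconn <- exp(-d / (spec$dist_scale * diam))
  pconn <- pmin(1, pconn * spec$edge_density / mean(pconn))
  on <- runif(nrow(pairs)) < pconn
  lam0 <- ifelse(on, spec$mean_fibers *
                   exp(-d / (spec$dist_scale * diam)) /
                   mean(exp(-d / (spec$dist_scale * diam))[on]) *
                   exp(rnorm(nrow(pairs), 0, 0.3)), 0)
  cohort <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    lam_s <- lam0 * exp(rnorm(1, 0, spec$subject_sd)) *
      exp(rnorm(nrow(pairs), 0, spec$subject_sd))
    scans <- vector("list", spec$n_scans)
    for (sc in seq_len(spec$n_scans)) {
      lam <- lam_s * exp(rnorm(1, 0, spec$scan_sd)) *
        exp(rnorm(nrow(pairs), 0, spec$scan_sd))
      cnt <- rpois(nrow(pairs), lam)
      total <- sum(cnt)
      pts <- vector("list", total)
      t <- 0L
      for (e in which(cnt > 0L)) {
        i <- pairs[e, 1]; j <- pairs[e, 2]
        va <- members[[i]][sample.int(length(members[[i]]), cnt[e],
                                      replace = TRUE)]
        vb <- members[[j]][sample.int(length(members[[j]]), cnt[e],
                                      replace = TRUE)]
        for (m in seq_len(cnt[e])) {
          pts[[t + m]] <- rbind(coords[va[m], ], coords[vb[m], ])
        }
        t <- t + cnt[e]
      }
      scans[[sc]] <- streamline_set(pts, frame = "voxel")
    }
    cohort[[s]] <- scans
  }
  B <- matrix(0, N, N)
  B[pairs] <- lam0; B <- B + t(B)
  attr(cohort, "backbone") <- B
  cohort
}

#' Specification of a synthetic two-session BOLD cohort
#'
#' Parameters of the factor-model generator behind
#' [synth_bold_cohort()]: each subject owns smooth spatial loading
#' fields (fixed across sessions — the identity signal); each session
#' draws fresh temporal factors; voxel series are loadings times factors
#' plus white noise plus injected confound components.
#'
#' @param n_subjects subjects.
#' @param n_sessions sessions per subject.
#' @param t_len timepoints per session.
#' @param k_factors latent spatial factors per subject.
#' @param signal identity-signal strength (scale of the factor term;
#'   0 removes all subject identity from the covariance).
#' @param noise_sd SD of the white observation noise.
#' @param n_confounds number of confound regressors.
#' @param confound_amp amplitude of the injected confound components.
#' @return list of class `bold_spec`.
#' @export
synth_bold_spec <- function(n_subjects = 50, n_sessions = 2, t_len = 300,
                            k_factors = 6, signal = 1, noise_sd = 1,
                            n_confounds = 4, confound_amp = 0.5) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, t_len > n_confounds + 2,
            k_factors >= 1, signal >= 0, noise_sd >= 0, confound_amp >= 0)
  structure(as.list(environment()), class = "bold_spec")
}

#' Synthetic two-session BOLD cohort on a mask
#'
#' Returns a lazy cohort: sessions are generated on demand by
#' [bold_session()] so that large cohorts never sit in memory at once.
#' Subject spatial loadings are smooth sinusoidal fields of the voxel
#' coordinates with subject-specific frequencies and phases; they
#' persist across sessions, so the spatial covariance (and with it the
#' mFCV over a parcellation ensemble) is a stable subject fingerprint,
#' while temporal factors, noise and confounds are redrawn each session.
#'
#' @param spec a [synth_bold_spec()].
#' @param mask a [gm_mask()] supplying the voxel coordinates.
#' @param rng_seed integer; all sessions are reproducible from
#'   (spec, mask, rng_seed) regardless of generation order.
#' @return object of class `bold_cohort`.
#' @export
synth_bold_cohort <- function(spec, mask, rng_seed = 1) {
  stopifnot(inherits(spec, "bold_spec"), inherits(mask, "gm_mask"))
  structure(list(spec = spec, coords = mask_coords(mask),
                 rng_seed = as.integer(rng_seed)),
            class = "bold_cohort")
}

#' Generate one subject/session of a BOLD cohort
#'
#' @param cohort a [synth_bold_cohort()] object.
#' @param subject,session 1-based indices.
#' @return list with `ts` (t_len x V voxel series, columns in mask
#'   `idx0` order) and `confounds` (t_len x n_confounds).
#' @export
bold_session <- function(cohort, subject, session) {
  stopifnot(inherits(cohort, "bold_cohort"))
  spec <- cohort$spec
  coords <- cohort$coords
  V <- nrow(coords)
  ext <- pmax(apply(coords, 2, max) - apply(coords, 2, min), 1)

  # subject loadings: deterministic in (rng_seed, subject)
  set.seed(cohort$rng_seed + 131L * as.integer(subject))
  B <- matrix(0, V, spec$k_factors)
  for (k in seq_len(spec$k_factors)) {
    w <- runif(3, 0.5, 2.5) * 2 * pi / ext * sample(c(-1, 1), 3, TRUE)
    ph <- runif(2, 0, 2 * pi)
    B[, k] <- sin(coords %*% w + ph[1]) +
      0.5 * cos(coords %*% (w[c(2, 3, 1)]) + ph[2])
  }

  # session draws: deterministic in (rng_seed, subject, session)
  set.seed(cohort$rng_seed + 131L * as.integer(subject) +
             1000003L * as.integer(session))
  Fa <- matrix(rnorm(spec$t_len * spec$k_factors), spec$t_len)
  conf <- matrix(rnorm(spec$t_len * spec$n_confounds), spec$t_len)
  conf <- apply(conf, 2, function(v) as.numeric(stats::filter(
    v, rep(1 / 5, 5), sides = 1, circular = TRUE)))
  wc <- matrix(rnorm(spec$n_confounds * V), spec$n_confounds, V)
  ts <- spec$signal * (Fa %*% t(B)) +
    spec$confound_amp * (conf %*% wc)
  if (spec$noise_sd > 0)
    ts <- ts + matrix(rnorm(spec$t_len * V, 0, spec$noise_sd), spec$t_len)
  list(ts = ts, confounds = conf)
}

#' Synthetic metric cohort with injected variance components
#'
#' Draws global-metric values directly from the additive random-effects
#' model \eqn{G_{isp} = \mu + a_i + b_{is} + e_{isp}} with independent
#' normal subject effects a (SD `sigma_subject`), scan effects b (SD
#' `sigma_scan`) and parcellation noise e (SD `sigma_parcellation`) —
#' a dial-a-truth generator for validating the variance-decomposition
#' and ICC estimators without running the imaging pipeline.
#'
#' @param n_subjects,n_scans,n_parcellations cohort dimensions.
#' @param mu grand mean.
#' @param sigma_subject,sigma_scan,sigma_parcellation SDs of the three
#'   components.
#' @param metric metric label used in the output table.
#' @param rng_seed integer seed.
#' @return tidy data.frame with columns `subject`, `scan`,
#'   `parcellation`, `metric`, `value`.
#' @export
synth_metric_cohort <- function(n_subjects = 20, n_scans = 2,
                                n_parcellations = 50, mu = 1,
                                sigma_subject = 1, sigma_scan = 0.2,
                                sigma_parcellation = 0.5,
                                metric = "metric", rng_seed = 1) {
  set.seed(as.integer(rng_seed))
  a <- rnorm(n_subjects, 0, sigma_subject)
  df <- expand.grid(parcellation = seq_len(n_parcellations),
                    scan = seq_len(n_scans),
                    subject = seq_len(n_subjects))
  b <- rnorm(n_subjects * n_scans, 0, sigma_scan)
  bi <- (df$subject - 1L) * n_scans + df$scan
  df$value <- mu + a[df$subject] + b[bi] +
    rnorm(nrow(df), 0, sigma_parcellation)
  df$metric <- metric
  df[, c("subject", "scan", "parcellation", "metric", "value")]
}
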