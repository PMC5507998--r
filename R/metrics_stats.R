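#' Six global network metrics of a connectivity matrix
#'
#' Computes, on a symmetric zero-diagonal weight matrix:
#' \describe{
#'   \item{degree}{mean binary degree (an edge exists iff w > 0).}
#'   \item{strength}{mean weighted degree (row sum); for functional
#'     matrices negative weights enter the sum.}
#'   \item{clustering}{mean weighted clustering coefficient, Onnela
#'     geometric-mean form on weights scaled by the maximum weight.}
#'   \item{efficiency}{global efficiency: mean of 1/d over ordered node
#'     pairs, with shortest paths on edge costs 1/w (disconnected pairs
#'     contribute 0).}
#'   \item{modularity}{best Newman Q over multiple Louvain restarts.}
#'   \item{diversity}{mean Shannon-entropy diversity coefficient of node
#'     strength across the best Louvain modules, normalized by
#'     log(number of modules); a node whose strength is confined to one
#'     module has diversity 0.}
#' }
#' For functional (signed) matrices, clustering, efficiency, modularity
#' and diversity are computed on the positive weights only; strength
#' keeps the sign.
#'
#' @param C a `connectivity_matrix` or a plain symmetric matrix.
#' @param louvain_restarts number of Louvain restarts (best Q kept).
#' @param rng_seed seed for the restart sequence, making Q deterministic.
#' @return list of class `global_metrics` with the six metrics and the
#'   best module membership (`modules`).
#' @export
global_metrics <- function(C, louvain_restarts = 20, rng_seed = 1) {
  W <- if (inherits(C, "connectivity_matrix")) C$W else as.matrix(C)
  n <- nrow(W)
  diag(W) <- 0
  Wp <- pmax(W, 0)
  if (all(W == 0)) {
    warning("empty graph: all metrics zero")
    out <- list(degree = 0, strength = 0, clustering = 0,
                efficiency = 0, modularity = 0, diversity = 0,
                modules = rep(1L, n))
    class(out) <- "global_metrics"
    return(out)
  }
  degree <- mean(colSums(W != 0))
  strength <- mean(colSums(W))
  clustering <- onnela_clustering(Wp)
  efficiency <- global_efficiency(Wp)
  mod <- best_louvain(Wp, restarts = louvain_restarts, rng_seed = rng_seed)
  diversity <- diversity_coefficient(Wp, mod$membership)
  out <- list(degree = degree, strength = strength,
              clustering = clustering, efficiency = efficiency,
              modularity = mod$Q, diversity = diversity,
              modules = mod$membership)
  class(out) <- "global_metrics"
  out
}

#' @export
print.global_metrics <- function(x, ...) {
  v <- unlist(x[c("degree", "strength", "clustering", "efficiency",
                  "modularity", "diversity")])
  print(signif(v, 4))
  invisible(x)
}

metric_names <- function() c("degree", "strength", "clustering",
                             "efficiency", "modularity", "diversity")

# Onnela et al. weighted clustering: mean over nodes of
# diag((W/max)^(1/3) %^% 3) / (k (k-1)); nodes with k < 2 contribute 0.
onnela_clustering <- function(Wp) {
  mx <- max(Wp)
  if (mx == 0) return(0)
  W13 <- (Wp / mx)^(1 / 3)
  k <- colSums(Wp > 0)
  tri <- diag(W13 %*% W13 %*% W13)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

global_efficiency <- function(Wp) {
  n <- nrow(Wp)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# Louvain with multiple RNG restarts; returns the best-Q partition.
best_louvain <- function(Wp, restarts = 20, rng_seed = 1) {
  g <- igraph::graph_from_adjacency_matrix(Wp, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  best <- list(Q = -Inf, membership = rep(1L, nrow(Wp)))
  for (r in seq_len(restarts)) {
    set.seed(as.integer(rng_seed) + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = ew)
    q <- igraph::modularity(g, igraph::membership(cl), weights = ew)
    if (q > best$Q)
      best <- list(Q = q, membership = as.integer(igraph::membership(cl)))
  }
  best
}

# Shannon diversity of strength across modules, normalized by log(m).
diversity_coefficient <- function(Wp, membership) {
  m <- length(unique(membership))
  if (m < 2) return(0)
  S <- rowsum(t(Wp), group = membership)        # m x n: strength to module
  s <- colSums(S)
  P <- sweep(S, 2, ifelse(s > 0, s, 1), `/`)
  H <- -colSums(ifelse(P > 0, P * log(P), 0))
  mean(ifelse(s > 0, H / log(m), 0))
}

#' PBS distributions of global metrics
#'
#' Summarises the per-parcellation metric samples of a PBS ensemble:
#' values, mean, SD, and a Lilliefors (Kolmogorov-Smirnov with estimated
#' parameters) test of normality per metric. Constant samples or
#' ensembles smaller than `min_n` skip the test (p = NA, flagged).
#'
#' @param metrics matrix or data.frame, rows = parcellations, columns =
#'   metrics.
#' @param min_n minimum sample size for the normality test.
#' @return list per metric: `values`, `mean`, `sd`, `lilliefors_p`,
#'   `normality_skipped`.
#' @export
pbs_metric_distribution <- function(metrics, min_n = 20) {
  metrics <- as.data.frame(metrics)
  lapply(metrics, function(v) {
    v <- as.numeric(v)
    skipped <- length(v) < min_n || sd(v) == 0
    p <- if (skipped) NA_real_ else nortest::lillie.test(v)$p.value
    list(values = v, mean = mean(v), sd = sd(v),
         lilliefors_p = p, normality_skipped = skipped)
  })
}

#' Variance decomposition of PBS metric samples
#'
#' Splits the variation of each global metric into three components:
#' \describe{
#'   \item{sigma_parcellation}{SD of the metric across the PBS ensemble
#'     (scan 1), averaged over subjects — variation due to parcellation
#'     alone.}
#'   \item{sigma_bs}{between-scan variation
#'     \eqn{\sqrt{\frac{1}{M}\sum_i (\bar G^1_i - \bar G^2_i)^2}} of the
#'     subjectwise PBS means over the M subjects.}
#'   \item{sigma_subject}{SD across subjects of the scan-1 PBS means.}
#' }
#'
#' @param df tidy data.frame with columns `subject`, `scan`,
#'   `parcellation`, `metric`, `value`; exactly two scan levels, equal
#'   ensemble counts.
#' @return data.frame with one row per metric and the three sigma
#'   columns.
#' @export
variance_decomposition <- function(df) {
  req <- c("subject", "scan", "parcellation", "metric", "value")
  if (!all(req %in% names(df))) stop("df must have columns: ",
                                     paste(req, collapse = ", "))
  scans <- sort(unique(df$scan))
  if (length(scans) != 2L) stop("exactly two scans are required")
  subjects <- unique(df$subject)
  if (length(subjects) < 2L)
    stop("sigma_subject is undefined for a single subject")
  out <- lapply(split(df, df$metric), function(d) {
    d1 <- d[d$scan == scans[1], ]
    sig_parc <- mean(tapply(d1$value, d1$subject, sd))
    gbar <- tapply(d$value, list(d$subject, d$scan), mean)
    sig_bs <- sqrt(mean((gbar[, 1] - gbar[, 2])^2))
    sig_subj <- sd(gbar[, 1])
    data.frame(sigma_parcellation = sig_parc, sigma_bs = sig_bs,
               sigma_subject = sig_subj)
  })
  cbind(metric = names(out), do.call(rbind, out), row.names = NULL)
}

#' Intraclass correlation coefficient
#'
#' Default is the one-way random-effects single-measurement ICC(1,1)
#' from the one-way ANOVA decomposition,
#' \eqn{(MS_B - MS_W) / (MS_B + (k-1) MS_W)}; it can be negative.
#' `"ICC2"` and `"ICC3"` give the two-way random / mixed consistency
#' variants.
#'
#' @param tab numeric matrix, rows = subjects, columns = the k repeated
#'   measurements (e.g. two scans).
#' @param type `"ICC1"` (default), `"ICC2"` or `"ICC3"`.
#' @return a single ICC value.
#' @export
icc <- function(tab, type = c("ICC1", "ICC2", "ICC3")) {
  type <- match.arg(type)
  tab <- as.matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 measurements")
  if (var(as.vector(tab)) == 0)
    stop("degenerate table: zero total variance")
  gm <- mean(tab)
  rowm <- rowMeans(tab); colm <- colMeans(tab)
  ssb <- k * sum((rowm - gm)^2)          # between subjects
  ssw <- sum((tab - rowm)^2)             # within subjects (one-way)
  ssc <- n * sum((colm - gm)^2)          # between measurements
  sse <- sum((tab - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(type,
    ICC1 = (msb - msw) / (msb + (k - 1) * msw),
    ICC2 = (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n),
    ICC3 = (msb - mse) / (msb + (k - 1) * mse))
}

#' Compare test-retest ICC of PBS means vs single parcellations
#'
#' Two ways to compute test-retest ICC from a PBS ensemble: (i)
#' `icc_of_mean` — average the metric over the ensemble per
#' subject/scan, then take the ICC of the means; (ii) `mean_icc` —
#' treat each parcellation as a template, compute its ICC, and average.
#' Averaging over parcellations removes parcellation noise from the
#' within-subject variance, so `icc_of_mean` is expected to exceed
#' `mean_icc` whenever parcellation noise is independent across
#' parcellations. The reported p-value is a one-tailed one-sample t-test
#' of the per-parcellation ICC sample against `icc_of_mean`
#' (alternative: the per-parcellation ICCs are smaller).
#'
#' @inheritParams variance_decomposition
#' @param template_values optional named list (per metric) of
#'   subject x scan matrices from a template parcellation; adds
#'   `template_icc`.
#' @param type ICC variant, see [icc()].
#' @return data.frame, one row per metric: `icc_of_mean`, `mean_icc`,
#'   `p_value`, `template_icc`.
#' @export
icc_comparison <- function(df, template_values = NULL,
                           type = "ICC1") {
  scans <- sort(unique(df$scan))
  if (length(scans) != 2L) stop("exactly two scans are required")
  out <- lapply(split(df, df$metric), function(d) {
    gbar <- tapply(d$value, list(d$subject, d$scan), mean)
    icc_mean <- icc(gbar, type = type)
    iccs <- vapply(split(d, d$parcellation), function(dp) {
      icc(tapply(dp$value, list(dp$subject, dp$scan), mean), type = type)
    }, numeric(1))
    p <- if (sd(iccs) == 0) NA_real_ else
      t.test(iccs, mu = icc_mean, alternative = "less")$p.value
    data.frame(icc_of_mean = icc_mean, mean_icc = mean(iccs), p_value = p)
  })
  res <- cbind(metric = names(out), do.call(rbind, out), row.names = NULL)
  res$template_icc <- NA_real_
  if (!is.null(template_values)) {
    idx <- match(res$metric, names(template_values))
    res$template_icc <- vapply(seq_along(idx), function(i) {
      if (is.na(idx[i])) NA_real_ else
        icc(template_values[[idx[i]]], type = type)
    }, numeric(1))
  }
  res
}

#' Metrics table for a cohort of PBS network ensembles
#'
#' Convenience builder of the tidy table consumed by
#' [variance_decomposition()] and [icc_comparison()].
#'
#' @param networks nested list: `networks[[subject]][[scan]][[parcellation]]`
#'   is a `connectivity_matrix` (or plain matrix).
#' @param louvain_restarts,rng_seed passed to [global_metrics()].
#' @return tidy data.frame with columns `subject`, `scan`,
#'   `parcellation`, `metric`, `value`.
#' @export
cohort_metrics <- function(networks, louvain_restarts = 20, rng_seed = 1) {
  rows <- list()
  for (s in seq_along(networks))
    for (sc in seq_along(networks[[s]]))
      for (p in seq_along(networks[[s]][[sc]])) {
        gm <- global_metrics(networks[[s]][[sc]][[p]],
                             louvain_restarts = louvain_restarts,
                             rng_seed = rng_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, scan = sc, parcellation = p,
          metric = metric_names(),
          value = unlist(gm[metric_names()], use.names = FALSE))
      }
  do.call(rbind, rows)
}
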