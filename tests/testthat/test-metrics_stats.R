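test_that("complete graphs give the textbook metric values", {
  for (n in c(5, 8)) {
    Kn <- matrix(1, n, n); diag(Kn) <- 0
    gm <- global_metrics(Kn)
    expect_equal(gm$degree, n - 1)
    expect_equal(gm$strength, n - 1)
    expect_equal(gm$clustering, 1)
    expect_equal(gm$efficiency, 1)
  }
})

test_that("Louvain modularity matches the exhaustive partition oracle on two cliques", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  gm <- global_metrics(W)
  expect_equal(gm$modularity, 0.5)
  expect_equal(gm$modularity, best_partition_Q(W), tolerance = 1e-12)
  expect_equal(sort(unique(gm$modules[1:4])), gm$modules[1])
  # all strength confined to one module -> zero diversity
  expect_equal(gm$diversity, 0)
})

test_that("modularity never decreases with more restarts", {
  set.seed(3)
  W <- matrix(0, 30, 30)
  W[upper.tri(W)] <- rbinom(choose(30, 2), 1, 0.2) * runif(choose(30, 2))
  W <- W + t(W)
  qs <- vapply(c(1, 5, 20), function(r)
    global_metrics(W, louvain_restarts = r, rng_seed = 5)$modularity,
    numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("an empty graph warns and returns zero metrics", {
  expect_warning(gm <- global_metrics(matrix(0, 4, 4)), "empty")
  expect_equal(gm$degree, 0)
  expect_equal(gm$efficiency, 0)
})

test_that("signed functional matrices use positive weights except for strength", {
  W <- matrix(c(0, 0.5, -0.3,
                0.5, 0, 0.2,
                -0.3, 0.2, 0), 3, 3)
  gm <- global_metrics(W)
  expect_equal(gm$strength, mean(colSums(W)))          # signed sum
  expect_equal(gm$degree, mean(colSums(W != 0)))       # presence of any edge
  Wp <- pmax(W, 0)
  expect_equal(gm$efficiency, global_metrics(Wp)$efficiency)
})

test_that("ICC matches the ANOVA sums-of-squares oracle and known cases", {
  set.seed(9)
  tab <- matrix(rnorm(10), 5, 2)
  # oracle via one-way ANOVA on the long table
  long <- data.frame(y = as.vector(tab),
                     subj = factor(rep(1:5, 2)))
  ms <- anova(lm(y ~ subj, data = long))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  expect_equal(icc(tab), (msb - msw) / (msb + msw), tolerance = 1e-10)
  # identical columns, distinct subjects -> 1
  expect_equal(icc(cbind(1:4, 1:4)), 1)
  # degenerate table
  expect_error(icc(matrix(1, 3, 2)), "degenerate")
  expect_error(icc(matrix(1:2, 1, 2)), ">= 2 subjects")
  # two-way variants agree with their defining formulas on this table
  n <- 5; k <- 2
  gmn <- mean(tab)
  msr <- k * sum((rowMeans(tab) - gmn)^2) / (n - 1)
  msc <- n * sum((colMeans(tab) - gmn)^2) / (k - 1)
  mse <- (sum((tab - gmn)^2) - (n - 1) * msr / k * k - (k - 1) * msc / n * n) /
    ((n - 1) * (k - 1))
  expect_equal(icc(tab, "ICC3"), (msr - mse) / (msr + (k - 1) * mse),
               tolerance = 1e-10)
})

test_that("negative ICC arises when within-subject spread dominates", {
  tab <- rbind(c(0, 10), c(10, 0), c(0, 10))
  expect_lt(icc(tab), 0)
})

test_that("variance decomposition handles exact and degenerate cases", {
  df <- synth_metric_cohort(n_subjects = 4, n_parcellations = 6, rng_seed = 2)
  # duplicated scans: between-scan variation is exactly zero
  d1 <- df[df$scan == 1, ]
  d2 <- d1; d2$scan <- 2
  vd <- variance_decomposition(rbind(d1, d2))
  expect_equal(vd$sigma_bs, 0)
  # two subjects with constant values 1 and 3
  dd <- expand.grid(subject = 1:2, scan = 1:2, parcellation = 1:3)
  dd$metric <- "m"; dd$value <- ifelse(dd$subject == 1, 1, 3)
  vd2 <- variance_decomposition(dd)
  expect_equal(vd2$sigma_bs, 0)
  expect_equal(vd2$sigma_subject, sd(c(1, 3)))
  expect_equal(vd2$sigma_parcellation, 0)
  dd1 <- dd[dd$subject == 1, ]
  expect_error(variance_decomposition(dd1), "single subject")
})

test_that("sigma estimators are invariant to metric-wise affine shifts", {
  df <- synth_metric_cohort(n_subjects = 6, n_parcellations = 8, rng_seed = 3)
  vd <- variance_decomposition(df)
  df2 <- df; df2$value <- df$value + 100
  expect_equal(variance_decomposition(df2)[, -1], vd[, -1],
               tolerance = 1e-10)
})

test_that("injected variance components are recovered by the decomposition", {
  truth <- c(subj = 0.8, scan = 0.25, parc = 0.5)
  P <- 50
  est <- sapply(1:6, function(r) {
    df <- synth_metric_cohort(n_subjects = 20, n_parcellations = P,
                              sigma_subject = truth["subj"],
                              sigma_scan = truth["scan"],
                              sigma_parcellation = truth["parc"],
                              rng_seed = 100 + r)
    vd <- variance_decomposition(df)
    c(vd$sigma_parcellation, vd$sigma_bs, vd$sigma_subject)
  })
  avg <- rowMeans(est)
  expected <- c(truth["parc"],
                sqrt(2 * truth["scan"]^2 + 2 * truth["parc"]^2 / P),
                sqrt(truth["subj"]^2 + truth["scan"]^2 + truth["parc"]^2 / P))
  expect_true(all(abs(avg - expected) / expected < 0.15))
})

test_that("PBS metric distributions report moments and Lilliefors normality", {
  set.seed(21)
  mm <- cbind(normal = rnorm(400, 5, 2), constant = rep(1, 400))
  out <- pbs_metric_distribution(mm)
  expect_equal(out$normal$mean, mean(mm[, 1]))
  expect_equal(out$normal$sd, sd(mm[, 1]))
  expect_false(out$normal$normality_skipped)
  expect_gt(out$normal$lilliefors_p, 0.001)
  expect_true(out$constant$normality_skipped)
  expect_true(is.na(out$constant$lilliefors_p))
  # too few samples: test skipped
  expect_true(pbs_metric_distribution(cbind(x = rnorm(10)))$x$normality_skipped)
})

test_that("Lilliefors test is calibrated near its nominal level on normal draws", {
  set.seed(77)
  rej <- mean(replicate(400, {
    pbs_metric_distribution(cbind(m = rnorm(400)))$m$lilliefors_p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("averaging over the ensemble raises ICC when parcellation noise is independent", {
  df <- synth_metric_cohort(n_subjects = 20, n_parcellations = 50,
                            sigma_subject = 1, sigma_scan = 0.3,
                            sigma_parcellation = 0.8, rng_seed = 5)
  rep_ <- icc_comparison(df)
  expect_gt(rep_$icc_of_mean, rep_$mean_icc)
  expect_lt(rep_$p_value, 0.05)
  expect_lte(rep_$icc_of_mean, 1)
})

test_that("identical parcellations make the two ICC summaries coincide", {
  base <- synth_metric_cohort(n_subjects = 8, n_parcellations = 1,
                              rng_seed = 4)
  df <- do.call(rbind, lapply(1:5, function(p) {
    d <- base; d$parcellation <- p; d
  }))
  rep_ <- icc_comparison(df)
  expect_equal(rep_$icc_of_mean, rep_$mean_icc)
  # template values feed through
  gbar <- tapply(base$value, list(base$subject, base$scan), mean)
  rep2 <- icc_comparison(df, template_values = list(metric = gbar))
  expect_equal(rep2$template_icc, icc(gbar))
})
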