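#' Mean functional connectivity of one network
#'
#' The mean of the strictly-upper-triangle entries of a functional
#' connectivity matrix (diagonal excluded) — a trivial global property
#' of the network that nonetheless fingerprints subjects once traced
#' across a PBS parcellation ensemble.
#'
#' @param C a `connectivity_matrix` or plain symmetric matrix.
#' @return a single number.
#' @export
mean_fc <- function(C) {
  W <- if (inherits(C, "connectivity_matrix")) C$W else as.matrix(C)
  mean(W[upper.tri(W)])
}

#' Mean-FC vector (mFCV) of a PBS ensemble
#'
#' One mean-FC value per parcellation of the ensemble, in parcellation
#' rank order. Comparing mFCVs across subjects requires that the i-th
#' parcellation is the same label volume for every subject and session.
#'
#' @param fcs list of `connectivity_matrix` objects (or plain matrices),
#'   one per parcellation, in ensemble order.
#' @param subject,session optional identifiers stored as attributes.
#' @return numeric vector of class `mfcv`, length = ensemble size.
#' @export
build_mfcv <- function(fcs, subject = NA, session = NA) {
  if (length(fcs) == 0L) stop("empty ensemble")
  v <- vapply(fcs, mean_fc, numeric(1))
  structure(v, subject = subject, session = session, class = "mfcv")
}

# rows = subjects, features in columns; returns identification result
identify_from_features <- function(F1, F2, what = "mFCV") {
  F1 <- as.matrix(F1); F2 <- as.matrix(F2)
  if (!all(dim(F1) == dim(F2)))
    stop(what, " feature matrices must agree in subjects and length")
  if (ncol(F1) < 2L) stop("need at least 2 features for Pearson similarity")
  v1 <- apply(F1, 1, sd); v2 <- apply(F2, 1, sd)
  if (any(v1 == 0) || any(v2 == 0))
    stop("zero-variance ", what, " for subject(s): ",
         paste(unique(c(which(v1 == 0), which(v2 == 0))), collapse = ", "))
  S <- cor(t(F1), t(F2))
  argmax_rows <- function(M) {
    apply(M, 1, function(r) {
      w <- which(r == max(r))
      if (length(w) > 1L) warning("similarity tie; lowest index taken")
      w[1]
    })
  }
  pred12 <- argmax_rows(S)       # subject i in session 1 -> best match in 2
  pred21 <- argmax_rows(t(S))    # subject k in session 2 -> best match in 1
  n <- nrow(S)
  structure(
    list(similarity = S,
         predicted_1to2 = pred12, predicted_2to1 = pred21,
         accuracy_1to2 = mean(pred12 == seq_len(n)),
         accuracy_2to1 = mean(pred21 == seq_len(n))),
    class = "identification_result")
}

#' Identify subjects across sessions from mFCVs
#'
#' Cross-session similarity is the Pearson correlation between mFCVs;
#' subject i of session 1 is predicted to be the session-2 subject with
#' maximal similarity (and vice versa). Accuracy is the fraction of
#' correct matches per direction.
#'
#' @param mfcv1,mfcv2 numeric matrices, rows = subjects (same order in
#'   both sessions), columns = parcellation ranks.
#' @return an `identification_result`: `similarity` (subjects x
#'   subjects), `predicted_1to2`, `predicted_2to1`, `accuracy_1to2`,
#'   `accuracy_2to1`.
#' @export
identify <- function(mfcv1, mfcv2) {
  identify_from_features(mfcv1, mfcv2, what = "mFCV")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "identification over %d subjects: accuracy %.3f (1->2), %.3f (2->1)\n",
    nrow(x$similarity), x$accuracy_1to2, x$accuracy_2to1))
  invisible(x)
}

#' Fingerprinting accuracy as a function of PBS sample count
#'
#' For each requested count, draws `reps` random subsets of parcellation
#' ranks (without replacement, the same subset applied to both
#' sessions), identifies subjects from the truncated mFCVs and averages
#' the two-direction accuracy over repetitions. When the count equals
#' the full ensemble length a single evaluation reproduces
#' [identify()].
#'
#' @inheritParams identify
#' @param counts integer vector of subset sizes (each >= 2 and <= the
#'   ensemble length).
#' @param reps subsets per count.
#' @param rng_seed seed for subset draws.
#' @return data.frame: `count`, `accuracy_1to2`, `accuracy_2to1`,
#'   `accuracy` (mean of the two directions), averaged over reps.
#' @export
accuracy_vs_samples <- function(mfcv1, mfcv2, counts, reps = 50,
                                rng_seed = 1) {
  mfcv1 <- as.matrix(mfcv1); mfcv2 <- as.matrix(mfcv2)
  L <- ncol(mfcv1)
  counts <- as.integer(counts)
  if (any(counts < 2L)) stop("counts must be >= 2 (Pearson similarity needs >= 2 samples; use identify_matrix_baseline for single-parcellation fingerprinting)")
  if (max(counts) > L) stop("counts exceed the ensemble length")
  set.seed(as.integer(rng_seed))
  out <- lapply(counts, function(cnt) {
    nr <- if (cnt == L) 1L else reps
    a12 <- a21 <- numeric(nr)
    for (r in seq_len(nr)) {
      idx <- if (cnt == L) seq_len(L) else sort(sample.int(L, cnt))
      res <- identify(mfcv1[, idx, drop = FALSE], mfcv2[, idx, drop = FALSE])
      a12[r] <- res$accuracy_1to2; a21[r] <- res$accuracy_2to1
    }
    data.frame(count = cnt, accuracy_1to2 = mean(a12),
               accuracy_2to1 = mean(a21),
               accuracy = mean(c(a12, a21)))
  })
  do.call(rbind, out)
}

#' Single-parcellation (template-style) fingerprinting baseline
#'
#' Identifies subjects from the full FC matrix of one shared
#' parcellation: similarity is the Pearson correlation between the
#' vectorized upper triangles of the two sessions' FC matrices — the
#' classic connectome-fingerprinting measure the mFCV approach is
#' compared against.
#'
#' @param fc1,fc2 lists of `connectivity_matrix` objects (or plain
#'   matrices), one per subject, sessions 1 and 2, built from the same
#'   parcellation.
#' @return an `identification_result`.
#' @export
identify_matrix_baseline <- function(fc1, fc2) {
  upper <- function(C) {
    W <- if (inherits(C, "connectivity_matrix")) C$W else as.matrix(C)
    W[upper.tri(W)]
  }
  feat <- function(fcs) do.call(rbind, lapply(fcs, upper))
  identify_from_features(feat(fc1), feat(fc2), what = "FC-matrix feature")
}
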