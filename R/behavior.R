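# Behavioral analysis of visuomotor-rotation learning: binned median endpoint
# errors, the five learning measures (early/late error on each day and
# savings), validated k-means subgrouping, and the sign-fixed PC1 learning
# score used as the scalar behavioral outcome.

#' Per-bin median endpoint error
#'
#' Trials are grouped into consecutive bins of eight (one trial per target);
#' the bin score is the median endpoint error of the trials present.
#' Discarded trials (e.g. reaction-time timeouts) may leave bins with fewer
#' than eight trials; a bin with no trials at all is an error.
#'
#' @param trials data.frame with columns `bin` and `error_deg` (a trial
#'   table restricted to the learning block of one day).
#' @param n_bins expected number of learning bins (default 40).
#' @return numeric vector of `n_bins` bin medians.
#' @export
binned_median_error <- function(trials, n_bins = 40L) {
  stopifnot(is.data.frame(trials), all(c("bin", "error_deg") %in%
                                         names(trials)))
  med <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    e <- trials$error_deg[trials$bin == b]
    if (!length(e)) stop_("empty bin ", b)
    med[b] <- stats::median(e)
  }
  med
}

#' Learning measures from two days of binned medians
#'
#' Early error is the mean of the first three bin medians (24 trials), late
#' error the mean of the last three (bins 38-40); savings is the Day-1 early
#' error minus the Day-2 early error.
#'
#' @param bins_day1,bins_day2 numeric vectors of 40 bin medians.
#' @return named numeric vector `early1, late1, early2, late2, savings`.
#' @export
learning_measures <- function(bins_day1, bins_day2) {
  for (b in list(bins_day1, bins_day2))
    if (length(b) != 40L || anyNA(b)) stop_("need 40 complete bins per day")
  early1 <- mean(bins_day1[1:3]); late1 <- mean(bins_day1[38:40])
  early2 <- mean(bins_day2[1:3]); late2 <- mean(bins_day2[38:40])
  c(early1 = early1, late1 = late1, early2 = early2, late2 = late2,
    savings = early1 - early2)
}

# Calinski-Harabasz index for a labeled point set
.calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  gm <- colMeans(x)
  W <- 0; B <- 0
  for (c in unique(labels)) {
    xi <- x[labels == c, , drop = FALSE]
    cm <- colMeans(xi)
    W <- W + sum(sweep(xi, 2L, cm)^2)
    B <- B + nrow(xi) * sum((cm - gm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

.mean_silhouette <- function(x, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  mean(cluster::silhouette(labels, stats::dist(as.matrix(x)))[, 3L])
}

#' Cluster participants on their learning measures
#'
#' Z-scores the measures, runs k-means with many random restarts for every
#' candidate `k` (the restart minimizing the within-cluster sum of squares is
#' kept), and scores each solution with the mean Silhouette width and the
#' Calinski-Harabasz index. The selected `k` is the argmax of each index;
#' when the two indices disagree, both candidates are reported and
#' `agreement` is `FALSE` (no silent resolution).
#'
#' @param measures numeric matrix, one row per subject (typically the five
#'   learning measures).
#' @param k_range candidate numbers of clusters (default `2:9`).
#' @param restarts random restarts per k (default 1,000).
#' @param max_iter k-means iteration cap per restart (default 10,000).
#' @param seed integer seed.
#' @param standardize z-score columns first (default `TRUE`).
#' @return object of class `participant_clusters`: `labels` (for the selected
#'   k when the indices agree, else for the Silhouette choice), `k_selected`,
#'   `agreement`, per-k `indices` data.frame, and the per-k labelings.
#' @export
cluster_participants <- function(measures, k_range = 2:9, restarts = 1000L,
                                 max_iter = 10000L, seed = 1L,
                                 standardize = TRUE) {
  x <- as.matrix(measures)
  if (anyNA(x)) stop_("missing values in measures")
  if (max(k_range) >= nrow(x)) stop_("k exceeds number of subjects")
  if (standardize) x <- scale(x)
  with_seed(seed, {
    per_k <- lapply(k_range, function(k) {
      km <- suppressWarnings(
        stats::kmeans(x, centers = k, nstart = restarts,
                      iter.max = max_iter))
      list(k = k, labels = km$cluster,
           sil = .mean_silhouette(x, km$cluster),
           ch = .calinski_harabasz(x, km$cluster))
    })
    idx <- data.frame(k = k_range,
                      silhouette = vapply(per_k, `[[`, 0, "sil"),
                      calinski_harabasz = vapply(per_k, `[[`, 0, "ch"))
    k_sil <- k_range[which.max(idx$silhouette)]
    k_ch <- k_range[which.max(idx$calinski_harabasz)]
    agreement <- k_sil == k_ch
    if (!agreement)
      warning("validity indices disagree: Silhouette selects k = ", k_sil,
              ", Calinski-Harabasz selects k = ", k_ch, call. = FALSE)
    sel <- per_k[[which(k_range == k_sil)]]
    structure(list(labels = sel$labels, k_selected = k_sil,
                   k_silhouette = k_sil, k_calinski = k_ch,
                   agreement = agreement, indices = idx,
                   labelings = lapply(per_k, `[[`, "labels")),
              class = "participant_clusters")
  })
}

#' @export
print.participant_clusters <- function(x, ...) {
  cat(sprintf("<participant_clusters> k = %d (indices %s), sizes: %s\n",
              x$k_selected,
              if (x$agreement) "agree" else
                sprintf("DISAGREE: sil %d / CH %d", x$k_silhouette,
                        x$k_calinski),
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Significance of a clustering solution against a multivariate-normal null
#'
#' Draws `n_iter` datasets of the same size from a multivariate normal with
#' the sample mean and covariance of the data, reruns the full
#' [cluster_participants()] sweep on each, and records the maximum value of
#' each validity index over k. The p value (one per index) is the proportion
#' of iterations whose maximum exceeds the observed maximum.
#'
#' @inheritParams cluster_participants
#' @param n_iter number of null iterations (>= 100).
#' @return list with `p` (named: silhouette, calinski_harabasz), observed
#'   maxima, and the null maxima.
#' @export
clustering_significance <- function(measures, k_range = 2:9,
                                    restarts = 1000L, n_iter = 1000L,
                                    max_iter = 10000L, seed = 1L,
                                    standardize = TRUE) {
  if (n_iter < 100) stop_("n_iter must be at least 100")
  x <- as.matrix(measures)
  obs <- cluster_participants(x, k_range, restarts, max_iter,
                              seed = derive_seed(seed, "obs"),
                              standardize = standardize)
  obs_max <- c(silhouette = max(obs$indices$silhouette),
               calinski_harabasz = max(obs$indices$calinski_harabasz))
  mu <- colMeans(x)
  S <- stats::cov(x)
  # shrink toward the diagonal if singular (reported via attribute)
  shrunk <- FALSE
  if (!all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 1e-10)) {
    S <- S + diag(1e-6 * mean(diag(S)), ncol(x))
    shrunk <- TRUE
  }
  null_max <- matrix(NA_real_, n_iter, 2L)
  for (b in seq_len(n_iter)) {
    xb <- with_seed(derive_seed(seed, "draw", b),
                    MASS::mvrnorm(nrow(x), mu, S))
    cb <- suppressWarnings(
      cluster_participants(xb, k_range, restarts, max_iter,
                           seed = derive_seed(seed, "fit", b),
                           standardize = standardize))
    null_max[b, ] <- c(max(cb$indices$silhouette),
                       max(cb$indices$calinski_harabasz))
  }
  p <- c(silhouette = mean(null_max[, 1L] > obs_max[1L]),
         calinski_harabasz = mean(null_max[, 2L] > obs_max[2L]))
  structure(list(p = p, observed = obs_max, null_max = null_max,
                 shrinkage_applied = shrunk), class = "clustering_sig")
}

#' Sign-fixed first principal component of the learning measures
#'
#' PCA on the (z-scored by default) subject-by-measure matrix. The sign of
#' PC1 is fixed so that higher scores correspond to faster learning: its
#' correlation with the mean early error across days is made negative.
#'
#' @param measures numeric matrix with columns including `early1` and
#'   `early2` (one row per subject).
#' @param standardize z-score columns first (correlation PCA, default TRUE).
#' @return object of class `behavioral_embedding`: `pc1` scores, `loadings`,
#'   `explained` variance fractions, full `scores`.
#' @export
behavioral_pc1 <- function(measures, standardize = TRUE) {
  x <- as.matrix(measures)
  if (nrow(x) < 3L) stop_("need at least 3 subjects")
  if (any(apply(x, 2L, stats::sd) == 0)) stop_("zero-variance measure")
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  scores <- pc$x
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  early <- if (all(c("early1", "early2") %in% colnames(x)))
    rowMeans(x[, c("early1", "early2")]) else rowMeans(x)
  s <- suppressWarnings(stats::cor(scores[, 1L], early))
  flip <- if (is.finite(s) && s > 0) -1 else 1
  structure(list(pc1 = flip * scores[, 1L],
                 loadings = pc$rotation, explained = expl,
                 scores = scores, sign_flipped = flip == -1),
            class = "behavioral_embedding")
}

#' @export
print.behavioral_embedding <- function(x, ...) {
  cat(sprintf("<behavioral_embedding> %d subjects; PC1 explains %.0f%% of variance\n",
              length(x$pc1), 100 * x$explained[1L]))
  invisible(x)
}
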