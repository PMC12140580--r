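# Module allegiance: the probability that two regions occupy the same module,
# pooled over time slices, partitions, and (optionally) subjects; recruitment
# and integration of labeled networks; network-composition similarity.

#' Module allegiance matrix
#'
#' Counts same-module co-assignments of every region pair over every time
#' slice of every partition of every supplied ensemble, giving the count
#' matrix `T`; the allegiance matrix is `P = T / C` where `C` is the total
#' number of time slices pooled. Optionally zeroes entries that do not exceed
#' a permutation null (module labels shuffled independently within each
#' slice).
#'
#' @param ensembles a `partition_ensemble` or list of them (e.g. one per
#'   subject for a group matrix). Counts are pooled before normalizing.
#' @param null_zero if `TRUE`, entries not exceeding the per-entry
#'   `null_percentile` of the label-permutation null are set to 0.
#' @param n_null number of null draws (default 1,000).
#' @param null_percentile percentile of the null used for zeroing
#'   (default 95).
#' @param seed integer seed for the null.
#' @return object of class `allegiance_matrix`: list with `P`, `T`, `C`.
#' @export
module_allegiance <- function(ensembles, null_zero = FALSE, n_null = 1000L,
                              null_percentile = 95, seed = 1L) {
  if (inherits(ensembles, "partition_ensemble")) ensembles <- list(ensembles)
  stopifnot(all(vapply(ensembles, inherits, TRUE, "partition_ensemble")))
  N <- ncol(ensembles[[1L]]$partitions[[1L]]$labels)
  for (e in ensembles)
    if (ncol(e$partitions[[1L]]$labels) != N)
      stop_("mismatched region sets across ensembles")
  Tm <- matrix(0, N, N)
  C <- 0L
  slices <- list() # kept for the permutation null
  for (e in ensembles) for (p in e$partitions) {
    for (l in seq_len(nrow(p$labels))) {
      g <- p$labels[l, ]
      Tm <- Tm + outer(g, g, "==")
      C <- C + 1L
      if (null_zero) slices[[length(slices) + 1L]] <- g
    }
  }
  P <- Tm / C
  if (null_zero) {
    check_number(n_null, "n_null", lower = 1, integer = TRUE)
    thr <- with_seed(seed, {
      acc <- array(0, dim = c(N, N, n_null))
      for (b in seq_len(n_null)) {
        Tn <- matrix(0, N, N)
        for (g in slices) {
          gp <- g[sample.int(N)]
          Tn <- Tn + outer(gp, gp, "==")
        }
        acc[, , b] <- Tn / C
      }
      apply(acc, c(1L, 2L), stats::quantile, probs = null_percentile / 100)
    })
    off <- !diag(N)
    zero <- off & (P <= thr)
    P[zero] <- 0
  }
  structure(list(P = P, T = Tm, C = C), class = "allegiance_matrix")
}

#' @export
print.allegiance_matrix <- function(x, ...) {
  cat(sprintf("<allegiance_matrix> %d regions, C = %d slices, mean off-diagonal P = %.3f\n",
              nrow(x$P), x$C, mean(x$P[!diag(nrow(x$P))])))
  invisible(x)
}

.get_P <- function(P) {
  if (inherits(P, "allegiance_matrix")) P$P else as.matrix(P)
}

#' Interaction between two labeled networks
#'
#' `I_{k1,k2} = (sum_{i in C_k1, j in C_k2} P_ij) / (|C_k1| |C_k2|)`: the mean
#' allegiance over the ordered block of region pairs, diagonal included when
#' `k1 == k2`.
#'
#' @param P an `allegiance_matrix` or plain N x N matrix.
#' @param k1,k2 community labels.
#' @param assign integer/character vector of length N mapping each region to a
#'   community label.
#' @return interaction value in `[0, 1]` for P in `[0, 1]`.
#' @export
interaction_strength <- function(P, k1, k2, assign) {
  P <- .get_P(P)
  i1 <- which(assign == k1)
  i2 <- which(assign == k2)
  if (!length(i1) || !length(i2)) stop_("empty community")
  mean(P[i1, i2, drop = FALSE])
}

#' Recruitment of a labeled network
#'
#' The network's interaction with itself, `I_{k,k}`: the consistency with
#' which its regions are co-assigned to the same module over time.
#'
#' @inheritParams interaction_strength
#' @param k community label.
#' @export
recruitment <- function(P, k, assign) {
  interaction_strength(P, k, k, assign)
}

#' Normalized integration between two labeled networks
#'
#' `I'_{k1,k2} = I_{k1,k2} / sqrt(I_{k1,k1} I_{k2,k2})`: between-network
#' interaction normalized by the geometric mean of the two recruitments. The
#' value may exceed 1 and is not clamped.
#'
#' @inheritParams interaction_strength
#' @export
integration <- function(P, k1, k2, assign) {
  if (identical(k1, k2)) stop_("integration requires k1 != k2")
  r1 <- recruitment(P, k1, assign)
  r2 <- recruitment(P, k2, assign)
  if (r1 <= 0 || r2 <= 0) stop_("undefined normalization: zero recruitment")
  interaction_strength(P, k1, k2, assign) / sqrt(r1 * r2)
}

#' Jaccard similarity of two region sets (percent)
#'
#' `100 * |A intersect B| / |A union B|`.
#'
#' @param setA,setB vectors of region ids.
#' @return similarity in percent.
#' @export
jaccard_similarity <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  u <- union(setA, setB)
  if (!length(u)) stop_("both sets empty")
  100 * length(intersect(setA, setB)) / length(u)
}

#' Correlation between two allegiance matrices
#'
#' Pearson correlation over the `N(N-1)/2` unordered off-diagonal entries
#' (10,011 pairs at N = 142).
#'
#' @param P1,P2 `allegiance_matrix` objects or plain matrices over the same
#'   region set.
#' @return Pearson r.
#' @export
allegiance_similarity <- function(P1, P2) {
  P1 <- .get_P(P1); P2 <- .get_P(P2)
  if (!identical(dim(P1), dim(P2))) stop_("mismatched region sets")
  ut <- upper.tri(P1)
  v1 <- P1[ut]; v2 <- P2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_("zero variance in allegiance entries")
  stats::cor(v1, v2)
}
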