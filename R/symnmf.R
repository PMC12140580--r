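# Symmetric nonnegative matrix factorization: Y ~ H H' with H >= 0, fitted by
# a Newton-like (curvature-scaled projected-gradient) scheme with Armijo
# backtracking, best-of-many random initializations, and rank-selection
# criteria (reconstruction error, dispersion, cophenetic correlation,
# explained variance) computed from the consensus of the initializations.

.symnmf_loss <- function(Y, H) {
  R <- tcrossprod(H) - Y
  sum(R * R)
}

# one fit from a given initialization; monotone decrease enforced by the
# Armijo line search on the scaled projected-gradient step
.symnmf_fit <- function(Y, H, max_iter = 500L, tol = 1e-6) {
  f <- .symnmf_loss(Y, H)
  for (it in seq_len(max_iter)) {
    HtH <- crossprod(H)
    G <- 4 * (H %*% HtH - Y %*% H) # gradient of ||Y - HH'||_F^2
    # diagonal curvature scaling: per-column Gram diagonal, floored
    scale <- 4 * pmax(diag(HtH), 1e-8)
    D <- sweep(G, 2L, scale, "/")
    alpha <- 1
    repeat {
      Hn <- pmax(H - alpha * D, 0)
      fn <- .symnmf_loss(Y, Hn)
      # projected-gradient Armijo sufficient decrease; additionally reject
      # total collapse to the all-zero stationary point (reachable in one
      # overshooting step when HH' starts far above Y), which would freeze
      # the fit at H = 0
      collapsed <- all(Hn == 0) && any(Y > 0)
      if (!collapsed && fn <= f - 1e-4 * sum(G * (H - Hn))) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { Hn <- H; fn <- f; break }
    }
    if (fn > f) { Hn <- H; fn <- f }
    rel <- (f - fn) / max(f, 1e-30)
    H <- Hn
    f <- fn
    if (rel < tol) break
  }
  list(H = H, loss = f, iters = it)
}

#' Symmetric NMF of a nonnegative symmetric matrix
#'
#' Minimizes `||Y - H H'||_F^2` over `H >= 0` (N x rank) using a Newton-like
#' curvature-scaled projected-gradient scheme with Armijo backtracking. The
#' model is fitted from `n_inits` random initializations with entries drawn
#' uniformly on `[0, 1]`, and the best fit by loss is returned.
#'
#' @param Y symmetric nonnegative matrix (e.g. a module allegiance matrix).
#' @param rank number of factors r.
#' @param n_inits number of random initializations (default 250).
#' @param seed integer seed.
#' @param max_iter,tol optimizer controls (relative loss-change stopping).
#' @param keep_inits if `TRUE`, keep every converged `H` (needed by
#'   [symnmf_rank_selection()]).
#' @return object of class `symnmf`: `H` (best factor matrix), `rmse`,
#'   `loss`, per-init `losses`, `best_init`, and optionally `inits`.
#' @export
symnmf <- function(Y, rank, n_inits = 250L, seed = 1L, max_iter = 500L,
                   tol = 1e-6, keep_inits = FALSE) {
  Y <- as.matrix(Y)
  if (!isSymmetric(unname(Y), tol = 1e-10)) stop_("Y must be symmetric")
  if (any(Y < 0)) stop_("Y must be nonnegative")
  check_number(rank, "rank", lower = 1, integer = TRUE)
  check_number(n_inits, "n_inits", lower = 1, integer = TRUE)
  N <- nrow(Y)
  losses <- numeric(n_inits)
  best <- NULL
  inits <- if (keep_inits) vector("list", n_inits) else NULL
  for (i in seq_len(n_inits)) {
    H0 <- with_seed(derive_seed(seed, "init", i),
                    matrix(stats::runif(N * rank), N, rank))
    fit <- .symnmf_fit(Y, H0, max_iter, tol)
    losses[i] <- fit$loss
    if (keep_inits) inits[[i]] <- fit$H
    if (is.null(best) || fit$loss < best$loss) {
      best <- fit
      best$init <- i
    }
  }
  structure(list(H = best$H, loss = best$loss,
                 rmse = sqrt(best$loss / N^2), losses = losses,
                 best_init = best$init, rank = rank, inits = inits),
            class = "symnmf")
}

#' @export
print.symnmf <- function(x, ...) {
  cat(sprintf("<symnmf> rank %d, best of %d inits (init %d), RMSE = %.4g\n",
              x$rank, length(x$losses), x$best_init, x$rmse))
  invisible(x)
}

#' Hard cluster assignment from a factor matrix
#'
#' Assigns each region to the factor on which it loads most strongly, with
#' ties broken deterministically toward the lowest factor index; empty
#' factors are dropped and the remaining labels renumbered 1..K.
#'
#' @param H nonnegative factor matrix (or a `symnmf` fit).
#' @return integer vector of cluster labels.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "symnmf")) H <- H$H
  H <- as.matrix(H)
  if (any(rowSums(H) == 0)) {
    stop_("unassignable region: all-zero loading row ",
          which(rowSums(H) == 0)[1L])
  }
  lab <- max.col(H, ties.method = "first")
  match(lab, sort(unique(lab)))
}

#' Rank selection for symmetric NMF
#'
#' For each rank in `ranks`, fits [symnmf()] from `n_inits` initializations
#' and reports: mean RMSE over inits; the dispersion coefficient
#' `rho = (1/N^2) sum_ij 4 (cbar_ij - 1/2)^2` of the consensus matrix `cbar`
#' (the across-init mean same-cluster indicator); the cophenetic correlation
#' between average-linkage cophenetic distances on `1 - cbar` and `1 - cbar`
#' itself; and explained variance `1 - ||Y - HH'||^2 / ||Y - mean(Y)||^2`
#' for the best fit (also reported against zero as `ev_zero`).
#'
#' @param Y symmetric nonnegative matrix.
#' @param ranks integer vector of candidate ranks (default `2:15`).
#' @param n_inits initializations per rank (default 250).
#' @param seed integer seed.
#' @param ... passed to [symnmf()].
#' @return object of class `symnmf_ranks`: data.frame `criteria` with one row
#'   per rank, plus the per-rank best fits in `fits`.
#' @export
symnmf_rank_selection <- function(Y, ranks = 2:15, n_inits = 250L, seed = 1L,
                                  ...) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  denom_mean <- sum((Y - mean(Y))^2)
  denom_zero <- sum(Y^2)
  rows <- vector("list", length(ranks))
  fits <- vector("list", length(ranks))
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    fit <- symnmf(Y, r, n_inits = n_inits, seed = derive_seed(seed, "rank", r),
                  keep_inits = TRUE, ...)
    cons <- matrix(0, N, N)
    for (H in fit$inits) {
      # consensus uses the raw argmax; an all-zero loading row (a region the
      # init left unreconstructed) falls to the tie-break factor rather than
      # aborting the whole sweep
      g <- max.col(H, ties.method = "first")
      cons <- cons + outer(g, g, "==")
    }
    cons <- cons / length(fit$inits)
    dispersion <- mean(4 * (cons - 0.5)^2)
    coph <- .cophenetic_cor(cons)
    rows[[ri]] <- data.frame(
      rank = r,
      mean_rmse = mean(sqrt(fit$losses / N^2)),
      best_rmse = fit$rmse,
      dispersion = dispersion,
      cophenetic = coph,
      explained_variance = 1 - fit$loss / denom_mean,
      ev_zero = 1 - fit$loss / denom_zero)
    fit$inits <- NULL
    fits[[ri]] <- fit
  }
  structure(list(criteria = do.call(rbind, rows), fits = fits, ranks = ranks),
            class = "symnmf_ranks")
}

# cophenetic correlation of a consensus matrix: average-linkage clustering of
# d = 1 - consensus, correlating cophenetic distances with d
.cophenetic_cor <- function(cons) {
  d <- stats::as.dist(1 - cons)
  if (stats::sd(d) == 0) return(1) # perfectly consistent: define as 1
  hc <- stats::hclust(d, method = "average")
  stats::cor(stats::cophenetic(hc), d)
}

#' @export
print.symnmf_ranks <- function(x, ...) {
  cat("<symnmf_ranks>\n")
  print(x$criteria, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Default rank heuristic: smallest rank with explained variance >= cutoff
#'
#' @param rs a `symnmf_ranks` object.
#' @param cutoff explained-variance cutoff (default 0.8).
#' @return chosen rank (integer); errors if no rank reaches the cutoff.
#' @export
select_rank <- function(rs, cutoff = 0.8) {
  ok <- rs$criteria$explained_variance >= cutoff
  if (!any(ok)) stop_("no candidate rank reaches explained variance ", cutoff)
  rs$criteria$rank[which(ok)[1L]]
}
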