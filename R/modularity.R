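# Multilayer (multislice) modularity: the quality function with the
# Newman-Girvan intra-layer null model and ordinal inter-layer coupling, a
# generalized Louvain maximization heuristic with probabilistic move
# selection, partition ensembles, and null-network significance testing.

#' Quality-function parameters
#'
#' @param gamma structural resolution (> 0, default 1).
#' @param omega inter-layer coupling strength (>= 0, default 1); temporally
#'   adjacent layers are coupled.
#' @return object of class `quality_params`.
#' @export
quality_params <- function(gamma = 1, omega = 1) {
  check_number(gamma, "gamma", lower = 1e-12)
  check_number(omega, "omega", lower = 0)
  structure(list(gamma = gamma, omega = omega), class = "quality_params")
}

# supra-modularity matrix B (NL x NL) and total weight 2mu.
# Block (l,l) holds A_l - gamma k k'/(2 m_l); blocks (l, l+-1) hold omega I.
.supra_modularity <- function(net, params) {
  layers <- net$layers
  L <- length(layers)
  N <- nrow(layers[[1L]])
  B <- matrix(0, N * L, N * L)
  twom_total <- 0
  for (l in seq_len(L)) {
    A <- layers[[l]]
    k <- rowSums(A)
    twom <- sum(k)
    twom_total <- twom_total + twom
    P <- if (twom > 0) params$gamma * tcrossprod(k) / twom else 0
    idx <- (l - 1L) * N + seq_len(N)
    B[idx, idx] <- A - P
  }
  if (L > 1L && params$omega > 0) {
    for (l in seq_len(L - 1L)) {
      i1 <- (l - 1L) * N + seq_len(N)
      i2 <- l * N + seq_len(N)
      B[cbind(i1, i2)] <- B[cbind(i1, i2)] + params$omega
      B[cbind(i2, i1)] <- B[cbind(i2, i1)] + params$omega
    }
  }
  twomu <- twom_total + 2 * params$omega * N * (L - 1L)
  if (twomu <= 0) stop_("undefined Q: empty network with omega = 0")
  list(B = B, twomu = twomu, N = N, L = L)
}

#' Multilayer modularity quality Q of a labeling
#'
#' Evaluates
#' `Q = (1/2mu) * sum_ijlr [ (A_ijl - gamma k_il k_jl / (2 m_l)) delta_lr
#'  + delta_ij omega c_lr ] delta(g_il, g_jr)`
#' with the Newman-Girvan intra-layer null model, ordinal coupling `c_lr = 1`
#' for `|l - r| = 1`, and `2mu` the total multilayer weight including
#' couplings.
#'
#' @param net a `multilayer_network`.
#' @param labels L x N integer matrix of module assignments `g_il`.
#' @param params a [quality_params()].
#' @return scalar Q.
#' @export
multilayer_quality <- function(net, labels, params = quality_params()) {
  sup <- .supra_modularity(net, params)
  g <- as.vector(t(labels)) # supra order: layer-major, node within layer
  if (length(g) != sup$N * sup$L) stop_("labels shaped wrong for network")
  same <- outer(g, g, "==")
  sum(sup$B[same]) / sup$twomu
}

# --- generalized Louvain ---------------------------------------------------

# Q (unnormalized: sum of B within communities) for labels on matrix B
.sumB <- function(B, g) {
  sum(B[outer(g, g, "==")])
}

# one Louvain pass on modularity matrix B with node weights implicit.
# Probabilistic move rule: a node is reassigned to a module drawn from all
# strictly improving moves with probability proportional to the gain.
.louvain_moves <- function(B, g, max_sweeps = 1000L) {
  n <- length(g)
  diagB <- diag(B)
  Bo <- B
  diag(Bo) <- 0
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in sample.int(n)) {
      s <- Bo[i, ]
      cs <- rowsum(s, g, reorder = FALSE)
      comms <- as.integer(rownames(cs))
      cur <- match(g[i], comms)
      gain <- cs[, 1L] - cs[cur, 1L]
      pos <- which(gain > 1e-13)
      if (length(pos)) {
        pick <- if (length(pos) == 1L) pos else
          pos[sample.int(length(pos), 1L, prob = gain[pos])]
        g[i] <- comms[pick]
        moved <- TRUE
      }
    }
    if (!moved) return(list(g = g, sweeps = sweep))
  }
  stop_("generalized Louvain failed to converge within ", max_sweeps,
        " sweeps")
}

# aggregate B by community labels (labels assumed 1..K)
.aggregate_B <- function(B, g) {
  K <- max(g)
  ind <- matrix(0, length(g), K)
  ind[cbind(seq_along(g), g)] <- 1
  crossprod(ind, B %*% ind)
}

# full Louvain (move phase + aggregation rounds) from an initial labeling;
# returns labels on the original nodes
.louvain_once <- function(B, init, max_sweeps = 1000L, max_agg = 100L) {
  g <- match(init, unique(init))
  g <- .louvain_moves(B, g, max_sweeps)$g
  g <- match(g, unique(g))
  for (it in seq_len(max_agg)) {
    Bagg <- .aggregate_B(B, g)
    gm <- .louvain_moves(Bagg, seq_len(nrow(Bagg)), max_sweeps)$g
    gm <- match(gm, unique(gm))
    if (identical(gm, seq_len(nrow(Bagg)))) return(g)
    g <- gm[g]
  }
  stop_("generalized Louvain failed to converge within ", max_agg,
        " aggregation rounds")
}

#' Generalized Louvain partition of a multilayer network
#'
#' Maximizes the multilayer quality function over the `L*N` supra-node
#' problem. Node sweeps consider all strictly improving module reassignments
#' and select among them at random with probability proportional to the
#' quality gain; aggregation rounds are deterministic. The converged partition
#' is re-fed as the starting point until the output equals the input (up to
#' module relabeling).
#'
#' @param net a `multilayer_network`.
#' @param params a [quality_params()].
#' @param seed integer seed for the run.
#' @param max_outer cap on the stable-partition outer loop.
#' @return object of class `ml_partition`: list with `labels` (L x N integer
#'   matrix) and `quality` Q.
#' @export
genlouvain_partition <- function(net, params = quality_params(), seed = 1L,
                                 max_outer = 100L) {
  sup <- .supra_modularity(net, params)
  with_seed(seed, {
    g <- seq_len(sup$N * sup$L) # singleton start
    for (outer in seq_len(max_outer)) {
      g2 <- .louvain_once(sup$B, g)
      g2 <- match(g2, unique(g2))
      if (identical(match(g, unique(g)), g2)) break
      g <- g2
      if (outer == max_outer)
        stop_("stable-partition loop failed to converge within ", max_outer,
              " iterations")
    }
    labels <- matrix(g, nrow = sup$L, byrow = TRUE)
    structure(list(labels = canonical_labels(labels),
                   quality = sum(sup$B[outer(g, g, "==")]) / sup$twomu),
              class = "ml_partition")
  })
}

#' @export
print.ml_partition <- function(x, ...) {
  cat(sprintf("<ml_partition> %d layers x %d regions, %d modules, Q = %.4f\n",
              nrow(x$labels), ncol(x$labels), length(unique(as.vector(x$labels))),
              x$quality))
  invisible(x)
}

#' Ensemble of independent generalized Louvain partitions
#'
#' Runs the heuristic `R` times with seeds derived from `seed`, collecting the
#' partitions and their qualities; `mean_q` is the subject-level modularity
#' score.
#'
#' @param net a `multilayer_network`.
#' @param R number of runs (default 100).
#' @param params a [quality_params()].
#' @param seed master seed; run r uses `derive_seed(seed, "run", r)`.
#' @return object of class `partition_ensemble`: list with `partitions`,
#'   `q` (vector), `mean_q`.
#' @export
partition_ensemble <- function(net, R = 100L, params = quality_params(),
                               seed = 1L) {
  check_number(R, "R", lower = 1, integer = TRUE)
  parts <- vector("list", R)
  q <- numeric(R)
  for (r in seq_len(R)) {
    parts[[r]] <- genlouvain_partition(net, params,
                                       seed = derive_seed(seed, "run", r))
    q[r] <- parts[[r]]$quality
  }
  structure(list(partitions = parts, q = q, mean_q = mean(q)),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition_ensemble> R = %d runs, mean Q = %.4f (range %.4f-%.4f)\n",
              length(x$q), x$mean_q, min(x$q), max(x$q)))
  invisible(x)
}

# null networks for the modularity significance check
.null_network <- function(net, kind, seed) {
  with_seed(seed, {
    out <- net
    L <- length(net$layers)
    N <- nrow(net$layers[[1L]])
    if (kind == "temporal") {
      out$layers <- net$layers[sample.int(L)]
    } else if (kind == "connectional") {
      ut <- which(upper.tri(matrix(0, N, N)))
      out$layers <- lapply(net$layers, function(A) {
        w <- A[ut]
        A[ut] <- w[sample.int(length(w))]
        A[lower.tri(A)] <- t(A)[lower.tri(A)]
        A
      })
    } else if (kind == "nodal") {
      # scramble which node a node is coupled to across layers: relabel each
      # layer's rows/columns by an independent permutation, equivalently
      # rewiring the identity inter-layer couplings
      out$layers <- lapply(net$layers, function(A) {
        p <- sample.int(N)
        A[p, p]
      })
    } else stop_("unknown null kind: ", kind)
    out
  })
}

#' Significance of observed modularity against null networks
#'
#' Compares the observed mean ensemble Q with the mean Q of ensembles fitted
#' to null networks drawn by layer-order permutation (`temporal`),
#' within-layer edge-weight permutation (`connectional`), or per-layer node
#' relabeling that scrambles the inter-layer couplings (`nodal`).
#'
#' @param net a `multilayer_network`.
#' @param n_nulls number of null networks (>= 19).
#' @param null_kind one of `"temporal"`, `"connectional"`, `"nodal"`.
#' @param R ensemble size per network.
#' @param params a [quality_params()].
#' @param seed integer seed.
#' @return list with `p` (add-one permutation p value), `observed` mean Q and
#'   `null_q` vector.
#' @export
modularity_null_test <- function(net, n_nulls = 99L,
                                 null_kind = c("connectional", "temporal",
                                               "nodal"),
                                 R = 10L, params = quality_params(),
                                 seed = 1L) {
  null_kind <- match.arg(null_kind)
  check_number(n_nulls, "n_nulls", lower = 1, integer = TRUE)
  if (n_nulls < 19) stop_("n_nulls must be at least 19")
  obs <- partition_ensemble(net, R = R, params = params,
                            seed = derive_seed(seed, "obs"))$mean_q
  null_q <- numeric(n_nulls)
  for (b in seq_len(n_nulls)) {
    nn <- .null_network(net, null_kind, derive_seed(seed, "null", b))
    null_q[b] <- partition_ensemble(nn, R = R, params = params,
                                    seed = derive_seed(seed, "nullfit", b))$mean_q
  }
  list(p = (1 + sum(null_q >= obs)) / (n_nulls + 1), observed = obs,
       null_q = null_q)
}
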