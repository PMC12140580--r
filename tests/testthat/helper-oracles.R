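# Independent oracles used across the suite: literal-formula implementations
# kept deliberately naive (loops, enumerations) so they share no code with
# the package internals they check.

# random symmetric nonnegative multilayer network
random_net <- function(N, L, density = 0.6, seed = 1) {
  set.seed(seed)
  layers <- lapply(seq_len(L), function(l) {
    A <- matrix(0, N, N)
    ut <- which(upper.tri(A))
    on <- sample(ut, round(density * length(ut)))
    A[on] <- runif(length(on))
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    A
  })
  structure(list(layers = layers, window_spec = window_spec(),
                 band = c(0.125, 0.25), threshold = 0, sparsity = NA,
                 tr = 2, regions = paste0("r", 1:N), subject = "oracle"),
            class = "multilayer_network")
}

# literal quadruple-sum multilayer quality:
# Q = (1/2mu) sum_{ijlr} [ (A_ijl - g k_il k_jl/(2 m_l)) d_lr
#     + d_ij w c_lr ] d(g_il, g_jr)
oracle_quality <- function(net, labels, gamma = 1, omega = 1) {
  L <- length(net$layers); N <- nrow(net$layers[[1]])
  twom <- sapply(net$layers, sum)
  k <- sapply(net$layers, rowSums) # N x L
  total <- 0
  for (l in seq_len(L)) for (r in seq_len(L)) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (labels[l, i] != labels[r, j]) next
      if (l == r) {
        pen <- if (twom[l] > 0)
          gamma * k[i, l] * k[j, l] / twom[l] else 0
        total <- total + net$layers[[l]][i, j] - pen
      }
      if (i == j && abs(l - r) == 1) total <- total + omega
    }
  }
  twomu <- sum(twom) + 2 * omega * N * (L - 1)
  total / twomu
}

# all set partitions of n elements as restricted growth strings (matrix,
# one row per partition); memoized
.rgs_cache <- new.env()
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.rgs_cache[[key]])) return(.rgs_cache[[key]])
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(c(1L), 1L)
  m <- do.call(rbind, out)
  .rgs_cache[[key]] <- m
  m
}

# exhaustive maximum of the multilayer quality over all supra-node set
# partitions (feasible for N*L <= 10)
oracle_max_quality <- function(net, gamma = 1, omega = 1) {
  L <- length(net$layers); N <- nrow(net$layers[[1]])
  sup <- dynmod:::.supra_modularity(net, quality_params(gamma, omega))
  B <- sup$B
  n <- N * L
  P <- all_partitions(n)
  q <- rep(sum(diag(B)), nrow(P))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    q <- q + (P[, i] == P[, j]) * (2 * B[i, j])
  }
  max(q) / sup$twomu
}

# explicit event-enumeration reconfiguration oracle
oracle_reconfig <- function(labels) {
  L <- nrow(labels); N <- ncol(labels)
  coh <- numeric(N); dis <- numeric(N)
  for (l in seq_len(L - 1)) {
    for (i in seq_len(N)) {
      if (labels[l, i] == labels[l + 1, i]) next
      partners <- 0
      for (j in seq_len(N)) {
        if (j == i) next
        if (labels[l, j] == labels[l, i] &&
            labels[l + 1, j] == labels[l + 1, i] &&
            labels[l, j] != labels[l + 1, j])
          partners <- partners + 1
      }
      coh[i] <- coh[i] + partners
      if (partners == 0) dis[i] <- dis[i] + 1
    }
  }
  list(cohesion = coh / (L - 1), disjointedness = dis / (L - 1))
}

# triple-loop allegiance counting oracle
oracle_allegiance <- function(ensembles) {
  if (inherits(ensembles, "partition_ensemble")) ensembles <- list(ensembles)
  N <- ncol(ensembles[[1]]$partitions[[1]]$labels)
  Tm <- matrix(0, N, N); C <- 0
  for (e in ensembles) for (p in e$partitions) {
    for (l in seq_len(nrow(p$labels))) {
      C <- C + 1
      for (i in seq_len(N)) for (j in seq_len(N)) {
        if (p$labels[l, i] == p$labels[l, j]) Tm[i, j] <- Tm[i, j] + 1
      }
    }
  }
  list(P = Tm / C, T = Tm, C = C)
}

# double-loop interaction oracle
oracle_interaction <- function(P, k1, k2, assign) {
  i1 <- which(assign == k1); i2 <- which(assign == k2)
  s <- 0
  for (i in i1) for (j in i2) s <- s + P[i, j]
  s / (length(i1) * length(i2))
}

# random partition ensemble
random_ensemble <- function(N, L, K, R, seed = 1) {
  set.seed(seed)
  parts <- lapply(seq_len(R), function(r) {
    structure(list(labels = matrix(sample.int(K, L * N, replace = TRUE),
                                   L, N),
                   quality = runif(1)), class = "ml_partition")
  })
  structure(list(partitions = parts,
                 q = sapply(parts, `[[`, "quality"),
                 mean_q = mean(sapply(parts, `[[`, "quality"))),
            class = "partition_ensemble")
}

# multiplicative-update symmetric NMF cross-check (beta-stabilized)
symnmf_mu <- function(Y, rank, seed = 1, iters = 2000) {
  set.seed(seed)
  H <- matrix(runif(nrow(Y) * rank), nrow(Y))
  beta <- 0.5
  for (it in seq_len(iters)) {
    num <- Y %*% H
    den <- H %*% crossprod(H)
    H <- H * (1 - beta + beta * num / pmax(den, 1e-12))
  }
  H
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny panel with two planted modules for connectivity checks
planted_panel <- function(N = 12, Tn = 96, rho = 0.8, noise_sd = 1,
                          seed = 1, n_modules = 2) {
  set.seed(seed)
  g <- rep_len(seq_len(n_modules), N)
  lat <- matrix(rnorm(n_modules * Tn), n_modules)
  x <- lat[g, ] + noise_sd * sqrt(1 / rho - 1) * matrix(rnorm(N * Tn), N)
  list(panel = timeseries_panel(x, 2), modules = g)
}
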