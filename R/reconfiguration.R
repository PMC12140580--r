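# Coordinated vs. uncoordinated modular reconfiguration.
#
# At each transition between consecutive windows, a region either keeps its
# module, moves together with partners (same source module AND same target
# module), or moves alone. Cohesion strength counts mutual moves summed over
# partners; disjointedness counts lone moves; both are normalized by the
# number of transitions (L - 1).

# per-transition bookkeeping: for each region, the number of partners making
# the identical source -> target move, or -1 if the region did not change
.move_partners <- function(g_from, g_to) {
  changed <- g_from != g_to
  out <- rep(-1L, length(g_from))
  if (!any(changed)) return(out)
  key <- paste(g_from[changed], g_to[changed])
  cnt <- table(key)
  out[changed] <- as.integer(cnt[key]) - 1L
  out
}

#' Cohesion strength of a multilayer partition
#'
#' For region i, the number of times it changes modules together with each
#' other region (same source and target module), summed over all other
#' regions and transitions, divided by the number of transitions `L - 1`.
#'
#' @param partition an `ml_partition` or an L x N label matrix.
#' @return numeric vector of per-region cohesion strengths (>= 0).
#' @export
cohesion_strength <- function(partition) {
  labels <- if (inherits(partition, "ml_partition")) partition$labels else
    as.matrix(partition)
  L <- nrow(labels)
  if (L < 2L) stop_("no transitions: need at least 2 layers")
  acc <- numeric(ncol(labels))
  for (l in seq_len(L - 1L)) {
    p <- .move_partners(labels[l, ], labels[l + 1L, ])
    acc <- acc + pmax(p, 0L)
  }
  acc / (L - 1L)
}

#' Disjointedness of a multilayer partition
#'
#' For region i, the number of transitions at which it changes modules with
#' no other region making the same source-to-target move, divided by the
#' number of transitions `L - 1`. Values lie in `[0, 1]`.
#'
#' @inheritParams cohesion_strength
#' @return numeric vector of per-region disjointedness values.
#' @export
disjointedness <- function(partition) {
  labels <- if (inherits(partition, "ml_partition")) partition$labels else
    as.matrix(partition)
  L <- nrow(labels)
  if (L < 2L) stop_("no transitions: need at least 2 layers")
  acc <- numeric(ncol(labels))
  for (l in seq_len(L - 1L)) {
    p <- .move_partners(labels[l, ], labels[l + 1L, ])
    acc <- acc + (p == 0L)
  }
  acc / (L - 1L)
}

#' Reconfiguration scores of a partition ensemble
#'
#' Computes cohesion strength and disjointedness for every partition in the
#' ensemble, averages per region over partitions, and summarizes each subject
#' as the mean over regions.
#'
#' @param ensemble a `partition_ensemble`.
#' @return object of class `reconfig_scores`: list with per-region `cohesion`
#'   and `disjointedness` vectors and scalar `subject_cohesion`,
#'   `subject_disjointedness`.
#' @export
ensemble_reconfig <- function(ensemble) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  coh <- rowMeans(vapply(ensemble$partitions, cohesion_strength,
                         numeric(ncol(ensemble$partitions[[1L]]$labels))))
  dis <- rowMeans(vapply(ensemble$partitions, disjointedness,
                         numeric(ncol(ensemble$partitions[[1L]]$labels))))
  structure(list(cohesion = coh, disjointedness = dis,
                 subject_cohesion = mean(coh),
                 subject_disjointedness = mean(dis)),
            class = "reconfig_scores")
}

#' @export
print.reconfig_scores <- function(x, ...) {
  cat(sprintf("<reconfig_scores> %d regions: mean cohesion %.3f, mean disjointedness %.3f\n",
              length(x$cohesion), x$subject_cohesion,
              x$subject_disjointedness))
  invisible(x)
}
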