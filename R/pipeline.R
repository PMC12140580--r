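# End-to-end orchestration: simulate/read -> connectivity -> partitions ->
# reconfiguration + allegiance metrics -> behavior -> brain-behavior
# regression, with per-stage derived seeds, light content-hash caching of the
# expensive partition stage, and a machine-readable report.

.obj_md5 <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Read a serialized cohort directory
#'
#' Counterpart of [generate_cohort()] with `dir` set: reads the manifest,
#' per-subject panels and trial tables, and the region sidecar.
#'
#' @param dir cohort directory.
#' @return a `synthetic_cohort`-shaped list (without ground-truth partition
#'   matrices unless present in the per-subject truth files).
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  regions <- utils::read.delim(file.path(dir, "regions.tsv"))
  subjects <- lapply(man$subjects, function(sid) {
    sd <- file.path(dir, sid)
    truth <- jsonlite::read_json(file.path(sd, "truth.json"),
                                 simplifyVector = TRUE)
    list(rest1 = read_timeseries_panel(file.path(sd, "rest1.tsv"), sid),
         rest2 = read_timeseries_panel(file.path(sd, "rest2.tsv"), sid),
         trials = read_trial_table(file.path(sd, "trials.tsv")),
         truth = truth)
  })
  structure(list(subjects = subjects, config = NULL,
                 region_networks = regions$task_network,
                 profiles = man$profiles),
            class = "synthetic_cohort")
}

.log_stage <- function(quiet, ...) {
  if (!quiet) message(sprintf("[dynmod] %s", sprintf(...)))
}

# cached partition ensemble: labels + q are persisted per (subject, scan)
# with an input hash; a missing or stale file triggers recomputation
.cached_ensemble <- function(net, R, params, seed, cache_dir, tag, quiet) {
  if (is.null(cache_dir)) {
    return(partition_ensemble(net, R = R, params = params, seed = seed))
  }
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .obj_md5(list(layers = net$layers, R = R, params = params,
                        seed = seed))
  fl <- file.path(cache_dir, paste0(tag, "_labels.tsv"))
  fm <- file.path(cache_dir, paste0(tag, "_meta.json"))
  if (file.exists(fl) && file.exists(fm)) {
    meta <- jsonlite::read_json(fm, simplifyVector = TRUE)
    if (identical(meta$hash, hash)) {
      .log_stage(quiet, "partition %s: cached", tag)
      lab <- as.matrix(utils::read.table(fl))
      L <- length(net$layers)
      q <- as.numeric(meta$q) # stored as %.17g strings: exact round-trip
      parts <- lapply(seq_len(R), function(r) {
        structure(list(labels = unname(lab[(r - 1) * L + seq_len(L), ,
                                           drop = FALSE]),
                       quality = q[r]), class = "ml_partition")
      })
      return(structure(list(partitions = parts, q = q, mean_q = mean(q)),
                       class = "partition_ensemble"))
    }
  }
  ens <- partition_ensemble(net, R = R, params = params, seed = seed)
  lab <- do.call(rbind, lapply(ens$partitions, `[[`, "labels"))
  utils::write.table(lab, fl, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(hash = hash, q = sprintf("%.17g", ens$q)), fm,
                       auto_unbox = FALSE)
  ens
}

#' Run the full analysis pipeline on a cohort
#'
#' For every subject and requested scan: MODWT scale-`scale` windowed
#' coherence with a shuffle-null threshold, generalized Louvain partition
#' ensemble, reconfiguration scores, node strength, and subject-level
#' allegiance with recruitment/integration of the labeled networks.
#' Cohort-level: behavioral learning measures, validated subgrouping, the
#' PC1 learning score, and permutation-validated regression of every network
#' measure on PC1 with FDR families for the recruitment and integration
#' sweeps.
#'
#' Defaults use a reduced compute profile (`runs = 25`, `null_iters = 1000`,
#' `n_perm = 999`, `restarts = 100`); study-scale values (100 / 10,000 /
#' 10,000 / 1,000) can be supplied through the corresponding arguments.
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()]) or a cohort
#'   directory path (read with [read_cohort()]).
#' @param scans which resting scans to analyze (subset of
#'   `c("rest1", "rest2")`).
#' @param spec a [window_spec()].
#' @param scale MODWT scale.
#' @param params a [quality_params()].
#' @param runs partition-ensemble size per subject.
#' @param null_iters iterations of the coherence shuffle null.
#' @param percentile coherence-null percentile.
#' @param restarts k-means restarts.
#' @param k_range candidate cluster counts.
#' @param n_perm LOOCV permutations per regression.
#' @param relearn_network,learn_network labels (in the region sidecar /
#'   `region_networks`) of the networks whose recruitment and mutual
#'   integration are the focal predictors.
#' @param seed master seed (default 1).
#' @param out_dir optional directory for cached stage outputs and the report.
#' @param quiet suppress progress messages.
#' @return object of class `dynmod_report`: per-scan subject metric tables,
#'   behavioral results, regression models (raw and FDR-adjusted p), and
#'   provenance.
#' @export
run_pipeline <- function(cohort, scans = "rest1", spec = window_spec(),
                         scale = 1L, params = quality_params(), runs = 25L,
                         null_iters = 1000L, percentile = 95,
                         restarts = 100L, k_range = 2:9, n_perm = 999L,
                         relearn_network = 1L, learn_network = 2L,
                         seed = 1L, out_dir = NULL, quiet = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  stopifnot(all(scans %in% c("rest1", "rest2")))
  nsub <- length(cohort$subjects)
  nets <- cohort$region_networks
  net_labels <- sort(unique(nets))
  cache_dir <- if (!is.null(out_dir)) file.path(out_dir, "partitions")
  per_scan <- list()
  ensembles <- list()
  for (scan in scans) {
    rows <- vector("list", nsub)
    ens_list <- vector("list", nsub)
    for (s in seq_len(nsub)) {
      panel <- cohort$subjects[[s]][[scan]]
      .log_stage(quiet, "connect %s sub %d/%d", scan, s, nsub)
      thr <- coherence_null_threshold(
        panel, spec, scale, n_iter = null_iters, percentile = percentile,
        seed = derive_seed(seed, "null", scan, s))
      net <- build_multilayer(panel, spec, scale, threshold = as.numeric(thr))
      ens <- .cached_ensemble(net, runs, params,
                              derive_seed(seed, "partition", scan, s),
                              cache_dir, sprintf("sub%02d_%s", s, scan),
                              quiet)
      rec <- ensemble_reconfig(ens)
      P <- module_allegiance(ens)
      recs <- vapply(net_labels, function(k) recruitment(P, k, nets), 0)
      ints <- vapply(setdiff(net_labels, relearn_network), function(k)
        integration(P, relearn_network, k, nets), 0)
      rows[[s]] <- data.frame(
        subject = s, scan = scan,
        q = ens$mean_q,
        cohesion = rec$subject_cohesion,
        disjointedness = rec$subject_disjointedness,
        strength = node_strength(net)$subject,
        sparsity = net$sparsity,
        threshold = as.numeric(thr),
        recruitment = recs[which(net_labels == relearn_network)],
        integration = ints[which(setdiff(net_labels, relearn_network) ==
                                   learn_network)],
        t(stats::setNames(recs, paste0("recruit_", net_labels))),
        t(stats::setNames(ints, paste0("integrate_",
                                       setdiff(net_labels,
                                               relearn_network)))))
      ens_list[[s]] <- ens
    }
    per_scan[[scan]] <- do.call(rbind, rows)
    ensembles[[scan]] <- ens_list
  }
  # behavior
  .log_stage(quiet, "behavior: measures, clustering, PC1")
  meas <- t(vapply(cohort$subjects, function(su)
    trial_learning_measures(su$trials), numeric(5)))
  clus <- cluster_participants(meas, k_range = k_range, restarts = restarts,
                               seed = derive_seed(seed, "kmeans"))
  emb <- behavioral_pc1(meas)
  # regression of every measure on PC1, with FDR families for the
  # recruitment sweep (all networks) and the integration sweep (others vs
  # the focal network)
  y <- emb$pc1
  tab1 <- per_scan[[scans[1L]]]
  fit_one <- function(xcol, label) {
    x <- tab1[[xcol]]
    fit <- ols_fit(x, y)
    lo <- loocv_permutation(x, y, n_perm = n_perm,
                            seed = derive_seed(seed, "perm", label))
    data.frame(measure = label, beta = unname(stats::coef(fit)[2L]),
               r_squared = fit$r_squared, f = fit$f_statistic,
               p = fit$p_value, loocv_mse = lo$mse, loocv_sd = lo$sd,
               perm_p = lo$p)
  }
  .log_stage(quiet, "predict: regressions with LOOCV permutation")
  base_models <- do.call(rbind, lapply(
    c("q", "cohesion", "disjointedness", "strength"),
    function(m) fit_one(m, m)))
  recruit_models <- do.call(rbind, lapply(net_labels, function(k)
    fit_one(paste0("recruit_", k), paste0("recruit_", k))))
  recruit_models$p_fdr <- fdr_adjust(recruit_models$p)
  int_nets <- setdiff(net_labels, relearn_network)
  integ_models <- do.call(rbind, lapply(int_nets, function(k)
    fit_one(paste0("integrate_", k), paste0("integrate_", k))))
  integ_models$p_fdr <- fdr_adjust(integ_models$p)
  report <- structure(list(
    metrics = per_scan, behavior = list(measures = meas, clusters = clus,
                                        embedding = emb),
    models = list(base = base_models, recruitment = recruit_models,
                  integration = integ_models),
    networks = list(assign = nets, relearn = relearn_network,
                    learn = learn_network),
    ensembles = ensembles,
    provenance = list(seed = seed, scans = scans, runs = runs,
                      null_iters = null_iters, n_perm = n_perm,
                      scale = scale, gamma = params$gamma,
                      omega = params$omega,
                      config_hash = .obj_md5(cohort$config %||% NA))),
    class = "dynmod_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (scan in scans)
      utils::write.table(per_scan[[scan]],
                         file.path(out_dir, paste0("metrics_", scan, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(models = report$models,
           behavior = list(k_selected = clus$k_selected,
                           agreement = clus$agreement,
                           pc1 = unname(y),
                           explained = emb$explained),
           provenance = report$provenance),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}

#' @export
print.dynmod_report <- function(x, ...) {
  cat(sprintf("<dynmod_report> %d subjects, scans: %s\n",
              nrow(x$metrics[[1L]]), paste(names(x$metrics),
                                           collapse = ", ")))
  cat(sprintf("  behavior: k = %d, PC1 explains %.0f%% of variance\n",
              x$behavior$clusters$k_selected,
              100 * x$behavior$embedding$explained[1L]))
  cat("  focal models (predictor -> PC1):\n")
  tab <- rbind(x$models$base,
               x$models$recruitment[
                 x$models$recruitment$measure ==
                   paste0("recruit_", x$networks$relearn), -9L],
               x$models$integration[
                 x$models$integration$measure ==
                   paste0("integrate_", x$networks$learn), -9L])
  print(tab[, c("measure", "beta", "r_squared", "p", "perm_p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare two resting scans of the same cohort
#'
#' Per measure: paired t test of the Rest2 - Rest1 difference, and Steiger's
#' dependent-correlation test of whether the measure's correlation with the
#' outcome differs between scans (using the cross-scan correlation of the
#' measure itself). FDR is applied within each declared family.
#'
#' @param report a `dynmod_report` containing both scans (or a list with
#'   `metrics$rest1` and `metrics$rest2` tables).
#' @param outcome numeric outcome vector (default: the report's PC1).
#' @param measures measure columns to test.
#' @param steiger_measures subset of `measures` forming the
#'   correlation-change FDR family (default: all but `q`, whose predictive
#'   correlation is not a focal test).
#' @return data.frame with paired and Steiger statistics and FDR-adjusted
#'   p values.
#' @export
compare_scans <- function(report, outcome = NULL,
                          measures = c("q", "cohesion", "disjointedness",
                                       "recruitment", "integration",
                                       "strength"),
                          steiger_measures = setdiff(measures, "q")) {
  m1 <- report$metrics$rest1
  m2 <- report$metrics$rest2
  if (is.null(m1) || is.null(m2)) stop_("report must contain both scans")
  if (!identical(m1$subject, m2$subject)) stop_("subject mismatch")
  if (is.null(outcome)) outcome <- report$behavior$embedding$pc1
  rows <- lapply(measures, function(m) {
    a <- m1[[m]]; b <- m2[[m]]
    pt <- paired_test(b, a)
    st <- if (m %in% steiger_measures) {
      r23 <- stats::cor(a, b)
      if (r23 >= 1 - 1e-12) {
        # the scans carry identical values: the two dependent correlations
        # coincide and the statistic is identically zero
        list(t = 0, df = length(a) - 3L, p = 1)
      } else {
        steiger_dependent_corr(stats::cor(outcome, a),
                               stats::cor(outcome, b), r23, length(a))
      }
    } else list(t = NA_real_, df = NA_integer_, p = NA_real_)
    data.frame(measure = m, diff_mean = pt$mean_diff, paired_t = pt$t,
               paired_df = pt$df, paired_p = pt$p,
               r_rest1 = stats::cor(outcome, a),
               r_rest2 = stats::cor(outcome, b),
               steiger_t = st$t, steiger_p = st$p)
  })
  out <- do.call(rbind, rows)
  out$paired_p_fdr <- fdr_adjust(out$paired_p)
  sel <- out$measure %in% steiger_measures
  out$steiger_p_fdr <- NA_real_
  out$steiger_p_fdr[sel] <- fdr_adjust(out$steiger_p[sel])
  out
}
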