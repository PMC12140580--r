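# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes: per-subject region-by-time panels with planted, window-varying
# community structure (shared module-level latent signals plus region noise),
# subject-varying coupling strength and reconfiguration coordination, and
# trial tables whose exponential error decay is linked to the planted
# coupling so that brain-behavior recovery is testable end to end.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the target study: 32 subjects in three learner profiles
#' (FF fast both days, SS slow both days, SF slow then fast) of sizes
#' 15/10/7; 142 regions, 180 volumes at a 2-s sampling interval per resting
#' scan; 5 planted modules; 40 learning bins of 8 trials per day.
#'
#' Within a planted block, regions of the same module share a latent Gaussian
#' signal; region noise is scaled so that the within-module correlation
#' equals the profile's coupling strength at `noise_sd = 1` (and 1 at
#' `noise_sd = 0`). Trial errors decay as `a exp(-t/tau) + b` with profile
#' time constants modulated by the planted coupling through `effect_slope`.
#'
#' @param n_subjects number of subjects.
#' @param n_regions regions per panel (default 142).
#' @param n_volumes volumes per scan (default 180).
#' @param tr sampling interval in seconds (default 2).
#' @param n_modules_planted planted module count (default 5).
#' @param subgroup_sizes named counts for profiles FF/SS/SF (sum to
#'   `n_subjects`).
#' @param coupling_strength_by_profile within-module correlation targets in
#'   (0, 1) per profile.
#' @param cohesion_rate_by_profile expected coordinated (grouped) module-
#'   switch events per planted transition, per profile.
#' @param disjoint_rate_by_profile expected lone-switch events per planted
#'   transition, per profile.
#' @param noise_sd region-noise scale (default 1; 0 gives noiseless panels).
#' @param behav_noise_sd trial-error noise in degrees (default 2).
#' @param effect_slope link coefficient from planted coupling to learning
#'   rate (default 2).
#' @param amplitude_deg,baseline_deg error-curve amplitude and asymptote.
#' @param tau_by_profile day-1/day-2 decay constants (trials) per profile.
#' @param rest2_coupling_delta per-profile additive change of coupling in the
#'   second resting scan (default 0: both scans statistically identical).
#' @param block_volumes length of a planted-partition block in volumes
#'   (default 32, one analysis window).
#' @param coupling_jitter half-width of the uniform per-subject coupling
#'   perturbation (default 0.05).
#' @param seed master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 32L, n_regions = 142L,
                          n_volumes = 180L, tr = 2.0,
                          n_modules_planted = 5L,
                          subgroup_sizes = c(FF = 15L, SS = 10L, SF = 7L),
                          coupling_strength_by_profile =
                            c(FF = 0.8, SS = 0.3, SF = 0.55),
                          cohesion_rate_by_profile =
                            c(FF = 2, SS = 0.5, SF = 1),
                          disjoint_rate_by_profile =
                            c(FF = 0.5, SS = 3, SF = 1.5),
                          noise_sd = 1, behav_noise_sd = 2,
                          effect_slope = 2,
                          amplitude_deg = 40, baseline_deg = 5,
                          tau_by_profile = list(FF = c(25, 18),
                                                SS = c(130, 110),
                                                SF = c(130, 18)),
                          rest2_coupling_delta = c(FF = 0, SS = 0, SF = 0),
                          block_volumes = 32L, coupling_jitter = 0.05,
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_number(n_regions, "n_regions", lower = 2, integer = TRUE)
  check_number(n_volumes, "n_volumes", lower = 2, integer = TRUE)
  check_number(n_modules_planted, "n_modules_planted", lower = 2,
               integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(behav_noise_sd, "behav_noise_sd", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  profs <- c("FF", "SS", "SF")
  stopifnot(all(profs %in% names(subgroup_sizes)),
            all(profs %in% names(coupling_strength_by_profile)),
            all(profs %in% names(cohesion_rate_by_profile)),
            all(profs %in% names(disjoint_rate_by_profile)))
  if (sum(subgroup_sizes) != n_subjects)
    stop_("subgroup sizes must sum to n_subjects")
  if (any(coupling_strength_by_profile <= 0 |
            coupling_strength_by_profile >= 1))
    stop_("coupling strengths must lie in (0, 1)")
  if (any(cohesion_rate_by_profile < 0) || any(disjoint_rate_by_profile < 0))
    stop_("switch rates must be nonnegative")
  for (p in profs) if (any(tau_by_profile[[p]] <= 0))
    stop_("nonpositive tau for profile ", p)
  if (n_volumes < block_volumes) stop_("series too short")
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_volumes = as.integer(n_volumes), tr = tr,
    n_modules_planted = as.integer(n_modules_planted),
    subgroup_sizes = subgroup_sizes,
    coupling_strength_by_profile = coupling_strength_by_profile,
    cohesion_rate_by_profile = cohesion_rate_by_profile,
    disjoint_rate_by_profile = disjoint_rate_by_profile,
    noise_sd = noise_sd, behav_noise_sd = behav_noise_sd,
    effect_slope = effect_slope, amplitude_deg = amplitude_deg,
    baseline_deg = baseline_deg, tau_by_profile = tau_by_profile,
    rest2_coupling_delta = rest2_coupling_delta,
    block_volumes = as.integer(block_volumes),
    coupling_jitter = coupling_jitter, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects (FF/SS/SF = %s), %d regions x %d volumes, %d planted modules, seed %d\n",
              x$n_subjects, paste(x$subgroup_sizes[c("FF", "SS", "SF")],
                                  collapse = "/"),
              x$n_regions, x$n_volumes, x$n_modules_planted, x$seed))
  invisible(x)
}

#' Profile labels of a cohort, in subject order
#' @param config a [cohort_config()].
#' @return character vector of length `n_subjects`.
#' @export
subject_profiles <- function(config) {
  rep(c("FF", "SS", "SF"),
      times = config$subgroup_sizes[c("FF", "SS", "SF")])
}

# per-subject planted coupling: profile value plus a deterministic jitter
.subject_coupling <- function(config, subject, scan = 1L) {
  prof <- subject_profiles(config)[subject]
  jit <- with_seed(derive_seed(config$seed, "coupling", subject),
                   stats::runif(1, -config$coupling_jitter,
                                config$coupling_jitter))
  rho <- config$coupling_strength_by_profile[[prof]] + jit
  if (scan == 2L) rho <- rho + config$rest2_coupling_delta[[prof]]
  min(max(rho, 0.02), 0.98)
}

# planted base partition: contiguous balanced modules, identical across
# subjects (so labeled networks are comparable cohort-wide)
.base_partition <- function(n_regions, n_modules) {
  sort(rep_len(seq_len(n_modules), n_regions))
}

# evolve the partition across blocks with cohesive (grouped) and disjoint
# (lone) switch events; modules are never emptied
.evolve_partition <- function(g, n_modules, coh_rate, dis_rate) {
  n_coh <- stats::rpois(1L, coh_rate)
  n_dis <- stats::rpois(1L, dis_rate)
  if (n_coh > 0) for (e in seq_len(n_coh)) {
    sizes <- tabulate(g, n_modules)
    src <- which(sizes >= 4L)
    if (!length(src)) break
    s <- src[sample.int(length(src), 1L)]
    grp_n <- min(sample(3:5, 1L), sizes[s] - 1L)
    movers <- sample(which(g == s), grp_n)
    t_mod <- sample(setdiff(seq_len(n_modules), s), 1L)
    g[movers] <- t_mod
  }
  if (n_dis > 0) for (e in seq_len(n_dis)) {
    sizes <- tabulate(g, n_modules)
    src <- which(sizes >= 2L)
    if (!length(src)) break
    s <- src[sample.int(length(src), 1L)]
    mover <- sample(which(g == s), 1L)
    g[mover] <- sample(setdiff(seq_len(n_modules), s), 1L)
  }
  g
}

#' Generate one subject's modular region-by-time panel
#'
#' Within each planted block of `block_volumes` volumes, regions of the same
#' planted module share a common standard-normal latent signal; region noise
#' with standard deviation `noise_sd * sqrt(1/rho - 1)` is added so that the
#' within-module correlation equals the subject's planted coupling `rho` at
#' the default `noise_sd = 1`. Module memberships change between blocks by
#' cohesive (grouped) and disjoint (lone) switch events at the profile's
#' rates. Rows are z-scored.
#'
#' @param config a [cohort_config()].
#' @param subject subject index.
#' @param scan resting-scan index (1 or 2; independent noise streams).
#' @return list with `panel` (a [timeseries_panel()]) and `truth` (profile,
#'   planted coupling, per-layer planted partitions for the default window
#'   spec, per-block partitions, block length).
#' @export
generate_modular_timeseries <- function(config, subject, scan = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  check_number(subject, "subject", lower = 1, upper = config$n_subjects,
               integer = TRUE)
  if (config$n_volumes < config$block_volumes) stop_("series too short")
  prof <- subject_profiles(config)[subject]
  rho <- .subject_coupling(config, subject, scan)
  N <- config$n_regions; Tn <- config$n_volumes
  M <- config$n_modules_planted
  bl <- config$block_volumes
  n_blocks <- ceiling(Tn / bl)
  with_seed(derive_seed(config$seed, "timeseries", subject, scan), {
    parts <- matrix(0L, n_blocks, N)
    parts[1L, ] <- .base_partition(N, M)
    if (n_blocks > 1L) for (b in 2:n_blocks) {
      parts[b, ] <- .evolve_partition(
        parts[b - 1L, ], M,
        config$cohesion_rate_by_profile[[prof]],
        config$disjoint_rate_by_profile[[prof]])
    }
    x <- matrix(0, N, Tn)
    sigma <- config$noise_sd * sqrt(1 / rho - 1)
    for (b in seq_len(n_blocks)) {
      cols <- ((b - 1L) * bl + 1L):min(b * bl, Tn)
      lat <- matrix(stats::rnorm(M * length(cols)), M)
      x[, cols] <- lat[parts[b, ], , drop = FALSE] +
        sigma * matrix(stats::rnorm(N * length(cols)), N)
    }
    panel <- timeseries_panel(x, config$tr,
                              subject = sprintf("sub-%02d", subject))
    spec <- window_spec(bl, bl %/% 2L)
    sl <- window_slices(Tn, spec)
    layer_parts <- parts[(sl$start - 1L) %/% bl + 1L, , drop = FALSE]
    list(panel = panel,
         truth = list(profile = prof, coupling = rho,
                      block_partitions = parts,
                      layer_partitions = layer_parts,
                      block_volumes = bl, scan = scan))
  })
}

#' Generate one subject's trial table
#'
#' Two days of 40 learning bins (8 trials each). Trial error follows
#' `a exp(-t / tau_day) + b` plus truncated Gaussian noise, with the day
#' time constants taken from the subject's profile and modulated by the
#' planted coupling: `tau = tau_profile * exp(-effect_slope * (rho -
#' rho_profile))`, so that within every profile stronger planted coupling
#' gives faster learning.
#'
#' @param config a [cohort_config()].
#' @param subject subject index.
#' @return data.frame with columns `day`, `trial`, `bin`, `target_deg`,
#'   `error_deg`, and attributes `tau` (per day) and `profile`.
#' @export
generate_behavioral_trials <- function(config, subject) {
  stopifnot(inherits(config, "cohort_config"))
  check_number(subject, "subject", lower = 1, upper = config$n_subjects,
               integer = TRUE)
  prof <- subject_profiles(config)[subject]
  rho <- .subject_coupling(config, subject)
  rho0 <- config$coupling_strength_by_profile[[prof]]
  tau <- config$tau_by_profile[[prof]] *
    exp(-config$effect_slope * (rho - rho0))
  if (any(tau <= 0)) stop_("nonpositive tau")
  targets <- seq(0, 315, by = 45)
  with_seed(derive_seed(config$seed, "behavior", subject), {
    rows <- lapply(1:2, function(day) {
      t_idx <- seq_len(40L * 8L)
      err <- config$amplitude_deg * exp(-t_idx / tau[day]) +
        config$baseline_deg +
        stats::rnorm(length(t_idx), 0, config$behav_noise_sd)
      err <- pmin(pmax(err, -180), 180)
      data.frame(day = day, trial = t_idx,
                 bin = (t_idx - 1L) %/% 8L + 1L,
                 target_deg = as.vector(
                   replicate(40L, sample(targets))),
                 error_deg = err)
    })
    out <- do.call(rbind, rows)
    attr(out, "tau") <- tau
    attr(out, "profile") <- prof
    out
  })
}

#' Learning measures of one subject directly from a trial table
#' @param trials a trial table from [generate_behavioral_trials()] or
#'   [read_trial_table()].
#' @return named vector as in [learning_measures()].
#' @export
trial_learning_measures <- function(trials) {
  b1 <- binned_median_error(trials[trials$day == 1, ])
  b2 <- binned_median_error(trials[trials$day == 2, ])
  learning_measures(b1, b2)
}

# --- serialization ---------------------------------------------------------

.write_matrix_tsv <- function(x, path, tr = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tr)) writeLines(sprintf("# tr=%.17g", tr), con)
  writeLines(apply(x, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
}

#' Read a region-by-time panel from delimited text
#'
#' Expects a first header line `# tr=<seconds>` followed by N rows of T
#' tab-separated values.
#'
#' @param path file path.
#' @param subject optional subject id.
#' @return a [timeseries_panel()].
#' @export
read_timeseries_panel <- function(path, subject = NA_character_) {
  lines <- readLines(path)
  if (!grepl("^# tr=", lines[1L])) stop_("missing '# tr=' header in ", path)
  tr <- as.numeric(sub("^# tr=", "", lines[1L]))
  x <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  timeseries_panel(x, tr, subject = subject)
}

#' Read a trial table from delimited text
#' @param path file path (TSV with header day/trial/bin/target_deg/error_deg).
#' @return data.frame.
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Generate and optionally serialize a full synthetic cohort
#'
#' Produces, for every subject, two resting-scan panels, one trial table and
#' a ground-truth record, plus a cohort manifest. With `dir = NULL`
#' everything is returned in memory; otherwise one directory per subject is
#' written (timeseries as `# tr=` headed TSV, trials as TSV, truth and
#' manifest as JSON, and a region sidecar table mapping regions to planted
#' task-network labels).
#'
#' @param config a [cohort_config()].
#' @param dir output directory or `NULL`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return object of class `synthetic_cohort`: per-subject list with
#'   `rest1`, `rest2`, `trials`, `truth`; plus `config` and
#'   `region_networks` (planted task-network label per region).
#' @export
generate_cohort <- function(config, dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
      stop_("output directory exists; use overwrite = TRUE")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  nets <- .base_partition(config$n_regions, config$n_modules_planted)
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    r1 <- generate_modular_timeseries(config, s, scan = 1L)
    r2 <- generate_modular_timeseries(config, s, scan = 2L)
    trials <- generate_behavioral_trials(config, s)
    truth <- list(profile = r1$truth$profile, coupling = r1$truth$coupling,
                  coupling_rest2 = r2$truth$coupling,
                  tau = as.numeric(attr(trials, "tau")),
                  layer_partitions = r1$truth$layer_partitions)
    subjects[[s]] <- list(rest1 = r1$panel, rest2 = r2$panel,
                          trials = trials, truth = truth,
                          truth_full = list(rest1 = r1$truth,
                                            rest2 = r2$truth))
    if (!is.null(dir)) {
      sd <- file.path(dir, sprintf("sub-%02d", s))
      dir.create(sd, showWarnings = FALSE)
      .write_matrix_tsv(r1$panel$x, file.path(sd, "rest1.tsv"), config$tr)
      .write_matrix_tsv(r2$panel$x, file.path(sd, "rest2.tsv"), config$tr)
      utils::write.table(trials, file.path(sd, "trials.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      jsonlite::write_json(truth, file.path(sd, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(dir)) {
    regions <- data.frame(region = paste0("r", seq_len(config$n_regions)),
                          name = sprintf("region_%03d",
                                         seq_len(config$n_regions)),
                          task_network = nets)
    utils::write.table(regions, file.path(dir, "regions.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest <- list(n_subjects = config$n_subjects,
                     subjects = sprintf("sub-%02d",
                                        seq_len(config$n_subjects)),
                     profiles = subject_profiles(config),
                     n_regions = config$n_regions,
                     n_volumes = config$n_volumes, tr = config$tr,
                     seed = config$seed)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(subjects = subjects, config = config,
                 region_networks = nets,
                 profiles = subject_profiles(config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d regions, %d planted networks\n",
              length(x$subjects), x$config$n_regions,
              x$config$n_modules_planted))
  invisible(x)
}
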