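# Evaluate expr with a private RNG state seeded at `seed`, restoring the
# caller's state afterwards (keeps cohort generation bit-reproducible
# without clobbering the session RNG).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Design of a synthetic resting-state cohort
#'
#' Describes a two-group cohort (patients scanned in ON and OFF
#' medication sessions, controls once) of multivariate ROI time series
#' with block-structured correlation: a uniform baseline coupling among
#' all node pairs and an elevated coupling within a designated pain
#' network, which may differ by group. Motion traces are smooth
#' low-amplitude drift with occasional spikes, and the clinical pain
#' score (number of words chosen, NWC) is linearly linked to the true
#' pain-network global efficiency, giving a planted association the
#' pipeline should recover.
#'
#' @param n_patients,n_controls Group sizes (defaults 24 and 27,
#'   mirroring the study design this generator emulates).
#' @param n_nodes Number of atlas nodes (default 264).
#' @param n_frames Frames per scan (default 199: a 202-volume scan after
#'   discarding the first three equilibration volumes; generated series
#'   represent the post-discard scan).
#' @param baseline_r Correlation among all node pairs outside the pain
#'   block, in `[0, 1)`.
#' @param pain_r Named numeric vector `c(patient = , control = )`:
#'   correlation among pain-network node pairs, per group, in `[0, 1)`.
#' @param pain_nodes 1-based indices of the pain-network nodes; defaults
#'   to the packaged 16-node pain set when `n_nodes` is 264.
#' @param noise_sd SD of independent observation noise added to the
#'   latent correlated signal (signal units; latent signal has unit SD).
#' @param motion_spike_prob Per-frame probability of a motion spike.
#' @param motion_spike_mm Spike magnitude in mm (added transiently to
#'   one translation axis).
#' @param beta_pain NWC units per unit of true pain-network global
#'   efficiency (the planted association; 0 plants none).
#' @param pain_noise_sd SD of the NWC noise term.
#' @param cas_params Per-group mean/SD for the two colored-analogue-scale
#'   scores (generated independently of topology, clipped to `[0, 100]`).
#' @param chronic_pain_prob Named per-group probability of chronic pain.
#' @param seed Integer seed; everything the design generates is a
#'   deterministic function of it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 24L, n_controls = 27L,
                          n_nodes = 264L, n_frames = 199L,
                          baseline_r = 0.1,
                          pain_r = c(patient = 0.4, control = 0.3),
                          pain_nodes = NULL,
                          noise_sd = 0.3,
                          motion_spike_prob = 0.02, motion_spike_mm = 2,
                          beta_pain = 30, pain_noise_sd = 6,
                          cas_params = list(
                            patient = c(mean = 16, sd = 20),
                            control = c(mean = 4, sd = 9)),
                          chronic_pain_prob = c(patient = 0.75,
                                                control = 11 / 27),
                          seed = 1L) {
  if (n_patients < 2L || n_controls < 2L)
    stop("need at least 2 subjects per group (downstream statistics ",
         "are undefined otherwise)")
  if (baseline_r < 0 || baseline_r >= 1)
    stop("baseline_r must lie in [0, 1)")
  if (is.null(names(pain_r)) || !all(c("patient", "control") %in% names(pain_r)))
    stop("pain_r must be named with entries for 'patient' and 'control'")
  if (any(pain_r < 0) || any(pain_r >= 1))
    stop("pain_r entries must lie in [0, 1)")
  if (is.null(pain_nodes)) {
    if (n_nodes == 264L) pain_nodes <- load_nodeset("pain")$indices
    else stop("pain_nodes must be given explicitly when n_nodes != 264")
  }
  pain_nodes <- as.integer(pain_nodes)
  if (any(pain_nodes < 1L) || any(pain_nodes > n_nodes) ||
      anyDuplicated(pain_nodes))
    stop("pain_nodes must be unique indices in [1, n_nodes]")
  if (length(pain_nodes) < 2L)
    stop("the pain block needs at least 2 nodes")
  if (motion_spike_prob < 0 || motion_spike_prob > 1)
    stop("motion_spike_prob must be a probability")
  design <- structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         n_nodes = as.integer(n_nodes), n_frames = as.integer(n_frames),
         baseline_r = baseline_r, pain_r = pain_r,
         pain_nodes = pain_nodes, noise_sd = noise_sd,
         motion_spike_prob = motion_spike_prob,
         motion_spike_mm = motion_spike_mm,
         beta_pain = beta_pain, pain_noise_sd = pain_noise_sd,
         cas_params = cas_params, chronic_pain_prob = chronic_pain_prob,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
  # fail early if the implied covariance is invalid
  for (g in c("patient", "control")) .target_correlation(design, g)
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_design> %d patients (ON+OFF) + %d controls; %d nodes ",
    "(%d pain), %d frames\n  baseline r = %g; pain r: patient %g, ",
    "control %g; noise sd = %g\n  planted NWC link: beta = %g, ",
    "noise sd = %g; seed = %d\n"),
    x$n_patients, x$n_controls, x$n_nodes, length(x$pain_nodes),
    x$n_frames, x$baseline_r, x$pain_r[["patient"]], x$pain_r[["control"]],
    x$noise_sd, x$beta_pain, x$pain_noise_sd, x$seed))
  invisible(x)
}

# Target correlation matrix for one group; rejects non-PSD combinations.
.target_correlation <- function(design, group) {
  n <- design$n_nodes
  C <- matrix(design$baseline_r, n, n)
  p <- design$pain_nodes
  C[p, p] <- design$pain_r[[group]]
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf(
      paste0("target covariance for group '%s' is not positive ",
             "semi-definite (min eigenvalue %.3g) with baseline_r = %g, ",
             "pain_r = %g"),
      group, min(ev), design$baseline_r, design$pain_r[[group]]))
  C
}

# True pain-network GE of one scan: sample correlation of the noise-free
# latent pain-block series, Fisher-transformed, complete-graph GE. Varies
# across scans through finite-sample variation of the latent correlations,
# which is what makes the planted NWC link recoverable from estimated GE.
.ge_pain_true <- function(latent, pain_nodes) {
  r <- stats::cor(latent[, pain_nodes, drop = FALSE])
  r <- (r + t(r)) / 2
  global_efficiency(fisher_transform(r))
}

#' Simulate one subject-session scan
#'
#' Draws a latent zero-mean multivariate normal series with the design's
#' block correlation for the given group, adds independent observation
#' noise, simulates a motion trace (AR(1) drift, coefficient 0.95,
#' innovation SD 0.02 mm or rad, plus transient translation spikes), and
#' generates pain scores. The NWC score is
#' `round(max(0, beta_pain * GE_true + noise))` where `GE_true` is the
#' pain-network global efficiency of the noise-free latent series.
#'
#' @param design A [cohort_design()].
#' @param group `"patient"` or `"control"`.
#' @param seed Integer seed for this subject-session.
#' @param subject_id,session Identifiers stored on the record.
#' @return A `subject_record`: list with `subject_id`, `group`,
#'   `session`, `time_series` ([roi_timeseries()]), `motion`
#'   ([motion_trace()]), `cas_intensity`, `cas_affect`, `nwc`,
#'   `chronic_pain`, and `ge_pain_true`.
#' @export
simulate_subject <- function(design, group = c("patient", "control"),
                             seed = design$seed,
                             subject_id = "sub-001",
                             session = if (group == "control") "single"
                                       else "OFF") {
  stopifnot(inherits(design, "cohort_design"))
  group <- match.arg(group)
  C <- .target_correlation(design, group)
  .with_seed(seed, {
    latent <- MASS::mvrnorm(design$n_frames, mu = rep(0, design$n_nodes),
                            Sigma = C)
    obs <- latent
    if (design$noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(length(obs), sd = design$noise_sd),
                          nrow(obs), ncol(obs))
    ts <- roi_timeseries(obs)

    # motion: per-parameter AR(1) drift; spikes on a random translation axis.
    # Innovation sd 0.02 mm (translations) / 0.02 deg (rotations, stored rad).
    drift <- matrix(0, design$n_frames, 6L)
    innov_sd <- c(rep(0.02, 3L), rep(0.02 * pi / 180, 3L))
    for (j in 1:6) {
      e <- stats::rnorm(design$n_frames, sd = innov_sd[j])
      drift[, j] <- as.numeric(stats::filter(e, 0.95, method = "recursive"))
    }
    spikes <- which(stats::runif(design$n_frames) < design$motion_spike_prob)
    for (f in spikes) {
      axis <- sample.int(3L, 1L)
      drift[f, axis] <- drift[f, axis] +
        design$motion_spike_mm * sample(c(-1, 1), 1L)
    }
    motion <- motion_trace(drift)

    ge_true <- .ge_pain_true(latent, design$pain_nodes)
    cas <- design$cas_params[[group]]
    cas_i <- min(100, max(0, stats::rnorm(1, cas[["mean"]], cas[["sd"]])))
    cas_a <- min(100, max(0, stats::rnorm(1, cas[["mean"]], cas[["sd"]])))
    nwc <- round(max(0, design$beta_pain * ge_true +
                        stats::rnorm(1, sd = design$pain_noise_sd)))
    chronic <- stats::runif(1) < design$chronic_pain_prob[[group]]

    structure(
      list(subject_id = subject_id, group = group, session = session,
           time_series = ts, motion = motion,
           cas_intensity = cas_i, cas_affect = cas_a, nwc = as.integer(nwc),
           chronic_pain = chronic, ge_pain_true = ge_true),
      class = "subject_record"
    )
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "<subject_record> %s (%s, %s): %d frames x %d nodes; NWC = %d\n",
    x$subject_id, x$group, x$session, nrow(x$time_series$values),
    ncol(x$time_series$values), x$nwc))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Patients are scanned twice (ON and OFF medication sessions, drawn
#' independently); controls once. Chronic-pain status is drawn per
#' subject and shared across a patient's sessions. Per-session seeds are
#' derived deterministically from the design seed.
#'
#' @param design A [cohort_design()].
#' @return An object of class `cohort`: list with `subjects` (list of
#'   `subject_record`s, one per subject-session) and `table` (one row
#'   per subject-session: `subject_id`, `group`, `session`,
#'   `cas_intensity`, `cas_affect`, `nwc`, `chronic_pain`, plus the
#'   generator-truth column `ge_pain_true`).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  plan <- rbind(
    data.frame(subject_id = sprintf("pd-%03d", seq_len(design$n_patients)),
               group = "patient",
               session = rep(c("ON", "OFF"), each = design$n_patients),
               stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("hc-%03d", seq_len(design$n_controls)),
               group = "control", session = "single",
               stringsAsFactors = FALSE)
  )
  plan <- plan[order(plan$subject_id, plan$session), ]
  subjects <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    seed_i <- (design$seed + 7919L * i) %% .Machine$integer.max
    subjects[[i]] <- simulate_subject(design, plan$group[i], seed = seed_i,
                                      subject_id = plan$subject_id[i],
                                      session = plan$session[i])
  }
  # chronic pain is a subject-level trait: copy the first session's draw
  ids <- vapply(subjects, `[[`, "", "subject_id")
  for (id in unique(ids)) {
    k <- which(ids == id)
    if (length(k) > 1L)
      for (j in k[-1L]) subjects[[j]]$chronic_pain <- subjects[[k[1L]]]$chronic_pain
  }
  tab <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               session = s$session, cas_intensity = s$cas_intensity,
               cas_affect = s$cas_affect, nwc = s$nwc,
               chronic_pain = s$chronic_pain,
               ge_pain_true = s$ge_pain_true, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(design = design, subjects = subjects, table = tab),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subject-sessions (%d patients x 2 + %d controls)\n",
    length(x$subjects), x$design$n_patients, x$design$n_controls))
  invisible(x)
}

#' Write a simulated cohort to TSV files
#'
#' Writes `<id>_<session>_timeseries.tsv` (frames x nodes, header = node
#' labels), `<id>_<session>_motion.tsv` (frames x 6, translations in mm,
#' rotations in radians) and `cohort.tsv` (columns `subject_id`,
#' `group`, `session`, `cas_intensity`, `cas_affect`, `nwc`,
#' `chronic_pain`).
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    stem <- sprintf("%s_%s", s$subject_id, s$session)
    utils::write.table(
      s$time_series$values, file.path(dir, paste0(stem, "_timeseries.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      s$motion$values, file.path(dir, paste0(stem, "_motion.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cols <- c("subject_id", "group", "session", "cas_intensity",
            "cas_affect", "nwc", "chronic_pain")
  utils::write.table(cohort$table[, cols], file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a ROI time-series TSV
#'
#' @param path Tab-separated file, header row of node labels, one frame
#'   per line.
#' @param tr_seconds Sampling interval recorded on the result.
#' @return A [roi_timeseries()].
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2.15) {
  v <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  roi_timeseries(as.matrix(v), node_labels = colnames(v),
                 tr_seconds = tr_seconds)
}

#' Read a motion-parameter TSV
#'
#' @param path Tab-separated file with the six motion columns
#'   (translations mm, rotations rad), one frame per line.
#' @return A [motion_trace()].
#' @export
read_motion_tsv <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t")
  motion_trace(as.matrix(v))
}
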