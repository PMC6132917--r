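#' Pipeline run configuration
#'
#' Collects every analysis-relevant switch of the end-to-end pipeline,
#' each defaulting to the choice the analysis is built around
#' (documented on the function implementing it).
#'
#' @param design A [cohort_design()] describing the synthetic cohort to
#'   simulate, or `NULL` to read a previously written cohort from
#'   `input_dir`.
#' @param input_dir Directory holding `cohort.tsv` plus per-scan
#'   time-series/motion TSVs (as written by [write_cohort()]); ignored
#'   when `design` is given.
#' @param nodesets Character vector of node-set names or definition
#'   files for subnetwork summaries. When `design` is given, defaults to
#'   the design's pain block (named `"pain"`); for 264-node data the
#'   packaged `c("pain", "dmn")` sets.
#' @param drop_volumes Initial volumes to discard per scan. Default 0
#'   for simulated cohorts (the generator emits post-equilibration
#'   series); use 3 for raw 202-volume scans.
#' @param fd_threshold_mm Scrub threshold, mm (default 1.5, strict `>`).
#' @param head_radius_mm Rotation-to-mm radius (default 50).
#' @param drop_preceding Scrub the frame before a flagged transition
#'   too (default `FALSE`).
#' @param negative_policy Negative-weight policy for graph metrics
#'   (default `"zero"`).
#' @param subnetwork_ge Subnetwork GE mode (default `"induced"`).
#' @param sd_type BC z-score convention (default `"population"`).
#' @param p_enter Stepwise entry threshold (default 0.05).
#' @param seed Seed for the run (overrides the design seed if given).
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = NULL, input_dir = NULL, nodesets = NULL,
                       drop_volumes = if (is.null(design)) 3L else 0L,
                       fd_threshold_mm = 1.5, head_radius_mm = 50,
                       drop_preceding = FALSE,
                       negative_policy = "zero",
                       subnetwork_ge = "induced",
                       sd_type = "population",
                       p_enter = 0.05, seed = NULL) {
  if (is.null(design) && is.null(input_dir))
    stop("either a cohort design or an input directory is required")
  if (!is.null(design)) {
    stopifnot(inherits(design, "cohort_design"))
    if (!is.null(seed)) design$seed <- as.integer(seed)
  }
  structure(
    list(design = design, input_dir = input_dir, nodesets = nodesets,
         drop_volumes = as.integer(drop_volumes),
         fd_threshold_mm = fd_threshold_mm,
         head_radius_mm = head_radius_mm, drop_preceding = drop_preceding,
         negative_policy = negative_policy, subnetwork_ge = subnetwork_ge,
         sd_type = sd_type, p_enter = p_enter),
    class = "run_config"
  )
}

# node sets used for a run: explicit names/files, or derived from the design
.resolve_nodesets <- function(config) {
  if (!is.null(config$nodesets))
    return(lapply(config$nodesets, load_nodeset))
  if (!is.null(config$design)) {
    d <- config$design
    if (d$n_nodes == 264L &&
        identical(d$pain_nodes, load_nodeset("pain")$indices))
      return(list(load_nodeset("pain"), load_nodeset("dmn")))
    return(list(node_set("pain", d$pain_nodes, d$n_nodes)))
  }
  list(load_nodeset("pain"), load_nodeset("dmn"))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, builds each scan's scrubbed Fisher-z
#' adjacency matrix, summarizes network topology (whole-brain GE;
#' GE and mean z-scored BC per subnetwork), and runs the statistical
#' layer: Mann-Whitney group comparisons of the pain scores, the
#' chronic-pain chi-square, covariate-adjusted group comparisons of the
#' topology measures (patients vs controls, per session), and per-group
#' forward-stepwise regressions of NWC on pain-network BC and GE with
#' average motion forced into the model.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes
#'   `topology_summary.tsv`, `pain_group_tests.tsv`,
#'   `topology_group_tests.tsv`, `stepwise_<group>.txt` and
#'   `manifest.json`.
#' @return An object of class `painnet_run`: list with `summary` (per
#'   subject-session topology table joined to the cohort table),
#'   `pain_tests`, `chronic_pain`, `topology_tests`, `stepwise`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  nodesets <- .resolve_nodesets(config)

  if (!is.null(config$design)) {
    cohort <- simulate_cohort(config$design)
    records <- cohort$subjects
    ctab <- cohort$table
  } else {
    ctab <- utils::read.table(file.path(config$input_dir, "cohort.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    records <- lapply(seq_len(nrow(ctab)), function(i) {
      stem <- sprintf("%s_%s", ctab$subject_id[i], ctab$session[i])
      list(subject_id = ctab$subject_id[i], group = ctab$group[i],
           session = ctab$session[i],
           time_series = read_timeseries_tsv(
             file.path(config$input_dir, paste0(stem, "_timeseries.tsv"))),
           motion = read_motion_tsv(
             file.path(config$input_dir, paste0(stem, "_motion.tsv"))))
    })
  }

  summary_tab <- do.call(rbind, lapply(records, function(s) {
    conn <- build_adjacency(s$time_series, s$motion,
                            drop_volumes = config$drop_volumes,
                            fd_threshold_mm = config$fd_threshold_mm,
                            head_radius_mm = config$head_radius_mm,
                            drop_preceding = config$drop_preceding)
    summarize_topology(conn$adjacency, nodesets,
                       subject_id = s$subject_id, session = s$session,
                       mean_motion = conn$mean_motion,
                       n_frames_retained = conn$n_frames_retained,
                       subnetwork_ge = config$subnetwork_ge,
                       negative_policy = config$negative_policy,
                       sd_type = config$sd_type)
  }))
  summary_tab <- merge(summary_tab, ctab, by = c("subject_id", "session"),
                       sort = FALSE)
  summary_tab <- summary_tab[order(summary_tab$subject_id,
                                   summary_tab$session), ]
  rownames(summary_tab) <- NULL

  # group labels per session: controls vs patients ON / OFF
  grp_of <- function(session) {
    hc <- summary_tab[summary_tab$group == "control", ]
    pd <- summary_tab[summary_tab$group == "patient" &
                        summary_tab$session == session, ]
    list(hc = hc, pd = pd)
  }

  pain_tests <- NULL
  chronic <- NULL
  if (all(c("cas_intensity", "cas_affect", "nwc") %in% names(summary_tab))) {
    pain_tests <- do.call(rbind, lapply(c("OFF", "ON"), function(sess) {
      g <- grp_of(sess)
      if (!nrow(g$pd)) return(NULL)
      do.call(rbind, lapply(c("cas_intensity", "cas_affect", "nwc"),
        function(v) {
          mw <- mann_whitney(g$hc[[v]], g$pd[[v]], mode = "normal")
          data.frame(measure = v, contrast = paste0("HC_vs_PD_", sess),
                     U = mw$U, p = mw$p.value, stringsAsFactors = FALSE)
        }))
    }))
    subj <- unique(summary_tab[, c("subject_id", "group", "chronic_pain")])
    tab2 <- table(factor(subj$group, c("patient", "control")),
                  factor(subj$chronic_pain, c(TRUE, FALSE)))
    chronic <- tryCatch(chi2_2x2(tab2), error = function(e) NULL)
  }

  measures <- intersect(
    c("ge_whole_brain",
      unlist(lapply(nodesets, function(ns)
        c(paste0("ge_", ns$name), paste0("bc_", ns$name))))),
    names(summary_tab))
  topology_tests <- do.call(rbind, lapply(c("OFF", "ON"), function(sess) {
    g <- grp_of(sess)
    if (!nrow(g$pd)) return(NULL)
    both <- rbind(g$hc, g$pd)
    res <- ancova_group(both[, measures, drop = FALSE],
                        factor(both$group, c("control", "patient")),
                        both$mean_motion)
    out <- res$per_dv
    out$contrast <- paste0("HC_vs_PD_", sess)
    out$wilks_lambda <- res$wilks$lambda
    out$wilks_p <- res$wilks$p
    out
  }))

  stepwise <- NULL
  pain_name <- nodesets[[1L]]$name
  bc_col <- paste0("bc_", pain_name); ge_col <- paste0("ge_", pain_name)
  if (!is.null(summary_tab$nwc) &&
      all(c(bc_col, ge_col) %in% names(summary_tab))) {
    groups <- list(HC = summary_tab$group == "control",
                   PD_ON = summary_tab$group == "patient" &
                     summary_tab$session == "ON",
                   PD_OFF = summary_tab$group == "patient" &
                     summary_tab$session == "OFF")
    stepwise <- lapply(groups, function(idx) {
      d <- summary_tab[idx, ]
      if (nrow(d) < 8L) return(NULL)
      forward_stepwise(
        d$nwc,
        candidates = stats::setNames(
          data.frame(d[[bc_col]], d[[ge_col]]), c(bc_col, ge_col)),
        forced = data.frame(mean_motion = d$mean_motion),
        p_enter = config$p_enter)
    })
  }

  manifest <- list(
    package = "painnet",
    version = as.character(utils::packageVersion("painnet")),
    seed = if (!is.null(config$design)) config$design$seed else NA,
    n_scans = nrow(summary_tab),
    n_statistical_tests = sum(!is.null(pain_tests) * NROW(pain_tests),
                              NROW(topology_tests), !is.null(chronic)),
    decisions = list(
      fd_threshold_mm = config$fd_threshold_mm,
      fd_comparison = "strict >",
      scrubbed_frame = if (config$drop_preceding) "latter + preceding"
                       else "latter",
      drop_volumes = config$drop_volumes,
      head_radius_mm = config$head_radius_mm,
      negative_weight_policy = config$negative_policy,
      subnetwork_ge = config$subnetwork_ge,
      bc_zscore_sd = config$sd_type,
      stepwise_p_enter = config$p_enter,
      alpha = 0.05, sided = "two-sided",
      multiple_testing_correction = "none"
    )
  )

  run <- structure(
    list(summary = summary_tab, pain_tests = pain_tests,
         chronic_pain = chronic, topology_tests = topology_tests,
         stepwise = stepwise, manifest = manifest, config = config),
    class = "painnet_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(summary_tab, "topology_summary.tsv")
    if (!is.null(pain_tests)) wt(pain_tests, "pain_group_tests.tsv")
    if (!is.null(topology_tests)) wt(topology_tests,
                                     "topology_group_tests.tsv")
    if (!is.null(stepwise))
      for (g in names(stepwise))
        if (!is.null(stepwise[[g]])) {
          con <- file(file.path(out_dir, sprintf("stepwise_%s.txt", g)), "w")
          sink(con); print(stepwise[[g]]); sink(); close(con)
        }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

#' @export
print.painnet_run <- function(x, ...) {
  cat(sprintf("<painnet_run> %d subject-sessions\n", nrow(x$summary)))
  if (!is.null(x$chronic_pain)) {
    cat("Chronic pain (patients vs controls): ")
    print(x$chronic_pain)
  }
  if (!is.null(x$topology_tests)) {
    cat("Topology group comparisons (covariate-adjusted):\n")
    tt <- x$topology_tests
    for (i in seq_len(nrow(tt)))
      cat(sprintf("  %-14s %-13s F(%d, %d) = %6.3f, p = %.4g\n",
                  tt$dv[i], tt$contrast[i], tt$df1[i], tt$df2[i],
                  tt$F[i], tt$p[i]))
  }
  if (!is.null(x$stepwise)) {
    cat("Stepwise NWC regressions (selected predictors):\n")
    for (g in names(x$stepwise)) {
      sel <- if (is.null(x$stepwise[[g]])) "(group too small)"
             else if (length(x$stepwise[[g]]$selected))
               paste(x$stepwise[[g]]$selected, collapse = ", ")
             else "none"
      cat(sprintf("  %-7s %s\n", g, sel))
    }
  }
  invisible(x)
}
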