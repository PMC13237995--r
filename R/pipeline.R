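#' Pipeline configuration
#'
#' Validated configuration for an end-to-end synthetic-cohort planning run.
#' Unknown fields are rejected.
#'
#' @param n_subjects cohort size.
#' @param base a [subject_spec()] shared by all subjects.
#' @param varus_range_deg injected kinematic varus range (deg).
#' @param seed global seed; per-subject/stage seeds are split from it.
#' @param out_dir output directory.
#' @param strategies gap-balance strategies to run (besides MB).
#' @param constraints a [tibial_constraints()].
#' @param sa an [sa_config()] (seed field is overridden by the split rule).
#' @param gb a [gb_config()] template (strategy/seed overridden per run).
#' @param ligaments compute ligament sweeps and the tension protocol?
#' @param write_plots write simple PNG gap/ligament curve plots?
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8,
                            base = subject_spec(),
                            varus_range_deg = c(0.7, 7.0),
                            seed = 1L,
                            out_dir = tempfile("kneeplan_run_"),
                            strategies = c("GB_full", "GB_standing",
                                           "GB_standing_90"),
                            constraints = tibial_constraints(),
                            sa = sa_config(),
                            gb = gb_config(),
                            ligaments = TRUE,
                            write_plots = FALSE) {
  stopifnot(n_subjects >= 1, inherits(base, "subject_spec"),
            inherits(constraints, "tibial_constraints"),
            inherits(sa, "sa_config"), inherits(gb, "gb_config"))
  strategies <- match.arg(strategies,
                          c("GB_full", "GB_standing", "GB_standing_90"),
                          several.ok = TRUE)
  structure(list(n_subjects = as.integer(n_subjects), base = base,
                 varus_range_deg = varus_range_deg, seed = as.integer(seed),
                 out_dir = out_dir, strategies = strategies,
                 constraints = constraints, sa = sa, gb = gb,
                 ligaments = isTRUE(ligaments),
                 write_plots = isTRUE(write_plots)),
            class = "pipeline_config")
}

#' Deterministic seed splitting for subjects and stages
#'
#' Small multiplicative string hash of (subject_id, stage) folded into the
#' global seed; always below 2^31 so every derived seed is a valid R
#' integer. Subjects are therefore independently reproducible.
#'
#' @param seed global integer seed.
#' @param subject_id,stage labels.
#' @return an integer seed.
#' @export
split_seed <- function(seed, subject_id, stage) {
  h <- 0
  for (ch in utf8ToInt(paste0(subject_id, "/", stage)))
    h <- (h * 131 + ch) %% 2147483629
  as.integer((h + as.numeric(seed) * 7919) %% 2147483629 + 1)
}

plan_subject <- function(knee, config) {
  kin <- correct_varus_valgus(knee$kinematics, knee$alignment)
  sid <- knee$spec$subject_id

  sa <- config$sa
  sa$seed <- split_seed(config$seed, sid, "tibial_sa")
  tplan <- optimize_tibial_placement(knee$tibia_mesh, knee$tray_catalog,
                                     knee$landmarks, knee$alignment,
                                     config$constraints, sa)
  if (!tplan$feasible) stop("tibial planning found no feasible placement")

  mb <- build_mb_plan(knee$femur_mesh, knee$landmarks,
                      knee$femoral_component_mesh,
                      knee$spec$distal_thickness_mm,
                      knee$spec$posterior_thickness_mm)
  mb_profile <- gap_profile(knee$femoral_component_mesh, mb$component_pose,
                            kin, tplan$resection_plane, "MB")
  gb_plans <- list()
  profiles <- list(MB = mb_profile)
  for (st in config$strategies) {
    gb <- config$gb
    gb$strategy <- st
    gb$seed <- split_seed(config$seed, sid, paste0("gb_", st))
    plan <- optimize_gb(mb, kin, tplan$resection_plane,
                        knee$femoral_component_mesh, gb)
    gb_plans[[st]] <- plan
    profiles[[st]] <- plan$gap_profile
  }

  ligament <- NULL
  if (config$ligaments) {
    bundles <- default_ligament_bundles(knee$landmarks)
    native <- lapply(bundles, sweep_lengths, knee = knee, kinematics = kin,
                     implanted = FALSE)
    pose_gb <- if ("GB_full" %in% names(gb_plans))
      gb_plans$GB_full$optimized_pose else mb$component_pose
    implanted <- lapply(bundles, sweep_lengths, knee = knee,
                        kinematics = kin, implanted = TRUE,
                        component_pose = pose_gb)
    ligament <- list(native = native, implanted = implanted,
                     protocol = build_tension_protocol(implanted))
  }
  list(subject_id = sid, kinematics = kin, tibial = tplan, mb = mb,
       gb = gb_plans, profiles = profiles, ligament = ligament)
}

write_subject_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tp <- res$tibial
  plan_json <- list(
    subject_id = res$subject_id,
    tibial = list(in_plane_pose = as.list(tp$in_plane_pose),
                  size = tp$chosen_size_id, pci_percent = tp$pci_percent,
                  overhang_mm = tp$overhang_mm,
                  plane_point = tp$resection_plane$point,
                  plane_normal = tp$resection_plane$normal),
    mb_pose = unclass(res$mb$component_pose),
    gb = lapply(res$gb, function(g) list(
      delta_from_mb = unclass(g$delta_from_mb),
      loss_mm = g$loss_mm, mb_loss_mm = g$mb_loss_mm,
      recommended_insert_mm = g$recommended_insert_mm,
      insert_flagged = g$insert_flagged)))
  jsonlite::write_json(plan_json, file.path(dir, "plan.json"),
                       auto_unbox = TRUE, digits = NA)
  gaps <- gap_profiles_table(res$profiles,
                             rep(res$subject_id, length(res$profiles)))
  utils::write.csv(gaps, file.path(dir, "gap_profiles.csv"),
                   row.names = FALSE)
  if (!is.null(res$ligament)) {
    lig <- do.call(rbind, lapply(c("native", "implanted"), function(mode)
      do.call(rbind, lapply(res$ligament[[mode]], function(sw)
        cbind(mode = mode, bundle = attr(sw, "bundle"),
              as.data.frame(sw))))))
    utils::write.csv(lig, file.path(dir, "ligament_sweeps.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ligament$protocol,
                     file.path(dir, "tension_protocol.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Run the full planning pipeline on a synthetic cohort
#'
#' Generates the cohort, runs tibial placement, MB and the configured GB
#' strategies per subject, computes gap-difference curves, strategy
#' comparison tables (paired Wilcoxon + Holm), optional ligament sweeps and
#' tension protocols, and writes per-subject plan JSONs, CSV tables and a
#' run manifest under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `subjects`, `profiles` (long table),
#'   `comparisons`, `summary`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cohort <- stage("cohort",
                  generate_cohort(config$n_subjects, config$base,
                                  config$varus_range_deg,
                                  split_seed(config$seed, "cohort", "draw")))
  subjects <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sid <- cohort[[i]]$spec$subject_id
    subjects[[i]] <- stage(paste0("subject_", sid),
                           plan_subject(cohort[[i]], config))
    write_subject_outputs(subjects[[i]],
                          file.path(config$out_dir, sid))
  }
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")

  long <- do.call(rbind, lapply(subjects, function(s)
    gap_profiles_table(s$profiles, rep(s$subject_id, length(s$profiles)))))
  utils::write.csv(long, file.path(config$out_dir, "gap_profiles.csv"),
                   row.names = FALSE)

  comparisons <- list()
  for (st in config$strategies) {
    cmp <- stage(paste0("compare_MB_vs_", st),
                 compare_strategies(long, "MB", st))
    comparisons[[paste0("MB_vs_", st)]] <- cmp
    utils::write.csv(cmp, file.path(config$out_dir,
                                    sprintf("comparison_MB_vs_%s.csv", st)),
                     row.names = FALSE)
  }

  summary <- stage("summary", summarize_cohort(subjects))
  utils::write.csv(summary, file.path(config$out_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "kneeplan",
    version = as.character(utils::packageVersion("kneeplan")),
    r_version = R.version.string,
    seed = config$seed,
    n_subjects = config$n_subjects,
    varus_range_deg = config$varus_range_deg,
    subject_seeds = lapply(names(subjects), function(sid) list(
      tibial_sa = split_seed(config$seed, sid, "tibial_sa"),
      gb = lapply(stats::setNames(config$strategies, config$strategies),
                  function(st) split_seed(config$seed, sid,
                                          paste0("gb_", st))))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  if (config$write_plots) write_pipeline_plots(subjects, long, config$out_dir)

  invisible(list(subjects = subjects, profiles = long,
                 comparisons = comparisons, summary = summary,
                 out_dir = config$out_dir))
}

write_pipeline_plots <- function(subjects, long, out_dir) {
  long$gd <- abs(abs(long$d_l_mm) - abs(long$d_m_mm))
  agg <- stats::aggregate(gd ~ flexion_deg + strategy, long, mean)
  grDevices::png(file.path(out_dir, "gap_difference_curves.png"),
                 width = 900, height = 600)
  on.exit(grDevices::dev.off())
  strategies <- unique(agg$strategy)
  cols <- seq_along(strategies)
  plot(NULL, xlim = range(agg$flexion_deg), ylim = c(0, max(agg$gd) * 1.1),
       xlab = "Flexion (deg)", ylab = "Mean |medial-lateral gap diff| (mm)")
  for (i in seq_along(strategies)) {
    a <- agg[agg$strategy == strategies[i], ]
    graphics::lines(a$flexion_deg, a$gd, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = strategies, col = cols, lwd = 2)
}

#' Cohort summary table (mean and SD of the headline quantities)
#'
#' Summarizes PCI, Insall rotation deviation, the six GB pose deltas per
#' strategy, and the mean absolute medial--lateral gap difference per
#' strategy. With a single subject, SD is reported as 0.
#'
#' @param subjects list of per-subject results from [run_pipeline()] /
#'   `plan_subject`.
#' @return data.frame: metric, strategy, mean, sd, n.
#' @export
summarize_cohort <- function(subjects) {
  stopifnot(length(subjects) >= 1)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  row <- function(metric, strategy, x)
    data.frame(metric = metric, strategy = strategy,
               mean = mean(x), sd = sd0(x), n = length(x))
  out <- list(
    row("pci_percent", "",
        vapply(subjects, function(s) s$tibial$pci_percent, 0)),
    row("insall_rotation_deg", "",
        vapply(subjects, function(s)
          abs(s$tibial$in_plane_pose[["rotation_deg"]]), 0)))
  strategies <- unique(unlist(lapply(subjects, function(s) names(s$gb))))
  dof <- c("AP_mm", "PD_mm", "ML_mm", "FE_deg", "AA_deg", "IE_deg")
  for (st in strategies) {
    have <- vapply(subjects, function(s) st %in% names(s$gb), TRUE)
    if (!any(have)) {
      message("strategy ", st, " absent from all subjects; omitted")
      next
    }
    sub <- subjects[have]
    for (d in dof)
      out[[length(out) + 1]] <- row(paste0("gb_delta_abs_", d), st,
        vapply(sub, function(s) abs(s$gb[[st]]$delta_from_mb[[d]]), 0))
    out[[length(out) + 1]] <- row("gb_loss_mm", st,
      vapply(sub, function(s) s$gb[[st]]$loss_mm, 0))
  }
  for (st in c("MB", strategies)) {
    vals <- vapply(subjects, function(s)
      if (st %in% names(s$profiles)) gap_loss(s$profiles[[st]]) else NA_real_,
      0)
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0)
      out[[length(out) + 1]] <- row("mean_gap_diff_mm", st, vals)
  }
  do.call(rbind, out)
}
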