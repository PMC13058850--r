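#' Configuration of a full simulated study
#'
#' Bundles everything [run_study()] needs: cohort size, runs per
#' participant, the environment (trajectory) design, the BOLD simulation
#' settings, optional per-group overrides of the simulation (e.g. a lower
#' modulation amplitude in an older group), the fold symmetries to analyse
#' and the QC policy. Trajectories are shared across participants within a
#' run index (each run has its own fixed path), mirroring a passive design
#' where all participants see the same movement.
#'
#' @param n_participants cohort size (ignored when `groups` is given).
#' @param n_runs runs per participant.
#' @param env an [environment_config()].
#' @param sim a [simulation_config()]; per-voxel hemisphere labels are set
#'   automatically (first half `left`, second half `right`).
#' @param groups optional named list of per-group settings, each a list with
#'   `n` and any [simulation_config()] fields to override
#'   (e.g. `list(young = list(n = 10, modulation_amplitude = 0.6),
#'   older = list(n = 10, modulation_amplitude = 0.2))`).
#' @param folds fold symmetries analysed for every participant.
#' @param apply_qc drop voxels failing the tSNR fence before analysis.
#' @param seed master seed; all per-participant and per-run seeds derive
#'   from it deterministically.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_participants = 20, n_runs = 2,
                         env = environment_config(),
                         sim = simulation_config(),
                         groups = NULL,
                         folds = c(1, 5, 6, 7),
                         apply_qc = TRUE,
                         seed = 1L) {
  if (!is.null(groups)) {
    stopifnot(!is.null(names(groups)),
              all(vapply(groups, function(g) is.numeric(g$n), logical(1))))
    n_participants <- sum(vapply(groups, function(g) g$n, numeric(1)))
  }
  stopifnot(n_participants >= 1, n_runs >= 1)
  structure(list(n_participants = n_participants, n_runs = n_runs,
                 env = env, sim = sim, groups = groups, folds = folds,
                 apply_qc = apply_qc, seed = seed),
            class = "study_config")
}

.participant_sims <- function(config) {
  base <- config$sim
  if (is.null(config$groups)) {
    return(data.frame(participant = sprintf("p%03d", seq_len(config$n_participants)),
                      group = "all", stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(config$groups), function(g)
    data.frame(participant = NA_character_, group = g,
               stringsAsFactors = FALSE)[rep(1, config$groups[[g]]$n), ]))
}

.override_sim <- function(sim, overrides) {
  for (f in setdiff(names(overrides), "n")) sim[[f]] <- overrides[[f]]
  class(sim) <- "simulation_config"
  sim
}

#' Run a complete simulated study end to end
#'
#' Generates the shared trajectories, simulates every participant's runs,
#' performs the two-stage grid-code analysis for all folds and hemispheres,
#' computes stability and tSNR QC, and runs the group statistics
#' (one-sample tests per hemisphere x fold with Bonferroni families,
#' temporal stability against its 50% chance level, and Welch group
#' comparisons when groups are configured). Fully reproducible from
#' `(config, config$seed)`.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV/TSV plus a JSON manifest with seeds, versions and file checksums.
#' @return list with `trajectories`, `cells`, `participant_level`,
#'   `stability`, `qc`, `group_stats`, `participants` (group table),
#'   `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_participants
  seeds <- with_seed(config$seed, list(
    trajectory = sample.int(.Machine$integer.max - 1L, config$n_runs),
    participant = matrix(sample.int(.Machine$integer.max - 1L,
                                    n * config$n_runs),
                         nrow = n)))
  trajectories <- lapply(seeds$trajectory, function(s)
    generate_trajectory(config$env, seed = s))
  events_list <- lapply(trajectories, function(tr) tr$events)

  participants <- .participant_sims(config)
  participants$participant <- sprintf("p%03d", seq_len(n))
  half <- config$sim$n_voxels %/% 2
  masks <- list(left = seq_len(half),
                right = (half + 1L):config$sim$n_voxels)

  cells <- list(); part_level <- list(); stab <- list(); qc <- list()
  flags <- list()
  for (i in seq_len(n)) {
    sim_i <- config$sim
    if (!is.null(config$groups))
      sim_i <- .override_sim(sim_i, config$groups[[participants$group[i]]])
    runs <- lapply(seq_len(config$n_runs), function(r)
      simulate_bold(trajectories[[r]], sim_i, seed = seeds$participant[i, r]))

    masks_i <- masks
    for (r in seq_len(config$n_runs)) {
      qcr <- tsnr_filter(runs[[r]])
      qc[[length(qc) + 1L]] <- data.frame(
        participant = participants$participant[i], run = r,
        n_voxels = length(qcr$tsnr), n_excluded = sum(qcr$excluded),
        tsnr_median = stats::median(qcr$tsnr, na.rm = TRUE),
        threshold = qcr$threshold)
      if (config$apply_qc && any(qcr$excluded))
        masks_i <- lapply(masks_i, function(m) setdiff(m, qcr$excluded_indices))
    }
    res <- run_participant(runs, events_list, masks_i, folds = config$folds,
                           participant = participants$participant[i])
    cells[[i]] <- res$cells
    part_level[[i]] <- res$participant_level
    if (length(res$flags)) flags[[participants$participant[i]]] <- res$flags

    # stability at the grid fold: orientations from each half, per run
    kgrid <- if (6 %in% config$folds) 6 else config$folds[1]
    for (r in seq_len(config$n_runs)) {
      halves <- split_run(runs[[r]], events_list[[r]], warn_sparse = FALSE)
      for (h in names(masks_i)) {
        roi <- masks_i[[h]]
        if (length(roi) < 2) next
        th <- lapply(halves[c("estimation", "test")], function(hf) {
          d <- build_design(hf$events, kgrid, hf$run$n_scans, hf$run$TR,
                            carryover_events = hf$carryover)
          estimate_orientations(fit_glm(hf$run$data[roi, , drop = FALSE], d),
                                k = kgrid)
        })
        ts <- temporal_stability(th[[1]]$theta, th[[2]]$theta, k = kgrid)
        ss <- spatial_stability(th[[1]]$theta, k = kgrid)
        stab[[length(stab) + 1L]] <- data.frame(
          participant = participants$participant[i], hemisphere = h, run = r,
          fold = kgrid, temporal_fraction = ts$temporal_fraction,
          chance_level = ts$chance_level, rayleigh_Z = ss$rayleigh_Z,
          rayleigh_p = ss$rayleigh_p, n_voxels = ts$n_voxels)
      }
    }
  }
  cells <- do.call(rbind, cells)
  part_level <- do.call(rbind, part_level)
  part_level <- merge(part_level, participants, by = "participant")
  stab <- do.call(rbind, stab)
  qc <- do.call(rbind, qc)

  group_stats <- .study_group_stats(part_level, stab, config)
  manifest <- list(package = "gridls",
                   version = as.character(utils::packageVersion("gridls")),
                   r_version = R.version.string,
                   master_seed = config$seed,
                   trajectory_seeds = seeds$trajectory,
                   n_participants = n, n_runs = config$n_runs,
                   folds = config$folds,
                   warnings = flags)
  out <- list(trajectories = trajectories, cells = cells,
              participant_level = part_level, stability = stab, qc = qc,
              group_stats = group_stats, participants = participants,
              manifest = manifest)
  if (!is.null(out_dir)) .write_study(out, out_dir)
  out
}

.study_group_stats <- function(part_level, stab, config) {
  rows <- list()
  fam <- function(k) if (k == 6) "primary" else if (k %in% c(5, 7)) "control"
  else "unimodal"
  for (k in config$folds) for (h in unique(part_level$hemisphere)) {
    vals <- part_level$magnitude[part_level$fold == k &
                                   part_level$hemisphere == h]
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2) next
    ts <- one_sample_test(vals)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("gls_%dfold_%s", k, h), family = fam(k),
      t = ts$t, df = ts$df, p = ts$p, d = ts$d,
      bf10 = ts$bf10, bf01 = ts$bf01, mean = mean(vals), n = ts$n)
  }
  # temporal stability against its chance level
  agg <- stats::aggregate(temporal_fraction ~ participant, data = stab,
                          FUN = mean)
  if (nrow(agg) >= 2 && stats::sd(agg$temporal_fraction) > 0) {
    ts <- one_sample_test(agg$temporal_fraction,
                          null_value = stab$chance_level[1])
    rows[[length(rows) + 1L]] <- data.frame(
      id = "temporal_stability_vs_chance", family = "stability",
      t = ts$t, df = ts$df, p = ts$p, d = ts$d, bf10 = ts$bf10,
      bf01 = ts$bf01, mean = mean(agg$temporal_fraction), n = ts$n)
  }
  # group comparisons on the grid fold
  if (!is.null(config$groups) && length(config$groups) == 2 &&
      6 %in% config$folds) {
    gnames <- names(config$groups)
    for (h in unique(part_level$hemisphere)) {
      sel <- part_level$fold == 6 & part_level$hemisphere == h
      a <- part_level$magnitude[sel & part_level$group == gnames[1]]
      b <- part_level$magnitude[sel & part_level$group == gnames[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) next
      wt <- welch_test(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("group_diff_6fold_%s", h), family = "group",
        t = wt$t, df = wt$df, p = wt$p, d = wt$d, bf10 = wt$bf10,
        bf01 = wt$bf01, mean = mean(a) - mean(b), n = wt$n1 + wt$n2)
    }
  }
  bonferroni_families(do.call(rbind, rows))
}

.write_study <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (r in seq_along(out$trajectories)) {
    f <- file.path(out_dir, sprintf("run%d_events.tsv", r))
    write_events(out$trajectories[[r]], f)
    files <- c(files, f)
  }
  tabs <- list(gls_cells = out$cells, gls_participant = out$participant_level,
               stability = out$stability, qc = out$qc,
               group_stats = out$group_stats, participants = out$participants)
  for (nm in names(tabs)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- out$manifest
  manifest$files <- data.frame(path = basename(files),
                               md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
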