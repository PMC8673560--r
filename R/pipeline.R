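#' Configuration of a synthetic pressure/time experiment
#'
#' The default grid reproduces the study design: explants held at
#' transpulmonary pressures of -100, -400 and -1000 Pa for 24, 48 and
#' 72 h, three replicates each, plus a t = 0 baseline per replicate.
#'
#' @param pressures_Pa pressures in Pa.
#' @param timepoints_h culture times in hours (> 0).
#' @param replicates replicate explants per condition (>= 1).
#' @param spacing_um voxel spacing for the image pipeline.
#' @param seed global seed; per-replicate seeds are derived by a counter
#'   scheme so adding replicates never perturbs existing ones.
#' @param growth named list of [growth_config()] overrides.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(pressures_Pa = c(-100, -400, -1000),
                              timepoints_h = c(24, 48, 72),
                              replicates = 3,
                              spacing_um = 2.5,
                              seed = 1,
                              growth = list(),
                              out_dir = NULL) {
  if (length(pressures_Pa) == 0 || length(timepoints_h) == 0) {
    stop("pressure and time lists must be non-empty")
  }
  if (any(timepoints_h <= 0)) stop("timepoints must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(pressures_Pa = pressures_Pa,
                 timepoints_h = timepoints_h,
                 replicates = as.integer(replicates),
                 spacing_um = spacing_um,
                 seed = as.integer(seed),
                 growth = growth,
                 out_dir = out_dir),
            class = "experiment_config")
}

growth_config_for <- function(config, pressure, time, seed_r) {
  # certify generated trees down to the resolution this experiment
  # actually measures at
  geometry <- list(certify_spacings =
                     sort(unique(c(3.5, 3, config$spacing_um)),
                          decreasing = TRUE))
  args <- utils::modifyList(
    list(pressure_Pa = pressure, time_h = time, rng_seed = seed_r,
         geometry = geometry),
    config$growth
  )
  do.call(growth_config, args)
}

#' Run the full synthetic experiment
#'
#' For every (pressure, timepoint, replicate): generates the ground-truth
#' tree, rasterizes it, and measures it through both the closed-form
#' oracle and the image pipeline (skeletonization, lineage annotation,
#' voxel morphometry). Fold-changes are computed per replicate against the
#' t = 0 baseline of the same seed. The pooled allometric power law is
#' fitted to the pipeline-measured (area fold, branch fold) points, a
#' per-pressure collapse test is run, and an RCr-radius table by pressure
#' and time is assembled.
#'
#' With `out_dir` set, writes `records.csv`, `allometric_fit.json`,
#' `rcr_radius.csv` and `log.txt` (seeds, package version, wall times);
#' outputs are regenerable bit-identically from config + seed.
#'
#' @param config an [experiment_config()].
#' @return an `airway_experiment`: list with `records` (tibble),
#'   `fit` (pooled `allometric_fit` or NULL), `fits_by_pressure`,
#'   `collapse`, `rcr_table`, and `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  log_lines <- c(sprintf("airwaymorph %s",
                         as.character(utils::packageVersion("airwaymorph"))),
                 sprintf("global seed %d", config$seed))
  records <- list()
  for (r in seq_len(config$replicates)) {
    seed_r <- derive_seed(config$seed, 1000L + r)
    cfg0 <- growth_config_for(config, config$pressures_Pa[1], 1, seed_r)
    tree0 <- build_canonical_tree(cfg0)
    vol0 <- rasterize(tree0, config$spacing_um)
    t0 <- Sys.time()
    meas0 <- measure_volume(vol0)
    oracle0 <- analytic_metrics(tree0)
    log_lines <- c(log_lines,
                   sprintf("replicate %d baseline seed %d measured in %.1fs",
                           r, seed_r,
                           as.numeric(Sys.time() - t0, units = "secs")))
    records[[length(records) + 1]] <- dplyr::bind_cols(
      tibble(record_id = sprintf("r%d_t0", r), replicate = r,
             pressure_Pa = NA_real_, time_h = 0, seed = seed_r),
      meas0$record,
      tibble(oracle_terminals = oracle0$terminal_branch_count,
             oracle_area_um2 = oracle0$surface_area_um2,
             oracle_volume_um3 = oracle0$volume_um3)
    )
    for (p in config$pressures_Pa) {
      for (tt in config$timepoints_h) {
        t0 <- Sys.time()
        cfg <- growth_config_for(config, p, tt, seed_r)
        tree <- grow_tree(tree0, cfg)
        vol <- rasterize(tree, config$spacing_um)
        meas <- measure_volume(vol)
        oracle <- analytic_metrics(tree)
        log_lines <- c(log_lines,
                       sprintf("replicate %d p %g t %g done in %.1fs",
                               r, p, tt,
                               as.numeric(Sys.time() - t0, units = "secs")))
        records[[length(records) + 1]] <- dplyr::bind_cols(
          tibble(record_id = sprintf("r%d_p%g_t%g", r, p, tt),
                 replicate = r, pressure_Pa = p, time_h = tt, seed = seed_r),
          meas$record,
          tibble(oracle_terminals = oracle$terminal_branch_count,
                 oracle_area_um2 = oracle$surface_area_um2,
                 oracle_volume_um3 = oracle$volume_um3)
        )
      }
    }
  }
  records <- dplyr::bind_rows(records)

  # fold-changes per replicate against its own t = 0 baseline
  records <- dplyr::bind_rows(lapply(split(records, records$replicate),
                                     function(d) {
    fold_change_series(d, d$record_id[d$time_h == 0][1])
  }))
  records <- dplyr::arrange(records, replicate, pressure_Pa, time_h)

  grown <- records[records$time_h > 0, ]
  fit <- NULL
  fits_by_pressure <- NULL
  collapse <- NULL
  if (nrow(grown) >= 3) {
    fit <- fit_power_law(grown$fold_area, grown$fold_branches)
    fit$bootstrap_ci_95 <- bootstrap_ci(grown$fold_area,
                                        grown$fold_branches,
                                        n_boot = 500,
                                        seed = derive_seed(config$seed, 77L))
    if (length(config$pressures_Pa) >= 2 &&
          all(table(grown$pressure_Pa) >= 3)) {
      fits_by_pressure <- lapply(split(grown, grown$pressure_Pa), function(d) {
        fit_power_law(d$fold_area, d$fold_branches)
      })
      collapse <- collapse_test(fits_by_pressure)
    }
  } else {
    warning("fewer than 3 grown records: allometric fit skipped")
  }

  rcr <- grown
  rcr$rcr_radius_um <- vapply(grown$branch_radii, function(b) {
    if ("RCr" %in% names(b)) b[["RCr"]] else NA_real_
  }, numeric(1))
  rcr_table <- dplyr::summarise(
    dplyr::group_by(rcr, .data$pressure_Pa, .data$time_h),
    mean_rcr_um = mean(.data$rcr_radius_um, na.rm = TRUE),
    n = dplyr::n(),
    .groups = "drop"
  )

  log_lines <- c(log_lines,
                 sprintf("total %.1fs",
                         as.numeric(Sys.time() - t_start, units = "secs")))
  out <- structure(list(records = records, fit = fit,
                        fits_by_pressure = fits_by_pressure,
                        collapse = collapse, rcr_table = rcr_table,
                        config = config, log = log_lines),
                   class = "airway_experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- exp$records
  rec$branch_radii <- vapply(rec$branch_radii, function(b) {
    paste(sprintf("%s=%.3f", names(b), b), collapse = ";")
  }, character(1))
  write.csv(rec, file.path(out_dir, "records.csv"), row.names = FALSE)
  if (!is.null(exp$fit)) {
    jsonlite::write_json(
      list(exponent_a = exp$fit$exponent_a,
           prefactor_c = exp$fit$prefactor_c,
           r_squared = exp$fit$r_squared,
           n_points = exp$fit$n_points,
           bootstrap_ci_95 = exp$fit$bootstrap_ci_95,
           collapse_delta_a = if (!is.null(exp$collapse)) exp$collapse$delta_a_max,
           collapse_pass = if (!is.null(exp$collapse)) exp$collapse$pass),
      file.path(out_dir, "allometric_fit.json"),
      auto_unbox = TRUE, digits = NA)
  }
  write.csv(exp$rcr_table, file.path(out_dir, "rcr_radius.csv"),
            row.names = FALSE)
  # wall times are stripped so outputs regenerate bit-identically
  log_det <- sub(" (measured in|done in) [0-9.]+s$", "", exp$log)
  log_det <- log_det[!grepl("^total ", log_det)]
  writeLines(log_det, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.airway_experiment <- function(x, ...) {
  cat("<airway_experiment>\n")
  cat(sprintf("  %d records (%d replicates x %d pressures x %d timepoints + baselines)\n",
              nrow(x$records), x$config$replicates,
              length(x$config$pressures_Pa), length(x$config$timepoints_h)))
  if (!is.null(x$fit)) {
    cat(sprintf("  pooled scaling: a = %.3f (R^2 = %.3f)\n",
                x$fit$exponent_a, x$fit$r_squared))
  }
  if (!is.null(x$collapse)) {
    cat(sprintf("  collapse: max |delta a| = %.3f (%s)\n",
                x$collapse$delta_a_max,
                if (x$collapse$pass) "pass" else "fail"))
  }
  invisible(x)
}

#' Write the deterministic phantom fixture library
#'
#' Generates the small phantom set used for validation -- a capped
#' cylinder, a ball, a Y-shaped tube, and a canonical airway tree -- as
#' TIFF volumes with SWC ground truth and a JSON file of closed-form
#' expected metrics. Identical seeds give identical files.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the canonical tree.
#' @param spacing_um voxel spacing of the phantom volumes.
#' @return invisible list of written paths.
#' @export
make_fixtures <- function(out_dir, seed = 1, spacing_um = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  expected <- list()

  cyl <- phantom_cylinder(radius = 10, length = 200)
  ball <- phantom_ball(radius = 50)
  ytube <- phantom_y_tube()
  canon <- build_canonical_tree(growth_config(rng_seed = seed))

  for (nm in c("cylinder", "ball", "ytube", "canonical")) {
    tree <- switch(nm, cylinder = cyl, ball = ball, ytube = ytube,
                   canonical = canon)
    vol <- rasterize(tree, spacing_um)
    tp <- file.path(out_dir, paste0(nm, ".tif"))
    sp <- file.path(out_dir, paste0(nm, ".swc"))
    write_volume_tiff(vol, tp)
    write_swc(tree, sp)
    topo <- tree_skeleton_topology(tree)
    expected[[nm]] <- list(
      surface_area_um2 = analytic_surface_area(tree),
      volume_um3 = analytic_volume(tree),
      n_terminal = topo$n_terminal,
      n_endpoint = topo$n_endpoint,
      n_junction = topo$n_junction
    )
    paths[[nm]] <- c(tp, sp)
  }
  jsonlite::write_json(expected, file.path(out_dir, "expected_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Analytic phantoms
#'
#' Single-segment and Y-shaped ground-truth trees with closed-form
#' geometry, used as oracles for the voxel pipeline.
#'
#' @param radius tube/ball radius in um.
#' @param length cylinder axis length in um.
#' @return an `airway_tree`.
#' @export
phantom_cylinder <- function(radius = 10, length = 200) {
  pts <- cbind(0, seq(0, -length, length.out = max(3, ceiling(length / 10))), 0)
  new_airway_tree(tibble(
    segment_id = 1L, parent_id = NA_integer_, label = "cyl",
    generation = 0L, is_terminal = TRUE, attach_frac = NA_real_,
    points = list(pts), radii = list(rep(radius, nrow(pts)))
  ))
}

#' @rdname phantom_cylinder
#' @export
phantom_ball <- function(radius = 50) {
  pts <- rbind(c(0, 0, 0), c(0, -1e-6, 0))
  new_airway_tree(tibble(
    segment_id = 1L, parent_id = NA_integer_, label = "ball",
    generation = 0L, is_terminal = TRUE, attach_frac = NA_real_,
    points = list(pts), radii = list(rep(radius, 2))
  ))
}

#' @rdname phantom_cylinder
#' @export
phantom_y_tube <- function(radius = 12, stem = 150, arm = 120) {
  stem_pts <- cbind(0, seq(0, -stem, length.out = 13), 0)
  d1 <- unit3(c(sin(40 * pi / 180), -cos(40 * pi / 180), 0))
  d2 <- unit3(c(-sin(40 * pi / 180), -cos(40 * pi / 180), 0))
  a1 <- sweep(outer(seq(0, arm, length.out = 11), d1), 2,
              stem_pts[nrow(stem_pts), ], `+`)
  a2 <- sweep(outer(seq(0, arm, length.out = 11), d2), 2,
              stem_pts[nrow(stem_pts), ], `+`)
  new_airway_tree(tibble(
    segment_id = 1:3,
    parent_id = c(NA_integer_, 1L, 1L),
    label = c("stem", "arm1", "arm2"),
    generation = c(0L, 1L, 1L),
    is_terminal = c(FALSE, TRUE, TRUE),
    attach_frac = c(NA_real_, 1, 1),
    points = list(stem_pts, a1, a2),
    radii = list(rep(radius, nrow(stem_pts)), rep(radius, 11),
                 rep(radius, 11))
  ))
}
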