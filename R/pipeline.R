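#' Default end-to-end run configuration
#'
#' Study conditions for the synthetic scenario: nine dual-tagged individuals
#' foraging around a two-island lagoon monitored by a 63-receiver array with
#' habitat-dependent detection ranges (d50 185 m over reef/seagrass, 350 m
#' over sand/lagoon), acoustic transmitter delays U(50, 130) s, and Argos
#' fixes at ~3/day with location-class-dependent error. A 57-h receiver
#' outage two days into the study mirrors a maintenance disruption.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir output directory.
#' @param n_tags number of simulated individuals.
#' @param duration_days tracking duration per individual (recycled).
#' @return a nested configuration list.
#' @export
default_run_config <- function(seed = 1, outdir = tempfile("trackcompare_run_"),
                               n_tags = 9, duration_days = 16) {
  start <- as.POSIXct("2017-05-02 00:00:00", tz = "UTC")
  list(
    seed = seed, outdir = outdir, n_tags = n_tags,
    duration_days = rep_len(duration_days, n_tags),
    start_time = start,
    habitat = list(extent_km = 20, cell_size = 100, land_fraction = 0.08),
    movement = list(sigma2 = 4e6, tau_pos = 2 * 86400, tau_vel = NULL,
                    dt_s = 60),
    receivers = list(n = 63, strategy = "random"),
    kernels = list(reef = c(d50 = 185, d01 = 520),
                   sand = c(d50 = 350, d01 = 1100)),
    range_test = list(distances = c(0, 250, 500, 750), n_per_distance = 200),
    acoustic = list(delay_range_s = c(50, 130), coa_bin_s = 1800,
                    dbbmm = list(window = 49, margin = 15, cell_size = 50,
                                 min_locations = 49)),
    argos = list(fixes_per_day = 3, class_probs = default_class_probs(),
                 class_sds = default_class_sds(),
                 dbbmm = list(window = 13, margin = 3, cell_size = 100,
                              min_locations = 13),
                 se_cap = 3000, v_max = 2),
    blackouts = data.frame(start = start + 2 * 86400,
                           end = start + 2 * 86400 + 57 * 3600),
    rd = list(cell_size = 100, max_fit_n = 400),
    best = list(n_iter = 10000, burn = 1000),
    cost = cost_params())
}

#' Simulate a complete synthetic telemetry dataset
#'
#' Writes the CSV schemas the pipelines read (detections.csv, receivers.csv,
#' rangetest.csv, argos.csv, deployments.csv), the habitat as an ESRI ASCII
#' grid, and a ground-truth manifest (true movement parameters and seeds).
#'
#' @param config a [default_run_config()] list.
#' @return the dataset directory, invisibly; the ground truth is also
#'   returned as attribute `"truth"` (habitat, receivers, tracks).
#' @export
run_simulate <- function(config = default_run_config()) {
  if (config$n_tags < 1) stop("need at least one tag")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$outdir)) stop("cannot create output directory")
  hab <- make_habitat(config$habitat$extent_km, config$habitat$cell_size,
                      config$habitat$land_fraction, seed = config$seed)
  recv <- place_receivers(hab, config$receivers$n, config$receivers$strategy,
                          seed = config$seed + 1)
  kernels <- lapply(names(config$kernels), function(cl) {
    kernel_from_ranges(config$kernels[[cl]]["d50"],
                       config$kernels[[cl]]["d01"], cl)
  })
  names(kernels) <- names(config$kernels)

  rt <- do.call(rbind, lapply(seq_along(kernels), function(i) {
    simulate_range_test(kernels[[i]], config$range_test$distances,
                        config$range_test$n_per_distance,
                        seed = config$seed + 10 + i)
  }))

  tags <- sprintf("T%02d", seq_len(config$n_tags))
  # individual home centres scattered over water near the lagoon
  set.seed(config$seed + 2)
  homes <- list()
  for (i in seq_len(config$n_tags)) {
    repeat {
      cand <- hab$home_centre + stats::rnorm(2, sd = 1500)
      if (on_water(hab, cand[1], cand[2])) break
    }
    homes[[i]] <- cand
  }
  tracks <- list(); det <- list(); argos <- list()
  for (i in seq_len(config$n_tags)) {
    tr <- simulate_ou_track(
      hab, sigma2 = config$movement$sigma2, tau_pos = config$movement$tau_pos,
      tau_vel = config$movement$tau_vel,
      duration_s = config$duration_days[i] * 86400,
      dt_s = config$movement$dt_s, home = homes[[i]],
      start_time = config$start_time + (i - 1) * 3600,
      tag_id = tags[i], seed = config$seed + 100 + i)
    tracks[[tags[i]]] <- tr
    det[[i]] <- simulate_acoustic_detections(tr, recv, kernels,
                                             config$acoustic$delay_range_s,
                                             seed = config$seed + 200 + i)
    argos[[i]] <- simulate_argos_fixes(tr, config$argos$fixes_per_day,
                                       config$argos$class_probs,
                                       config$argos$class_sds,
                                       seed = config$seed + 300 + i)
  }
  det <- do.call(rbind, det); argos <- do.call(rbind, argos)
  dep <- data.frame(tag_id = tags,
                    release_time = config$start_time +
                      (seq_len(config$n_tags) - 1) * 3600,
                    x = vapply(homes, `[`, numeric(1), 1),
                    y = vapply(homes, `[`, numeric(1), 2))

  wcsv <- function(d, f) {
    for (cn in names(d)) if (inherits(d[[cn]], "POSIXct")) d[[cn]] <- format_utc(d[[cn]])
    utils::write.csv(d, file.path(config$outdir, f), row.names = FALSE)
  }
  names(dep)[2] <- "release_time"
  wcsv(det, "detections.csv")
  wcsv(recv, "receivers.csv")
  wcsv(rt, "rangetest.csv")
  wcsv(argos, "argos.csv")
  wcsv(dep, "deployments.csv")
  write_ascii_grid(hab$classes, hab$grid, file.path(config$outdir, "habitat.asc"))
  manifest <- list(seed = config$seed, tags = tags,
                   movement = config$movement,
                   duration_days = config$duration_days,
                   homes = lapply(homes, as.numeric),
                   kernels = lapply(kernels, function(k)
                     list(class = k$habitat_class, a = k$a, b = k$b,
                          d50 = k$d50, d01 = k$d01)))
  jsonlite::write_json(manifest, file.path(config$outdir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- config$outdir
  attr(out, "truth") <- list(habitat = hab, receivers = recv,
                             kernels = kernels, tracks = tracks,
                             deployments = dep)
  invisible(out)
}

#' Read a dataset directory written by [run_simulate()]
#'
#' @param dir dataset directory.
#' @return list of parsed tables plus the habitat grid.
#' @export
read_dataset <- function(dir) {
  rcsv <- function(f, tcols = "timestamp") {
    d <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    for (cn in intersect(tcols, names(d))) d[[cn]] <- parse_utc(d[[cn]])
    d
  }
  habf <- read_ascii_grid(file.path(dir, "habitat.asc"))
  lv <- c("land", "reef", "seagrass", "sand", "lagoon")
  classes <- habf$values
  hab <- structure(list(grid = habf$grid, classes = classes, levels = lv,
                        water = classes != 1,
                        home_centre = c(habf$grid$origin_x, habf$grid$origin_y) +
                          0.47 * habf$grid$n_cols * habf$grid$cell_size),
                   class = "habitat_grid")
  list(detections = rcsv("detections.csv"),
       receivers = rcsv("receivers.csv", character(0)),
       rangetest = rcsv("rangetest.csv", character(0)),
       argos = rcsv("argos.csv"),
       deployments = rcsv("deployments.csv", "release_time"),
       habitat = hab)
}

#' Run the full simulate-to-comparison analysis
#'
#' Executes the complete workflow on a dataset directory: detection
#' filtering, kernel fitting, relocation and COAs; Argos prefiltering, SDA
#' filtering, CTCRW state-space smoothing; acoustic and satellite occurrence
#' distributions (dBBMM) and range distributions (CTMM + weighted KDE);
#' method comparison (areas, ratios, Bhattacharyya affinity, Bayesian
#' two-group probability), receiver-coverage analysis, and the cost table.
#' Individual-level stage failures (e.g. too few COAs for a dBBMM) are
#' logged and skipped; remaining individuals continue.
#'
#' @param config a [default_run_config()]; `config$outdir` must contain a
#'   dataset (see [run_simulate()]).
#' @param dataset optionally, a pre-read [read_dataset()] list.
#' @return list of class `trackcompare_report`: per-tag products, comparison
#'   tables, coverage result, cost table, and a manifest of filter counts.
#' @export
run_full_analysis <- function(config = default_run_config(), dataset = NULL) {
  t_start <- Sys.time()
  logf <- file.path(config$outdir, "analysis.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logf, append = TRUE)
    message(line)
  }
  if (is.null(dataset)) dataset <- read_dataset(config$outdir)
  hab <- dataset$habitat
  manifest <- list(seed = config$seed, stages = list())

  kernels <- lapply(names(config$kernels), function(cl)
    fit_detection_kernel(dataset$rangetest, cl))
  names(kernels) <- names(config$kernels)
  logmsg("kernels fitted: %s",
         paste(sprintf("%s d50=%.0fm", names(kernels),
                       vapply(kernels, function(k) k$d50, numeric(1))),
               collapse = ", "))

  filt <- filter_detections(dataset$detections, dataset$deployments,
                            config$blackouts)
  manifest$stages$detection_filter <- as.list(attr(filt, "filter_report"))
  reloc <- relocate_detections(filt, dataset$receivers, kernels, hab,
                               seed = config$seed + 400)
  coas_all <- compute_coas(reloc, config$acoustic$coa_bin_s)
  utils::write.csv(within(as.data.frame(coas_all), time <- format_utc(time)),
                   file.path(config$outdir, "coas.csv"), row.names = FALSE)
  logmsg("acoustic: %d detections -> %d COAs", nrow(filt), nrow(coas_all))

  tags <- dataset$deployments$tag_id
  ac_od <- list(); sat_od <- list(); ac_rd <- list(); sat_rd <- list()
  sat_fit <- list()
  cfg_ac <- do.call(dbbmm_config, config$acoustic$dbbmm)
  cfg_sat <- do.call(dbbmm_config, config$argos$dbbmm)
  for (tg in tags) {
    coas <- coas_all[coas_all$tag_id == tg, , drop = FALSE]
    ac_od[[tg]] <- try_stage(tg, "acoustic OD", logmsg, {
      estimate_od(coas, cfg_ac, hab)
    })
    ac_rd[[tg]] <- try_stage(tg, "acoustic RD", logmsg, {
      locs <- speed_outlier_filter(coas, config$argos$v_max)
      fit <- fit_ctmm_candidates(locs, config$rd$max_fit_n)
      estimate_rd(locs, hab, fit, config$rd$cell_size)
    })
    fx <- dataset$argos[dataset$argos$tag_id == tg, , drop = FALSE]
    sat_smoothed <- try_stage(tg, "satellite SSM", logmsg, {
      pf <- prefilter_argos(fx, dataset$deployments, config$argos$v_max)
      pf <- sda_filter(pf, config$argos$v_max)
      fit <- fit_ctcrw_ssm(pf, config$argos$class_sds)
      predict_and_postfilter(fit, hab, config$argos$se_cap)
    })
    if (!is.null(sat_smoothed)) {
      sat_fit[[tg]] <- sat_smoothed
      sat_od[[tg]] <- try_stage(tg, "satellite OD", logmsg, {
        estimate_od(sat_smoothed, cfg_sat, hab)
      })
      sat_rd[[tg]] <- try_stage(tg, "satellite RD", logmsg, {
        pf <- prefilter_argos(fx, dataset$deployments, config$argos$v_max)
        locs <- speed_outlier_filter(pf, config$argos$v_max)
        fit <- fit_ctmm_candidates(locs, config$rd$max_fit_n)
        estimate_rd(locs, hab, fit, config$rd$cell_size)
      })
    }
  }
  drop_null <- function(l) Filter(Negate(is.null), l)
  ac_od <- drop_null(ac_od); sat_od <- drop_null(sat_od)
  ac_rd <- drop_null(ac_rd); sat_rd <- drop_null(sat_rd)

  cmp_od <- if (length(intersect(names(ac_od), names(sat_od))) >= 2) {
    compare_methods(ac_od, sat_od, ud_type = "OD",
                    best_seed = config$seed, best_iter = config$best$n_iter)
  } else NULL
  cmp_rd <- if (length(intersect(names(ac_rd), names(sat_rd))) >= 2) {
    compare_methods(ac_rd, sat_rd, ud_type = "RD",
                    best_seed = config$seed, best_iter = config$best$n_iter)
  } else NULL

  coverage <- if (length(sat_od)) {
    regions <- lapply(sat_od, function(od) od$regions[["0.95"]])
    names(regions) <- names(sat_od)
    coverage_analysis(regions, dataset$receivers, kernels)
  } else NULL

  costs <- build_cost_table(config$cost)

  for (nm in c("cmp_od", "cmp_rd")) {
    obj <- get(nm)
    if (!is.null(obj)) {
      utils::write.csv(obj$table,
                       file.path(config$outdir, paste0(nm, "_individuals.csv")),
                       row.names = FALSE)
      utils::write.csv(obj$summary,
                       file.path(config$outdir, paste0(nm, "_summary.csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(costs, file.path(config$outdir, "cost_table.csv"),
                   row.names = FALSE)
  if (!is.null(coverage)) {
    utils::write.csv(coverage$outside,
                     file.path(config$outdir, "coverage_outside.csv"),
                     row.names = FALSE)
    write_geojson(list(coverage_p50 = coverage$coverage_p50,
                       coverage_p01 = coverage$coverage_p01,
                       receiver_mcp = coverage$mcp),
                  file.path(config$outdir, "coverage.geojson"))
  }
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("analysis complete in %.1f s", manifest$elapsed_s)
  structure(list(acoustic_od = ac_od, satellite_od = sat_od,
                 acoustic_rd = ac_rd, satellite_rd = sat_rd,
                 satellite_locations = sat_fit,
                 coas = coas_all, kernels = kernels,
                 comparison_od = cmp_od, comparison_rd = cmp_rd,
                 coverage = coverage, costs = costs, manifest = manifest),
            class = "trackcompare_report")
}

try_stage <- function(tag, stage, logmsg, expr) {
  res <- tryCatch(expr, error = function(e) {
    logmsg("tag %s: %s skipped (%s)", tag, stage, conditionMessage(e))
    NULL
  })
  res
}


#' @export
print.trackcompare_report <- function(x, ...) {
  cat("trackcompare pipeline report\n")
  cat(sprintf("  acoustic ODs: %d; satellite ODs: %d; acoustic RDs: %d; satellite RDs: %d\n",
              length(x$acoustic_od), length(x$satellite_od),
              length(x$acoustic_rd), length(x$satellite_rd)))
  if (!is.null(x$comparison_od)) { cat("-- occurrence distributions --\n"); print(x$comparison_od) }
  if (!is.null(x$comparison_rd)) { cat("-- range distributions --\n"); print(x$comparison_rd) }
  if (!is.null(x$coverage)) print(x$coverage)
  invisible(x)
}
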