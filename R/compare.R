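#' Bhattacharyya affinity between two utilization distributions
#'
#' BA = sum over cells of sqrt(p_i * q_i), from 0 (disjoint) to 1 (identical).
#' Surfaces on different grids are resampled (mass-conserving) onto a common
#' grid — the finer cell size, covering both extents. With `level` given,
#' each surface is first truncated to its own level-contour cells and
#' renormalized; with `level = NULL` the whole surfaces are compared.
#'
#' @param ud_a,ud_b [probability_surface()] objects (or `occurrence_dist` /
#'   `range_dist`, whose surfaces are used).
#' @param level optional contour level for truncation (e.g. 0.95).
#' @return BA in \[0, 1\].
#' @export
bhattacharyya_affinity <- function(ud_a, ud_b, level = NULL) {
  sa <- extract_surface(ud_a); sb <- extract_surface(ud_b)
  sa <- renormalize_surface(sa); sb <- renormalize_surface(sb)
  if (!same_grid(sa$grid, sb$grid)) {
    h <- min(sa$grid$cell_size, sb$grid$cell_size)
    x0 <- min(sa$grid$origin_x, sb$grid$origin_x)
    y0 <- min(sa$grid$origin_y, sb$grid$origin_y)
    x1 <- max(grid_xmax(sa$grid), grid_xmax(sb$grid))
    y1 <- max(grid_ymax(sa$grid), grid_ymax(sb$grid))
    common <- grid_spec(x0, y0, h, ceiling((y1 - y0) / h),
                        ceiling((x1 - x0) / h))
    sa <- renormalize_surface(resample_surface(sa, common))
    sb <- renormalize_surface(resample_surface(sb, common))
  }
  da <- sa$density; db <- sb$density
  if (!is.null(level)) {
    da <- truncate_to_level(sa, level)
    db <- truncate_to_level(sb, level)
  }
  sum(sqrt(da * db))
}

extract_surface <- function(x) {
  if (inherits(x, "probability_surface")) return(x)
  if (!is.null(x$surface)) return(x$surface)
  stop("cannot extract a probability surface from class ", class(x)[1])
}

renormalize_surface <- function(s) {
  tot <- sum(s$density)
  if (tot <= 0) stop("surface has no mass")
  if (abs(tot - 1) > 1e-12) {
    s$density <- s$density / tot
    s$clipped <- FALSE
  }
  s
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$origin_x, a$origin_y, a$cell_size, a$n_rows, a$n_cols),
                   c(b$origin_x, b$origin_y, b$cell_size, b$n_rows, b$n_cols)))
}
grid_xmax <- function(g) g$origin_x + g$n_cols * g$cell_size
grid_ymax <- function(g) g$origin_y + g$n_rows * g$cell_size

truncate_to_level <- function(surf, level) {
  reg <- contour_region(surf, level)
  d <- matrix(0, surf$grid$n_rows, surf$grid$n_cols)
  idx <- cbind(reg$rows, reg$cols)
  d[idx] <- surf$density[idx]
  d / sum(d)
}

#' Bayesian two-group comparison of space-use areas
#'
#' A robust Bayesian estimation of the difference between two groups of area
#' estimates (satellite vs acoustic): each group is t-distributed with its
#' own mean and sd and a shared normality parameter nu, with broad
#' uninformative priors — means ~ Normal(pooled mean, 1000 x pooled sd), sds
#' ~ Uniform(pooled sd / 1000, pooled sd x 1000), nu - 1 ~ Exponential(1/29).
#' Sampling is by MCMC (JAGS) with two seeded chains. The headline output is
#' the posterior probability that the satellite group mean exceeds the
#' acoustic group mean.
#'
#' @param areas_sat,areas_ac numeric vectors (>= 2 values each).
#' @param n_iter post-burn-in iterations per chain.
#' @param burn burn-in iterations.
#' @param seed integer seed (chains use seed and seed + 1).
#' @param log_transform compare on the log scale?
#' @return object of class `best_result`: `prob_sat_greater`, posterior
#'   summaries, effect size, and chain diagnostics (split R-hat, effective
#'   sample size).
#' @export
best_two_group <- function(areas_sat, areas_ac, n_iter = 10000, burn = 1000,
                           seed = 1, log_transform = FALSE) {
  stopifnot(length(areas_sat) >= 2, length(areas_ac) >= 2)
  y1 <- as.numeric(areas_sat); y2 <- as.numeric(areas_ac)
  if (log_transform) { y1 <- log(y1); y2 <- log(y2) }
  pooled <- c(y1, y2)
  psd <- stats::sd(pooled)
  if (!is.finite(psd) || psd <= 0) stop("zero pooled standard deviation")
  model_txt <- "
model {
  for (i in 1:n1) { y1[i] ~ dt(mu1, tau1, nu) }
  for (i in 1:n2) { y2[i] ~ dt(mu2, tau2, nu) }
  mu1 ~ dnorm(pooled_mean, prec_mu)
  mu2 ~ dnorm(pooled_mean, prec_mu)
  sigma1 ~ dunif(sd_lo, sd_hi)
  sigma2 ~ dunif(sd_lo, sd_hi)
  tau1 <- pow(sigma1, -2)
  tau2 <- pow(sigma2, -2)
  nu <- nu_minus_1 + 1
  nu_minus_1 ~ dexp(0.0345)
}"
  data <- list(y1 = y1, y2 = y2, n1 = length(y1), n2 = length(y2),
               pooled_mean = mean(pooled),
               prec_mu = 1 / (1000 * psd)^2,
               sd_lo = psd / 1000, sd_hi = psd * 1000)
  inits <- lapply(seed + 0:1, function(s) {
    list(mu1 = mean(y1), mu2 = mean(y2),
         sigma1 = max(stats::sd(y1), psd / 100),
         sigma2 = max(stats::sd(y2), psd / 100), nu_minus_1 = 29,
         .RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  jm <- rjags::jags.model(textConnection(model_txt), data = data,
                          inits = inits, n.chains = 2, quiet = TRUE)
  stats::update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("mu1", "mu2", "sigma1", "sigma2", "nu"),
                              n_iter, progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  diffs <- draws[, "mu1"] - draws[, "mu2"]
  eff <- diffs / sqrt((draws[, "sigma1"]^2 + draws[, "sigma2"]^2) / 2)
  gd <- coda::gelman.diag(samp[, c("mu1", "mu2")], autoburnin = FALSE,
                          multivariate = FALSE)
  structure(list(
    prob_sat_greater = mean(diffs > 0),
    posterior = data.frame(
      parameter = c("mu_sat", "mu_ac", "sigma_sat", "sigma_ac", "nu",
                    "mu_diff", "effect_size"),
      mean = c(colMeans(draws[, c("mu1", "mu2", "sigma1", "sigma2", "nu")]),
               mean(diffs), mean(eff)),
      sd = c(apply(draws[, c("mu1", "mu2", "sigma1", "sigma2", "nu")], 2,
                   stats::sd), stats::sd(diffs), stats::sd(eff))),
    effect_size = mean(eff),
    diagnostics = list(split_rhat = gd$psrf[, 1],
                       n_eff = coda::effectiveSize(samp[, c("mu1", "mu2")])),
    log_transform = log_transform, seed = seed,
    n_iter = n_iter, burn = burn),
    class = "best_result")
}

#' @export
print.best_result <- function(x, ...) {
  cat(sprintf("Bayesian two-group comparison%s\n",
              if (x$log_transform) " (log scale)" else ""))
  cat(sprintf("  P(mu_sat - mu_ac > 0) = %.3f; effect size %.2f\n",
              x$prob_sat_greater, x$effect_size))
  cat(sprintf("  split R-hat: %s\n",
              paste(sprintf("%.3f", x$diagnostics$split_rhat), collapse = ", ")))
  invisible(x)
}

#' Receiver-array coverage analysis of utilization distributions
#'
#' Builds the array coverage as the union of detection-range disks at the
#' 50% (d50) and 1% (d01) detection-probability radii of each receiver's
#' habitat kernel, plus the receiver minimum convex polygon, and computes the
#' fraction of each UD contour region falling outside each reference.
#'
#' @param ud_regions named list of [region_set()] objects (e.g. the `regions`
#'   of an `occurrence_dist`).
#' @param receivers receiver table with `x`, `y`, `kernel_class`.
#' @param kernels named list of [detection_kernel()] by kernel class.
#' @return object of class `coverage_result`: coverages, their areas (km^2),
#'   the MCP, and an `outside` data.frame of fractions.
#' @export
coverage_analysis <- function(ud_regions, receivers, kernels) {
  if (nrow(receivers) == 0) stop("no receivers")
  d50 <- vapply(receivers$kernel_class, function(cl) kernels[[cl]]$d50,
                numeric(1))
  d01 <- vapply(receivers$kernel_class, function(cl) kernels[[cl]]$d01,
                numeric(1))
  cov50 <- union_of_disks(receivers$x, receivers$y, d50)
  cov01 <- union_of_disks(receivers$x, receivers$y, d01)
  array_mcp <- mcp(receivers$x, receivers$y)
  refs <- list(coverage_p50 = cov50, coverage_p01 = cov01, mcp = array_mcp)
  outside <- do.call(rbind, lapply(names(ud_regions), function(nm) {
    data.frame(region = nm,
               outside_p50 = proportion_outside(ud_regions[[nm]], cov50),
               outside_p01 = proportion_outside(ud_regions[[nm]], cov01),
               outside_mcp = proportion_outside(ud_regions[[nm]], array_mcp))
  }))
  structure(list(coverage_p50 = cov50, coverage_p01 = cov01, mcp = array_mcp,
                 area_p50_km2 = cov50$area_km2, area_p01_km2 = cov01$area_km2,
                 mcp_area_km2 = array_mcp$area_km2, outside = outside),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage_result: %.2f km^2 at p=0.50, %.2f km^2 at p=0.01, MCP %.2f km^2\n",
              x$area_p50_km2, x$area_p01_km2, x$mcp_area_km2))
  print(x$outside, row.names = FALSE)
  invisible(x)
}

#' Restrict two telemetry streams to their common active period
#'
#' Both streams are trimmed to the intersection of their time spans
#' (`[max(starts), min(ends)]`); blackout windows (receiver outages) are also
#' excised from the satellite stream so both methods see the same time base.
#'
#' @param acoustic_data,satellite_data data.frames with a `timestamp` column.
#' @param blackout_windows data.frame with `start`, `end` (POSIXct), or NULL.
#' @return list with trimmed `acoustic` and `satellite` tables and the
#'   `window` used.
#' @export
match_durations <- function(acoustic_data, satellite_data,
                            blackout_windows = NULL) {
  if (!nrow(acoustic_data) || !nrow(satellite_data)) {
    stop("both streams must be nonempty")
  }
  t0 <- max(min(acoustic_data$timestamp), min(satellite_data$timestamp))
  t1 <- min(max(acoustic_data$timestamp), max(satellite_data$timestamp))
  if (t0 > t1) stop("no temporal overlap between acoustic and satellite data")
  ac <- acoustic_data[acoustic_data$timestamp >= t0 &
                        acoustic_data$timestamp <= t1, , drop = FALSE]
  sat <- satellite_data[satellite_data$timestamp >= t0 &
                          satellite_data$timestamp <= t1, , drop = FALSE]
  if (!is.null(blackout_windows) && nrow(blackout_windows)) {
    for (i in seq_len(nrow(blackout_windows))) {
      sat <- sat[!(sat$timestamp >= blackout_windows$start[i] &
                     sat$timestamp <= blackout_windows$end[i]), , drop = FALSE]
    }
  }
  list(acoustic = ac, satellite = sat,
       window = c(start = t0, end = t1))
}

#' Restrict satellite fixes to the acoustic array's maximum detection range
#'
#' Exploratory rerun support: keeps only satellite fixes inside the 1%
#' detection-probability coverage of the array.
#'
#' @param satellite_fixes data.frame with `x`, `y`.
#' @param coverage_p01 a [union_of_disks()] coverage at the d01 radii.
#' @return the restricted data.frame.
#' @export
restrict_to_coverage <- function(satellite_fixes, coverage_p01) {
  if (length(coverage_p01$x) == 0) stop("empty coverage")
  keep <- coverage_contains(coverage_p01, satellite_fixes$x, satellite_fixes$y)
  out <- satellite_fixes[keep, , drop = FALSE]
  if (!nrow(out)) stop("no satellite fixes remain inside the 1% coverage")
  rownames(out) <- NULL
  out
}

#' Method-comparison report across individuals
#'
#' Builds, per UD type (OD/RD) and contour level, the per-individual areas,
#' satellite:acoustic area ratios, group means with standard errors,
#' Bhattacharyya affinities, and the Bayesian probability that satellite
#' areas exceed acoustic areas.
#'
#' @param acoustic,satellite named lists (by individual) of `occurrence_dist`
#'   or `range_dist` objects for the same UD type. Individuals present in
#'   both lists are compared.
#' @param levels contour levels to report.
#' @param ud_type label ("OD" or "RD").
#' @param best_seed seed for the Bayesian comparison.
#' @param best_iter MCMC iterations.
#' @return object of class `method_comparison`: `table` (per individual x
#'   level) and `summary` (per level).
#' @export
compare_methods <- function(acoustic, satellite, levels = c(0.95, 0.50),
                            ud_type = "OD", best_seed = 1, best_iter = 10000) {
  ids <- intersect(names(acoustic), names(satellite))
  if (!length(ids)) stop("no individuals present in both methods")
  rows <- list(); summaries <- list()
  for (lv in levels) {
    lv_key <- sprintf("%g", lv)
    a_area <- vapply(ids, function(id)
      area_at_level(acoustic[[id]], lv), numeric(1))
    s_area <- vapply(ids, function(id)
      area_at_level(satellite[[id]], lv), numeric(1))
    ba <- vapply(ids, function(id)
      bhattacharyya_affinity(acoustic[[id]], satellite[[id]], level = lv),
      numeric(1))
    rows[[lv_key]] <- data.frame(
      ud_type = ud_type, level = lv, id = ids,
      area_acoustic_km2 = unname(a_area),
      area_satellite_km2 = unname(s_area),
      ratio_sat_ac = unname(s_area / a_area),
      ba = unname(ba))
    prob <- if (length(ids) >= 2) {
      best_two_group(s_area, a_area, n_iter = best_iter,
                     seed = best_seed)$prob_sat_greater
    } else NA_real_
    summaries[[lv_key]] <- data.frame(
      ud_type = ud_type, level = lv, n = length(ids),
      mean_acoustic_km2 = mean(a_area),
      se_acoustic = stats::sd(a_area) / sqrt(length(ids)),
      mean_satellite_km2 = mean(s_area),
      se_satellite = stats::sd(s_area) / sqrt(length(ids)),
      mean_ratio = mean(s_area / a_area),
      mean_ba = mean(ba),
      prob_sat_greater = prob)
  }
  structure(list(table = do.call(rbind, rows),
                 summary = do.call(rbind, summaries)),
            class = "method_comparison")
}

area_at_level <- function(ud, level) {
  i <- match(TRUE, abs(ud$areas$level - level) < 1e-9)
  if (is.na(i)) stop("UD does not carry level ", level)
  ud$areas$area_km2[i]
}

#' @export
print.method_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
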