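#' Acoustic detection-probability kernel
#'
#' Logistic detection-probability curve p(d) = 1 / (1 + exp(-(a + b d))),
#' strictly decreasing with distance (b < 0). `d50` is the conventional
#' detection range (50% of expected transmissions detected) and `d01` the
#' maximum (1%) range.
#'
#' @param a intercept (dimensionless).
#' @param b slope (per metre), must be negative.
#' @param habitat_class label for the habitat the kernel applies to.
#' @return object of class `detection_kernel` with fields `a`, `b`, `d50`,
#'   `d01`.
#' @export
detection_kernel <- function(a, b, habitat_class = "unknown") {
  if (!is.finite(a) || !is.finite(b) || b >= 0) {
    stop("detection kernel needs finite coefficients with negative slope")
  }
  structure(list(habitat_class = habitat_class, a = a, b = b,
                 d50 = -a / b,
                 d01 = (stats::qlogis(0.01) - a) / b),
            class = "detection_kernel")
}

#' @export
print.detection_kernel <- function(x, ...) {
  cat(sprintf("detection_kernel [%s]: a=%.4f, b=%.6f /m, d50=%.1f m, d01=%.1f m\n",
              x$habitat_class, x$a, x$b, x$d50, x$d01))
  invisible(x)
}

#' Detection probability at distance
#' @param kernel a [detection_kernel()].
#' @param d distance (m).
#' @return probabilities in (0, 1).
#' @export
kernel_prob <- function(kernel, d) stats::plogis(kernel$a + kernel$b * d)

#' Build a kernel from its 50% and 1% detection ranges
#'
#' Solves the two-point logistic system p(d50) = 0.5, p(d01) = 0.01:
#' b = -log(99) / (d01 - d50), a = -b * d50.
#'
#' @param d50,d01 detection ranges (m), d01 > d50 > 0.
#' @param habitat_class habitat label.
#' @return a [detection_kernel()].
#' @export
kernel_from_ranges <- function(d50, d01, habitat_class = "unknown") {
  stopifnot(d01 > d50, d50 > 0)
  b <- -log(99) / (d01 - d50)
  detection_kernel(-b * d50, b, habitat_class)
}

#' Filter raw acoustic detections
#'
#' Applies, in order: removal of exact duplicates (same tag, receiver, and
#' timestamp to the second); removal of detections before release; removal of
#' detections within the 24 h post-release acclimation window; removal of
#' detections inside any blackout window (e.g. receiver maintenance
#' disruptions); and finally removal of lone detections — a detection with no
#' other detection of the same tag, at any receiver, within one hour before
#' or after it.
#'
#' @param detections data.frame with `tag_id`, `receiver_id`, `timestamp`
#'   (POSIXct UTC).
#' @param deployments data.frame with `tag_id`, `release_time` (POSIXct), and
#'   release coordinates.
#' @param blackout_windows data.frame with `start`, `end` (POSIXct), or NULL.
#' @param acclimation_s post-release discard window (s), default 24 h.
#' @param lone_window_s lone-detection neighbourhood (s), default 1 h.
#' @return the filtered data.frame with attribute `"filter_report"`: counts
#'   removed per rule.
#' @export
filter_detections <- function(detections, deployments, blackout_windows = NULL,
                              acclimation_s = 86400, lone_window_s = 3600) {
  unknown <- setdiff(unique(detections$tag_id), deployments$tag_id)
  if (length(unknown)) {
    stop("detections reference tags with no deployment record: ",
         paste(unknown, collapse = ", "))
  }
  report <- c(duplicates = 0L, pre_release = 0L, acclimation = 0L,
              blackout = 0L, lone = 0L)
  d <- detections[order(detections$tag_id, detections$timestamp), , drop = FALSE]

  key <- paste(d$tag_id, d$receiver_id, format_utc(round(d$timestamp)))
  dup <- duplicated(key)
  report["duplicates"] <- sum(dup)
  d <- d[!dup, , drop = FALSE]

  rel <- deployments$release_time[match(d$tag_id, deployments$tag_id)]
  pre <- d$timestamp < rel
  report["pre_release"] <- sum(pre)
  d <- d[!pre, , drop = FALSE]; rel <- rel[!pre]

  acc <- d$timestamp < rel + acclimation_s
  report["acclimation"] <- sum(acc)
  d <- d[!acc, , drop = FALSE]

  if (!is.null(blackout_windows) && nrow(blackout_windows)) {
    inblk <- rep(FALSE, nrow(d))
    for (i in seq_len(nrow(blackout_windows))) {
      inblk <- inblk | (d$timestamp >= blackout_windows$start[i] &
                        d$timestamp <= blackout_windows$end[i])
    }
    report["blackout"] <- sum(inblk)
    d <- d[!inblk, , drop = FALSE]
  }

  # lone-detection rule, evaluated last across all receivers of each tag
  keep <- rep(TRUE, nrow(d))
  for (tg in unique(d$tag_id)) {
    idx <- which(d$tag_id == tg)
    tt <- as.numeric(d$timestamp[idx])
    if (length(tt) == 1) { keep[idx] <- FALSE; next }
    gap_prev <- c(Inf, diff(tt))
    gap_next <- c(diff(tt), Inf)
    keep[idx] <- gap_prev <= lone_window_s | gap_next <= lone_window_s
  }
  report["lone"] <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "filter_report") <- report
  d
}

#' Fit a detection kernel from range-test data
#'
#' Maximum-likelihood binomial logistic regression of detections/expected
#' against distance, via [stats::glm()].
#'
#' @param rangetest data.frame with `distance_m`, `n_expected`, `n_detected`
#'   (optionally restricted to one `habitat_class`).
#' @param habitat_class label stored on the kernel; when the table carries a
#'   `habitat_class` column, rows are subset to it.
#' @return a [detection_kernel()].
#' @export
fit_detection_kernel <- function(rangetest, habitat_class = "unknown") {
  if (!is.null(rangetest$habitat_class) &&
      habitat_class %in% rangetest$habitat_class) {
    rangetest <- rangetest[rangetest$habitat_class == habitat_class, , drop = FALSE]
  }
  rangetest <- rangetest[rangetest$n_expected > 0, , drop = FALSE]
  if (length(unique(rangetest$distance_m)) < 2) {
    stop("need range-test data at >= 2 distinct distances")
  }
  if (sum(rangetest$n_detected) == 0) {
    stop("all-zero detections: cannot fit a detection kernel")
  }
  fit <- suppressWarnings(stats::glm(
    cbind(n_detected, n_expected - n_detected) ~ distance_m,
    family = stats::binomial(), data = rangetest))
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[2] >= 0 || abs(cf[2]) > 1) {
    stop("detection-kernel fit failed (separation or non-decreasing curve); ",
         "coefficients: ", paste(signif(cf, 4), collapse = ", "))
  }
  k <- detection_kernel(unname(cf[1]), unname(cf[2]), habitat_class)
  k$fit <- fit
  k
}

#' Reassign detections to positions within the detection range
#'
#' Each detection is moved from the receiver coordinate to a random position
#' inside the receiver's detection range: bearing uniform on (0, 2pi), radius
#' drawn from a density proportional to d * p(d) on \[0, d01\] — a
#' uniform-in-area prior weighted by the detection-probability kernel, sampled
#' by rejection. Points falling on land are redrawn (cap `max_redraw`, else an
#' error naming the receiver).
#'
#' @param detections filtered detection table.
#' @param receivers receiver table (with `x`, `y`, `kernel_class`).
#' @param kernels named list of [detection_kernel()] by kernel class.
#' @param habitat habitat grid for the land test (NULL = all water).
#' @param radius_weight `"area"` (density proportional to d * p(d), default) or
#'   `"distance"` (proportional to p(d)).
#' @param seed integer seed.
#' @param max_redraw land-redraw cap per detection.
#' @return detections with added columns `x`, `y` (sampled position) and
#'   `radius_m` (distance from the receiver).
#' @export
relocate_detections <- function(detections, receivers, kernels, habitat = NULL,
                                radius_weight = c("area", "distance"),
                                seed = 1, max_redraw = 1000) {
  radius_weight <- match.arg(radius_weight)
  set.seed(seed)
  ridx <- match(detections$receiver_id, receivers$receiver_id)
  if (anyNA(ridx)) stop("detections reference unknown receivers")
  kcls <- receivers$kernel_class[ridx]
  if (any(!kcls %in% names(kernels))) {
    stop("no detection kernel for habitat class: ",
         paste(setdiff(unique(kcls), names(kernels)), collapse = ", "))
  }
  n <- nrow(detections)
  out_x <- numeric(n); out_y <- numeric(n); out_r <- numeric(n)
  for (cls in unique(kcls)) {
    k <- kernels[[cls]]
    sel <- which(kcls == cls)
    # rejection envelope for the radius density on [0, d01]
    dgrid <- seq(0, k$d01, length.out = 512)
    wfun <- if (radius_weight == "area") {
      function(d) d * kernel_prob(k, d)
    } else {
      function(d) kernel_prob(k, d)
    }
    M <- max(wfun(dgrid)) * 1.001
    draw_radii <- function(m) {
      out <- numeric(0)
      while (length(out) < m) {
        cand <- stats::runif(2 * (m - length(out)) + 16, 0, k$d01)
        acc <- stats::runif(length(cand)) < wfun(cand) / M
        out <- c(out, cand[acc])
      }
      out[seq_len(m)]
    }
    rx <- receivers$x[ridx[sel]]; ry <- receivers$y[ridx[sel]]
    rad <- draw_radii(length(sel))
    th <- stats::runif(length(sel), 0, 2 * pi)
    px <- rx + rad * cos(th); py <- ry + rad * sin(th)
    bad <- which(!on_water(habitat, px, py))
    tries <- 0
    while (length(bad)) {
      tries <- tries + 1
      if (tries > max_redraw) {
        stop("land-redraw cap exceeded for receiver ",
             detections$receiver_id[sel[bad[1]]])
      }
      rad[bad] <- draw_radii(length(bad))
      th2 <- stats::runif(length(bad), 0, 2 * pi)
      px[bad] <- rx[bad] + rad[bad] * cos(th2)
      py[bad] <- ry[bad] + rad[bad] * sin(th2)
      bad <- bad[!on_water(habitat, px[bad], py[bad])]
    }
    out_x[sel] <- px; out_y[sel] <- py; out_r[sel] <- rad
  }
  detections$x <- out_x; detections$y <- out_y; detections$radius_m <- out_r
  detections
}

#' Centres of activity from relocated detections
#'
#' Mean-position COAs in fixed time bins aligned to clock half-hours (UTC):
#' the COA is the arithmetic mean of the relocated detection positions in the
#' bin, labelled at the bin midpoint. The error radius is the mean distance
#' from each contributing detection's receiver to its relocated position.
#'
#' @param relocated a [relocate_detections()] table.
#' @param bin_width_s bin width (s), default 30 minutes.
#' @return data.frame of class `coa_table`: `tag_id`, `time` (bin midpoint),
#'   `x`, `y`, `n_detections`, `error_radius_m`.
#' @export
compute_coas <- function(relocated, bin_width_s = 1800) {
  if (nrow(relocated) == 0) {
    out <- data.frame(tag_id = character(0),
                      time = as.POSIXct(character(0), tz = "UTC"),
                      x = numeric(0), y = numeric(0),
                      n_detections = integer(0), error_radius_m = numeric(0))
    class(out) <- c("coa_table", "data.frame")
    return(out)
  }
  bin <- floor(as.numeric(relocated$timestamp) / bin_width_s)
  key <- interaction(relocated$tag_id, bin, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  out <- data.frame(
    tag_id = as.character(tapply(relocated$tag_id, key, `[`, 1)),
    time = as.POSIXct(agg(bin, function(v) v[1]) * bin_width_s + bin_width_s / 2,
                      origin = "1970-01-01", tz = "UTC"),
    x = agg(relocated$x, mean),
    y = agg(relocated$y, mean),
    n_detections = as.integer(agg(relocated$x, length)),
    error_radius_m = agg(relocated$radius_m, mean),
    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coa_table", "data.frame")
  out
}
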