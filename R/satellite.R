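argos_class_order <- c("3", "2", "1", "0", "A", "B", "Z")

#' Prefilter raw Argos fixes
#'
#' Applies, in order: validation of location classes; removal of LC Z
#' (nominally invalid) fixes; removal of duplicate transmissions (same tag and
#' timestamp), keeping the numerically better class (3 > 2 > 1 > 0 > A > B);
#' removal of fixes within the first 24 h post-release; and removal of
#' implausible leading fixes — initial fixes whose implied speed from the
#' release position exceeds `v_max`.
#'
#' @param fixes data.frame with `tag_id`, `timestamp` (POSIXct), `lc`, `x`,
#'   `y` (planar m).
#' @param deployments data.frame with `tag_id`, `release_time`, `x`, `y`
#'   (release position, m).
#' @param v_max speed bound (m/s) for the leading-fix rule.
#' @param acclimation_s post-release discard window (s).
#' @return filtered fixes with attribute `"filter_report"`.
#' @export
prefilter_argos <- function(fixes, deployments, v_max = 2,
                            acclimation_s = 86400) {
  bad <- setdiff(unique(fixes$lc), argos_class_order)
  if (length(bad)) stop("unknown Argos location class: ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(fixes$tag_id), deployments$tag_id)
  if (length(unknown)) stop("fixes reference tags with no deployment: ",
                            paste(unknown, collapse = ", "))
  report <- c(lc_z = 0L, duplicates = 0L, acclimation = 0L, leading = 0L)

  z <- fixes$lc == "Z"
  report["lc_z"] <- sum(z)
  f <- fixes[!z, , drop = FALSE]

  # duplicates: order by class quality within tag+timestamp, keep the best
  rank <- match(f$lc, argos_class_order)
  f <- f[order(f$tag_id, f$timestamp, rank), , drop = FALSE]
  dup <- duplicated(paste(f$tag_id, format_utc(f$timestamp)))
  report["duplicates"] <- sum(dup)
  f <- f[!dup, , drop = FALSE]

  rel <- deployments$release_time[match(f$tag_id, deployments$tag_id)]
  acc <- f$timestamp < rel + acclimation_s
  report["acclimation"] <- sum(acc)
  f <- f[!acc, , drop = FALSE]

  # implied speed of leading fixes is taken from the end of the acclimation
  # window (the earliest time the animal could first be heard from)
  keep <- rep(TRUE, nrow(f))
  for (tg in unique(f$tag_id)) {
    idx <- which(f$tag_id == tg)
    dep <- deployments[deployments$tag_id == tg, ]
    t0 <- as.numeric(dep$release_time) + acclimation_s
    for (i in idx) {
      dt <- as.numeric(f$timestamp[i]) - t0
      dist <- sqrt((f$x[i] - dep$x)^2 + (f$y[i] - dep$y)^2)
      if (dt > 0 && dist / dt > v_max) keep[i] <- FALSE else break
    }
  }
  report["leading"] <- sum(!keep)
  f <- f[keep, , drop = FALSE]
  rownames(f) <- NULL
  attr(f, "filter_report") <- report
  f
}

#' Speed-distance-angle outlier filter
#'
#' Iterates to a fixed point: first removes fixes whose implied speed exceeds
#' `v_max` on both adjacent segments, then removes spike fixes — an internal
#' turning angle below `angles[1]` with either adjacent step longer than
#' `dists[1]`, or below `angles[2]` with either step longer than `dists[2]`.
#'
#' @param fixes data.frame (single tag) with `timestamp`, `x`, `y`, sorted by
#'   time.
#' @param v_max speed bound (m/s).
#' @param angles internal angle thresholds (degrees), tight and loose.
#' @param dists step-length thresholds (m) paired with `angles`.
#' @return the filtered data.frame (a fixed point of the filter).
#' @export
sda_filter <- function(fixes, v_max = 2, angles = c(15, 25),
                       dists = c(1500, 3000)) {
  f <- fixes[order(fixes$timestamp), , drop = FALSE]
  repeat {
    changed <- FALSE
    # speed rule: drop fixes that are fast on both sides
    repeat {
      n <- nrow(f)
      if (n < 3) break
      tt <- as.numeric(f$timestamp)
      sp <- sqrt(diff(f$x)^2 + diff(f$y)^2) / pmax(diff(tt), 1e-9)
      bad <- which(c(FALSE, sp) > v_max & c(sp, FALSE) > v_max)
      if (!length(bad)) break
      f <- f[-bad[1], , drop = FALSE]
      changed <- TRUE
    }
    # angle/distance spike rule
    n <- nrow(f)
    if (n >= 3) {
      dx1 <- f$x[2:(n - 1)] - f$x[1:(n - 2)]
      dy1 <- f$y[2:(n - 1)] - f$y[1:(n - 2)]
      dx2 <- f$x[3:n] - f$x[2:(n - 1)]
      dy2 <- f$y[3:n] - f$y[2:(n - 1)]
      s1 <- sqrt(dx1^2 + dy1^2); s2 <- sqrt(dx2^2 + dy2^2)
      # internal angle at the vertex: angle between the two edges meeting there
      cosint <- (-(dx1 * dx2 + dy1 * dy2)) / pmax(s1 * s2, 1e-12)
      ang <- acos(pmin(pmax(cosint, -1), 1)) * 180 / pi
      spike <- (ang < angles[1] & (s1 > dists[1] | s2 > dists[1])) |
               (ang < angles[2] & (s1 > dists[2] | s2 > dists[2]))
      bad <- which(spike)
      if (length(bad)) {
        f <- f[-(bad[1] + 1), , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (nrow(f) < 2) stop("fewer than 2 fixes remain after the SDA filter")
  rownames(f) <- NULL
  f
}

# --- CTCRW (integrated Ornstein-Uhlenbeck velocity) state-space machinery ---

# Per-axis transition and process noise over a step of length dt:
# state (position, velocity); dv = -beta v dt + sigma dW; dx = v dt.
ctcrw_disc <- function(beta, sigma, dt) {
  eb <- exp(-beta * dt)
  Phi <- rbind(c(1, (1 - eb) / beta), c(0, eb))
  s2 <- sigma^2
  qvv <- s2 / (2 * beta) * (1 - eb^2)
  qxv <- s2 / (2 * beta^2) * (1 - 2 * eb + eb^2)
  qxx <- s2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
  list(Phi = Phi, Q = rbind(c(qxx, qxv), c(qxv, qvv)))
}

# Kalman filter for one axis; returns loglik and (optionally) stored moments.
ctcrw_filter_axis <- function(z, tt, meas_sd, beta, sigma, keep = FALSE) {
  n <- length(z)
  m <- c(z[1], 0)
  P <- rbind(c(meas_sd[1]^2 + 1e6, 0), c(0, sigma^2 / (2 * beta) * 10))
  ll <- 0
  if (keep) {
    mp <- matrix(0, n, 2); Pp <- array(0, c(n, 2, 2))
    mf <- matrix(0, n, 2); Pf <- array(0, c(n, 2, 2))
    Phis <- array(0, c(n, 2, 2))
  }
  for (i in seq_len(n)) {
    if (i > 1) {
      d <- ctcrw_disc(beta, sigma, tt[i] - tt[i - 1])
      m <- d$Phi %*% m
      P <- d$Phi %*% P %*% t(d$Phi) + d$Q
      if (keep) Phis[i, , ] <- d$Phi
    }
    if (keep) { mp[i, ] <- m; Pp[i, , ] <- P }
    S <- P[1, 1] + meas_sd[i]^2
    v <- z[i] - m[1]
    ll <- ll + stats::dnorm(v, 0, sqrt(S), log = TRUE)
    K <- P[, 1] / S
    m <- m + K * v
    P <- P - K %o% P[1, ]
    P <- (P + t(P)) / 2
    if (keep) { mf[i, ] <- m; Pf[i, , ] <- P }
  }
  if (!keep) return(list(loglik = ll))
  # Rauch-Tung-Striebel smoother
  ms <- mf; Ps <- Pf
  for (i in (n - 1):1) {
    if (n < 2) break
    Ppn <- Pp[i + 1, , ]
    Ppn <- Ppn + diag(1e-9 * max(diag(Ppn), 1e-12), 2)
    G <- Pf[i, , ] %*% t(Phis[i + 1, , ]) %*% solve(Ppn)
    ms[i, ] <- mf[i, ] + G %*% (ms[i + 1, ] - mp[i + 1, ])
    Ps[i, , ] <- Pf[i, , ] + G %*% (Ps[i + 1, , ] - Pp[i + 1, , ]) %*% t(G)
  }
  list(loglik = ll, mean = ms, var_x = pmax(Ps[, 1, 1], 1e-12),
       filt_mean = mf)
}

#' Fit a continuous-time correlated random walk state-space model
#'
#' Latent state per axis is (position, velocity) with Ornstein-Uhlenbeck
#' velocity (autocorrelation parameter beta, process intensity sigma);
#' exact transition matrices handle irregular fix intervals. Measurements are
#' the planar fix coordinates with Gaussian error whose standard deviation is
#' set per Argos location class by `class_sd_map` (configuration, not an
#' estimate). beta and sigma are estimated by maximizing the Kalman-filter
#' likelihood from several starting points.
#'
#' @param fixes data.frame (one tag) with `timestamp`, `lc`, `x`, `y`;
#'   strictly increasing timestamps, >= 10 fixes.
#' @param class_sd_map named per-class measurement sds (m).
#' @param n_starts number of optimizer starts (>= 3).
#' @return object of class `ctcrw_fit`: `beta` (1/s), `sigma_proc`, the
#'   class-sd map used, `loglik`, `converged`, and the data.
#' @export
fit_ctcrw_ssm <- function(fixes, class_sd_map = default_class_sds(),
                          n_starts = 3) {
  f <- fixes[order(fixes$timestamp), , drop = FALSE]
  if (nrow(f) < 10) stop("need >= 10 fixes to fit the CTCRW SSM")
  tt <- as.numeric(f$timestamp)
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  meas_sd <- unname(class_sd_map[f$lc])
  if (anyNA(meas_sd)) stop("class_sd_map missing a class present in the data")
  meas_sd <- pmax(meas_sd, 1e-6)

  negll <- function(par) {
    beta <- exp(par[1]); sigma <- exp(par[2])
    if (!is.finite(beta) || !is.finite(sigma)) return(1e10)
    # keep the velocity timescale between ~1 s and ~10x the track span
    if (beta > 1 || beta < 1 / (10 * (tt[length(tt)] - tt[1] + 1))) return(1e10)
    if (sigma > 100 || sigma < 1e-6) return(1e10)
    llx <- ctcrw_filter_axis(f$x, tt, meas_sd, beta, sigma)$loglik
    lly <- ctcrw_filter_axis(f$y, tt, meas_sd, beta, sigma)$loglik
    v <- -(llx + lly)
    if (!is.finite(v)) 1e10 else v
  }
  med_dt <- stats::median(diff(tt))
  starts <- list(c(log(1 / med_dt), log(0.05)),
                 c(log(1 / (10 * med_dt)), log(0.5)),
                 c(log(1 / 3600), log(0.01)))
  if (n_starts > 3) {
    for (i in seq_len(n_starts - 3)) {
      starts[[3 + i]] <- c(log(1 / med_dt) + stats::rnorm(1),
                           stats::rnorm(1, log(0.1), 1))
    }
  }
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, negll, method = "Nelder-Mead",
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    stop("CTCRW optimization failed from all starting points")
  }
  structure(list(tag_id = if (!is.null(f$tag_id)) f$tag_id[1] else NA_character_,
                 beta = exp(best$par[1]), sigma_proc = exp(best$par[2]),
                 class_sd_map = class_sd_map, loglik = -best$value,
                 converged = best$convergence == 0,
                 fixes = f, times = tt, meas_sd = meas_sd),
            class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf(
    "ctcrw_fit %s: beta=%.3e /s (tau_vel=%.2f h), sigma=%.4g, logLik=%.2f%s\n",
    x$tag_id, x$beta, 1 / x$beta / 3600, x$sigma_proc, x$loglik,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
logLik.ctcrw_fit <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Brute-force CTCRW likelihood (small tracks)
#'
#' Builds the joint Gaussian distribution of all observed positions by
#' explicit propagation of the state mean/covariance (no recursive filtering)
#' and evaluates the multivariate-normal density. An independent cross-check
#' of the Kalman likelihood; quadratic memory, intended for <= ~10 fixes.
#'
#' @param z observations for one axis; @param tt times (s);
#' @param meas_sd per-fix measurement sds; @param beta,sigma CTCRW parameters.
#' @return log-likelihood for that axis.
#' @export
ctcrw_loglik_bruteforce <- function(z, tt, meas_sd, beta, sigma) {
  n <- length(z)
  # joint covariance of stacked states via the linear recursion
  mu <- matrix(0, 2 * n, 1)
  mu[1] <- z[1]
  Sig <- matrix(0, 2 * n, 2 * n)
  Sig[1:2, 1:2] <- rbind(c(meas_sd[1]^2 + 1e6, 0),
                         c(0, sigma^2 / (2 * beta) * 10))
  for (i in 2:n) {
    d <- ctcrw_disc(beta, sigma, tt[i] - tt[i - 1])
    ii <- (2 * i - 1):(2 * i)
    prev <- 1:(2 * (i - 1))
    cross <- Sig[prev, (2 * i - 3):(2 * i - 2), drop = FALSE] %*% t(d$Phi)
    Sig[prev, ii] <- cross
    Sig[ii, prev] <- t(cross)
    Pi1 <- Sig[(2 * i - 3):(2 * i - 2), (2 * i - 3):(2 * i - 2)]
    Sig[ii, ii] <- d$Phi %*% Pi1 %*% t(d$Phi) + d$Q
    mu[ii] <- d$Phi %*% mu[(2 * i - 3):(2 * i - 2)]
  }
  pos <- seq(1, 2 * n, by = 2)
  C <- Sig[pos, pos] + diag(meas_sd^2, n)
  r <- z - mu[pos]
  ch <- chol(C)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

#' Smoothed locations with standard errors, post-filtered
#'
#' Runs the Kalman smoother at the observation times, reports per-axis
#' standard errors and their minimum, then drops locations on land and
#' locations whose smaller standard error exceeds `se_cap`.
#'
#' @param fit a converged [fit_ctcrw_ssm()].
#' @param habitat habitat grid for the land test (NULL = all water).
#' @param se_cap maximum allowed `se_min` (m), default 3 km.
#' @return data.frame of class `fitted_locations`: `tag_id`, `timestamp`,
#'   `x`, `y`, `se_x`, `se_y`, `se_min`; attribute `"drop_report"` counts the
#'   locations removed by each rule.
#' @export
predict_and_postfilter <- function(fit, habitat = NULL, se_cap = 3000) {
  stopifnot(inherits(fit, "ctcrw_fit"))
  if (!fit$converged) stop("CTCRW fit did not converge")
  sx <- ctcrw_filter_axis(fit$fixes$x, fit$times, fit$meas_sd,
                          fit$beta, fit$sigma_proc, keep = TRUE)
  sy <- ctcrw_filter_axis(fit$fixes$y, fit$times, fit$meas_sd,
                          fit$beta, fit$sigma_proc, keep = TRUE)
  out <- data.frame(tag_id = fit$tag_id,
                    timestamp = fit$fixes$timestamp,
                    x = sx$mean[, 1], y = sy$mean[, 1],
                    se_x = sqrt(sx$var_x), se_y = sqrt(sy$var_x))
  out$se_min <- pmin(out$se_x, out$se_y)
  land <- !on_water(habitat, out$x, out$y)
  out <- out[!land, , drop = FALSE]
  high <- out$se_min > se_cap
  out <- out[!high, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_report") <- c(on_land = sum(land), se_over_cap = sum(high))
  class(out) <- c("fitted_locations", "data.frame")
  out
}
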