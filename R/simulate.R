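#' Simulate a confined foraging track (OU / OUF ground truth)
#'
#' Exact-discretization simulation of an Ornstein-Uhlenbeck position process
#' around a home centre (or, when `tau_vel` is given, an OUF process with
#' autocorrelated velocities). Steps landing on land are redrawn (up to
#' `max_redraw` times, else the animal holds position), which confines the
#' track to water. A stationary draw initializes the state and a burn-in is
#' discarded so recorded positions start in (truncated) stationarity.
#'
#' @param habitat a [make_habitat()] grid, or NULL for unconstrained water.
#' @param sigma2 stationary position variance per axis (m^2).
#' @param tau_pos position autocorrelation timescale (s).
#' @param tau_vel optional velocity timescale (s) for an OUF process; must be
#'   < `tau_pos`.
#' @param duration_s track duration (s).
#' @param dt_s sampling step (s); should be much smaller than `tau_pos`.
#' @param home home centre c(x, y) in m; defaults to the habitat's.
#' @param start_time POSIXct UTC start of the recorded track.
#' @param tag_id tag identifier.
#' @param seed integer seed.
#' @param burn_in number of discarded initial steps.
#' @param max_redraw land-rejection redraw cap per step.
#' @return object of class `true_track`: vectors `t` (s), `time` (POSIXct),
#'   `x`, `y` (m), plus the generating parameters.
#' @export
simulate_ou_track <- function(habitat = NULL, sigma2, tau_pos, tau_vel = NULL,
                              duration_s, dt_s = 60,
                              home = if (!is.null(habitat)) habitat$home_centre else c(0, 0),
                              start_time = as.POSIXct("2017-05-02 00:00:00", tz = "UTC"),
                              tag_id = "tag1", seed = 1,
                              burn_in = 100, max_redraw = 100) {
  stopifnot(sigma2 > 0, tau_pos > 0, dt_s > 0, duration_s > 0)
  if (!is.null(tau_vel) && tau_vel >= tau_pos) {
    stop("tau_vel must be smaller than tau_pos")
  }
  if (!on_water(habitat, home[1], home[2])) stop("home centre lies on land")
  set.seed(seed)
  n <- floor(duration_s / dt_s) + 1
  total <- n + burn_in

  if (is.null(tau_vel)) {
    phi <- exp(-dt_s / tau_pos)
    innov_sd <- sqrt(sigma2 * (1 - phi^2))
    x <- numeric(total); y <- numeric(total)
    x[1] <- home[1] + stats::rnorm(1, sd = sqrt(sigma2))
    y[1] <- home[2] + stats::rnorm(1, sd = sqrt(sigma2))
    for (i in 2:total) {
      px <- home[1] + phi * (x[i - 1] - home[1])
      py <- home[2] + phi * (y[i - 1] - home[2])
      for (k in seq_len(max_redraw)) {
        cx <- px + stats::rnorm(1, sd = innov_sd)
        cy <- py + stats::rnorm(1, sd = innov_sd)
        if (on_water(habitat, cx, cy)) break
        cx <- x[i - 1]; cy <- y[i - 1]
      }
      x[i] <- cx; y[i] <- cy
    }
  } else {
    tr <- ouf_transition(tau_pos, tau_vel, sigma2, dt_s)
    zx <- c(stats::rnorm(1, sd = sqrt(sigma2)),
            stats::rnorm(1, sd = sqrt(sigma2 / (tau_pos * tau_vel))))
    zy <- c(stats::rnorm(1, sd = sqrt(sigma2)),
            stats::rnorm(1, sd = sqrt(sigma2 / (tau_pos * tau_vel))))
    x <- numeric(total); y <- numeric(total)
    x[1] <- home[1] + zx[1]; y[1] <- home[2] + zy[1]
    for (i in 2:total) {
      mx <- tr$Phi %*% zx; my <- tr$Phi %*% zy
      for (k in seq_len(max_redraw)) {
        cx <- mx + tr$L %*% stats::rnorm(2)
        cy <- my + tr$L %*% stats::rnorm(2)
        if (on_water(habitat, home[1] + cx[1], home[2] + cy[1])) break
        cx <- zx; cy <- zy
      }
      zx <- as.numeric(cx); zy <- as.numeric(cy)
      x[i] <- home[1] + zx[1]; y[i] <- home[2] + zy[1]
    }
  }
  keep <- (burn_in + 1):total
  t_rel <- (seq_along(keep) - 1) * dt_s
  structure(list(tag_id = tag_id, t = t_rel,
                 time = start_time + t_rel,
                 x = x[keep], y = y[keep],
                 home = home, sigma2 = sigma2, tau_pos = tau_pos,
                 tau_vel = tau_vel, dt_s = dt_s, seed = seed),
            class = "true_track")
}

# Exact transition of the stationary OUF state (position, velocity):
# distinct relaxation timescales tau_pos > tau_vel; Phi = expm(A dt) via
# eigen-decomposition, innovation covariance from stationarity.
ouf_transition <- function(tau_pos, tau_vel, sigma2, dt) {
  l1 <- -1 / tau_pos; l2 <- -1 / tau_vel
  V <- rbind(c(1, 1), c(l1, l2))
  Phi <- V %*% diag(exp(c(l1, l2) * dt)) %*% solve(V)
  Pinf <- diag(c(sigma2, sigma2 / (tau_pos * tau_vel)))
  Q <- Pinf - Phi %*% Pinf %*% t(Phi)
  Q <- (Q + t(Q)) / 2
  list(Phi = Phi, L = t(chol(Q + diag(1e-12, 2))))
}

#' @export
print.true_track <- function(x, ...) {
  cat(sprintf("true_track %s: %d positions at dt=%gs, sigma2=%g m^2, tau_pos=%gs%s\n",
              x$tag_id, length(x$x), x$dt_s, x$sigma2, x$tau_pos,
              if (is.null(x$tau_vel)) "" else sprintf(", tau_vel=%gs", x$tau_vel)))
  invisible(x)
}

# Linear interpolation of a track at arbitrary times (s from track start)
track_position_at <- function(track, t_query) {
  list(x = stats::approx(track$t, track$x, t_query, rule = 2)$y,
       y = stats::approx(track$t, track$y, t_query, rule = 2)$y)
}

#' Place acoustic receivers on water
#'
#' @param habitat a [make_habitat()] grid.
#' @param n number of receivers.
#' @param strategy `"random"` (habitat-weighted: reef, seagrass and lagoon
#'   cells are strongly preferred over open sand, emulating arrays placed
#'   around islands and foraging beds), `"grid"` (near-uniform lattice
#'   snapped to water), or `"clustered"`.
#' @param seed integer seed.
#' @return data.frame: `receiver_id`, `x`, `y` (m), `habitat_class`, and
#'   `kernel_class` ("reef" for reef/seagrass, "sand" for sand/lagoon).
#' @export
place_receivers <- function(habitat, n = 63, strategy = c("random", "grid", "clustered"),
                            seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  set.seed(seed)
  g <- habitat$grid
  water_idx <- which(habitat$water, arr.ind = TRUE)
  if (nrow(water_idx) < n) stop("not enough water cells for ", n, " receivers")
  cc <- cell_centres(g)
  wx <- cc$x[water_idx[, 2]]; wy <- cc$y[water_idx[, 1]]
  pick <- switch(strategy,
    random = {
      # receivers target structured habitat (reef/seagrass/lagoon) the way
      # real coastal arrays ring islands and foraging beds
      cls <- habitat$classes[water_idx]
      w <- ifelse(habitat$levels[cls] %in% c("reef", "seagrass", "lagoon"),
                  12, 1)
      sample.int(nrow(water_idx), n, prob = w)
    },
    grid = {
      side <- ceiling(sqrt(n))
      ext_x <- range(wx); ext_y <- range(wy)
      gx <- seq(ext_x[1], ext_x[2], length.out = side + 2)[2:(side + 1)]
      gy <- seq(ext_y[1], ext_y[2], length.out = side + 2)[2:(side + 1)]
      targets <- expand.grid(x = gx, y = gy)[seq_len(n), ]
      used <- integer(0)
      vapply(seq_len(n), function(i) {
        d2 <- (wx - targets$x[i])^2 + (wy - targets$y[i])^2
        d2[used] <- Inf
        k <- which.min(d2); used <<- c(used, k); k
      }, integer(1))
    },
    clustered = {
      centres <- sample.int(nrow(water_idx), max(3, ceiling(n / 12)))
      probs <- rowSums(vapply(centres, function(k) {
        stats::dnorm(sqrt((wx - wx[k])^2 + (wy - wy[k])^2),
                     sd = 0.06 * g$n_cols * g$cell_size)
      }, numeric(length(wx))))
      sample.int(nrow(water_idx), n, prob = probs)
    })
  cls <- habitat$levels[habitat$classes[water_idx[pick, , drop = FALSE]]]
  data.frame(receiver_id = sprintf("R%03d", seq_len(n)),
             x = wx[pick], y = wy[pick],
             habitat_class = cls,
             kernel_class = ifelse(cls %in% c("reef", "seagrass"),
                                   "reef", "sand"),
             stringsAsFactors = FALSE)
}

#' Simulate an acoustic range test
#'
#' Transmissions at fixed distances are detected as binomial draws under a
#' detection-probability kernel; the test design mirrors tethered-transmitter
#' range tests at 0/250/500/750 m.
#'
#' @param kernel a [detection_kernel()].
#' @param distances test distances (m), all >= 0.
#' @param n_per_distance expected transmissions per distance, >= 1.
#' @param seed integer seed.
#' @return data.frame: `habitat_class`, `distance_m`, `n_expected`,
#'   `n_detected`.
#' @export
simulate_range_test <- function(kernel, distances = c(0, 250, 500, 750),
                                n_per_distance = 100, seed = 1) {
  stopifnot(inherits(kernel, "detection_kernel"))
  if (any(distances < 0)) stop("range-test distances must be >= 0")
  if (n_per_distance < 1) stop("n_per_distance must be >= 1")
  set.seed(seed)
  p <- kernel_prob(kernel, distances)
  data.frame(habitat_class = kernel$habitat_class,
             distance_m = distances,
             n_expected = n_per_distance,
             n_detected = stats::rbinom(length(distances), n_per_distance, p),
             stringsAsFactors = FALSE)
}

#' Simulate acoustic detections of a track by a receiver array
#'
#' Transmission times follow successive uniform delays (default U(50, 130) s,
#' mean 90 s). Each transmission is detected independently by each receiver
#' with probability given by that receiver's habitat kernel at the
#' transmitter-receiver distance; one transmission can be logged by several
#' receivers.
#'
#' @param track a [simulate_ou_track()] result.
#' @param receivers a [place_receivers()] table.
#' @param kernels named list of [detection_kernel()] objects, indexed by
#'   `kernel_class`.
#' @param delay_range_s transmitter delay interval (s).
#' @param seed integer seed.
#' @return data.frame: `tag_id`, `receiver_id`, `timestamp` (POSIXct UTC).
#' @export
simulate_acoustic_detections <- function(track, receivers, kernels,
                                         delay_range_s = c(50, 130), seed = 1) {
  if (nrow(receivers) == 0) {
    return(data.frame(tag_id = character(0), receiver_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC")))
  }
  set.seed(seed)
  dur <- max(track$t)
  n_max <- ceiling(dur / delay_range_s[1]) + 10
  tx <- cumsum(stats::runif(n_max, delay_range_s[1], delay_range_s[2]))
  tx <- tx[tx <= dur]
  pos <- track_position_at(track, tx)
  out_tag <- character(0); out_rec <- character(0); out_t <- numeric(0)
  for (r in seq_len(nrow(receivers))) {
    k <- kernels[[receivers$kernel_class[r]]]
    if (is.null(k)) stop("no kernel for class ", receivers$kernel_class[r])
    d <- sqrt((pos$x - receivers$x[r])^2 + (pos$y - receivers$y[r])^2)
    near <- which(d <= k$d01 * 1.5)
    if (!length(near)) next
    p <- kernel_prob(k, d[near])
    hit <- near[stats::runif(length(near)) < p]
    if (length(hit)) {
      out_tag <- c(out_tag, rep(track$tag_id, length(hit)))
      out_rec <- c(out_rec, rep(receivers$receiver_id[r], length(hit)))
      out_t <- c(out_t, tx[hit])
    }
  }
  ord <- order(out_t)
  data.frame(tag_id = out_tag[ord], receiver_id = out_rec[ord],
             timestamp = track$time[1] + out_t[ord],
             stringsAsFactors = FALSE)
}

#' Default Argos location-class mix
#'
#' Chosen so LC 3+2 make up ~6% of fixes and LC 0-3 ~12%, with the remaining
#' mass split across A/B/Z — the class mix juvenile-turtle Argos tracks
#' typically show in shallow coastal water.
#' @return named numeric vector over classes 3,2,1,0,A,B,Z summing to 1.
#' @export
default_class_probs <- function() {
  c(`3` = 0.02, `2` = 0.04, `1` = 0.03, `0` = 0.03,
    A = 0.30, B = 0.52, Z = 0.06)
}

#' Default per-class Argos error standard deviations (m)
#'
#' Consistent with published class error bounds (<250 m for LC 3 up to
#' kilometres for LC B); LC Z, nominally invalid, gets the largest spread.
#' @return named numeric vector (m).
#' @export
default_class_sds <- function() {
  c(`3` = 150, `2` = 350, `1` = 1000, `0` = 2500,
    A = 2500, B = 5000, Z = 10000)
}

#' Simulate Argos satellite fixes along a track
#'
#' Fix times follow a Poisson process (surfacing-limited transmission is
#' subsumed into the rate); each fix gets a location class from `class_probs`
#' and isotropic Gaussian position noise with the class standard deviation.
#'
#' @param track a [simulate_ou_track()] result.
#' @param fixes_per_day Poisson rate of fixes.
#' @param class_probs named probabilities over classes 3,2,1,0,A,B,Z.
#' @param class_sd_m named per-class error sds (m), all >= 0.
#' @param proj a [tm_projection()] used to report lon/lat.
#' @param seed integer seed.
#' @return data.frame: `tag_id`, `timestamp`, `lc`, `lon`, `lat`, `x`, `y`.
#' @export
simulate_argos_fixes <- function(track, fixes_per_day = 3,
                                 class_probs = default_class_probs(),
                                 class_sd_m = default_class_sds(),
                                 proj = tm_projection(), seed = 1) {
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  if (any(class_sd_m < 0)) stop("class error sds must be >= 0")
  need <- c("3", "2", "1", "0", "A", "B", "Z")
  if (!all(need %in% names(class_probs)) || !all(need %in% names(class_sd_m))) {
    stop("class_probs and class_sd_m must cover classes 3,2,1,0,A,B,Z")
  }
  set.seed(seed)
  dur_days <- max(track$t) / 86400
  n <- stats::rpois(1, fixes_per_day * dur_days)
  tq <- sort(stats::runif(n, 0, max(track$t)))
  pos <- track_position_at(track, tq)
  lc <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
  sd <- unname(class_sd_m[lc])
  px <- pos$x + stats::rnorm(n, sd = sd)
  py <- pos$y + stats::rnorm(n, sd = sd)
  ll <- project_coordinates(proj, px, py, "inverse")
  data.frame(tag_id = track$tag_id, timestamp = track$time[1] + tq,
             lc = lc, lon = ll$x, lat = ll$y, x = px, y = py,
             stringsAsFactors = FALSE)
}
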