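#' Iterative speed-outlier filter
#'
#' Repeatedly removes the location implying the largest above-threshold speed
#' (on either adjacent segment) until no implied speed exceeds `v_max`.
#'
#' @param locations data.frame with `x`, `y` and `time` (POSIXct) or `t` (s).
#' @param v_max speed bound (m/s); `Inf` disables the filter.
#' @return the filtered data.frame.
#' @export
speed_outlier_filter <- function(locations, v_max = 2) {
  f <- locations
  tt <- loc_times(f)
  ord <- order(tt)
  f <- f[ord, , drop = FALSE]; tt <- tt[ord]
  if (nrow(f) < 2) stop("need >= 2 locations")
  repeat {
    n <- nrow(f)
    if (n < 2) stop("fewer than 2 locations survive the speed filter")
    sp <- sqrt(diff(f$x)^2 + diff(f$y)^2) / pmax(diff(tt), 1e-9)
    if (!any(sp > v_max)) break
    # the fastest segment joins locations k and k+1; the outlier is the
    # endpoint that is also fast on its other side
    k <- which.max(sp)
    other <- function(i) {  # speed of location i's other adjacent segment
      if (i == k) { if (i > 1) sp[i - 1] else -Inf }
      else { if (i <= length(sp)) sp[i] else -Inf }
    }
    drop <- if (other(k) > other(k + 1)) k else k + 1
    f <- f[-drop, , drop = FALSE]
    tt <- tt[-drop]
  }
  rownames(f) <- NULL
  f
}

loc_times <- function(locations) {
  if (!is.null(locations$t)) return(as.numeric(locations$t))
  if (!is.null(locations$time)) return(as.numeric(locations$time))
  if (!is.null(locations$timestamp)) return(as.numeric(locations$timestamp))
  stop("locations need a time column (t, time, or timestamp)")
}

# ---- exact Gaussian likelihoods of the isotropic CTMM candidates ----

# IID: independent bivariate normal around the mean.
ctmm_loglik_iid <- function(x, y, sigma2) {
  rx <- x - mean(x); ry <- y - mean(y)
  sum(stats::dnorm(rx, 0, sqrt(sigma2), log = TRUE)) +
    sum(stats::dnorm(ry, 0, sqrt(sigma2), log = TRUE))
}

# OU: exact conditional factorization for irregular sampling.
ctmm_loglik_ou <- function(x, y, tt, mu, sigma2, tau) {
  phi <- exp(-diff(tt) / tau)
  ll <- 0
  for (z in list(x - mu[1], y - mu[2])) {
    cond_mean <- phi * z[-length(z)]
    cond_var <- sigma2 * (1 - phi^2)
    ll <- ll + stats::dnorm(z[1], 0, sqrt(sigma2), log = TRUE) +
      sum(stats::dnorm(z[-1], cond_mean, sqrt(cond_var), log = TRUE))
  }
  ll
}

# OUF: full covariance factorization; autocovariance
# C(h) = sigma2 (tau_p e^{-h/tau_p} - tau_v e^{-h/tau_v}) / (tau_p - tau_v).
ctmm_loglik_ouf <- function(x, y, tt, mu, sigma2, tau_p, tau_v) {
  h <- abs(outer(tt, tt, "-"))
  C <- sigma2 * (tau_p * exp(-h / tau_p) - tau_v * exp(-h / tau_v)) /
    (tau_p - tau_v)
  ch <- try(chol(C + diag(1e-9 * sigma2, length(tt))), silent = TRUE)
  if (inherits(ch, "try-error")) return(-Inf)
  n <- length(tt)
  ll <- 0
  for (z in list(x - mu[1], y - mu[2])) {
    u <- backsolve(ch, z, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(u^2))
  }
  ll
}

#' Fit and select continuous-time movement models
#'
#' Fits the IID, OU (position autocorrelation) and OUF (position + velocity
#' autocorrelation) candidates by exact Gaussian maximum likelihood on
#' irregular timestamps, without a measurement-error term, and selects the
#' candidate with the lowest AIC (`2k - 2 logLik`).
#'
#' @param locations data.frame with `x`, `y` and a time column.
#' @param max_n if the track is longer, it is thinned evenly to `max_n`
#'   locations before fitting (the same thinned data underlies every
#'   candidate, so AIC comparisons remain valid); full data should be used
#'   for the subsequent density estimate.
#' @return object of class `ctmm_selection`: `candidates` (list of fits with
#'   `model`, `sigma2`, `tau_pos`, `tau_vel`, `loglik`, `k`, `aic`,
#'   `converged`) and `selected` (the minimum-AIC candidate).
#' @export
fit_ctmm_candidates <- function(locations, max_n = Inf) {
  if (is.finite(max_n) && nrow(locations) > max_n) {
    locations <- locations[round(seq(1, nrow(locations), length.out = max_n)), ,
                           drop = FALSE]
  }
  tt <- loc_times(locations)
  ord <- order(tt)
  x <- locations$x[ord]; y <- locations$y[ord]; tt <- tt[ord]
  tt <- tt - tt[1]
  n <- length(x)
  if (n < 10) stop("need >= 10 locations to fit movement models")
  dur <- tt[n]
  cands <- list()

  # IID (k = 3: mean x, mean y, sigma2)
  s2_hat <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (2 * n)
  cands$IID <- list(model = "IID", sigma2 = s2_hat, tau_pos = NULL,
                    tau_vel = NULL, loglik = ctmm_loglik_iid(x, y, s2_hat),
                    k = 3, converged = TRUE)

  # OU (k = 4)
  ou_obj <- function(par) {
    v <- -ctmm_loglik_ou(x, y, tt, par[1:2], exp(par[3]), exp(par[4]))
    if (is.finite(v)) v else 1e10
  }
  med_dt <- stats::median(diff(tt))
  ou <- try(stats::optim(c(mean(x), mean(y), log(s2_hat),
                           log(max(10 * med_dt, dur / 20))),
                         ou_obj, method = "Nelder-Mead",
                         control = list(maxit = 1000)), silent = TRUE)
  if (!inherits(ou, "try-error") && is.finite(ou$value) && ou$value < 1e10) {
    cands$OU <- list(model = "OU", sigma2 = exp(ou$par[3]),
                     tau_pos = exp(ou$par[4]), tau_vel = NULL,
                     loglik = -ou$value, k = 4,
                     converged = ou$convergence == 0)
  }

  # OUF (k = 5); tau_vel constrained below tau_pos via a logistic fraction
  if (!is.null(cands$OU)) {
    ouf_obj <- function(par) {
      tau_p <- exp(par[4]); tau_v <- tau_p * stats::plogis(par[5]) * 0.999
      v <- -ctmm_loglik_ouf(x, y, tt, par[1:2], exp(par[3]), tau_p, tau_v)
      if (is.finite(v)) v else 1e10
    }
    st <- c(cands$OU$sigma2, cands$OU$tau_pos)
    ouf <- try(stats::optim(c(mean(x), mean(y), log(st[1]), log(st[2]),
                              stats::qlogis(0.1)),
                            ouf_obj, method = "Nelder-Mead",
                            control = list(maxit = 1000)), silent = TRUE)
    if (!inherits(ouf, "try-error") && is.finite(ouf$value) && ouf$value < 1e10) {
      tau_p <- exp(ouf$par[4])
      cands$OUF <- list(model = "OUF", sigma2 = exp(ouf$par[3]),
                        tau_pos = tau_p,
                        tau_vel = tau_p * stats::plogis(ouf$par[5]) * 0.999,
                        loglik = -ouf$value, k = 5,
                        converged = ouf$convergence == 0)
    }
  }

  ok <- Filter(function(cd) cd$converged, cands)
  if (!length(ok)) stop("all movement-model candidates failed to converge")
  for (nm in names(cands)) cands[[nm]]$aic <- 2 * cands[[nm]]$k - 2 * cands[[nm]]$loglik
  aics <- vapply(ok, function(cd) 2 * cd$k - 2 * cd$loglik, numeric(1))
  sel <- ok[[which.min(aics)]]
  sel$aic <- min(aics)
  structure(list(candidates = cands, selected = sel, n = n,
                 duration_s = dur),
            class = "ctmm_selection")
}

#' @export
print.ctmm_selection <- function(x, ...) {
  tab <- do.call(rbind, lapply(x$candidates, function(cd) {
    data.frame(model = cd$model, sigma2 = cd$sigma2,
               tau_pos_h = if (is.null(cd$tau_pos)) NA else cd$tau_pos / 3600,
               tau_vel_h = if (is.null(cd$tau_vel)) NA else cd$tau_vel / 3600,
               logLik = cd$loglik, k = cd$k, AIC = cd$aic)
  }))
  print(tab, row.names = FALSE)
  cat("selected:", x$selected$model, "\n")
  invisible(x)
}

#' Effective sample size of a movement-model fit
#'
#' Number of statistically independent "range crossings" in the track:
#' `duration / tau_pos` for the autocorrelated models, the number of
#' locations for IID. A fit with `N_eff <= 1` carries a low-sample warning
#' attribute.
#'
#' @param fit a candidate from [fit_ctmm_candidates()] (or the `selected`
#'   element).
#' @param duration_s track duration (s).
#' @param n number of locations (used for IID).
#' @return N_eff (numeric), possibly with attribute `low_n_eff = TRUE`.
#' @export
effective_sample_size <- function(fit, duration_s, n = NULL) {
  neff <- if (is.null(fit$tau_pos)) {
    if (is.null(n)) stop("n is required for the IID model") else n
  } else duration_s / fit$tau_pos
  if (neff <= 1) attr(neff, "low_n_eff") <- TRUE
  neff
}

#' Autocorrelation-informed weighted kernel range distribution
#'
#' Kernel density home-range estimate whose reference bandwidth is computed
#' from the fitted stationary variance and inflated for autocorrelation via
#' the effective sample size (`bandwidth^2 = sigma2 * N_eff^(-1/3)` per
#' axis), with per-location weights proportional to the inverse local
#' sampling intensity (the time spanned around each location, normalized to
#' sum to n) to debias irregular sampling. The density is masked to water and
#' renormalized before contouring.
#'
#' @param locations data.frame with `x`, `y` and a time column.
#' @param habitat habitat grid (or NULL for no land boundary).
#' @param fit optional [fit_ctmm_candidates()] result (fitted if missing).
#' @param cell_size raster cell (m), default 100.
#' @param levels contour levels.
#' @param grid optional explicit [grid_spec()].
#' @return object of class `range_dist`: surface, regions with areas,
#'   selected model, `n_eff`, `bandwidth_m`.
#' @export
estimate_rd <- function(locations, habitat = NULL, fit = NULL,
                        cell_size = 100, levels = c(0.95, 0.50),
                        grid = NULL) {
  tt <- loc_times(locations)
  ord <- order(tt)
  x <- locations$x[ord]; y <- locations$y[ord]; tt <- tt[ord]
  n <- length(x)
  if (is.null(fit)) fit <- fit_ctmm_candidates(locations)
  sel <- if (inherits(fit, "ctmm_selection")) fit$selected else fit
  dur <- tt[n] - tt[1]
  neff <- effective_sample_size(sel, dur, n)
  low <- isTRUE(attr(neff, "low_n_eff"))
  if (low) warning("low effective sample size (N_eff <= 1): ",
                   "range estimate has wide uncertainty")
  neff_b <- max(as.numeric(neff), 2)
  bw <- sqrt(sel$sigma2 * neff_b^(-1 / 3))

  # inverse-sampling-intensity weights: half the time gap on each side
  if (n > 1) {
    gaps <- diff(tt)
    wts <- c(gaps[1] / 2, (gaps[-1] + gaps[-(n - 1)]) / 2, gaps[n - 1] / 2)
    if (all(gaps < 1e-9)) wts <- rep(1, n)
  } else wts <- 1
  wts <- wts / sum(wts) * n

  if (is.null(grid)) {
    pad <- 3 * bw + cell_size
    x0 <- floor((min(x) - pad) / cell_size) * cell_size
    y0 <- floor((min(y) - pad) / cell_size) * cell_size
    nc <- ceiling((max(x) + pad - x0) / cell_size)
    nr <- ceiling((max(y) + pad - y0) / cell_size)
    grid <- grid_spec(x0, y0, cell_size, nr, nc)
  }
  xe <- grid$origin_x + (0:grid$n_cols) * cell_size
  ye <- grid$origin_y + (0:grid$n_rows) * cell_size
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(n)) {
    c_lo <- max(1L, findInterval(x[i] - 6 * bw, xe))
    c_hi <- min(grid$n_cols, findInterval(x[i] + 6 * bw, xe) + 1L)
    r_lo <- max(1L, findInterval(y[i] - 6 * bw, ye))
    r_hi <- min(grid$n_rows, findInterval(y[i] + 6 * bw, ye) + 1L)
    px <- diff(stats::pnorm(xe[c_lo:(c_hi + 1)], x[i], bw))
    py <- diff(stats::pnorm(ye[r_lo:(r_hi + 1)], y[i], bw))
    dens[r_lo:r_hi, c_lo:c_hi] <- dens[r_lo:r_hi, c_lo:c_hi] +
      wts[i] * (py %o% px)
  }
  wm <- water_mask_on_grid(habitat, grid)
  dens[!wm] <- 0
  if (sum(dens) <= 0) stop("no density mass remains on water")
  surf <- probability_surface(grid, dens / sum(dens), wm)
  regions <- lapply(levels, function(lv) contour_region(surf, lv))
  names(regions) <- sprintf("%g", levels)
  structure(list(surface = surf, regions = regions,
                 areas = data.frame(level = levels,
                                    area_km2 = vapply(regions, function(r)
                                      r$area_km2, numeric(1))),
                 model = sel$model, fit = sel, n = n, n_eff = as.numeric(neff),
                 low_n_eff = low, bandwidth_m = bw),
            class = "range_dist")
}

#' @export
print.range_dist <- function(x, ...) {
  cat(sprintf("range_dist (weighted autocorrelation KDE): model %s, n=%d, N_eff=%.1f, bw=%.0f m%s\n",
              x$model, x$n, x$n_eff, x$bandwidth_m,
              if (x$low_n_eff) " [low N_eff]" else ""))
  print(x$areas, row.names = FALSE)
  invisible(x)
}

#' @export
plot.range_dist <- function(x, ...) {
  plot(x$surface, main = "range distribution", ...)
  invisible(x)
}
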