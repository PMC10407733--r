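#' Construct a growth curve
#'
#' Container for one well's OD600 time series. Times must be strictly
#' increasing with at least 10 points; all readings must be finite.
#'
#' @param times numeric vector of times in hours, strictly increasing.
#' @param od numeric vector of OD600 readings, same length as `times`.
#' @param condition,replicate identifiers.
#' @param blank optional scalar media blank (OD600, non-negative),
#'   subtracted before log transformation.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, condition = "unknown", replicate = 1L,
                         blank = NULL) {
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (length(times) < 10) stop("a growth curve needs at least 10 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(od))) stop("all od values must be finite")
  if (!is.null(blank) && (length(blank) != 1 || blank < 0))
    stop("blank must be a single non-negative value")
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 condition = condition, replicate = replicate, blank = blank),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s/%s: %d points, t %.2f-%.2f h, OD %.4f-%.4f\n",
              x$condition, x$replicate, length(x$times), min(x$times),
              max(x$times), min(x$od), max(x$od)))
  invisible(x)
}

# blank-subtracted, floored od
.curve_od <- function(curve, log_floor) {
  od <- curve$od
  if (!is.null(curve$blank)) od <- od - curve$blank
  pmax(od, log_floor)
}

.runmean <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# robust measurement-noise estimate from second differences; trend
# contributes ~od*(mu*dt)^2 per point, negligible against noise except
# in mid-log, and the median ignores that minority of points
.est_noise <- function(od) {
  d2 <- diff(od, differences = 2)
  stats::median(abs(d2)) / (0.6745 * sqrt(6))
}

# carrying capacity by the two-point logistic tail solution:
# od(t) = K / (1 + B exp(-mu t)) evaluated at two tail points a known
# rate apart gives K in closed form; degenerate geometry falls back to
# the maximum observed density
.cap_from_tail <- function(ts, ods, mu, odmax) {
  n <- length(ods)
  dt <- stats::median(diff(ts))
  gap <- max(2, round(2 / dt))
  if (n <= gap || !is.finite(mu) || mu <= 0) return(odmax)
  od1 <- ods[n - gap]
  od2 <- ods[n]
  if (od1 <= 0 || od2 <= 0) return(odmax)
  e <- exp(-mu * gap * dt)
  den <- 1 / od2 - e / od1
  if (den <= 0) return(odmax)
  min(max((1 - e) / den, odmax), 10 * odmax)
}

#' Moving-window slopes of the log-transformed growth curve
#'
#' Natural-log-transforms the (blank-subtracted, floored) OD series,
#' drops all points before `exclude_first_h`, and fits an ordinary
#' least-squares line to every run of `window` consecutive points. One
#' slope per window, ordered by window start time.
#'
#' @param curve a [growth_curve()].
#' @param window number of consecutive points per slope window.
#' @param exclude_first_h initial span (hours) excluded from slope
#'   windows; points with `t >= exclude_first_h` are kept.
#' @param log_floor positive floor applied to OD before taking logs.
#' @return numeric vector of slopes (per hour) with attribute `windows`,
#'   a data frame of per-window diagnostics (centroid time, centroid log
#'   OD, window-mean OD).
#' @export
window_slopes <- function(curve, window = 3, exclude_first_h = 3,
                          log_floor = 1e-4) {
  stopifnot(inherits(curve, "growth_curve"))
  keep <- curve$times >= exclude_first_h
  ts <- curve$times[keep]
  od <- .curve_od(curve, log_floor)[keep]
  n <- length(ts)
  if (n < window)
    stop(sprintf("need at least %d points after excluding the first %g h; have %d",
                 window, exclude_first_h, n))
  y <- log(od)
  m <- n - window + 1
  slope <- t_mid <- y_mid <- od_mean <- numeric(m)
  for (i in seq_len(m)) {
    idx <- i:(i + window - 1)
    tt <- ts[idx]
    slope[i] <- stats::cov(tt, y[idx]) / stats::var(tt)
    t_mid[i] <- mean(tt)
    y_mid[i] <- mean(y[idx])
    od_mean[i] <- mean(od[idx])
  }
  structure(slope, windows = data.frame(t = t_mid, log_od = y_mid,
                                        od = od_mean))
}

#' Specific growth rate from ranked window slopes
#'
#' Sorts the slopes in decreasing order, discards the `n_drop` highest,
#' and returns the arithmetic mean of the next `n_avg` (ranks 3-7 with
#' the defaults).
#'
#' @param slopes numeric vector of window slopes (per hour).
#' @param n_drop number of top slopes discarded.
#' @param n_avg number of slopes averaged after the discard.
#' @return specific growth rate, per hour.
#' @export
specific_growth_rate <- function(slopes, n_drop = 2, n_avg = 5) {
  slopes <- as.numeric(slopes)
  if (length(slopes) < n_drop + n_avg)
    stop(sprintf("need at least %d slopes; have %d", n_drop + n_avg,
                 length(slopes)))
  sorted <- sort(slopes, decreasing = TRUE)
  mean(sorted[(n_drop + 1):(n_drop + n_avg)])
}

#' Growth efficiency (OD_Max - OD_Min)
#'
#' Total increase in population size: mean of the `n_high` largest raw
#' readings minus mean of the `n_low` smallest. Readings are treated as
#' a multiset; time order is irrelevant.
#'
#' @param curve a [growth_curve()].
#' @param n_low,n_high numbers of extreme readings averaged.
#' @return growth efficiency in OD600 units.
#' @export
growth_efficiency <- function(curve, n_low = 2, n_high = 6) {
  stopifnot(inherits(curve, "growth_curve"))
  od <- curve$od
  if (length(od) < n_low + n_high)
    stop(sprintf("need at least %d readings; have %d", n_low + n_high,
                 length(od)))
  sorted <- sort(od)
  mean(sorted[(length(od) - n_high + 1):length(od)]) - mean(sorted[seq_len(n_low)])
}

#' Lag-phase endpoint by line intersection
#'
#' Intersects the line through `anchor` with slope `mu` (the
#' extrapolated maximum-growth line in log space) with the horizontal
#' line at the log initial population density. The intersection time,
#' clamped to the observed time range, is the lag-phase endpoint.
#'
#' When `mu` falls below `mu_tol` the lag is undefined (non-growing
#' culture) and flagged as such rather than erroring.
#'
#' @param curve a [growth_curve()].
#' @param mu specific growth rate (per hour) of the extrapolated line.
#' @param anchor numeric length-2 vector `c(t, log_od)`: a point on the
#'   maximum-growth line.
#' @param initial_od initial population density (OD600). Defaults to the
#'   mean of the `n_low` lowest readings.
#' @param mu_tol growth-rate tolerance below which lag is undefined.
#' @param n_low readings averaged for the default `initial_od`.
#' @return list with `lag_h` (hours, `NA` when undefined), `defined`
#'   (logical) and `clamped` (logical, `TRUE` when a negative
#'   intersection was reported as 0).
#' @export
lag_time <- function(curve, mu, anchor, initial_od = NULL, mu_tol = 1e-3,
                     n_low = 2) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.finite(mu) || mu <= mu_tol)
    return(list(lag_h = NA_real_, defined = FALSE, clamped = FALSE))
  if (is.null(initial_od))
    initial_od <- mean(sort(curve$od)[seq_len(n_low)])
  if (initial_od <= 0) stop("initial_od must be positive")
  lag <- anchor[[1]] + (log(initial_od) - anchor[[2]]) / mu
  clamped <- lag < 0
  lag <- min(max(lag, 0), max(curve$times))
  list(lag_h = lag, defined = TRUE, clamped = clamped)
}

#' Configuration for growth-parameter extraction
#'
#' @param window points per slope window.
#' @param exclude_first_h initial span (hours) excluded from slope windows.
#' @param log_floor positive OD floor before log transformation.
#' @param n_drop,n_avg ranked-slope rule: drop the `n_drop` highest
#'   window slopes, average the next `n_avg`.
#' @param n_low,n_high extreme-reading counts for OD_Min / OD_Max.
#' @param snr_min minimum window mean OD, in units of the estimated
#'   measurement noise SD, for a window to enter the ranked list.
#' @param smooth_w moving-average width (points) applied to the OD
#'   series before slope windows; `NULL` selects it from the estimated
#'   relative noise (1 for clean data, up to 15 for noisy data).
#' @param mu_tol growth-rate tolerance below which lag is undefined.
#' @param correct_capacity logical; correct window slopes for proximity
#'   to carrying capacity (logistic saturation) before ranking.
#' @return list of settings, class `growth_config`.
#' @export
growth_config <- function(window = 3, exclude_first_h = 3, log_floor = 1e-4,
                          n_drop = 2, n_avg = 5, n_low = 2, n_high = 6,
                          snr_min = 20, smooth_w = NULL, mu_tol = 1e-3,
                          correct_capacity = TRUE) {
  structure(list(window = window, exclude_first_h = exclude_first_h,
                 log_floor = log_floor, n_drop = n_drop, n_avg = n_avg,
                 n_low = n_low, n_high = n_high, snr_min = snr_min,
                 smooth_w = smooth_w, mu_tol = mu_tol,
                 correct_capacity = correct_capacity),
            class = "growth_config")
}

#' Extract lag time, specific growth rate and growth efficiency
#'
#' Composes [window_slopes()], [specific_growth_rate()],
#' [growth_efficiency()] and [lag_time()] into the full per-curve fit,
#' with numerical safeguards for noisy low-inoculum data:
#'
#' * measurement noise is estimated from second differences and the OD
#'   series is pre-smoothed with a noise-adaptive moving average;
#' * slope windows whose mean OD sits below `snr_min` noise SDs are
#'   excluded from the ranked list (they carry no slope information);
#' * window slopes are corrected for logistic saturation using a
#'   carrying capacity solved from the curve tail, so the ranked-slope
#'   average estimates the intrinsic rate rather than the locally
#'   depressed one;
#' * the lag line is the exponential-phase asymptote, fit by weighted
#'   least squares in capacity-corrected log space over the early
#'   growth points, and the initial population density is the mean of
#'   the readings in the (iteratively delimited) pre-growth plateau.
#'
#' @param curve a [growth_curve()].
#' @param config a [growth_config()].
#' @return object of class `growth_parameters`: list with `lag_h`,
#'   `mu_per_h`, `efficiency_od`, `lag_defined`, `condition`,
#'   `replicate` and a `diagnostics` list (noise SD, smoothing width,
#'   capacity estimate, selected windows, lag-line coefficients).
#' @export
fit_growth_parameters <- function(curve, config = growth_config()) {
  stopifnot(inherits(curve, "growth_curve"))
  cfg <- config
  t <- curve$times
  odraw <- .curve_od(curve, cfg$log_floor)
  need <- cfg$n_drop + cfg$n_avg
  dt <- stats::median(diff(t))

  sigma <- .est_noise(odraw)
  init <- mean(odraw[seq_len(min(4, length(odraw)))])
  w <- cfg$smooth_w
  if (is.null(w)) {
    w <- min(15, max(1, round(30 * sigma / init)))
    if (w %% 2 == 0) w <- w + 1
  }
  odmax <- mean(sort(odraw, decreasing = TRUE)[seq_len(cfg$n_high)])

  ods <- .runmean(odraw, w)
  ok <- !is.na(ods)
  smooth_curve <- growth_curve(t[ok], pmax(ods[ok], cfg$log_floor),
                               condition = curve$condition,
                               replicate = curve$replicate)
  slopes <- window_slopes(smooth_curve, window = cfg$window,
                          exclude_first_h = cfg$exclude_first_h,
                          log_floor = cfg$log_floor)
  win <- attr(slopes, "windows")
  m <- length(slopes)

  # od actually feeding each smoothed window slope: the raw points under
  # the smoothing span, weighted as the log-slope estimator weights them
  # (density-weighted mean <od^2>/<od>)
  keep <- t[ok] >= cfg$exclude_first_h
  ts <- t[ok][keep]
  raw_win <- pmax(odraw[ok][keep], cfg$log_floor)
  span <- cfg$window + w - 1
  ctr <- seq((cfg$window + 1) / 2, length.out = m)
  sp1 <- .runmean(raw_win, span)[ctr]
  sp2 <- .runmean(raw_win^2, span)[ctr]
  q <- sp2 / sp1
  q[!is.finite(q)] <- win$od[!is.finite(q)]

  elig <- win$od >= cfg$snr_min * sigma
  if (sum(elig) < need) elig <- rank(-win$od, ties.method = "first") <= need

  mu <- tryCatch(specific_growth_rate(slopes[elig], cfg$n_drop, cfg$n_avg),
                 error = function(e) NA_real_)
  cap_hat <- odmax
  sel_idx <- which(elig)
  if (cfg$correct_capacity && is.finite(mu) && mu > cfg$mu_tol) {
    odk <- pmax(ods[ok][keep], cfg$log_floor)
    for (it in 1:3) {
      cap_hat <- .cap_from_tail(ts, odk, mu, odmax)
      corr <- pmax(1 - q / cap_hat, 0.5)
      slc <- as.numeric(slopes) / corr
      elig2 <- elig & win$od <= 0.5 * cap_hat
      use <- if (sum(elig2) >= need) elig2 else elig
      mu <- specific_growth_rate(slc[use], cfg$n_drop, cfg$n_avg)
      sel_idx <- which(use)[order(slc[use], decreasing = TRUE)][
        (cfg$n_drop + 1):(cfg$n_drop + cfg$n_avg)]
    }
  } else if (is.finite(mu)) {
    sel_idx <- which(elig)[order(slopes[elig], decreasing = TRUE)][
      (cfg$n_drop + 1):(cfg$n_drop + cfg$n_avg)]
  }

  efficiency <- growth_efficiency(curve, cfg$n_low, cfg$n_high)

  # lag: weighted OLS asymptote in capacity-corrected log space
  lag_res <- list(lag_h = NA_real_, defined = FALSE, clamped = FALSE)
  line <- c(NA_real_, NA_real_)
  if (is.finite(mu) && mu > cfg$mu_tol) {
    lo <- max(2.5 * sigma, 1.5 * init)
    pts <- which(raw_win >= lo & raw_win <= 0.8 * cap_hat)
    if (length(pts) < 3)
      pts <- order(abs(raw_win - 0.25 * cap_hat))[seq_len(min(5, length(raw_win)))]
    ystar <- log(raw_win[pts]) - log(pmax(1 - raw_win[pts] / cap_hat, 0.05))
    # inverse-variance weights for additive OD noise mapped through the
    # logit transform: var(y*) ~ sigma^2 (1/od + 1/(K - od))^2
    wt <- (raw_win[pts] * pmax(1 - raw_win[pts] / cap_hat, 0.05))^2
    fitl <- stats::lm.wfit(cbind(1, ts[pts]), ystar, wt)
    b0 <- fitl$coefficients[[1]]
    b1 <- fitl$coefficients[[2]]
    line <- c(b0, b1)
    if (is.finite(b1) && b1 > cfg$mu_tol) {
      # the asymptote fixes the growth line; the lag is where that line
      # leaves the pre-growth plateau. Fit the one-parameter piecewise
      # model od(t) = exp(b0 + b1 * max(t, L)) by least squares over
      # the early region - the transition points carry far more
      # information on L than the plateau level alone
      od_hi <- 0.2 * cap_hat
      t_early <- min((log(od_hi) - b0) / b1, max(t))
      if (t_early > min(t)) {
        sel <- t <= t_early
        grid <- seq(0, t_early, by = dt / 6)
        model_od <- function(L) {
          e <- exp(b0 + b1 * pmax(t[sel], L))  # asymptote space
          cap_hat * e / (cap_hat + e)          # back to density
        }
        sse <- vapply(grid, function(L)
          sum((odraw[sel] - model_od(L))^2), numeric(1))
        raw_lag <- grid[which.min(sse)]
        lag <- min(max(raw_lag, 0), max(t))
        lag_res <- list(lag_h = lag, defined = TRUE,
                        clamped = raw_lag <= 0)
      }
    }
  }
  if (!is.finite(mu)) mu <- NA_real_
  if (is.finite(mu) && mu <= cfg$mu_tol) mu <- max(mu, 0)

  structure(list(
    lag_h = lag_res$lag_h,
    mu_per_h = mu,
    efficiency_od = efficiency,
    lag_defined = lag_res$defined,
    condition = curve$condition,
    replicate = curve$replicate,
    diagnostics = list(noise_sd = sigma, smooth_w = w, capacity = cap_hat,
                       n_eligible = sum(elig), selected_windows = sel_idx,
                       selected_t = win$t[sel_idx], lag_line = line,
                       initial_od = if (lag_res$defined)
                         exp(line[1] + line[2] * lag_res$lag_h) else init)),
    class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat(sprintf("<growth_parameters> %s/%s: mu %.4g /h, lag %s h, efficiency %.4g OD\n",
              x$condition, x$replicate, x$mu_per_h,
              if (x$lag_defined) sprintf("%.3g", x$lag_h) else "undefined",
              x$efficiency_od))
  invisible(x)
}

#' Read growth curves from a delimited file
#'
#' Long format expects columns `time_h`, `od600`, `condition`,
#' `replicate`. Wide (plate) format expects a `time_h` column followed
#' by one column per well, plus a `layout` data frame mapping `well` to
#' `condition` and `replicate`.
#'
#' @param path TSV/CSV file (separator inferred from the extension).
#' @param format `"long"` or `"wide"`.
#' @param layout data frame with columns `well`, `condition`,
#'   `replicate`; required for wide format.
#' @return list of [growth_curve()] objects.
#' @export
read_growth_curves <- function(path, format = c("long", "wide"), layout = NULL) {
  format <- match.arg(format)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "long") {
    req <- c("time_h", "od600", "condition", "replicate")
    if (!all(req %in% names(df)))
      stop("long format needs columns: ", paste(req, collapse = ", "))
    parts <- split(df, list(df$condition, df$replicate), drop = TRUE)
    lapply(unname(parts), function(p) {
      p <- p[order(p$time_h), ]
      growth_curve(p$time_h, p$od600, condition = p$condition[1],
                   replicate = p$replicate[1])
    })
  } else {
    if (is.null(layout)) stop("wide format requires a layout")
    if (!"time_h" %in% names(df)) stop("wide format needs a time_h column")
    wells <- setdiff(names(df), "time_h")
    missing_wells <- setdiff(wells, layout$well)
    if (length(missing_wells))
      stop("layout lacks wells: ", paste(missing_wells, collapse = ", "))
    lapply(wells, function(wl) {
      row <- layout[layout$well == wl, ][1, ]
      growth_curve(df$time_h, df[[wl]], condition = row$condition,
                   replicate = row$replicate)
    })
  }
}

#' Fit growth parameters for a list of curves
#'
#' @param curves list of [growth_curve()] objects.
#' @param config a [growth_config()].
#' @return data frame with one row per curve: condition, replicate,
#'   `mu_per_h`, `lag_h`, `efficiency_od`, `lag_defined`.
#' @export
fit_growth_table <- function(curves, config = growth_config()) {
  rows <- lapply(curves, function(cv) {
    p <- fit_growth_parameters(cv, config)
    data.frame(condition = p$condition, replicate = p$replicate,
               mu_per_h = p$mu_per_h, lag_h = p$lag_h,
               efficiency_od = p$efficiency_od, lag_defined = p$lag_defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
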