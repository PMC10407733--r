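#' Seeded synthetic-data generators
#'
#' Every analysis stage in otstox consumes one of six input kinds:
#' plate-reader OD600 time series, flow-cytometry forward-scatter event
#' lists, label-free protein quantification tables, reporter-peptide MS1
#' chromatograms, tRNA sequences, and gel densitometry tables. The
#' `simulate_*` family generates each of them from a known model with a
#' fixed seed and returns the generating parameters alongside the data
#' ("truth record"), so recovery by the downstream estimators can be
#' asserted exactly.
#'
#' All generators are deterministic: the same arguments and seed yield
#' identical output. Randomness is scoped to the call (no global RNG
#' state is consumed or altered).
#'
#' @name synthetic-data
NULL

#' Simulate a plate-reader growth curve
#'
#' Three-phase model: optical density stays at `od0` until `lag_h`, then
#' follows a logistic trajectory with intrinsic rate `mu` from `od0`
#' toward `capacity`. Gaussian measurement noise is added and readings
#' are floored at a small positive value, mimicking detector behaviour
#' near blank.
#'
#' The defaults mirror a standard microplate protocol: inoculation at
#' OD600 0.01, readings every 10 minutes for 16 h.
#'
#' @param od0 inoculum density (OD600), `0 < od0 < capacity`.
#' @param lag_h lag-phase duration in hours, `0 <= lag_h < duration_h`.
#' @param mu intrinsic specific growth rate, per hour.
#' @param capacity carrying capacity (saturation OD600).
#' @param noise_sd additive Gaussian noise SD in OD units.
#' @param dt_min sampling interval in minutes.
#' @param duration_h total duration in hours.
#' @param seed integer seed.
#' @param condition,replicate identifiers attached to the curve.
#' @return list with elements `curve` (a [growth_curve()]) and `truth`
#'   (named list of the generating parameters).
#' @examples
#' sim <- simulate_growth_curve(lag_h = 2, mu = 0.6, seed = 1)
#' length(sim$curve$times)  # 97 points
#' @export
simulate_growth_curve <- function(od0 = 0.01, lag_h = 2, mu = 0.6,
                                  capacity = 1.0, noise_sd = 0.005,
                                  dt_min = 10, duration_h = 16, seed = 1,
                                  condition = "sim", replicate = 1L) {
  if (od0 <= 0 || capacity <= 0) stop("od0 and capacity must be positive")
  if (od0 >= capacity) stop("od0 must be below capacity")
  if (mu < 0) stop("mu must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (lag_h < 0 || lag_h >= duration_h) stop("lag_h must lie in [0, duration_h)")
  times <- seq(0, duration_h, by = dt_min / 60)
  grown <- times >= lag_h
  od <- rep(od0, length(times))
  tg <- times[grown] - lag_h
  od[grown] <- capacity * od0 * exp(mu * tg) /
    (capacity - od0 + od0 * exp(mu * tg))
  od <- withr::with_seed(seed, {
    pmax(od + stats::rnorm(length(od), 0, noise_sd), .od_floor)
  })
  curve <- growth_curve(times, od, condition = condition, replicate = replicate)
  truth <- list(generator = "growth_curve", od0 = od0, lag_h = lag_h,
                mu = mu, capacity = capacity, noise_sd = noise_sd)
  list(curve = curve, truth = truth)
}

.od_floor <- 1e-4

#' Simulate forward-scatter events
#'
#' Events are drawn from a log-normal distribution parameterized by its
#' arithmetic mean and coefficient of variation, giving the strictly
#' positive, right-skewed shape characteristic of scatter data.
#'
#' @param mean_au arithmetic mean in arbitrary scatter units, positive.
#' @param cv coefficient of variation (SD/mean), positive.
#' @param n_events number of events, at least 1.
#' @param seed integer seed.
#' @param condition,replicate identifiers attached to the sample.
#' @return list with `sample` (an [fsc_sample()]) and `truth`.
#' @export
simulate_fsc <- function(mean_au, cv = 0.3, n_events = 1e5, seed = 1,
                         condition = "sim", replicate = 1L) {
  if (mean_au <= 0) stop("mean_au must be positive")
  if (cv <= 0) stop("cv must be positive")
  if (n_events < 1) stop("n_events must be at least 1")
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mean_au) - sdlog^2 / 2
  values <- withr::with_seed(seed, stats::rlnorm(n_events, meanlog, sdlog))
  list(sample = fsc_sample(values, condition = condition, replicate = replicate),
       truth = list(generator = "fsc", mean_au = mean_au, cv = cv))
}

#' Simulate a label-free protein quantification table
#'
#' Baseline log2 intensities are drawn from a wide normal distribution;
#' a labelled fraction of proteins is shifted by `+log2_effect` (up) or
#' `-log2_effect` (down) in condition B; replicate noise is added on the
#' log2 scale; cells are dropped missing-at-random at `missing_rate`.
#' The iBAQ channel divides each intensity by a per-protein size factor
#' (a stand-in for the theoretical peptide count), so iBAQ rank order is
#' decoupled from the LFQ channel.
#'
#' @param n_proteins number of proteins.
#' @param n_reps replicates per condition (at least 2).
#' @param frac_dys fraction of proteins dysregulated in condition B.
#' @param log2_effect absolute shift (log2 units) of dysregulated proteins.
#' @param rep_sd_log2 replicate noise SD (log2 units).
#' @param missing_rate probability any one cell is missing.
#' @param baseline_mean,baseline_sd location/scale of baseline log2
#'   intensities.
#' @param seed integer seed.
#' @return list with `table` (a [quant_table()]) and `truth` (data frame
#'   with one row per protein: `protein_id`, `label` in
#'   `c("up","down","null")`, `true_log2fc`).
#' @export
simulate_proteome <- function(n_proteins = 2000, n_reps = 3, frac_dys = 0.05,
                              log2_effect = 2, rep_sd_log2 = 0.25,
                              missing_rate = 0.1, baseline_mean = 26,
                              baseline_sd = 2.5, seed = 1) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (frac_dys < 0 || frac_dys > 1) stop("frac_dys must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  n_dys <- round(frac_dys * n_proteins)
  if (frac_dys > 0 && n_dys < 1) {
    warning("frac_dys * n_proteins < 1; no proteins dysregulated")
    n_dys <- 0
  }
  ids <- sprintf("P%04d", seq_len(n_proteins))
  samples <- c(paste0("A_", seq_len(n_reps)), paste0("B_", seq_len(n_reps)))
  cond <- rep(c("A", "B"), each = n_reps)

  out <- withr::with_seed(seed, {
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    label <- rep("null", n_proteins)
    if (n_dys > 0) {
      dys <- sample.int(n_proteins, n_dys)
      n_up <- ceiling(n_dys / 2)
      label[dys[seq_len(n_up)]] <- "up"
      if (n_dys > n_up) label[dys[(n_up + 1):n_dys]] <- "down"
    }
    fc <- ifelse(label == "up", log2_effect,
                 ifelse(label == "down", -log2_effect, 0))
    log2m <- matrix(base, n_proteins, 2 * n_reps)
    log2m[, cond == "B"] <- log2m[, cond == "B"] + fc
    log2m <- log2m + matrix(stats::rnorm(length(log2m), 0, rep_sd_log2),
                            n_proteins)
    if (missing_rate > 0) {
      log2m[matrix(stats::runif(length(log2m)) < missing_rate,
                   n_proteins)] <- NA
    }
    size <- pmax(1, round(stats::rlnorm(n_proteins, log(20), 0.6)))
    list(log2m = log2m, label = label, fc = fc, size = size)
  })

  lfq <- 2^out$log2m
  ibaq <- lfq / out$size
  colnames(lfq) <- colnames(ibaq) <- samples
  rownames(lfq) <- rownames(ibaq) <- ids
  tab <- quant_table(lfq = lfq, ibaq = ibaq,
                     sample_conditions = stats::setNames(cond, samples))
  truth <- data.frame(protein_id = ids, label = out$label,
                      true_log2fc = out$fc, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Simulate reporter-peptide MS1 chromatograms
#'
#' One Gaussian elution peak per amino-acid variant and replicate, on a
#' flat baseline with additive noise. Peak areas are `base_area` times
#' the variant's relative ratio; the pSer variant is the reference and
#' must carry ratio 1. Peak boundaries (center +/- 4 sigma) are included
#' so integration windows need no peak picking.
#'
#' @param variant_ratios named numeric vector of relative areas; must
#'   contain `pSer = 1`.
#' @param rt_centers named numeric vector of retention-time centers
#'   (minutes), one per variant, all distinct.
#' @param peak_sigma Gaussian peak SD in minutes.
#' @param base_area area (intensity x min) of the pSer peak.
#' @param noise_sd additive intensity noise SD.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list with `set` (a [chromatogram_set()]) and `truth`.
#' @export
simulate_chromatograms <- function(variant_ratios = c(pSer = 1, Gly = 1, Thr = 1),
                                   rt_centers = NULL, peak_sigma = 0.1,
                                   base_area = 1e6, noise_sd = 0, n_reps = 3,
                                   seed = 1) {
  if (!"pSer" %in% names(variant_ratios)) stop("variant_ratios must include 'pSer'")
  if (abs(variant_ratios[["pSer"]] - 1) > 1e-12)
    stop("the pSer reference ratio must be 1")
  if (any(variant_ratios < 0)) stop("ratios must be non-negative")
  if (peak_sigma <= 0) stop("peak_sigma must be positive")
  variants <- names(variant_ratios)
  if (is.null(rt_centers)) {
    rt_centers <- stats::setNames(10 + seq_along(variants), variants)
  }
  if (anyDuplicated(rt_centers)) stop("rt centers must be distinct")
  if (!all(variants %in% names(rt_centers))) stop("rt_centers must cover every variant")

  dt <- peak_sigma / 5
  rt <- seq(min(rt_centers) - 6 * peak_sigma, max(rt_centers) + 6 * peak_sigma,
            by = dt)
  traces <- withr::with_seed(seed, {
    do.call(rbind, lapply(variants, function(v) {
      do.call(rbind, lapply(seq_len(n_reps), function(r) {
        mu <- rt_centers[[v]]
        signal <- base_area * variant_ratios[[v]] *
          stats::dnorm(rt, mu, peak_sigma)
        noisy <- pmax(signal + stats::rnorm(length(rt), 0, noise_sd), 0)
        data.frame(variant = v, replicate = r, rt_min = rt,
                   intensity = noisy, stringsAsFactors = FALSE)
      }))
    }))
  })
  bounds <- do.call(rbind, lapply(variants, function(v) {
    data.frame(variant = v, replicate = seq_len(n_reps),
               rt_start = rt_centers[[v]] - 4 * peak_sigma,
               rt_end = rt_centers[[v]] + 4 * peak_sigma,
               stringsAsFactors = FALSE)
  }))
  set <- chromatogram_set(traces, bounds)
  truth <- list(generator = "chromatograms", ratios = variant_ratios,
                base_area = base_area, peak_sigma = peak_sigma)
  list(set = set, truth = truth)
}

#' Simulate gel densitometry of a reporter protein
#'
#' Band intensities respond linearly to loaded mass. The standards lane
#' series carries known masses; the sample contributes one total band
#' (plain SDS-PAGE) and two PhosTag bands splitting the total mass by
#' `phos_fraction` (upper = phosphorylated).
#'
#' @param known_ng numeric vector of standard masses (ng), at least two
#'   distinct values.
#' @param response_per_ng detector response slope (intensity per ng).
#' @param sample_total_ng total reporter mass in the sample lane (ng).
#' @param phos_fraction fraction of the reporter that is phosphorylated,
#'   in `[0, 1]`.
#' @param noise_sd additive intensity noise SD.
#' @param seed integer seed.
#' @return list with `gel` (a [gel_quant_table()]) and `truth`.
#' @export
simulate_densitometry <- function(known_ng = c(25, 50, 100, 200),
                                  response_per_ng = 10,
                                  sample_total_ng = 100,
                                  phos_fraction = 0.6,
                                  noise_sd = 0, seed = 1) {
  if (length(unique(known_ng)) < 2) stop("need at least 2 distinct standard masses")
  if (phos_fraction < 0 || phos_fraction > 1) stop("phos_fraction must lie in [0, 1]")
  out <- withr::with_seed(seed, {
    std_int <- pmax(response_per_ng * known_ng +
                      stats::rnorm(length(known_ng), 0, noise_sd), 0)
    total <- pmax(response_per_ng * sample_total_ng +
                    stats::rnorm(1, 0, noise_sd), 0)
    upper <- pmax(response_per_ng * sample_total_ng * phos_fraction +
                    stats::rnorm(1, 0, noise_sd), 0)
    lower <- pmax(response_per_ng * sample_total_ng * (1 - phos_fraction) +
                    stats::rnorm(1, 0, noise_sd), 0)
    list(std_int = std_int, total = total, upper = upper, lower = lower)
  })
  gel <- gel_quant_table(
    standards = data.frame(ng = known_ng, intensity = out$std_int),
    total_intensity = out$total,
    upper_intensity = out$upper,
    lower_intensity = out$lower)
  truth <- list(generator = "densitometry", response_per_ng = response_per_ng,
                sample_total_ng = sample_total_ng, phos_fraction = phos_fraction)
  list(gel = gel, truth = truth)
}
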