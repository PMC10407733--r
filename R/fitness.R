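#' Construct a condition phenotype
#'
#' Replicate-aggregated growth and size parameters for one strain or
#' construct: the inputs to relative-fitness calculation.
#'
#' @param condition identifier.
#' @param mu_per_h,lag_h,efficiency_od,fsc_mean_au replicate means of
#'   the four phenotype parameters.
#' @param mu_sd,lag_sd,efficiency_sd,fsc_sd replicate SDs (optional).
#' @param n_replicates number of replicates aggregated.
#' @param viable logical; `FALSE` marks a condition that could not be
#'   established (no growth / no data).
#' @return object of class `condition_phenotype`.
#' @export
condition_phenotype <- function(condition, mu_per_h, lag_h, efficiency_od,
                                fsc_mean_au, mu_sd = NA, lag_sd = NA,
                                efficiency_sd = NA, fsc_sd = NA,
                                n_replicates = 1L, viable = TRUE) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  sds <- c(mu_sd, lag_sd, efficiency_sd, fsc_sd)
  if (any(!is.na(sds) & sds < 0)) stop("SDs must be non-negative")
  structure(list(condition = condition, mu_per_h = mu_per_h, lag_h = lag_h,
                 efficiency_od = efficiency_od, fsc_mean_au = fsc_mean_au,
                 mu_sd = mu_sd, lag_sd = lag_sd, efficiency_sd = efficiency_sd,
                 fsc_sd = fsc_sd, n_replicates = n_replicates,
                 viable = isTRUE(viable)),
            class = "condition_phenotype")
}

#' Aggregate per-replicate growth and size results into phenotypes
#'
#' @param growth data frame as returned by [fit_growth_table()].
#' @param size optional data frame with columns `condition` and
#'   `fsc_mean` (replicate-level FSC means, e.g. from [summarize_fsc()]).
#' @param mu_tol growth-rate tolerance below which a condition is
#'   flagged non-viable.
#' @return named list of [condition_phenotype()] objects.
#' @export
aggregate_phenotypes <- function(growth, size = NULL, mu_tol = 1e-3) {
  out <- lapply(split(growth, growth$condition), function(g) {
    fsc <- NA_real_
    fsc_sd <- NA_real_
    if (!is.null(size)) {
      s <- size[size$condition == g$condition[1], ]
      if (nrow(s)) {
        fsc <- mean(s$fsc_mean)
        fsc_sd <- if (nrow(s) > 1) stats::sd(s$fsc_mean) else NA_real_
      }
    }
    mu <- mean(g$mu_per_h, na.rm = TRUE)
    condition_phenotype(
      condition = g$condition[1],
      mu_per_h = mu,
      lag_h = mean(g$lag_h, na.rm = TRUE),
      efficiency_od = mean(g$efficiency_od, na.rm = TRUE),
      fsc_mean_au = fsc,
      mu_sd = if (nrow(g) > 1) stats::sd(g$mu_per_h) else NA_real_,
      lag_sd = if (nrow(g) > 1) stats::sd(g$lag_h) else NA_real_,
      efficiency_sd = if (nrow(g) > 1) stats::sd(g$efficiency_od) else NA_real_,
      fsc_sd = fsc_sd,
      n_replicates = nrow(g),
      viable = is.finite(mu) && mu > mu_tol)
  })
  out
}

#' Background-normalized parameter ratios
#'
#' Each ratio is oriented so that larger means fitter: growth rate and
#' efficiency as condition/background, lag inverted
#' (background/condition, since a longer lag is less fit), and cell
#' size as condition/background (size reduction marks stress).
#'
#' @param cond,background [condition_phenotype()] objects; the
#'   background must be viable with positive parameters.
#' @param lag_ratio_max cap applied to the lag ratio when the condition
#'   lag is 0 (or nearly so).
#' @return named numeric vector (`r_mu`, `r_lag`, `r_eff`, `r_size`);
#'   empty when `cond` is non-viable. Attribute `capped` flags a capped
#'   lag ratio.
#' @export
parameter_ratios <- function(cond, background, lag_ratio_max = 10) {
  stopifnot(inherits(cond, "condition_phenotype"),
            inherits(background, "condition_phenotype"))
  if (!background$viable) stop("background must be viable")
  bg <- c(background$mu_per_h, background$lag_h, background$efficiency_od,
          background$fsc_mean_au)
  if (any(!is.finite(bg)) || any(bg <= 0))
    stop("background parameters must all be positive")
  if (!cond$viable) return(structure(numeric(0), capped = FALSE))
  capped <- FALSE
  if (cond$lag_h <= background$lag_h / lag_ratio_max) {
    r_lag <- lag_ratio_max
    capped <- TRUE
  } else {
    r_lag <- background$lag_h / cond$lag_h
  }
  structure(c(r_mu = cond$mu_per_h / background$mu_per_h,
              r_lag = r_lag,
              r_eff = cond$efficiency_od / background$efficiency_od,
              r_size = cond$fsc_mean_au / background$fsc_mean_au),
            capped = capped)
}

#' Composite relative fitness
#'
#' Weighted geometric mean of the oriented parameter ratios. The
#' background maps to exactly 1; a non-viable condition (empty ratio
#' set) maps to 0.
#'
#' @param ratios named numeric vector from [parameter_ratios()].
#' @param weights optional named weights (same names as `ratios`,
#'   non-negative, summing to 1); default uniform.
#' @return single dimensionless fitness value.
#' @export
composite_fitness <- function(ratios, weights = NULL) {
  if (!length(ratios)) return(0)
  if (any(ratios <= 0)) stop("all ratios must be positive")
  if (is.null(weights)) {
    weights <- rep(1 / length(ratios), length(ratios))
    names(weights) <- names(ratios)
  }
  if (!setequal(names(weights), names(ratios)))
    stop("weights must cover exactly the ratio names")
  weights <- weights[names(ratios)]
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  exp(sum(weights * log(ratios)))
}

#' Full fitness profile of a condition against a background
#'
#' @inheritParams parameter_ratios
#' @param weights optional weights passed to [composite_fitness()].
#' @return object of class `fitness_profile`: list with `condition`,
#'   `ratios`, `composite`, `viable`.
#' @export
fitness_profile <- function(cond, background, weights = NULL,
                            lag_ratio_max = 10) {
  ratios <- parameter_ratios(cond, background, lag_ratio_max)
  structure(list(condition = cond$condition,
                 ratios = ratios,
                 composite = composite_fitness(ratios, weights),
                 viable = cond$viable),
            class = "fitness_profile")
}

#' @export
print.fitness_profile <- function(x, ...) {
  if (!x$viable) {
    cat(sprintf("<fitness_profile> %s: N.V.\n", x$condition))
  } else {
    cat(sprintf("<fitness_profile> %s: composite %.4g (%s)\n", x$condition,
                x$composite,
                paste(sprintf("%s=%.3g", names(x$ratios), x$ratios),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Tabulate fitness profiles
#'
#' One row per condition with the four ratios, the composite value, and
#' the rendering used in heat maps (non-viable printed as `"N.V."`).
#'
#' @param profiles list of [fitness_profile()] objects.
#' @return data frame.
#' @export
fitness_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    r <- p$ratios
    get <- function(nm) if (nm %in% names(r)) r[[nm]] else NA_real_
    data.frame(condition = p$condition, r_mu = get("r_mu"),
               r_lag = get("r_lag"), r_eff = get("r_eff"),
               r_size = get("r_size"), composite = p$composite,
               display = if (p$viable) sprintf("%.3f", p$composite) else "N.V.",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
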