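#' Construct a chromatogram set
#'
#' MS1 extracted-ion traces of reporter-peptide variants, one trace per
#' variant and replicate, with integration boundaries.
#'
#' @param traces data frame with columns `variant`, `replicate`,
#'   `rt_min` (strictly increasing within a trace), `intensity`
#'   (non-negative).
#' @param boundaries data frame with columns `variant`, `replicate`,
#'   `rt_start`, `rt_end`; boundaries must lie within the trace span.
#' @return object of class `chromatogram_set`.
#' @export
chromatogram_set <- function(traces, boundaries) {
  req <- c("variant", "replicate", "rt_min", "intensity")
  if (!all(req %in% names(traces)))
    stop("traces needs columns: ", paste(req, collapse = ", "))
  reqb <- c("variant", "replicate", "rt_start", "rt_end")
  if (!all(reqb %in% names(boundaries)))
    stop("boundaries needs columns: ", paste(reqb, collapse = ", "))
  if (any(traces$intensity < 0)) stop("intensities must be non-negative")
  parts <- split(traces, list(traces$variant, traces$replicate), drop = TRUE)
  for (p in parts) {
    if (any(diff(p$rt_min) <= 0))
      stop("retention times must be strictly increasing within a trace")
    b <- boundaries[boundaries$variant == p$variant[1] &
                      boundaries$replicate == p$replicate[1], ]
    if (nrow(b) != 1)
      stop(sprintf("need exactly one boundary row for %s/%s",
                   p$variant[1], p$replicate[1]))
    if (b$rt_start >= b$rt_end) stop("rt_start must precede rt_end")
    if (b$rt_start < min(p$rt_min) || b$rt_end > max(p$rt_min))
      stop("boundaries must lie within the trace span")
  }
  structure(list(traces = traces, boundaries = boundaries),
            class = "chromatogram_set")
}

#' @export
print.chromatogram_set <- function(x, ...) {
  cat(sprintf("<chromatogram_set> %d variants x %d replicates\n",
              length(unique(x$traces$variant)),
              length(unique(x$traces$replicate))))
  invisible(x)
}

#' Read chromatograms from long CSV plus a boundaries file
#'
#' @param chrom_path CSV with columns `variant`, `replicate`, `rt_min`,
#'   `intensity` (one row per sampled point).
#' @param bounds_path CSV with columns `variant`, `replicate`,
#'   `rt_start`, `rt_end`.
#' @return a [chromatogram_set()].
#' @export
read_chromatograms <- function(chrom_path, bounds_path) {
  rd <- function(p) {
    sep <- if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  }
  chromatogram_set(rd(chrom_path), rd(bounds_path))
}

#' Integrate peak area under the curve
#'
#' Trapezoidal integral of `(intensity - baseline)+` over the boundary
#' window. The default baseline is the minimum intensity inside the
#' window; `"none"` integrates the raw trace.
#'
#' @param rt,intensity numeric vectors describing one trace.
#' @param bounds numeric length-2 vector `c(start, end)` in minutes.
#' @param baseline `"flat_min"` or `"none"`.
#' @return area in intensity x minutes.
#' @export
integrate_auc <- function(rt, intensity, bounds = range(rt),
                          baseline = c("flat_min", "none")) {
  baseline <- match.arg(baseline)
  sel <- rt >= bounds[1] & rt <= bounds[2]
  if (sum(sel) < 2) stop("need at least 2 points inside the boundary window")
  x <- rt[sel]
  y <- intensity[sel]
  if (baseline == "flat_min") y <- y - min(y)
  y <- pmax(y, 0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# robust noise scale of the trace outside the boundary window; the
# upper-quantile deviation stays valid when the baseline is clipped at
# zero (which zeroes an ordinary MAD)
.trace_noise <- function(rt, intensity, bounds) {
  out <- intensity[rt < bounds[1] | rt > bounds[2]]
  if (length(out) < 4) return(NA_real_)
  dev <- abs(out - stats::median(out))
  stats::quantile(dev, 0.9, names = FALSE) / 1.2816
}

#' pSer-normalized incorporation profile
#'
#' Within each replicate, every variant's peak area is divided by the
#' pSer area of the same replicate (within-sample normalization); the
#' profile reports the mean and SD of those per-replicate ratios. A
#' variant is below the limit of detection when its in-window signal
#' (upper-quantile intensity) fails to reach `lod_snr` times the robust
#' noise scale of its trace outside the window; such variants report
#' ratio 0 with a flag rather than being dropped.
#'
#' @param set a [chromatogram_set()] containing a `pSer` variant in
#'   every replicate.
#' @param lod_snr signal-to-noise threshold for detection.
#' @param baseline passed to [integrate_auc()].
#' @return data frame (class `incorporation_profile`): one row per
#'   variant with `mean_auc`, `auc_sd`, `ratio` (variant:pSer),
#'   `ratio_sd`, `below_lod`, `n_replicates`. Attribute
#'   `excluded_replicates` lists replicates dropped for a zero pSer
#'   area.
#' @export
incorporation_profile <- function(set, lod_snr = 3,
                                  baseline = c("flat_min", "none")) {
  stopifnot(inherits(set, "chromatogram_set"))
  baseline <- match.arg(baseline)
  reps <- sort(unique(set$traces$replicate))
  variants <- unique(set$traces$variant)
  if (!"pSer" %in% variants) stop("a pSer variant is required")
  have_pser <- unique(set$traces$replicate[set$traces$variant == "pSer"])
  if (!all(reps %in% have_pser))
    stop("the pSer variant must be present in every replicate")

  per <- expand.grid(variant = variants, replicate = reps,
                     stringsAsFactors = FALSE)
  per$auc <- NA_real_
  per$detected <- NA
  for (i in seq_len(nrow(per))) {
    tr <- set$traces[set$traces$variant == per$variant[i] &
                       set$traces$replicate == per$replicate[i], ]
    b <- set$boundaries[set$boundaries$variant == per$variant[i] &
                          set$boundaries$replicate == per$replicate[i], ]
    if (!nrow(tr)) next
    bounds <- c(b$rt_start, b$rt_end)
    per$auc[i] <- integrate_auc(tr$rt_min, tr$intensity, bounds, baseline)
    noise <- .trace_noise(tr$rt_min, tr$intensity, bounds)
    inwin <- tr$intensity[tr$rt_min >= bounds[1] & tr$rt_min <= bounds[2]]
    # signal statistic: upper-quantile in-window intensity (a peak
    # holds a sizeable window fraction near its apex; a lone noise
    # maximum does not)
    signal <- stats::quantile(inwin, 0.9, names = FALSE)
    per$detected[i] <- if (is.na(noise) || noise == 0) {
      signal > 0
    } else {
      signal >= lod_snr * noise
    }
  }

  pser_auc <- per$auc[per$variant == "pSer"]
  names(pser_auc) <- per$replicate[per$variant == "pSer"]
  usable <- names(pser_auc)[pser_auc > 0]
  excluded <- setdiff(names(pser_auc), usable)
  if (!length(usable)) stop("pSer area is zero in every replicate")

  rows <- lapply(variants, function(v) {
    sub <- per[per$variant == v & per$replicate %in% usable, ]
    ratios <- sub$auc / pser_auc[as.character(sub$replicate)]
    detected <- any(sub$detected, na.rm = TRUE)
    data.frame(variant = v,
               mean_auc = mean(sub$auc),
               auc_sd = if (nrow(sub) > 1) stats::sd(sub$auc) else NA_real_,
               ratio = if (detected) mean(ratios) else 0,
               ratio_sd = if (detected && nrow(sub) > 1) stats::sd(ratios) else NA_real_,
               below_lod = !detected,
               n_replicates = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("incorporation_profile", "data.frame")
  attr(out, "excluded_replicates") <- excluded
  out
}

#' Fit a densitometry standard curve
#'
#' Ordinary least-squares line `intensity = slope * ng + intercept`
#' through the known-mass standards.
#'
#' @param standards data frame with columns `ng` and `intensity`, at
#'   least two distinct masses.
#' @return list with `slope` (intensity/ng) and `intercept` (intensity).
#' @export
fit_standard_curve <- function(standards) {
  if (length(unique(standards$ng)) < 2)
    stop("need at least 2 distinct standard masses")
  fit <- stats::lm(intensity ~ ng, data = standards)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Construct a gel quantification table
#'
#' @param standards data frame with columns `ng`, `intensity` (the
#'   known-mass ladder), at least two distinct masses.
#' @param total_intensity sample band intensity on the plain gel.
#' @param upper_intensity,lower_intensity PhosTag band intensities
#'   (upper = phosphorylated, lower = non-phosphorylated).
#' @param culture_ml,od_equivalents optional bookkeeping for volumetric
#'   yield conversion.
#' @return object of class `gel_quant_table`.
#' @export
gel_quant_table <- function(standards, total_intensity, upper_intensity,
                            lower_intensity, culture_ml = NA,
                            od_equivalents = NA) {
  if (length(unique(standards$ng)) < 2)
    stop("need at least 2 distinct standard masses")
  if (any(standards$intensity < 0) || total_intensity < 0 ||
      upper_intensity < 0 || lower_intensity < 0)
    stop("intensities must be non-negative")
  structure(list(standards = standards, total_intensity = total_intensity,
                 upper_intensity = upper_intensity,
                 lower_intensity = lower_intensity,
                 culture_ml = culture_ml, od_equivalents = od_equivalents),
            class = "gel_quant_table")
}

#' Read a gel quantification table
#'
#' Expects a TSV with a `role` column: rows with role `standard` carry
#' `ng` and `intensity`; rows with roles `total`, `upper`, `lower`
#' carry the corresponding band `intensity`.
#'
#' @param path TSV file path.
#' @return a [gel_quant_table()].
#' @export
read_gel_quant <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  std <- df[df$role == "standard", c("ng", "intensity")]
  pick <- function(role) {
    v <- df$intensity[df$role == role]
    if (length(v) != 1) stop("need exactly one ", role, " band row")
    v
  }
  gel_quant_table(std, pick("total"), pick("upper"), pick("lower"))
}

#' Total reporter mass from a gel table
#'
#' Inverts the standard curve at the sample's total band intensity.
#'
#' @param gel a [gel_quant_table()].
#' @return estimated mass in ng.
#' @export
total_mass_from_gel <- function(gel) {
  stopifnot(inherits(gel, "gel_quant_table"))
  curve <- fit_standard_curve(gel$standards)
  (gel$total_intensity - curve$intercept) / curve$slope
}

#' Phosphoprotein yield from band partitioning
#'
#' Adjusts a total yield by the phosphorylated fraction derived from
#' the PhosTag band intensities: `total * upper / (upper + lower)`.
#'
#' @param total_yield total reporter yield (any mass or mass/volume
#'   unit; the result carries the same unit).
#' @param upper,lower PhosTag band intensities (upper =
#'   phosphorylated).
#' @return phosphoprotein yield in the unit of `total_yield`.
#' @export
phosphoprotein_yield <- function(total_yield, upper, lower) {
  if (upper < 0 || lower < 0) stop("band intensities must be non-negative")
  if (upper + lower <= 0) stop("upper + lower must be positive")
  total_yield * upper / (upper + lower)
}
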