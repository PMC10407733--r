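#' Construct a forward-scatter event sample
#'
#' @param values numeric vector of per-event FSC values (arbitrary
#'   units), all positive, non-empty.
#' @param condition,replicate identifiers.
#' @return object of class `fsc_sample`.
#' @export
fsc_sample <- function(values, condition = "unknown", replicate = 1L) {
  values <- as.numeric(values)
  if (!length(values)) stop("an FSC sample must contain at least one event")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all FSC values must be positive and finite")
  structure(list(values = values, condition = condition,
                 replicate = replicate), class = "fsc_sample")
}

#' @export
print.fsc_sample <- function(x, ...) {
  cat(sprintf("<fsc_sample> %s/%s: %d events, mean %.3g A.U.\n",
              x$condition, x$replicate, length(x$values), mean(x$values)))
  invisible(x)
}

# histogram mode: center of the maximal-count equal-width bin over
# [min, max]; ties resolved toward the lowest-valued bin
.hist_mode <- function(values, n_bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(values, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  i <- which.max(counts)  # which.max returns the first (lowest) maximum
  (breaks[i] + breaks[i + 1]) / 2
}

#' Summarize an FSC distribution as a cell-size proxy
#'
#' Computes mean, SD, median and histogram mode of the event values,
#' plus bootstrap standard deviations of the median and the mode (the
#' spread of those statistics over `bootstrap_b` resamples).
#'
#' @param sample an [fsc_sample()].
#' @param n_bins equal-width histogram bins used for the mode.
#' @param bootstrap_b bootstrap resamples for `median_sd`/`mode_sd`;
#'   samples with fewer than 10 events skip the bootstrap (SDs `NA`).
#' @param seed integer seed for the bootstrap.
#' @return object of class `size_summary`: list with `mean`, `sd`,
#'   `median`, `mode`, `median_sd`, `mode_sd`, `n_events`, `condition`,
#'   `replicate`.
#' @export
summarize_fsc <- function(sample, n_bins = 256, bootstrap_b = 200, seed = 1) {
  stopifnot(inherits(sample, "fsc_sample"))
  v <- sample$values
  n <- length(v)
  med_sd <- mode_sd <- NA_real_
  if (n >= 10 && bootstrap_b > 0) {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(bootstrap_b), function(b) {
        vb <- v[sample.int(n, n, replace = TRUE)]
        c(stats::median(vb), .hist_mode(vb, n_bins))
      }, numeric(2))
    })
    med_sd <- stats::sd(boots[1, ])
    mode_sd <- stats::sd(boots[2, ])
  }
  structure(list(mean = mean(v), sd = stats::sd(v),
                 median = stats::median(v), mode = .hist_mode(v, n_bins),
                 median_sd = med_sd, mode_sd = mode_sd, n_events = n,
                 condition = sample$condition, replicate = sample$replicate),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(paste0("<size_summary> %s/%s: n=%d, mean %.3g (sd %.3g), ",
                     "median %.3g, mode %.3g A.U.\n"),
              x$condition, x$replicate, x$n_events, x$mean, x$sd,
              x$median, x$mode))
  invisible(x)
}

#' Compare two size summaries
#'
#' @param a,b [summarize_fsc()] results; `a` is the numerator.
#' @return list with `fold_change` (`a$mean / b$mean`) and `deltas`, a
#'   data frame of per-statistic differences (`a - b`).
#' @export
compare_size <- function(a, b) {
  stopifnot(inherits(a, "size_summary"), inherits(b, "size_summary"))
  stats_names <- c("mean", "sd", "median", "mode")
  deltas <- data.frame(
    statistic = stats_names,
    a = vapply(stats_names, function(s) a[[s]], numeric(1)),
    b = vapply(stats_names, function(s) b[[s]], numeric(1)))
  deltas$delta <- deltas$a - deltas$b
  list(fold_change = a$mean / b$mean, deltas = deltas)
}

#' Read FSC events from a CSV file
#'
#' Expects one row per event with columns `fsc`, `condition`,
#' `replicate`. Native FCS binaries are not parsed; convert upstream.
#'
#' @param path CSV (or TSV) file path.
#' @return list of [fsc_sample()] objects, one per condition/replicate.
#' @export
read_fsc_events <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("fsc", "condition", "replicate")
  if (!all(req %in% names(df)))
    stop("FSC event file needs columns: ", paste(req, collapse = ", "))
  parts <- split(df, list(df$condition, df$replicate), drop = TRUE)
  lapply(unname(parts), function(p)
    fsc_sample(p$fsc, condition = p$condition[1], replicate = p$replicate[1]))
}
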