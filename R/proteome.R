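#' Construct a protein quantification table
#'
#' Holds the LFQ and iBAQ channels of a label-free proteomics
#' experiment as protein-by-sample matrices plus the sample-to-condition
#' assignment. Missing cells are `NA`; present intensities must be
#' positive.
#'
#' @param lfq,ibaq numeric matrices (proteins x samples) with identical
#'   dimnames; `ibaq` may be `NULL` if only differential analysis is
#'   needed.
#' @param sample_conditions named character vector mapping each sample
#'   (column) to exactly one condition.
#' @return object of class `quant_table`.
#' @export
quant_table <- function(lfq, ibaq = NULL, sample_conditions) {
  if (is.null(colnames(lfq)) || is.null(rownames(lfq)))
    stop("lfq must carry protein row names and sample column names")
  if (!all(colnames(lfq) %in% names(sample_conditions)))
    stop("every sample must be mapped to a condition")
  if (any(lfq[!is.na(lfq)] <= 0)) stop("present intensities must be positive")
  if (!is.null(ibaq)) {
    if (!identical(dim(ibaq), dim(lfq)) ||
        !identical(dimnames(ibaq), dimnames(lfq)))
      stop("ibaq must match lfq in dimensions and dimnames")
    if (any(ibaq[!is.na(ibaq)] <= 0)) stop("present iBAQ scores must be positive")
  }
  structure(list(lfq = lfq, ibaq = ibaq,
                 sample_conditions = sample_conditions[colnames(lfq)]),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d proteins x %d samples (%s)\n",
              nrow(x$lfq), ncol(x$lfq),
              paste(unique(x$sample_conditions), collapse = ", ")))
  invisible(x)
}

#' Read a protein-groups style quantification table
#'
#' Expects a delimited file with a `protein_id` column plus
#' `LFQ.<sample>` and (optionally) `iBAQ.<sample>` columns. When a
#' `flags` column is present, rows with a non-empty flag (contaminants,
#' reversed decoys) are dropped. Zero intensities are treated as
#' missing, following the common protein-groups convention.
#'
#' @param path TSV/CSV file path (separator inferred from extension).
#' @param sample_conditions named character vector mapping sample names
#'   (the part after `LFQ.`) to conditions.
#' @return a [quant_table()].
#' @export
read_quant_table <- function(path, sample_conditions) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"protein_id" %in% names(df)) stop("need a protein_id column")
  if ("flags" %in% names(df)) {
    flg <- df$flags
    df <- df[is.na(flg) | flg == "", ]
  }
  take <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(df), value = TRUE)
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
    rownames(m) <- df$protein_id
    m[!is.na(m) & m <= 0] <- NA
    m
  }
  lfq <- take("LFQ")
  if (is.null(lfq)) stop("no LFQ.<sample> columns found")
  quant_table(lfq, take("iBAQ"), sample_conditions)
}

#' Differential-abundance configuration
#'
#' @param p_threshold two-sided p-value threshold.
#' @param fdr target permutation-estimated false discovery rate.
#' @param s0 softening constant added to the per-protein standard error
#'   in the moderated statistic `d = delta / (se + s0)`.
#' @param n_permutations label permutations for the null distribution
#'   (all distinct assignments are enumerated when fewer exist).
#' @param min_valid_per_group minimum valid values per condition for a
#'   protein to be tested.
#' @param equal_var equal-variance (pooled) t-test when `TRUE` (the
#'   default), Welch otherwise.
#' @return list of settings, class `de_config`.
#' @export
de_config <- function(p_threshold = 0.05, fdr = 0.1, s0 = 0.1,
                      n_permutations = 250, min_valid_per_group = 2,
                      equal_var = TRUE) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must lie in (0,1)")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)")
  if (s0 < 0) stop("s0 must be non-negative")
  if (n_permutations < 25) stop("n_permutations must be at least 25")
  structure(list(p_threshold = p_threshold, fdr = fdr, s0 = s0,
                 n_permutations = n_permutations,
                 min_valid_per_group = min_valid_per_group,
                 equal_var = equal_var),
            class = "de_config")
}

# group means/vars/counts honouring NAs, for a logical column selector
.grp_stats <- function(X0, M, sel) {
  n <- rowSums(M[, sel, drop = FALSE])
  s <- rowSums(X0[, sel, drop = FALSE])
  mean <- s / n
  ss <- rowSums((X0[, sel, drop = FALSE])^2) - n * mean^2
  list(n = n, mean = mean, ss = pmax(ss, 0))
}

.d_stat <- function(X0, M, selB, s0, equal_var) {
  selA <- !selB
  a <- .grp_stats(X0, M, selA)
  b <- .grp_stats(X0, M, selB)
  delta <- b$mean - a$mean
  if (equal_var) {
    df <- a$n + b$n - 2
    sp2 <- (a$ss + b$ss) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$ss / (a$n - 1)
    vb <- b$ss / (b$n - 1)
    se <- sqrt(va / a$n + vb / b$n)
    df <- (va / a$n + vb / b$n)^2 /
      (va^2 / (a$n^2 * (a$n - 1)) + vb^2 / (b$n^2 * (b$n - 1)))
  }
  list(delta = delta, se = se, df = df, t = delta / se,
       d = delta / (se + s0))
}

#' Differential protein abundance with permutation FDR
#'
#' Per protein, on log2 LFQ intensities: a two-sided two-sample t-test
#' (condition B minus A) and the s0-moderated statistic
#' `d = delta / (se + s0)`. The null distribution of `d` is built from
#' random label permutations (all distinct label assignments when fewer
#' than `n_permutations` exist). The significance cutoff is the
#' smallest `|d|` threshold whose permutation-estimated FDR (mean null
#' exceedances per permutation over observed exceedances) stays at or
#' below the configured target. A protein is dysregulated when both
#' `p < p_threshold` and `|d| >= cutoff` hold - the conjunction drawn as
#' asymptotic lines on a volcano plot.
#'
#' @param table a [quant_table()].
#' @param condA,condB condition labels (contrast is B - A).
#' @param config a [de_config()].
#' @param seed integer seed for the permutation draw.
#' @return data frame (class `dysregulation_result`) with one row per
#'   tested protein: `protein_id`, `log2_diff`, `t`, `d`, `p_value`,
#'   `perm_p`, `significant`, `direction` (`up`/`down`/`ns`), valid
#'   counts. Attributes: `d_cutoff`, `excluded` (proteins failing the
#'   valid-value filter), `cutoff_curve` (volcano-space significance
#'   boundary), `n_permutations_used`, `exhaustive`.
#' @export
differential_abundance <- function(table, condA, condB, config = de_config(),
                                   seed = 1) {
  stopifnot(inherits(table, "quant_table"))
  cond <- table$sample_conditions
  if (!condA %in% cond) stop("condition not in sample map: ", condA)
  if (!condB %in% cond) stop("condition not in sample map: ", condB)
  cols <- names(cond)[cond %in% c(condA, condB)]
  X <- log2(table$lfq[, cols, drop = FALSE])
  isB <- cond[cols] == condB
  M <- !is.na(X)
  keep <- rowSums(M[, !isB, drop = FALSE]) >= config$min_valid_per_group &
    rowSums(M[, isB, drop = FALSE]) >= config$min_valid_per_group
  excluded <- rownames(X)[!keep]
  X <- X[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  if (!nrow(X)) stop("no proteins pass the valid-value filter")
  X0 <- X
  X0[!M] <- 0

  obs <- .d_stat(X0, M, isB, config$s0, config$equal_var)
  p <- 2 * stats::pt(-abs(obs$t), obs$df)

  n <- length(cols)
  nB <- sum(isB)
  all_assign <- utils::combn(n, nB)
  exhaustive <- ncol(all_assign) <= config$n_permutations
  perm_sets <- if (exhaustive) {
    lapply(seq_len(ncol(all_assign)), function(j) all_assign[, j])
  } else {
    withr::with_seed(seed, {
      lapply(seq_len(config$n_permutations),
             function(j) sample.int(n, nB))
    })
  }
  B <- length(perm_sets)
  abs_obs <- abs(obs$d)
  exceed <- numeric(nrow(X))
  pool <- vector("list", B)
  tie_eps <- 1e-9 * (1 + abs_obs)  # float-safe ties (log2 round trips)
  for (j in seq_len(B)) {
    selB <- seq_len(n) %in% perm_sets[[j]]
    dj <- .d_stat(X0, M, selB, config$s0, config$equal_var)$d
    dj[!is.finite(dj)] <- 0
    exceed <- exceed + (abs(dj) >= abs_obs - tie_eps)
    pool[[j]] <- abs(dj)
  }
  perm_p <- if (exhaustive) exceed / B else (exceed + 1) / (B + 1)

  # smallest |d| threshold with estimated FDR <= target; the identity
  # and complement assignments replay any true effects, so they are
  # excluded from the null used for FDR estimation (they still count
  # toward the permutation p-values above)
  obs_set <- sort(which(isB))
  comp_set <- sort(which(!isB))
  is_null_perm <- vapply(perm_sets, function(s) {
    ss <- sort(s)
    !(identical(ss, obs_set) || identical(ss, comp_set))
  }, logical(1))
  null_pool <- pool[is_null_perm]
  cand <- sort(unique(abs_obs))
  n_obs_ge <- length(abs_obs) - findInterval(cand - 1e-12, sort(abs_obs))
  counts <- vapply(lapply(null_pool, sort), function(pj)
    length(pj) - findInterval(cand - 1e-12, pj), numeric(length(cand)))
  # median across permutations: robust to partial replay of true
  # effects in permutations that split the real groups unevenly
  n_null_ge <- apply(matrix(counts, nrow = length(cand)), 1, stats::median)
  fdr_hat <- pmin(1, n_null_ge / pmax(n_obs_ge, 1))
  ok <- which(fdr_hat <= config$fdr)
  d_cutoff <- if (length(ok)) cand[min(ok)] else Inf

  significant <- p < config$p_threshold & abs_obs >= d_cutoff
  direction <- ifelse(!significant, "ns", ifelse(obs$delta > 0, "up", "down"))

  res <- data.frame(protein_id = rownames(X), log2_diff = obs$delta,
                    t = obs$t, d = obs$d, p_value = p, perm_p = perm_p,
                    n_valid_A = rowSums(M[, !isB, drop = FALSE]),
                    n_valid_B = rowSums(M[, isB, drop = FALSE]),
                    significant = significant, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("dysregulation_result", "data.frame")
  attr(res, "d_cutoff") <- d_cutoff
  attr(res, "excluded") <- excluded
  attr(res, "n_permutations_used") <- B
  attr(res, "exhaustive") <- exhaustive
  attr(res, "contrast") <- c(A = condA, B = condB)
  attr(res, "cutoff_curve") <- .cutoff_curve(obs, d_cutoff, config)
  res
}

# volcano-space boundary of the conjunction p < p_threshold and
# |d| >= cutoff: for a given |delta|, |t| must reach
# cutoff*|delta| / (|delta| - cutoff*s0); translated to -log10 p with
# the median test df
.cutoff_curve <- function(obs, d_cutoff, config) {
  if (!is.finite(d_cutoff)) return(NULL)
  df <- stats::median(obs$df)
  dmax <- max(abs(obs$delta), 1) * 1.2
  delta <- seq(d_cutoff * config$s0 * 1.001, dmax, length.out = 200)
  t_req <- d_cutoff * delta / (delta - d_cutoff * config$s0)
  p_req <- 2 * stats::pt(-t_req, df)
  p_cap <- pmin(p_req, config$p_threshold)
  rbind(data.frame(log2_diff = -rev(delta), neg_log10_p = -log10(rev(p_cap))),
        data.frame(log2_diff = delta, neg_log10_p = -log10(p_cap)))
}

#' iBAQ abundance rank of a protein
#'
#' Within each replicate of the condition, proteins are sorted by iBAQ
#' score in decreasing order (rank 1 = most abundant); ties share the
#' minimal rank. Replicates in which the protein is not quantified are
#' skipped.
#'
#' @param table a [quant_table()] with an iBAQ channel.
#' @param condition condition whose replicates are ranked.
#' @param protein protein id.
#' @return object of class `abundance_rank`: list with `protein`,
#'   `ranks` (named per-replicate), `mean_rank`, `rank_sd`.
#' @export
rank_abundance <- function(table, condition, protein) {
  stopifnot(inherits(table, "quant_table"))
  if (is.null(table$ibaq)) stop("table has no iBAQ channel")
  if (!protein %in% rownames(table$ibaq)) stop("unknown protein: ", protein)
  cols <- names(table$sample_conditions)[table$sample_conditions == condition]
  if (!length(cols)) stop("condition not in sample map: ", condition)
  ranks <- c()
  for (cl in cols) {
    v <- table$ibaq[, cl]
    if (is.na(v[protein])) next
    quantified <- !is.na(v)
    r <- rank(-v[quantified], ties.method = "min")
    ranks[cl] <- r[[protein]]
  }
  if (!length(ranks)) stop("protein not quantified in any replicate of ", condition)
  structure(list(protein = protein, ranks = ranks, mean_rank = mean(ranks),
                 rank_sd = if (length(ranks) > 1) stats::sd(ranks) else NA_real_),
            class = "abundance_rank")
}

#' @export
print.abundance_rank <- function(x, ...) {
  cat(sprintf("<abundance_rank> %s: %.0f +/- %.0f (n=%d)\n", x$protein,
              x$mean_rank, x$rank_sd, length(x$ranks)))
  invisible(x)
}

.sig_set <- function(res, direction) {
  sig <- res[res$significant, , drop = FALSE]
  if (direction != "either") sig <- sig[sig$direction == direction, , drop = FALSE]
  sig$protein_id
}

#' Overlap of dysregulated sets across conditions
#'
#' Exact set algebra over the significant proteins of two or more
#' differential-abundance results, computed separately for up, down and
#' either direction. Membership lists are returned, not just counts.
#'
#' @param results named list of [differential_abundance()] results.
#' @param direction `"either"`, `"up"` or `"down"`.
#' @return list with `membership` (data frame: protein and the
#'   comma-joined set key of results containing it), `counts` (table of
#'   proteins per subset key), `unique` (named list of proteins found in
#'   exactly one result) and `shared` (proteins found in all results).
#' @export
overlap_sets <- function(results, direction = c("either", "up", "down")) {
  direction <- match.arg(direction)
  if (length(results) < 2) stop("need at least 2 result sets")
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be named")
  sets <- lapply(results, .sig_set, direction = direction)
  universe <- sort(unique(unlist(sets)))
  key <- vapply(universe, function(p) {
    paste(names(sets)[vapply(sets, function(s) p %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  membership <- data.frame(protein_id = universe, sets = unname(key),
                           stringsAsFactors = FALSE)
  uniq <- lapply(names(sets), function(nm)
    membership$protein_id[membership$sets == nm])
  names(uniq) <- names(sets)
  shared_key <- paste(names(sets), collapse = "&")
  list(membership = membership,
       counts = table(membership$sets),
       unique = uniq,
       shared = membership$protein_id[membership$sets == shared_key])
}

#' Remove common-core proteins from a dysregulated set
#'
#' Set difference that preserves the per-protein statistics: rows whose
#' protein appears in `core` are dropped.
#'
#' @param target a [differential_abundance()] result (or any data frame
#'   with a `protein_id` column).
#' @param core character vector of common-core protein ids.
#' @return the filtered data frame (attributes preserved).
#' @export
remove_common_core <- function(target, core) {
  keep <- !target$protein_id %in% core
  out <- target[keep, , drop = FALSE]
  for (a in setdiff(names(attributes(target)),
                    c("names", "row.names", "class")))
    attr(out, a) <- attr(target, a)
  out
}
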