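# independent brute-force oracle: classical pooled t and exhaustive
# label-permutation p for one protein's 3v3 values
brute_perm <- function(a, b, s0 = 0) {
  x <- c(a, b)
  nA <- length(a)
  stat <- function(sel) {
    g1 <- x[-sel]
    g2 <- x[sel]
    sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
      (length(g1) + length(g2) - 2)
    se <- sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
    (mean(g2) - mean(g1)) / (se + s0)
  }
  sels <- combn(length(x), length(b), simplify = FALSE)
  obs <- stat(seq(nA + 1, nA + length(b)))
  perms <- vapply(sels, stat, numeric(1))
  list(d = obs, perm_p = mean(abs(perms) >= abs(obs) - 1e-9 * (1 + abs(obs))))
}

toy_table <- function(vals) {
  # vals: list of c(a1,a2,a3,b1,b2,b3) per protein
  lfq <- 2^do.call(rbind, vals)
  rownames(lfq) <- paste0("P", seq_along(vals))
  colnames(lfq) <- c("A_1", "A_2", "A_3", "B_1", "B_2", "B_3")
  quant_table(lfq, sample_conditions = setNames(rep(c("A", "B"), each = 3),
                                               colnames(lfq)))
}

test_that("with s0 = 0 the moderated statistic is the classical t and the
           permutation p matches exhaustive enumeration", {
  vals <- list(c(10, 10.2, 9.9, 12, 12.3, 11.8),
               c(8, 8.1, 7.9, 8.05, 7.95, 8.02),
               c(14, 13.5, 14.2, 12.9, 13.1, 13.4),
               c(20, 20.1, 19.8, 20.2, 19.9, 20.05))
  tab <- toy_table(vals)
  res <- differential_abundance(tab, "A", "B",
                                de_config(s0 = 0, n_permutations = 25))
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations_used"), choose(6, 3))
  for (i in seq_along(vals)) {
    oracle <- brute_perm(vals[[i]][1:3], vals[[i]][4:6], s0 = 0)
    row <- res[res$protein_id == paste0("P", i), ]
    expect_equal(row$d, oracle$d, tolerance = 1e-8)
    expect_equal(row$t, oracle$d, tolerance = 1e-8)  # s0 = 0
    expect_equal(row$perm_p, oracle$perm_p, tolerance = 1e-12)
    # parametric p agrees with t.test's pooled-variance p
    tt <- t.test(vals[[i]][4:6], vals[[i]][1:3], var.equal = TRUE)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("spike-in effects are recovered with the FDR under control", {
  sp <- simulate_proteome(n_proteins = 800, frac_dys = 0.05, log2_effect = 2,
                          rep_sd_log2 = 0.25, seed = 21)
  res <- differential_abundance(sp$table, "A", "B", seed = 21)
  m <- merge(res, sp$truth, by = "protein_id")
  tp <- sum(m$significant & m$label != "null")
  fp <- sum(m$significant & m$label == "null")
  expect_gte(tp / sum(m$label != "null"), 0.8)
  expect_lte(fp / max(1, tp + fp), 0.2)
  # direction agrees with the spiked sign
  sig <- m[m$significant & m$label != "null", ]
  expect_true(all(sig$direction == ifelse(sig$label == "up", "up", "down")))
})

test_that("proteins failing the valid-value filter are excluded and listed", {
  vals <- list(c(10, 10.2, 9.9, 12, 12.3, 11.8),
               c(8, 8.1, 7.9, 8.05, 7.95, 8.02))
  tab <- toy_table(vals)
  tab$lfq["P2", c("B_1", "B_2")] <- NA
  res <- differential_abundance(tab, "A", "B",
                                de_config(s0 = 0, n_permutations = 25))
  expect_equal(attr(res, "excluded"), "P2")
  expect_equal(res$protein_id, "P1")
  expect_error(differential_abundance(tab, "A", "Z"), "not in sample map")
})

test_that("iBAQ ranks use decreasing order with minimal tie ranks", {
  ibaq <- rbind(P1 = c(100, 100, 100), P2 = c(50, 60, 55),
                P3 = c(50, 40, 30), P4 = c(10, 20, 15))
  colnames(ibaq) <- paste0("A_", 1:3)
  lfq <- ibaq * 7
  tab <- quant_table(lfq, ibaq,
                     setNames(rep("A", 3), colnames(lfq)))
  top <- rank_abundance(tab, "A", "P1")
  expect_equal(top$mean_rank, 1)
  expect_equal(top$rank_sd, 0)
  # P2 and P3 tie in replicate 1 -> both rank 2
  expect_equal(unname(rank_abundance(tab, "A", "P2")$ranks[1]), 2)
  expect_equal(unname(rank_abundance(tab, "A", "P3")$ranks[1]), 2)
  expect_error(rank_abundance(tab, "A", "P9"), "unknown protein")
})

test_that("constructed ranks reproduce the mean +/- SD convention", {
  # a protein ranked 99, 101, 103 across replicates reads 101 +/- 2
  n <- 120
  ibaq <- matrix(rep(seq(n, 1), 3), n, 3)
  rownames(ibaq) <- paste0("P", seq_len(n))
  colnames(ibaq) <- paste0("A_", 1:3)
  target <- "P100"
  ibaq[target, ] <- c(ibaq[22, 1], ibaq[18, 2], ibaq[26, 3]) +
    c(0.5, 0.5, 0.5) # sits between existing values
  ranks <- rank_abundance(quant_table(ibaq * 3, ibaq,
                                      setNames(rep("A", 3), colnames(ibaq))),
                          "A", target)
  expect_equal(unname(ranks$ranks), c(22, 18, 26))
  expect_equal(ranks$mean_rank, 22)
  expect_equal(ranks$rank_sd, 4)
})

test_that("rank order is invariant under monotone iBAQ transforms", {
  sp <- simulate_proteome(n_proteins = 60, seed = 3, missing_rate = 0)
  tab <- sp$table
  tab2 <- quant_table(tab$lfq, tab$ibaq^3 * 10, tab$sample_conditions)
  for (p in rownames(tab$lfq)[c(1, 17, 42)]) {
    expect_identical(rank_abundance(tab, "A", p)$ranks,
                     rank_abundance(tab2, "A", p)$ranks)
  }
})

test_that("set overlap enumerates memberships exactly", {
  mk <- function(ids, dirs) {
    df <- data.frame(protein_id = ids, log2_diff = ifelse(dirs == "up", 1, -1),
                     significant = TRUE, direction = dirs,
                     stringsAsFactors = FALSE)
    class(df) <- c("dysregulation_result", "data.frame")
    df
  }
  a <- mk(c("p1", "p2", "p3"), c("up", "up", "down"))
  b <- mk(c("p2", "p3", "p4"), c("up", "down", "down"))
  ov <- overlap_sets(list(A = a, B = b))
  expect_setequal(ov$shared, c("p2", "p3"))
  expect_equal(ov$unique$A, "p1")
  expect_equal(ov$unique$B, "p4")
  expect_equal(sum(ov$counts), 4)  # |A union B|
  up <- overlap_sets(list(A = a, B = b), direction = "up")
  expect_equal(up$shared, "p2")
  # identical and disjoint cases
  same <- overlap_sets(list(A = a, B = a))
  expect_setequal(same$shared, c("p1", "p2", "p3"))
  expect_length(same$unique$A, 0)
  disj <- overlap_sets(list(A = mk(paste0("x", 1:3), rep("up", 3)),
                            B = mk(paste0("y", 1:5), rep("up", 5))))
  expect_length(disj$shared, 0)
  expect_length(disj$unique$A, 3)
  expect_length(disj$unique$B, 5)
  expect_error(overlap_sets(list(a)), "at least 2")
})

test_that("common-core removal is a statistics-preserving set difference", {
  df <- data.frame(protein_id = paste0("p", 1:10), d = rnorm(10),
                   significant = TRUE, direction = "up",
                   stringsAsFactors = FALSE)
  out <- remove_common_core(df, paste0("p", c(2, 4, 6, 8)))
  expect_equal(nrow(out), 6)
  expect_identical(out$d, df$d[!df$protein_id %in% paste0("p", c(2, 4, 6, 8))])
  expect_equal(nrow(remove_common_core(df, df$protein_id)), 0)
  expect_identical(remove_common_core(df, "zz")$protein_id, df$protein_id)
})

test_that("the protein-groups reader drops flagged rows and zero intensities", {
  dir <- withr::local_tempdir()
  df <- data.frame(protein_id = c("P1", "P2", "CON1"),
                   `LFQ.A_1` = c(100, 200, 300), `LFQ.B_1` = c(110, 0, 330),
                   `iBAQ.A_1` = c(10, 20, 30), `iBAQ.B_1` = c(11, 21, 33),
                   flags = c("", "", "+"), check.names = FALSE)
  f <- file.path(dir, "quant.tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- read_quant_table(f, setNames(c("A", "B"), c("A_1", "B_1")))
  expect_equal(rownames(tab$lfq), c("P1", "P2"))
  expect_true(is.na(tab$lfq["P2", "B_1"]))  # zero treated as missing
  expect_equal(tab$ibaq["P1", "A_1"], 10)
})
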