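test_that("trapezoidal integration handles canonical shapes", {
  # triangle (0,0)-(1,2)-(2,0): area 2
  expect_equal(integrate_auc(c(0, 1, 2), c(0, 2, 0), c(0, 2), "none"), 2)
  # finely sampled Gaussian: area within 1% of A * sigma * sqrt(2*pi)
  A <- 1e5; sg <- 0.1
  rt <- seq(-5 * sg, 5 * sg, by = sg / 20) + 10
  y <- A * exp(-(rt - 10)^2 / (2 * sg^2))
  expect_lt(abs(integrate_auc(rt, y, range(rt), "none") /
                  (A * sg * sqrt(2 * pi)) - 1), 0.01)
  # all-zero trace
  expect_equal(integrate_auc(rt, rep(0, length(rt)), range(rt), "none"), 0)
  expect_error(integrate_auc(rt, y, c(10.99, 11)), "at least 2 points")
})

test_that("integration is linear and the flat-min baseline removes offsets", {
  rt <- seq(0, 4, by = 0.01)
  y <- exp(-(rt - 2)^2 / 0.08)
  a1 <- integrate_auc(rt, y, range(rt), "none")
  expect_equal(integrate_auc(rt, 3.7 * y, range(rt), "none"), 3.7 * a1,
               tolerance = 1e-12)
  expect_equal(integrate_auc(rt, y + 5, range(rt), "flat_min"), a1,
               tolerance = 1e-9)
})

test_that("identical traces give unit ratio and zero spread", {
  sim <- simulate_chromatograms(c(pSer = 1, Gly = 1), noise_sd = 0, seed = 1)
  prof <- incorporation_profile(sim$set)
  gly <- prof[prof$variant == "Gly", ]
  expect_equal(gly$ratio, 1, tolerance = 1e-9)
  expect_equal(gly$ratio_sd, 0, tolerance = 1e-12)
})

test_that("ratios are recovered within 10% under 5% peak noise", {
  truth <- c(pSer = 1, Gly = 5, Thr = 5, Ser = 0.5)
  peak_height <- 1e6 * stats::dnorm(0, 0, 0.1)
  est <- sapply(1:10, function(sd) {
    sim <- simulate_chromatograms(truth, base_area = 1e6, peak_sigma = 0.1,
                                  noise_sd = 0.05 * peak_height,
                                  n_reps = 3, seed = sd)
    prof <- incorporation_profile(sim$set)
    prof$ratio[match(c("Gly", "Thr", "Ser"), prof$variant)]
  })
  med <- apply(est, 1, median)
  expect_lt(abs(med[1] / 5 - 1), 0.1)
  expect_lt(abs(med[2] / 5 - 1), 0.1)
  expect_lt(abs(med[3] / 0.5 - 1), 0.1)
})

test_that("a zero-area variant is flagged below the limit of detection", {
  sim <- simulate_chromatograms(c(pSer = 1, Thr = 0), noise_sd = 20,
                                base_area = 1e6, seed = 2)
  prof <- incorporation_profile(sim$set)
  thr <- prof[prof$variant == "Thr", ]
  expect_true(thr$below_lod)
  expect_equal(thr$ratio, 0)
  expect_false(prof$below_lod[prof$variant == "pSer"])
})

test_that("replicates with zero pSer area are excluded with a diagnostic", {
  sim <- simulate_chromatograms(c(pSer = 1, Gly = 2), noise_sd = 0, seed = 1)
  tr <- sim$set$traces
  tr$intensity[tr$variant == "pSer" & tr$replicate == 2] <- 0
  set2 <- chromatogram_set(tr, sim$set$boundaries)
  prof <- incorporation_profile(set2)
  expect_equal(attr(prof, "excluded_replicates"), "2")
  expect_equal(prof$n_replicates[prof$variant == "Gly"], 2)
  tr$intensity[tr$variant == "pSer"] <- 0
  expect_error(incorporation_profile(chromatogram_set(tr, sim$set$boundaries)),
               "zero in every replicate")
})

test_that("ratios are invariant under per-replicate intensity scaling", {
  sim <- simulate_chromatograms(c(pSer = 1, Gly = 3), noise_sd = 0,
                                n_reps = 2, seed = 1)
  tr <- sim$set$traces
  tr$intensity[tr$replicate == 2] <- tr$intensity[tr$replicate == 2] * 12
  prof <- incorporation_profile(chromatogram_set(tr, sim$set$boundaries))
  expect_equal(prof$ratio[prof$variant == "Gly"], 3, tolerance = 1e-9)
  expect_equal(prof$ratio_sd[prof$variant == "Gly"], 0, tolerance = 1e-9)
})

test_that("the chromatogram reader round-trips the generator output", {
  dir <- withr::local_tempdir()
  sim <- simulate_chromatograms(c(pSer = 1, Gly = 2), noise_sd = 0, seed = 1)
  fc <- file.path(dir, "chrom.csv")
  fb <- file.path(dir, "bounds.csv")
  write.csv(sim$set$traces, fc, row.names = FALSE)
  write.csv(sim$set$boundaries, fb, row.names = FALSE)
  set <- read_chromatograms(fc, fb)
  prof <- incorporation_profile(set)
  expect_equal(prof$ratio[prof$variant == "Gly"], 2, tolerance = 1e-6)
})

test_that("the standard curve is exact on collinear points", {
  fit <- fit_standard_curve(data.frame(ng = c(10, 20), intensity = c(100, 200)))
  expect_equal(fit$slope, 10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  fit3 <- fit_standard_curve(data.frame(ng = c(5, 10, 20),
                                        intensity = c(60, 110, 210)))
  expect_equal(fit3$slope, 10)
  expect_equal(fit3$intercept, 10, tolerance = 1e-10)
  expect_error(fit_standard_curve(data.frame(ng = c(7, 7),
                                             intensity = c(1, 2))),
               "distinct")
})

test_that("gel mass inversion and phospho adjustment follow the model", {
  sim <- simulate_densitometry(sample_total_ng = 140, phos_fraction = 0.25,
                               noise_sd = 0, seed = 1)
  expect_equal(total_mass_from_gel(sim$gel), 140)
  expect_equal(phosphoprotein_yield(100, 60, 40), 60)
  expect_equal(phosphoprotein_yield(100, 50, 50), 50)
  expect_equal(phosphoprotein_yield(100, 80, 0), 100)
  expect_error(phosphoprotein_yield(100, 0, 0), "positive")
})

test_that("the gel reader reconstructs the quant table", {
  dir <- withr::local_tempdir()
  df <- rbind(
    data.frame(role = "standard", ng = c(25, 50, 100), intensity = c(250, 500, 1000)),
    data.frame(role = "total", ng = NA, intensity = 700),
    data.frame(role = "upper", ng = NA, intensity = 420),
    data.frame(role = "lower", ng = NA, intensity = 280))
  f <- file.path(dir, "gel.tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  gel <- read_gel_quant(f)
  expect_equal(total_mass_from_gel(gel), 70)
  expect_equal(phosphoprotein_yield(total_mass_from_gel(gel),
                                    gel$upper_intensity, gel$lower_intensity),
               42)
})
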