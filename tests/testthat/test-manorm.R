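test_that("compute_ma matches closed forms and is inverse-consistent", {
  expect_equal(compute_ma(8, 2), data.frame(m = 2, a = 2))
  expect_equal(compute_ma(4, 4), data.frame(m = 0, a = 2))
  expect_equal(compute_ma(1, 16), data.frame(m = -4, a = 2))
  set.seed(1)
  ko <- 2^runif(50, 0, 12); wt <- 2^runif(50, 0, 12)
  ma <- compute_ma(ko, wt)
  expect_equal(2^(ma$a + ma$m / 2), ko)
  expect_equal(2^(ma$a - ma$m / 2), wt)
  expect_error(compute_ma(0, 1), "positive")
})

test_that("robust fit recovers a noiseless line exactly and resists outliers", {
  a <- seq(2, 12, length.out = 100)
  m <- 0.5 + 0.25 * a
  fit <- fit_normalization(data.frame(m = m, a = a))
  expect_equal(fit$intercept, 0.5, tolerance = 1e-8)
  expect_equal(fit$slope, 0.25, tolerance = 1e-8)

  m_out <- m
  m_out[1:10] <- m_out[1:10] + 5
  fit2 <- fit_normalization(data.frame(m = m_out, a = a))
  # oracle: ordinary least squares restricted to the 90 clean points
  ols <- coef(lm(m_out[11:100] ~ a[11:100]))
  expect_lt(abs(fit2$slope - ols[2]), 0.05)

  expect_error(fit_normalization(data.frame(m = m[1:5], a = a[1:5])),
               "insufficient")
})

test_that("Huber IRLS agrees with the independent rlm implementation", {
  set.seed(42)
  a <- runif(400, 4, 12)
  m <- 0.4 + 0.1 * a + rnorm(400, 0, 0.3)
  m[1:40] <- m[1:40] + 4
  fit <- fit_normalization(data.frame(m = m, a = a))
  ref <- MASS::rlm(m ~ a, k = 1.345, maxit = 50)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 0.01)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 0.005)
})

test_that("normalization and classification follow their definitions", {
  model <- structure(list(intercept = 0.5, slope = 0.25),
                     class = "normalization_model")
  expect_equal(normalize_m(data.frame(m = 2, a = 4), model), 0.5)
  expect_equal(normalize_m(data.frame(m = 0.5 + 0.25 * 6, a = 6), model), 0)
  ident <- structure(list(intercept = 0, slope = 0),
                     class = "normalization_model")
  expect_equal(normalize_m(data.frame(m = 1.7, a = 3), ident), 1.7)

  expect_equal(as.character(classify_peaks(c(1.2, -1.5, 1.0, -1.0, 0))),
               c("ko_specific", "wt_specific", "common", "common", "common"))
  expect_error(classify_peaks(1, threshold = 0), "threshold")
})

# identical catalogs with exact power-of-two counts; no rounding artifacts
exact_fixture <- function(mult_ko = 1) {
  n <- 40L
  start <- seq(0, by = 5000, length.out = n)
  len <- 1000
  a <- seq(4, 12, length.out = n)
  count_wt <- 2^a * len / 1000
  ps <- peak_set("chr1", start, start + len, read_count = count_wt)
  counts <- data.frame(chrom = "chr1", start = start, end = start + len,
                       count_ko = count_wt * mult_ko, count_wt = count_wt)
  list(ps = ps, counts = counts)
}

test_that("self-comparison yields zero normalized M and no specific peaks", {
  fx <- exact_fixture()
  fit <- manorm(fx$ps, fx$ps, counts = fx$counts, pseudocount = 0)
  expect_equal(residuals(fit), rep(0, nrow(fx$counts)), tolerance = 1e-12)
  expect_equal(sum(fit$table$label != "common"), 0L)
})

test_that("normalization is equivariant under a global scaling of one sample", {
  fx1 <- exact_fixture(1)
  fx4 <- exact_fixture(2^2)  # KO densities multiplied by 2^2
  fit1 <- manorm(fx1$ps, fx1$ps, counts = fx1$counts, pseudocount = 0)
  fit4 <- manorm(fx4$ps, fx4$ps, counts = fx4$counts, pseudocount = 0)
  # every raw M shifts by k = 2; normalized M is unchanged after refit
  expect_equal(fit4$table$m_raw - fit1$table$m_raw,
               rep(2, nrow(fx1$counts)), tolerance = 1e-9)
  expect_equal(residuals(fit4), residuals(fit1), tolerance = 1e-6)
})

test_that("zero counts error without a pseudocount and warn when one-sided", {
  fx <- exact_fixture()
  fx$counts$count_ko[1] <- 0
  expect_error(manorm(fx$ps, fx$ps, counts = fx$counts, pseudocount = 0),
               "pseudocount")
  fx$counts$count_ko[] <- 0
  expect_warning(fit <- manorm(fx$ps, fx$ps, counts = fx$counts),
                 "all-zero")
  expect_true(all(is.finite(residuals(fit))))
})

test_that("unique peaks require cross-sample counts", {
  ko <- peak_set("chr1", c(0, 5000), c(1000, 6000), read_count = c(10, 20))
  wt <- peak_set("chr1", 0, 1000, read_count = 12)
  expect_error(manorm(ko, wt), "cross-sample")
})

test_that("the pipeline recovers the latent scaling of a simulated experiment", {
  sim <- small_sim()
  fit <- manorm(sim$experiment$ko, sim$experiment$wt,
                counts = sim$experiment$counts)
  cf <- coef(fit)
  p <- sim$params
  expect_lt(abs(cf["intercept"] - p$c0), 0.1)
  expect_lt(abs(cf["slope"] - p$c1), 0.02)
  # residual centering over the peaks used for the fit
  expect_lt(abs(mean(residuals(fit)[fit$table$used_in_fit])), 0.05)
  # origin bookkeeping: every catalog peak appears exactly once
  expect_equal(nrow(fit$table),
               nrow(fit$pairing$common_pairs) +
                 length(fit$pairing$unique_a) +
                 length(fit$pairing$unique_b))
})

test_that("a mask excludes overlapping common peaks from the fit only", {
  sim <- small_sim()
  counts <- sim$experiment$counts
  tr <- sim$experiment$truth$region
  common_idx <- which(tr$truth == "null_common")
  contaminated <- common_idx[seq_len(round(0.1 * length(common_idx)))]
  counts2 <- counts
  counts2$count_ko[contaminated] <- counts2$count_ko[contaminated] * 2^5
  mask <- peak_set(counts$chrom[contaminated], counts$start[contaminated],
                   counts$end[contaminated])

  fit_clean <- manorm(sim$experiment$ko, sim$experiment$wt, counts = counts,
                      mask = mask)
  fit_cont <- manorm(sim$experiment$ko, sim$experiment$wt, counts = counts2,
                     mask = mask)
  expect_equal(coef(fit_cont), coef(fit_clean), tolerance = 1e-6)
  expect_equal(fit_cont$model$excluded_n, length(contaminated))
  # without the mask the contamination biases the fit
  fit_nomask <- manorm(sim$experiment$ko, sim$experiment$wt,
                       counts = counts2)
  expect_gt(abs(coef(fit_nomask)["intercept"] -
                  coef(fit_clean)["intercept"]), 1e-3)
  # masked peaks are still normalized and present in the output
  expect_equal(nrow(fit_cont$table), nrow(fit_clean$table))
})

test_that("manorm methods expose the fit consistently", {
  fx <- exact_fixture(2)
  fit <- manorm(fx$ps, fx$ps, counts = fx$counts, pseudocount = 0)
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(predict(fit, a = 0), coef(fit)[["intercept"]])
  expect_equal(unname(residuals(fit)),
               fit$table$m_raw - predict(fit), tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.manorm")
  expect_equal(s$n_regions, nrow(fx$counts))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), sum(fit$table$used_in_fit))
  f <- withr::local_tempfile()
  write_manorm(fit, f)
  rt <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(rt), nrow(fit$table))
  expect_equal(rt$m_normalized, fit$table$m_normalized, tolerance = 1e-12)
})
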