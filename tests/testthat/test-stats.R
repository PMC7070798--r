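# statistics layer: OLS against a hand-written normal-equations oracle,
# grouped fits, sequential ANOVA

# normal-equations oracle, independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  se <- sqrt(ssres / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * pt(-abs(tstat), n - 2), r2 = 1 - ssres / sstot)
}

test_that("linear_fit reproduces exact lines and the worked example", {
  x <- 0:4
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  f <- linear_fit(c(0, 1, 2, 3), c(0, 2, 3, 5))
  expect_equal(f$slope, 1.6, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-10)
  expect_equal(f$r_squared, 0.9846154, tolerance = 1e-6)
})

test_that("linear_fit agrees with the normal-equations oracle to 1e-10", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n)
    f <- linear_fit(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$se_slope, o$se, tolerance = 1e-10)
    expect_equal(f$p_value, o$p, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-10)
    # R^2 equals the squared Pearson correlation
    expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("linear_fit rejects degenerate input", {
  expect_error(linear_fit(rep(1, 5), rnorm(5)), "variance")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
  expect_error(linear_fit(1:4, 1:5), "equal length")
})

make_records <- function(n_per = 4, treatments = c("A", "B", "C"),
                         seed = 1, noise = 0) {
  set.seed(seed)
  k <- length(treatments) * n_per
  truth <- data.frame(treatment = rep(treatments, each = n_per),
                      plot = rep(seq_len(n_per), length(treatments)),
                      true_shoot_volume = runif(k, 1e-3, 5e-3))
  truth$true_biomass <- 450 * truth$true_shoot_volume
  vols <- data.frame(n_scans = rpois(k, 300), n_points = rpois(k, 5000),
                     volume_total = truth$true_shoot_volume * 1.1,
                     volume_no_structures = truth$true_shoot_volume)
  biomass <- truth$true_biomass * (1 + rnorm(k, 0, noise))
  batch_records(truth, vols, biomass)
}

test_that("grouped fits: exact link gives R^2 = 1; labels and order invariance", {
  rec <- make_records()
  fits <- fits_by_group(rec, "volume_no_structures")
  expect_equal(nrow(fits), 4)  # 3 treatments + pooled
  expect_true(all(abs(fits$r_squared - 1) < 1e-12))
  expect_true(all(abs(fits$estimate - 450) < 1e-9))

  # pooled row equals a direct fit on all records
  pooled <- fits[fits$treatment == "all", ]
  direct <- linear_fit(rec$volume_no_structures, rec$biomass)
  expect_equal(pooled$estimate, direct$slope)
  expect_equal(pooled$r_squared, direct$r_squared)

  # permuting record order changes nothing
  rec2 <- rec[sample(nrow(rec)), ]
  class(rec2) <- class(rec)
  fits2 <- fits_by_group(rec2, "volume_no_structures")
  a <- fits2[order(fits2$treatment), -2]
  b <- fits[order(fits$treatment), -2]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)

  # a tiny group is skipped with a warning
  rec3 <- rec[rec$treatment != "C" | rec$plot <= 2, ]
  class(rec3) <- class(rec)
  expect_warning(f3 <- fits_by_group(rec3, "volume_no_structures"),
                 "fewer than 3")
  expect_false("C" %in% f3$treatment)
})

test_that("sequential ANOVA detects a constructed signal and rejects singular designs", {
  set.seed(5)
  rec <- make_records(n_per = 6)
  # response exactly equal to the predictor, treatment is noise
  rec$biomass <- rec$n_scans
  a <- anova_records(rec, "n_scans")
  expect_lt(a["n_scans", "Pr(>F)"], 1e-12)
  expect_gt(a["treatment", "Pr(>F)"], 0.01)

  # one observation per treatment: no residual degrees of freedom
  rec1 <- make_records(n_per = 1)
  expect_error(anova_records(rec1, "n_scans"), "singular")
})

test_that("ANOVA p-values are uniform under the null", {
  # pure-noise response: the predictor p-value over seeded replicates must
  # be indistinguishable from Uniform(0,1) (KS test at the 1% level)
  set.seed(123)
  reps <- 500
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    k <- 20
    rec <- data.frame(treatment = rep(c("A", "B", "C", "D"), each = 5),
                      n_scans = rnorm(k), biomass = rnorm(k))
    a <- anova_records(rec, "n_scans")
    p[r] <- a["n_scans", "Pr(>F)"]
  }
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
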