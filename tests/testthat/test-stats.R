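test_that("choose_and_compare gates on normality and handles edge cases", {
  set.seed(1)
  a <- rnorm(8, 1.340, 0.001)

  # identical groups: never significant
  r <- choose_and_compare(a, a)
  expect_gte(r$p_value, 0.05)
  expect_false(r$significant)

  # clearly normal groups take the t path
  set.seed(2)
  b <- rnorm(8, 1.345, 0.001)
  r2 <- choose_and_compare(a, b)
  expect_equal(r2$path, "normal->ttest")
  expect_true(r2$significant)

  # a heavy outlier breaks normality and routes to Mann-Whitney
  r3 <- choose_and_compare(c(a, 2.5), b)
  expect_equal(r3$path, "nonnormal->mannwhitney")
  expect_equal(r3$test, "mannwhitney")

  # degenerate zero-variance inputs: Mann-Whitney with a warning flag
  expect_warning(r4 <- choose_and_compare(rep(1, 4), rep(1, 4)),
                 "zero-variance")
  expect_true(r4$degenerate)
  expect_equal(r4$test, "mannwhitney")
  expect_false(r4$significant)

  expect_error(choose_and_compare(1, c(1, 2)), "at least 2")
})

test_that("t-test power on a 5-sigma effect is near 1 over 200 seeds", {
  reject <- vapply(1:200, function(s) {
    set.seed(s)
    choose_and_compare(rnorm(15, 1.340, 0.001),
                       rnorm(15, 1.345, 0.001))$significant
  }, TRUE)
  expect_gte(mean(reject), 0.99)
})

test_that("Mann-Whitney p matches brute-force rank enumeration", {
  # the textbook disjoint case: U = 0, exact two-sided p = 0.1
  r <- choose_and_compare(c(1, 2, 3), c(4, 5, 6), force = "mannwhitney")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(mw_enum_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)

  # random tie-free cases agree with the enumeration oracle
  for (s in 1:5) {
    set.seed(s)
    a <- sample(seq(1, 40), 4)
    b <- sample(seq(0.5, 40.5), 5)
    r <- choose_and_compare(a, b, force = "mannwhitney")
    expect_equal(r$p_value, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("one-way ANOVA reduces to the squared t-test at k = 2", {
  set.seed(3)
  g1 <- rnorm(9, 0, 1); g2 <- rnorm(7, 0.8, 1)
  ow <- holoRI:::oneway_f(list(a = g1, b = g2))
  tt <- choose_and_compare(g1, g2, force = "ttest")
  expect_equal(ow$table$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(ow$table$p_value, tt$p_value, tolerance = 1e-12)
  expect_error(compare_across_stages(list(a = g1, b = g2)), "3 groups")
})

test_that("compare_across_stages flags only the shifted group", {
  set.seed(4)
  groups <- lapply(1:5, function(i) rnorm(8, 0, 1))
  names(groups) <- paste0("g", 1:5)
  groups$g5 <- groups$g5 + 5   # 5 sigma shift
  res <- compare_across_stages(groups)
  expect_true(res$significant)
  hit <- grepl("g5", res$tukey$pair)
  expect_true(all(res$tukey$p_adj[hit] < 0.05))
  expect_true(all(res$tukey$p_adj[!hit] >= 0.05))
  # letters: g5 shares no letter with the others
  l5 <- strsplit(res$letters[["g5"]], "")[[1]]
  for (g in paste0("g", 1:4))
    expect_length(intersect(l5, strsplit(res$letters[[g]], "")[[1]]), 0)
})

test_that("type-I error stays controlled under the null (500 reps)", {
  mc <- 2 * sqrt(0.05 * 0.95 / 500)
  # two-group paths
  rej_t <- rej_mw <- logical(500)
  for (s in 1:500) {
    set.seed(s)
    a <- rnorm(8); b <- rnorm(8)
    rej_t[s] <- choose_and_compare(a, b, force = "ttest")$significant
    rej_mw[s] <- choose_and_compare(a, b, force = "mannwhitney")$significant
  }
  expect_lte(mean(rej_t), 0.05 + mc)
  expect_lte(mean(rej_mw), 0.05 + mc)

  # ANOVA + Tukey family-wise error over 5 identical groups
  fwe <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    g <- lapply(1:5, function(i) rnorm(5))
    names(g) <- paste0("g", 1:5)
    any(compare_across_stages(g)$tukey$p_adj < 0.05)
  }, TRUE)
  expect_lte(mean(fwe), 0.07)
})

test_that("Tukey-adjusted p is never below the unadjusted pairwise p", {
  for (s in 1:3) {
    set.seed(s)
    g <- lapply(1:4, function(i) rnorm(6, mean = i * 0.3))
    names(g) <- paste0("g", 1:4)
    res <- compare_across_stages(g)
    ow <- holoRI:::oneway_f(g)
    mse <- sum(stats::residuals(ow$fit)^2) / ow$table$df2
    for (i in seq_len(nrow(res$tukey))) {
      pr <- strsplit(res$tukey$pair[i], "-")[[1]]
      se <- sqrt(mse * (1 / length(g[[pr[1]]]) + 1 / length(g[[pr[2]]])))
      p_un <- 2 * stats::pt(-abs(res$tukey$diff[i]) / se, ow$table$df2)
      expect_gte(res$tukey$p_adj[i] + 1e-12, p_un)
    }
  }
})

test_that("radius sensitivity is zero at f = 0 and grows with |f|", {
  cfg <- cfg_small()
  ctr <- field_centre(cfg)
  roi <- circular_roi(ctr[["x"]], ctr[["y"]], 50)
  truth <- phantom_phase(sphere_spec(cfg, 50, 0.004), cfg)
  tab <- radius_sensitivity(truth, roi, cfg,
                            perturb_fracs = c(-0.15, -0.05, 0, 0.05, 0.15))
  expect_equal(tab$rel_change[tab$fraction == 0], 0)
  up <- abs(tab$rel_change[tab$fraction > 0])
  dn <- abs(rev(tab$rel_change[tab$fraction < 0]))
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
  expect_true(all(is.finite(tab$mean_ri)))
})

test_that("background sensitivity: zero amplitude and pure offsets do nothing", {
  cfg <- cfg_small()
  ctr <- field_centre(cfg)
  roi <- circular_roi(ctr[["x"]], ctr[["y"]], 50)
  truth <- phantom_phase(sphere_spec(cfg, 50, 0.004), cfg)
  bg0 <- background_sensitivity(truth, roi, cfg, 0)
  expect_equal(bg0$rel_change, 0)
  # constant offsets are killed exactly by the ring subtraction
  shifted <- phase_map(truth$values + 123.4, wrapped = FALSE)
  b1 <- background_sensitivity(truth, roi, cfg, 0.2)
  b2 <- background_sensitivity(shifted, roi, cfg, 0.2)
  expect_equal(b1$rel_change, b2$rel_change, tolerance = 1e-9)
  expect_error(background_sensitivity(truth, roi, cfg, -1))
})

test_that("energy_density reproduces the dosimetry arithmetic", {
  # 30 uW for 60 s on a 780 um spot: 0.4 J/cm^2 at one decimal
  expect_equal(round(energy_density(30e-6, 60, 780e-6), 1), 0.4)
  # linearity in exposure
  expect_equal(energy_density(30e-6, 120, 780e-6),
               2 * energy_density(30e-6, 60, 780e-6))
  # unit construction: 1 W, 1 s, spot radius sqrt(1/pi) cm -> exactly 1
  expect_equal(energy_density(1, 1, 2 * sqrt(1 / pi) / 100), 1,
               tolerance = 1e-12)
  expect_error(energy_density(0, 1, 1), "positive")
})
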