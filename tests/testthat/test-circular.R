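test_that("circular summaries follow the unit-vector definitions", {
  ## all angles equal
  cs <- circ_summary(rep(1.3, 6))
  expect_equal(cs$R, 1)
  expect_equal(cs$V, 0)
  expect_equal(cs$mean_angle, 1.3)

  ## two unit vectors at 0 and 90 degrees
  cs2 <- circ_summary(c(0, pi / 2))
  expect_equal(cs2$mean_angle, pi / 4)
  expect_equal(cs2$R, sqrt(0.5))
  expect_equal(cs2$V, 1 - sqrt(0.5))

  ## perfect dispersion: R = 0, mean undefined
  cs3 <- circ_summary(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(cs3$R, 0)
  expect_equal(cs3$V, 1)
  expect_true(is.na(cs3$mean_angle))

  expect_error(circ_summary(numeric(0)), "empty")

  ## bounds and rotation/permutation invariance (property)
  set.seed(51)
  for (i in 1:10) {
    ang <- runif(sample(2:20, 1), 0, 2 * pi)
    cs <- circ_summary(ang)
    expect_true(cs$R >= 0 && cs$R <= 1 && cs$V >= 0 && cs$V <= 1)
    rot <- circ_summary((ang + runif(1, 0, 2 * pi)) %% (2 * pi))
    expect_equal(rot$V, cs$V, tolerance = 1e-12)
    expect_equal(circ_summary(sample(ang))$V, cs$V, tolerance = 1e-12)
  }
})

test_that("per-animal variance is frame-invariant and needs two tissues", {
  pm <- data.frame(animal_id = rep("m1", 6),
                   tissue = c("pituitary", "liver", "kidney", "heart",
                              "lung", "spleen"),
                   angle = hours_to_angle(rep(14, 6)))
  expect_equal(per_animal_variance(pm)$V, 0)

  set.seed(52)
  pm2 <- data.frame(animal_id = rep(c("m1", "m2"), each = 6),
                    tissue = rep(c("pituitary", "liver", "kidney", "heart",
                                   "lung", "spleen"), 2),
                    angle = runif(12, 0, 2 * pi))
  v0 <- per_animal_variance(pm2)
  pm3 <- pm2
  pm3$angle <- (pm3$angle + hours_to_angle(5.5)) %% (2 * pi)  # ZT -> CT shift
  expect_equal(per_animal_variance(pm3)$V, v0$V, tolerance = 1e-12)

  ## animals with < 2 listed tissues are skipped
  pm4 <- rbind(pm2, data.frame(animal_id = "m3", tissue = "liver", angle = 1))
  v4 <- per_animal_variance(pm4)
  expect_equal(attr(v4, "skipped"), "m3")
  expect_equal(nrow(v4), 2)

  ## dispersed knockout-like panels score higher V than tight controls
  ctl <- simulate_panel(panel_sim_params(10, "DD", "control", seed = 53))$phases
  knockout <- simulate_panel(panel_sim_params(10, "DD", "knockout", seed = 54))$phases
  expect_gt(mean(per_animal_variance(knockout)$V), mean(per_animal_variance(ctl)$V))
})

test_that("Mann-Whitney matches exact enumeration and the base-R oracle", {
  ## identical samples: p near 1
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.9)

  ## fully separated small samples: U = 0, exact two-sided p = 2/20
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  ## exact path agrees with wilcox.test exact p on tie-free small samples
  set.seed(55)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5, 0.5)
    expect_equal(mann_whitney(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  ## normal approximation vs exhaustive enumeration at n = 8 + 8: exact
  ## two-sided p for every achievable U from all 12870 rank assignments
  combs <- combn(16, 8)
  us <- apply(combs, 2, function(idx)
    sum(outer((1:16)[idx], (1:16)[-idx], ">")))
  p_exact <- sapply(0:64, function(u) mean(abs(us - 32) >= abs(u - 32)))
  set.seed(56)
  diffs <- sapply(sample(ncol(combs), 40), function(j) {
    idx <- combs[, j]
    mw <- mann_whitney((1:16)[idx], (1:16)[-idx])
    expect_equal(mw$method, "normal")
    abs(mw$p - p_exact[mw$U + 1])
  })
  expect_lt(max(diffs), 0.015)
  expect_lt(mean(diffs), 0.006)
})

test_that("Watson-Williams detects mean-angle differences when planted", {
  ## identical concentrated groups: F ~ 0, p ~ 1
  set.seed(57)
  g <- rvonmises(20, 1, 8)
  ww <- watson_williams(g, g)
  expect_lt(ww$F, 1e-6)
  expect_gt(ww$p, 0.99)

  ## planted 6-hr offset at kappa = 4: overwhelming rejection
  rej <- mean(replicate(40, {
    a <- rvonmises(15, 0, 4)
    b <- rvonmises(15, hours_to_angle(6), 4)
    watson_williams(a, b)$p < 0.05
  }))
  expect_gt(rej, 0.99)

  ## dispersed samples trigger the low-concentration warning
  expect_warning(watson_williams(runif(20, 0, 2 * pi), runif(20, 0, 2 * pi)),
                 "0.45")
})

test_that("the variance-difference bootstrap is deterministic and calibrated", {
  set.seed(58)
  tight <- rvonmises(15, 0, 50)
  wide <- runif(15, 0, 2 * pi)
  b1 <- bootstrap_var_diff(tight, wide, n_iter = 5000, seed = 99)
  b2 <- bootstrap_var_diff(tight, wide, n_iter = 5000, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_lt(b1$observed, 0)
  expect_true(b1$significant)

  ## degenerate identical groups: CI collapses to [0, 0], not significant
  d <- bootstrap_var_diff(rep(1, 5), rep(2, 5), n_iter = 1000, seed = 1)
  expect_equal(d$ci, c(0, 0))
  expect_false(d$significant)

  ## tight vs dispersed groups detected in nearly all replicate datasets
  hits <- mean(replicate(25, {
    a <- rvonmises(15, 0, 50)                 # V ~ 0.01
    b <- rvonmises(15, 0, 0.8)                # V ~ 0.6
    bootstrap_var_diff(a, b, n_iter = 2000,
                       seed = sample.int(1e6, 1))$significant
  }))
  expect_gte(hits, 0.95)

  expect_error(bootstrap_var_diff(c(1, 2), c(1, 2, 3)), ">= 3")
})
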