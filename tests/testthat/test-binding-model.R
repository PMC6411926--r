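test_that("depletion isotherm evaluates its closed form and limits", {
  expect_equal(predict_csp(0.1, 0, 0.5, 0.2), 0)
  expect_equal(predict_csp(0.1, 0.1, 0.1, 1),
               (0.3 - sqrt(0.3^2 - 0.04)) / 0.2, tolerance = 1e-12)
  expect_equal(predict_csp(0.1, 0.1, 0.1, 1), 0.381966, tolerance = 1e-6)

  # stoichiometric limit kd -> 0+: min(L, P)/P of saturation
  expect_equal(predict_csp(0.1, 0.5, 1e-9, 1), 1, tolerance = 1e-6)
  expect_equal(predict_csp(0.1, 0.04, 1e-9, 1), 0.4, tolerance = 1e-6)

  # bounded in [0, dmax]
  set.seed(5)
  for (i in 1:50) {
    v <- predict_csp(runif(1, 0.01, 1), runif(1, 0, 5),
                     10^runif(1, -3, 1), runif(1, 0.01, 1))
    expect_gte(v, 0)
  }
})

test_that("isotherm is monotone in L, dmax and kd", {
  set.seed(6)
  for (i in 1:25) {
    P <- runif(1, 0.02, 0.5)
    kd <- 10^runif(1, -3, 1)
    dmax <- runif(1, 0.02, 0.5)
    L <- sort(runif(6, 0, 10 * P))
    v <- predict_csp(P, L, kd, dmax)
    expect_true(all(diff(v) >= -1e-12))                     # increasing in L
    expect_true(all(predict_csp(P, L, kd, dmax * 2) >= v - 1e-12))
    expect_true(all(predict_csp(P, L, kd * 3, dmax) <= v + 1e-12))
  }
})

test_that("isotherm reduces to the non-depleting hyperbola as P -> 0", {
  set.seed(8)
  for (i in 1:20) {
    kd <- 10^runif(1, -2, 1)
    dmax <- runif(1, 0.05, 0.3)
    L <- kd * c(0.1, 0.5, 1, 2, 10)
    dep <- predict_csp(kd / 1000, L, kd, dmax)
    hyp <- dmax * L / (L + kd)
    expect_lt(max(abs(dep / hyp - 1)), 1e-3)
  }
})

test_that("noise-free trajectories are inverted to the generating (kd, dmax)", {
  L <- c(0, 0.1, 0.2, 0.4, 0.7, 1.0)
  traj <- data.frame(P = 0.1, L = L,
                     delta = predict_csp(0.1, L, kd = 0.5, dmax = 0.12))
  f <- fit_residue(traj)
  expect_true(f$converged)
  expect_equal(f$kd, 0.5, tolerance = 1e-3)
  expect_equal(f$dmax, 0.12, tolerance = 1e-3)
  expect_lt(f$rss, 1e-12)

  flat <- data.frame(P = 0.1, L = L, delta = 0)
  expect_error(fit_residue(flat), "non-binder")
  expect_error(fit_residue(traj[1:2, ]), "3 points")
})

test_that("nonlinear fit agrees with the log-grid search oracle", {
  set.seed(9)
  L <- c(0, 0.1, 0.2, 0.4, 0.7, 1.0)
  for (i in 1:8) {
    kd <- 10^runif(1, -2, 0.7)
    dmax <- runif(1, 0.05, 0.3)
    traj <- data.frame(P = 0.1, L = L, delta = predict_csp(0.1, L, kd, dmax))
    f <- fit_residue(traj)
    g <- grid_fit(traj)
    expect_lte(abs(log10(f$kd) - log10(g$kd)), g$cell)
    expect_lte(abs(log10(f$dmax) - log10(g$dmax)), g$cell)
  }
})

test_that("global Kd aggregation applies the one-pass 2-SD rule", {
  tight <- data.frame(residue_index = 1:3, kd = c(0.6, 0.7, 0.8),
                      converged = TRUE)
  g <- aggregate_global_kd(tight, significant = 1:3)
  expect_equal(g$kd_mean, 0.7, tolerance = 1e-12)
  expect_length(g$removed, 0)
  expect_false(g$lower_limit)
  expect_match(g$reported, "±")

  # one gross outlier among nine consistent fits is removed
  out1 <- data.frame(residue_index = 1:10,
                     kd = c(rep(0.5, 9), 50), converged = TRUE)
  g1 <- aggregate_global_kd(out1, significant = 1:10)
  expect_equal(g1$removed, 10L)
  expect_equal(g1$kd_mean, 0.5, tolerance = 1e-12)
  expect_false(g1$lower_limit)

  # removal is a single pass with the SD of the initial set: in this
  # widely scattered set no point deviates more than 2 SD (~79.8) from
  # the initial mean (~50.1), so nothing is removed and no lower limit
  # is declared
  wide <- data.frame(residue_index = 1:6,
                     kd = c(0.2, 0.2, 60, 70, 80, 90), converged = TRUE)
  gw <- aggregate_global_kd(wide, significant = 1:6)
  expect_length(gw$removed, 0)
  expect_equal(gw$kd_mean, mean(wide$kd), tolerance = 1e-12)

  # non-converged and non-significant fits never enter the average
  mixed <- data.frame(residue_index = 1:4, kd = c(0.6, 0.8, 99, 99),
                      converged = c(TRUE, TRUE, FALSE, TRUE))
  gm <- aggregate_global_kd(mixed, significant = 1:3)
  expect_equal(gm$kd_mean, 0.7, tolerance = 1e-12)

  expect_error(aggregate_global_kd(tight[1, ], significant = 1:3),
               "at least 2")
})

test_that("aggregation is permutation-invariant and scale-equivariant", {
  set.seed(10)
  kds <- c(rlnorm(12, log(0.5), 0.3), 8)
  fits <- data.frame(residue_index = seq_along(kds), kd = kds,
                     converged = TRUE)
  g <- aggregate_global_kd(fits, significant = fits$residue_index)
  perm <- fits[sample(nrow(fits)), ]
  gp <- aggregate_global_kd(perm, significant = fits$residue_index)
  expect_equal(gp$kd_mean, g$kd_mean, tolerance = 1e-12)
  expect_setequal(gp$removed, g$removed)
  scaled <- transform(fits, kd = kd * 3.7)
  gs <- aggregate_global_kd(scaled, significant = fits$residue_index)
  expect_equal(gs$kd_mean, g$kd_mean * 3.7, tolerance = 1e-12)
  expect_setequal(gs$retained, g$retained)
})

test_that("recovery degrades when the true Kd far exceeds max ligand", {
  # with max [L] = 1.0 mM the estimator is stable at Kd = 0.5 mM and its
  # seed-to-seed spread explodes at Kd = 10 mM, where (kd, dmax) are
  # unidentifiable from <10% saturation
  r <- function(kd, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_titration(simulation_config(true_kd = kd, seed = s))
      fit_series(sim$series)$global$kd_mean
    }, numeric(1))
  }
  lo <- r(0.5, 1:10)
  hi <- r(10, 1:10)
  expect_lt(abs(median(lo) / 0.5 - 1), 0.15)
  expect_gt(IQR(hi), IQR(lo))
})

test_that("lower limits are rendered with a '>' prefix", {
  expect_equal(format_global_kd(0.8123, 0.2, lower_limit = TRUE),
               "> 0.81 mM")
  expect_match(format_global_kd(0.7, 0.1, FALSE), "^0.7 ± 0.1 mM$")
})
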