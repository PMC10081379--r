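# build a minimal replication_fit carrying a fixed gamma, for testing the
# deterministic statistics downstream of inference
fixed_gamma_fit <- function(gamma, D_max = 2.3e6) {
  structure(list(draws = tibble::tibble(beta1 = 1, beta2 = 0,
                                        kappa = 20, gamma = gamma),
                 gamma_mean = gamma, kappa_mean = 20, D_max = D_max,
                 n_genes = 100, method = "fixed"),
            class = "replication_fit")
}

test_that("the circular regression recovers wrapped linear gene angles", {
  set.seed(41)
  n <- 600
  D <- runif(n, 0, 2.3e6)
  x <- D / max(D) * 2 * pi - pi
  # noiseless wrap at gamma_true = 2
  y <- (2 * x + 0.7) %% (2 * pi)
  theta_g <- (y / (2 * pi)) * 360
  fit <- fit_gene_angle_regression(theta_g, D, seed = 2)
  expect_gt(fit$gamma_mean, 1.9)
  expect_lt(fit$gamma_mean, 2.1)
  # predictions agree with the generating line
  pred <- predict_gene_angle(fit, D[1:20])
  resid <- abs(angle_difference(theta_g[1:20] - 180, pred - 180))
  expect_lt(max(resid), 5)

  # gamma = 1 with zero phase offset: beta2 ~ 0, beta1 > 0
  theta1 <- (x + pi) / (2 * pi) * 360   # so the standardized angle equals x
  fit1 <- fit_gene_angle_regression(theta1, D, seed = 2)
  expect_gt(fit1$gamma_mean, 0.95)
  expect_lt(fit1$gamma_mean, 1.05)
  expect_gt(fit1$map["beta1"], 0)
  expect_lt(abs(atan2(fit1$map["beta2"], fit1$map["beta1"])), 0.1)
})

test_that("von Mises noise concentration is recovered", {
  set.seed(42)
  n <- 800
  D <- runif(n, 0, 2.3e6)
  x <- D / max(D) * 2 * pi - pi
  y <- (1.6 * x + 0.3 + rvonmises(n, 0, 20)) %% (2 * pi)
  fit <- fit_gene_angle_regression(y / (2 * pi) * 360, D, seed = 3)
  expect_lt(abs(fit$kappa_mean - 20) / 20, 0.3)
  expect_lt(abs(fit$gamma_mean - 1.6) / 1.6, 0.05)
})

test_that("posterior gamma is accurate across growth regimes", {
  # parameter recovery over replicates and gamma values
  set.seed(43)
  rel_err <- c()
  for (gamma_true in c(1.2, 1.8, 2.4)) {
    for (rep in 1:4) {
      D <- runif(500, 0, 2.3e6)
      x <- D / max(D) * 2 * pi - pi
      y <- (gamma_true * x + runif(1, 0, 2 * pi) +
              rvonmises(500, 0, 20)) %% (2 * pi)
      fit <- fit_gene_angle_regression(y / (2 * pi) * 360, D,
                                       n_draws = 500, seed = rep)
      rel_err <- c(rel_err, abs(fit$gamma_mean - gamma_true) / gamma_true)
    }
  }
  expect_lt(median(rel_err), 0.1)
})

test_that("replication statistics transform gamma exactly", {
  expect_equal(replication_stats(fixed_gamma_fit(1), 26)$overlap_fraction, 0)
  expect_equal(replication_stats(fixed_gamma_fit(2), 26)$overlap_fraction,
               0.5)
  # t_d = 26 min at 295.9 deg/Mb implies ~780 bp/s
  g <- 295.9 * 2.3 / 360   # standardized gamma giving that gradient
  st <- replication_stats(fixed_gamma_fit(g), 26,
                          origin_ter_distance_mb = 2.3)
  expect_equal(st$gamma_deg_per_mb, 295.9, tolerance = 1e-9)
  expect_equal(st$v_dnap_bp_s, 6e6 / (26 * 295.9), tolerance = 1e-9)
  expect_equal(st$v_dnap_bp_s, 780, tolerance = 1)
  # round trip: v and overlap are deterministic transforms of gamma
  st2 <- replication_stats(fixed_gamma_fit(g), 26,
                           origin_ter_distance_mb = 2.3)
  expect_identical(st$v_dnap_bp_s, st2$v_dnap_bp_s)
})

test_that("the trig ridge fits representable angular responses", {
  th <- (0:39 + 0.5) * 9
  tg <- (0:39 + 0.5) * 9
  grid <- outer(th, tg, function(a, b) cos((a - b) * pi / 180))
  em <- fit_cell_gene_model(grid, th, tg)
  expect_gt(em$r_squared, 0.99)
  # constant response: coefficients shrink to zero, intercept carries it
  em0 <- fit_cell_gene_model(matrix(1.7, 40, 40), th, tg)
  expect_lt(max(abs(em0$coef)), 1e-6)
  expect_equal(em0$intercept, 1.7)
  # infinite penalty: predictions collapse to the grand mean
  em_inf <- fit_cell_gene_model(grid, th, tg, alpha = 1e12)
  pr <- predict_expression(em_inf, c(10, 100, 250), c(30, 30, 30))
  expect_equal(pr, rep(mean(grid), 3), tolerance = 1e-3)
  expect_error(fit_cell_gene_model(grid * NA, th, tg), "NaN")
})

test_that("replication-only predictions depend on genes only through D", {
  set.seed(44)
  D <- c(a = 1e6, b = 1e6, c = 2e6)
  fit <- fixed_gamma_fit(1.6)
  th <- (0:99 + 0.5) * 3.6
  grid <- outer(th, (0:99 + 0.5) * 3.6,
                function(a, b) cos((a - b) * pi / 180))
  em <- fit_cell_gene_model(grid, th, (0:99 + 0.5) * 3.6)
  pred <- predict_replication_expression(em, fit, th, D)
  # equal D: identical predicted profiles
  expect_equal(pred[, "a"], pred[, "b"])
  expect_false(isTRUE(all.equal(pred[, "a"], pred[, "c"])))
  # gene order does not matter
  pred2 <- predict_replication_expression(em, fit, th, D[c(3, 1, 2)])
  expect_equal(pred2[, "a"], pred[, "a"])
  # genes without D are excluded and listed
  D3 <- c(D, d = NA)
  pred3 <- predict_replication_expression(em, fit, th, D3)
  expect_equal(attr(pred3, "excluded"), "d")
  expect_equal(ncol(pred3), 3)
})

test_that("divergence scores measure departure from the prediction", {
  set.seed(45)
  obs <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
  # observed equals predicted: sigma_corrected is exactly zero
  d0 <- divergence_score(obs, obs, rep(TRUE, 6))
  expect_equal(d0$sigma_corrected, rep(0, 6), ignore_attr = TRUE)
  expect_false(any(d0$divergent))
  # a phase-shifted (delayed) profile is flagged; faithful ones are not
  th <- (0:99 + 0.5) * 3.6
  pred <- sapply(1:6, function(j) cos((th - j * 60) * pi / 180))
  colnames(pred) <- paste0("g", 1:6)
  obs2 <- pred
  obs2[, "g3"] <- cos((th - 180 - 100) * pi / 180)   # 100 deg delay
  d1 <- divergence_score(obs2, pred, rep(TRUE, 6), threshold = 0.6)
  expect_true(d1$divergent[3])
  expect_false(any(d1$divergent[-3]))
  # non-HVG genes are never flagged
  d2 <- divergence_score(obs2, pred, rep(FALSE, 6), threshold = 0.6)
  expect_false(any(d2$divergent))
  # sigma is invariant to adding a shared constant
  d3 <- divergence_score(obs2 + 5, pred + 5, rep(TRUE, 6), threshold = 0.6)
  expect_equal(d3$sigma_corrected, d1$sigma_corrected)
})
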