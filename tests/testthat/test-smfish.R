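test_that("spherocylinder geometry inverts the projected-area model", {
  # sphere limit: L = d, A = pi d^2 / 4, V = pi d^3 / 6
  g <- spherocylinder_geometry(2, pi)
  expect_equal(g$width, 2, tolerance = 1e-12)
  expect_equal(g$volume, 4 * pi / 3, tolerance = 1e-12)
  # round trip through the forward area model
  g2 <- spherocylinder_geometry(4, 3)
  expect_equal(spherocylinder_area(4, g2$width), 3, tolerance = 1e-10)
  # long rod: volume approaches the cylinder pi d^2 L / 4
  g3 <- spherocylinder_geometry(100, 100 * 1 - 1 + pi / 4)  # d ~ 1
  expect_equal(g3$volume / (pi * g3$width^2 * 100 / 4), 1, tolerance = 0.01)
  expect_error(spherocylinder_geometry(1, 10), "inconsistent")
})

test_that("the cell-length law has the stated sharp and smoothed forms", {
  L0 <- 3.43
  expect_equal(length_pdf(L0, L0, 0), 2 / L0)
  expect_equal(length_pdf(2 * L0, L0, 0), 1 / (2 * L0))
  expect_equal(length_pdf(c(0.9 * L0, 2.1 * L0), L0, 0), c(0, 0))
  # smoothed law integrates to one (adaptive quadrature over the support;
  # at sigma well below L0 the Gaussian tail never crosses zero length)
  for (sg in c(0.2, 0.4, 0.56)) {
    total <- stats::integrate(function(L) length_pdf(L, L0, sg),
                              0, 2 * L0 + 10 * sg,
                              rel.tol = 1e-9, subdivisions = 400)$value
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("length-distribution MLE recovers the generating parameters", {
  L0 <- 3.43; sigma <- 0.56
  x <- sample_lengths(5000, L0, sigma, seed = 61)
  fit <- fit_length_distribution(x)
  expect_lt(abs(fit$L0 - L0), 2 * fit$se_L0 + 0.02)
  expect_lt(abs(fit$sigma - sigma), 2 * fit$se_sigma + 0.02)
  # scale equivariance: doubling all lengths doubles L0
  fit2 <- fit_length_distribution(2 * x)
  expect_equal(fit2$L0 / fit$L0, 2, tolerance = 0.02)
  # sigma -> 0 sample: fitted sigma collapses, L0 approaches the minimum
  x0 <- sample_lengths(2000, L0, 0, seed = 62)
  fit0 <- fit_length_distribution(x0)
  expect_lt(fit0$sigma, 0.05)
  expect_equal(fit0$L0, min(x0), tolerance = 0.05)
  expect_error(fit_length_distribution(x[1:50]), "100 cells")
})

test_that("sinusoid phase alignment reads off the birth angle", {
  # the closed-form mapping at the canonical inputs
  expect_equal(round(length_at_initiation(3.34, 155), 1), 5.2)
  L0 <- 3.34
  set.seed(63)
  lengths <- runif(4000, L0, 2 * L0)
  beta <- 2 * pi * (lengths / L0 - 1)
  th <- runif(4000, 0, 360)
  for (phi_true in c(0, 90, 120, 155, 300)) {
    sm <- data.frame(length_um = lengths,
                     mrna_conc = 2 + 0.5 * sin(beta + phi_true * pi / 180 +
                                                 0.4))
    sc <- data.frame(theta_c = th,
                     mrna_fraction = 1 + 0.3 * sin(th * pi / 180 + 0.4))
    pa <- sinusoid_phase_alignment(sm, sc, L0)
    err <- abs(angle_difference(pa$phi_deg, phi_true))
    expect_lt(err, 5)
    if (phi_true == 0) expect_lt(abs(angle_difference(pa$phi_deg, 0)), 1)
  }
  # amplitude below the noise floor: phase undefined
  flat <- data.frame(length_um = lengths, mrna_conc = rep(2, 4000))
  sc <- data.frame(theta_c = th, mrna_fraction = 1 + 0.3 * sin(th * pi / 180))
  expect_error(sinusoid_phase_alignment(flat, sc, L0), "noise floor")
})

test_that("the two-Hill dosage fit recovers its parameters", {
  set.seed(64)
  L <- sample_lengths(2000, 3.43, 0.56)
  mu <- hill_dosage_mean(L, 5, 4, 10, 2)
  y <- rpois(2000, mu)
  fit <- fit_hill_dosage(L, y)
  est <- setNames(fit$coef$estimate, fit$coef$term)
  expect_lt(abs(est["n2"] - 2) / 2, 0.05)
  expect_lt(abs(est["c_base"] - 5) / 5, 0.1)
  # plateaus of the model itself
  expect_equal(hill_dosage_mean(1e-6, 5, 4, 10, 2) / 5, 1, tolerance = 1e-6)
  expect_equal(hill_dosage_mean(1e6, 5, 4, 10, 2) / 5, 4, tolerance = 1e-3)
  # short-cell plateau: fitted baseline matches the observed plateau mean
  short <- L < 3
  if (sum(short) > 30) {
    expect_lt(abs(est["c_base"] - mean(y[short])) / est["c_base"], 0.2)
  }
  # step-function limit: the replication length lands at the jump
  Ls <- seq(2, 8, length.out = 2000)
  ys <- ifelse(Ls < 4.5, 5, ifelse(Ls < 6.5, 10, 20))
  fit_s <- fit_hill_dosage(Ls, ys, bin_frac = NULL,
                           start = list(c_base = 5, Lr = 5, k = 20, n2 = 1.5))
  est_s <- setNames(fit_s$coef$estimate, fit_s$coef$term)
  expect_equal(unname(est_s["Lr"]), 4.5, tolerance = 0.1)
})

test_that("the DNA content model is continuous with 3:2:6 branch rates", {
  T <- 26; T_C <- 42; T_D <- 20
  b1 <- T - T_D; b2 <- 3 * T - T_C - T_D
  eps <- 1e-9
  expect_equal(dna_content(b1 - eps, T, T_C, T_D),
               dna_content(b1, T, T_C, T_D), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(dna_content(b2 - eps, T, T_C, T_D),
               dna_content(b2, T, T_C, T_D), tolerance = 1e-6,
               ignore_attr = TRUE)
  # branch slopes x T_C are 3, 2, 6 (DNA production rate ratio; the three
  # phases run 3, 2 and 6 replication fork pairs)
  slope <- function(t) as.numeric(dna_content(t + 1e-6, T, T_C, T_D) -
                                    dna_content(t, T, T_C, T_D)) / 1e-6
  expect_equal(slope(2) * T_C, 3, tolerance = 1e-3)
  expect_equal(slope(10) * T_C, 2, tolerance = 1e-3)
  expect_equal(slope(20) * T_C, 6, tolerance = 1e-3)
  g <- dna_content(c(2, 10, 20), T, T_C, T_D)
  expect_equal(attr(g, "fork_pairs"), c(3L, 2L, 6L))
  # g(T) = 2 g(0) and continuity across random valid parameter draws
  set.seed(65)
  for (i in 1:100) {
    TC <- runif(1, 30, 60)
    TDm <- runif(1, 5, 25)
    lo <- max(TDm, TC / 2); hi <- (TC + TDm) / 2
    if (lo >= hi) next
    Tm <- runif(1, lo + 0.01, hi - 0.01)
    expect_equal(dna_content(Tm - 1e-8, Tm, TC, TDm),
                 2 * dna_content(0, Tm, TC, TDm), tolerance = 1e-5,
                 ignore_attr = TRUE)
    bb <- c(Tm - TDm, 3 * Tm - TC - TDm)
    for (b in bb[bb > 0 & bb < Tm]) {
      expect_equal(dna_content(b - 1e-8, Tm, TC, TDm),
                   dna_content(b, Tm, TC, TDm), tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
  # regime violations are named
  expect_error(dna_content(1, 40, 42, 20), "T < \\(T_C \\+ T_D\\) / 2")
  expect_error(dna_content(1, 15, 42, 10), "T > T_C / 2")
  expect_error(dna_content(1, 19, 42, 20), "T > T_D")
})

test_that("DAPI fits recover the replication timing parameters", {
  p <- smfish_params()
  cells <- generate_smfish_cells(p, n_cells = 4000, seed = 66)
  fit <- fit_dapi_profile(cells$length_um, cells$dapi_au, L_birth = p$L0,
                          T = p$dna$T)
  expect_false(fit$discarded)
  expect_gt(fit$r_squared, 0.7)
  # recovered ratios near the generating (T_C/T, T_D/T)
  expect_lt(abs(fit$rc - 42 / 26), 0.15)
  expect_lt(abs(fit$rd - 20 / 26), 0.15)
  # oriC-replication length within 10% of the generator's implied value
  L_oric_true <- p$L0 * 2^(3 - 42 / 26 - 20 / 26)
  expect_lt(abs(fit$L_at_oric - L_oric_true) / L_oric_true, 0.1)
  # noiseless signal: essentially exact recovery
  p0 <- p; p0$dapi_noise_sd <- 1e-6; p0$sigma <- 0.3
  cells0 <- generate_smfish_cells(p0, n_cells = 3000, seed = 67)
  fit0 <- fit_dapi_profile(cells0$length_um, cells0$dapi_au, L_birth = p$L0)
  expect_gt(fit0$r_squared, 0.999)
  expect_lt(abs(fit0$rc - 42 / 26), 0.02)
  # pure noise: fit discarded by the r-squared rule
  set.seed(68)
  expect_warning(
    bad <- fit_dapi_profile(cells$length_um,
                            rnorm(nrow(cells), 100, 10)),
    "discarded")
  expect_true(bad$discarded)
})
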