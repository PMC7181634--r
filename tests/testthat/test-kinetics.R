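tab <- mdh_kinetic_params()
row_of <- function(enzyme, ph) as.list(tab[tab$enzyme == enzyme & tab$ph == ph, ])

test_that("absorbance slopes convert by Beer-Lambert with the NADH coefficient", {
  expect_equal(rate_from_absorbance(0.0622), 10 / 60)     # 10 uM/min
  expect_equal(rate_from_absorbance(0), 0)
  expect_equal(rate_from_absorbance(0.0622, path_length_cm = 0.5),
               2 * rate_from_absorbance(0.0622))
  expect_error(rate_from_absorbance(1, extinction_coeff = 0), "positive")
})

test_that("the rate law behaves at its limits and at tabulated points", {
  p6 <- row_of("MsMDH", 6)
  expect_equal(substrate_inhibition_velocity(p6, 0), 0)
  # initial slope = kcat/km
  eps <- 1e-8
  expect_equal(substrate_inhibition_velocity(p6, eps) / eps,
               p6$kcat / p6$km, tolerance = 1e-4)
  expect_equal(p6$kcat / p6$km, 15.2, tolerance = 0.01)
  # direct evaluation at the standard assay concentration
  expect_equal(substrate_inhibition_velocity(p6, 100),
               18700 / (12.3 + 100 + 10000 / 67.4))
  expect_error(substrate_inhibition_velocity(p6, -1), "non-negative")
  # ki = Inf reduces to Michaelis-Menten over a wide range
  mm <- list(kcat = 100, km = 20, ki = Inf)
  Sg <- seq(0, 200, by = 0.5)
  vs_inf <- substrate_inhibition_velocity(mm, Sg)
  for (ki in 10^(4:7)) {
    v <- substrate_inhibition_velocity(list(kcat = 100, km = 20, ki = ki), Sg)
    expect_lt(max(abs(v - vs_inf)), 100 * 20 * 10 / ki)  # sup-norm -> 0
  }
  expect_equal(vs_inf, 100 * Sg / (20 + Sg))
})

test_that("printed efficiency column is consistent with kcat over km", {
  # the table prints kcat/km to one decimal from unrounded fits; agreement
  # is checked at that printed precision given rounded inputs
  expect_true(all(abs(tab$kcat / tab$km - tab$kcat_km) < 0.1))
  expect_equal(catalytic_efficiency(list(kcat = 187.0, km = 12.3)), 15.2,
               tolerance = 0.01)
  expect_equal(catalytic_efficiency(list(kcat = 689.1, km = 52.0)), 13.3,
               tolerance = 0.01)
  expect_equal(catalytic_efficiency(list(kcat = 5, km = 5)), 1)
})

test_that("velocity peaks at sqrt(km*ki) for every tabulated parameter set", {
  for (i in seq_len(nrow(tab))) {
    p <- as.list(tab[i, ])
    if (!is.finite(p$ki)) next
    s_star <- sqrt(p$km * p$ki)
    grid <- seq(0.05 * s_star, 5 * s_star, length.out = 4001)
    v <- substrate_inhibition_velocity(p, grid)
    expect_equal(grid[which.max(v)], s_star,
                 tolerance = 2 * diff(grid[1:2]) / s_star,
                 info = paste(p$enzyme, p$ph))
  }
})

test_that("noiseless curves return the generating parameters", {
  for (sel in list(c("MsMDH", 6), c("CgMDH", 6), c("CgMDH", 7),
                   c("MsMDH_G11Q", 8))) {
    truth <- row_of(sel[1], as.numeric(sel[2]))
    pts <- generate_assay_dataset(truth, noise_cv = 0)
    fit <- fit_substrate_inhibition(pts)
    expect_equal(fit$kcat, truth$kcat, tolerance = 1e-4, info = sel[1])
    expect_equal(fit$km, truth$km, tolerance = 1e-4, info = sel[1])
    expect_equal(fit$ki, truth$ki, tolerance = 1e-4, info = sel[1])
    expect_true(fit$inhibition)
  }
  # Michaelis-Menten data: inhibition flagged off, efficiency recovered
  mm_truth <- list(kcat = 500, km = 40, ki = Inf)
  pts <- suppressWarnings(generate_assay_dataset(mm_truth, noise_cv = 0))
  fit <- fit_substrate_inhibition(pts)
  expect_false(fit$inhibition)
  expect_identical(fit$ki, Inf)
  expect_equal(fit$kcat_km, 500 / 40, tolerance = 1e-6)
  expect_error(fit_substrate_inhibition(
    tibble::tibble(conc_uM = c(1, 2, 3, 4), velocity_per_s = 1:4)),
    "at least 5")
})

test_that("fitted optimum never loses to a dense grid search", {
  truth <- row_of("MsMDH", 6)
  pts <- generate_assay_dataset(truth, noise_cv = 0.1, replicates = 2,
                                seed = 9)
  fit <- fit_substrate_inhibition(pts)
  S <- pts$conc_uM; v <- pts$velocity_per_s
  grid <- expand.grid(kcat = seq(100, 300, length.out = 25),
                      km = seq(5, 30, length.out = 25),
                      ki = seq(30, 150, length.out = 25))
  sse <- apply(grid, 1, function(g) {
    vhat <- g[1] * S / (g[2] + S + S^2 / g[3])
    sum(((v - vhat) / vhat)^2)  # same weighted objective as the fit
  })
  expect_lte(fit$sse, min(sse) + 1e-9)
})

test_that("noisy replicated assays recover parameters with honest errors", {
  truth <- row_of("CgMDH", 7)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 6)
  for (r in seq_len(n_rep)) {
    pts <- generate_assay_dataset(truth, noise_cv = 0.05, replicates = 3,
                                  seed = 1000 + r)
    f <- fit_substrate_inhibition(pts)
    est[r, ] <- c(f$kcat, f$km, f$ki, f$se_kcat, f$se_km, f$se_ki)
  }
  true_v <- c(truth$kcat, truth$km, truth$ki)
  for (j in 1:3) {
    bias <- mean(est[, j]) / true_v[j] - 1
    expect_lt(abs(bias), 0.05)
    covered <- mean(abs(est[, j] - true_v[j]) <= 2 * est[, j + 3])
    expect_gte(covered, 0.90)
  }
})

test_that("relative activities compare enzymes at the standard assay point", {
  p7m <- row_of("MsMDH", 7); p7c <- row_of("CgMDH", 7)
  expect_equal(relative_activity(p7m, p7m), 1)
  # tabulated parameters imply ~4.9-fold for the C. glutamicum enzyme (the
  # measured comparison reported 4.4-fold; model-vs-measurement gap)
  expect_equal(relative_activity(p7c, p7m), 4.85, tolerance = 0.01)
  doubled <- p7m; doubled$kcat <- 2 * p7m$kcat
  expect_equal(relative_activity(doubled, p7m), 2)
})

test_that("pH optimum and physiological velocity follow the tabulated profiles", {
  ms <- tab[tab$enzyme == "MsMDH", ]
  cg <- tab[tab$enzyme == "CgMDH", ]
  expect_equal(ph_profile_summary(ms)$optimum_ph, 9)
  expect_equal(ph_profile_summary(cg)$optimum_ph, 7)
  expect_warning(one <- ph_profile_summary(ms[1, ]), "single")
  expect_equal(one$optimum_ph, 5)
  expect_error(ph_profile_summary(ms[0, ]), "empty")

  # at a grid pH: direct evaluation, inhibition factor from closed form
  pv <- physiological_velocity(ms, physiological_state(ph = 7))
  S <- 26.11
  expect_equal(pv$velocity,
               substrate_inhibition_velocity(row_of("MsMDH", 7), S))
  expect_equal(pv$inhibition_factor,
               (18.2 + S) / (18.2 + S + S^2 / 47.3), tolerance = 1e-9)
  expect_equal(pv$inhibition_factor, 0.754, tolerance = 0.001)
  # interpolated pH lies between the bracketing parameter sets
  pv2 <- physiological_velocity(ms, physiological_state())
  expect_gt(pv2$params$kcat, min(ms$kcat[ms$ph %in% 6:7]))
  expect_lt(pv2$params$kcat, max(ms$kcat[ms$ph %in% 6:7]))
  # no inhibition means factor one
  noinhib <- tibble::tibble(ph = c(5, 9), kcat = c(100, 100),
                            km = c(10, 10), ki = c(Inf, Inf))
  expect_equal(physiological_velocity(
    noinhib, physiological_state(ph = 7))$inhibition_factor, 1)
  expect_error(physiological_velocity(ms, physiological_state(ph = 4.5)),
               "outside")
})
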