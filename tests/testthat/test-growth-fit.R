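test_that("unified-Richards curve has the right anchors and limits", {
  expect_equal(urichards(0, 0.12, 0.005, 2.7, 1.4), 0.005)
  expect_equal(urichards(0, 0.12, 0.005, 2.7, 0.67), 0.005)
  expect_equal(urichards(1e3, 0.12, 0.005, 2.7, 1.4), 0.12,
               tolerance = 1e-9)
  # monotone increasing towards the asymptote
  k <- seq(0, 2, by = 0.05)
  for (S in c(0.67, 1, 1.4, 2)) {
    w <- urichards(k, 0.12, 0.005, 2.7, S)
    expect_true(all(diff(w) > 0))
    expect_true(all(w <= 0.12 + 1e-12))
  }
  expect_error(urichards(0, -1, 0.005, 2.7, 1.4), "A and W0")
})

test_that("the S -> 1 branch is the Gompertz limit of the general form", {
  k <- seq(0.1, 1, by = 0.1)
  g <- urichards(k, 0.12, 0.005, 2.7, 1)
  for (S in c(1 - 1e-7, 1 + 1e-7)) {
    u <- urichards(k, 0.12, 0.005, 2.7, S)
    expect_lt(max(abs(u / g - 1)), 1e-5)
  }
  # explicit Gompertz form A*(W0/A)^exp(-e*G*k)
  expect_equal(g, 0.12 * (0.005 / 0.12)^exp(-exp(1) * 2.7 * k))
})

test_that("adjusted-time origin is the first sample with enough cells", {
  crv <- growth_curve(mcs = c(0, 1000, 2000, 3000),
                      area_mm2 = c(1, 2, 3, 4) * 1e-3,
                      cell_count = c(5, 9, 16, 30))
  expect_identical(attr(set_growth_origin(crv), "origin_mcs"), 2000L)
  all15 <- growth_curve(0:3 * 1000, 1:4 * 1e-3, c(20, 25, 30, 31))
  expect_identical(attr(set_growth_origin(all15), "origin_mcs"), 0L)
  low <- growth_curve(0:3 * 1000, 1:4 * 1e-3, c(2, 3, 4, 9))
  expect_error(set_growth_origin(low), "maximum observed: 9")
})

test_that("noiseless parameter recovery is exact for all model classes", {
  cases <- list(c(0.12, 0.005, 2.7, 1.4), c(0.12, 0.005, 2.7, 0.67),
                c(0.2, 0.01, 1.5, 2), c(0.05, 0.002, 4, 1))
  for (cs in cases) {
    crv <- simulate_growth_curve(cs[1], cs[2], cs[3], cs[4], noise_sd = 0)
    fit <- fit_growth(crv)
    expect_equal(unname(coef(fit)), cs, tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-12)
  }
})

test_that("classical-model data is recognised by the free shape fit", {
  gomp <- simulate_growth_curve(0.12, 0.005, 2.7, 1, noise_sd = 0)
  expect_lt(abs(coef(fit_growth(gomp))["S"] - 1), 0.02)
  logi <- simulate_growth_curve(0.12, 0.005, 2.7, 2, noise_sd = 0)
  expect_lt(abs(coef(fit_growth(logi))["S"] - 2), 0.02)
})

test_that("shape recovery stays accurate under 1% multiplicative noise", {
  set.seed(2024)
  S_true <- rep(c(0.67, 1.0, 1.4, 2.0), length.out = 50)
  err <- vapply(seq_along(S_true), function(i) {
    crv <- simulate_growth_curve(0.12, 0.005, 2.7, S_true[i],
                                 noise_sd = 0.01)
    abs(coef(fit_growth(crv))["S"] - S_true[i])
  }, numeric(1))
  expect_lt(stats::median(err), 0.05)
})

test_that("the unified fit dominates its nested classical submodels", {
  set.seed(7)
  crv <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.02)
  fits <- compare_growth_fits(crv)
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  expect_gte(r2["urichards"] + 1e-9, max(r2))
  # S = 2 data: logistic beats Bertalanffy among the classical tags
  crv2 <- simulate_growth_curve(0.12, 0.005, 2.7, 2, noise_sd = 0.01,
                                seed = 8)
  f2 <- compare_growth_fits(crv2)
  expect_gt(f2$logistic$r_squared, f2$bertalanffy$r_squared)
  # S -> 1 data: Gompertz is the best classical submodel
  crv1 <- simulate_growth_curve(0.12, 0.005, 2.7, 1, noise_sd = 0.01,
                                seed = 9)
  f1 <- compare_growth_fits(crv1)
  expect_gt(f1$gompertz$r_squared, f1$bertalanffy$r_squared)
  expect_gt(f1$gompertz$r_squared, f1$logistic$r_squared)
})

test_that("time-unit rescaling leaves S and R^2 invariant and rescales G", {
  crv <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.01,
                               seed = 11)
  f1 <- fit_growth(crv)
  # relabel the clock: each sample now spans 2 kMCS
  crv2 <- growth_curve(crv$mcs * 2L, crv$area_mm2, crv$cell_count)
  f2 <- fit_growth(crv2)
  expect_equal(coef(f2)["S"], coef(f1)["S"], tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  expect_equal(coef(f2)["G"], coef(f1)["G"] / 2, tolerance = 1e-6)
})

test_that("fit objects support the standard modelling methods", {
  crv <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.01,
                               seed = 3)
  fit <- fit_growth(crv)
  expect_named(coef(fit), c("A", "W0", "G", "S"))
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(predict(fit, mcs = fit$origin_mcs), coef(fit)[["W0"]],
               tolerance = 1e-9)
  s <- summary(fit)
  expect_s3_class(s, "summary.growth_fit")
  expect_true(all(is.finite(s[c("A", "G"), "ci95_halfwidth"])))
  expect_true(all(is.finite(fit$ci_halfwidths)))
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "growth_curve")
  expect_output(print(fit), "R\\^2")
})

test_that("growth curves round-trip through CSV", {
  crv <- simulate_growth_curve(0.12, 0.005, 2.7, 1.4, noise_sd = 0.01,
                               seed = 4)
  crv <- set_growth_origin(crv)
  path <- tempfile(fileext = ".csv")
  write_growth_curve(crv, path)
  back <- read_growth_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(crv), tolerance = 1e-12)
  expect_identical(attr(back, "origin_mcs"), attr(crv, "origin_mcs"))
})
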