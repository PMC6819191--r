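test_that("saturated ratcheting strain is linear above threshold, clamped below", {
  expect_equal(saturated_strain(0.59, k_r = 1, e_rth = 0), 0.59)
  expect_equal(saturated_strain(0.4, k_r = 2, e_rth = 0.4), 0)
  expect_equal(saturated_strain(0.1, k_r = 1, e_rth = 0.4), 0)  # clamp
  expect_equal(saturated_strain(1.2, k_r = 0.5, e_rth = 0.2), 0.5)
  expect_error(saturated_strain(1, k_r = -1), "positive")
})

test_that("evolution parameters follow the fitted linear stress relations", {
  expect_equal(evolution_alpha(1.76), 53.565 + 10.571 * 1.76)
  expect_equal(evolution_alpha(1.76), 72.170, tolerance = 1e-4)
  expect_equal(evolution_beta(1.76), 0.13 - 0.035 * 1.76)
  expect_equal(evolution_beta(1.76), 0.0684, tolerance = 1e-6)
  expect_equal(evolution_alpha(c(1, 2), a1 = 0), rep(53.565, 2))
  expect_warning(evolution_beta(3.8), "beta")  # 0.13 - 0.035*3.8 < 0
})

test_that("model evaluation matches hand arithmetic and saturates", {
  p <- urmk_params(K = 0.01, k_r = 1, e_rth = 0)
  # hand oracle at N = 1, e_r = 1.76: 0.01 * 1.76 * (1 - 1/72.170)
  expect_equal(urmk_evaluate(1, 1.76, p), 0.017356, tolerance = 1e-4)
  expect_equal(urmk_evaluate(1, 1.76, p),
               0.0176 * (1 - evolution_alpha(1.76)^(-1)), tolerance = 1e-12)
  # saturation bound and limit K * X_SR
  for (e_r in c(0.59, 1.18, 1.76)) {
    xr <- urmk_evaluate(c(1:10, 100, 1e4, 1e8), e_r, p)
    expect_true(all(xr < 0.01 * e_r))
    expect_true(all(diff(xr) > 0))
    expect_equal(xr[length(xr)], 0.01 * e_r, tolerance = 1e-3)
  }
  # zero amplitude: stress at the threshold gives identically zero strain
  p_th <- urmk_params(K = 0.01, k_r = 1, e_rth = 0.59)
  expect_equal(urmk_evaluate(1:50, 0.59, p_th), rep(0, 50))
  # parameter-domain errors under the default form
  expect_error(urmk_evaluate(1:5, 1, urmk_params(alpha = 0.5, beta = 0.1)),
               "alpha")
  expect_error(urmk_evaluate(1:5, 1, urmk_params(alpha = 50, beta = 1.2)),
               "beta")
  expect_error(urmk_evaluate(0, 1.76, p), ">= 1")
})

test_that("per-cycle increments are strictly positive and decreasing", {
  for (e_r in c(0.59, 0.88, 1.18, 1.76)) {
    xr <- urmk_evaluate(1:200, e_r, urmk_params())
    inc <- diff(xr)
    expect_true(all(inc > 0))
    expect_true(all(diff(inc) < 0))
  }
  # increasing in e_r above threshold at any fixed N
  p <- urmk_params()
  at_n <- sapply(c(0.59, 0.88, 1.18, 1.76),
                 function(e) urmk_evaluate(50, e, p))
  expect_true(all(diff(at_n) > 0))
})

test_that("fitting a noise-free model curve recovers its parameters", {
  for (e_r in c(0.59, 1.18, 1.76)) {
    fit <- fit_ratcheting_curve(model_curve(e_r))
    expect_equal(fit$amplitude, 0.01 * e_r, tolerance = 1e-3)
    expect_equal(fit$alpha, evolution_alpha(e_r), tolerance = 1e-3)
    expect_equal(fit$beta, evolution_beta(e_r), tolerance = 1e-3)
    expect_equal(fit$pearson_r, 1, tolerance = 1e-6)
  }
})

test_that("fitting handles degenerate and short inputs", {
  const <- ratcheting_curve(1:50, rep(0.042, 50))
  fit <- fit_ratcheting_curve(const)
  expect_true(fit$degenerate)
  expect_equal(fit$amplitude, 0.042)
  expect_error(fit_ratcheting_curve(ratcheting_curve(1:5, (1:5) / 10)),
               "at least 10 cycles")
})

test_that("material coefficient is the origin-constrained amplitude slope", {
  ers <- c(0.59, 1.18, 1.76)
  # amplitudes exactly K * X_SR give back K exactly
  expect_equal(fit_material_coefficient(0.0137 * ers, ers), 0.0137)
  expect_equal(fit_material_coefficient(0.01 * 2 * (ers - 0.1), ers,
                                        k_r = 2, e_rth = 0.1), 0.01)
  expect_error(fit_material_coefficient(0.01, 0.59), "distinct")
  expect_error(fit_material_coefficient(c(0, 0), c(0.1, 0.2), e_rth = 0.5),
               "zero")
})

test_that("parameter-stress relations are recovered by OLS", {
  ers <- c(0.59, 1.18, 1.76)
  rel <- fit_parameter_relations(ers, evolution_alpha(ers),
                                 evolution_beta(ers))
  expect_equal(rel$alpha_intercept, 53.565, tolerance = 1e-9)
  expect_equal(rel$alpha_slope, 10.571, tolerance = 1e-9)
  expect_equal(rel$beta_intercept, 0.13, tolerance = 1e-9)
  expect_equal(rel$beta_slope, -0.035, tolerance = 1e-9)
  expect_error(fit_parameter_relations(c(1, 1), c(60, 60), c(0.1, 0.1)),
               "distinct")
})

test_that("prediction interpolates consistently and errors on extrapolation", {
  ers <- c(0.59, 1.18, 1.76)
  rel <- fit_parameter_relations(ers, evolution_alpha(ers),
                                 evolution_beta(ers))
  N <- 1:200
  # at a training stress the prediction equals direct evaluation
  pred <- predict_ratcheting(1.18, N, rel, K = 0.01)
  expect_equal(pred$ratcheting_strain, urmk_evaluate(N, 1.18, urmk_params()),
               tolerance = 1e-12)
  # an intermediate stress lies between its neighbours pointwise
  p088 <- predict_ratcheting(0.88, N, rel, K = 0.01)
  lo <- urmk_evaluate(N, 0.59, urmk_params())
  hi <- urmk_evaluate(N, 1.18, urmk_params())
  expect_true(all(p088$ratcheting_strain > lo))
  expect_true(all(p088$ratcheting_strain < hi))
  expect_true(all(diff(p088$ratcheting_strain) > 0))
  # beta(e_r) <= 0 beyond e_r ~ 3.71: extrapolation error
  expect_error(predict_ratcheting(3.8, N, rel, extrapolation = Inf),
               "extrapolation")
  # outside the configured stress band around the training stresses
  expect_error(predict_ratcheting(2.5, N, rel, extrapolation = 0.3),
               "band")
})

test_that("parameters and fits serialize to JSON and back", {
  p <- urmk_params(K = 0.0093, k_r = 1.2, e_rth = 0.05)
  path <- tempfile(fileext = ".json")
  write_urmk_json(p, path)
  q <- read_urmk_json(path)
  expect_equal(q$K, p$K)
  expect_equal(q$k_r, p$k_r)
  expect_equal(q$e_rth, p$e_rth)
  expect_equal(q$form_id, p$form_id)
})
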