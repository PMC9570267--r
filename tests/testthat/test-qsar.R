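hct_design <- function(response = "identity") {
  build_design_matrix(
    bundled_fixture("reactivity_inputs"),
    bundled_fixture("physchem"),
    model_spec(c("e_lumo", "chi", "s_soft", "logp", "n_rotb"),
               response, phase = "aqueous"),
    bundled_fixture("activities"),
    "HCT")
}

test_that("response transforms match their definitions", {
  expect_equal(transform_response(1, "log10"), 0)
  expect_equal(round(transform_response(22.80, "log10_reciprocal"), 3), -1.358)
  expect_equal(round(transform_response(0.06, "reciprocal"), 3), 16.667)
  ic <- c(0.06, 1.95, 22.8, 140.48)
  expect_equal(transform_response(ic, "log10_reciprocal"),
               -transform_response(ic, "log10"))
  for (kind in c("identity", "reciprocal", "log10_reciprocal", "log10")) {
    expect_equal(inverse_transform_response(
      transform_response(ic, kind), kind), ic)
  }
  expect_error(transform_response(-1, "log10"), class = "deskqsar_domain_error")
  expect_error(transform_response(0, "reciprocal"),
               class = "deskqsar_domain_error")
  expect_equal(transform_response(-1, "identity"), -1)
})

test_that("design matrix assembles the observed HCT panel", {
  dm <- hct_design()
  expect_equal(dim(dm$x), c(4, 5))
  expect_equal(colnames(dm$x),
               c("e_lumo_ev", "chi", "s_soft", "logp", "n_rotb"))
  expect_equal(dm$compounds, c("2H", "6H", "7H", "9H"))
  expect_equal(dm$y, c(22.80, 43.25, 1.95, 0.06))
  expect_equal(length(dm$dropped), 0)
  # cell line with censoring: only 7H and 9H were assayed on A549
  dm2 <- build_design_matrix(
    bundled_fixture("reactivity_inputs"), bundled_fixture("physchem"),
    model_spec("logp"), bundled_fixture("activities"), "A549")
  expect_equal(dm2$compounds, c("7H", "9H"))
  expect_equal(sort(dm2$dropped), c("2H", "6H"))
  expect_equal(ncol(dm2$x), 1)
})

test_that("design matrix errors are informative", {
  expect_error(
    build_design_matrix(
      bundled_fixture("reactivity_inputs"), bundled_fixture("physchem"),
      model_spec("not_a_descriptor"), bundled_fixture("activities"), "HCT"),
    "valid names", class = "deskqsar_schema_error")
  expect_error(
    build_design_matrix(
      bundled_fixture("reactivity_inputs"), bundled_fixture("physchem"),
      model_spec("logp"), bundled_fixture("activities"), "LNCaP"),
    class = "deskqsar_lookup_error")
  expect_error(model_spec(character()), class = "deskqsar_validation_error")
  expect_error(model_spec(c("logp", "logp")),
               class = "deskqsar_validation_error")
})

test_that("fit_ols agrees with lm on well-determined designs", {
  set.seed(41)
  n <- 20
  x <- cbind(a = runif(n), b = rnorm(n))
  y0 <- 1 + 2 * x[, "a"] - 3 * x[, "b"]
  f <- fit_ols(x, y0)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), c(2, -3), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-8)
  expect_false(f$underdetermined)

  y <- y0 + rnorm(n, 0, 0.3)
  f2 <- fit_ols(x, y)
  ref <- lm(y ~ a + b, data = data.frame(x, y))
  expect_equal(c(f2$intercept, unname(f2$coefficients)),
               unname(coef(ref)), tolerance = 1e-10)
  expect_equal(f2$r2, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(f2$adj_r2, summary(ref)$adj.r.squared, tolerance = 1e-10)
  expect_equal(unname(f2$se), unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  ci <- coef_confint(f2)
  expect_equal(unname(ci), unname(confint(ref)), tolerance = 1e-10)
})

test_that("underdetermined fits interpolate, flag, and minimize norm", {
  dm <- hct_design()
  f <- fit_ols(dm$x, dm$y)
  expect_true(f$underdetermined)
  expect_equal(f$r2, 1, tolerance = 1e-6)
  expect_true(is.na(f$adj_r2))
  expect_true(all(is.na(f$se)))
  expect_lt(max(abs(f$residuals)), 1e-8)
  # minimum-norm characterization: coefficient vector orthogonal to the
  # null space of the augmented design
  x1 <- cbind(1, dm$x)
  nullspace <- svd(x1, nv = ncol(x1))$v[, (qr(x1)$rank + 1):ncol(x1)]
  beta <- c(f$intercept, f$coefficients)
  expect_lt(max(abs(t(nullspace) %*% beta)), 1e-8)
  expect_error(coef_confint(f), class = "deskqsar_domain_error")
})

test_that("degenerate fits follow the documented conventions", {
  x <- cbind(a = 1:10)
  f <- fit_ols(x, rep(2, 10))        # constant response: r2 = 0
  expect_equal(f$r2, 0)
  expect_error(fit_ols(x[0, , drop = FALSE], numeric()),
               class = "deskqsar_domain_error")
  expect_error(fit_ols(cbind(a = c(1, NA)), c(1, 2)),
               class = "deskqsar_validation_error")
  # collinear columns are rank-deficient, hence flagged even with n > p + 1
  xc <- cbind(a = 1:10, b = 2 * (1:10))
  expect_true(fit_ols(xc, rnorm(10))$underdetermined)
})

test_that("r_squared follows its definition and clamping convention", {
  expect_equal(as.numeric(r_squared(1:5, 1:5)), 1)
  expect_equal(as.numeric(r_squared(1:5, rep(3, 5))), 0)
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  # SS_res = 0.10, SS_tot = 5
  expect_equal(as.numeric(r_squared(obs, pred)), 1 - 0.1 / 5)
  bad <- r_squared(c(1, 2, 3), c(9, -4, 12))
  expect_equal(as.numeric(bad), 0)        # clamped
  expect_lt(attr(bad, "raw"), 0)          # raw retained
  expect_error(r_squared(1:3, 1:4), class = "deskqsar_dimension_error")
})

test_that("r2 is invariant under affine rescaling of descriptors (refit)", {
  set.seed(43)
  n <- 30
  x <- cbind(a = runif(n, -2, 2), b = runif(n, 100, 500))
  y <- 0.5 + 1.2 * x[, "a"] - 0.004 * x[, "b"] + rnorm(n, 0, 0.2)
  r2_base <- fit_ols(x, y)$r2
  x2 <- cbind(a = 10 * x[, "a"] + 3, b = 0.01 * x[, "b"] - 2)
  expect_equal(fit_ols(x2, y)$r2, r2_base, tolerance = 1e-10)
})

test_that("forward stepwise recovers the generating descriptor pair", {
  set.seed(47)
  n <- 40
  cand <- as.data.frame(matrix(runif(n * 6), ncol = 6,
                               dimnames = list(NULL, paste0("d", 1:6))))
  y <- 1 + 2 * cand$d3 - 1.5 * cand$d5     # noiseless, depends on d3 and d5
  st <- stepwise_forward(cand, y, max_terms = 4)
  expect_setequal(st$selected[1:2], c("d3", "d5"))
  expect_equal(length(st$selected), 2)     # no third term improves r2
  expect_equal(st$fit$r2, 1, tolerance = 1e-8)
  expect_equal(st$trace$r2, sort(st$trace$r2))

  one <- stepwise_forward(cand["d3"], y, max_terms = 3)
  expect_equal(one$selected, "d3")

  # 4 observations cap the model at 2 descriptors (p + 1 < n required)
  dm <- hct_design("log10_reciprocal")
  st4 <- stepwise_forward(as.data.frame(dm$x), dm$y, max_terms = 5)
  expect_lte(length(st4$selected), 2)
  expect_error(stepwise_forward(data.frame(), y, 2),
               class = "deskqsar_domain_error")
})

test_that("apply_model is pure evaluation", {
  expect_equal(apply_model(1, c(x = 2), data.frame(x = 3)), 7)
  rows <- data.frame(x = 1:4, z = 0)
  expect_equal(apply_model(5, c(x = 0, z = 0), rows), rep(5, 4))
  expect_error(apply_model(0, c(q = 1), rows), class = "deskqsar_schema_error")
  # reported first-model equation evaluated on the 2H gas descriptors gives a
  # value far from the observed 22.80 -- the equation is kept evaluable but
  # is not certified against the observed activities
  desc <- descriptor_table(bundled_fixture("reactivity_inputs"), "gas")
  row <- merge(desc, bundled_fixture("physchem"), by = "compound")
  row <- row[row$compound == "2H", ]
  pred <- apply_model(-223, c(e_lumo_ev = -3.58, chi = 11.55, s_soft = 50.9,
                              logp = -9.089, n_rotb = -15.61), row)
  expect_equal(round(pred, 1), -171.1)
})

test_that("predicted_vs_observed has zero residual sum with an intercept", {
  set.seed(53)
  n <- 25
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 2 + x[, "a"] + rnorm(n, 0, 0.5)
  f <- fit_ols(x, y)
  pvo <- predicted_vs_observed(f, x, y)
  expect_equal(sum(pvo$residual), 0, tolerance = 1e-8)
  expect_equal(pvo$observed - pvo$predicted, pvo$residual)

  y0 <- 1 + 3 * x[, "a"]
  f0 <- fit_ols(x, y0)
  pvo0 <- predicted_vs_observed(f0, x, y0)
  expect_lt(max(abs(pvo0$residual)), 1e-8)
  expect_error(predicted_vs_observed(f, x[0, , drop = FALSE], numeric()),
               class = "deskqsar_domain_error")
  expect_error(predicted_vs_observed(f, x[, 1, drop = FALSE], y),
               class = "deskqsar_dimension_error")
})

test_that("log10_reciprocal predictions mirror log10 predictions", {
  dm_a <- hct_design("log10_reciprocal")
  dm_b <- hct_design("log10")
  fa <- fit_ols(dm_a$x, dm_a$y)
  fb <- fit_ols(dm_b$x, dm_b$y)
  pa <- predicted_vs_observed(fa, dm_a$x, dm_a$y)$predicted
  pb <- predicted_vs_observed(fb, dm_b$x, dm_b$y)$predicted
  expect_equal(pa, -pb, tolerance = 1e-8)
  # holds on well-determined synthetic designs too
  set.seed(59)
  sim <- simulate_compounds(simulation_config(n_compounds = 30, seed = 60))
  for (kind in c("log10", "log10_reciprocal")) {
    spec <- model_spec(c("logp", "s_soft", "n_rotb"), kind)
    dm <- build_design_matrix(sim$quantum, sim$physchem, spec,
                              sim$activity, "HCT")
    f <- fit_ols(dm$x, dm$y)
    assign(paste0("pred_", kind),
           predicted_vs_observed(f, dm$x, dm$y)$predicted)
  }
  expect_equal(pred_log10_reciprocal, -pred_log10, tolerance = 1e-8)
})
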