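# PGLS with Pagel's lambda: GLS core, lambda profiling, relative measures.

test_that("PGLS at lambda = 0 equals ordinary least squares", {
  d <- simulate_grade_dataset(simulate_tree(40, seed = 1), seed = 2)
  f <- fit_pgls(d$traits, log_neurons ~ log_brain, d$tree, lambda = 0)
  ols <- lm(log_neurons ~ log_brain, data = d$traits)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f$residuals), unname(resid(ols)), tolerance = 1e-8)
})

test_that("PGLS at fixed lambda matches the dense GLS oracle", {
  tr <- simulate_tree(5, seed = 9)
  d <- simulate_grade_dataset(tr, seed = 10)
  for (lam in c(0.3, 1)) {
    f <- fit_pgls(d$traits, log_neurons ~ log_brain, tr, lambda = lam,
                  method = "ML")
    x_mat <- cbind(1, d$traits$log_brain)
    v <- lambda_transform(bm_covariance(tr)[d$traits$species, d$traits$species], lam)
    o <- dense_gls_oracle(d$traits$log_neurons, x_mat, v)
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2_reml, tolerance = 1e-8)
    expect_equal(f$loglik_ml, o$loglik_ml, tolerance = 1e-8)
    expect_equal(f$loglik_reml, o$loglik_reml, tolerance = 1e-8)
  }
})

test_that("estimated fits agree with nlme::gls with corPagel", {
  skip_if_not_installed("nlme")
  d <- simulate_grade_dataset(simulate_tree(80, seed = 2), lambda = 0.6, seed = 3)
  f <- fit_pgls(d$traits, log_neurons ~ log_brain, d$tree, method = "REML")
  dd <- as.data.frame(d$traits)
  g <- nlme::gls(log_neurons ~ log_brain, data = dd,
                 correlation = ape::corPagel(0.5, d$tree, form = ~species),
                 method = "REML")
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-5)
  expect_equal(f$lambda,
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)
  expect_equal(f$loglik_reml, as.numeric(logLik(g)), tolerance = 1e-5)
})

test_that("fit metadata is coherent: df, t, p, boundary flags", {
  d <- simulate_grade_dataset(simulate_tree(30, seed = 4), seed = 5)
  f <- fit_pgls(d$traits, log_neurons ~ log_brain, d$tree)
  expect_equal(f$df_residual, f$n - 2)
  expect_equal(unname(f$t_value), unname(f$coefficients / f$se))
  expect_equal(unname(f$p_value),
               unname(2 * pt(-abs(f$t_value), f$df_residual)))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  # singular design
  d2 <- d$traits
  d2$dup <- d2$log_brain
  expect_error(fit_pgls(d2, log_neurons ~ log_brain + dup, d$tree), "singular")
})

test_that("normal equations hold in the fitted metric", {
  d <- simulate_grade_dataset(simulate_tree(50, seed = 6), seed = 7)
  f <- fit_pgls(d$traits, log_neurons ~ log_brain, d$tree)
  v <- lambda_transform(bm_covariance(f$tree)[f$species, f$species], f$lambda)
  x_mat <- cbind(1, f$data$log_brain)
  score <- t(x_mat) %*% solve(v, f$residuals)
  expect_lt(max(abs(score)), 1e-8)
})

test_that("species name matching prunes and warns", {
  d <- simulate_grade_dataset(simulate_tree(20, seed = 8), seed = 9)
  extra <- d$traits
  extra$species[1] <- "not_in_tree"
  expect_warning(f <- fit_pgls(extra, log_neurons ~ log_brain, d$tree),
                 "pruned")
  expect_equal(f$n, 19)
})

test_that("relative measures behave like regression residuals", {
  tr <- simulate_tree(25, seed = 12)
  d <- simulate_grade_dataset(tr, seed = 13)
  # exact collinear data: residuals are zero
  d0 <- d$traits
  d0$log_neurons <- 7 + 0.7 * d0$log_brain
  r0 <- relative_measure(d0, "log_brain", "log_neurons", tr)
  expect_lt(max(abs(r0$relative)), 1e-10)
  # location equivariance: adding a constant leaves residuals unchanged
  r1 <- relative_measure(d$traits, "log_brain", "log_neurons", tr)
  shifted <- d$traits
  shifted$log_neurons <- shifted$log_neurons + 2.5
  r2 <- relative_measure(shifted, "log_brain", "log_neurons", tr)
  expect_equal(r1$relative, r2$relative, tolerance = 1e-8)
  # V-inverse-weighted residual mean is zero (intercept normal equation)
  fit <- attr(r1, "fit")
  v <- lambda_transform(bm_covariance(fit$tree)[fit$species, fit$species],
                        fit$lambda)
  expect_lt(abs(sum(solve(v, r1$relative))), 1e-8)
  # tiny scopes are refused
  expect_error(relative_measure(d$traits, "log_brain", "log_neurons", tr,
                                scope = d$traits$species[1:3]),
               "at least 4")
})
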