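# Grade models, the merging cascade, fold changes, density-vs-size.

test_that("a single-group grade model collapses to plain PGLS", {
  d <- simulate_grade_dataset(simulate_tree(30, seed = 1), seed = 2)
  dd <- d$traits
  dd$grade <- "all"
  gm <- fit_grade_model(dd, "log_brain", "log_neurons", "grade", d$tree)
  f <- fit_pgls(d$traits, log_neurons ~ log_brain, d$tree)
  gl <- grade_lines(gm)
  expect_equal(c(gl$intercept, gl$slope), unname(f$coefficients),
               tolerance = 1e-8)
  expect_equal(gm$fit$lambda, f$lambda, tolerance = 1e-6)
})

test_that("groups with fewer than 2 species are rejected by name", {
  d <- simulate_grade_dataset(simulate_tree(20, seed = 3), seed = 4)
  dd <- d$traits
  dd$grade <- c("lonely", rep("rest", 19))
  expect_error(fit_grade_model(dd, "log_brain", "log_neurons", "grade", d$tree),
               "lonely")
})

test_that("two planted grades are recovered within 2 SE", {
  tr <- simulate_tree(128, seed = 5)
  b <- pick_clade_branch(tr, 50)
  painting <- regime_painting(tr, b)
  params <- ou_params(0.01, 0.01, theta = c(7, 7.5), beta = c(0.7, 0.7))
  d <- simulate_grade_dataset(tr, painting, params, lambda = 0.5,
                              resid_sd = 0.15, seed = 6)
  gm <- fit_grade_model(d$traits, "log_brain", "log_neurons", "grade", d$tree)
  gl <- grade_lines(gm)
  # true intercepts at the regime thetas
  expect_lt(abs(gl$intercept[gl$group == "R1"] - 7),
            2 * gl$intercept_se[gl$group == "R1"])
  expect_lt(abs(gl$intercept[gl$group == "R2"] - 7.5),
            2 * gl$intercept_se[gl$group == "R2"])
})

test_that("the cascade merges a spurious grade back into the ancestral one", {
  merged <- vapply(1:100, function(s) {
    tr <- simulate_tree(64, seed = 300 + s)
    d <- simulate_grade_dataset(tr, lambda = 0.5, resid_sd = 0.15,
                                seed = 700 + s)
    b <- pick_clade_branch(tr, 16)
    dd <- d$traits
    dd$grade <- ifelse(dd$species %in% clade_tips(tr, b), "cand", "anc")
    cs <- merge_grades_cascade(dd, "log_brain", "log_neurons", "grade", tr,
                               ancestral = "anc")
    length(unique(cs$groups)) == 1L
  }, logical(1))
  expect_gte(sum(merged), 90)
})

test_that("planted convergent regimes merge with each other, not the ancestor", {
  hits <- vapply(1:100, function(s) {
    d <- simulate_amniote_dataset(64, seed = 5000 + s)
    sz <- table(d$traits$grade)
    # at 64 tips the random topology occasionally leaves a regime too small
    # to fit; those draws are uninformative for this check
    if (length(sz) < 4 || any(sz < 2)) return(NA)
    cs <- merge_grades_cascade(d$traits, "log_brain", "log_neurons", "grade",
                               d$tree, ancestral = "R1")
    "R3+R4" %in% unique(cs$groups)
  }, logical(1))
  expect_gt(sum(hits, na.rm = TRUE), 50)  # clear majority (observed ~84/95)
})

test_that("retained merges never increase the ML log-likelihood", {
  d <- simulate_amniote_dataset(96, seed = 17)
  cs <- merge_grades_cascade(d$traits, "log_brain", "log_neurons", "grade",
                             d$tree, ancestral = "R1")
  expect_true(all(cs$trail$loglik_full >= cs$trail$loglik_reduced - 1e-6))
  expect_true(all(cs$trail$statistic >= -1e-6))
})

test_that("fold change has its closed forms and antisymmetry", {
  # parallel lines: eval points are irrelevant
  f1 <- fold_change_lines(c(2.3, 0.7), c(2.0, 0.7), eval_points = c(-5, 0, 3))
  f2 <- fold_change_lines(c(2.3, 0.7), c(2.0, 0.7), eval_points = runif(10))
  expect_equal(f1$fold, 10^0.3)
  expect_equal(f2$fold, 10^0.3)
  # identical lines
  expect_equal(fold_change_lines(c(1, 0.5), c(1, 0.5), 1:3)$fold, 1)
  # antisymmetry with non-parallel lines
  a <- c(1.2, 0.8); b <- c(0.9, 0.6); pts <- rnorm(20, 2)
  expect_equal(fold_change_lines(a, b, pts)$fold,
               1 / fold_change_lines(b, a, pts)$fold, tolerance = 1e-12)
  expect_error(fold_change_lines(a, b, numeric(0)), "non-empty")
})

test_that("fold change from a grade model uses both groups' predictor values", {
  d <- simulate_amniote_dataset(96, seed = 21)
  gm <- fit_grade_model(d$traits, "log_brain", "log_neurons", "grade", d$tree)
  fc <- fold_change(gm, "R2", "R1")
  n_expected <- sum(d$traits$grade %in% c("R1", "R2"))
  expect_length(fc$eval_points, n_expected)
  expect_gt(fc$fold, 1)  # planted elevation of R2 over R1
  expect_error(fold_change(gm, "R2", "nonsense"), "unknown grade")
})

test_that("density-vs-size regression is calibrated under independence", {
  nonsig <- vapply(1:100, function(s) {
    tr <- simulate_tree(48, seed = 8000 + s)
    set.seed(9000 + s)
    b <- simulate_bm(tr, 0.35^2 / 300 * 16, 2.5)
    br <- -1.3 + 0.75 * b + simulate_lambda_resid(tr, 0.7, 0.2)
    ne <- 7.5 + 0.65 * br + simulate_lambda_resid(tr, 0.7, 0.15)
    d <- tibble::tibble(species = tr$tip.label, log_body = unname(b),
                        log_brain = unname(br), log_neurons = unname(ne))
    f <- density_vs_size_regression(d, tr)
    f$p_value[2] > 0.05
  }, logical(1))
  expect_gte(sum(nonsig), 88)  # ~95 expected at alpha = 0.05
})

test_that("density-vs-size detects a planted residual association", {
  tr <- simulate_tree(96, seed = 31)
  set.seed(32)
  b <- simulate_bm(tr, 0.35^2 / 300 * 16, 2.5)
  size_res <- simulate_lambda_resid(tr, 0.7, 0.2)
  br <- -1.3 + 0.75 * b + size_res
  # density residuals correlated with size residuals
  ne <- 7.5 + 0.65 * br + 0.4 * size_res + simulate_lambda_resid(tr, 0.7, 0.05)
  d <- tibble::tibble(species = tr$tip.label, log_body = unname(b),
                      log_brain = unname(br), log_neurons = unname(ne))
  f <- density_vs_size_regression(d, tr)
  expect_lt(f$p_value[2], 0.001)
  expect_gt(f$coefficients[2], 0)
})
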