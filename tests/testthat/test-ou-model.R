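# Multi-regime OU regression likelihood and the shift priors.

test_that("K = 1 OU likelihood approaches the BM regression likelihood", {
  tr <- simulate_tree(15, seed = 1, depth = 2)
  d <- simulate_grade_dataset(tr, seed = 2)
  xv <- setNames(d$traits$log_brain, d$traits$species)
  yv <- setNames(d$traits$log_neurons, d$traits$species)
  theta <- 7.4; beta <- 0.68; s2 <- 0.05
  ll_ou <- ou_regression_loglik(xv, yv, tr, regime_painting(tr),
                                ou_params(1e-8, s2, theta, beta))
  # BM regression density with the same line
  v <- s2 * bm_covariance(tr)
  r <- yv[tr$tip.label] - (theta + beta * xv[tr$tip.label])
  ll_bm <- mvtnorm_logd <- -0.5 * (length(r) * log(2 * pi) +
                                     determinant(v)$modulus +
                                     t(r) %*% solve(v, r))
  expect_equal(ll_ou, as.numeric(ll_bm), tolerance = 1e-5)
})

test_that("the OU likelihood matches a hand-built dense MVN on 3 taxa", {
  tr <- read_phylogeny("((A:1,B:1):1,C:2);")
  p <- regime_painting(tr, shifts = 5L)
  alpha <- 0.8; s2 <- 0.3
  theta <- c(1, 2); beta <- c(0.5, 0.9)
  x <- c(A = 0.3, B = -0.2, C = 1.1)
  y <- c(A = 2.0, B = 1.4, C = 1.8)
  # mean: explicit segment sums for each tip
  wA2 <- exp(-alpha * (2 - 2)) - exp(-alpha * (2 - 0))  # shifted clade path
  wA1 <- 1 - wA2
  mu <- c(wA1 * theta[1] + wA2 * theta[2] + (wA1 * beta[1] + wA2 * beta[2]) * x["A"],
          wA1 * theta[1] + wA2 * theta[2] + (wA1 * beta[1] + wA2 * beta[2]) * x["B"],
          theta[1] + beta[1] * x["C"])
  # covariance: closed form per pair
  vd <- s2 / (2 * alpha) * (1 - exp(-2 * alpha * 2))
  vab <- s2 / (2 * alpha) * exp(-2 * alpha * 1) * (1 - exp(-2 * alpha * 1))
  v <- matrix(c(vd, vab, 0, vab, vd, 0, 0, 0, vd), 3)
  r <- as.numeric(y - mu)
  ll_oracle <- -0.5 * (3 * log(2 * pi) + as.numeric(determinant(v)$modulus) +
                         as.numeric(t(r) %*% solve(v, r)))
  ll <- ou_regression_loglik(x, y, tr, p, ou_params(alpha, s2, theta, beta))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
})

test_that("the C++ pruning likelihood agrees with the dense R implementation", {
  for (s in 1:8) {
    tr <- simulate_tree(sample(10:40, 1), seed = 100 + s)
    bt <- branch_table(tr)
    sh <- sample(bt$branch[!bt$is_tip], sample(0:3, 1))
    p <- regime_painting(tr, sh)
    pars <- ou_params(runif(1, 1e-3, 0.1), runif(1, 1e-4, 0.1),
                      theta = rnorm(p$k, 7, 1), beta = rnorm(p$k, 0.7, 0.2))
    d <- simulate_grade_dataset(tr, p, pars, residual_mode = "ou",
                                seed = 200 + s)
    xv <- setNames(d$traits$log_brain, d$traits$species)
    yv <- setNames(d$traits$log_neurons, d$traits$species)
    ll_r <- ou_regression_loglik(xv, yv, tr, p, pars)
    td <- allogrades:::sampler_tree_data(tr, xv, yv)
    reg <- p$regime[as.character(td$branch_ids)] - 1L
    ll_c <- allogrades:::ou_loglik_fast(td, reg, pars$alpha, pars$sigma_sq,
                                        pars$theta, pars$beta)
    expect_equal(ll_r, ll_c, tolerance = 1e-8)
  }
})

test_that("true parameters beat theta perturbed by 2 stationary SDs", {
  wins <- vapply(1:100, function(s) {
    tr <- simulate_tree(64, seed = 7000 + s)
    p <- regime_painting(tr)
    alpha <- 2 / 300
    s2 <- 0.1^2 * 2 * alpha
    pars <- ou_params(alpha, s2, theta = 7.5, beta = 0.65)
    d <- simulate_grade_dataset(tr, p, pars, residual_mode = "ou",
                                seed = 7500 + s)
    xv <- setNames(d$traits$log_brain, d$traits$species)
    yv <- setNames(d$traits$log_neurons, d$traits$species)
    pert <- ou_params(alpha, s2, theta = 7.5 + 0.2, beta = 0.65)
    ou_regression_loglik(xv, yv, tr, p, pars) >
      ou_regression_loglik(xv, yv, tr, p, pert)
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("shift priors implement the stated hyperpriors on branch counts", {
  tr <- simulate_tree(251, seed = 9)  # 500 branches
  d <- simulate_grade_dataset(tr, seed = 10)
  pr <- shift_priors(tr, setNames(d$traits$log_brain, d$traits$species),
                     setNames(d$traits$log_neurons, d$traits$species))
  expect_equal(pr$n_branch, 500)
  expect_equal(pr$pois_mean, 10)
  expect_equal(pr$max_shifts, 100)
  expect_equal(pr$theta_mean, mean(d$traits$log_neurons))
  expect_equal(pr$theta_sd, 1.5 * sd(d$traits$log_neurons))
  expect_equal(pr$beta_sd, 0.3)
})

test_that("log prior assembles the closed-form component densities", {
  tr <- read_phylogeny("((A:1,B:1):1,C:2);")
  pr <- shift_priors(tr, c(A = 1, B = 2, C = 3), c(A = 1, B = 2, C = 3),
                     beta_mean = 0.7)
  pars <- ou_params(alpha = 0.1, sigma_sq = 0.2, theta = 1.5, beta = 0.6)
  got <- log_prior(pars, regime_painting(tr), pr)
  hc <- function(x, s) log(2 / (pi * s)) - log1p((x / s)^2)
  pois_norm <- sum(dpois(0:pr$max_shifts, pr$pois_mean))
  want <- hc(0.1, 0.1) + hc(0.2, 0.1) +
    dnorm(1.5, pr$theta_mean, pr$theta_sd, log = TRUE) +
    dnorm(0.6, 0.7, 0.3, log = TRUE) +
    dpois(0, pr$pois_mean, log = TRUE) - log(pois_norm)
  # zero shifts: the location term contributes nothing
  expect_equal(got, want, tolerance = 1e-12)
  # at x = scale the half-Cauchy density is 1 / (pi * scale)
  expect_equal(hc(0.1, 0.1), log(1 / (pi * 0.1)))
  # shift counts above the truncation bound are impossible
  bt <- branch_table(tr)
  p_all <- regime_painting(tr, bt$branch[1])
  pr_tight <- pr
  pr_tight$max_shifts <- 0
  pars2 <- ou_params(0.1, 0.2, theta = c(1, 1), beta = c(0.6, 0.6))
  expect_identical(log_prior(pars2, p_all, pr_tight), -Inf)
})
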