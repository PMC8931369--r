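# Reversible-jump sampler: internal consistency, recovery, determinism.

test_that("the trace's log-likelihood and log-prior are honest", {
  d <- simulate_amniote_dataset(48, seed = 1)
  ch <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                   n_iter = 2e4, thin = 200, n_chains = 1, seed = 5)
  chain <- ch$chains[[1]]
  td <- allogrades:::sampler_tree_data(
    ch$tree,
    setNames(d$traits$log_brain, d$traits$species)[ch$tree$tip.label],
    setNames(d$traits$log_neurons, d$traits$species)[ch$tree$tip.label])
  for (i in sample(nrow(chain$draws), 10)) {
    row <- chain$draws[i, ]
    shifts <- chain$shift_branches[i, ]
    shifts <- shifts[!is.na(shifts)]
    painting <- regime_painting(ch$tree, shifts)
    theta <- c(row$theta_root, chain$shift_theta[i, seq_along(shifts)])
    beta <- c(row$beta_root, chain$shift_beta[i, seq_along(shifts)])
    pars <- ou_params(row$alpha, row$sigma2, theta, beta)
    reg <- painting$regime[as.character(td$branch_ids)] - 1L
    ll <- allogrades:::ou_loglik_fast(td, reg, row$alpha, row$sigma2,
                                      theta, beta)
    expect_equal(row$loglik, ll, tolerance = 1e-8)
    expect_equal(row$logprior, log_prior(pars, painting, ch$priors),
                 tolerance = 1e-8)
  }
})

test_that("identical seeds give bit-identical chains", {
  d <- simulate_grade_dataset(simulate_tree(32, seed = 21), seed = 22)
  a <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                  n_iter = 2e4, thin = 20, n_chains = 2, seed = 7)
  b <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                  n_iter = 2e4, thin = 20, n_chains = 2, seed = 7)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$chains[[1]]$shift_branches, b$chains[[1]]$shift_branches)
  c2 <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                   n_iter = 2e4, thin = 20, n_chains = 1, seed = 8)
  expect_false(identical(a$chains[[1]]$draws$alpha, c2$chains[[1]]$draws$alpha))
})

test_that("a prior-only run reproduces the truncated Poisson shift-count prior", {
  d <- simulate_grade_dataset(simulate_tree(64, seed = 11), seed = 12)
  ch <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                   n_iter = 6.5e5, thin = 50, n_chains = 1, seed = 99,
                   prior_only = TRUE)
  k <- ch$chains[[1]]$draws$k[!ch$chains[[1]]$draws$warmup]
  expect_gte(length(k), 1e4)
  pr <- ch$priors
  expected <- dpois(0:pr$max_shifts, pr$pois_mean)
  expected <- expected / sum(expected)
  obs <- tabulate(k + 1L, nbins = pr$max_shifts + 1L)
  cut <- max(which(expected * length(k) >= 5))
  obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  exp2 <- c(expected[1:cut], sum(expected[-(1:cut)]))
  gof <- suppressWarnings(chisq.test(obs2, p = exp2))
  expect_gt(gof$p.value, 0.01)
})

test_that("a planted pair of shifts is found and a no-shift tree stays clean", {
  # strong-signal single check; the multi-seed study-scale version lives in
  # the acceptance suite
  d <- two_shift_scenario(128, seed = 45)
  ch <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                   n_iter = 1e5, thin = 100, n_chains = 2, seed = 1005)
  su <- suppressWarnings(summarize_shifts(ch))
  pp_true <- su$branches$pp[match(d$painting$shifts, su$branches$branch)]
  expect_true(all(pp_true > 0.7))
  others <- su$branches$pp[su$branches$clade_size >= 4 &
                             !(su$branches$branch %in% d$painting$shifts)]
  expect_true(all(others <= 0.7))
  # null data: nothing should be called
  d0 <- simulate_grade_dataset(simulate_tree(96, seed = 61),
                               params = ou_params(2 / 300, 0.1^2 * 4 / 300,
                                                  7.5, 0.65),
                               residual_mode = "ou", seed = 62)
  ch0 <- rjmcmc_run(d0$traits, "log_brain", "log_neurons", d0$tree,
                    n_iter = 1e5, thin = 100, n_chains = 2, seed = 77)
  su0 <- suppressWarnings(summarize_shifts(ch0))
  expect_equal(length(su0$accepted), 0L)
})

test_that("summarize_shifts applies the pp and clade-size filters", {
  d <- simulate_grade_dataset(simulate_tree(16, seed = 31), seed = 32)
  ch <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                   n_iter = 5e3, thin = 50, n_chains = 2, seed = 3)
  # forge the pooled samples: every sample carries a shift on one deep
  # branch and on one 2-tip cherry
  bt <- branch_table(ch$tree)
  deep <- bt$branch[!bt$is_tip][which.max(
    vapply(bt$branch[!bt$is_tip],
           function(b) length(clade_tips(ch$tree, b)), integer(1)))]
  cherry <- bt$branch[!bt$is_tip][vapply(
    bt$branch[!bt$is_tip],
    function(b) length(clade_tips(ch$tree, b)) == 2L, logical(1))][1]
  for (i in seq_along(ch$chains)) {
    ns <- nrow(ch$chains[[i]]$shift_branches)
    ch$chains[[i]]$shift_branches[, 1] <- deep
    ch$chains[[i]]$shift_branches[, 2] <- cherry
    ch$chains[[i]]$shift_theta[, 1:2] <- 8
    ch$chains[[i]]$shift_beta[, 1:2] <- 0.7
  }
  su <- suppressWarnings(summarize_shifts(ch))
  tab <- su$branches
  expect_equal(tab$pp[tab$branch == deep], 1)
  expect_equal(tab$pp[tab$branch == cherry], 1)
  expect_true(tab$accepted[tab$branch == deep])
  # pp = 0.95+ but only 2 species: excluded by the clade filter
  expect_false(tab$accepted[tab$branch == cherry])
  expect_true(all(tab$pp >= 0) && all(tab$pp <= 1))
})

test_that("posterior concentrates as tips double in the planted scenario", {
  mean_pp <- function(n_tips) {
    vapply(1:5, function(s) {
      d <- two_shift_scenario(n_tips, seed = 40 + s)
      ch <- rjmcmc_run(d$traits, "log_brain", "log_neurons", d$tree,
                       n_iter = 1e5, thin = 100, n_chains = 2,
                       seed = 2000 + s)
      su <- suppressWarnings(summarize_shifts(ch))
      mean(su$branches$pp[match(d$painting$shifts, su$branches$branch)])
    }, numeric(1))
  }
  expect_gte(mean(mean_pp(128)), mean(mean_pp(64)))
})
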