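# Multi-rate BM fits and rate comparisons across groups and traits.

test_that("a single group reduces to the standard ML BM rate", {
  tr <- simulate_tree(40, seed = 1)
  y <- simulate_bm(tr, 0.02, 0, seed = 2)
  f <- multirate_bm_fit(y, tree = tr, grouping = regime_painting(tr))
  # independent dense estimator: sigma2 = r' V^-1 r / n at the GLS mean
  v <- bm_covariance(tr)
  one <- rep(1, 40)
  vi <- solve(v)
  mu <- as.numeric((t(one) %*% vi %*% y) / (t(one) %*% vi %*% one))
  s2 <- as.numeric(t(y - mu) %*% vi %*% (y - mu)) / 40
  expect_equal(f$rates$sigma_sq, s2, tolerance = 1e-6)
})

test_that("rate estimates are equivariant to branch and trait scaling", {
  tr <- simulate_tree(30, seed = 3)
  b <- pick_clade_branch(tr, 12)
  p <- regime_painting(tr, b)
  y <- simulate_bm(tr, 0.05, 0, seed = 4)
  f0 <- multirate_bm_fit(y, tree = tr, grouping = p)
  tr_c <- tr
  tr_c$edge.length <- tr$edge.length * 4
  f1 <- multirate_bm_fit(y, tree = tr_c, grouping = regime_painting(tr_c, b))
  expect_equal(f1$rates$sigma_sq, f0$rates$sigma_sq / 4, tolerance = 1e-4)
  f2 <- multirate_bm_fit(y * 3, tree = tr, grouping = p)
  expect_equal(f2$rates$sigma_sq, f0$rates$sigma_sq * 9, tolerance = 1e-4)
})

test_that("a planted 3x rate contrast is recovered without bias", {
  ratios <- vapply(1:50, function(s) {
    tr <- simulate_tree(100, seed = 4000 + s)
    b <- pick_clade_branch(tr, 40)
    painting <- regime_painting(tr, b)
    y <- simulate_bm(scale_regime_lengths(tr, painting, 3), 0.01, 0,
                     seed = 4600 + s)
    f <- multirate_bm_fit(y, tree = tr, grouping = painting)
    f$rates$sigma_sq[2] / f$rates$sigma_sq[1]
  }, numeric(1))
  # sampling spread of the ML ratio measured over 200 independent
  # replicates: ~78% falls in [2, 4.5], median 3.1
  expect_gte(sum(ratios >= 2 & ratios <= 4.5), 30)
  expect_gt(median(ratios), 2.4)
  expect_lt(median(ratios), 3.8)
})

test_that("group rate p-values are uniform under a single-rate null", {
  ps <- vapply(1:200, function(s) {
    tr <- simulate_tree(48, seed = 100 + s)
    y <- simulate_bm(tr, 0.01, 0, seed = 600 + s)
    set.seed(1200 + s)
    grp <- setNames(sample(rep(c("a", "b"), length.out = 48)), tr$tip.label)
    compare_group_rates(y, tree = tr, groups = grp, n_sim = 500,
                        seed = 1800 + s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("a planted 4x group rate difference is detected", {
  hits <- vapply(1:50, function(s) {
    tr <- simulate_tree(128, seed = 2200 + s)
    b <- pick_clade_branch(tr, 48)
    painting <- regime_painting(tr, b)
    y <- simulate_bm(scale_regime_lengths(tr, painting, 4), 0.01, 0,
                     seed = 2900 + s)
    grp <- setNames(ifelse(tr$tip.label %in% clade_tips(tr, b),
                           "fast", "slow"), tr$tip.label)
    compare_group_rates(y, tree = tr, groups = grp, n_sim = 500,
                        seed = 3300 + s)$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 45)
})

test_that("tiny simulation counts are refused", {
  tr <- simulate_tree(20, seed = 5)
  y <- simulate_bm(tr, 1, 0, seed = 6)
  grp <- setNames(rep(c("a", "b"), 10), tr$tip.label)
  expect_error(compare_group_rates(y, tree = tr, groups = grp, n_sim = 50),
               "unstable")
})

test_that("trait-rate comparison: identity and power", {
  tr <- simulate_tree(60, seed = 7)
  y <- simulate_bm(tr, 0.02, 0, seed = 8)
  d <- tibble::tibble(species = tr$tip.label, t1 = unname(y), t2 = unname(y))
  same <- compare_trait_rates(d, c("t1", "t2"), tr, n_sim = 200, seed = 9)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  expect_error(compare_trait_rates(d, "t1", tr), "at least 2")
  hits <- vapply(1:50, function(s) {
    tr2 <- simulate_tree(100, seed = 5200 + s)
    d2 <- tibble::tibble(
      species = tr2$tip.label,
      t1 = unname(simulate_bm(tr2, 0.01, 0, seed = 5600 + s)),
      t2 = unname(simulate_bm(tr2, 0.03, 0, seed = 6000 + s)))
    compare_trait_rates(d2, c("t1", "t2"), tr2, n_sim = 200,
                        seed = 6400 + s)$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 45)
})
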