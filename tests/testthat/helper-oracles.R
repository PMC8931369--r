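# Independent oracles and shared fixtures. Everything here is deliberately
# naive (dense solve(), explicit loops) so it cannot share code paths with
# the implementations it checks.

# dense GLS with explicit inverses: beta, sigma2 (ML and REML), logLik
dense_gls_oracle <- function(y, x_mat, v) {
  vi <- solve(v)
  xtvx <- t(x_mat) %*% vi %*% x_mat
  beta <- solve(xtvx, t(x_mat) %*% vi %*% y)
  r <- y - x_mat %*% beta
  rss <- as.numeric(t(r) %*% vi %*% r)
  n <- length(y); p <- ncol(x_mat)
  s2_ml <- rss / n
  s2_reml <- rss / (n - p)
  ll_ml <- -0.5 * (n * log(2 * pi) + n * log(s2_ml) +
                     determinant(v)$modulus + n)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2_reml) +
                       determinant(v)$modulus + determinant(xtvx)$modulus +
                       (n - p))
  list(beta = as.numeric(beta), sigma2_ml = s2_ml, sigma2_reml = s2_reml,
       loglik_ml = as.numeric(ll_ml), loglik_reml = as.numeric(ll_reml))
}

# brute-force BM covariance by enumerating root-to-tip paths
path_cov_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  path_nodes <- function(v) {
    p <- v; cur <- v
    repeat {
      pe <- tree$edge[tree$edge[, 2] == cur, 1]
      if (!length(pe)) break
      p <- c(pe, p); cur <- pe
    }
    p
  }
  paths <- lapply(seq_len(n), path_nodes)
  v <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v[i, j] <- max(h[intersect(paths[[i]], paths[[j]])])
    }
  }
  v
}

# dense GLS ancestral-state oracle: conditional mean given tips, root at
# the GLS mean
dense_anc_oracle <- function(tree, y) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  nn <- n + tree$Nnode
  path_nodes <- function(v) {
    p <- v; cur <- v
    repeat {
      pe <- tree$edge[tree$edge[, 2] == cur, 1]
      if (!length(pe)) break
      p <- c(pe, p); cur <- pe
    }
    p
  }
  paths <- lapply(seq_len(nn), path_nodes)
  full <- matrix(0, nn, nn)
  for (i in seq_len(nn)) {
    for (j in seq_len(nn)) {
      full[i, j] <- max(h[intersect(paths[[i]], paths[[j]])])
    }
  }
  cy <- full[1:n, 1:n]
  ca <- full[(n + 1):nn, 1:n, drop = FALSE]
  one <- rep(1, n)
  ciy <- solve(cy)
  mu <- as.numeric((t(one) %*% ciy %*% y) / (t(one) %*% ciy %*% one))
  as.numeric(mu + ca %*% ciy %*% (y - mu))
}

# planted two-shift OU scenario: two disjoint clades of ~15% of tips each
# jump from (theta, beta) = (7.5, 0.65) to (8.1, 0.8); alpha * depth = 2;
# stationary residual SD 0.1 (typical within-grade allometric scatter).
# Clades are chosen by closest size (the empty lo > hi window disables the
# stem-length preference) so the scenario is frozen independently of the
# preset.
two_shift_scenario <- function(n_tips, seed, sd_stationary = 0.1) {
  tr <- simulate_tree(n_tips, seed = seed)
  b1 <- pick_clade_branch(tr, round(0.15 * n_tips), lo = 1, hi = 0)
  b2 <- pick_clade_branch(tr, round(0.15 * n_tips), lo = 1, hi = 0,
                          avoid = list(clade_tips(tr, b1)))
  alpha <- 2 / 300
  params <- ou_params(alpha, sd_stationary^2 * 2 * alpha,
                      theta = c(7.5, 8.1, 8.1), beta = c(0.65, 0.8, 0.8))
  simulate_grade_dataset(tr, regime_painting(tr, c(b1, b2)), params,
                         residual_mode = "ou", seed = seed + 500)
}

# branch-length rescaling of the branches painted with regime 2, for
# multi-rate simulations
scale_regime_lengths <- function(tree, painting, factor) {
  reg <- painting$regime[as.character(tree$edge[, 2])]
  tree$edge.length <- tree$edge.length * ifelse(reg == 2, factor, 1)
  tree
}

pick_clade_branch <- allogrades:::pick_clade_branch
simulate_lambda_resid <- allogrades:::simulate_lambda_resid
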