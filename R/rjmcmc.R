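# R-side driver for the reversible-jump sampler: tree preprocessing, chain
# management, and the posterior container.

# Summaries of the tree the C++ sampler needs. Edges are passed in
# cladewise (preorder) order; `branch_ids` maps edge index -> child node.
sampler_tree_data <- function(tree, x, y) {
  tree <- ape::reorder.phylo(as_phylogeny(tree), "cladewise")
  if (!isTRUE(attr(tree, "ultrametric"))) {
    stop("shift detection requires an ultrametric (time-calibrated) tree")
  }
  x <- align_to_tips(x, tree)
  y <- align_to_tips(y, tree)
  child <- tree$edge[, 2]
  parent_edge <- match(tree$edge[, 1], child) - 1L
  parent_edge[is.na(parent_edge)] <- -1L
  segs <- tip_path_segments(tree)
  h <- node_heights(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    x = x, y = y,
    depth = h[seq_len(ape::Ntip(tree))],
    seg_tip = segs$tip_id - 1L,
    seg_edge = match(segs$branch, child) - 1L,
    seg_t0 = segs$t_start, seg_t1 = segs$t_end,
    nedge = nrow(tree$edge), parent_edge = parent_edge,
    po_parent = po$edge[, 1] - 1L, po_child = po$edge[, 2] - 1L,
    po_t0 = h[po$edge[, 1]], po_t1 = h[po$edge[, 2]],
    nnode = ape::Ntip(tree) + tree$Nnode,
    branch_ids = child, tree = tree
  )
}

#' Reversible-jump MCMC over multi-regime OU allometries
#'
#' Samples the joint posterior of the shift configuration (which branches
#' start a new scaling regime) and the OU regression parameters
#' (`alpha`, `sigma_sq`, per-regime `theta` and `beta`) by
#' Metropolis-Hastings within reversible jump. Moves are chosen uniformly
#' among: birth of a shift on a random unshifted branch (regime parameters
#' proposed from their priors), death of a random shift, relocation of a
#' shift, and random-walk updates of `alpha`, `sigma_sq` (log scale) and of
#' a random regime's `theta` and `beta`. Proposal step sizes adapt during
#' burn-in only. Chains are reproducible from `seed`.
#'
#' @inheritParams fit_pgls
#' @param x,y names of the log10 predictor and response columns in `data`.
#' @param priors a [shift_priors()] spec; built from the data when `NULL`.
#' @param n_iter iterations per chain (the analysis scale of the original
#'   studies is in the millions; see the vignette for guidance).
#' @param thin keep every `thin`-th iteration.
#' @param burn_in fraction of samples discarded as burn-in.
#' @param n_chains number of independent chains (>= 2 for diagnostics).
#' @param seed integer; chain c uses `seed + c - 1`.
#' @param prior_only if `TRUE` the likelihood is held constant, so the
#'   sampler targets the prior (used for calibration checks).
#' @return a `posterior_chains` object; see [summarize_shifts()],
#'   [gelman_rhat()], [tidy.posterior_chains()].
#' @export
rjmcmc_run <- function(data, x, y, tree, priors = NULL, n_iter = 200000,
                       thin = 100, burn_in = 0.2, n_chains = 4, seed = 1,
                       prior_only = FALSE, species = "species") {
  if (n_iter < thin) stop("`n_iter` must be at least `thin`")
  if (burn_in < 0 || burn_in >= 1) stop("`burn_in` must be in [0, 1)")
  md <- match_tree_data(data, tree, species, c(x, y))
  xv <- stats::setNames(md$data[[x]], md$data[[species]])
  yv <- stats::setNames(md$data[[y]], md$data[[species]])
  td <- sampler_tree_data(md$tree, xv, yv)
  if (is.null(priors)) priors <- shift_priors(td$tree, td$x, td$y)
  chains <- purrr::map(seq_len(n_chains), function(ch) {
    set.seed(seed + ch - 1L)
    ctrl <- list(
      n_iter = as.integer(n_iter), thin = as.integer(thin),
      prior_only = prior_only,
      adapt_until = as.integer(floor(burn_in * n_iter)),
      step_alpha = 0.6, step_sigma = 0.6,
      step_theta = max(0.2 * priors$theta_sd, 1e-3),
      step_beta = max(0.3 * priors$beta_sd, 1e-3),
      init_alpha = min(max(abs(stats::rcauchy(1, 0, priors$alpha_scale)), 1e-4), 5),
      init_sigma2 = min(max(abs(stats::rcauchy(1, 0, priors$sigma_scale)), 1e-6), 5),
      init_theta = stats::rnorm(1, priors$theta_mean, priors$theta_sd),
      init_beta = stats::rnorm(1, priors$beta_mean, priors$beta_sd)
    )
    raw <- rjmcmc_chain(td[c("x", "y", "depth", "seg_tip", "seg_edge",
                             "seg_t0", "seg_t1", "nedge", "parent_edge",
                             "po_parent", "po_child", "po_t0", "po_t1",
                             "nnode")],
                        unclass(priors), ctrl)
    draws <- tibble::as_tibble(raw$trace)
    draws$iteration <- seq_len(nrow(draws)) * thin
    draws$warmup <- draws$iteration <= burn_in * n_iter
    se <- raw$shift_edges
    se[] <- ifelse(is.na(se), NA_integer_, td$branch_ids[se + 1L])
    list(draws = draws, shift_branches = se,
         shift_theta = raw$shift_theta, shift_beta = raw$shift_beta,
         acceptance = raw$acceptance, steps = raw$steps, seed = seed + ch - 1L)
  })
  structure(list(chains = chains, tree = td$tree, priors = priors,
                 branch_ids = td$branch_ids,
                 x = x, y = y, n_iter = n_iter, thin = thin,
                 burn_in = burn_in, seed = seed, prior_only = prior_only),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("RJ-MCMC posterior: ", length(x$chains), " chain(s) x ",
      x$n_iter, " iterations (thin ", x$thin, ", burn-in ", x$burn_in,
      if (x$prior_only) ", prior-only", ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Posterior draws as a tibble
#'
#' @param x a `posterior_chains` object.
#' @param ... unused.
#' @return tibble with one row per retained sample per chain; `warmup`
#'   marks burn-in samples.
#' @export
tidy.posterior_chains <- function(x, ...) {
  purrr::imap(x$chains, function(ch, i) {
    dplyr::mutate(ch$draws, chain = i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Convergence overview of an RJ-MCMC run
#'
#' @param x a `posterior_chains` object.
#' @param ... unused.
#' @return a tibble with R-hat and effective sample size for `alpha`,
#'   `sigma_sq` (as sigma2), the shift count `k`, and the root regime's
#'   `theta` and `beta`, from pooled post-burn-in samples.
#' @export
glance.posterior_chains <- function(x, ...) {
  pars <- c("alpha", "sigma2", "k", "theta_root", "beta_root")
  purrr::map(pars, function(p) {
    tr <- post_burnin_traces(x, p)
    tibble::tibble(parameter = p,
                   rhat = if (length(tr) >= 2) gelman_rhat(x, p) else NA_real_,
                   ess = effective_sample_size(unlist(tr)))
  }) |> dplyr::bind_rows()
}

post_burnin_traces <- function(chains, parameter) {
  purrr::map(chains$chains, function(ch) {
    ch$draws[[parameter]][!ch$draws$warmup]
  })
}
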