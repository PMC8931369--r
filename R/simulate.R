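# Synthetic phylogenies and trait datasets with planted scaling-regime
# shifts. These generators define the conditions for every recovery and
# calibration test: amniote-like tree depth (300 My), log10 body masses
# spanning roughly five orders of magnitude, lambda- or OU-structured
# residuals around clade-specific allometric lines.

#' Simulate a pure-birth, time-calibrated phylogeny
#'
#' A Yule tree conditioned on `n_tips`, rescaled to the requested depth
#' (default 300 My, evoking the age of crown amniotes).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed (optional).
#' @param depth tree depth in My.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = NULL, depth = 300) {
  if (n_tips < 2) stop("`n_tips` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(node_heights(tree))
  tree$edge.length <- tree$edge.length * depth / h
  as_phylogeny(tree)
}

#' Simulate Brownian motion on a tree
#'
#' Tip values drawn from `N(root_state, sigma_sq * V_BM)` with the exact
#' covariance structure (Cholesky of the BM covariance).
#'
#' @param tree a `phylo`.
#' @param sigma_sq Brownian variance per unit branch length (>= 0).
#' @param root_state trait value at the root.
#' @param seed RNG seed (optional).
#' @return named numeric vector over tips.
#' @export
simulate_bm <- function(tree, sigma_sq = 1, root_state = 0, seed = NULL) {
  if (sigma_sq < 0) stop("`sigma_sq` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  if (sigma_sq == 0) {
    return(stats::setNames(rep(root_state, n), tree$tip.label))
  }
  v <- sigma_sq * bm_covariance(tree)
  x <- root_state + as.numeric(crossprod(chol(v), stats::rnorm(n)))
  stats::setNames(x, tree$tip.label)
}

# residuals with unit tip variance and lambda-structured correlation
simulate_lambda_resid <- function(tree, lambda, sd) {
  if (sd == 0) return(stats::setNames(rep(0, ape::Ntip(tree)), tree$tip.label))
  v <- lambda_transform(bm_covariance(tree), lambda)
  v <- v / mean(diag(v))
  r <- as.numeric(crossprod(chol(v), stats::rnorm(ape::Ntip(tree))))
  stats::setNames(sd * r, tree$tip.label)
}

#' Simulate a trait dataset with planted allometric grades
#'
#' Generates log10 body mass by Brownian motion (tip spread set by
#' `body_span`, roughly the log10 range), a log10 brain mass from a fixed
#' brain-body allometry, and log10 neuron counts from clade-specific
#' regime lines `theta_k + beta_k * x` with either lambda-structured
#' residuals (default; matches the PGLS/grade machinery) or OU-structured
#' residuals with the regime-weighted mean (matches the shift sampler).
#' Ground truth (painting, parameters, lambda, residual SD, seed) is
#' stored so expected values can be recomputed exactly.
#'
#' @param tree a `phylo`, e.g. from [simulate_tree()].
#' @param painting a [regime_painting()]; default no shifts.
#' @param params an [ou_params()] with one theta/beta per regime. For
#'   lambda-mode only `theta` and `beta` are used.
#' @param lambda Pagel's lambda of the neuron-count residuals
#'   (lambda mode).
#' @param resid_sd residual SD on the log10 scale (lambda mode).
#' @param predictor which trait drives the neuron regression:
#'   `"log_brain"` or `"log_body"`.
#' @param residual_mode `"lambda"` or `"ou"`.
#' @param body_span approximate log10 range of body mass.
#' @param body_centre mean log10 body mass (g).
#' @param brain_line `c(intercept, slope, resid_sd)` of the log10
#'   brain-body allometry.
#' @param seed RNG seed (optional).
#' @return a `synthetic_dataset`: list with `tree`, `traits` (tibble:
#'   species, log_body, log_brain, log_neurons, grade), `painting`,
#'   `params`, `lambda`, `resid_sd`, `mode`, `seed`.
#' @export
simulate_grade_dataset <- function(tree, painting = NULL, params = NULL,
                                   lambda = 0.8, resid_sd = 0.15,
                                   predictor = c("log_brain", "log_body"),
                                   residual_mode = c("lambda", "ou"),
                                   body_span = 5, body_centre = 2.5,
                                   brain_line = c(-1.3, 0.75, 0.2),
                                   seed = NULL) {
  predictor <- match.arg(predictor)
  residual_mode <- match.arg(residual_mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(painting)) painting <- regime_painting(tree)
  if (is.null(params)) {
    params <- ou_params(alpha = 2 / max(node_heights(tree)), sigma_sq = 0.01,
                        theta = seq(0, 0.6, length.out = painting$k),
                        beta = rep(0.7, painting$k))
  }
  if (params$k != painting$k) stop("painting/params regime mismatch")
  n <- ape::Ntip(tree)
  depth <- max(node_heights(tree))
  sigma_body <- (body_span / 4)^2 / depth   # tip SD ~ span/4
  log_body <- simulate_bm(tree, sigma_body, body_centre)
  log_brain <- brain_line[1] + brain_line[2] * log_body +
    simulate_lambda_resid(tree, lambda, brain_line[3])
  x <- if (predictor == "log_brain") log_brain else log_body
  bt <- branch_table(tree)
  tip_regime <- painting$regime[as.character(bt$branch[bt$is_tip])]
  tip_regime <- tip_regime[order(bt$branch[bt$is_tip])]  # tip id order
  if (residual_mode == "lambda") {
    mu <- params$theta[tip_regime] + params$beta[tip_regime] * unname(x)
    log_neurons <- mu + simulate_lambda_resid(tree, lambda, resid_sd)
  } else {
    w <- ou_weight_matrix(tree, painting, params$alpha)
    mu <- as.numeric(w %*% params$theta + (w %*% params$beta) * unname(x))
    v <- ou_covariance(tree, params$alpha, params$sigma_sq)
    log_neurons <- mu + as.numeric(crossprod(chol(v), stats::rnorm(n)))
  }
  traits <- tibble::tibble(
    species = tree$tip.label,
    log_body = unname(log_body),
    log_brain = unname(log_brain),
    log_neurons = unname(log_neurons),
    grade = paste0("R", tip_regime)
  )
  structure(list(tree = tree, traits = traits, painting = painting,
                 params = params, lambda = lambda, resid_sd = resid_sd,
                 predictor = predictor, mode = residual_mode, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", ape::Ntip(x$tree), "tips,", x$painting$k,
      "regime(s),", x$mode, "residuals\n")
  print(utils::head(x$traits))
  invisible(x)
}

# pick an internal branch whose clade size is near `target`, restricted to
# branches within `within` (tip set) and disjoint from `avoid` (list of tip
# sets). Among branches in the eligible size range ([lo, hi] x target) the
# longest stem is preferred: shifts are planted where they are
# identifiable, mirroring the long stem branches on which empirical regime
# shifts are detected.
pick_clade_branch <- function(tree, target, within = NULL, avoid = list(),
                              lo = 0.55, hi = 2) {
  bt <- branch_table(tree)
  cand_tbl <- bt[!bt$is_tip, ]
  sizes <- vapply(cand_tbl$branch, function(b) {
    tips <- clade_tips(tree, b)
    if (!is.null(within) && !all(tips %in% within)) return(NA_integer_)
    if (any(vapply(avoid, function(a) any(tips %in% a), logical(1)))) {
      return(NA_integer_)
    }
    length(tips)
  }, integer(1))
  ok <- !is.na(sizes)
  if (!any(ok)) stop("no eligible branch for clade of ~", target, " tips")
  in_window <- ok & sizes >= lo * target & sizes <= hi * target
  if (any(in_window)) {
    cand_tbl$branch[in_window][which.max(cand_tbl$length[in_window])]
  } else {
    cand_tbl$branch[ok][which.min(abs(sizes[ok] - target))]
  }
}

#' Amniote-like synthetic preset
#'
#' Tree plus traits with the planted structure the empirical analyses
#' expect: an ancestral (reptile-like) regime, one large derived clade
#' with elevated neuron scaling (bird/mammal-like), and two smaller
#' unrelated clades planted with an identical, further-elevated regime
#' (core landbird / anthropoid-primate-like convergence). The two
#' convergent regimes share `theta` and `beta` exactly, so the grade
#' cascade should merge them with each other but not with the ancestral
#' grades.
#'
#' @param n_tips number of tips.
#' @param seed RNG seed.
#' @param delta_theta intercept elevation of the derived grade; the
#'   convergent sub-grades sit another `delta_theta` higher.
#' @param delta_beta slope change of the derived grade.
#' @param lambda,resid_sd residual structure passed to
#'   [simulate_grade_dataset()]; in OU mode `resid_sd` sets the
#'   stationary SD.
#' @param residual_mode `"lambda"` (hard regime means, Pagel-structured
#'   residuals; what the PGLS/grade machinery assumes) or `"ou"`
#'   (regime-weighted means, OU residuals; what the shift sampler
#'   assumes).
#' @return a `synthetic_dataset` whose painting has 4 regimes (2 of them
#'   identical in parameters).
#' @export
simulate_amniote_dataset <- function(n_tips = 128, seed = 1,
                                     delta_theta = 0.6, delta_beta = 0.1,
                                     lambda = 0.8, resid_sd = 0.12,
                                     residual_mode = c("lambda", "ou")) {
  residual_mode <- match.arg(residual_mode)
  tree <- simulate_tree(n_tips, seed = seed)
  derived <- pick_clade_branch(tree, round(0.5 * n_tips), lo = 0.7, hi = 1.3)
  derived_tips <- clade_tips(tree, derived)
  conv1 <- pick_clade_branch(tree, round(0.15 * n_tips), within = derived_tips)
  conv1_tips <- clade_tips(tree, conv1)
  # keep at least 4 species in the derived-but-not-convergent grade
  sub_target <- round(0.15 * n_tips)
  hi2 <- max(1, (length(derived_tips) - length(conv1_tips) - 4) / sub_target)
  conv2 <- pick_clade_branch(tree, sub_target, within = derived_tips,
                             avoid = list(conv1_tips), hi = min(2, hi2))
  painting <- regime_painting(tree, c(derived, conv1, conv2))
  base_theta <- 7.5   # log10 neurons at log10 brain mass 0 (1 g brain)
  base_beta <- 0.65
  alpha <- log(2) / 50   # phylogenetic half-life of 50 My
  params <- ou_params(
    alpha = alpha, sigma_sq = resid_sd^2 * 2 * alpha,  # stationary SD = resid_sd
    theta = c(base_theta, base_theta + delta_theta,
              base_theta + 2 * delta_theta, base_theta + 2 * delta_theta),
    beta = c(base_beta, base_beta + delta_beta,
             base_beta + delta_beta, base_beta + delta_beta)
  )
  simulate_grade_dataset(tree, painting, params, lambda = lambda,
                         resid_sd = resid_sd, residual_mode = residual_mode,
                         seed = seed + 1)
}
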