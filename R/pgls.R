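# Phylogenetic generalized least squares with Pagel's lambda.
#
# The GLS core whitens through the Cholesky factor of V(lambda) and profiles
# lambda on [0, 1] by a grid multistart followed by bounded refinement, ties
# broken toward larger lambda.

# Dense GLS at a fixed covariance. Returns everything the wrappers need.
gls_core <- function(y, x_mat, v) {
  n <- length(y)
  p <- ncol(x_mat)
  cl <- chol(v)
  z <- backsolve(cl, y, transpose = TRUE)
  zx <- backsolve(cl, x_mat, transpose = TRUE)
  xtvix <- crossprod(zx)
  beta <- solve(xtvix, crossprod(zx, z))
  rw <- z - zx %*% beta
  rss <- sum(rw^2)
  logdet_v <- 2 * sum(log(diag(cl)))
  sigma2_ml <- rss / n
  sigma2_reml <- rss / (n - p)
  ll_ml <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdet_v + n)
  ll_reml <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2_reml) +
                       logdet_v + as.numeric(determinant(xtvix)$modulus) + (n - p))
  vcov_beta <- sigma2_reml * solve(xtvix)
  resid <- as.numeric(y - x_mat %*% beta)
  names(resid) <- rownames(x_mat)
  list(beta = as.numeric(beta), vcov = vcov_beta, residuals = resid,
       fitted = as.numeric(x_mat %*% beta), rss_white = rss,
       sigma2_ml = sigma2_ml, sigma2_reml = sigma2_reml,
       loglik_ml = ll_ml, loglik_reml = ll_reml, n = n, p = p)
}

profile_lambda <- function(y, x_mat, v_bm, method, grid_by = 0.05) {
  obj <- function(lam) {
    fit <- gls_core(y, x_mat, lambda_transform(v_bm, lam))
    if (method == "REML") fit$loglik_reml else fit$loglik_ml
  }
  grid <- seq(0, 1, by = grid_by)
  vals <- vapply(grid, obj, numeric(1))
  best <- max(which(vals == max(vals)))    # ties toward larger lambda
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  lam <- grid[best]
  if (hi > lo) {
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-7)
    if (opt$objective > vals[best] + 1e-10) lam <- opt$maximum
  }
  # ties toward larger lambda: snap to the upper boundary when it is
  # indistinguishable from the interior optimum
  if (obj(1) >= obj(lam) - 1e-8) lam <- 1
  lam
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `formula` by GLS with residual covariance `sigma^2 * V(lambda)`,
#' where `V` is the Brownian-motion covariance of the phylogeny and
#' `lambda` rescales its off-diagonal entries. `lambda` is estimated by
#' profiling the (restricted) likelihood on \[0, 1\] unless fixed.
#'
#' @param data a data frame with one row per species, including the column
#'   named by `species` and all model variables (log10 scale for
#'   allometric fits).
#' @param formula a model formula, e.g. `log_brain ~ log_body`.
#' @param tree a `phylo` object; tips are matched to `data[[species]]`
#'   after whitespace/underscore normalization, and both sides are pruned
#'   to the common species set (a warning reports any drops).
#' @param species name of the species identifier column.
#' @param method `"REML"` (default) or `"ML"` likelihood for the lambda
#'   profile and reported fit.
#' @param lambda optional fixed value in \[0, 1\]; skips estimation.
#' @return a `pgls_fit` object; see [tidy.pgls_fit()], [glance.pgls_fit()].
#' @export
#' @examples
#' d <- simulate_grade_dataset(simulate_tree(32, seed = 1), seed = 2)
#' fit_pgls(d$traits, log_neurons ~ log_body, d$tree)
fit_pgls <- function(data, formula, tree, species = "species",
                     method = c("REML", "ML"), lambda = NULL) {
  method <- match.arg(method)
  md <- match_tree_data(data, tree, species, all.vars(formula))
  mf <- stats::model.frame(formula, md$data)
  y <- stats::model.response(mf)
  x_mat <- stats::model.matrix(formula, mf)
  rownames(x_mat) <- md$data[[species]]
  n <- nrow(x_mat)
  if (qr(x_mat)$rank < ncol(x_mat)) stop("singular design matrix")
  if (n <= ncol(x_mat) + 1L) stop("too few species (", n, ") for ", ncol(x_mat), " coefficients")
  v_bm <- bm_covariance(md$tree)[rownames(x_mat), rownames(x_mat)]
  fixed <- !is.null(lambda)
  if (!fixed) lambda <- profile_lambda(y, x_mat, v_bm, method)
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]")
  core <- gls_core(y, x_mat, lambda_transform(v_bm, lambda))
  se <- sqrt(diag(core$vcov))
  tval <- core$beta / se
  df <- n - core$p
  structure(list(
    coefficients = stats::setNames(core$beta, colnames(x_mat)),
    se = stats::setNames(se, colnames(x_mat)),
    t_value = stats::setNames(tval, colnames(x_mat)),
    p_value = stats::setNames(2 * stats::pt(-abs(tval), df), colnames(x_mat)),
    df_residual = df,
    lambda = lambda, lambda_fixed = fixed,
    lambda_boundary = !fixed && (lambda < 1e-6 || lambda > 1 - 1e-6),
    sigma2 = core$sigma2_reml, sigma2_ml = core$sigma2_ml,
    loglik_ml = core$loglik_ml, loglik_reml = core$loglik_reml,
    method = method, n = n,
    residuals = core$residuals, fitted = core$fitted,
    formula = formula, species = rownames(x_mat),
    data = md$data, tree = md$tree, species_col = species
  ), class = "pgls_fit")
}

# Match species names between a trait table and a tree; prune both.
match_tree_data <- function(data, tree, species, vars = NULL,
                            min_species = 3L) {
  if (!species %in% names(data)) stop("no `", species, "` column in data")
  data <- tibble::as_tibble(data)
  data[[species]] <- normalize_labels(as.character(data[[species]]))
  if (anyDuplicated(data[[species]])) {
    stop("duplicated species in data: ",
         paste(unique(data[[species]][duplicated(data[[species]])]), collapse = ", "))
  }
  if (!is.null(vars)) {
    keep <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
    if (any(!keep)) {
      message("dropping ", sum(!keep), " species with incomplete traits")
      data <- data[keep, , drop = FALSE]
    }
  }
  common <- intersect(tree$tip.label, data[[species]])
  n_drop_tree <- ape::Ntip(tree) - length(common)
  n_drop_data <- nrow(data) - length(common)
  if (n_drop_tree > 0 || n_drop_data > 0) {
    warning("pruned to ", length(common), " matched species (dropped ",
            n_drop_tree, " tips, ", n_drop_data, " table rows)")
  }
  if (length(common) < min_species) {
    stop("fewer than ", min_species, " species shared by tree and data")
  }
  tree <- ape::keep.tip(tree, common)
  data <- data[match(tree$tip.label, data[[species]]), , drop = FALSE]
  list(data = data, tree = tree)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$method, "), n = ", x$n,
      ", lambda = ", signif(x$lambda, 3),
      if (x$lambda_fixed) " (fixed)", "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a PGLS fit into a coefficient table
#'
#' @param x a `pgls_fit`.
#' @param ... unused.
#' @return a tibble with term, estimate, std.error, statistic, p.value.
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t_value),
    p.value = unname(x$p_value)
  )
}

#' One-row model summary of a PGLS fit
#'
#' @param x a `pgls_fit`.
#' @param ... unused.
#' @return a tibble with lambda, sigma2, logLik (of the fitting method),
#'   nobs and residual df.
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2,
    logLik = if (x$method == "REML") x$loglik_reml else x$loglik_ml,
    logLik_ML = x$loglik_ml,
    nobs = x$n, df.residual = x$df_residual
  )
}

#' Species-level results of a PGLS fit
#'
#' @param x a `pgls_fit`.
#' @param ... unused.
#' @return a tibble with species, fitted and residual columns.
#' @export
augment.pgls_fit <- function(x, ...) {
  tibble::tibble(species = x$species, .fitted = x$fitted,
                 .resid = unname(x$residuals))
}

#' @export
logLik.pgls_fit <- function(object, ...) {
  ll <- if (object$method == "REML") object$loglik_reml else object$loglik_ml
  structure(ll, df = length(object$coefficients) + 2, class = "logLik")
}

#' Relative measure: residuals from a within-scope PGLS allometry
#'
#' A relative measure (relative brain size, relative neuron density, ...)
#' is the residual from the single-slope, single-intercept PGLS regression
#' of `y` on `x` across the group of interest.
#'
#' @inheritParams fit_pgls
#' @param x,y names of the log10 predictor and response columns.
#' @param scope optional character vector of species defining the group of
#'   interest; at least 4 species (lambda is unstable below that).
#' @return a tibble with `species` and `relative` columns; the underlying
#'   fit is attached as attribute `"fit"`.
#' @export
relative_measure <- function(data, x, y, tree, scope = NULL, species = "species",
                             method = "REML") {
  data <- tibble::as_tibble(data)
  if (!is.null(scope)) {
    scope <- normalize_labels(scope)
    data <- data[normalize_labels(as.character(data[[species]])) %in% scope, , drop = FALSE]
  }
  if (nrow(data) < 4L) stop("scope must contain at least 4 species")
  fml <- stats::as.formula(paste(y, "~", x))
  fit <- fit_pgls(data, fml, tree, species = species, method = method)
  out <- tibble::tibble(species = fit$species, relative = unname(fit$residuals))
  attr(out, "fit") <- fit
  out
}
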