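# Allometric grades: grouped PGLS regressions (one slope and intercept per
# grade), the top-down model-selection cascade that confirms grades and
# merges convergent ones, and the fold-change statistic between grade lines.

#' Fit a grouped allometry (grade) model
#'
#' Fits `y ~ x * group` by PGLS with a shared lambda and residual variance:
#' every grade gets its own intercept and slope (cell-means
#' parametrization), so the coefficient table reads directly as one
#' regression line per grade.
#'
#' @inheritParams fit_pgls
#' @param x,y names of the log10 predictor and response columns.
#' @param group name of the column assigning each species to a putative
#'   grade (factor or character); every group needs at least 2 species.
#' @return a `grade_model`: the underlying `pgls_fit` plus the group map
#'   and per-grade lines (see [grade_lines()]).
#' @export
fit_grade_model <- function(data, x, y, group, tree, species = "species",
                            method = c("REML", "ML"), lambda = NULL) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  data[[group]] <- factor(data[[group]])
  sizes <- table(data[[group]])
  if (any(sizes < 2)) {
    stop("grade(s) with fewer than 2 species: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fml <- if (nlevels(data[[group]]) == 1L) {
    stats::as.formula(paste(y, "~", x))   # collapse case: plain allometry
  } else {
    stats::as.formula(paste(y, "~ 0 +", group, "+", x, ":", group))
  }
  fit <- fit_pgls(data, fml, tree, species = species, method = method,
                  lambda = lambda)
  structure(list(fit = fit, x = x, y = y, group = group,
                 groups = stats::setNames(as.character(fit$data[[group]]),
                                          fit$species)),
            class = "grade_model")
}

#' @export
print.grade_model <- function(x, ...) {
  cat("Grade model:", length(unique(x$groups)), "grade(s), n =", x$fit$n,
      ", lambda =", signif(x$fit$lambda, 3), "\n")
  print(grade_lines(x))
  invisible(x)
}

#' Per-grade regression lines of a grade model
#'
#' @param object a `grade_model`.
#' @return a tibble with `group`, `intercept`, `slope` and their standard
#'   errors.
#' @export
grade_lines <- function(object) {
  stopifnot(inherits(object, "grade_model"))
  cf <- object$fit$coefficients
  se <- object$fit$se
  lev <- levels(factor(object$groups))
  if (length(lev) == 1L) {
    return(tibble::tibble(group = lev,
                          intercept = unname(cf[1]), intercept_se = unname(se[1]),
                          slope = unname(cf[2]), slope_se = unname(se[2])))
  }
  ic <- paste0(object$group, lev)
  sl_a <- paste0(object$group, lev, ":", object$x)
  sl_b <- paste0(object$x, ":", object$group, lev)
  sl <- ifelse(sl_a %in% names(cf), sl_a, sl_b)
  tibble::tibble(
    group = lev,
    intercept = unname(cf[ic]), intercept_se = unname(se[ic]),
    slope = unname(cf[sl]), slope_se = unname(se[sl])
  )
}

#' @export
tidy.grade_model <- function(x, ...) {
  tidyr::pivot_longer(grade_lines(x), c("intercept", "slope"),
                      names_to = "term", values_to = "estimate") |>
    dplyr::mutate(std.error = ifelse(.data$term == "intercept",
                                     .data$intercept_se, .data$slope_se)) |>
    dplyr::select("group", "term", "estimate", "std.error")
}

#' @export
glance.grade_model <- function(x, ...) {
  dplyr::mutate(glance(x$fit), n_grades = length(unique(x$groups)),
                .before = 1)
}

# ML fit of a grouping (cascade currency); lambda optionally fixed
grouping_fit <- function(data, x, y, grp, tree, species, lambda = NULL) {
  d <- data
  d$..grade <- grp
  fit_grade_model(d, x, y, "..grade", tree, species = species,
                  method = "ML", lambda = lambda)
}

#' Top-down grade-merging cascade
#'
#' Starting from the full model with every putative grade distinct, each
#' non-ancestral grade is tentatively merged into its ancestral grade; the
#' simpler model is adopted when the likelihood-ratio test does not reject
#' it (p > `alpha`). Retained grades are then merged pairwise with each
#' other, most similar pair first, to identify convergent regimes (clades
#' sharing one allometric line without sharing ancestry). Comparisons use
#' ML fits so that fixed-effects structures are comparable. By default
#' Pagel's lambda is profiled on the reduced (null) model of each
#' comparison and held fixed for both sides: letting lambda float per
#' candidate model lets clade-level residual fluctuations be absorbed
#' twice and empirically inflates the test to about three times its
#' nominal level at moderate n (see the vignette);
#' `lambda_mode = "per-model"` restores the floating behaviour.
#'
#' @inheritParams fit_grade_model
#' @param ancestral name of the ancestral (root-regime) grade; defaults to
#'   the first factor level of `data[[group]]`.
#' @param ancestral_of optional named character vector giving, for a nested
#'   grade, the grade it falls back into when merged; defaults to
#'   `ancestral` for every grade.
#' @param alpha significance level for retaining a grade (default 0.05).
#' @param lambda_mode `"fixed-from-null"` (default) or `"per-model"`.
#' @return a `grade_cascade`: final `grade_model` (fitted with `method`),
#'   the final species-to-grade map, and an audit `trail` tibble with one
#'   row per tested merge.
#' @export
merge_grades_cascade <- function(data, x, y, group, tree, species = "species",
                                 ancestral = NULL, ancestral_of = NULL,
                                 alpha = 0.05, method = c("REML", "ML"),
                                 lambda_mode = c("fixed-from-null", "per-model")) {
  method <- match.arg(method)
  lambda_mode <- match.arg(lambda_mode)
  data <- tibble::as_tibble(data)
  grp <- as.character(data[[group]])
  if (is.null(ancestral)) ancestral <- levels(factor(data[[group]]))[1]
  if (!ancestral %in% grp) stop("ancestral grade `", ancestral, "` not present")
  candidates <- setdiff(unique(grp), ancestral)
  fallback <- stats::setNames(rep(ancestral, length(candidates)), candidates)
  if (!is.null(ancestral_of)) fallback[names(ancestral_of)] <- ancestral_of
  trail <- list()
  # one nested comparison; lambda profiled on the reduced (null) model and
  # held fixed for both sides unless lambda_mode = "per-model"
  compare <- function(grp_full, grp_reduced) {
    red <- grouping_fit(data, x, y, grp_reduced, tree, species)
    lam <- NULL
    if (lambda_mode == "fixed-from-null") {
      lam <- red$fit$lambda
      red <- grouping_fit(data, x, y, grp_reduced, tree, species, lambda = lam)
    }
    full <- grouping_fit(data, x, y, grp_full, tree, species, lambda = lam)
    stat <- 2 * (full$fit$loglik_ml - red$fit$loglik_ml)
    list(ll_full = full$fit$loglik_ml, ll_red = red$fit$loglik_ml,
         stat = stat, p = stats::pchisq(stat, df = 2, lower.tail = FALSE))
  }
  # stage 1: confirm each putative grade against its ancestral grade
  for (g in candidates) {
    target <- fallback[[g]]
    if (!target %in% grp) target <- ancestral
    reduced <- ifelse(grp == g, target, grp)
    cm <- compare(grp, reduced)
    merged <- cm$p > alpha
    trail[[length(trail) + 1L]] <- tibble::tibble(
      stage = "ancestral", grade_a = g, grade_b = target,
      loglik_full = cm$ll_full, loglik_reduced = cm$ll_red,
      statistic = cm$stat, df = 2, p.value = cm$p, merged = merged)
    if (merged) grp <- reduced
  }
  # stage 2: merge unrelated retained grades to identify convergence
  repeat {
    left <- setdiff(unique(grp), ancestral)
    if (length(left) < 2L) break
    pairs <- utils::combn(left, 2, simplify = FALSE)
    res <- purrr::map(pairs, function(pr) {
      merged_name <- paste(sort(pr), collapse = "+")
      reduced <- ifelse(grp %in% pr, merged_name, grp)
      c(list(pair = pr, name = merged_name, reduced = reduced),
        compare(grp, reduced))
    })
    ps <- vapply(res, `[[`, numeric(1), "p")
    best <- which.max(ps)
    r <- res[[best]]
    merged <- r$p > alpha
    trail[[length(trail) + 1L]] <- tibble::tibble(
      stage = "convergence", grade_a = r$pair[1], grade_b = r$pair[2],
      loglik_full = r$ll_full, loglik_reduced = r$ll_red,
      statistic = r$stat, df = 2, p.value = r$p, merged = merged)
    if (!merged) break
    grp <- r$reduced
  }
  d <- data
  d$..grade <- grp
  final <- fit_grade_model(d, x, y, "..grade", tree, species = species,
                           method = method)
  structure(list(model = final,
                 groups = stats::setNames(grp, data[[species]]),
                 ancestral = ancestral,
                 trail = dplyr::bind_rows(trail)),
            class = "grade_cascade")
}

#' @export
print.grade_cascade <- function(x, ...) {
  cat("Grade cascade: ", length(unique(x$groups)), " final grade(s) [",
      paste(sort(unique(x$groups)), collapse = ", "), "]\n", sep = "")
  print(x$trail)
  invisible(x)
}

#' @export
tidy.grade_cascade <- function(x, ...) x$trail

#' Average fold change between two grade regression lines
#'
#' Because grade lines need not be parallel, the intercept difference does
#' not capture their separation. The fold change is instead the vertical
#' difference between the two lines evaluated at every reference body size
#' (by default the log10 body sizes of all species in the two grades),
#' averaged, and exponentiated: `F = 10 ^ mean(line_a - line_b)`.
#'
#' @param object a `grade_model` or `grade_cascade`.
#' @param grade_a,grade_b grade names; the change is expressed as grade_a
#'   relative to grade_b (F > 1 means grade_a lies above).
#' @param eval_points log10 predictor values at which to evaluate the
#'   lines; defaults to the predictor values of all species in the two
#'   grades.
#' @return a `fold_change_result` with `delta_log10` (mean log10 offset),
#'   `fold` and the evaluation points.
#' @export
fold_change <- function(object, grade_a, grade_b, eval_points = NULL) {
  if (inherits(object, "grade_cascade")) object <- object$model
  stopifnot(inherits(object, "grade_model"))
  gl <- grade_lines(object)
  if (!all(c(grade_a, grade_b) %in% gl$group)) {
    stop("unknown grade(s): ",
         paste(setdiff(c(grade_a, grade_b), gl$group), collapse = ", "))
  }
  if (is.null(eval_points)) {
    keep <- object$groups %in% c(grade_a, grade_b)
    eval_points <- object$fit$data[[object$x]][keep]
  }
  la <- gl[gl$group == grade_a, ]
  lb <- gl[gl$group == grade_b, ]
  fold_change_lines(c(la$intercept, la$slope), c(lb$intercept, lb$slope),
                    eval_points)
}

#' Fold change between two explicit log10-scale lines
#'
#' @param line_a,line_b numeric `c(intercept, slope)` on the log10 scale.
#' @param eval_points log10 predictor values; must be non-empty.
#' @return a `fold_change_result`.
#' @export
fold_change_lines <- function(line_a, line_b, eval_points) {
  if (!length(eval_points) || anyNA(eval_points)) {
    stop("`eval_points` must be a non-empty numeric vector")
  }
  delta <- mean((line_a[1] + line_a[2] * eval_points) -
                  (line_b[1] + line_b[2] * eval_points))
  structure(list(delta_log10 = delta, fold = 10^delta,
                 eval_points = eval_points),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("Fold change: ", signif(x$fold, 4), " (mean log10 offset ",
      signif(x$delta_log10, 4), ", ", length(x$eval_points),
      " evaluation points)\n", sep = "")
  invisible(x)
}

#' Relative neuron density against relative size
#'
#' Computes the two relative measures within `scope` — relative size as
#' residuals of `size_y` on `size_x` (e.g. brain on body mass) and relative
#' neuron density as residuals of `dens_y` on `dens_x` (e.g. neuron number
#' on brain mass) — and regresses density on size by PGLS. A positive,
#' significant slope means larger-than-expected structures also pack more
#' neurons than expected.
#'
#' @inheritParams relative_measure
#' @param size_x,size_y,dens_x,dens_y column names (log10 scale).
#' @return a `pgls_fit` of relative density on relative size; the two
#'   residual tibbles are attached as attribute `"relative_measures"`.
#' @export
density_vs_size_regression <- function(data, tree, size_x = "log_body",
                                       size_y = "log_brain",
                                       dens_x = "log_brain",
                                       dens_y = "log_neurons",
                                       scope = NULL, species = "species",
                                       method = "REML") {
  rel_size <- relative_measure(data, size_x, size_y, tree, scope = scope,
                               species = species, method = method)
  rel_dens <- relative_measure(data, dens_x, dens_y, tree, scope = scope,
                               species = species, method = method)
  joined <- dplyr::inner_join(
    dplyr::rename(rel_size, rel_size = "relative"),
    dplyr::rename(rel_dens, rel_density = "relative"), by = "species")
  fit <- fit_pgls(joined, rel_density ~ rel_size, tree, species = "species",
                  method = method)
  attr(fit, "relative_measures") <- joined
  fit
}
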