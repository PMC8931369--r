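# Posterior summarization of shift locations and the filters used to
# accept them.

#' Summarize posterior shift support per branch
#'
#' The posterior probability of a shift on a branch is the fraction of
#' pooled post-burn-in samples in which that branch carries a shift.
#' A shift is accepted when its probability exceeds `pp_threshold` and the
#' clade it subtends contains at least `min_clade` species (the
#' "more than three species" reporting rule corresponds to the default).
#' Convergence is gated on R-hat of `alpha`, `sigma_sq` and the shift
#' count; failure does not suppress the summary but flags it prominently.
#'
#' @param chains a `posterior_chains` object from [rjmcmc_run()].
#' @param pp_threshold posterior-probability threshold for acceptance.
#' @param min_clade minimum number of species a shift's clade must contain.
#' @param rhat_gate R-hat above which the run is flagged as non-converged.
#' @return a `shift_summary`: per-branch tibble (`branch`, `label`, `pp`,
#'   `clade_size`, `theta_mean`, `beta_mean`, `accepted`), root-regime
#'   posterior means, diagnostics, and `converged` flag.
#' @export
summarize_shifts <- function(chains, pp_threshold = 0.7, min_clade = 4,
                             rhat_gate = 1.1) {
  stopifnot(inherits(chains, "posterior_chains"))
  diag_tbl <- glance(chains)
  gate <- diag_tbl$rhat[diag_tbl$parameter %in% c("alpha", "sigma2", "k")]
  converged <- all(is.na(gate) | gate < rhat_gate)
  if (!converged) {
    warning("convergence gate failed: max R-hat = ",
            signif(max(gate, na.rm = TRUE), 4),
            " (summary produced anyway; treat with caution)")
  }
  keep <- purrr::map(chains$chains, function(ch) {
    idx <- which(!ch$draws$warmup)
    list(branch = ch$shift_branches[idx, , drop = FALSE],
         theta = ch$shift_theta[idx, , drop = FALSE],
         beta = ch$shift_beta[idx, , drop = FALSE])
  })
  n_samp <- sum(vapply(keep, function(k) nrow(k$branch), integer(1)))
  all_branch <- unlist(lapply(keep, function(k) as.vector(k$branch)))
  all_theta <- unlist(lapply(keep, function(k) as.vector(k$theta)))
  all_beta <- unlist(lapply(keep, function(k) as.vector(k$beta)))
  ok <- !is.na(all_branch)
  tree <- chains$tree
  bt <- branch_table(tree)
  counts <- table(factor(all_branch[ok], levels = bt$branch))
  per_branch <- tibble::tibble(
    branch = bt$branch, label = bt$label,
    pp = as.numeric(counts) / n_samp,
    clade_size = vapply(bt$branch, function(b) length(clade_tips(tree, b)),
                        integer(1))
  )
  agg <- tibble::tibble(branch = all_branch[ok], theta = all_theta[ok],
                        beta = all_beta[ok]) |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(theta_mean = mean(.data$theta),
                     beta_mean = mean(.data$beta), .groups = "drop")
  per_branch <- dplyr::left_join(per_branch, agg, by = "branch") |>
    dplyr::mutate(accepted = .data$pp > pp_threshold &
                    .data$clade_size >= min_clade) |>
    dplyr::arrange(dplyr::desc(.data$pp))
  root_draws <- tidy(chains) |> dplyr::filter(!.data$warmup)
  structure(list(
    branches = per_branch,
    accepted = per_branch$branch[per_branch$accepted],
    root_theta = mean(root_draws$theta_root),
    root_beta = mean(root_draws$beta_root),
    alpha_mean = mean(root_draws$alpha),
    sigma_sq_mean = mean(root_draws$sigma2),
    pp_threshold = pp_threshold, min_clade = min_clade,
    n_samples = n_samp, diagnostics = diag_tbl, converged = converged,
    tree = tree
  ), class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat("Shift summary (", x$n_samples, " pooled samples; pp > ",
      x$pp_threshold, ", clade >= ", x$min_clade, " species)\n", sep = "")
  if (!x$converged) cat("** NOT CONVERGED: interpret with caution **\n")
  cat(length(x$accepted), "accepted shift(s)\n")
  print(utils::head(x$branches, 10))
  invisible(x)
}

#' @export
tidy.shift_summary <- function(x, ...) x$branches

#' Regime painting induced by the accepted shifts
#'
#' @param summary a `shift_summary`.
#' @return a [regime_painting()] on the summary's tree.
#' @export
painting_from_shifts <- function(summary) {
  stopifnot(inherits(summary, "shift_summary"))
  regime_painting(summary$tree, summary$accepted)
}

#' Putative grade labels from accepted shifts
#'
#' Each species is assigned the regime painting its terminal branch:
#' `"ancestral"` for the root regime, otherwise the label of the branch
#' whose shift defines the regime. This grouping seeds
#' [merge_grades_cascade()].
#'
#' @param summary a `shift_summary` (or a `regime_painting` plus `tree`).
#' @param tree required when `summary` is a painting.
#' @return tibble with `species` and `grade` columns.
#' @export
grades_from_shifts <- function(summary, tree = NULL) {
  if (inherits(summary, "shift_summary")) {
    painting <- painting_from_shifts(summary)
    tree <- summary$tree
  } else {
    painting <- summary
    if (is.null(tree)) stop("`tree` required when passing a painting")
  }
  bt <- branch_table(tree)
  shift_label <- stats::setNames(bt$label[match(painting$shifts, bt$branch)],
                                 seq_along(painting$shifts) + 1L)
  tip_branch <- bt$branch[bt$is_tip]
  regime <- painting$regime[as.character(tip_branch)]
  tibble::tibble(
    species = bt$label[bt$is_tip],
    grade = ifelse(regime == 1L, "ancestral",
                   paste0("shift_", shift_label[as.character(regime)]))
  )
}
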