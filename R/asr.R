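# Ancestral state reconstruction under Brownian motion and the derived
# relative-brain-size reconstruction at internal nodes.

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML estimates of the internal-node states (equivalently, the GLS
#' solution of the joint tip-and-node normal model), computed by the
#' two-pass pruning algorithm of [phytools::fastAnc()], with estimation
#' variances.
#'
#' @param data a data frame with the species column and the trait column,
#'   or a named numeric vector over tips.
#' @param trait name of the (log10) trait column; ignored for a vector.
#' @param tree a `phylo`.
#' @param species species column name.
#' @return a tibble with `node` (ape node number), `estimate` and `var`.
#' @export
ancestral_states_bm <- function(data, trait = NULL, tree = NULL,
                                species = "species") {
  if (is.numeric(data) && !is.null(names(data))) {
    vec <- data
    stopifnot(inherits(trait, "phylo") || inherits(tree, "phylo"))
    if (inherits(trait, "phylo")) tree <- trait
  } else {
    md <- match_tree_data(data, tree, species, trait)
    tree <- md$tree
    vec <- stats::setNames(md$data[[trait]], md$data[[species]])
  }
  if (anyNA(vec)) stop("trait vector must be complete over tips")
  vec <- vec[tree$tip.label]
  # zero-length pendant branches make the tip state an exact ancestor
  # estimate; fastAnc handles this through its matrix algebra
  a <- phytools::fastAnc(tree, vec, vars = TRUE)
  tibble::tibble(node = as.integer(names(a$ace)),
                 estimate = unname(a$ace), var = unname(a$var))
}

#' Relative brain size at internal nodes
#'
#' Reconstructs (log10) brain and body mass independently at every
#' internal node under Brownian motion, then expresses each node's brain
#' estimate as a residual from the tip-level PGLS allometry of brain on
#' body: `residual = anc_brain - (a + b * anc_body)`.
#'
#' @inheritParams fit_pgls
#' @param brain,body names of the log10 brain- and body-mass columns.
#' @return a tibble with `node`, `brain`, `body` (reconstructed states)
#'   and `relative` (node residual); the tip-level fit is attached as
#'   attribute `"fit"`.
#' @export
ancestral_relative_brain_size <- function(data, tree, brain = "log_brain",
                                          body = "log_body",
                                          species = "species") {
  md <- match_tree_data(data, tree, species, c(brain, body))
  fit <- fit_pgls(md$data, stats::as.formula(paste(brain, "~", body)),
                  md$tree, species = species)
  anc_brain <- ancestral_states_bm(md$data, brain, md$tree, species = species)
  anc_body <- ancestral_states_bm(md$data, body, md$tree, species = species)
  cf <- fit$coefficients
  out <- tibble::tibble(
    node = anc_brain$node,
    brain = anc_brain$estimate,
    body = anc_body$estimate,
    relative = anc_brain$estimate - (cf[1] + cf[2] * anc_body$estimate)
  )
  attr(out, "fit") <- fit
  out
}
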