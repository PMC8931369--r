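# Phylogenetic covariance and regime-weight matrices. All matrices are
# tip-by-tip in the tree's tip order.

#' Brownian-motion covariance of a phylogeny
#'
#' `V[i, j]` is the height of the most recent common ancestor of tips i and
#' j (the shared root-to-tip path length); the diagonal holds tip depths.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return an n x n symmetric matrix, units of branch length (My).
#' @export
bm_covariance <- function(tree) {
  if (ape::Ntip(tree) == 1L) {
    v <- matrix(sum(tree$edge.length), 1, 1,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(v)
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` is pure Brownian structure, `lambda = 0`
#' phylogenetic independence.
#'
#' @param v symmetric covariance matrix.
#' @param lambda scalar in \[0, 1\].
#' @return the transformed covariance.
#' @export
lambda_transform <- function(v, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single value in [0, 1]")
  }
  d <- diag(v)
  out <- v * lambda
  diag(out) <- d
  out
}

#' Ornstein-Uhlenbeck covariance on an ultrametric tree (fixed root)
#'
#' Under a single OU process with attraction `alpha` and diffusion
#' `sigma_sq` started at the root state (no stationarity assumed at the
#' root), tips i, j whose MRCA sits at height `t_a` on a tree of depth `T`
#' covary as `sigma_sq / (2 alpha) * exp(-2 alpha (T - t_a)) *
#' (1 - exp(-2 alpha t_a))`. With `stationary_root = TRUE` the root state
#' is drawn from the stationary distribution and the covariance becomes
#' `sigma_sq / (2 alpha) * exp(-2 alpha (T - t_a))`.
#'
#' @param tree an ultrametric `phylo` object.
#' @param alpha attraction strength (1/My), > 0. For `alpha = 0` use
#'   [bm_covariance()], the analytic limit.
#' @param sigma_sq diffusion variance (trait^2/My), > 0.
#' @param stationary_root draw the root from the stationary distribution?
#' @return an n x n covariance matrix in trait^2 units.
#' @export
ou_covariance <- function(tree, alpha, sigma_sq, stationary_root = FALSE) {
  if (!isTRUE(attr(as_phylogeny(tree), "ultrametric"))) {
    stop("OU covariance closed form requires an ultrametric (time-calibrated) tree")
  }
  if (alpha <= 0) stop("`alpha` must be > 0; use bm_covariance() for the alpha -> 0 limit")
  if (sigma_sq <= 0) stop("`sigma_sq` must be > 0")
  ta <- bm_covariance(tree)           # MRCA heights
  total_depth <- max(diag(ta))
  core <- exp(-2 * alpha * (total_depth - ta))
  if (!stationary_root) core <- core * (1 - exp(-2 * alpha * ta))
  sigma_sq / (2 * alpha) * core
}

#' OU regime weight matrix
#'
#' Row i gives the contribution of each regime's optimum to the expected
#' value at tip i: summing `exp(-alpha (T_i - t_end)) - exp(-alpha (T_i -
#' t_start))` over the segments of tip i's root-to-tip path painted with
#' regime k, with the residual root weight `exp(-alpha T_i)` assigned to
#' the root (ancestral) regime. Rows sum to one.
#'
#' @param tree a `phylo` object.
#' @param painting a [regime_painting()].
#' @param alpha attraction strength (1/My), > 0.
#' @return an n x K matrix, rows named by tip label.
#' @export
ou_weight_matrix <- function(tree, painting, alpha) {
  stopifnot(inherits(painting, "regime_painting"))
  if (alpha <= 0) stop("`alpha` must be > 0")
  segs <- tip_path_segments(tree)
  miss <- setdiff(segs$branch, as.integer(names(painting$regime)))
  if (length(miss)) stop("painting does not cover branches: ", paste(miss, collapse = ", "))
  n <- ape::Ntip(tree)
  depth <- node_heights(tree)[seq_len(n)]
  w <- matrix(0, n, painting$k, dimnames = list(tree$tip.label, NULL))
  reg <- painting$regime[as.character(segs$branch)]
  ti <- depth[segs$tip_id]
  contrib <- exp(-alpha * (ti - segs$t_end)) - exp(-alpha * (ti - segs$t_start))
  for (i in seq_len(nrow(segs))) {
    w[segs$tip_id[i], reg[i]] <- w[segs$tip_id[i], reg[i]] + contrib[i]
  }
  w[, 1L] <- w[, 1L] + exp(-alpha * depth)
  w
}
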