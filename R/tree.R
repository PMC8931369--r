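# Tree handling. Trees are ape "phylo" objects throughout; branches are
# identified by the node at their tipward (child) end, using ape's node
# numbering (tips 1..n, root n+1, internal nodes above).

#' Read and validate a time-calibrated phylogeny
#'
#' Parses a Newick string or file into an [ape::read.tree()] `phylo` object
#' and enforces the contracts the downstream models rely on: branch lengths
#' present and non-negative, unique tip labels, a rooted topology.
#' Polytomies are resolved deterministically into zero-length bifurcations
#' (input order preserved) so that a binary tree with `n` tips always has
#' `2n - 2` branches. An ultrametricity flag (all tips equidistant from the
#' root within `tol`) is stored as attribute `"ultrametric"`.
#'
#' @param source a Newick string (contains "(") or a path to a Newick file.
#' @param tol relative tolerance for the ultrametricity check.
#' @return a `phylo` object with attribute `ultrametric` (logical).
#' @export
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' attr(tr, "ultrametric")
read_phylogeny <- function(source, tol = 1e-8) {
  if (length(source) != 1L || !is.character(source)) {
    stop("`source` must be a single Newick string or file path")
  }
  txt <- if (grepl("\\(", source)) source else paste(readLines(source), collapse = "")
  txt <- trimws(txt)
  if (!grepl(";\\s*$", txt)) txt <- paste0(txt, ";")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close) {
    stop("malformed Newick: ", n_open, " '(' vs ", n_close, "' )'")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse failure: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: unreadable tree string")
  as_phylogeny(tree, tol = tol)
}

#' Coerce and validate a phylo object for use in allometric models
#'
#' @param tree a `phylo` object.
#' @inheritParams read_phylogeny
#' @return the validated `phylo` with attribute `ultrametric`.
#' @export
as_phylogeny <- function(tree, tol = 1e-8) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  tree$tip.label <- normalize_labels(tree$tip.label)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (ape::Ntip(tree) == 1L) {
    warning("degenerate single-tip tree")
  } else {
    if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
      # deterministic resolution of polytomies (incl. a basal one) into
      # zero-length bifurcations
      tree <- ape::multi2di(tree, random = FALSE)
      tree$edge.length[is.na(tree$edge.length)] <- 0
    }
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
  }
  h <- node_heights(tree)
  tip_h <- h[seq_len(ape::Ntip(tree))]
  attr(tree, "ultrametric") <- diff(range(tip_h)) <= tol * max(max(tip_h), 1)
  tree
}

normalize_labels <- function(x) gsub("\\s+", "_", trimws(x))

#' Write a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
write_phylogeny <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node heights measured from the root
#'
#' @param tree a `phylo` object.
#' @return numeric vector over all nodes (tips first), My from the root.
#' @export
node_heights <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  h <- numeric(nn)
  root <- n + 1L
  # preorder so parents are visited before children
  ord <- if (n == 1L) seq_len(nrow(tree$edge)) else order(tree$edge[, 1])
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {
    h[po$edge[i, 2]] <- h[po$edge[i, 1]] + po$edge.length[i]
  }
  h
}

#' Branch table of a phylogeny
#'
#' One row per branch (edge), keyed by the child node. `t_start`/`t_end`
#' are heights from the root of the branch's rootward and tipward ends.
#'
#' @param tree a `phylo` object.
#' @return a tibble with columns `branch`, `parent`, `length`, `t_start`,
#'   `t_end`, `is_tip`, `label`.
#' @export
branch_table <- function(tree) {
  h <- node_heights(tree)
  n <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  tibble::tibble(
    branch = child,
    parent = tree$edge[, 1],
    length = tree$edge.length,
    t_start = h[tree$edge[, 1]],
    t_end = h[child],
    is_tip = child <= n,
    label = ifelse(child <= n, tree$tip.label[pmin(child, n)],
                   paste0("node_", child))
  )
}

#' Tips descending from a branch
#'
#' @param tree a `phylo` object.
#' @param branch branch id (child-node number).
#' @return character vector of tip labels in the clade subtended by `branch`.
#' @export
clade_tips <- function(tree, branch) {
  n <- ape::Ntip(tree)
  branch <- as.integer(branch)
  if (length(branch) != 1L || !(branch %in% tree$edge[, 2] || branch == n + 1L)) {
    stop("unknown branch id: ", branch)
  }
  if (branch <= n) return(tree$tip.label[branch])
  tips <- phangorn::Descendants(tree, branch, type = "tips")[[1]]
  tree$tip.label[tips]
}

#' Paint tree branches into scaling regimes from a set of shift points
#'
#' A shift sits at the rootward end of its branch and starts a new regime
#' inherited by all descendant branches until overridden by a nested shift.
#' The root segment carries regime 1 (the ancestral regime), so `K`
#' regimes = number of shifts + 1. Regime numbering follows the order of
#' `shifts`.
#'
#' @param tree a `phylo` object.
#' @param shifts integer vector of branch ids (child-node numbers) carrying
#'   shifts; at most one shift per branch.
#' @return a `regime_painting`: list with `shifts`, `regime` (named integer
#'   vector over branch ids), and `k` (regime count).
#' @export
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' p <- regime_painting(tr, shifts = 5L)  # shift on the (A,B) stem
#' p$k
regime_painting <- function(tree, shifts = integer(0)) {
  shifts <- as.integer(shifts)
  if (anyDuplicated(shifts)) stop("at most one shift per branch")
  if (length(shifts) && !all(shifts %in% tree$edge[, 2])) {
    stop("shift on unknown branch: ",
         paste(setdiff(shifts, tree$edge[, 2]), collapse = ", "))
  }
  child <- tree$edge[, 2]
  regime <- integer(nrow(tree$edge))
  names(regime) <- child
  # preorder traversal: parent regime known before child
  ord <- order(match(tree$edge[, 1], c(ape::Ntip(tree) + 1L, child)))
  parent_regime <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_regime[ape::Ntip(tree) + 1L] <- 1L
  for (i in ord) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    r <- if (ch %in% shifts) 1L + match(ch, shifts) else parent_regime[p]
    regime[as.character(ch)] <- r
    parent_regime[ch] <- r
  }
  structure(list(shifts = shifts, regime = regime, k = length(shifts) + 1L),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", x$k, "regime(s),",
      length(x$shifts), "shift(s)\n")
  if (length(x$shifts)) cat("  shifts on branches:", paste(x$shifts, collapse = ", "), "\n")
  invisible(x)
}

#' Root-to-tip path segments of every tip
#'
#' Used by the OU regime weight matrix: each row is one branch traversed on
#' the way from the root to a tip, with its start and end heights.
#'
#' @param tree a `phylo` object.
#' @return tibble with columns `tip` (label), `tip_id`, `branch`,
#'   `t_start`, `t_end`.
#' @export
tip_path_segments <- function(tree) {
  bt <- branch_table(tree)
  n <- ape::Ntip(tree)
  parent_of <- stats::setNames(bt$parent, bt$branch)
  root <- n + 1L
  rows <- purrr::map(seq_len(n), function(i) {
    path <- integer(0)
    node <- i
    while (node != root) {
      path <- c(path, node)
      node <- parent_of[[as.character(node)]]
    }
    tibble::tibble(tip = tree$tip.label[i], tip_id = i, branch = path)
  })
  dplyr::left_join(dplyr::bind_rows(rows),
                   dplyr::select(bt, "branch", "t_start", "t_end"),
                   by = "branch")
}
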