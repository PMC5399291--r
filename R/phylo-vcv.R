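#' Brownian-motion variance-covariance matrix of a tree
#'
#' Under Brownian-motion trait evolution, the variance of a tip is its
#' root-to-tip branch length and the covariance of two tips is the depth of
#' their most recent common ancestor. Computed here from the edge matrix
#' directly (depth accumulation plus deepest-common-ancestor lookups), so it
#' can be cross-checked against independent implementations.
#'
#' @param tree a rooted `phylo` with branch lengths
#' @return an M x M matrix with tip labels as dimnames
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' vcv_from_tree(tr)   # [[2,1,0],[1,2,0],[0,0,2]]
vcv_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  M0 <- length(tree$tip.label)
  # a pure star (every edge from the root) is a legitimate rooted shape even
  # though ape classes basal polytomies as unrooted
  is_star <- sum(tree$edge[, 1L] == M0 + 1L) == M0 && nrow(tree$edge) == M0
  if (!ape::is.rooted(tree) && !is_star) abort("tree must be rooted")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  M <- length(tree$tip.label)
  root <- M + 1L
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  blen <- numeric(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  depth <- numeric(nnode)
  # cladewise order guarantees each parent is visited before its children
  ctree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ctree$edge))) {
    ch <- ctree$edge[e, 2L]
    depth[ch] <- depth[ctree$edge[e, 1L]] + ctree$edge.length[e]
  }
  # ancestor paths per tip (root first)
  paths <- lapply(seq_len(M), function(tip) {
    path <- tip
    v <- tip
    while (v != root) {
      v <- parent[v]
      path <- c(v, path)
    }
    path
  })
  V <- matrix(0, M, M, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(M)) {
    V[a, a] <- depth[a]
    if (a < M) for (b in seq((a + 1L), M)) {
      pa <- paths[[a]]; pb <- paths[[b]]
      nshared <- min(length(pa), length(pb))
      k <- match(FALSE, pa[seq_len(nshared)] == pb[seq_len(nshared)],
                 nomatch = nshared + 1L)
      mrca <- pa[k - 1L]
      V[a, b] <- V[b, a] <- depth[mrca]
    }
  }
  V
}

#' Scale a Brownian VCV to unit height and invert it
#'
#' Divides the matrix by the tree height so the diagonal is 1 (the matrix
#' becomes a correlation-like structure and the regression's \eqn{\sigma^2}
#' is interpretable as residual variance), then inverts via Cholesky.
#'
#' @param vcv a symmetric positive-definite Brownian VCV
#' @param warn_condition warn when the scaled matrix's reciprocal condition
#'   number falls below this (near-duplicate tips)
#' @return a list: `scaled` (unit-diagonal matrix), `inverse`, `height`
#' @export
scale_and_invert <- function(vcv, warn_condition = 1e-10) {
  stopifnot(is.matrix(vcv), nrow(vcv) == ncol(vcv))
  if (max(abs(vcv - t(vcv))) > 1e-8) abort("matrix is not symmetric")
  height <- max(diag(vcv))
  if (height <= 0) abort("matrix has nonpositive diagonal")
  scaled <- vcv / height
  rc <- rcond(scaled)
  if (rc < warn_condition) {
    warn(sprintf("scaled VCV is near-singular (rcond %.2e): tips nearly coincide", rc))
  }
  ch <- tryCatch(chol(scaled), error = function(e) {
    abort(paste0("scaled VCV is not positive definite: ", conditionMessage(e)))
  })
  list(scaled = scaled, inverse = chol2inv(ch), height = height)
}

#' Build the inverse-VCV array for a tree set
#'
#' Converts every tree in a set to its Brownian VCV, scales each to unit
#' height and inverts it, giving the M x M x R array of precision-structure
#' slices the comparative regression mixes over. Tip order follows `taxa`.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) sharing one tip set
#' @param taxa character vector fixing the row/column order (default: tip
#'   order of the first tree)
#' @return an object of class `vcv_array`: list with `omega` (inverses),
#'   `scaled` (scaled VCVs), `heights`, `taxa`
#' @export
build_vcv_array <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  taxa <- taxa %||% trees[[1]]$tip.label
  M <- length(taxa)
  Rq <- length(trees)
  omega <- array(NA_real_, c(M, M, Rq), dimnames = list(taxa, taxa, NULL))
  scaled <- array(NA_real_, c(M, M, Rq), dimnames = list(taxa, taxa, NULL))
  heights <- numeric(Rq)
  for (q in seq_len(Rq)) {
    tr <- trees[[q]]
    if (!setequal(tr$tip.label, taxa)) {
      abort(sprintf("tree %d tip set does not match the taxon set", q))
    }
    V <- vcv_from_tree(tr)[taxa, taxa]
    si <- scale_and_invert(V)
    omega[, , q] <- si$inverse
    scaled[, , q] <- si$scaled
    heights[q] <- si$height
  }
  structure(list(omega = omega, scaled = scaled, heights = heights, taxa = taxa),
            class = "vcv_array")
}

#' @export
print.vcv_array <- function(x, ...) {
  cat(sprintf("<vcv_array> %d taxa x %d trees (scaled to unit height)\n",
              length(x$taxa), dim(x$omega)[3]))
  invisible(x)
}

#' Read or write a multi-tree Newick file
#'
#' One Newick string per line. On reading, tip sets must agree across
#' trees; ultrametricity is checked and deviations beyond `tol` produce a
#' warning by default (tree sets from posterior samples are often only
#' near-ultrametric) or an error with `ultrametric = "error"`.
#'
#' @param path file path
#' @param ultrametric `"warn"` (default), `"error"`, or `"ignore"`
#' @param tol relative tolerance on root-to-tip height spread
#' @return `read_trees()` returns a `multiPhylo`
#' @export
read_trees <- function(path, ultrametric = c("warn", "error", "ignore"), tol = 1e-6) {
  ultrametric <- match.arg(ultrametric)
  trees <- ape::read.tree(path)
  if (is.null(trees)) abort(sprintf("could not parse any Newick tree from %s", path))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  tips1 <- sort(trees[[1]]$tip.label)
  for (q in seq_along(trees)) {
    if (!identical(sort(trees[[q]]$tip.label), tips1)) {
      abort(sprintf("tree %d has a different tip set than tree 1", q))
    }
  }
  if (ultrametric != "ignore") {
    dev <- vapply(trees, function(tr) {
      d <- diag(vcv_from_tree(tr))
      (max(d) - min(d)) / max(d)
    }, numeric(1))
    if (any(dev > tol)) {
      msg <- sprintf("%d tree(s) deviate from ultrametricity by up to %.2e",
                     sum(dev > tol), max(dev))
      if (ultrametric == "error") abort(msg) else warn(msg)
    }
  }
  trees
}

#' @param trees a `multiPhylo` or list of `phylo`
#' @rdname read_trees
#' @return `write_trees()` returns `path` invisibly
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path)
  invisible(path)
}
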