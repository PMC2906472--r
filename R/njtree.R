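#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion.  Deterministic:
#' ties in Q are broken by the smallest (row, column) index pair of the
#' current matrix.  On an additive matrix the generating topology and exact
#' branch lengths are recovered.  Negative branch lengths are retained (and
#' flagged with a warning) unless `clamp_negative = TRUE`, in which case a
#' negative edge is set to zero and its length transferred to the sister
#' edge so leaf-to-leaf path lengths are preserved where possible.
#'
#' @param D an `srcr_dist`, `dist`, or square symmetric numeric matrix with
#'   >= 3 labelled rows and no missing cells.
#' @param clamp_negative zero out negative branch lengths (with
#'   compensation on the sister edge)?
#' @return An unrooted [ape] `phylo` with a trifurcating root.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  if (inherits(D, "srcr_dist")) D <- D$values
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("need >= 3 taxa for neighbor joining")
  if (any(is.na(D)))
    stop("distance matrix has missing cells; impute or prune before NJ")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))

  fmt <- function(x) sprintf("%.12g", x)
  # build newick over placeholder leaf names (labels may hold characters
  # that are special in newick, e.g. the apostrophe in d'), restore after
  node <- paste0("L", seq_along(labels))
  act <- D
  n <- nrow(act)
  while (n > 3L) {
    R <- rowSums(act)
    Q <- (n - 2) * act - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- act[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- dij - li
    new_lab <- paste0("(", node[i], ":", fmt(li), ",",
                      node[j], ":", fmt(lj), ")")
    dnew <- (act[i, ] + act[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    node <- c(node[keep], new_lab)
    n <- n - 1L
  }
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  nwk <- paste0("(", node[1], ":", fmt(b1), ",", node[2], ":", fmt(b2),
                ",", node[3], ":", fmt(b3), ");")
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^L", "", tree$tip.label))]
  if (any(tree$edge.length < 0)) {
    if (clamp_negative) {
      tree <- clamp_negative_edges(tree)
    } else {
      warning(sum(tree$edge.length < 0),
              " negative branch length(s) retained")
    }
  }
  tree
}

# zero a negative edge and add its (negative) length to the sister edge,
# preserving root-to-tip path length through the parent
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    tree$edge.length[sisters] <- tree$edge.length[sisters] +
      tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (all(tree$edge.length[sisters] < 0) && length(sisters) == 0) break
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the point-estimate NJ tree from the full alignment, then `B`
#' column-resampled replicates; the support of an internal edge is the
#' fraction of replicate trees containing the same bipartition, stored in
#' `node.label`.  Internal edges of (numerically) zero length in the point
#' tree are collapsed first, so uninformative resolutions (e.g. identical
#' sequences) carry no supported bipartitions.
#'
#' @param alignment a [new_alignment()].
#' @param model_tag distance model (see [correct_distance()]).
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed for the resampling stream.
#' @param collapse_zero collapse zero-length internal edges of the point
#'   tree before computing supports?
#' @return A `phylo` with `node.label` holding supports in `[0, 1]`
#'   (`NA` at the root).
#' @export
bootstrap_tree <- function(alignment, model_tag = "p", B = 100L, seed,
                           collapse_zero = TRUE) {
  stopifnot(B >= 100L)
  if (missing(seed)) stop("bootstrap_tree requires an explicit seed")
  main <- neighbor_joining(distance_matrix(alignment, model_tag))
  if (collapse_zero) main <- ape::di2multi(main, tol = 1e-10)
  m <- alignment_matrix(alignment)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- new_alignment(alignment$labels,
                             apply(m[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""))
    # replicate trees routinely carry small negative edges; the flag is
    # only informative on the point estimate
    boots[[b]] <- suppressWarnings(
      neighbor_joining(distance_matrix(rep_aln, model_tag)))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / B
  support[1] <- NA_real_          # root of the unrooted representation
  main$node.label <- support
  main
}

#' Newick input/output
#'
#' Thin wrappers over [ape::read.tree()]/[ape::write.tree()] adding the
#' checks this package relies on: unique leaf labels, a parse error on
#' malformed input, and supports serialized as internal node labels.
#'
#' @param path file path.
#' @return `read_newick`: a `phylo` (numeric `node.label` when supports are
#'   present).
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick (", n_open, " '(' vs ",
         n_close, " ')')")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) stop("newick parse error in '", path, "'")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate leaf label(s): ",
                        paste(unique(dup), collapse = ", "))
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    sup <- suppressWarnings(as.numeric(lab))
    # numeric labels are supports; keep character labels as-is
    if (!any(is.na(sup) & nzchar(lab))) tree$node.label <- sup
  }
  tree
}

#' @rdname read_newick
#' @param tree a `phylo`.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              sprintf("%.6g", tree$node.label))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(NULL)
}

#' Leaf sets of the supported bipartitions of a tree
#'
#' For every internal edge with support at or above `threshold`, both sides
#' of its bipartition are returned as candidate clades (on an unrooted tree
#' either side may be the biologically meaningful group).  Trees without
#' node labels are treated as fully supported with `NA` recorded support.
#'
#' @param tree a `phylo`, optionally with supports in `node.label`.
#' @param threshold minimum support in `[0, 1]`.
#' @return A list of entries with `leaves` (character) and `support`.
#' @export
supported_sides <- function(tree, threshold = 0.70) {
  n_tip <- length(tree$tip.label)
  if (!is.null(tree$node.label) && is.character(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    if (!any(is.na(sup) & nzchar(tree$node.label))) tree$node.label <- sup
  }
  has_sup <- !is.null(tree$node.label) && is.numeric(tree$node.label)
  sides <- list()
  internal <- which(tree$edge[, 2] > n_tip)
  for (e in internal) {
    child <- tree$edge[e, 2]
    sup <- if (has_sup) tree$node.label[child - n_tip] else NA_real_
    if (has_sup && (is.na(sup) || sup < threshold)) next
    below <- ape::extract.clade(tree, child)$tip.label
    if (length(below) < 2L || length(below) > n_tip - 2L) next
    sides[[length(sides) + 1L]] <- list(leaves = below, support = sup)
    sides[[length(sides) + 1L]] <-
      list(leaves = setdiff(tree$tip.label, below), support = sup)
  }
  sides
}
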