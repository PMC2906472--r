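# Independent oracles used by the property tests.  These deliberately take
# the slow, obviously-correct route (exhaustive enumeration, least squares,
# closed forms) and never share code with the implementation they check.

# --- exhaustive affine-gap global alignment ------------------------------
# Enumerates every monotone alignment path of a vs b and scores it with
# gap cost gap_open + k * gap_ext per maximal gap run; terminal gaps are
# penalized.  Exponential: keep inputs tiny.
enumerate_align_score <- function(a, b, m, gap_open, gap_ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + m[ca[i], cb[j]], "m")
    if (i <= length(ca))
      rec(i + 1, j, score - gap_ext - if (state != "x") gap_open else 0, "x")
    if (j <= length(cb))
      rec(i, j + 1, score - gap_ext - if (state != "y") gap_open else 0, "y")
  }
  rec(1, 1, 0, "m")
  best
}

# --- brute-force motif tetramers -----------------------------------------
# All 2 * 3 * 2 = 12 tetramers matching Y-(Q/E)-(D/C/E)-(I/L).
wc1_tetramers <- function() {
  out <- character()
  for (p2 in c("Q", "E")) for (p3 in c("D", "C", "E")) for (p4 in c("I", "L"))
    out <- c(out, paste0("Y", p2, p3, p4))
  out
}

# brute-force scan: positions where any of the 12 tetramers occurs
brute_wc1_positions <- function(seq) {
  tets <- wc1_tetramers()
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 4) return(integer())
  found <- integer()
  for (i in seq_len(n - 3))
    if (paste(chars[i:(i + 3)], collapse = "") %in% tets)
      found <- c(found, i)
  found
}

# --- exhaustive topology search for small NJ problems --------------------
# Every unrooted binary topology over the given labels (phangorn's
# enumeration, independent of this package's tree construction).
all_unrooted_topologies <- function(labels) {
  stopifnot(length(labels) >= 4, length(labels) <= 6)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  # [[ expands the multiPhylo's compressed tip labels per tree
  lapply(seq_along(trees), function(i) trees[[i]])
}

# least-squares branch-length fit of a distance matrix on a topology;
# returns the residual sum of squares
ls_fit_ss <- function(tree, D) {
  labs <- rownames(D)
  n <- length(labs)
  pairs <- t(combn(n, 2))
  ne <- nrow(tree$edge)
  X <- matrix(0, nrow(pairs), ne)
  y <- numeric(nrow(pairs))
  tree$edge.length <- rep(1, ne)
  for (r in seq_len(nrow(pairs))) {
    path_edges <- edges_on_path(tree, labs[pairs[r, 1]], labs[pairs[r, 2]])
    X[r, path_edges] <- 1
    y[r] <- D[pairs[r, 1], pairs[r, 2]]
  }
  fit <- qr.solve(crossprod(X) + diag(1e-10, ne), crossprod(X, y))
  sum((X %*% fit - y)^2)
}

edges_on_path <- function(tree, from, to) {
  n_tip <- length(tree$tip.label)
  i <- which(tree$tip.label == from)
  j <- which(tree$tip.label == to)
  anc <- function(node) {
    path <- node
    while (TRUE) {
      up <- tree$edge[tree$edge[, 2] == node, 1]
      if (!length(up)) break
      path <- c(path, up); node <- up
    }
    path
  }
  ai <- anc(i); aj <- anc(j)
  common <- intersect(ai, aj)[1]
  nodes <- c(ai[seq_len(which(ai == common) - 1)],
             aj[seq_len(which(aj == common) - 1)])
  which(tree$edge[, 2] %in% nodes)
}

# --- misc -----------------------------------------------------------------
random_aa_string <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
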