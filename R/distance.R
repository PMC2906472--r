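#' Proportion of differing sites between two aligned rows
#'
#' The p-distance: differing columns divided by the number of columns where
#' neither row carries a gap or an unknown residue (`X`).  With
#' `deletion_mode = "complete"` the caller is expected to have removed
#' gapped columns alignment-wide already (see [distance_matrix()]); the
#' per-pair computation is the same.
#'
#' @param row_a,row_b equal-length aligned strings.
#' @param deletion_mode `"pairwise"` (default) or `"complete"`.
#' @return A list: `p` (NA when no comparable columns) and `L_effective`
#'   (the denominator).
#' @export
p_distance <- function(row_a, row_b, deletion_mode = c("pairwise",
                                                       "complete")) {
  deletion_mode <- match.arg(deletion_mode)
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows must have equal length")
  usable <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  L <- sum(usable)
  if (L == 0L) return(list(p = NA_real_, L_effective = 0L))
  list(p = sum(a[usable] != b[usable]) / L, L_effective = L)
}

#' Closed-form standard error of a p-distance
#'
#' Binomial sampling error `sqrt(p (1 - p) / L)`, the large-B limit of the
#' column-resampling bootstrap.
#'
#' @param p proportion of differing sites in `[0, 1]`.
#' @param L number of compared columns (>= 1).
#' @return The standard error.
#' @export
analytic_se <- function(p, L) {
  stopifnot(all(p >= 0 & p <= 1), all(L >= 1))
  sqrt(p * (1 - p) / L)
}

#' Bootstrap standard error of a pairwise distance
#'
#' Resamples alignment columns with replacement `B` times and returns the
#' standard deviation of the resampled distances.  Deterministic given
#' `seed`; converges to [analytic_se()] for the p model as `B` grows.
#'
#' @inheritParams p_distance
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed (required: the replicate stream must be
#'   reproducible).
#' @param model_tag distance model applied to each replicate (see
#'   [correct_distance()]).
#' @return The bootstrap standard error.
#' @export
bootstrap_se <- function(row_a, row_b, B = 1000L, seed,
                         model_tag = "p") {
  stopifnot(B >= 100L)
  if (missing(seed)) stop("bootstrap_se requires an explicit seed")
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows must have equal length")
  usable <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
  diffs <- (a != b)[usable]
  L <- length(diffs)
  if (L == 0L) stop("no comparable columns: distance undefined")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  reps <- vapply(seq_len(B), function(i) {
    d <- diffs[sample.int(L, L, replace = TRUE)]
    correct_distance(mean(d), model_tag)
  }, numeric(1))
  sd(reps)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Correct an observed p-distance for multiple substitutions
#'
#' `"p"` returns the input unchanged; `"poisson"` applies `-log(1 - p)`;
#' `"jtt_like"` finds the evolutionary time `d` at which the JTT rate matrix
#' (see [load_matrix()]) yields expected proportion of differing sites `p`,
#' by inverting the monotone map `p(d) = 1 - sum_i pi_i [exp(Qd)]_ii`.
#' Distances at or beyond a model's saturation point are returned as `Inf`
#' with a warning.
#'
#' @param p observed proportion(s) of differing sites.
#' @param model_tag `"p"`, `"poisson"` or `"jtt_like"`.
#' @return Corrected distance(s), substitutions per site.
#' @export
correct_distance <- function(p, model_tag = c("p", "poisson", "jtt_like")) {
  model_tag <- match.arg(model_tag)
  stopifnot(all(p >= 0 & p <= 1))
  if (model_tag == "p") return(p)
  if (model_tag == "poisson") {
    out <- ifelse(p < 1, -log(1 - p), Inf)
    if (any(!is.finite(out))) warning("p-distance at Poisson saturation")
    return(out)
  }
  # jtt_like: p(d) is monotone in d and saturates at 1 - sum(pi^2) ~ 0.94
  sat <- 1 - sum(jtt_generator()$pi^2)
  vapply(p, function(pi1) {
    if (pi1 == 0) return(0)
    if (pi1 >= sat - 1e-9) {
      warning("p-distance at/above JTT saturation (", signif(sat, 4), ")")
      return(Inf)
    }
    uniroot(function(d) jtt_expected_p(d) - pi1,
            lower = 0, upper = 500, tol = 1e-10)$root
  }, numeric(1))
}

#' Pairwise distance matrix over alignment rows
#'
#' Fills all pairs with the chosen distance model; when `B > 0` a parallel
#' matrix of bootstrap standard errors is computed (one independent seeded
#' replicate stream per pair).  Undefined distances (no comparable columns)
#' are reported as `NA`, never as 0.
#'
#' @param alignment a [new_alignment()] with >= 2 rows.
#' @param model_tag see [correct_distance()].
#' @param deletion_mode `"pairwise"` (default) keeps each pair's own
#'   comparable columns; `"complete"` first drops every column containing a
#'   gap or `X` in any row.
#' @param B bootstrap replicates for standard errors; 0 skips them.
#' @param seed integer seed, required when `B > 0`.
#' @return An object of class `srcr_dist`: list with `labels`, `values`,
#'   `se` (or NULL), `L_effective`, `model_tag`.
#' @export
distance_matrix <- function(alignment, model_tag = "p",
                            deletion_mode = c("pairwise", "complete"),
                            B = 0L, seed = NULL) {
  deletion_mode <- match.arg(deletion_mode)
  if (length(alignment$labels) < 2L) stop("need >= 2 rows")
  if (B > 0L && is.null(seed)) stop("seed is required when B > 0")
  m <- alignment_matrix(alignment)
  if (deletion_mode == "complete") {
    keep <- colSums(m == "-" | m == "X") == 0L
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  labels <- alignment$labels
  vals <- matrix(0, n, n, dimnames = list(labels, labels))
  Leff <- matrix(ncol(m), n, n, dimnames = list(labels, labels))
  ses <- if (B > 0L) vals else NULL
  rows <- apply(m, 1L, paste, collapse = "")
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    pd <- p_distance(rows[i], rows[j])
    Leff[i, j] <- Leff[j, i] <- pd$L_effective
    v <- if (is.na(pd$p)) NA_real_ else correct_distance(pd$p, model_tag)
    vals[i, j] <- vals[j, i] <- v
    if (B > 0L) {
      s <- if (is.na(pd$p)) NA_real_ else
        bootstrap_se(rows[i], rows[j], B = B,
                     seed = pair_seed(seed, i, j), model_tag = model_tag)
      ses[i, j] <- ses[j, i] <- s
    }
  }
  structure(list(labels = labels, values = vals, se = ses,
                 L_effective = Leff, model_tag = model_tag),
            class = "srcr_dist")
}

# deterministic per-pair sub-seed, kept within 32-bit integer range
pair_seed <- function(seed, i, j) {
  as.integer((as.numeric(seed) * 2654435761 + i * 40503 + j) %% 2147483647)
}

#' @export
print.srcr_dist <- function(x, ...) {
  cat(sprintf("<srcr_dist> %d labels, model '%s'%s\n", length(x$labels),
              x$model_tag, if (is.null(x$se)) "" else ", with SEs"))
  invisible(x)
}

#' Extract a rectangular block of a distance matrix
#'
#' Reproduces the row-protein x column-protein layout used in published
#' divergence tables: rows are one protein's domains, columns another's.
#'
#' @param d an `srcr_dist`.
#' @param row_labels,col_labels label subsets.
#' @return A list with `values` and `se` (NULL when absent) sub-matrices.
#' @export
dist_block <- function(d, row_labels, col_labels) {
  stopifnot(all(row_labels %in% d$labels), all(col_labels %in% d$labels))
  list(values = d$values[row_labels, col_labels, drop = FALSE],
       se = if (is.null(d$se)) NULL
       else d$se[row_labels, col_labels, drop = FALSE])
}

#' Render a distance block in the value-(se) table layout
#'
#' Prints each distance to three decimals with its standard error in
#' parentheses beneath, mirroring the layout of published divergence
#' tables, which makes visual diffing against them trivial.
#'
#' @param block a [dist_block()] result (SEs required).
#' @return A character vector of lines, invisibly printed with `cat` when
#'   `print = TRUE`.
#' @param print print the lines to the console?
#' @export
render_distance_table <- function(block, print = FALSE) {
  v <- block$values
  stopifnot(!is.null(block$se))
  s <- block$se
  lines <- c(paste(c("", colnames(v)), collapse = "\t"))
  for (i in seq_len(nrow(v))) {
    lines <- c(lines,
               paste(c(rownames(v)[i], sprintf("%.3f", v[i, ])),
                     collapse = "\t"),
               paste(c("", sprintf("(%.3f)", s[i, ])), collapse = "\t"))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a distance matrix (and optional SEs) as TSV
#'
#' @param d an `srcr_dist`.
#' @param path output file for values; SEs, when present, go to
#'   `<path base>_se.<ext>`.
#' @export
write_distance_matrix <- function(d, path) {
  write.table(cbind(label = d$labels, as.data.frame(d$values)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(d$se)) {
    se_path <- sub("(\\.[^.]+)?$", "_se\\1", path)
    write.table(cbind(label = d$labels, as.data.frame(d$se)), se_path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
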