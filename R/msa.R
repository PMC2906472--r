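#' Alignment parameters
#'
#' Defaults follow common practice for protein family alignment: gap opening
#' 10.0, gap extension 0.10, Gonnet PAM-250 scoring.  A gap of length k costs
#' `gap_open + k * gap_extend`.  Terminal gaps are penalized by default (a
#' deterministic choice; set `penalize_ends = FALSE` for end-free overlap
#' alignment).
#'
#' @param gap_open gap opening penalty (> `gap_extend`).
#' @param gap_extend per-residue gap extension penalty (> 0).
#' @param matrix symmetric 20 x 20 substitution matrix with residue dimnames;
#'   any equivalently scaled matrix is pluggable.
#' @param penalize_ends logical; charge terminal gaps?
#' @return An object of class `align_params`.
#' @export
align_params <- function(gap_open = 10.0, gap_extend = 0.10,
                         matrix = load_matrix("gonnet250"),
                         penalize_ends = TRUE) {
  stopifnot(gap_open > gap_extend, gap_extend > 0,
            is.matrix(matrix), nrow(matrix) == 20L,
            isTRUE(all.equal(matrix, t(matrix))))
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix, penalize_ends = penalize_ends),
            class = "align_params")
}

# substitution matrix extended with an 'X' (and '-') row/column scoring 0,
# so unknown residues are neutral rather than penalized
extend_matrix <- function(m) {
  ext <- matrix(0, 22, 22, dimnames = list(c(rownames(m), "X", "-"),
                                           c(colnames(m), "X", "-")))
  ext[seq_len(20), seq_len(20)] <- m
  ext
}

#' Construct a domain alignment
#'
#' An alignment is an ordered set of equal-length gapped rows.  The class
#' invariant -- removing gaps from any row reproduces the source sequence
#' exactly -- is asserted by every operation that returns one.
#'
#' @param labels row labels (unique).
#' @param seqs aligned strings over residues plus `-`, all the same length.
#' @return An object of class `domain_alignment`.
#' @export
new_alignment <- function(labels, seqs) {
  stopifnot(length(labels) == length(seqs), !anyDuplicated(labels))
  nc <- unique(nchar(seqs))
  if (length(nc) > 1L) stop("ragged alignment: row lengths ",
                            paste(nc, collapse = ", "))
  structure(list(labels = as.character(labels), seqs = as.character(seqs),
                 ncol = if (length(nc)) nc else 0L),
            class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat(sprintf("<domain_alignment> %d rows x %d columns\n",
              length(x$labels), x$ncol))
  invisible(x)
}

#' @rdname new_alignment
#' @param x a `domain_alignment`.
#' @export
alignment_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$labels
  m
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Read/write aligned FASTA
#'
#' @param path file path.
#' @name alignment_io
#' @export
read_alignment <- function(path) {
  recs <- read_fasta_raw(path)
  new_alignment(recs$ids, recs$seqs)
}

# FASTA reader that tolerates '-' (gap) characters, for alignments
read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- parse_fasta_checked(path)
  if (length(set) == 0L) stop("no records in '", path, "'")
  ids <- sub("[[:space:]].*$", "", names(set))
  check_unique_ids(ids)
  list(ids = ids, seqs = toupper(as.character(set)))
}

#' @rdname alignment_io
#' @param aln a `domain_alignment`.
#' @param width line wrap width.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$labels)) {
    writeLines(paste0(">", aln$labels[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(NULL)
}

seq_chars <- function(x) {
  if (inherits(x, "protein_record")) x <- x$sequence
  strsplit(toupper(x), "")[[1]]
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment of two protein sequences.  Percent
#' identity is computed over columns where neither row is a gap.  Tied
#' optima are resolved deterministically (match preferred over a gap in the
#' second sequence, over a gap in the first) so results are identical across
#' platforms.
#'
#' @param a,b sequences (strings or [protein_record()]s), non-empty.
#' @param params an [align_params()] object.
#' @return A list: `alignment` (two-row [new_alignment()]), `score` (matrix
#'   units) and `percent_identity` (0-100).
#' @export
pairwise_global_align <- function(a, b, params = align_params()) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (!length(ca) || !length(cb)) stop("empty sequence")
  m <- extend_matrix(params$matrix)
  S <- m[ca, cb, drop = FALSE]
  res <- .nw_affine_cpp(S, params$gap_open, params$gap_extend,
                        params$penalize_ends)
  ra <- ifelse(res$path_a > 0L, ca[pmax(res$path_a, 1L)], "-")
  rb <- ifelse(res$path_b > 0L, cb[pmax(res$path_b, 1L)], "-")
  la <- if (inherits(a, "protein_record")) a$id else "a"
  lb <- if (inherits(b, "protein_record")) b$id else "b"
  if (la == lb) lb <- paste0(lb, "_2")
  aln <- new_alignment(c(la, lb), c(paste(ra, collapse = ""),
                                    paste(rb, collapse = "")))
  stopifnot(ungap(aln$seqs[1]) == paste(ca, collapse = ""),
            ungap(aln$seqs[2]) == paste(cb, collapse = ""))
  both <- ra != "-" & rb != "-"
  pid <- if (any(both)) 100 * sum(ra[both] == rb[both]) / sum(both) else NA_real_
  list(alignment = aln, score = res$score, percent_identity = pid)
}

# residue frequency profile of an alignment block: 20 x ncol, gap/X weight 0,
# normalized by the number of rows (so gappy columns carry less weight)
profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  nr <- nrow(m)
  prof <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(match(m[, j], AA20), nbins = 20L)
  }, numeric(20))
  prof / nr
}

# pairwise p-distance matrix from all pairwise global alignments
pairwise_pdist <- function(seqs, params) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    pa <- pairwise_global_align(seqs[[i]], seqs[[j]], params)
    rows <- pa$alignment$seqs
    D[i, j] <- D[j, i] <- p_distance(rows[1], rows[2])$p
  }
  D
}

#' UPGMA guide tree for progressive alignment
#'
#' Average-linkage clustering on p-distances from all pairwise global
#' alignments.  Deterministic given the global alignment tie-break.
#'
#' @param seqs named list/vector of sequences (>= 2) or `protein_record`s.
#' @param params an [align_params()].
#' @return An [ape::as.phylo()] ultrametric tree whose leaves are the
#'   sequence names.
#' @export
build_guide_tree <- function(seqs, params = align_params()) {
  seqs <- name_seqs(seqs)
  if (length(seqs) < 2L) stop("need >= 2 sequences for a guide tree")
  D <- pairwise_pdist(seqs, params)
  hc <- hclust(as.dist(D), method = "average")
  ape::as.phylo(hc)
}

name_seqs <- function(seqs) {
  if (inherits(seqs, "protein_record")) seqs <- list(seqs)
  seqs <- as.list(seqs)
  ids <- names(seqs)
  from_rec <- vapply(seqs, function(s)
    if (inherits(s, "protein_record")) s$id else NA_character_, character(1))
  if (is.null(ids)) ids <- from_rec
  ids[is.na(ids) | !nzchar(ids)] <-
    from_rec[is.na(ids) | !nzchar(ids)]
  if (anyNA(ids) || any(!nzchar(ids)))
    ids <- ifelse(is.na(ids) | !nzchar(ids),
                  paste0("seq", seq_along(seqs)), ids)
  check_unique_ids(ids)
  seqs <- lapply(seqs, function(s)
    if (inherits(s, "protein_record")) s$sequence else toupper(as.character(s)))
  names(seqs) <- ids
  seqs
}

#' Progressive multiple alignment
#'
#' Profile-profile merges along a UPGMA guide tree, scoring merged columns by
#' the expected substitution score between the two column profiles
#' (sum-of-pairs under the chosen matrix) with the same affine gap penalties
#' as the pairwise aligner.
#'
#' @inheritParams build_guide_tree
#' @return A [new_alignment()] whose rows ungap to the inputs.
#' @export
progressive_align <- function(seqs, params = align_params()) {
  seqs <- name_seqs(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need >= 2 sequences to align")
  D <- pairwise_pdist(seqs, params)
  hc <- hclust(as.dist(D), method = "average")
  groups <- lapply(seq_len(n), function(i)
    list(labels = names(seqs)[i], rows = seqs[[i]]))
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(idx) if (idx < 0) groups[[-idx]] else merged[[idx]]
    A <- pick(hc$merge[k, 1]); B <- pick(hc$merge[k, 2])
    merged[[k]] <- merge_blocks(A, B, params)
  }
  out <- merged[[length(merged)]]
  # restore input order
  ord <- match(names(seqs), out$labels)
  aln <- new_alignment(out$labels[ord], out$rows[ord])
  stopifnot(identical(vapply(aln$seqs, ungap, character(1), USE.NAMES = FALSE),
                      unname(unlist(seqs))))
  aln
}

merge_blocks <- function(A, B, params) {
  PA <- profile_of(A$rows); PB <- profile_of(B$rows)
  S <- t(PA) %*% params$matrix %*% PB
  res <- .nw_affine_cpp(S, params$gap_open, params$gap_extend,
                        params$penalize_ends)
  gap_expand <- function(rows, path) {
    m <- do.call(rbind, strsplit(rows, ""))
    out <- matrix("-", nrow(m), length(path))
    keep <- path > 0L
    out[, keep] <- m[, path[keep], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  list(labels = c(A$labels, B$labels),
       rows = c(gap_expand(A$rows, res$path_a),
                gap_expand(B$rows, res$path_b)))
}

#' Project an alignment onto a model's core columns
#'
#' Uses reference rows shared between the alignment and the domain model to
#' map each of the model's core columns to one alignment column, then
#' extracts exactly those columns.  Insertions relative to the core are
#' dropped; the result always has `model$core_length` columns, so distances
#' computed on it use a fixed column count.
#'
#' @param alignment a [new_alignment()] containing at least one reference row
#'   known to the model (matched by label).
#' @param model a [build_domain_model()] object.
#' @return A `domain_alignment` with `core_length` columns.
#' @export
trim_to_core <- function(alignment, model) {
  refs <- intersect(alignment$labels, model$ref$labels)
  if (!length(refs)) stop("no reference row present in alignment")
  L <- model$core_length
  col_map <- rep(NA_integer_, L)
  for (r in refs) {
    # ordinal (ungapped position) of the reference residue sitting in each
    # core column of the model's source alignment
    src <- strsplit(model$ref$seqs[model$ref$labels == r], "")[[1]]
    ord_src <- cumsum(src != "-")
    res_ord <- ifelse(src[model$core_columns] != "-",
                      ord_src[model$core_columns], NA_integer_)
    new <- strsplit(alignment$seqs[alignment$labels == r], "")[[1]]
    pos_of_ord <- which(new != "-")
    fill <- which(is.na(col_map) & !is.na(res_ord))
    col_map[fill] <- pos_of_ord[res_ord[fill]]
    if (!anyNA(col_map)) break
  }
  if (anyNA(col_map))
    stop("reference rows do not cover all core columns (",
         sum(is.na(col_map)), " unmapped)")
  m <- alignment_matrix(alignment)[, col_map, drop = FALSE]
  new_alignment(alignment$labels, apply(m, 1L, paste, collapse = ""))
}
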