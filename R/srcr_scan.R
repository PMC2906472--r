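#' Build a group-B SRCR domain model from a labelled reference alignment
#'
#' The model is a position-specific scoring profile over the alignment's
#' core columns (columns occupied in more than half of the reference rows),
#' together with the location of the eight consensus cysteines.  Group-B
#' SRCR domains carry eight cysteines forming disulfide bonds between the
#' 1st and 4th, 2nd and 7th, 3rd and 8th, and 5th and 6th cysteines; the
#' eight cysteine columns are those where cysteine frequency is maximal and
#' at least 0.5 (majority rule), taken left to right.  Reference row ids may
#' encode nomenclature letters as `"<protein>|<domain_ordinal>|<letter>"`;
#' the letters are retained for downstream clade assignment.
#'
#' @param reference_alignment a [new_alignment()] with >= 2 equal-length rows.
#' @param min_span,max_span accepted domain length window in residues.
#' @param pseudocount uniform pseudocount used in the per-column residue
#'   profile.
#' @return An object of class `domain_model` with elements `profile` (20 x
#'   core_length log-odds scores, half-bit units), `core_columns` (source
#'   alignment columns retained), `core_length`, `cys_columns` (cysteine
#'   ordinal 1..8 -> core column index), `disulfide_pairs`, `min_span`,
#'   `max_span`, `consensus`, `self_score` and the reference rows.
#' @export
build_domain_model <- function(reference_alignment, min_span = 78L,
                               max_span = 110L, pseudocount = 1) {
  aln <- reference_alignment
  if (length(aln$labels) < 2L) stop("reference alignment needs >= 2 rows")
  m <- alignment_matrix(aln)
  occupancy <- colMeans(m != "-")
  core_columns <- which(occupancy > 0.5)
  L <- length(core_columns)
  if (L < 8L) stop("not a group-B reference: fewer than 8 core columns")

  counts <- vapply(core_columns, function(j)
    tabulate(match(m[, j], AA20), nbins = 20L), numeric(20))
  rownames(counts) <- AA20
  n_eff <- colSums(counts)
  freq <- sweep(counts + pseudocount / 20,
                2L, n_eff + pseudocount, "/")
  cys_freq <- counts["C", ] / pmax(n_eff, 1)
  cys_columns <- which(cys_freq >= 0.5)
  if (length(cys_columns) < 8L)
    stop("not a group-B reference: only ", length(cys_columns),
         " conserved-cysteine columns (need 8)")
  if (length(cys_columns) > 8L)
    cys_columns <- cys_columns[order(cys_freq[cys_columns],
                                     decreasing = TRUE)[1:8]]
  cys_columns <- sort(cys_columns)

  profile <- 2 * log2(freq / (1 / 20))   # half-bit log-odds vs uniform
  consensus <- AA20[apply(freq, 2L, which.max)]
  letters_ref <- parse_ref_letters(aln$labels)
  structure(list(
    profile = profile,
    core_columns = core_columns,
    core_length = L,
    cys_columns = setNames(cys_columns, paste0("C", 1:8)),
    disulfide_pairs = list(c(1L, 4L), c(2L, 7L), c(3L, 8L), c(5L, 6L)),
    min_span = as.integer(min_span),
    max_span = as.integer(max_span),
    consensus = paste(consensus, collapse = ""),
    self_score = sum(apply(profile, 2L, max)),
    ref = list(labels = aln$labels, seqs = aln$seqs, letters = letters_ref)
  ), class = "domain_model")
}

# "<protein>|<ordinal>|<letter>" -> letter; anything else -> NA
parse_ref_letters <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  vapply(parts, function(p) if (length(p) >= 3L) p[3] else NA_character_,
         character(1))
}

#' @export
print.domain_model <- function(x, ...) {
  cat(sprintf(paste0("<domain_model> %d core columns, cysteines at %s,\n",
                     "  span window [%d, %d], self score %.1f\n"),
              x$core_length,
              paste(x$cys_columns, collapse = ","), x$min_span, x$max_span,
              x$self_score))
  invisible(x)
}

#' Scan a protein for group-B SRCR domains
#'
#' Locally aligns the domain profile against the protein (affine-gap
#' Smith-Waterman against the position-specific profile) and reports
#' non-overlapping hits above the score threshold.  Hits are collected
#' greedily by score: the best-scoring placement is accepted, its residues
#' are masked, and the scan repeats until no acceptable placement remains.
#' Ties between equal-scoring placements go to the smaller start coordinate.
#' Domains missing cysteines are still reported -- cysteine presence
#' informs the report, not the acceptance decision.
#'
#' @param record a [protein_record()].
#' @param model a [build_domain_model()] model.
#' @param score_threshold minimum accepted score, in profile (half-bit)
#'   units.  Default: 40% of the model self-match score, chosen to accept
#'   domains as diverged as the most distant pairs seen between SRCR domain
#'   classes (p-distance above 0.8) while rejecting linkers.
#' @param edge_slack residues by which a hit may undershoot `min_span`
#'   (ragged domain edges at low-information terminal columns).
#' @return A data frame of hits (possibly empty): `protein_id`,
#'   `domain_index`, `start`, `end`, `score`, `cys_present` (comma string),
#'   `missing_cysteines`, `group_call`, plus a `core_mapping` list column
#'   giving the residue (or `"-"`) mapped to each core column.
#' @export
scan_protein <- function(record, model,
                         score_threshold = 0.4 * model$self_score,
                         edge_slack = 6L) {
  stopifnot(inherits(record, "protein_record"),
            inherits(model, "domain_model"))
  chars <- seq_chars(record)
  n <- length(chars)
  prof <- model$profile                      # 20 x L
  idx <- match(chars, AA20)                  # NA for X scores 0
  S <- matrix(0, nrow = model$core_length, ncol = n)
  known <- which(!is.na(idx))
  S[, known] <- t(prof[idx[known], , drop = FALSE])

  # steep gap extension keeps a single profile pass from straddling two
  # domains across a linker (insertions then cost more than they recover)
  gap_open <- 12; gap_ext <- 2
  hits <- list()
  masked <- rep(FALSE, n)
  repeat {
    Sm <- S
    if (any(masked)) Sm[, masked] <- -1e9
    res <- .sw_affine_cpp(Sm, gap_open, gap_ext)
    if (res$score < score_threshold) break
    raw_span <- res$b_end - res$b_start + 1L
    accepted <- FALSE
    if (raw_span <= model$max_span &&
        !any(masked[res$b_start:res$b_end])) {
      # local alignment trims low-scoring terminal columns; complete the
      # envelope to the full model span first (where sequence and masking
      # allow, residues mapping one-to-one), then judge the span
      core_map <- rep("-", model$core_length)
      mapped <- res$path_a > 0L & res$path_b > 0L
      core_map[res$path_a[mapped]] <- chars[res$path_b[mapped]]
      first_col <- min(res$path_a[mapped]); last_col <- max(res$path_a[mapped])
      start <- res$b_start; end <- res$b_end
      ext <- 0L
      while (first_col - ext > 1L && start > 1L && !masked[start - 1L]) {
        ext <- ext + 1L; start <- start - 1L
        core_map[first_col - ext] <- chars[start]
      }
      ext <- 0L
      while (last_col + ext < model$core_length && end < n &&
             !masked[end + 1L]) {
        ext <- ext + 1L; end <- end + 1L
        core_map[last_col + ext] <- chars[end]
      }
      if (end - start + 1L >= model$min_span - edge_slack) {
        cys <- which(core_map[model$cys_columns] == "C")
        hits[[length(hits) + 1L]] <- list(
          start = start, end = end, score = res$score,
          core_mapping = core_map, cys_present = cys)
        masked[start:end] <- TRUE
        accepted <- TRUE
      }
    }
    if (!accepted) {
      # mask consumed residues so the scan always terminates; an over-long
      # (rejected) hit only burns its leading min_span window, leaving any
      # downstream domain it straddled discoverable on later iterations
      mask_end <- if (raw_span > model$max_span)
        min(res$b_end, res$b_start + model$min_span - 1L) else res$b_end
      masked[res$b_start:mask_end] <- TRUE
    }
    if (all(masked)) break
  }
  if (!length(hits)) {
    return(data.frame(protein_id = character(), domain_index = integer(),
                      start = integer(), end = integer(), score = numeric(),
                      cys_present = character(),
                      missing_cysteines = character(),
                      group_call = character(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(vapply(hits, `[[`, integer(1), "start"))
  hits <- hits[ord]
  out <- data.frame(
    protein_id = record$id,
    domain_index = seq_along(hits),
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    score = vapply(hits, `[[`, numeric(1), "score"),
    cys_present = vapply(hits, function(h)
      paste(h$cys_present, collapse = ","), character(1)),
    missing_cysteines = vapply(hits, function(h)
      paste(setdiff(1:8, h$cys_present), collapse = ","), character(1)),
    group_call = vapply(hits, function(h)
      if (length(h$cys_present) == 8L) "B" else "B_atypical", character(1)),
    stringsAsFactors = FALSE)
  out$core_mapping <- lapply(hits, `[[`, "core_mapping")
  out
}

#' Cysteine pattern of a domain hit
#'
#' @param hit one row of a [scan_protein()] result (a list or one-row data
#'   frame with `cys_present`), or an integer vector of present cysteine
#'   ordinals.
#' @return A list: `missing` (ordinals 1..8 absent), `intact_disulfides`
#'   (list of pairs with both members present, from the group-B pairing
#'   (1,4), (2,7), (3,8), (5,6)) and `group_call` (`"B"` when nothing is
#'   missing, else `"B_atypical"`).
#' @export
cysteine_pattern <- function(hit) {
  present <- if (is.numeric(hit)) as.integer(hit)
  else {
    cp <- if (is.data.frame(hit)) hit$cys_present[1] else hit$cys_present
    if (is.character(cp)) as.integer(strsplit(cp, ",")[[1]]) else as.integer(cp)
  }
  present <- present[!is.na(present)]
  stopifnot(all(present %in% 1:8))
  pairs <- list(c(1L, 4L), c(2L, 7L), c(3L, 8L), c(5L, 6L))
  intact <- Filter(function(p) all(p %in% present), pairs)
  list(missing = setdiff(1:8, present),
       intact_disulfides = intact,
       group_call = if (length(present) == 8L) "B" else "B_atypical")
}

#' Convert scan hits to a domain annotation table
#'
#' @param hits result of [scan_protein()] (or several results row-bound).
#' @param letters optional letters to attach (default `"undesignated"`).
#' @return A validated annotation table (see [validate_annotations()]).
#' @export
hits_to_annotations <- function(hits, letters = NULL) {
  tab <- data.frame(protein_id = hits$protein_id,
                    domain_index = hits$domain_index,
                    start = hits$start, end = hits$end, score = hits$score,
                    letter = if (is.null(letters)) "undesignated" else letters,
                    missing_cysteines = hits$missing_cysteines,
                    stringsAsFactors = FALSE)
  validate_annotations(tab)
  tab
}
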