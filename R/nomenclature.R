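#' Assign nomenclature letters to query SRCR domains by clade placement
#'
#' Each query leaf is placed against letter-labelled reference leaves on a
#' support-annotated tree.  On an unrooted tree both sides of every
#' supported bipartition count as candidate clades.  The rules, applied per
#' query:
#'
#' 1. The smallest supported clade containing the query and at least one
#'    reference decides when its references are letter-consistent: the
#'    query takes that letter (`method = "clade"`).  A clade mixing only
#'    the letters `d` and `d'` assigns `d'` to a protein's C-terminal
#'    domain and `d` otherwise, encoding the convention that `d'` is the
#'    membrane-proximal (terminal) domain.
#' 2. A query whose smallest reference-containing clade mixes letters (or
#'    which reaches no reference at all) but which sits in a supported
#'    reference-free clade of two or more such queries: the *maximal*
#'    reference-free clade receives one shared, newly allocated letter
#'    (`method = "new_letter"`).
#' 3. Everything else is `"undesignated"`.
#'
#' On a tree with no informative internal edge (e.g. two leaves) the whole
#' leaf set is the clade, so a query takes its lone reference's letter.
#' Trees without
#' support values (no node labels) are treated as fully resolved.  New
#' letters are allocated alphabetically from `o` onward, skipping letters
#' already used by the references, in order of each new clade's first query
#' in the tree's leaf order.
#'
#' @param tree a `phylo` whose leaves are references plus queries;
#'   supports (0..1) in `node.label` (see [bootstrap_tree()]).
#' @param reference_labels named character vector: reference leaf -> letter.
#' @param threshold minimum clade support for an assignment.
#' @param terminal_queries optional character vector of query leaves that
#'   are their protein's C-terminal domain (used for the d/d' rule).  When
#'   `NULL`, leaves named `"<protein>|<index>"` are parsed and the largest
#'   index per protein is taken as terminal.
#' @return A data frame: `leaf`, `letter`, `method`
#'   (`clade`/`new_letter`/`undesignated`), `support`.
#' @export
assign_letters <- function(tree, reference_labels, threshold = 0.70,
                           terminal_queries = NULL) {
  leaves <- tree$tip.label
  refs <- names(reference_labels)
  if (!all(refs %in% leaves))
    stop("reference leaf(s) absent from tree: ",
         paste(setdiff(refs, leaves), collapse = ", "))
  queries <- setdiff(leaves, refs)
  if (!length(queries))
    return(data.frame(leaf = character(), letter = character(),
                      method = character(), support = numeric()))
  bad <- setdiff(reference_labels, valid_letter_alphabet())
  if (length(bad))
    stop("reference letter(s) outside the declared alphabet: ",
         paste(bad, collapse = ", "))
  if (is.null(terminal_queries)) terminal_queries <- guess_terminal(queries)

  sides <- supported_sides(tree, threshold)
  sizes <- vapply(sides, function(s) length(s$leaves), integer(1))
  has_ref <- vapply(sides, function(s) any(s$leaves %in% refs), logical(1))

  out <- data.frame(leaf = queries, letter = "undesignated",
                    method = "undesignated", support = NA_real_,
                    stringsAsFactors = FALSE)
  ref_letter_of <- function(side) {
    inside <- unique(reference_labels[intersect(side$leaves, refs)])
    if (length(inside) == 1L) inside
    else if (setequal(inside, c("d", "d'"))) "d|d'"
    else NA_character_
  }

  needs_free <- logical(length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    containing <- which(vapply(sides, function(s) q %in% s$leaves,
                               logical(1)))
    withref <- containing[has_ref[containing]]
    if (length(withref)) {
      # smallest supported clade holding the query plus >= 1 reference
      best <- sides[[withref[order(sizes[withref])][1]]]
      letter <- ref_letter_of(best)
      if (!is.na(letter)) {
        if (letter == "d|d'")
          letter <- if (q %in% terminal_queries) "d'" else "d"
        out$letter[qi] <- letter
        out$method[qi] <- "clade"
        out$support[qi] <- best$support
        next
      }
    }
    # letter-mixed or no reference in reach: candidate for a new letter
    needs_free[qi] <- any(!has_ref[containing])
    if (!length(containing) && length(sides) == 0L) {
      # no informative edge at all (e.g. two-leaf tree): the whole tree
      # is the clade
      letter <- ref_letter_of(list(leaves = leaves))
      if (!is.na(letter) && letter != "d|d'") {
        out$letter[qi] <- letter
        out$method[qi] <- "clade"
        out$support[qi] <- 1.0
      }
    }
  }

  # --- new-letter allocation: maximal supported reference-free sides -----
  free <- which(!has_ref & sizes >= 2L)
  free_groups <- list()
  for (k in free[order(-sizes[free])]) {
    lv <- sides[[k]]$leaves
    if (!any(lv %in% queries[needs_free])) next
    covered <- any(vapply(free_groups, function(g)
      all(lv %in% g$leaves), logical(1)))
    if (!covered) free_groups[[length(free_groups) + 1L]] <-
        list(leaves = lv, support = sides[[k]]$support)
  }
  if (length(free_groups)) {
    # allocation order: position of each group's first leaf in tree order
    first_pos <- vapply(free_groups, function(g)
      min(match(g$leaves, leaves)), numeric(1))
    free_groups <- free_groups[order(first_pos)]
    pool <- new_letter_pool(exclude = unique(reference_labels))
    for (g in seq_along(free_groups)) {
      idx <- which(out$leaf %in% free_groups[[g]]$leaves & needs_free &
                     out$method == "undesignated")
      if (length(idx) < 2L) next
      out$letter[idx] <- pool[g]
      out$method[idx] <- "new_letter"
      out$support[idx] <- free_groups[[g]]$support
    }
  }
  out
}

valid_letter_alphabet <- function() {
  c("a", "b", "c", "d", "d'", "e", "h", "i", "j", "k", "l", "m", "n")
}

new_letter_pool <- function(exclude) {
  pool <- setdiff(c(letters[15:26], letters[1:14]), c(exclude, "x"))
  pool
}

# parse "<protein>|<index>" leaves; the largest index per protein is terminal
guess_terminal <- function(queries) {
  parts <- strsplit(queries, "|", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  pid <- vapply(parts, `[`, character(1), 1)
  idx <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  term <- character()
  for (p in unique(pid[ok & !is.na(idx)])) {
    sel <- which(pid == p & !is.na(idx))
    term <- c(term, queries[sel[which.max(idx[sel])]])
  }
  term
}

#' Positional refinement of letter assignments
#'
#' An undesignated domain whose flanking assigned letters match exactly one
#' context in the reference architectures (same left and right letters,
#' protein termini matching architecture termini) is promoted to that
#' context's letter with `method = "positional"`.  Clade assignments are
#' never overridden.
#'
#' @param assignments data frame from [assign_letters()] augmented with
#'   `protein_id` and `domain_index` columns (see
#'   [assignments_for_proteins()]), or a plain data frame with columns
#'   `protein_id`, `domain_index`, `letter`, `method`.
#' @param reference_architectures list/vector of architecture strings (e.g.
#'   `"m-l-b-c-n-d-e-d'"`) or of letter vectors.
#' @return The assignments with qualifying rows promoted.
#' @export
positional_refine <- function(assignments, reference_architectures) {
  ref_archs <- lapply(reference_architectures, function(a)
    if (length(a) == 1L && is.character(a)) parse_architecture(a) else a)
  # reference contexts: left letter, candidate, right letter ("^"/"$" = ends)
  ctx <- list()
  for (arch in ref_archs) {
    padded <- c("^", arch, "$")
    for (i in seq_along(arch)) {
      key <- paste(padded[i], padded[i + 2], sep = "~")
      ctx[[key]] <- unique(c(ctx[[key]], arch[i]))
    }
  }
  for (p in unique(assignments$protein_id)) {
    rows <- which(assignments$protein_id == p)
    rows <- rows[order(assignments$domain_index[rows])]
    lets <- assignments$letter[rows]
    padded <- c("^", lets, "$")
    for (k in seq_along(rows)) {
      if (assignments$method[rows[k]] != "undesignated") next
      left <- padded[k]; right <- padded[k + 2]
      if (left == "undesignated" || right == "undesignated") next
      cand <- ctx[[paste(left, right, sep = "~")]]
      if (length(cand) == 1L) {
        assignments$letter[rows[k]] <- cand
        assignments$method[rows[k]] <- "positional"
      }
    }
  }
  assignments
}

#' Architecture string of a protein's letter assignments
#'
#' Letters in N-to-C domain order joined by `-`; undesignated domains
#' render as `x`.  `parse_architecture()` inverts the rendering.
#'
#' @param protein_id protein to render.
#' @param assignments data frame with `protein_id`, `domain_index`,
#'   `letter`.
#' @return An object of class `architecture` (character scalar with a
#'   `letters` attribute).
#' @export
architecture_string <- function(protein_id, assignments) {
  rows <- assignments[assignments$protein_id == protein_id, ]
  if (!nrow(rows)) stop("no assignments for protein '", protein_id, "'")
  rows <- rows[order(rows$domain_index), ]
  if (!identical(as.integer(rows$domain_index), seq_len(nrow(rows))))
    stop("gap in domain indices for protein '", protein_id, "'")
  lets <- ifelse(rows$letter == "undesignated", "x", rows$letter)
  structure(paste(lets, collapse = "-"), letters = lets,
            class = "architecture")
}

#' @rdname architecture_string
#' @param x an architecture string like `"h-i-j-k-b-c-d-e-d'"`.
#' @export
parse_architecture <- function(x) {
  strsplit(unclass(x), "-", fixed = TRUE)[[1]]
}

#' @export
print.architecture <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}

#' Classify a receptor's family type from its domain architecture
#'
#' Diagnostic letters, in precedence order: `k` marks CD163A (or CD163b);
#' `a` together with any of `m`, `l`, `n` marks a WC1/CD163c-alpha hybrid;
#' `a` alone marks WC1; `m`/`l`/`n` alone mark CD163c-alpha; anything else
#' is unclassified.
#'
#' @param arch an architecture string or [architecture_string()] object.
#' @return One of `"CD163A_like"`, `"hybrid"`, `"WC1_like"`,
#'   `"CD163c_alpha_like"`, `"unclassified"`.
#' @export
classify_family <- function(arch) {
  lets <- parse_architecture(arch)
  if (!length(lets)) stop("empty architecture")
  has <- function(x) any(lets %in% x)
  if (has("k")) return("CD163A_like")
  if (has("a") && has(c("m", "l", "n"))) return("hybrid")
  if (has("a")) return("WC1_like")
  if (has(c("m", "l", "n"))) return("CD163c_alpha_like")
  "unclassified"
}

#' Attach protein/domain coordinates to leaf-level assignments
#'
#' Splits `"<protein>|<index>"` leaf names into `protein_id` and
#' `domain_index` columns so positional refinement and architecture
#' rendering can operate per protein.
#'
#' @param assignments result of [assign_letters()].
#' @return The data frame with `protein_id` and `domain_index` columns.
#' @export
assignments_for_proteins <- function(assignments) {
  parts <- strsplit(assignments$leaf, "|", fixed = TRUE)
  assignments$protein_id <- vapply(parts, `[`, character(1), 1)
  assignments$domain_index <-
    as.integer(vapply(parts, `[`, character(1), 2))
  assignments
}
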