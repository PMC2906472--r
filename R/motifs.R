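# Kyte-Doolittle hydropathy index
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                   X = 0)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' A transparent stand-in for server-based transmembrane predictors: the
#' mean Kyte-Doolittle hydropathy over a sliding window marks candidate TM
#' cores, which are merged and extended to at least the window length.
#' Known coordinates can be supplied instead via `tm_regions`
#' (`source = "user_supplied"`), bypassing prediction entirely.
#'
#' @param record a [protein_record()].
#' @param window window width in residues (odd recommended).
#' @param threshold mean-hydropathy cutoff for a TM core.
#' @param tm_regions optional user-supplied matrix/data frame of
#'   `start`, `end` pairs (1-based inclusive), bypassing prediction.
#' @return A `topology_call`: list with `protein_id`, `tm_regions` (two-
#'   column matrix, possibly 0-row), `cytoplasmic_start` (position after the
#'   last TM, `NA` when no TM) and `source`.
#' @export
predict_tm <- function(record, window = 19L, threshold = 1.6,
                       tm_regions = NULL) {
  stopifnot(inherits(record, "protein_record"))
  n <- nchar(record$sequence)
  if (!is.null(tm_regions)) {
    tm <- as.matrix(as.data.frame(tm_regions)[, 1:2])
    colnames(tm) <- c("start", "end")
    tm <- tm[order(tm[, 1]), , drop = FALSE]
    stopifnot(all(tm[, 1] >= 1), all(tm[, 2] <= n),
              all(tm[, 2] >= tm[, 1]))
    return(topology_call(record$id, tm, n, "user_supplied"))
  }
  if (n < window) {
    warning("sequence '", record$id, "' shorter than the window: no TM call")
    return(topology_call(record$id,
                         matrix(integer(), 0, 2,
                                dimnames = list(NULL, c("start", "end"))),
                         n, "predicted"))
  }
  h <- KD_HYDROPATHY[seq_chars(record)]
  means <- as.numeric(stats::filter(h, rep(1 / window, window),
                                    sides = 2))
  core <- which(!is.na(means) & means >= threshold)
  tm <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (length(core)) {
    breaks <- c(0L, which(diff(core) > 1L), length(core))
    for (b in seq_len(length(breaks) - 1L)) {
      # a run of qualifying window centers, grown symmetrically to at
      # least one full window
      run <- core[(breaks[b] + 1L):breaks[b + 1L]]
      s <- min(run); e <- max(run)
      need <- window - (e - s + 1L)
      if (need > 0L) {
        s <- s - ceiling(need / 2); e <- e + floor(need / 2)
      }
      if (s < 1L) { e <- min(n, e + (1L - s)); s <- 1L }
      if (e > n) { s <- max(1L, s - (e - n)); e <- n }
      tm <- rbind(tm, c(s, e))
    }
    # merge overlaps created by extension
    if (nrow(tm) > 1L) {
      merged <- tm[1, , drop = FALSE]
      for (r in 2:nrow(tm)) {
        if (tm[r, 1] <= merged[nrow(merged), 2] + 1L)
          merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], tm[r, 2])
        else merged <- rbind(merged, tm[r, , drop = FALSE])
      }
      tm <- merged
    }
  }
  topology_call(record$id, tm, n, "predicted")
}

topology_call <- function(protein_id, tm, n, source) {
  storage.mode(tm) <- "integer"
  structure(list(protein_id = protein_id, tm_regions = tm,
                 cytoplasmic_start = if (nrow(tm))
                   unname(tm[nrow(tm), 2]) + 1L else NA_integer_,
                 protein_length = n, source = source),
            class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat(sprintf("<topology_call> %s: %d TM region(s) [%s]\n", x$protein_id,
              nrow(x$tm_regions), x$source))
  invisible(x)
}

#' Cytoplasmic domain of a receptor
#'
#' Residues C-terminal to the last transmembrane region.  An empty tail is
#' valid (TM ending at the protein's last residue); a protein with no TM
#' has no cytoplasmic domain and raises an error.
#'
#' @param record a [protein_record()].
#' @param topology a [predict_tm()] result for the same protein.
#' @return The tail subsequence (possibly `""`).
#' @export
cytoplasmic_domain <- function(record, topology) {
  stopifnot(topology$protein_id == record$id)
  if (nrow(topology$tm_regions) == 0L)
    stop("no cytoplasmic domain: protein '", record$id, "' has no TM region")
  start <- topology$cytoplasmic_start
  n <- nchar(record$sequence)
  if (start > n) return("")
  substr(record$sequence, start, n)
}

WC1_MOTIF_SETS <- list(c("Y"), c("Q", "E"), c("D", "C", "E"), c("I", "L"))

#' Scan for the WC1-type tyrosine motif Y-(Q/E)-(D/C/E)-(I/L)
#'
#' Reports every tetramer matching the motif (overlaps included) and,
#' tagged separately, near-misses where the fourth position is a threonine
#' (`pattern_id = "wc1_like_T"`); near-misses are informational and never
#' count as motif hits.
#'
#' @param seq amino-acid string (a cytoplasmic tail, typically) or
#'   [protein_record()].
#' @param protein_id id recorded in the hits (defaults to the record id).
#' @return A data frame of hits: `protein_id`, `position` (1-based index of
#'   the tyrosine), `tetramer`, `pattern_id`.
#' @export
scan_wc1_motif <- function(seq, protein_id = NULL) {
  if (inherits(seq, "protein_record")) {
    if (is.null(protein_id)) protein_id <- seq$id
    seq <- seq$sequence
  }
  if (is.null(protein_id)) protein_id <- ""
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  hits <- data.frame(protein_id = character(), position = integer(),
                     tetramer = character(), pattern_id = character(),
                     stringsAsFactors = FALSE)
  if (n < 4L) return(hits)
  for (i in seq_len(n - 3L)) {
    tet <- chars[i:(i + 3L)]
    ok123 <- tet[1] == "Y" && tet[2] %in% WC1_MOTIF_SETS[[2]] &&
      tet[3] %in% WC1_MOTIF_SETS[[3]]
    if (!ok123) next
    if (tet[4] %in% WC1_MOTIF_SETS[[4]]) {
      hits[nrow(hits) + 1L, ] <- list(protein_id, i,
                                      paste(tet, collapse = ""), "wc1_like")
    } else if (tet[4] == "T") {
      hits[nrow(hits) + 1L, ] <- list(protein_id, i,
                                      paste(tet, collapse = ""),
                                      "wc1_like_T")
    }
  }
  hits
}

#' Find exact (literal) motifs
#'
#' All exact occurrences of each motif, overlapping and self-overlapping
#' starts included.
#'
#' @param seq amino-acid string or [protein_record()].
#' @param motifs character vector of uppercase motifs (non-empty).
#' @param protein_id id recorded in the hits.
#' @return A data frame: `protein_id`, `position`, `tetramer` (the matched
#'   string), `pattern_id` (`"literal:<motif>"`).
#' @export
find_literal_motifs <- function(seq, motifs, protein_id = NULL) {
  if (inherits(seq, "protein_record")) {
    if (is.null(protein_id)) protein_id <- seq$id
    seq <- seq$sequence
  }
  if (is.null(protein_id)) protein_id <- ""
  stopifnot(length(motifs) >= 1L, all(nzchar(motifs)))
  seq <- toupper(seq)
  out <- list()
  for (mo in motifs) {
    starts <- integer()
    from <- 1L
    repeat {                      # overlapping matches: advance by 1
      hit <- regexpr(mo, substring(seq, from), fixed = TRUE)
      if (hit < 0) break
      starts <- c(starts, from + as.integer(hit) - 1L)
      from <- from + as.integer(hit)
    }
    if (length(starts))
      out[[mo]] <- data.frame(protein_id = protein_id, position = starts,
                              tetramer = mo,
                              pattern_id = paste0("literal:", mo),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(protein_id = character(), position = integer(),
                      tetramer = character(), pattern_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$position), , drop = FALSE]
}

#' Tag motif hits with their topological region
#'
#' A hit is `cytoplasmic` when its position lies at or beyond the position
#' after the last transmembrane segment, `other` otherwise.
#'
#' @param hits a data frame from [scan_wc1_motif()] or
#'   [find_literal_motifs()] with positions on the full protein.
#' @param topology the protein's [predict_tm()] call.
#' @return The hits with a `region` column.
#' @export
tag_motif_region <- function(hits, topology) {
  cs <- topology$cytoplasmic_start
  hits$region <- if (is.na(cs)) "other"
  else ifelse(hits$position >= cs, "cytoplasmic", "other")
  hits
}
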