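#' Protein record
#'
#' Lightweight container for one identified amino-acid sequence.  The
#' sequence is stored uppercase over the 20 standard residues plus `X`
#' (unknown residue, e.g. a translated gap in a genomic prediction); `X` is
#' treated as missing data by all downstream comparisons.
#'
#' @param id short unique token identifying the protein.
#' @param sequence amino-acid string; lowercase input is uppercased.
#' @param species free-text species tag (e.g. `"Bt"`, `"Hs"`), may be empty.
#' @param description free-text description, may be empty.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, species = "", description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("protein id must be a non-empty string")
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must have length >= 1 (protein '", id, "')")
  if (grepl("[[:space:]]", sequence))
    stop("sequence of '", id, "' contains whitespace")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_VALID)
  if (length(bad))
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1],
         " in protein '", id, "'")
  structure(list(id = id, species = species, description = description,
                 sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s, %d aa)\n", x$id,
              if (nzchar(x$species)) x$species else "species unset",
              nchar(x$sequence)))
  invisible(x)
}

# Biostrings parsing with strict residue checking: invalid one-letter codes
# are silently dropped by readAAStringSet (with a warning); here they are a
# hard error located by a raw scan of the offending line.
parse_fasta_checked <- function(path) {
  withCallingHandlers(
    tryCatch(Biostrings::readAAStringSet(path, format = "fasta"),
             error = function(e) stop("FASTA parse error in '", path,
                                      "': ", conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter", conditionMessage(w)))
        stop_at_illegal_char(path)
      invokeRestart("muffleWarning")
    })
}

stop_at_illegal_char <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- 0L
  for (ln in seq_along(lines)) {
    if (startsWith(lines[ln], ">")) { pos <- 0L; next }
    chars <- strsplit(lines[ln], "")[[1]]
    bad <- which(!grepl("[A-Za-z*.-]", chars))
    if (length(bad))
      stop("illegal residue character '", chars[bad[1]],
           "' at sequence position ", pos + bad[1],
           " (line ", ln, ") in '", path, "'")
    pos <- pos + length(chars)
  }
  stop("invalid residue code(s) in '", path, "'")
}

check_unique_ids <- function(ids) {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  invisible(ids)
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; records are then
#' validated (unique ids, legal residues) and wrapped as [protein_record()]
#' objects.  Multi-line and lowercase sequences are handled; order is
#' preserved.  The species tag is taken as the prefix of the id up to the
#' first underscore when the id looks like `"Bt_..."`, otherwise left empty.
#'
#' @param path FASTA file.
#' @return A list of `protein_record` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- parse_fasta_checked(path)
  if (length(set) == 0L) stop("no records in '", path, "'")
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  check_unique_ids(ids)
  species <- ifelse(grepl("^[A-Z][a-z]{1,2}_", ids), sub("_.*$", "", ids), "")
  lapply(seq_along(set), function(i)
    protein_record(ids[i], as.character(set[[i]]), species[i], desc[i]))
}

#' Write protein records to FASTA
#'
#' Round-trips with [read_fasta()]: writing then reading yields identical
#' ids and sequences.
#'
#' @param records list of [protein_record()] objects (an empty list writes an
#'   empty file).
#' @param path output file.
#' @param width line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    stopifnot(inherits(rec, "protein_record"))
    header <- if (nzchar(rec$description))
      paste(rec$id, rec$description) else rec$id
    writeLines(paste0(">", header), con)
    s <- rec$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(NULL)
}

#' Validate a domain annotation table
#'
#' A domain annotation table is a data frame with one row per SRCR domain:
#' `protein_id`, `domain_index` (1-based ordinal, N- to C-terminal),
#' `start`/`end` (1-based inclusive protein coordinates), `score`, `letter`
#' (nomenclature letter or `"undesignated"`) and `missing_cysteines`
#' (comma-separated subset of 1..8, `""` when the domain has all eight).
#'
#' @param table data frame to validate.
#' @param proteins optional list of [protein_record()]s to check coordinates
#'   against.
#' @return The table, invisibly, after passing all checks.
#' @export
validate_annotations <- function(table, proteins = NULL) {
  needed <- c("protein_id", "domain_index", "start", "end", "score",
              "letter", "missing_cysteines")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(table) == 0L) return(invisible(table))
  stopifnot(all(table$start >= 1L), all(table$end >= table$start))
  for (pid in unique(table$protein_id)) {
    rows <- table[table$protein_id == pid, ]
    rows <- rows[order(rows$start), ]
    if (!identical(as.integer(rows$domain_index), seq_len(nrow(rows))))
      stop("domain_index not consecutive from 1 for protein '", pid, "'")
    if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)]))
      stop("overlapping domains in protein '", pid, "'")
    if (!is.null(proteins)) {
      rec <- Filter(function(r) r$id == pid, proteins)
      if (length(rec) && any(rows$end > nchar(rec[[1]]$sequence)))
        stop("domain end beyond protein length for '", pid, "'")
    }
  }
  mc <- table$missing_cysteines
  ok <- vapply(strsplit(ifelse(is.na(mc), "", mc), ","), function(v) {
    v <- v[nzchar(v)]
    all(v %in% as.character(1:8))
  }, logical(1))
  if (!all(ok)) stop("missing_cysteines entries must be subsets of 1..8")
  invisible(table)
}

#' Write (or re-read) domain annotations
#'
#' `format = "tsv"` writes a header plus one row per domain and round-trips
#' through [read_domain_annotations()].  `format = "gff3"` writes
#' protein-coordinate GFF3 features of type `SRCR_domain` (1-based inclusive
#' coordinates, nomenclature letter and missing cysteines in the attribute
#' column).
#'
#' @param table a validated annotation table (see [validate_annotations()]).
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @export
write_domain_annotations <- function(table, path, format = c("tsv", "gff3")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format '",
                                              format[1], "'"))
  validate_annotations(table)
  if (format == "tsv") {
    write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    if (nrow(table)) {
      attr_col <- sprintf("ID=%s.srcr%d;letter=%s;missing_cysteines=%s",
                          table$protein_id, table$domain_index, table$letter,
                          ifelse(nzchar(table$missing_cysteines),
                                 table$missing_cysteines, "none"))
      writeLines(paste(table$protein_id, "srcrtools", "SRCR_domain",
                       table$start, table$end,
                       formatC(table$score, format = "f", digits = 2),
                       ".", ".", attr_col, sep = "\t"), con)
    }
  }
  invisible(NULL)
}

#' @rdname write_domain_annotations
#' @export
read_domain_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(missing_cysteines = "character"))
  tab$missing_cysteines[is.na(tab$missing_cysteines)] <- ""
  validate_annotations(tab)
  tab
}
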