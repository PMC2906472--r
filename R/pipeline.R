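#' Pipeline configuration
#'
#' Bundles every parameter of the end-to-end analysis.  Paths are checked
#' up front so a misconfigured run fails before any stage executes; the
#' seed is mandatory whenever bootstrap replicates are requested.
#'
#' @param input_fasta path(s) to protein FASTA file(s).
#' @param reference_alignment path to the letter-labelled reference domain
#'   alignment (aligned FASTA, ids `"<protein>|<ordinal>|<letter>"`).
#' @param out_dir output directory (created if needed).
#' @param score_threshold_frac scan acceptance threshold as a fraction of
#'   the model self-match score.
#' @param support_threshold minimum clade support for letter assignment.
#' @param model_tag distance model (see [correct_distance()]).
#' @param deletion_mode column-deletion scheme for distances.
#' @param B bootstrap replicates (SEs and tree support); 0 disables both.
#' @param seed integer seed, required when `B > 0`.
#' @param tm_mode `"predict"` or `"user"`; with `"user"`, supply
#'   `tm_file`, a TSV of `protein_id`, `start`, `end`.
#' @param tm_file optional TSV of user transmembrane coordinates.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_fasta, reference_alignment, out_dir,
                            score_threshold_frac = 0.4,
                            support_threshold = 0.70,
                            model_tag = "p",
                            deletion_mode = "pairwise",
                            B = 100L, seed = NULL,
                            tm_mode = c("predict", "user"),
                            tm_file = NULL) {
  tm_mode <- match.arg(tm_mode)
  for (p in c(input_fasta, reference_alignment,
              if (tm_mode == "user") tm_file))
    if (!file.exists(p)) stop("pre-flight failure: path not found: ", p)
  if (B > 0L && is.null(seed)) stop("seed is required when B > 0")
  structure(list(input_fasta = input_fasta,
                 reference_alignment = reference_alignment,
                 out_dir = out_dir,
                 score_threshold_frac = score_threshold_frac,
                 support_threshold = support_threshold,
                 model_tag = model_tag, deletion_mode = deletion_mode,
                 B = as.integer(B), seed = seed,
                 tm_mode = tm_mode, tm_file = tm_file),
            class = "pipeline_config")
}

#' Run the full receptor analysis pipeline
#'
#' scan -> align -> trim to core -> distances (+SEs) -> NJ tree (+support)
#' -> letter assignment -> positional refinement -> architecture strings
#' and family calls -> transmembrane/cytoplasmic partition -> motif scan.
#' Every product is written under `config$out_dir` and also returned; a
#' run log records every parameter and seed.  Identical config and inputs
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `annotations`, `alignment` (trimmed),
#'   `distances`, `tree`, `assignments`, `architectures` (data frame with
#'   family calls), `motifs`, `topology`, and `log` (character lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("srcrtools run_pipeline %s", as.character(Sys.time())),
           sprintf("parameter %s = %s",
                   names(unclass(config))[!vapply(unclass(config), is.null,
                                                  logical(1))],
                   vapply(Filter(Negate(is.null), unclass(config)),
                          function(x) paste(format(x), collapse = ","),
                          character(1))))
  fail <- function(stage, msg) stop("pipeline stage '", stage, "': ", msg,
                                    call. = FALSE)

  # --- load inputs --------------------------------------------------------
  records <- tryCatch(
    do.call(c, lapply(config$input_fasta, read_fasta)),
    error = function(e) fail("read", conditionMessage(e)))
  ref_aln <- tryCatch(read_alignment(config$reference_alignment),
                      error = function(e) fail("reference",
                                               conditionMessage(e)))
  model <- build_domain_model(ref_aln)
  log <- c(log, sprintf("model: %d core columns, self score %.1f",
                        model$core_length, model$self_score))

  # --- scan ---------------------------------------------------------------
  thr <- config$score_threshold_frac * model$self_score
  hits <- do.call(rbind, lapply(records, function(r)
    scan_protein(r, model, score_threshold = thr)))
  if (is.null(hits) || nrow(hits) == 0L) fail("scan", "no domains found")
  annotations <- hits_to_annotations(hits)
  log <- c(log, sprintf("scan: %d domains in %d proteins (threshold %.1f)",
                        nrow(annotations),
                        length(unique(annotations$protein_id)), thr))

  # --- align domains with the reference, trim to core ---------------------
  dom_seqs <- lapply(seq_len(nrow(hits)), function(i) {
    rec <- Filter(function(r) r$id == hits$protein_id[i], records)[[1]]
    substr(rec$sequence, hits$start[i], hits$end[i])
  })
  names(dom_seqs) <- paste0(hits$protein_id, "|", hits$domain_index)
  all_seqs <- c(setNames(as.list(gsub("-", "", ref_aln$seqs, fixed = TRUE)),
                         ref_aln$labels), dom_seqs)
  aln <- progressive_align(all_seqs)
  core <- trim_to_core(aln, model)
  write_alignment(core, file.path(config$out_dir, "core_alignment.fasta"))

  # --- distances ----------------------------------------------------------
  D <- distance_matrix(core, model_tag = config$model_tag,
                       deletion_mode = config$deletion_mode,
                       B = config$B, seed = config$seed)
  write_distance_matrix(D, file.path(config$out_dir, "distances.tsv"))
  if (!is.null(D$se)) {
    qlab <- names(dom_seqs)
    tb <- render_distance_table(dist_block(D, qlab, qlab))
    writeLines(tb, file.path(config$out_dir, "distance_table.txt"))
  }

  # --- tree ---------------------------------------------------------------
  tree <- if (config$B > 0L)
    bootstrap_tree(core, model_tag = config$model_tag, B = config$B,
                   seed = pair_seed(config$seed, 3L, 1L))
  else neighbor_joining(D)
  write_newick(tree, file.path(config$out_dir, "tree.nwk"))

  # --- letters, architectures, family calls -------------------------------
  ref_letters <- setNames(parse_ref_letters(ref_aln$labels), ref_aln$labels)
  ref_letters <- ref_letters[!is.na(ref_letters)]
  assignments <- assign_letters(tree, ref_letters,
                                threshold = config$support_threshold)
  assignments <- assignments_for_proteins(assignments)
  ref_archs <- reference_architectures(ref_aln$labels)
  assignments <- positional_refine(assignments, ref_archs)
  assignments <- assignments[order(assignments$protein_id,
                                   assignments$domain_index), ]
  annotations$letter <- assignments$letter[
    match(paste0(annotations$protein_id, "|", annotations$domain_index),
          assignments$leaf)]
  write_domain_annotations(annotations,
                           file.path(config$out_dir, "domains.tsv"), "tsv")
  write_domain_annotations(annotations,
                           file.path(config$out_dir, "domains.gff3"), "gff3")
  arch_df <- do.call(rbind, lapply(unique(assignments$protein_id),
                                   function(p) {
    a <- architecture_string(p, assignments)
    data.frame(protein_id = p, architecture = unclass(a),
               family_call = classify_family(a), stringsAsFactors = FALSE)
  }))
  write.table(arch_df, file.path(config$out_dir, "architectures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(assignments[, c("protein_id", "domain_index", "letter",
                              "method", "support")],
              file.path(config$out_dir, "letters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- topology + motifs --------------------------------------------------
  user_tm <- if (config$tm_mode == "user")
    read.delim(config$tm_file, stringsAsFactors = FALSE) else NULL
  topo <- lapply(records, function(r) {
    if (!is.null(user_tm) && any(user_tm$protein_id == r$id))
      predict_tm(r, tm_regions = user_tm[user_tm$protein_id == r$id,
                                         c("start", "end")])
    else suppressWarnings(predict_tm(r))
  })
  names(topo) <- vapply(records, `[[`, character(1), "id")
  motifs <- do.call(rbind, lapply(records, function(r) {
    h <- rbind(scan_wc1_motif(r), find_literal_motifs(r, "YREM"))
    if (nrow(h)) tag_motif_region(h, topo[[r$id]]) else NULL
  }))
  if (is.null(motifs))
    motifs <- data.frame(protein_id = character(), position = integer(),
                         tetramer = character(), pattern_id = character(),
                         region = character(), stringsAsFactors = FALSE)
  write.table(motifs, file.path(config$out_dir, "motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  topo_df <- do.call(rbind, lapply(topo, function(tc) {
    if (nrow(tc$tm_regions) == 0L)
      return(data.frame(protein_id = tc$protein_id, start = NA_integer_,
                        end = NA_integer_, source = tc$source,
                        stringsAsFactors = FALSE))
    data.frame(protein_id = tc$protein_id, start = tc$tm_regions[, 1],
               end = tc$tm_regions[, 2], source = tc$source,
               stringsAsFactors = FALSE)
  }))
  write.table(topo_df, file.path(config$out_dir, "topology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log <- c(log, sprintf("assigned %d/%d domains a letter",
                        sum(assignments$letter != "undesignated"),
                        nrow(assignments)),
           sprintf("motif hits: %d", nrow(motifs)))
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(annotations = annotations, alignment = core, distances = D,
                 tree = tree, assignments = assignments,
                 architectures = arch_df, motifs = motifs, topology = topo,
                 log = log))
}

# architecture strings implied by the reference labels
# ("<protein>|<ordinal>|<letter>") for positional refinement
reference_architectures <- function(ref_labels) {
  parts <- strsplit(ref_labels, "|", fixed = TRUE)
  ok <- lengths(parts) >= 3L
  pid <- vapply(parts[ok], `[`, character(1), 1)
  ord <- as.integer(vapply(parts[ok], `[`, character(1), 2))
  let <- vapply(parts[ok], `[`, character(1), 3)
  lapply(split(seq_along(pid), pid), function(ix)
    let[ix][order(ord[ix])])
}
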