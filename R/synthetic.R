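# residue pools used by the generator; cysteine is reserved for the scaffold
AA_NC <- setdiff(AA20, "C")                 # 19 letters
LINKER_POOL <- strsplit("PGSTNQEDKR", "")[[1]]
TAIL_POOL <- setdiff(LINKER_POOL, "Y")      # tails: hydrophilic, no Y, no C
TM_POOL <- strsplit("LLLIIVVFA", "")[[1]]   # hydrophobic, Leu-rich

#' Configuration for the synthetic receptor-family generator
#'
#' Defaults emulate the divergence structure seen between and within SRCR
#' domain classes in multi-domain receptors: domain copies of one letter
#' class sit ~0.10 p-distance from their class prototype (published
#' intra-class diagonals run ~0.09-0.23) while prototypes of different
#' letters sit ~0.55 apart (inter-class values run ~0.45-0.82).  The three
#' default architectures are the bovine WC1, CD163A and CD163c-alpha domain
#' organizations.
#'
#' @param seed mandatory integer seed; the generator is a pure function of
#'   the config.
#' @param letters nomenclature letters available to architectures.
#' @param core_length domain length in residues (no indels are simulated
#'   inside domains; linkers between domains play that role).
#' @param prototype_divergence target expected pairwise p-distance between
#'   letter prototypes, in `[0, 1)`.
#' @param within_letter_rate expected p-distance of a domain copy from its
#'   letter prototype.
#' @param architectures named list of architecture strings.
#' @param n_copies receptors generated per architecture.
#' @param linker_length_range min/max inter-domain linker length.
#' @param tm include a 21-residue hydrophobic transmembrane segment?
#' @param tail_motif `"wc1_like"` (embeds YEEL), `"yrem"` (embeds YREM) or
#'   `"none"`.
#' @param cys_dropout probability that a domain loses one random
#'   non-anchor cysteine (ordinals 2..7; the flanking C1/C8 anchors are
#'   kept).
#' @return A `family_config` list.
#' @export
family_config <- function(seed,
                          letters = c("a", "b", "c", "d", "d'", "e", "h",
                                      "i", "j", "k", "l", "m", "n"),
                          core_length = 78L,
                          prototype_divergence = 0.55,
                          within_letter_rate = 0.10,
                          architectures = list(
                            BtWC1 = "a-b-c-d-e-d-b-c-d-e-d'",
                            BtCD163A = "h-i-j-k-b-c-d-e-d'",
                            BtCD163c = "m-l-b-c-n-d-e-d'"),
                          n_copies = 4L,
                          linker_length_range = c(8L, 15L),
                          tm = TRUE,
                          tail_motif = c("wc1_like", "yrem", "none"),
                          cys_dropout = 0) {
  if (missing(seed)) stop("family_config requires a seed")
  tail_motif <- match.arg(tail_motif)
  stopifnot(prototype_divergence >= 0, prototype_divergence < 1,
            within_letter_rate >= 0, within_letter_rate < 1,
            cys_dropout >= 0, cys_dropout <= 1,
            core_length >= 20L, n_copies >= 1L)
  used <- unique(unlist(lapply(architectures, parse_architecture)))
  extra <- setdiff(used, letters)
  if (length(extra))
    stop("architecture letter(s) not in the declared alphabet: ",
         paste(extra, collapse = ", "))
  structure(list(seed = as.integer(seed), letters = letters,
                 core_length = as.integer(core_length),
                 prototype_divergence = prototype_divergence,
                 within_letter_rate = within_letter_rate,
                 architectures = architectures,
                 n_copies = as.integer(n_copies),
                 linker_length_range = as.integer(linker_length_range),
                 tm = isTRUE(tm), tail_motif = tail_motif,
                 cys_dropout = cys_dropout),
            class = "family_config")
}

# scaffold cysteine columns at fixed relative positions; the spacing admits
# the group-B disulfide pairing (1,4),(2,7),(3,8),(5,6)
scaffold_cys_columns <- function(L) {
  cols <- unique(pmin(L, pmax(1L, round(L * c(0.06, 0.20, 0.31, 0.47,
                                              0.63, 0.71, 0.83, 0.95)))))
  stopifnot(length(cols) == 8L, all(diff(cols) > 0))
  as.integer(cols)
}

#' Letter prototype domains
#'
#' Prototypes share the 8-cysteine scaffold and a set of conserved
#' background columns; a fixed fraction of "variable" columns is drawn
#' independently per letter, sized so the expected pairwise prototype
#' p-distance hits `prototype_divergence` (two independent uniform draws
#' over 19 residues differ with probability 18/19, so `n_var =
#' divergence * L * 19/18` variable columns are used).  Prototype sets are
#' redrawn (deterministically, up to 25 attempts) until every realized
#' pairwise distance is within 0.08 of the target; at divergence 0 the
#' prototypes are identical except for a forced distinct tag residue at
#' the first non-cysteine column.
#'
#' @param config a [family_config()].
#' @return Named character vector of prototypes (one per letter), with
#'   attributes `cys_columns` and `variable_columns`.
#' @export
make_prototypes <- function(config) {
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  L <- config$core_length
  cys <- scaffold_cys_columns(L)
  noncys <- setdiff(seq_len(L), cys)
  target <- config$prototype_divergence
  n_var <- round(target * L / (18 / 19))
  if (n_var > length(noncys)) {
    warning("prototype divergence ", target, " unsatisfiable at L = ", L,
            "; realized divergence will be ~",
            round(length(noncys) * (18 / 19) / L, 3))
    n_var <- length(noncys)
  }
  nl <- length(config$letters)
  for (attempt in seq_len(25L)) {
    ancestor <- character(L)
    ancestor[cys] <- "C"
    ancestor[noncys] <- sample(AA_NC, length(noncys), replace = TRUE)
    var_cols <- if (n_var > 0) sort(sample(noncys, n_var)) else integer()
    protos <- vapply(seq_len(nl), function(i) {
      s <- ancestor
      if (length(var_cols))
        s[var_cols] <- sample(AA_NC, length(var_cols), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    names(protos) <- config$letters
    if (target == 0 && nl > 1L) {
      tag <- noncys[1]
      for (i in seq_len(nl))
        substr(protos[i], tag, tag) <- AA_NC[((i - 1L) %% 19L) + 1L]
    }
    if (nl < 2L) break
    d <- realized_pairwise(protos)
    if (target == 0 || all(abs(d - target) <= 0.08)) break
    if (attempt == 25L)
      warning("prototype divergences off target after 25 draws; realized ",
              "range [", round(min(d), 3), ", ", round(max(d), 3), "]")
  }
  structure(protos, cys_columns = cys, variable_columns = var_cols)
}

realized_pairwise <- function(protos) {
  n <- length(protos)
  chars <- strsplit(protos, "")
  d <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    d <- c(d, mean(chars[[i]] != chars[[j]]))
  d
}

#' Evolve a domain copy from its prototype
#'
#' Each non-cysteine column substitutes independently with probability
#' `rate`; a substitution draws uniformly from the 18 non-cysteine residues
#' different from the current one, so every fired substitution changes the
#' column and the expected p-distance of the copy from its prototype is
#' exactly `rate * (1 - 8 / nchar(prototype))` (cysteine columns never
#' change unless dropout fires).  With probability `cys_dropout` one
#' non-anchor cysteine (ordinal 2..7, chosen uniformly) is replaced by
#' serine; the dropped ordinal is recorded in the `dropped_cys` attribute.
#'
#' @param prototype prototype sequence (from [make_prototypes()]).
#' @param rate per-column substitution probability in `[0, 1)`.
#' @param seed optional integer seed; when omitted the current RNG stream
#'   is used (callers such as [generate_family()] seed once globally).
#' @param preserve_cys keep scaffold cysteines fixed (dropout aside)?
#' @param cys_dropout probability of losing one non-anchor cysteine.
#' @param cys_columns cysteine column positions (defaults to the
#'   prototype's `cys_columns` attribute or the standard scaffold).
#' @return The evolved sequence, with attribute `dropped_cys` (integer
#'   ordinal, or `NA` when no dropout fired).
#' @export
evolve_domain <- function(prototype, rate, seed = NULL, preserve_cys = TRUE,
                          cys_dropout = 0, cys_columns = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  s <- strsplit(prototype, "")[[1]]
  L <- length(s)
  if (is.null(cys_columns))
    cys_columns <- attr(prototype, "cys_columns")
  if (is.null(cys_columns)) cys_columns <- scaffold_cys_columns(L)
  mutable <- if (preserve_cys) setdiff(seq_len(L), cys_columns)
  else seq_len(L)
  fire <- mutable[runif(length(mutable)) < rate]
  for (i in fire) {
    choices <- setdiff(AA_NC, s[i])
    s[i] <- choices[sample.int(length(choices), 1L)]
  }
  dropped <- NA_integer_
  if (cys_dropout > 0 && runif(1) < cys_dropout) {
    dropped <- sample(2:7, 1L)
    s[cys_columns[dropped]] <- "S"
  }
  structure(paste(s, collapse = ""), dropped_cys = dropped)
}

#' Generate a synthetic receptor family with full ground truth
#'
#' For each architecture x copy, assembles a receptor: a short leader,
#' evolved domain copies separated by random hydrophilic linkers, then
#' (optionally) a 21-residue hydrophobic transmembrane segment and a
#' cytoplasmic tail carrying the configured tyrosine motif.  Everything is
#' a pure function of the config seed.  Domain copies evolve independently
#' from their letter prototype (a "star" genealogy within each letter), so
#' the truth tree is the star-of-stars: one multifurcating clade per
#' letter.  For benchmarking tree reconstruction on a fully resolved
#' genealogy use [generate_domain_genealogy()].
#'
#' @param config a [family_config()].
#' @return A `synthetic_family`: list with `records` (protein records),
#'   `truth_domains` (annotation table with true letters and coordinates),
#'   `truth_alignment` (gap-free alignment of all domain copies, labelled
#'   `"<protein>|<index>"`), `truth_letters` (named letter per leaf),
#'   `truth_tree` (`phylo`), `truth_motifs`, `truth_architectures`,
#'   `prototypes`, and the `config`.
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  protos <- make_prototypes(config)
  old <- local_seed(pair_seed(config$seed, 7L, 11L))
  on.exit(restore_seed(old))
  cys <- attr(protos, "cys_columns")
  L <- config$core_length
  lr <- config$linker_length_range

  records <- list()
  dom_rows <- list()
  dom_seqs <- character()
  dom_letters <- character()
  motif_rows <- list()
  archs <- character()
  for (an in names(config$architectures)) {
    arch_letters <- parse_architecture(config$architectures[[an]])
    for (cp in seq_len(config$n_copies)) {
      pid <- paste0(an, "_c", cp)
      seq_parts <- paste0("M", paste(sample(LINKER_POOL, 9L, replace = TRUE),
                                     collapse = ""))
      pos <- nchar(seq_parts)
      for (k in seq_along(arch_letters)) {
        let <- arch_letters[k]
        dom <- evolve_domain(protos[[let]], config$within_letter_rate,
                             cys_dropout = config$cys_dropout,
                             cys_columns = cys)
        start <- pos + 1L
        end <- pos + L
        dropped <- attr(dom, "dropped_cys")
        dom_rows[[length(dom_rows) + 1L]] <- data.frame(
          protein_id = pid, domain_index = k, start = start, end = end,
          score = NA_real_, letter = let,
          missing_cysteines = if (is.na(dropped)) "" else
            as.character(dropped),
          stringsAsFactors = FALSE)
        dom_seqs <- c(dom_seqs, as.character(dom))
        dom_letters <- c(dom_letters, let)
        names(dom_seqs)[length(dom_seqs)] <- paste0(pid, "|", k)
        seq_parts <- paste0(seq_parts, dom)
        pos <- end
        if (k < length(arch_letters)) {
          linker <- paste(sample(LINKER_POOL, sample(lr[1]:lr[2], 1L),
                                 replace = TRUE), collapse = "")
          seq_parts <- paste0(seq_parts, linker)
          pos <- pos + nchar(linker)
        }
      }
      if (config$tm) {
        stalk <- paste(sample(LINKER_POOL, 6L, replace = TRUE),
                       collapse = "")
        tm_seg <- paste(sample(TM_POOL, 21L, replace = TRUE),
                        collapse = "")
        tail_bg <- sample(TAIL_POOL, 35L, replace = TRUE)
        motif <- switch(config$tail_motif, wc1_like = "YEEL",
                        yrem = "YREM", none = NULL)
        tail <- paste(tail_bg, collapse = "")
        seq_parts <- paste0(seq_parts, stalk, "RK", tm_seg, "KR")
        tail_at <- 10L
        if (!is.null(motif)) {
          tail <- paste0(substr(tail, 1L, tail_at - 1L), motif,
                         substr(tail, tail_at, nchar(tail)))
          motif_rows[[length(motif_rows) + 1L]] <- data.frame(
            protein_id = pid,
            position = nchar(seq_parts) + tail_at,
            tetramer = motif, stringsAsFactors = FALSE)
        }
        seq_parts <- paste0(seq_parts, tail)
      }
      records[[length(records) + 1L]] <-
        protein_record(pid, seq_parts, species = "synthetic",
                       description = paste("synthetic", an, "copy", cp))
      archs[pid] <- config$architectures[[an]]
    }
  }
  truth_domains <- do.call(rbind, dom_rows)
  validate_annotations(truth_domains, records)
  truth_alignment <- new_alignment(names(dom_seqs), unname(dom_seqs))
  names(dom_letters) <- names(dom_seqs)
  truth_tree <- star_of_stars_tree(dom_letters,
                                   config$prototype_divergence,
                                   config$within_letter_rate)
  truth_motifs <- if (length(motif_rows)) do.call(rbind, motif_rows)
  else data.frame(protein_id = character(), position = integer(),
                  tetramer = character(), stringsAsFactors = FALSE)
  structure(list(records = records, truth_domains = truth_domains,
                 truth_alignment = truth_alignment,
                 truth_letters = dom_letters,
                 truth_tree = truth_tree, truth_motifs = truth_motifs,
                 truth_architectures = archs,
                 prototypes = protos, config = config),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family> %d proteins, %d domains, seed %d\n",
              length(x$records), nrow(x$truth_domains), x$config$seed))
  invisible(x)
}

# multifurcating truth genealogy: root -> one clade per letter -> copies
star_of_stars_tree <- function(letters_by_leaf, divergence, rate) {
  lets <- unique(letters_by_leaf)
  q <- function(x) paste0("'", x, "'")   # quote: d' contains an apostrophe
  parts <- vapply(lets, function(l) {
    lv <- names(letters_by_leaf)[letters_by_leaf == l]
    if (length(lv) == 1L) sprintf("%s:%g", q(lv), rate + divergence / 2)
    else sprintf("(%s):%g",
                 paste(sprintf("%s:%g", q(lv), rate), collapse = ","),
                 divergence / 2)
  }, character(1))
  ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
}

#' Reference alignment from letter prototypes
#'
#' Builds a labelled reference set for model building and clade-based
#' nomenclature: `per_letter` evolved copies of each prototype, labelled
#' `"REF<copy>|<letter_index>|<letter>"`.  Gap-free (prototypes have a
#' common coordinate system), so it is a valid domain alignment as-is.
#'
#' @param prototypes result of [make_prototypes()].
#' @param per_letter reference copies per letter.
#' @param rate divergence of reference copies from the prototype.
#' @param seed integer seed.
#' @return A [new_alignment()] with letters encoded in the labels.
#' @export
synthetic_reference <- function(prototypes, per_letter = 2L, rate = 0.05,
                                seed = 1L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cys <- attr(prototypes, "cys_columns")
  labels <- character(); seqs <- character()
  for (li in seq_along(prototypes)) {
    for (cp in seq_len(per_letter)) {
      labels <- c(labels, sprintf("REF%d|%d|%s", cp, li,
                                  names(prototypes)[li]))
      seqs <- c(seqs, as.character(
        evolve_domain(prototypes[[li]], rate, cys_columns = cys)))
    }
  }
  new_alignment(labels, seqs)
}

#' Resolved domain genealogy with exactly additive distances
#'
#' Generates a random rooted binary genealogy over `n` domain copies and
#' evolves a domain along it in infinite-sites fashion: every edge receives
#' at least one substitution, and every substituted column is used by
#' exactly one edge, so the matrix of pairwise p-distances is exactly
#' additive on the genealogy and neighbor joining provably recovers the
#' topology and branch lengths.  Intended for benchmarking tree
#' reconstruction at low divergence; errors if the substitution budget
#' exceeds the number of mutable columns.
#'
#' @param n number of leaves (>= 4).
#' @param subs_per_edge expected substitutions per edge (Poisson).
#' @param min_subs_per_edge floor on per-edge substitutions; raise it when
#'   downstream analyses need strong per-edge signal (e.g. bootstrap
#'   support studies).
#' @param core_length domain length.
#' @param seed integer seed.
#' @return List with `alignment` (gap-free, leaves `t1..tn`), `tree` (the
#'   truth `phylo`, edge lengths in substitutions per site).
#' @export
generate_domain_genealogy <- function(n, subs_per_edge = 2,
                                      min_subs_per_edge = 1L,
                                      core_length = 78L, seed = 1L) {
  stopifnot(n >= 4L, min_subs_per_edge >= 1L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  L <- core_length
  cys <- scaffold_cys_columns(L)
  noncys <- setdiff(seq_len(L), cys)
  tree <- ape::rtree(n, rooted = TRUE, br = NULL)
  ne <- nrow(tree$edge)
  m_e <- pmax(as.integer(min_subs_per_edge),
              stats::rpois(ne, subs_per_edge))
  if (sum(m_e) > length(noncys))
    stop("substitution budget ", sum(m_e), " exceeds the ",
         length(noncys), " mutable columns; lower n or subs_per_edge")
  cols <- sample(noncys, sum(m_e))
  edge_cols <- split(cols, rep(seq_len(ne), m_e))

  root <- n + 1L
  anc <- character(L)
  anc[cys] <- "C"
  anc[noncys] <- sample(AA_NC, length(noncys), replace = TRUE)
  seqs_by_node <- list()
  seqs_by_node[[root]] <- anc
  # ape's cladewise edge order is a preorder: parents precede children
  for (e in seq_len(ne)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- seqs_by_node[[parent]]
    for (col in edge_cols[[e]]) {
      choices <- setdiff(AA_NC, s[col])
      s[col] <- choices[sample.int(length(choices), 1L)]
    }
    seqs_by_node[[child]] <- s
  }
  leaves <- vapply(seq_len(n), function(i)
    paste(seqs_by_node[[i]], collapse = ""), character(1))
  tree$edge.length <- m_e / L
  list(alignment = new_alignment(tree$tip.label, leaves), tree = tree)
}

#' Synthetic stand-ins for the bovine CD163A and CD163c-alpha receptors
#'
#' Constructs two synthetic receptors realizing the published *description*
#' of the bovine proteins -- CD163A with nine SRCR domains in the
#' arrangement `h-i-j-k-b-c-d-e-d'` whose 8th domain lacks cysteines 2 and
#' 7, and a YREM tail motif; CD163c-alpha with eight domains
#' `m-l-b-c-n-d-e-d'` whose 5th domain lacks cysteines 2 and 7, and a YEDI
#' tail motif.  The sequences themselves are simulated (the real ones are
#' not bundled); they are stand-ins for exercising the pipeline, not the
#' biological sequences.
#'
#' @param seed integer seed.
#' @return List with `records` (2 protein records `synBtCD163A`,
#'   `synBtCD163c`), `truth_domains`, `prototypes`, and `reference` (a
#'   labelled reference alignment for the full letter alphabet).
#' @export
synthetic_cd163_standins <- function(seed = 163L) {
  cfg <- family_config(seed = seed)
  protos <- make_prototypes(cfg)
  old <- local_seed(pair_seed(seed, 2L, 3L))
  on.exit(restore_seed(old))
  cys <- attr(protos, "cys_columns")
  L <- cfg$core_length

  build <- function(pid, arch, atypical_index, tail_motif) {
    lets <- parse_architecture(arch)
    seq <- paste0("M", paste(sample(LINKER_POOL, 9L, replace = TRUE),
                             collapse = ""))
    rows <- list()
    for (k in seq_along(lets)) {
      dom <- as.character(evolve_domain(protos[[lets[k]]],
                                        cfg$within_letter_rate,
                                        cys_columns = cys))
      miss <- ""
      if (k == atypical_index) {
        # the atypical domain lacks the second and seventh cysteines,
        # i.e. one whole disulfide pair
        s <- strsplit(dom, "")[[1]]
        s[cys[c(2L, 7L)]] <- "S"
        dom <- paste(s, collapse = "")
        miss <- "2,7"
      }
      rows[[k]] <- data.frame(protein_id = pid, domain_index = k,
                              start = nchar(seq) + 1L,
                              end = nchar(seq) + L, score = NA_real_,
                              letter = lets[k], missing_cysteines = miss,
                              stringsAsFactors = FALSE)
      seq <- paste0(seq, dom)
      if (k < length(lets))
        seq <- paste0(seq, paste(sample(LINKER_POOL, 10L, replace = TRUE),
                                 collapse = ""))
    }
    tail <- paste(sample(TAIL_POOL, 30L, replace = TRUE), collapse = "")
    tail <- paste0(substr(tail, 1, 9), tail_motif, substr(tail, 10, 30))
    seq <- paste0(seq, paste(sample(LINKER_POOL, 6L, replace = TRUE),
                             collapse = ""),
                  "RK", paste(sample(TM_POOL, 21L, replace = TRUE),
                              collapse = ""), "KR", tail)
    list(record = protein_record(pid, seq, species = "synthetic",
                                 description = "synthetic stand-in"),
         rows = do.call(rbind, rows))
  }
  a <- build("synBtCD163A", "h-i-j-k-b-c-d-e-d'", 8L, "YREM")
  b <- build("synBtCD163c", "m-l-b-c-n-d-e-d'", 5L, "YEDI")
  truth <- rbind(a$rows, b$rows)
  validate_annotations(truth, list(a$record, b$record))
  list(records = list(a$record, b$record), truth_domains = truth,
       prototypes = protos,
       reference = synthetic_reference(protos, seed = pair_seed(seed, 5L, 9L)))
}
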