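test_that("the generator is a pure function of its seed", {
  f1 <- generate_family(family_config(seed = 17))
  f2 <- generate_family(family_config(seed = 17))
  expect_identical(lapply(f1$records, `[[`, "sequence"),
                   lapply(f2$records, `[[`, "sequence"))
  expect_identical(f1$truth_domains, f2$truth_domains)
  f3 <- generate_family(family_config(seed = 18))
  expect_false(identical(f1$records[[1]]$sequence,
                         f3$records[[1]]$sequence))
})

test_that("architectures drive the truth tables", {
  cfg <- family_config(seed = 5,
                       architectures = list(C = "m-l-b-c-n-d-e-d'"),
                       n_copies = 1L)
  fam <- generate_family(cfg)
  tr <- fam$truth_domains
  expect_equal(nrow(tr), 8)
  expect_equal(tr$letter, c("m", "l", "b", "c", "n", "d", "e", "d'"))
  expect_equal(tr$domain_index, 1:8)
  expect_true(all(diff(tr$start) > 0))
  validate_annotations(tr, fam$records)
})

test_that("prototype divergences land near the configured target", {
  cfg <- family_config(seed = 7)
  protos <- make_prototypes(cfg)
  d <- srcrtools:::realized_pairwise(protos)
  expect_true(all(abs(d - cfg$prototype_divergence) <= 0.08))

  # cysteine scaffold identical across prototypes
  cys <- attr(protos, "cys_columns")
  for (p in protos)
    expect_equal(strsplit(p, "")[[1]][cys], rep("C", 8))

  # divergence 0: identical up to the forced tag column
  protos0 <- make_prototypes(family_config(seed = 7,
                                           prototype_divergence = 0))
  tag <- setdiff(seq_len(nchar(protos0[1])), cys)[1]
  stripped <- vapply(protos0, function(p)
    paste0(substr(p, 1, tag - 1), substr(p, tag + 1, nchar(p))),
    character(1))
  expect_equal(length(unique(stripped)), 1)
  expect_equal(length(unique(substr(protos0, tag, tag))),
               length(protos0))
})

test_that("domain evolution has the documented expected divergence", {
  cfg <- family_config(seed = 9)
  protos <- make_prototypes(cfg)
  cys <- attr(protos, "cys_columns")
  p0 <- protos[["a"]]
  expect_equal(as.character(evolve_domain(p0, 0, seed = 1,
                                          cys_columns = cys)), p0)

  rate <- 0.10
  L <- nchar(p0)
  n_rep <- 400
  ps <- vapply(seq_len(n_rep), function(i) {
    e <- evolve_domain(p0, rate, seed = 1000 + i, cys_columns = cys)
    mean(strsplit(as.character(e), "")[[1]] != strsplit(p0, "")[[1]])
  }, numeric(1))
  expected <- rate * (1 - 8 / L)
  se <- sd(ps) / sqrt(n_rep)
  expect_lt(abs(mean(ps) - expected), 3 * se + 1e-6)

  # forced dropout removes exactly one non-anchor cysteine
  e <- evolve_domain(p0, 0, seed = 3, cys_dropout = 1, cys_columns = cys)
  expect_true(attr(e, "dropped_cys") %in% 2:7)
  chars <- strsplit(as.character(e), "")[[1]]
  expect_equal(sum(chars[cys] == "C"), 7)
})

test_that("generated tails carry the configured motif and the scanner finds it", {
  fam <- small_family()
  expect_equal(nrow(fam$truth_motifs), length(fam$records))
  for (i in seq_len(nrow(fam$truth_motifs))) {
    pid <- fam$truth_motifs$protein_id[i]
    rec <- Filter(function(r) r$id == pid, fam$records)[[1]]
    hits <- scan_wc1_motif(rec)
    expect_true(fam$truth_motifs$position[i] %in%
                  hits$position[hits$pattern_id == "wc1_like"])
  }

  none <- generate_family(family_config(seed = 6, tail_motif = "none",
                                        n_copies = 1L,
                                        architectures = list(A = "a-b")))
  expect_equal(nrow(none$truth_motifs), 0)
})

test_that("truth invariants hold across random configurations", {
  set.seed(51)
  for (k in 1:8) {
    cfg <- family_config(
      seed = sample.int(1e6, 1),
      prototype_divergence = runif(1, 0.35, 0.6),
      within_letter_rate = runif(1, 0.03, 0.18),
      architectures = list(A = "a-b-c-d'", B = "m-b-e-d'"),
      n_copies = sample(1:2, 1),
      cys_dropout = sample(c(0, 0.3), 1))
    fam <- suppressWarnings(generate_family(cfg))
    validate_annotations(fam$truth_domains, fam$records)
    # domain sequences in the records match the truth alignment rows
    m <- setNames(fam$truth_alignment$seqs, fam$truth_alignment$labels)
    for (r in seq_len(nrow(fam$truth_domains))) {
      row <- fam$truth_domains[r, ]
      rec <- Filter(function(x) x$id == row$protein_id, fam$records)[[1]]
      expect_equal(substr(rec$sequence, row$start, row$end),
                   unname(m[paste0(row$protein_id, "|", row$domain_index)]))
    }
    expect_setequal(unique(fam$truth_domains$letter),
                    unique(unlist(lapply(cfg$architectures,
                                         parse_architecture))))
  }
})

test_that("the additive genealogy generator enforces its budget", {
  expect_error(generate_domain_genealogy(n = 30, subs_per_edge = 10,
                                         seed = 1),
               "budget")
  g <- generate_domain_genealogy(n = 6, subs_per_edge = 2, seed = 2)
  expect_equal(length(g$alignment$labels), 6)
  # distances are exactly additive on the truth tree
  D <- distance_matrix(g$alignment)$values
  pd <- ape::cophenetic.phylo(g$tree)[rownames(D), colnames(D)]
  expect_lt(max(abs(D - pd)), 1e-12)
})

test_that("synthetic receptor stand-ins realize the described organization", {
  st <- synthetic_cd163_standins(seed = 163)
  expect_equal(vapply(st$records, `[[`, character(1), "id"),
               c("synBtCD163A", "synBtCD163c"))
  a <- st$truth_domains[st$truth_domains$protein_id == "synBtCD163A", ]
  b <- st$truth_domains[st$truth_domains$protein_id == "synBtCD163c", ]
  expect_equal(nrow(a), 9)
  expect_equal(nrow(b), 8)
  expect_equal(a$letter, c("h", "i", "j", "k", "b", "c", "d", "e", "d'"))
  expect_equal(b$letter, c("m", "l", "b", "c", "n", "d", "e", "d'"))
  expect_equal(a$missing_cysteines, c(rep("", 7), "2,7", ""))
  expect_equal(b$missing_cysteines, c(rep("", 4), "2,7", rep("", 3)))
  # tails carry the described tyrosine motifs
  expect_gt(nrow(find_literal_motifs(st$records[[1]], "YREM")), 0)
  expect_gt(nrow(find_literal_motifs(st$records[[2]], "YEDI")), 0)
})
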