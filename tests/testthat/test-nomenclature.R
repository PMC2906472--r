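ref_map <- function(...) {
  v <- c(...)
  setNames(unname(v), names(v))
}

test_that("a query sister to a single reference takes its letter", {
  tr <- ape::read.tree(text = "((q1:1,refm:1)1.0:1,refb:2,refc:2);")
  asg <- assign_letters(tr, c(refm = "m", refb = "b", refc = "c"),
                        threshold = 0.7)
  expect_equal(asg$letter[asg$leaf == "q1"], "m")
  expect_equal(asg$method[asg$leaf == "q1"], "clade")
  expect_equal(asg$support[asg$leaf == "q1"], 1.0)
})

test_that("a supported reference-free clade of queries earns one new letter", {
  # the query pair is strongly supported but its link to the 'a' references
  # is not, and every supported clade joining the queries to references
  # mixes letters: the pair clusters apart from designated domains
  tr <- ape::read.tree(
    text = "(((q1:1,q2:1)0.95:1,(refa1:1,refa2:1)0.9:1)0.6:1,refb:2,refc:2);")
  asg <- assign_letters(tr, c(refa1 = "a", refa2 = "a", refb = "b",
                              refc = "c"), threshold = 0.7)
  q <- asg[asg$leaf %in% c("q1", "q2"), ]
  expect_equal(unique(q$method), "new_letter")
  expect_equal(length(unique(q$letter)), 1)
  expect_equal(unique(q$letter), "o")     # first free letter after n
  expect_false(unique(q$letter) %in% c("a", "b", "c"))
})

test_that("two-leaf trees fall back to the whole-tree clade", {
  tr <- ape::read.tree(text = "(q1:1,refk:1);")
  asg <- assign_letters(tr, c(refk = "k"))
  expect_equal(asg$letter, "k")
  expect_equal(asg$method, "clade")
})

test_that("letter-mixed smallest clades leave the query undesignated", {
  tr <- ape::read.tree(text = "((q1:1,(refb:1,refc:1)0.9:1)0.95:1,refa:2,refe:2);")
  asg <- assign_letters(tr, c(refa = "a", refb = "b", refc = "c",
                              refe = "e"))
  expect_equal(asg$letter[asg$leaf == "q1"], "undesignated")
})

test_that("d/d' mixtures resolve by terminal position", {
  tr <- ape::read.tree(
    text = "((P|2:1,(refd:1,refdp:1)0.9:1)0.95:1,refa:2,refb:2);")
  refs <- c(refd = "d", refdp = "d'", refa = "a", refb = "b")
  # P|2 is an internal domain of a 3-domain protein -> d
  asg <- assign_letters(tr, refs, terminal_queries = character())
  expect_equal(asg$letter[asg$leaf == "P|2"], "d")
  # the same leaf marked C-terminal -> d'
  asg2 <- assign_letters(tr, refs, terminal_queries = "P|2")
  expect_equal(asg2$letter[asg2$leaf == "P|2"], "d'")
})

test_that("assignment rejects unknown reference letters and absent leaves", {
  tr <- ape::read.tree(text = "(q1:1,refz:1,refb:2);")
  expect_error(assign_letters(tr, c(refz = "z", refb = "b")), "alphabet")
  expect_error(assign_letters(tr, c(ghost = "a")), "absent")
})

test_that("assignment is invariant to query relabeling and leaf rotation", {
  g <- generate_domain_genealogy(n = 6, subs_per_edge = 4, seed = 31)
  fam <- small_family()
  model <- small_model(fam)
  ref <- synthetic_reference(fam$prototypes, per_letter = 2, seed = 33)
  refs <- setNames(srcrtools:::parse_ref_letters(ref$labels), ref$labels)
  # queries: fresh copies of two letters
  cys <- attr(fam$prototypes, "cys_columns")
  qs <- c(`X|1` = as.character(evolve_domain(fam$prototypes[["a"]], 0.08,
                                             seed = 41, cys_columns = cys)),
          `X|2` = as.character(evolve_domain(fam$prototypes[["b"]], 0.08,
                                             seed = 42, cys_columns = cys)))
  aln <- new_alignment(c(ref$labels, names(qs)),
                       c(ref$seqs, unname(qs)))
  tr <- bootstrap_tree(aln, B = 100, seed = 9)
  a1 <- assign_letters(tr, refs)
  expect_equal(a1$letter[a1$leaf == "X|1"], "a")
  expect_equal(a1$letter[a1$leaf == "X|2"], "b")
  # rotate the underlying matrix rows: same assignments
  perm <- rev(seq_along(aln$labels))
  tr2 <- bootstrap_tree(new_alignment(aln$labels[perm], aln$seqs[perm]),
                        B = 100, seed = 9)
  a2 <- assign_letters(tr2, refs)
  expect_equal(a2$letter[match(a1$leaf, a2$leaf)], a1$letter)
})

test_that("positional refinement promotes unique contexts only", {
  asg <- data.frame(protein_id = "P", domain_index = 1:5,
                    letter = c("b", "c", "undesignated", "e", "d'"),
                    method = c("clade", "clade", "undesignated", "clade",
                               "clade"),
                    stringsAsFactors = FALSE)
  out <- positional_refine(asg, list("b-c-d-e-d'"))
  expect_equal(out$letter[3], "d")
  expect_equal(out$method[3], "positional")

  # ambiguous context: two reference architectures disagree -> unchanged
  out2 <- positional_refine(asg, list("b-c-d-e-d'", "b-c-n-e-d'"))
  expect_equal(out2$letter[3], "undesignated")

  # fully assigned proteins are untouched, clade calls never overridden
  done <- asg; done$letter[3] <- "d"; done$method[3] <- "clade"
  out3 <- positional_refine(done, list("b-c-k-e-d'"))
  expect_equal(out3, done)
})

test_that("architecture strings render and parse canonically", {
  asg <- data.frame(protein_id = "BtCD163A",
                    domain_index = 1:9,
                    letter = c("h", "i", "j", "k", "b", "c", "d", "e", "d'"),
                    stringsAsFactors = FALSE)
  a <- architecture_string("BtCD163A", asg)
  expect_equal(as.character(a), "h-i-j-k-b-c-d-e-d'")
  expect_equal(parse_architecture(a),
               c("h", "i", "j", "k", "b", "c", "d", "e", "d'"))

  asg2 <- data.frame(protein_id = "BtCD163c",
                     domain_index = 1:8,
                     letter = c("m", "l", "b", "c", "n", "d", "e", "d'"),
                     stringsAsFactors = FALSE)
  expect_equal(as.character(architecture_string("BtCD163c", asg2)),
               "m-l-b-c-n-d-e-d'")

  one <- data.frame(protein_id = "p", domain_index = 1, letter = "a",
                    stringsAsFactors = FALSE)
  expect_equal(as.character(architecture_string("p", one)), "a")

  undes <- data.frame(protein_id = "q", domain_index = 1:2,
                      letter = c("a", "undesignated"),
                      stringsAsFactors = FALSE)
  expect_equal(as.character(architecture_string("q", undes)), "a-x")

  gap <- data.frame(protein_id = "r", domain_index = c(1, 3),
                    letter = c("a", "b"), stringsAsFactors = FALSE)
  expect_error(architecture_string("r", gap), "gap")
})

test_that("family classification follows the diagnostic-letter precedence", {
  expect_equal(classify_family("h-i-j-k-b-c-d-e-d'"), "CD163A_like")
  expect_equal(classify_family("a-x-c-n-d-e-d'"), "hybrid")
  expect_equal(classify_family("a-b-c-d-e-d-b-c-d-e-d'"), "WC1_like")
  expect_equal(classify_family("m-l-b-c-n-d-e-d'"), "CD163c_alpha_like")
  expect_equal(classify_family("b-c-d"), "unclassified")
  # k beats everything, hybrid beats plain a
  expect_equal(classify_family("a-k-n"), "CD163A_like")
  expect_equal(classify_family("a-c-a-b-c-x-e-d'"), "WC1_like")
})
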