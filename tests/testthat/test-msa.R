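test_that("identical sequences align gap-free at 100% identity", {
  r <- pairwise_global_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(r$percent_identity, 100)
  expect_false(any(grepl("-", r$alignment$seqs)))
})

test_that("a single deletion costs one gap open plus one extension", {
  p <- align_params()
  r <- pairwise_global_align("ACDE", "ACE")
  expect_equal(sum(strsplit(r$alignment$seqs[2], "")[[1]] == "-"), 1)
  m <- p$matrix
  expected <- m["A", "A"] + m["C", "C"] + m["E", "E"] -
    (p$gap_open + p$gap_extend)
  expect_equal(r$score, expected)
})

test_that("pairwise scores equal exhaustive enumeration on tiny inputs", {
  p <- align_params()
  set.seed(31)
  for (i in 1:12) {
    a <- random_aa_string(sample(3:7, 1))
    b <- random_aa_string(sample(3:7, 1))
    got <- pairwise_global_align(a, b, p)$score
    want <- enumerate_align_score(a, b, p$matrix, p$gap_open, p$gap_extend)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric and rows always ungap to inputs", {
  set.seed(32)
  for (i in 1:8) {
    a <- random_aa_string(sample(10:40, 1), alphabet = AA_TEST)
    b <- random_aa_string(sample(10:40, 1), alphabet = AA_TEST)
    ra <- pairwise_global_align(a, b)
    rb <- pairwise_global_align(b, a)
    expect_equal(ra$score, rb$score)
    expect_equal(gsub("-", "", ra$alignment$seqs[1]), a)
    expect_equal(gsub("-", "", ra$alignment$seqs[2]), b)
  }
})

test_that("guide trees join the obvious pairs first", {
  t2 <- build_guide_tree(c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKV"))
  expect_equal(sort(t2$tip.label), c("s1", "s2"))

  t3 <- build_guide_tree(c(x = "ACDEFGHIKL", y = "ACDEFGHIKL",
                           z = "KLKLKLKLKL"))
  # the identical pair must be a cherry
  pairs <- ape::prop.part(t3)
  cherry <- Filter(function(p) length(p) == 2, pairs)
  has_xy <- any(vapply(cherry, function(p)
    setequal(attr(pairs, "labels")[p], c("x", "y")), logical(1)))
  expect_true(has_xy || ape::is.monophyletic(t3, c("x", "y")))
})

test_that("progressive alignment of identical sequences is gap-free", {
  aln <- progressive_align(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                             c = "ACDEFGHIKL"))
  expect_false(any(grepl("-", aln$seqs)))
  expect_equal(aln$ncol, 10)
})

test_that("aligning same-letter generator domains recovers true homology", {
  fam <- small_family()
  cys <- attr(fam$prototypes, "cys_columns")
  doms <- vapply(1:8, function(i)
    as.character(evolve_domain(fam$prototypes[["b"]], 0.10, seed = 100 + i,
                               cys_columns = cys)), character(1))
  names(doms) <- paste0("d", 1:8)
  aln <- progressive_align(doms)
  # no indels were simulated: true homology columns are the identity map,
  # recovered iff the alignment stays at the domain length
  expect_equal(aln$ncol, fam$config$core_length)
  expect_equal(gsub("-", "", aln$seqs), unname(doms))
})

test_that("duplicating a row leaves other rows' pairwise identities unchanged", {
  seqs <- c(a = "MKVLACDEFGHIKL", b = "MKVLACDEFGHIKV", c = "MKVGACDEFGHAKL")
  base <- progressive_align(seqs)
  dup <- progressive_align(c(seqs, d = unname(seqs["c"])))
  pid <- function(aln, i, j) {
    a <- strsplit(aln$seqs[i], "")[[1]]; b <- strsplit(aln$seqs[j], "")[[1]]
    both <- a != "-" & b != "-"
    100 * sum(a[both] == b[both]) / sum(both)
  }
  expect_equal(pid(dup, 1, 2), pid(base, 1, 2))
  expect_equal(pid(dup, 1, 3), pid(base, 1, 3))
})

test_that("trim_to_core projects onto exactly the model's core columns", {
  fam <- small_family()
  model <- small_model(fam)
  L <- model$core_length
  # an alignment equal to the reference core is unchanged
  ref_aln <- new_alignment(model$ref$labels, model$ref$seqs)
  expect_equal(trim_to_core(ref_aln, model)$seqs, ref_aln$seqs)

  # a 5-column insertion in a query is dropped by the projection
  ins_at <- 30
  gappy_ref <- paste0(substr(model$ref$seqs[1], 1, ins_at), "-----",
                      substr(model$ref$seqs[1], ins_at + 1, L))
  query <- paste0(substr(model$ref$seqs[2], 1, ins_at), "WWWWW",
                  substr(model$ref$seqs[2], ins_at + 1, L))
  aln <- new_alignment(c(model$ref$labels[1], "query"),
                       c(gappy_ref, query))
  trimmed <- trim_to_core(aln, model)
  expect_equal(trimmed$ncol, L)
  expect_equal(trimmed$seqs[2], model$ref$seqs[2])
  expect_error(trim_to_core(new_alignment("q", strrep("A", L)), model),
               "no reference")
})

test_that("guide tree groups generator domains by letter class", {
  fam <- small_family()
  cys <- attr(fam$prototypes, "cys_columns")
  seqs <- list()
  for (l in c("a", "b", "e")) for (i in 1:3)
    seqs[[paste0(l, i)]] <-
      as.character(evolve_domain(fam$prototypes[[l]], 0.05,
                                 seed = 200 + 10 * match(l, letters) + i,
                                 cys_columns = cys))
  gt <- build_guide_tree(seqs)
  for (l in c("a", "b", "e"))
    expect_true(ape::is.monophyletic(gt, paste0(l, 1:3)))
})
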