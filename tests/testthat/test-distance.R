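test_that("p-distance counts differing columns over comparable columns", {
  expect_equal(p_distance("ACDE", "ACDE")$p, 0)

  # 78 columns differing at 14: the canonical 0.179 cell
  a <- strrep("A", 78)
  b <- paste0(strrep("V", 14), strrep("A", 64))
  pd <- p_distance(a, b)
  expect_equal(pd$p, 14 / 78)
  expect_equal(round(pd$p, 3), 0.179)
  expect_equal(pd$L_effective, 78)

  # gap and X columns drop out of the denominator
  expect_equal(p_distance("AC-E", "ACDE")$L_effective, 3)
  expect_equal(p_distance("ACXE", "ACDE")$L_effective, 3)
  expect_true(is.na(p_distance("----", "ACDE")$p))
})

test_that("analytic SE reproduces the printed-precision values", {
  expect_equal(analytic_se(0, 78), 0)
  expect_equal(round(analytic_se(0.115, 78), 3), 0.036)
  expect_equal(round(analytic_se(0.692, 78), 3), 0.052)
  expect_equal(round(analytic_se(14 / 78, 78), 3), 0.043)
})

test_that("bootstrap SE is seeded, reproducible and converges to the closed form", {
  a <- strrep("A", 78)
  expect_equal(bootstrap_se(a, a, B = 200, seed = 1), 0)

  b <- paste0(strrep("V", 14), strrep("A", 64))
  s1 <- bootstrap_se(a, b, B = 500, seed = 42)
  s2 <- bootstrap_se(a, b, B = 500, seed = 42)
  expect_identical(s1, s2)

  set.seed(77)
  for (k in 1:3) {
    nd <- sample(5:60, 1)
    x <- paste0(strrep("V", nd), strrep("A", 78 - nd))
    se <- bootstrap_se(a, x, B = 4000, seed = 7 + k)
    expect_equal(se, analytic_se(nd / 78, 78), tolerance = 0.05)
  }
})

test_that("distance corrections match their closed forms and an ML oracle", {
  expect_equal(correct_distance(0, "p"), 0)
  expect_equal(correct_distance(0, "poisson"), 0)
  expect_equal(correct_distance(0, "jtt_like"), 0)
  expect_equal(correct_distance(0.5, "poisson"), log(2))
  expect_equal(correct_distance(c(0.1, 0.3), "p"), c(0.1, 0.3))
  expect_warning(d <- correct_distance(1, "poisson"), "saturation")
  expect_true(is.infinite(d))

  # oracle: direct matrix-exponential inversion via Matrix::expm on a grid,
  # refined by optimize -- an independent route to the same quantity
  skip_if_not_installed("Matrix")
  jtt <- load_matrix("jtt")
  pi <- jtt$freq
  Q <- jtt$Q * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(pi * diag(Q))
  pfun <- function(d) {
    P <- as.matrix(Matrix::expm(Q * d))
    1 - sum(pi * diag(P))
  }
  set.seed(9)
  for (p in runif(5, 0.05, 0.7)) {
    want <- optimize(function(d) (pfun(d) - p)^2, c(0, 10),
                     tol = 1e-12)$minimum
    expect_equal(correct_distance(p, "jtt_like"), want, tolerance = 1e-4)
  }
})

test_that("distance matrices are symmetric with missing (not zero) undefined cells", {
  aln <- new_alignment(c("r1", "r2"),
                       c(strrep("A", 78),
                         paste0(strrep("V", 14), strrep("A", 64))))
  D <- distance_matrix(aln)
  expect_equal(D$values["r1", "r2"], 14 / 78)
  expect_equal(D$values, t(D$values))
  expect_equal(diag(D$values), c(r1 = 0, r2 = 0))

  D2 <- distance_matrix(aln, B = 200, seed = 3)
  expect_equal(D2$se, t(D2$se))
  expect_error(distance_matrix(aln, B = 200), "seed")

  # non-overlapping rows: undefined distance reported as missing
  aln3 <- new_alignment(c("u", "v", "w"),
                        c("AAAA----", "----VVVV", "AAAAVVVV"))
  D3 <- distance_matrix(aln3)
  expect_true(is.na(D3$values["u", "v"]))
  expect_false(any(is.na(c(D3$values["u", "w"], D3$values["v", "w"]))))
})

test_that("p-distance is a metric on gap-free rows", {
  set.seed(13)
  for (k in 1:25) {
    trip <- replicate(3, random_aa_string(30, AA_TEST))
    dxy <- p_distance(trip[1], trip[2])$p
    dxz <- p_distance(trip[1], trip[3])$p
    dyz <- p_distance(trip[2], trip[3])$p
    expect_lte(dxy, dxz + dyz + 1e-12)
    expect_gte(dxy, 0)
  }
  expect_equal(p_distance("ACDE", "ACDE")$p, 0)
})

test_that("recovered family distances sit within 2 analytic SEs of the truth", {
  fam <- small_family()
  model <- small_model(fam)
  # truth: direct p-distances on the true domain sequences (no indels)
  truthD <- distance_matrix(fam$truth_alignment)
  # measured: scan, excise, align with reference, trim, distance
  dom <- list()
  for (rec in fam$records) {
    hits <- scan_protein(rec, model)
    tr <- fam$truth_domains[fam$truth_domains$protein_id == rec$id, ]
    for (i in seq_len(nrow(hits))) {
      k <- which(abs(tr$start - hits$start[i]) <= 2)   # label by truth row
      if (length(k) != 1) next
      dom[[paste0(rec$id, "|", tr$domain_index[k])]] <-
        substr(rec$sequence, hits$start[i], hits$end[i])
    }
  }
  ref <- synthetic_reference(fam$prototypes, seed = 12L)
  aln <- progressive_align(c(setNames(as.list(gsub("-", "", ref$seqs)),
                                      ref$labels), dom))
  core <- trim_to_core(aln, model)
  D <- distance_matrix(core)
  shared <- intersect(truthD$labels, D$labels)
  expect_gte(length(shared), 0.95 * length(truthD$labels))
  L <- fam$config$core_length
  for (i in head(shared, 10)) for (j in tail(shared, 10)) {
    if (i == j) next
    tol <- 2 * analytic_se(max(truthD$values[i, j], 1 / L), L)
    expect_lte(abs(D$values[i, j] - truthD$values[i, j]), tol + 1e-9)
  }
})

test_that("distance tables render in the value-(se) layout", {
  aln <- new_alignment(c("r1", "r2", "r3"),
                       c(strrep("A", 78),
                         paste0(strrep("V", 14), strrep("A", 64)),
                         paste0(strrep("W", 9), strrep("A", 69))))
  D <- distance_matrix(aln, B = 200, seed = 5)
  lines <- render_distance_table(dist_block(D, "r1", c("r2", "r3")))
  expect_match(lines[2], "0.179")
  expect_match(lines[3], "^\\t\\(0\\.0")
  f <- tmp_path(".tsv")
  write_distance_matrix(D, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.tsv$", "_se.tsv", f)))
})
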