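test_that("site counts separate transitions from transversions", {
  sc <- site_counts("ACGT", "ACGT")
  expect_identical(c(sc$comparable, sc$transitions, sc$transversions),
                   c(4L, 0L, 0L))
  sc <- site_counts("AAAA", "GGGG")
  expect_identical(c(sc$comparable, sc$transitions, sc$transversions),
                   c(4L, 4L, 0L))
  # A->G ts; C=C; G->T tv; T->A tv
  sc <- site_counts("ACGT", "GCTA")
  expect_identical(c(sc$comparable, sc$transitions, sc$transversions),
                   c(4L, 1L, 2L))
  expect_error(site_counts("NNNN", "ACGT"), "zero comparable")
})

test_that("p-distance applies pairwise deletion", {
  expect_identical(p_distance("ACGT", "ACGT"), 0)
  expect_identical(p_distance("ACGA", "ACGT"), 0.25)
  expect_equal(p_distance("AC-A", "ACGT"), 1 / 3)
})

test_that("closed-form corrections match independent evaluation", {
  expect_identical(jc69(0), 0)
  expect_equal(jc69(0.25), -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-15)
  expect_equal(jc69(0.25), 0.30409883, tolerance = 1e-8)
  expect_error(jc69(0.75), "saturated")

  expect_identical(k2p(0, 0), 0)
  P <- 0.1; Q <- 0.05
  expect_equal(k2p(P, Q),
               -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
               tolerance = 1e-12)
  expect_error(k2p(0.5, 0), "saturated")

  expect_identical(tamura92(0, 0, 0.4, 0.6), 0)
  expect_error(tamura92(0.1, 0.05, 0, 0), "degenerate")
})

test_that("T92 reduces to K2P at theta = 0.5 and matches brute force", {
  for (P in c(0.02, 0.1, 0.2)) {
    for (Q in c(0.01, 0.05, 0.15)) {
      expect_equal(tamura92(P, Q, 0.5, 0.5), k2p(P, Q), tolerance = 1e-12)
    }
  }
  # toy pair with known counts, against the formula written out
  sc <- site_counts("AACGTT", "AACGCT")
  P <- sc$transitions / sc$comparable
  Q <- sc$transversions / sc$comparable
  theta <- (sc$gc_a + sc$gc_b) / 2
  h <- 2 * theta * (1 - theta)
  expect_equal(tamura92(P, Q, sc$gc_a, sc$gc_b),
               -h * log(1 - P / h - Q) - 0.5 * (1 - h) * log(1 - 2 * Q),
               tolerance = 1e-12)
})

test_that("gamma generalisation has the right limits", {
  expect_equal(jc69(0.25, alpha = 1e6), jc69(0.25), tolerance = 1e-6)
  expect_equal(k2p(0.1, 0.05, alpha = 1e6), k2p(0.1, 0.05), tolerance = 1e-6)
  expect_identical(jc69(0, alpha = 0.5), 0)
  # JC+G closed form at p = 0.25, alpha = 0.5
  expect_equal(jc69(0.25, alpha = 0.5),
               0.75 * 0.5 * ((1 - 4 * 0.25 / 3)^(-1 / 0.5) - 1),
               tolerance = 1e-12)
  expect_error(jc69(0.2, alpha = -1), "alpha")
})

test_that("correction inflates distances: jc69(p) >= p", {
  set.seed(5)
  p <- runif(50, 0, 0.7)
  expect_true(all(jc69(p) >= p))
})

test_that("distance_matrix satisfies its invariants and equals pairwise ops", {
  aln <- alignment(c(a = "ACGTACGTAC", b = "ACGAACGTAC", c = "GCGTACTTAC"))
  dm <- distance_matrix(aln, "jc69")
  expect_true(isSymmetric(unclass(dm)))
  expect_identical(unname(diag(dm)), c(0, 0, 0))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(dm[i, j],
                 jc69(p_distance(unclass(aln)[[i]], unclass(aln)[[j]])))
  }
  dm2 <- distance_matrix(alignment(c(x = "ACGT", y = "ACGT")), "p")
  expect_equal(unname(unclass(dm2)), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("distance_matrix is permutation-equivariant", {
  set.seed(9)
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  seqs <- vapply(1:5, function(i) {
    s <- base
    mut <- sample(60, 8)
    s[mut] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  dm <- distance_matrix(alignment(seqs), "k2p")
  perm <- c(3, 1, 5, 2, 4)
  dmp <- distance_matrix(alignment(seqs[perm]), "k2p")
  expect_equal(unclass(dmp), unclass(dm)[perm, perm], ignore_attr = TRUE)
})

test_that("distance_matrix agrees with ape::dist.dna", {
  set.seed(21)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  seqs <- vapply(1:6, function(i) {
    s <- base
    mut <- sample(200, 30)
    s[mut] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
    s[sample(200, 8)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:6)
  aln <- alignment(seqs)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  for (pair in list(c("p", "raw"), c("jc69", "JC69"), c("k2p", "K80"),
                    c("t92", "T92"))) {
    ours <- distance_matrix(aln, pair[1])
    ref <- as.matrix(ape::dist.dna(bin, model = pair[2],
                                   pairwise.deletion = TRUE))
    # T92 only: GC content conventions differ slightly under gaps (we use
    # the pairwise-deleted sites; ape uses each sequence's own sites)
    tol <- if (pair[1] == "t92") 1e-3 else 1e-10
    expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
                 tolerance = tol, ignore_attr = TRUE)
  }
})

test_that("saturated pairs fail loudly, naming the pair", {
  aln <- alignment(c(good = "AAAACCCC", bad = "GGGGTTTT"))
  expect_error(distance_matrix(aln, "jc69"), "good.*bad|bad.*good")
})

test_that("complete deletion drops gap columns globally", {
  aln <- alignment(c(a = "ACGTAC", b = "AC-TAC", c = "ACGTAT"))
  dm <- distance_matrix(aln, "p", gaps = "complete")
  # column 3 removed for every pair: a vs c differ at final site among 5 kept
  expect_equal(dm["a", "c"], 1 / 5)
  expect_equal(dm["a", "b"], 0)
})

test_that("distance CSV round-trips values and metadata", {
  aln <- alignment(c(a = "ACGTACGT", b = "ACGAACGA", c = "GCGTACTT"))
  dm <- distance_matrix(aln, "t92", gamma_alpha = 0.8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(dm, f)
  back <- read_distance_csv(f)
  expect_equal(unclass(back), unclass(dm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(back, "model"), "t92")
  expect_equal(attr(back, "gamma_alpha"), 0.8)
})
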