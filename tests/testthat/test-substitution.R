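test_that("category table covers all residues with closed vocabularies", {
  tab <- aa_category_table()
  expect_setequal(rownames(tab), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_identical(tab["K", "charge"], "positive")
  expect_identical(tab["D", "charge"], "negative")
  expect_identical(tab["Y", "polarity"], "polar")
})

test_that("classification follows the one-category-change rule", {
  expect_identical(classify_substitution("D", "K")$verdict, "radical")
  expect_true("charge" %in% classify_substitution("D", "K")$changed)
  for (pair in list(c("L", "P"), c("L", "A"), c("L", "T"), c("Y", "F"))) {
    expect_identical(classify_substitution(pair[1], pair[2])$verdict, "radical")
  }
  il <- classify_substitution("I", "L")
  expect_identical(il$verdict, "conservative")
  expect_length(il$changed, 0L)
  expect_error(classify_substitution("L", "L"), "identical")
  expect_error(classify_substitution("L", "Z"), "nonstandard")
})

test_that("verdicts are symmetric and partition all 190 pairs", {
  aas <- rownames(aa_category_table())
  verdicts <- character(0)
  for (i in seq_along(aas)) {
    for (j in seq_along(aas)) {
      if (i >= j) next
      a <- classify_substitution(aas[i], aas[j])
      b <- classify_substitution(aas[j], aas[i])
      expect_identical(a$verdict, b$verdict)
      expect_setequal(a$changed, b$changed)
      expect_identical(a$verdict == "radical", length(a$changed) > 0L)
      verdicts <- c(verdicts, a$verdict)
    }
  }
  expect_length(verdicts, 190L)
  expect_true(all(verdicts %in% c("radical", "conservative")))
})

test_that("substitution records compare columns and skip indel columns", {
  expect_identical(nrow(substitutions_vs_reference("MAL", "MAL")), 0L)
  recs <- substitutions_vs_reference("MTL", "MAL")
  expect_identical(recs$column, 2L)
  expect_identical(recs$ref, "A")
  expect_identical(recs$alt, "T")
  expect_identical(recs$verdict, "radical")  # A (nonpolar) -> T (polar)

  gap <- substitutions_vs_reference("MAKL", "MA-L")
  expect_identical(nrow(gap), 0L)
  expect_identical(attr(gap, "n_indel_columns"), 1L)
  expect_error(substitutions_vs_reference("MAL", "MALG"), "length")
})

test_that("domain proportions divide counts by domain length", {
  ann <- read_domain_annotation()
  none <- substitutions_vs_reference("MAL", "MAL")
  expect_true(all(domain_proportions(none, ann) == 0))

  # two substitutions inside the 38-residue N-terminus
  ref <- strrep("A", 389)
  qry <- paste0("V", substr(ref, 2, 9), "V", substr(ref, 11, 389))
  recs <- substitutions_vs_reference(qry, ref)
  props <- domain_proportions(recs, ann)
  expect_equal(unname(props["N-term"]), 2 / 38)
  expect_true(all(props[setdiff(names(props), "N-term")] == 0))

  # conservation: sum(proportion * length) = substitution count
  lens <- setNames(ann$end - ann$start + 1L, ann$label)
  expect_equal(sum(props * lens[names(props)]), nrow(recs))

  # order invariance
  shuf <- recs[rev(seq_len(nrow(recs))), ]
  expect_identical(domain_proportions(shuf, ann), props)

  out <- substitutions_vs_reference("MV", "MA")
  small_ann <- structure(data.frame(label = "X", start = 1L, end = 1L),
                         class = c("domain_annotation", "data.frame"))
  expect_error(domain_proportions(out, small_ann), "outside")
})

test_that("per-total denominator and per-species wrapper agree", {
  ann <- read_domain_annotation()
  ref <- strrep("A", 389)
  qry <- paste0("VV", substr(ref, 3, 389))
  recs <- substitutions_vs_reference(qry, ref)
  by_total <- domain_proportions(recs, ann, denominator = "total_substitutions")
  expect_equal(unname(by_total["N-term"]), 1)

  aln <- alignment(c(human = ref, sp1 = qry, sp2 = ref), alphabet = "aa")
  props <- substitution_proportions(aln, "human", ann)
  expect_identical(rownames(props), c("sp1", "sp2"))
  expect_equal(unname(props["sp1", "N-term"]), 2 / 38)
  expect_true(all(props["sp2", ] == 0))
})

test_that("group comparison is the Welch t-test", {
  expect_identical(group_proportion_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  sep <- group_proportion_test(c(0, 0, 1e-9), c(1, 1, 1 + 1e-9))
  expect_lt(sep$p_value, 1e-6)

  a <- c(0.10, 0.15, 0.20); b <- c(0.05, 0.06, 0.04)
  got <- group_proportion_test(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(got$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$df, df, tolerance = 1e-9)
  expect_error(group_proportion_test(c(1), c(1, 2)), "at least 2")
})
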