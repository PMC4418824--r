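test_that("MC equals hand-enumerated clade sizes on canonical trees", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tra <- trait_assignment(c(A = "M", B = "M", C = "N", D = "N"))
  expect_identical(mc_statistic(tr, tra, "M"), 2L)
  expect_identical(mc_statistic(tr, tra, "N"), 2L)

  all_m <- trait_assignment(c(A = "M", B = "M", C = "M", D = "M"),
                            valid_states = c("M", "N"))
  expect_identical(mc_statistic(tr, all_m, "M"), 4L)

  one <- trait_assignment(c(A = "M", B = "N", C = "N", D = "N"))
  expect_identical(mc_statistic(tr, one, "M"), 1L)

  cherry <- ape::read.tree(text = "(A,B);")
  expect_identical(
    mc_statistic(cherry, trait_assignment(c(A = "M", B = "M"),
                                          valid_states = c("M", "N")), "M"),
    2L)

  poly <- ape::read.tree(text = "(A,B,C);")
  poly$edge.length <- rep(1, nrow(poly$edge))
  expect_identical(
    mc_statistic(poly, trait_assignment(c(A = "M", B = "M", C = "M"),
                                        valid_states = c("M", "N")), "M"),
    3L)
})

test_that("MC errors on absent states and uncovered tips", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tra <- trait_assignment(c(A = "M", B = "M", C = "N", D = "N"))
  expect_error(mc_statistic(tr, tra, "Z"), "absent")
  short <- trait_assignment(c(A = "M", B = "N", C = "M"))
  expect_error(mc_statistic(tr, short, "M"), "missing")
})

test_that("MC is a topology-only statistic", {
  tr <- random_rooted_tree(8, seed = 12)
  set.seed(13)
  tra <- random_binary_traits(tr)
  base <- mc_statistic(tr, tra, "A")
  tr2 <- tr
  tr2$edge.length <- runif(length(tr$edge.length), 0.001, 10)
  expect_identical(mc_statistic(tr2, tra, "A"), base)
})

test_that("fast MC matches the brute-force oracle on random instances", {
  set.seed(14)
  for (i in 1:60) {
    tr <- random_rooted_tree(sample(5:12, 1))
    tra <- random_binary_traits(tr)
    for (st in c("A", "B")) {
      if (!st %in% unclass(tra)) next
      expect_identical(mc_statistic(tr, tra, st),
                       mc_statistic_bruteforce(tr, tra, st))
    }
  }
})

test_that("adding a tip of the other state cannot increase MC", {
  set.seed(15)
  for (i in 1:20) {
    tr <- random_rooted_tree(sample(5:10, 1))
    tra <- random_binary_traits(tr)
    if (!"A" %in% unclass(tra)) next
    base <- mc_statistic(tr, tra, "A")
    # graft a B-state tip onto a random edge
    tr2 <- phangorn::add.tips(tr, "zz_new", sample(length(tr$tip.label), 1))
    tra2 <- trait_assignment(c(unclass(tra), zz_new = "B"),
                             valid_states = c("A", "B"))
    expect_lte(mc_statistic(tr2, tra2, "A"), base)
  }
})

test_that("mc_observed summarises the per-tree distribution", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tra <- trait_assignment(c(A = "M", B = "M", C = "N", D = "N"))
  ts <- tree_sample(list(tr, tr, tr))
  obs <- mc_observed(ts, tra, "M")
  expect_identical(obs$per_tree, c(2L, 2L, 2L))
  expect_identical(obs$ci, c(2, 2))

  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  tra2 <- trait_assignment(c(A = "M", B = "M", C = "M", D = "M"),
                           valid_states = c("M", "N"))
  # force different MC values via different traits on two topologies
  mixed <- tree_sample(list(tr, t2))
  tra3 <- trait_assignment(c(A = "M", B = "M", C = "N", D = "M"))
  per <- mc_observed(mixed, tra3, "M")$per_tree
  expect_identical(mean(per), mc_observed(mixed, tra3, "M")$mean)
  expect_true(mc_observed(mixed, tra3, "M")$mean >= min(per) &&
              mc_observed(mixed, tra3, "M")$mean <= max(per))
})

test_that("mc_test p-values follow the add-one permutation convention", {
  tr <- make_caterpillar(8)
  tra <- trait_assignment(setNames(c(rep("M", 4), rep("N", 4)),
                                   paste0("t", 1:8)))
  r1 <- mc_test(tree_sample(list(tr)), tra, "M", n_replicates = 1,
                seed = 3)
  expect_true(r1$p_value %in% c(0.5, 1))

  # perfectly clustered trait on a 16-tip caterpillar
  tr16 <- make_caterpillar(16)
  tra16 <- trait_assignment(setNames(c(rep("M", 8), rep("N", 8)),
                                     paste0("t", 1:16)))
  res <- mc_test(tree_sample(list(tr16)), tra16, "M",
                 n_replicates = 1000, seed = 4)
  expect_lte(res$p_value, 0.01)
  expect_identical(res$observed_mc, 8)
  expect_lt(res$expected_mc, 3)
})

test_that("mc_test is deterministic under a fixed seed", {
  tr <- random_rooted_tree(10, seed = 16)
  set.seed(17)
  tra <- random_binary_traits(tr)
  ts <- tree_sample(list(tr))
  a <- mc_test(ts, tra, "A", n_replicates = 200, seed = 99)
  b <- mc_test(ts, tra, "A", n_replicates = 200, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$expected_mc, b$expected_mc)
})

test_that("single-tree replicate mode and median null summary work", {
  tr <- random_rooted_tree(10, seed = 18)
  set.seed(19)
  tra <- random_binary_traits(tr)
  ts <- tree_sample(list(tr, random_rooted_tree(10, seed = 20)))
  # second tree has different tips; rebuild a valid sample instead
  ts <- tree_sample(list(tr, tr))
  res <- mc_test(ts, tra, "A", n_replicates = 100, seed = 5,
                 null_summary = "median", replicate_mode = "single_tree")
  expect_identical(res$null_summary, "median")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})
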