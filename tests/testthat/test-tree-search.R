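small_sim <- function(n_taxa, n_char, seed, ...) {
  cfg <- sim_config(n_taxa = n_taxa, n_characters = n_char,
                    fraction_ordered = 0.4, states_per_character = 3,
                    substitution_rate = 0.4, seed = seed, ...)
  simulate_characters(simulate_tree(cfg), cfg)
}

test_that("random addition is deterministic and exact for trivial cases", {
  sm <- char_matrix(c("a", "b", "c"),
                    matrix(bitwShiftL(1L, c(0L, 1L, 1L, 0L, 0L, 1L)), nrow = 3),
                    c("binary", "binary"))
  t3 <- random_addition_tree(sm, seed = 1)
  expect_equal(ape::Ntip(t3), 3)   # the unique unrooted topology
  sm6 <- small_sim(6, 20, 2)
  a <- random_addition_tree(sm6, seed = 9)
  b <- random_addition_tree(sm6, seed = 9)
  expect_equal(ape::write.tree(a), ape::write.tree(b))
})

test_that("homoplasy-free matrices are recovered at their known optimum", {
  # each clade marker changes once on the generating tree, so the optimum
  # is the character count; stepwise addition can be misled by placement
  # ties on such sparse matrices, but a TBR pass always lands on it
  set.seed(3)
  for (rep in 1:5) {
    gen <- rand_unrooted_tree(6)
    m <- clean_clade_matrix(gen)
    expect_equal(tree_length(gen, m), n_char(m))
    expect_equal(branch_and_bound(m)$best_length, n_char(m))
    tr <- random_addition_tree(m, seed = rep)
    expect_gte(tree_length(tr, m), n_char(m))
    sw <- branch_swap(tr, m, "TBR", fixpoint = TRUE)
    expect_equal(attr(sw, "steps"), n_char(m))
  }
})

test_that("branch swapping stops at a global optimum and improves otherwise", {
  # quartet already optimal: unchanged
  m <- char_matrix(c("A", "B", "C", "D"),
                   matrix(bitwShiftL(1L, c(0L, 0L, 1L, 1L)), ncol = 1),
                   "binary")
  q <- quartet_tree()
  sw <- branch_swap(q, m, "TBR", fixpoint = TRUE)
  expect_equal(attr(sw, "steps"), 1L)
  expect_equal(robinson_foulds(sw, q), 0)

  # TBR explores a superset of SPR: its fixpoint is never worse
  for (s in 1:10) {
    sm <- small_sim(8, 25, s + 50)
    st <- random_addition_tree(sm, seed = s)
    t_tbr <- branch_swap(st, sm, "TBR", fixpoint = TRUE)
    t_spr <- branch_swap(st, sm, "SPR", fixpoint = TRUE)
    expect_lte(attr(t_tbr, "steps"), attr(t_spr, "steps"))
    expect_lte(attr(t_tbr, "steps"), tree_length(st, sm))
  }
})

test_that("TBR swapping from random starts usually reaches the optimum", {
  hits <- 0
  for (s in 1:25) {
    sm <- small_sim(8, 30, s + 100)
    opt <- branch_and_bound(sm)$best_length
    st <- random_addition_tree(sm, seed = s * 13)
    sw <- branch_swap(st, sm, "TBR", fixpoint = TRUE)
    expect_gte(attr(sw, "steps"), opt)
    if (attr(sw, "steps") == opt) hits <- hits + 1
  }
  expect_gte(hits, 22)  # local optima are rare at this size
})

test_that("branch and bound matches unpruned exhaustive enumeration", {
  skip_if_not_installed("phangorn")
  for (s in 1:10) {
    n <- if (s <= 5) 6 else 7
    sm <- small_sim(n, 15, s + 200)
    bb <- branch_and_bound(sm)
    all_trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = sm$taxa)
    lens <- vapply(all_trees, tree_length, 1, m = sm)
    expect_equal(bb$best_length, min(lens))
    opt_sigs <- sort(vapply(all_trees[lens == min(lens)],
                            moriomorph:::topology_signature, ""))
    bb_sigs <- sort(vapply(bb$best_trees, moriomorph:::topology_signature, ""))
    expect_equal(bb_sigs, opt_sigs)
  }
})

test_that("branch and bound handles degenerate and tiny instances", {
  # one informative character on 4 taxa: exactly 1 of the 3 topologies
  m <- char_matrix(c("A", "B", "C", "D"),
                   matrix(bitwShiftL(1L, c(0L, 0L, 1L, 1L)), ncol = 1),
                   "binary")
  bb <- branch_and_bound(m)
  expect_equal(bb$best_length, 1L)
  expect_equal(length(bb$best_trees), 1L)
  expect_equal(robinson_foulds(bb$best_trees[[1]], quartet_tree()), 0)

  # all-constant matrix: every topology is optimal at length 0
  mc <- char_matrix(paste0("t", 1:6),
                    matrix(bitwShiftL(1L, rep(0L, 12)), nrow = 6),
                    rep("binary", 2))
  bbc <- branch_and_bound(mc)
  expect_equal(bbc$best_length, 0L)
  expect_equal(length(bbc$best_trees), 105L)

  expect_error(branch_and_bound(small_sim(12, 5, 1)), "11 taxa")
})

test_that("the ratchet is reproducible and never worse than plain swapping", {
  for (s in 1:6) {
    sm <- small_sim(9, 30, s + 300)
    st <- random_addition_tree(sm, seed = 1)
    plain <- branch_swap(st, sm, "TBR", fixpoint = TRUE)
    rs <- ratchet_search(sm, search_config(seed = 1, n_ratchet_iterations = 10,
                                           n_addition_replicates = 1))
    expect_lte(rs$best_length, attr(plain, "steps"))
    expect_true(all(diff(rs$trajectory) <= 0))
    # every reported tree re-scores to the reported length
    for (t in rs$best_trees)
      expect_equal(tree_length(t, sm), rs$best_length)
  }
  sm <- small_sim(10, 40, 999)
  cfg <- search_config(seed = 4, n_ratchet_iterations = 15,
                       n_addition_replicates = 2)
  r1 <- ratchet_search(sm, cfg)
  r2 <- ratchet_search(sm, cfg)
  expect_identical(vapply(r1$best_trees, ape::write.tree, ""),
                   vapply(r2$best_trees, ape::write.tree, ""))
})

test_that("search configuration is validated", {
  expect_error(search_config(perturb_fraction = 0))
  expect_error(search_config(perturb_fraction = 1))
  expect_error(search_config(perturb_weight = 1))
  expect_error(search_config(n_ratchet_iterations = -1))
})

test_that("outgroup rooting preserves topology and isolates the ingroup", {
  q <- quartet_tree()
  r <- root_at_outgroup(q, "A")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == ape::Ntip(r) + 1, 2]
  expect_true(1 %in% kids)  # A is one child of the root
  expect_error(root_at_outgroup(q, "nope"), "unknown outgroup")

  sm <- small_sim(8, 20, 5)
  tr <- random_addition_tree(sm, seed = 2)
  rooted <- root_at_outgroup(tr, sm$taxa[3])
  expect_equal(tree_length(rooted, sm), tree_length(tr, sm))
  # the other 7 taxa form a single clade
  ingroup <- setdiff(sm$taxa, sm$taxa[3])
  sub <- ape::extract.clade(rooted,
                            ape::getMRCA(rooted, ingroup))
  expect_setequal(sub$tip.label, ingroup)
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- rand_unrooted_tree(8)
  expect_equal(robinson_foulds(strict_consensus(list(t1, t1)), t1), 0)
  t2 <- branch_swap(t1, clean_clade_matrix(rand_unrooted_tree(8)), "SPR")
  cons <- strict_consensus(list(t1, t2))
  shared <- intersect(moriomorph:::bipartition_strings(t1),
                      moriomorph:::bipartition_strings(t2))
  expect_setequal(moriomorph:::bipartition_strings(cons), shared)
  # fully conflicting quartets collapse to the star tree
  qa <- quartet_tree()
  qb <- ape::unroot(ape::read.tree(text = "((A,C),(B,D));"))
  cons2 <- strict_consensus(list(qa, qb))
  expect_equal(length(moriomorph:::bipartition_strings(cons2)), 0)
  expect_error(strict_consensus(list(t1, ape::rtree(5))), "mismatch")
})

test_that("Robinson-Foulds distance counts unshared bipartitions", {
  skip_if_not_installed("phangorn")
  t1 <- rand_unrooted_tree(10)
  expect_equal(robinson_foulds(t1, t1), 0)
  qa <- quartet_tree(); qb <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(qa, qb), 2)
  set.seed(31)
  for (rep in 1:20) {
    a <- rand_unrooted_tree(10)
    b <- rand_unrooted_tree(10)
    b$tip.label <- sample(a$tip.label)
    expect_equal(robinson_foulds(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
  expect_error(robinson_foulds(t1, ape::rtree(4)), "mismatch")
})
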