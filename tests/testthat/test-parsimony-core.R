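test_that("step matrices implement unit and unit-additive costs", {
  expect_equal(step_matrix("unordered", 3),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(step_matrix("ordered", 4)[1, ], c(0, 1, 2, 3))
  expect_equal(step_matrix("binary", 2), step_matrix("unordered", 2))
})

test_that("quartet lengths match hand-enumerated values", {
  q <- quartet_tree()
  expect_equal(character_length(q, c(0, 0, 0, 0)), 0)
  expect_equal(character_length(q, c(0, 0, 1, 1), "unordered"), 1)
  expect_equal(character_length(q, c(0, 0, 3, 3), "ordered"), 3)
  # split across the cherries, each cherry spans the full 0-3 range
  expect_equal(character_length(q, c(0, 3, 0, 3), "ordered"), 6)
  expect_equal(oracle_column_length(q, as.list(c(0, 3, 0, 3)), "ordered"), 6)
  expect_equal(character_length(q, c(0, 1, 0, 1), "unordered"), 2)
})

test_that("lengths agree with exhaustive internal-assignment enumeration", {
  set.seed(42)
  for (rep in 1:500) {
    n <- sample(4:7, 1)
    k <- sample(2:4, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    tree <- rand_unrooted_tree(n)
    col <- rand_col(n, k)
    expect_equal(character_length(tree, col, kind),
                 oracle_column_length(tree, col, kind),
                 info = sprintf("rep %d n=%d k=%d %s", rep, n, k, kind))
  }
})

test_that("unit-cost lengths match an independent Fitch implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(5:10, 1)
    tree <- rand_unrooted_tree(n)
    col <- vapply(rand_col(n, 4, miss = 0.1, poly = 0),
                  function(s) if (length(s) == 1 && is.na(s)) "?"
                              else as.character(s), "")
    pd <- phangorn::phyDat(matrix(col, ncol = 1,
                                  dimnames = list(tree$tip.label, NULL)),
                           type = "USER", levels = as.character(0:3),
                           ambiguity = "?")
    expect_equal(character_length(tree, col, "unordered"),
                 as.integer(phangorn::parsimony(tree, pd, method = "fitch")))
  }
})

test_that("length is invariant under rerooting", {
  set.seed(11)
  m <- load_moriomorphini()
  for (rep in 1:10) {
    n <- sample(5:7, 1)
    cfg <- sim_config(n_taxa = n, n_characters = 15, fraction_ordered = 0.5,
                      states_per_character = 4, missing_rate = 0.1, seed = rep)
    sm <- degrade_matrix(simulate_characters(simulate_tree(cfg), cfg), cfg)
    tree <- rand_unrooted_tree(n)
    tree$tip.label <- sm$taxa
    base <- tree_length(tree, sm)
    for (tx in sm$taxa)
      expect_equal(tree_length(root_at_outgroup(tree, tx), sm), base)
  }
  # and on the bundled data for one arbitrary binary tree
  tr <- random_addition_tree(m, seed = 5)
  expect_equal(tree_length(root_at_outgroup(tr, "Trechus obtusus"), m),
               tree_length(tr, m))
})

test_that("min_steps and max_steps bracket observed steps", {
  expect_equal(min_steps(c(NA, NA, NA)), 0)
  expect_equal(min_steps(c(0, 1, 2, 1), "unordered"), 2)
  expect_equal(min_steps(c(0, 3), "ordered"), 3)
  expect_equal(min_steps(list(c(0, 1), 0, 1), "unordered"), 1)  # 0 and 1 obligate
  expect_equal(min_steps(list(c(0, 1), 0, 0), "unordered"), 0)  # ambiguity resolvable
  expect_equal(max_steps(c(0, 0, 1, 1), "unordered"), 2)
  expect_equal(max_steps(c(0, 1, 2), "ordered"), 2)
  expect_equal(max_steps(c(0, 0, 0)), 0)

  set.seed(13)
  for (rep in 1:200) {
    n <- sample(4:8, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    col <- rand_col(n, 4)
    tree <- rand_unrooted_tree(n)
    s <- character_length(tree, col, kind)
    expect_gte(s, min_steps(col, kind))
    expect_lte(s, max_steps(col, kind))
  }
})

test_that("replacing a cell by missing never increases length", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    col <- rand_col(n, 4, miss = 0.1, poly = 0.2)
    tree <- rand_unrooted_tree(n)
    base <- character_length(tree, col, kind)
    i <- sample(n, 1)
    col[[i]] <- NA_integer_
    expect_lte(character_length(tree, col, kind), base)
  }
})

test_that("ancestral states realize the minimum length", {
  q <- ape::root(quartet_tree(), outgroup = "A", resolve.root = TRUE)
  # constant column: every node keeps the state
  expect_true(all(ancestral_states(q, c(2, 2, 2, 2), "unordered") == 2))
  # one informative split: both internal nodes 0, single 0->1 change on the
  # edge subtending {C,D}, under either resolution
  for (res in c("ACCTRAN", "DELTRAN")) {
    a <- ancestral_states(q, c(0, 0, 1, 1), "unordered", res)
    expect_equal(implied_cost(q, a, "unordered", 2), 1)
    expect_equal(a[1:4], c(0L, 0L, 1L, 1L))
  }

  set.seed(23)
  for (rep in 1:100) {
    n <- sample(4:7, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    col <- rand_col(n, 4, miss = 0.2, poly = 0.2)
    tree <- ape::root(rand_unrooted_tree(n), outgroup = "t1",
                      resolve.root = TRUE)
    want <- character_length(tree, col, kind)
    for (res in c("ACCTRAN", "DELTRAN")) {
      a <- ancestral_states(tree, col, kind, res)
      k <- max(a) + 1L
      expect_equal(implied_cost(tree, a, kind, max(k, 2)), want,
                   info = sprintf("rep %d %s", rep, res))
    }
  }
})

test_that("ancestral_states rejects unrooted trees", {
  expect_error(ancestral_states(quartet_tree(), c(0, 0, 1, 1)), "rooted")
})

test_that("strict polymorphism scoring charges the obligate state span", {
  m <- load_moriomorphini()
  tr <- random_addition_tree(m, seed = 2)
  # the three polymorphic cells each span one step on every tree
  expect_equal(tree_length(tr, m, "strict"), tree_length(tr, m) + 3L)

  set.seed(29)
  for (rep in 1:20) {
    cfg <- sim_config(n_taxa = 7, n_characters = 12, polymorphism_rate = 0.3,
                      states_per_character = 3, fraction_ordered = 0.5,
                      seed = rep)
    sm <- degrade_matrix(simulate_characters(simulate_tree(cfg), cfg), cfg)
    tree <- rand_unrooted_tree(7)
    tree$tip.label <- sm$taxa
    expect_gte(tree_length(tree, sm, "strict"), tree_length(tree, sm))
  }
})
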