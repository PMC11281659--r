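test_that("ordered character length matches brute-force minimization", {
  two <- ape::read.tree(text = "(a,b);")
  expect_equal(ordered_char_length(two, c(a = 3, b = 9)), 6)

  q <- quartet("ab|cd")
  st <- c(a = 0, b = 2, c = 5, d = 5)
  expect_equal(ordered_char_length(q, st), 5)
  expect_equal(ordered_char_length(q, st), brute_wagner(q, st))
  expect_equal(ordered_char_length(q, c(a = 4, b = 4, c = 4, d = 4)), 0)
  expect_error(ordered_char_length(q, c(a = 1, b = 2, c = 3)),
               "leaf without state")

  # brute-force agreement on random 5/6-taxon trees with <= 4 internal nodes
  set.seed(11)
  for (n in c(5, 6)) {
    for (rep in 1:5) {
      edge <- todchron:::tc_random_topology(n)
      phy <- todchron:::tc_to_phylo(edge, paste0("t", 1:n))
      st <- stats::setNames(sample(0:6, n, TRUE), phy$tip.label)
      expect_equal(ordered_char_length(phy, st), brute_wagner(phy, st))
    }
  }

  # missing states act as free leaves
  expect_equal(ordered_char_length(q, c(a = 0, b = NA, c = 5, d = 5)), 5)
})

test_that("tree length is additive, root-invariant and errors on mismatch", {
  q <- quartet("ab|cd")
  cm <- cm_of(cbind(ch1 = c(0L, 2L, 5L, 5L), ch2 = c(1L, 1L, 1L, 1L)))
  expect_equal(tree_length(q, cm), 5)
  cm1 <- cm_of(cbind(ch1 = c(0L, 2L, 5L, 5L)))
  expect_equal(tree_length(q, cm1), ordered_char_length(q, c(a = 0, b = 2, c = 5, d = 5)))
  cmdup <- cm_of(cbind(c(0L, 2L, 5L, 5L), c(0L, 2L, 5L, 5L)))
  expect_equal(tree_length(q, cmdup), 2 * tree_length(q, cm1))

  bad <- cm_of(matrix(0L, 4, 1, dimnames = list(c("a", "b", "c", "x"), "ch")))
  expect_error(tree_length(q, bad), "taxon mismatch.*[dx]")

  # root invariance over every rooting of 20 random trees
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    edge <- todchron:::tc_random_topology(n)
    phy <- todchron:::tc_to_phylo(edge, letters[1:n])
    cmr <- random_cm(n, 4)
    rownames(cmr$states) <- letters[1:n]
    len0 <- tree_length(phy, cmr)
    for (i in seq_len(nrow(phy$edge))) {
      expect_equal(tree_length(root_on_edge(phy, i), cmr), len0)
    }
  }
})

test_that("per-character step bounds match their definitions", {
  expect_equal(char_min_steps(c(0, 2, 5, 5)), 5)
  expect_equal(char_max_steps(c(0, 2, 5, 5)), 8)   # sum|x - z| minimized at z in 2..5
  expect_equal(char_min_steps(c(4, 4, 4)), 0)
  expect_equal(char_max_steps(c(4, 4, 4)), 0)
  expect_equal(char_min_steps(c(0, 7)), 7)
  expect_equal(char_max_steps(c(0, 7)), 7)
  expect_error(char_min_steps(c(NA, NA)), "all states missing")

  # bounds bracket the observed length on random data
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    cm <- random_cm(n, 3)
    phy <- todchron:::tc_to_phylo(todchron:::tc_random_topology(n),
                                  rownames(cm$states))
    for (j in 1:3) {
      s <- ordered_char_length(phy, stats::setNames(cm$states[, j],
                                                    rownames(cm$states)))
      expect_gte(s, char_min_steps(cm$states[, j]))
      expect_lte(s, char_max_steps(cm$states[, j]))
    }
  }
})

test_that("retention index follows (G - S)/(G - M)", {
  q <- quartet("ab|cd")
  # s = m for both characters -> RI = 1
  cm_perfect <- cm_of(cbind(c(0L, 0L, 9L, 9L), c(0L, 2L, 9L, 9L)))
  expect_equal(retention_index(q, cm_perfect), 1)
  # single maximally homoplastic character -> RI = 0
  cm0 <- cm_of(cbind(c(0L, 2L, 0L, 2L)))
  expect_equal(retention_index(q, cm0), 0)
  # mixture: (12 - 9) / (12 - 7) = 0.6
  cm_mix <- cm_of(cbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 5L, 5L)))
  expect_equal(retention_index(q, cm_mix), 0.6)
  expect_error(retention_index(q, cm_of(cbind(c(1L, 1L, 1L, 1L)))),
               "no retention signal")
})

test_that("stepwise addition groups compatible taxa deterministically", {
  cm3 <- cm_of(matrix(c(0L, 1L, 2L), 3, 1))
  t3 <- stepwise_addition(cm3)
  expect_equal(ape::Ntip(t3), 3)

  cm <- cm_of(cbind(c(0L, 0L, 9L, 9L), c(0L, 0L, 9L, 9L)))
  # brute-force oracle over the three quartet topologies
  lens <- vapply(c("ab|cd", "ac|bd", "ad|bc"), function(s)
    tree_length(quartet(s), cm), numeric(1))
  expect_equal(unname(lens), c(18, 36, 36))
  tr <- stepwise_addition(cm)
  expect_equal(topo_key(tr), topo_key(quartet("ab|cd")))
  expect_equal(tree_length(tr, cm), 18)
  # determinism under a seed
  expect_equal(topo_key(stepwise_addition(cm, seed = 9, "random")),
               topo_key(stepwise_addition(cm, seed = 9, "random")))
  expect_error(stepwise_addition(cm_of(matrix(0L, 2, 1))), ">= 3 taxa")
})

test_that("branch swapping only improves and recovers the quartet optimum", {
  cm <- cm_of(cbind(c(0L, 0L, 9L, 9L), c(0L, 0L, 9L, 9L)))
  best <- quartet("ab|cd")
  expect_equal(topo_key(branch_swap_search(best, cm)), topo_key(best))
  mis <- quartet("ac|bd")
  rec <- branch_swap_search(mis, cm, moves = "NNI")
  expect_equal(topo_key(rec), topo_key(best))
  # contract: length never increases
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:7, 1)
    cmr <- random_cm(n, 4)
    start <- todchron:::tc_to_phylo(todchron:::tc_random_topology(n),
                                    rownames(cmr$states))
    for (mv in c("NNI", "SPR")) {
      out <- branch_swap_search(start, cmr, moves = mv)
      expect_lte(tree_length(out, cmr), tree_length(start, cmr))
    }
  }
})

test_that("mp_search matches exhaustive enumeration and is reproducible", {
  cm <- cm_of(cbind(c(0L, 0L, 9L, 9L), c(1L, 1L, 8L, 8L)))
  sr1 <- mp_search(cm, n_replicates = 3, seed = 7, g1_trees = 0)
  sr2 <- mp_search(cm, n_replicates = 3, seed = 7, g1_trees = 0)
  expect_equal(length(sr1$best_trees), 1)
  expect_equal(topo_key(sr1$best_trees[[1]]), topo_key(sr2$best_trees[[1]]))
  expect_equal(sr1$length, sr2$length)

  set.seed(31)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    cmr <- random_cm(n, sample(2:5, 1))
    sr <- mp_search(cmr, n_replicates = 3, seed = rep, g1_trees = 0)
    expect_equal(sr$length, exhaustive_best_length(cmr))
  }

  # duplicated taxa sit as sisters in the best tree
  m <- rbind(a = c(0L, 1L), b = c(0L, 1L), c = c(7L, 8L), d = c(9L, 9L),
             e = c(3L, 5L))
  colnames(m) <- c("p1", "p2")
  sr <- mp_search(character_matrix(m), n_replicates = 4, seed = 2, g1_trees = 0)
  splits <- todchron:::tc_bipartitions(sr$best_trees[[1]]$edge, 5,
                                       sr$best_trees[[1]]$tip.label)
  expect_true(any(vapply(strsplit(splits, "\\|"), function(s)
    setequal(s, c("a", "b")) || setequal(s, c("c", "d", "e")), logical(1))))
})

test_that("mp_search agrees with phangorn's Sankoff parsimony scoring", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  cm <- random_cm(6, 4, n_states = 5L)
  phy <- todchron:::tc_to_phylo(todchron:::tc_random_topology(6),
                                rownames(cm$states))
  S <- 5L
  cost <- outer(0:(S - 1), 0:(S - 1), function(i, j) abs(i - j))
  chr <- matrix(as.character(cm$states), nrow(cm$states),
                dimnames = dimnames(cm$states))
  dat <- phangorn::phyDat(chr, type = "USER",
                          levels = as.character(0:(S - 1)))
  expect_equal(tree_length(phy, cm),
               as.numeric(phangorn::parsimony(phy, dat, method = "sankoff",
                                              cost = cost)))
})

test_that("g1 statistic is the moment skewness of sampled tree lengths", {
  expect_equal(todchron:::g1_skewness(c(1, 2, 3)), 0)
  expect_equal(todchron:::g1_skewness(c(0, 0, 10)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(todchron:::g1_skewness(c(2, 2, 2)), "zero variance")

  cm <- random_cm(6, 4)
  g1a <- g1_statistic(cm, 50, seed = 4)
  g1b <- g1_statistic(cm, 50, seed = 4)
  expect_identical(g1a, g1b)
  expect_error(g1_statistic(cm, 2, seed = 1), "at least 3")
})

test_that("bootstrap supports tally resampled bipartitions", {
  cm <- cm_of(matrix(rep(c(0L, 0L, 9L, 9L), 4), 4,
                     dimnames = list(letters[1:4], paste0("p", 1:4))))
  bs <- bootstrap_support(cm, n_replicates = 20, seed = 5,
                          search_params = list(n_replicates = 1L))
  expect_equal(nrow(bs), 1)
  expect_setequal(strsplit(bs$bipartition, "\\|")[[1]], c("c", "d"))
  expect_equal(bs$support, 1)

  bs1 <- bootstrap_support(cm, n_replicates = 1, seed = 5,
                           search_params = list(n_replicates = 1L))
  expect_true(all(bs1$support %in% c(0, 1)))
})

test_that("relabeling taxa permutes results without changing length", {
  set.seed(17)
  cm <- random_cm(6, 4)
  sr <- mp_search(cm, n_replicates = 2, seed = 1, g1_trees = 0)
  perm <- sample(6)
  cm2 <- cm
  cm2$states <- cm$states[perm, , drop = FALSE]
  sr2 <- mp_search(cm2, n_replicates = 2, seed = 1, g1_trees = 0)
  expect_equal(sr$length, sr2$length)
})
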