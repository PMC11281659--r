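test_that("Venn incidence encodes group membership per taxon", {
  vg <- c(f1 = "BEV", f2 = "V", f3 = "ABEV")
  inc <- venn_incidence(vg)
  expect_equal(unname(inc[, "f1"]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(inc[, "f2"]), c(0L, 0L, 0L, 1L))
  expect_equal(unname(inc[, "f3"]), c(1L, 1L, 1L, 1L))
  expect_error(venn_incidence(vg, taxa = c("A", "B")), "at least 3")
})

test_that("uncorrected-P distances are normalized Hamming distances", {
  inc <- rbind(x = c(1, 1, 0, 0), y = c(1, 0, 1, 0), z = c(1, 1, 0, 0))
  d <- uncorrected_p(inc)
  expect_equal(d["x", "z"], 0)
  expect_equal(d["x", "y"], 0.5)
  expect_equal(uncorrected_p(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 1)
  # triangle inequality on random binary data
  set.seed(14)
  for (rep in 1:10) {
    m <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12)
    rownames(m) <- letters[1:5]
    dd <- uncorrected_p(m)
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
})

test_that("NeighborNet recovers tree splits exactly on additive metrics", {
  # ((A:1,B:1):1,(E:1,V:1)) metric
  d <- matrix(c(0, 2, 3, 3,  2, 0, 3, 3,  3, 3, 0, 2,  3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "E", "V"), c("A", "B", "E", "V")))
  ss <- neighbor_net(d)
  expect_equal(length(ss$splits), 5)
  expect_true(all(abs(ss$weights - 1) < 1e-8))
  expect_lt(ss$fit, 1e-12)
  keys <- split_keys_of(ss)
  expect_true(paste(sort(c("E", "V")), collapse = "|") %in% keys)

  # three taxa: closed-form trivial weights
  d3 <- matrix(c(0, 3, 4,  3, 0, 5,  4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s3 <- neighbor_net(d3)
  w <- stats::setNames(s3$weights,
                       vapply(s3$splits, paste, character(1), collapse = "|"))
  expect_equal(unname(w[c("b|c", "b", "c")]), c(1, 2, 3))

  # equidistant matrix: fitted pairwise sums reproduce the constant
  dc <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dc) <- 0
  sc <- neighbor_net(dc)
  for (i in 1:3) for (j in (i + 1):4) {
    fit_ij <- sum(sc$weights[vapply(sc$splits, function(s)
      xor(letters[i] %in% s, letters[j] %in% s), logical(1))])
    expect_equal(fit_ij, 2, tolerance = 1e-6)
  }

  expect_error(neighbor_net(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NeighborNet is consistent on random 4-6 taxon tree metrics", {
  set.seed(19)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tm <- random_tree_metric(n)
    ss <- neighbor_net(tm$d, weight_threshold = 1e-6)
    nontrivial <- split_keys_of_each(ss)[lengths(ss$splits) %in% 2:(n - 2)]
    expect_setequal(nontrivial, tm$splits)
    expect_lt(ss$fit, 1e-10)
  }
})

test_that("relabeling taxa permutes splits without changing weights", {
  set.seed(4)
  tm <- random_tree_metric(5)
  perm <- sample(5)
  d2 <- tm$d[perm, perm]
  s1 <- neighbor_net(tm$d)
  s2 <- neighbor_net(d2)
  w1 <- stats::setNames(s1$weights, split_keys_of_each(s1))
  w2 <- stats::setNames(s2$weights, split_keys_of_each(s2))
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))], tolerance = 1e-8)
})

test_that("split bootstrap supports repeated patterns fully", {
  vg <- c(rep("ABE", 30), rep("ABEV", 30), rep("EV", 15))
  inc <- venn_incidence(stats::setNames(vg, paste0("f", seq_along(vg))))
  ss <- split_bootstrap(inc, n_replicates = 25, seed = 3)
  expect_true(all(ss$support >= 0 & ss$support <= 1))
  triv <- lengths(ss$splits) %in% c(1, 3)
  expect_true(all(ss$support[triv] == 1))

  s1 <- split_bootstrap(inc, n_replicates = 1, seed = 3)
  expect_true(all(s1$support %in% c(0, 1)))
  # bit-for-bit reproducibility under the seed
  sa <- split_bootstrap(inc, n_replicates = 10, seed = 11)
  sb <- split_bootstrap(inc, n_replicates = 10, seed = 11)
  expect_identical(sa$support, sb$support)
  expect_identical(sa$weights, sb$weights)
})

test_that("SPLITS NEXUS output carries cycle, weights and confidences", {
  d <- matrix(c(0, 2, 3, 3,  2, 0, 3, 3,  3, 3, 0, 2,  3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "E", "V"), c("A", "B", "E", "V")))
  ss <- neighbor_net(d)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus_splits(ss, path)
  txt <- readLines(path)
  expect_true(any(grepl("BEGIN SPLITS;", txt)))
  expect_true(any(grepl("CYCLE", txt)))
  expect_true(any(grepl("CONFIDENCES=NO", txt)))
  expect_equal(sum(grepl("^\\s*\\[\\d+\\]", txt)), length(ss$splits))

  ss$support <- rep(0.95, length(ss$splits))
  write_nexus_splits(ss, path)
  expect_true(any(grepl("CONFIDENCES=YES", readLines(path))))
  tab <- splits_table(ss)
  expect_equal(nrow(tab), length(ss$splits))
})
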