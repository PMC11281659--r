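# Independent oracles and fixture builders shared across test files.

# Brute-force Wagner length: minimize sum of |i - j| edge costs over all
# internal-node state assignments by exhaustive enumeration. Independent of
# the Sankoff DP under test.
brute_wagner <- function(tree, states, max_state = max(states, na.rm = TRUE)) {
  edge <- tree$edge
  internal <- sort(unique(edge[edge > length(tree$tip.label)]))
  vals <- 0:max_state
  grid <- do.call(expand.grid, rep(list(vals), length(internal)))
  leaf <- states[tree$tip.label]
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_ <- numeric(max(edge))
    assign_[seq_along(leaf)] <- leaf
    assign_[internal] <- as.numeric(grid[r, ])
    cost <- sum(abs(assign_[edge[, 1]] - assign_[edge[, 2]]))
    if (cost < best) best <- cost
  }
  best
}

quartet <- function(split = c("ab|cd", "ac|bd", "ad|bc"),
                    labels = c("a", "b", "c", "d")) {
  split <- match.arg(split)
  nwk <- switch(split,
                "ab|cd" = "((%s,%s),%s,%s);",
                "ac|bd" = "((%s,%s),%s,%s);",
                "ad|bc" = "((%s,%s),%s,%s);")
  ord <- switch(split,
                "ab|cd" = labels[c(1, 2, 3, 4)],
                "ac|bd" = labels[c(1, 3, 2, 4)],
                "ad|bc" = labels[c(1, 4, 2, 3)])
  ape::read.tree(text = do.call(sprintf, c(list(nwk), as.list(ord))))
}

# character_matrix from a plain matrix with default names
cm_of <- function(m, n_states = 24L) {
  if (is.null(rownames(m))) rownames(m) <- letters[seq_len(nrow(m))]
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  character_matrix(m, n_states = n_states)
}

random_cm <- function(n_taxa, n_char, n_states = 10L) {
  m <- matrix(sample.int(n_states, n_taxa * n_char, replace = TRUE) - 1L,
              n_taxa, n_char)
  cm_of(m, n_states = 24L)
}

# Exhaustive minimum length over all unrooted topologies.
exhaustive_best_length <- function(cm) {
  n <- nrow(cm$states)
  tops <- todchron:::tc_all_topologies(n)
  min(vapply(tops, todchron:::tc_length, numeric(1),
             states = cm$states, n_states = cm$n_states))
}

# Canonical bipartition key set of a phylo (for topology comparison; the
# package keys are label-anchored so this is tree-order independent).
topo_key <- function(phy) {
  paste(todchron:::tc_bipartitions(phy$edge, length(phy$tip.label),
                                   phy$tip.label), collapse = ";")
}

# A random additive (tree-metric) distance matrix over n taxa with positive
# branch lengths; returns the matrix and the tree's non-trivial splits as
# canonical keys.
random_tree_metric <- function(n) {
  edge <- todchron:::tc_random_topology(n)
  len <- stats::runif(nrow(edge), 0.5, 2)
  taxa <- paste0("t", seq_len(n))
  maxid <- max(edge)
  adj <- lapply(seq_len(maxid), function(i) integer(0))
  wt <- new.env()
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    assign(paste(min(a, b), max(a, b)), len[r], wt)
  }
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, maxid)
    dist[s] <- 0
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      for (u in adj[[v]]) if (is.na(dist[u])) {
        dist[u] <- dist[v] + get(paste(min(u, v), max(u, v)), wt)
        stack <- c(stack, u)
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  keys <- unlist(lapply(seq_len(nrow(edge)), function(r) {
    side <- todchron:::tc_clade_tips(edge, r, n)
    if (length(side) < 2 || length(side) > n - 2) return(character(0))
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    paste(sort(taxa[side]), collapse = "|")
  }))
  list(d = d, splits = sort(unique(keys)), taxa = taxa)
}

# per-split canonical keys, in split order (anchor: side without the
# lexicographically smallest taxon, so keys compare across taxon orders)
split_keys_of_each <- function(ss) {
  anchor <- sort(ss$taxa)[1]
  vapply(ss$splits, function(s) {
    if (anchor %in% s) s <- setdiff(ss$taxa, s)
    paste(sort(s), collapse = "|")
  }, character(1))
}

split_keys_of <- function(ss) sort(split_keys_of_each(ss))

# tiny census used across files
tiny_census <- function() {
  ab <- matrix(c(5, 0, 2, 1,
                 0, 3, 0, 0,
                 4, 4, 4, 4), nrow = 3, byrow = TRUE,
               dimnames = list(c("c.37.1.12", "b.1.1.1", "a.8.9.1"),
                               c("p1", "p2", "p3", "p4")))
  labels <- data.frame(proteome = paste0("p", 1:4),
                       code = c("A", "B", "E", "V"),
                       subgroup = c("", "", "", "eukaryovirus"))
  census_matrix(ab, labels)
}
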