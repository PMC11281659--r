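# Light edge-matrix tree utilities.
#
# Unrooted binary trees are held the ape way: a (parent, child) edge matrix
# with tips numbered 1..ntip and a basal trifurcation at the root node.
# Internal node ids only need to be > ntip and unique, which lets search
# moves edit edge matrices in place; trees are canonicalized through Newick
# when returned to the user.

tc_root <- function(edge) {
  setdiff(edge[, 1], edge[, 2])[1]
}

# Edge row order with every child subtree before its parent edge
# (reverse preorder).
tc_postorder <- function(edge) {
  root <- tc_root(edge)
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  ord <- integer(nrow(edge))
  n <- 0L
  stack <- kids[[as.character(root)]]
  while (length(stack)) {
    e <- stack[[1]]
    stack <- stack[-1]
    n <- n + 1L
    ord[n] <- e
    ch <- kids[[as.character(edge[e, 2])]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  edge[rev(ord), , drop = FALSE]
}

# Minimum Wagner tree length, summed over characters (the C++ core orders
# edges itself).
tc_length <- function(edge, states, n_states) {
  sum(.sankoff_lengths(edge, states, n_states))
}

tc_newick <- function(edge, tip_label) {
  kids <- split(edge[, 2], edge[, 1])
  render <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(tip_label[v])
    paste0("(", paste(vapply(ch, render, character(1)), collapse = ","), ")")
  }
  paste0(render(tc_root(edge)), ";")
}

tc_to_phylo <- function(edge, tip_label) {
  ape::read.tree(text = tc_newick(edge, tip_label))
}

# Descendant tip indices below the child of edge row i.
tc_clade_tips <- function(edge, i, ntip) {
  kids <- split(edge[, 2], edge[, 1])
  out <- integer(0)
  stack <- edge[i, 2]
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    if (v <= ntip) out <- c(out, v) else
      stack <- c(kids[[as.character(v)]], stack)
  }
  sort(out)
}

# Non-trivial bipartitions as canonical keys: the tip-label set on the side
# not containing the lexicographically smallest label, sorted and joined
# with "|" (label-anchored, so keys are comparable across trees).
tc_bipartitions <- function(edge, ntip, tip_label) {
  internal <- which(edge[, 2] > ntip & edge[, 1] != 0)
  anchor <- which.min(rank(tip_label[seq_len(ntip)]))
  keys <- character(0)
  for (i in internal) {
    side <- tc_clade_tips(edge, i, ntip)
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (anchor %in% side) side <- setdiff(seq_len(ntip), side)
    keys <- c(keys, paste(sort(tip_label[side]), collapse = "|"))
  }
  sort(unique(keys))
}

# Insert tip x on edge row i, using w as the new internal node id.
tc_insert_tip <- function(edge, i, x, w) {
  child <- edge[i, 2]
  edge[i, 2] <- w
  rbind(edge, c(w, child), c(w, x))
}

# All NNI rearrangements around internal edges, as a list of edge matrices.
tc_nni_moves <- function(edge, ntip) {
  moves <- list()
  rows_of_parent <- function(u) which(edge[, 1] == u)
  for (i in seq_len(nrow(edge))) {
    v <- edge[i, 2]
    if (v <= ntip) next
    u <- edge[i, 1]
    vkids <- rows_of_parent(v)
    ukids <- setdiff(rows_of_parent(u), i)
    if (!length(ukids)) next
    j <- ukids[1]                      # deterministic sibling choice
    for (k in vkids) {
      e2 <- edge
      tmp <- e2[j, 2]
      e2[j, 2] <- e2[k, 2]
      e2[k, 2] <- tmp
      moves[[length(moves) + 1L]] <- e2
    }
  }
  moves
}

# Prune the subtree hanging from edge row i; returns list(rest, sub, graft,
# spare) where `graft` is the subtree's root node to reattach and `spare` a
# free internal node id, or NULL when the prune is degenerate.
tc_prune <- function(edge, i, ntip) {
  u <- edge[i, 1]; v <- edge[i, 2]
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  sub_rows <- integer(0)
  stack <- kids[[as.character(v)]]
  while (length(stack)) {
    e <- stack[[1]]; stack <- stack[-1]
    sub_rows <- c(sub_rows, e)
    ch <- kids[[as.character(edge[e, 2])]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  rest_rows <- setdiff(seq_len(nrow(edge)), c(i, sub_rows))
  rest <- edge[rest_rows, , drop = FALSE]
  up <- which(rest[, 2] == u)
  if (length(up)) {                    # u internal non-root: suppress it
    down <- which(rest[, 1] == u)
    if (length(down) != 1) return(NULL)
    rest[up, 2] <- rest[down, 2]
    rest <- rest[-down, , drop = FALSE]
  } else {                             # u was the basal trifurcation
    down <- which(rest[, 1] == u)
    if (length(down) != 2) return(NULL)
    c1 <- rest[down[1], 2]; c2 <- rest[down[2], 2]
    if (c1 <= ntip && c2 <= ntip) return(NULL)
    r <- if (c1 > ntip) c1 else c2
    other <- if (c1 > ntip) c2 else c1
    rest <- rest[-down, , drop = FALSE]
    rest <- rbind(rest, c(r, other))
  }
  list(rest = rest, sub = edge[sub_rows, , drop = FALSE], graft = v, spare = u)
}

# Reattach a pruned subtree on edge row j of `rest`.
tc_regraft <- function(pr, j) {
  rest <- pr$rest
  child <- rest[j, 2]
  rest[j, 2] <- pr$spare
  rbind(rest, c(pr$spare, child), c(pr$spare, pr$graft), pr$sub)
}

# Uniform random unrooted binary topology over tips 1..n (sequential
# addition at uniformly chosen edges).
tc_random_topology <- function(n) {
  edge <- cbind(n + 1L, 1:3)
  w <- n + 1L
  for (x in seq_len(n)[-(1:3)]) {
    w <- w + 1L
    edge <- tc_insert_tip(edge, sample.int(nrow(edge), 1), x, w)
  }
  edge
}

# All unrooted binary topologies on tips 1..n (n <= 8 or so), as edge
# matrices: exhaustive sequential addition.
tc_all_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- cbind(n + 1L, 1:3)
  acc <- list(base)
  w <- n + 1L
  for (x in seq_len(n)[-(1:3)]) {
    w <- w + 1L
    acc <- unlist(lapply(acc, function(e) {
      lapply(seq_len(nrow(e)), function(i) tc_insert_tip(e, i, x, w))
    }), recursive = FALSE)
  }
  acc
}
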