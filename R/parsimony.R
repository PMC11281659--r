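# Maximum parsimony for linearly ordered (Wagner) multistate characters.
# The per-character minimum is computed by Sankoff dynamic programming over
# the 0..S-1 state lattice with |i - j| edge costs (src/sankoff.cpp).

# Align a character matrix's taxa to a tree's tips; error on any mismatch.
cm_states_for <- function(phy, cm) {
  a <- phy$tip.label
  b <- rownames(cm$states)
  if (!setequal(a, b) || length(a) != length(b)) {
    stop("taxon mismatch between tree and matrix: ",
         paste(c(setdiff(a, b), setdiff(b, a)), collapse = ", "))
  }
  cm$states[match(a, b), , drop = FALSE]
}

#' Minimum Wagner steps of one character on a tree
#'
#' Returns the minimum, over all internal-node state assignments, of the sum
#' of per-edge costs `|i - j|` on the linear state graph. `NA` states are
#' missing (`?`): the leaf is initialized at zero cost for every state.
#'
#' @param tree a `phylo` (rooted or unrooted; the result is root-invariant).
#' @param states named integer vector over the tree's tips; `NA` = missing.
#' @param n_states number of ordered states (default `max(states) + 1`).
#' @return integer step count.
#' @export
ordered_char_length <- function(tree, states, n_states = NULL) {
  missing_tip <- setdiff(tree$tip.label, names(states))
  if (length(missing_tip))
    stop("leaf without state entry: ", paste(missing_tip, collapse = ", "))
  v <- as.integer(states[tree$tip.label])
  if (is.null(n_states)) n_states <- max(v, 0L, na.rm = TRUE) + 1L
  m <- matrix(v, ncol = 1)
  sum(.sankoff_lengths(tree$edge, m, as.integer(n_states)))
}

#' Total Wagner parsimony length of a tree on a character matrix
#'
#' @param tree a `phylo` whose tips match the matrix taxa.
#' @param cm a `character_matrix`.
#' @return total steps, summed over characters (root-invariant).
#' @export
tree_length <- function(tree, cm) {
  st <- cm_states_for(tree, cm)
  tc_length(tree$edge, st, cm$n_states)
}

#' Minimum conceivable steps of a character (its state range)
#' @param states integer vector, `NA` = missing.
#' @return `max - min` over non-missing states.
#' @export
char_min_steps <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) stop("all states missing")
  max(states) - min(states)
}

#' Maximum steps of a character: its cost on the fully unresolved bush
#' @param states integer vector, `NA` = missing.
#' @return `min over central state z of sum(|state - z|)`.
#' @export
char_max_steps <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) stop("all states missing")
  min(vapply(min(states):max(states),
             function(z) sum(abs(states - z)), numeric(1)))
}

#' Retention index of a tree on a character matrix
#'
#' `RI = (G - S) / (G - M)` with `G` the summed bush maxima
#' ([char_max_steps()]), `S` the observed tree length and `M` the summed
#' state ranges ([char_min_steps()]); clamped to `[0, 1]`. RI = 1 means no
#' homoplasy beyond the minimum, RI = 0 a star-tree fit.
#'
#' @inheritParams tree_length
#' @return fraction in `[0, 1]`.
#' @export
retention_index <- function(tree, cm) {
  st <- cm_states_for(tree, cm)
  g <- sum(apply(st, 2, char_max_steps))
  m <- sum(apply(st, 2, char_min_steps))
  if (g == m) stop("no retention signal: all characters have max == min steps")
  s <- tree_length(tree, cm)
  min(1, max(0, (g - s) / (g - m)))
}

# Internal core shared by stepwise_addition and mp_search: returns the edge
# matrix over tips 1..ntaxa (matrix row order).
stepwise_core <- function(states, n_states, order_idx) {
  n <- nrow(states)
  o <- order_idx
  edge <- cbind(n + 1L, o[1:3])
  w <- n + 1L
  for (x in o[-(1:3)]) {
    w <- w + 1L
    best <- Inf
    best_edge <- NULL
    for (i in seq_len(nrow(edge))) {
      cand <- tc_insert_tip(edge, i, x, w)
      len <- tc_length(cand, states, n_states)
      if (len < best) {         # strict: ties keep the lowest edge index
        best <- len
        best_edge <- cand
      }
    }
    edge <- best_edge
  }
  edge
}

#' Build a starting tree by greedy stepwise addition
#'
#' Taxa are inserted one at a time at the edge minimizing total tree length;
#' ties are broken by the lowest edge index in a deterministic traversal, so
#' a given seed always yields the same tree.
#'
#' @param cm a `character_matrix` with at least 3 taxa.
#' @param seed integer seed (used only when `addition_order = "random"`).
#' @param addition_order `"as-is"` (matrix row order) or `"random"`.
#' @return an unrooted `phylo`.
#' @export
stepwise_addition <- function(cm, seed = 1L, addition_order = c("as-is", "random")) {
  addition_order <- match.arg(addition_order)
  n <- nrow(cm$states)
  if (n < 3) stop("stepwise addition needs >= 3 taxa")
  o <- seq_len(n)
  if (addition_order == "random") {
    o <- withr_seed(seed, sample.int(n))
  }
  edge <- stepwise_core(cm$states, cm$n_states, o)
  tc_to_phylo(edge, rownames(cm$states))
}

# run expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hill-climb on edge matrices; returns list(edge, length).
swap_core <- function(edge, states, n_states, ntip, moves = "NNI",
                      max_rounds = 20L) {
  len <- tc_length(edge, states, n_states)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    if (moves == "NNI") {
      cands <- tc_nni_moves(edge, ntip)
      for (cand in cands) {
        l2 <- tc_length(cand, states, n_states)
        if (l2 < len) {
          edge <- cand; len <- l2; improved <- TRUE
        }
      }
    } else {  # SPR: best improvement over all prune/regraft pairs per sweep
      best_cand <- NULL
      best_l <- len
      for (i in seq_len(nrow(edge))) {
        pr <- tc_prune(edge, i, ntip)
        if (is.null(pr)) next
        for (j in seq_len(nrow(pr$rest))) {
          cand <- tc_regraft(pr, j)
          l2 <- tc_length(cand, states, n_states)
          if (l2 < best_l) {
            best_l <- l2
            best_cand <- cand
          }
        }
      }
      if (!is.null(best_cand)) {
        edge <- best_cand; len <- best_l; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(edge = edge, length = len)
}

#' Improve a tree by branch swapping
#'
#' Hill-climbs through NNI or SPR rearrangements, accepting strict length
#' improvements, until a full sweep yields none or `max_rounds` is reached.
#'
#' @param start a binary `phylo` starting tree.
#' @param cm a `character_matrix`.
#' @param moves `"NNI"` (default) or `"SPR"`.
#' @param max_rounds sweep limit.
#' @return a `phylo` with length less than or equal to the start's.
#' @export
branch_swap_search <- function(start, cm, moves = c("NNI", "SPR"),
                               max_rounds = 20L) {
  moves <- match.arg(moves)
  st <- cm_states_for(start, cm)
  res <- swap_core(start$edge, st, cm$n_states, length(start$tip.label),
                   moves, max_rounds)
  tc_to_phylo(res$edge, start$tip.label)
}

#' Heuristic maximum-parsimony search
#'
#' Runs `n_replicates` random-addition-order stepwise builds (distinct seeds
#' derived from `seed`), each followed by branch swapping, and collects all
#' distinct topologies tying at the best length.
#'
#' @param cm a `character_matrix` (use [informative_filter()] first).
#' @param n_replicates number of random-addition replicates.
#' @param seed integer seed.
#' @param moves branch-swapping move set, `"NNI"` or `"SPR"`.
#' @param max_rounds swap sweep limit per replicate.
#' @param g1_trees random topologies used for the g1 statistic (0 skips it).
#' @return object of class `search_result`: list with `best_trees` (list of
#'   `phylo`), `length`, `retention_index`, `g1`, `replicates`, `seed`.
#' @export
mp_search <- function(cm, n_replicates = 10L, seed = 1L,
                      moves = c("NNI", "SPR"), max_rounds = 20L,
                      g1_trees = 100L) {
  moves <- match.arg(moves)
  n <- nrow(cm$states)
  if (n < 3) stop("mp_search needs >= 3 taxa")
  states <- cm$states
  best_len <- Inf
  best <- list()
  keys <- character(0)
  for (r in seq_len(n_replicates)) {
    o <- if (r == 1) seq_len(n) else withr_seed(seed + r, sample.int(n))
    edge <- stepwise_core(states, cm$n_states, o)
    res <- swap_core(edge, states, cm$n_states, n, moves, max_rounds)
    if (res$length < best_len - 1e-9) {
      best_len <- res$length
      best <- list(res$edge)
      keys <- paste(tc_bipartitions(res$edge, n, rownames(states)),
                    collapse = ";")
    } else if (abs(res$length - best_len) < 1e-9) {
      k <- paste(tc_bipartitions(res$edge, n, rownames(states)), collapse = ";")
      if (!k %in% keys) {
        best <- c(best, list(res$edge))
        keys <- c(keys, k)
      }
    }
  }
  trees <- lapply(best, tc_to_phylo, tip_label = rownames(states))
  ri <- tryCatch(retention_index(trees[[1]], cm), error = function(e) NA_real_)
  g1 <- if (g1_trees >= 3)
    tryCatch(g1_statistic(cm, g1_trees, seed), error = function(e) NA_real_)
  else NA_real_
  structure(list(best_trees = trees, length = best_len,
                 retention_index = ri, g1 = g1,
                 replicates = n_replicates, seed = seed),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: %d best tree(s), length %d, RI %.3f, g1 %.4f (%d replicates, seed %d)\n",
              length(x$best_trees), x$length, x$retention_index, x$g1,
              x$replicates, x$seed))
  invisible(x)
}

# sample skewness with moment (n) denominators, as used for tree-length
# distributions
g1_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("degenerate length distribution: zero variance")
  mean((x - m)^3) / m2^1.5
}

#' Skewness (g1) of tree lengths over random topologies
#'
#' Samples uniformly random unrooted binary topologies, scores each with
#' [tree_length()], and returns the sample skewness `g1 = m3 / m2^(3/2)`.
#' Strongly negative g1 indicates phylogenetic signal.
#'
#' @param cm a `character_matrix`.
#' @param n_random_trees number of sampled topologies (>= 3).
#' @param seed integer seed.
#' @return real skewness value.
#' @export
g1_statistic <- function(cm, n_random_trees = 1000L, seed = 1L) {
  if (n_random_trees < 3) stop("need at least 3 random trees")
  n <- nrow(cm$states)
  lens <- withr_seed(seed, vapply(seq_len(n_random_trees), function(i) {
    tc_length(tc_random_topology(n), cm$states, cm$n_states)
  }, numeric(1)))
  g1_skewness(lens)
}

#' Bootstrap support of bipartitions
#'
#' Resamples characters with replacement (same count), reruns [mp_search()]
#' per replicate, and tallies internal bipartitions; within a replicate,
#' equally parsimonious trees contribute by strict majority rule.
#'
#' @param cm a `character_matrix`.
#' @param n_replicates number of bootstrap replicates (study-scale default
#'   2000; scale down for interactive use).
#' @param seed integer seed.
#' @param search_params list passed to [mp_search()] (e.g.
#'   `list(n_replicates = 2, moves = "NNI")`).
#' @return data.frame with columns `bipartition` (canonical label set key),
#'   `support` in `[0, 1]` and `n_replicates`.
#' @export
bootstrap_support <- function(cm, n_replicates = 2000L, seed = 1L,
                              search_params = list(n_replicates = 2L)) {
  nch <- ncol(cm$states)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(n_replicates)) {
    idx <- withr_seed(seed + b, sample.int(nch, nch, replace = TRUE))
    bcm <- cm
    bcm$states <- cm$states[, idx, drop = FALSE]
    colnames(bcm$states) <- paste0("bs", seq_len(nch))
    args <- c(list(cm = bcm, seed = seed + b, g1_trees = 0L), search_params)
    sr <- do.call(mp_search, args)
    ntree <- length(sr$best_trees)
    keysets <- lapply(sr$best_trees, function(tr)
      tc_bipartitions(tr$edge, length(tr$tip.label), tr$tip.label))
    counts <- table(unlist(keysets))
    maj <- names(counts)[counts > ntree / 2]
    for (k in maj)
      assign(k, (if (exists(k, tally)) get(k, tally) else 0) + 1, tally)
  }
  keys <- ls(tally)
  data.frame(bipartition = keys,
             support = vapply(keys, get, numeric(1), envir = tally) / n_replicates,
             n_replicates = n_replicates,
             row.names = NULL, stringsAsFactors = FALSE)
}
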