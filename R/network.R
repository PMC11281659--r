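# Circular split networks from Venn incidence data: uncorrected-P distances,
# NeighborNet agglomeration, non-negative least-squares split weights and
# bootstrap supports.

#' Binary incidence matrix of Venn groups over taxa
#'
#' @param vg character vector of canonical Venn groups, one per feature.
#' @param taxa supergroup codes to use as taxa (>= 3; default all four).
#' @return 0/1 matrix, taxa x features.
#' @export
venn_incidence <- function(vg, taxa = SUPERGROUP_CODES) {
  if (length(taxa) < 3) stop("need at least 3 taxa")
  inc <- vapply(vg, function(g) as.integer(taxa %in% strsplit(g, "")[[1]]),
                integer(length(taxa)))
  rownames(inc) <- taxa
  colnames(inc) <- if (!is.null(names(vg))) names(vg) else
    paste0("f", seq_along(vg))
  if (any(colSums(inc) == 0)) stop("all-zero incidence column")
  inc
}

#' Uncorrected-P distances between taxa of an incidence matrix
#'
#' @param inc binary matrix, taxa x features.
#' @return symmetric distance matrix: fraction of differing columns per pair.
#' @export
uncorrected_p <- function(inc) {
  if (!ncol(inc)) stop("incidence matrix has no columns")
  n <- nrow(inc)
  d <- as.matrix(stats::dist(inc, method = "manhattan")) / ncol(inc)
  dimnames(d) <- list(rownames(inc), rownames(inc))
  d
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  P <- rep(FALSE, n)
  for (iter in seq_len(30 * n + 30)) {
    w <- crossprod(A, b - A %*% x)
    if (all(P) || max(w[!P]) <= tol * max(1, max(abs(w)))) break
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[P] > tol)) break
      neg <- P & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P <- P & x > tol
      if (!any(P)) break
    }
    x <- z
    x[!P] <- 0
  }
  pmax(x, 0)
}

# NeighborNet circular ordering (Bryant & Moulton agglomeration with the
# standard 3 -> 2 node reduction). Returns taxon indices in circular order.
nn_ordering <- function(d) {
  n <- nrow(d)
  if (n <= 3) return(seq_len(n))
  d <- unname(d)
  CL <- as.list(seq_len(n))        # active endpoint node ids per cluster
  ORD <- as.list(seq_len(n))       # full taxon ordering per cluster chain
  cluster_dist <- function(CL) {
    l <- length(CL)
    DM <- matrix(0, l, l)
    for (i in seq_len(l - 1)) for (j in (i + 1):l)
      DM[i, j] <- DM[j, i] <- mean(d[CL[[i]], CL[[j]]])
    DM
  }
  # reduction of chain x - y - z to two nodes stored in slots x and z
  reduce3 <- function(x, y, z) {
    u <- (2 * d[x, ] + d[y, ]) / 3
    v <- (2 * d[z, ] + d[y, ]) / 3
    uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
    d[x, ] <<- u; d[, x] <<- u
    d[z, ] <<- v; d[, z] <<- v
    d[x, z] <<- uv; d[z, x] <<- uv
    d[x, x] <<- 0; d[z, z] <<- 0
  }
  while (length(CL) > 1) {
    l <- length(CL)
    DM <- cluster_dist(CL)
    if (l > 2) {
      r <- rowSums(DM) / (l - 2)
      Q <- DM - outer(r, r, "+")
      diag(Q) <- Inf
      idx <- arrayInd(which.min(Q), dim(Q))
      e1 <- min(idx); e2 <- max(idx)
    } else {
      e1 <- 1L; e2 <- 2L
    }
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])
    if (n1 == 1 && n2 == 1) {
      new_cl <- c(CL[[e1]], CL[[e2]])
      new_ord <- c(ORD[[e1]], ORD[[e2]])
    } else {
      # choose the endpoint pair to link, treating endpoints as singletons
      ends <- c(CL[[e1]], CL[[e2]])
      others <- CL[-c(e1, e2)]
      ltmp <- length(ends) + length(others)
      rt <- vapply(ends, function(xi) {
        s <- sum(d[xi, setdiff(ends, xi)])
        if (length(others))
          s <- s + sum(vapply(others, function(cl) mean(d[xi, cl]), numeric(1)))
        s
      }, numeric(1))
      if (ltmp > 2) rt <- rt / (ltmp - 2)
      Q2 <- d[ends, ends, drop = FALSE] - outer(rt, rt, "+")
      cross <- Q2[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
      pick <- arrayInd(which.min(cross), dim(cross))
      i1 <- pick[1]; i2 <- pick[2]   # link CL[[e1]][i1] -- CL[[e2]][i2]
      a_keep <- if (n1 == 2) CL[[e1]][3 - i1] else NULL
      b_keep <- if (n2 == 2) CL[[e2]][3 - i2] else NULL
      a_link <- CL[[e1]][i1]
      b_link <- CL[[e2]][i2]
      ord1 <- if (i1 == n1) ORD[[e1]] else rev(ORD[[e1]])
      ord2 <- if (i2 == 1)  ORD[[e2]] else rev(ORD[[e2]])
      new_ord <- c(ord1, ord2)
      if (n1 == 2 && n2 == 1) {
        reduce3(a_keep, a_link, b_link)
        new_cl <- c(a_keep, b_link)
      } else if (n1 == 1 && n2 == 2) {
        reduce3(a_link, b_link, b_keep)
        new_cl <- c(a_link, b_keep)
      } else {
        reduce3(a_keep, a_link, b_link)
        reduce3(a_keep, b_link, b_keep)
        new_cl <- c(a_keep, b_keep)
      }
    }
    CL[[e1]] <- new_cl
    ORD[[e1]] <- new_ord
    CL <- CL[-e2]
    ORD <- ORD[-e2]
  }
  ORD[[1]]
}

# all splits compatible with a circular ordering, as index vectors into the
# ordering (arcs not containing the first element)
circular_splits <- function(ord) {
  n <- length(ord)
  out <- list()
  for (i in 2:n) for (j in i:n)
    out[[length(out) + 1L]] <- ord[i:j]
  out
}

split_key <- function(members, taxa) {
  if (taxa[1] %in% members) members <- setdiff(taxa, members)
  paste(sort(members), collapse = "|")
}

#' NeighborNet circular split network
#'
#' Agglomerative NeighborNet selection (neighbor-joining criterion over
#' cluster chains with the standard three-node reduction) produces a circular
#' taxon ordering; the weights of all splits compatible with that ordering
#' are then estimated by non-negative least squares against the input
#' distances. Splits with weight below `weight_threshold` are dropped, except
#' trivial (singleton) splits which are always retained.
#'
#' @param dm symmetric non-negative distance matrix with taxon dimnames.
#' @param weight_threshold minimum retained split weight (default 1e-8).
#' @return object of class `split_system`: list with `taxa`, `order`
#'   (circular ordering), `splits` (list of taxon-label vectors, each the
#'   side not containing the first taxon), `weights`, `support` (`NA` until
#'   [split_bootstrap()]), and `fit` (residual sum of squares).
#' @export
neighbor_net <- function(dm, weight_threshold = 1e-8) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  if (!isSymmetric(unname(dm), tol = 1e-12) || any(dm < 0))
    stop("distance matrix must be symmetric and non-negative")
  taxa <- rownames(dm)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  ord <- nn_ordering(dm)
  arcs <- circular_splits(ord)
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  A <- vapply(arcs, function(s) {
    inA <- seq_len(n) %in% s
    as.numeric(xor(inA[pairs[, 1]], inA[pairs[, 2]]))
  }, numeric(nrow(pairs)))
  b <- dm[upper.tri(dm)]
  w <- nnls_solve(A, b)
  trivial <- lengths(arcs) %in% c(1L, n - 1L)
  keep <- trivial | w >= weight_threshold
  fit <- sum((A %*% w - b)^2)
  splits <- lapply(arcs[keep], function(s) sort(taxa[s]))
  splits <- lapply(splits, function(s)
    if (taxa[1] %in% s) sort(setdiff(taxa, s)) else s)
  structure(list(taxa = taxa, order = taxa[ord], splits = splits,
                 weights = w[keep], support = rep(NA_real_, sum(keep)),
                 fit = fit),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system over %d taxa (circular order: %s)\n",
              length(x$taxa), paste(x$order, collapse = " ")))
  for (i in seq_along(x$splits)) {
    cat(sprintf("  %-20s w=%.4g%s\n",
                paste(x$splits[[i]], collapse = "|"), x$weights[i],
                if (!is.na(x$support[i]))
                  sprintf(" support=%.2f", x$support[i]) else ""))
  }
  invisible(x)
}

#' Bootstrap supports for NeighborNet splits
#'
#' Resamples incidence columns with replacement, recomputes uncorrected-P
#' distances and the NeighborNet per replicate, and scores each split of the
#' full-data network by the fraction of replicates whose retained splits
#' include the identical bipartition.
#'
#' @param inc binary incidence matrix, taxa x features.
#' @param n_replicates bootstrap replicates (study-scale default 2000).
#' @param seed integer seed.
#' @param weight_threshold passed to [neighbor_net()].
#' @return the full-data `split_system` with `support` filled in.
#' @export
split_bootstrap <- function(inc, n_replicates = 2000L, seed = 1L,
                            weight_threshold = 1e-8) {
  base <- neighbor_net(uncorrected_p(inc), weight_threshold)
  keys <- vapply(base$splits, split_key, character(1), taxa = base$taxa)
  hits <- stats::setNames(numeric(length(keys)), keys)
  nc <- ncol(inc)
  for (b in seq_len(n_replicates)) {
    idx <- withr_seed(seed + b, sample.int(nc, nc, replace = TRUE))
    ss <- neighbor_net(uncorrected_p(inc[, idx, drop = FALSE]),
                       weight_threshold)
    bk <- unique(vapply(ss$splits, split_key, character(1), taxa = base$taxa))
    got <- keys %in% bk
    hits[got] <- hits[got] + 1
  }
  base$support <- as.numeric(hits / n_replicates)
  base$n_replicates <- n_replicates
  base
}

#' Write a split system as a SplitsTree-compatible NEXUS file
#'
#' Emits TAXA and SPLITS blocks with a CYCLE statement, split weights and,
#' when present, bootstrap confidences.
#'
#' @param ss a `split_system`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_nexus_splits <- function(ss, path) {
  n <- length(ss$taxa)
  cyc <- match(ss$order, ss$taxa)
  has_conf <- any(!is.na(ss$support))
  rows <- vapply(seq_along(ss$splits), function(i) {
    idx <- sort(match(ss$splits[[i]], ss$taxa))
    sprintf("[%d] %.8g%s %s,", i, ss$weights[i],
            if (has_conf) sprintf(" %.4f", ss$support[i]) else "",
            paste(idx, collapse = " "))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", n),
    "  TAXLABELS",
    sprintf("    '%s'", ss$taxa),
    "  ;",
    "END;",
    "BEGIN SPLITS;",
    sprintf("  DIMENSIONS NTAX=%d NSPLITS=%d;", n, length(ss$splits)),
    sprintf("  FORMAT LABELS=NO WEIGHTS=YES CONFIDENCES=%s;",
            if (has_conf) "YES" else "NO"),
    sprintf("  CYCLE %s;", paste(cyc, collapse = " ")),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  ), con)
  invisible(path)
}

#' Tabulate a split system
#'
#' @param ss a `split_system`.
#' @return data.frame with `split` (label-set key), `weight`, `support`.
#' @export
splits_table <- function(ss) {
  data.frame(split = vapply(ss$splits, paste, character(1), collapse = "|"),
             weight = ss$weights, support = ss$support,
             stringsAsFactors = FALSE)
}
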