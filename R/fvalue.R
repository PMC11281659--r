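# Proteome-occupancy (f-value) statistics: per-supergroup distribution
# indices, rank-sum comparisons between virus-shared and cell-unique
# features, and f-value chronologies.

#' Per-supergroup occupancy fractions (f-values)
#'
#' The f-value of a family in a supergroup is the fraction of that
#' supergroup's proteomes containing the family; it measures how widely a
#' domain has spread.
#'
#' @param occ an [to_occurrence()] matrix with at least one proteome per
#'   supergroup code present in the labels.
#' @return numeric matrix, families x codes, values in `[0, 1]`.
#' @export
f_values <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  codes <- sort(unique(occ$labels$code))
  out <- vapply(codes, function(cd) {
    idx <- occ$labels$code == cd
    if (!sum(idx)) stop("supergroup with zero proteomes: ", cd)
    rowMeans(occ$presence[, idx, drop = FALSE])
  }, numeric(nrow(occ$presence)))
  rownames(out) <- rownames(occ$presence)
  out
}

#' Two-sample rank-sum (Mann-Whitney) test with midranks
#'
#' Computes the U statistic of `x` against `y` using midranks for ties. For
#' `length(x) + length(y) <= 12` the two-sided p-value is obtained by exact
#' enumeration of all rank assignments (valid under ties); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative only `"two.sided"` is provided.
#' @return list with `U` (for `x`), `p`, `n_x`, `n_y`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  stopifnot(alternative == "two.sided")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (N <= 12) {
    combos <- utils::combn(N, nx)
    Us <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
    mid <- nx * ny / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = p, n_x = nx, n_y = ny, method = method)
}

#' Compare f-values of virus-shared vs cell-unique families in one supergroup
#'
#' Restricted to families present in the given supergroup (f > 0), tests
#' whether the f-value distributions of the two categories differ
#' (two-sided rank-sum). `U` is oriented for the virus-shared sample, so
#' `U > n_viruses * n_cells / 2` with small `p` means virus-shared families
#' occupy more proteomes.
#'
#' @param fv an [f_values()] matrix.
#' @param category named character vector (`"viruses"`/`"cells"`) per family.
#' @param code supergroup code, one of A/B/E.
#' @return list of class `group_comparison`: `code`, `n_cells`, `n_viruses`,
#'   `U`, `p_two_sided`, `median_viruses`, `median_cells`.
#' @export
compare_categories <- function(fv, category, code) {
  if (!code %in% colnames(fv)) stop("no f-values for code: ", code)
  f <- fv[, code]
  category <- category[rownames(fv)]
  present <- f > 0
  xv <- f[present & category == "viruses"]
  xc <- f[present & category == "cells"]
  if (!length(xv)) stop("no virus-shared families present in code ", code)
  if (!length(xc)) stop("no cell-unique families present in code ", code)
  rs <- rank_sum_test(xv, xc)
  structure(list(code = code, n_cells = length(xc), n_viruses = length(xv),
                 U = rs$U, p_two_sided = rs$p,
                 median_viruses = stats::median(xv),
                 median_cells = stats::median(xc), method = rs$method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison [%s]: U = %.1f (n_viruses=%d, n_cells=%d), p = %.4g (%s)\n  median f: viruses %.3f vs cells %.3f\n",
    x$code, x$U, x$n_viruses, x$n_cells, x$p_two_sided, x$method,
    x$median_viruses, x$median_cells))
  invisible(x)
}

#' f-value chronology along the domain timeline
#'
#' Orders per-family f-values of one supergroup by node distance and adds a
#' sliding-window median (robust to the heavy upper tail of f).
#'
#' @param fv an [f_values()] matrix.
#' @param nd named numeric vector of per-family node distances.
#' @param category named character vector per family.
#' @param code supergroup code.
#' @param window nd window width for the running median (default 0.05).
#' @return data.frame sorted by nd: `id`, `nd`, `f`, `category`,
#'   `window_median`.
#' @export
f_chronology <- function(fv, nd, category, code, window = 0.05) {
  ids <- rownames(fv)
  if (!all(ids %in% names(nd))) stop("nd missing for some families")
  df <- data.frame(id = ids, nd = as.numeric(nd[ids]), f = fv[ids, code],
                   category = as.character(category[ids]),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(df$nd, df$id), ]
  half <- window / 2
  df$window_median <- vapply(seq_len(nrow(df)), function(i) {
    sel <- abs(df$nd - df$nd[i]) <= half & df$category == df$category[i]
    stats::median(df$f[sel])
  }, numeric(1))
  rownames(df) <- NULL
  df
}
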