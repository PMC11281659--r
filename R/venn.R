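# Venn groups over {A, B, E, V}, evolutionary phases, accumulation curves,
# phase-count tables and the phase-presence grid.

PHASE_LABELS <- c("0", "I", "II", "III", "IV", "V")

ALL_VENN_GROUPS <- {
  g <- unlist(lapply(1:4, function(k)
    apply(utils::combn(SUPERGROUP_CODES, k), 2, paste, collapse = "")))
  g
}

canonical_group <- function(codes) {
  paste(SUPERGROUP_CODES[SUPERGROUP_CODES %in% codes], collapse = "")
}

#' Venn group of one family
#'
#' The Venn group of a feature is the set of supergroup codes whose proteomes
#' contain it, named canonically in the fixed order A, B, E, V (15 possible
#' non-empty groups, e.g. `"ABEV"`, `"BEV"`, `"V"`).
#'
#' @param occ an [to_occurrence()] matrix.
#' @param family family id.
#' @return canonical group name.
#' @export
venn_group <- function(occ, family) {
  if (!family %in% rownames(occ$presence))
    stop("unknown family id: ", family)
  codes <- unique(occ$labels$code[occ$presence[family, ]])
  if (!length(codes)) stop("orphan family (present in no proteome): ", family)
  canonical_group(codes)
}

#' Venn groups of every family in an occurrence matrix
#'
#' @param occ an [to_occurrence()] matrix.
#' @param orphans `"error"` (default) or `"drop"` families present nowhere.
#' @return named character vector of canonical group names.
#' @export
venn_groups <- function(occ, orphans = c("error", "drop")) {
  orphans <- match.arg(orphans)
  pres <- occ$presence
  code <- occ$labels$code
  hit <- vapply(SUPERGROUP_CODES, function(cd)
    rowSums(pres[, code == cd, drop = FALSE]) > 0, logical(nrow(pres)))
  empty <- rowSums(hit) == 0
  if (any(empty)) {
    if (orphans == "error")
      stop("orphan family (present in no proteome): ",
           paste(rownames(pres)[empty], collapse = ", "))
    hit <- hit[!empty, , drop = FALSE]
  }
  stats::setNames(apply(hit, 1, function(h) canonical_group(SUPERGROUP_CODES[h])),
                  rownames(hit))
}

#' Category of a Venn group: shared with viruses or unique to cells
#'
#' @param vg canonical Venn group name(s).
#' @return `"viruses"` when V is a member, else `"cells"` (vectorized).
#' @export
category_of <- function(vg) {
  bad <- setdiff(unique(vg), ALL_VENN_GROUPS)
  if (length(bad)) stop("invalid Venn group: ", paste(bad, collapse = ", "))
  ifelse(grepl("V", vg), "viruses", "cells")
}

#' First appearance (minimum nd) of each Venn group
#'
#' @param nd named numeric vector of per-feature node distances.
#' @param vg named character vector of per-feature Venn groups (same ids).
#' @return named numeric vector: per group present, its minimum nd, ordered
#'   by appearance.
#' @export
first_appearances <- function(nd, vg) {
  ids <- names(nd)
  if (is.null(ids) || !setequal(ids, names(vg)))
    stop("nd and vg must be named over the same features")
  vg <- vg[ids]
  first <- tapply(nd, vg, min)
  sort(stats::setNames(as.numeric(first), names(first)))
}

DEFAULT_MARKERS <- list(
  I   = "ABE",
  II  = "BEV",
  III = c("ABV", "BV", "AB", "B"),
  IV  = "V",
  V   = c("AEV", "EV", "AE", "E")
)

#' Delimit the six evolutionary phases from Venn-group first appearances
#'
#' Phase boundaries are the first-appearance nd values of designated marker
#' groups: by default Phase I opens with ABE, II with BEV, III with the
#' earliest bacterial-side group (ABV/BV/AB/B), IV with the virus-specific
#' group V, and V with the earliest eukaryal-side group (AEV/EV/AE/E).
#' Phases are half-open `[b_k, b_{k+1})`, so a feature at an exact boundary
#' belongs to the later phase; Phase 0 is `[0, b1)` and Phase V runs to 1
#' inclusive.
#'
#' @param first a [first_appearances()] map.
#' @param marker_map named list (phases I..V) of candidate marker groups.
#' @return object of class `phase_timeline`: list with `boundaries` (named
#'   b1..b5) and `markers` (the group realizing each boundary).
#' @export
delimit_phases <- function(first, marker_map = DEFAULT_MARKERS) {
  if (!identical(names(marker_map), c("I", "II", "III", "IV", "V")))
    stop("marker_map must name phases I..V")
  boundaries <- numeric(5)
  markers <- character(5)
  for (k in 1:5) {
    cand <- intersect(marker_map[[k]], names(first))
    if (!length(cand))
      stop("missing marker group for phase ", names(marker_map)[k], ": ",
           paste(marker_map[[k]], collapse = "/"))
    b <- min(first[cand])
    boundaries[k] <- b
    markers[k] <- cand[which.min(first[cand])]
  }
  if (any(diff(boundaries) <= 0))
    stop("non-increasing phase boundaries: ",
         paste(signif(boundaries, 4), collapse = ", "))
  names(boundaries) <- names(markers) <- c("I", "II", "III", "IV", "V")
  structure(list(boundaries = boundaries, markers = markers),
            class = "phase_timeline")
}

#' @export
print.phase_timeline <- function(x, ...) {
  cat("phase_timeline boundaries (nd):\n")
  print(round(x$boundaries, 4))
  cat("markers:", paste(sprintf("%s<-%s", names(x$markers), x$markers),
                        collapse = " "), "\n")
  invisible(x)
}

#' An evenly spaced six-phase timeline
#'
#' Boundaries at `k/6` for `k = 1..5`. Used as the [run_pipeline()] fallback
#' when the configured marker groups do not delimit increasing boundaries on
#' a recovered chronology (small or noisy censuses), and to lay printed
#' phase-count tables onto the `[0, 1]` axis.
#'
#' @return a `phase_timeline`.
#' @export
even_phase_timeline <- function() {
  structure(list(
    boundaries = stats::setNames(1:5 / 6, c("I", "II", "III", "IV", "V")),
    markers = stats::setNames(rep("(even)", 5), c("I", "II", "III", "IV", "V"))),
    class = "phase_timeline")
}

#' Assign features to evolutionary phases
#'
#' @param nd numeric vector of node distances in `[0, 1]`.
#' @param timeline a [delimit_phases()] result.
#' @return factor with levels `0, I, II, III, IV, V`.
#' @export
phase_of <- function(nd, timeline) {
  stopifnot(inherits(timeline, "phase_timeline"))
  idx <- findInterval(nd, timeline$boundaries) + 1L
  factor(PHASE_LABELS[idx], levels = PHASE_LABELS)
}

round2 <- function(x) round_half_up(x * 100) / 100

#' Per-phase counts of domains and prototypes with prototype/domain ratios
#'
#' Counts features by the phase of their first appearance, split into the
#' virus-shared and cell-unique categories and by feature kind, and derives
#' the prototypes/domains ratio per phase and category (half-up to 2
#' decimals; `"-"` where the domain count is zero).
#'
#' @param features data.frame with columns `nd`, `vg` (canonical Venn group)
#'   and `kind` (`"domain"` or `"prototype"`).
#' @param timeline a [delimit_phases()] result.
#' @return data.frame: `phase`, `category`, `prototypes`, `domains`, `ratio`
#'   (numeric, `NA` when undefined) and `ratio_label` (printed form).
#' @export
phase_count_table <- function(features, timeline) {
  stopifnot(all(c("nd", "vg", "kind") %in% names(features)))
  ph <- phase_of(features$nd, timeline)
  cat_ <- factor(category_of(features$vg), levels = c("viruses", "cells"))
  kind <- factor(features$kind, levels = c("prototype", "domain"))
  tab <- table(phase = ph, category = cat_, kind = kind)
  out <- expand.grid(phase = PHASE_LABELS, category = c("viruses", "cells"),
                     stringsAsFactors = FALSE)
  out$prototypes <- mapply(function(p, cc) tab[p, cc, "prototype"],
                           out$phase, out$category)
  out$domains <- mapply(function(p, cc) tab[p, cc, "domain"],
                        out$phase, out$category)
  out$ratio <- ifelse(out$domains > 0, round2(out$prototypes / out$domains),
                      NA_real_)
  out$ratio_label <- ifelse(is.na(out$ratio), "-", sprintf("%.2f", out$ratio))
  out
}

#' Cumulative feature counts at phase boundaries
#'
#' For each phase boundary (and the timeline end at nd = 1), counts features
#' that appeared strictly before the boundary, per Venn group and per
#' category, so the cumulative count at a boundary equals the sum of the
#' completed phases' counts.
#'
#' @param nd named numeric vector of feature node distances.
#' @param vg named character vector of feature Venn groups.
#' @param timeline a [delimit_phases()] result.
#' @return list with data.frames `by_category` and `by_group` (one row per
#'   boundary, columns `boundary`, `nd`, then cumulative counts).
#' @export
accumulation_curves <- function(nd, vg, timeline) {
  stopifnot(inherits(timeline, "phase_timeline"))
  cuts <- c(timeline$boundaries, end = 1)
  cat_ <- category_of(vg)
  groups <- intersect(ALL_VENN_GROUPS, unique(vg))
  cum_at <- function(b, strict) if (strict) nd < b else nd <= b
  rows_cat <- lapply(seq_along(cuts), function(k) {
    sel <- cum_at(cuts[k], strict = names(cuts)[k] != "end")
    data.frame(boundary = names(cuts)[k], nd = as.numeric(cuts[k]),
               viruses = sum(sel & cat_ == "viruses"),
               cells = sum(sel & cat_ == "cells"),
               stringsAsFactors = FALSE)
  })
  rows_grp <- lapply(seq_along(cuts), function(k) {
    sel <- cum_at(cuts[k], strict = names(cuts)[k] != "end")
    cnt <- vapply(groups, function(g) sum(sel & vg == g), numeric(1))
    cbind(data.frame(boundary = names(cuts)[k], nd = as.numeric(cuts[k]),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cnt), check.names = FALSE))
  })
  list(by_category = do.call(rbind, rows_cat),
       by_group = do.call(rbind, rows_grp))
}

#' Supergroup-specificity percentages
#'
#' Percentage of features whose Venn group is a singleton ({A}, {B}, {E} or
#' {V}), to 2 decimals, plus the shared fraction `100 - sum(singletons)` to
#' 1 decimal.
#'
#' @param vg character vector of canonical Venn groups.
#' @return list with `singletons` (named numeric, percent per code) and
#'   `shared` (percent).
#' @export
specificity_summary <- function(vg) {
  if (!length(vg)) stop("no features")
  n <- length(vg)
  singles <- vapply(SUPERGROUP_CODES, function(cd)
    round2(100 * sum(vg == cd) / n), numeric(1))
  shared <- round_half_up((100 - sum(singles)) * 10) / 10
  list(singletons = singles, shared = shared)
}

#' Venn-group x phase presence grid
#'
#' @param nd named numeric vector of feature node distances.
#' @param vg named character vector of feature Venn groups.
#' @param timeline a [delimit_phases()] result.
#' @return logical matrix: 15 canonical Venn groups x 6 phases; `TRUE` when
#'   at least one feature of the group first appears within the phase.
#' @export
presence_grid <- function(nd, vg, timeline) {
  ph <- phase_of(nd, timeline)
  grid <- matrix(FALSE, length(ALL_VENN_GROUPS), length(PHASE_LABELS),
                 dimnames = list(ALL_VENN_GROUPS, PHASE_LABELS))
  tab <- table(vg, ph) > 0
  grid[rownames(tab), colnames(tab)] <- tab
  grid
}
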