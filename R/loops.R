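# Loop-prototype to domain-family mappings: e-value filtering, the
# non-modular criterion, and projection of prototypes onto the domain
# chronology and Venn framework.

#' Construct a prototype-to-family map
#'
#' @param edges data.frame with columns `prototype`, `family`, `evalue`.
#' @param threshold strict e-value cutoff; edges with `evalue < threshold`
#'   are retained, all others dropped (the count is recorded).
#' @return object of class `prototype_map`: list with `edges` (retained) and
#'   `threshold`; attribute `n_dropped`.
#' @export
prototype_map <- function(edges, threshold = 0.001) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("prototype", "family", "evalue") %in% names(edges)))
  edges$evalue <- as.numeric(edges$evalue)
  if (any(is.na(edges$evalue))) stop("malformed e-value in prototype map")
  keep <- edges$evalue < threshold
  out <- structure(list(edges = edges[keep, , drop = FALSE],
                        threshold = threshold),
                   class = "prototype_map")
  attr(out, "n_dropped") <- sum(!keep)
  rownames(out$edges) <- NULL
  out
}

#' Read a prototype-to-family mapping TSV
#'
#' Expects columns `prototype` (ArchDB-style ids such as
#' `"DS.HH.1.1.190"`), `family` (SCOP ccs) and `evalue`; retains edges with
#' e-value strictly below `threshold`.
#'
#' @param path TSV path.
#' @param threshold strict e-value cutoff (default 0.001).
#' @return a [prototype_map()].
#' @export
read_prototype_map <- function(path, threshold = 0.001) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("prototype", "family", "evalue") %in% names(tab)))
    stop("prototype map needs columns prototype, family, evalue")
  ev <- suppressWarnings(as.numeric(tab$evalue))
  if (any(is.na(ev)))
    stop("malformed e-value at line ", which(is.na(ev))[1] + 1L)
  tab$evalue <- ev
  prototype_map(tab, threshold)
}

#' Identify non-modular prototypes
#'
#' A prototype is non-modular when it maps to exactly one domain family, or,
#' with `nd_window > 0`, when all its mapped families have similar times of
#' origin (nd span at most `nd_window`). Modular prototypes — recruited into
#' families of clearly different ages — are excluded.
#'
#' @param pm a [prototype_map()].
#' @param nd named numeric vector of per-family node distances (must cover
#'   every mapped family when `nd_window > 0`).
#' @param nd_window maximum allowed nd span (default 0: strict single-family
#'   criterion).
#' @return character vector of non-modular prototype ids.
#' @export
non_modular_filter <- function(pm, nd = NULL, nd_window = 0) {
  stopifnot(inherits(pm, "prototype_map"))
  fams <- split(pm$edges$family, pm$edges$prototype)
  fams <- fams[unique(pm$edges$prototype)]    # preserve first-seen order
  keep <- vapply(fams, function(f) {
    f <- unique(f)
    if (length(f) == 1) return(TRUE)
    if (nd_window <= 0) return(FALSE)
    if (is.null(nd) || !all(f %in% names(nd)))
      stop("nd required for every mapped family when nd_window > 0")
    diff(range(nd[f])) <= nd_window
  }, logical(1))
  names(fams)[keep]
}

#' Project prototypes onto the domain chronology
#'
#' The time of origin of a prototype is the minimum nd among its mapped
#' families (its earliest structural use).
#'
#' @param pm a [prototype_map()].
#' @param nd named numeric vector of per-family node distances.
#' @param prototypes optional subset of prototype ids (e.g. the
#'   [non_modular_filter()] output); default all mapped prototypes.
#' @return named numeric vector: nd per prototype.
#' @export
prototype_chronology <- function(pm, nd, prototypes = NULL) {
  stopifnot(inherits(pm, "prototype_map"))
  edges <- pm$edges
  if (!is.null(prototypes)) edges <- edges[edges$prototype %in% prototypes, ]
  miss <- setdiff(unique(edges$family), names(nd))
  if (length(miss)) stop("nd missing for mapped families: ",
                         paste(miss, collapse = ", "))
  out <- tapply(nd[edges$family], edges$prototype, min)
  stats::setNames(as.numeric(out), names(out))[unique(edges$prototype)]
}

#' Venn groups of prototypes
#'
#' A prototype's Venn group is the union of supergroup codes over its mapped
#' families' groups.
#'
#' @param pm a [prototype_map()].
#' @param vg named character vector of per-family canonical Venn groups.
#' @param prototypes optional subset of prototype ids.
#' @return named character vector of canonical groups per prototype.
#' @export
prototype_venn <- function(pm, vg, prototypes = NULL) {
  stopifnot(inherits(pm, "prototype_map"))
  edges <- pm$edges
  if (!is.null(prototypes)) edges <- edges[edges$prototype %in% prototypes, ]
  miss <- setdiff(unique(edges$family), names(vg))
  if (length(miss)) stop("Venn group missing for mapped families: ",
                         paste(miss, collapse = ", "))
  fams <- split(edges$family, edges$prototype)
  out <- vapply(fams, function(f)
    canonical_group(unique(unlist(strsplit(vg[unique(f)], "")))),
    character(1))
  out[unique(edges$prototype)]
}
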