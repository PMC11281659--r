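#' @useDynLib todchron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SUPERGROUP_CODES <- c("A", "B", "E", "V")

#' Construct a domain-family abundance census
#'
#' A census records the total count (abundance) of each protein domain family
#' (rows, identified e.g. by SCOP concise classification strings such as
#' `"c.37.1.12"`) in a set of proteomes (columns), each proteome labelled with
#' one of the four supergroup codes `A` (Archaea), `B` (Bacteria), `E`
#' (Eukarya) or `V` (viruses) and an optional subgroup tag (e.g.
#' `"eukaryovirus"`).
#'
#' @param abundance integer matrix of non-negative counts; rownames are family
#'   ids, colnames are proteome ids.
#' @param labels data.frame with columns `proteome`, `code` and optionally
#'   `subgroup`, covering every proteome of `abundance`.
#' @return an object of class `census_matrix`: a list with elements
#'   `abundance` (integer matrix) and `labels` (data.frame, one row per
#'   proteome, in column order of the matrix).
#' @export
census_matrix <- function(abundance, labels) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs family rownames and proteome colnames")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate family id: ",
         paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
               collapse = ", "))
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate proteome id: ",
         paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
               collapse = ", "))
  if (any(is.na(abundance)))
    stop("abundance contains missing values")
  if (any(abundance < 0) || any(abundance != floor(abundance))) {
    bad <- which(abundance < 0 | abundance != floor(abundance),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("abundance must be non-negative integers; offending cell (%s, %s)",
                 rownames(abundance)[bad[1]], colnames(abundance)[bad[2]]))
  }
  storage.mode(abundance) <- "integer"
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (!all(c("proteome", "code") %in% names(labels)))
    stop("labels need columns 'proteome' and 'code'")
  if (is.null(labels$subgroup)) labels$subgroup <- ""
  labels$subgroup[is.na(labels$subgroup)] <- ""
  missing_lab <- setdiff(colnames(abundance), labels$proteome)
  if (length(missing_lab))
    stop("unlabeled proteome: ", paste(missing_lab, collapse = ", "))
  labels <- labels[match(colnames(abundance), labels$proteome),
                   c("proteome", "code", "subgroup")]
  rownames(labels) <- NULL
  bad_code <- setdiff(unique(labels$code), SUPERGROUP_CODES)
  if (length(bad_code))
    stop("invalid supergroup code: ", paste(bad_code, collapse = ", "))
  zero_rows <- rownames(abundance)[rowSums(abundance) == 0]
  out <- structure(list(abundance = abundance, labels = labels),
                   class = "census_matrix")
  attr(out, "zero_rows") <- zero_rows
  out
}

#' @export
print.census_matrix <- function(x, ...) {
  cat(sprintf("census_matrix: %d domain families x %d proteomes\n",
              nrow(x$abundance), ncol(x$abundance)))
  tab <- table(factor(x$labels$code, levels = SUPERGROUP_CODES))
  cat("proteomes per supergroup:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  zr <- attr(x, "zero_rows")
  if (length(zr)) cat(sprintf("zero-abundance families retained: %d\n", length(zr)))
  invisible(x)
}

#' Read a census and its proteome labels from TSV files
#'
#' The census table has one header line of proteome ids, family ids in the
#' first column, and integer abundance cells. The labels table has columns
#' `proteome`, `code` (one of A/B/E/V) and optionally `subgroup`.
#'
#' @param path path to the census TSV.
#' @param labels_path path to the proteome label TSV.
#' @return a [census_matrix()].
#' @export
read_census <- function(path, labels_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("census table needs a family id column and >=1 proteome")
  fam <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(fam, colnames(m))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric abundance cell at (%s, %s): '%s'",
                 fam[bad[1]], colnames(m)[bad[2]], m[bad[1], bad[2]]))
  }
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  census_matrix(num, labels)
}

#' Write a census and its labels to TSV files
#'
#' @param census a [census_matrix()].
#' @param path census TSV output path.
#' @param labels_path labels TSV output path.
#' @return invisibly, `census`.
#' @export
write_census <- function(census, path, labels_path) {
  stopifnot(inherits(census, "census_matrix"))
  df <- data.frame(family = rownames(census$abundance),
                   census$abundance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(census$labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(census)
}

#' Derive a presence/absence (occurrence) matrix from a census
#'
#' @param census a [census_matrix()].
#' @return an object of class `occurrence_matrix`: list with `presence`
#'   (logical matrix, same axes as the census) and `labels`.
#' @export
to_occurrence <- function(census) {
  stopifnot(inherits(census, "census_matrix"))
  structure(list(presence = census$abundance > 0, labels = census$labels),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d families x %d proteomes (%.1f%% present)\n",
              nrow(x$presence), ncol(x$presence), 100 * mean(x$presence)))
  invisible(x)
}

#' Per-supergroup occupancy of one family
#'
#' Counts, for each supergroup code, how many of its proteomes contain the
#' family, relative to the supergroup's proteome total.
#'
#' @param occ an [to_occurrence()] result.
#' @param family a family id present in the occurrence matrix.
#' @return named list per code: integer vector `c(present, total)`.
#' @export
supergroup_occupancy <- function(occ, family) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (!family %in% rownames(occ$presence))
    stop("unknown family id: ", family)
  codes <- sort(unique(occ$labels$code))
  out <- lapply(codes, function(cd) {
    idx <- occ$labels$code == cd
    c(present = sum(occ$presence[family, idx]), total = sum(idx))
  })
  names(out) <- codes
  out
}
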