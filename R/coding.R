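# Character coding: abundance census -> ordered multistate characters.
# Taxa are domain families; characters are proteomes.

NEXUS_SYMBOLS <- strsplit("0123456789ABCDEFGHIJKLMN", "")[[1]]

round_half_up <- function(x) floor(x + 0.5)

#' Encode an abundance census as ordered multistate characters
#'
#' Raw abundances are log-transformed, rescaled per proteome by its maximum
#' abundance, and binned into `n_states` ordered states:
#' `state = round((n_states - 1) * ln(a + 1) / ln(m + 1))` with `m` the
#' per-proteome maximum (rounding half-up). Zero abundance always maps to
#' state 0 and the proteome maximum to `n_states - 1`, so the coding is
#' monotone in abundance within each proteome and robust to unequal proteome
#' sizes. Proteomes whose abundances are all zero are encoded as all-zero
#' characters and flagged.
#'
#' @param census a [census_matrix()].
#' @param n_states number of ordered states (default 24, the NEXUS alphabet
#'   limit of [write_nexus()]).
#' @param rescale `"per-proteome"` (default) normalizes by each proteome's
#'   maximum; `"global"` by the global maximum.
#' @return object of class `character_matrix`: list with `states` (integer
#'   matrix taxa x characters), `labels` (proteome labels), `n_states`, and
#'   attribute `degenerate` naming all-zero proteomes.
#' @export
encode_states <- function(census, n_states = 24L,
                          rescale = c("per-proteome", "global")) {
  stopifnot(inherits(census, "census_matrix"), n_states >= 2)
  rescale <- match.arg(rescale)
  a <- census$abundance
  m <- switch(rescale,
              "per-proteome" = apply(a, 2, max),
              "global" = rep(max(a), ncol(a)))
  degenerate <- colnames(a)[m == 0]
  denom <- ifelse(m > 0, log(m + 1), 1)
  st <- round_half_up((n_states - 1) * log(a + 1) /
                        matrix(denom, nrow(a), ncol(a), byrow = TRUE))
  st[, m == 0] <- 0L
  storage.mode(st) <- "integer"
  if (length(degenerate))
    warning("all-zero proteome(s) encoded as constant state 0: ",
            paste(degenerate, collapse = ", "))
  structure(list(states = st, labels = census$labels,
                 n_states = as.integer(n_states)),
            class = "character_matrix", degenerate = degenerate)
}

#' Construct a character matrix directly from states
#'
#' @param states integer matrix (taxa x characters), `NA` = missing.
#' @param n_states number of ordered states.
#' @param labels optional proteome label data.frame (`proteome`, `code`).
#' @return a `character_matrix`.
#' @export
character_matrix <- function(states, n_states = 24L, labels = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states)))
    rownames(states) <- paste0("t", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- paste0("ch", seq_len(ncol(states)))
  storage.mode(states) <- "integer"
  if (any(states < 0 | states > n_states - 1, na.rm = TRUE))
    stop("states must lie in 0..n_states-1")
  if (is.null(labels))
    labels <- data.frame(proteome = colnames(states), code = NA_character_,
                         subgroup = "", stringsAsFactors = FALSE)
  structure(list(states = states, labels = labels,
                 n_states = as.integer(n_states)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters, %d ordered states\n",
              nrow(x$states), ncol(x$states), x$n_states))
  invisible(x)
}

#' Drop parsimony-uninformative characters
#'
#' A character is retained when at least two distinct states are each carried
#' by at least two taxa (shared-and-derived criterion); otherwise it is
#' dropped as `"constant"` (a single observed state) or
#' `"autapomorphic-only"` (variation confined to single taxa). Missing
#' entries are ignored when counting.
#'
#' @param cm a `character_matrix`.
#' @return list with `matrix` (the filtered `character_matrix`) and `report`
#'   (list with `kept` ids and `dropped` data.frame of id/reason).
#' @export
informative_filter <- function(cm) {
  stopifnot(inherits(cm, "character_matrix"))
  reason <- vapply(seq_len(ncol(cm$states)), function(j) {
    tab <- table(cm$states[, j], useNA = "no")
    if (length(tab) < 2) return("constant")
    if (sum(tab >= 2) < 2) return("autapomorphic-only")
    ""
  }, character(1))
  keep <- reason == ""
  if (!any(keep)) stop("no informative characters")
  kept <- colnames(cm$states)[keep]
  dropped <- data.frame(id = colnames(cm$states)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- cm
  out$states <- cm$states[, keep, drop = FALSE]
  out$labels <- cm$labels[keep, , drop = FALSE]
  list(matrix = out, report = list(kept = kept, dropped = dropped))
}

#' Write a character matrix as a NEXUS DATA block
#'
#' States 0..23 map to the fixed symbol order `0123456789ABCDEFGHIJKLMN`
#' (`FORMAT RESPECTCASE`); missing states are written as `?`. Taxon labels
#' are single-quoted so SCOP ids with dots survive round trips. A minimal
#' ASSUMPTIONS block declares all characters ordered (Wagner).
#'
#' @param cm a `character_matrix` with `n_states <= 24`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_nexus <- function(cm, path) {
  stopifnot(inherits(cm, "character_matrix"))
  if (cm$n_states > 24) stop("alphabet exhausted: n_states > 24")
  st <- cm$states
  sym <- matrix("?", nrow(st), ncol(st))
  ok <- !is.na(st)
  sym[ok] <- NEXUS_SYMBOLS[st[ok] + 1L]
  rows <- apply(sym, 1, paste, collapse = "")
  lab <- sprintf("'%s'", rownames(st))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? RESPECTCASE;",
            paste(NEXUS_SYMBOLS[seq_len(min(cm$n_states, 24L))], collapse = "")),
    "  MATRIX",
    sprintf("    %-*s %s", max(nchar(lab)), lab, rows),
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    sprintf("  TYPESET * default = ord: 1-%d;", ncol(st)),
    "END;"
  ), con)
  invisible(path)
}

#' Read a NEXUS DATA block written by [write_nexus()]
#'
#' A minimal reader for the dialect this package emits (single-quoted taxon
#' labels, one matrix row per taxon, `?` for missing).
#'
#' @param path NEXUS file path.
#' @param n_states number of ordered states to record.
#' @return a `character_matrix`.
#' @export
read_nexus_states <- function(path, n_states = 24L) {
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", lines)[1]
  if (is.na(i0)) stop("no MATRIX statement found")
  i1 <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > i0)[1]
  body <- trimws(lines[(i0 + 1):(i1 - 1)])
  body <- body[nzchar(body)]
  m <- regmatches(body, regexec("^'([^']*)'\\s+(\\S+)$", body))
  if (any(lengths(m) != 3)) stop("unparseable matrix row")
  labels <- vapply(m, `[`, character(1), 2)
  rows <- vapply(m, `[`, character(1), 3)
  chars <- strsplit(rows, "")
  if (length(unique(lengths(chars))) != 1) stop("ragged matrix rows")
  st <- t(vapply(chars, function(ch) {
    v <- match(ch, NEXUS_SYMBOLS) - 1L
    v[ch == "?"] <- NA_integer_
    if (any(is.na(v) & ch != "?")) stop("unknown state symbol")
    v
  }, integer(length(chars[[1]]))))
  rownames(st) <- labels
  colnames(st) <- paste0("ch", seq_len(ncol(st)))
  character_matrix(st, n_states = n_states)
}
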