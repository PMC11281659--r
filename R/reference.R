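# Printed summary counts from the published structural phylogenomic census
# of 3892 SCOP domain families across 8127 proteomes and 5125 non-modular
# loop prototypes. These are desk-scale inputs for worked examples and
# consistency checks; the underlying census itself is not redistributed.

#' Reference summary counts of the published domain/loop census
#'
#' Returns the printed summary tables of the census this package's analysis
#' chain was designed around: proteome counts per supergroup, per-phase
#' counts of newly appearing domains and non-modular loop prototypes split by
#' the virus-shared and cell-unique categories, Venn category totals, and
#' supergroup-specific (singleton) feature counts. Singleton counts other
#' than the 95 virus-specific domain families are reconstructed from printed
#' percentages (they round-trip to the printed values; the viral prototype
#' percentage is a known rounding artefact of the source).
#'
#' @return list with elements `proteomes` (named counts, plus
#'   `virus_subgroups`), `phase_counts` (data.frame: phase, category,
#'   prototypes, domains), `category_totals` (list `domains`, `prototypes`),
#'   and `singletons` (list `domains`, `prototypes`, reconstructed counts).
#' @export
reference_counts <- function() {
  phases <- c("0", "I", "II", "III", "IV", "V")
  phase_counts <- data.frame(
    phase = rep(phases, 2),
    category = rep(c("viruses", "cells"), each = 6),
    prototypes = c(128, 196, 495, 629, 879, 535,
                   0, 40, 378, 656, 1146, 303),
    domains = c(20, 47, 162, 368, 670, 259,
                0, 12, 161, 450, 1445, 298),
    stringsAsFactors = FALSE
  )
  list(
    proteomes = c(A = 139L, B = 1734L, E = 210L, V = 6044L),
    virus_subgroups = c(archaeovirus = 85L, bacteriovirus = 2161L,
                        eukaryovirus = 4224L),
    phase_counts = phase_counts,
    category_totals = list(domains = c(viruses = 1526L, cells = 2366L),
                           prototypes = c(viruses = 2722L, cells = 2403L)),
    singletons = list(domains = c(A = 33L, B = 324L, E = 448L, V = 95L),
                      prototypes = c(A = 15L, B = 206L, E = 220L, V = 68L))
  )
}

#' Expand reference phase counts into a per-feature table
#'
#' Builds one synthetic feature per counted unit, placed at its phase's
#' midpoint on an evenly spaced six-phase timeline and tagged with a Venn
#' group of the right category (ABEV/BEV for virus-shared, ABE for
#' cell-unique), so the package's phase-accounting operations can be run
#' directly on the printed counts.
#'
#' @param kind `"domain"`, `"prototype"` or `"both"`.
#' @return list with `features` (data.frame id/nd/vg/kind) and `timeline`
#'   (the evenly spaced [delimit_phases()]-shaped `phase_timeline`).
#' @export
reference_features <- function(kind = c("both", "domain", "prototype")) {
  kind <- match.arg(kind)
  rc <- reference_counts()
  timeline <- even_phase_timeline()
  mids <- stats::setNames(seq(0, 5) / 6 + 1 / 12, c("0", PHASE_LABELS[-1]))
  rows <- list()
  for (r in seq_len(nrow(rc$phase_counts))) {
    pc <- rc$phase_counts[r, ]
    vg <- if (pc$category == "viruses") "BEV" else "ABE"
    for (k in c("prototype", "domain")) {
      if (kind != "both" && kind != k) next
      cnt <- if (k == "prototype") pc$prototypes else pc$domains
      if (cnt == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        nd = rep(mids[[pc$phase]], cnt), vg = vg, kind = k,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  features$id <- sprintf("ref%05d", seq_len(nrow(features)))
  list(features = features[, c("id", "nd", "vg", "kind")],
       timeline = timeline)
}
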