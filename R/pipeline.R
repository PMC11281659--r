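# End-to-end orchestration: census -> coding -> MP search -> Lundberg rooting
# -> chronology -> Venn timeline -> f-values -> split network (-> prototype
# projection), with a JSON run manifest.

#' Run the full analysis pipeline
#'
#' Executes every stage of the domain-chronology analysis on a census and
#' writes all artifacts plus a JSON manifest (seeds, stage counts, file
#' checksums) to `out_dir`. Stage failures abort with the stage name; partial
#' outputs are preserved next to an `INCOMPLETE` marker file.
#'
#' @param census a [census_matrix()].
#' @param out_dir output directory (created if needed).
#' @param prototype_map optional [prototype_map()]; when supplied, prototypes
#'   are filtered to the non-modular set and projected onto the chronology.
#' @param n_states ordered character states (default 24).
#' @param search list of [mp_search()] arguments
#'   (`n_replicates`, `moves`, `max_rounds`).
#' @param rooting ancestor mode for [lundberg_root()], `"max"` or `"min"`.
#' @param cal a [clock_calibration()].
#' @param marker_map phase marker map for [delimit_phases()].
#' @param bootstrap_replicates tree bootstrap replicates (0 skips).
#' @param network_bootstrap split-network bootstrap replicates (0 skips).
#' @param seed integer master seed; stage seeds are derived from it.
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(census, out_dir, prototype_map = NULL,
                         n_states = 24L,
                         search = list(n_replicates = 3L, moves = "NNI",
                                       max_rounds = 50L),
                         rooting = "max", cal = clock_calibration(),
                         marker_map = DEFAULT_MARKERS,
                         bootstrap_replicates = 0L, network_bootstrap = 100L,
                         seed = 1L) {
  stopifnot(inherits(census, "census_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  files <- character(0)
  info <- list(package = "todchron",
               version = as.character(utils::packageVersion("todchron")),
               seed = seed, counts = list())
  emit <- function(name) files <<- c(files, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  out <- function(name) file.path(out_dir, name)
  stage("census", {
    write_census(census, out("census.tsv"), out("labels.tsv"))
    emit("census.tsv"); emit("labels.tsv")
    info$counts$families <- nrow(census$abundance)
    info$counts$proteomes <- ncol(census$abundance)
  })
  occ <- to_occurrence(census)
  cm <- NULL
  stage("encode", {
    cm0 <- suppressWarnings(encode_states(census, n_states))
    flt <- informative_filter(cm0)
    cm <- flt$matrix
    info$counts$characters_kept <- length(flt$report$kept)
    info$counts$characters_dropped <- nrow(flt$report$dropped)
    write_nexus(cm, out("states.nex"))
    emit("states.nex")
  })
  sr <- NULL
  stage("search", {
    args <- c(list(cm = cm, seed = seed + 1000L), search)
    sr <- do.call(mp_search, args)
    ape::write.tree(sr$best_trees[[1]], out("tree.nwk"))
    emit("tree.nwk")
    info$counts$tree_length <- sr$length
    info$counts$retention_index <- sr$retention_index
    info$counts$g1 <- sr$g1
    info$counts$n_best_trees <- length(sr$best_trees)
  })
  if (bootstrap_replicates > 0) stage("bootstrap", {
    bs <- bootstrap_support(cm, bootstrap_replicates, seed + 2000L)
    utils::write.table(bs, out("bootstrap.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("bootstrap.tsv")
  })
  chron <- NULL
  stage("root", {
    anc <- make_ancestor(cm, rooting)
    rooted <- lundberg_root(sr$best_trees[[1]], cm, anc)
    ape::write.tree(rooted, out("rooted.nwk"))
    emit("rooted.nwk")
    chron <- chronology(rooted, cal)
    utils::write.table(chron, out("chronology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("chronology.tsv")
  })
  nd <- stats::setNames(chron$nd, chron$id)
  vg <- NULL
  timeline <- NULL
  stage("venn", {
    vg <- venn_groups(occ, orphans = "drop")
    keep <- intersect(names(nd), names(vg))
    first <- first_appearances(nd[keep], vg[keep])
    timeline <- tryCatch(delimit_phases(first, marker_map),
                          error = function(e) {
      info$counts$timeline_fallback <<- conditionMessage(e)
      even_phase_timeline()
    })
    feats <- data.frame(id = keep, nd = as.numeric(nd[keep]),
                        venn = as.character(vg[keep]),
                        category = category_of(vg[keep]),
                        phase = as.character(phase_of(nd[keep], timeline)),
                        stringsAsFactors = FALSE)
    utils::write.table(feats, out("features.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("features.tsv")
    pct <- phase_count_table(data.frame(nd = feats$nd, vg = feats$venn,
                                        kind = "domain"), timeline)
    utils::write.table(pct, out("phase_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("phase_counts.tsv")
    acc <- accumulation_curves(nd[keep], vg[keep], timeline)
    utils::write.table(acc$by_category, out("accumulation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("accumulation.tsv")
    grid <- presence_grid(nd[keep], vg[keep], timeline)
    utils::write.table(data.frame(venn = rownames(grid), grid,
                                  check.names = FALSE),
                       out("presence_grid.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("presence_grid.tsv")
    info$counts$phase_boundaries <- as.list(timeline$boundaries)
    spec <- specificity_summary(vg[keep])
    info$counts$specificity <- c(as.list(spec$singletons),
                                 shared = spec$shared)
  })
  stage("fvalue", {
    fv <- f_values(occ)
    cat_ <- stats::setNames(category_of(vg), names(vg))
    long <- data.frame(
      id = rep(rownames(fv), ncol(fv)),
      code = rep(colnames(fv), each = nrow(fv)),
      f = as.numeric(fv),
      nd = as.numeric(nd[rep(rownames(fv), ncol(fv))]),
      category = as.character(cat_[rep(rownames(fv), ncol(fv))]),
      stringsAsFactors = FALSE)
    utils::write.table(long, out("fvalues.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("fvalues.tsv")
    cmp <- lapply(intersect(c("A", "B", "E"), colnames(fv)), function(cd)
      tryCatch(unclass(compare_categories(fv, cat_, cd)),
               error = function(e) list(code = cd,
                                        error = conditionMessage(e))))
    jsonlite::write_json(cmp, out("comparisons.json"), auto_unbox = TRUE,
                         digits = NA)
    emit("comparisons.json")
  })
  stage("network", {
    inc <- venn_incidence(vg)
    ss <- if (network_bootstrap > 0)
      split_bootstrap(inc, network_bootstrap, seed + 3000L)
    else neighbor_net(uncorrected_p(inc))
    write_nexus_splits(ss, out("splits.nex"))
    emit("splits.nex")
    utils::write.table(splits_table(ss), out("splits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("splits.tsv")
  })
  if (!is.null(prototype_map)) stage("loops", {
    nm <- non_modular_filter(prototype_map, nd)
    pnd <- prototype_chronology(prototype_map, nd, nm)
    pvg <- prototype_venn(prototype_map, vg, nm)
    pdf <- data.frame(id = names(pnd), nd = as.numeric(pnd),
                      venn = as.character(pvg[names(pnd)]),
                      category = category_of(pvg[names(pnd)]),
                      phase = as.character(phase_of(pnd, timeline)),
                      stringsAsFactors = FALSE)
    utils::write.table(pdf, out("prototypes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("prototypes.tsv")
    info$counts$non_modular_prototypes <- length(nm)
  }) else info$skipped <- "loops (no prototype map supplied)"

  info$files <- files
  info$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(info$checksums) <- files
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  invisible(info)
}
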