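test_that("Venn groups are the canonical supergroup membership sets", {
  cen <- tiny_census()   # labels A, B, E, V over p1..p4
  occ <- to_occurrence(cen)
  expect_equal(venn_group(occ, "a.8.9.1"), "ABEV")
  expect_equal(venn_group(occ, "c.37.1.12"), "AEV")
  expect_equal(venn_group(occ, "b.1.1.1"), "B")
  expect_equal(unname(venn_groups(occ)), c("AEV", "B", "ABEV"))

  ab <- matrix(c(0, 0, 1, 1), 1, dimnames = list("vfam", paste0("p", 1:4)))
  cen2 <- census_matrix(ab, cen$labels)
  expect_equal(venn_group(to_occurrence(cen2), "vfam"), "EV")

  ab0 <- rbind(ab, orphan = 0)
  occ0 <- to_occurrence(census_matrix(ab0, cen$labels))
  expect_error(venn_group(occ0, "orphan"), "orphan family")
  expect_equal(unname(venn_groups(occ0, orphans = "drop")), "EV")
})

test_that("category splits the 15 groups into 8 viruses and 7 cells", {
  expect_equal(category_of("ABEV"), "viruses")
  expect_equal(category_of("ABE"), "cells")
  expect_equal(category_of("V"), "viruses")
  groups <- todchron:::ALL_VENN_GROUPS
  expect_length(groups, 15)
  tab <- table(category_of(groups))
  expect_equal(unname(tab[c("viruses", "cells")]), c(8L, 7L),
               ignore_attr = TRUE)
  expect_error(category_of("XYZ"), "invalid Venn group")
})

test_that("first appearances take per-group minima in order", {
  nd <- c(f1 = 0, f2 = 0.2, f3 = 0.15)
  vg <- c(f1 = "ABEV", f2 = "ABEV", f3 = "BEV")
  fa <- first_appearances(nd, vg)
  expect_equal(fa, c(ABEV = 0, BEV = 0.15))
})

test_that("phase delimitation builds half-open intervals from markers", {
  first <- c(ABEV = 0, ABE = 0.1, BEV = 0.2, B = 0.3, V = 0.47, E = 0.8)
  tl <- delimit_phases(first)
  expect_equal(unname(tl$boundaries), c(0.1, 0.2, 0.3, 0.47, 0.8))
  expect_equal(unname(tl$markers), c("ABE", "BEV", "B", "V", "E"))
  # boundary value belongs to the later phase
  expect_equal(as.character(phase_of(c(0, 0.09, 0.1, 0.3, 0.47, 0.99), tl)),
               c("0", "0", "I", "III", "IV", "V"))
  expect_error(delimit_phases(first[-2]), "missing marker.*I")
  bad <- c(ABEV = 0, ABE = 0.5, BEV = 0.2, B = 0.3, V = 0.47, E = 0.8)
  expect_error(delimit_phases(bad), "non-increasing")
})

even_timeline <- function() {
  structure(list(
    boundaries = stats::setNames(1:5 / 6, c("I", "II", "III", "IV", "V")),
    markers = stats::setNames(c("ABE", "BEV", "B", "V", "E"),
                              c("I", "II", "III", "IV", "V"))),
    class = "phase_timeline")
}

test_that("phase count table computes rounded ratios with '-' handling", {
  tl <- even_timeline()
  feats <- rbind(
    data.frame(nd = rep(0.05, 128), vg = "BEV", kind = "prototype"),
    data.frame(nd = rep(0.05, 20), vg = "BEV", kind = "domain"),
    data.frame(nd = rep(0.9, 3), vg = "ABE", kind = "prototype"),
    data.frame(nd = rep(0.9, 2), vg = "ABE", kind = "domain"))
  tab <- phase_count_table(feats, tl)
  v0 <- tab[tab$phase == "0" & tab$category == "viruses", ]
  expect_equal(v0$prototypes, 128)
  expect_equal(v0$domains, 20)
  expect_equal(v0$ratio, 6.4)
  c0 <- tab[tab$phase == "0" & tab$category == "cells", ]
  expect_equal(c0$ratio_label, "-")
  expect_true(is.na(c0$ratio))
  # partition property: counts sum to totals
  expect_equal(sum(tab$prototypes), 131)
  expect_equal(sum(tab$domains), 22)
  empty <- phase_count_table(feats[0, ], tl)
  expect_true(all(empty$prototypes == 0) && all(empty$domains == 0))
})

test_that("accumulation curves count strictly completed phases", {
  tl <- even_timeline()
  nd <- c(a = 0.05, b = 0.05, c = 0.3, d = 1 / 6, e = 0.9)
  vg <- c(a = "ABEV", b = "ABE", c = "V", d = "BEV", e = "E")
  acc <- accumulation_curves(nd, vg, tl)
  bc <- acc$by_category
  # at b1 = 1/6 only a and b have appeared (d sits exactly on the boundary)
  expect_equal(bc[bc$boundary == "I", c("viruses", "cells")],
               data.frame(viruses = 1L, cells = 1L), ignore_attr = TRUE)
  expect_equal(bc[bc$boundary == "II", "viruses"], 3)  # a, d and c (0.3 < 1/3)
  # end point is inclusive and conserves totals
  expect_equal(bc[bc$boundary == "end", "viruses"], 3)
  expect_equal(bc[bc$boundary == "end", "cells"], 2)
  expect_equal(acc$by_group[acc$by_group$boundary == "end", "ABEV"], 1)
})

test_that("specificity summary reports singleton percentages and the rest", {
  vg <- c(rep("V", 95), rep("ABEV", 3892 - 95))
  sp <- specificity_summary(vg)
  expect_equal(unname(sp$singletons["V"]), 2.44)
  expect_equal(unname(sp$singletons["A"]), 0)
  expect_equal(sp$shared, 97.6)
  expect_equal(specificity_summary(rep("ABEV", 10))$shared, 100)
  all_single <- specificity_summary(c("A", "B", "E", "V"))
  expect_equal(all_single$shared, 0)
})

test_that("presence grid flags group-phase occupancy", {
  tl <- even_timeline()
  nd <- c(a = 0.7, b = 0.95, c = 0.01)
  vg <- c(a = "BV", b = "E", c = "ABEV")
  g <- presence_grid(nd, vg, tl)
  expect_true(g["BV", "IV"])
  expect_false(any(g["BV", setdiff(colnames(g), "IV")]))
  expect_true(g["E", "V"])
  expect_true(g["ABEV", "0"])
  # empty phase gives an all-false column
  expect_false(any(g[, "II"]))
  # absent groups are all-false rows
  expect_false(any(g["AEV", ]))
})
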