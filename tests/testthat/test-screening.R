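table3_stats <- function() {
  t3 <- load_fixture("table3_antioxidant")
  grd <- load_fixture("table2_grd")
  # compounds absent from the printed table carry no selection evidence;
  # treat them as below both thresholds (VIP 0, coefficient 0)
  all_ids <- grd$peak
  mk <- function(col) {
    v <- setNames(rep(0, length(all_ids)), all_ids)
    v[t3$peak] <- t3[[col]]
    v
  }
  list(dpph_vip = mk("DPPH_vip"), dpph_coef = mk("DPPH_coef"),
       frap_vip = mk("FRAP_vip"), frap_coef = mk("FRAP_coef"))
}

test_that("selection rule is strict on both thresholds", {
  cfg <- screening_config()
  vip <- c(a = 1.0, b = 1.01, c = 2)
  coef <- c(a = 0.5, b = 0.1, c = 0.2)
  # a fails VIP (exactly 1.0), b fails coefficient (exactly 0.1)
  expect_identical(select_by_assay(vip, coef, cfg), "c")
  # absolute mode admits negative coefficients of large magnitude
  coef2 <- c(a = 0.5, b = -0.9, c = 0.2)
  expect_identical(select_by_assay(c(a = 1.2, b = 1.2, c = 1.2), coef2,
                                   screening_config(coef_mode = "absolute")),
                   c("a", "b", "c"))
  expect_identical(select_by_assay(c(a = 1.2, b = 1.2, c = 1.2), coef2, cfg),
                   c("a", "c"))
  expect_error(select_by_assay(c(1, 2), c(0.2)), "lengths differ")
})

test_that("printed antioxidant statistics select {1,3,5,7} + {1,3,5,7,18}", {
  st <- table3_stats()
  cfg <- screening_config()
  dpph <- select_by_assay(st$dpph_vip, st$dpph_coef, cfg)
  frap <- select_by_assay(st$frap_vip, st$frap_coef, cfg)
  expect_setequal(dpph, c("1", "3", "5", "7"))     # peak 18: VIP 0.89 < 1
  expect_setequal(frap, c("1", "3", "5", "7", "18"))
  u <- union_candidates(list(DPPH = dpph, FRAP = frap), "antioxidant", cfg)
  expect_identical(as.character(u), c("1", "3", "5", "7", "18"))
  expect_identical(attr(u, "provenance")[["18"]], "FRAP")
})

test_that("union respects set algebra and configuration errors", {
  cfg <- screening_config(union_assays = list(g = c("A", "B"), one = "A"))
  u <- union_candidates(list(A = "1", B = "2"), "g", cfg)
  expect_identical(as.character(u), c("1", "2"))
  u2 <- union_candidates(list(A = character(0), B = c("2", "10")), "g", cfg)
  expect_identical(as.character(u2), c("2", "10"))  # numeric-aware order
  expect_identical(as.character(union_candidates(list(A = c("3", "1"), B = "1"),
                                                 "one", cfg)), c("1", "3"))
  expect_error(union_candidates(list(A = "1"), "zzz", cfg), "not configured")
  expect_error(union_candidates(list(A = "1"), "g", cfg), "no selection for assay")
})

test_that("GRD annotation flags but never removes candidates", {
  grd <- matrix(c(0.97, 0.85, 0.97, 0.95), 2, 2,
                dimnames = list(c("5", "9"), c("DPPH", "FRAP")))
  gra <- structure(list(grd = grd, config = gra_config()), class = "gra_result")
  ann <- annotate_with_grd(c("5", "9"), gra, screening_config())
  expect_identical(ann$compound, c("5", "9"))
  expect_identical(ann$below_grd_floor, c(FALSE, TRUE))
  expect_error(annotate_with_grd("77", gra), "absent from GRA")

  # fixture check: peak 5 carries high degrees on all three assays, no flag
  t2 <- load_fixture("table2_grd")
  m <- as.matrix(t2[, -1]); rownames(m) <- t2$peak
  gra2 <- structure(list(grd = m, config = gra_config()), class = "gra_result")
  ann2 <- annotate_with_grd("5", gra2, screening_config())
  expect_false(ann2$below_grd_floor)
  expect_equal(unname(unlist(ann2[, 2:4])), c(0.967, 0.974, 0.972))
})

test_that("selection is monotone in both thresholds", {
  set.seed(31)
  vip <- setNames(runif(22, 0, 2), as.character(1:22))
  coef <- setNames(runif(22, -0.3, 0.5), as.character(1:22))
  base <- select_by_assay(vip, coef, screening_config())
  for (vt in c(1.1, 1.5)) for (ct in c(0.15, 0.3)) {
    tighter <- select_by_assay(vip, coef,
                               screening_config(vip_threshold = vt,
                                                coef_threshold = ct))
    expect_true(all(tighter %in% base))
  }
})

test_that("screen_pipeline recovers planted actives and is deterministic", {
  d <- generate_dataset(synthetic_config(seed = 17))
  res <- screen_pipeline(d$peaks, d$acts, seed = 17)
  truth <- attr(d$acts, "ground_truth")$active_sets

  # the antioxidant union catches most of the planted antioxidant actives
  expect_gte(length(intersect(res$groups$antioxidant, truth$DPPH)), 4)
  # union equals the set union of its member assays
  expect_setequal(res$groups$antioxidant,
                  union(res$per_assay$DPPH$selected, res$per_assay$FRAP$selected))
  # single-assay group: union is that assay's set
  expect_setequal(res$groups$antiinflammatory, res$per_assay$NO_inhibition$selected)

  res2 <- screen_pipeline(d$peaks, d$acts, seed = 17)
  expect_identical(serialize(res$evidence, NULL), serialize(res2$evidence, NULL))

  # evidence table carries VIP, coefficient, GRD and flags for all compounds
  expect_identical(res$evidence$compound, d$peaks$compound_ids)
  expect_true(all(c("vip_DPPH", "coef_FRAP", "grd_NO_inhibition",
                    "selected_DPPH", "below_grd_floor") %in% names(res$evidence)))

  pt0 <- peak_table(matrix(1:3, 3, 1), paste0("s", 1:3), "1")
  at0 <- activity_table(matrix(rnorm(3), 3, 1), paste0("s", 1:3), "DPPH")
  expect_error(screen_pipeline(pt0, at0), "at least 2 compounds")
})
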