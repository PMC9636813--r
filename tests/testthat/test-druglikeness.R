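aspirin_like <- list(mw = 180.16, logp_mlogp = 1.31, logp_wlogp = 1.31,
                     logp_xlogp = 1.19, tpsa = 63.6, hbd = 1, hba = 4,
                     rotatable_bonds = 3, molar_refractivity = 44.9,
                     heavy_atoms = 13, rings = 1, carbons = 9, heteroatoms = 4)

test_that("rule engine applies the published thresholds", {
  r <- evaluate_rules(aspirin_like)
  expect_true(r$lipinski$pass)
  expect_length(r$lipinski$violations, 0)
  expect_true(r$veber$pass)
  expect_true(r$egan$pass)
  expect_false(r$ghose$pass)  # 13 heavy atoms < 20

  # two Lipinski violations exceed the single-violation tolerance
  heavy <- within(aspirin_like, { mw <- 700; hbd <- 7; hba <- 13 })
  expect_false(evaluate_rules(heavy)$lipinski$pass)

  flexible <- within(aspirin_like, { rotatable_bonds <- 11; tpsa <- 100 })
  rv <- evaluate_rules(flexible)$veber
  expect_false(rv$pass)
  expect_identical(rv$violations, "rotatable_bonds > 10")

  # missing descriptor: every affected rule reports not evaluable, with one
  # warning each (veber, egan and muegge all need tpsa)
  incomplete <- aspirin_like; incomplete$tpsa <- NA
  ws <- capture_warnings(ri <- evaluate_rules(incomplete))
  expect_length(ws, 3)
  expect_match(ws, "not evaluable", all = TRUE)
  expect_false(ri$veber$evaluable)
  expect_true(ri$lipinski$evaluable)
})

test_that("GA classification is a closed point-in-rotated-ellipse test", {
  e <- ga_ellipse()
  expect_identical(classify_ga(e$center[["tpsa"]], e$center[["wlogp"]]), "high")
  expect_identical(classify_ga(e$center[["tpsa"]] + 10 * e$a,
                               e$center[["wlogp"]]), "low")
  # a boundary point along the (rotated) major axis is inside the closed region
  bx <- e$center[["tpsa"]] + e$a * cos(e$theta)
  by <- e$center[["wlogp"]] + e$a * sin(e$theta)
  expect_identical(classify_ga(bx, by), "high")
  # rotating the ellipse by 2*pi changes nothing
  e2 <- e; e2$theta <- e$theta + 2 * pi
  set.seed(12)
  tp <- runif(50, 0, 250); wl <- runif(50, -5, 8)
  expect_identical(classify_ga(tp, wl, e), classify_ga(tp, wl, e2))
  expect_error(classify_ga(50, 1, list(center = e$center, a = 0, b = 1, theta = 0)),
               "degenerate")
})

test_that("admission combines GA, rule count and the content override", {
  pass_all <- evaluate_rules(aspirin_like)  # 3 of 5 pass (ghose, muegge fail)
  rep1 <- admit_marker(pass_all, "high", 1, 1)
  expect_true(rep1$admissible)
  expect_false(rep1$override_applied)
  expect_identical(rep1$rules_passed, 3L)

  # low GA but 25-fold content: admitted via override
  rep2 <- admit_marker(pass_all, "low", 25, 1)
  expect_true(rep2$admissible)
  expect_true(rep2$override_applied)

  rep3 <- admit_marker(pass_all, "low", 1, 1)
  expect_false(rep3$admissible)
  expect_error(admit_marker(pass_all, "low", -1, 1), "non-negative")
})

test_that("admission logic matches its truth table exhaustively", {
  # all 2^5 rule patterns x GA x content ratio: admissible iff
  # (high GA and >= 3 passes) or ratio > 20
  tmpl <- aspirin_like
  for (bits in 0:31) {
    pattern <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L, 16L)) > 0)
    rules <- lapply(pattern, function(p)
      list(pass = p, evaluable = TRUE, violations = character(0)))
    names(rules) <- c("lipinski", "ghose", "veber", "egan", "muegge")
    for (ga in c("high", "low")) for (ratio in c(1, 25)) {
      rep_i <- admit_marker(rules, ga, ratio, 1)
      expect_identical(rep_i$admissible,
                       (ga == "high" && sum(pattern) >= 3) || ratio > 20)
      expect_identical(rep_i$rules_passed, sum(pattern))
    }
  }
})

test_that("report over the marker fixtures mirrors the study narrative", {
  desc <- load_fixture("marker_descriptors")
  cont <- load_fixture("marker_contents_synthetic")
  contents <- setNames(cont$relative_content, cont$compound_id)
  rep <- druglikeness_report(desc, contents)

  # cichoric acid (peak 7): very polar diester -> low GA, only 2 rules pass,
  # admitted purely through its dominant content
  row7 <- rep[rep$compound_id == "7", ]
  expect_identical(row7$ga_class, "low")
  expect_lt(row7$rules_passed, 3)
  expect_true(row7$admissible)
  expect_true(row7$override_applied)
  expect_gt(row7$content_ratio, 20)

  # the six other markers are admitted on their ADME profile
  others <- rep[rep$compound_id != "7", ]
  expect_true(all(others$ga_class == "high"))
  expect_true(all(others$rules_passed >= 3))
  expect_true(all(others$admissible))
  expect_false(any(others$override_applied))
})
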