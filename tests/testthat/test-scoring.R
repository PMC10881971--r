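test_that("the scoring dose is the highest dose keeping viability >= 50%", {
  s <- data.frame(dose_uM = c(100, 10, 1), viability_pct = c(20, 80, 95))
  sel <- select_scoring_dose(s)
  expect_equal(sel$dose_uM, 10)
  expect_false(sel$all_cytotoxic)

  all_ok <- data.frame(dose_uM = c(100, 10, 1),
                       viability_pct = c(75, 90, 99))
  expect_equal(select_scoring_dose(all_ok)$dose_uM, 100)

  all_toxic <- data.frame(dose_uM = c(100, 10, 1),
                          viability_pct = c(5, 20, 45))
  sel2 <- select_scoring_dose(all_toxic)
  expect_equal(sel2$dose_uM, 1)
  expect_true(sel2$all_cytotoxic)

  # the 50% floor itself qualifies
  edge <- data.frame(dose_uM = c(100, 10), viability_pct = c(50, 90))
  expect_equal(select_scoring_dose(edge)$dose_uM, 100)
  expect_error(select_scoring_dose(data.frame()), "empty")
})

test_that("the four tier rules reproduce their worked examples", {
  expect_equal(assign_score(85, 1.3, 2.0, 0.001), 3L)
  expect_equal(assign_score(60, 1.2, 1.8, 0.002), 2L)
  expect_equal(assign_score(90, 0.6, 1.8, 0.01), 1L)
  expect_equal(assign_score(95, 0.5, 1.02, 0.4), 0L)
})

test_that("viability-band boundaries partition as specified", {
  expect_equal(assign_score(70, 1.5, 2, 0.01), 2L)   # exactly 70 -> tier 2
  expect_equal(assign_score(50, 1.5, 2, 0.01), 2L)   # exactly 50 -> tier 2
  expect_equal(assign_score(50, 0.9, 2, 0.01), 0L)   # tier 1 needs > 50
  expect_equal(assign_score(70.01, 1.5, 2, 0.01), 3L)
  expect_equal(assign_score(49.99, 1.5, 2, 0.01), 0L)
  # induction boundaries: ratios of exactly 1 do not qualify
  expect_equal(assign_score(90, 1, 2, 0.01), 1L)
  expect_equal(assign_score(90, 1, 1, 0.01), 0L)
  expect_equal(assign_score(90, 0.5, 1.5, 0.05), 0L) # p = alpha not enough
  expect_error(assign_score(-1, 1, 1, 0.5), "non-negative")
})

test_that("tier assignment agrees with the brute-force rule table on a grid", {
  vs <- c(seq(0, 120, by = 6), 49.99, 50, 50.01, 69.99, 70, 70.01)
  rps <- c(seq(0, 2, by = 0.22), 1)
  rns <- c(seq(0, 3, by = 0.45), 1)
  ps <- c(0.001, 0.049, 0.05, 0.2, 1)
  grid <- expand.grid(v = vs, rp = rps, rn = rns, p = ps)
  expect_gte(nrow(grid), 1e4)
  got <- assign_score(grid$v, grid$rp, grid$rn, grid$p)
  want <- mapply(oracle_score, grid$v, grid$rp, grid$rn, grid$p)
  expect_identical(as.integer(got), as.integer(want))
})

test_that("tier score is monotone in induction at fixed viability", {
  for (v in c(55, 65, 75, 95)) {
    sc <- assign_score(rep(v, 50), seq(0, 2.5, length.out = 50), 1.8, 0.01)
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("condition sums are bounded by 12 and reach it only at all 3s", {
  expect_equal(sum_condition(c(AP1 = 3, P53 = 3, Nrf2 = 3, NFkB = 3)), 12L)
  expect_equal(sum_condition(c(AP1 = 0, P53 = 0, Nrf2 = 0, NFkB = 0)), 0L)
  expect_equal(sum_condition(c(AP1 = 3, P53 = 1, Nrf2 = 0, NFkB = 2)), 6L)
  combos <- expand.grid(AP1 = 0:3, P53 = 0:3, Nrf2 = 0:3, NFkB = 0:3)
  sums <- apply(combos, 1, function(s) sum_condition(s))
  expect_true(all(sums >= 0 & sums <= 12))
  expect_identical(sums == 12, apply(combos, 1, function(s) all(s == 3)))
  expect_error(sum_condition(c(AP1 = 3, P53 = 3, Nrf2 = 3)), "pathway")
  expect_error(sum_condition(c(AP1 = 3, P53 = 3, Nrf2 = 3, Nrf2 = 1)),
               "pathway")
  expect_error(sum_condition(c(AP1 = 4, P53 = 3, Nrf2 = 3, NFkB = 3)),
               "0..3")
})

test_that("S9-dependence classification follows the activity rules", {
  expect_equal(classify_s9_dependence(0, 5), "s9_plus_more_active")
  expect_equal(classify_s9_dependence(5, 0), "s9_minus_more_active")
  expect_equal(classify_s9_dependence(6, 6), "consistent")
  expect_equal(classify_s9_dependence(2, 2), "non_responsive")
  # both active: delta >= 2 breaks the tie
  expect_equal(classify_s9_dependence(3, 5), "s9_plus_more_active")
  expect_equal(classify_s9_dependence(5, 4), "consistent")
  expect_equal(classify_s9_dependence(12, 3), "s9_minus_more_active")
  # threshold boundary: sum of exactly 3 is active
  expect_equal(classify_s9_dependence(3, 0), "s9_minus_more_active")
  expect_equal(classify_s9_dependence(3, 0, strict = TRUE), "non_responsive")
  expect_error(classify_s9_dependence(13, 0), "0..12")
})

test_that("pathway activity groups cover all four patterns", {
  expect_equal(classify_pathway_group(3, 3), "commonly_active")
  expect_equal(classify_pathway_group(2, 0), "s9_minus_specific")
  expect_equal(classify_pathway_group(0, 1), "s9_plus_specific")
  expect_equal(classify_pathway_group(0, 0), "inactive")
  # a raised floor demotes weak activity
  expect_equal(classify_pathway_group(1, 0, activity_floor = 2), "inactive")
})

test_that("Venn membership partitions active compounds over 15 regions", {
  scores <- expand.grid(compound_id = c("pan", "ap1only", "silent"),
                        pathway = pathways(), condition = conditions(),
                        stringsAsFactors = FALSE)
  scores$score <- 0L
  scores$score[scores$compound_id == "pan"] <- 3L
  scores$score[scores$compound_id == "ap1only" &
                 scores$pathway == "AP1"] <- 1L
  vm <- venn_membership(scores, "S9minus")
  expect_true(all(vapply(vm$sets, function(s) "pan" %in% s, logical(1))))
  expect_identical(vm$sets$AP1, c("ap1only", "pan"))
  expect_false(any(vapply(vm$sets, function(s) "silent" %in% s,
                          logical(1))))
  expect_equal(vm$region_counts[["AP1&P53&Nrf2&NFkB"]], 1L)
  expect_equal(vm$region_counts[["AP1"]], 1L)
  # regions partition: totals equal compounds with >= 1 active pathway
  expect_equal(sum(vm$region_counts), 2L)
})

test_that("a scored noise-free screen recovers every planted class", {
  sim <- simulate_screen(sim_config(noise_cv = 0), default_truths(1))
  scr <- score_screen(sim)
  intended <- vapply(sim$truths, `[[`, character(1), "intended_class")
  ids <- vapply(sim$truths, `[[`, character(1), "compound_id")
  got <- scr$profiles$s9_class[match(ids, scr$profiles$compound_id)]
  expect_identical(got, unname(truth_class_to_output[intended]))
  expect_true(all(scr$profiles$sum_s9_minus ==
                    rowSums(scr$matrix[, grep("S9minus", colnames(scr$matrix))])))
  # a planted pan-responder lands in the 4-way Venn region in both conditions
  fx <- matrix(4.5, 4, 2, dimnames = list(pathways(), conditions()))
  pan <- compound_truth("panactive", fx, c(S9minus = 1e6, S9plus = 1e6),
                        intended_class = "consistent")
  scr2 <- score_screen(simulate_screen(sim_config(noise_cv = 0), list(pan)))
  for (cond in conditions()) {
    vm <- venn_membership(scr2$scores, cond)
    expect_equal(vm$region_counts[["AP1&P53&Nrf2&NFkB"]], 1L)
  }
})
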