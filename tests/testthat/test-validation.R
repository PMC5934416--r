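test_that("relative expression anchors at the maximal stimulated control", {
  tbl <- make_ct_tbl(
    list("P1", "W1", "empty_vector", "empty_vector", "stimulated", "Cxcl2", 24),
    list("P1", "W1", "empty_vector", "empty_vector", "stimulated", "Ube2l3", 20),
    list("P1", "W2", "empty_vector", "empty_vector", "stimulated", "Cxcl2", 25),
    list("P1", "W2", "empty_vector", "empty_vector", "stimulated", "Ube2l3", 20),
    list("P1", "W3", "shA_1", "A", "stimulated", "Cxcl2", 25),
    list("P1", "W3", "shA_1", "A", "stimulated", "Ube2l3", 20)
  )
  rel <- relative_expression(tbl, "Ube2l3")
  # the best stimulated control well (delta-ct 4) defines 1.0
  expect_equal(rel$rel_expr[rel$well_id == "W1"], 1)
  # one cycle higher halves the value
  expect_equal(rel$rel_expr[rel$well_id == "W3"], 0.5)

  # independent series get independent anchors
  tbl$series <- c("s1", "s1", "s2", "s2", "s2", "s2")
  rel2 <- relative_expression(tbl, "Ube2l3")
  expect_equal(rel2$rel_expr[rel2$well_id == "W2"], 1)  # anchor of series 2
  expect_equal(rel2$rel_expr[rel2$well_id == "W3"], 1)  # same delta-ct in s2

  no_ref <- tbl[tbl$construct != "empty_vector", ]
  expect_error(relative_expression(no_ref, "Ube2l3"), "reference")
})

test_that("the 1.5-fold rule classifies effects and is fold/1-fold symmetric", {
  folds <- tibble::tibble(target = letters[1:3], comparison = "basal",
                          fold = c(1.6, 0.60, 1.4))
  lab <- classify_effects(folds)$label
  expect_equal(lab, c("corepressor", "coactivator", "none"))

  set.seed(6)
  f <- exp(rnorm(100))
  a <- classify_effects(tibble::tibble(fold = f))$label
  b <- classify_effects(tibble::tibble(fold = 1 / f))$label
  swap <- c(coactivator = "corepressor", corepressor = "coactivator", none = "none")
  expect_equal(unname(swap[a]), b)

  expect_error(classify_effects(tibble::tibble(fold = -1)), "positive")
  expect_error(classify_effects(folds, threshold = 0.9), "exceed 1")
})

test_that("overlap counts partition the affected factors", {
  ov <- effect_overlap(list(basal = c("A", "B"), stimulated = c("B", "C"),
                            regulation = character(0)))
  expect_equal(ov[["basal_only"]], 1L)
  expect_equal(ov[["basal_stimulated"]], 1L)
  expect_equal(ov[["stimulated_only"]], 1L)
  expect_equal(ov[["total_affected"]], 3L)
  expect_equal(sum(ov[1:7]), ov[["total_affected"]])

  empty <- effect_overlap(list(basal = character(0), stimulated = character(0),
                               regulation = character(0)))
  expect_true(all(empty == 0))

  # 5-element fixture enumerated by hand: basal {a,b,c,d}, stim {a,b,c,d},
  # regulation {} -> all mass in the basal/stimulated pairwise region
  same <- effect_overlap(list(basal = letters[1:4], stimulated = letters[1:4],
                              regulation = character(0)))
  expect_equal(same[["basal_stimulated"]], 4L)
  expect_equal(same[["all_three"]], 0L)
  expect_equal(same[["total_affected"]], 4L)
  # identical across all three sets -> triple intersection
  trip <- effect_overlap(list(basal = letters[1:5], stimulated = letters[1:5],
                              regulation = letters[1:5]))
  expect_equal(trip[["all_three"]], 5L)
  expect_equal(sum(trip[1:6]), 0L)

  # invariant to ordering
  shuf <- effect_overlap(list(basal = c("B", "A"), stimulated = c("C", "B"),
                              regulation = character(0)))
  expect_equal(shuf, ov)
})

test_that("overlap from classified tables enforces a common roster", {
  eff <- classify_effects(tibble::tibble(
    target = rep(c("A", "B"), 3),
    comparison = rep(c("basal", "stimulated", "regulation"), each = 2),
    fold = c(2, 1, 2, 1, 1, 1)
  ))
  ov <- effect_overlap(eff)
  expect_equal(ov[["basal_stimulated"]], 1L)
  bad <- eff[-1, ]
  expect_error(effect_overlap(bad), "roster")
})

test_that("rank_matrix sorts stably by the requested key", {
  df <- tibble::tibble(target = c("a", "b", "c", "d"),
                       fold = c(2, 0.5, 2, 1))
  up <- rank_matrix(df, "fold")
  expect_equal(up$target, c("b", "d", "a", "c"))  # ties keep input order
  down <- rank_matrix(df, "fold", decreasing = TRUE)
  expect_equal(down$target, c("a", "c", "d", "b"))
  expect_error(rank_matrix(df, "nope"), "nope")
})

test_that("the rank-sum test matches exhaustive enumeration", {
  a <- c(1.1, 1.3, 1.8, 2.0)
  b <- c(3.2, 3.5, 4.1, 5.0)
  got <- group_difference_test(a, b)
  expect_equal(got$p_value, 2 / 70, tolerance = 1e-12)
  expect_true(got$significant)

  # oracle: enumerate all C(8,4) assignments of the pooled ranks
  pooled <- rank(c(a, b))
  obs <- sum(pooled[1:4])
  sums <- combn(8, 4, function(idx) sum(pooled[idx]))
  exhaustive <- mean(abs(sums - mean(sums)) >= abs(obs - mean(sums)))
  expect_equal(got$p_value, exhaustive, tolerance = 1e-12)

  # symmetry and the identical-group case
  expect_equal(group_difference_test(b, a)$p_value, got$p_value)
  same <- group_difference_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(group_difference_test(numeric(0), 1), "nonempty")
})

test_that("validation folds recover implanted 2-fold effects accurately", {
  # triplicate pooled-knockdown wells, 0.2 ct noise, half the targets shifted
  d <- make_design(12, 3, mode = "pooled", targets_per_plate = 6,
                   replicates = 3)
  shifts <- rep(c(1, -1, 0), each = 4)  # +-1 ct = 2-fold, or null
  effects <- tibble::tibble(target = d$targets, basal_shift = shifts,
                            stim_shift = shifts)
  acc <- vapply(1:20, function(s) {
    p <- default_sim_params(knockdown_effects = effects, well_noise_sd = 0.2,
                            efficiency_sd = 0, off_target_prob = 0)
    sim <- simulate_screen(d, p, seed = 3000 + s)
    rel <- relative_expression(sim$ct, d$housekeeping)
    folds <- validation_folds(rel)
    eff <- classify_effects(folds)
    merged <- merge(eff, sim$truth,
                    by.x = c("target", "comparison"),
                    by.y = c("target", "comparison"))
    truth_label <- ifelse(merged$direction == "none", "none", merged$direction)
    mean(merged$label == truth_label)
  }, 0)
  expect_gte(mean(acc), 0.95)
})
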