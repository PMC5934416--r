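test_that("per-target aggregation averages hairpin delta-ct values", {
  d <- make_design(1, 3)
  dct <- tibble::tibble(
    plate_id = "P01", well_id = c("W1", "W2", "W3"),
    construct = c("shTGT001_1", "shTGT001_2", "shTGT001_3"),
    target_gene = "TGT001", condition = "untreated",
    readout_gene = "Cxcl2", delta_ct = c(9.8, 10.2, 10.0)
  )
  agg <- suppressMessages(aggregate_target_dct(dct, d))
  expect_equal(agg$delta_ct, 10.0)
  expect_equal(agg$n_wells, 3L)

  single <- suppressMessages(aggregate_target_dct(dct[2, ], d))
  expect_equal(single$delta_ct, 10.2)

  # one undetermined among three: dropped upstream, mean of the rest
  two <- suppressMessages(aggregate_target_dct(dct[c(1, 3), ], d))
  expect_equal(two$delta_ct, 9.9)
})

test_that("the three comparisons follow the ddct equations", {
  mk <- function(dct_unt, dct_stim) tibble::tibble(
    target_gene = "A", condition = c("untreated", "stimulated"),
    readout_gene = "Cxcl2", plate_id = "P01",
    delta_ct = c(dct_unt, dct_stim), n_wells = 1L
  )
  ctrl <- tibble::tibble(plate_id = "P01",
                         condition = c("untreated", "stimulated"),
                         readout_gene = "Cxcl2", delta_ct = c(10, 4))
  folds <- function(res) setNames(res$fold, res$comparison)

  # stimulated-only suppression: regulation drops from 64- to 8-fold
  f <- folds(compare_targets(mk(10, 7), ctrl))
  expect_equal(unname(f[c("basal", "stimulated", "regulation")]),
               c(1, 0.125, 0.125), tolerance = 1e-12)

  # knockdown identical to control
  f <- folds(compare_targets(mk(10, 4), ctrl))
  expect_equal(unname(f), c(1, 1, 1), tolerance = 1e-12)

  # both conditions shifted alike: the regulation comparison is blind to it
  f <- folds(compare_targets(mk(12, 6), ctrl))
  expect_equal(unname(f[c("basal", "stimulated", "regulation")]),
               c(0.25, 0.25, 1), tolerance = 1e-12)
})

test_that("fold_regulation * fold_basal = fold_stimulated on random fixtures", {
  set.seed(31)
  for (i in 1:50) {
    tgt <- tibble::tibble(
      target_gene = "A", condition = c("untreated", "stimulated"),
      readout_gene = "Cxcl2", plate_id = "P01",
      delta_ct = rnorm(2, 7, 3), n_wells = 1L
    )
    ctrl <- tibble::tibble(plate_id = "P01",
                           condition = c("untreated", "stimulated"),
                           readout_gene = "Cxcl2", delta_ct = rnorm(2, 7, 3))
    f <- setNames(compare_targets(tgt, ctrl)$fold, c("basal", "stimulated", "regulation"))
    expect_equal(f[["regulation"]] * f[["basal"]] / f[["stimulated"]], 1,
                 tolerance = 1e-12)
  }
})

test_that("a missing plate control falls back to the screen mean with a warning", {
  tgt <- tibble::tibble(
    target_gene = "A", condition = c("untreated", "stimulated"),
    readout_gene = "Cxcl2", plate_id = "P02",
    delta_ct = c(10, 4), n_wells = 1L
  )
  ctrl <- tibble::tibble(plate_id = "P01",
                         condition = c("untreated", "stimulated"),
                         readout_gene = "Cxcl2", delta_ct = c(9, 5))
  expect_warning(res <- compare_targets(tgt, ctrl), "screen-wide mean")
  expect_equal(res$ddct[res$comparison == "basal"], 1)
})

test_that("z-ranking standardizes within stratum and flags an implanted outlier", {
  d <- full_scale_design("pooled")
  p <- default_sim_params(
    knockdown_effects = tibble::tibble(target = "TGT050",
                                       basal_shift = 3, stim_shift = 3),
    efficiency_sd = 0, off_target_prob = 0
  )
  sim <- simulate_screen(d, p, seed = 77)
  res <- analyze_screen(sim$ct, d, "II")
  for (cmp in c("basal", "stimulated")) {
    sub <- res[res$comparison == cmp, ]
    expect_lt(abs(mean(sub$z)), 1e-10)
    expect_equal(sd(sub$z), 1, tolerance = 1e-10)
    expect_equal(sub$target[which.max(abs(sub$z))], "TGT050")
    # direct recomputation of the implanted target's z
    expect_equal(sub$z[sub$target == "TGT050"],
                 (sub$ddct[sub$target == "TGT050"] - mean(sub$ddct)) / sd(sub$ddct))
    # ranking is a permutation of the targets
    expect_setequal(sub$target, d$targets)
    expect_true(!is.unsorted(sub$z))
  }
})

test_that("hits require the z threshold in every screen plus sign concordance", {
  mk <- function(screen, targets, z, ddct) tibble::tibble(
    target = targets, readout_gene = "Cxcl2", comparison = "basal",
    ddct = ddct, fold = 2^-ddct, z = z, screen_id = screen
  )
  r1 <- mk("I", c("A", "B", "D"), c(1.4, -1.2, 0.3), c(1.2, -1.0, 0.2))
  r2 <- mk("II", c("A", "C", "D"), c(1.1, -1.3, 0.4), c(0.9, -1.1, 0.3))
  hits <- call_hits(list(r1, r2))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$target, "A")
  expect_equal(hits$direction, "coactivator")
  expect_equal(hits$screens_supporting, "I,II")

  # discordant signs are rejected even with large |z|
  r2b <- mk("II", "A", -1.4, -1.2)
  expect_equal(nrow(call_hits(list(mk("I", "A", 1.4, 1.2), r2b))), 0L)
  # ... unless concordance is waived
  expect_equal(nrow(call_hits(list(mk("I", "A", 1.4, 1.2), r2b),
                              require_concordance = FALSE)), 1L)
  # ties at the threshold are included
  expect_equal(nrow(call_hits(list(mk("I", "A", 1.0, 0.5),
                                   mk("II", "A", -1.0, 0.4)),
                              require_concordance = TRUE)), 1L)
  expect_error(call_hits(r1), "at least two screens")
})

test_that("a single strong implanted effect is the only call on a small screen", {
  d1 <- make_design(5, 5)
  d2 <- make_design(5, 5, mode = "pooled", targets_per_plate = 5)
  p <- default_sim_params(
    well_noise_sd = 0.05, plate_effect_sd = 0.2,
    efficiency_sd = 0, off_target_prob = 0,
    knockdown_effects = tibble::tibble(target = "TGT003",
                                       basal_shift = 2, stim_shift = 2)
  )
  s1 <- simulate_screen(d1, p, seed = 41)
  s2 <- simulate_screen(d2, p, seed = 42)
  hits <- call_hits(list(analyze_screen(s1$ct, d1, "I"),
                         analyze_screen(s2$ct, d2, "II")))
  for (cmp in c("basal", "stimulated")) {
    sub <- hits[hits$comparison == cmp, ]
    expect_equal(sub$target, "TGT003")
    expect_equal(sub$direction, "coactivator")
  }
})

test_that("dual-screen hits are a subset of each single-screen hit set", {
  d1 <- full_scale_design("individual")
  d2 <- full_scale_design("pooled")
  p <- default_sim_params()
  s1 <- simulate_screen(d1, p, seed = 61)
  s2 <- simulate_screen(d2, p, seed = 62)
  r1 <- analyze_screen(s1$ct, d1, "I")
  r2 <- analyze_screen(s2$ct, d2, "II")
  dual <- call_hits(list(r1, r2))
  key <- function(h) paste(h$target, h$comparison)
  for (r in list(r1, r2)) {
    single <- call_hits(r, require_concordance = FALSE)
    expect_true(all(key(dual) %in% key(single)))
  }
})

test_that("pipeline results equal a straight-line oracle on a small fixture", {
  d1 <- make_design(8, 4, targets_per_plate = 4)
  d2 <- make_design(8, 4, mode = "pooled", targets_per_plate = 8)
  p <- default_sim_params(
    knockdown_effects = tibble::tibble(target = c("TGT002", "TGT007"),
                                       basal_shift = c(1.5, -1), stim_shift = c(1.5, 1))
  )
  s1 <- simulate_screen(d1, p, seed = 51)
  s2 <- simulate_screen(d2, p, seed = 52)
  r1 <- analyze_screen(s1$ct, d1, "I")
  r2 <- analyze_screen(s2$ct, d2, "II")
  o1 <- oracle_screen(s1$ct, d1, "I")
  o2 <- oracle_screen(s2$ct, d2, "II")

  for (pair in list(list(r1, o1), list(r2, o2))) {
    got <- pair[[1]][order(pair[[1]]$comparison, pair[[1]]$target), ]
    want <- pair[[2]][order(pair[[2]]$comparison, pair[[2]]$target), ]
    expect_equal(got$ddct, want$ddct, tolerance = 1e-12)
    expect_equal(got$fold, want$fold, tolerance = 1e-12)
    expect_equal(got$z, want$z, tolerance = 1e-12)
  }

  hits <- call_hits(list(r1, r2))
  ohits <- oracle_hits(o1, o2)
  expect_equal(nrow(hits), if (is.null(ohits)) 0L else nrow(ohits))
  if (!is.null(ohits)) {
    expect_setequal(paste(hits$target, hits$comparison, hits$direction),
                    paste(ohits$target, ohits$comparison, ohits$direction))
  }
})
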