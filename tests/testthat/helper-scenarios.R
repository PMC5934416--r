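# Study-condition scenarios shared by the calibration/recovery tests and
# mirrored by scripts/acceptance.R.

# Fraction of targets called per comparison on a pure-noise dual screen
# (170 targets, default noise, no implanted effects).
null_hit_fractions <- function(seed) {
  d1 <- full_scale_design("individual")
  d2 <- full_scale_design("pooled")
  params <- default_sim_params()
  s1 <- simulate_screen(d1, params, seed = seed)
  s2 <- simulate_screen(d2, params, seed = seed + 500000L)
  r1 <- analyze_screen(s1$ct, d1, "I")
  r2 <- analyze_screen(s2$ct, d2, "II")
  hits <- call_hits(list(r1, r2))
  n <- table(factor(hits$comparison,
                    levels = c("basal", "stimulated", "regulation")))
  as.numeric(n) / length(d1$targets)
}

# Recovery of 10 implanted 1.5-ct effects (5 coactivator, 5 corepressor,
# same shift in both conditions) among 170 targets across both screen
# formats; returns the fraction of (implanted target x affected comparison)
# cells called with the correct direction.
recovery_fraction <- function(seed) {
  d1 <- full_scale_design("individual")
  d2 <- full_scale_design("pooled")
  set.seed(seed)
  implanted <- sample(d1$targets, 10)
  shift <- rep(c(1.5, -1.5), each = 5)
  effects <- tibble::tibble(target = implanted, basal_shift = shift,
                            stim_shift = shift)
  params <- default_sim_params(knockdown_effects = effects)
  s1 <- simulate_screen(d1, params, seed = seed + 1L)
  s2 <- simulate_screen(d2, params, seed = seed + 500001L)
  r1 <- analyze_screen(s1$ct, d1, "I")
  r2 <- analyze_screen(s2$ct, d2, "II")
  hits <- call_hits(list(r1, r2))
  truth <- s1$truth[s1$truth$target %in% implanted &
                      s1$truth$comparison %in% c("basal", "stimulated"), ]
  ok <- mapply(function(tg, cmp, dir) {
    any(hits$target == tg & hits$comparison == cmp & hits$direction == dir)
  }, truth$target, truth$comparison, truth$direction)
  mean(ok)
}
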