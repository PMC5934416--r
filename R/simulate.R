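#' Default simulation parameters
#'
#' Study-condition defaults for the synthetic ct-table generator. The
#' inducible readout (Cxcl2) sits at high basal ct (low abundance, 30
#' cycles) and gains -6 ct under stimulation (roughly 64-fold induction);
#' the housekeeping readout (Ube2l3, baseline 20 ct) is unshifted by
#' stimulation. GFP control wells are shifted +1.5 ct on every readout
#' (GFP expression suppresses mRNA levels, i.e. raises ct). Per-shRNA
#' knockdown efficiency scales each hairpin's effect and is drawn once per
#' construct from Normal(1, 0.2) truncated to [0, 1.5]; with small
#' probability (`off_target_prob`) a hairpin's effect sign flips,
#' emulating an off-target construct.
#'
#' @param baseline_ct named numeric: ct per readout in vector-control
#'   untreated cells.
#' @param stimulation_shift named numeric: cycles added under stimulation
#'   (negative = induction). Must be 0 for the housekeeping readout unless
#'   deliberately probing housekeeping drift.
#' @param plate_effect_sd sd (cycles) of the per-plate additive offset
#'   applied to all measurements on a plate.
#' @param well_noise_sd sd (cycles) of independent Gaussian noise per
#'   measurement.
#' @param gfp_shift cycles added to every readout in GFP control wells.
#' @param knockdown_effects data frame with columns `target`,
#'   `basal_shift`, `stim_shift`: the ct shift (cycles) a full-efficiency
#'   knockdown adds to non-housekeeping readouts in untreated and
#'   stimulated wells. Positive shift = raised ct = suppressed expression
#'   = the target is a coactivator.
#' @param shrna_readout_shift named numeric: global ct shift applied to a
#'   readout in all shRNA (non-control) wells; models transfection
#'   artifacts such as the ActB depression seen with hairpin vectors.
#' @param efficiency_mean,efficiency_sd per-construct efficiency
#'   distribution (truncated to [0, 1.5]).
#' @param off_target_prob probability a hairpin's effect sign is flipped.
#' @param max_cycles instrument cap; simulated ct above it is flagged
#'   undetermined.
#' @param seed RNG seed used by [simulate_screen()] when none is passed.
#' @return an object of class `sim_params`.
#' @export
default_sim_params <- function(baseline_ct = c(Cxcl2 = 30, Ube2l3 = 20),
                               stimulation_shift = c(Cxcl2 = -6, Ube2l3 = 0),
                               plate_effect_sd = 0.5,
                               well_noise_sd = 0.25,
                               gfp_shift = 1.5,
                               knockdown_effects = NULL,
                               shrna_readout_shift = NULL,
                               efficiency_mean = 1,
                               efficiency_sd = 0.2,
                               off_target_prob = 0.02,
                               max_cycles = 40,
                               seed = NULL) {
  if (is.null(knockdown_effects)) {
    knockdown_effects <- tibble::tibble(target = character(),
                                        basal_shift = numeric(),
                                        stim_shift = numeric())
  }
  knockdown_effects <- tibble::as_tibble(knockdown_effects)
  need <- c("target", "basal_shift", "stim_shift")
  if (!all(need %in% names(knockdown_effects))) {
    stop("knockdown_effects needs columns target, basal_shift, stim_shift",
         call. = FALSE)
  }
  stopifnot(plate_effect_sd >= 0, well_noise_sd >= 0, efficiency_sd >= 0,
            off_target_prob >= 0, off_target_prob <= 1, max_cycles > 0)
  structure(
    list(
      baseline_ct = baseline_ct,
      stimulation_shift = stimulation_shift,
      plate_effect_sd = plate_effect_sd,
      well_noise_sd = well_noise_sd,
      gfp_shift = gfp_shift,
      knockdown_effects = knockdown_effects,
      shrna_readout_shift = shrna_readout_shift,
      efficiency_mean = efficiency_mean,
      efficiency_sd = efficiency_sd,
      off_target_prob = off_target_prob,
      max_cycles = max_cycles,
      seed = seed
    ),
    class = "sim_params"
  )
}

#' Read / write simulation parameters (YAML)
#'
#' @param path YAML file.
#' @return `sim_params` for `read_sim_params`; the path, invisibly, for
#'   `write_sim_params`.
#' @export
read_sim_params <- function(path) {
  y <- yaml::read_yaml(path)
  ke <- if (length(y$knockdown_effects)) {
    tibble::as_tibble(lapply(as.data.frame(
      do.call(rbind, lapply(y$knockdown_effects, as.data.frame))
    ), unlist))
  } else NULL
  default_sim_params(
    baseline_ct = unlist(y$baseline_ct),
    stimulation_shift = unlist(y$stimulation_shift),
    plate_effect_sd = y$plate_effect_sd,
    well_noise_sd = y$well_noise_sd,
    gfp_shift = y$gfp_shift,
    knockdown_effects = ke,
    shrna_readout_shift = if (length(y$shrna_readout_shift)) unlist(y$shrna_readout_shift) else NULL,
    efficiency_mean = y$efficiency_mean,
    efficiency_sd = y$efficiency_sd,
    off_target_prob = y$off_target_prob,
    max_cycles = y$max_cycles,
    seed = y$seed
  )
}

#' @rdname read_sim_params
#' @param params a `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  y <- list(
    baseline_ct = as.list(params$baseline_ct),
    stimulation_shift = as.list(params$stimulation_shift),
    plate_effect_sd = params$plate_effect_sd,
    well_noise_sd = params$well_noise_sd,
    gfp_shift = params$gfp_shift,
    knockdown_effects = if (nrow(params$knockdown_effects)) {
      lapply(seq_len(nrow(params$knockdown_effects)), function(i)
        as.list(params$knockdown_effects[i, ]))
    } else list(),
    shrna_readout_shift = if (length(params$shrna_readout_shift)) as.list(params$shrna_readout_shift) else NULL,
    efficiency_mean = params$efficiency_mean,
    efficiency_sd = params$efficiency_sd,
    off_target_prob = params$off_target_prob,
    max_cycles = params$max_cycles,
    seed = params$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1.5) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a ct-value screen
#'
#' Generates a long-format ct table for a [screen_design()] under the
#' additive model
#' `ct = baseline + plate effect + stimulation shift + knockdown shift
#'  + GFP shift + Gaussian well noise`,
#' together with the implanted ground truth. Knockdown shifts act on
#' non-housekeeping readouts only, scaled per hairpin by a once-per-construct
#' efficiency draw (individual mode) or by the mean of the constituent
#' hairpins' scaled effects (pooled mode). The same seed and parameters
#' yield an identical table.
#'
#' @param design a [screen_design()].
#' @param params a [default_sim_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return list with `ct` (measurement tibble as from [load_ct_table()])
#'   and `truth` (tibble `target`, `comparison`, `direction`, `magnitude`
#'   in delta-ct units; `direction` is `coactivator`, `corepressor` or
#'   `none`).
#' @export
simulate_screen <- function(design, params = default_sim_params(), seed = NULL) {
  stopifnot(inherits(design, "screen_design"), inherits(params, "sim_params"))
  missing_base <- setdiff(design$readouts, names(params$baseline_ct))
  if (length(missing_base)) {
    stop("baseline_ct missing readout(s): ", paste(missing_base, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)

  layout <- plan_layout(design)
  plates <- unique(layout$plate_id)

  # RNG draw order is fixed: plate effects, construct efficiencies,
  # off-target flips, then one noise draw per measurement row.
  plate_eff <- stats::setNames(
    stats::rnorm(length(plates), 0, params$plate_effect_sd), plates)
  sh <- design$shrna_manifest
  eff <- rnorm_trunc(nrow(sh), params$efficiency_mean, params$efficiency_sd)
  flip <- ifelse(stats::runif(nrow(sh)) < params$off_target_prob, -1, 1)
  scale_by_shrna <- stats::setNames(eff * flip, sh$shrna)
  scale_by_target <- tapply(eff * flip, sh$target, mean)

  ke <- params$knockdown_effects
  basal_shift <- stats::setNames(rep(0, length(design$targets)), design$targets)
  stim_shift_kd <- basal_shift
  if (nrow(ke)) {
    unknown <- setdiff(ke$target, design$targets)
    if (length(unknown)) {
      stop("knockdown_effects for unknown target(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    basal_shift[ke$target] <- ke$basal_shift
    stim_shift_kd[ke$target] <- ke$stim_shift
  }

  rows <- tidyr::crossing(layout, readout_gene = design$readouts)
  is_control <- rows$construct %in% CONTROL_CONSTRUCTS
  is_hk <- rows$readout_gene == design$housekeeping
  stim <- rows$condition == "stimulated"

  ct <- params$baseline_ct[rows$readout_gene] +
    plate_eff[rows$plate_id] +
    ifelse(stim, params$stimulation_shift[rows$readout_gene], 0)

  # knockdown term: per-construct scale times the target's condition shift
  kd_scale <- numeric(nrow(rows))
  if (design$mode == "individual") {
    idx <- !is_control
    kd_scale[idx] <- scale_by_shrna[rows$construct[idx]]
  } else {
    idx <- !is_control
    kd_scale[idx] <- scale_by_target[rows$target_gene[idx]]
  }
  kd_effect <- ifelse(stim, stim_shift_kd[rows$target_gene],
                      basal_shift[rows$target_gene])
  kd_effect[is.na(kd_effect)] <- 0
  ct <- ct + ifelse(!is_control & !is_hk, kd_scale * kd_effect, 0)

  if (length(params$shrna_readout_shift)) {
    extra <- params$shrna_readout_shift[rows$readout_gene]
    extra[is.na(extra)] <- 0
    ct <- ct + ifelse(!is_control, extra, 0)
  }
  ct <- ct + ifelse(rows$construct == "gfp", params$gfp_shift, 0)
  ct <- ct + stats::rnorm(nrow(rows), 0, params$well_noise_sd)

  ct <- unname(ct)
  undet <- ct > params$max_cycles
  tbl <- tibble::tibble(
    plate_id = rows$plate_id,
    well_id = rows$well_id,
    construct = rows$construct,
    target_gene = rows$target_gene,
    condition = rows$condition,
    readout_gene = rows$readout_gene,
    ct = ifelse(undet, NA_real_, ct),
    undetermined = undet
  )

  reg_shift <- stim_shift_kd - basal_shift
  truth <- tibble::tibble(
    target = rep(design$targets, times = 3L),
    comparison = rep(c("basal", "stimulated", "regulation"),
                     each = length(design$targets)),
    magnitude = unname(c(abs(basal_shift), abs(stim_shift_kd), abs(reg_shift))),
    direction = effect_direction(c(basal_shift, stim_shift_kd, reg_shift))
  )
  list(ct = tbl, truth = truth)
}

effect_direction <- function(shift) {
  out <- rep("none", length(shift))
  out[shift > 0] <- "coactivator"
  out[shift < 0] <- "corepressor"
  out
}

#' Write a ground-truth table
#'
#' @param truth tibble from [simulate_screen()].
#' @param path output TSV.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
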