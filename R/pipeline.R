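#' Default run configuration
#'
#' Thresholds default to the screening conventions: a two-sided z cutoff of
#' 1 SD for hit calling, 1.5-fold for validation classification, 0.5 ct for
#' housekeeping stability, 0.4 for interaction-edge confidence.
#'
#' @param seed RNG seed driving the whole run.
#' @param n_targets number of cofactor targets in the demo design.
#' @param shrnas_per_target hairpins per target.
#' @param z_threshold hit-calling z cutoff (SD units).
#' @param fold_threshold validation fold cutoff.
#' @param hk_shift_threshold housekeeping median-shift cutoff (cycles).
#' @param network_min_score edge confidence cutoff.
#' @param require_concordance require agreeing effect signs across screens.
#' @param knockdown_effects implanted effects (see [default_sim_params()]);
#'   `NULL` implants coactivator/corepressor effects on two demo targets.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L, n_targets = 24L,
                               shrnas_per_target = 5L,
                               z_threshold = 1, fold_threshold = 1.5,
                               hk_shift_threshold = 0.5,
                               network_min_score = 0.4,
                               require_concordance = TRUE,
                               knockdown_effects = NULL,
                               out_dir = tempfile("ctscreen_run_")) {
  if (is.null(knockdown_effects)) {
    knockdown_effects <- tibble::tibble(
      target = c("TGT01", "TGT02"),
      basal_shift = c(1.5, -1.5),
      stim_shift = c(1.5, -1.5)
    )
  }
  structure(
    list(seed = as.integer(seed), n_targets = as.integer(n_targets),
         shrnas_per_target = as.integer(shrnas_per_target),
         z_threshold = z_threshold, fold_threshold = fold_threshold,
         hk_shift_threshold = hk_shift_threshold,
         network_min_score = network_min_score,
         require_concordance = isTRUE(require_concordance),
         knockdown_effects = knockdown_effects,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_run_config()] arguments.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(default_run_config)))]
  if (!is.null(args$knockdown_effects)) {
    args$knockdown_effects <- tibble::as_tibble(
      lapply(as.data.frame(do.call(rbind, lapply(args$knockdown_effects, as.data.frame))), unlist)
    )
  }
  do.call(default_run_config, args)
}

#' Build a demo screen design pair
#'
#' One roster of `n_targets` cofactors covered by `shrnas_per_target`
#' hairpins each, realised as an individual-mode screen (screen I) and a
#' pooled-mode screen (screen II).
#'
#' @param n_targets,shrnas_per_target design dimensions.
#' @return list with `individual` and `pooled` [screen_design()]s.
#' @export
demo_designs <- function(n_targets = 24L, shrnas_per_target = 5L) {
  targets <- sprintf("TGT%02d", seq_len(n_targets))
  manifest <- tibble::tibble(
    shrna = paste0("sh", rep(targets, each = shrnas_per_target), "_",
                   rep(seq_len(shrnas_per_target), n_targets)),
    target = rep(targets, each = shrnas_per_target)
  )
  list(
    individual = screen_design(targets, manifest, mode = "individual",
                               targets_per_plate = 4L),
    pooled = screen_design(targets, manifest, mode = "pooled",
                           targets_per_plate = 20L)
  )
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate-screen-call pipeline
#'
#' Simulates both screen formats with the configured implanted effects,
#' analyzes each screen (delta-ct, aggregation, the three comparisons,
#' z-ranking), calls concordant dual-screen hits, and writes the artifact
#' bundle (ct tables, ranked comparisons, hit calls, ground truth) as TSV
#' files with a provenance header (`# key: value` lines carrying the config
#' fingerprint, seed and package version). Deterministic given the seed.
#'
#' @param config a `run_config` (or path to a YAML file).
#' @return invisibly, a list with `designs`, `screens` (ct + truth),
#'   `results` (ranked comparisons per screen), `hits`, and `files`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(tool = "ctscreen",
               version = as.character(utils::packageVersion("ctscreen")),
               config = config_fingerprint(config),
               seed = config$seed)

  designs <- demo_designs(config$n_targets, config$shrnas_per_target)
  params <- default_sim_params(knockdown_effects = config$knockdown_effects)

  screens <- list(
    I = simulate_screen(designs$individual, params, seed = config$seed),
    II = simulate_screen(designs$pooled, params, seed = config$seed + 1L)
  )
  results <- list(
    I = analyze_screen(screens$I$ct, designs$individual, "I"),
    II = analyze_screen(screens$II$ct, designs$pooled, "II")
  )
  hits <- call_hits(results, z_threshold = config$z_threshold,
                    require_concordance = config$require_concordance)

  files <- c(
    ct_I = file.path(config$out_dir, "ct_screen_I.tsv"),
    ct_II = file.path(config$out_dir, "ct_screen_II.tsv"),
    comparisons = file.path(config$out_dir, "comparisons.tsv"),
    hits = file.path(config$out_dir, "hits.tsv"),
    truth = file.path(config$out_dir, "ground_truth.tsv")
  )
  write_ct_table(screens$I$ct, files[["ct_I"]], provenance = prov)
  write_ct_table(screens$II$ct, files[["ct_II"]], provenance = prov)
  comp <- dplyr::bind_rows(results)
  comp <- comp[, c("screen_id", "comparison", "readout_gene", "target",
                   "ddct", "fold", "z")]
  comp_out <- comp
  for (col in c("ddct", "fold", "z")) {
    comp_out[[col]] <- vapply(comp_out[[col]], format_full, character(1))
  }
  write_with_provenance(comp_out, files[["comparisons"]], provenance = prov)
  write_with_provenance(hits, files[["hits"]], provenance = prov)
  write_with_provenance(screens$I$truth, files[["truth"]], provenance = prov)

  invisible(list(designs = designs, screens = screens, results = results,
                 hits = hits, files = files, provenance = prov))
}
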