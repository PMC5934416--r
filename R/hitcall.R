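COMPARISONS <- c("basal", "stimulated", "regulation")

#' Aggregate per-well delta-ct values to one value per target and condition
#'
#' In individual mode the delta-ct values of the 4-5 hairpins per target
#' (and any replicate wells) are averaged arithmetically; in pooled mode
#' the single well pair per target passes through (replicate pooled wells,
#' if present, are averaged the same way). Control wells are excluded.
#' Targets with no valid record for a condition are reported missing and
#' excluded downstream.
#'
#' @param dct tibble from [delta_ct_table()].
#' @param design the [screen_design()].
#' @return tibble with columns `target_gene`, `condition`, `readout_gene`,
#'   `plate_id`, `delta_ct` (mean), `n_wells`.
#' @export
aggregate_target_dct <- function(dct, design) {
  stopifnot(inherits(design, "screen_design"))
  sub <- dct[!dct$construct %in% CONTROL_CONSTRUCTS, ]
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$target_gene, .data$condition, .data$readout_gene),
    plate_id = dplyr::first(.data$plate_id),
    delta_ct = mean(.data$delta_ct),
    n_wells = dplyr::n(),
    .groups = "drop"
  )
  expected <- tidyr::crossing(
    target_gene = design$targets,
    condition = CONDITIONS,
    readout_gene = setdiff(design$readouts, design$housekeeping)
  )
  miss <- dplyr::anti_join(expected, agg,
                           by = c("target_gene", "condition", "readout_gene"))
  if (nrow(miss)) {
    message(nrow(miss), " (target, condition) cell(s) have no valid measurement ",
            "and are excluded: ",
            paste(unique(miss$target_gene), collapse = ", "))
  }
  agg
}

#' Per-plate vector-control delta-ct values
#'
#' @param dct tibble from [delta_ct_table()].
#' @param control construct used as the quantification reference.
#' @return tibble `plate_id`, `condition`, `readout_gene`, `delta_ct`.
#' @export
control_dct <- function(dct, control = "empty_vector") {
  sub <- dct[dct$construct == control, ]
  if (!nrow(sub)) stop("no wells for control construct '", control, "'", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(sub, .data$plate_id, .data$condition, .data$readout_gene),
    delta_ct = mean(.data$delta_ct), .groups = "drop"
  )
}

#' The three knockdown comparisons
#'
#' For each target, relative to the same-plate vector control:
#' * `basal`: ddct = dct(knockdown, untreated) - dct(control, untreated)
#' * `stimulated`: the same in stimulated cells
#' * `regulation`: the change in the extent of stimulus-mediated
#'   induction, fold = fold_stimulated / fold_basal, i.e.
#'   ddct = ddct_stimulated - ddct_basal.
#' Fold = 2^-ddct throughout, so fold_regulation * fold_basal =
#' fold_stimulated identically. A plate missing its control falls back to
#' the screen-wide mean control with a warning.
#'
#' @param target_dct tibble from [aggregate_target_dct()].
#' @param ctrl tibble from [control_dct()].
#' @return tibble `target`, `readout_gene`, `comparison`, `ddct`, `fold`.
#' @export
compare_targets <- function(target_dct, ctrl) {
  ctrl_wide <- tidyr::pivot_wider(ctrl, names_from = "condition",
                                  values_from = "delta_ct",
                                  names_prefix = "ctrl_")
  tgt_wide <- tidyr::pivot_wider(
    target_dct[, c("target_gene", "condition", "readout_gene", "plate_id", "delta_ct")],
    names_from = "condition", values_from = "delta_ct", names_prefix = "dct_"
  )
  for (col in c("dct_untreated", "dct_stimulated")) {
    if (!col %in% names(tgt_wide)) tgt_wide[[col]] <- NA_real_
  }
  joined <- dplyr::left_join(tgt_wide, ctrl_wide,
                             by = c("plate_id", "readout_gene"))
  no_ctrl <- is.na(joined$ctrl_untreated) | is.na(joined$ctrl_stimulated)
  if (any(no_ctrl)) {
    warning(sum(no_ctrl), " target(s) lack a same-plate control; ",
            "falling back to the screen-wide mean control", call. = FALSE)
    fb <- dplyr::summarise(dplyr::group_by(ctrl_wide, .data$readout_gene),
                           fb_unt = mean(.data$ctrl_untreated, na.rm = TRUE),
                           fb_stim = mean(.data$ctrl_stimulated, na.rm = TRUE),
                           .groups = "drop")
    joined <- dplyr::left_join(joined, fb, by = "readout_gene")
    joined$ctrl_untreated[no_ctrl] <- joined$fb_unt[no_ctrl]
    joined$ctrl_stimulated[no_ctrl] <- joined$fb_stim[no_ctrl]
  }
  ddct_basal <- joined$dct_untreated - joined$ctrl_untreated
  ddct_stim <- joined$dct_stimulated - joined$ctrl_stimulated
  out <- tibble::tibble(
    target = rep(joined$target_gene, 3L),
    readout_gene = rep(joined$readout_gene, 3L),
    comparison = rep(COMPARISONS, each = nrow(joined)),
    ddct = c(ddct_basal, ddct_stim, ddct_stim - ddct_basal)
  )
  out$fold <- 2^(-out$ddct)
  out[!is.na(out$ddct), ]
}

#' Z-score ranking of comparison results
#'
#' Z-scores are computed on the ddct values (log2 scale of the ratio)
#' within each (screen, comparison, readout) stratum, and results are
#' sorted by z within stratum.
#'
#' @param comparisons tibble from [compare_targets()].
#' @param screen_id identifier recorded in the output.
#' @return input with `screen_id` and `z` columns added, ranked by z.
#' @export
rank_by_z <- function(comparisons, screen_id) {
  ranked <- dplyr::mutate(
    dplyr::group_by(comparisons, .data$comparison, .data$readout_gene),
    z = zscores(.data$ddct)
  )
  ranked <- dplyr::arrange(dplyr::ungroup(ranked),
                           .data$comparison, .data$readout_gene, .data$z)
  ranked$screen_id <- screen_id
  ranked
}

#' Run the per-screen analysis
#'
#' ct table to ranked comparison results: delta-ct normalization, per-target
#' aggregation, per-plate vector-control comparison, z-ranking.
#'
#' @param ct_tbl measurement tibble.
#' @param design the [screen_design()].
#' @param screen_id identifier for this screen.
#' @param control reference construct.
#' @return ranked comparison tibble (see [rank_by_z()]).
#' @export
analyze_screen <- function(ct_tbl, design, screen_id, control = "empty_vector") {
  dct <- delta_ct_table(ct_tbl, design$housekeeping)
  agg <- aggregate_target_dct(dct, design)
  ctrl <- control_dct(dct, control)
  rank_by_z(compare_targets(agg, ctrl), screen_id)
}

#' Call concordant hits across screens
#'
#' A target is a hit for a comparison when its |z| meets the threshold in
#' every screen and (by default) the ddct signs agree across screens.
#' Direction follows the sign: ddct > 0 (fold < 1, knockdown suppressed
#' expression) labels the target a coactivator; ddct < 0 a corepressor.
#' Ties at exactly the threshold are included.
#'
#' @param screen_results a single ranked tibble covering several screens or
#'   a list of per-screen ranked tibbles ([rank_by_z()] output).
#' @param z_threshold two-sided z cutoff (SD units).
#' @param require_concordance require agreeing ddct signs across screens.
#' @return tibble `target`, `readout_gene`, `comparison`, `direction`,
#'   `screens_supporting` (comma-joined ids), `min_abs_z`, `mean_ddct`.
#' @export
call_hits <- function(screen_results, z_threshold = 1, require_concordance = TRUE) {
  if (is.list(screen_results) && !is.data.frame(screen_results)) {
    screen_results <- dplyr::bind_rows(screen_results)
  }
  n_screens <- length(unique(screen_results$screen_id))
  if (n_screens < 2L && require_concordance) {
    stop("concordance across screens requires results from at least two screens",
         call. = FALSE)
  }
  grouped <- dplyr::group_by(screen_results, .data$target,
                             .data$readout_gene, .data$comparison)
  calls <- dplyr::summarise(
    grouped,
    n_supporting = dplyr::n(),
    all_pass = all(abs(.data$z) >= z_threshold),
    concordant = length(unique(sign(.data$ddct))) == 1L && all(.data$ddct != 0),
    screens_supporting = paste(sort(unique(.data$screen_id)), collapse = ","),
    min_abs_z = min(abs(.data$z)),
    mean_ddct = mean(.data$ddct),
    .groups = "drop"
  )
  hits <- calls[calls$n_supporting == n_screens & calls$all_pass &
                  (!require_concordance | calls$concordant), ]
  hits$direction <- ifelse(hits$mean_ddct > 0, "coactivator", "corepressor")
  tibble::as_tibble(hits[, c("target", "readout_gene", "comparison", "direction",
                             "screens_supporting", "min_abs_z", "mean_ddct")])
}
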