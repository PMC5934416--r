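#' Delta-ct normalization
#'
#' ct of the readout minus ct of the housekeeping gene measured on the same
#' material; the log2-scale normalized expression. `NA` (undetermined)
#' inputs yield `NA`.
#'
#' @param ct_target,ct_housekeeping ct values (cycles), vectorized.
#' @return delta-ct in cycles.
#' @examples
#' delta_ct(30, 20)  # 10
#' @export
delta_ct <- function(ct_target, ct_housekeeping) {
  ct_target - ct_housekeeping
}

#' 2^-ddct fold change
#'
#' The ddct relative-quantification rule with PCR efficiency fixed at
#' perfect doubling: `ddct = delta_ct_sample - delta_ct_reference`,
#' `fold = 2^-ddct`. A positive ddct (sample needs more cycles) means
#' lower expression, fold < 1.
#'
#' @param delta_ct_sample,delta_ct_reference delta-ct values (cycles).
#' @return tibble with columns `ddct` and `fold`.
#' @examples
#' fold_change_ddct(5, 4)  # ddct 1, fold 0.5
#' @export
fold_change_ddct <- function(delta_ct_sample, delta_ct_reference) {
  ddct <- delta_ct_sample - delta_ct_reference
  tibble::tibble(ddct = ddct, fold = 2^(-ddct))
}

#' Z-scores
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation by
#' default; the population convention is available and with screen-sized
#' strata the two are indistinguishable.
#'
#' @param values numeric vector, length >= 2, nonzero spread.
#' @param sd_type `"sample"` (n-1 denominator) or `"population"` (n).
#' @return numeric vector of z-scores (mean 0, sd 1 under the chosen
#'   convention).
#' @export
zscores <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("z-scores need at least two values", call. = FALSE)
  }
  if (anyNA(values)) stop("z-scores need finite values", call. = FALSE)
  s <- stats::sd(values)
  if (sd_type == "population") {
    s <- s * sqrt((length(values) - 1) / length(values))
  }
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero spread, z-scores undefined", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Per-well delta-ct table
#'
#' Joins each non-housekeeping measurement with the housekeeping ct from
#' the same well and subtracts. Wells where either measurement is
#' undetermined are dropped (never imputed); the number of dropped records
#' is reported as a message.
#'
#' @param ct_tbl measurement tibble ([load_ct_table()] / [simulate_screen()]).
#' @param housekeeping housekeeping readout gene.
#' @return tibble with columns `plate_id`, `well_id`, `construct`,
#'   `target_gene`, `condition`, `readout_gene`, `delta_ct`.
#' @export
delta_ct_table <- function(ct_tbl, housekeeping) {
  if (!housekeeping %in% ct_tbl$readout_gene) {
    stop("housekeeping readout '", housekeeping, "' not present in ct table",
         call. = FALSE)
  }
  hk <- ct_tbl[ct_tbl$readout_gene == housekeeping,
               c("plate_id", "well_id", "ct")]
  names(hk)[3] <- "ct_hk"
  out <- dplyr::left_join(
    ct_tbl[ct_tbl$readout_gene != housekeeping, ],
    hk, by = c("plate_id", "well_id")
  )
  out$delta_ct <- out$ct - out$ct_hk
  dropped <- sum(is.na(out$delta_ct))
  if (dropped > 0) {
    message(dropped, " record(s) dropped (undetermined ct in readout or housekeeping)")
  }
  out <- out[!is.na(out$delta_ct), ]
  tibble::as_tibble(out[, c("plate_id", "well_id", "construct", "target_gene",
                            "condition", "readout_gene", "delta_ct")])
}

#' Housekeeping-gene stability check
#'
#' Compares the median ct of each candidate housekeeping readout between
#' shRNA wells and empty-vector control wells, per condition. A candidate
#' whose median shifts by more than `threshold` cycles in either condition
#' is flagged to be omitted from normalization (the fate of ActB in the
#' original screens, whose median dropped in hairpin-transfected wells).
#'
#' @param ct_tbl measurement tibble.
#' @param candidates candidate housekeeping readout genes.
#' @param control_construct construct labelling the reference wells.
#' @param threshold absolute median ct shift (cycles) above which a
#'   candidate is flagged.
#' @return tibble with columns `readout_gene`, `condition`, `median_shift`
#'   (shRNA minus control), and `omit` (flag, constant per readout).
#' @export
housekeeping_stability <- function(ct_tbl, candidates,
                                   control_construct = "empty_vector",
                                   threshold = 0.5) {
  missing <- setdiff(candidates, unique(ct_tbl$readout_gene))
  if (length(missing)) {
    stop("candidate readout(s) absent from ct table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- ct_tbl[ct_tbl$readout_gene %in% candidates & !is.na(ct_tbl$ct), ]
  sub$group <- ifelse(sub$construct == control_construct, "control",
                      ifelse(sub$construct %in% CONTROL_CONSTRUCTS, NA, "shrna"))
  sub <- sub[!is.na(sub$group), ]
  med <- dplyr::summarise(
    dplyr::group_by(sub, .data$readout_gene, .data$condition, .data$group),
    median_ct = stats::median(.data$ct), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(med, names_from = "group", values_from = "median_ct")
  wide$median_shift <- wide$shrna - wide$control
  out <- dplyr::mutate(
    dplyr::group_by(wide, .data$readout_gene),
    omit = any(abs(.data$median_shift) > threshold)
  )
  dplyr::ungroup(out)[, c("readout_gene", "condition", "median_shift", "omit")]
}
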