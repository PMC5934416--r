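#' ChIP-qPCR percent-of-input enrichment
#'
#' `2^-(ct_ip - ct_input)`, the immunoprecipitated signal relative to the
#' input-DNA aliquot (by convention a 1% aliquot). The raw formula value is
#' returned by default; `rescale_to_total = TRUE` converts to percent of
#' the total input (`value * input_fraction * 100`, the identity when the
#' aliquot is 1%). If the recorded input ct was measured on undiluted
#' material rather than the diluted aliquot, `dilution_cycles` (log2 of the
#' dilution factor, e.g. `log2(10)` for 1:10) corrects the input ct to the
#' aliquot reference; it is 0 by default, assuming the dilution is already
#' reflected in the recorded ct.
#'
#' @param ct_ip,ct_input ct values (cycles), vectorized; `NA` in, `NA` out.
#' @param input_fraction fraction of input represented by the aliquot.
#' @param rescale_to_total report percent of total input.
#' @param dilution_cycles cycle correction for an unreflected input dilution.
#' @return enrichment values.
#' @examples
#' percent_of_input(25, 25)  # 1
#' percent_of_input(27, 25)  # 0.25
#' @export
percent_of_input <- function(ct_ip, ct_input, input_fraction = 0.01,
                             rescale_to_total = FALSE, dilution_cycles = 0) {
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must lie in (0, 1]", call. = FALSE)
  }
  v <- 2^(-(ct_ip - ct_input + dilution_cycles))
  if (rescale_to_total) v <- v * input_fraction * 100
  v
}

#' Region-by-antibody ChIP enrichment table
#'
#' Computes percent-of-input per (region, antibody, condition) and, when
#' present, the ratio to the matching IgG measurement (same region and
#' condition) and to a gene-free negative-control region (same antibody
#' and condition). Missing references leave the ratio `NA` with a warning.
#'
#' @param measurements tibble with columns `region`, `antibody`,
#'   `condition`, `ct_ip`, `ct_input`.
#' @param igg_label antibody label of the isotype control.
#' @param negative_region region label of the gene-free control region.
#' @param ... passed to [percent_of_input()].
#' @return input tibble with `enrichment`, `ratio_to_igg`,
#'   `ratio_to_negative` columns.
#' @export
enrichment_table <- function(measurements, igg_label = "IgG",
                             negative_region = NULL, ...) {
  need <- c("region", "antibody", "condition", "ct_ip", "ct_input")
  if (!all(need %in% names(measurements))) {
    stop("measurements need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(measurements)) stop("no measurements supplied", call. = FALSE)
  out <- tibble::as_tibble(measurements)
  out$enrichment <- percent_of_input(out$ct_ip, out$ct_input, ...)

  igg <- out[out$antibody == igg_label, c("region", "condition", "enrichment")]
  names(igg)[3] <- "igg_enrichment"
  if (nrow(igg)) {
    out <- dplyr::left_join(out, igg, by = c("region", "condition"))
    out$ratio_to_igg <- out$enrichment / out$igg_enrichment
    out$igg_enrichment <- NULL
  } else {
    warning("no '", igg_label, "' measurements; IgG ratios omitted", call. = FALSE)
    out$ratio_to_igg <- NA_real_
  }

  if (!is.null(negative_region) && negative_region %in% out$region) {
    neg <- out[out$region == negative_region,
               c("antibody", "condition", "enrichment")]
    names(neg)[3] <- "neg_enrichment"
    out <- dplyr::left_join(out, neg, by = c("antibody", "condition"))
    out$ratio_to_negative <- out$enrichment / out$neg_enrichment
    out$neg_enrichment <- NULL
  } else {
    if (!is.null(negative_region)) {
      warning("negative-control region '", negative_region,
              "' absent; ratios omitted", call. = FALSE)
    }
    out$ratio_to_negative <- NA_real_
  }
  out
}
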