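#' Normalized relative expression
#'
#' Conventional RT-qPCR presentation: linear expression `2^-delta_ct`,
#' rescaled per readout gene so that the maximal vector-control stimulated
#' value equals 1. When a `series` column is present, experiment series are
#' normalized independently (anchors per series) and never pooled.
#'
#' @param ct_tbl measurement tibble, optionally with a `series` column.
#' @param housekeeping housekeeping readout gene.
#' @param control construct anchoring the scale.
#' @return delta-ct tibble with a `rel_expr` column.
#' @export
relative_expression <- function(ct_tbl, housekeeping, control = "empty_vector") {
  has_series <- "series" %in% names(ct_tbl)
  dct <- delta_ct_table(ct_tbl, housekeeping)
  if (has_series) {
    key <- ct_tbl[ct_tbl$readout_gene != housekeeping,
                  c("plate_id", "well_id", "readout_gene", "series")]
    dct <- dplyr::left_join(dct, key, by = c("plate_id", "well_id", "readout_gene"))
  } else {
    dct$series <- "all"
  }
  dct$expr <- 2^(-dct$delta_ct)
  ref <- dct[dct$construct == control & dct$condition == "stimulated", ]
  if (!nrow(ref)) {
    stop("no stimulated '", control, "' reference wells in the table", call. = FALSE)
  }
  anchors <- dplyr::summarise(
    dplyr::group_by(ref, .data$readout_gene, .data$series),
    anchor = max(.data$expr), .groups = "drop"
  )
  need <- unique(dct[, c("readout_gene", "series")])
  miss <- dplyr::anti_join(need, anchors, by = c("readout_gene", "series"))
  if (nrow(miss)) {
    stop("no stimulated '", control, "' reference wells for readout/series: ",
         paste(paste(miss$readout_gene, miss$series, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(dct, anchors, by = c("readout_gene", "series"))
  out$rel_expr <- out$expr / out$anchor
  if (!has_series) out$series <- NULL
  out[, setdiff(names(out), c("expr", "anchor"))]
}

#' Fold changes per knockdown from validation data
#'
#' Fold = mean normalized expression in knockdown wells divided by the mean
#' in vector-control wells, per condition, with means taken on the linear
#' scale (matching bar-graph presentation); set `log_scale = TRUE` to
#' average on the delta-ct (log2) scale instead. The regulation fold is the
#' ratio of the stimulated to the basal fold.
#'
#' @param rel tibble from [relative_expression()].
#' @param control reference construct.
#' @param log_scale average on the log2 scale.
#' @return tibble `target`, `readout_gene`, `comparison`, `fold` (plus
#'   `series` when present in `rel`).
#' @export
validation_folds <- function(rel, control = "empty_vector", log_scale = FALSE) {
  groups <- c("target_gene", "condition", "readout_gene",
              if ("series" %in% names(rel)) "series")
  avg <- if (log_scale) {
    function(x) 2^mean(log2(x))
  } else {
    mean
  }
  means <- dplyr::summarise(
    dplyr::group_by(rel, dplyr::across(dplyr::all_of(groups))),
    mean_expr = avg(.data$rel_expr),
    is_control = dplyr::first(.data$target_gene) == control,
    .groups = "drop"
  )
  ctrl <- means[means$target_gene == control, setdiff(names(means), c("target_gene", "is_control"))]
  names(ctrl)[names(ctrl) == "mean_expr"] <- "ctrl_expr"
  kd <- means[!means$target_gene %in% CONTROL_CONSTRUCTS, ]
  joined <- dplyr::left_join(kd, ctrl,
                             by = setdiff(names(ctrl), "ctrl_expr"))
  joined$fold <- joined$mean_expr / joined$ctrl_expr
  wide <- tidyr::pivot_wider(
    joined[, c("target_gene", "readout_gene", "condition", "fold",
               if ("series" %in% names(rel)) "series")],
    names_from = "condition", values_from = "fold"
  )
  out <- tibble::tibble(
    target = rep(wide$target_gene, 3L),
    readout_gene = rep(wide$readout_gene, 3L),
    comparison = rep(c("basal", "stimulated", "regulation"), each = nrow(wide)),
    fold = c(wide$untreated, wide$stimulated, wide$stimulated / wide$untreated)
  )
  if ("series" %in% names(rel)) out$series <- rep(wide$series, 3L)
  out[!is.na(out$fold), ]
}

#' Classify knockdown effects at a fold threshold
#'
#' The 1.5-fold rule: fold >= threshold labels the knocked-down factor a
#' corepressor (its loss derepressed the gene), fold <= 1/threshold a
#' coactivator (its loss suppressed the gene), anything inside the band
#' `none`. Symmetric under fold <-> 1/fold.
#'
#' @param folds tibble with a positive `fold` column.
#' @param threshold fold cutoff (> 1).
#' @return input with a `label` column; class `effect_matrix`.
#' @export
classify_effects <- function(folds, threshold = 1.5) {
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  if (any(!is.finite(folds$fold)) || any(folds$fold <= 0)) {
    stop("fold values must be positive and finite", call. = FALSE)
  }
  folds$label <- ifelse(folds$fold >= threshold, "corepressor",
                        ifelse(folds$fold <= 1 / threshold, "coactivator", "none"))
  class(folds) <- c("effect_matrix", class(folds))
  folds
}

#' Overlap of affected factors across the three comparisons
#'
#' Counts, for the sets of factors affecting the basal level, the
#' stimulated level and the extent of regulation, how many fall in each
#' region of the three-set Venn diagram. Accepts either an
#' [classify_effects()] table (affected = label != "none", requiring an
#' identical target roster per comparison) or a named list of three
#' character vectors.
#'
#' @param effects `effect_matrix` tibble or list with elements `basal`,
#'   `stimulated`, `regulation`.
#' @return named integer vector of the 7 Venn regions plus `total_affected`.
#' @export
effect_overlap <- function(effects) {
  if (is.data.frame(effects)) {
    rosters <- split(effects$target, effects$comparison)
    if (!all(COMPARISONS %in% names(rosters))) {
      stop("effect table must cover the basal, stimulated and regulation comparisons",
           call. = FALSE)
    }
    sorted <- lapply(rosters, function(x) sort(unique(x)))
    if (!all(vapply(sorted, identical, logical(1), y = sorted[[1]]))) {
      stop("cofactor roster differs between comparisons", call. = FALSE)
    }
    affected <- lapply(split(effects, effects$comparison),
                       function(d) unique(d$target[d$label != "none"]))
    effects <- affected[COMPARISONS]
  }
  if (!all(COMPARISONS %in% names(effects))) {
    stop("need sets named basal, stimulated, regulation", call. = FALSE)
  }
  a <- unique(effects$basal); b <- unique(effects$stimulated)
  c_ <- unique(effects$regulation)
  all3 <- intersect(intersect(a, b), c_)
  ab <- setdiff(intersect(a, b), all3)
  ac <- setdiff(intersect(a, c_), all3)
  bc <- setdiff(intersect(b, c_), all3)
  only_a <- setdiff(a, union(b, c_))
  only_b <- setdiff(b, union(a, c_))
  only_c <- setdiff(c_, union(a, b))
  c(basal_only = length(only_a),
    stimulated_only = length(only_b),
    regulation_only = length(only_c),
    basal_stimulated = length(ab),
    basal_regulation = length(ac),
    stimulated_regulation = length(bc),
    all_three = length(all3),
    total_affected = length(unique(c(a, b, c_))))
}

#' Rank an effect table by a key
#'
#' Stable sort of rows by the given key (ties keep input order), the
#' ordering used for gene-by-knockdown heatmap displays.
#'
#' @param effects data frame.
#' @param key column name to sort by.
#' @param decreasing sort direction.
#' @return the reordered data frame.
#' @export
rank_matrix <- function(effects, key, decreasing = FALSE) {
  if (!key %in% names(effects)) {
    stop("ranking key '", key, "' not present", call. = FALSE)
  }
  effects[order(effects[[key]], decreasing = decreasing, method = "radix"), ]
}

#' Two-group rank-sum test
#'
#' Exact two-sided Mann-Whitney (Wilcoxon rank-sum) p-value for small
#' samples, with a significance flag at p < 0.05. Ties fall back to the
#' normal approximation.
#'
#' @param values_a,values_b numeric vectors, each nonempty.
#' @return list with `p_value`, `statistic` (rank-sum W) and `significant`.
#' @export
group_difference_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = TRUE, correct = FALSE)
  )
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       significant = ht$p.value < 0.05)
}
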