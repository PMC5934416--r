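#' Control construct labels
#'
#' The three per-plate control transfections carried on every screening plate:
#' the empty knockdown vector (the reference for all fold-change
#' calculations), a scrambled non-targeting hairpin, and a GFP expression
#' control used to monitor transfection efficiency.
#' @export
CONTROL_CONSTRUCTS <- c("empty_vector", "scrambled", "gfp")

#' Conditions recognised in ct tables
#' @export
CONDITIONS <- c("untreated", "stimulated")

#' Construct a screen design
#'
#' Describes one shRNA screen: the cofactor target roster, the hairpin
#' manifest, the plate format and the qPCR readouts. Two formats are
#' supported: `"individual"` (each hairpin transfected into its own well
#' pair) and `"pooled"` (all hairpins against a target combined into a
#' single well pair).
#'
#' @param targets character vector of cofactor gene symbols.
#' @param shrna_manifest mapping of shRNA id to target gene: either a named
#'   character vector (names = shRNA ids, values = targets) or a data frame
#'   with columns `shrna` and `target`.
#' @param mode `"individual"` or `"pooled"`.
#' @param targets_per_plate number of targets laid out per plate. Defaults
#'   to 4 for individual screens and 20 for pooled screens.
#' @param replicates replicate well pairs per construct (a well pair is one
#'   untreated plus one stimulated well).
#' @param readouts readout genes measured per well; must contain
#'   `housekeeping`.
#' @param housekeeping readout gene used for delta-ct normalization.
#' @param stimulation_label free-text description of the stimulus.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(targets, shrna_manifest,
                          mode = c("individual", "pooled"),
                          targets_per_plate = NULL,
                          replicates = 1L,
                          readouts = c("Cxcl2", "Ube2l3"),
                          housekeeping = "Ube2l3",
                          stimulation_label = "IL-1 1 h") {
  mode <- match.arg(mode)
  if (is.null(targets_per_plate)) {
    targets_per_plate <- if (mode == "individual") 4L else 20L
  }
  manifest <- normalize_manifest(shrna_manifest)
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("design requires at least one target", call. = FALSE)
  if (anyDuplicated(targets)) stop("duplicated target symbols in roster", call. = FALSE)
  missing_sh <- setdiff(targets, manifest$target)
  if (length(missing_sh)) {
    stop("every target needs at least one shRNA; missing for: ",
         paste(missing_sh, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(manifest$target, targets)
  if (length(extra)) {
    stop("manifest maps shRNAs to targets not in the roster: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (targets_per_plate < 1L) stop("targets_per_plate must be >= 1", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (!housekeeping %in% readouts) {
    stop("housekeeping gene '", housekeeping, "' must be among the readouts",
         call. = FALSE)
  }
  structure(
    list(
      targets = targets,
      shrna_manifest = manifest,
      mode = mode,
      targets_per_plate = as.integer(targets_per_plate),
      replicates = as.integer(replicates),
      readouts = as.character(readouts),
      housekeeping = housekeeping,
      stimulation_label = stimulation_label
    ),
    class = "screen_design"
  )
}

normalize_manifest <- function(shrna_manifest) {
  if (is.data.frame(shrna_manifest)) {
    if (!all(c("shrna", "target") %in% names(shrna_manifest))) {
      stop("manifest data frame needs columns 'shrna' and 'target'", call. = FALSE)
    }
    manifest <- tibble::tibble(
      shrna = as.character(shrna_manifest$shrna),
      target = as.character(shrna_manifest$target)
    )
  } else if (is.character(shrna_manifest) && !is.null(names(shrna_manifest))) {
    manifest <- tibble::tibble(
      shrna = names(shrna_manifest),
      target = unname(shrna_manifest)
    )
  } else {
    stop("manifest must be a named character vector or a data frame", call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(manifest$shrna)) {
    stop("duplicated shRNA ids in manifest", call. = FALSE)
  }
  manifest
}

#' @export
print.screen_design <- function(x, ...) {
  cat("shRNA screen design (", x$mode, " mode)\n", sep = "")
  cat("  targets:          ", length(x$targets), "\n", sep = "")
  cat("  shRNAs:           ", nrow(x$shrna_manifest), "\n", sep = "")
  cat("  targets per plate: ", x$targets_per_plate,
      " (replicate well pairs: ", x$replicates, ")\n", sep = "")
  cat("  readouts:         ", paste(x$readouts, collapse = ", "),
      " (housekeeping: ", x$housekeeping, ")\n", sep = "")
  cat("  stimulation:      ", x$stimulation_label, "\n", sep = "")
  invisible(x)
}

#' Summarize an shRNA manifest
#'
#' Basic design arithmetic: how many constructs cover how many targets.
#'
#' @param design a [screen_design()].
#' @return a list with `n_targets`, `n_shrnas`, `mean_shrnas_per_target`
#'   (rounded to 2 decimals) and `exact_ratio`.
#' @examples
#' d <- screen_design(c("A", "B"), c(sh1 = "A", sh2 = "A", sh3 = "B"))
#' summarize_manifest(d)$mean_shrnas_per_target  # 1.5
#' @export
summarize_manifest <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  n_targets <- length(design$targets)
  n_shrnas <- nrow(design$shrna_manifest)
  if (n_targets == 0L || n_shrnas == 0L) stop("empty manifest", call. = FALSE)
  ratio <- n_shrnas / n_targets
  list(
    n_targets = n_targets,
    n_shrnas = n_shrnas,
    mean_shrnas_per_target = round(ratio, 2L),
    exact_ratio = ratio
  )
}

#' Plan plate layouts for a screen
#'
#' Assigns targets to plates (`ceiling(n_targets / targets_per_plate)`
#' plates) and lays out one well per construct, condition and replicate.
#' Every plate additionally carries the three control constructs
#' (empty vector, scrambled, GFP), each in both conditions. Well
#' coordinates are opaque labels; no plate geometry beyond capacity is
#' modeled.
#'
#' @param design a [screen_design()].
#' @param max_wells plate capacity (48-well format by default).
#' @return a tibble with columns `plate_id`, `well_id`, `construct`,
#'   `target_gene`, `condition`, `replicate`. Control wells carry their
#'   control label in both `construct` and `target_gene`.
#' @export
plan_layout <- function(design, max_wells = 48L) {
  stopifnot(inherits(design, "screen_design"))
  n_targets <- length(design$targets)
  n_plates <- ceiling(n_targets / design$targets_per_plate)
  plate_of <- rep(seq_len(n_plates), each = design$targets_per_plate)[seq_len(n_targets)]

  per_target <- lapply(seq_len(n_targets), function(i) {
    tg <- design$targets[[i]]
    constructs <- if (design$mode == "individual") {
      design$shrna_manifest$shrna[design$shrna_manifest$target == tg]
    } else {
      paste0("pool_", tg)
    }
    grid <- expand.grid(
      construct = constructs,
      replicate = seq_len(design$replicates),
      condition = CONDITIONS,
      stringsAsFactors = FALSE
    )
    grid$target_gene <- tg
    grid$plate_id <- sprintf("P%02d", plate_of[[i]])
    grid
  })
  wells <- dplyr::bind_rows(per_target)

  controls <- expand.grid(
    construct = CONTROL_CONSTRUCTS,
    condition = CONDITIONS,
    plate_id = sprintf("P%02d", seq_len(n_plates)),
    stringsAsFactors = FALSE
  )
  controls$target_gene <- controls$construct
  controls$replicate <- 1L

  layout <- dplyr::bind_rows(wells, controls)
  layout <- dplyr::arrange(layout, .data$plate_id, .data$target_gene,
                           .data$construct, .data$condition, .data$replicate)

  counts <- table(layout$plate_id)
  if (any(counts > max_wells)) {
    worst <- names(counts)[which.max(counts)]
    stop("plate capacity exceeded: plate ", worst, " needs ", max(counts),
         " wells but only ", max_wells, " are available (overflow ",
         max(counts) - max_wells, ")", call. = FALSE)
  }
  layout <- dplyr::group_by(layout, .data$plate_id)
  layout <- dplyr::mutate(layout, well_id = sprintf("W%02d", dplyr::row_number()))
  layout <- dplyr::ungroup(layout)
  tibble::as_tibble(layout[, c("plate_id", "well_id", "construct",
                               "target_gene", "condition", "replicate")])
}

#' Number of plates a layout spans
#' @param layout output of [plan_layout()].
#' @export
n_plates <- function(layout) length(unique(layout$plate_id))

ct_table_columns <- c(plate_id = "plate", well_id = "well",
                      construct = "construct", target_gene = "target",
                      condition = "condition", readout_gene = "readout",
                      ct = "ct")

#' Read a long-format ct table
#'
#' Expects one row per qPCR measurement with columns `plate`, `well`,
#' `construct`, `target`, `condition`, `readout`, `ct` (header names
#' configurable via `col_map`, matched case-insensitively). ct entries
#' equal to `undetermined_token` (case-insensitive) or exceeding
#' `max_cycles` are kept as records flagged `undetermined` with `ct = NA`;
#' they are excluded from all downstream averaging.
#'
#' @param path file to read.
#' @param delim field delimiter; `NULL` picks `,` for `.csv`, tab otherwise.
#' @param manifest optional [screen_design()] used to validate that every
#'   non-control construct is known.
#' @param col_map optional named character vector remapping the canonical
#'   header names, e.g. `c(ct = "Cq")`.
#' @param undetermined_token token marking a failed amplification.
#' @param max_cycles instrument cycle cap; finite ct above it is treated as
#'   undetermined.
#' @return tibble with columns `plate_id`, `well_id`, `construct`,
#'   `target_gene`, `condition`, `readout_gene`, `ct`, `undetermined`.
#' @export
load_ct_table <- function(path, delim = NULL, manifest = NULL, col_map = NULL,
                          undetermined_token = "Undetermined",
                          max_cycles = 40) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
  wanted <- ct_table_columns
  if (!is.null(col_map)) wanted[names(col_map)] <- unname(col_map)

  idx <- match(tolower(wanted), tolower(names(raw)))
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop("ct table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tibble::as_tibble(stats::setNames(raw[idx], names(wanted)))

  bad_cond <- setdiff(unique(tbl$condition), CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown condition value(s): ", paste(bad_cond, collapse = ", "),
         "; expected ", paste(CONDITIONS, collapse = "/"), call. = FALSE)
  }

  is_token <- !is.na(tbl$ct) &
    tolower(trimws(tbl$ct)) == tolower(undetermined_token)
  ct_num <- suppressWarnings(as.numeric(tbl$ct))
  unparseable <- !is_token & is.na(ct_num) & !is.na(tbl$ct)
  if (any(unparseable)) {
    stop("unparseable ct value(s), e.g. '", tbl$ct[which(unparseable)[1]],
         "' (row ", which(unparseable)[1], ")", call. = FALSE)
  }
  over_cap <- !is.na(ct_num) & ct_num > max_cycles
  nonpos <- !is.na(ct_num) & ct_num <= 0
  if (any(nonpos)) {
    stop("ct values must be positive (row ", which(nonpos)[1], ")", call. = FALSE)
  }
  tbl$undetermined <- is_token | over_cap
  tbl$ct <- ifelse(tbl$undetermined, NA_real_, ct_num)

  if (!is.null(manifest)) {
    stopifnot(inherits(manifest, "screen_design"))
    known <- c(manifest$shrna_manifest$shrna,
               paste0("pool_", manifest$targets),
               CONTROL_CONSTRUCTS)
    unknown <- setdiff(unique(tbl$construct), known)
    if (length(unknown)) {
      stop("construct(s) absent from design manifest: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  tbl
}

#' Write a ct table
#'
#' Inverse of [load_ct_table()]: numeric ct values are written at full
#' precision, undetermined records as the token, so that write-then-load
#' is the identity on valid records.
#'
#' @param tbl tibble as returned by [load_ct_table()] or [simulate_screen()].
#' @param path output file.
#' @param delim field delimiter.
#' @param undetermined_token token written for flagged records.
#' @param provenance optional named list written as leading `#` comment lines.
#' @export
write_ct_table <- function(tbl, path, delim = "\t",
                           undetermined_token = "Undetermined",
                           provenance = NULL) {
  need <- names(ct_table_columns)
  if (!all(need %in% names(tbl))) {
    stop("ct table to write is missing column(s): ",
         paste(setdiff(need, names(tbl)), collapse = ", "), call. = FALSE)
  }
  undet <- if ("undetermined" %in% names(tbl)) tbl$undetermined else is.na(tbl$ct)
  out <- tibble::tibble(
    plate = tbl$plate_id, well = tbl$well_id, construct = tbl$construct,
    target = tbl$target_gene, condition = tbl$condition,
    readout = tbl$readout_gene,
    ct = ifelse(undet, undetermined_token,
                vapply(tbl$ct, format_full, character(1)))
  )
  write_with_provenance(out, path, delim, provenance)
  invisible(path)
}

format_full <- function(x) {
  if (is.na(x)) return(NA_character_)
  format(x, digits = 17, scientific = FALSE, trim = TRUE)
}

write_with_provenance <- function(df, path, delim = "\t", provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, character(1))), con)
  }
  writeLines(paste(names(df), collapse = delim), con)
  if (nrow(df)) {
    body <- apply(as.data.frame(lapply(df, as.character)), 1L,
                  paste, collapse = delim)
    writeLines(body, con)
  }
}

#' Write a labelled matrix as TSV
#'
#' Header row of column labels plus a leading row-label column.
#' @param mat matrix with dimnames.
#' @param path output file.
#' @param row_label header for the row-name column.
#' @export
write_matrix_tsv <- function(mat, path, row_label = "row") {
  df <- tibble::as_tibble(mat, rownames = row_label)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a screen design manifest (JSON)
#'
#' The manifest carries keys `targets`, `shrnas` (id to target mapping),
#' `mode`, `targets_per_plate`, `replicates`, `readouts`, `housekeeping`,
#' `stimulation_label`.
#'
#' @param path JSON file.
#' @return [screen_design()] for `read_design`; the path, invisibly, for
#'   `write_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("targets", "shrnas", "mode")
  if (!all(need %in% names(j))) {
    stop("design manifest is missing key(s): ",
         paste(setdiff(need, names(j)), collapse = ", "), call. = FALSE)
  }
  screen_design(
    targets = j$targets,
    shrna_manifest = unlist(j$shrnas),
    mode = j$mode,
    targets_per_plate = j$targets_per_plate,
    replicates = if (is.null(j$replicates)) 1L else j$replicates,
    readouts = if (is.null(j$readouts)) c("Cxcl2", "Ube2l3") else j$readouts,
    housekeeping = if (is.null(j$housekeeping)) "Ube2l3" else j$housekeeping,
    stimulation_label = if (is.null(j$stimulation_label)) "IL-1 1 h" else j$stimulation_label
  )
}

#' @rdname read_design
#' @param design a [screen_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "screen_design"))
  j <- list(
    targets = design$targets,
    shrnas = stats::setNames(as.list(design$shrna_manifest$target),
                             design$shrna_manifest$shrna),
    mode = design$mode,
    targets_per_plate = design$targets_per_plate,
    replicates = design$replicates,
    readouts = design$readouts,
    housekeeping = design$housekeeping,
    stimulation_label = design$stimulation_label
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
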