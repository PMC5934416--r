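# Shared fixture builders and an independent straight-line oracle for the
# screen analysis. The oracle deliberately uses only base loops, no package
# aggregation helpers, so it can certify the pipeline output.

make_design <- function(n_targets, shrnas_per_target = 5L,
                        mode = "individual",
                        targets_per_plate = if (mode == "individual") 4L else 20L,
                        ...) {
  targets <- sprintf("TGT%03d", seq_len(n_targets))
  manifest <- data.frame(
    shrna = paste0("sh", rep(targets, each = shrnas_per_target), "_",
                   rep(seq_len(shrnas_per_target), n_targets)),
    target = rep(targets, each = shrnas_per_target)
  )
  screen_design(targets, manifest, mode = mode,
                targets_per_plate = targets_per_plate, ...)
}

# the full screening-scale study: 170 targets, 791 hairpins (111 x 5 + 59 x 4)
full_scale_design <- function(mode = "individual",
                              targets_per_plate = if (mode == "individual") 4L else 20L) {
  targets <- sprintf("TGT%03d", 1:170)
  nsh <- c(rep(5L, 111), rep(4L, 59))
  manifest <- data.frame(
    shrna = unlist(mapply(function(t, n) paste0("sh", t, "_", seq_len(n)),
                          targets, nsh, SIMPLIFY = FALSE)),
    target = rep(targets, nsh)
  )
  screen_design(targets, manifest, mode = mode,
                targets_per_plate = targets_per_plate)
}

# minimal long-format ct table built row by row
make_ct_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    plate_id = vapply(rows, `[[`, "", 1),
    well_id = vapply(rows, `[[`, "", 2),
    construct = vapply(rows, `[[`, "", 3),
    target_gene = vapply(rows, `[[`, "", 4),
    condition = vapply(rows, `[[`, "", 5),
    readout_gene = vapply(rows, `[[`, "", 6),
    ct = vapply(rows, function(r) as.numeric(r[[7]]), 0),
    undetermined = vapply(rows, function(r) is.na(as.numeric(r[[7]])), TRUE)
  )
}

# Straight-line recomputation of ddct / fold / z for one screen.
oracle_screen <- function(ct_tbl, design, screen_id) {
  hk <- design$housekeeping
  readouts <- setdiff(design$readouts, hk)
  dct_of_well <- function(plate, well, readout) {
    r <- ct_tbl$ct[ct_tbl$plate_id == plate & ct_tbl$well_id == well &
                     ct_tbl$readout_gene == readout]
    h <- ct_tbl$ct[ct_tbl$plate_id == plate & ct_tbl$well_id == well &
                     ct_tbl$readout_gene == hk]
    r - h
  }
  mean_dct <- function(rows_idx, readout) {
    vals <- c()
    for (i in rows_idx) {
      v <- dct_of_well(ct_tbl$plate_id[i], ct_tbl$well_id[i], readout)
      if (length(v) == 1 && !is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  out <- NULL
  for (readout in readouts) {
    base_idx <- which(ct_tbl$readout_gene == readout)
    for (tg in design$targets) {
      tg_idx <- base_idx[ct_tbl$target_gene[base_idx] == tg &
                           !(ct_tbl$construct[base_idx] %in% CONTROL_CONSTRUCTS)]
      plate <- unique(ct_tbl$plate_id[tg_idx])
      ctrl_idx <- which(ct_tbl$readout_gene == readout &
                          ct_tbl$construct == "empty_vector" &
                          ct_tbl$plate_id %in% plate)
      dd <- list()
      for (cond in c("untreated", "stimulated")) {
        t_dct <- mean_dct(tg_idx[ct_tbl$condition[tg_idx] == cond], readout)
        c_dct <- mean_dct(ctrl_idx[ct_tbl$condition[ctrl_idx] == cond], readout)
        dd[[cond]] <- t_dct - c_dct
      }
      out <- rbind(out, data.frame(
        target = tg, readout_gene = readout,
        comparison = c("basal", "stimulated", "regulation"),
        ddct = c(dd$untreated, dd$stimulated, dd$stimulated - dd$untreated)
      ))
    }
  }
  out$fold <- 2^(-out$ddct)
  out$z <- NA_real_
  for (readout in readouts) {
    for (cmp in c("basal", "stimulated", "regulation")) {
      idx <- which(out$readout_gene == readout & out$comparison == cmp)
      x <- out$ddct[idx]
      out$z[idx] <- (x - mean(x)) / sd(x)
    }
  }
  out$screen_id <- screen_id
  out
}

# Straight-line hit decisions from two oracle tables.
oracle_hits <- function(o1, o2, z_threshold = 1, require_concordance = TRUE) {
  hits <- NULL
  for (tg in unique(o1$target)) {
    for (cmp in c("basal", "stimulated", "regulation")) {
      a <- o1[o1$target == tg & o1$comparison == cmp, ]
      b <- o2[o2$target == tg & o2$comparison == cmp, ]
      if (nrow(a) != 1 || nrow(b) != 1) next
      pass <- abs(a$z) >= z_threshold && abs(b$z) >= z_threshold
      conc <- sign(a$ddct) == sign(b$ddct) && a$ddct != 0 && b$ddct != 0
      if (pass && (!require_concordance || conc)) {
        dir <- if ((a$ddct + b$ddct) / 2 > 0) "coactivator" else "corepressor"
        hits <- rbind(hits, data.frame(target = tg, comparison = cmp,
                                       direction = dir))
      }
    }
  }
  hits
}
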