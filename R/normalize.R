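#' Summarize on-plate controls
#'
#' Computes, per (plate, pathway, condition), the mean and standard error
#' of the negative-control GFP metric, the negative-control live-cell
#' metric, and the positive-control GFP metric. Every downstream ratio is
#' strictly per-plate: controls sit on each plate precisely so that
#' treated wells are compared against their own plate.
#'
#' @param wells Well measurement table (as produced by [simulate_screen()]
#'   or [quantify_screen()]), with a `role` column distinguishing
#'   `treated`, `neg_ctrl` and `pos_ctrl` wells.
#' @param gfp_metric Column used as the GFP readout (default per-cell mean
#'   intensity; `"gfp_total_area"` and `"gfp_pos_count"` are the
#'   alternatives recorded by the quantifier).
#' @param live_metric `"live_count"` (live_fraction x nuclei_count,
#'   default) or `"nuclei_count"`.
#' @return Data frame of class `hepascreen_controls`, one row per
#'   (plate_id, pathway, condition), with columns `neg_gfp_mean`,
#'   `neg_gfp_sem`, `neg_live_mean`, `neg_live_sem`, `pos_gfp_mean`,
#'   `pos_gfp_sem`, `n_neg`, `n_pos`.
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(noise_cv = 0), default_truths(1))
#' head(summarize_controls(sim$wells))
summarize_controls <- function(wells,
                               gfp_metric = "gfp_mean_intensity",
                               live_metric = c("live_count",
                                               "nuclei_count")) {
  live_metric <- match.arg(live_metric)
  wells <- add_live_count(wells)
  lm_col <- if (live_metric == "live_count") "live_count" else "nuclei_count"
  keys <- unique(wells[, c("plate_id", "pathway", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    w <- wells[wells$plate_id == k$plate_id &
                 wells$pathway == k$pathway &
                 wells$condition == k$condition, ]
    neg <- w[w$role == "neg_ctrl", ]
    pos <- w[w$role == "pos_ctrl", ]
    if (nrow(neg) == 0 || nrow(pos) == 0)
      stopf("plate '%s' is missing %s control wells", k$plate_id,
            if (nrow(neg) == 0) "negative" else "positive")
    data.frame(
      plate_id = k$plate_id, pathway = k$pathway, condition = k$condition,
      neg_gfp_mean = mean(neg[[gfp_metric]]),
      neg_gfp_sem = sem(neg[[gfp_metric]]),
      neg_live_mean = mean(neg[[lm_col]]),
      neg_live_sem = sem(neg[[lm_col]]),
      pos_gfp_mean = mean(pos[[gfp_metric]]),
      pos_gfp_sem = sem(pos[[gfp_metric]]),
      n_neg = nrow(neg), n_pos = nrow(pos),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("hepascreen_controls", "data.frame")
  out
}

add_live_count <- function(wells) {
  need <- c("plate_id", "well", "pathway", "condition", "role",
            "nuclei_count", "live_fraction")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("well table lacks columns: %s",
                          paste(miss, collapse = ", "))
  wells$live_count <- wells$live_fraction * wells$nuclei_count
  wells
}

#' Normalize wells against their on-plate controls
#'
#' Appends the control-relative readouts to every well: `viability_pct`
#' (live metric as % of the plate's negative-control mean),
#' `gfp_ratio_neg` (GFP fold over the negative-control mean),
#' `gfp_ratio_pos` (GFP fold over the positive-control mean), and
#' `p_value_vs_neg`, the two-sided t-test p-value of the replicate GFP
#' values of the same compound x dose against the plate's negative-control
#' GFP values (control wells get NA).
#'
#' @inheritParams summarize_controls
#' @param ctrl Optional precomputed [summarize_controls()] table; computed
#'   from `wells` when omitted.
#' @param var_equal Use Student's t (pooled variance) instead of Welch.
#' @return The well table with the normalized columns appended.
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(noise_cv = 0), default_truths(1))
#' nw <- normalize_wells(sim$wells)
#' subset(nw, role == "treated")[1:3, c("compound_id", "dose_uM",
#'                                      "viability_pct", "gfp_ratio_neg")]
normalize_wells <- function(wells, ctrl = NULL,
                            gfp_metric = "gfp_mean_intensity",
                            live_metric = c("live_count", "nuclei_count"),
                            var_equal = FALSE) {
  live_metric <- match.arg(live_metric)
  if (is.null(ctrl))
    ctrl <- summarize_controls(wells, gfp_metric = gfp_metric,
                               live_metric = live_metric)
  wells <- add_live_count(wells)
  lm_col <- if (live_metric == "live_count") "live_count" else "nuclei_count"
  key <- paste(wells$plate_id, wells$pathway, wells$condition)
  ckey <- paste(ctrl$plate_id, ctrl$pathway, ctrl$condition)
  idx <- match(key, ckey)
  if (anyNA(idx)) stopf("wells reference plates without control summaries")
  neg_live <- ctrl$neg_live_mean[idx]
  neg_gfp <- ctrl$neg_gfp_mean[idx]
  pos_gfp <- ctrl$pos_gfp_mean[idx]
  if (any(neg_live <= 0) || any(neg_gfp <= 0) || any(pos_gfp <= 0))
    stopf("degenerate plate: a control mean is zero")
  wells$viability_pct <- 100 * wells[[lm_col]] / neg_live
  wells$gfp_ratio_neg <- wells[[gfp_metric]] / neg_gfp
  wells$gfp_ratio_pos <- wells[[gfp_metric]] / pos_gfp

  wells$p_value_vs_neg <- NA_real_
  treated <- which(wells$role == "treated")
  if (length(treated)) {
    grp <- paste(wells$plate_id[treated], wells$pathway[treated],
                 wells$condition[treated], wells$compound_id[treated],
                 wells$dose_uM[treated])
    for (g in unique(grp)) {
      rows <- treated[grp == g]
      plate <- wells$plate_id[rows[1]]
      negrows <- which(wells$plate_id == plate & wells$role == "neg_ctrl" &
                         wells$pathway == wells$pathway[rows[1]] &
                         wells$condition == wells$condition[rows[1]])
      p <- if (length(rows) >= 2)
        test_induction(wells[[gfp_metric]][rows],
                       wells[[gfp_metric]][negrows],
                       var_equal = var_equal) else NA_real_
      wells$p_value_vs_neg[rows] <- p
    }
  }
  wells
}

#' Two-sided t-test of GFP induction
#'
#' Compares replicate GFP readouts of treated wells against the plate's
#' negative-control wells with a two-sided two-sample t-test (Welch by
#' default; set `var_equal = TRUE` for Student's t). Two degenerate
#' zero-variance cases are defined rather than errors: identical constant
#' groups give p = 1, constant groups at different levels give p = 0.
#'
#' @param treated,control Numeric vectors of replicate values (each of
#'   length >= 2).
#' @param var_equal Assume equal variances (Student's t).
#' @return The two-sided p-value.
#' @export
#' @examples
#' test_induction(c(10, 11, 12), c(1, 2, 3)) < 0.05
test_induction <- function(treated, control, var_equal = FALSE) {
  if (length(treated) < 2 || length(control) < 2)
    stopf("need at least 2 replicates per group")
  vt <- stats::var(treated)
  vc <- stats::var(control)
  if (vt == 0 && vc == 0) {
    return(if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0)
  }
  stats::t.test(treated, control, var.equal = var_equal)$p.value
}

#' Aggregate normalized wells into dose-response series
#'
#' Collapses replicate wells to one row per compound x pathway x
#' condition x dose: mean viability %, mean GFP ratios, the shared
#' induction p-value, and the replicate count. This is the table
#' [select_scoring_dose()] operates on.
#'
#' @param normalized Output of [normalize_wells()].
#' @return Data frame with one row per (compound_id, pathway, condition,
#'   dose_uM).
#' @export
dose_response_table <- function(normalized) {
  tr <- normalized[normalized$role == "treated", , drop = FALSE]
  if (nrow(tr) == 0) stopf("no treated wells to aggregate")
  if (!"viability_pct" %in% names(tr))
    stopf("input is not normalized; run normalize_wells() first")
  key <- list(compound_id = tr$compound_id, pathway = tr$pathway,
              condition = tr$condition, dose_uM = tr$dose_uM)
  agg <- stats::aggregate(
    tr[, c("viability_pct", "gfp_ratio_neg", "gfp_ratio_pos")],
    by = key, FUN = mean)
  pv <- stats::aggregate(list(p_value_vs_neg = tr$p_value_vs_neg),
                         by = key, FUN = function(x) x[1])
  n <- stats::aggregate(list(n_wells = tr$viability_pct),
                        by = key, FUN = length)
  out <- merge(merge(agg, pv), n)
  out[order(out$compound_id, out$pathway, out$condition, -out$dose_uM), ,
      drop = FALSE]
}
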