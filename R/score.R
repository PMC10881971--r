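#' Select the scoring dose of a dose series
#'
#' GFP induction is only considered reliable at concentrations that do not
#' strongly depress viability, so each compound x pathway x condition series
#' is scored at the highest dose whose viability is at least 50% of the
#' negative-control level. When every dose is below 50% the lowest dose is
#' returned and flagged `all_cytotoxic`; its score will in practice be 0.
#'
#' @param series Data frame with one row per dose, containing at least
#'   `dose_uM` and `viability_pct` (plus whatever normalized columns the
#'   caller wants carried through).
#' @return The selected row, with a logical `all_cytotoxic` column added.
#' @export
#' @examples
#' s <- data.frame(dose_uM = c(100, 10, 1), viability_pct = c(20, 80, 95))
#' select_scoring_dose(s)$dose_uM  # 10
select_scoring_dose <- function(series) {
  if (is.null(series) || nrow(series) == 0) stopf("empty dose series")
  if (anyNA(series$dose_uM)) stopf("dose series contains NA doses")
  ok <- series$viability_pct >= 50
  if (any(ok)) {
    i <- which(ok)[which.max(series$dose_uM[ok])]
    flag <- FALSE
  } else {
    i <- which.min(series$dose_uM)
    flag <- TRUE
  }
  out <- series[i, , drop = FALSE]
  out$all_cytotoxic <- flag
  rownames(out) <- NULL
  out
}

#' Assign the four-tier pathway activity score
#'
#' Implements the tier rules of the screen, applied to the well selected by
#' [select_scoring_dose()]:
#' \describe{
#'   \item{3 ("positive increase")}{viability above 70% and GFP above the
#'     positive-chemical level (`gfp_ratio_pos > 1`).}
#'   \item{2 ("positive cause")}{viability in the 50-70% band (inclusive)
#'     and GFP above the positive-chemical level.}
#'   \item{1 ("possible cause")}{viability above 50%, GFP at or below the
#'     positive chemical but significantly above the negative control
#'     (`gfp_ratio_neg > 1` and `p < 0.05`).}
#'   \item{0 ("no effect")}{anything else.}
#' }
#' The viability bands partition: exactly 70% falls in tier 2, exactly 50%
#' qualifies for tier 2 (given induction above the positive control) but
#' not tier 1. A missing p-value is treated as not significant. All
#' arguments are vectorized.
#'
#' @param viability_pct Viability as % of the negative-control live metric.
#' @param gfp_ratio_pos GFP fold vs the positive-control mean.
#' @param gfp_ratio_neg GFP fold vs the negative-control mean.
#' @param p_value Two-sided p-value of induction vs the negative control.
#' @param alpha Significance level for the tier-1 test (default 0.05).
#' @return Integer score(s) in 0..3.
#' @export
#' @examples
#' assign_score(85, 1.3, 2.0, 0.001)  # 3
#' assign_score(60, 1.2, 1.8, 0.002)  # 2
#' assign_score(90, 0.6, 1.8, 0.01)   # 1
#' assign_score(95, 0.5, 1.02, 0.4)   # 0
assign_score <- function(viability_pct, gfp_ratio_pos, gfp_ratio_neg,
                         p_value, alpha = 0.05) {
  n <- max(length(viability_pct), length(gfp_ratio_pos),
           length(gfp_ratio_neg), length(p_value))
  v <- rep_len(viability_pct, n)
  rp <- rep_len(gfp_ratio_pos, n)
  rn <- rep_len(gfp_ratio_neg, n)
  p <- rep_len(p_value, n)
  if (any(v < 0 | rp < 0 | rn < 0, na.rm = TRUE))
    stopf("viability and GFP ratios must be non-negative")
  p[is.na(p)] <- 1
  score <- integer(n)
  score[v > 70 & rp > 1] <- 3L
  score[v >= 50 & v <= 70 & rp > 1] <- 2L
  score[v > 50 & rp <= 1 & rn > 1 & p < alpha] <- 1L
  score
}

#' Sum the four pathway scores of one condition
#'
#' The per-condition hazard sum: the arithmetic total of the AP1, P53,
#' Nrf2 and NF-kB tier scores, at most 12 (all four at tier 3).
#'
#' @param scores Numeric vector of four scores in 0..3, named by pathway
#'   (or a data frame with `pathway` and `score` columns).
#' @return Integer sum in 0..12.
#' @export
#' @examples
#' sum_condition(c(AP1 = 3, P53 = 3, Nrf2 = 3, NFkB = 3))  # 12
sum_condition <- function(scores) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$pathway)
  if (is.null(names(scores)) || !setequal(names(scores), pathways()))
    stopf("need exactly one score per pathway (%s)",
          paste(pathways(), collapse = ", "))
  if (length(scores) != 4) stopf("need exactly 4 scores, one per pathway")
  if (any(!scores %in% 0:3)) stopf("scores must lie in 0..3")
  as.integer(sum(scores))
}

#' Classify S9 metabolic dependence from the two hazard sums
#'
#' A condition is "active" when its hazard sum reaches `hazard_threshold`
#' (score 3 or higher flags likely toxicity). A compound active under only
#' one condition is specific to it; a compound active under both is called
#' more active under the condition whose sum leads by at least
#' `delta_threshold` points, otherwise consistent; a compound active under
#' neither is non-responsive.
#'
#' @param sum_s9_minus,sum_s9_plus Hazard sums (0..12) without / with S9.
#' @param hazard_threshold Activity threshold on the sums (default 3).
#' @param delta_threshold Minimum sum difference to call one condition
#'   "more active" when both are active (default 2).
#' @param strict If `TRUE`, activity requires the sum to exceed (not reach)
#'   `hazard_threshold`.
#' @return One of `"consistent"`, `"s9_minus_more_active"`,
#'   `"s9_plus_more_active"`, `"non_responsive"`.
#' @export
#' @examples
#' classify_s9_dependence(0, 5)  # "s9_plus_more_active"
#' classify_s9_dependence(6, 6)  # "consistent"
classify_s9_dependence <- function(sum_s9_minus, sum_s9_plus,
                                   hazard_threshold = 3,
                                   delta_threshold = 2,
                                   strict = FALSE) {
  if (any(c(sum_s9_minus, sum_s9_plus) < 0) ||
      any(c(sum_s9_minus, sum_s9_plus) > 12))
    stopf("hazard sums must lie in 0..12")
  active <- function(s) if (strict) s > hazard_threshold else
    s >= hazard_threshold
  am <- active(sum_s9_minus)
  ap <- active(sum_s9_plus)
  if (!am && !ap) return("non_responsive")
  if (ap && !am) return("s9_plus_more_active")
  if (am && !ap) return("s9_minus_more_active")
  d <- sum_s9_plus - sum_s9_minus
  if (d >= delta_threshold) return("s9_plus_more_active")
  if (-d >= delta_threshold) return("s9_minus_more_active")
  "consistent"
}

#' Classify one pathway's activity pattern across conditions
#'
#' Pathway-level analogue of the compound classification: a pathway is
#' active in a condition when its tier score reaches `activity_floor`
#' (default 1, i.e. any significant GFP increase over control).
#'
#' @param score_s9_minus,score_s9_plus Tier scores (0..3).
#' @param activity_floor Minimum score counted as active.
#' @return One of `"commonly_active"`, `"s9_minus_specific"`,
#'   `"s9_plus_specific"`, `"inactive"`.
#' @export
#' @examples
#' classify_pathway_group(3, 3)  # "commonly_active"
#' classify_pathway_group(2, 0)  # "s9_minus_specific"
classify_pathway_group <- function(score_s9_minus, score_s9_plus,
                                   activity_floor = 1) {
  if (any(!c(score_s9_minus, score_s9_plus) %in% 0:3))
    stopf("scores must lie in 0..3")
  am <- score_s9_minus >= activity_floor
  ap <- score_s9_plus >= activity_floor
  if (am && ap) return("commonly_active")
  if (am) return("s9_minus_specific")
  if (ap) return("s9_plus_specific")
  "inactive"
}

#' Pathway membership sets for a four-set Venn summary
#'
#' For one metabolic condition, lists which compounds are active (score >=
#' `activity_floor`) in each of the four pathways, and tabulates the 15
#' non-empty Venn regions of the four sets.
#'
#' @param scores Data frame of per-compound scores with columns
#'   `compound_id`, `pathway`, `condition`, `score` (the `$scores` element
#'   of a [score_screen()] result).
#' @param condition `"S9minus"` or `"S9plus"`.
#' @param activity_floor Minimum score counted as active (default 1).
#' @return List with `sets` (named list of compound-id vectors, one per
#'   pathway) and `region_counts` (named integer vector over the 15
#'   intersection regions, e.g. `"AP1&P53"`).
#' @export
venn_membership <- function(scores, condition, activity_floor = 1) {
  if (nrow(scores) == 0) stopf("no scores supplied")
  if (!condition %in% conditions()) stopf("unknown condition '%s'", condition)
  sc <- scores[scores$condition == condition, , drop = FALSE]
  sets <- lapply(setNames(nm = pathways()), function(pw)
    sort(unique(sc$compound_id[sc$pathway == pw & sc$score >= activity_floor])))
  ids <- sort(unique(sc$compound_id))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, pathways()))
  patterns <- venn_region_names()
  counts <- setNames(integer(length(patterns)), patterns)
  if (length(ids)) {
    key <- apply(member, 1, function(m)
      paste(pathways()[m], collapse = "&"))
    tab <- table(key[key != ""])
    counts[names(tab)] <- as.integer(tab)
  }
  list(sets = sets, region_counts = counts)
}

# The 15 non-empty subsets of the four pathways, in size order.
venn_region_names <- function() {
  pw <- pathways()
  unlist(lapply(1:4, function(k)
    apply(utils::combn(pw, k), 2, paste, collapse = "&")))
}

#' Score a normalized screen
#'
#' The scoring stage of the pipeline: aggregates normalized wells to dose
#' series, selects the scoring dose per compound x pathway x condition,
#' assigns the 0-3 tier score, and derives the compound-level profile:
#' per-condition hazard sums (max 12), hazard flags (sum >=
#' `hazard_threshold`), the S9-dependence class, and per-pathway activity
#' groups.
#'
#' @param normalized Normalized well table from [normalize_wells()] (or a
#'   `hepascreen_sim` object, which is normalized first).
#' @param hazard_threshold Hazard-flag threshold on the sums (default 3).
#' @param delta_threshold Tie-break margin for [classify_s9_dependence()].
#' @param activity_floor Pathway-activity floor for groups and Venn sets.
#' @param alpha Significance level of the tier-1 rule.
#' @param strict_hazard Use a strict (>) hazard threshold instead of >=.
#' @return Object of class `hepascreen_screen`: list with `scores` (one
#'   row per compound x pathway x condition), `profiles` (one row per
#'   compound), and `matrix` (compounds x 8 score matrix with
#'   `pathway_condition` columns).
#' @export
#' @examples
#' sim <- simulate_screen(sim_config(noise_cv = 0), default_truths(1))
#' scr <- score_screen(normalize_wells(sim$wells))
#' scr$profiles[, c("compound_id", "sum_s9_minus", "sum_s9_plus", "s9_class")]
score_screen <- function(normalized, hazard_threshold = 3,
                         delta_threshold = 2, activity_floor = 1,
                         alpha = 0.05, strict_hazard = FALSE) {
  if (inherits(normalized, "hepascreen_sim"))
    normalized <- normalize_wells(normalized$wells)
  dr <- dose_response_table(normalized)
  keys <- unique(dr[, c("compound_id", "pathway", "condition")])
  scores <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    series <- dr[dr$compound_id == k$compound_id &
                   dr$pathway == k$pathway &
                   dr$condition == k$condition, , drop = FALSE]
    sel <- select_scoring_dose(series)
    data.frame(
      compound_id = k$compound_id, pathway = k$pathway,
      condition = k$condition, selected_dose = sel$dose_uM,
      viability_pct = sel$viability_pct,
      gfp_ratio_pos = sel$gfp_ratio_pos, gfp_ratio_neg = sel$gfp_ratio_neg,
      p_value_vs_neg = sel$p_value_vs_neg,
      all_cytotoxic = sel$all_cytotoxic,
      score = assign_score(sel$viability_pct, sel$gfp_ratio_pos,
                           sel$gfp_ratio_neg, sel$p_value_vs_neg,
                           alpha = alpha),
      stringsAsFactors = FALSE
    )
  }))
  rownames(scores) <- NULL

  cpds <- sort(unique(scores$compound_id))
  profiles <- do.call(rbind, lapply(cpds, function(id) {
    sc <- scores[scores$compound_id == id, ]
    sums <- vapply(conditions(), function(cond)
      sum_condition(sc[sc$condition == cond, c("pathway", "score")]),
      integer(1))
    hz <- if (strict_hazard) sums > hazard_threshold else
      sums >= hazard_threshold
    groups <- vapply(pathways(), function(pw)
      classify_pathway_group(
        sc$score[sc$pathway == pw & sc$condition == "S9minus"],
        sc$score[sc$pathway == pw & sc$condition == "S9plus"],
        activity_floor = activity_floor), character(1))
    out <- data.frame(
      compound_id = id,
      sum_s9_minus = sums[["S9minus"]], sum_s9_plus = sums[["S9plus"]],
      hazard_s9_minus = hz[["S9minus"]], hazard_s9_plus = hz[["S9plus"]],
      s9_class = classify_s9_dependence(
        sums[["S9minus"]], sums[["S9plus"]],
        hazard_threshold = hazard_threshold,
        delta_threshold = delta_threshold, strict = strict_hazard),
      stringsAsFactors = FALSE
    )
    for (pw in pathways()) out[[paste0("group_", pw)]] <- groups[[pw]]
    out
  }))
  rownames(profiles) <- NULL

  mat <- matrix(0L, nrow = length(cpds), ncol = 8,
                dimnames = list(cpds, paste(
                  rep(pathways(), times = 2),
                  rep(conditions(), each = 4), sep = "_")))
  for (i in seq_len(nrow(scores)))
    mat[scores$compound_id[i],
        paste(scores$pathway[i], scores$condition[i], sep = "_")] <-
      as.integer(scores$score[i])

  structure(list(scores = scores, profiles = profiles, matrix = mat,
                 params = list(hazard_threshold = hazard_threshold,
                               delta_threshold = delta_threshold,
                               activity_floor = activity_floor,
                               alpha = alpha,
                               strict_hazard = strict_hazard)),
            class = "hepascreen_screen")
}

#' @export
print.hepascreen_screen <- function(x, ...) {
  cat(sprintf("Scored screen: %d compounds x %d pathways x %d conditions\n",
              nrow(x$profiles), length(pathways()), length(conditions())))
  tab <- table(factor(x$profiles$s9_class,
                      levels = c("consistent", "s9_minus_more_active",
                                 "s9_plus_more_active", "non_responsive")))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
summary.hepascreen_screen <- function(object, ...) {
  print(object)
  cat("\nHazard sums (0-12):\n")
  print(object$profiles[, c("compound_id", "sum_s9_minus", "sum_s9_plus",
                            "hazard_s9_minus", "hazard_s9_plus",
                            "s9_class")], row.names = FALSE)
  invisible(object)
}

#' Plot a scored screen as a clustered heatmap
#'
#' Draws the compounds x (pathway, condition) score matrix as a heatmap
#' with hierarchical clustering on both axes (Euclidean distance, average
#' linkage by default), the integrative view of the screen.
#'
#' @param x A `hepascreen_screen`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param ... Passed to [pheatmap::pheatmap()].
#' @export
plot.hepascreen_screen <- function(x, linkage = "average", ...) {
  m <- x$matrix
  rcl <- cluster_score_matrix(m, "rows", linkage = linkage)
  ccl <- cluster_score_matrix(m, "columns", linkage = linkage)
  pheatmap::pheatmap(m, cluster_rows = rcl$hclust, cluster_cols = ccl$hclust,
                     legend_breaks = 0:3, ...)
}
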