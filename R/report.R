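#' Hierarchically cluster the score matrix
#'
#' Agglomerative clustering of the compounds x (pathway, condition) score
#' matrix along one axis, Euclidean distance and average linkage by
#' default. [stats::hclust()] is deterministic; equal distances are
#' resolved by original index order, so the leaf order is stable across
#' runs.
#'
#' @param m Numeric matrix (values 0-3) with row and column names.
#' @param axis `"rows"` or `"columns"`.
#' @param dist_method Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `hclust` (the tree), `order` (leaf permutation) and
#'   `labels` (leaf labels in that order).
#' @export
#' @examples
#' m <- matrix(c(3, 3, 0, 0, 3, 3, 0, 1), 4, 2,
#'             dimnames = list(paste0("c", 1:4), c("a", "b")))
#' cluster_score_matrix(m, "rows")$labels
cluster_score_matrix <- function(m, axis = c("rows", "columns"),
                                 dist_method = "euclidean",
                                 linkage = "average") {
  axis <- match.arg(axis)
  x <- if (axis == "rows") m else t(m)
  if (nrow(x) < 2) stopf("need >= 2 items on the %s axis", axis)
  hc <- stats::hclust(stats::dist(x, method = dist_method),
                      method = linkage)
  list(hclust = hc, order = hc$order, labels = rownames(x)[hc$order])
}

#' Write the report bundle of a scored screen
#'
#' Writes the integrative outputs: `scores.csv`, `profiles.csv`, the
#' compounds x 8 `score_matrix.csv`, per-condition Venn region counts
#' (`venn_counts_<condition>.csv`) and membership lists, S9-class
#' membership lists (`s9_classes.csv`), a clustered heatmap
#' (`heatmap.png`), per-condition four-set Venn diagrams, and a versioned
#' machine-readable `summary.json`. Rerunning on identical input
#' reproduces identical tables.
#'
#' @param screen A [score_screen()] result with at least one compound.
#' @param out_dir Output directory (created if needed).
#' @param activity_floor Score floor defining Venn membership.
#' @return Invisible named list of written paths.
#' @export
render_outputs <- function(screen, out_dir,
                           activity_floor = screen$params$activity_floor) {
  stopifnot(inherits(screen, "hepascreen_screen"))
  if (nrow(screen$profiles) == 0) stopf("empty profile list; nothing to report")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    tryCatch(utils::write.csv(df, p, row.names = FALSE),
             error = function(e) stopf("failed writing %s: %s", p,
                                       conditionMessage(e)))
    paths[[name]] <<- p
  }
  wr(screen$scores, "scores.csv")
  wr(screen$profiles, "profiles.csv")
  wr(data.frame(compound_id = rownames(screen$matrix), screen$matrix,
                check.names = FALSE), "score_matrix.csv")
  wr(screen$profiles[, c("compound_id", "s9_class")], "s9_classes.csv")

  venns <- list()
  for (cond in conditions()) {
    vm <- venn_membership(screen$scores, cond, activity_floor)
    venns[[cond]] <- vm
    wr(data.frame(region = names(vm$region_counts),
                  count = as.integer(vm$region_counts)),
       sprintf("venn_counts_%s.csv", cond))
    p <- file.path(out_dir, sprintf("venn_%s.png", cond))
    grDevices::png(p, width = 720, height = 620)
    plot_venn4(vm$region_counts, main = sprintf("Active pathways (%s)", cond))
    grDevices::dev.off()
    paths[[basename(p)]] <- p
  }

  if (nrow(screen$matrix) >= 2) {
    p <- file.path(out_dir, "heatmap.png")
    grDevices::png(p, width = 800, height = 200 + 18 * nrow(screen$matrix))
    plot(screen)
    grDevices::dev.off()
    paths[["heatmap.png"]] <- p
  }

  summary <- list(
    schema_version = "1.0",
    n_compounds = nrow(screen$profiles),
    params = screen$params,
    s9_class_counts = as.list(table(screen$profiles$s9_class)),
    hazard_counts = list(
      S9minus = sum(screen$profiles$hazard_s9_minus),
      S9plus = sum(screen$profiles$hazard_s9_plus)),
    venn_region_counts = lapply(venns, function(v)
      as.list(v$region_counts)),
    venn_sets = lapply(venns, `[[`, "sets")
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["summary.json"]] <- p
  invisible(paths)
}

# Four-ellipse Venn diagram; region label positions are found numerically
# as centroids of the rasterized intersection regions, so labels always
# fall inside their region.
plot_venn4 <- function(region_counts, main = "") {
  centers <- matrix(c(0.35, 0.47, 0.45, 0.57, 0.55, 0.57, 0.65, 0.47),
                    ncol = 2, byrow = TRUE)
  angles <- c(-40, -40, 40, 40) * pi / 180
  a <- 0.32; b <- 0.17
  inside <- function(x, y, i) {
    dx <- x - centers[i, 1]; dy <- y - centers[i, 2]
    u <- dx * cos(angles[i]) + dy * sin(angles[i])
    v <- -dx * sin(angles[i]) + dy * cos(angles[i])
    (u / a)^2 + (v / b)^2 <= 1
  }
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1.1), asp = 1)
  graphics::title(main = main)
  cols <- c("#1b9e7755", "#d95f0255", "#7570b355", "#e7298a55")
  tt <- seq(0, 2 * pi, length.out = 200)
  for (i in 1:4) {
    u <- a * cos(tt); v <- b * sin(tt)
    x <- centers[i, 1] + u * cos(angles[i]) - v * sin(angles[i])
    y <- centers[i, 2] + u * sin(angles[i]) + v * cos(angles[i])
    graphics::polygon(x, y, col = cols[i], border = "grey30")
  }
  g <- seq(0.005, 0.995, by = 0.004)
  grid <- expand.grid(x = g, y = g)
  memb <- sapply(1:4, function(i) inside(grid$x, grid$y, i))
  pattern <- apply(memb, 1, function(m)
    paste(pathways()[m], collapse = "&"))
  for (nm in names(region_counts)) {
    pts <- grid[pattern == nm, ]
    if (nrow(pts) == 0) next
    graphics::text(mean(pts$x), mean(pts$y), region_counts[[nm]], cex = 1.1)
  }
  lab_pos <- rbind(c(0.10, 0.70), c(0.30, 0.86), c(0.70, 0.86),
                   c(0.90, 0.70))
  for (i in 1:4) graphics::text(lab_pos[i, 1], lab_pos[i, 2], pathways()[i],
                                font = 2)
}

#' Run the full screening pipeline
#'
#' Simulate (or accept) a screen, optionally re-derive the well metrics
#' through the image path, normalize against on-plate controls, score,
#' and (optionally) write the report bundle. Stage timings are logged via
#' `message()`. With a fixed configuration seed the bundle is identical
#' across runs.
#'
#' @param config A [sim_config()].
#' @param truths Compound truths (default the 24-compound reference set).
#' @param wells Optional pre-existing well measurement table; skips
#'   simulation.
#' @param use_images Push every well through render + quantify instead of
#'   using the table metrics (slow; intended for small screens).
#' @param out_dir If non-NULL, [render_outputs()] writes the bundle here.
#' @param ... Passed to [score_screen()].
#' @return Invisible list of class `hepascreen_run` with `sim`,
#'   `normalized`, `screen` and `paths`.
#' @export
#' @examples
#' run <- run_pipeline(sim_config(noise_cv = 0), default_truths(1))
#' run$screen$profiles$s9_class
run_pipeline <- function(config = sim_config(), truths = default_truths(),
                         wells = NULL, use_images = FALSE, out_dir = NULL,
                         ...) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  sim <- NULL
  if (is.null(wells)) {
    sim <- stage("simulate", simulate_screen(config, truths))
    wells <- sim$wells
  }
  if (use_images) {
    if (is.null(sim)) stopf("use_images requires a simulated screen")
    wells <- stage("quantify", quantify_screen(sim))
  }
  normalized <- stage("normalize", normalize_wells(wells))
  screen <- stage("score", score_screen(normalized, ...))
  paths <- if (!is.null(out_dir))
    stage("report", render_outputs(screen, out_dir)) else NULL
  invisible(structure(list(sim = sim, normalized = normalized,
                           screen = screen, paths = paths),
                      class = "hepascreen_run"))
}

#' @export
print.hepascreen_run <- function(x, ...) {
  cat("Pipeline run\n")
  print(x$screen)
  invisible(x)
}
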