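#' Quantification parameters
#'
#' Settings for nuclei detection and cell scoring, the counterpart of a
#' high-content imager's "count nuclei" / "cell scoring" module settings.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma (px).
#' @param nucleus_min_area,nucleus_max_area Accepted nucleus area band
#'   (px^2).
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed.
#' @param gfp_threshold_method `"k_sigma_background"` (positive when the
#'   cell's mean reporter intensity exceeds background mean + k x SD) or
#'   `"fixed"` (absolute threshold `fixed_gfp_threshold`).
#' @param gfp_k Multiplier k of the background SD (default 3).
#' @param fixed_gfp_threshold Absolute threshold for the fixed method.
#' @param live_k Background-SD multiplier of the live-cell call on the
#'   viability channel.
#' @param cell_region_radius Radius (px) by which the nucleus is dilated
#'   to form the measured cell region.
#' @return Object of class `hepascreen_quant_params`.
#' @export
quant_params <- function(smoothing_sigma = 2, nucleus_min_area = 20,
                         nucleus_max_area = 800, split_touching = TRUE,
                         gfp_threshold_method = c("k_sigma_background",
                                                  "fixed"),
                         gfp_k = 3, fixed_gfp_threshold = NULL,
                         live_k = 3, cell_region_radius = 5) {
  gfp_threshold_method <- match.arg(gfp_threshold_method)
  if (!(nucleus_min_area > 0 && nucleus_min_area < nucleus_max_area))
    stopf("need 0 < nucleus_min_area < nucleus_max_area")
  if (gfp_k <= 0 || live_k <= 0) stopf("gfp_k and live_k must be > 0")
  if (gfp_threshold_method == "fixed" && is.null(fixed_gfp_threshold))
    stopf("fixed_gfp_threshold required for method 'fixed'")
  structure(list(smoothing_sigma = smoothing_sigma,
                 nucleus_min_area = nucleus_min_area,
                 nucleus_max_area = nucleus_max_area,
                 split_touching = split_touching,
                 gfp_threshold_method = gfp_threshold_method,
                 gfp_k = gfp_k, fixed_gfp_threshold = fixed_gfp_threshold,
                 live_k = live_k,
                 cell_region_radius = cell_region_radius),
            class = "hepascreen_quant_params")
}

#' Detect nuclei in the Hoechst channel
#'
#' Gaussian smoothing, automatic global (Otsu) thresholding, optional
#' distance-transform watershed splitting of touching objects, and an
#' area filter. A constant (degenerate) image yields zero nuclei with a
#' warning. Centroids are 1-based (row, col) pixel coordinates.
#'
#' @param field A `hepascreen_field` (or any list with a `nuclei` matrix
#'   and `bit_depth`).
#' @param params A [quant_params()].
#' @return Data frame with one row per accepted nucleus (`nucleus_id`,
#'   `row`, `col`, `nucleus_area`); the label image is attached as
#'   attribute `"labels"` for [score_cells()].
#' @export
#' @examples
#' fld <- render_field(30, field_size = 128, min_separation = 12, seed = 2)
#' nrow(count_nuclei(fld, quant_params()))
count_nuclei <- function(field, params = quant_params()) {
  img <- field$nuclei / (2^(field$bit_depth %||% 16) - 1)
  empty <- data.frame(nucleus_id = integer(0), row = numeric(0),
                      col = numeric(0), nucleus_area = numeric(0))
  if (diff(range(img)) == 0) {
    warning("degenerate (constant) nuclei channel; no nuclei detected")
    attr(empty, "labels") <- EBImage::Image(matrix(0L, nrow(img), ncol(img)))
    return(empty)
  }
  sm <- EBImage::gblur(EBImage::Image(img), sigma = params$smoothing_sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > th
  labels <- if (params$split_touching)
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
  else EBImage::bwlabel(mask)
  areas <- table(labels[labels > 0])
  bad <- as.integer(names(areas)[areas < params$nucleus_min_area |
                                   areas > params$nucleus_max_area])
  if (length(bad)) labels <- EBImage::rmObjects(labels, bad, reenumerate = TRUE)
  if (max(labels) == 0) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  mom <- EBImage::computeFeatures.moment(labels)
  areas <- as.numeric(table(labels[labels > 0]))
  out <- data.frame(nucleus_id = seq_len(nrow(mom)),
                    row = mom[, "m.cx"], col = mom[, "m.cy"],
                    nucleus_area = areas)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}

#' Score cells on the reporter and viability channels
#'
#' For every detected nucleus a cell region is formed by dilating the
#' nucleus by `cell_region_radius` (overlaps resolved by nearest-nucleus
#' propagation) and measured on the reporter and viability channels.
#' Background is estimated from pixels outside all cell regions; a cell
#' is GFP-positive when its mean reporter intensity exceeds background
#' mean + `gfp_k` x background SD (or the fixed threshold), and live when
#' the analogous criterion holds on the viability channel. `gfp_mean` is
#' background-subtracted so it scales with the true per-cell reporter
#' signal.
#'
#' @param field A `hepascreen_field`.
#' @param nuclei Output of [count_nuclei()] on the same field.
#' @param params A [quant_params()].
#' @return Data frame of cell records: `cell_id`, `row`, `col`,
#'   `nucleus_area`, `gfp_mean`, `gfp_area`, `gfp_positive`, `live`.
#' @export
score_cells <- function(field, nuclei, params = quant_params()) {
  empty <- data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), nucleus_area = numeric(0),
                      gfp_mean = numeric(0), gfp_area = numeric(0),
                      gfp_positive = logical(0), live = logical(0))
  if (nrow(nuclei) == 0) return(empty)
  labels <- attr(nuclei, "labels")
  if (is.null(labels)) stopf("nuclei must come from count_nuclei()")
  r <- params$cell_region_radius
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  cellmask <- EBImage::dilate(labels > 0, brush)
  zero <- EBImage::Image(matrix(0, dim(labels)[1], dim(labels)[2]))
  regions <- EBImage::propagate(zero, labels, mask = cellmask)

  rep_ch <- field$reporter
  via_ch <- field$viability
  rvec <- as.numeric(EBImage::imageData(regions))
  inside <- rvec > 0
  bg_rep <- rep_ch[!inside]
  bg_via <- via_ch[!inside]
  bg_mean <- mean(bg_rep); bg_sd <- max(stats::sd(bg_rep), 1e-9)
  vbg_mean <- mean(bg_via); vbg_sd <- max(stats::sd(bg_via), 1e-9)

  idx <- factor(rvec[inside], levels = seq_len(nrow(nuclei)))
  rep_means <- tapply(rep_ch[inside], idx, mean)
  via_means <- tapply(via_ch[inside], idx, mean)
  gfp_thr <- if (params$gfp_threshold_method == "fixed")
    params$fixed_gfp_threshold else bg_mean + params$gfp_k * bg_sd
  gfp_area <- tapply(rep_ch[inside] > gfp_thr, idx, sum)
  live_thr <- vbg_mean + params$live_k * vbg_sd

  data.frame(
    cell_id = nuclei$nucleus_id, row = nuclei$row, col = nuclei$col,
    nucleus_area = nuclei$nucleus_area,
    gfp_mean = pmax(as.numeric(rep_means) - bg_mean, 0),
    gfp_area = as.numeric(gfp_area),
    gfp_positive = as.numeric(rep_means) > gfp_thr,
    live = as.numeric(via_means) > live_thr
  )
}

#' Aggregate cell records to well metrics
#'
#' Collapses the per-cell records of all fields of one well to the
#' well-level measurement row used by the plate statistics: nuclei count,
#' live fraction, GFP-positive count, mean per-cell GFP intensity (over
#' all cells), and total GFP-positive area. An empty record list is valid
#' and yields zero counts with `no_cells = TRUE`.
#'
#' @param records Data frame of cell records from [score_cells()] (rows
#'   from several fields may be concatenated).
#' @return One-row data frame with `nuclei_count`, `live_fraction`,
#'   `gfp_pos_count`, `gfp_mean_intensity`, `gfp_total_area`, `no_cells`.
#' @export
#' @examples
#' summarize_well(data.frame(gfp_mean = c(10, 20, 30), gfp_area = 0,
#'                           gfp_positive = FALSE, live = TRUE))
summarize_well <- function(records) {
  n <- nrow(records)
  if (n == 0)
    return(data.frame(nuclei_count = 0L, live_fraction = 0,
                      gfp_pos_count = 0L, gfp_mean_intensity = 0,
                      gfp_total_area = 0, no_cells = TRUE))
  data.frame(
    nuclei_count = as.integer(n),
    live_fraction = sum(records$live) / n,
    gfp_pos_count = as.integer(sum(records$gfp_positive)),
    gfp_mean_intensity = mean(records$gfp_mean),
    gfp_total_area = sum(records$gfp_area),
    no_cells = FALSE
  )
}

#' Quantify a simulated screen through the image path
#'
#' Renders one field per well from the simulated well table and pushes it
#' through [count_nuclei()], [score_cells()] and [summarize_well()],
#' returning a well table of the same shape as `sim$wells` but with
#' image-derived metrics. Intended for modest screens (it renders and
#' segments every well); the table path of [simulate_screen()] is the
#' fast route for large designs.
#'
#' @param sim A `hepascreen_sim`.
#' @param params A [quant_params()].
#' @param cells_per_field Cells rendered per field (the well's cell count
#'   scaled down to one field).
#' @param field_size Field side length (px).
#' @param intensity_gain Factor from table GFP intensity units to blob
#'   amplitude.
#' @param intensity_cv,read_noise_sd Passed to [render_field()]; zero for
#'   noise-free fixtures.
#' @return Well measurement table with image-derived metrics.
#' @export
quantify_screen <- function(sim, params = quant_params(),
                            cells_per_field = 60, field_size = 256,
                            intensity_gain = 4, intensity_cv = 0,
                            read_noise_sd = 5) {
  stopifnot(inherits(sim, "hepascreen_sim"))
  wells <- sim$wells
  out <- wells
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    n <- min(cells_per_field,
             max(0, round(cells_per_field * w$nuclei_count /
                            sim$config$cells_per_well_mean)))
    fld <- render_field(
      n_cells = n, field_size = field_size,
      live_fraction = w$live_fraction,
      gfp_pos_fraction = min(1, w$gfp_pos_count / max(w$nuclei_count, 1)),
      gfp_intensity_pos = w$gfp_mean_intensity * intensity_gain,
      gfp_intensity_neg = w$gfp_mean_intensity * intensity_gain,
      intensity_cv = intensity_cv, read_noise_sd = read_noise_sd,
      min_separation = 12,
      seed = plate_seed(sim$config$rng_seed, 100000 + i)
    )
    rec <- score_cells(fld, count_nuclei(fld, params), params)
    m <- summarize_well(rec)
    out$nuclei_count[i] <- m$nuclei_count
    out$live_fraction[i] <- m$live_fraction
    out$gfp_pos_count[i] <- m$gfp_pos_count
    out$gfp_mean_intensity[i] <- m$gfp_mean_intensity
    out$gfp_total_area[i] <- m$gfp_total_area
  }
  out
}
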