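#' Render a synthetic three-channel microscopy field
#'
#' Draws one imaged field of a well: nuclei as 2-D Gaussian blobs at
#' uniformly placed centroids (optionally with a minimum separation,
#' enforced by rejection sampling), a reporter channel whose per-cell
#' intensity is drawn log-normally around the GFP-positive or
#' GFP-negative class mean, and a viability (Calcein) channel rendered
#' only for live cells. Live and GFP-positive flags are Bernoulli per
#' cell. Additive Gaussian read noise and a constant background are
#' applied to every channel; intensities are clipped to the bit-depth
#' range well below saturation.
#'
#' Coordinates are 1-based (row, col) pixel centers of the image matrix.
#'
#' @param n_cells Exact number of cells to plant (>= 0).
#' @param field_size Side length in pixels (>= 64).
#' @param live_fraction Probability a cell is live.
#' @param gfp_pos_fraction Probability a cell is GFP-positive.
#' @param gfp_intensity_pos,gfp_intensity_neg Mean reporter blob amplitude
#'   of GFP-positive / negative cells.
#' @param intensity_cv CV of the per-cell log-normal intensity draw.
#' @param nucleus_intensity Nuclei-channel blob amplitude.
#' @param nucleus_sigma,reporter_sigma Gaussian blob sigmas (px).
#' @param background Constant background level added to all channels.
#' @param read_noise_sd SD of the additive Gaussian read noise.
#' @param min_separation Minimum centroid distance (px); 0 disables.
#' @param bit_depth Intensity bit depth (default 16).
#' @param seed RNG seed for the field.
#' @return Object of class `hepascreen_field`: list with numeric matrices
#'   `nuclei`, `reporter`, `viability`, the `bit_depth`, and `truth`, a
#'   data frame with one row per planted cell (`cell_id`, `row`, `col`,
#'   `gfp_intensity`, `gfp_positive`, `live`).
#' @export
#' @examples
#' fld <- render_field(50, field_size = 128, gfp_pos_fraction = 0.4,
#'                     min_separation = 10, seed = 1)
#' nrow(fld$truth)
render_field <- function(n_cells, field_size = 256, live_fraction = 1,
                         gfp_pos_fraction = 0, gfp_intensity_pos = 5000,
                         gfp_intensity_neg = 50, intensity_cv = 0.15,
                         nucleus_intensity = 12000, nucleus_sigma = 2.5,
                         reporter_sigma = 3.5, background = 300,
                         read_noise_sd = 15, min_separation = 0,
                         bit_depth = 16, seed = 1L) {
  if (field_size < 64) stopf("field_size must be >= 64 px")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (min_separation > 0 &&
      n_cells * min_separation^2 > 0.55 * field_size^2)
    stopf("requested density exceeds geometric capacity at min_separation %g",
          min_separation)
  maxval <- 2^bit_depth - 1
  with_seed(seed, {
    pos <- place_centroids(n_cells, field_size, min_separation)
    live <- if (n_cells) rbinom(n_cells, 1, live_fraction) == 1 else logical(0)
    gpos <- if (n_cells) rbinom(n_cells, 1, gfp_pos_fraction) == 1 else
      logical(0)
    amp_mean <- ifelse(gpos, gfp_intensity_pos, gfp_intensity_neg)
    gfp_amp <- amp_mean * ln_noise(n_cells, intensity_cv)

    nuc <- matrix(0, field_size, field_size)
    rep_ch <- matrix(0, field_size, field_size)
    via <- matrix(0, field_size, field_size)
    for (i in seq_len(n_cells)) {
      nuc <- add_blob(nuc, pos[i, 1], pos[i, 2], nucleus_intensity,
                      nucleus_sigma)
      rep_ch <- add_blob(rep_ch, pos[i, 1], pos[i, 2], gfp_amp[i],
                         reporter_sigma)
      if (live[i])
        via <- add_blob(via, pos[i, 1], pos[i, 2], 8000, reporter_sigma)
    }
    clip <- function(m) {
      m <- m + background
      if (read_noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, read_noise_sd),
                        nrow(m), ncol(m))
      pmin(pmax(m, 0), maxval)
    }
    truth <- data.frame(
      cell_id = seq_len(n_cells),
      row = if (n_cells) pos[, 1] else numeric(0),
      col = if (n_cells) pos[, 2] else numeric(0),
      gfp_intensity = gfp_amp, gfp_positive = gpos, live = live
    )
    structure(list(nuclei = clip(nuc), reporter = clip(rep_ch),
                   viability = clip(via), bit_depth = bit_depth,
                   truth = truth),
              class = "hepascreen_field")
  })
}

# Uniform centroids with optional minimum pairwise separation; rejection
# sampling with a generous retry budget, keeping a margin off the border so
# blobs are fully in frame.
place_centroids <- function(n, size, min_sep) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  margin <- 8
  pts <- matrix(NA_real_, n, 2)
  tries <- 0
  k <- 0
  max_tries <- 400 * n + 1000
  while (k < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stopf("could not place %d centroids at min_separation %g", n, min_sep)
    cand <- stats::runif(2, margin, size - margin)
    if (min_sep > 0 && k > 0) {
      d2 <- (pts[1:k, 1] - cand[1])^2 + (pts[1:k, 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    k <- k + 1
    pts[k, ] <- cand
  }
  pts
}

# Add a Gaussian blob of amplitude `amp` and sd `sigma` centered at
# (r, c) to matrix `m`, evaluated on a 4-sigma window.
add_blob <- function(m, r, c, amp, sigma) {
  w <- ceiling(4 * sigma)
  rr <- max(1, floor(r - w)):min(nrow(m), ceiling(r + w))
  cc <- max(1, floor(c - w)):min(ncol(m), ceiling(c + w))
  dr <- (rr - r)^2
  dc <- (cc - c)^2
  m[rr, cc] <- m[rr, cc] + amp * exp(-outer(dr, dc, "+") / (2 * sigma^2))
  m
}

#' Write / read a field as 16-bit grayscale TIFFs
#'
#' One file per channel, named `{plate}_{well}_{channel}.tif` with
#' channels `nuclei`, `reporter`, `viability` — the on-disk interchange
#' format of the simulated screen.
#'
#' @param field A `hepascreen_field` (for reading, the `truth` element is
#'   absent).
#' @param dir Directory for the TIFF files.
#' @param plate,well Identifiers used in the file names.
#' @return `write_field_tiff()` returns the written paths invisibly;
#'   `read_field_tiff()` returns a `hepascreen_field` without ground truth.
#' @export
write_field_tiff <- function(field, dir, plate, well) {
  stopifnot(inherits(field, "hepascreen_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxval <- 2^field$bit_depth - 1
  paths <- character(0)
  for (ch in c("nuclei", "reporter", "viability")) {
    p <- file.path(dir, sprintf("%s_%s_%s.tif", plate, well, ch))
    tiff::writeTIFF(field[[ch]] / maxval, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_tiff
#' @param bit_depth Bit depth to restore intensities to (default 16).
#' @export
read_field_tiff <- function(dir, plate, well, bit_depth = 16) {
  maxval <- 2^bit_depth - 1
  chans <- lapply(setNames(nm = c("nuclei", "reporter", "viability")),
                  function(ch) {
    p <- file.path(dir, sprintf("%s_%s_%s.tif", plate, well, ch))
    if (!file.exists(p)) stopf("missing channel file: %s", p)
    tiff::readTIFF(p) * maxval
  })
  shapes <- vapply(chans, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) stopf("channel shapes differ")
  structure(c(chans, list(bit_depth = bit_depth, truth = NULL)),
            class = "hepascreen_field")
}
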