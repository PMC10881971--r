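#' Read and write well measurement tables
#'
#' CSV interchange for the well-level schema shared by the simulator and
#' the image quantifier: `plate_id, well, compound_id, dose_uM, pathway,
#' condition, role, nuclei_count, live_fraction, gfp_pos_count,
#' gfp_mean_intensity, gfp_total_area`.
#'
#' @param wells Well table data frame.
#' @param path CSV file path.
#' @return `read_well_table()` returns the validated data frame;
#'   `write_well_table()` returns `path` invisibly.
#' @export
write_well_table <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  wells <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "compound_id", "dose_uM", "pathway",
            "condition", "role", "nuclei_count", "live_fraction",
            "gfp_pos_count", "gfp_mean_intensity", "gfp_total_area")
  miss <- setdiff(need, names(wells))
  if (length(miss)) stopf("well table %s lacks columns: %s", path,
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(wells$role), c("treated", "neg_ctrl", "pos_ctrl"))
  if (length(bad)) stopf("unknown well role(s): %s", paste(bad, collapse = ", "))
  wells
}
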