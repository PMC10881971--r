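# Shared fixtures and independent oracles for the test suite.

# Construct a bare field with Gaussian nuclei blobs at given (row, col)
# centers, bypassing render_field so segmentation tests control geometry
# exactly.
make_blob_field <- function(centers, size = 128, amp = 12000, sigma = 3,
                            background = 300) {
  m <- matrix(0, size, size)
  for (i in seq_len(nrow(centers)))
    m <- hepascreen:::add_blob(m, centers[i, 1], centers[i, 2], amp, sigma)
  flat <- matrix(background, size, size)
  structure(list(nuclei = m + background, reporter = flat, viability = flat,
                 bit_depth = 16, truth = NULL),
            class = "hepascreen_field")
}

# Match detected cell records to planted truth rows by nearest centroid.
match_to_truth <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i)
    which.min((truth$row - records$row[i])^2 +
                (truth$col - records$col[i])^2), integer(1))
}

# Independent brute-force tier oracle: a viability-band x induction-level
# decision table, structured differently from the implementation.
oracle_score <- function(v, rp, rn, p) {
  band <- if (v > 70) "high" else if (v >= 50) "mid" else "low"
  induction <- if (rp > 1) "above_pos" else
    if (rn > 1 && p < 0.05) "above_neg" else "none"
  tab <- c("high above_pos" = 3, "mid above_pos" = 2,
           "high above_neg" = 1, "mid above_neg" = 1)
  s <- tab[paste(band, induction)]
  s <- if (is.na(s)) 0 else unname(s)
  if (s == 1 && v <= 50) s <- 0  # tier 1 needs viability strictly above 50
  s
}

# Map truth-class labels onto classifier output labels.
truth_class_to_output <- c(consistent = "consistent",
                           s9_minus_specific = "s9_minus_more_active",
                           s9_plus_specific = "s9_plus_more_active",
                           non_responsive = "non_responsive")

# Small single-compound truth with two active pathways, no cytotoxicity.
nontoxic_truth <- function(id = "X1", fold = 4.5, cond = NULL) {
  fx <- matrix(1, 4, 2, dimnames = list(pathways(), conditions()))
  cls <- "consistent"
  if (is.null(cond)) fx[c(1, 4), ] <- fold
  else {
    fx[c(1, 4), cond] <- fold
    cls <- if (cond == "S9minus") "s9_minus_specific" else "s9_plus_specific"
  }
  compound_truth(id, fx, c(S9minus = 1e6, S9plus = 1e6),
                 intended_class = cls)
}
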