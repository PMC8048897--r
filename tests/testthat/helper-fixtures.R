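# Study-table fixtures used across tests (built in code, no files).

# Per-tree summary of the four study species: diameter over bark, maximum and
# fissure-corrected bark thickness (cm), plus printed reading statistics.
study_trees <- function() {
  tibble::tibble(
    species = c(
      "Eucalyptus crebra", "Eucalyptus albens",
      "Callitris glaucophylla", "Allocasuarina luehmannii"
    ),
    dob_cm = c(28.3, 20.3, 25.4, 28.0),
    bt_max_cm = c(3.1, 1.0, 1.1, 0.9),
    bt_f_cm = c(2.1, 0.9, 1.0, 0.8),
    mean_bt_f_cm = c(2.08, 0.94, 1.00, 0.77),
    sd_cm = c(0.74, 0.15, 0.15, 0.29),
    cv_pct = c(35.75, 15.77, 15.35, 37.99)
  )
}

# circle polygon helper
circle_poly <- function(r, n = 720, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

# measurement CSV written to a tempfile; returns the path
write_fixture_csv <- function(lines, delim = ",") {
  path <- tempfile(fileext = ".csv")
  writeLines(gsub(",", delim, lines, fixed = TRUE), path)
  path
}
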