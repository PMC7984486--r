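# Small fixtures built in code.

# A toy tissue set: per category, tissues sharing one composition at
# different densities, so every target quantity is exactly linear in RED
# within a category.
toy_collinear_set <- function() {
  w <- as.data.frame(water_reference())
  rows <- list()
  dens <- list(fat = c(0.92, 0.96, 1.00), soft = c(1.02, 1.05, 1.08),
               bone = c(1.2, 1.5, 1.9))
  for (cc in names(dens)) {
    for (d in dens[[cc]]) {
      r <- w
      r$name <- sprintf("%s_%g", cc, d)
      r$category <- cc
      r$density <- d
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tissue_set", "data.frame")
  out
}

# Write a one-row tissue CSV and return its path.
write_water_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("name,category,density,H,O",
               "water_analogue,soft,1.0,11.19,88.81"), path)
  path
}

# Independent element constants for brute-force oracles (kept separate from
# the package registry on purpose).
oracle_elements <- function() {
  data.frame(
    symbol = c("H", "C", "N", "O", "Ca", "P", "Na",
               "Mg", "S", "Cl", "K", "Fe", "I"),
    Z = c(1, 6, 7, 8, 20, 15, 11, 12, 16, 17, 19, 26, 53),
    A = c(1.008, 12.011, 14.007, 15.999, 40.078, 30.973761998, 22.98976928,
          24.305, 32.06, 35.45, 39.0983, 55.845, 126.90447),
    I_eV = c(19.2, 78.0, 82.0, 95.0, 191, 173, 149,
             156, 180, 174, 190, 286, 491),
    stringsAsFactors = FALSE
  )
}

# Brute-force electron moles per gram: explicit per-element loop.
oracle_electron_moles <- function(tissue_row) {
  el <- oracle_elements()
  total <- 0
  for (k in seq_len(nrow(el))) {
    w <- tissue_row[[el$symbol[k]]]
    total <- total + (w / 100) * el$Z[k] / el$A[k]
  }
  total
}
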