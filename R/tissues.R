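# Tissue tables.
#
# A tissue set is a data frame with class c("tissue_set", "data.frame") and
# columns: name, category ("fat"/"soft"/"bone"), density (g/cm^3), then one
# weight column per element in element_symbols() (percent by mass, summing
# to 100 after load-time normalization).  Simulated sets carry two extra
# leading columns, `parent` and `index`.

.categories <- c("fat", "soft", "bone")

.tissue_columns <- function() c("name", "category", "density", element_symbols())

.as_tissue_set <- function(df, provenance = NA_character_) {
  class(df) <- c("tissue_set", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

#' Extract the elemental weight matrix of a tissue set
#'
#' @param tissues A tissue set (see [load_tissue_table()]).
#' @return Numeric matrix, one row per tissue, one column per element in
#'   [element_symbols()] order, weights in percent.
#' @export
weight_matrix <- function(tissues) {
  m <- as.matrix(as.data.frame(tissues)[, element_symbols(), drop = FALSE])
  rownames(m) <- tissues$name
  m
}

.validate_tissue_set <- function(df, source, normalize = TRUE) {
  need <- c("name", "category", "density")
  if (!all(need %in% names(df))) {
    stop("tissue table ", source, " lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  extra <- setdiff(names(df), c(.tissue_columns(), "parent", "index"))
  if (length(extra)) {
    stop("unknown element or column in ", source, ": ",
         paste(extra, collapse = ", "))
  }
  # absent element columns mean weight 0
  for (el in setdiff(element_symbols(), names(df))) df[[el]] <- 0
  df <- df[, c(intersect(c("parent", "index"), names(df)), .tissue_columns())]

  if (anyNA(df$density) || !is.numeric(df$density)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$density))))
    stop("non-numeric density in ", source, ", row(s) ",
         paste(bad, collapse = ", "))
  }
  w <- as.matrix(df[, element_symbols()])
  if (!is.numeric(w) || anyNA(w)) {
    stop("non-numeric elemental weight in ", source, ", row(s) ",
         paste(unique(which(is.na(w), arr.ind = TRUE)[, 1]), collapse = ", "))
  }
  if (any(df$density <= 0)) stop("non-positive density in ", source)
  if (any(w < 0)) stop("negative elemental weight in ", source)
  if (anyDuplicated(df$name)) {
    stop("duplicated tissue name(s) in ", source, ": ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  if (!all(df$category %in% .categories)) {
    stop("category must be one of ", paste(.categories, collapse = "/"),
         " in ", source)
  }
  sums <- rowSums(w)
  off <- abs(sums - 100) > 0.5
  if (any(off)) {
    stop("elemental weights of ", paste(df$name[off], collapse = ", "),
         " sum to ", paste(round(sums[off], 2), collapse = ", "),
         " (must be within 0.5 of 100)")
  }
  if (normalize) df[, element_symbols()] <- w * (100 / sums)
  df
}

#' Load a tissue table
#'
#' Reads a tissue table either from a packaged builtin or from a CSV file in
#' the dialect `name,category,density,H,C,N,O,Ca,P,Na,Mg,S,Cl,K,Fe,I`
#' (density in g/cm^3, elemental weights in percent, category one of
#' `fat`/`soft`/`bone`).  The builtin `"icrp23_reference"` is the set of 32
#' reference human tissues (3 fat, 18 non-fat soft, 11 bone) with ICRP
#' publication 23 densities and compositions, grouped by similarity of
#' chemical composition.
#'
#' Elemental weights of each tissue are validated (row sums must lie within
#' 0.5 of 100) and then renormalized multiplicatively so that they sum to
#' exactly 100, which the mass-fraction formulas downstream assume.
#'
#' @param source Either the name of a builtin table (currently
#'   `"icrp23_reference"`) or the path to a CSV file.
#' @return A `tissue_set` data frame.
#' @examples
#' ref <- load_tissue_table("icrp23_reference")
#' table(ref$category)
#' @export
load_tissue_table <- function(source = "icrp23_reference") {
  if (source == "icrp23_reference") {
    path <- system.file("extdata", "icrp23_reference.csv", package = "redspr",
                        mustWork = TRUE)
    provenance <- "builtin:icrp23_reference"
  } else {
    if (!file.exists(source)) stop("no such tissue table: ", source)
    path <- source
    provenance <- source
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- .validate_tissue_set(df, source)
  .as_tissue_set(df, provenance)
}

#' Write a tissue table to CSV
#'
#' Inverse of [load_tissue_table()]: writes the standard tissue CSV dialect.
#' Densities and normalized weights are written at full precision so that a
#' write/load round trip is exact.
#'
#' @param tissues A tissue set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_table <- function(tissues, path) {
  utils::write.csv(format(as.data.frame(tissues), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The water reference medium
#'
#' Water at 1.0 g/cm^3 with the H/O mass fractions implied by the standard
#' atomic weights (2 * A_H and A_O out of 2 * A_H + A_O, about 11.19% and
#' 88.81%).  All CT-number and stopping-power quantities in the package are
#' normalized to this medium.
#'
#' @return A one-row `tissue_set`.
#' @examples
#' water_reference()$H  # ~11.19
#' @export
water_reference <- function() {
  a_h <- .elem("H", "A_w")
  a_o <- .elem("O", "A_w")
  w <- data.frame(name = "Water", category = "soft", density = 1.0,
                  stringsAsFactors = FALSE)
  for (el in element_symbols()) w[[el]] <- 0
  w$H <- 100 * 2 * a_h / (2 * a_h + a_o)
  w$O <- 100 * a_o / (2 * a_h + a_o)
  .as_tissue_set(w, "definition:water")
}

#' @export
print.tissue_set <- function(x, ...) {
  cat("Tissue set (", nrow(x), " tissues: ",
      paste(vapply(.categories, function(cc) sum(x$category == cc),
                   integer(1)), .categories, collapse = ", "),
      ")\n", sep = "")
  if (!is.na(attr(x, "provenance"))) {
    cat("source:", attr(x, "provenance"), "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}
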