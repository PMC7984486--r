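# Calibration: fitting the CT-number model to phantom measurements and
# building the segmented RED -> HU_scale and RED -> SPR calibration curves.

#' Fit the kV CT-number model to phantom measurements
#'
#' Ordinary least squares of measured scaled CT numbers on the three model
#' regressors `RED * Z_tilde^3.62`, `RED * Z_hat^1.86` and `RED` (no
#' intercept: the model has exactly three terms).  The measurements come
#' from tissue-equivalent substitutes of known (vendor-supplied) density and
#' composition scanned on the machine to be calibrated.
#'
#' @param measurements A data frame in the tissue CSV dialect (see
#'   [load_tissue_table()]) with an extra numeric column
#'   `hu_scale_measured`, one row per substitute.
#' @return A [kv_fit_parameters()] object with attributes `r_squared`,
#'   `fitted` and `residuals` describing the fit quality.
#' @examples
#' ref <- load_tissue_table("icrp23_reference")
#' m <- as.data.frame(ref)
#' m$hu_scale_measured <- kv_hu_scale(ref)  # noiseless synthetic scan
#' fit_kv_parameters(m)                     # recovers the default A, B, C
#' @export
fit_kv_parameters <- function(measurements) {
  if (!"hu_scale_measured" %in% names(measurements)) {
    stop("measurements need a 'hu_scale_measured' column")
  }
  hu <- measurements$hu_scale_measured
  if (!is.numeric(hu) || any(hu <= 0)) {
    stop("hu_scale_measured must be positive numbers")
  }
  m <- measurements[, setdiff(names(measurements), "hu_scale_measured")]
  # substitute files need no category column; it plays no role in the fit
  if (!"category" %in% names(m)) m$category <- "soft"
  tis <- .validate_tissue_set(m, "measurements")
  tis <- .as_tissue_set(tis)
  if (nrow(tis) < 3) {
    stop("need at least 3 substitute measurements to determine A, B, C")
  }
  red <- relative_electron_density(tis)
  zz <- effective_atomic_numbers(tis)
  X <- cbind(pe = red * zz$Z_tilde^3.62,
             coh = red * zz$Z_hat^1.86,
             compton = red)
  if (qr(X)$rank < 3) {
    stop("rank-deficient design: substitutes do not span the three model terms")
  }
  ls <- stats::lm.fit(X, hu)
  coefs <- ls$coefficients
  out <- kv_fit_parameters(coefs[["pe"]], coefs[["coh"]], coefs[["compton"]])
  attr(out, "r_squared") <- 1 - sum(ls$residuals^2) / sum((hu - mean(hu))^2)
  attr(out, "fitted") <- stats::setNames(ls$fitted.values, tis$name)
  attr(out, "residuals") <- stats::setNames(ls$residuals, tis$name)
  out
}

#' Build a segmented linear calibration curve
#'
#' Fits, separately within each tissue category (fat, non-fat soft, bone),
#' an unweighted least-squares line of the target quantity against RED.  The
#' target values are computed from the exact tissue compositions with the
#' stoichiometric model ([kv_hu_scale()]) or the Bethe ratio
#' ([proton_spr()]).  Segmenting by category keeps the chemical composition
#' within each line's support similar; segments are fitted independently and
#' are not forced to join at category boundaries.
#'
#' @inheritParams tissue_physics
#' @param target `"HU_scale"` or `"SPR"`.
#' @param intercept Fit an affine line (default) or force a zero intercept
#'   (sensitivity option).
#' @return An object of class `calibration_curve`: a list with `target`,
#'   `intercept` and `segments`, the latter a data frame with one row per
#'   category (`slope`, `intercept`, `r_squared`, `n_points`).
#' @examples
#' ref <- load_tissue_table("icrp23_reference")
#' build_calibration_curve(ref, "SPR")
#' @export
build_calibration_curve <- function(tissues,
                                    target = c("HU_scale", "SPR"),
                                    fit = default_kv_fit(),
                                    beam = proton_beam(),
                                    intercept = TRUE,
                                    iw_mode = c("bragg_additivity", "fixed"),
                                    iw_eV = 78) {
  target <- match.arg(target)
  red <- relative_electron_density(tissues)
  y <- if (target == "HU_scale") {
    kv_hu_scale(tissues, fit)
  } else {
    proton_spr(tissues, beam, iw_mode, iw_eV)
  }
  segs <- lapply(.categories, function(cc) {
    in_cat <- tissues$category == cc
    if (sum(in_cat) < 2) {
      stop("category '", cc, "' has fewer than 2 tissues; cannot fit a line")
    }
    f <- if (intercept) y[in_cat] ~ red[in_cat] else y[in_cat] ~ 0 + red[in_cat]
    m <- stats::lm(f)
    co <- stats::coef(m)
    data.frame(category = cc,
               slope = unname(co[length(co)]),
               intercept = if (intercept) unname(co[1]) else 0,
               r_squared = .r_squared(m, intercept),
               n_points = sum(in_cat),
               stringsAsFactors = FALSE)
  })
  structure(list(target = target, intercept = intercept,
                 segments = do.call(rbind, segs)),
            class = "calibration_curve")
}

# Coefficient of determination without summary.lm's perfect-fit warning;
# uses the uncentered total sum of squares for zero-intercept fits, as lm does.
.r_squared <- function(m, intercept = TRUE) {
  y <- m$model[[1]]
  tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  1 - sum(stats::residuals(m)^2) / tss
}

#' Evaluate a calibration curve
#'
#' Returns `slope * red + intercept` of the segment belonging to each
#' tissue's category.  This is the clinical estimate: it uses only RED and
#' the category, never the tissue's actual composition, so at a fitted
#' tissue's RED it returns the line value, not the ground truth.
#'
#' @param curve A [build_calibration_curve()] result.
#' @param red Numeric vector of RED values.
#' @param category Character vector (recycled) of categories.
#' @return Numeric vector of estimates.
#' @export
evaluate_curve <- function(curve, red, category) {
  idx <- match(category, curve$segments$category)
  if (anyNA(idx)) {
    stop("unknown category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "))
  }
  curve$segments$slope[idx] * red + curve$segments$intercept[idx]
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Segmented calibration curve: RED ->", x$target,
      if (!x$intercept) "(zero intercept)", "\n")
  print(x$segments, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Export / import a calibration curve as JSON
#'
#' @param curve A `calibration_curve`.
#' @param path JSON file path.
#' @return `write_curve_json()` returns `path` invisibly;
#'   `read_curve_json()` returns the curve.
#' @export
write_curve_json <- function(curve, path) {
  jsonlite::write_json(list(target = curve$target,
                            intercept = curve$intercept,
                            segments = curve$segments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(target = x$target, intercept = x$intercept,
                 segments = as.data.frame(x$segments)),
            class = "calibration_curve")
}
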