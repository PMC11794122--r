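## qPCR standard-curve machinery: forward simulation of Ct values from a
## log-linear curve with Gaussian replicate noise and max-cycle censoring,
## OLS fitting of dilution series, inversion, and an all-replicates-detected
## limit-of-detection rule.
##
## Convention: X = -log10(dilution), so larger X means more dilute template
## and the slope is positive. Absolute concentrations are anchored by the
## user-supplied concentration at X = 0 (conc_at_x0).

#' qPCR standard curve
#'
#' The fitted line Ct = slope * X + intercept with X = -log10(dilution).
#'
#' @slot slope Ct change per unit X (cycles per 10-fold dilution).
#' @slot intercept Ct at X = 0.
#' @slot r_squared coefficient of determination of the fit (1 for an exact
#'   two-point or noiseless fit).
#' @slot x_range fitted X domain, `c(min, max)`; inversion outside it is
#'   extrapolation.
#' @seealso [standardCurve()], [fitStandardCurve()], [invertCt()]
#' @export
setClass("StandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        r_squared = "numeric", x_range = "numeric"))

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (!is.finite(object@slope) || object@slope == 0)
    msgs <- c(msgs, "slope must be finite and nonzero")
  if (!is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be finite")
  if (object@r_squared < 0 || object@r_squared > 1)
    msgs <- c(msgs, "r_squared must be in [0, 1]")
  if (length(object@x_range) != 2L || object@x_range[1] > object@x_range[2])
    msgs <- c(msgs, "x_range must be c(min, max)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a StandardCurve
#'
#' Defaults are the reference full-length ligation template curve this
#' package ships with: Ct = 4.059 X + 8.144.
#'
#' @param slope,intercept line parameters (cycles, cycles per unit X).
#' @param r_squared goodness of fit; 1 when stated exactly.
#' @param x_range fitted X domain.
#' @return a [StandardCurve].
#' @examples
#' standardCurve()
#' @export
standardCurve <- function(slope = 4.059, intercept = 8.144, r_squared = 1,
                          x_range = c(0, 5)) {
  new("StandardCurve", slope = slope, intercept = intercept,
      r_squared = r_squared, x_range = as.numeric(x_range))
}

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: Ct = %.4g * X + %.4g  (R^2 = %.4g, X in [%.3g, %.3g])\n",
              object@slope, object@intercept, object@r_squared,
              object@x_range[1], object@x_range[2]))
})

#' @describeIn standardCurve slope accessor.
#' @param curve a `StandardCurve`.
#' @export
curveSlope <- function(curve) curve@slope

#' @describeIn standardCurve intercept accessor.
#' @export
curveIntercept <- function(curve) curve@intercept

#' @describeIn standardCurve R-squared accessor.
#' @export
curveRsquared <- function(curve) curve@r_squared

#' Simulate Ct values for a qPCR well
#'
#' Ct = slope * x + intercept + Gaussian(0, noise_sd), censored to
#' undetermined (`NA`) when the value exceeds `max_cycles` or the template
#' concentration is zero (`x = Inf`). Undetermined wells are censored, never
#' imputed.
#'
#' @param x dilution exponent(s), X = -log10(dilution); `Inf` encodes zero
#'   template.
#' @param curve a [StandardCurve].
#' @param noise_sd replicate noise SD in cycles (default 0.2, typical
#'   replicate scatter).
#' @param max_cycles censoring limit (default 40).
#' @param seed integer seed.
#' @return numeric vector of Ct values, `NA` for undetermined wells.
#' @examples
#' simulateCt(1, standardCurve(), noise_sd = 0)   # 12.203
#' @export
simulateCt <- function(x, curve, noise_sd = 0.2, max_cycles = 40,
                       seed = NULL) {
  stopifnot(is(curve, "StandardCurve"))
  .assertNonneg(noise_sd, "noise_sd")
  .assertNonneg(max_cycles, "max_cycles")
  if (any(is.na(x))) stop("'x' must not contain NA", call. = FALSE)
  .withSeed(seed, {
    ct <- curve@slope * x + curve@intercept +
      if (noise_sd > 0) rnorm(length(x), 0, noise_sd) else 0
    ct[!is.finite(x) | ct > max_cycles] <- NA_real_
    ct
  })
}

#' Build a plate data.frame of qPCR wells
#'
#' Standard plate layout used throughout the package: one row per well with
#' columns `well`, `target`, `ct` (`NA` = undetermined) and `dilution_x`
#' (`NA` when the well is not part of a standard series).
#'
#' @param target target identifiers.
#' @param ct Ct values, `NA` for undetermined.
#' @param dilution_x X values for standard-series wells.
#' @param well well identifiers (defaults to `W1, W2, ...`).
#' @return a `data.frame`.
#' @export
qpcrPlate <- function(target, ct, dilution_x = NA_real_, well = NULL) {
  n <- max(length(target), length(ct), length(dilution_x))
  if (is.null(well)) well <- paste0("W", seq_len(n))
  out <- data.frame(well = rep_len(well, n),
                    target = rep_len(target, n),
                    ct = rep_len(as.numeric(ct), n),
                    dilution_x = rep_len(as.numeric(dilution_x), n),
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$ct) & out$ct <= 0
  if (any(bad)) stop("determined Ct values must be positive", call. = FALSE)
  out
}

#' Read / write plate CSVs
#'
#' Plate files have columns `well,target,ct,dilution_x`, with `NA` for
#' undetermined Ct values.
#'
#' @param path CSV file path.
#' @return `readPlate()`: a plate `data.frame`; `writePlate()`: `path`,
#'   invisibly.
#' @export
readPlate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "target", "ct", "dilution_x")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  qpcrPlate(df$target, df$ct, df$dilution_x, well = df$well)
}

#' @rdname readPlate
#' @param plate plate `data.frame` from [qpcrPlate()].
#' @export
writePlate <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Fit a standard curve to a dilution series
#'
#' Ordinary least squares of Ct on X over the determined wells; undetermined
#' wells are excluded (their count is reported in a message). The fit is
#' invariant to well order and to duplicating whole replicate sets.
#'
#' @param x dilution exponents of the series wells.
#' @param ct matching Ct values (`NA` = undetermined, excluded).
#' @return a [StandardCurve] with `x_range` set to the span of the points
#'   used.
#' @examples
#' x <- 0:4
#' fitStandardCurve(x, 4.059 * x + 8.144)  # recovers the reference curve
#' @export
fitStandardCurve <- function(x, ct) {
  stopifnot(length(x) == length(ct))
  keep <- !is.na(ct) & is.finite(x)
  n_censored <- sum(!keep)
  if (n_censored > 0)
    message(n_censored, " undetermined/unusable well(s) excluded from the fit")
  x <- x[keep]; ct <- ct[keep]
  if (length(unique(x)) < 2L)
    stop("need determined Ct values at >= 2 distinct dilution levels",
         call. = FALSE)
  fit <- lm(ct ~ x)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  standardCurve(slope = unname(coef(fit)[2L]),
                intercept = unname(coef(fit)[1L]),
                r_squared = min(max(r2, 0), 1), x_range = range(x))
}

#' Invert a Ct value through a standard curve
#'
#' @param ct determined Ct value(s).
#' @param curve a [StandardCurve].
#' @param warn_extrapolation warn when the inverted X falls outside the
#'   fitted range?
#' @return x = (ct - intercept) / slope.
#' @examples
#' invertCt(12.203, standardCurve())   # 1
#' @export
invertCt <- function(ct, curve, warn_extrapolation = TRUE) {
  stopifnot(is(curve, "StandardCurve"))
  if (any(is.na(ct)))
    stop("cannot invert an undetermined (NA) Ct value", call. = FALSE)
  x <- (ct - curve@intercept) / curve@slope
  if (warn_extrapolation &&
      any(x < curve@x_range[1] | x > curve@x_range[2]))
    warning("inverted X outside the fitted range [",
            curve@x_range[1], ", ", curve@x_range[2], "]; extrapolating",
            call. = FALSE)
  x
}

#' Limit of detection of a replicated dilution series
#'
#' The most dilute level at which every replicate is determined (no
#' censoring). This in/out-of-range rule mirrors how instrument operators
#' read a dilution series; no probit modelling is attempted.
#'
#' @param series named list mapping dilution level (name or numeric
#'   `concentration`) to a vector of replicate Ct values (`NA` =
#'   undetermined).
#' @param concentrations optional numeric concentrations for the levels, in
#'   decreasing-concentration order of `series`; defaults to
#'   `as.numeric(names(series))`. Used to decide which level is most dilute.
#' @return the concentration (or name) of the LOD level, or `NA` when no
#'   level has all replicates determined.
#' @examples
#' estimateLod(list(`10` = c(15, 15.1), `1` = c(19, NA)))  # 10
#' @export
estimateLod <- function(series, concentrations = NULL) {
  if (length(series) == 0L) stop("empty dilution series", call. = FALSE)
  if (is.null(concentrations)) concentrations <- as.numeric(names(series))
  if (anyNA(concentrations))
    stop("levels need numeric concentrations (names or 'concentrations')",
         call. = FALSE)
  all_det <- vapply(series, function(v) length(v) > 0 && !anyNA(v), logical(1))
  if (!any(all_det)) return(NA_real_)
  min(concentrations[all_det])
}

#' Amplification efficiency implied by a curve slope
#'
#' E = 10^(1/|slope|) - 1; a slope magnitude of log2(10) ~ 3.32 cycles per
#' 10-fold dilution corresponds to perfect doubling (E = 1). Steeper curves
#' (like the packaged reference at 4.059) imply sub-ideal efficiency.
#'
#' @param curve a [StandardCurve].
#' @return efficiency as a fraction.
#' @examples
#' amplificationEfficiency(standardCurve())   # ~ 0.764
#' @export
amplificationEfficiency <- function(curve) {
  stopifnot(is(curve, "StandardCurve"))
  10^(1 / abs(curve@slope)) - 1
}

#' Persist / load a standard curve as JSON
#'
#' @param curve a [StandardCurve].
#' @param path JSON file path.
#' @return `writeCurve()`: `path`, invisibly; `readCurve()`: a
#'   [StandardCurve].
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "StandardCurve"))
  jsonlite::write_json(list(slope = curve@slope, intercept = curve@intercept,
                            r_squared = curve@r_squared,
                            x_range = curve@x_range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  standardCurve(slope = j$slope, intercept = j$intercept,
                r_squared = j$r_squared, x_range = j$x_range)
}

#' Dilution exponent of a concentration under an anchor
#'
#' X = -log10(conc / conc_at_x0); zero concentration maps to `Inf` (never
#' amplifies).
#'
#' @param conc concentration(s), same units as `conc_at_x0`.
#' @param conc_at_x0 the concentration at X = 0 (the undiluted anchor).
#' @return dilution exponent(s).
#' @export
concToX <- function(conc, conc_at_x0) {
  .assertNonneg(conc_at_x0, "conc_at_x0")
  if (conc_at_x0 <= 0) stop("'conc_at_x0' must be > 0", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE))
    stop("concentrations must be >= 0", call. = FALSE)
  ifelse(conc == 0, Inf, -log10(conc / conc_at_x0))
}

#' @rdname concToX
#' @param x dilution exponent(s).
#' @export
xToConc <- function(x, conc_at_x0) {
  if (conc_at_x0 <= 0) stop("'conc_at_x0' must be > 0", call. = FALSE)
  conc_at_x0 * 10^(-x)
}
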