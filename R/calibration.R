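## Saturation-exponential calibration: I(C) = A (1 - exp(-B C)).
## A (ERF) is the saturation plateau and varies run to run; B (mL/ng) is the
## assay sensitivity and is stable across runs, so quantification freezes B
## from prior calibrations and re-identifies A within each run. The inverse
## for a neat-sample concentration with dilution D and recombinant/native
## mass ratio k is C_x = (k / (B D)) log(A / (A - I_x)).

#' Calibration point table
#'
#' @param concentration in-channel concentrations, ng/mL, >= 0.
#' @param fluorescence background-subtracted fluorescences, ERF.
#' @return data frame of class `calibration_points`.
#' @export
calibration_points <- function(concentration, fluorescence) {
  .check_finite(concentration, "concentration")
  .check_finite(fluorescence, "fluorescence")
  if (any(concentration < 0)) .stopf("concentrations must be >= 0")
  structure(data.frame(concentration = concentration,
                       fluorescence = fluorescence),
            class = c("calibration_points", "data.frame"))
}

#' Calibration fit container
#'
#' @param A,B model parameters (ERF, mL/ng), both > 0.
#' @param dA,dB standard uncertainties, >= 0.
#' @param rss residual sum of squares.
#' @param n number of points fitted.
#' @param method fit description.
#' @return object of class `calibration_fit`.
#' @export
calibration_fit <- function(A, B, dA = 0, dB = 0, rss = NA_real_,
                            n = NA_integer_, method = "manual") {
  if (!is.finite(A) || A <= 0) .stopf("A must be > 0")
  if (!is.finite(B) || B <= 0) .stopf("B must be > 0")
  if (dA < 0 || dB < 0) .stopf("uncertainties must be >= 0")
  structure(list(A = A, B = B, dA = dA, dB = dB, rss = rss, n = n,
                 method = method),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> A = %.1f +- %.1f ERF, B = %.4f +- %.4f mL/ng (%s, n = %s)\n",
              x$A, x$dA, x$B, x$dB, x$method, x$n))
  invisible(x)
}

#' Saturation-exponential calibration model
#'
#' `I(C) = A (1 - exp(-B C))`: zero at C = 0, monotone increasing,
#' asymptote A.
#'
#' @param A saturation plateau, ERF.
#' @param B sensitivity, mL/ng.
#' @param C concentration(s), ng/mL.
#' @return model fluorescence, ERF (vectorized in C).
#' @export
saturation_model <- function(A, B, C) A * (-expm1(-B * C))

#' Full two-parameter calibration fit
#'
#' Nonlinear least squares for (A, B), excluding zero-concentration points
#' (the model passes through the origin by construction, and the negative
#' control is reserved for the detection limit). Standard errors come from
#' the linearized covariance at the optimum.
#'
#' @param points a [calibration_points()] table.
#' @return a [calibration_fit()].
#' @export
fit_full <- function(points) {
  pts <- points[points$concentration > 0, , drop = FALSE]
  if (nrow(pts) < 2L || length(unique(pts$concentration)) < 2L)
    .stopf("need >= 2 points with distinct nonzero concentrations")
  A0 <- 1.1 * max(pts$fluorescence)
  o <- order(pts$concentration)
  C1 <- pts$concentration[o[1]]; I1 <- pts$fluorescence[o[1]]
  B0 <- -log(max(1 - I1 / A0, 0.05)) / C1
  fit <- tryCatch(
    stats::nls(fluorescence ~ A * (1 - exp(-B * concentration)),
               data = pts, start = list(A = A0, B = B0),
               algorithm = "port", lower = c(A = 1e-12, B = 1e-12),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) .stopf("calibration fit failed: %s", conditionMessage(e)))
  co <- summary(fit)$coefficients
  se <- co[, 2]
  se[!is.finite(se)] <- 0            # exact fit with zero residual df
  calibration_fit(A = co["A", 1], B = co["B", 1],
                  dA = se[["A"]], dB = se[["B"]],
                  rss = sum(stats::resid(fit)^2), n = nrow(pts),
                  method = "nls full (A, B)")
}

#' One-parameter fit of A with B frozen
#'
#' The within-run identification strategy: B is treated as known from prior
#' calibrations, and A is found by linear least squares on the regressor
#' `g(C) = 1 - exp(-B C)`, optionally appending the (0, 0) anchor as an
#' ordinary point. Closed form: `A = sum(I g) / sum(g^2)`.
#'
#' @param points a [calibration_points()] table (the high-concentration
#'   reference channels).
#' @param B_known frozen sensitivity, mL/ng.
#' @param include_origin append the (0, 0) point.
#' @param dB uncertainty carried on the frozen B (enters the error budget).
#' @return a [calibration_fit()].
#' @export
fit_A_fixed_B <- function(points, B_known, include_origin = TRUE, dB = 0) {
  if (B_known <= 0) .stopf("B_known must be > 0")
  pts <- points[points$concentration > 0, , drop = FALSE]
  if (nrow(pts) < 1L) .stopf("need >= 1 nonzero-concentration point")
  C <- pts$concentration; I <- pts$fluorescence
  if (include_origin) { C <- c(0, C); I <- c(0, I) }
  g <- 1 - exp(-B_known * C)
  A <- sum(I * g) / sum(g^2)
  res <- I - A * g
  n <- length(C)
  dA <- if (n > 1) sqrt(sum(res^2) / (n - 1) / sum(g^2)) else 0
  calibration_fit(A = A, B = B_known, dA = dA, dB = dB,
                  rss = sum(res^2), n = n, method = "fixed-B linear A")
}

#' Quantification input
#'
#' @param I_x sample's background-subtracted fluorescence, ERF.
#' @param dilution dilution factor D in (0, 1] (in-channel over neat).
#' @param mass_ratio ratio k between the molecular masses of the native
#'   protein and the recombinant standard.
#' @param dI_x uncertainty on I_x, ERF (default 0).
#' @return object of class `quant_input`.
#' @export
quant_input <- function(I_x, dilution = 0.1, mass_ratio = 1.6, dI_x = 0) {
  .check_finite(c(I_x, dilution, mass_ratio, dI_x), "quant input")
  if (!(dilution > 0 && dilution <= 1)) .stopf("dilution must be in (0, 1]")
  if (mass_ratio <= 0) .stopf("mass_ratio must be > 0")
  structure(list(I_x = I_x, dilution = dilution, mass_ratio = mass_ratio,
                 dI_x = dI_x),
            class = "quant_input")
}

#' Invert the calibration model to a neat-sample concentration
#'
#' `C_x = (k / (B D)) log(A / (A - I_x))`; the exact algebraic inverse of
#' the forward model evaluated at the in-channel concentration `C_x D / k`.
#'
#' @param fit a [calibration_fit()].
#' @param input a [quant_input()].
#' @param allow_negative tolerate slightly negative `I_x` (maps to `C_x` 0).
#' @return concentration C_x, ng/mL.
#' @export
invert_concentration <- function(fit, input, allow_negative = FALSE) {
  I <- input$I_x
  if (I < 0) {
    if (!allow_negative) .stopf("I_x < 0; enable allow_negative to map to 0")
    return(0)
  }
  if (I >= fit$A)
    .stopf("saturated: I_x (%.3g) >= A (%.3g); concentration unresolvable",
           I, fit$A)
  ## log(A / (A - I)) = -log1p(-I/A), accurate for I << A
  -input$mass_ratio / (fit$B * input$dilution) * log1p(-I / fit$A)
}

#' Quadrature error budget of the inverted concentration
#'
#' First-order propagation through the inversion:
#' `dCx^2 = (dCx/dA)^2 dA^2 + (dCx/dB)^2 dB^2 + (dCx/dIx)^2 dIx^2`
#' with analytic partials
#' `dCx/dA = -(k/(B D)) Ix / (A (A - Ix))`, `dCx/dB = -Cx / B`,
#' `dCx/dIx = (k/(B D)) / (A - Ix)`.
#'
#' @param fit a [calibration_fit()].
#' @param input a [quant_input()]; its `dI_x` enters the budget.
#' @return list with `dC_x` and the per-parameter `contributions` (ng/mL).
#' @export
propagate_error <- function(fit, input) {
  Cx <- invert_concentration(fit, input)
  A <- fit$A; B <- fit$B; I <- input$I_x
  kBD <- input$mass_ratio / (B * input$dilution)
  dA_term <- -kBD * I / (A * (A - I)) * fit$dA
  dB_term <- -Cx / B * fit$dB
  dI_term <- kBD / (A - I) * input$dI_x
  contrib <- c(A = abs(dA_term), B = abs(dB_term), I_x = abs(dI_term))
  list(dC_x = sqrt(sum(contrib^2)), contributions = contrib)
}

#' Limit of detection from the negative control
#'
#' The negative-control channel's (background-subtracted) fluorescence is
#' inverted like a sample; concentrations below the resulting `c_min` are
#' out of range.
#'
#' @param fit a [calibration_fit()].
#' @param negative_control_I negative-control fluorescence, ERF.
#' @param dilution,mass_ratio as in [quant_input()].
#' @return detection limit c_min, ng/mL.
#' @export
detection_limit <- function(fit, negative_control_I, dilution = 0.1,
                            mass_ratio = 1.6) {
  if (negative_control_I < 0) return(0)
  invert_concentration(fit, quant_input(negative_control_I, dilution,
                                        mass_ratio))
}

#' Quantify a sample against a calibration fit
#'
#' Runs inversion, the quadrature error budget and the detection-limit flag
#' in one step.
#'
#' @param fit a [calibration_fit()].
#' @param input a [quant_input()].
#' @param c_min detection limit, ng/mL (0 disables the flag).
#' @return object of class `quant_result` with `C_x`, `dC_x`,
#'   `contributions`, `in_range`, `c_min`.
#' @export
quantify_sample <- function(fit, input, c_min = 0) {
  Cx <- invert_concentration(fit, input, allow_negative = TRUE)
  pe <- if (input$I_x >= 0) propagate_error(fit, input)
        else list(dC_x = NA_real_, contributions = c(A = NA, B = NA, I_x = NA))
  structure(list(C_x = Cx, dC_x = pe$dC_x, contributions = pe$contributions,
                 in_range = Cx >= c_min, c_min = c_min),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> C_x = %.1f +- %.1f ng/mL (c_min = %.2f, %s)\n",
              x$C_x, x$dC_x, x$c_min,
              if (x$in_range) "in range" else "OUT OF RANGE"))
  invisible(x)
}

#' Read / write calibration tables as CSV
#'
#' Columns `concentration_ng_per_mL, fluorescence_ERF`.
#'
#' @param path file path.
#' @return for the reader, a [calibration_points()] table.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("concentration_ng_per_mL", "fluorescence_ERF")
  if (!all(need %in% names(df)))
    .stopf("calibration CSV must have columns %s", paste(need, collapse = ", "))
  calibration_points(df$concentration_ng_per_mL, df$fluorescence_ERF)
}

#' @rdname read_calibration_csv
#' @param points a [calibration_points()] table.
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(data.frame(concentration_ng_per_mL = points$concentration,
                              fluorescence_ERF = points$fluorescence),
                   path, row.names = FALSE)
  invisible(path)
}
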