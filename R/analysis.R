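#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param VED End-diastolic volume (cm^3).
#' @param VES End-systolic volume (cm^3), with `VED > VES >= 0`.
#' @return Ejection fraction in percent, `100 * (VED - VES) / VED`.
#' @examples
#' ejection_fraction(320, 275) # 14.06 %
#' @export
ejection_fraction <- function(VED, VES) {
  if (any(VES < 0) || any(VED <= VES)) {
    stop("need VED > VES >= 0", call. = FALSE)
  }
  100 * (VED - VES) / VED
}

#' Fit an exponential diastolic stiffness curve
#'
#' Fits the end-diastolic pressure-volume relation `P = a * exp(b * V)` by
#' log-linear least squares. Points whose standardised log-residual exceeds
#' `exclude_threshold` are flagged as outliers (e.g. patients whose
#' ventricle has not yet reverse-remodelled) and the curve is refit once
#' without them.
#'
#' @param V Volumes (cm^3).
#' @param P Pressures (mmHg), all > 0.
#' @param exclude_threshold Standardised-residual multiplier above which a
#'   point is excluded (default 2.5); `Inf` disables exclusion.
#' @return List with `a`, `b`, `excluded` (integer indices into the input,
#'   possibly empty) and `fitted` (fitted pressures at the input volumes).
#' @export
fit_diastolic_stiffness <- function(V, P, exclude_threshold = 2.5) {
  if (length(V) != length(P)) stop("V and P must have equal length", call. = FALSE)
  if (length(V) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(P <= 0)) stop("all pressures must be positive", call. = FALSE)
  loglin <- function(idx) {
    fit <- stats::lm.fit(cbind(1, V[idx]), log(P[idx]))
    list(a = exp(fit$coefficients[[1]]), b = fit$coefficients[[2]],
         resid = fit$residuals)
  }
  idx <- seq_along(V)
  f <- loglin(idx)
  # robust standardisation: with a minority of grossly stiffer/softer
  # patients, the ordinary residual SD (and the fit itself) is dragged by
  # the outliers, so centre on the median and scale by the MAD
  ctr <- f$resid - stats::median(f$resid)
  s <- max(stats::mad(f$resid), 1e-10)
  excluded <- integer(0)
  if (is.finite(exclude_threshold)) {
    out <- abs(ctr) / s > exclude_threshold
    if (any(out) && sum(!out) >= 3) {
      excluded <- idx[out]
      f <- loglin(idx[!out])
    }
  }
  list(a = f$a, b = f$b, excluded = excluded,
       fitted = f$a * exp(f$b * V))
}

#' Linearised diastolic stiffness slope at a working volume
#'
#' Derivative of `P = a * exp(b * V)` at `V_work`:
#' `dP/dV = a * b * exp(b * V_work)`, the slope of the tangent drawn at the
#' ventricular working point.
#'
#' @param a,b Exponential stiffness coefficients.
#' @param V_work Working-point volume (cm^3).
#' @return Slope (mmHg/cm^3).
#' @export
linearize_stiffness <- function(a, b, V_work) {
  a * b * exp(b * V_work)
}

#' Extract per-cycle pressure-volume loops of a ventricle
#'
#' Cycle boundaries are taken from the simulator's cycle counter (driven by
#' the ventricular activation clock, which stays well defined even when the
#' ventricle never ejects under full pump support).
#'
#' @param result A `cvr_result` from [cvr_simulate()].
#' @param chamber `"lv"` or `"rv"`.
#' @param n Number of loops to extract (last `n` complete cycles).
#' @return List of `cvr_pvloop` objects: each a list with `V`, `P` (closed
#'   sample paths), `SV`, `VED`, `VES`, `EF` (percent) and `P_peak`.
#' @export
extract_pv_loops <- function(result, chamber = c("lv", "rv"), n = 1) {
  chamber <- match.arg(chamber)
  ts <- as.data.frame(result$timeseries)
  vcol <- if (chamber == "lv") "Vlv" else "Vrv"
  pcol <- if (chamber == "lv") "Plv" else "Prv"
  cyc <- ts$cycle
  complete <- cyc > min(cyc) & cyc < max(cyc) # only whole cycles
  ids <- unique(cyc[complete])
  if (length(ids) < n) stop("result spans fewer complete cycles than requested",
                            call. = FALSE)
  ids <- utils::tail(ids, n)
  lapply(ids, function(id) {
    sel <- cyc == id
    V <- c(ts[[vcol]][sel], ts[[vcol]][sel][1]) # close the curve
    P <- c(ts[[pcol]][sel], ts[[pcol]][sel][1])
    VED <- max(V)
    VES <- min(V)
    structure(list(V = V, P = P, SV = VED - VES, VED = VED, VES = VES,
                   EF = 100 * (VED - VES) / VED, P_peak = max(P)),
              class = "cvr_pvloop")
  })
}
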