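#' Blank-correct raw gas readings
#'
#' Subtracts, at every recording time, the mean reading of the same run's
#' blank bottles from each bottle's raw reading, and stores the result in a
#' `"corrected"` assay.  Negative corrected values are retained (truncating
#' them would bias the fitted asymptote downward) but raise a warning unless
#' `quiet = TRUE`.
#'
#' @param x a [FermStudy-class] with a `"gas"` assay.
#' @param quiet suppress the negative-value warning.
#' @return the study with a `"corrected"` assay added.
#' @rdname blankCorrect
#' @export
setMethod("blankCorrect", "FermStudy", function(x, quiet = FALSE) {
  g <- assay(x, "gas")
  run <- colData(x)$run
  blank <- isBlank(x)
  corrected <- g
  for (r in unique(run)) {
    inrun <- run == r
    if (!any(blank & inrun))
      stop("no blank available for run ", r, call. = FALSE)
    bmean <- rowMeans(g[, blank & inrun, drop = FALSE])
    corrected[, inrun] <- g[, inrun, drop = FALSE] - bmean
  }
  nneg <- sum(corrected[, !blank, drop = FALSE] < 0)
  if (nneg > 0 && !quiet)
    warning(nneg, " negative blank-corrected reading(s) retained",
            call. = FALSE)
  assay(x, "corrected") <- corrected
  x
})

#' Normalize corrected gas to incubated organic matter (OMCV)
#'
#' Divides each substrate bottle's blank-corrected readings by its incubated
#' OM (g), giving cumulative gas in mL per g incubated OM.  Blank bottles
#' get `NA`.
#'
#' @param x a [FermStudy-class]; [blankCorrect()] is applied first if the
#'   `"corrected"` assay is absent.
#' @return the study with an `"omcv"` assay added.
#' @rdname toOMCV
#' @export
setMethod("toOMCV", "FermStudy", function(x) {
  if (!"corrected" %in% assayNames(x)) x <- blankCorrect(x, quiet = TRUE)
  om <- colData(x)$incubated_om_g
  blank <- isBlank(x)
  if (any(om[!blank] <= 0))
    stop("incubated OM must be > 0 for substrate bottles", call. = FALSE)
  omcv <- sweep(assay(x, "corrected"), 2, ifelse(blank, NA_real_, om), "/")
  assay(x, "omcv") <- omcv
  x
})

#' Evaluate the sigmoidal gas-production model
#'
#' Computes \eqn{G(t) = A / (1 + (B/t)^C)} (mL per g incubated OM) for
#' `t > 0`, and its limit 0 at `t = 0`.  `G` is strictly increasing in t,
#' equals `A/2` at `t = B`, and tends to `A` as t grows.
#'
#' @param params a [GrootParams-class] object.
#' @param t time(s) in hours, `>= 0`; vectorized.
#' @return gas production in mL per g incubated OM.
#' @examples
#' predictGas(GrootParams(A = 250, B = 10, C = 2), c(0, 10, 30))
#' @rdname predictGas
#' @export
setMethod("predictGas", "GrootParams", function(params, t) {
  validObject(params)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  .groot(params@A, params@B, params@C, t)
})

#' Time of the maximum fermentation rate
#'
#' Closed form \eqn{T_{max} = B ((C-1)/(C+1))^{1/C}}, the argmax over t of
#' the model's time-derivative.  Only defined for `C > 1`: for `C <= 1` the
#' rate is maximal as t tends to 0 and no interior maximum exists.
#'
#' @param params a [GrootParams-class] object with `C > 1`.
#' @return Tmax in hours.
#' @rdname computeTmax
#' @export
setMethod("computeTmax", "GrootParams", function(params) {
  validObject(params)
  if (params@C <= 1)
    stop("Tmax is undefined for C <= 1 (rate is maximal as t -> 0)",
         call. = FALSE)
  params@B * ((params@C - 1) / (params@C + 1))^(1 / params@C)
})

#' Maximum fermentation rate
#'
#' Closed form
#' \eqn{R_{max} = A C B^C T_{max}^{-C-1} / (1 + B^C T_{max}^{-C})^2},
#' the model's time-derivative evaluated at [computeTmax()].  Only defined
#' for `C > 1`.
#'
#' @param params a [GrootParams-class] object with `C > 1`.
#' @return Rmax in mL/h (per g incubated OM).
#' @rdname computeRmax
#' @export
setMethod("computeRmax", "GrootParams", function(params) {
  tm <- computeTmax(params)
  A <- params@A; B <- params@B; C <- params@C
  A * C * B^C * tm^(-C - 1) / (1 + B^C * tm^(-C))^2
})

#' Fit the sigmoidal model to one gas curve
#'
#' Unweighted least squares on cumulative volumes via bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM]).  Starting values and bounds
#' are deterministic functions of the data: `A0 = 1.1 * max(g)`, `B0` the
#' earliest time at which `g >= A0/2` (else the median time), `C0 = 1.5`;
#' bounds `A in (0, 3 max g]`, `B in (0, 2 max t]`, `C in [0.05, 10]`.
#' Non-convergence is reported through the `converged` flag, never as a
#' silent success.
#'
#' @param curve a [GasCurve-class], or a numeric time vector if `gas` is
#'   given.
#' @param gas optional numeric vector of OMCV readings (mL/g) matching
#'   `curve` when the latter is a time vector.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return a [KineticFit-class]; `tmax`/`rmax` are `NA` when the fitted
#'   `C <= 1`.
#' @examples
#' p <- GrootParams(250, 10, 2)
#' tt <- c(2, 4, 8, 12, 24, 48, 96)
#' fitGroot(GasCurve(tt, predictGas(p, tt)))
#' @export
fitGroot <- function(curve, gas = NULL, maxiter = 200) {
  if (!is(curve, "GasCurve")) {
    if (is.null(gas)) stop("supply a GasCurve or time and gas vectors",
                           call. = FALSE)
    curve <- GasCurve(curve, gas)
  }
  validObject(curve)
  tt <- curve@time; g <- curve@gas
  gmax <- max(g)
  if (gmax <= 0)
    stop("gas curve has no positive readings; nothing to fit", call. = FALSE)
  A0 <- 1.1 * gmax
  above <- which(g >= A0 / 2)
  B0 <- if (length(above)) tt[above[1]] else stats::median(tt)
  start <- c(A = A0, B = B0, C = 1.5)
  lower <- c(A = 1e-8, B = 1e-8, C = 0.05)
  upper <- c(A = 3 * gmax, B = 2 * max(tt), C = 10)
  fit <- try(minpack.lm::nlsLM(
    g ~ A / (1 + (B / tt)^C),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    params <- GrootParams(A0, max(B0, 1e-6), 1.5)
    return(new("KineticFit", params = params, rss = sum((g - 0)^2),
               n_points = length(tt), converged = FALSE,
               tmax = NA_real_, rmax = NA_real_))
  }
  cf <- stats::coef(fit)
  params <- GrootParams(unname(cf["A"]), unname(cf["B"]), unname(cf["C"]))
  conv <- isTRUE(fit$convInfo$isConv)
  tmax <- rmax <- NA_real_
  if (params@C > 1) {
    tmax <- computeTmax(params)
    rmax <- computeRmax(params)
  }
  new("KineticFit", params = params,
      rss = sum(stats::resid(fit)^2), n_points = length(tt),
      converged = conv, tmax = tmax, rmax = rmax)
}

#' Fit the sigmoidal model to every substrate bottle of a study
#'
#' Runs [fitGroot()] on each substrate bottle's OMCV curve (blank correction
#' and OM normalization are applied first if needed) and returns a
#' bottle-level table.  Fitting is per bottle; group summaries average the
#' per-bottle parameters.
#'
#' @param x a [FermStudy-class] object.
#' @param ... passed to [fitGroot()].
#' @return a `data.frame` with one row per substrate bottle: `bottle_id`,
#'   `substrate`, `run`, `replicate`, `A`, `B`, `C`, `tmax_h`, `rmax_ml_h`,
#'   `rss`, `n_points`, `converged`.
#' @rdname fitKinetics
#' @export
setMethod("fitKinetics", "FermStudy", function(x, ...) {
  if (!"omcv" %in% assayNames(x)) x <- toOMCV(x)
  tt <- gasTimes(x)
  keep <- which(!isBlank(x))
  cd <- colData(x)
  rows <- lapply(keep, function(j) {
    fit <- fitGroot(GasCurve(tt, assay(x, "omcv")[, j],
                             om_g = cd$incubated_om_g[j]), ...)
    if (!fit@converged)
      warning("fit did not converge for bottle ", cd$bottle_id[j],
              call. = FALSE)
    data.frame(bottle_id = cd$bottle_id[j], substrate = cd$substrate[j],
               run = cd$run[j], replicate = cd$replicate[j],
               A = fit@params@A, B = fit@params@B, C = fit@params@C,
               tmax_h = fit@tmax, rmax_ml_h = fit@rmax,
               rss = fit@rss, n_points = fit@n_points,
               converged = fit@converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
})
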