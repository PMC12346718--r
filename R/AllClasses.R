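#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' FermStudy: a bottle-level in vitro gas-production study
#'
#' `FermStudy` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' complete in vitro fermentation study.  Rows are recording times, columns
#' are serum bottles.  The `"gas"` assay holds raw cumulative gas readings
#' (mL); [blankCorrect()] and [toOMCV()] add `"corrected"` (mL) and `"omcv"`
#' (mL per g incubated organic matter) assays.  `colData` carries the bottle
#' metadata: substrate label (`"BLANK"` for blank bottles), factor levels
#' (cut, plant part), gas run, replicate index, incubated DM and OM (g),
#' residue OM (g), the six volatile fatty acid end-point concentrations
#' (mM per g incubated substrate) and end pH.
#'
#' @section Validity:
#' Recording times (`rowData(x)$time_h`) must be strictly increasing and
#' positive; substrate bottles must have incubated OM > 0 and
#' 0 <= residue OM <= incubated OM; blank bottles have incubated OM = 0.
#'
#' @aliases FermStudy
#' @exportClass FermStudy
setClass("FermStudy", contains = "SummarizedExperiment")

.vfa_cols <- c("vfa_acetate", "vfa_propionate", "vfa_isobutyrate",
               "vfa_butyrate", "vfa_isovalerate", "vfa_valerate")

.validFermStudy <- function(object) {
  msg <- character()
  tt <- rowData(object)$time_h
  if (is.null(tt))
    return("rowData must contain a 'time_h' column")
  if (any(tt <= 0) || any(diff(tt) <= 0))
    msg <- c(msg, "recording times must be positive and strictly increasing")
  cd <- colData(object)
  need <- c("bottle_id", "substrate", "run", "replicate",
            "incubated_dm_g", "incubated_om_g", "residue_om_g", .vfa_cols)
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData is missing columns:", paste(miss, collapse = ", ")))
  blank <- cd$substrate == "BLANK"
  if (any(!blank & cd$incubated_om_g <= 0))
    msg <- c(msg, "substrate bottles must have incubated OM > 0")
  if (any(blank & cd$incubated_om_g != 0))
    msg <- c(msg, "blank bottles must have incubated OM = 0")
  bad <- !blank & (cd$residue_om_g < 0 | cd$residue_om_g > cd$incubated_om_g)
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "residue OM must lie in [0, incubated OM]")
  if (any(assay(object, "gas") < 0, na.rm = TRUE))
    msg <- c(msg, "raw gas readings must be non-negative")
  if (length(msg)) msg else TRUE
}

setValidity("FermStudy", .validFermStudy)

#' Construct a FermStudy from a gas matrix and bottle metadata
#'
#' @param gas numeric matrix of raw cumulative gas readings (mL), one row per
#'   recording time and one column per bottle.
#' @param time_h numeric vector of recording times (h), one per row of `gas`.
#' @param bottles a `data.frame`/`DataFrame` of bottle metadata with one row
#'   per column of `gas` (see [FermStudy-class] for required columns).
#' @param metadata optional list stored in the object's metadata slot.
#' @return a [FermStudy-class] object.
#' @export
FermStudy <- function(gas, time_h, bottles, metadata = list()) {
  gas <- as.matrix(gas)
  stopifnot(nrow(gas) == length(time_h), ncol(gas) == nrow(bottles))
  colnames(gas) <- bottles$bottle_id
  se <- SummarizedExperiment(
    assays = list(gas = gas),
    rowData = DataFrame(time_h = as.numeric(time_h)),
    colData = DataFrame(bottles, row.names = bottles$bottle_id),
    metadata = metadata)
  new("FermStudy", se)
}

#' Sigmoidal gas-curve parameters
#'
#' The three parameters of the Groot-type cumulative gas model
#' \eqn{G(t) = A / (1 + (B/t)^C)}: `A`, asymptotic gas production (mL per g
#' incubated OM); `B`, the time at which half of `A` is reached (h); `C`,
#' the dimensionless curve-switch (shape) parameter.  All three must be
#' strictly positive.
#'
#' @aliases GrootParams
#' @exportClass GrootParams
setClass("GrootParams",
         representation(A = "numeric", B = "numeric", C = "numeric"),
         prototype(A = 1, B = 1, C = 1.5))

setValidity("GrootParams", function(object) {
  ok <- length(object@A) == 1 && length(object@B) == 1 && length(object@C) == 1
  if (!ok) return("A, B and C must each have length 1")
  if (!all(is.finite(c(object@A, object@B, object@C))))
    return("A, B and C must be finite")
  if (object@A <= 0 || object@B <= 0 || object@C <= 0)
    return("A, B and C must all be > 0")
  TRUE
})

#' @param A,B,C numeric scalars, see [GrootParams-class].
#' @rdname GrootParams-class
#' @export
GrootParams <- function(A, B, C) {
  # slot-wise assignment: an argument named `C` passed through new(...)
  # would partially match new()'s `Class` parameter
  obj <- new("GrootParams")
  obj@A <- as.numeric(A); obj@B <- as.numeric(B); obj@C <- as.numeric(C)
  validObject(obj)
  obj
}

setMethod("show", "GrootParams", function(object) {
  cat(sprintf("GrootParams: A = %.4g mL/g, B = %.4g h, C = %.4g\n",
              object@A, object@B, object@C))
})

#' A single blank-corrected, OM-normalized gas curve
#'
#' Ordered (time, gas) pairs for one bottle, with gas expressed in mL per g
#' incubated organic matter.  At least 4 distinct time points are required
#' (a 3-parameter fit needs them); times must be strictly increasing and
#' positive.  Raw noise may make the curve locally non-monotone; decreases
#' larger than `mono_tol` set the `non_monotone` flag.
#'
#' @aliases GasCurve
#' @exportClass GasCurve
setClass("GasCurve",
         representation(time = "numeric", gas = "numeric", om_g = "numeric",
                        non_monotone = "logical"))

setValidity("GasCurve", function(object) {
  if (length(object@time) != length(object@gas))
    return("time and gas must have equal length")
  if (length(object@time) < 4)
    return("at least 4 time points are required for a 3-parameter fit")
  if (any(object@time <= 0) || any(diff(object@time) <= 0))
    return("times must be positive and strictly increasing")
  if (!all(is.finite(object@gas)))
    return("gas values must be finite")
  TRUE
})

#' @param time,gas numeric vectors of equal length (h; mL per g OM).
#' @param om_g incubated organic matter (g) the curve was normalized by.
#' @param mono_tol decreases in cumulative gas larger than this (mL/g) set
#'   the `non_monotone` flag.
#' @rdname GasCurve-class
#' @export
GasCurve <- function(time, gas, om_g = NA_real_, mono_tol = 1e-8) {
  ord <- order(time)
  time <- as.numeric(time)[ord]
  gas <- as.numeric(gas)[ord]
  flag <- any(diff(gas) < -mono_tol)
  new("GasCurve", time = time, gas = gas, om_g = om_g, non_monotone = flag)
}

setMethod("show", "GasCurve", function(object) {
  cat(sprintf("GasCurve: %d points, t in [%g, %g] h, max gas %.4g mL/g%s\n",
              length(object@time), min(object@time), max(object@time),
              max(object@gas),
              if (object@non_monotone) " [non-monotone]" else ""))
})

#' Result of fitting the sigmoidal model to one gas curve
#'
#' Holds the fitted [GrootParams-class], the residual sum of squares, the
#' number of points, a convergence flag, and the derived maximum fermentation
#' rate `rmax` (mL/h) with its time `tmax` (h).  `tmax`/`rmax` are defined
#' (non-`NA`) iff the fitted `C > 1`; for `C <= 1` the rate is maximal as
#' t tends to 0 and no interior maximum exists.
#'
#' @aliases KineticFit
#' @exportClass KineticFit
setClass("KineticFit",
         representation(params = "GrootParams", rss = "numeric",
                        n_points = "integer", converged = "logical",
                        tmax = "numeric", rmax = "numeric"))

setValidity("KineticFit", function(object) {
  if (object@rss < 0) return("rss must be >= 0")
  defined <- is.finite(object@tmax)
  if (defined != is.finite(object@rmax))
    return("tmax and rmax must be defined together")
  if (defined && object@params@C <= 1)
    return("tmax/rmax are only defined for C > 1")
  TRUE
})

setMethod("show", "KineticFit", function(object) {
  p <- object@params
  cat(sprintf(paste0("KineticFit (%s): A = %.4g mL/g, B = %.4g h, C = %.4g; ",
                     "Tmax = %.4g h, Rmax = %.4g mL/h; RSS = %.4g on %d points\n"),
              if (object@converged) "converged" else "NOT converged",
              p@A, p@B, p@C, object@tmax, object@rmax,
              object@rss, object@n_points))
})

#' Synthetic-study configuration
#'
#' Everything needed to simulate a complete in vitro study with known ground
#' truth: the substrate table (true kinetic parameters, VFA end-point means,
#' true OM degradability, OM fraction of DM, pH), the design (runs,
#' replicates, blanks, recording grid) and the noise model.
#'
#' @section Substrate table columns:
#' `label`, `cut`, `part` (factor levels; `NA` where a factor is absent),
#' `A` (mL/g), `B` (h), `C` (dimensionless), `dom` (true OM degradability,
#' fraction in (0,1)), `om_frac` (OM fraction of incubated DM),
#' `ac`, `pr`, `ib`, `bu`, `iv`, `va` (true VFA end-point means, mM per g
#' incubated substrate), `ph`.
#'
#' @section Noise model:
#' Gas readings get additive Gaussian noise (`gas_sd_ml`), truncated at 0.
#' Blank gas is a per-run constant drawn from
#' Normal(`blank_mean_ml`, `blank_sd_ml`) plus per-reading noise.  VFA
#' end-points are drawn log-normally about their true means with
#' coefficient of variation `vfa_cv`.  Per-bottle OM degradability is
#' Normal(`dom`, `dom_sd`) truncated to (0, 1).  Incubated DM is
#' Normal(`dm_g`, `dm_sd_g`) truncated at a small positive value.
#'
#' @aliases StudyConfig
#' @exportClass StudyConfig
setClass("StudyConfig",
         representation(substrates = "data.frame",
                        runs = "integer", replicates = "integer",
                        blanks_per_run = "integer",
                        horizon_h = "numeric", times_h = "numeric",
                        gas_sd_ml = "numeric",
                        blank_mean_ml = "numeric", blank_sd_ml = "numeric",
                        vfa_cv = "numeric", dom_sd = "numeric",
                        dm_g = "numeric", dm_sd_g = "numeric",
                        seed = "integer"))

.substrate_cols <- c("label", "cut", "part", "A", "B", "C", "dom", "om_frac",
                     "ac", "pr", "ib", "bu", "iv", "va", "ph")

setValidity("StudyConfig", function(object) {
  s <- object@substrates
  miss <- setdiff(.substrate_cols, colnames(s))
  if (length(miss))
    return(paste("substrate table is missing columns:",
                 paste(miss, collapse = ", ")))
  if (nrow(s) < 1) return("at least one substrate is required")
  if (any(s$A <= 0) || any(s$B <= 0) || any(s$C <= 0))
    return("all true kinetic parameters A, B, C must be > 0")
  if (any(s[, c("ac", "pr", "ib", "bu", "iv", "va")] < 0))
    return("all true VFA means must be >= 0")
  if (any(s$dom <= 0 | s$dom >= 1))
    return("true dOM fractions must lie in (0, 1)")
  if (any(s$om_frac <= 0 | s$om_frac > 1))
    return("om_frac must lie in (0, 1]")
  tt <- object@times_h
  if (length(tt) < 4 || any(diff(tt) <= 0) || tt[1] <= 0 ||
      tt[length(tt)] > object@horizon_h)
    return(paste("sampling times must be strictly increasing, start > 0,",
                 "end <= horizon, with at least 4 points"))
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (object@runs < 1L) return("runs must be >= 1")
  if (object@blanks_per_run < 1L) return("at least 1 blank per run is required")
  if (object@gas_sd_ml < 0 || object@blank_sd_ml < 0 || object@vfa_cv < 0 ||
      object@dom_sd < 0 || object@dm_sd_g < 0)
    return("noise standard deviations / CV must be >= 0")
  if (object@blank_mean_ml < 0) return("blank gas mean must be >= 0")
  TRUE
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(paste0("StudyConfig: %d substrate(s) x %d replicate(s) x %d ",
                     "run(s) (+%d blank(s)/run), %g h horizon, %d times, ",
                     "seed %d\n"),
              nrow(object@substrates), object@replicates, object@runs,
              object@blanks_per_run, object@horizon_h,
              length(object@times_h), object@seed))
})
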