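#' Non-structural carbohydrates by difference
#'
#' `NSC = 100 - (NDF + CP + EE + Ash)`, all in % DM.  Accepts either four
#' numeric vectors or a composition `data.frame` with columns `ndf`, `cp`,
#' `ee`, `ash`.  Analytes must lie in \[0, 100\]; a negative NSC (analytes
#' summing past 100) is returned with a warning.
#'
#' @param ndf neutral-detergent fiber (% DM), or a composition data.frame.
#' @param cp,ee,ash crude protein, ether extract, ash (% DM).
#' @return NSC in % DM.
#' @examples
#' nsc(ndf = 39.5, cp = 15.1, ee = 2.32, ash = 14.4)  # 28.68
#' @export
nsc <- function(ndf, cp = NULL, ee = NULL, ash = NULL) {
  if (is.data.frame(ndf)) {
    comp <- ndf
    stopifnot(all(c("ndf", "cp", "ee", "ash") %in% names(comp)))
    ndf <- comp$ndf; cp <- comp$cp; ee <- comp$ee; ash <- comp$ash
  }
  v <- cbind(ndf, cp, ee, ash)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100))
    stop("analytes must be finite and within [0, 100] % DM", call. = FALSE)
  out <- 100 - (ndf + cp + ee + ash)
  if (any(out < 0))
    warning("analytes sum past 100% DM; negative NSC returned",
            call. = FALSE)
  out
}

#' Metabolizable energy from 24 h gas production and crude protein
#'
#' The Menke-Steingass regression
#' \deqn{ME = 2.2 + 0.1357\,GP + 0.0057\,CP + 0.0002859\,CP^2}
#' with `GP` the blank-corrected gas at 24 h scaled to 200 mg incubated DM.
#' The unit in which CP is substituted is declared explicitly by the caller
#' and used as given, with no silent conversion: published applications of
#' the equation are ambiguous between % DM and g/kg DM, and the two differ
#' tenfold.  The reporting pipeline uses % DM, the only choice numerically
#' consistent with metabolizable energies of 6-10 MJ/kg DM at forage-typical
#' gas productions.
#'
#' @param gp24 gas production at 24 h (mL per 200 mg incubated DM), >= 0.
#' @param cp crude protein concentration, >= 0.
#' @param cp_units `"percentDM"` or `"gPerKgDM"`; mandatory, no default.
#' @return ME in MJ/kg DM.
#' @export
metabolizableEnergy <- function(gp24, cp, cp_units = c("percentDM",
                                                       "gPerKgDM")) {
  if (missing(cp_units))
    stop("declare cp_units explicitly (\"percentDM\" or \"gPerKgDM\")",
         call. = FALSE)
  cp_units <- match.arg(cp_units)
  if (any(!is.finite(gp24)) || any(gp24 < 0) ||
      any(!is.finite(cp)) || any(cp < 0))
    stop("gp24 and cp must be finite and >= 0", call. = FALSE)
  me <- 2.2 + 0.1357 * gp24 + 0.0057 * cp + 0.0002859 * cp^2
  attr(me, "cp_units") <- cp_units
  me
}

#' In vitro organic-matter degradability
#'
#' `dOM = 100 * (incubated OM - residue OM) / incubated OM`, the fraction of
#' incubated organic matter lost over the incubation, as a percentage.
#'
#' @param incubated_om_g incubated organic matter (g), > 0.
#' @param residue_om_g residue organic matter (g), in \[0, incubated\].
#' @return dOM in percent.
#' @examples
#' domPercent(1.0, 0.443)  # 55.7
#' @export
domPercent <- function(incubated_om_g, residue_om_g) {
  if (any(!is.finite(incubated_om_g)) || any(incubated_om_g <= 0))
    stop("incubated OM must be > 0", call. = FALSE)
  if (any(!is.finite(residue_om_g)) || any(residue_om_g < 0) ||
      any(residue_om_g > incubated_om_g))
    stop("residue OM must lie in [0, incubated OM]", call. = FALSE)
  100 * (incubated_om_g - residue_om_g) / incubated_om_g
}

#' Round to significant figures, half away from zero
#'
#' Table-style rounding used by the report builders: 3 significant figures
#' by default, ties rounded away from zero (unlike [signif()], which rounds
#' half to even).
#'
#' @param x numeric.
#' @param digits significant figures.
#' @return rounded numeric.
#' @export
signifHalfUp <- function(x, digits = 3) {
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    mag <- floor(log10(abs(x[nz])))
    fac <- 10^(digits - 1 - mag)
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * fac + 0.5) / fac
  }
  out
}

#' Per-bottle nutritive-value table for a study
#'
#' Combines the study's degradability records with a substrate composition
#' table: per bottle, dOM (%) from incubated and residue OM; per substrate,
#' NSC (% DM) and Menke-Steingass ME from blank-corrected 24 h gas scaled to
#' 200 mg incubated DM and CP in the declared units.  Condensed tannins and
#' total polyphenols are carried through as annotations.
#'
#' @param study a [FermStudy-class] object.
#' @param composition a `data.frame` like [defaultComposition()] returns.
#' @param cp_units passed to [metabolizableEnergy()].
#' @return a `data.frame` with one row per substrate bottle.
#' @export
nutritiveTable <- function(study, composition, cp_units = "percentDM") {
  if (!"corrected" %in% assayNames(study))
    study <- blankCorrect(study, quiet = TRUE)
  keep <- !isBlank(study)
  cd <- colData(study)[keep, ]
  comp <- composition[match(cd$substrate, composition$substrate), ]
  tt <- gasTimes(study)
  i24 <- which(tt == 24)
  if (!length(i24)) i24 <- which.min(abs(tt - 24))
  gas24 <- assay(study, "corrected")[i24[1], keep]
  gp24 <- gas24 * 0.2 / cd$incubated_dm_g
  data.frame(bottle_id = cd$bottle_id, substrate = cd$substrate,
             run = cd$run, replicate = cd$replicate,
             dom_pct = domPercent(cd$incubated_om_g, cd$residue_om_g),
             gp24_ml_200mg = gp24,
             me_mj_kg = as.numeric(
               metabolizableEnergy(pmax(gp24, 0), comp$cp, cp_units)),
             nsc_pct = nsc(comp$ndf, comp$cp, comp$ee, comp$ash),
             ct_g_kg = comp$ct_g_kg, tp_gae_g_kg = comp$tp_gae_g_kg,
             stringsAsFactors = FALSE)
}
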