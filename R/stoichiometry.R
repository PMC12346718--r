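#' Assemble and validate a VFA end-point profile
#'
#' Six-acid end-point concentrations in mM per g incubated substrate
#' (treated as mmol/g by the stoichiometric formulas).  All arguments are
#' vectorized; a `data.frame` with one row per profile is returned.
#'
#' @param acetate,propionate,isobutyrate,butyrate,isovalerate,valerate
#'   non-negative concentrations (mM/g).
#' @return a `data.frame` of class-checked profiles.
#' @export
vfaProfile <- function(acetate, propionate, isobutyrate, butyrate,
                       isovalerate, valerate) {
  p <- data.frame(acetate = acetate, propionate = propionate,
                  isobutyrate = isobutyrate, butyrate = butyrate,
                  isovalerate = isovalerate, valerate = valerate)
  .checkProfile(p)
  p
}

.acids <- c("acetate", "propionate", "isobutyrate", "butyrate",
            "isovalerate", "valerate")

.checkProfile <- function(profile) {
  profile <- as.data.frame(profile)
  miss <- setdiff(.acids, names(profile))
  if (length(miss))
    stop("VFA profile is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- as.matrix(profile[, .acids])
  if (any(!is.finite(v)) || any(v < 0))
    stop("VFA concentrations must be finite and >= 0", call. = FALSE)
  invisible(profile)
}

#' Stoichiometric fermentation-gas partition from VFA end-points
#'
#' Fermentative carbon dioxide and methane (mmol per g incubated substrate)
#' are estimated from the molar amounts of acetate (a), propionate (p) and
#' butyrate (b):
#' \deqn{CO_2 = a/2 + p/4 + 1.5 b}
#' \deqn{CH_4 = a + 2b - CO_2}
#' Acetate and butyrate production release hydrogen (methanogenic
#' substrate); propionate is a hydrogen sink, so propionate-dominated
#' profiles can drive the estimated methane negative — such values are
#' returned with a warning, never clamped.  The two estimates satisfy
#' `CO2 + CH4 = a + 2b` exactly.  Iso-acids and valerate do not enter the
#' partition.
#'
#' @param profile a profile as returned by [vfaProfile()] (or any
#'   data.frame/list with the six acid columns); vectorized over rows.
#' @return mmol per g incubated substrate.
#' @export
fermentativeCO2 <- function(profile) {
  p <- .checkProfile(profile)
  p$acetate / 2 + p$propionate / 4 + 1.5 * p$butyrate
}

#' @rdname fermentativeCO2
#' @export
fermentativeCH4 <- function(profile) {
  p <- .checkProfile(profile)
  ch4 <- p$acetate + 2 * p$butyrate - fermentativeCO2(p)
  if (any(ch4 < 0))
    warning(sum(ch4 < 0), " profile(s) give negative fermentative CH4 ",
            "(propionate-dominated); values retained", call. = FALSE)
  ch4
}

#' Convert a molar gas amount to a volume
#'
#' @param n amount in mmol.
#' @param molar_volume mL per mmol; the default 25.59 is the ideal-gas molar
#'   volume at the 39 degree C incubation temperature and 1 atm.
#' @return volume in mL.
#' @export
mmolToMl <- function(n, molar_volume = 25.59) {
  if (!is.finite(molar_volume) || molar_volume <= 0)
    stop("molar volume must be > 0", call. = FALSE)
  n * molar_volume
}

#' Methane as a percentage of total gas
#'
#' @param ch4_ml_per_g methane volume (mL per g incubated OM).
#' @param omcv_ml_per_g total cumulative gas (mL per g incubated OM) at the
#'   same incubation end-point.
#' @return percent of total gas.
#' @export
ch4PercentOfTotalGas <- function(ch4_ml_per_g, omcv_ml_per_g) {
  if (any(!is.finite(omcv_ml_per_g)) || any(omcv_ml_per_g <= 0))
    stop("total gas (OMCV) must be > 0", call. = FALSE)
  100 * ch4_ml_per_g / omcv_ml_per_g
}

#' VFA summary statistics
#'
#' `totalVFA()` sums the six acids; `bcfaPercent()` is the branched-chain
#' fraction `100 * (isobutyrate + isovalerate) / total` (an index of protein
#' fermentation); `acetatePropionateRatio()` is `acetate / propionate`.
#' All are vectorized over profile rows.
#'
#' @inheritParams fermentativeCO2
#' @return numeric vector (mM/g, percent, or dimensionless ratio).
#' @export
totalVFA <- function(profile) {
  p <- .checkProfile(profile)
  rowSums(as.matrix(as.data.frame(p)[, .acids]))
}

#' @rdname totalVFA
#' @export
bcfaPercent <- function(profile) {
  p <- .checkProfile(profile)
  tot <- totalVFA(p)
  if (any(tot <= 0)) stop("total VFA must be > 0", call. = FALSE)
  100 * (p$isobutyrate + p$isovalerate) / tot
}

#' @rdname totalVFA
#' @export
acetatePropionateRatio <- function(profile) {
  p <- .checkProfile(profile)
  if (any(p$propionate <= 0)) stop("propionate must be > 0", call. = FALSE)
  p$acetate / p$propionate
}

#' Per-bottle gas partition table for a study
#'
#' Applies the stoichiometric partition to every substrate bottle's VFA
#' end-point and relates the methane volume to the bottle's final-time OMCV.
#' Ratio statistics (BCFA%, acetate:propionate) are computed per bottle;
#' group reports average them afterwards.
#'
#' @param study a [FermStudy-class] object.
#' @param molar_volume mL per mmol, see [mmolToMl()].
#' @return a `data.frame` with one row per substrate bottle: `bottle_id`,
#'   `substrate`, `run`, `replicate`, `co2_mmol_g`, `ch4_mmol_g`,
#'   `ch4_ml_g`, `ch4_pct_total_gas`, `vfa_total`, `bcfa_pct`, `a_p_ratio`.
#' @export
gasPartition <- function(study, molar_volume = 25.59) {
  if (!"omcv" %in% assayNames(study)) study <- toOMCV(study)
  keep <- !isBlank(study)
  cd <- colData(study)[keep, ]
  prof <- vfaData(study)
  omcv_end <- assay(study, "omcv")[nrow(study), keep]
  co2 <- fermentativeCO2(prof)
  ch4 <- suppressWarnings(fermentativeCH4(prof))
  ch4_ml <- mmolToMl(ch4, molar_volume)
  data.frame(bottle_id = cd$bottle_id, substrate = cd$substrate,
             run = cd$run, replicate = cd$replicate,
             co2_mmol_g = co2, ch4_mmol_g = ch4, ch4_ml_g = ch4_ml,
             ch4_pct_total_gas = ch4PercentOfTotalGas(ch4_ml, omcv_end),
             vfa_total = totalVFA(prof), bcfa_pct = bcfaPercent(prof),
             a_p_ratio = acetatePropionateRatio(prof),
             stringsAsFactors = FALSE)
}
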