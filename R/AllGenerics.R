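#' @rdname blankCorrect
#' @export
setGeneric("blankCorrect", function(x, ...) standardGeneric("blankCorrect"))

#' @rdname toOMCV
#' @export
setGeneric("toOMCV", function(x, ...) standardGeneric("toOMCV"))

#' @rdname fitKinetics
#' @export
setGeneric("fitKinetics", function(x, ...) standardGeneric("fitKinetics"))

#' @rdname predictGas
#' @export
setGeneric("predictGas", function(params, t) standardGeneric("predictGas"))

#' @rdname computeTmax
#' @export
setGeneric("computeTmax", function(params) standardGeneric("computeTmax"))

#' @rdname computeRmax
#' @export
setGeneric("computeRmax", function(params) standardGeneric("computeRmax"))

#' Accessors for FermStudy objects
#'
#' `gasTimes()` returns the recording grid (h); `bottleData()` the bottle
#' metadata as a `DataFrame`; `isBlank()` a logical vector flagging blank
#' bottles; `vfaData()` the six VFA end-point columns (mM/g) of the
#' substrate bottles as a plain `data.frame` named by acid.
#'
#' @param x a [FermStudy-class] object.
#' @return see the individual descriptions.
#' @name FermStudy-accessors
#' @rdname FermStudy-accessors
#' @export
setGeneric("gasTimes", function(x) standardGeneric("gasTimes"))

#' @rdname FermStudy-accessors
#' @export
setGeneric("bottleData", function(x) standardGeneric("bottleData"))

#' @rdname FermStudy-accessors
#' @export
setGeneric("isBlank", function(x) standardGeneric("isBlank"))

#' @rdname FermStudy-accessors
#' @export
setGeneric("vfaData", function(x) standardGeneric("vfaData"))

setMethod("gasTimes", "FermStudy", function(x) rowData(x)$time_h)

setMethod("bottleData", "FermStudy", function(x) colData(x))

setMethod("isBlank", "FermStudy", function(x) colData(x)$substrate == "BLANK")

setMethod("vfaData", "FermStudy", function(x) {
  cd <- as.data.frame(colData(x)[!isBlank(x), .vfa_cols])
  names(cd) <- c("acetate", "propionate", "isobutyrate",
                 "butyrate", "isovalerate", "valerate")
  cd
})

setMethod("show", "FermStudy", function(object) {
  nb <- sum(isBlank(object))
  cat(sprintf(paste0("FermStudy: %d bottles (%d substrate, %d blank), ",
                     "%d recording times in [%g, %g] h\n"),
              ncol(object), ncol(object) - nb, nb, nrow(object),
              min(gasTimes(object)), max(gasTimes(object))))
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  subs <- unique(colData(object)$substrate)
  cat("substrates:", paste(setdiff(subs, "BLANK"), collapse = ", "), "\n")
})
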