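#' @name accessors
#' @title Accessors for hashing configurations and reports
#' @description Slot accessors for \code{\link{HashConfig}},
#'   \code{\link{CrcParams}} and the report classes.
#' @param x the object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("preprocessing", function(x) standardGeneric("preprocessing"))

#' @rdname accessors
#' @export
setGeneric("hashFamily", function(x) standardGeneric("hashFamily"))

#' @rdname accessors
#' @export
setGeneric("crcParams", function(x) standardGeneric("crcParams"))

#' @rdname accessors
#' @export
setGeneric("hashSeed", function(x) standardGeneric("hashSeed"))

#' @rdname accessors
#' @export
setGeneric("configLabel", function(x) standardGeneric("configLabel"))

#' @rdname accessors
#' @export
setGeneric("collisions", function(x) standardGeneric("collisions"))

#' @rdname accessors
#' @export
setGeneric("meanFlip", function(x) standardGeneric("meanFlip"))

setMethod("preprocessing", "HashConfig", function(x) x@preprocessing)
setMethod("hashFamily", "HashConfig", function(x) x@family)
setMethod("crcParams", "HashConfig", function(x) x@params)
setMethod("hashSeed", "HashConfig", function(x) x@seed)
setMethod("collisions", "CollisionReport", function(x) x@collisions)
setMethod("meanFlip", "AvalancheReport", function(x) x@meanFlip)

setMethod("show", "CrcParams", function(object) {
  cat("CrcParams: poly", hex32(object@poly),
      "init", hex32(object@init), "xorOut", hex32(object@xorOut), "\n")
})

setMethod("show", "HashConfig", function(object) {
  cat("HashConfig:", configLabel(object), "\n")
})

setMethod("show", "CollisionReport", function(object) {
  cat("CollisionReport:", object@configLabel, "\n",
      " k =", object@k, " total =", format(object@total, big.mark = ","),
      " distinct =", format(object@distinct, big.mark = ","),
      " collisions =", format(object@collisions, big.mark = ","), "\n",
      " replicates =", object@replicates,
      " consistent =", object@consistent,
      " backend =", object@backend, "\n")
})

setMethod("show", "UniformityReport", function(object) {
  cat("UniformityReport:", object@configLabel,
      sprintf("[%s] m = %d chi2 = %.3f df = %d p = %.4f\n",
              object@dataset, object@m, object@chi2, object@df, object@p))
})

setMethod("show", "AvalancheReport", function(object) {
  cat("AvalancheReport:", object@configLabel,
      sprintf("pairs = %g b = %d meanFlip = %.4f sd = %.4f\n",
              object@nPairs, object@b, object@meanFlip, object@flipSD))
})

#' @export
as.data.frame.CollisionReport <- function(x, ...) {
  data.frame(config_label = x@configLabel, k = x@k, total = x@total,
             distinct = x@distinct, collisions = x@collisions,
             replicates = x@replicates, consistent = x@consistent,
             backend = x@backend, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.UniformityReport <- function(x, ...) {
  data.frame(config_label = x@configLabel, dataset = x@dataset, m = x@m,
             chi2 = x@chi2, df = x@df, p = x@p, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.AvalancheReport <- function(x, ...) {
  data.frame(config_label = x@configLabel, n_pairs = x@nPairs, b = x@b,
             mean_flip = x@meanFlip, flip_sd = x@flipSD,
             stringsAsFactors = FALSE)
}
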