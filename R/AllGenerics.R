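#' @import methods
#' @importFrom BiocGenerics counts
NULL

#' Group factor of a count set
#'
#' @param object an \linkS4class{NBCountSet}.
#' @return For \code{groupFactor} the two-level factor; for
#'   \code{groupCodes} the corresponding 0/1 dummy coding (first observed
#'   level is the reference, coded 0).
#' @export
setGeneric("groupFactor", function(object) standardGeneric("groupFactor"))

#' @rdname groupFactor
#' @export
setGeneric("groupCodes", function(object) standardGeneric("groupCodes"))

#' Library sizes of a count set
#'
#' @param object an \linkS4class{NBCountSet}.
#' @return Named numeric vector of per-sample library sizes.
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))

#' Per-sample offsets (natural log of library size)
#'
#' The negative binomial regression uses the log library size as an offset
#' with coefficient fixed at 1, so that modelled means are proportional to
#' sequencing depth.
#'
#' @param object an \linkS4class{NBCountSet}.
#' @return Named numeric vector of offsets.
#' @export
setGeneric("computeOffsets", function(object) standardGeneric("computeOffsets"))

#' Proportion of features without any zero count
#'
#' Features with no zero observation cannot carry information about zero
#' inflation; their relative frequency is a useful dataset descriptor when
#' interpreting the zero-inflation screen.
#'
#' @param object a count matrix (features in rows) or an
#'   \linkS4class{NBCountSet}.
#' @return Fraction in [0, 1] of features whose row contains no zero.
#' @export
setGeneric("zeroFreeProportion", function(object) standardGeneric("zeroFreeProportion"))

#' Retained component degrees of an orthonormal basis
#'
#' @param object an \linkS4class{OrthonormalBasis}.
#' @return Integer vector of the monomial degrees of the retained
#'   components (one smooth-test component per degree).
#' @export
setGeneric("retainedComponents", function(object) standardGeneric("retainedComponents"))

#' @rdname retainedComponents
#' @export
setGeneric("basisOrder", function(object) standardGeneric("basisOrder"))
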