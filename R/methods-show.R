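# Accessors and show methods for the S4 result classes.

#' @rdname GCComposition-class
#' @export
setMethod("compositionTable", "GCComposition", function(x) x@table)

#' @rdname GCComposition-class
#' @export
setMethod("organismIds", "GCComposition", function(x) x@table$organism_id)

#' @rdname OxygenPairSet-class
#' @export
setMethod("pairTable", "OxygenPairSet", function(x) x@pairs)

#' @rdname OxygenPairSet-class
#' @export
setMethod("length", "OxygenPairSet", function(x) nrow(x@pairs))

#' @rdname PGLSFit-class
#' @export
setMethod("lambdaHat", "PGLSFit", function(x) x@lambda)

#' @rdname PGLSFit-class
#' @param object A `PGLSFit`.
#' @param ... Unused.
#' @export
setMethod("coef", "PGLSFit", function(object, ...) object@coefficients)

setMethod("show", "GCComposition", function(object) {
  tab <- object@table
  cat(sprintf("GCComposition with %d organism(s)\n", nrow(tab)))
  print(head(tab, 6L), row.names = FALSE, digits = 6)
  if (nrow(tab) > 6L) cat(sprintf("... and %d more\n", nrow(tab) - 6L))
})

setMethod("show", "OxygenPairSet", function(object) {
  p <- object@pairs
  cat(sprintf("OxygenPairSet: %d phylogenetically independent pair(s) [mode: %s]\n",
              nrow(p), paste(unique(p$mode), collapse = ", ")))
  print(head(p, 10L), row.names = FALSE)
  if (nrow(p) > 10L) cat(sprintf("... and %d more\n", nrow(p) - 10L))
})

setMethod("show", "PGLSFit", function(object) {
  cat(sprintf("PGLS fit (n = %d, lambda = %.4f [%s], logLik = %.4f)\n",
              object@n, object@lambda, object@lambdaMode, object@logLik))
  tab <- data.frame(Estimate = object@coefficients, `Std. Error` = object@se,
                    t = object@tValue, `p (two-tailed)` = object@pValue,
                    check.names = FALSE)
  print(tab, digits = 5)
})

#' Coerce a PGLSFit to a one-row data.frame
#'
#' @param x A `PGLSFit`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A one-row data.frame with slope, intercept, errors, lambda, p, n.
#' @export
as.data.frame.PGLSFit <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    intercept = x@coefficients[[1L]], slope = x@coefficients[[2L]],
    se_slope = x@se[[2L]], t = x@tValue[[2L]], p = x@pValue[[2L]],
    lambda = x@lambda, n = x@n, loglik = x@logLik)
}
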