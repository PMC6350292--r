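#' GCComposition: per-organism GC content at whole-genome and codon site
#' classes
#'
#' Container for GC fractions measured on whole sequences, at fourfold
#' degenerate third codon positions (4FDS) and at zerofold redundant second
#' codon positions (ZRS), together with the number of sites each fraction was
#' computed from. A fraction is `NA` exactly when its site count is zero.
#'
#' @slot table data.frame with columns `organism_id`, `gc_genome`, `gc_4fds`,
#'   `gc_zrs`, `n_sites_genome`, `n_sites_4fds`, `n_sites_zrs`.
#' @seealso [gcComposition()], [writeCompositionTSV()]
#' @export
setClass("GCComposition", representation(table = "data.frame"))

.compositionColumns <- c("organism_id", "gc_genome", "gc_4fds", "gc_zrs",
                         "n_sites_genome", "n_sites_4fds", "n_sites_zrs")

setValidity("GCComposition", function(object) {
  tab <- object@table
  msgs <- character(0)
  if (!all(.compositionColumns %in% names(tab)))
    return(paste("missing columns:",
                 paste(setdiff(.compositionColumns, names(tab)), collapse = ", ")))
  if (anyDuplicated(tab$organism_id))
    msgs <- c(msgs, "duplicated organism_id")
  for (cls in c("genome", "4fds", "zrs")) {
    gc <- tab[[paste0("gc_", cls)]]
    n <- tab[[paste0("n_sites_", cls)]]
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
      msgs <- c(msgs, sprintf("gc_%s outside [0,1]", cls))
    if (any(is.na(gc) != (n == 0)))
      msgs <- c(msgs, sprintf("gc_%s must be NA exactly when n_sites_%s == 0",
                              cls, cls))
    if (any(n < 0))
      msgs <- c(msgs, sprintf("negative n_sites_%s", cls))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' OxygenPairSet: phylogenetically independent aerobe-anaerobe pairs
#'
#' One row per state-change event on the phylogeny: the representative aerobic
#' tip, the representative anaerobic tip, the event id, the 16S identity of the
#' pair (if known) and the representative-selection mode. Across a pair set
#' every tip appears at most once, which is what makes the per-pair GC
#' differences statistically independent.
#'
#' @slot pairs data.frame with columns `event_id`, `aerobic_tip`,
#'   `anaerobic_tip`, `identity_16s`, `mode`.
#' @seealso [extractIndependentPairs()], [filterPairsByIdentity()]
#' @export
setClass("OxygenPairSet", representation(pairs = "data.frame"))

.pairColumns <- c("event_id", "aerobic_tip", "anaerobic_tip",
                  "identity_16s", "mode")

setValidity("OxygenPairSet", function(object) {
  p <- object@pairs
  if (!all(.pairColumns %in% names(p)))
    return(paste("missing columns:",
                 paste(setdiff(.pairColumns, names(p)), collapse = ", ")))
  tips <- c(p$aerobic_tip, p$anaerobic_tip)
  if (anyDuplicated(tips))
    return("tips shared between pairs: pair set is not phylogenetically independent")
  if (any(!is.na(p$identity_16s) & (p$identity_16s < 0 | p$identity_16s > 100)))
    return("identity_16s outside [0,100]")
  if (!all(p$mode %in% c("slow", "fast")))
    return("mode must be 'slow' or 'fast'")
  TRUE
})

#' PGLSFit: result of a phylogenetic generalized least squares fit
#'
#' @slot coefficients Named numeric: intercept and slope.
#' @slot se Standard errors of the coefficients.
#' @slot tValue t statistics (coefficient / se).
#' @slot pValue Two-tailed p values on n - 2 residual degrees of freedom.
#' @slot lambda Pagel's lambda used in the fit (estimated or fixed).
#' @slot lambdaMode `"ML"`, `"REML"` or `"fixed"`.
#' @slot n Number of tips used.
#' @slot logLik Log-likelihood at the reported lambda.
#' @slot sigma2 Residual variance estimate (RSS / (n - 2)).
#' @seealso [pglsFit()]
#' @export
setClass("PGLSFit", representation(
  coefficients = "numeric", se = "numeric", tValue = "numeric",
  pValue = "numeric", lambda = "numeric", lambdaMode = "character",
  n = "integer", logLik = "numeric", sigma2 = "numeric"))

setValidity("PGLSFit", function(object) {
  if (object@lambda < 0 || object@lambda > 1) return("lambda outside [0,1]")
  if (any(object@pValue < 0 | object@pValue > 1)) return("p value outside [0,1]")
  if (object@n < 3L) return("n must be >= 3")
  tv <- object@tValue
  cf <- object@coefficients
  if (any(sign(tv[cf != 0]) != sign(cf[cf != 0]))) return("sign(t) != sign(coefficient)")
  TRUE
})
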