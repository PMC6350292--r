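# Seeded synthetic-data generators with known ground truth.
#
# Each generator derives its own pseudo-random stream from the master seed
# and a stream name, so any stage can be re-simulated independently and every
# output is a pure function of (parameters, seed).

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation: starting from one lineage at time 0, each of the k
#' current lineages splits at rate `birthRate`, until `nTips` lineages exist.
#' The returned tree is rooted and ultrametric; the stem below the first
#' split is kept in `root.edge`. The tree is observed one (censored) waiting
#' period after the last split, so total tip age (stem included) is
#' `sum(1 / (k * birthRate))` in expectation over k = 1 .. nTips.
#'
#' @param nTips Number of tips (>= 3).
#' @param birthRate Per-lineage speciation rate (> 0).
#' @param seed Master integer seed.
#' @return A rooted ultrametric `ape::phylo`.
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1L) {
  if (nTips < 3L) stop("nTips must be >= 3", call. = FALSE)
  stopifnot(birthRate > 0)
  .withSeed(.streamSeed(seed, "tree"), {
    nEv <- nTips - 1L
    # waiting time at k lineages ~ Exp(k * birthRate); the tree is observed
    # a censored waiting period after the last split, so no tip branch is 0
    waits <- rexp(nTips, rate = birthRate * seq_len(nTips))
    evTime <- cumsum(waits[seq_len(nEv)])
    total <- evTime[nEv] + waits[nTips]
    birth <- 0
    splitEv <- NA_integer_
    children <- vector("list", nEv)
    active <- 1L
    for (k in seq_len(nEv)) {
      pick <- active[sample.int(length(active), 1L)]
      splitEv[pick] <- k
      id1 <- length(birth) + 1L
      id2 <- id1 + 1L
      birth[c(id1, id2)] <- evTime[k]
      splitEv[c(id1, id2)] <- NA_integer_
      children[[k]] <- c(id1, id2)
      active <- c(active[active != pick], id1, id2)
    }
    tipNo <- 0L
    lin2nwk <- function(id) {
      len <- (if (is.na(splitEv[id])) total else evTime[splitEv[id]]) - birth[id]
      if (is.na(splitEv[id])) {
        tipNo <<- tipNo + 1L
        sprintf("t%d:%.12g", tipNo, len)
      } else {
        kids <- children[[splitEv[id]]]
        sprintf("(%s,%s):%.12g", lin2nwk(kids[1L]), lin2nwk(kids[2L]), len)
      }
    }
    ape::read.tree(text = paste0(lin2nwk(1L), ";"))
  })
}

#' Simulate an oxygen-requirement history with a fixed number of transitions
#'
#' Places exactly `nTransitions` state flips on distinct, uniformly chosen
#' edges; every tip inherits the parity of flips on its root-to-tip path,
#' starting from an anaerobic root. This emulates phylogenies on which only a
#' few changes in oxygen requirement occurred.
#'
#' @param tree `ape::phylo`.
#' @param nTransitions Number of flipped edges (<= number of edges).
#' @param seed Master integer seed.
#' @return Named character vector over tips, `"aerobic"`/`"anaerobic"`, with
#'   attribute `flipped_edges` (row indices into `tree$edge`).
#' @export
simulateOxygenStates <- function(tree, nTransitions, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  nEdge <- nrow(tree$edge)
  if (nTransitions < 0L || nTransitions > nEdge)
    stop(sprintf("nTransitions must lie in [0, %d]", nEdge), call. = FALSE)
  .withSeed(.streamSeed(seed, "states"), {
    flips <- if (nTransitions > 0L) sort(sample.int(nEdge, nTransitions))
             else integer(0)
    flipped <- logical(nEdge)
    flipped[flips] <- TRUE
    n <- length(tree$tip.label)
    root <- n + 1L
    parentEdge <- integer(n + tree$Nnode)
    parentEdge[tree$edge[, 2L]] <- seq_len(nEdge)
    # tip state = parity of flipped edges on the root-to-tip path
    out <- vapply(seq_len(n), function(tip) {
      v <- tip; flipsOnPath <- 0L
      while (v != root) {
        e <- parentEdge[v]
        if (flipped[e]) flipsOnPath <- flipsOnPath + 1L
        v <- tree$edge[e, 1L]
      }
      if (flipsOnPath %% 2L == 1L) "aerobic" else "anaerobic"
    }, character(1L))
    names(out) <- tree$tip.label
    attr(out, "flipped_edges") <- flips
    out
  })
}

#' Simulate a GC-like continuous trait under Brownian motion with a
#' state-dependent mean shift
#'
#' Generates `y = intercept + slope * x + e`, where `x` is the ordinal
#' oxygen code (3 aerobic, 2 anaerobic) and
#' `e ~ MVN(0, sigma2 * C(lambda))` with `C` the Brownian covariance of the
#' tree -- exactly the generative model that PGLS with Pagel's lambda
#' assumes.
#'
#' @param tree Rooted `ape::phylo`.
#' @param states Named tip states (merged via [mergeOxygenState()]).
#' @param intercept,slope True regression coefficients.
#' @param sigma2 Brownian rate (>= 0; 0 gives the noise-free limit).
#' @param lambda True Pagel's lambda in `[0, 1]`.
#' @param seed Master integer seed.
#' @return Named numeric tip values with attribute `ground_truth`.
#' @export
simulateGCTrait <- function(tree, states, intercept = 0, slope = 0,
                            sigma2 = 1, lambda = 1, seed = 1L) {
  stopifnot(sigma2 >= 0)
  merged <- mergeOxygenState(states[tree$tip.label])
  x <- ifelse(merged == "aerobic", 3, 2)
  mu <- intercept + slope * x
  eps <- 0
  if (sigma2 > 0) {
    C <- brownianCovariance(tree)
    U <- chol(lambdaTransform(C, lambda))
    eps <- .withSeed(.streamSeed(seed, "trait"),
                     sqrt(sigma2) * drop(crossprod(U, rnorm(length(x)))))
  }
  y <- setNames(mu + eps, tree$tip.label)
  attr(y, "ground_truth") <- list(intercept = intercept, slope = slope,
                                  sigma2 = sigma2, lambda = lambda,
                                  seed = seed, x = setNames(x, tree$tip.label))
  y
}

#' Generate an in-frame CDS with prescribed site-class GC content
#'
#' Builds a stop-free coding sequence from fourfold-degenerate codon
#' families only, so that every third position is a fourfold degenerate site
#' and every second position a (non-stop) zerofold redundant site. The
#' number of G/C third positions is `round(gc4Target * nCodons)` and the
#' number of codons drawn from families with a G/C second base is
#' `round(gczrsTarget * nCodons)`, so both realised fractions are within
#' `1 / nCodons` of their targets.
#'
#' @param nCodons Number of codons (>= 10).
#' @param gc4Target Target GC fraction at fourfold third positions.
#' @param gczrsTarget Target GC fraction at second positions.
#' @param table Genetic code id (default `"11"`).
#' @param seed Master integer seed.
#' @return Single CDS string with attributes `gc4_realised`,
#'   `gczrs_realised`, `n_codons`.
#' @export
generateCDS <- function(nCodons, gc4Target, gczrsTarget, table = "11",
                        seed = 1L) {
  if (nCodons < 10L) stop("nCodons must be >= 10", call. = FALSE)
  stopifnot(gc4Target >= 0, gc4Target <= 1, gczrsTarget >= 0, gczrsTarget <= 1)
  deg <- .degeneracyTable(table)
  prefixes <- unique(substr(rownames(deg$classes), 1L, 2L))
  fourfold <- prefixes[vapply(prefixes, function(p)
    deg$classes[paste0(p, "A"), 3L] == "fourfold", logical(1L))]
  gc2 <- fourfold[substr(fourfold, 2L, 2L) %in% c("G", "C")]
  at2 <- setdiff(fourfold, gc2)
  if (length(gc2) == 0L || length(at2) == 0L)
    stop(sprintf(
      "infeasible second-position target under code %s: achievable GC fraction is %s",
      table, if (length(gc2)) "1" else "0"), call. = FALSE)
  .withSeed(.streamSeed(seed, "cds"), {
    nGC2 <- round(gczrsTarget * nCodons)
    nGC4 <- round(gc4Target * nCodons)
    pre <- character(nCodons)
    idx2 <- sample.int(nCodons, nGC2)
    pre[idx2] <- sample(gc2, nGC2, replace = TRUE)
    pre[-idx2] <- sample(at2, nCodons - nGC2, replace = TRUE)
    if (nGC2 == 0L) pre <- sample(at2, nCodons, replace = TRUE)
    third <- character(nCodons)
    idx4 <- sample.int(nCodons, nGC4)
    third[idx4] <- sample(c("G", "C"), nGC4, replace = TRUE)
    third[-idx4] <- sample(c("A", "T"), nCodons - nGC4, replace = TRUE)
    if (nGC4 == 0L) third <- sample(c("A", "T"), nCodons, replace = TRUE)
    cds <- paste0(pre, third, collapse = "")
    attr(cds, "gc4_realised") <- nGC4 / nCodons
    attr(cds, "gczrs_realised") <- nGC2 / nCodons
    attr(cds, "n_codons") <- nCodons
    cds
  })
}

#' Generate an aligned 16S-like sequence pair with known identity
#'
#' The second sequence differs from the first at exactly
#' `round((1 - identityTarget / 100) * length)` positions. Optional gap
#' columns (a gap in one sequence, a base in the other) exercise the
#' mismatch-only identity rule: they are excluded from the comparison, so
#' the realised identity is unchanged.
#'
#' @param length Number of comparable columns.
#' @param identityTarget Percent identity in `[0, 100]`.
#' @param seed Master integer seed.
#' @param gapColumns Number of gap columns to interleave (default 0).
#' @return Character vector `c(a = ..., b = ...)` with attribute
#'   `identity_realised`.
#' @export
generate16SPair <- function(length, identityTarget, seed = 1L,
                            gapColumns = 0L) {
  stopifnot(length >= 1L, identityTarget >= 0, identityTarget <= 100,
            gapColumns >= 0L)
  .withSeed(.streamSeed(seed, "16s"), {
    a <- sample(.BASES, length, replace = TRUE)
    b <- a
    nDiff <- round((1 - identityTarget / 100) * length)
    if (nDiff > 0L) {
      pos <- sample.int(length, nDiff)
      b[pos] <- vapply(a[pos], function(base)
        sample(setdiff(.BASES, base), 1L), character(1L))
    }
    if (gapColumns > 0L) {
      total <- length + gapColumns
      gapAt <- sort(sample.int(total, gapColumns))
      A <- character(total); B <- character(total)
      A[gapAt] <- ifelse(seq_len(gapColumns) %% 2L == 1L, "-",
                         sample(.BASES, gapColumns, replace = TRUE))
      B[gapAt] <- ifelse(A[gapAt] == "-",
                         sample(.BASES, gapColumns, replace = TRUE), "-")
      A[-gapAt] <- a; B[-gapAt] <- b
      a <- A; b <- B
    }
    out <- c(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
    attr(out, "identity_realised") <- 100 * (1 - nDiff / length)
    out
  })
}
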