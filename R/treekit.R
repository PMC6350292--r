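# Pairwise distances, 16S identity, neighbour joining, bootstrap support.
#
# All distances use pairwise deletion: an alignment column contributes to a
# pair only when both sequences carry an unambiguous A/C/G/T base there. This
# matches the use of *identity* (mismatches only) rather than *similarity*
# (gaps counted) for fragmentary 16S sequences, where large alignment gaps
# reflect incomplete assemblies, not indel events.

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of sites at which two aligned nucleotide sequences differ,
#' among the sites actually compared. Columns where either sequence has a gap
#' or an ambiguity symbol are excluded (pairwise deletion).
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' pDistance("AAAA", "AAAT")  # 0.25
#' pDistance("AA-A", "AACA")  # 0: the gap column is excluded
#' @export
pDistance <- function(a, b) {
  ca <- .charVec(a); cb <- .charVec(b)
  if (length(ca) != length(cb))
    stop("aligned sequences must have equal length", call. = FALSE)
  ok <- ca %in% .BASES & cb %in% .BASES
  if (!any(ok))
    stop("undefined distance: no comparable (both-unambiguous) columns",
         call. = FALSE)
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Percent identity of two aligned sequences
#'
#' `100 * (1 - pDistance)`: only mismatches count against identity, gap
#' columns are excluded entirely.
#'
#' @inheritParams pDistance
#' @return Percent in `[0, 100]`.
#' @examples
#' identityPercent("AC--GT", "ACTAGT")  # 100: gap columns excluded
#' @export
identityPercent <- function(a, b) 100 * (1 - pDistance(a, b))

#' Pairwise p-distance matrix of an alignment
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sequence
#'   names.
#' @export
pDistanceMatrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L, !is.null(names(alignment)))
  labs <- names(alignment)
  chars <- lapply(alignment, .charVec)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- chars[[i]] %in% .BASES & chars[[j]] %in% .BASES
    if (!any(ok))
      stop(sprintf("undefined distance between '%s' and '%s'", labs[i], labs[j]),
           call. = FALSE)
    d[i, j] <- d[j, i] <- sum(chars[[i]][ok] != chars[[j]][ok]) / sum(ok)
  }
  d
}

# Saitou-Nei neighbour joining with two conventions made explicit:
#  * tie-break: among pairs minimising Q, join the pair whose (sorted) label
#    pair is lexicographically smallest; internal nodes are keyed by the
#    smallest tip label in their subtree, so the result is deterministic and
#    independent of input order and of any RNG;
#  * negative branch lengths are clamped to zero with the deficit moved to
#    the sister branch, preserving the path length through the new node.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. On an additive distance matrix the
#' returned unrooted tree reproduces the input distances exactly (up to
#' floating-point error). Ties in the Q criterion are broken by joining the
#' lexicographically smallest label pair; negative branch-length estimates
#' are clamped to zero with the deficit transferred to the sister branch
#' (reported via `message()`).
#'
#' @param dm Symmetric numeric matrix with row/column names (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("insufficient taxa: neighbour joining needs >= 3", call. = FALSE)
  labs <- rownames(dm)
  stopifnot(!is.null(labs), !anyDuplicated(labs))
  if (max(abs(dm - t(dm))) > 1e-12 || any(dm < 0))
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)

  # Active nodes: newick fragment, sort key (smallest tip label in subtree).
  frag <- labs
  key <- labs
  d <- dm
  clamped <- 0L

  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(d) > 3L) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ord <- order(pmin(key[cand[, 1L]], key[cand[, 2L]]),
                 pmax(key[cand[, 1L]], key[cand[, 2L]]))
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]

    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0; clamped <- clamped + 1L }
    if (lj < 0) { li <- li + lj; lj <- 0; clamped <- clamped + 1L }

    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newKey <- min(key[i], key[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    d <- d2
    frag <- c(frag[keep], newFrag)
    key <- c(key[keep], newKey)
  }

  # Terminal three-node star: closed-form branch lengths.
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- c(l1, l2, l3)
  if (any(ls < 0)) { clamped <- clamped + sum(ls < 0); ls[ls < 0] <- 0 }
  if (clamped > 0L)
    message(sprintf("njTree: %d negative branch length(s) clamped to 0", clamped))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(ls[1]),
                 frag[2], fmt(ls[2]), frag[3], fmt(ls[3]))
  ape::read.tree(text = nwk)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment's p-distance matrix, then
#' resamples alignment columns with replacement `nReps` times, rebuilds the
#' tree per replicate, and annotates each internal bipartition of the
#' full-data tree with the percentage of replicates containing it (integer,
#' stored in `node.label`).
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (>= 3).
#' @param nReps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @return An `ape::phylo` with integer percent supports in `node.label`.
#' @export
bootstrapSupport <- function(alignment, nReps = 1000L, seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1", call. = FALSE)
  stopifnot(length(alignment) >= 3L)
  # Canonical tip order so supports are invariant to input permutation.
  alignment <- alignment[order(names(alignment))]
  chars <- do.call(rbind, lapply(alignment, .charVec))
  full <- njTree(pDistanceMatrix(alignment))
  reps <- .withSeed(.streamSeed(seed, "bootstrap"), {
    lapply(seq_len(nReps), function(k) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      aln <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste, collapse = ""),
                      rownames(chars))
      njTree(pDistanceMatrix(aln))
    })
  })
  counts <- ape::prop.clades(full, part = ape::prop.part(reps), rooted = FALSE)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.integer(round(100 * counts / nReps))
  full
}
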