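# Extraction of phylogenetically independent aerobe-anaerobe pairs.
#
# The operational rule: merge each maximal state-uniform clade of the rooted
# tree into one group; wherever a mixed internal node has unclaimed uniform
# group children of both oxygen states, that node records one state-change
# event pairing the largest aerobic group with the largest anaerobic group
# (remaining opposite-state group children at a multifurcation are discarded,
# which keeps pairs tip-disjoint and therefore statistically independent).
# One representative tip per group is then chosen by branch length: the most
# slowly evolved (shortest root-to-tip path within the group) or the most
# quickly evolved, with ties broken by annotation-gene count, then by label.

.OXYGEN_STATES <- c("aerobe", "anaerobe", "obligate_aerobe", "obligate_anaerobe")

#' Merge detailed oxygen-requirement categories into two groups
#'
#' Obligate aerobes merge with aerobes into `"aerobic"`, obligate anaerobes
#' with anaerobes into `"anaerobic"`. Input is normalised (case, spaces).
#'
#' @param state Character vector over aerobe / anaerobe / obligate aerobe /
#'   obligate anaerobe (underscores or spaces).
#' @return Character vector over `"aerobic"` / `"anaerobic"`, names kept.
#' @examples
#' mergeOxygenState(c("obligate aerobe", "anaerobe"))
#' @export
mergeOxygenState <- function(state) {
  s <- gsub("[ -]+", "_", tolower(trimws(state)))
  s <- sub("^(aerobic)$", "aerobe", s)
  s <- sub("^(anaerobic)$", "anaerobe", s)
  bad <- !(s %in% c(.OXYGEN_STATES, "aerobic", "anaerobic"))
  if (any(bad))
    stop("unknown oxygen state(s): ", paste(unique(state[bad]), collapse = ", "),
         call. = FALSE)
  out <- ifelse(s %in% c("aerobe", "obligate_aerobe", "aerobic"),
                "aerobic", "anaerobic")
  names(out) <- names(state)
  out
}

#' Taxonomic prefilter for mixed-state groups
#'
#' Walks the taxonomic ranks from species upward (species, genus, family,
#' order, class). At each rank, groups that contain both merged oxygen states
#' among the not-yet-claimed records are kept, and their members are claimed;
#' higher ranks only see what remains. Records never falling in a mixed group
#' are dropped.
#'
#' @param records data.frame with columns `organism_id`, `oxygen_state` and
#'   the rank columns `species`, `genus`, `family`, `order`, `class` (any
#'   subset, lowest first in that order, is used).
#' @return The qualifying subset of `records` with an added column
#'   `qualified_rank`.
#' @export
taxonomicPrefilter <- function(records) {
  ranks <- intersect(c("species", "genus", "family", "order", "class"),
                     names(records))
  stopifnot(length(ranks) >= 1L, "organism_id" %in% names(records),
            "oxygen_state" %in% names(records))
  if (nrow(records) == 0L) {
    records$qualified_rank <- character(0)
    return(records)
  }
  merged <- mergeOxygenState(records$oxygen_state)
  claimed <- rep(FALSE, nrow(records))
  qualified <- rep(NA_character_, nrow(records))
  for (rank in ranks) {
    grp <- records[[rank]]
    for (g in unique(grp[!claimed & !is.na(grp)])) {
      idx <- which(!claimed & !is.na(grp) & grp == g)
      if (length(unique(merged[idx])) == 2L) {
        claimed[idx] <- TRUE
        qualified[idx] <- rank
      }
    }
  }
  out <- records[claimed, , drop = FALSE]
  out$qualified_rank <- qualified[claimed]
  rownames(out) <- NULL
  out
}

# Children list per internal node of a phylo object.
#' @noRd
.childrenList <- function(tree) {
  n <- length(tree$tip.label)
  ch <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1L]]] <- c(ch[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  ch
}

#' Find oxygen-requirement state-change events on a labelled tree
#'
#' Collapses maximal state-uniform clades and records one event at every
#' mixed internal node with unclaimed uniform group children of both states
#' (see the package rule above; at a multifurcation only the two largest
#' opposite-state groups are paired, the rest are discarded).
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param states Named character vector over all tips; detailed categories
#'   are merged via [mergeOxygenState()].
#' @return List of events; each has `event_id`, `aerobic` (tip labels),
#'   `anaerobic` (tip labels) and `node` (the mixed node).
#' @export
findStateChangeEvents <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(states)))
    stop("labelling error: tips without an oxygen state: ",
         paste(setdiff(tips, names(states)), collapse = ", "), call. = FALSE)
  merged <- mergeOxygenState(states[tips])
  n <- length(tips)
  nodes <- n + seq_len(tree$Nnode)
  ch <- .childrenList(tree)

  # Post-order over internal nodes (children before parents).
  root <- n + 1L
  stack <- root
  ord <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ord <- c(ord, v)
    kids <- ch[[v]]
    internals <- kids[kids > n]
    for (k in internals) stack <- c(stack, k)
  }
  postorder <- rev(ord)

  # uniform state of each subtree ("aerobic"/"anaerobic"/NA for mixed)
  uni <- c(unname(merged), rep(NA_character_, tree$Nnode))
  for (v in postorder) {
    s <- unique(uni[ch[[v]]])
    uni[v] <- if (length(s) == 1L && !is.na(s)) s else NA_character_
  }
  tipsUnder <- function(v) if (v <= n) tips[v] else
    unlist(lapply(ch[[v]], tipsUnder), use.names = FALSE)

  if (!is.na(uni[root])) return(list())  # single-state tree

  claimed <- rep(FALSE, n + tree$Nnode)
  events <- list()
  groupKey <- function(g) min(g)
  for (v in postorder) {
    if (!is.na(uni[v])) next  # only mixed nodes host events
    kids <- ch[[v]]
    groups <- kids[!is.na(uni[kids]) & !claimed[kids]]
    aer <- groups[uni[groups] == "aerobic"]
    ana <- groups[uni[groups] == "anaerobic"]
    if (length(aer) >= 1L && length(ana) >= 1L) {
      pick <- function(g) {
        sizes <- vapply(g, function(k) length(tipsUnder(k)), integer(1L))
        keys <- vapply(g, function(k) groupKey(tipsUnder(k)), character(1L))
        g[order(-sizes, keys)][1L]
      }
      ga <- pick(aer); gn <- pick(ana)
      events[[length(events) + 1L]] <- list(
        event_id = length(events) + 1L,
        aerobic = tipsUnder(ga), anaerobic = tipsUnder(gn), node = v)
      claimed[c(aer, ana)] <- TRUE  # discard unpaired groups at multifurcations
    }
  }
  events
}

#' Choose the representative tip of a state-uniform group
#'
#' `mode = "slow"` picks the tip with the shortest path from the group's
#' most recent common ancestor (the most slowly evolved lineage); `"fast"`
#' picks the longest. Ties (to within 1e-9) are broken in favour of the
#' genome with more annotated genes, then by the lexicographically smallest
#' label.
#'
#' @param group Character vector of tip labels (non-empty).
#' @param tree Rooted `ape::phylo` containing all the group's tips.
#' @param mode `"slow"` or `"fast"`.
#' @param annotationCounts Optional named numeric vector of annotated-gene
#'   counts per tip, used only for tie-breaking.
#' @return A single tip label.
#' @export
selectRepresentative <- function(group, tree, mode = c("slow", "fast"),
                                 annotationCounts = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(group) >= 1L)
  if (length(group) == 1L) return(group)
  idx <- match(group, tree$tip.label)
  stopifnot(!anyNA(idx))
  depths <- ape::node.depth.edgelength(tree)
  mrca <- ape::getMRCA(tree, group)
  path <- depths[idx] - depths[mrca]
  score <- if (mode == "slow") path else -path
  best <- score <= min(score) + 1e-9
  cand <- group[best]
  if (length(cand) > 1L && !is.null(annotationCounts)) {
    cnt <- annotationCounts[cand]
    cnt[is.na(cnt)] <- -Inf
    cand <- cand[cnt == max(cnt)]
  }
  sort(cand)[1L]
}

#' Extract phylogenetically independent aerobe-anaerobe pairs
#'
#' One pair per state-change event: the representative of the event's aerobic
#' group versus the representative of its anaerobic group. Slow and fast mode
#' produce pair sets with identical event ids, differing only in which tip
#' represents each group.
#'
#' @inheritParams findStateChangeEvents
#' @inheritParams selectRepresentative
#' @param identities Optional symmetric matrix of pairwise 16S percent
#'   identities (dimnames = tip labels), or a function of two tip labels.
#' @return An [OxygenPairSet-class].
#' @export
extractIndependentPairs <- function(tree, states, mode = c("slow", "fast"),
                                    annotationCounts = NULL,
                                    identities = NULL) {
  mode <- match.arg(mode)
  events <- findStateChangeEvents(tree, states)
  lookupIdentity <- function(a, b) {
    if (is.null(identities)) return(NA_real_)
    if (is.function(identities)) return(identities(a, b))
    if (a %in% rownames(identities) && b %in% colnames(identities))
      return(identities[a, b])
    NA_real_
  }
  rows <- lapply(events, function(ev) {
    a <- selectRepresentative(ev$aerobic, tree, mode, annotationCounts)
    b <- selectRepresentative(ev$anaerobic, tree, mode, annotationCounts)
    data.frame(event_id = ev$event_id, aerobic_tip = a, anaerobic_tip = b,
               identity_16s = lookupIdentity(a, b), mode = mode,
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(0), aerobic_tip = character(0),
               anaerobic_tip = character(0), identity_16s = numeric(0),
               mode = character(0), stringsAsFactors = FALSE)
  new("OxygenPairSet", pairs = pairs)
}

#' Filter pairs by 16S identity threshold
#'
#' Keeps pairs whose 16S identity is at or above `threshold` percent. At a
#' positive threshold, pairs lacking an identity are excluded with a warning;
#' at threshold 0 every pair is kept.
#'
#' @param pairs An [OxygenPairSet-class].
#' @param threshold Percent identity in `[0, 100]`.
#' @return A filtered [OxygenPairSet-class].
#' @export
filterPairsByIdentity <- function(pairs, threshold) {
  stopifnot(is(pairs, "OxygenPairSet"), threshold >= 0, threshold <= 100)
  p <- pairs@pairs
  if (threshold == 0) return(pairs)
  if (any(is.na(p$identity_16s)))
    warning(sprintf("%d pair(s) without 16S identity excluded at threshold %g",
                    sum(is.na(p$identity_16s)), threshold), call. = FALSE)
  keep <- !is.na(p$identity_16s) & p$identity_16s >= threshold
  new("OxygenPairSet", pairs = p[keep, , drop = FALSE])
}

#' Sweep identity thresholds over a pair set
#'
#' @inheritParams filterPairsByIdentity
#' @param thresholds Numeric vector of percent thresholds.
#' @return Named list of [OxygenPairSet-class] objects, one per threshold.
#' @export
identityThresholdSweep <- function(pairs, thresholds) {
  out <- lapply(thresholds, function(t)
    suppressWarnings(filterPairsByIdentity(pairs, t)))
  names(out) <- as.character(thresholds)
  out
}
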