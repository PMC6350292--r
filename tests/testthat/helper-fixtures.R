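# Shared fixtures and independent oracles, built in code.

# Worked-example phylogeny: eleven species plus two conspecific strains, with
# exactly three oxygen-requirement transitions (strain1/strain2 within one
# species; the anaerobic clade sp4-6 sister to the aerobic clade sp7-8; the
# anaerobic sp10 sister to the aerobic sp11). Branch lengths make sp6 and sp7
# the slowly evolved representatives of their groups and sp5/sp8 the fast
# ones.
exampleTransitionTree <- function() {
  nwk <- paste0(
    "((strain1:1,strain2:1):1,",
    "(sp1:1,(sp2:1,sp3:1):1):1,",
    "(((sp4:1.2,sp5:1.5):0.5,sp6:0.8):1,(sp7:0.9,sp8:1.4):1):1,",
    "sp9:3,",
    "(sp10:1,sp11:1):1);")
  ape::read.tree(text = nwk)
}

exampleTransitionStates <- function() {
  c(strain1 = "aerobe", strain2 = "anaerobe",
    sp1 = "anaerobe", sp2 = "anaerobe", sp3 = "anaerobe",
    sp4 = "anaerobe", sp5 = "anaerobe", sp6 = "anaerobe",
    sp7 = "aerobe", sp8 = "aerobe",
    sp9 = "anaerobe", sp10 = "anaerobe", sp11 = "aerobe")
}

# --- independent oracles -------------------------------------------------

# Degeneracy class by literal substitution enumeration, written independently
# of the package's cached table.
oracleDegeneracy <- function(codon, position, table = "11") {
  code <- Biostrings::getGeneticCode(table)
  aa <- code[[codon]]
  nSame <- 0L
  for (b in c("A", "C", "G", "T")) {
    alt <- codon
    substr(alt, position, position) <- b
    if (code[[alt]] == aa) nSame <- nSame + 1L
  }
  c("zerofold", "twofold", "threefold", "fourfold")[nSame]
}

# Two-tailed exact Wilcoxon signed-rank p by literal enumeration of all 2^n
# sign assignments (feasible for n <= 15 or so).
oracleWilcoxonP <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  lower <- mean(Ws <= W + 1e-9)
  upper <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Two-tailed exact Mann-Whitney p by enumeration of all choose(N, n1) group
# labelings.
oracleMannWhitneyP <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  sets <- combn(N, n1)
  R1s <- apply(sets, 2L, function(idx) sum(r[idx]))
  lower <- mean(R1s <= R1 + 1e-9)
  upper <- mean(R1s >= R1 - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Brute-force Brownian covariance: root-to-MRCA path length per tip pair.
oracleBrownianCovariance <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    anc <- if (i == j) i else ape::getMRCA(tree, c(i, j))
    C[i, j] <- depths[anc]
  }
  C
}

reverseComplement <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
        collapse = "")
}

# Random tree with strictly positive branch lengths (additive test input).
randomAdditiveTree <- function(nTips) {
  tr <- ape::rtree(nTips)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  tr
}
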