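# GC content of whole sequences and of codon-degeneracy site classes.
#
# Site classes follow the standard codon-degeneracy vocabulary: a codon
# position is fourfold degenerate (4FDS) when every nucleotide substitution at
# that position preserves the encoded amino acid, and zerofold when none does.
# The zerofold-redundant-site (ZRS) measure is defined operationally as the
# second nucleotide of every non-stop codon; a strict degeneracy-computed
# zerofold mode is available for sensitivity analysis.

.BASES <- c("A", "C", "G", "T")

#' GC content of a nucleotide sequence
#'
#' Counts are case-insensitive; symbols outside A/C/G/T (gaps, ambiguity
#' codes) are excluded from both numerator and denominator. Several sequences
#' are pooled into one fraction.
#'
#' @param x Character vector of nucleotide sequences (or an `XStringSet`);
#'   all elements are pooled.
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gcContent("GGCC")   # 1
#' gcContent("ATGN")   # 1/3: N carries no weight
#' @export
gcContent <- function(x) {
  counts <- .gcCounts(x)
  if (counts[["n"]] == 0L)
    stop("undefined composition: no unambiguous A/C/G/T bases", call. = FALSE)
  counts[["gc"]] / counts[["n"]]
}

#' @noRd
.gcCounts <- function(x) {
  if (inherits(x, "XStringSet") || inherits(x, "XString")) x <- as.character(x)
  s <- toupper(paste(x, collapse = ""))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  gc <- sum(chars == "G" | chars == "C")
  n <- gc + sum(chars == "A" | chars == "T")
  c(gc = gc, n = n)
}

# Degeneracy classes for all 64 codons x 3 positions under one genetic code,
# computed once per code by exhaustive substitution and cached. Rows are
# codons, columns positions; values in {zerofold, twofold, threefold,
# fourfold}. Stop codons are classified like any other codon but flagged.
.degeneracyCache <- new.env(parent = emptyenv())

#' @noRd
.degeneracyTable <- function(table = "11") {
  table <- as.character(table)
  if (!is.null(.degeneracyCache[[table]])) return(.degeneracyCache[[table]])
  code <- Biostrings::getGeneticCode(table)
  codons <- names(code)
  cls <- matrix(NA_character_, nrow = 64L, ncol = 3L,
                dimnames = list(codons, NULL))
  for (codon in codons) {
    aa <- code[[codon]]
    for (pos in 1:3) {
      variants <- vapply(.BASES, function(b) {
        v <- codon; substr(v, pos, pos) <- b; code[[v]]
      }, character(1L))
      same <- sum(variants == aa)  # includes the codon itself
      cls[codon, pos] <- switch(as.character(same),
                                "1" = "zerofold", "2" = "twofold",
                                "3" = "threefold", "4" = "fourfold")
    }
  }
  out <- list(classes = cls, stops = codons[code == "*"], code = code)
  .degeneracyCache[[table]] <- out
  out
}

#' Degeneracy class of a codon position
#'
#' A position is fourfold degenerate when all four nucleotide substitutions at
#' that position leave the encoded amino acid unchanged, and zerofold when
#' every substitution changes it. Codons containing ambiguity symbols are
#' reported as `"other"`. Stop codons are classified like any codon but the
#' result carries attribute `stop_codon = TRUE`.
#'
#' @param codon Three-letter nucleotide string.
#' @param position Codon position, 1 to 3.
#' @param table Genetic code id as understood by
#'   [Biostrings::getGeneticCode()]; defaults to the bacterial/archaeal code
#'   `"11"`.
#' @return One of `"zerofold"`, `"twofold"`, `"threefold"`, `"fourfold"`,
#'   `"other"`.
#' @examples
#' classifyCodonPosition("GGA", 3)  # fourfold (glycine family)
#' classifyCodonPosition("ATG", 2)  # zerofold
#' @export
classifyCodonPosition <- function(codon, position, table = "11") {
  stopifnot(length(codon) == 1L, nchar(codon) == 3L,
            position %in% 1:3)
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1L]] %in% .BASES)) return("other")
  deg <- .degeneracyTable(table)
  out <- unname(deg$classes[codon, position])
  if (codon %in% deg$stops) attr(out, "stop_codon") <- TRUE
  out
}

# Split a set of CDS strings into a pooled codon vector, skipping (with a
# warning) sequences that are not a multiple of 3 or contain internal stops.
# A terminal stop codon is retained in the codon list; site-class functions
# decide whether it contributes sites.
#' @noRd
.pooledCodons <- function(cds, table = "11") {
  deg <- .degeneracyTable(table)
  kept <- list(); skipped <- 0L
  for (i in seq_along(cds)) {
    s <- toupper(as.character(cds[[i]]))
    if (nchar(s) %% 3L != 0L) {
      skipped <- skipped + 1L
      warning(sprintf("CDS %d skipped: length %d not divisible by 3",
                      i, nchar(s)), call. = FALSE)
      next
    }
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    internal <- codons[-length(codons)]
    if (any(internal %in% deg$stops)) {
      skipped <- skipped + 1L
      warning(sprintf("CDS %d skipped: internal stop codon", i), call. = FALSE)
      next
    }
    kept[[length(kept) + 1L]] <- codons
  }
  list(codons = unlist(kept), n_skipped = skipped)
}

#' GC content at fourfold degenerate third codon positions
#'
#' Pools, across a whole CDS set, the third positions of all codons whose
#' third position is fourfold degenerate, and returns the GC fraction over
#' those sites. CDSs whose length is not a multiple of 3 or that contain an
#' internal stop codon are skipped with a warning. Codons containing
#' ambiguity symbols contribute no site.
#'
#' @param cds Character vector (or list) of in-frame CDS nucleotide strings.
#' @inheritParams classifyCodonPosition
#' @return List with `gc` (fraction), `n_sites` (pooled fourfold third
#'   positions) and `n_skipped` (malformed CDSs dropped).
#' @examples
#' gcAt4FDS("GGGGGC")  # gc = 1, n_sites = 2
#' @export
gcAt4FDS <- function(cds, table = "11") {
  pooled <- .pooledCodons(cds, table)
  deg <- .degeneracyTable(table)
  codons <- pooled$codons
  clean <- codons[!is.na(codons) & grepl("^[ACGT]{3}$", codons)]
  four <- clean[deg$classes[clean, 3L] == "fourfold"]
  if (length(four) == 0L)
    stop("undefined composition: no fourfold degenerate sites in the CDS set",
         call. = FALSE)
  third <- substr(four, 3L, 3L)
  list(gc = sum(third %in% c("G", "C")) / length(third),
       n_sites = length(third), n_skipped = pooled$n_skipped)
}

#' GC content at zerofold redundant sites
#'
#' By default implements the operational definition: the second nucleotides of
#' all codons except stop codons, pooled across the CDS set. With
#' `strictZerofold = TRUE` the site set is instead the degeneracy-computed one
#' (second positions classified zerofold), for sensitivity analysis.
#'
#' @inheritParams gcAt4FDS
#' @param strictZerofold Use degeneracy-computed zerofold second positions
#'   instead of all non-stop second positions.
#' @return List with `gc`, `n_sites`, `n_skipped` as in [gcAt4FDS()].
#' @examples
#' gcAtZRS("ATGGGA")  # second bases T, G -> gc = 0.5
#' @export
gcAtZRS <- function(cds, table = "11", strictZerofold = FALSE) {
  pooled <- .pooledCodons(cds, table)
  deg <- .degeneracyTable(table)
  codons <- pooled$codons
  clean <- codons[grepl("^[ACGT]{3}$", codons)]
  clean <- clean[!(clean %in% deg$stops)]
  if (strictZerofold) clean <- clean[deg$classes[clean, 2L] == "zerofold"]
  if (length(clean) == 0L)
    stop("undefined composition: no zerofold redundant sites in the CDS set",
         call. = FALSE)
  second <- substr(clean, 2L, 2L)
  list(gc = sum(second %in% c("G", "C")) / length(second),
       n_sites = length(second), n_skipped = pooled$n_skipped)
}

#' Orthologue distance-ratio filter
#'
#' Screens a putative orthologue pair using an outgroup reference: with
#' ingroup-ingroup distance `dInIn` and the two ingroup-outgroup distances,
#' ratio 1 = `dInIn / dIn1Out` and ratio 2 = `dInIn / dIn2Out`. The pair is
#' kept when both ratios are at or below the threshold (default 0.8), i.e.
#' when the two ingroup sequences have not diverged anomalously fast relative
#' to the outgroup.
#'
#' @param dInIn Distance between the two ingroup orthologue candidates.
#' @param dIn1Out,dIn2Out Distances from each ingroup sequence to the
#'   outgroup orthologue.
#' @param threshold Ratio threshold; boundary values are kept.
#' @return Logical: keep (`TRUE`) or discard; attribute `reason` explains a
#'   discard.
#' @examples
#' orthologRatioFilter(0.1, 0.5, 0.5)  # TRUE
#' @export
orthologRatioFilter <- function(dInIn, dIn1Out, dIn2Out, threshold = 0.8) {
  stopifnot(dInIn >= 0, dIn1Out >= 0, dIn2Out >= 0)
  if (dIn1Out == 0 || dIn2Out == 0) {
    message("orthologRatioFilter: zero outgroup distance, pair discarded")
    out <- FALSE
    attr(out, "reason") <- "zero outgroup distance"
    return(out)
  }
  r1 <- dInIn / dIn1Out
  r2 <- dInIn / dIn2Out
  keep <- (r1 <= threshold) && (r2 <= threshold)
  if (!keep) attr(keep, "reason") <-
      sprintf("ratio1 = %.4f, ratio2 = %.4f exceed threshold %.4f", r1, r2, threshold)
  keep
}

#' Build a GCComposition from per-organism sequences
#'
#' @param organisms Named list; each element is a list with components
#'   `genome` (character vector of genome/contig sequences, optional) and
#'   `cds` (character vector of in-frame CDS sequences, optional). Missing
#'   components yield `NA` fractions with zero site counts.
#' @inheritParams classifyCodonPosition
#' @param strictZerofold Passed to [gcAtZRS()].
#' @return A [GCComposition-class] object.
#' @export
gcComposition <- function(organisms, table = "11", strictZerofold = FALSE) {
  stopifnot(is.list(organisms), !is.null(names(organisms)))
  rows <- lapply(names(organisms), function(id) {
    org <- organisms[[id]]
    gcg <- NA_real_; ng <- 0L
    if (!is.null(org$genome) && length(org$genome)) {
      cnt <- .gcCounts(org$genome)
      if (cnt[["n"]] > 0L) { gcg <- cnt[["gc"]] / cnt[["n"]]; ng <- cnt[["n"]] }
    }
    gc4 <- NA_real_; n4 <- 0L; gcz <- NA_real_; nz <- 0L
    if (!is.null(org$cds) && length(org$cds)) {
      r4 <- tryCatch(gcAt4FDS(org$cds, table), error = function(e) NULL)
      if (!is.null(r4)) { gc4 <- r4$gc; n4 <- r4$n_sites }
      rz <- tryCatch(gcAtZRS(org$cds, table, strictZerofold),
                     error = function(e) NULL)
      if (!is.null(rz)) { gcz <- rz$gc; nz <- rz$n_sites }
    }
    data.frame(organism_id = id, gc_genome = gcg, gc_4fds = gc4, gc_zrs = gcz,
               n_sites_genome = ng, n_sites_4fds = n4, n_sites_zrs = nz,
               stringsAsFactors = FALSE)
  })
  new("GCComposition", table = do.call(rbind, rows))
}

#' Write a GCComposition as TSV
#'
#' Fractions are printed to 6 decimal places.
#'
#' @param x A [GCComposition-class].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeCompositionTSV <- function(x, path) {
  stopifnot(is(x, "GCComposition"))
  tab <- x@table
  for (col in c("gc_genome", "gc_4fds", "gc_zrs"))
    tab[[col]] <- ifelse(is.na(tab[[col]]), NA, sprintf("%.6f", tab[[col]]))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
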