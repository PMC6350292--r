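# End-to-end orchestration: simulated or file-based studies, pairwise
# (Wilcoxon) and PGLS analyses, TSV reports and a JSON run manifest.

.GC_MEASURES <- c("gc_genome", "gc_4fds", "gc_zrs")

#' Simulate a complete comparative study
#'
#' Generates, from one master seed, every input the analysis pipeline needs:
#' a Yule tree, an oxygen-state history with a controlled number of
#' transitions, per-organism coding sequences whose site-class GC targets
#' carry a preset-dependent aerobiosis effect, 16S-like pairwise identities,
#' and annotation-gene counts. The presets encode the study conditions:
#' `"null"` (no aerobiosis effect), `"shift"` (one common upward GC shift in
#' all aerobic organisms) and `"graded"` (effect ordered obligate aerobe >
#' aerobe > anaerobe > obligate anaerobe).
#'
#' @param nTips Number of organisms (default 40).
#' @param nTransitions Oxygen-requirement transitions on the tree (default 8,
#'   a small number relative to the tree, as in real prokaryote phylogenies).
#' @param preset `"null"`, `"shift"` or `"graded"`.
#' @param nCodons Codons per simulated CDS (default 400).
#' @param seed Master integer seed.
#' @return List with `tree`, `states` (detailed), `merged`, `compositions`
#'   ([GCComposition-class]), `traits` (data.frame for [runPGLSAnalysis()]),
#'   `annotationCounts`, `identities`, and `ground_truth`.
#' @export
simulateStudy <- function(nTips = 40L, nTransitions = 8L,
                          preset = c("null", "shift", "graded"),
                          nCodons = 400L, seed = 1L) {
  preset <- match.arg(preset)
  tree <- simulateTree(nTips, birthRate = 1, seed = seed)
  merged <- simulateOxygenStates(tree, nTransitions, seed = seed)
  effect <- switch(preset,
    null = c(obligate_anaerobe = 0, anaerobe = 0, aerobe = 0,
             obligate_aerobe = 0),
    shift = c(obligate_anaerobe = 0, anaerobe = 0, aerobe = 0.15,
              obligate_aerobe = 0.15),
    graded = c(obligate_anaerobe = 0, anaerobe = 0.02, aerobe = 0.06,
               obligate_aerobe = 0.12))
  .withSeed(.streamSeed(seed, "study"), {
    tips <- tree$tip.label
    obligate <- sample(c(TRUE, FALSE), nTips, replace = TRUE)
    states <- ifelse(merged == "aerobic",
                     ifelse(obligate, "obligate_aerobe", "aerobe"),
                     ifelse(obligate, "obligate_anaerobe", "anaerobe"))
    names(states) <- tips
    base4 <- 0.45; baseZ <- 0.40
    noise <- rnorm(nTips, 0, 0.02)
    t4 <- pmin(0.95, pmax(0.05, base4 + effect[states] + noise))
    tz <- pmin(0.95, pmax(0.05, baseZ + effect[states] / 2 + noise))
    cdsSeeds <- sample.int(2^20, nTips)
    organisms <- setNames(lapply(seq_len(nTips), function(i) {
      cds <- generateCDS(nCodons, t4[i], tz[i], seed = cdsSeeds[i])
      list(genome = as.character(cds), cds = as.character(cds))
    }), tips)
    annotationCounts <- setNames(sample(1000:5000, nTips, replace = TRUE), tips)
    idm <- matrix(NA_real_, nTips, nTips, dimnames = list(tips, tips))
    vals <- runif(nTips * (nTips - 1) / 2, 85, 100)
    idm[lower.tri(idm)] <- vals
    idm[upper.tri(idm)] <- t(idm)[upper.tri(idm)]
    diag(idm) <- 100
    compositions <- gcComposition(organisms)
    traits <- compositionTable(compositions)
    traits$oxygen_state <- unname(states[traits$organism_id])
    list(tree = tree, states = states, merged = merged,
         compositions = compositions, traits = traits,
         annotationCounts = annotationCounts, identities = idm,
         ground_truth = list(preset = preset, effect = effect, seed = seed,
                             nTransitions = nTransitions))
  })
}

#' Pairwise aerobe-anaerobe comparison of GC content
#'
#' Extracts phylogenetically independent pairs (in each requested
#' representative mode), optionally filters them by 16S identity thresholds,
#' and runs a two-tailed Wilcoxon signed-rank test on the per-pair GC
#' differences (aerobic minus anaerobic) for each GC measure. Scatter data
#' follow the diagonal convention: a point above the diagonal is a pair in
#' which the anaerobe has the higher GC content.
#'
#' @param tree Rooted `ape::phylo`.
#' @param states Named oxygen states for all tips (detailed or merged).
#' @param compositions A [GCComposition-class] covering the paired tips.
#' @param annotationCounts,identities Passed to
#'   [extractIndependentPairs()].
#' @param modes Representative modes to run (default both).
#' @param thresholds 16S identity thresholds in percent (default 0 = no
#'   filtering).
#' @param outDir Optional directory for TSV reports and a JSON manifest.
#' @return List with `results` (one row per mode x threshold x measure),
#'   `pairs` (list of [OxygenPairSet-class] per mode) and `scatter`.
#' @export
runPairwiseAnalysis <- function(tree, states, compositions,
                                annotationCounts = NULL, identities = NULL,
                                modes = c("slow", "fast"), thresholds = 0,
                                outDir = NULL) {
  stopifnot(is(compositions, "GCComposition"))
  comp <- compositionTable(compositions)
  rownames(comp) <- comp$organism_id
  resRows <- list(); scatterRows <- list(); pairSets <- list()
  for (mode in modes) {
    pairs <- extractIndependentPairs(tree, states, mode, annotationCounts,
                                     identities)
    if (length(pairs) < 2L)
      stop(sprintf("insufficient pairs: %d found in mode '%s' (need >= 2)",
                   length(pairs), mode), call. = FALSE)
    pairSets[[mode]] <- pairs
    for (thr in thresholds) {
      kept <- filterPairsByIdentity(pairs, thr)
      p <- pairTable(kept)
      for (measure in .GC_MEASURES) {
        gcA <- comp[p$aerobic_tip, measure]
        gcN <- comp[p$anaerobic_tip, measure]
        ok <- !is.na(gcA) & !is.na(gcN)
        if (sum(ok) < 2L) next
        test <- wilcoxonSignedRank(gcA[ok] - gcN[ok])
        resRows[[length(resRows) + 1L]] <- data.frame(
          mode = mode, identity_threshold = thr, measure = measure,
          n_pairs = sum(ok), n_anaerobe_higher = sum(gcN[ok] > gcA[ok]),
          statistic = unname(test$statistic), p = test$p.value,
          method = sub("^Wilcoxon signed-rank test, ", "", test$method),
          stringsAsFactors = FALSE)
        if (thr == min(thresholds))
          scatterRows[[length(scatterRows) + 1L]] <- data.frame(
            mode = mode, event_id = p$event_id[ok], measure = measure,
            aerobic_tip = p$aerobic_tip[ok], anaerobic_tip = p$anaerobic_tip[ok],
            gc_aerobic = gcA[ok], gc_anaerobic = gcN[ok],
            stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, resRows)
  scatter <- do.call(rbind, scatterRows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(results, file.path(outDir, "pairwise_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scatter, file.path(outDir, "pairwise_scatter.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (mode in names(pairSets))
      write.table(pairTable(pairSets[[mode]]),
                  file.path(outDir, sprintf("pairs_%s.tsv", mode)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = results, pairs = pairSets, scatter = scatter)
}

#' PGLS regression of GC content on oxygen-requirement codes
#'
#' For each requested contrast and each GC measure, encodes the ordinal 2/3
#' oxygen codes, prunes the tree to the organisms in the contrast,
#' log-transforms GC content (percent scale, natural log) and fits a PGLS
#' regression, reporting lambda, slope, two-tailed p and n per cell.
#' Contrasts with fewer than 3 usable organisms, or with organisms on only
#' one side, are skipped with a warning.
#'
#' @param tree Rooted `ape::phylo` covering all trait-table organisms.
#' @param traits data.frame with columns `organism_id`, `oxygen_state` and
#'   the GC measures `gc_genome`, `gc_4fds`, `gc_zrs` (fractions; `NA`
#'   allowed).
#' @param contrasts Character vector of contrast names from
#'   [oxygenContrasts()] (default all seven).
#' @param measures GC measure columns to analyse.
#' @param lambda `"ML"`, `"REML"` or a fixed value in `[0, 1]`.
#' @param logGC Log-transform GC (percent scale, natural log) before
#'   fitting (default TRUE).
#' @param outDir Optional directory for the TSV report and JSON manifest.
#' @return data.frame with one row per contrast x measure: `contrast`,
#'   `measure`, `n`, `lambda`, `slope`, `p`.
#' @export
runPGLSAnalysis <- function(tree, traits, contrasts = names(oxygenContrasts()),
                            measures = .GC_MEASURES, lambda = "ML",
                            logGC = TRUE, outDir = NULL) {
  stopifnot(all(c("organism_id", "oxygen_state") %in% names(traits)))
  missing <- setdiff(traits$organism_id, tree$tip.label)
  if (length(missing))
    stop("organism(s) absent from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  states <- setNames(traits$oxygen_state, traits$organism_id)
  rows <- list()
  for (ct in contrasts) {
    codes <- tryCatch(encodeOxygen(states, ct), error = function(e) NULL)
    if (is.null(codes)) {
      warning(sprintf("contrast '%s' skipped: one side is empty", ct),
              call. = FALSE)
      next
    }
    for (measure in measures) {
      gc <- setNames(traits[[measure]], traits$organism_id)[names(codes)]
      use <- names(codes)[!is.na(gc) & gc > 0]
      if (length(use) < 3L || length(unique(codes[use])) < 2L) {
        warning(sprintf("contrast '%s', measure '%s' skipped: n < 3 or one-sided",
                        ct, measure), call. = FALSE)
        next
      }
      sub <- ape::keep.tip(tree, use)
      C <- brownianCovariance(sub)
      y <- if (logGC) logTransformGC(gc[use]) else gc[use]
      fit <- pglsFit(y, codes[use], C, lambda = lambda)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct, measure = measure, n = fit@n,
        lambda = lambdaHat(fit), slope = coef(fit)[["slope"]],
        p = fit@pValue[["slope"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(out, file.path(outDir, "pgls_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run a complete study from a configuration
#'
#' The configuration is a list (or path to a YAML file) with exactly one of:
#' \describe{
#'   \item{`preset`}{Name of a simulation preset for [simulateStudy()]
#'     (`"null"`, `"shift"`, `"graded"`), with optional `n_tips`,
#'     `n_transitions`, `n_codons`.}
#'   \item{`inputs`}{List of file paths: `tree` (rooted Newick), `traits`
#'     (TSV with organism_id, oxygen_state, optional annotation_count) and
#'     `compositions` (TSV as written by [writeCompositionTSV()]).}
#' }
#' plus optional `seed`, `modes`, `thresholds`, `contrasts`, `lambda` and
#' `out_dir`. Runs the pairwise and the PGLS analysis on the same
#' composition records and writes TSV reports plus a JSON manifest.
#'
#' @param config List or path to a YAML file.
#' @return List with `pairwise`, `pgls` and the resolved `config`.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (sum(c("preset", "inputs") %in% names(config)) != 1L)
    stop("config must set exactly one of 'preset' or 'inputs'", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  modes <- if (is.null(config$modes)) c("slow", "fast") else config$modes
  thresholds <- if (is.null(config$thresholds)) 0 else as.numeric(config$thresholds)
  contrasts <- if (is.null(config$contrasts)) names(oxygenContrasts())
               else config$contrasts
  lambda <- if (is.null(config$lambda)) "ML" else config$lambda
  outDir <- config$out_dir

  if (!is.null(config$preset)) {
    study <- simulateStudy(
      nTips = if (is.null(config$n_tips)) 40L else as.integer(config$n_tips),
      nTransitions = if (is.null(config$n_transitions)) 8L
                     else as.integer(config$n_transitions),
      preset = config$preset,
      nCodons = if (is.null(config$n_codons)) 400L
                else as.integer(config$n_codons),
      seed = seed)
    tree <- study$tree; states <- study$states
    compositions <- study$compositions; traits <- study$traits
    annotationCounts <- study$annotationCounts; identities <- study$identities
  } else {
    paths <- config$inputs
    stopifnot(all(c("tree", "traits", "compositions") %in% names(paths)))
    tree <- ape::read.tree(paths$tree)
    tt <- read.delim(paths$traits, stringsAsFactors = FALSE)
    comp <- read.delim(paths$compositions, stringsAsFactors = FALSE)
    compositions <- new("GCComposition", table = comp)
    states <- setNames(tt$oxygen_state, tt$organism_id)
    annotationCounts <- if ("annotation_count" %in% names(tt))
      setNames(tt$annotation_count, tt$organism_id) else NULL
    identities <- NULL
    traits <- merge(comp, tt[, c("organism_id", "oxygen_state")],
                    by = "organism_id")
  }
  pairwise <- runPairwiseAnalysis(tree, states, compositions,
                                  annotationCounts, identities,
                                  modes = modes, thresholds = thresholds,
                                  outDir = outDir)
  pgls <- runPGLSAnalysis(tree, traits, contrasts = contrasts,
                          lambda = lambda, outDir = outDir)
  if (!is.null(outDir)) {
    manifest <- list(seed = seed, modes = modes, thresholds = thresholds,
                     contrasts = contrasts, lambda = lambda,
                     preset = config$preset, inputs = config$inputs,
                     package = "oxyGC",
                     version = as.character(utils::packageVersion("oxyGC")))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  list(pairwise = pairwise, pgls = pgls, config = config)
}
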