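# Internal helpers shared across modules.

#' @noRd
.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Derive a reproducible sub-seed for a named pseudo-random stream, so the
# generators can be re-run independently from one master seed. Kept below
# 2^31 - 1 (R integers are 32-bit).
#' @noRd
.streamSeed <- function(seed, stream) {
  .assertScalarNumber(seed, "seed")
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes)) %% 99991
  as.integer((abs(seed) * 48271 + offset) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
#' @noRd
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Split sequences into uppercase character matrices / vectors.
#' @noRd
.charVec <- function(s) {
  if (inherits(s, "XString") || inherits(s, "XStringSet")) s <- as.character(s)
  strsplit(toupper(as.character(s)), "", fixed = TRUE)[[1L]]
}

#' Read a FASTA file as a named character vector
#'
#' Thin convenience wrapper around [Biostrings::readDNAStringSet()] returning
#' plain uppercase character strings named by the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a (multi-)FASTA file of nucleotide sequences.
#' @return Named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1L), 1L)
  out
}
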