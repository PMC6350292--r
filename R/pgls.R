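# Phylogenetic generalized least squares with Pagel's lambda.
#
# Under Brownian motion on a rooted tree, a trait's covariance between two
# tips equals the shared root-to-MRCA path length; Pagel's lambda scales the
# off-diagonal (shared-history) part of that matrix, interpolating between
# pure Brownian structure (lambda = 1) and phylogenetic independence
# (lambda = 0). GLS with this covariance gives slope and intercept estimates
# that account for the similar residuals produced by shared ancestry.

#' Brownian covariance matrix of a rooted tree
#'
#' `C[i, j]` is the root-to-MRCA path length of tips i and j; the diagonal
#' holds root-to-tip path lengths. Zero-length terminal branches receive a
#' 1e-8 jitter (reported) so that `C` stays positive definite.
#'
#' @param tree Rooted `ape::phylo` with non-negative branch lengths and
#'   >= 3 tips.
#' @return Symmetric positive-semidefinite matrix labelled by tip.
#' @export
brownianCovariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) stop("need >= 3 tips", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted before computing a Brownian covariance; ",
         "root it explicitly (e.g. with an outgroup)", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  terminal <- tree$edge[, 2L] <= length(tree$tip.label)
  zero <- terminal & tree$edge.length == 0
  if (any(zero)) {
    message(sprintf("brownianCovariance: %d zero-length terminal branch(es) jittered by 1e-8",
                    sum(zero)))
    tree$edge.length[zero] <- 1e-8
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Value in `[0, 1]`.
#' @return Transformed matrix.
#' @export
lambdaTransform <- function(C, lambda) {
  .assertScalarNumber(lambda, "lambda")
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# One GLS fit at a fixed lambda. Returns estimates plus both the ML and REML
# log-likelihoods of the Gaussian model y ~ N(X beta, sigma2 * C(lambda)).
#' @noRd
.glsAtLambda <- function(y, X, C, lambda) {
  Cl <- lambdaTransform(C, lambda)
  U <- tryCatch(chol(Cl), error = function(e)
    stop(sprintf("C(lambda) is not positive definite (condition number %.3g): %s",
                 kappa(Cl), conditionMessage(e)), call. = FALSE))
  # Whiten with L^{-1} where C = L L' and L = t(U).
  wX <- backsolve(U, X, transpose = TRUE)
  wy <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(wX)
  beta <- drop(solve(XtX, crossprod(wX, wy)))
  resid <- drop(wy - wX %*% beta)
  rss <- sum(resid^2)
  n <- length(y); p <- ncol(X)
  logDetC <- 2 * sum(log(diag(U)))
  s2ml <- rss / n
  llML <- -0.5 * (n * log(2 * pi * s2ml) + n + logDetC)
  s2reml <- rss / (n - p)
  llREML <- -0.5 * ((n - p) * log(2 * pi * s2reml) + (n - p) + logDetC +
                      determinant(XtX, logarithm = TRUE)$modulus[[1L]])
  list(beta = beta, rss = rss, XtXinv = solve(XtX), llML = llML,
       llREML = llREML)
}

#' Phylogenetic generalized least squares fit
#'
#' Fits `y = b0 + b1 * x` by GLS with covariance `sigma2 * C(lambda)`.
#' `lambda` may be fixed, or profiled out by maximising the multivariate
#' normal log-likelihood (`"ML"`, the default) or the restricted likelihood
#' (`"REML"`) over `[0, 1]` by bounded scalar optimisation (tolerance 1e-6).
#' Standard errors use `sigma2_hat = RSS_C / (n - 2)`; the slope test is a t
#' test on `n - 2` degrees of freedom, two-tailed.
#'
#' @param y Named numeric response (e.g. log GC content).
#' @param x Named numeric predictor (e.g. oxygen codes 2/3). Names of `y`,
#'   `x` and `C` must agree; vectors are aligned to the row order of `C`.
#' @param C Phylogenetic covariance from [brownianCovariance()].
#' @param lambda `"ML"`, `"REML"`, or a fixed numeric value in `[0, 1]`.
#' @return A [PGLSFit-class].
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' C <- brownianCovariance(tr)
#' y <- c(a = 1.2, b = 0.8, c = 2.1, d = 1.9)
#' x <- c(a = 2, b = 2, c = 3, d = 3)
#' pglsFit(y, x, C, lambda = 1)
#' @export
pglsFit <- function(y, x, C, lambda = "ML") {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  labs <- rownames(C)
  if (!is.null(labs) && !is.null(names(y))) {
    if (!setequal(names(y), labs) || !setequal(names(x), labs))
      stop("names of y/x do not match the covariance labels", call. = FALSE)
    y <- y[labs]; x <- x[labs]
  }
  n <- length(y)
  stopifnot(length(x) == n, nrow(C) == n)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (var(x) == 0)
    stop("degenerate design: predictor is constant", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))

  if (is.numeric(lambda)) {
    lam <- lambda
    mode <- "fixed"
    fit <- .glsAtLambda(y, X, C, lam)
    ll <- fit$llML
  } else {
    mode <- match.arg(lambda, c("ML", "REML"))
    objective <- function(l) {
      f <- .glsAtLambda(y, X, C, l)
      if (mode == "ML") f$llML else f$llREML
    }
    opt <- optimize(objective, c(0, 1), maximum = TRUE, tol = 1e-6)
    # optimize never evaluates the exact endpoints; take the best of the
    # interior optimum and the two boundaries so lambda-hat can reach 0 or 1.
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, objective(0), objective(1))
    lam <- cand[which.max(vals)]
    fit <- .glsAtLambda(y, X, C, lam)
    ll <- if (mode == "ML") fit$llML else fit$llREML
  }
  df <- n - 2L
  s2 <- fit$rss / df
  se <- sqrt(s2 * diag(fit$XtXinv))
  tv <- fit$beta / se
  pv <- 2 * pt(-abs(tv), df)
  new("PGLSFit",
      coefficients = setNames(fit$beta, c("(Intercept)", "slope")),
      se = setNames(se, c("(Intercept)", "slope")),
      tValue = setNames(tv, c("(Intercept)", "slope")),
      pValue = setNames(pv, c("(Intercept)", "slope")),
      lambda = lam, lambdaMode = mode, n = as.integer(n),
      logLik = ll, sigma2 = s2)
}

#' The seven oxygen-requirement contrasts
#'
#' Named list of contrasts between oxygen-requirement groups. In each
#' contrast the `high` group is coded 3 (more oxygen-preferring) and the
#' `low` group 2; organisms outside the two groups are dropped.
#'
#' @return Named list with elements `high` and `low` (detailed state names).
#' @export
oxygenContrasts <- function() {
  list(
    aerobes_obligate_aerobes_vs_anaerobes_obligate_anaerobes = list(
      high = c("aerobe", "obligate_aerobe"),
      low = c("anaerobe", "obligate_anaerobe")),
    aerobes_vs_anaerobes = list(high = "aerobe", low = "anaerobe"),
    obligate_aerobes_vs_obligate_anaerobes = list(
      high = "obligate_aerobe", low = "obligate_anaerobe"),
    obligate_aerobes_vs_anaerobes = list(high = "obligate_aerobe",
                                         low = "anaerobe"),
    obligate_aerobes_vs_aerobes = list(high = "obligate_aerobe",
                                       low = "aerobe"),
    aerobes_vs_obligate_anaerobes = list(high = "aerobe",
                                         low = "obligate_anaerobe"),
    anaerobes_vs_obligate_anaerobes = list(high = "anaerobe",
                                           low = "obligate_anaerobe"))
}

#' Encode oxygen requirement as ordinal 2/3 codes for one contrast
#'
#' @param states Named character vector of detailed oxygen states (aerobe,
#'   anaerobe, obligate_aerobe, obligate_anaerobe; spaces tolerated).
#' @param contrast Name of a contrast from [oxygenContrasts()], or a list
#'   with components `high` and `low`.
#' @return Named numeric vector of codes (3 = more oxygen-preferring group,
#'   2 = less) over the organisms belonging to the contrast.
#' @export
encodeOxygen <- function(states, contrast) {
  if (is.character(contrast)) {
    all <- oxygenContrasts()
    if (!contrast %in% names(all))
      stop("unknown contrast '", contrast, "'", call. = FALSE)
    contrast <- all[[contrast]]
  }
  s <- gsub("[ -]+", "_", tolower(trimws(states)))
  names(s) <- names(states)
  hi <- names(s)[s %in% contrast$high]
  lo <- names(s)[s %in% contrast$low]
  if (length(hi) == 0L || length(lo) == 0L)
    stop("empty group: contrast requires organisms on both sides", call. = FALSE)
  setNames(c(rep(3, length(hi)), rep(2, length(lo))), c(hi, lo))
}

#' Log-transform a GC fraction
#'
#' Natural log of GC content on the percent scale, `log(100 * gc)`; a log10
#' or proportion-scale variant is available (changing base or scale rescales
#' or shifts the regression slope/intercept but leaves signs and p values
#' unchanged).
#'
#' @param gc GC fraction(s) in `(0, 1]`.
#' @param base Logarithm base (default natural).
#' @param percent Multiply by 100 before logging (default TRUE).
#' @return Transformed value(s).
#' @examples
#' logTransformGC(0.5)  # log(50)
#' @export
logTransformGC <- function(gc, base = exp(1), percent = TRUE) {
  if (any(!is.na(gc) & gc <= 0))
    stop("domain error: GC content must be positive to log-transform",
         call. = FALSE)
  log(if (percent) 100 * gc else gc, base = base)
}
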