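test_that("Brownian covariance equals shared path lengths", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  C <- brownianCovariance(tr)
  expect_equal(C["a", "b"], 1)
  expect_equal(C["a", "c"], 0)
  expect_equal(C["a", "a"], 2)
  # star tree: identity
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1):0;")
  expect_equal(unname(brownianCovariance(star)), diag(5))
  # comb tree matches the brute-force MRCA-path oracle
  comb <- ape::read.tree(text = "((((a:1,b:2):1,c:3):1,d:4):1,e:5);")
  expect_equal(brownianCovariance(comb), oracleBrownianCovariance(comb))
  expect_error(brownianCovariance(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("lambda transform scales only the off-diagonal", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  C <- brownianCovariance(tr)
  expect_equal(lambdaTransform(C, 1), C)
  expect_equal(lambdaTransform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  expect_equal(lambdaTransform(C, 0.5)["a", "b"], 0.5)
  expect_equal(diag(lambdaTransform(C, 0.5)), diag(C))
  expect_error(lambdaTransform(C, 1.2), "lambda")
})

test_that("GLS reduces to OLS when the covariance is proportional to I", {
  set.seed(5)
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:30), collapse = ","), "):0;"))
  C <- brownianCovariance(star)
  y <- setNames(rnorm(30), star$tip.label)
  x <- setNames(sample(c(2, 3), 30, replace = TRUE), star$tip.label)
  fit <- pglsFit(y, x, C, lambda = 1)
  ols <- summary(lm(y ~ x))
  expect_equal(coef(fit)[["slope"]], ols$coefficients["x", "Estimate"],
               tolerance = 1e-8)
  expect_equal(fit@se[["slope"]], ols$coefficients["x", "Std. Error"],
               tolerance = 1e-8)
  expect_equal(fit@pValue[["slope"]], ols$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-8)
  # lambda = 0 on an ultrametric tree also reproduces OLS
  tr <- simulateTree(30, 1, 2)
  C2 <- brownianCovariance(tr)
  y2 <- setNames(rnorm(30), tr$tip.label)
  x2 <- setNames(sample(c(2, 3), 30, replace = TRUE), tr$tip.label)
  fit0 <- pglsFit(y2, x2, C2, lambda = 0)
  ols2 <- summary(lm(y2[tr$tip.label] ~ x2[tr$tip.label]))
  expect_equal(coef(fit0)[["slope"]], ols2$coefficients[2, "Estimate"],
               tolerance = 1e-8)
  expect_equal(fit0@pValue[["slope"]], ols2$coefficients[2, "Pr(>|t|)"],
               tolerance = 1e-8)
})

test_that("PGLS agrees with nlme::gls under corPagel at fixed lambda", {
  skip_if_not_installed("nlme")
  tr <- simulateTree(40, 1, 8)
  st <- simulateOxygenStates(tr, 4, 8)
  y <- simulateGCTrait(tr, st, intercept = 2, slope = 1, sigma2 = 0.5,
                       lambda = 0.7, seed = 8)
  x <- attr(y, "ground_truth")$x
  C <- brownianCovariance(tr)
  dat <- data.frame(y = as.numeric(y[tr$tip.label]),
                    x = as.numeric(x[tr$tip.label]),
                    row.names = tr$tip.label)
  for (lam in c(0.3, 0.7, 1)) {
    fit <- pglsFit(y, x, C, lambda = lam)
    # data rows are ordered as tr$tip.label, which is what corPagel assumes
    ref <- suppressWarnings(
      nlme::gls(y ~ x, data = dat,
                correlation = ape::corPagel(lam, tr, form = ~1, fixed = TRUE),
                method = "ML"))
    rs <- summary(ref)$tTable
    expect_equal(coef(fit)[["slope"]], unname(coef(ref)["x"]),
                 tolerance = 1e-6, label = paste("slope at lambda", lam))
    expect_equal(fit@se[["slope"]], unname(rs["x", "Std.Error"]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate PGLS inputs raise informative errors", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  C <- brownianCovariance(tr)
  y <- c(a = 1, b = 2, c = 3, d = 4)
  expect_error(pglsFit(y, c(a = 2, b = 2, c = 2, d = 2), C, lambda = 1),
               "degenerate design")
  expect_error(pglsFit(y[1:3], c(a = 2, b = 3, c = 2), C, lambda = 1))
})

test_that("zero-length terminal branches are jittered, not fatal", {
  tr <- ape::read.tree(text = "((a:0,b:1):1,(c:1,d:1):1);")
  expect_message(C <- brownianCovariance(tr), "jittered")
  expect_true(all(eigen(lambdaTransform(C, 1), only.values = TRUE)$values > 0))
})

test_that("oxygen encoding follows the seven contrasts", {
  states <- c(o1 = "obligate_aerobe", o2 = "obligate_aerobe",
              o3 = "obligate_anaerobe", o4 = "obligate_anaerobe",
              o5 = "obligate_anaerobe", o6 = "aerobe", o7 = "anaerobe")
  codes <- encodeOxygen(states, "obligate_aerobes_vs_obligate_anaerobes")
  expect_equal(sort(unname(codes)), c(2, 2, 2, 3, 3))
  expect_setequal(names(codes), paste0("o", 1:5))  # aerobe/anaerobe dropped
  codes2 <- encodeOxygen(states, "obligate_aerobes_vs_anaerobes")
  expect_false("o6" %in% names(codes2))  # plain aerobe excluded
  expect_error(encodeOxygen(states[6:7],
                            "obligate_aerobes_vs_obligate_anaerobes"),
               "empty group")
  expect_length(oxygenContrasts(), 7L)
})

test_that("GC log transform uses the percent scale", {
  expect_equal(logTransformGC(1), log(100))
  expect_equal(logTransformGC(0.5), log(50))
  expect_equal(logTransformGC(0.5, base = 10), log10(50))
  expect_error(logTransformGC(0), "domain error")
})

test_that("positive simulated aerobiosis effects give positive slopes", {
  tr <- simulateTree(80, 1, 13)
  st <- simulateOxygenStates(tr, 6, 13)
  skip_if(length(unique(st)) < 2)
  y <- simulateGCTrait(tr, st, intercept = 1, slope = 4, sigma2 = 0.5,
                       lambda = 1, seed = 13)
  fit <- pglsFit(y, attr(y, "ground_truth")$x, brownianCovariance(tr),
                 lambda = "ML")
  expect_gt(coef(fit)[["slope"]], 0)
  expect_equal(sign(fit@tValue[["slope"]]), sign(coef(fit)[["slope"]]))
})

test_that("ML lambda is recovered at both ends of its range", {
  # data simulated at lambda = 1 should estimate near 1; at lambda = 0 near 0
  nRep <- 60
  hit1 <- 0L; hit0 <- 0L; used <- 0L
  for (i in seq_len(nRep)) {
    tr <- simulateTree(150, 1, 300 + i)
    st <- simulateOxygenStates(tr, 5, 300 + i)
    if (length(unique(st)) < 2) next
    used <- used + 1L
    C <- brownianCovariance(tr)
    x <- setNames(ifelse(st == "aerobic", 3, 2), names(st))
    y1 <- simulateGCTrait(tr, st, 0, 1, 1, 1, seed = 300 + i)
    f1 <- pglsFit(y1, x, C, lambda = "ML")
    if (lambdaHat(f1) >= 0.9) hit1 <- hit1 + 1L
    y0 <- simulateGCTrait(tr, st, 0, 1, 1, 0, seed = 700 + i)
    f0 <- pglsFit(y0, x, C, lambda = "ML")
    if (lambdaHat(f0) <= 0.1) hit0 <- hit0 + 1L
  }
  expect_gte(hit1 / used, 0.9)
  expect_gte(hit0 / used, 0.9)
})
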