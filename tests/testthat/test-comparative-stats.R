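test_that("model-space enumeration matches its combinatorial definition", {
  p1 <- enumerateModelSubsets(1)
  expect_length(p1, 2430)
  p2 <- enumerateModelSubsets(2)
  expect_length(p2, 728)
  # every reduced spec drops the population effect and all slopes
  for (pair in p1[c(1, 500, 2430)]) {
    expect_true(pair$full$include_population)
    expect_false(pair$reduced$include_population)
    expect_false(any(pair$reduced$groups == 2L))
    expect_identical(pair$full$groups >= 1L, pair$reduced$groups >= 1L)
  }
  # interaction only ever appears together with both main effects
  fixed <- unique(lapply(p1, function(p) p$full$fixed))
  for (f in fixed) if ("h:L" %in% f) expect_true(all(c("h", "L") %in% f))
})

test_that("association fit reduces to OLS without group variance", {
  set.seed(41)
  n <- 120
  d <- data.frame(log_pop = rnorm(n), family = sample(LETTERS[1:4], n, TRUE),
                  corpus = "c1", macro_area = "m1", country = "c",
                  script = "s", language = paste0("L", 1:n))
  d$difficulty <- -0.3 * d$log_pop + rnorm(n)  # no group effects at all
  spec <- enumerateModelSubsets(1)[[1]]$full
  spec$groups[] <- 0L; spec$groups["family"] <- 1L
  fit <- fitAssociationLmer(d, spec)
  ols <- lm(difficulty ~ log_pop, data = d)
  expect_lt(abs(fit$beta - coef(ols)[2]), 2 * fit$se)
})

test_that("the population coefficient is estimated consistently under grouping", {
  set.seed(42)
  hits <- replicate(50, {
    n <- 200
    fam <- sample(paste0("F", 1:8), n, TRUE)
    fam_e <- rnorm(8, 0, 0.4)
    d <- data.frame(log_pop = rnorm(n), family = fam, corpus = "c1",
                    macro_area = "m1", country = "c", script = "s",
                    language = paste0("L", 1:n))
    d$difficulty <- -0.3 * d$log_pop + fam_e[as.integer(factor(fam))] + rnorm(n)
    spec <- enumerateModelSubsets(1)[[1]]$full
    spec$groups[] <- 0L; spec$groups["family"] <- 1L
    fit <- fitAssociationLmer(d, spec)
    rs <- enumerateModelSubsets(1)[[1]]$reduced
    rs$groups[] <- 0L
    rs$groups["family"] <- 1L
    red <- fitAssociationLmer(d, rs)
    c(cover = abs(fit$beta + 0.3) < 1.96 * fit$se,
      aic_pref = fit$aic < red$aic)
  })
  expect_gte(mean(hits["cover", ]), 0.9)
  expect_gte(mean(hits["aic_pref", ]), 0.95)
})

test_that("delta-AIC verdicts follow the aptness rules", {
  mk <- function(aic, conv = TRUE)
    structure(list(beta = 0, se = 1, aic = aic, converged = conv),
              class = "assoc_fit")
  r <- deltaAicCompare(mk(100), mk(110))
  expect_equal(r$delta_aic, 10)
  expect_identical(r$verdict, "full")
  expect_identical(deltaAicCompare(mk(100), mk(NA, FALSE))$verdict, "full")
  expect_identical(deltaAicCompare(mk(100), mk(100))$verdict, "reduced")
  expect_identical(deltaAicCompare(mk(105), mk(100))$verdict, "reduced")
  expect_true(is.na(deltaAicCompare(mk(NA, FALSE), mk(NA, FALSE))$verdict))
})

test_that("FMA weights follow the AIC-exponential formula", {
  mk <- function(beta, aic, conv = TRUE)
    structure(list(beta = beta, se = 1, aic = aic, converged = conv),
              class = "assoc_fit")
  one <- fmaEstimate(list(mk(-0.05, 123)))
  expect_equal(one$beta_fma, -0.05)
  expect_equal(one$weights, 1)
  sym <- fmaEstimate(list(mk(0, 50), mk(1, 50)))
  expect_equal(sym$beta_fma, 0.5)
  # hand evaluation: weights prop to exp(0), exp(-1), exp(-2)
  h <- fmaEstimate(list(mk(1, 10), mk(2, 12), mk(3, 14)))
  wref <- exp(-c(0, 1, 2)) / sum(exp(-c(0, 1, 2)))
  expect_equal(unname(h$weights), wref)
  expect_equal(h$beta_fma, sum(wref * 1:3))
  # shift invariance and exclusion of non-converged fits
  h2 <- fmaEstimate(list(mk(1, 1010), mk(2, 1012), mk(3, 1014)))
  expect_equal(h2$beta_fma, h$beta_fma)
  h3 <- fmaEstimate(list(mk(1, 10), mk(2, 12, conv = FALSE)))
  expect_equal(h3$weights[2], 0)
  expect_equal(h3$beta_fma, 1)
  expect_equal(sum(h3$weights), 1)
  expect_error(fmaEstimate(list(mk(1, 10, conv = FALSE))), "no converged")
})

test_that("candidate sets have the documented spline and product structure", {
  set.seed(43)
  n <- 80
  df <- data.frame(corpus = sample(c("c1", "c2"), n, TRUE),
                   family = sample(paste0("F", 1:4), n, TRUE),
                   script = sample(c("s1", "s2"), n, TRUE),
                   macro_area = sample(c("m1", "m2"), n, TRUE),
                   egids = sample(3:7, n, TRUE),
                   latitude = runif(n, -40, 60),
                   longitude = runif(n, -120, 150),
                   h = runif(n, 1, 4), L = runif(n, 1e3, 1e5),
                   range_size = exp(rnorm(n, 10)),
                   distance_to_water = exp(rnorm(n, 3)),
                   altitude = exp(rnorm(n, 5)),
                   climate_pc1 = rnorm(n), climate_pc2 = rnorm(n),
                   n_countries = sample(1:5, n, TRUE))
  small <- buildCandidateSet(df, "small")
  # 7 B-spline columns per coordinate axis: 3 interior knots + degree 3 + 1
  expect_equal(sum(grepl("^lat_bs", colnames(small))), 7)
  expect_equal(sum(grepl("^lon_bs", colnames(small))), 7)
  med <- buildCandidateSet(df, "medium")
  expect_equal(sum(grepl("_x_lon_bs", colnames(med))), 49)
  big <- buildCandidateSet(df, "big")
  expect_true(all(colnames(small) %in% colnames(med)))
  expect_true(all(colnames(med) %in% colnames(big)))
  expect_gt(ncol(big), ncol(med))
  df$latitude <- 5
  expect_warning(buildCandidateSet(df, "small"), "degenerate|constant")
})

test_that("double selection deconfounds and degrades gracefully", {
  set.seed(44)
  n <- 150
  # no candidates -> the simple regression slope
  x <- rnorm(n); y <- -0.3 * x + rnorm(n)
  d0 <- doubleSelection(y, x)
  expect_equal(d0$beta, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
  # a real confounder biases the naive slope; DS removes the bias
  cc <- rnorm(n)
  x2 <- 0.6 * cc + rnorm(n, 0, sqrt(1 - 0.36))
  y2 <- -0.3 * x2 + 1.0 * cc + rnorm(n)
  C <- cbind(conf = cc, matrix(rnorm(n * 10), n,
                               dimnames = list(NULL, paste0("z", 1:10))))
  naive <- coef(lm(y2 ~ x2))[2]
  oracle <- coef(lm(y2 ~ x2 + cc))[2]
  ds <- doubleSelection(y2, x2, C, seed = 44)
  expect_gt(abs(naive - (-0.3)), 0.2)        # visibly biased
  expect_lt(abs(ds$beta - (-0.3)), 2 * ds$se)
  expect_lt(abs(ds$beta - oracle), 0.1)
  expect_true("conf" %in% ds$selected)
  # pure-noise candidates: few selections, slope near the simple one
  set.seed(45)
  sel_sizes <- replicate(20, {
    Z <- matrix(rnorm(n * 8), n)
    d <- doubleSelection(y, x, Z, seed = sample.int(1e6, 1))
    c(length(d$selected), d$beta)
  })
  expect_lte(median(sel_sizes[1, ]), 2)
  expect_lt(abs(median(sel_sizes[2, ]) - d0$beta), 0.05)
})

test_that("Freedman-Lane test behaves at the extremes", {
  set.seed(46)
  n <- 60
  x <- rnorm(n)
  # perfect effect, no controls: the smallest achievable p
  res <- suppressWarnings(freedmanLaneTest(x, x, NULL, n_perm = 99, seed = 1))
  expect_lte(res$p, 1 / 99)
  expect_length(res$permuted, 99)
  expect_warning(freedmanLaneTest(x, x, NULL, n_perm = 50, seed = 1),
                 "coarse")
  # the default permutation count is the full 10,000 of the reference design
  expect_equal(formals(freedmanLaneTest)$n_perm, 10000)
})

test_that("PGLS equals OLS on a star tree and is exact on perfect data", {
  star <- ape::stree(20, "star")
  star$edge.length <- rep(1, 20)
  set.seed(47)
  x <- setNames(rnorm(20), star$tip.label)
  y <- setNames(-0.3 * x + rnorm(20), star$tip.label)
  pg <- fitPGLS(y, x, star)
  expect_equal(pg$beta, unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
  # perfect linear relation
  y2 <- setNames(2 - 0.5 * x, star$tip.label)
  expect_equal(fitPGLS(y2, x, star)$r2, 1, tolerance = 1e-10)
  expect_error(fitPGLS(setNames(1:3, c("t1", "t2", "zzz")),
                       setNames(1:3, c("t1", "t2", "zzz")), star), "zzz")
})

test_that("PGLS agrees with the nlme GLS oracle under Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(48)
  tr <- simulatePhylogeny(30, seed = 48)
  V <- ape::vcv(tr)
  Lc <- t(chol(V))
  x <- setNames(as.vector(Lc %*% rnorm(30)), tr$tip.label)
  y <- setNames(-0.3 * x + as.vector(Lc %*% rnorm(30)), tr$tip.label)
  mine <- fitPGLS(y, x, tr)
  dd <- data.frame(y = y, x = x, sp = names(y))
  ref <- nlme::gls(y ~ x, data = dd,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  expect_equal(mine$beta, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("haversine distances match the closed form and the geosphere oracle", {
  expect_equal(haversineMatrix(c(10, 10), c(20, 20))[1, 2], 0)
  anti <- haversineMatrix(c(0, 0), c(0, 180))
  expect_equal(anti[1, 2], pi * 6371, tolerance = 1e-9)
  set.seed(49)
  lat <- runif(6, -80, 80); lon <- runif(6, -170, 170)
  D <- haversineMatrix(lat, lon)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon[1], lat[1]),
                                  cbind(lon[-1], lat[-1]), r = 6371)
  expect_equal(D[1, -1], ref, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(haversineMatrix(95, 0), "out of range")
})

test_that("inverse-distance weights are row-standardized with capped zeros", {
  d <- matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3)  # a zero off-diagonal distance
  W <- inverseDistanceWeights(d)
  expect_equal(rowSums(W), rep(1, 3))
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0))
  expect_equal(W[2, 3], W[2, 1])  # capped zero equals the smallest distance
})

test_that("the spatial error model nests OLS and ignores unit order", {
  set.seed(50)
  n <- 100
  W1 <- inverseDistanceWeights(as.matrix(dist(cbind(runif(n), runif(n)))))
  W2 <- inverseDistanceWeights(as.matrix(dist(cbind(runif(n), runif(n)))))
  x <- rnorm(n)
  y <- 1 - 0.3 * x + rnorm(n)  # lambda = 0
  s <- fitSAR(y, x, W1, W2)
  ols <- lm(y ~ x)
  expect_lt(abs(s$beta - coef(ols)[2]), 2 * s$se)
  # permuting the unit order leaves the estimate unchanged
  pidx <- sample.int(n)
  s2 <- fitSAR(y[pidx], x[pidx], W1[pidx, pidx], W2[pidx, pidx])
  expect_equal(s2$beta, s$beta, tolerance = 1e-10)
})

test_that("SAR permutation inference flags a perfect association", {
  set.seed(51)
  n <- 60
  W1 <- inverseDistanceWeights(as.matrix(dist(cbind(runif(n), runif(n)))))
  W2 <- inverseDistanceWeights(as.matrix(dist(cbind(runif(n), runif(n)))))
  x <- rnorm(n)
  res <- sarPermutationTest(x, x, W1, W2, n_perm = 99, seed = 2)
  expect_lte(res$p, 1 / 99)
  expect_equal(formals(sarPermutationTest)$n_perm, 10000)
})
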