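#' Enumerate the association model space
#'
#' Builds every candidate mixed-model specification for the
#' difficulty-vs-population analyses, paired full/reduced. A full model always
#' contains the fixed effect of log speaker population size (plus any random
#' slopes for it); its reduced counterpart removes the population fixed effect
#' and all random slopes but is otherwise identical.
#'
#' Study 1: fixed control part from \{none, h, L, h+L, h+L+h:L\}, language
#' random intercept in/out, and each of corpus / family / macro area /
#' country / script absent, intercept-only, or intercept+slope: 5 x 2 x 3^5 =
#' 2430 full specs, 4860 fits counting the reduced partners. Study 2: each of
#' script / macro area / country / family / subfamily / sub-branch in three
#' states, excluding the all-absent configuration: 3^6 - 1 = 728 full specs,
#' 1456 fits.
#'
#' @param study 1 or 2.
#' @return List of pairs; each element is `list(full = spec, reduced = spec)`
#'   where a spec holds `fixed`, `lang_int`, `groups` (named 0/1/2 vector:
#'   absent / intercept / intercept + slope), `include_population`, `study`.
#' @export
enumerateModelSubsets <- function(study = 1) {
  stopifnot(study %in% c(1, 2))
  mkspec <- function(fixed, lang_int, groups, pop, study) {
    list(fixed = fixed, lang_int = lang_int, groups = groups,
         include_population = pop, study = study)
  }
  reduce <- function(spec) {
    spec$include_population <- FALSE
    spec$groups[spec$groups == 2L] <- 1L
    spec
  }
  if (study == 1) {
    fixed_opts <- list(character(0), "h", "L", c("h", "L"), c("h", "L", "h:L"))
    gnames <- c("corpus", "family", "macro_area", "country", "script")
    lang_opts <- c(FALSE, TRUE)
  } else {
    fixed_opts <- list(character(0))
    gnames <- c("script", "macro_area", "country", "family", "subfamily",
                "sub_branch")
    lang_opts <- FALSE
  }
  grid <- as.matrix(expand.grid(rep(list(0:2), length(gnames)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- gnames
  if (study == 2) grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  out <- vector("list", length(fixed_opts) * length(lang_opts) * nrow(grid))
  k <- 0
  for (fo in fixed_opts) for (li in lang_opts) for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    storage.mode(g) <- "integer"
    full <- mkspec(fo, li, g, TRUE, study)
    k <- k + 1
    out[[k]] <- list(full = full, reduced = reduce(full))
  }
  out
}

specFormula <- function(spec) {
  rhs <- character(0)
  if (spec$include_population) rhs <- "log_pop"
  rhs <- c(rhs, spec$fixed)
  if (isTRUE(spec$lang_int)) rhs <- c(rhs, "(1 | language)")
  for (g in names(spec$groups)) {
    s <- spec$groups[[g]]
    if (s >= 1L) rhs <- c(rhs, sprintf("(1 | %s)", g))
    if (s == 2L && spec$include_population)
      rhs <- c(rhs, sprintf("(0 + log_pop | %s)", g))
  }
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste("difficulty ~", paste(rhs, collapse = " + ")))
}

#' Standardize outcome and controls per corpus
#'
#' Subtracts the corpus-specific mean and divides by the corpus-specific
#' standard deviation (a zero standard deviation maps to zero), as applied to
#' the Study-1 outcome `b` and the fixed controls `h` and `L` before model
#' fitting.
#'
#' @param df data.frame with a `corpus` column.
#' @param cols columns to standardize.
#' @export
standardizePerCorpus <- function(df, cols = c("difficulty", "h", "L")) {
  for (cl in intersect(cols, names(df))) {
    df[[cl]] <- stats::ave(df[[cl]], df$corpus, FUN = function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
  }
  df
}

#' Fit one association mixed model
#'
#' Outcome `difficulty` (standardized `b` for Study 1, `mu` for Study 2),
#' fixed effect of natural-log speaker population plus the spec's controls,
#' crossed independent random intercepts and population slopes. Fitted by
#' maximum likelihood with an iteration cap (any solution at the cap is
#' accepted); a singular or failed fit is reported as `converged = FALSE`
#' rather than an error.
#'
#' @param data data.frame with `difficulty`, `log_pop`, the control and
#'   grouping columns named in the spec.
#' @param spec a spec from [enumerateModelSubsets()].
#' @param iter_cap optimizer iteration cap (defaults: 20 for Study 1, 100 for
#'   Study 2, mapped to a function-evaluation budget of `100 * iter_cap`).
#' @return An `assoc_fit`: `beta` (population coefficient, `NA` in reduced
#'   models), `se`, `aic`, `converged`, `spec`.
#' @export
fitAssociationLmer <- function(data, spec, iter_cap = NULL) {
  if (is.null(iter_cap)) iter_cap <- if (spec$study == 1) 20 else 100
  fml <- specFormula(spec)
  has_ranef <- length(lme4::findbars(fml)) > 0
  res <- tryCatch({
    if (has_ranef) {
      fit <- suppressMessages(suppressWarnings(lme4::lmer(
        fml, data = data, REML = FALSE,
        control = lme4::lmerControl(
          optCtrl = list(maxfun = 100 * iter_cap),
          calc.derivs = FALSE,
          check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)))))
      conv <- fit@optinfo$conv$opt == 0 && !lme4::isSingular(fit, tol = 1e-4)
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    } else {
      fit <- stats::lm(fml, data = data)
      conv <- TRUE
      cf <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
    }
    beta <- if (spec$include_population) unname(cf["log_pop"]) else NA_real_
    sb <- if (spec$include_population) unname(se["log_pop"]) else NA_real_
    list(beta = beta, se = sb, aic = stats::AIC(fit), converged = conv)
  }, error = function(e)
    list(beta = NA_real_, se = NA_real_, aic = NA_real_, converged = FALSE))
  structure(c(res, list(spec = spec)), class = "assoc_fit")
}

#' Compare a full/reduced model pair by AIC
#'
#' `delta_aic = AIC_reduced - AIC_full`. The full model is counted as more apt
#' if its AIC is lower (`delta_aic > 0`) or if the reduced model failed to
#' fit; in all other cases (ties included) the reduced model wins.
#'
#' @param full,reduced `assoc_fit` objects.
#' @return list with `delta_aic` and `verdict` (`"full"`, `"reduced"`, or `NA`
#'   if both failed).
#' @export
deltaAicCompare <- function(full, reduced) {
  full_ok <- is.finite(full$aic)
  red_ok <- is.finite(reduced$aic) && reduced$converged
  if (!full_ok && !red_ok)
    return(list(delta_aic = NA_real_, verdict = NA_character_))
  if (!red_ok) return(list(delta_aic = NA_real_, verdict = "full"))
  if (!full_ok) return(list(delta_aic = NA_real_, verdict = "reduced"))
  d <- reduced$aic - full$aic
  list(delta_aic = d, verdict = if (d > 0) "full" else "reduced")
}

#' Frequentist model averaging of population coefficients
#'
#' Averages the population coefficient over candidate models with
#' AIC-exponential weights `omega_j = c_j * exp(-AIC_j / 2) / sum(...)`, where
#' `c_j` indicates convergence. AIC values are shifted by their minimum before
#' exponentiation (the weights are invariant to the shift).
#'
#' @param fits list of `assoc_fit` objects (full models).
#' @return An `fma_result`: `beta_fma`, `weights`, `converged` indicators.
#' @export
fmaEstimate <- function(fits) {
  aic <- vapply(fits, function(f) f$aic, 0)
  beta <- vapply(fits, function(f) f$beta, 0)
  cj <- vapply(fits, function(f) isTRUE(f$converged), TRUE) &
    is.finite(aic) & is.finite(beta)
  if (!any(cj)) stop("no converged fit to average")
  w <- numeric(length(fits))
  w[cj] <- exp(-(aic[cj] - min(aic[cj])) / 2)
  w <- w / sum(w)
  structure(list(beta_fma = sum(w[cj] * beta[cj]), weights = w,
                 converged = cj),
            class = "fma_result")
}

#' Build a candidate control-variable set
#'
#' Candidate controls for the double-selection lasso: the small tier holds
#' level indicators (corpus, family, script, macro area, EGIDS), cubic
#' (third-order) B-spline bases for latitude and longitude with interior knots
#' at the 25th/50th/75th percentiles (7 basis columns per axis), and the
#' continuous covariates (log h, log L, log range size, log distance to water,
#' log altitude, climate PC1/PC2, log number of countries). The medium tier
#' adds the pairwise products of the two coordinate bases; the big tier also
#' adds pairwise products of the level indicators. Constant columns are
#' dropped with a warning.
#'
#' @param df per-language data.frame with the metadata columns plus `h` and
#'   `L`.
#' @param tier `"small"`, `"medium"` or `"big"`.
#' @return Numeric matrix of candidate controls.
#' @export
buildCandidateSet <- function(df, tier = c("small", "medium", "big")) {
  tier <- match.arg(tier)
  ind_cols <- c("corpus", "family", "script", "macro_area", "egids")
  ind <- do.call(cbind, lapply(intersect(ind_cols, names(df)), function(cl) {
    f <- factor(df[[cl]])
    if (nlevels(f) < 2) {
      m <- matrix(1, nrow(df), 1)  # constant; dropped below with a warning
    } else {
      m <- stats::model.matrix(~ 0 + f)
    }
    colnames(m) <- paste0(cl, "_", levels(f)[seq_len(ncol(m))])
    m
  }))
  spline7 <- function(x, nm) {
    if (length(unique(x)) < 5) {
      warning("degenerate coordinate '", nm, "': basis dropped")
      return(NULL)
    }
    kn <- stats::quantile(x, c(0.25, 0.5, 0.75))
    m <- splines::bs(x, knots = kn, degree = 3, intercept = TRUE)
    m <- as.matrix(m)
    colnames(m) <- paste0(nm, "_bs", seq_len(ncol(m)))
    m
  }
  blat <- spline7(df$latitude, "lat")
  blon <- spline7(df$longitude, "lon")
  cont <- cbind(log_h = log(df$h), log_L = log(df$L),
                log_range = log(df$range_size),
                log_dist_water = log(df$distance_to_water),
                log_altitude = log(df$altitude),
                climate_pc1 = df$climate_pc1, climate_pc2 = df$climate_pc2,
                log_n_countries = log(df$n_countries))
  out <- cbind(ind, blat, blon, cont)
  if (tier %in% c("medium", "big") && !is.null(blat) && !is.null(blon)) {
    prods <- do.call(cbind, lapply(seq_len(ncol(blat)), function(i) {
      m <- blat[, i] * blon
      colnames(m) <- paste0(colnames(blat)[i], "_x_", colnames(blon))
      m
    }))
    out <- cbind(out, prods)
  }
  if (tier == "big" && ncol(ind) >= 2) {
    pr <- utils::combn(seq_len(ncol(ind)), 2)
    prods <- vapply(seq_len(ncol(pr)), function(k)
      ind[, pr[1, k]] * ind[, pr[2, k]], numeric(nrow(ind)))
    colnames(prods) <- apply(pr, 2, function(ij)
      paste0(colnames(ind)[ij[1]], "_x_", colnames(ind)[ij[2]]))
    out <- cbind(out, prods)
  }
  keep <- apply(out, 2, function(x) stats::sd(x) > 0 && all(is.finite(x)))
  if (any(!keep))
    warning(sum(!keep), " constant/degenerate candidate column(s) dropped")
  out[, keep, drop = FALSE]
}

#' Double-selection lasso regression
#'
#' Selects controls by (i) a lasso of the exposure on the candidates and
#' (ii) a lasso of the outcome on the candidates (penalties by 10-fold
#' cross-validation with a seeded fold split), then regresses the outcome on
#' the exposure plus the union of the two selections by least squares, with
#' standard errors clustered on `cluster` (typically the language).
#'
#' @param outcome numeric outcome (e.g. log b).
#' @param exposure numeric exposure (log speaker population).
#' @param candidates candidate control matrix (standardized internally).
#' @param cluster optional cluster ids for the standard errors.
#' @param seed seed for the cross-validation fold split.
#' @param rule penalty rule: `"lambda.1se"` (default; the sparsest model
#'   within one standard error of the CV optimum, the conservative standard
#'   when observations are few relative to candidates) or `"lambda.min"`.
#' @return A `ds_fit`: `beta`, `se`, `tstat`, `selected` (control names),
#'   `fit`.
#' @export
doubleSelection <- function(outcome, exposure, candidates = NULL,
                            cluster = NULL, seed = 1,
                            rule = c("lambda.1se", "lambda.min")) {
  rule <- match.arg(rule)
  n <- length(outcome)
  if (n == 0) stop("empty data")
  if (is.null(candidates) || NCOL(candidates) == 0) {
    sel <- character(0)
    C <- NULL
  } else {
    C <- as.matrix(candidates)
    if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
    C <- scale(C)
    C <- C[, apply(C, 2, function(x) all(is.finite(x))), drop = FALSE]
    if (ncol(C) < 2) {
      sel <- colnames(C)
    } else {
      set.seed(seed)
      foldid <- sample(rep_len(seq_len(10), n))
      cv1 <- glmnet::cv.glmnet(C, exposure, foldid = foldid)
      cv2 <- glmnet::cv.glmnet(C, outcome, foldid = foldid)
      nz <- function(cv) {
        cf <- as.matrix(stats::coef(cv, s = rule))
        rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
      }
      sel <- union(nz(cv1), nz(cv2))
    }
  }
  dat <- data.frame(.y = outcome, .x = exposure)
  if (length(sel) > 0) dat <- cbind(dat, as.data.frame(C[, sel, drop = FALSE]))
  fit <- stats::lm(.y ~ ., data = dat)
  vc <- if (is.null(cluster)) sandwich::vcovHC(fit, type = "HC1")
        else sandwich::vcovCL(fit, cluster = cluster)
  se <- sqrt(vc[".x", ".x"])
  beta <- stats::coef(fit)[".x"]
  structure(list(beta = unname(beta), se = unname(se),
                 tstat = unname(beta / se), selected = sel, fit = fit),
            class = "ds_fit")
}

#' Freedman-Lane permutation test
#'
#' Tests whether the exposure adds information about the outcome beyond the
#' controls: (1) fit the full regression and record the exposure t-statistic;
#' (2) fit the reduced regression (controls only) for fitted values and
#' residuals; (3) permute the residuals and rebuild a synthetic outcome;
#' (4) refit the full regression on it and record t*; (5) repeat; (6) the
#' p-value is the share of |t*| at least as large as |t_obs|.
#'
#' @param outcome,exposure numeric vectors.
#' @param controls control matrix (possibly `NULL`), typically the
#'   double-selection union.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return A `permutation_result`: `observed`, `permuted`, `p`, `n_perm`.
#' @export
freedmanLaneTest <- function(outcome, exposure, controls = NULL,
                             n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  n <- length(outcome)
  C <- if (is.null(controls)) NULL else as.matrix(controls)
  X <- cbind(`(Intercept)` = 1, x = exposure, C)
  Xr <- cbind(`(Intercept)` = rep(1, n), C)
  qf <- qr(X)
  p <- qf$rank
  Q <- qr.Q(qf)
  R <- qr.R(qf)
  ipos <- 2L  # exposure column
  xtxinv <- chol2inv(R)
  tstatOf <- function(Y) {
    qty <- crossprod(Q, Y)
    coefs <- backsolve(R, qty)
    rss <- colSums(Y^2) - colSums(qty^2)
    sig2 <- rss / (n - p)
    coefs[ipos, ] / sqrt(sig2 * xtxinv[ipos, ipos])
  }
  t_obs <- tstatOf(matrix(outcome, ncol = 1))[1]
  fr <- stats::lm.fit(Xr, outcome)
  fitted_r <- fr$fitted.values
  resid_r <- fr$residuals
  set.seed(seed)
  tstar <- numeric(n_perm)
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    P <- vapply(seq_len(m), function(i) resid_r[sample.int(n)], numeric(n))
    tstar[done + seq_len(m)] <- tstatOf(fitted_r + P)
    done <- done + m
  }
  structure(list(observed = t_obs, permuted = tstar,
                 p = sum(abs(tstar) >= abs(t_obs)) / n_perm, n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression of difficulty on log population with a Brownian-motion
#' covariance from the tree (shared branch length from the root), fitted by
#' maximum likelihood. Also refits without the population term for the AIC
#' comparison. `r2` is the squared Pearson correlation between observed
#' outcome and model prediction.
#'
#' @param outcome named numeric vector (names = language ids, matching tips).
#' @param exposure named numeric vector (log population).
#' @param tree `ape::phylo` whose tips cover the analysed languages.
#' @return A `pgls_fit`: `beta`, `se`, `loglik`, `aic`, `aic_reduced`,
#'   `delta_aic`, `r2`.
#' @export
fitPGLS <- function(outcome, exposure, tree) {
  langs <- names(outcome)
  miss <- setdiff(langs, tree$tip.label)
  if (length(miss) > 0)
    stop("language(s) missing from tree: ", paste(miss, collapse = ", "))
  tr <- ape::keep.tip(tree, langs)
  V <- ape::vcv(tr)[langs, langs]
  U <- chol(V)
  wh <- function(M) backsolve(U, M, transpose = TRUE)
  n <- length(langs)
  glsFit <- function(X) {
    Xw <- wh(X)
    yw <- wh(matrix(outcome, ncol = 1))
    f <- stats::lm.fit(Xw, yw)
    rss <- sum(f$residuals^2)
    sig2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sig2) + 2 * sum(log(diag(U))) + n)
    k <- ncol(X) + 1  # + sigma^2
    list(coef = f$coefficients, rss = rss, loglik = ll,
         aic = -2 * ll + 2 * k, Xw = Xw)
  }
  X <- cbind(1, exposure)
  full <- glsFit(X)
  red <- glsFit(matrix(1, n, 1))
  sig2u <- full$rss / (n - 2)
  se <- sqrt(diag(sig2u * chol2inv(chol(crossprod(full$Xw)))))[2]
  pred <- as.vector(X %*% full$coef)
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(outcome, pred)^2
  structure(list(beta = unname(full$coef[2]), se = unname(se),
                 loglik = full$loglik, aic = full$aic,
                 aic_reduced = red$aic, delta_aic = red$aic - full$aic,
                 r2 = r2, coef = full$coef),
            class = "pgls_fit")
}

#' Haversine great-circle distance matrix
#'
#' @param lat,lon coordinates in degrees (`lat` in \[-90, 90\], `lon` in
#'   \[-180, 180\]).
#' @param labels language ids for the dimnames.
#' @param radius_km Earth radius (6371 km).
#' @return Symmetric zero-diagonal matrix of distances in kilometres.
#' @export
haversineMatrix <- function(lat, lon, labels = NULL, radius_km = 6371) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  dphi <- outer(phi, phi, `-`) / 2
  dlam <- outer(lam, lam, `-`) / 2
  a <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  d <- 2 * radius_km * asin(sqrt(pmin(pmax(a, 0), 1)))
  diag(d) <- 0
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  d
}

#' Row-standardized inverse-distance weights
#'
#' `w_ij = 1 / d_ij` off the diagonal (zero distances between distinct units
#' are replaced by the smallest positive distance, since co-located languages
#' occur in real data), zero diagonal, rows standardized to sum to one.
#'
#' @param d symmetric nonnegative distance matrix.
#' @return Weight matrix of the same dimension.
#' @export
inverseDistanceWeights <- function(d) {
  d <- as.matrix(d)
  off <- d[upper.tri(d) | lower.tri(d)]
  minpos <- min(off[off > 0])
  w <- d
  w[w == 0] <- minpos
  w <- 1 / w
  diag(w) <- 0
  w / rowSums(w)
}

#' Spatial autoregressive error regression with two weight matrices
#'
#' Regression of difficulty on log population with errors
#' `u = lambda1 W1 u + lambda2 W2 u + eps`, estimated by a moment-based
#' residual autoregression for `(lambda1, lambda2)` followed by feasible GLS
#' (Cochrane-Orcutt-style transformation), iterated once. With both lambdas
#' zero this reduces to ordinary least squares. `r2` is the squared
#' correlation of observed and predicted outcome.
#'
#' @param outcome,exposure numeric vectors.
#' @param W1,W2 row-standardized weight matrices (see
#'   [inverseDistanceWeights()]); labels must align with the data order.
#' @return A `sar_fit`: `beta`, `lambda` (length 2), `se`, `z`, `r2`, `coef`.
#' @export
fitSAR <- function(outcome, exposure, W1, W2) {
  n <- length(outcome)
  stopifnot(nrow(W1) == n, nrow(W2) == n)
  X <- cbind(1, exposure)
  beta <- stats::.lm.fit(X, outcome)$coefficients
  lam <- c(0, 0)
  for (it in 1:2) {
    u <- outcome - as.vector(X %*% beta)
    Z <- cbind(as.vector(W1 %*% u), as.vector(W2 %*% u))
    lam <- tryCatch(stats::.lm.fit(Z, u)$coefficients,
                    error = function(e) c(0, 0))
    lam[!is.finite(lam)] <- 0
    s <- sum(abs(lam))
    if (s > 0.95) lam <- lam * 0.95 / s  # keep the error process stable
    ys <- outcome - lam[1] * as.vector(W1 %*% outcome) -
      lam[2] * as.vector(W2 %*% outcome)
    Xs <- X - lam[1] * (W1 %*% X) - lam[2] * (W2 %*% X)
    f <- stats::.lm.fit(Xs, ys)
    beta <- f$coefficients
  }
  rss <- sum(f$residuals^2)
  sig2 <- rss / (n - ncol(X))
  covb <- sig2 * chol2inv(chol(crossprod(Xs)))
  se <- sqrt(covb[2, 2])
  pred <- as.vector(X %*% beta)
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(outcome, pred)^2
  structure(list(beta = unname(beta[2]), lambda = as.vector(lam),
                 se = se, z = unname(beta[2]) / se, r2 = r2, coef = beta),
            class = "sar_fit")
}

#' Permutation test for the spatial error model
#'
#' Permutes the exposure, refits the full two-matrix error model each time and
#' compares |z*| with the observed |z|; the p-value is the exceedance share
#' over `n_perm` permutations. A refit failure in a permutation is redrawn
#' (count reported in the result).
#'
#' @inheritParams fitSAR
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return A `permutation_result` (plus `redrawn` count and the observed
#'   `sar_fit` as `fit`).
#' @export
sarPermutationTest <- function(outcome, exposure, W1, W2, n_perm = 10000,
                               seed = 1) {
  obs <- fitSAR(outcome, exposure, W1, W2)
  set.seed(seed)
  zstar <- numeric(n_perm)
  redrawn <- 0L
  i <- 1L
  while (i <= n_perm) {
    zp <- tryCatch(
      fitSAR(outcome, exposure[sample.int(length(exposure))], W1, W2)$z,
      error = function(e) NA_real_)
    if (is.finite(zp)) {
      zstar[i] <- zp
      i <- i + 1L
    } else redrawn <- redrawn + 1L
  }
  structure(list(observed = obs$z, permuted = zstar,
                 p = sum(abs(zstar) >= abs(obs$z)) / n_perm, n_perm = n_perm,
                 redrawn = redrawn, fit = obs),
            class = "permutation_result")
}
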