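#' Grid initialization for the learning-curve ansatz
#'
#' The ansatz `r_l = h + A * log(l) / l^b` is awkward to fit directly, so
#' initial values are approximated in linear space: for each grid value
#' `phi = 0.01, 0.02, ..., 10` (1000 candidates) compute
#' `Phi = log(l) / l^phi` and fit `log(r_l) = beta_h + beta_A * Phi` by
#' ordinary least squares. The candidate with the smallest RMSE among those
#' with `beta_A > 0` is selected.
#'
#' @param curve a `learning_curve` (or data.frame with columns `l`, `r_l`).
#' @return A `grid_init` with `phi_m`, `beta_h`, `beta_A`, `rmse`.
#' @export
initAnsatzGrid <- function(curve) {
  l <- curve$l
  r <- curve$r_l
  if (length(l) < 3) stop("need at least 3 checkpoints")
  if (any(r <= 0)) stop("all r_l must be positive")
  y <- log(r)
  if (stats::sd(y) < 1e-12)
    stop(structure(class = c("glottolearn_init_failure", "error", "condition"),
                   list(message = "constant curve: no shape information",
                        call = sys.call(-1))))
  phis <- seq_len(1000) / 100  # 0.01, 0.02, ..., 10
  Phi <- outer(log(l), rep(1, length(phis))) / outer(l, phis, `^`)
  n <- length(l)
  sy <- sum(y)
  sx <- colSums(Phi)
  sxx <- colSums(Phi^2)
  sxy <- colSums(Phi * y)
  denom <- sxx - sx^2 / n
  slope <- (sxy - sx * sy / n) / denom
  intercept <- (sy - slope * sx) / n
  resid2 <- colSums((y - Phi * rep(slope, each = n) -
                       rep(intercept, each = n))^2)
  rmse <- sqrt(resid2 / n)
  ok <- is.finite(slope) & slope > 0
  if (!any(ok))
    stop(structure(class = c("glottolearn_init_failure", "error", "condition"),
                   list(message = "no grid candidate with beta_A > 0 (flat or inconsistent curve)",
                        call = sys.call(-1))))
  m <- which(ok)[which.min(rmse[ok])]
  structure(list(phi_m = phis[m], beta_h = intercept[m], beta_A = slope[m],
                 rmse = rmse[m]), class = "grid_init")
}

#' Fit the learning-curve ansatz
#'
#' Fits `r_l = exp(h*) + exp(A') * log(l) / l^exp(b')` by log-least squares
#' (residuals on the log scale) with a derivative-based nonlinear least-squares
#' optimizer. The exponential parameterization `A = exp(A')`, `b = exp(b')`,
#' `h = exp(h*)` guarantees positivity of all three parameters. Initial values
#' come from [initAnsatzGrid()]: `h*` starts at `beta_h`, `A'` at
#' `exp(beta_A)` and `b'` at `exp(phi_m)`; because that conventional starting
#' point can sit far from the optimum in `b'`, the optimizer is additionally
#' restarted from the algebraically consistent point
#' `(beta_h, log(beta_A * exp(beta_h)), log(phi_m))` and the lower-RMSE
#' solution is kept.
#'
#' @param curve a `learning_curve`.
#' @param init optional `grid_init`; computed from `curve` if missing.
#' @param max_iter iteration cap for the optimizer.
#' @return An `ansatz_fit` with `h`, `A`, `b` (all positive), the internal
#'   transforms, `rmse` (log scale) and a `converged` flag. `b` is the
#'   learning-difficulty shape parameter: larger `b` means the compression
#'   rate approaches the entropy rate `h` faster (easier to learn).
#' @export
fitAnsatz <- function(curve, init = NULL, max_iter = 200) {
  if (is.null(init)) init <- initAnsatzGrid(curve)
  l <- curve$l
  y <- log(curve$r_l)
  model <- function(p) {
    v <- exp(p[1]) + exp(p[2]) * log(l) / l^exp(p[3])
    v
  }
  residfun <- function(p) {
    v <- model(p)
    if (any(!is.finite(v)) || any(v <= 0)) return(rep(1e6, length(y)))
    y - log(v)
  }
  starts <- list(
    c(init$beta_h, exp(init$beta_A), exp(init$phi_m)),
    c(init$beta_h, log(init$beta_A) + init$beta_h, log(init$phi_m))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = residfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(residfun(fit$par)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(par = fit$par, rmse = rmse,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("ansatz fit failed: non-finite residuals")
  p <- best$par
  structure(list(h = exp(p[1]), A = exp(p[2]), b = exp(p[3]),
                 h_star = p[1], A_prime = p[2], b_prime = p[3],
                 rmse = best$rmse, converged = best$converged,
                 init = init),
            class = "ansatz_fit")
}

#' @export
print.ansatz_fit <- function(x, ...) {
  cat(sprintf("Ansatz fit: h = %.4g bits/symbol, A = %.4g, b = %.4g (rmse %.3g, %s)\n",
              x$h, x$A, x$b, x$rmse,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Estimate learning difficulty from a document stream
#'
#' Convenience wrapper: computes the incremental-compression learning curve and
#' fits the ansatz. A grid-initialization failure (no positive-slope grid
#' candidate, e.g. a flat curve) flags the document for exclusion from the
#' downstream association analyses rather than raising an error.
#'
#' @inheritParams compressionCurve
#' @return A one-row data.frame with `h`, `A`, `b`, `rmse`, `converged`,
#'   `excluded` and the document length `L`.
#' @export
estimateDifficulty <- function(stream, config = compressorConfig(),
                               n_checkpoints = 20) {
  curve <- compressionCurve(stream, config, n_checkpoints)
  fit <- tryCatch(fitAnsatz(curve),
                  glottolearn_init_failure = function(e) NULL,
                  error = function(e) NULL)
  if (!is.null(fit)) {
    pars <- c(fit$h, fit$A, fit$b)
    if (!all(is.finite(pars)) || any(pars <= 0)) fit <- NULL
  }
  if (is.null(fit)) {
    return(data.frame(h = NA_real_, A = NA_real_, b = NA_real_, rmse = NA_real_,
                      converged = FALSE, excluded = TRUE, L = attr(curve, "L")))
  }
  data.frame(h = fit$h, A = fit$A, b = fit$b, rmse = fit$rmse,
             converged = fit$converged, excluded = FALSE, L = attr(curve, "L"))
}

#' Forward-evaluate the learning-curve ansatz
#'
#' @param l symbol counts.
#' @param h limiting entropy rate (bits/symbol).
#' @param A proportionality constant.
#' @param b learning-difficulty shape parameter.
#' @return `h + A * log(l) / l^b`.
#' @export
ansatzCurve <- function(l, h, A, b) h + A * log(l) / l^b
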