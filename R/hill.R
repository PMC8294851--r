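#' Hill law for calcium-dependent open-pore conductance
#'
#' Constructs a Hill dose-response law
#' \deqn{f(x) = c + \frac{a}{1 + (K/x)^n}}
#' describing how the mean open-pore conductance depends on the free calcium
#' concentration. `f(0) = c` (the calcium-independent, SNARE-alone level) and
#' `f(Inf) = a + c` (the saturating level). Defaults are the experimental
#' best-fit values for the nanodisc-cell fusion assay.
#'
#' @param a Amplitude above baseline (pS). Default 343.7.
#' @param c Baseline conductance at zero calcium (pS). Default 164.2.
#' @param n Hill coefficient (dimensionless). Default 2.3.
#' @param K Half-saturation free calcium concentration (uM). Default 23.
#' @return An object of class `hill_law`.
#' @seealso [hill_conductance()], [fit_hill()]
#' @export
#' @examples
#' law <- hill_law()
#' hill_conductance(c(0, 23, 1e6), law)
hill_law <- function(a = 343.7, c = 164.2, n = 2.3, K = 23) {
  stopifnot(is.numeric(a), is.numeric(c), is.numeric(n), is.numeric(K))
  if (a < 0 || c < 0) stop("hill_law: amplitudes 'a' and 'c' must be >= 0")
  if (n <= 0) stop("hill_law: Hill coefficient 'n' must be > 0")
  if (K <= 0) stop("hill_law: half-saturation 'K' must be > 0")
  structure(list(a = a, c = c, n = n, K = K), class = "hill_law")
}

#' @export
print.hill_law <- function(x, ...) {
  cat(sprintf("Hill law: f(x) = %.4g + %.4g / (1 + (%.4g/x)^%.3g)\n",
              x$c, x$a, x$K, x$n))
  cat(sprintf("  f(0) = %.4g   f(K) = %.4g   f(Inf) = %.4g\n",
              x$c, x$c + x$a / 2, x$a + x$c))
  invisible(x)
}

#' Evaluate a Hill law at given calcium concentrations
#'
#' @param calcium Free calcium concentration(s), uM. Must be >= 0.
#' @param law A [hill_law()] object.
#' @return Conductance(s) in pS, same length as `calcium`.
#' @export
hill_conductance <- function(calcium, law = hill_law()) {
  stopifnot(inherits(law, "hill_law"), is.numeric(calcium))
  if (any(calcium < 0)) stop("hill_conductance: calcium must be >= 0")
  # K/0 = Inf so the x = 0 limit evaluates to c exactly
  law$c + law$a / (1 + (law$K / calcium)^law$n)
}

#' Least-squares Hill fit of a calcium titration
#'
#' Fits `y = c + a / (1 + (K/x)^n)` by Levenberg-Marquardt nonlinear least
#' squares. The Hill coefficient and/or half-saturation can be held fixed,
#' as is done when a conductance-derived (n, K) pair is reused to fit a
#' second signal such as the pore expansion rate.
#'
#' @param x Free calcium concentrations (uM); zeros are allowed.
#' @param y Signal values (any unit; typically pS or nS/s).
#' @param fix_n,fix_K Optional fixed values for `n` and `K`.
#' @param start Optional named list of starting values (`a`, `c`, `n`, `K`).
#' @return An object of class `hill_fit`: a list with `law` (the fitted
#'   [hill_law()]), `coefficients`, `conf_int` (95% Wald intervals),
#'   `r_squared`, `fitted`, `residuals`, and the underlying `nls` fit.
#' @export
fit_hill <- function(x, y, fix_n = NULL, fix_K = NULL, start = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(x < 0)) stop("fit_hill: calcium must be >= 0")
  n_free <- is.null(fix_n)
  k_free <- is.null(fix_K)
  n_distinct <- length(unique(x))
  need <- 2L + n_free + k_free
  if (n_distinct < need) {
    stop(sprintf("fit_hill: need >= %d distinct x values, got %d",
                 need, n_distinct))
  }

  dat <- data.frame(x = x, y = y)
  s <- list(
    a = max(y) - min(y),
    c = max(min(y), 1e-6 * max(abs(y), 1)),
    n = if (n_free) 1.5 else fix_n,
    K = if (k_free) stats::median(x[x > 0]) else fix_K
  )
  if (!is.null(start)) s[names(start)] <- start

  rhs <- "c + a / (1 + (K/x)^n)"
  form <- stats::as.formula(paste("y ~", rhs))
  par0 <- s[c("a", "c", if (n_free) "n", if (k_free) "K")]
  fixed <- s[c(if (!n_free) "n", if (!k_free) "K")]

  if (length(fixed)) dat <- cbind(dat, fixed)
  fit <- minpack.lm::nlsLM(
    form, data = dat, start = par0,
    lower = c(a = -Inf, c = -Inf, n = 1e-3, K = 1e-6)[names(par0)],
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )

  est <- stats::coef(fit)
  all_par <- c(as.list(est), fixed)
  law <- hill_law(a = max(all_par$a, 0), c = max(all_par$c, 0),
                  n = all_par$n, K = all_par$K)
  se <- sqrt(diag(stats::vcov(fit)))
  tcrit <- stats::qt(0.975, df = stats::df.residual(fit))
  ci <- cbind(lower = est - tcrit * se, upper = est + tcrit * se)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)

  structure(list(
    law = law, coefficients = est, fixed = unlist(fixed), conf_int = ci,
    r_squared = r2, fitted = stats::fitted(fit), residuals = res, fit = fit
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit: y = c + a / (1 + (K/x)^n)\n")
  co <- x$coefficients
  for (nm in names(co)) {
    cat(sprintf("  %s = %.4g  [95%% CI %.4g, %.4g]\n",
                nm, co[[nm]], x$conf_int[nm, 1], x$conf_int[nm, 2]))
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), signif(x$fixed, 4),
                          sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param calcium Calcium concentrations (uM) at which to evaluate.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, calcium, ...) {
  p <- c(as.list(object$coefficients), as.list(object$fixed))
  p$c + p$a / (1 + (p$K / calcium)^p$n)
}
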