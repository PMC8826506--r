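# Four-parameter Hill dose-response fitting by bounded multi-start least
# squares.

#' Hill dose-response curve
#'
#' `B + E_max * c^h / (EC50^h + c^h)` evaluated at concentrations `conc`.
#'
#' @param conc concentrations (mM).
#' @param E_max,EC50,h,B Hill parameters.
#' @return numeric vector of responses.
#' @export
hill_response <- function(conc, E_max, EC50, h, B = 0) {
  B + E_max * conc^h / (EC50^h + conc^h)
}

#' Fit a Hill curve to a dose series
#'
#' Bounded least squares (`L-BFGS-B`) of the four-parameter Hill model,
#' multi-started from quantile-based initial EC50 values and Hill slopes
#' of 1 and 2 to avoid local minima. The Hill coefficient is constrained
#' to `[0.5, 10]`, `E_max` and `B` to be non-negative, and EC50 to a wide
#' band around the observed concentration range. Flat series converge to
#' `E_max` near 0 with `B` at the series mean.
#'
#' @param conc concentrations (mM, > 0); at least 4 distinct values.
#' @param response responses (same length, finite).
#' @return object of class `hill_fit`: list with `E_max`, `EC50`, `h`,
#'   `B`, `rss`, `converged`.
#' @export
fit_hill <- function(conc, response) {
  if (length(conc) != length(response)) stop2("conc/response length mismatch")
  if (!all(is.finite(response)) || !all(is.finite(conc))) {
    stop2("non-finite concentrations or responses")
  }
  if (any(conc <= 0)) stop2("concentrations must be > 0")
  if (length(unique(conc)) < 4L) stop2("need >= 4 distinct concentrations")
  rng <- max(response) - min(response)
  scale <- max(rng, 1e-8)
  lower <- c(E_max = 0, EC50 = min(conc) / 100, h = 0.5, B = 0)
  upper <- c(E_max = max(10 * scale, 1), EC50 = max(conc) * 100, h = 10,
             B = max(max(response), 1e-8))
  rss_fn <- function(par) {
    sum((response - hill_response(conc, par[1], par[2], par[3], par[4]))^2)
  }
  ec50_starts <- unique(quantile(conc, c(0.25, 0.5, 0.75), names = FALSE))
  starts <- expand.grid(E_max = rng, EC50 = ec50_starts, h = c(1, 2),
                        B = max(min(response), 0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      optim(par0, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(E_max = NA_real_, EC50 = NA_real_, h = NA_real_,
                          B = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "hill_fit"))
  }
  structure(list(E_max = best$par[1], EC50 = best$par[2], h = best$par[3],
                 B = best$par[4], rss = best$value,
                 converged = best$convergence == 0 && all(is.finite(best$par))),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: E_max = %.4g, EC50 = %.4g mM, h = %.3g, B = %.4g (rss %.4g%s)\n",
    x$E_max, x$EC50, x$h, x$B, x$rss,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}
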