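#' Two-fold dilution series design for binding assays
#'
#' The microscale-thermophoresis design used for HRD-metal titrations: a
#' fifteen-step two-fold dilution series of the ligand from a 20 mM top
#' concentration plus a no-ligand control, mixed 1:1 with the protein stock so
#' every concentration is halved in the final sample.
#'
#' @param top top ligand concentration before mixing (molar).
#' @param steps number of dilution steps (default 15).
#' @param mix_ratio fraction of final volume contributed by the ligand
#'   dilution (default 0.5 for 1:1 mixing).
#' @return Numeric vector of `steps + 1` final concentrations, strictly
#'   two-fold decreasing then a terminal 0 (the no-ligand control).
#' @examples
#' design_dilution_series(20e-3)  # first cell 10 mM after 1:1 mixing
#' @export
design_dilution_series <- function(top = 20e-3, steps = 15L, mix_ratio = 0.5) {
  stopifnot(top > 0, steps >= 1L, mix_ratio > 0, mix_ratio <= 1)
  c(top * mix_ratio / 2^(seq_len(steps) - 1L), 0)
}

#' Fraction of protein bound under 1:1 mass action
#'
#' Exact solution of P + L <-> PL with total protein `p`, total ligand `l` and
#' dissociation constant `kd`:
#' \deqn{f = \frac{(p+l+K_d) - \sqrt{(p+l+K_d)^2 - 4pl}}{2p}.}
#' Unlike the hyperbolic approximation l/(Kd+l), this remains correct when the
#' protein concentration is not negligible against Kd — the regime of the HRD
#' titrations, where protein at 20-40 uM meets Kd values down to ~44 uM.
#'
#' @param p total protein concentration (molar, > 0).
#' @param l total ligand concentration(s) (molar, >= 0).
#' @param kd dissociation constant (molar, > 0).
#' @return Fraction bound in [0, 1], vectorised over `l`.
#' @export
fraction_bound <- function(p, l, kd) {
  stopifnot(p > 0, all(l >= 0), kd > 0)
  s <- p + l + kd
  disc <- pmax(s^2 - 4 * p * l, 0)
  f <- (s - sqrt(disc)) / (2 * p)
  pmin(pmax(f, 0), 1)
}

#' Assemble a dose-response series
#'
#' @param concentration ligand concentrations (molar, after mixing):
#'   non-negative, strictly decreasing apart from a final zero control.
#' @param signal measured signals (arbitrary units), same length.
#' @param protein protein concentration after mixing (molar).
#' @param metal,buffer optional metadata labels.
#' @return A data frame of class `dose_response_series` with attributes
#'   `protein`, `metal`, `buffer`.
#' @export
dose_response_series <- function(concentration, signal, protein,
                                 metal = NA_character_, buffer = NA_character_) {
  stopifnot(length(concentration) == length(signal), all(concentration >= 0),
            protein > 0)
  nz <- concentration[concentration > 0]
  if (is.unsorted(rev(nz), strictly = TRUE)) {
    stop("nonzero concentrations must be strictly decreasing", call. = FALSE)
  }
  out <- data.frame(concentration = concentration, signal = signal)
  attr(out, "protein") <- protein
  attr(out, "metal") <- metal
  attr(out, "buffer") <- buffer
  class(out) <- c("dose_response_series", "data.frame")
  out
}

#' Fit a 1:1 binding isotherm to a dose-response series
#'
#' Least-squares fit of
#' `signal = s_unbound + (s_bound - s_unbound) * fraction_bound(p, l, Kd)`
#' with Kd parameterised on the log scale (positivity enforced by
#' construction) and initialised at the geometric mean of the nonzero
#' concentrations. The standard error of Kd is obtained from the Jacobian at
#' the optimum via the delta method. A series whose fitted amplitude
#' `|s_bound - s_unbound|` is below `no_binding_factor` times the residual
#' standard deviation is reported as "no binding", mirroring the categorical
#' entries of instrument reports.
#'
#' @param series a [dose_response_series()], or a data frame with columns
#'   `concentration` and `signal`.
#' @param protein protein concentration (molar); taken from the series
#'   attribute when absent.
#' @param no_binding_factor amplitude-to-noise ratio below which "no binding"
#'   is declared (default 3).
#' @return An object of class `binding_fit` with components `kd`,
#'   `kd_standard_error` (molar), `signal_unbound`, `signal_bound`,
#'   `residual_norm`, `no_binding` (logical), `data`, `protein`, and the
#'   underlying `nls` fit. Supports [coef()], [predict()], [fitted()],
#'   [residuals()], [summary()] and [plot()].
#' @examples
#' conc <- design_dilution_series(20e-3)
#' sig <- 800 + 200 * fraction_bound(20e-6, conc, 44e-6)
#' fit_binding(dose_response_series(conc, sig, protein = 20e-6))
#' @export
fit_binding <- function(series, protein = attr(series, "protein"),
                        no_binding_factor = 3) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "signal") %in% names(series)))
  if (is.null(protein)) stop("protein concentration required", call. = FALSE)
  l <- series$concentration
  y <- series$signal
  if (length(y) < 4L) stop("need at least 4 points to fit", call. = FALSE)

  lkd0 <- mean(log(l[l > 0]))
  df <- data.frame(l = l, y = y)
  if (diff(range(y)) == 0) {
    # perfectly flat series carries no binding information at all
    out <- list(kd = NA_real_, kd_standard_error = NA_real_,
                signal_unbound = y[1], signal_bound = y[1],
                residual_norm = 0, sigma = 0, amplitude = 0,
                no_binding = TRUE, no_binding_factor = no_binding_factor,
                protein = protein, data = df, fit = NULL)
    class(out) <- "binding_fit"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ s0 + (s1 - s0) * fraction_bound(protein, l, exp(lkd)),
      data = df,
      start = list(s0 = y[which.min(l)], s1 = y[which.max(l)], lkd = lkd0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      # a singular fit on a dose-independent series is itself evidence of no
      # binding: compare the high/low-dose contrast against the scatter
      ord <- order(l)
      lo <- mean(y[ord][seq_len(min(4L, length(y)))])
      hi <- mean(y[rev(ord)][seq_len(min(4L, length(y)))])
      if (abs(hi - lo) <= no_binding_factor * stats::sd(y)) {
        return(NULL)
      }
      stop("binding fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(fit)) {
    res <- y - mean(y)
    out <- list(kd = NA_real_, kd_standard_error = NA_real_,
                signal_unbound = mean(y), signal_bound = mean(y),
                residual_norm = sqrt(sum(res^2)),
                sigma = stats::sd(y), amplitude = 0,
                no_binding = TRUE, no_binding_factor = no_binding_factor,
                protein = protein, data = df, fit = NULL)
    class(out) <- "binding_fit"
    return(out)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / max(1L, length(res) - 3L))
  amplitude <- abs(est[["s1"]] - est[["s0"]])
  no_binding <- amplitude <= no_binding_factor * sigma
  kd <- exp(est[["lkd"]])
  out <- list(
    kd = kd,
    kd_standard_error = kd * se[["lkd"]],  # delta method on log scale
    signal_unbound = est[["s0"]],
    signal_bound = est[["s1"]],
    residual_norm = sqrt(sum(res^2)),
    sigma = sigma,
    amplitude = amplitude,
    no_binding = no_binding,
    no_binding_factor = no_binding_factor,
    protein = protein,
    data = df,
    fit = fit
  )
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("1:1 binding isotherm fit\n")
  if (x$no_binding) {
    cat(sprintf("  no binding (amplitude %.3g < %g x residual sd %.3g)\n",
                x$amplitude, x$no_binding_factor, x$sigma))
  } else {
    cat(sprintf("  Kd: %.4g M (%.4g uM), SE %.3g M\n",
                x$kd, x$kd * 1e6, x$kd_standard_error))
    cat(sprintf("  signal unbound: %.4g, bound: %.4g\n",
                x$signal_unbound, x$signal_bound))
  }
  cat(sprintf("  residual norm: %.4g over %d points\n",
              x$residual_norm, nrow(x$data)))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, signal_unbound = object$signal_unbound,
    signal_bound = object$signal_bound)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  l <- if (is.null(newdata)) object$data$l else newdata$concentration
  if (is.na(object$kd)) return(rep(object$signal_unbound, length(l)))
  object$signal_unbound + (object$signal_bound - object$signal_unbound) *
    fraction_bound(object$protein, l, object$kd)
}

#' @export
fitted.binding_fit <- function(object, ...) predict(object)

#' @export
residuals.binding_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
summary.binding_fit <- function(object, ...) {
  structure(list(fit = object,
                 nls_summary = if (!is.null(object$fit)) summary(object$fit)),
            class = "summary.binding_fit")
}

#' @export
print.summary.binding_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$nls_summary)) {
    cat("\nUnderlying nonlinear least squares (Kd on log scale):\n")
    print(x$nls_summary$coefficients)
  }
  invisible(x)
}

#' @export
plot.binding_fit <- function(x, ...) {
  pos <- x$data$l > 0
  graphics::plot(x$data$l[pos], x$data$y[pos], log = "x",
                 xlab = "ligand concentration (M)", ylab = "signal (a.u.)", ...)
  grid_l <- exp(seq(log(min(x$data$l[pos])), log(max(x$data$l)), length.out = 200))
  graphics::lines(grid_l, predict(x, data.frame(concentration = grid_l)))
  invisible(x)
}
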