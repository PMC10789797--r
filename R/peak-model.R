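#' Asymmetric peak width
#'
#' Width of the skewed bell-shaped binding curve at temperature `t`. The
#' width interpolates logistically from the left width `s_L` (well below the
#' peak) to the right width `s_R` (well above it), switching around the peak
#' temperature `t_star` over a scale of `w` degrees:
#' \deqn{s(t) = s_L + (s_R - s_L) / (1 + e^{-(t - t^*)/w})}
#'
#' @param t Numeric vector of temperatures (degrees Celsius); must be finite.
#' @param params Named list or vector with elements `t_star`, `s_L`, `s_R`,
#'   `w` (all in degrees Celsius; `s_L`, `s_R`, `w` positive).
#' @return Numeric vector of widths, strictly between `min(s_L, s_R)` and
#'   `max(s_L, s_R)` when the two differ.
#' @examples
#' asym_width(40, list(t_star = 50, s_L = 10, s_R = 20, w = 5))
#' @export
asym_width <- function(t, params) {
  p <- as.list(params)
  check_peak_params(p)
  if (anyNA(t) || any(!is.finite(t))) stop("'t' must be finite")
  p$s_L + (p$s_R - p$s_L) / (1 + exp(-(t - p$t_star) / p$w))
}

#' Skewed Gaussian-like peak model for fluorescence
#'
#' Predicted fluorescence of the binding assay at temperature `t`:
#' \deqn{F'(t) = F_0 + (F^* - F_0)\, e^{-((t - t^*)/s(t))^2}}
#' with the asymmetric width \eqn{s(t)} from [asym_width()]. The curve rises
#' from the baseline `F0` to the peak intensity `F_star` at `t_star` and
#' decays back to `F0`, with possibly different widths on either flank.
#'
#' @param t Numeric vector of temperatures (degrees Celsius); finite.
#' @param params Named list or vector with `F0`, `F_star`, `t_star`, `s_L`,
#'   `s_R`, `w`.
#' @return Predicted intensities (arbitrary units), in `[F0, F_star]`.
#' @examples
#' peak_fluorescence(40, list(F0 = 100, F_star = 500, t_star = 50,
#'                            s_L = 10, s_R = 20, w = 5))
#' @export
peak_fluorescence <- function(t, params) {
  p <- as.list(params)
  check_peak_params(p, full = TRUE)
  if (anyNA(t) || any(!is.finite(t))) stop("'t' must be finite")
  s <- p$s_L + (p$s_R - p$s_L) / (1 + exp(-(t - p$t_star) / p$w))
  p$F0 + (p$F_star - p$F0) * exp(-((t - p$t_star) / s)^2)
}

check_peak_params <- function(p, full = FALSE) {
  need <- c("t_star", "s_L", "s_R", "w")
  if (full) need <- c("F0", "F_star", need)
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing peak parameter(s): ", paste(miss, collapse = ", "))
  if (p$s_L <= 0 || p$s_R <= 0 || p$w <= 0)
    stop("widths s_L, s_R and rate w must be positive")
  if (full && p$F_star < p$F0)
    stop("peak fluorescence F_star must be >= baseline F0")
  invisible(TRUE)
}

## Sum of squared residuals on the unconstrained parameterization
## theta = (F0, log amplitude, t_star, log s_L, log s_R); w fixed.
peak_sse <- function(theta, tt, ff, w) {
  F0 <- theta[1L]
  Fs <- F0 + exp(theta[2L])
  ts <- theta[3L]
  sL <- exp(theta[4L])
  sR <- exp(theta[5L])
  s <- sL + (sR - sL) / (1 + exp(-(tt - ts) / w))
  r <- ff - (F0 + (Fs - F0) * exp(-((tt - ts) / s)^2))
  sum(r * r)
}

#' Fit the skewed peak model to a fluorescence profile
#'
#' Least-squares fit of the five free parameters (`F0`, `F_star`, `t_star`,
#' `s_L`, `s_R`) of the skewed Gaussian-like model ([peak_fluorescence()])
#' to all replicate datapoints of a binding profile, with the transition
#' rate `w` held fixed. Replicates enter as individual residuals (for the
#' standard design of 3 replicates at 11 temperatures, 33 residuals), not as
#' per-temperature means.
#'
#' Optimization is derivative-free Nelder-Mead ([stats::optim()]) on a
#' reparameterized space that enforces the model invariants: widths are
#' optimized on the log scale and the amplitude as `F_star = F0 + exp(g)`,
#' so `s_L, s_R > 0` and `F_star >= F0` hold by construction. Five
#' deterministic restarts offset the starting peak temperature by 0 and
#' +/-5, +/-10 degrees; the lowest-SSE solution is kept.
#'
#' A fit is flagged non-identifiable when the fitted amplitude
#' `F_star - F0` is below three times the pooled replicate standard
#' deviation (a flat profile whose peak cannot be distinguished from
#' noise); `t_star` should not be interpreted in that case.
#'
#' @param profile A [fluor_profile] with `assay_kind = "binding"` (a
#'   stability profile is accepted but fitting one is rarely meaningful).
#' @param fit_range Optional numeric length-2 interval; only datapoints at
#'   temperatures inside `[fit_range[1], fit_range[2]]` are fitted. A
#'   [stable_range()] result may be passed directly.
#' @param init Optional named list of starting values (`F0`, `F_star`,
#'   `t_star`, `s_L`, `s_R`). Defaults are taken from the replicate means:
#'   `t_star` at the maximum-mean temperature, `F0`/`F_star` at the
#'   minimum/maximum mean, both widths 10 degrees.
#' @param w Fixed transition rate in degrees Celsius (default 5); never
#'   optimized.
#' @param n_starts Number of deterministic restarts (default 5).
#' @param control Passed to [stats::optim()]; sensible defaults supplied.
#' @return An object of class `peak_fit` with components `params` (named
#'   list `F0`, `F_star`, `t_star`, `s_L`, `s_R`, `w`), `sse`, `n_points`,
#'   `fit_range`, `converged`, `identifiable`, plus the data used. Standard
#'   methods `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot` and `simulate` are available.
#' @seealso [bootstrap_peak_ci()] for confidence intervals on `t_star`.
#' @examples
#' set.seed(1)
#' prof <- simulate_binding_profile(
#'   true_params = list(F0 = 100, F_star = 1000, t_star = 52.9,
#'                      s_L = 8, s_R = 12, w = 5),
#'   noise_sd = 20, seed = 1)$profile
#' fit <- fit_peak(prof)
#' fit
#' coef(fit)
#' @export
fit_peak <- function(profile, fit_range = NULL, init = NULL, w = 5,
                     n_starts = 5L, control = list()) {
  stopifnot(inherits(profile, "fluor_profile"))
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("'w' must be a single positive number")
  if (!is.null(fit_range)) {
    if (inherits(fit_range, "stability_result"))
      fit_range <- c(fit_range$stable_min, fit_range$stable_max)
    if (length(fit_range) != 2L || fit_range[1L] >= fit_range[2L])
      stop("'fit_range' must be an interval with lower < upper")
    keep <- profile$temperatures >= fit_range[1L] &
      profile$temperatures <= fit_range[2L]
    if (!any(keep)) stop("no datapoints inside 'fit_range'")
    profile <- fluor_profile(profile$protein_id,
                             profile$temperatures[keep],
                             profile$fluorescence[, keep, drop = FALSE],
                             profile$assay_kind)
  } else {
    fit_range <- range(profile$temperatures)
  }
  tt <- rep(profile$temperatures, each = nrow(profile$fluorescence))
  ff <- as.vector(profile$fluorescence)
  if (length(ff) < 6L)
    stop("at least 6 datapoints are required (got ", length(ff), ")")
  if (length(unique(tt)) < 3L)
    stop("at least 3 distinct temperatures are required")

  means <- profile_means(profile)
  if (is.null(init)) {
    init <- list(F0 = min(means), F_star = max(means),
                 t_star = profile$temperatures[which.max(means)],
                 s_L = 10, s_R = 10)
  }
  amp0 <- max(init$F_star - init$F0, 1e-6 * max(abs(ff), 1))
  theta0 <- c(init$F0, log(amp0), init$t_star,
              log(max(init$s_L, 1e-3)), log(max(init$s_R, 1e-3)))

  ctrl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-10), control)
  offsets <- c(0, -10, -5, 5, 10)[seq_len(max(1L, min(n_starts, 5L)))]
  best <- NULL
  any_conv <- FALSE
  for (off in offsets) {
    th <- theta0
    th[3L] <- theta0[3L] + off
    opt <- stats::optim(th, peak_sse, tt = tt, ff = ff, w = w,
                        method = "Nelder-Mead", control = ctrl)
    if (opt$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ## polish: restart the simplex at its own solution until it stops moving
  ## (Nelder-Mead can report convergence on a collapsed simplex)
  for (k in 1:4) {
    opt <- stats::optim(best$par, peak_sse, tt = tt, ff = ff, w = w,
                        method = "Nelder-Mead", control = ctrl)
    if (opt$convergence == 0L) any_conv <- TRUE
    improved <- opt$value < best$value - abs(best$value) * 1e-9
    if (opt$value < best$value) best <- opt
    if (!improved) break
  }
  sse0 <- peak_sse(theta0, tt, ff, w)
  th <- best$par
  params <- list(F0 = th[1L], F_star = th[1L] + exp(th[2L]), t_star = th[3L],
                 s_L = exp(th[4L]), s_R = exp(th[5L]), w = w)
  pooled_sd <- pooled_replicate_sd(profile)
  amp <- params$F_star - params$F0
  ## noise floor from replicate scatter, plus a relative floor so an
  ## exactly constant profile is never declared to have a peak
  floor_amp <- max(3 * pooled_sd, 1e-5 * max(abs(ff), 1))
  identifiable <- amp >= floor_amp

  structure(
    list(params = params,
         sse = best$value,
         sse_init = sse0,
         n_points = length(ff),
         fit_range = as.numeric(fit_range),
         converged = best$convergence == 0L || any_conv,
         identifiable = identifiable,
         profile = profile,
         t = tt, y = ff),
    class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Skewed peak fit for '%s'\n", x$profile$protein_id))
  if (!x$identifiable) {
    cat("  NOT identifiable: peak indistinguishable from baseline;",
        "t_star not interpretable\n")
  } else {
    cat(sprintf("  Peak temperature t* = %.*g degC\n", digits, x$params$t_star))
  }
  cat(sprintf("  F0 = %.*g, F* = %.*g a.u.; s_L = %.*g, s_R = %.*g degC (w = %g)\n",
              digits, x$params$F0, digits, x$params$F_star,
              digits, x$params$s_L, digits, x$params$s_R, x$params$w))
  cat(sprintf("  SSE = %.*g over %d datapoints in [%g, %g] degC; converged: %s\n",
              digits, x$sse, x$n_points, x$fit_range[1L], x$fit_range[2L],
              x$converged))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) {
  unlist(object$params[c("F0", "F_star", "t_star", "s_L", "s_R")])
}

#' @rdname fit_peak
#' @param object,x A `peak_fit` object.
#' @param newdata Optional numeric vector of temperatures, or a data frame
#'   with a `temperature_C` (or `temperature`) column; defaults to the
#'   fitted datapoints' temperatures.
#' @param ... Unused.
#' @export
predict.peak_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    t <- object$t
  } else if (is.data.frame(newdata)) {
    col <- intersect(c("temperature_C", "temperature"), names(newdata))[1L]
    if (is.na(col)) stop("newdata must contain a temperature column")
    t <- newdata[[col]]
  } else {
    t <- as.numeric(newdata)
  }
  peak_fluorescence(t, object$params)
}

#' @export
fitted.peak_fit <- function(object, ...) peak_fluorescence(object$t, object$params)

#' @export
residuals.peak_fit <- function(object, ...) object$y - fitted(object)

#' @export
summary.peak_fit <- function(object, ...) {
  r <- residuals(object)
  structure(
    list(fit = object,
         coef = coef(object),
         rse = sqrt(object$sse / max(1L, object$n_points - 5L)),
         resid_summary = summary(r)),
    class = "summary.peak_fit")
}

#' @export
print.summary.peak_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  Residual SE (df = %d): %.*g a.u.\n",
              x$fit$n_points - 5L, digits, x$rse))
  cat("  Residuals:\n")
  print(signif(x$resid_summary, digits))
  invisible(x)
}

#' @rdname fit_peak
#' @param y Unused (graphics generic).
#' @export
plot.peak_fit <- function(x, y, ...) {
  tgrid <- seq(x$fit_range[1L], x$fit_range[2L], length.out = 200L)
  graphics::plot(x$t, x$y, pch = 19, col = "grey40",
                 xlab = "Temperature (°C)", ylab = "Fluorescence (a.u.)",
                 main = sprintf("%s: t* = %.1f °C", x$profile$protein_id,
                                x$params$t_star), ...)
  graphics::lines(tgrid, peak_fluorescence(tgrid, x$params), col = "firebrick",
                  lwd = 2)
  if (x$identifiable)
    graphics::abline(v = x$params$t_star, lty = 2, col = "firebrick")
  invisible(x)
}

#' @rdname fit_peak
#' @param nsim Number of simulated replicate datasets.
#' @param seed Integer seed for the simulated noise.
#' @param noise_sd Noise standard deviation for simulation; defaults to the
#'   residual standard error of the fit.
#' @export
simulate.peak_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$sse / max(1L, object$n_points - 5L))
  mu <- fitted(object)
  out <- lapply(seq_len(nsim), function(i) {
    yy <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
    m <- matrix(yy, nrow = nrow(object$profile$fluorescence))
    fluor_profile(object$profile$protein_id, object$profile$temperatures, m,
                  object$profile$assay_kind)
  })
  if (nsim == 1L) out[[1L]] else out
}
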