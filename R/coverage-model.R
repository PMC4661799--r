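#' Two-way ANOVA on amplicon performance
#'
#' Additive individuals x fragments model with one observation per cell
#' (the interaction is the error stratum), as used to apportion depth and
#' sensitivity variance between individual and fragment effects. Requires a
#' complete layout.
#'
#' @param stats data.frame from \code{\link{compute_amplicon_stats}}
#' @param response \code{"mean_depth"} or \code{"sensitivity"}
#' @return data.frame of class \code{anova_table}: source, ss, df, ms, f, p
#' @export
two_way_anova <- function(stats, response = c("mean_depth", "sensitivity")) {
  response <- match.arg(response)
  y <- stats[[response]]
  ind <- factor(stats$individual)
  frg <- factor(stats$fragment)
  tab <- table(ind, frg)
  if (any(tab != 1L)) {
    stop("design must be complete with one observation per ",
         "individual x fragment cell", call. = FALSE)
  }
  I <- nlevels(ind); J <- nlevels(frg)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_ind <- J * sum((tapply(y, ind, mean) - grand)^2)
  ss_frg <- I * sum((tapply(y, frg, mean) - grand)^2)
  ss_err <- ss_total - ss_ind - ss_frg
  df <- c(I - 1L, J - 1L, (I - 1L) * (J - 1L), I * J - 1L)
  ss <- c(ss_ind, ss_frg, ss_err, ss_total)
  ms <- c(ss[1:3] / df[1:3], NA)
  f <- if (ms[3] > 0) c(ms[1] / ms[3], ms[2] / ms[3], NA, NA)
       else rep(NA_real_, 4)
  p <- c(stats::pf(f[1], df[1], df[3], lower.tail = FALSE),
         stats::pf(f[2], df[2], df[3], lower.tail = FALSE), NA, NA)
  out <- data.frame(source = c("individual", "fragment", "error", "total"),
                    ss = ss, df = df, ms = ms, f = f, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Method-of-moments variance components from the additive two-way ANOVA
#'
#' For the model y_ij = mu + b_i + c_j + e_ij, E(MS_ind) = sigma_e^2 +
#' J sigma_ind^2 and E(MS_frag) = sigma_e^2 + I sigma_frag^2; estimates are
#' truncated at zero.
#'
#' @param anova an \code{anova_table}
#' @param n_individuals,n_fragments layout dimensions (derived from df when
#'   omitted)
#' @return named vector: sigma2_individual, sigma2_fragment, sigma2_error
#' @export
anova_variance_components <- function(anova, n_individuals = NULL,
                                      n_fragments = NULL) {
  I <- n_individuals %||% (anova$df[1] + 1L)
  J <- n_fragments %||% (anova$df[2] + 1L)
  ms <- anova$ms
  c(sigma2_individual = max((ms[1] - ms[3]) / J, 0),
    sigma2_fragment = max((ms[2] - ms[3]) / I, 0),
    sigma2_error = ms[3])
}

# sensitivity-depth sigmoid with asymptotes fixed at 0 and 1
boltzmann_s <- function(x, x0, dx) 1 - 1 / (1 + exp((x - x0) / dx))

#' Fit the Boltzmann sensitivity-depth curve
#'
#' Nonlinear least squares of sensitivity on mean amplicon depth under
#' S(x) = 1 - 1/(1 + exp((x - x0)/dx)) with the lower and upper asymptotes
#' fixed at 0 and 1; only the half-sensitivity depth x0 and the shape dx
#' are free. Fitting is multi-start (Gauss-Newton via \code{nls}, port
#' algorithm with dx > 0) keeping the best residual sum of squares.
#'
#' @param x mean coverage depth (fold) per amplicon
#' @param s observed sensitivity in [0, 1]
#' @return object of class \code{boltzmann_fit}: estimates, SEs, r-squared,
#'   residual SE, covariance, and a 95 percent prediction-band function
#' @export
fit_boltzmann <- function(x, s) {
  stopifnot(length(x) == length(s))
  keep <- is.finite(x) & is.finite(s)
  x <- x[keep]; s <- s[keep]
  if (length(x) < 10L) {
    stop("need at least 10 (depth, sensitivity) points", call. = FALSE)
  }
  dat <- data.frame(x = x, s = s)
  best <- NULL
  for (x0_0 in c(10, 20, 50)) for (dx_0 in c(5, 15)) {
    fit <- tryCatch(suppressWarnings(
      stats::nls(s ~ 1 - 1 / (1 + exp((x - x0) / dx)), data = dat,
                 start = list(x0 = x0_0, dx = dx_0),
                 algorithm = "port",
                 lower = c(x0 = -Inf, dx = 1e-6),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("Boltzmann fit failed to converge from all starts; ",
         "check that the points span the sensitivity transition",
         call. = FALSE)
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  # near-degenerate fits (e.g. a step-like transition driving dx -> 0)
  # can make the gradient singular; report NA uncertainty then
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  rss <- best$rss
  tss <- sum((s - mean(s))^2)
  n <- length(x); p <- 2L
  sigma <- sqrt(rss / (n - p))
  vc <- tryCatch(stats::vcov(fit),
                 error = function(e) matrix(NA_real_, 2, 2,
                                            dimnames = list(c("x0", "dx"),
                                                            c("x0", "dx"))))
  grad <- function(xx) {
    e <- exp((xx - cf["x0"]) / cf["dx"])
    d <- (1 + e)^2
    cbind(x0 = -e / (cf["dx"] * d),
          dx = -e * (xx - cf["x0"]) / (cf["dx"]^2 * d))
  }
  band <- function(xx, level = 0.95) {
    g <- grad(xx)
    se_pred <- sqrt(pmax(rowSums((g %*% vc) * g), 0) + sigma^2)
    tq <- stats::qt(1 - (1 - level) / 2, n - p)
    mid <- boltzmann_s(xx, cf["x0"], cf["dx"])
    data.frame(x = xx, fit = mid, lower = mid - tq * se_pred,
               upper = mid + tq * se_pred)
  }
  structure(list(x0 = unname(cf["x0"]), dx = unname(cf["dx"]),
                 se = if (!is.null(sm))
                   stats::setNames(sm$coefficients[, "Std. Error"],
                                   c("x0", "dx"))
                 else c(x0 = NA_real_, dx = NA_real_),
                 r2 = 1 - rss / tss, sigma = sigma, vcov = vc, n = n,
                 prediction_band = band),
            class = "boltzmann_fit")
}

#' Predicted sensitivity at a given mean depth
#'
#' S(x) = 1 - 1/(1 + exp((x - x0)/dx)); S(x0) = 0.5 and S is strictly
#' increasing with limits 0 and 1.
#'
#' @param x mean coverage depth (fold); vectorised
#' @param fit a \code{boltzmann_fit}, or a list with elements x0 and dx
#' @return predicted sensitivity in (0, 1)
#' @export
predict_sensitivity <- function(x, fit) {
  boltzmann_s(x, fit$x0, fit$dx)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann sensitivity-depth fit: x0 = %.3f +/- %.3f, dx = %.3f +/- %.3f (r2 = %.3f, n = %d)\n",
    x$x0, x$se["x0"], x$dx, x$se["dx"], x$r2, x$n))
  invisible(x)
}
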