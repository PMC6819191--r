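#' Saturated ratcheting strain from ratcheting stress
#'
#' The plateau toward which the ratcheting strain evolves is taken linear in
#' the ratcheting stress above a threshold:
#' `X_SR = k_r * (e_r - e_rth)`, clamped at 0 below the threshold.
#'
#' @param e_r Ratcheting stress (MPa); the peak stress of the cycle, since the
#'   valley is 0 MPa. Vectorised.
#' @param k_r Ratcheting coefficient (strain per MPa), > 0. Default 1.
#' @param e_rth Ratcheting threshold stress (MPa), >= 0. Default 0.
#' @return Saturated ratcheting strain (dimensionless), >= 0.
#' @export
saturated_strain <- function(e_r, k_r = 1, e_rth = 0) {
  if (!is.finite(k_r) || k_r <= 0) stop("`k_r` must be positive")
  if (!is.finite(e_rth) || e_rth < 0) stop("`e_rth` must be non-negative")
  pmax(0, k_r * (e_r - e_rth))
}

#' Evolution parameters as linear functions of ratcheting stress
#'
#' The evolution parameters of the saturating ratcheting law depend
#' monotonically on ratcheting stress and are modelled as affine functions
#' `alpha = a0 + a1 * e_r` and `beta = b0 + b1 * e_r`. The default
#' coefficients are the fitted relations for sheep lumbar discs
#' (`alpha = 53.565 + 10.571 e_r`, `beta = 0.13 - 0.035 e_r`).
#'
#' @param e_r Ratcheting stress (MPa). Vectorised.
#' @param a0,a1 Intercept and slope of the alpha relation.
#' @param b0,b1 Intercept and slope of the beta relation.
#' @return Numeric vector of parameter values. `evolution_beta()` warns when
#'   any value is <= 0 (the relation extrapolated beyond its validity range).
#' @export
evolution_alpha <- function(e_r, a0 = 53.565, a1 = 10.571) a0 + a1 * e_r

#' @rdname evolution_alpha
#' @export
evolution_beta <- function(e_r, b0 = 0.13, b1 = -0.035) {
  b <- b0 + b1 * e_r
  if (any(b <= 0))
    warning("beta(e_r) <= 0: the linear relation is extrapolated beyond its ",
            "validity range")
  b
}

# ---- functional-form registry ------------------------------------------------

# Each form maps (N, alpha, beta) to the saturation fraction f(N) in [0, 1),
# with a validator for its parameter domain. "power_saturating" is the default:
# f(N) = 1 - alpha^(-N^beta), increasing and saturating for alpha > 1,
# 0 < beta < 1. "exp_saturating" (f = 1 - alpha^(-beta*N)) is kept for
# comparison only.
.urmk_forms <- list(
  power_saturating = list(
    f = function(N, alpha, beta) 1 - alpha^(-(N^beta)),
    validate = function(alpha, beta) {
      if (any(alpha <= 1))
        stop("parameter domain: `alpha` must be > 1 for form 'power_saturating'")
      if (any(beta <= 0 | beta >= 1))
        stop("parameter domain: `beta` must lie in (0, 1) for form ",
             "'power_saturating'")
      invisible(TRUE)
    }
  ),
  exp_saturating = list(
    f = function(N, alpha, beta) 1 - alpha^(-beta * N),
    validate = function(alpha, beta) {
      if (any(alpha <= 1))
        stop("parameter domain: `alpha` must be > 1 for form 'exp_saturating'")
      if (any(beta <= 0))
        stop("parameter domain: `beta` must be > 0 for form 'exp_saturating'")
      invisible(TRUE)
    }
  )
)

#' Available ratcheting evolution functional forms
#'
#' @return Character vector of registered form identifiers; the first is the
#'   default.
#' @export
urmk_forms <- function() names(.urmk_forms)

#' Parameter set of the ratcheting evolution model
#'
#' Bundles every symbol of the one-parameter-controlled ratcheting evolution
#' law `X_r(N) = K * X_SR * f(N; alpha, beta)` with
#' `X_SR = k_r * (e_r - e_rth)`:
#' the material coefficient `K`, the ratcheting coefficient `k_r` and
#' threshold `e_rth`, the per-condition evolution parameters `alpha`, `beta`
#' (or their linear-in-stress coefficients), and the functional-form id.
#'
#' @param K Material coefficient (dimensionless), > 0.
#' @param k_r Ratcheting coefficient (strain/MPa), > 0.
#' @param e_rth Ratcheting threshold (MPa), >= 0.
#' @param alpha,beta Per-condition evolution parameters; `NULL` when the
#'   linear relations are used instead.
#' @param alpha_intercept,alpha_slope Coefficients of `alpha(e_r)`.
#' @param beta_intercept,beta_slope Coefficients of `beta(e_r)`.
#' @param form_id Functional form, one of [urmk_forms()].
#' @return An object of class `urmk_params`.
#' @export
#' @examples
#' urmk_params()  # disc defaults: K = 0.01, relations fitted for sheep discs
urmk_params <- function(K = 0.01, k_r = 1, e_rth = 0,
                        alpha = NULL, beta = NULL,
                        alpha_intercept = 53.565, alpha_slope = 10.571,
                        beta_intercept = 0.13, beta_slope = -0.035,
                        form_id = urmk_forms()[1]) {
  if (!is.finite(K) || K <= 0) stop("`K` must be positive")
  if (!is.finite(k_r) || k_r <= 0) stop("`k_r` must be positive")
  if (!is.finite(e_rth) || e_rth < 0) stop("`e_rth` must be non-negative")
  form_id <- match.arg(form_id, urmk_forms())
  structure(list(K = K, k_r = k_r, e_rth = e_rth,
                 alpha = alpha, beta = beta,
                 alpha_intercept = alpha_intercept, alpha_slope = alpha_slope,
                 beta_intercept = beta_intercept, beta_slope = beta_slope,
                 form_id = form_id),
            class = "urmk_params")
}

#' @export
print.urmk_params <- function(x, ...) {
  cat("Ratcheting evolution model parameters (form:", x$form_id, ")\n")
  cat(sprintf("  K = %.4g, k_r = %.4g strain/MPa, e_rth = %.4g MPa\n",
              x$K, x$k_r, x$e_rth))
  if (!is.null(x$alpha) || !is.null(x$beta)) {
    cat(sprintf("  per-condition alpha = %s, beta = %s\n",
                format(x$alpha), format(x$beta)))
  } else {
    cat(sprintf("  alpha(e_r) = %.4g + %.4g e_r; beta(e_r) = %.4g + %.4g e_r\n",
                x$alpha_intercept, x$alpha_slope,
                x$beta_intercept, x$beta_slope))
  }
  invisible(x)
}

# resolve alpha/beta for a given stress: per-condition values win over relations
.resolve_evolution <- function(params, e_r) {
  alpha <- if (!is.null(params$alpha)) params$alpha
           else evolution_alpha(e_r, params$alpha_intercept, params$alpha_slope)
  beta <- if (!is.null(params$beta)) params$beta
          else params$beta_intercept + params$beta_slope * e_r
  list(alpha = alpha, beta = beta)
}

#' Evaluate the ratcheting evolution model
#'
#' Computes the ratcheting strain after `N` cycles at ratcheting stress `e_r`:
#' `X_r(N) = K * X_SR * f(N; alpha, beta)` where, under the default form,
#' `f(N) = 1 - alpha^(-N^beta)`. The output is strictly increasing in `N`,
#' bounded above by the saturation level `K * X_SR`, and (above threshold)
#' increasing in `e_r`.
#'
#' @param N Cycle numbers (>= 1); numeric vector.
#' @param e_r Ratcheting stress (MPa), scalar.
#' @param params A [urmk_params()] object. When its `alpha`/`beta` are `NULL`
#'   they are computed from the linear relations at `e_r`.
#' @return Ratcheting strain (dimensionless), same length as `N`.
#' @export
#' @examples
#' p <- urmk_params()
#' urmk_evaluate(1:5, e_r = 1.76, params = p)
urmk_evaluate <- function(N, e_r, params = urmk_params()) {
  stopifnot(inherits(params, "urmk_params"), length(e_r) == 1L)
  if (any(!is.finite(N)) || any(N < 1)) stop("`N` must be >= 1")
  form <- .urmk_forms[[params$form_id]]
  ev <- .resolve_evolution(params, e_r)
  form$validate(ev$alpha, ev$beta)
  amp <- params$K * saturated_strain(e_r, params$k_r, params$e_rth)
  amp * form$f(N, ev$alpha, ev$beta)
}

# ---- fitting -----------------------------------------------------------------

#' Fit the saturating ratcheting law to one ratcheting curve
#'
#' Nonlinear least squares of `amplitude * f(N; alpha, beta)` (plus an
#' optional additive offset) against a per-cycle ratcheting-strain curve,
#' with the amplitude `K * X_SR` free. A multi-start over a beta grid guards
#' the shallow-transient identifiability problem; the best-RSS converged
#' solution is returned together with the Pearson correlation between the
#' fitted curve and the data.
#'
#' @param curve A [ratcheting_curve()] object, or a data.frame/list with
#'   components `cycle` and `ratcheting_strain`.
#' @param form_id Functional form id, one of [urmk_forms()].
#' @param beta_grid Starting values for beta. Default
#'   `c(0.02, 0.05, 0.1, 0.2, 0.5)`.
#' @param fit_offset If `TRUE`, an additive constant is estimated alongside
#'   the model (needed for curves carrying an elastic mean-strain offset,
#'   e.g. those extracted from full stress-strain records). Default `FALSE`.
#' @param alpha_max Upper bound for alpha. Default `1e4`.
#' @return An object of class `urmk_fit`: list with `amplitude`, `alpha`,
#'   `beta`, `offset`, `rss`, `pearson_r`, `r_squared`, `fitted`, `degenerate`
#'   (flag for near-constant input), `form_id`, and `n_cycles`.
#' @export
fit_ratcheting_curve <- function(curve, form_id = urmk_forms()[1],
                                 beta_grid = c(0.02, 0.05, 0.1, 0.2, 0.5),
                                 fit_offset = FALSE, alpha_max = 1e4) {
  d <- as_curve_df(curve)
  N <- d$cycle
  y <- d$ratcheting_strain
  if (length(N) < 10L) stop("need at least 10 cycles to fit the model")
  form_id <- match.arg(form_id, urmk_forms())
  f <- .urmk_forms[[form_id]]$f

  degenerate <- stats::sd(y) < 1e-12 * max(1, abs(mean(y)))
  if (degenerate) {
    amp <- if (fit_offset) 0 else mean(y)
    fitted <- rep(if (fit_offset) mean(y) else amp, length(N))
    return(structure(list(amplitude = amp, alpha = NA_real_, beta = NA_real_,
                          offset = if (fit_offset) mean(y) else 0,
                          rss = sum((y - fitted)^2), pearson_r = NA_real_,
                          r_squared = NA_real_, fitted = fitted,
                          degenerate = TRUE, form_id = form_id,
                          n_cycles = length(N)),
                     class = "urmk_fit"))
  }

  # Variable projection: the model is linear in (amplitude, offset) given
  # (alpha, beta), so those are profiled out by ordinary least squares and
  # the Levenberg-Marquardt search runs over (alpha, beta) only. This sects
  # the near-collinearity between amplitude and offset when the transient is
  # shallow (saturation fraction already close to 1 at N = 1).
  profile_linear <- function(alpha, beta) {
    fv <- f(N, alpha, beta)
    X <- if (fit_offset) cbind(fv, 1) else cbind(fv)
    co <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(e) rep(NA_real_, ncol(X)))
    if (any(!is.finite(co))) co <- c(0, if (fit_offset) mean(y))
    list(A = co[1], c0 = if (fit_offset) co[2] else 0,
         fitted = as.numeric(X %*% co))
  }
  residual_fn <- function(par) {
    pl <- profile_linear(par[1], par[2])
    y - pl$fitted
  }

  beta_hi <- if (form_id == "power_saturating") 1 - 1e-8 else 5
  # alpha start from the first point: y1 close to the plateau means large alpha
  frac1 <- min(max((y[1] - min(y)) / max(max(y) - min(y), 1e-300), 1e-6),
               1 - 1e-6)
  alpha_starts <- unique(c(max(1.5, min(1 / (1 - frac1), alpha_max / 10)),
                           10, 100))

  best <- NULL
  for (b0 in beta_grid) {
    for (a0 in alpha_starts) {
      fit <- try(minpack.lm::nls.lm(
        par = c(alpha = a0, beta = b0), fn = residual_fn,
        lower = c(1 + 1e-8, 1e-6), upper = c(alpha_max, beta_hi),
        control = minpack.lm::nls.lm.control(maxiter = 400,
                                             ftol = 1e-14, ptol = 1e-14)),
        silent = TRUE)
      if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) next
      rss <- fit$deviance
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("model fit failed to converge from all starts (beta grid: ",
         paste(beta_grid, collapse = ", "), "); n = ", length(N),
         ", curve range = ", signif(max(y) - min(y), 4))

  par <- best$fit$par
  pl <- profile_linear(par[1], par[2])
  r <- suppressWarnings(stats::cor(pl$fitted, y))
  structure(list(amplitude = unname(pl$A), alpha = unname(par[1]),
                 beta = unname(par[2]), offset = unname(pl$c0),
                 rss = best$rss, pearson_r = r, r_squared = r^2,
                 fitted = pl$fitted, degenerate = FALSE,
                 form_id = form_id, n_cycles = length(N)),
            class = "urmk_fit")
}

#' @export
print.urmk_fit <- function(x, ...) {
  cat("Saturating ratcheting-law fit (form:", x$form_id, ")\n")
  if (x$degenerate) {
    cat("  degenerate (near-constant) curve; amplitude =",
        format(x$amplitude), "\n")
  } else {
    cat(sprintf("  amplitude = %.6g, alpha = %.4f, beta = %.4f%s\n",
                x$amplitude, x$alpha, x$beta,
                if (x$offset != 0) sprintf(", offset = %.6g", x$offset) else ""))
    cat(sprintf("  RSS = %.4g, Pearson R = %.4f over %d cycles\n",
                x$rss, x$pearson_r, x$n_cycles))
  }
  invisible(x)
}

#' Estimate the material coefficient K across conditions
#'
#' Given per-condition fitted amplitudes `A_i = K * X_SR(e_r_i)`, the material
#' coefficient is the least-squares slope of amplitude against saturated
#' ratcheting strain through the origin:
#' `K = sum(A_i X_SR_i) / sum(X_SR_i^2)`.
#'
#' @param amplitudes Fitted per-condition amplitudes.
#' @param e_r Ratcheting stresses (MPa), same length, at least two distinct.
#' @param k_r,e_rth Ratcheting coefficient and threshold used for `X_SR`.
#' @return The estimated material coefficient K (scalar).
#' @export
fit_material_coefficient <- function(amplitudes, e_r, k_r = 1, e_rth = 0) {
  if (length(amplitudes) != length(e_r))
    stop("`amplitudes` and `e_r` must have the same length")
  if (length(unique(e_r)) < 2L)
    stop("need at least 2 conditions with distinct ratcheting stress")
  xsr <- saturated_strain(e_r, k_r, e_rth)
  if (all(xsr == 0))
    stop("all saturated ratcheting strains are zero (stresses below threshold)")
  sum(amplitudes * xsr) / sum(xsr^2)
}

#' Fit the linear evolution-parameter relations
#'
#' Ordinary least-squares lines `alpha = a0 + a1 * e_r` and
#' `beta = b0 + b1 * e_r` through per-condition fitted evolution parameters.
#'
#' @param e_r Ratcheting stresses (MPa), at least two distinct values.
#' @param alpha,beta Per-condition fitted evolution parameters.
#' @return A list of class `urmk_relations`: `alpha_intercept`, `alpha_slope`,
#'   `beta_intercept`, `beta_slope`, and per-line `r_squared`.
#' @export
fit_parameter_relations <- function(e_r, alpha, beta) {
  if (length(unique(e_r)) < 2L)
    stop("need at least 2 distinct ratcheting stresses to fit the relations")
  stopifnot(length(alpha) == length(e_r), length(beta) == length(e_r))
  fa <- stats::lm(alpha ~ e_r)
  fb <- stats::lm(beta ~ e_r)
  r2 <- function(m) suppressWarnings(summary(m)$r.squared)
  structure(list(alpha_intercept = unname(stats::coef(fa)[1]),
                 alpha_slope = unname(stats::coef(fa)[2]),
                 beta_intercept = unname(stats::coef(fb)[1]),
                 beta_slope = unname(stats::coef(fb)[2]),
                 alpha_r_squared = r2(fa), beta_r_squared = r2(fb),
                 e_r = e_r, alpha = alpha, beta = beta),
            class = "urmk_relations")
}

#' @export
print.urmk_relations <- function(x, ...) {
  cat("Evolution-parameter relations (OLS):\n")
  cat(sprintf("  alpha(e_r) = %.4f + %.4f e_r   (R^2 = %.4f)\n",
              x$alpha_intercept, x$alpha_slope, x$alpha_r_squared))
  cat(sprintf("  beta(e_r)  = %.4f + %.4f e_r   (R^2 = %.4f)\n",
              x$beta_intercept, x$beta_slope, x$beta_r_squared))
  invisible(x)
}

#' Predict ratcheting strain evolution at a new stress level
#'
#' Evaluates the fitted model at an unseen ratcheting stress using the linear
#' evolution-parameter relations: `alpha(e_r_new)`, `beta(e_r_new)`,
#' `X_SR(e_r_new)` and the material coefficient `K`.
#'
#' @param e_r_new Ratcheting stress to predict at (MPa).
#' @param N Cycle numbers (>= 1).
#' @param relations A [fit_parameter_relations()] result, or a `urmk_params`
#'   object carrying the relation coefficients.
#' @param K Material coefficient.
#' @param k_r,e_rth Ratcheting coefficient and threshold.
#' @param extrapolation Allowed extrapolation beyond the training stress range
#'   (MPa); only enforced when `relations` carries its training stresses.
#'   Default 0.3; `Inf` disables the band check.
#' @param form_id Functional form id.
#' @return A [ratcheting_curve()] with the predicted evolution.
#' @export
predict_ratcheting <- function(e_r_new, N, relations, K = 0.01,
                               k_r = 1, e_rth = 0, extrapolation = 0.3,
                               form_id = urmk_forms()[1]) {
  stopifnot(length(e_r_new) == 1L)
  if (inherits(relations, "urmk_relations") && is.finite(extrapolation) &&
      !is.null(relations$e_r)) {
    lo <- min(relations$e_r) - extrapolation
    hi <- max(relations$e_r) + extrapolation
    if (e_r_new < lo || e_r_new > hi)
      stop("extrapolation error: e_r_new = ", e_r_new,
           " MPa outside the allowed band [", signif(lo, 4), ", ",
           signif(hi, 4), "] around the training stresses")
  }
  beta_new <- relations$beta_intercept + relations$beta_slope * e_r_new
  if (beta_new <= 0)
    stop("extrapolation error: beta(e_r_new) = ", signif(beta_new, 4),
         " <= 0; the evolution relations are invalid at e_r = ", e_r_new)
  p <- urmk_params(K = K, k_r = k_r, e_rth = e_rth,
                   alpha_intercept = relations$alpha_intercept,
                   alpha_slope = relations$alpha_slope,
                   beta_intercept = relations$beta_intercept,
                   beta_slope = relations$beta_slope,
                   form_id = form_id)
  xr <- urmk_evaluate(N, e_r_new, p)
  ratcheting_curve(cycle = N, ratcheting_strain = xr,
                   stress_variation = e_r_new, stress_rate = NA_real_,
                   segment = NA_character_)
}
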