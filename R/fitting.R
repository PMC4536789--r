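# Weighted nonlinear least-squares estimation of polymer-model parameters
# from contact profiles. Levenberg-Marquardt (minpack.lm) with box bounds
# and a multi-start grid; asymptotic standard errors from the Jacobian at
# the optimum.

#' Fitting options
#'
#' Tolerances and multi-start grids for the nonlinear least-squares fits.
#' The helix objective is oscillatory in `D` and `P`, so [fit_helix()]
#' launches one local search from every combination of `start_D`,
#' `start_P` and `start_S` (with `K` started from a closed-form scale
#' match at the smallest separation) and keeps the lowest-SSR converged
#' solution.
#'
#' @param ftol Relative reduction in the sum of squares below which a
#'   local search stops.
#' @param ptol Relative parameter-change tolerance.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param start_S Kuhn-segment starting values (kb) for the helix fit.
#' @param start_D,start_P Helix diameter / pitch starting grids (nm).
#' @param start_S_unconstrained Kuhn-segment starts for unconstrained fits.
#' @param start_L Linear-density starts (nm/kb) when `L` is fitted freely.
#' @param start_alpha Exponent starts for the power-law fit.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(ftol = 1e-10, ptol = 1e-10, maxiter = 1000,
                        start_S = c(2, 4),
                        start_D = c(100, 200, 300, 400),
                        start_P = c(50, 150, 250, 400),
                        start_S_unconstrained = c(1, 2, 4, 8),
                        start_L = c(5, 10, 15),
                        start_alpha = c(-0.5, -1, -1.5)) {
  structure(
    list(
      ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
      start_S = start_S, start_D = start_D, start_P = start_P,
      start_S_unconstrained = start_S_unconstrained,
      start_L = start_L, start_alpha = start_alpha
    ),
    class = "fit_control"
  )
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the mean of the observations. May be negative for a nonlinear model
#' that fits worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`.
#' @return A single number `<= 1`.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("`observed` has zero variance; R^2 is undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

# ---- internal machinery -----------------------------------------------------

.resolve_weights <- function(profile, weights = c("auto", "sem", "uniform")) {
  weights <- match.arg(weights)
  sem <- profile$sem
  have_sem <- all(is.finite(sem)) && all(sem > 0)
  if (weights == "sem" && !have_sem) {
    stop("weights = \"sem\" requires a positive SEM for every observation")
  }
  if (weights == "uniform" || (weights == "auto" && !have_sem)) {
    rep(1, nrow(profile))
  } else {
    1 / sem^2
  }
}

.num_jacobian <- function(fn, par) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]), 1e-12) * 1e-6
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  colnames(J) <- names(par)
  J
}

# Asymptotic standard errors from (J' W J)^-1 scaled by residual variance;
# NA when the (weighted) information matrix is singular (e.g. along the
# K/L scale degeneracy of the unconstrained model with L free).
.asymptotic_se <- function(model_fn, par, w, ssr_w, n) {
  p <- length(par)
  se <- rep(NA_real_, p)
  names(se) <- names(par)
  if (n <= p) return(se)
  J <- tryCatch(.num_jacobian(model_fn, par), error = function(e) NULL)
  if (is.null(J) || any(!is.finite(J))) return(se)
  jtj <- crossprod(J * sqrt(w))
  # a rank-deficient Jacobian (exactly parallel columns, e.g. K and L in
  # the unconstrained model) must not yield spurious finite errors
  if (!all(is.finite(jtj)) || rcond(jtj) < 1e-12) return(se)
  s2 <- ssr_w / (n - p)
  cov <- tryCatch(chol2inv(chol(jtj)) * s2, error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(par)
  se
}

# One multi-start bounded Levenberg-Marquardt minimisation of
# sum(w * (x - model_fn(par))^2). `starts` is a list of named numeric
# vectors; returns the best converged solution (or best overall with
# converged = FALSE when no start converges).
.ls_multistart <- function(x, w, model_fn, starts, lower, control) {
  ctrl <- minpack.lm::nls.lm.control(
    ftol = control$ftol, ptol = control$ptol,
    maxiter = min(control$maxiter, 1024L), maxfev = 100000L
  )
  sw <- sqrt(w)
  best <- NULL
  for (st in starts) {
    # individual starts may stall without harm; convergence is tracked
    # through `info`, so optimizer chatter is muffled
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st,
        fn = function(par) {
          f <- model_fn(par)
          if (any(!is.finite(f))) return(rep(1e150, length(x)))
          sw * (x - f)
        },
        lower = lower, control = ctrl
      )),
      error = function(e) NULL
    )
    if (is.null(res)) next
    cand <- list(
      par = stats::coef(res),
      ssr = res$deviance,
      converged = res$info %in% 1:4
    )
    better <- is.null(best) ||
      (cand$converged && !best$converged) ||
      (cand$converged == best$converged && cand$ssr < best$ssr)
    if (better) best <- cand
  }
  if (is.null(best)) {
    best <- list(par = starts[[1]], ssr = NA_real_, converged = FALSE)
  }
  best$n_starts <- length(starts)
  best
}

# Closed-form K (or k) start: match the model curve to the observation at
# the smallest separation.
.scale_match <- function(s, x, unit_curve) {
  i <- which.min(s)
  ref <- unit_curve[i]
  if (!is.finite(ref) || ref <= 0 || x[i] <= 0) 1 else x[i] / ref
}

.make_fit_result <- function(model_id, par, se, s, x, w, fit, model_fn,
                             sh_kb = NULL, fixed = NULL) {
  fitted <- model_fn(par)
  structure(
    list(
      model_id = model_id,
      params = par,
      stderr = se,
      fixed = fixed,
      r_squared = r_squared(x, fitted),
      ssr = fit$ssr,
      n_obs = length(x),
      converged = fit$converged,
      n_starts = fit$n_starts,
      sh_kb = sh_kb,
      fitted = fitted,
      residuals = x - fitted,
      weights = w,
      data = data.frame(separation_kb = s, frequency = x)
    ),
    class = "chromatin_fit"
  )
}

# ---- user-facing fits -------------------------------------------------------

#' Fit the unconstrained-chromatin model
#'
#' Estimates the local chromatin parameters of the combined FJC/WLC model
#' with the unconstrained reduced separation `beta = s/S` by weighted
#' nonlinear least squares. `L` may be held fixed (the mouse analyses fix
#' it from the nucleosome repeat length) or fitted freely. Note that `K`
#' and `L` enter the model only through `K * (L*S)^-3`, so with `L` free
#' only `S` and the overall amplitude are identifiable; the reported `L`
#' then stays near its starting value and its standard error is `NA`.
#'
#' @param profile A [contact_profile()] with at least 4 observations.
#' @param L Linear mass density handling: a positive number fixes `L`;
#'   `NULL` (default) uses the profile's `fixed_L` attribute if present and
#'   otherwise fits `L` freely; the string `"free"` forces a free `L`.
#' @param weights `"auto"` (inverse-variance `1/sem^2` when every
#'   observation has a positive SEM, else uniform), `"sem"`, or
#'   `"uniform"`.
#' @param control A [fit_control()] object.
#' @return A `chromatin_fit` object: fitted parameters, asymptotic
#'   standard errors, `r_squared`, weighted `ssr`, residuals and
#'   convergence metadata.
#' @examples
#' pr <- simulate_3c_profile(seq(2, 60, 2), K = 1, L = 9.7, S = 2.7)
#' fit_unconstrained(pr, L = 9.7)
#' @export
fit_unconstrained <- function(profile, L = NULL,
                              weights = c("auto", "sem", "uniform"),
                              control = fit_control()) {
  stopifnot(inherits(profile, "contact_profile"))
  if (is.null(L)) {
    L <- attr(profile, "fixed_L") # NULL => free
  } else if (identical(L, "free")) {
    L <- NULL
  } else {
    stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  }
  if (nrow(profile) < 4L) stop("at least 4 observations are required")
  s <- profile$separation_kb
  x <- profile$frequency
  w <- .resolve_weights(profile, weights)
  free_L <- is.null(L)

  if (free_L) {
    model_fn <- function(par) {
      model_curve(s, K = par[["K"]], L = par[["L"]], S = par[["S"]])
    }
    grid <- expand.grid(L = control$start_L, S = control$start_S_unconstrained)
    starts <- lapply(seq_len(nrow(grid)), function(i) {
      L0 <- grid$L[i]; S0 <- grid$S[i]
      K0 <- .scale_match(s, x, model_curve(s, K = 1, L = L0, S = S0))
      c(K = K0, L = L0, S = S0)
    })
    lower <- c(K = 0, L = 1e-6, S = 1e-6)
  } else {
    model_fn <- function(par) {
      model_curve(s, K = par[["K"]], L = L, S = par[["S"]])
    }
    starts <- lapply(control$start_S_unconstrained, function(S0) {
      K0 <- .scale_match(s, x, model_curve(s, K = 1, L = L, S = S0))
      c(K = K0, S = S0)
    })
    lower <- c(K = 0, S = 1e-6)
  }
  fit <- .ls_multistart(x, w, model_fn, starts, lower, control)
  se <- .asymptotic_se(model_fn, fit$par, w, fit$ssr, length(x))
  .make_fit_result("unconstrained", fit$par, se, s, x, w, fit, model_fn,
                   fixed = if (free_L) NULL else c(L = L))
}

#' Fit the statistical-helix model
#'
#' Estimates `K`, `S` and the supranucleosomal helix parameters `D` (mean
#' diameter, nm) and `P` (mean pitch, nm) by weighted nonlinear least
#' squares with a multi-start grid over `(D, P, S)` (the helix objective
#' is oscillatory and single starts stall in local minima). `L` is always
#' fixed, as in the mouse analyses where it derives from the nucleosome
#' repeat length. The helix-turn length `Sh` is computed from the fitted
#' `D`, `P` via [helix_turn_length()].
#'
#' @param profile A [contact_profile()] with at least 5 observations.
#' @param L Fixed linear mass density (nm/kb); defaults to the profile's
#'   `fixed_L` attribute.
#' @inheritParams fit_unconstrained
#' @return A `chromatin_fit` with `model_id = "helix"` and `sh_kb` set.
#' @examples
#' pr <- simulate_3c_profile(seq(5, 250, 5), K = 1.07e3, L = 9.7, S = 2.7,
#'                           D = 255, P = 201)
#' fit_helix(pr, L = 9.7)
#' @export
fit_helix <- function(profile, L = NULL,
                      weights = c("auto", "sem", "uniform"),
                      control = fit_control()) {
  stopifnot(inherits(profile, "contact_profile"))
  if (is.null(L)) L <- attr(profile, "fixed_L")
  if (is.null(L)) stop("the helix fit requires a fixed `L` (nm/kb)")
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (nrow(profile) < 5L) stop("at least 5 observations are required")
  s <- profile$separation_kb
  x <- profile$frequency
  w <- .resolve_weights(profile, weights)

  model_fn <- function(par) {
    model_curve(s, K = par[["K"]], L = L, S = par[["S"]],
                D = par[["D"]], P = par[["P"]])
  }
  grid <- expand.grid(D = control$start_D, P = control$start_P,
                      S = control$start_S)
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    D0 <- grid$D[i]; P0 <- grid$P[i]; S0 <- grid$S[i]
    K0 <- .scale_match(
      s, x, model_curve(s, K = 1, L = L, S = S0, D = D0, P = P0)
    )
    c(K = K0, S = S0, D = D0, P = P0)
  })
  lower <- c(K = 0, S = 1e-6, D = 0, P = 1e-6)
  fit <- .ls_multistart(x, w, model_fn, starts, lower, control)
  se <- .asymptotic_se(model_fn, fit$par, w, fit$ssr, length(x))
  sh <- helix_turn_length(D = fit$par[["D"]], P = fit$par[["P"]], L = L)
  .make_fit_result("helix", fit$par, se, s, x, w, fit, model_fn,
                   sh_kb = sh, fixed = c(L = L))
}

#' Fit a globule power law
#'
#' Fits `X(s) = k * s^alpha` by nonlinear least squares on the linear
#' scale (not a log-log regression), as used to compare observed decay
#' curves against the equilibrium-globule (`alpha = -3/2`) and crumpled-
#' globule (`alpha = -1`) scalings.
#'
#' @param profile A [contact_profile()] with at least 3 observations.
#' @inheritParams fit_unconstrained
#' @return A `chromatin_fit` with `model_id = "powerlaw"` and parameters
#'   `k`, `alpha`.
#' @examples
#' pr <- simulate_3c_profile(seq(5, 100, 5), K = 1, L = 10, S = 3)
#' fit_powerlaw(pr)
#' @export
fit_powerlaw <- function(profile, weights = c("auto", "sem", "uniform"),
                         control = fit_control()) {
  stopifnot(inherits(profile, "contact_profile"))
  if (nrow(profile) < 3L) stop("at least 3 observations are required")
  s <- profile$separation_kb
  x <- profile$frequency
  w <- .resolve_weights(profile, weights)
  model_fn <- function(par) powerlaw_frequency(s, k = par[["k"]],
                                               alpha = par[["alpha"]])
  starts <- lapply(control$start_alpha, function(a0) {
    k0 <- .scale_match(s, x, s^a0)
    c(k = k0, alpha = a0)
  })
  lower <- c(k = 1e-300, alpha = -Inf)
  fit <- .ls_multistart(x, w, model_fn, starts, lower, control)
  se <- .asymptotic_se(model_fn, fit$par, w, fit$ssr, length(x))
  .make_fit_result("powerlaw", fit$par, se, s, x, w, fit, model_fn)
}

# ---- result methods ---------------------------------------------------------

#' @export
coef.chromatin_fit <- function(object, ...) object$params

#' @export
print.chromatin_fit <- function(x, ...) {
  cat(sprintf("<chromatin_fit: %s model>\n", x$model_id))
  tab <- data.frame(
    estimate = signif(x$params, 6),
    std.error = signif(x$stderr, 3)
  )
  print(tab)
  if (!is.null(x$fixed)) {
    cat(sprintf("fixed: %s\n",
                paste(names(x$fixed), signif(x$fixed, 6),
                      sep = " = ", collapse = ", ")))
  }
  if (!is.null(x$sh_kb)) {
    cat(sprintf("helix turn Sh = %.1f kb\n", x$sh_kb))
  }
  cat(sprintf("R^2 = %.4f | weighted SSR = %.6g | n = %d | converged = %s (%d starts)\n",
              x$r_squared, x$ssr, x$n_obs, x$converged, x$n_starts))
  invisible(x)
}

#' Flatten a fit into a one-row table
#'
#' @param x A `chromatin_fit`.
#' @param row.names,optional,... Passed for S3 completeness; unused.
#' @return A one-row `data.frame` with the model id, parameter estimates
#'   (`NA` for parameters the model lacks), standard errors, `R^2`,
#'   weighted SSR, helix-turn length and convergence metadata.
#' @export
as.data.frame.chromatin_fit <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  all_par <- c("K", "L", "S", "D", "P", "k", "alpha")
  est <- se <- stats::setNames(rep(NA_real_, length(all_par)), all_par)
  est[names(x$params)] <- x$params
  se[names(x$params)] <- x$stderr
  if (!is.null(x$fixed)) est[names(x$fixed)] <- x$fixed
  out <- data.frame(model_id = x$model_id, t(est))
  names(out)[-1] <- all_par
  se_df <- data.frame(t(se))
  names(se_df) <- paste0("se_", all_par)
  cbind(out, se_df,
        data.frame(sh_kb = if (is.null(x$sh_kb)) NA_real_ else x$sh_kb,
                   r_squared = x$r_squared, ssr = x$ssr, n_obs = x$n_obs,
                   converged = x$converged, n_starts = x$n_starts))
}

#' Compare fits of one profile
#'
#' Builds a flat comparison table from several fits of the same profile,
#' sorted by `R^2` (descending); ties are broken by model id so the order
#' is stable.
#'
#' @param ... `chromatin_fit` objects, or a single list of them.
#' @return A `data.frame`, one row per fit (see
#'   [as.data.frame.chromatin_fit()]).
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "chromatin_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "chromatin_fit")))
  tab <- do.call(rbind, lapply(fits, as.data.frame))
  tab <- tab[order(-tab$r_squared, tab$model_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
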