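#' Configuration for seasonal spline fitting
#'
#' The seasonal curve of each lake is a natural cubic smoothing spline in
#' week-of-year minimizing `sum (y - f(w))^2 + lambda * integral f''(w)^2 dw`
#' with the predictor in week units, so `lambda` has a fixed, tool-independent
#' meaning: `lambda = 1` tracks seasonal bumps a few weeks wide while
#' suppressing week-to-week noise; large `lambda` degenerates to the
#' least-squares line.
#'
#' `trim` drives an optional robust-fitting mode (off by default): the fit is
#' repeated while excluding observations whose absolute residual exceeds the
#' `trim` quantile of absolute residuals, until the exclusion set stabilizes.
#'
#' @param lambda Roughness penalty weight (> 0), week units; default 1.0.
#' @param trim Quantile in `[0, 1)` used by the robust mode; default 0.6.
#' @param trim_mode Enable iterative quantile trimming (default FALSE).
#' @param min_obs Minimum non-NA weeks required to fit a lake (default 10).
#' @param prediction_floor Predictions are clamped to this floor (ug/L)
#'   before dividing for relative residuals (default 0.1, a typical MDL).
#' @return A list of class `"spline_config"`.
#' @export
spline_config <- function(lambda = 1.0, trim = 0.6, trim_mode = FALSE,
                          min_obs = 10L, prediction_floor = 0.1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    abort_config("lambda", "must be > 0")
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 1)
    abort_config("trim", "must be in [0, 1)")
  if (!is.logical(trim_mode) || length(trim_mode) != 1L)
    abort_config("trim_mode", "must be TRUE or FALSE")
  if (!is_count(min_obs, min = 4L))
    abort_config("min_obs", "must be an integer >= 4")
  if (!is.numeric(prediction_floor) || prediction_floor <= 0)
    abort_config("prediction_floor", "must be > 0")
  structure(list(lambda = lambda, trim = trim, trim_mode = trim_mode,
                 min_obs = as.integer(min_obs),
                 prediction_floor = prediction_floor),
            class = "spline_config")
}

# penalized natural cubic smoothing spline with the penalty measured in
# predictor (week) units; smooth.spline scales x to [0,1] internally and
# integrates f''(t)^2 over that scale, hence the range^3 conversion.
# smooth.spline's B-spline computations degrade for extreme penalties, so
# beyond a conservative threshold the exact eigen-based operator solves the
# same objective instead (its fit is a natural cubic spline through the
# smoothed knot values, extended linearly outside).
fit_penalized_spline <- function(x, y, lambda) {
  r <- diff(range(x))
  if (lambda / r^3 <= 1e3)
    return(stats::smooth.spline(x, y, lambda = lambda / r^3,
                                all.knots = TRUE, keep.data = FALSE))
  ord <- order(x)
  ops <- spline_operators(x[ord], lambda)
  structure(list(x = x[ord], g = drop(ops$S %*% y[ord]), lambda = lambda),
            class = "gs_spline")
}

#' @export
predict.gs_spline <- function(object, x, deriv = 0, ...) {
  if (deriv != 0)
    abort_contract("derivatives are not available in the large-penalty regime")
  stats::spline(object$x, object$g, xout = x, method = "natural")
}

# Exact linear operators of the penalized natural cubic smoothing spline
# (Green & Silverman banded formulation, solved densely; series are short):
# S, the smoother matrix on the fitted knots, and W, the weights expressing
# predictions at arbitrary points x0 as linear functionals of the fitted
# observations (natural-spline interpolation between knots, linear
# extrapolation outside). Used to put in-sample and out-of-sample residuals
# on a common variance footing for inference.
spline_operators <- function(xb, lambda, x0 = numeric()) {
  n <- length(xb)
  h <- diff(xb)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j,     i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) { R[i, i + 1] <- h[j] / 6; R[i + 1, i] <- h[j] / 6 }
  }
  Rinv_Qt <- solve(R, t(Q))
  # eigen-based inverse of I + lambda*K stays stable for arbitrarily large
  # penalties (direct solve() turns singular once lambda*K dominates)
  K <- Q %*% Rinv_Qt
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eK$values
  d[d < max(d) * 1e-10] <- 0   # exact null space (constant + linear trend)
  shrink <- 1 / (1 + lambda * d)
  S <- eK$vectors %*% (t(eK$vectors) * shrink)
  G <- Rinv_Qt %*% S                 # second derivatives at knots, as rows on y
  W <- NULL
  if (length(x0)) {
    W <- matrix(0, length(x0), n)
    gamma_full <- rbind(0, G, 0)     # natural boundary: zero curvature
    for (k in seq_along(x0)) {
      x <- x0[k]
      if (x <= xb[1]) {              # linear extrapolation from the left end
        slope <- (S[2, ] - S[1, ]) / h[1] - h[1] / 6 * (2 * gamma_full[1, ] + gamma_full[2, ])
        W[k, ] <- S[1, ] - (xb[1] - x) * slope
      } else if (x >= xb[n]) {       # ... and from the right end
        slope <- (S[n, ] - S[n - 1, ]) / h[n - 1] +
          h[n - 1] / 6 * (gamma_full[n - 1, ] + 2 * gamma_full[n, ])
        W[k, ] <- S[n, ] + (x - xb[n]) * slope
      } else {
        j <- findInterval(x, xb)
        hj <- h[j]; a <- xb[j + 1] - x; b <- x - xb[j]
        W[k, ] <- (a * S[j, ] + b * S[j + 1, ]) / hj -
          a * b / 6 * ((1 + a / hj) * gamma_full[j, ] +
                       (1 + b / hj) * gamma_full[j + 1, ])
      }
    }
  }
  list(S = S, W = W)
}

#' Fit one lake's seasonal chlorophyll-a curve
#'
#' Fits the penalized smoothing spline over week-of-year and returns
#' predictions, residuals (observed minus predicted, ug/L) and relative
#' residuals (observed divided by floored predicted) at the observed weeks.
#' Lakes with fewer than `min_obs` usable weeks are not fitted: the result
#' is returned with `converged = FALSE` rather than an error, so sparse
#' lakes are flagged, never silently dropped.
#'
#' `fit_weeks` restricts which weeks the curve is *estimated* from
#' (predictions and residuals still cover every observed week). The residual
#' pipeline uses it to keep smoke-exposed weeks out of the baseline so the
#' seasonal curve is not dragged toward the very response being tested.
#'
#' Because weeks inside the fitting set are in-sample (their residuals are
#' shrunk by the smoother's leverage) while excluded weeks are out-of-sample,
#' the fit also carries `std_residual`: residuals of excluded weeks are kept
#' as is (they are unbiased for any signal added on top of the baseline),
#' while in-sample residuals are rescaled to the lake's average out-of-sample
#' residual variance using the exact smoother and prediction operators. All
#' weeks then share a common variance under iid noise, which keeps downstream
#' group comparisons calibrated. The raw `residual` always reconstructs the
#' observation exactly.
#'
#' @param chla Weekly chlorophyll-a values (NAs allowed).
#' @param week Week indices (default positions).
#' @param config A [spline_config()].
#' @param lake_id Identifier carried into the result.
#' @param fit_weeks Optional logical mask (same length) of weeks eligible for
#'   curve estimation; default all.
#' @return An object of class `"seasonal_fit"`: a list with `lake_id`,
#'   `week`, `observed`, `predicted`, `residual`, `std_residual`,
#'   `relative_residual` (aligned with `week`), `n_used`, `converged`, and
#'   the fitted `spline` (NULL when unfit).
#' @export
fit_seasonal_spline <- function(chla, week = seq_along(chla),
                                config = spline_config(),
                                lake_id = NA_character_,
                                fit_weeks = NULL) {
  if (!inherits(config, "spline_config"))
    abort_config("config", "must be created with spline_config()")
  if (length(week) != length(chla))
    abort_validation("week and chla must have the same length")
  if (any(!is.na(chla) & !is.finite(chla)))
    abort_validation("chlorophyll-a values must be finite or NA")
  fit_weeks <- fit_weeks %||% rep(TRUE, length(chla))
  if (length(fit_weeks) != length(chla))
    abort_validation("fit_weeks and chla must have the same length")
  obs <- which(!is.na(chla))
  fitset <- which(!is.na(chla) & fit_weeks)
  unfit <- function() {
    structure(list(lake_id = lake_id, week = week, observed = chla,
                   predicted = rep(NA_real_, length(chla)),
                   residual = rep(NA_real_, length(chla)),
                   std_residual = rep(NA_real_, length(chla)),
                   relative_residual = rep(NA_real_, length(chla)),
                   n_used = length(fitset), converged = FALSE, spline = NULL,
                   prediction_floor = config$prediction_floor),
              class = "seasonal_fit")
  }
  if (length(fitset) < config$min_obs || length(unique(week[fitset])) < 4L)
    return(unfit())

  use <- fitset
  fit <- fit_penalized_spline(week[use], chla[use], config$lambda)
  if (config$trim_mode) {
    for (it in seq_len(10L)) {
      res_fit <- chla[fitset] - predict(fit, week[fitset])$y
      thr <- quantile(abs(res_fit), config$trim, names = FALSE)
      # degenerate spread (e.g. noiseless data): nothing is an outlier
      if (thr <= 1e-8 * max(abs(chla[fitset]), 1)) break
      keep <- fitset[abs(res_fit) <= thr]
      if (length(keep) < max(config$min_obs, 4L) || identical(keep, use)) break
      use <- keep
      fit <- fit_penalized_spline(week[use], chla[use], config$lambda)
    }
  }
  predicted <- rep(NA_real_, length(chla))
  predicted[obs] <- predict(fit, week[obs])$y
  residual <- chla - predicted
  # variance-standardized residuals for inference: out-of-sample residuals
  # (weeks excluded from the fit) are unbiased for any added signal and are
  # left unscaled; in-sample residuals are shrunk by the smoother, so they
  # are rescaled to the average out-of-sample variance of this lake. Under
  # iid noise both groups then share the same variance, keeping downstream
  # ANOVAs calibrated without biasing event-week effect estimates.
  std_residual <- residual
  ord <- use[order(week[use])]
  held_out <- setdiff(obs, use)
  ops <- spline_operators(week[ord], config$lambda, x0 = week[held_out])
  var_in <- 1 - 2 * diag(ops$S) + rowSums(ops$S^2)
  v_out_mean <- if (length(held_out)) mean(1 + rowSums(ops$W^2)) else 1
  std_residual[ord] <- residual[ord] * sqrt(v_out_mean / pmax(var_in, 1e-8))
  relative <- chla / pmax(predicted, config$prediction_floor)
  structure(list(lake_id = lake_id, week = week, observed = chla,
                 predicted = predicted, residual = residual,
                 std_residual = std_residual,
                 relative_residual = relative, n_used = length(use),
                 converged = TRUE, spline = fit,
                 prediction_floor = config$prediction_floor),
            class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("<seasonal_fit> lake %s: %s (n_used = %d)\n", x$lake_id,
              if (x$converged) "fitted" else "unfit (too few observations)",
              x$n_used))
  invisible(x)
}

#' Residual table of a fitted lake
#'
#' @param series Observed weekly chlorophyll-a (NAs propagate).
#' @param fit A converged [fit_seasonal_spline()] result for that series.
#' @return Tibble: `week`, `observed`, `predicted`, `residual`,
#'   `relative_residual`.
#' @export
compute_residuals <- function(series, fit) {
  if (!inherits(fit, "seasonal_fit")) abort_contract("fit must be a seasonal_fit")
  if (!fit$converged) abort_contract("residuals require a converged fit")
  if (length(series) != length(fit$week))
    abort_validation("series length does not match the fit")
  predicted <- predict(fit$spline, fit$week)$y
  floor_p <- pmax(predicted, fit$prediction_floor %||% 0.1)
  tibble::tibble(week = fit$week, observed = series, predicted = predicted,
                 residual = series - predicted,
                 relative_residual = series / floor_p)
}

#' Fit seasonal splines for every lake in a record table
#'
#' With `baseline = "no_smoke"` (the default) each lake's seasonal curve is
#' estimated from its no-smoke weeks only, additionally excluding the
#' `exclude_after` weeks following every smoke week (the ephemeral response
#' window), so the baseline is not contaminated by the smoke response being
#' measured; residuals are still computed at every observed week. Longer
#' shadows widen the gaps the baseline must bridge, which inflates the
#' prediction variance and correlation of event-week residuals and degrades
#' the calibration of pooled inference, so the default masks one week.
#' `baseline = "all"` fits every observed week (the conventional
#' full-series fit, which partially absorbs event weeks into the curve).
#'
#' @param records Lake-week records (needs `lake_id`, `week_index`, `chla`;
#'   `label` for the masked baseline).
#' @param config A [spline_config()].
#' @param baseline `"no_smoke"` or `"all"`.
#' @param exclude_after Weeks after each smoke week also excluded from the
#'   masked baseline (default 1, the modal persistence of the response).
#' @return A list: `residuals`, a tibble of per-week rows (`lake_id`,
#'   `week_index`, `observed`, `predicted`, `residual`, `std_residual`,
#'   `relative_residual` plus any `at_mdl`, `density`, `label`, `week_start`
#'   columns present in the input), and `fits`, one row per lake (`lake_id`,
#'   `n_used`, `converged`). Residual columns of unfit lakes are NA.
#' @export
fit_lake_splines <- function(records, config = spline_config(),
                             baseline = c("no_smoke", "all"),
                             exclude_after = 1L) {
  baseline <- match.arg(baseline)
  # without exposure labels there is nothing to mask
  if (baseline == "no_smoke" && !"label" %in% names(records))
    baseline <- "all"
  records <- dplyr::arrange(records, .data$lake_id, .data$week_index)
  idx_by_lake <- split(seq_len(nrow(records)), records$lake_id)
  ids <- names(idx_by_lake)
  n <- nrow(records)
  predicted <- residual <- std_residual <- relative <- rep(NA_real_, n)
  n_used <- integer(length(ids))
  converged <- logical(length(ids))
  chla_all <- records$chla
  week_all <- records$week_index
  label_all <- if ("label" %in% names(records)) records$label else NULL
  for (i in seq_along(ids)) {
    idx <- idx_by_lake[[i]]
    mask <- if (baseline == "no_smoke")
      baseline_mask(label_all[idx], exclude_after) else NULL
    f <- fit_seasonal_spline(chla_all[idx], week_all[idx], config,
                             lake_id = ids[i], fit_weeks = mask)
    predicted[idx] <- f$predicted
    residual[idx] <- f$residual
    std_residual[idx] <- f$std_residual
    relative[idx] <- f$relative_residual
    n_used[i] <- f$n_used
    converged[i] <- f$converged
  }
  carry <- intersect(c("week_start", "at_mdl", "density", "label"), names(records))
  residuals <- tibble::tibble(
    lake_id = records$lake_id, week_index = week_all, observed = chla_all,
    predicted = predicted, residual = residual, std_residual = std_residual,
    relative_residual = relative)
  residuals[carry] <- records[carry]
  fits <- tibble::tibble(lake_id = ids, n_used = n_used, converged = converged)
  if (any(!converged))
    inform(sprintf("seasonal fit skipped for %d lake(s) with fewer than %d usable weeks",
                   sum(!converged), config$min_obs))
  list(residuals = residuals, fits = fits)
}

# weeks eligible for baseline estimation: labelled no-smoke and not within
# the post-event shadow of any smoke week (NA-labelled weeks are excluded)
baseline_mask <- function(label, exclude_after = 2L) {
  n <- length(label)
  mask <- !is.na(label) & label == "no_smoke"
  if (exclude_after >= 1L) {
    for (w in which(!is.na(label) & label == "smoke")) {
      shadow <- (w + 1L):(w + exclude_after)
      mask[shadow[shadow <= n]] <- FALSE
    }
  }
  mask
}
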