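# Exposure-response estimation: a Poisson log-link additive model for daily
# admission counts with day-of-week indicators, a linear lagged-exposure
# term and natural cubic spline smooths of calendar time and weather.
# Smoothness and the single-day exposure lag are chosen by AIC.

#' Build the regression design for the admissions model
#'
#' Columns: intercept; six day-of-week indicators (Monday reference); the
#' exposure series lagged by `lag` days (linear, per ug/m^3); a natural
#' cubic spline basis for calendar time; one spline basis per requested
#' confounder. A smooth with `df = 1` degenerates to a plain linear term.
#' Rows whose lagged exposure would precede the series are dropped.
#'
#' @param dataset Data frame with `date`, `admissions`, `pm10_ugm3` and the
#'   confounder columns named in `smooth_df`.
#' @param lag Exposure lag in days, >= 0.
#' @param smooth_df Named list/vector of spline df, e.g.
#'   `list(time = 4, t_max = 3, pressure_hpa = 3)`; `time` refers to
#'   calendar time, other names to columns of `dataset`.
#' @return A list of class `gam_design`: `X` (model matrix), `y` (counts),
#'   `pm10_col`, `lag`, `smooth_df`, `n`, `dates`.
#' @export
build_design <- function(dataset, lag,
                         smooth_df = list(time = 4, t_max = 3,
                                          pressure_hpa = 3)) {
  stopifnot(is.data.frame(dataset),
            all(c("date", "admissions", "pm10_ugm3") %in% names(dataset)))
  stop_if_not_scalar_number(lag, "lag", lower = 0)
  lag <- as.integer(lag)
  smooth_df <- as.list(smooth_df)
  n0 <- nrow(dataset)
  total_df <- sum(unlist(smooth_df))
  if (n0 <= lag + total_df + 8) {
    stop("dataset too short for the requested lag and smooth df",
         call. = FALSE)
  }
  keep <- (lag + 1):n0
  y <- dataset$admissions[keep]
  dates <- as.Date(dataset$date)[keep]
  pm_lag <- dataset$pm10_ugm3[keep - lag]

  dow <- factor(dow_index(dates), levels = 1:7,
                labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  dow_mat <- stats::model.matrix(~dow)[, -1, drop = FALSE]

  smooth_basis <- function(x, df, label) {
    if (df >= nrow(dataset)) {
      stop("requested df exceeds available rows for smooth '", label, "'",
           call. = FALSE)
    }
    if (df <= 1) {
      m <- matrix(x, ncol = 1)
      colnames(m) <- paste0(label, "_lin")
    } else {
      m <- splines::ns(x, df = df)
      colnames(m) <- paste0(label, "_ns", seq_len(ncol(m)))
    }
    m
  }
  parts <- list(`(Intercept)` = matrix(1, length(y), 1,
                                       dimnames = list(NULL, "(Intercept)")),
                dow = dow_mat,
                pm10 = matrix(pm_lag, ncol = 1,
                              dimnames = list(NULL, "pm10_lag")))
  for (nm in names(smooth_df)) {
    x <- if (nm == "time") as.numeric(dates - dates[1]) else {
      if (!nm %in% names(dataset)) {
        stop("confounder column '", nm, "' not in dataset", call. = FALSE)
      }
      dataset[[nm]][keep]
    }
    parts[[nm]] <- smooth_basis(x, smooth_df[[nm]], nm)
  }
  X <- do.call(cbind, parts)
  structure(list(X = X, y = y, pm10_col = which(colnames(X) == "pm10_lag"),
                 lag = lag, smooth_df = smooth_df, n = length(y),
                 dates = dates),
            class = "gam_design")
}

#' Fit the Poisson log-link admissions model
#'
#' Maximum likelihood by iteratively reweighted least squares
#' (`stats::glm`), with the exposure coefficient, its standard error from
#' the observed information, the 95% confidence interval (beta +/- 1.96 SE)
#' and AIC (= -2 loglik + 2 * number of parameters). A Pearson dispersion
#' diagnostic is attached; overdispersion is not modelled.
#'
#' @param design A `gam_design` from [build_design()].
#' @return An object of class `gam_fit` with fields `beta`, `se`, `ci95`,
#'   `alpha`, `lag`, `smooth_df`, `aic`, `n_obs`, `dispersion`,
#'   `coefficients`, `fitted`.
#' @export
fit_poisson_gam <- function(design) {
  stopifnot(inherits(design, "gam_design"))
  df <- as.data.frame(design$X[, -1, drop = FALSE])
  df$.y <- design$y
  fit <- stats::glm(.y ~ ., data = df, family = stats::poisson(),
                    control = stats::glm.control(maxit = 100))
  if (!fit$converged) {
    stop("Poisson IRLS did not converge within 100 iterations",
         call. = FALSE)
  }
  p <- ncol(design$X)
  if (fit$rank < p) {
    stop("rank-deficient design (", fit$rank, " < ", p, " columns)",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  # glm mangles non-syntactic column names; match by position instead
  beta <- as.numeric(sm[design$pm10_col, 1])
  se <- as.numeric(sm[design$pm10_col, 2])
  mu <- fit$fitted.values
  structure(list(
    beta = beta, se = se,
    ci95 = confidence_interval(beta, se, 0.95),
    alpha = as.numeric(sm[1, 1]),
    lag = design$lag, smooth_df = design$smooth_df,
    aic = fit$aic, n_obs = design$n,
    dispersion = sum((design$y - mu)^2 / mu) / (design$n - p),
    coefficients = stats::coef(fit),
    fitted = as.numeric(mu)
  ), class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Poisson exposure-response fit (n = %d, lag = %d d)\n",
           "  beta  = %.4g per ug/m3 (%.4g per mg/m3)\n",
           "  SE    = %.4g; 95%% CI (%.4g, %.4g) per ug/m3\n",
           "  RR per 10 ug/m3 = %.4f\n",
           "  AIC = %.2f; dispersion = %.3f\n"),
    x$n_obs, x$lag, x$beta, x$beta * 1000, x$se, x$ci95[1], x$ci95[2],
    relative_risk(x$beta, 10), x$aic, x$dispersion))
  invisible(x)
}

#' Select lag and smoothness by exhaustive AIC search
#'
#' Fits every combination of candidate lag and per-smooth df and returns
#' the fit with the smallest AIC; ties break toward fewer total df, then
#' the smaller lag. The full candidate grid (lag, df, AIC) is attached as
#' attribute `"candidates"`.
#'
#' @param dataset As in [build_design()].
#' @param lag_candidates Integer vector of single-day lags (default 0:7).
#' @param df_grid Named list of candidate df vectors per smooth term,
#'   e.g. `list(time = c(4, 6, 8), t_max = 3, pressure_hpa = 3)`.
#' @return The winning `gam_fit`.
#' @export
select_model <- function(dataset, lag_candidates = 0:7,
                         df_grid = list(time = c(4, 6, 8), t_max = 3,
                                        pressure_hpa = 3)) {
  if (!length(lag_candidates)) stop("no candidate lags", call. = FALSE)
  combos <- expand.grid(c(list(lag = lag_candidates),
                          lapply(df_grid, as.numeric)))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sdf <- as.list(combos[i, -1, drop = FALSE])
    fits[[i]] <- tryCatch(
      fit_poisson_gam(build_design(dataset, combos$lag[i], sdf)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)
  aic <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
  tot_df <- rowSums(combos[, -1, drop = FALSE])
  best <- fits[[rank_candidates(aic, tot_df, combos$lag)[1]]]
  attr(best, "candidates") <- cbind(combos, aic = aic)
  best
}

# Candidate ordering: smallest AIC first; AIC ties break toward fewer
# total df, then the smaller lag.
rank_candidates <- function(aic, total_df, lag) {
  order(aic, total_df, lag)
}

#' Wald confidence interval for the exposure coefficient
#'
#' @param beta Point estimate.
#' @param se Standard error, >= 0.
#' @param level Confidence level in (0, 1); at 0.95 the conventional
#'   z = 1.96 is used.
#' @return `c(lower, upper)`.
#' @export
confidence_interval <- function(beta, se, level = 0.95) {
  stop_if_not_scalar_number(level, "level")
  if (level <= 0 || level >= 1) {
    stop("confidence level must be in (0, 1)", call. = FALSE)
  }
  if (!is.finite(se) || se < 0) stop("se must be >= 0", call. = FALSE)
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

#' Relative risk for a concentration increment
#'
#' `RR = exp(beta * delta_c)`, the rate ratio between exposure levels
#' `delta_c` apart.
#'
#' @param beta Exposure-response coefficient, per ug/m^3.
#' @param delta_c Concentration increment, ug/m^3, >= 0.
#' @return The relative risk.
#' @export
relative_risk <- function(beta, delta_c) {
  if (any(delta_c < 0)) stop("delta_c must be >= 0", call. = FALSE)
  exp(beta * delta_c)
}
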