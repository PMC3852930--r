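# Variogram modelling for the station-to-grid interpolation. The study
# domain is small (fractions of a degree), so distances are planar degrees.

#' Construct a variogram model
#'
#' Semivariance `gamma(h)` for the three classic bounded families, using the
#' practical-range convention for the exponential and gaussian models.
#'
#' @param model One of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget Nugget variance, >= 0.
#' @param sill Total sill (nugget + partial sill), > 0.
#' @param range Range parameter in degrees, > 0.
#' @return An object of class `variogram_model`.
#' @export
variogram_model <- function(model = c("spherical", "exponential", "gaussian"),
                            nugget = 0, sill, range) {
  model <- match.arg(model)
  stop_if_not_scalar_number(nugget, "nugget", lower = 0)
  stop_if_not_scalar_number(sill, "sill", lower = 1e-300)
  stop_if_not_scalar_number(range, "range", lower = 1e-300)
  if (sill < nugget) stop("sill must be >= nugget", call. = FALSE)
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s, nugget %.4g, sill %.4g, range %.4g deg\n",
              x$model, x$nugget, x$sill, x$range))
  invisible(x)
}

#' Evaluate the semivariance of a variogram model
#'
#' @param vgm A [variogram_model()].
#' @param h Distances (degrees), >= 0.
#' @return Semivariances; `vgm_gamma(vgm, 0)` is 0 by convention (the nugget
#'   acts only at h > 0).
#' @export
vgm_gamma <- function(vgm, h) {
  psill <- vgm$sill - vgm$nugget
  a <- vgm$range
  g <- switch(vgm$model,
    spherical = ifelse(h >= a, psill,
                       psill * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = psill * (1 - exp(-3 * h / a)),
    gaussian = psill * (1 - exp(-3 * (h / a)^2))
  )
  ifelse(h > 0, vgm$nugget + g, 0)
}

#' Fit a variogram model to station data by weighted least squares
#'
#' Builds the empirical (Matheron) semivariogram from all station pairs,
#' bins it by distance, and fits the chosen model by Cressie-weighted least
#' squares (weights N_j / gamma_model^2). The nugget is fixed at 0 by
#' default, which makes ordinary kriging an exact interpolator at the
#' stations.
#'
#' @param coords Two-column matrix or data frame of (lon, lat) in degrees.
#' @param values Observed values at the coordinates.
#' @param model Variogram family, see [variogram_model()].
#' @param nugget Fixed nugget (default 0); set `estimate_nugget = TRUE` to
#'   fit it instead.
#' @param estimate_nugget Fit the nugget as a free parameter?
#' @param n_bins Number of distance bins for the empirical variogram.
#' @param cutoff Maximum pair distance used (default: half the largest
#'   inter-station distance).
#' @return A fitted [variogram_model()] with the empirical variogram attached
#'   as attribute `"empirical"`.
#' @export
fit_variogram <- function(coords, values,
                          model = c("spherical", "exponential", "gaussian"),
                          nugget = 0, estimate_nugget = FALSE,
                          n_bins = 12, cutoff = NULL) {
  model <- match.arg(model)
  coords <- as.matrix(as.data.frame(coords)[, 1:2])
  n <- nrow(coords)
  if (n < 3) stop("variogram fitting needs at least 3 stations", call. = FALSE)
  d <- dist_deg(coords)
  if (any(d[upper.tri(d)] < 1e-12)) {
    stop("duplicate station locations", call. = FALSE)
  }
  if (stats::var(values) < 1e-300) {
    warning("all station values identical; returning a degenerate variogram")
    return(variogram_model(model, nugget = 0, sill = 1e-6,
                           range = max(d)))
  }
  iu <- upper.tri(d)
  h <- d[iu]
  sv <- 0.5 * outer(values, values, "-")[iu]^2
  if (is.null(cutoff)) cutoff <- max(h) / 2
  keep <- h <= cutoff
  if (sum(keep) < 3) { # tiny networks: use every pair
    keep <- rep(TRUE, length(h))
    cutoff <- max(h)
  }
  h <- h[keep]; sv <- sv[keep]
  brk <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(h, brk, rightmost.closed = TRUE), 1), n_bins)
  emp <- data.frame(
    dist = tapply(h, bin, mean),
    gamma = tapply(sv, bin, mean),
    n = as.integer(table(factor(bin, levels = sort(unique(bin)))))
  )
  emp <- emp[is.finite(emp$gamma), , drop = FALSE]

  obj <- function(par) {
    ng <- if (estimate_nugget) exp(par[3]) else nugget
    vg <- variogram_model(model, nugget = ng, sill = ng + exp(par[1]),
                          range = exp(par[2]))
    gm <- vgm_gamma(vg, emp$dist)
    sum(emp$n * (emp$gamma - gm)^2 / pmax(gm, 1e-12)^2)
  }
  init <- c(log(stats::var(values)), log(cutoff / 2))
  if (estimate_nugget) init <- c(init, log(max(min(emp$gamma) / 2, 1e-8)))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  ng <- if (estimate_nugget) exp(opt$par[3]) else nugget
  out <- variogram_model(model, nugget = ng, sill = ng + exp(opt$par[1]),
                         range = exp(opt$par[2]))
  attr(out, "empirical") <- emp
  out
}
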