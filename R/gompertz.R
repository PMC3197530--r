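#' Gompertz tumor growth machinery
#'
#' Melanoma growth follows the two-parameter Gompertz law
#' `dx/dt = x (a - b ln x)`, i.e. a growth factor that decays in time and a
#' constant mortality factor, with carrying capacity `K = exp(a / b)` and
#' closed-form solution `x(t) = K exp(ln(x0 / K) exp(-b t))`.  Rates `a`
#' and `b` are per 8-hour timestep.  The simulator advances the law by
#' forward-Euler discretization, introducing `w = x_{t+1} - x_t` newborn
#' cancer cells each step.  The tumor is treated as a disk of cells of
#' known mean diameter, which converts caliper diameters to cell counts and
#' back.
#'
#' @name tumor_growth
NULL

#' Gompertz growth parameters
#'
#' @param a growth constant per timestep.
#' @param b deceleration constant per timestep (>= 0).
#' @return A list of class `gompertz_params` with the implied carrying
#'   capacity `K = exp(a / b)` (infinite when `b = 0`).
#' @export
gompertz_params <- function(a, b) {
  if (b < 0) stop("b must be non-negative")
  structure(list(a = a, b = b, K = if (b > 0) exp(a / b) else Inf),
            class = "gompertz_params")
}

#' Shipped default growth parameters
#'
#' Calibrated (see `scripts/calibrate_growth.R`) so an untreated tumor
#' seeded at `x0 = 200000` crosses the 450 mm^2 sacrifice threshold around
#' day 29, inside the day 25-33 window bounded by the 33-day horizon.
#'
#' @return A [gompertz_params()] object (`a = 0.1364`, `b = 0.00884` per
#'   8-hour step; `K` about 5e6 cells).
#' @export
gompertz_default_params <- function() gompertz_params(a = 0.1364, b = 0.00884)

#' Cell count from a caliper diameter (disk model)
#'
#' @param diameter_mm tumor diameter in mm (mean of two perpendicular
#'   calipers).
#' @param cell_diameter_um mean melanoma cell diameter in micrometers.
#' @return Estimated number of cancer cells,
#'   `round((diameter / cell_diameter)^2)`.
#' @export
cells_from_diameter <- function(diameter_mm, cell_diameter_um = 20) {
  if (any(cell_diameter_um <= 0)) stop("cell diameter must be positive")
  if (any(diameter_mm < 0)) stop("diameter must be non-negative")
  round((diameter_mm * 1000 / cell_diameter_um)^2)
}

#' Tumor area from a cell count (disk model)
#'
#' @param x number of cancer cells.
#' @param cell_diameter_um mean cell diameter in micrometers.
#' @return Tumor area in mm^2 (`x * cell_diameter_mm^2`); the inverse of
#'   [cells_from_diameter()] up to rounding.
#' @export
area_from_cells <- function(x, cell_diameter_um = 20) {
  if (any(x < 0)) stop("cell count must be non-negative")
  x * (cell_diameter_um / 1000)^2
}

#' Closed-form Gompertz solution
#'
#' @param t time in timesteps (vectorized).
#' @param params a [gompertz_params()].
#' @param x0 initial cell count at `t = 0`.
#' @return Expected cell counts `x(t)`.
#' @export
gompertz_cells <- function(t, params, x0) {
  if (params$b == 0) return(x0 * exp(params$a * t))
  params$K * exp(log(x0 / params$K) * exp(-params$b * t))
}

#' Forward-Euler newborn count for one step
#'
#' `x_{t+1} = x_t + dt * x_t * (a - b ln x_t)`; the integer part of the
#' increment is returned as the newborn count `w`, the fractional part is
#' carried in `residual` so no growth is lost to rounding.  At or above
#' carrying capacity the increment is clamped to zero (tumor cells are
#' effectively immortal; decline only comes from immune kills).
#'
#' @param x_t current cancer cell count.
#' @param params a [gompertz_params()].
#' @param dt step size in timesteps (default 1).
#' @param residual fractional carry-over from the previous step.
#' @return A list with integer `w` (>= 0) and the updated `residual`.
#' @export
euler_newborns <- function(x_t, params, dt = 1, residual = 0) {
  if (x_t < 0) stop("x_t must be non-negative")
  if (x_t == 0) return(list(w = 0L, residual = 0))
  rate <- params$a - params$b * log(x_t)
  incr <- dt * x_t * rate + residual
  if (incr <= 0) return(list(w = 0L, residual = 0))
  w <- floor(incr)
  list(w = as.integer(w), residual = incr - w)
}

#' Initial engrafted tumor load
#'
#' @param injected number of injected cancer cells.
#' @param death_fraction fraction dying before settling (default 0.6).
#' @return `round(injected * (1 - death_fraction))`; the canonical
#'   `0.5e6` injected cells with 60% loss give `x0 = 200000`.
#' @export
seed_initial_tumor <- function(injected, death_fraction = 0.6) {
  if (death_fraction < 0 || death_fraction > 1)
    stop("death_fraction must be in [0, 1]")
  round(injected * (1 - death_fraction))
}

#' Fit Gompertz parameters to a diameter series
#'
#' Converts caliper diameters to cell counts under the disk model and fits
#' `(a, b)` of the closed-form Gompertz solution by Levenberg-Marquardt
#' least squares on log counts, with `x0` fixed at the engrafted load.
#' Measurements from several mice sharing one growth law (the usual cage
#' of six) are pooled by stacking the series with a `mouse` column.
#'
#' @param series data frame with columns `day` (days post-injection,
#'   strictly increasing within a mouse) and `diameter_mm`; an optional
#'   `mouse` column pools several series into one fit.
#' @param cell_diameter_um mean cell diameter in micrometers.
#' @param x0 engrafted cell count at day 0.
#' @param steps_per_day timesteps per day (default 3: 8-hour steps).
#' @return An object of class `gompertz_fit` with components `a`, `b`, `K`
#'   (per-timestep units), `x0`, `residual_norm` (RMS of log-count
#'   residuals), `fitted` counts and the input `series`.
#' @seealso [generate_growth_fixture()] for synthetic series.
#' @export
fit_gompertz <- function(series, cell_diameter_um = 20, x0 = 200000,
                         steps_per_day = 3) {
  if (!is.data.frame(series) || !all(c("day", "diameter_mm") %in% names(series)))
    stop("series must have columns day and diameter_mm")
  if (nrow(series) < 3)
    stop("degenerate series: need at least 3 measurements")
  by_mouse <- if ("mouse" %in% names(series)) series$mouse else
    rep(1L, nrow(series))
  for (m in unique(by_mouse)) {
    if (any(diff(series$day[by_mouse == m]) <= 0))
      stop("days must be strictly increasing within a mouse")
  }
  x <- cells_from_diameter(series$diameter_mm, cell_diameter_um)
  if (length(unique(x[x > 0])) < 2)
    stop("degenerate series: need at least two distinct positive counts")
  t_steps <- series$day * steps_per_day
  lx <- log(pmax(x, 1))
  # starting values: K ~ 2 * max count, b from the spread of the series
  lK0 <- max(lx) + log(2)
  b0 <- 1 / max(t_steps)
  fit <- minpack.lm::nlsLM(
    lx ~ lK + (log(x0) - lK) * exp(-b * t_steps),
    start = list(lK = lK0, b = b0),
    lower = c(lK = log(x0) + 1e-6, b = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  b <- unname(est["b"])
  a <- b * unname(est["lK"])
  structure(list(a = a, b = b, K = exp(unname(est["lK"])), x0 = x0,
                 steps_per_day = steps_per_day,
                 cell_diameter_um = cell_diameter_um,
                 residual_norm = sqrt(mean(stats::resid(fit)^2)),
                 fitted = exp(stats::fitted(fit)), series = series),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz growth fit (per 8-hour timestep)\n")
  cat(sprintf("  a = %.5g   b = %.5g   K = %.4g cells\n", x$a, x$b, x$K))
  cat(sprintf("  x0 = %g, %d measurements, RMS log-residual %.3g\n",
              x$x0, nrow(x$series), x$residual_norm))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(a = object$a, b = object$b, K = object$K)
}

#' Predicted cell counts or areas from a Gompertz fit
#'
#' @param object a `gompertz_fit`.
#' @param days days post-injection at which to predict (defaults to the
#'   fitted series days).
#' @param type `"cells"` or `"area_mm2"`.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.gompertz_fit <- function(object, days = object$series$day,
                                 type = c("cells", "area_mm2"), ...) {
  type <- match.arg(type)
  gp <- gompertz_params(object$a, object$b)
  x <- gompertz_cells(days * object$steps_per_day, gp, object$x0)
  if (type == "area_mm2") area_from_cells(x, object$cell_diameter_um) else x
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  obs <- cells_from_diameter(x$series$diameter_mm, x$cell_diameter_um)
  days <- seq(0, max(x$series$day), length.out = 200)
  plot(x$series$day, area_from_cells(obs, x$cell_diameter_um),
       xlab = "day post-injection", ylab = expression(tumor ~ area ~ (mm^2)),
       pch = 19, ...)
  lines(days, predict(x, days, type = "area_mm2"), col = 2)
  invisible(x)
}

#' Synthetic caliper measurement series
#'
#' Stands in for undeposited in vivo caliper data: diameters follow the
#' closed-form Gompertz solution through the disk model.  Each recorded
#' diameter is the mean of two perpendicular caliper reads, each carrying
#' multiplicative lognormal noise with coefficient of variation
#' `noise_cv`; with `n_mice > 1` independent replicate series (one cage)
#' are stacked with a `mouse` column for pooled fitting.
#'
#' @param params a [gompertz_params()].
#' @param x0 engrafted cell count at day 0.
#' @param times_days measurement days.
#' @param noise_cv per-caliper coefficient of variation (0 = noise-free).
#' @param cell_diameter_um mean cell diameter in micrometers.
#' @param steps_per_day timesteps per day.
#' @param n_mice number of replicate mice sharing the growth law.
#' @return A data frame with columns `day`, `diameter_mm` (all
#'   non-negative) and, when `n_mice > 1`, `mouse`; suitable for
#'   [fit_gompertz()].
#' @export
generate_growth_fixture <- function(params, x0 = 200000,
                                    times_days = seq(3, 30, by = 3),
                                    noise_cv = 0.05,
                                    cell_diameter_um = 20,
                                    steps_per_day = 3,
                                    n_mice = 1) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  x <- gompertz_cells(times_days * steps_per_day, params, x0)
  d0 <- sqrt(x) * cell_diameter_um / 1000
  one_mouse <- function(m) {
    d <- d0
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      caliper <- function() stats::rlnorm(length(d), -sdlog^2 / 2, sdlog)
      d <- d * (caliper() + caliper()) / 2   # mean of 2 perpendicular reads
    }
    data.frame(day = times_days, diameter_mm = d, mouse = m)
  }
  out <- do.call(rbind, lapply(seq_len(n_mice), one_mouse))
  if (n_mice == 1) out$mouse <- NULL
  out
}
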