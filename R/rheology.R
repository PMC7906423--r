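#' Blood fluid properties
#'
#' Container for the density and constitutive parameters of blood. Two
#' rheology models are supported: the shear-thinning Bird-Carreau law, which
#' interpolates between a low-shear viscosity plateau \code{mu0} and a
#' high-shear plateau \code{mu_inf} with time constant \code{lambda_t} and
#' power-law index \code{n_index}, and a constant-viscosity Newtonian
#' comparator.
#'
#' Defaults are the values commonly used for whole blood at 37 C:
#' \code{rho} = 1060 kg/m^3, \code{mu0} = 0.056 Pa s, \code{mu_inf} =
#' 0.00345 Pa s, \code{lambda_t} = 3.313 s, \code{n_index} = 0.3568, and a
#' Newtonian viscosity of 0.004 Pa s.
#'
#' @param rho mass density [kg/m^3].
#' @param mu0 low-shear viscosity plateau [Pa s].
#' @param mu_inf high-shear viscosity plateau [Pa s].
#' @param lambda_t Bird-Carreau time constant [s].
#' @param n_index power-law index (0 < n <= 1).
#' @param model `"bird_carreau"` or `"newtonian"`.
#' @param mu_newt constant viscosity for the Newtonian model [Pa s].
#' @return An object of class `fluid_properties`.
#' @examples
#' props <- fluid_properties()
#' apparent_viscosity(c(0, 1, 1000), props)
#' @export
fluid_properties <- function(rho = 1060,
                             mu0 = 0.056,
                             mu_inf = 0.00345,
                             lambda_t = 3.313,
                             n_index = 0.3568,
                             model = c("bird_carreau", "newtonian"),
                             mu_newt = 0.004) {
  model <- match.arg(model)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (!(mu_inf > 0)) stop("mu_inf must be positive", call. = FALSE)
  if (mu0 < mu_inf) stop("mu0 must be >= mu_inf", call. = FALSE)
  if (lambda_t < 0) stop("lambda_t must be non-negative", call. = FALSE)
  if (!(n_index > 0 && n_index <= 1)) {
    stop("n_index must lie in (0, 1]", call. = FALSE)
  }
  if (model == "newtonian" && !(mu_newt > 0)) {
    stop("mu_newt must be positive for the newtonian model", call. = FALSE)
  }
  structure(
    list(rho = rho, mu0 = mu0, mu_inf = mu_inf, lambda_t = lambda_t,
         n_index = n_index, model = model, mu_newt = mu_newt),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("Fluid properties (", x$model, ")\n", sep = "")
  cat(sprintf("  rho     = %g kg/m^3\n", x$rho))
  if (x$model == "bird_carreau") {
    cat(sprintf("  mu0     = %g Pa s\n", x$mu0))
    cat(sprintf("  mu_inf  = %g Pa s\n", x$mu_inf))
    cat(sprintf("  lambda  = %g s\n", x$lambda_t))
    cat(sprintf("  n       = %g\n", x$n_index))
  } else {
    cat(sprintf("  mu      = %g Pa s\n", x$mu_newt))
  }
  invisible(x)
}

#' Apparent (shear-rate dependent) viscosity
#'
#' Evaluates the constitutive law of a [fluid_properties()] object at the
#' given shear rate(s). For the Bird-Carreau model,
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2},}
#' which is finite at \eqn{\dot\gamma = 0} (where it equals \eqn{\mu_0}) and
#' approaches \eqn{\mu_\infty} as \eqn{\dot\gamma \to \infty}. For the
#' Newtonian model the constant \code{mu_newt} is returned.
#'
#' @param gamma_dot shear rate(s) [1/s], non-negative; vectorized.
#' @param props a [fluid_properties()] object.
#' @return Viscosity [Pa s], same shape as `gamma_dot`. For the Bird-Carreau
#'   model the result always lies in `[mu_inf, mu0]`.
#' @export
apparent_viscosity <- function(gamma_dot, props = fluid_properties()) {
  stopifnot(inherits(props, "fluid_properties"), is.numeric(gamma_dot))
  if (any(gamma_dot < 0, na.rm = TRUE)) {
    stop("gamma_dot must be non-negative", call. = FALSE)
  }
  if (props$model == "newtonian") {
    return(reshape_like(rep_len(props$mu_newt, length(gamma_dot)), gamma_dot))
  }
  mu <- props$mu_inf + (props$mu0 - props$mu_inf) *
    (1 + (props$lambda_t * gamma_dot)^2)^((props$n_index - 1) / 2)
  mu
}

# keep dim attributes when broadcasting a scalar over an array input
reshape_like <- function(x, template) {
  if (!is.null(dim(template))) dim(x) <- dim(template)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reynolds number
#'
#' \eqn{Re = \rho U D / \mu} for a boundary of a haemodynamic chamber, with
#' characteristic velocity `U`, boundary diameter `D` and viscosity `mu`.
#'
#' @param rho density [kg/m^3], positive.
#' @param U velocity magnitude [m/s], non-negative; vectorized.
#' @param D boundary diameter [m], positive.
#' @param mu viscosity [Pa s], positive.
#' @return Dimensionless Reynolds number(s).
#' @export
reynolds_number <- function(rho, U, D, mu) {
  if (any(rho <= 0) || any(D <= 0) || any(mu <= 0)) {
    stop("rho, D and mu must be positive", call. = FALSE)
  }
  if (any(U < 0)) stop("U must be non-negative", call. = FALSE)
  rho * U * D / mu
}

#' Summarize a per-boundary Reynolds-number series
#'
#' Given the patch-averaged velocity series over one cardiac cycle and the
#' patch-and-time-averaged viscosity, computes the time-varying Reynolds
#' number and its min/mean/max, the statistics conventionally tabulated per
#' chamber boundary.
#'
#' @param boundary_name label of the boundary (e.g. `"SVC"`).
#' @param U_series numeric vector, patch-averaged velocity magnitude over one
#'   cycle [m/s].
#' @param D boundary diameter [m].
#' @param mu_used patch-and-time-averaged apparent viscosity [Pa s].
#' @param rho density [kg/m^3].
#' @return An object of class `reynolds_record`: a one-row data frame with
#'   columns `boundary_name`, `U`, `D`, `mu_used`, `re_min`, `re_mean`,
#'   `re_max`.
#' @export
reynolds_record <- function(boundary_name, U_series, D, mu_used, rho = 1060) {
  if (length(U_series) == 0L) stop("U_series must be non-empty", call. = FALSE)
  re <- reynolds_number(rho, U_series, D, mu_used)
  out <- data.frame(
    boundary_name = boundary_name,
    U = mean(U_series), D = D, mu_used = mu_used,
    re_min = min(re), re_mean = mean(re), re_max = max(re),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reynolds_record", "data.frame")
  out
}

#' Laminar-flow check
#'
#' Tests whether all supplied Reynolds numbers are below the laminar
#' threshold for internal flow (strictly less than 2300). Exceedances emit a
#' warning naming the offending boundary.
#'
#' @param re_values numeric vector (optionally named by boundary) of Reynolds
#'   numbers, or a data frame of [reynolds_record()] rows (the `re_max`
#'   column is used).
#' @param threshold laminar threshold, default 2300.
#' @return `TRUE` if `max(re_values) < threshold`, else `FALSE` (with one
#'   warning per exceedance).
#' @export
laminar_check <- function(re_values, threshold = 2300) {
  if (is.data.frame(re_values)) {
    nm <- re_values$boundary_name
    re_values <- stats::setNames(re_values$re_max, nm)
  }
  if (length(re_values) == 0L) {
    stop("re_values must be non-empty", call. = FALSE)
  }
  bad <- which(re_values >= threshold)
  if (length(bad)) {
    nms <- names(re_values)
    for (i in bad) {
      lab <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else paste0("#", i)
      warning(sprintf("boundary %s: Re = %.4g >= %g (not laminar)",
                      lab, re_values[i], threshold), call. = FALSE)
    }
  }
  length(bad) == 0L
}

#' Viscosity-shear rate table
#'
#' Tabulates the apparent viscosity of one or more rheology models on a
#' log-spaced shear-rate grid, for comparison plots of the Newtonian and
#' Bird-Carreau constitutive laws.
#'
#' @param props_list named list of [fluid_properties()] objects.
#' @param gamma_range range of shear rates [1/s], default `c(1e-2, 1e4)`.
#' @param n number of grid points.
#' @return Data frame with columns `gamma_dot` and one viscosity column per
#'   model.
#' @export
viscosity_table <- function(props_list = list(
                              bird_carreau = fluid_properties(),
                              newtonian = fluid_properties(model = "newtonian")),
                            gamma_range = c(1e-2, 1e4), n = 200) {
  gd <- exp(seq(log(gamma_range[1]), log(gamma_range[2]), length.out = n))
  out <- data.frame(gamma_dot = gd)
  for (nm in names(props_list)) {
    out[[nm]] <- apparent_viscosity(gd, props_list[[nm]])
  }
  out
}
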