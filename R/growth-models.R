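#' Sigmoid growth model families
#'
#' Constructs a three-parameter sigmoid growth model of one of the three
#' classical families used for livestock body-weight trajectories:
#'
#' \describe{
#'   \item{logistic}{\eqn{y(t) = A / (1 + b e^{-kt})}}
#'   \item{gompertz}{\eqn{y(t) = A e^{-b e^{-kt}}}}
#'   \item{von_bertalanffy}{\eqn{y(t) = A (1 - b e^{-kt})^3}}
#' }
#'
#' where `A` is the asymptotic (mature) weight in kg, `b` a dimensionless
#' shape parameter and `k` the rate constant per day. All three families
#' saturate at `A` as `t` grows. A Von Bertalanffy model with `b >= 1` is
#' undefined (negative cube root term) near birth; it is accepted but its
#' usable domain starts at `log(b)/k`.
#'
#' @param family One of `"logistic"`, `"gompertz"`, `"von_bertalanffy"`.
#' @param A Asymptotic weight (kg), `> 0`.
#' @param b Shape parameter, `> 0`.
#' @param k Rate constant (per day), `> 0`.
#' @return An object of class `growth_model`.
#' @examples
#' m <- growth_model("von_bertalanffy", A = 174.607, b = 0.852, k = 0.006)
#' predict_weight(m, c(0, 100, 400))
#' @export
growth_model <- function(family = c("logistic", "gompertz", "von_bertalanffy"),
                         A, b, k) {
  family <- match.arg(family)
  pars <- c(A = A, b = b, k = k)
  if (any(!is.finite(pars))) {
    stop("invalid growth model: non-finite parameter(s) ",
         paste(names(pars)[!is.finite(pars)], collapse = ", "))
  }
  if (any(pars <= 0)) {
    stop("invalid growth model: A, b and k must all be > 0")
  }
  structure(list(family = family, A = A, b = b, k = k),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s: A = %.4g kg, b = %.4g, k = %.4g /day\n",
              x$family, x$A, x$b, x$k))
  invisible(x)
}

# shared substitution u = b * exp(-k t); all derivatives below are
# polynomials in u times family-specific factors (du/dt = -k u)
.gm_u <- function(model, t) model$b * exp(-model$k * t)

#' Predict body weight from a growth model
#'
#' Evaluates the model weight (kg) at one or more ages. Vectorized over `t`.
#'
#' @param model A [growth_model()].
#' @param t Age(s) in days. Non-negative unless `allow_negative_age = TRUE`
#'   (useful for diagnostics around pre-birth roots).
#' @param allow_negative_age Permit `t < 0`.
#' @return Numeric vector of weights (kg), same length as `t`.
#' @export
predict_weight <- function(model, t, allow_negative_age = FALSE) {
  stopifnot(inherits(model, "growth_model"))
  if (!allow_negative_age && any(t < 0)) {
    stop("age must be >= 0 (set allow_negative_age = TRUE to override)")
  }
  u <- .gm_u(model, t)
  A <- model$A
  switch(model$family,
         logistic        = A / (1 + u),
         gompertz        = A * exp(-u),
         von_bertalanffy = A * (1 - u)^3)
}

#' Analytic growth-rate derivatives
#'
#' First, second or third time derivative of the growth curve, in closed
#' form (no numeric differencing). With the substitution
#' \eqn{u = b e^{-kt}} (so \eqn{du/dt = -ku}):
#'
#' \describe{
#'   \item{logistic}{\eqn{y' = Aku/(1+u)^2}, \eqn{y'' = -Ak^2 u(1-u)/(1+u)^3},
#'     \eqn{y''' = Ak^3 u (u^2-4u+1)/(1+u)^4}}
#'   \item{gompertz}{\eqn{y' = Aku e^{-u}}, \eqn{y'' = -Ak^2 u(1-u)e^{-u}},
#'     \eqn{y''' = Ak^3 u (u^2-3u+1) e^{-u}}}
#'   \item{von_bertalanffy}{\eqn{y' = 3Aku(1-u)^2},
#'     \eqn{y'' = -3Ak^2 u(1-u)(1-3u)}, \eqn{y''' = 3Ak^3 u(9u^2-8u+1)}}
#' }
#'
#' @param model A [growth_model()].
#' @param t Age(s) in days.
#' @param order Derivative order, 1, 2 or 3.
#' @return kg/day (order 1), kg/day^2 (2) or kg/day^3 (3); vectorized.
#' @export
growth_rate <- function(model, t, order = 1L) {
  stopifnot(inherits(model, "growth_model"))
  if (!(length(order) == 1L && order %in% 1:3)) {
    stop("unsupported derivative order: ", deparse(order))
  }
  u <- .gm_u(model, t)
  A <- model$A; k <- model$k
  switch(model$family,
    logistic = switch(order,
      A * k * u / (1 + u)^2,
      -A * k^2 * u * (1 - u) / (1 + u)^3,
      A * k^3 * u * (u^2 - 4 * u + 1) / (1 + u)^4),
    gompertz = switch(order,
      A * k * u * exp(-u),
      -A * k^2 * u * (1 - u) * exp(-u),
      A * k^3 * u * (u^2 - 3 * u + 1) * exp(-u)),
    von_bertalanffy = switch(order,
      3 * A * k * u * (1 - u)^2,
      -3 * A * k^2 * u * (1 - u) * (1 - 3 * u),
      3 * A * k^3 * u * (9 * u^2 - 8 * u + 1)))
}

# the inflection points are roots in u of the 2nd/3rd derivative factors;
# parameter-free per family
.gm_inflection_u <- function(family) {
  switch(family,
         logistic        = c(GRI = 2 + sqrt(3), MGI = 1,     RSI = 2 - sqrt(3)),
         gompertz        = c(GRI = (3 + sqrt(5)) / 2, MGI = 1, RSI = (3 - sqrt(5)) / 2),
         von_bertalanffy = c(GRI = (4 + sqrt(7)) / 9, MGI = 1 / 3, RSI = (4 - sqrt(7)) / 9))
}

#' Closed-form inflection-point analysis
#'
#' Computes the three growth-curve inflection points: MGI (age of maximum
#' growth rate, the root of the second derivative) and GRI/RSI (the two
#' roots of the third derivative, marking the transitions between the
#' gradually, rapidly and slowly increasing stages). Roots are obtained in
#' closed form via the substitution \eqn{u = b e^{-kt}},
#' \eqn{t = \log(b/u)/k}; each root is then self-checked against the
#' analytic derivative it is supposed to annihilate.
#'
#' The fraction of mature weight reached at MGI is a parameter-free
#' constant per family: 1/2 (logistic), 1/e (Gompertz), 8/27
#' (Von Bertalanffy).
#'
#' @param model A [growth_model()].
#' @param tol Relative tolerance for the derivative self-check, scaled by
#'   the natural magnitude `A*k^order` of each derivative.
#' @return An `inflection_report`: ages `t_GRI < t_MGI < t_RSI` (days),
#'   weights `w_GRI < w_MGI < w_RSI` (kg), `max_rate_g_per_day` (the first
#'   derivative at MGI, in g/day), the model, and `negative_age` flagging
#'   roots that fall before birth (e.g. a logistic model with `b < 1`).
#' @export
inflection_points <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "growth_model"))
  u <- .gm_inflection_u(model$family)
  tt <- log(model$b / u) / model$k
  negative <- any(tt < 0)
  if (negative) {
    warning("inflection root(s) at negative age (pre-birth) for this ",
            "parameter set; report flagged")
  }
  w <- predict_weight(model, tt, allow_negative_age = TRUE)

  # self-check: MGI annihilates y'', GRI/RSI annihilate y'''
  d2 <- growth_rate(model, tt[["MGI"]], order = 2L)
  d3 <- growth_rate(model, tt[c("GRI", "RSI")], order = 3L)
  scale2 <- model$A * model$k^2
  scale3 <- model$A * model$k^3
  if (abs(d2) > tol * scale2 || any(abs(d3) > tol * scale3)) {
    stop("inflection self-check failed: closed-form root does not ",
         "annihilate the analytic derivative")
  }

  structure(list(
    model = model,
    t_GRI = tt[["GRI"]], t_MGI = tt[["MGI"]], t_RSI = tt[["RSI"]],
    w_GRI = w[["GRI"]], w_MGI = w[["MGI"]], w_RSI = w[["RSI"]],
    max_rate_g_per_day = 1000 * growth_rate(model, tt[["MGI"]], order = 1L),
    negative_age = negative
  ), class = "inflection_report")
}

#' @export
print.inflection_report <- function(x, ...) {
  cat(sprintf("<inflection_report> %s model\n", x$model$family))
  cat(sprintf("  GRI %8.2f d  %7.2f kg   (GIS -> RIS)\n", x$t_GRI, x$w_GRI))
  cat(sprintf("  MGI %8.2f d  %7.2f kg   max rate %.2f g/day\n",
              x$t_MGI, x$w_MGI, x$max_rate_g_per_day))
  cat(sprintf("  RSI %8.2f d  %7.2f kg   (RIS -> SIS)\n", x$t_RSI, x$w_RSI))
  if (isTRUE(x$negative_age)) cat("  [flag] root(s) at negative age\n")
  invisible(x)
}

#' Assign an age to a growth stage
#'
#' Partitions ages into the gradually increasing stage (GIS, birth to GRI),
#' rapidly increasing stage (RIS, GRI to RSI] and slowly increasing stage
#' (SIS, beyond RSI). The partition is exhaustive and non-overlapping:
#' `t <= t_GRI` is GIS, `t_GRI < t <= t_RSI` is RIS, `t > t_RSI` is SIS.
#'
#' @param report An [inflection_points()] report.
#' @param t Age(s) in days, `>= 0`.
#' @return Factor with levels GIS, RIS, SIS.
#' @export
stage_of <- function(report, t) {
  stopifnot(inherits(report, "inflection_report"))
  if (any(t < 0)) stop("age must be >= 0")
  out <- ifelse(t <= report$t_GRI, "GIS",
                ifelse(t <= report$t_RSI, "RIS", "SIS"))
  factor(out, levels = c("GIS", "RIS", "SIS"))
}

#' Serialize a growth model + inflection report to JSON
#'
#' Round-trips the fitted parameters and staging summary through a flat
#' JSON object.
#'
#' @param report An `inflection_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_growth_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "inflection_report"))
  m <- report$model
  obj <- list(family = m$family, A = m$A, b = m$b, k = m$k,
              t_GRI = report$t_GRI, t_MGI = report$t_MGI, t_RSI = report$t_RSI,
              w_GRI = report$w_GRI, w_MGI = report$w_MGI, w_RSI = report$w_RSI,
              max_rate_g_per_day = report$max_rate_g_per_day)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a growth report JSON back into model + report
#'
#' @param path File written by [write_growth_report()].
#' @return An `inflection_report` recomputed from the stored parameters.
#' @export
read_growth_report <- function(path) {
  obj <- jsonlite::fromJSON(path)
  inflection_points(growth_model(obj$family, obj$A, obj$b, obj$k))
}
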