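#' Fit a sigmoid growth model to body-weight records
#'
#' Least-squares fit of one sigmoid family to longitudinal body-weight
#' records by damped (Levenberg-Marquardt) least squares with analytic
#' residual Jacobians, on the log-parameter scale so that `A`, `b`, `k`
#' stay positive. Sigmoid fits are multimodal in `(b, k)`, so the
#' optimizer is restarted from `n_starts` jittered versions of a
#' data-driven initial guess (`A0 = 1.2 * max(weight)`, `b0` from the
#' weight at the earliest age, `k0` from a log-linearization) and the
#' converged restart with the smallest SSE wins. Deterministic given
#' `seed`.
#'
#' @param records Data frame with numeric columns `age` (days, >= 0) and
#'   `weight` (kg, > 0); an `animal_id` column is allowed and ignored by
#'   the fit. Repeated ages (many animals per timepoint) are expected.
#' @param family Sigmoid family, as in [growth_model()].
#' @param init Optional named vector `c(A=, b=, k=)` overriding the
#'   data-driven initial guess.
#' @param seed Integer seed for the restart jitter.
#' @param n_starts Number of restarts.
#' @param max_iter Maximum iterations per restart.
#' @return A `fit_result`: `model` ([growth_model()]), `r_squared`, `sse`,
#'   `sst`, `n_obs`, `converged`, `n_iter`.
#' @export
fit_growth_model <- function(records,
                             family = c("logistic", "gompertz", "von_bertalanffy"),
                             init = NULL, seed = 1L, n_starts = 8L,
                             max_iter = 200L) {
  family <- match.arg(family)
  records <- .check_weight_records(records)
  if (length(unique(records$age)) < 4L) {
    stop("insufficient data: need >= 4 distinct ages to fit 3 parameters")
  }
  t <- records$age; w <- records$weight

  base <- if (is.null(init)) .gm_init(family, t, w) else log(init[c("A", "b", "k")])

  resid_fn <- function(lp) {
    m <- growth_model(family, exp(lp[1]), exp(lp[2]), exp(lp[3]))
    w - predict_weight(m, t, allow_negative_age = TRUE)
  }
  jac_fn <- function(lp) {
    A <- exp(lp[1]); b <- exp(lp[2]); k <- exp(lp[3])
    u <- b * exp(-k * t)
    d <- switch(family,
      logistic = cbind(1 / (1 + u),
                       -A * u / (b * (1 + u)^2),
                       A * t * u / (1 + u)^2),
      gompertz = cbind(exp(-u),
                       -A * exp(-u) * u / b,
                       A * exp(-u) * u * t),
      von_bertalanffy = cbind((1 - u)^3,
                              -3 * A * (1 - u)^2 * u / b,
                              3 * A * (1 - u)^2 * u * t))
    # residual = w - y, chain rule through the log-parameter scale
    -d %*% diag(c(A, b, k))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jitter <- rbind(0, matrix(stats::rnorm(3L * (n_starts - 1L), sd = 0.3),
                            ncol = 3L))

  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- base + jitter[i, ]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:3
    if (is.null(best) ||
        (conv && !best$converged) ||
        (conv == best$converged && sse < best$sse)) {
      best <- list(par = fit$par, sse = sse, converged = conv,
                   n_iter = fit$niter)
    }
  }
  if (is.null(best)) {
    best <- list(par = base, sse = sum(resid_fn(base)^2), converged = FALSE,
                 n_iter = 0L)
  }

  par <- unname(exp(best$par))
  model <- growth_model(family, par[1], par[2], par[3])
  sst <- sum((w - mean(w))^2)
  structure(list(model = model,
                 r_squared = 1 - best$sse / sst,
                 sse = best$sse, sst = sst, n_obs = length(w),
                 converged = best$converged, n_iter = best$n_iter),
            class = "fit_result")
}

# data-driven starting values on the log scale
.gm_init <- function(family, t, w) {
  A0 <- 1.2 * max(w)
  y0 <- mean(w[t == min(t)])
  y0 <- min(y0, 0.95 * A0)
  b0 <- switch(family,
               logistic        = max(A0 / y0 - 1, 1e-3),
               gompertz        = max(log(A0 / y0), 1e-3),
               von_bertalanffy = min(max(1 - (y0 / A0)^(1 / 3), 1e-3), 0.999))
  # log-linearization: each family has log(<transform>) = log(b) - k t
  z <- switch(family,
              logistic        = pmax(A0 / w - 1, 1e-6),
              gompertz        = pmax(log(pmax(A0 / w, 1 + 1e-6)), 1e-6),
              von_bertalanffy = pmax(1 - pmin(w / A0, 1 - 1e-6)^(1 / 3), 1e-6))
  sl <- stats::coef(stats::lm(log(z) ~ t))[2]
  k0 <- if (is.finite(sl) && sl < 0) -sl else 0.01
  log(c(A0, b0, k0))
}

.check_weight_records <- function(records) {
  if (!is.data.frame(records) || !all(c("age", "weight") %in% names(records))) {
    stop("records must be a data frame with columns 'age' and 'weight'")
  }
  if (any(!is.finite(records$age)) || any(!is.finite(records$weight))) {
    stop("non-finite age or weight in records")
  }
  if (any(records$age < 0)) stop("ages must be >= 0")
  if (any(records$weight <= 0)) stop("weights must be > 0")
  records
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  R^2 = %.4f  (n = %d, %s, %d iter)\n",
              x$model$family, x$r_squared, x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$model)
  invisible(x)
}

#' Coefficient of determination of a growth model on records
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} on raw (untransformed) weights.
#' Can be negative for models worse than the mean.
#'
#' @param model A [growth_model()].
#' @param records As in [fit_growth_model()].
#' @return Scalar R-squared.
#' @export
goodness_of_fit <- function(model, records) {
  records <- .check_weight_records(records)
  if (nrow(records) < 2L || stats::var(records$weight) == 0) {
    stop("R^2 undefined: need >= 2 records with non-constant weight")
  }
  pred <- predict_weight(model, records$age, allow_negative_age = TRUE)
  1 - sum((records$weight - pred)^2) / sum((records$weight - mean(records$weight))^2)
}

#' Select the best-fitting growth model
#'
#' Returns the converged fit with the highest R-squared. All families have
#' three parameters, so ties are broken by the fixed family order
#' logistic < gompertz < von_bertalanffy (first wins).
#'
#' @param fits List of `fit_result` objects.
#' @return The winning `fit_result`.
#' @export
select_best_model <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "fit_result")))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0L) stop("no converged fit to select from")
  order_key <- c(logistic = 1L, gompertz = 2L, von_bertalanffy = 3L)
  r2 <- vapply(conv, function(f) f$r_squared, 0)
  fam <- vapply(conv, function(f) order_key[[f$model$family]], 0L)
  conv[[order(-r2, fam)[1L]]]
}
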