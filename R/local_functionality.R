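#' Hyper-exponential model of local functionality decay
#'
#' Constructs the model `P_loc(n) = exp(-alpha*n - beta*n^2)` describing how
#' the local proportion of functional sequences decays with Hamming distance
#' `n` from a wildtype. The quadratic term captures negative epistasis:
#' functionality is lost faster than exponentially as mutations accumulate.
#'
#' `alpha` may be negative (an initial plateau or rise, as observed for GFP)
#' provided `beta > 0` so the model still decays at large `n`.
#'
#' @param alpha linear decay coefficient (per mutation).
#' @param beta quadratic decay coefficient (per mutation squared).
#' @return An object of class `"hyperexp_model"`.
#' @examples
#' m <- hyperexp_model(alpha = 0.104, beta = 0.019)  # beta-lactamase
#' p_loc(m, 0:5)
#' @export
hyperexp_model <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1, length(beta) == 1,
            is.finite(alpha), is.finite(beta))
  if (!(beta > 0 || (beta == 0 && alpha > 0)))
    stop("model must decay for large n: need beta > 0, ",
         "or beta == 0 with alpha > 0")
  structure(list(alpha = alpha, beta = beta), class = "hyperexp_model")
}

#' @export
print.hyperexp_model <- function(x, ...) {
  cat(sprintf(
    "Hyper-exponential local functionality: P_loc(n) = exp(-%g n - %g n^2)\n",
    x$alpha, x$beta))
  invisible(x)
}

#' @export
coef.hyperexp_model <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Evaluate a local-functionality model
#'
#' @param model a [hyperexp_model()].
#' @param n Hamming distance(s) from the wildtype (non-negative).
#' @return `exp(-alpha*n - beta*n^2)`; always 1 at `n = 0`.
#' @export
p_loc <- function(model, n) {
  stopifnot(inherits(model, "hyperexp_model"), is.numeric(n))
  if (any(n < 0)) stop("`n` must be non-negative")
  exp(-model$alpha * n - model$beta * n^2)
}

#' @export
predict.hyperexp_model <- function(object, n, ...) p_loc(object, n)

#' Maximum Hamming distance supporting extensive functional paths
#'
#' `n_max_from_model()` sets `P_loc(n) = P_th` and solves for `n`: the root
#' of `beta*n^2 + alpha*n = -ln(P_th)` (quadratic closed form, linear when
#' `beta = 0`), rounded to the nearest integer. Within this distance of the
#' wildtype the local proportion of functional sequences still exceeds the
#' percolation threshold, so extensive continuous functional paths can
#' exist.
#'
#' @param model a [hyperexp_model()].
#' @param P_th percolation threshold, in (0, 1).
#' @return Integer `n_max`. The attribute `"root"` carries the continuous
#'   root.
#' @examples
#' gfp <- hyperexp_model(-0.062, 0.058)
#' n_max_from_model(gfp, percolation_threshold(236))  # 12
#' @export
n_max_from_model <- function(model, P_th) {
  stopifnot(inherits(model, "hyperexp_model"),
            is.numeric(P_th), length(P_th) == 1)
  if (P_th <= 0 || P_th >= 1) stop("`P_th` must be in (0, 1)")
  rhs <- -log(P_th) # > 0
  if (model$beta == 0) {
    root <- rhs / model$alpha
  } else {
    disc <- model$alpha^2 + 4 * model$beta * rhs
    root <- (-model$alpha + sqrt(disc)) / (2 * model$beta)
  }
  if (!is.finite(root) || root <= 0)
    stop("model has no positive root at P_th = ", P_th)
  structure(as.integer(round(root)), root = root)
}

#' Stepwise mutation-tolerance schedule
#'
#' A per-mutation schedule of tolerated fractions: `per_step[k]` is the
#' fraction of variants that remain functional on acquiring the k-th
#' nonsynonymous mutation. Steps beyond the list reuse the final entry.
#'
#' @param per_step numeric vector of fractions in (0, 1], non-empty.
#' @return An object of class `"tolerance_schedule"`.
#' @examples
#' # beta-lactamase mutagenesis rounds: 100%, 61%, 61%, 55%, 55%, then 39%
#' sched <- tolerance_schedule(c(1, .61, .61, .55, .55, .39))
#' n_max_from_schedule(sched, percolation_threshold(263))  # 10
#' @export
tolerance_schedule <- function(per_step) {
  stopifnot(is.numeric(per_step))
  if (length(per_step) == 0) stop("schedule must be non-empty")
  if (any(per_step <= 0) || any(per_step > 1))
    stop("all schedule entries must lie in (0, 1]")
  structure(list(per_step = per_step), class = "tolerance_schedule")
}

#' @export
print.tolerance_schedule <- function(x, ...) {
  cat("Mutation tolerance schedule:",
      paste0(format(100 * x$per_step), "%", collapse = ", "),
      "(final entry repeats)\n")
  invisible(x)
}

#' Maximum Hamming distance from a stepwise tolerance product
#'
#' Estimates `P_loc(n)` as the running product of per-mutation tolerated
#' fractions and returns the largest `n` whose product still strictly
#' exceeds `P_th`.
#'
#' @param schedule a [tolerance_schedule()] or a bare numeric vector of
#'   fractions (final entry repeats for later steps).
#' @param P_th percolation threshold, in (0, 1).
#' @return Integer `n_max`.
#' @export
n_max_from_schedule <- function(schedule, P_th) {
  if (is.numeric(schedule)) schedule <- tolerance_schedule(schedule)
  stopifnot(inherits(schedule, "tolerance_schedule"),
            is.numeric(P_th), length(P_th) == 1)
  if (P_th <= 0 || P_th >= 1) stop("`P_th` must be in (0, 1)")
  steps <- schedule$per_step
  last <- steps[length(steps)]
  if (last >= 1)
    stop("schedule never decays: final (repeating) entry must be < 1")
  log_p <- 0
  log_th <- log(P_th)
  n <- 0L
  repeat {
    step <- if (n < length(steps)) steps[n + 1L] else last
    log_p <- log_p + log(step)
    if (log_p <= log_th) return(n)
    n <- n + 1L
  }
}

#' Rescale decay coefficients to nonsynonymous mutation counts
#'
#' When fitted decay coefficients count all mutations, substituting
#' `n -> n / fraction` (with `fraction` the nonsynonymous fraction, 0.69 for
#' random mutagenesis of coding sequence) re-expresses the model per
#' sequence-altering mutation: `alpha -> alpha/fraction`,
#' `beta -> beta/fraction^2`.
#'
#' @param alpha_raw,beta_raw coefficients fitted against total mutation
#'   counts.
#' @param fraction nonsynonymous fraction, in (0, 1] for physical use;
#'   values above 1 are accepted so a rescaling can be inverted with
#'   `1/fraction`.
#' @return A [hyperexp_model()] in nonsynonymous units.
#' @export
rescale_nonsynonymous <- function(alpha_raw, beta_raw, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1)
  if (!is.finite(fraction) || fraction <= 0)
    stop("`fraction` must be in (0, 1] (or its reciprocal to invert)")
  hyperexp_model(alpha_raw / fraction, beta_raw / fraction^2)
}

#' Fit a hyper-exponential decay to observed local functionality
#'
#' Nonlinear least squares of `p ~ exp(-alpha*n - beta*n^2)` in linear
#' p-space (Levenberg-Marquardt via \pkg{minpack.lm}), with starting values
#' from an ordinary regression of `-log(p)` on `n` and `n^2`. Observations
#' at excluded distances (e.g. an outlying `n = 1` point) are dropped before
#' fitting. A log-space option fits `-log(p) ~ alpha*n + beta*n^2` by linear
#' least squares instead, which weights the decades more evenly.
#'
#' @param n non-negative integer Hamming distances.
#' @param p observed functional proportions in (0, 1], same length as `n`.
#' @param exclude_n integer distances to drop before fitting.
#' @param log_space fit in log space instead of linear p-space (default
#'   `FALSE`, mirroring common curve-fitting practice on such data).
#' @return An object of class `"hyperexp_fit"`: the fitted
#'   [hyperexp_model()] plus residual sum of squares and the data used.
#'   Methods: `print`, `coef`, `predict`, `residuals`, `fitted`.
#' @examples
#' m <- hyperexp_model(0.104, 0.019)
#' fit <- fit_hyperexponential(1:10, p_loc(m, 1:10))
#' coef(fit)
#' @export
fit_hyperexponential <- function(n, p, exclude_n = integer(0),
                                 log_space = FALSE) {
  stopifnot(is.numeric(n), is.numeric(p), length(n) == length(p))
  if (any(p <= 0)) stop("observed proportions must be positive")
  if (any(n < 0)) stop("`n` must be non-negative")
  keep <- !(n %in% exclude_n)
  n <- n[keep]; p <- p[keep]
  if (length(n) < 3)
    stop("need at least 3 observations after exclusion (got ",
         length(n), ")")

  # starting values from the linearised model -log p = a n + b n^2
  lin <- stats::lm(I(-log(p)) ~ 0 + n + I(n^2))
  start <- list(alpha = unname(coef(lin)[1]), beta = unname(coef(lin)[2]))

  if (log_space) {
    alpha <- start$alpha; beta <- start$beta
    fitted_p <- exp(-alpha * n - beta * n^2)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ exp(-alpha * nn - beta * nn^2),
                        data = data.frame(nn = n, p = p),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop("hyper-exponential fit failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    cf <- stats::coef(fit)
    alpha <- unname(cf["alpha"]); beta <- unname(cf["beta"])
    fitted_p <- stats::fitted(fit)
  }
  structure(list(
    model = hyperexp_model(alpha, beta),
    rss = sum((p - fitted_p)^2),
    data = data.frame(n = n, p = p),
    fitted = as.numeric(fitted_p),
    excluded = exclude_n,
    log_space = log_space
  ), class = "hyperexp_fit")
}

#' @export
print.hyperexp_fit <- function(x, ...) {
  cat("Hyper-exponential fit (", if (x$log_space) "log" else "linear",
      " p-space, ", nrow(x$data), " observations",
      if (length(x$excluded)) paste0(", excluded n = ",
                                     paste(x$excluded, collapse = ",")),
      ")\n", sep = "")
  print(x$model)
  cat(sprintf("Residual sum of squares: %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.hyperexp_fit <- function(object, ...) coef(object$model)

#' @export
predict.hyperexp_fit <- function(object, n, ...) {
  if (missing(n)) return(object$fitted)
  p_loc(object$model, n)
}

#' @export
fitted.hyperexp_fit <- function(object, ...) object$fitted

#' @export
residuals.hyperexp_fit <- function(object, ...) object$data$p - object$fitted
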