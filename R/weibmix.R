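#' Mixture-of-Weibulls survival model
#'
#' Constructs a mixture Weibull model with survival function
#' \deqn{S(t) = \sum_j p_j \exp[-(t/\lambda_j)^{k_j}],}
#' the flexible parametric form used to represent delayed effects, crossing
#' hazards, cure-like plateaus and ordinary proportional-hazards behaviour
#' with one to three components.
#'
#' @param scale positive component scales (time units), length 1 to 3.
#' @param shape positive component shapes, same length.
#' @param weights positive mixing weights summing to 1; default equal.
#' @return An object of class `weibmix`. Fitted models (from
#'   [weibmix_fit]) additionally carry the transformed-scale parameter
#'   vector, its covariance, the maximized log-likelihood and fit metadata.
#' @examples
#' m <- weibmix(scale = c(2, 10), shape = c(1, 2.5), weights = c(0.4, 0.6))
#' predict(m, times = c(0, 1, 5), type = "survival")
#' @export
weibmix <- function(scale, shape, weights = NULL) {
  scale <- as.numeric(scale)
  shape <- as.numeric(shape)
  J <- length(scale)
  if (J < 1 || J > 3) stop("1 to 3 components supported", call. = FALSE)
  if (length(shape) != J) stop("scale and shape lengths differ", call. = FALSE)
  weights <- as.numeric(weights %||% rep(1 / J, J))
  if (length(weights) != J) stop("weights length must match components", call. = FALSE)
  if (any(scale <= 0) || any(shape <= 0) || any(weights <= 0))
    stop("scales, shapes and weights must be strictly positive", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-10)
    stop("weights must sum to 1 (within 1e-10)", call. = FALSE)
  structure(list(weights = weights, scale = scale, shape = shape,
                 J = J, par = weibmix_par(weights, scale, shape),
                 vcov = NULL, logLik = NA_real_,
                 n = NA_integer_, n_events = NA_integer_,
                 convergence = NA_integer_),
            class = "weibmix")
}

## transformed (unconstrained) parameterization:
## [logit weights vs last component (J-1), log scale (J), log shape (J)]
weibmix_par <- function(weights, scale, shape) {
  J <- length(scale)
  a <- if (J > 1) log(weights[-J]) - log(weights[J]) else numeric(0)
  p <- c(a, log(scale), log(shape))
  names(p) <- c(if (J > 1) paste0("logit_w", seq_len(J - 1)),
                paste0("log_scale", seq_len(J)),
                paste0("log_shape", seq_len(J)))
  p
}

## inverse of weibmix_par
weibmix_unpar <- function(par, J) {
  if (J > 1) {
    a <- c(par[seq_len(J - 1)], 0)
    e <- exp(a - max(a))
    w <- e / sum(e)
  } else w <- 1
  list(weights = unname(w),
       scale = exp(unname(par[(J - 1) + seq_len(J)])),
       shape = exp(unname(par[(J - 1) + J + seq_len(J)])))
}

## vectorized survival/density over t >= 0
mix_survival <- function(model, t) {
  if (any(t < 0)) stop("negative time", call. = FALSE)
  u <- exp_u(t, model$scale, model$shape)         # n x J
  as.vector(exp(-u) %*% model$weights)
}

mix_density <- function(model, t) {
  if (any(t < 0)) stop("negative time", call. = FALSE)
  if (any(t == 0) && any(model$shape < 1))
    stop("density diverges at t = 0 when any shape < 1", call. = FALSE)
  u <- exp_u(t, model$scale, model$shape)
  dens <- sapply(seq_len(model$J), function(j) {
    k <- model$shape[j]; lam <- model$scale[j]
    (k / lam) * (t / lam)^(k - 1) * exp(-u[, j])
  })
  if (is.null(dim(dens))) dens <- matrix(dens, ncol = model$J)
  as.vector(dens %*% model$weights)
}

## u_ij = (t_i / lambda_j)^{k_j}, capped to avoid overflow downstream
exp_u <- function(t, scale, shape) {
  n <- length(t)
  lt <- log(t)                      # -Inf at t = 0, handled by cap/exp
  ex <- sweep(outer(lt, log(scale), "-"), 2, shape, "*")
  matrix(exp(pmin(ex, 700)), nrow = n)
}

#' Predict survival, density, hazard or RMST from a mixture Weibull model
#'
#' @param object a `weibmix` model.
#' @param times evaluation times (horizons for `type = "rmst"`).
#' @param type one of `"survival"`, `"density"`, `"hazard"`, `"rmst"`.
#' @param ... unused.
#' @return numeric vector matching `times`.
#' @export
predict.weibmix <- function(object, times,
                            type = c("survival", "density", "hazard", "rmst"),
                            ...) {
  type <- match.arg(type)
  switch(type,
         survival = mix_survival(object, times),
         density = mix_density(object, times),
         hazard = mix_density(object, times) / mix_survival(object, times),
         rmst = mix_rmst_value(object, times))
}

#' Simulate event times from a mixture Weibull model
#'
#' Draws component labels with the mixing weights, then Weibull times by
#' inversion, so draws are reproducible given `seed`.
#'
#' @param object a `weibmix` model.
#' @param nsim number of event times.
#' @param seed optional integer seed; the caller's RNG stream is preserved.
#' @param ... unused.
#' @export
simulate.weibmix <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    j <- sample.int(object$J, nsim, replace = TRUE, prob = object$weights)
    u <- stats::runif(nsim)
    stats::qweibull(u, shape = object$shape[j], scale = object$scale[j])
  })
}

#' Censored-data log-likelihood of a mixture Weibull model
#'
#' Sum over subjects of `event * log f(t) + (1 - event) * log S(t)`,
#' accumulated on the log scale (log-sum-exp across components).
#'
#' @param model a `weibmix`.
#' @param time,event single-arm follow-up data (a data frame with columns
#'   `time`/`event` may be passed as `time`).
#' @return the log-likelihood (scalar).
#' @export
weibmix_loglik <- function(model, time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  ll <- mix_nll(model$par, model$J, time, event, negate = FALSE)
  if (!is.finite(ll))
    stop("log-likelihood is not finite for these data (e.g. an event at ",
         "time 0)", call. = FALSE)
  ll
}

#' @export
print.weibmix <- function(x, ...) {
  cat(sprintf("Mixture Weibull model (%d component%s)\n", x$J,
              if (x$J > 1) "s" else ""))
  tab <- data.frame(weight = x$weights, scale = x$scale, shape = x$shape)
  rownames(tab) <- paste0("component", seq_len(x$J))
  print(tab, digits = 4)
  if (is.finite(x$logLik))
    cat(sprintf("logLik = %.3f on n = %d (%d events); covariance %s\n",
                x$logLik, x$n, x$n_events,
                if (is.null(x$vcov)) "unavailable" else "available"))
  invisible(x)
}

#' @export
coef.weibmix <- function(object, ...) {
  cbind(weight = object$weights, scale = object$scale, shape = object$shape)
}

#' @export
logLik.weibmix <- function(object, ...) {
  structure(object$logLik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
vcov.weibmix <- function(object, ...) object$vcov
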