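## ---- censored mixture-Weibull likelihood on the transformed scale ----
##
## Parameter vector: [a_1..a_{J-1} (multinomial logits, last component as
## reference), log lambda_1..J, log k_1..J]. All internals are vectorized
## over subjects; exponents are capped at 700 so extreme shape/scale
## combinations degrade to zero weight rather than NaN.

## negative (default) log-likelihood; subjects with time == 0 must be
## censored (they contribute log S(0) = 0) and are removed by the fitter
mix_nll <- function(par, J, time, event, negate = TRUE) {
  np <- weibmix_unpar(par, J)
  lt <- log(time)
  ex <- sweep(outer(lt, log(np$scale), "-"), 2, np$shape, "*")
  u <- exp(pmin(ex, 700))
  lp <- rep(log(np$weights), each = length(time))
  lS <- matrix(lp, ncol = J) - u
  ev <- event == 1
  ll <- 0
  if (any(!ev)) ll <- ll + sum(row_logsumexp(lS[!ev, , drop = FALSE]))
  if (any(ev)) {
    lk <- rep(log(np$shape), each = sum(ev))
    lf <- matrix(lp[rep(ev, J)], ncol = J) + matrix(lk, ncol = J) +
      ex[ev, , drop = FALSE] - lt[ev] - u[ev, , drop = FALSE]
    ll <- ll + sum(row_logsumexp(lf))
  }
  if (!is.finite(ll)) ll <- -Inf
  if (negate) -ll else ll
}

## analytic gradient of the negative log-likelihood
mix_ngr <- function(par, J, time, event) {
  np <- weibmix_unpar(par, J)
  n <- length(time)
  lt <- log(time)
  ex <- sweep(outer(lt, log(np$scale), "-"), 2, np$shape, "*")
  u <- exp(pmin(ex, 700))
  lp <- matrix(rep(log(np$weights), each = n), ncol = J)
  ev <- event == 1

  g_a <- numeric(if (J > 1) J - 1 else 0)
  g_ll <- numeric(J)   # d/d log lambda
  g_lk <- numeric(J)   # d/d log k

  if (any(ev)) {
    lk <- matrix(rep(log(np$shape), each = sum(ev)), ncol = J)
    lf <- lp[ev, , drop = FALSE] + lk + ex[ev, , drop = FALSE] - lt[ev] -
      u[ev, , drop = FALSE]
    w <- exp(lf - row_logsumexp(lf))                       # posterior weights
    ue <- u[ev, , drop = FALSE]
    xe <- ex[ev, , drop = FALSE]
    g_ll <- g_ll + colSums(w * sweep(ue - 1, 2, np$shape, "*"))
    g_lk <- g_lk + colSums(w * (1 + xe - ue * xe))
    if (J > 1)
      g_a <- g_a + colSums(w[, -J, drop = FALSE]) -
        sum(ev) * np$weights[-J]
  }
  if (any(!ev)) {
    lS <- lp[!ev, , drop = FALSE] - u[!ev, , drop = FALSE]
    v <- exp(lS - row_logsumexp(lS))
    uc <- u[!ev, , drop = FALSE]
    xc <- ex[!ev, , drop = FALSE]
    g_ll <- g_ll + colSums(v * sweep(uc, 2, np$shape, "*"))
    g_lk <- g_lk + colSums(v * (-uc * xc))
    if (J > 1)
      g_a <- g_a + colSums(v[, -J, drop = FALSE]) -
        sum(!ev) * np$weights[-J]
  }
  -unname(c(g_a, g_ll, g_lk))
}

## Fast objective used by the optimizer: computes the negative
## log-likelihood and its analytic gradient in one pass, cached per
## parameter vector (L-BFGS-B evaluates fn and gr at the same points).
## Mirrors mix_nll/mix_ngr, which remain the reference implementations.
make_mix_objective <- function(J, time, event) {
  ev <- event == 1
  lt_e <- log(time[ev])
  lt_c <- log(time[!ev])
  ne <- length(lt_e)
  nc <- length(lt_c)
  cache_par <- NULL
  cache_val <- NULL
  compute <- function(par) {
    np <- weibmix_unpar(par, J)
    k <- np$shape
    p <- np$weights
    kll <- k * log(np$scale)
    ex_e <- tcrossprod(lt_e, k) - rep(kll, each = ne)
    u_e <- exp(pmin(ex_e, 700))
    lf <- ex_e - u_e - lt_e + rep(log(p) + log(k), each = ne)
    ls_f <- row_logsumexp(lf)
    ll <- sum(ls_f)
    if (nc) {
      ex_c <- tcrossprod(lt_c, k) - rep(kll, each = nc)
      u_c <- exp(pmin(ex_c, 700))
      lS <- rep(log(p), each = nc) - u_c
      ls_S <- row_logsumexp(lS)
      ll <- ll + sum(ls_S)
    }
    if (!is.finite(ll))
      return(list(nll = Inf, gr = rep(0, length(par))))
    w <- exp(lf - ls_f)
    g_ll <- colSums(w * (u_e - 1)) * k
    g_lk <- colSums(w * (1 + ex_e - u_e * ex_e))
    g_a <- if (J > 1) colSums(w)[-J] - ne * p[-J] else numeric(0)
    if (nc) {
      v <- exp(lS - ls_S)
      g_ll <- g_ll + colSums(v * u_c) * k
      g_lk <- g_lk - colSums(v * (u_c * ex_c))
      if (J > 1) g_a <- g_a + colSums(v)[-J] - nc * p[-J]
    }
    list(nll = -ll, gr = -unname(c(g_a, g_ll, g_lk)))
  }
  get_val <- function(par) {
    if (is.null(cache_par) || !identical(par, cache_par)) {
      cache_par <<- par
      cache_val <<- compute(par)
    }
    cache_val
  }
  list(fn = function(par) get_val(par)$nll,
       gr = function(par) get_val(par)$gr)
}

## quantile-split starting values: J contiguous blocks of the sorted times,
## scale = block mean, shape 1, equal weights
quantile_start <- function(time, J) {
  ts <- sort(time[time > 0])
  blocks <- if (J == 1) list(ts) else
    split(ts, cut(seq_along(ts), J, labels = FALSE))
  lam <- vapply(blocks, mean, numeric(1))
  lam[!is.finite(lam) | lam <= 0] <- stats::median(ts)
  c(rep(0, max(J - 1, 0)), log(lam), rep(0, J))
}

#' Fit a mixture Weibull model to right-censored single-arm data
#'
#' Maximizes the censored log-likelihood over the unconstrained
#' parameterization (component log-scales, log-shapes, multinomial-logit
#' weights) by multi-start L-BFGS-B with an analytic gradient. The first
#' start uses a quantile-split heuristic (contiguous blocks of the sorted
#' times set the scales); further starts jitter it with seeded Gaussian
#' noise (sd 0.5). The parameter covariance is the inverse of the observed
#' information, obtained by central finite differences of the score
#' (step 1e-4) at the optimum; an ill-conditioned information matrix
#' (condition number above 1e10) triggers a warning and a pseudo-inverse,
#' and a fully singular one leaves the covariance unavailable (inference
#' disabled). Components are returned in increasing order of scale.
#'
#' @param time,event single-arm data; a data frame with `time`/`event`
#'   columns may be passed as `time`. At least one event is required;
#'   events at time 0 are rejected (the Weibull likelihood is unbounded or
#'   zero there).
#' @param n_components number of Weibull components, 1 to 3 (default 3).
#' @param n_starts number of multi-start runs (default 10).
#' @param seed integer seed making the jittered starts reproducible.
#' @param maxit,reltol optimizer budget per start and relative
#'   log-likelihood convergence tolerance.
#' @return A fitted [weibmix] with covariance, log-likelihood, counts and
#'   per-start diagnostics in attribute `starts`.
#' @examples
#' set.seed(1)
#' t <- rweibull(200, shape = 1.5, scale = 2)
#' fit <- weibmix_fit(t, rep(1, 200), n_components = 1, seed = 1)
#' coef(fit)
#' @export
weibmix_fit <- function(time, event = NULL, n_components = 3, n_starts = 10,
                        seed = NULL, maxit = 500, reltol = 1e-9) {
  if (is.data.frame(time)) {
    if (!is.null(event))
      stop("when 'time' is a data frame, pass n_components and later ",
           "arguments by name", call. = FALSE)
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event))
  J <- as.integer(n_components)
  if (J < 1 || J > 3) stop("n_components must be 1, 2 or 3", call. = FALSE)
  n_all <- length(time)
  n_events <- sum(event == 1)
  if (n_events < 1) stop("at least one event is required to fit", call. = FALSE)
  if (any(time == 0 & event == 1))
    stop("event at time 0: Weibull likelihood undefined", call. = FALSE)

  ## deterministic given data content: sort so accumulation order is fixed
  keep <- !(time == 0 & event == 0)   # censored zeros contribute log S(0) = 0
  o <- order(time[keep], event[keep])
  tt <- time[keep][o]
  dd <- as.numeric(event[keep][o])

  npar <- 3L * J - 1L
  lower <- c(rep(-13.8155, max(J - 1, 0)),
             rep(log(min(tt[tt > 0])) - 10, J), rep(log(0.01), J))
  upper <- c(rep(13.8155, max(J - 1, 0)),
             rep(log(max(tt)) + 10, J), rep(log(100), J))

  base_start <- quantile_start(tt, J)
  starts <- with_seed(seed, {
    s <- list(pmin(pmax(base_start, lower), upper))
    while (length(s) < n_starts)
      s[[length(s) + 1]] <- pmin(pmax(
        base_start + stats::rnorm(npar, 0, 0.5), lower), upper)
    s
  })

  obj <- make_mix_objective(J, tt, dd)
  runs <- lapply(starts, function(p0) {
    tryCatch(
      stats::optim(p0, obj$fn, obj$gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit,
                                  factr = reltol / .Machine$double.eps)),
      error = function(e) list(value = Inf, convergence = -1L,
                               message = conditionMessage(e)))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  diag_tab <- data.frame(start = seq_along(runs),
                         logLik = -vals,
                         convergence = vapply(runs, function(r)
                           as.integer(r$convergence %||% -1L), integer(1)))
  if (!any(is.finite(vals))) {
    stop("all ", n_starts, " starts failed to converge; per-start log-",
         "likelihoods: ", paste(signif(-vals, 4), collapse = ", "),
         call. = FALSE)
  }
  best <- runs[[which.min(vals)]]

  ## canonical component order (increasing scale); the likelihood is
  ## invariant under this relabeling so the sorted vector is still optimal
  np <- weibmix_unpar(best$par, J)
  ord <- order(np$scale)
  weights <- np$weights[ord]
  scale <- np$scale[ord]
  shape <- np$shape[ord]
  if (any(weights <= 2e-6))
    warning("a mixture weight collapsed to the 1e-6 floor; consider fewer ",
            "components", call. = FALSE)
  par <- weibmix_par(weights, scale, shape)

  H <- num_jacobian(obj$gr, par)
  H <- (H + t(H)) / 2
  V <- information_inverse(H)
  if (!is.null(V)) dimnames(V) <- list(names(par), names(par))

  model <- weibmix(scale, shape, weights)
  model$par <- par
  model$vcov <- V
  model$logLik <- -best$value
  model$n <- n_all
  model$n_events <- as.integer(n_events)
  model$convergence <- as.integer(best$convergence %||% -1L)
  model$n_starts <- n_starts
  model$seed <- seed
  attr(model, "starts") <- diag_tab
  model
}

## invert the observed information; pseudo-inverse + warning when
## ill-conditioned, NULL when numerically singular
information_inverse <- function(H) {
  if (!all(is.finite(H))) return(NULL)
  e <- eigen(H, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-12
  pos <- e$values > tol
  if (!any(pos)) return(NULL)
  if (!all(pos) || max(e$values) / min(e$values[pos]) > 1e10) {
    warning("observed information is ill-conditioned (condition number > ",
            "1e10); covariance from pseudo-inverse", call. = FALSE)
    if (!all(pos)) {
      inv <- e$vectors[, pos, drop = FALSE] %*%
        (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
      dimnames(inv) <- dimnames(H)
      return(inv)
    }
  }
  inv <- e$vectors %*% (t(e$vectors) / e$values)
  dimnames(inv) <- dimnames(H)
  inv
}

#' Select the number of mixture components by AIC or BIC
#'
#' Fits each candidate component count and returns the model minimizing the
#' chosen criterion, with the comparison table attached as attribute
#' `"selection"`. Candidates whose fit fails are recorded with `NA` and
#' skipped; the call fails only if every candidate fails.
#'
#' @inheritParams weibmix_fit
#' @param candidates subset of 1:3 to try.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return the selected fitted [weibmix].
#' @export
select_components <- function(time, event = NULL, candidates = 1:3,
                              criterion = c("BIC", "AIC"), n_starts = 10,
                              seed = NULL) {
  criterion <- match.arg(criterion)
  if (is.data.frame(time)) {
    if (!is.null(event))
      stop("when 'time' is a data frame, pass later arguments by name",
           call. = FALSE)
    event <- time$event
    time <- time$time
  }
  stopifnot(all(candidates %in% 1:3))
  n <- length(time)
  fits <- lapply(candidates, function(J) {
    tryCatch(weibmix_fit(time, event, n_components = J,
                         n_starts = n_starts, seed = seed),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok))
    stop("all candidate component counts failed to fit", call. = FALSE)
  df <- vapply(candidates, function(J) 3 * J - 1, numeric(1))
  ll <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "condition")) NA_real_ else f$logLik, numeric(1)), NA)
  crit <- if (criterion == "AIC") 2 * df - 2 * ll else log(n) * df - 2 * ll
  tab <- data.frame(n_components = candidates, logLik = ll, df = df,
                    criterion = crit)
  names(tab)[4] <- criterion
  best <- fits[[which.min(ifelse(ok, crit, Inf))]]
  attr(best, "selection") <- tab
  best
}
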