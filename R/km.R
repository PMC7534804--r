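#' Kaplan-Meier product-limit fit for one arm
#'
#' Computes the product-limit estimate S(t) = prod over event times t_(i) <= t
#' of (1 - d_i/n_i), with the standard convention that deaths precede
#' censorings at tied times. Greenwood terms d_i/(n_i (n_i - d_i)) are
#' accumulated for variance work; the term is undefined when the risk set is
#' exhausted by events (n_i = d_i) and is recorded as `NA`.
#'
#' @param time follow-up times for a single arm, or a data frame with
#'   columns `time` and `event` (as produced by [arm_split]).
#' @param event 0/1 event indicators (ignored when `time` is a data frame).
#' @return An object of class `km_curve`: distinct event times, at-risk and
#'   event counts, survival values, cumulative Greenwood terms, and the
#'   largest observed (event or censored) time.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 0, 1))
#' @export
km_fit <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), all(is.finite(time)), all(time >= 0))
  event <- as.numeric(event)
  if (sum(event) < 1)
    stop("cannot estimate a survival curve from an arm with no events",
         call. = FALSE)
  dt <- sort(unique(time[event == 1]))
  n_risk <- vapply(dt, function(s) sum(time >= s), numeric(1))
  n_event <- vapply(dt, function(s) sum(time == s & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw_term <- ifelse(n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), NA_real_)
  ## cumulative area under the step function up to each event time
  cumarea <- cumsum(c(1, surv[-length(surv)]) * diff(c(0, dt)))
  structure(list(time = dt, n_risk = n_risk, n_event = n_event, surv = surv,
                 greenwood = cumsum(ifelse(is.na(gw_term), 0, gw_term)),
                 gw_term = gw_term, cumarea = cumarea,
                 max_time = max(time), n = length(time),
                 n_events = sum(event)),
            class = "km_curve")
}

## exact area under the KM step function on [0, tau]
km_area <- function(curve, tau) {
  m <- findInterval(tau, curve$time)
  if (m == 0) return(tau)
  curve$cumarea[m] + curve$surv[m] * (tau - curve$time[m])
}

#' @rdname rmst
#' @export
rmst.km_curve <- function(object, tau, alpha = 0.05, ...) {
  stopifnot(length(tau) == 1, tau > 0)
  if (tau > object$max_time)
    stop("tau = ", tau, " exceeds the curve support (largest observed time ",
         object$max_time, "); a Kaplan-Meier curve is not defined beyond ",
         "follow-up -- use the parametric mixture engine to extrapolate",
         call. = FALSE)
  est <- km_area(object, tau)
  idx <- which(object$time <= tau)
  if (any(is.na(object$gw_term[idx]))) {
    warning("variance term undefined where the risk set is exhausted ",
            "(n_i = d_i); term dropped", call. = FALSE)
  }
  areas <- est - object$cumarea[idx]
  terms <- object$gw_term[idx]
  v <- sum(areas^2 * terms, na.rm = TRUE)
  new_rmst_estimate(tau, est, sqrt(v), alpha, engine = "km")
}

#' Kaplan-Meier RMST contrast between two arms
#'
#' Difference (treatment minus control) and ratio of KM-based RMST at a
#' common horizon, arms treated as independent. The ratio interval is built
#' on the log scale and exponentiated.
#'
#' @param curve0,curve1 `km_curve` objects for the control and treatment arm.
#' @param tau horizon, within both curves' support.
#' @param alpha two-sided level for the confidence intervals.
#' @return list with components `difference` and `ratio`, each an
#'   `rmst_contrast`.
#' @export
km_rmst_contrast <- function(curve0, curve1, tau, alpha = 0.05) {
  r0 <- rmst(curve0, tau, alpha)
  r1 <- rmst(curve1, tau, alpha)
  list(difference = contrast_from_arms(r0$estimate, r0$se^2,
                                       r1$estimate, r1$se^2,
                                       tau, "difference", alpha, "km"),
       ratio = contrast_from_arms(r0$estimate, r0$se^2,
                                  r1$estimate, r1$se^2,
                                  tau, "ratio", alpha, "km"))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, %d distinct event times, max time = %g\n",
              x$n, x$n_events, length(x$time), x$max_time))
  invisible(x)
}

#' Tidy data frame of a Kaplan-Meier curve
#'
#' Columns `time`, `n_risk`, `n_event`, `survival`, `std_err` (Greenwood
#' standard error of the survival probability).
#'
#' @param x a `km_curve`.
#' @param ... unused.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             survival = x$surv, std_err = x$surv * sqrt(x$greenwood))
}
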