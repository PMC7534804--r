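## constructors and print methods for single-tau estimates and contrasts

new_rmst_estimate <- function(tau, estimate, se, alpha, engine,
                              truncate = NULL) {
  z <- z_crit(alpha)
  lo <- estimate - z * se
  hi <- estimate + z * se
  if (!is.null(truncate)) {
    lo <- max(lo, truncate[1])
    hi <- min(hi, truncate[2])
  }
  structure(list(tau = tau, estimate = estimate, se = se,
                 ci_low = lo, ci_high = hi, alpha = alpha, engine = engine),
            class = "rmst_estimate")
}

## Build a contrast (treatment vs control) from per-arm RMST point estimates
## and variances. Ratio-type contrasts carry their se on the log scale; the
## rmtl ratio compares restricted mean time lost (tau - mu).
contrast_from_arms <- function(mu0, var0, mu1, var1, tau, kind, alpha,
                               engine) {
  kind <- match.arg(kind, c("difference", "ratio", "rmtl_ratio"))
  z <- z_crit(alpha)
  if (kind == "difference") {
    est <- mu1 - mu0
    se <- sqrt(var0 + var1)
    lo <- est - z * se
    hi <- est + z * se
    p <- two_sided_p(est, se)
  } else {
    if (kind == "rmtl_ratio") {
      l0 <- tau - mu0
      l1 <- tau - mu1
      if (l0 <= 0 || l1 <= 0)
        stop("restricted mean time lost is nonpositive at tau = ", tau,
             "; rmtl ratio undefined", call. = FALSE)
      est <- l1 / l0
      se <- sqrt(var1 / l1^2 + var0 / l0^2)  # log scale
    } else {
      if (mu0 <= 0 || mu1 <= 0)
        stop("RMST must be positive for a ratio contrast", call. = FALSE)
      est <- mu1 / mu0
      se <- sqrt(var1 / mu1^2 + var0 / mu0^2)  # log scale
    }
    lo <- exp(log(est) - z * se)
    hi <- exp(log(est) + z * se)
    p <- two_sided_p(log(est), se)
  }
  structure(list(tau = tau, kind = kind, estimate = est, se = se,
                 ci_low = lo, ci_high = hi, p_value = p, alpha = alpha,
                 engine = engine),
            class = "rmst_contrast")
}

#' @export
print.rmst_estimate <- function(x, ...) {
  cat(sprintf("RMST (%s engine) at tau = %g: %.4f  se = %.4f  %d%% CI [%.4f, %.4f]\n",
              x$engine, x$tau, x$estimate, x$se,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
print.rmst_contrast <- function(x, ...) {
  lab <- c(difference = "RMST difference (trt - ctrl)",
           ratio = "RMST ratio (trt / ctrl)",
           rmtl_ratio = "RMTL ratio (trt / ctrl)")[x$kind]
  cat(sprintf("%s (%s engine) at tau = %g: %.4f  %d%% CI [%.4f, %.4f]  p = %.4g\n",
              lab, x$engine, x$tau, x$estimate,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}
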