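#' Dynamic RMST analysis of a two-arm trial
#'
#' Fits a mixture Weibull survival model to each arm of a right-censored
#' two-arm trial and traces the restricted mean survival time (RMST), its
#' between-arm difference \eqn{\Delta(\tau)} and ratio \eqn{\theta(\tau)}
#' (optionally the RMTL ratio) over a grid of restriction times, with
#' pointwise delta-method confidence intervals. Kaplan-Meier RMST
#' counterparts are computed wherever the horizon lies within an arm's
#' follow-up, giving the nonparametric reference the smooth parametric
#' curves are customarily checked against.
#'
#' The default horizon `tau` is the minimum over arms of the largest
#' observed (event or censored) time; the default grid spans 100 equally
#' spaced points from tau/100 to tau. The parametric curve may be evaluated
#' beyond follow-up, but the grid is clamped (with a warning) at
#' `extrapolation_factor` times the default tau to discourage long
#' extrapolation.
#'
#' @param formula a formula `survival::Surv(time, event) ~ arm`, or a
#'   ready-made [surv_dataset] (in which case `data` is ignored).
#' @param data data frame holding the formula variables.
#' @param control label of the control arm (default: first label
#'   encountered).
#' @param n_components Weibull components per arm: a single count shared by
#'   both arms or a length-2 vector `c(control, treatment)`; 1 to 3.
#' @param criterion if non-`NULL` (`"BIC"` or `"AIC"`), the component count
#'   is selected per arm among 1:3 by that criterion and `n_components` is
#'   ignored.
#' @param grid horizon grid: `NULL` for the default, a single integer for
#'   that many equally spaced points up to the default tau, or an
#'   increasing positive numeric vector of horizons.
#' @param alpha two-sided level for all intervals.
#' @param extrapolation_factor largest allowed grid horizon as a multiple
#'   of the default tau (default 1.5).
#' @param rmtl also compute the restricted-mean-time-lost ratio curve.
#' @param n_starts,seed multi-start budget and seed passed to
#'   [weibmix_fit] (the treatment arm uses `seed + 1`).
#' @return An object of class `dynrmst`: the tidy curve data frame
#'   (`$curve`), fitted per-arm models (`$models`), KM curves (`$km`), the
#'   dataset, the default tau and the KM support boundary. Methods:
#'   `print`, `summary`, `plot`, `coef`, `predict`, `residuals`.
#' @examples
#' sc <- trial_scenario("ph", n = 120, seed = 7)
#' ds <- simulate_trial(sc)
#' fit <- dynrmst(ds, n_components = 1, seed = 7, n_starts = 3)
#' print(fit)
#' @export
dynrmst <- function(formula, data = NULL, control = NULL, n_components = 3,
                    criterion = NULL, grid = NULL, alpha = 0.05,
                    extrapolation_factor = 1.5, rmtl = FALSE,
                    n_starts = 10, seed = NULL) {
  cl <- match.call()
  if (inherits(formula, "surv_dataset")) {
    ds <- formula
  } else {
    env <- new.env(parent = environment(formula) %||% parent.frame())
    env$Surv <- survival::Surv
    formula <- stats::as.formula(formula, env = env)
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    if (!survival::is.Surv(y))
      stop("left-hand side must be a survival::Surv(time, event) object",
           call. = FALSE)
    if (ncol(mf) != 2)
      stop("right-hand side must be a single arm variable", call. = FALSE)
    ds <- surv_dataset(y[, "time"], y[, "status"], as.character(mf[[2]]),
                       control = control)
  }
  stopifnot(alpha > 0, alpha < 1, extrapolation_factor >= 1)

  arms <- arm_split(ds)
  nc <- rep_len(as.integer(n_components), 2)
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1)
  fit_arm <- function(df, J, sd) {
    if (!is.null(criterion))
      select_components(df, candidates = 1:3, criterion = criterion,
                        n_starts = n_starts, seed = sd)
    else
      weibmix_fit(df, n_components = J, n_starts = n_starts, seed = sd)
  }
  models <- list(control = fit_arm(arms$control, nc[1], seeds[[1]]),
                 treatment = fit_arm(arms$treatment, nc[2], seeds[[2]]))
  km <- list(control = km_fit(arms$control),
             treatment = km_fit(arms$treatment))

  taud <- default_tau(ds)
  if (is.null(grid)) grid <- 100L
  if (length(grid) == 1 && grid == round(grid) && grid >= 1)
    grid <- seq(taud / grid, taud, length.out = grid)
  grid <- as.numeric(grid)
  if (!length(grid) || any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be a strictly increasing vector of positive horizons",
         call. = FALSE)
  cap <- extrapolation_factor * taud
  if (max(grid) > cap) {
    warning("grid clamped at ", signif(cap, 6), " (",
            extrapolation_factor, " x default tau); long extrapolation of ",
            "the parametric RMST curve is discouraged", call. = FALSE)
    grid <- grid[grid <= cap]
  }

  kinds <- c("difference", "ratio", if (rmtl) "rmtl_ratio")
  curve <- build_curve_rows(models, km, grid, kinds, alpha)

  structure(list(curve = curve, models = models, km = km, data = ds,
                 grid = grid, default_tau = taud,
                 km_boundary = min(km$control$max_time,
                                   km$treatment$max_time),
                 alpha = alpha, kinds = kinds, call = cl),
            class = "dynrmst")
}

## one tidy long data frame: per-arm RMST rows and contrast rows, both engines
build_curve_rows <- function(models, km, grid, kinds, alpha) {
  row1 <- function(tau, quantity, engine, e)
    data.frame(tau = tau, quantity = quantity, engine = engine,
               estimate = e$estimate, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high,
               p_value = if (!is.null(e$p_value)) e$p_value else NA_real_)
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    tau <- grid[i]
    ## per-arm estimate and delta-method variance computed once per tau
    v0 <- mu_var(models$control, tau)
    v1 <- mu_var(models$treatment, tau)
    m0 <- mix_rmst_value(models$control, tau)
    m1 <- mix_rmst_value(models$treatment, tau)
    rows <- list(
      row1(tau, "rmst_control", "mixture",
           new_rmst_estimate(tau, m0, sqrt(v0), alpha, "mixture", c(0, tau))),
      row1(tau, "rmst_treatment", "mixture",
           new_rmst_estimate(tau, m1, sqrt(v1), alpha, "mixture", c(0, tau))))
    for (kd in kinds)
      rows[[length(rows) + 1]] <-
        row1(tau, kd, "mixture",
             contrast_from_arms(m0, v0, m1, v1, tau, kd, alpha, "mixture"))
    k0 <- if (tau <= km$control$max_time) rmst(km$control, tau, alpha)
    k1 <- if (tau <= km$treatment$max_time) rmst(km$treatment, tau, alpha)
    if (!is.null(k0))
      rows[[length(rows) + 1]] <- row1(tau, "rmst_control", "km", k0)
    if (!is.null(k1))
      rows[[length(rows) + 1]] <- row1(tau, "rmst_treatment", "km", k1)
    if (!is.null(k0) && !is.null(k1))
      for (kd in kinds)
        rows[[length(rows) + 1]] <-
          row1(tau, kd, "km",
               contrast_from_arms(k0$estimate, k0$se^2, k1$estimate, k1$se^2,
                                  tau, kd, alpha, "km"))
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

curve_rows <- function(x, quantity, engine = "mixture") {
  x$curve[x$curve$quantity == quantity & x$curve$engine == engine, ,
          drop = FALSE]
}

#' @export
print.dynrmst <- function(x, ...) {
  ds <- x$data
  cat("Dynamic RMST analysis (mixture Weibull vs Kaplan-Meier)\n")
  cat(sprintf("  arms: control '%s' vs treatment '%s'; n = %d; default tau = %g\n",
              attr(ds, "control"), attr(ds, "treatment"), nrow(ds),
              x$default_tau))
  taud <- x$default_tau
  r0 <- rmst(x$models$control, taud, x$alpha)
  r1 <- rmst(x$models$treatment, taud, x$alpha)
  cat(sprintf("  RMST at default tau: treatment %.3f, control %.3f (mixture engine)\n",
              r1$estimate, r0$estimate))
  for (kd in x$kinds) {
    ct <- rmst_contrast(x$models$control, x$models$treatment, taud, kd,
                        x$alpha)
    print(ct)
  }
  invisible(x)
}

#' @export
summary.dynrmst <- function(object, ...) {
  structure(list(fit = object,
                 agreement = tryCatch(km_mixture_agreement(object),
                                      error = function(e) NULL),
                 followup = tryCatch(follow_up_adequacy(object),
                                     error = function(e) NULL)),
            class = "summary.dynrmst")
}

#' @export
print.summary.dynrmst <- function(x, ...) {
  print(x$fit)
  for (arm in c("control", "treatment")) {
    cat("\n", arm, " arm mixture fit:\n", sep = "")
    print(x$fit$models[[arm]])
  }
  if (!is.null(x$agreement)) {
    cat("\nKM vs mixture RMST agreement over the shared grid:\n")
    print(x$agreement, digits = 4)
  }
  if (!is.null(x$followup)) print(x$followup)
  invisible(x)
}

#' @export
coef.dynrmst <- function(object, ...) {
  list(control = coef(object$models$control),
       treatment = coef(object$models$treatment))
}

#' Single-horizon estimates from a fitted dynamic RMST analysis
#'
#' Re-evaluates the mixture engine at arbitrary horizons (including beyond
#' the fitted grid).
#'
#' @param object a `dynrmst` fit.
#' @param tau horizons.
#' @param kind `"difference"`, `"ratio"` or `"rmtl_ratio"`.
#' @param ... unused.
#' @return data frame with one row per horizon.
#' @export
predict.dynrmst <- function(object, tau = object$default_tau,
                            kind = "difference", ...) {
  do.call(rbind, lapply(tau, function(tt) {
    ct <- rmst_contrast(object$models$control, object$models$treatment, tt,
                        kind, object$alpha)
    data.frame(tau = tt, kind = kind, estimate = ct$estimate,
               ci_low = ct$ci_low, ci_high = ct$ci_high,
               p_value = ct$p_value)
  }))
}

#' @export
residuals.dynrmst <- function(object, type = "coxsnell", ...) {
  ## Cox-Snell residuals -log S_arm(t_i) from the fitted arm models;
  ## censored subjects keep their censored status in attribute "event"
  ds <- object$data
  r <- numeric(nrow(ds))
  for (arm in c("control", "treatment")) {
    lab <- attr(ds, arm)
    idx <- ds$arm == lab
    r[idx] <- -log(mix_survival(object$models[[arm]], ds$time[idx]))
  }
  attr(r, "event") <- ds$event
  r
}

#' Plot dynamic RMST difference and ratio curves
#'
#' Base-graphics panels of \eqn{\Delta(\tau)} and \eqn{\theta(\tau)} with
#' pointwise CI ribbons, mixture and (where defined) KM engines overlaid,
#' and the default tau marked.
#'
#' @param x a `dynrmst` fit.
#' @param what which contrast curves to draw.
#' @param ... passed to [graphics::plot].
#' @export
plot.dynrmst <- function(x, what = intersect(c("difference", "ratio"),
                                             x$kinds), ...) {
  op <- graphics::par(mfrow = c(1, length(what)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (kd in what) {
    mx <- curve_rows(x, kd, "mixture")
    km <- curve_rows(x, kd, "km")
    ref <- if (kd == "difference") 0 else 1
    ylim <- range(mx$ci_low, mx$ci_high, km$estimate, ref, finite = TRUE)
    graphics::plot(mx$tau, mx$estimate, type = "n", ylim = ylim,
                   xlab = expression(tau),
                   ylab = if (kd == "difference") "RMST difference"
                          else if (kd == "ratio") "RMST ratio"
                          else "RMTL ratio", ...)
    graphics::polygon(c(mx$tau, rev(mx$tau)), c(mx$ci_low, rev(mx$ci_high)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::lines(mx$tau, mx$estimate, col = "steelblue", lwd = 2)
    if (nrow(km))
      graphics::lines(km$tau, km$estimate, col = "firebrick", lty = 2)
    graphics::abline(h = ref, col = "grey50", lty = 3)
    graphics::abline(v = x$default_tau, col = "grey50", lty = 3)
    graphics::legend("topleft", bty = "n", lwd = c(2, 1), lty = c(1, 2),
                     col = c("steelblue", "firebrick"),
                     legend = c("mixture", "KM"))
  }
  invisible(x)
}

#' Export the dynamic curve as tidy CSV
#'
#' Columns `tau`, `quantity`, `engine`, `estimate`, `se`, `ci_low`,
#' `ci_high`, `p_value` (empty where not applicable); KM rows are simply
#' absent beyond follow-up.
#'
#' @param x a `dynrmst` fit.
#' @param path output path.
#' @export
export_curve <- function(x, path) {
  stopifnot(inherits(x, "dynrmst"))
  utils::write.csv(x$curve, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Agreement between mixture and Kaplan-Meier RMST curves
#'
#' Summarizes, per arm, the absolute discrepancy between the parametric and
#' the nonparametric RMST over the grid points where the KM estimate is
#' defined: maximum and mean absolute discrepancy, and the maximum in units
#' of the KM standard error.
#'
#' @param x a `dynrmst` fit with at least 3 KM-supported grid points.
#' @return data frame with one row per arm.
#' @export
km_mixture_agreement <- function(x) {
  stopifnot(inherits(x, "dynrmst"))
  out <- lapply(c("control", "treatment"), function(arm) {
    q <- paste0("rmst_", arm)
    mx <- curve_rows(x, q, "mixture")
    km <- curve_rows(x, q, "km")
    shared <- intersect(mx$tau, km$tau)
    if (length(shared) < 3)
      stop("fewer than 3 grid points with KM support; refine the grid ",
           "within follow-up", call. = FALSE)
    mx <- mx[mx$tau %in% shared, ]
    km <- km[km$tau %in% shared, ]
    d <- abs(mx$estimate - km$estimate)
    in_se <- ifelse(km$se > 0, d / km$se, ifelse(d == 0, 0, Inf))
    data.frame(arm = arm, n_shared = length(shared), max_abs = max(d),
               mean_abs = mean(d), max_se_units = max(in_se))
  })
  do.call(rbind, out)
}

#' Follow-up adequacy report from the trailing dynamic curve
#'
#' Descriptive check of whether the difference and ratio curves have
#' stabilized: reports the relative change of each contrast over the
#' trailing `window` fraction of the grid and flags a plateau when it falls
#' below `threshold`. Also reports the grid horizon nearest to where the
#' ratio crosses 1 (equivalently the difference crosses 0), if it does.
#'
#' @param x a `dynrmst` fit with at least 10 grid points.
#' @param window trailing fraction of the grid (default 0.2).
#' @param threshold relative-change threshold for the plateau flag
#'   (default 0.01, i.e. 1 percent).
#' @return a list of class `followup_report`.
#' @export
follow_up_adequacy <- function(x, window = 0.2, threshold = 0.01) {
  stopifnot(inherits(x, "dynrmst"))
  if (length(x$grid) < 10)
    stop("at least 10 grid points required", call. = FALSE)
  tail_of <- function(kind) {
    v <- curve_rows(x, kind, "mixture")$estimate
    m <- max(2L, ceiling(window * length(v)))
    w <- utils::tail(v, m)
    rel <- if (w[1] != 0) abs(w[length(w)] - w[1]) / abs(w[1]) else
      if (all(w == 0)) 0 else Inf
    list(relative_change = rel, plateau = rel < threshold)
  }
  ratio <- curve_rows(x, "ratio", "mixture")$estimate
  sgn <- sign(ratio - 1)
  cross_idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  crossing <- if (length(cross_idx))
    x$grid[cross_idx[1] + (abs(ratio[cross_idx[1] + 1] - 1) <
                             abs(ratio[cross_idx[1]] - 1))] else NA_real_
  structure(list(difference = tail_of("difference"),
                 ratio = tail_of("ratio"),
                 window = window, threshold = threshold,
                 ratio_crossing_tau = crossing),
            class = "followup_report")
}

#' @export
print.followup_report <- function(x, ...) {
  cat(sprintf("\nFollow-up adequacy (trailing %d%% of grid, threshold %g):\n",
              round(100 * x$window), x$threshold))
  for (kd in c("difference", "ratio"))
    cat(sprintf("  %s: relative change %.4g -> plateau: %s\n", kd,
                x[[kd]]$relative_change,
                ifelse(x[[kd]]$plateau, "yes", "no")))
  if (is.finite(x$ratio_crossing_tau))
    cat(sprintf("  ratio crosses 1 near tau = %g\n", x$ratio_crossing_tau))
  invisible(x)
}
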