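## a small fitted analysis reused across blocks
fit_small <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sc <- trial_scenario("ph", n = 150, seed = 42)
      ds <- simulate_trial(sc)
      val <<- suppressWarnings(
        dynrmst(ds, n_components = 1, seed = 42, n_starts = 3, grid = 40))
    }
    val
  }
})

test_that("formula and dataset interfaces agree", {
  sc <- trial_scenario("ph", n = 80, seed = 9)
  ds <- simulate_trial(sc)
  df <- as.data.frame(ds)
  f1 <- suppressWarnings(dynrmst(ds, n_components = 1, seed = 1,
                                 n_starts = 2, grid = 12))
  f2 <- suppressWarnings(
    dynrmst(survival::Surv(time, event) ~ arm, data = df,
            control = "control", n_components = 1, seed = 1,
            n_starts = 2, grid = 12))
  expect_equal(f1$curve, f2$curve)
  expect_equal(coef(f1), coef(f2))
})

test_that("a single-point grid reproduces the single-tau API bit-identically", {
  fit <- fit_small()
  taud <- fit$default_tau
  one <- suppressWarnings(
    dynrmst(fit$data, n_components = 1, seed = 42, n_starts = 3,
            grid = taud))
  row <- one$curve[one$curve$quantity == "difference" &
                     one$curve$engine == "mixture", ]
  direct <- rmst_contrast(fit$models$control, fit$models$treatment, taud,
                          "difference")
  expect_identical(row$estimate, direct$estimate)
  expect_identical(row$se, direct$se)
  expect_identical(row$p_value, direct$p_value)
  # and the full-grid curve holds the same values at the same tau
  full_row <- fit$curve[fit$curve$quantity == "difference" &
                          fit$curve$engine == "mixture" &
                          fit$curve$tau == taud, ]
  expect_identical(full_row$estimate, direct$estimate)
})

test_that("grid refinement changes nothing at shared horizons", {
  fit <- fit_small()
  taus <- fit$grid[c(10, 20, 40)]
  refined <- suppressWarnings(
    dynrmst(fit$data, n_components = 1, seed = 42, n_starts = 3,
            grid = sort(c(taus, taus - 0.05))))
  for (tt in taus) {
    a <- fit$curve[fit$curve$tau == tt, ]
    b <- refined$curve[refined$curve$tau == tt, ]
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("identical-arm data give flat null contrast curves", {
  set.seed(77)
  t <- rweibull(120, 1.3, 8)
  e <- as.numeric(t < 20)
  t <- pmin(t, 20)
  ds <- surv_dataset(c(t, t), c(e, e), rep(c("a", "b"), each = 120), "a")
  fit <- suppressWarnings(dynrmst(ds, n_components = 1, seed = 5,
                                  n_starts = 3, grid = 15))
  d <- fit$curve[fit$curve$quantity == "difference" &
                   fit$curve$engine == "mixture", ]
  r <- fit$curve[fit$curve$quantity == "ratio" &
                   fit$curve$engine == "mixture", ]
  # arms are fitted independently (different start seeds), so the curves
  # agree to optimizer precision rather than machine precision
  expect_equal(d$estimate, rep(0, nrow(d)), tolerance = 1e-5)
  expect_equal(r$estimate, rep(1, nrow(r)), tolerance = 1e-5)
})

test_that("mixture mu never exceeds tau and KM rows stop at the support boundary", {
  fit <- fit_small()
  mix <- fit$curve[fit$curve$engine == "mixture" &
                     grepl("^rmst_", fit$curve$quantity), ]
  expect_true(all(mix$estimate <= mix$tau + 1e-12))
  for (arm in c("control", "treatment")) {
    kmrows <- fit$curve[fit$curve$engine == "km" &
                          fit$curve$quantity == paste0("rmst_", arm), ]
    expect_true(all(kmrows$tau <= fit$km[[arm]]$max_time))
  }
  kmc <- fit$curve[fit$curve$engine == "km" &
                     fit$curve$quantity == "difference", ]
  expect_true(all(kmc$tau <= fit$km_boundary))
})

test_that("extrapolated grids are clamped with a warning", {
  fit <- fit_small()
  taud <- fit$default_tau
  w <- testthat::capture_warnings(
    wide <- dynrmst(fit$data, n_components = 1, seed = 42, n_starts = 2,
                    grid = c(taud / 2, taud, 1.4 * taud, 3 * taud)))
  expect_true(any(grepl("clamped", w)))
  expect_lte(max(wide$grid), 1.5 * taud)
  expect_error(suppressWarnings(
    dynrmst(fit$data, n_components = 1, seed = 42, n_starts = 2,
            grid = c(2, 1))), "increasing")
})

test_that("delayed-effect truth shows the late-separation sign pattern end to end", {
  sc <- trial_scenario("delayed", n = 2000, seed = 6)
  ds <- simulate_trial(sc)
  fit <- suppressWarnings(dynrmst(ds, n_components = c(1, 2), seed = 6,
                                  n_starts = 5, grid = 25))
  tr <- true_rmst_curve(sc, fit$grid)
  est <- fit$curve[fit$curve$quantity == "difference" &
                     fit$curve$engine == "mixture", "estimate"]
  # early: near zero; late: clearly positive, tracking the truth
  expect_lt(abs(est[1]), 0.15)
  expect_gt(est[length(est)], 1)
  expect_lt(max(abs(est - tr$difference)), 0.5)
})

test_that("km_mixture_agreement summarizes discrepancies and enforces overlap", {
  fit <- fit_small()
  agg <- km_mixture_agreement(fit)
  expect_equal(agg$arm, c("control", "treatment"))
  expect_true(all(agg$max_abs >= agg$mean_abs))
  expect_true(all(agg$n_shared >= 3))
  one <- suppressWarnings(
    dynrmst(fit$data, n_components = 1, seed = 42, n_starts = 2,
            grid = fit$default_tau))
  expect_error(km_mixture_agreement(one), "fewer than 3")
})

test_that("follow-up adequacy flags plateaus and finds ratio crossings", {
  fit <- fit_small()
  rep0 <- follow_up_adequacy(fit)
  expect_type(rep0$difference$relative_change, "double")

  # synthetic curves: constant trailing ratio -> plateau; rising -> none
  fake <- fit
  idx_r <- fake$curve$quantity == "ratio" & fake$curve$engine == "mixture"
  idx_d <- fake$curve$quantity == "difference" & fake$curve$engine == "mixture"
  fake$curve$estimate[idx_r] <- 1.4
  fake$curve$estimate[idx_d] <- seq(1, 1.1, length.out = sum(idx_d))
  rep1 <- follow_up_adequacy(fake)
  expect_true(rep1$ratio$plateau)
  expect_equal(rep1$ratio$relative_change, 0)
  fake$curve$estimate[idx_d] <- seq_len(sum(idx_d))  # strongly increasing
  rep2 <- follow_up_adequacy(fake)
  expect_false(rep2$difference$plateau)

  # crossing preset: reported crossing matches a root-bracketing of the truth
  sc <- trial_scenario("crossing", n = 3000, seed = 8)
  ds <- simulate_trial(sc)
  fitc <- suppressWarnings(dynrmst(ds, n_components = c(1, 2), seed = 8,
                                   n_starts = 5, grid = 50))
  repc <- follow_up_adequacy(fitc)
  tr <- true_rmst_curve(sc, seq(0.5, fitc$default_tau, length.out = 400))
  s <- sign(tr$ratio - 1)
  i <- which(diff(s) != 0)[1]
  true_cross <- tr$tau[i]
  expect_true(is.finite(repc$ratio_crossing_tau))
  expect_lt(abs(repc$ratio_crossing_tau - true_cross), 5)

  few <- suppressWarnings(dynrmst(fit$data, n_components = 1, seed = 42,
                                  n_starts = 2, grid = 5))
  expect_error(follow_up_adequacy(few), "at least 10")
})

test_that("tidy export, residuals, predict and plot methods work", {
  fit <- fit_small()
  path <- withr::local_tempfile(fileext = ".csv")
  export_curve(fit, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(fit$curve))
  expect_named(back, c("tau", "quantity", "engine", "estimate", "se",
                       "ci_low", "ci_high", "p_value"))

  r <- residuals(fit)
  expect_length(r, nrow(fit$data))
  expect_true(all(r >= 0))

  pr <- predict(fit, tau = c(5, 10), kind = "ratio")
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$estimate > 0))

  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path, width = 600, height = 300)
  plot(fit)
  grDevices::dev.off()
  expect_gt(file.info(png_path)$size, 0)

  expect_output(print(summary(fit)), "agreement")
})
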