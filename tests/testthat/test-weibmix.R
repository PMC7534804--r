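test_that("mixture survival matches term-by-term evaluation", {
  m <- weibmix(scale = c(1, 2), shape = c(1, 2), weights = c(0.5, 0.5))
  expect_equal(predict(m, 0, "survival"), 1)
  expect_equal(predict(m, 1, "survival"),
               0.5 * exp(-1) + 0.5 * exp(-0.25))
  e <- weibmix(1, 1)
  expect_equal(predict(e, 1, "survival"), exp(-1))
  expect_error(predict(m, -1, "survival"), "negative")
})

test_that("density and hazard behave like their definitions", {
  e <- weibmix(1, 1)
  tt <- c(0.3, 1, 2.5)
  expect_equal(predict(e, tt, "density"), exp(-tt))
  expect_equal(predict(e, tt, "hazard"), rep(1, 3))
  m <- weibmix(c(1.5, 6), c(0.8, 2.5), c(0.3, 0.7))
  # f integrates to 1
  total <- integrate(function(x) predict(m, x, "density"), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # h(t) = -d/dt log S(t) by central differences
  h <- 1e-5
  for (t0 in c(0.5, 2, 8)) {
    numeric_h <- -(log(predict(m, t0 + h, "survival")) -
                     log(predict(m, t0 - h, "survival"))) / (2 * h)
    expect_equal(predict(m, t0, "hazard"), numeric_h, tolerance = 1e-6)
  }
  expect_error(predict(m, 0, "density"), "shape < 1")
})

test_that("censored log-likelihood matches hand-evaluated terms", {
  e <- weibmix(1, 1)
  expect_equal(weibmix_loglik(e, 1, 1), -1)   # log f(1) = -1
  expect_equal(weibmix_loglik(e, 2, 0), -2)   # log S(2) = -2
  m <- weibmix(c(1, 2), c(1, 2), c(0.5, 0.5))
  t <- c(0.5, 1.5, 2, 3)
  d <- c(1, 0, 1, 0)
  f <- function(x) 0.5 * exp(-x) + 0.5 * (2 / 2) * (x / 2)^1 * exp(-(x / 2)^2)
  S <- function(x) 0.5 * exp(-x) + 0.5 * exp(-(x / 2)^2)
  by_hand <- log(f(0.5)) + log(S(1.5)) + log(f(2)) + log(S(3))
  expect_equal(weibmix_loglik(m, t, d), by_hand, tolerance = 1e-12)
})

test_that("analytic score matches central-difference gradients", {
  set.seed(11)
  t <- rweibull(60, 1.4, 3)
  e <- rbinom(60, 1, 0.7)
  for (J in 1:3) {
    par <- dynrmst:::weibmix_par(
      {w <- rgamma(J, 2) + 0.2; w / sum(w)},
      exp(runif(J, -0.5, 1.5)), exp(runif(J, -0.5, 0.8)))
    g_an <- dynrmst:::mix_ngr(par, J, t, e)
    g_num <- dynrmst:::num_grad(function(p) dynrmst:::mix_nll(p, J, t, e),
                                par, h = rep(1e-6, length(par)))
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
})

test_that("single-component fit recovers simulated Weibull parameters", {
  set.seed(21)
  t <- rweibull(2000, shape = 1.5, scale = 2)
  fit <- weibmix_fit(t, rep(1, 2000), n_components = 1, seed = 1,
                     n_starts = 3)
  expect_lt(abs(fit$scale - 2) / 2, 0.05)
  expect_lt(abs(fit$shape - 1.5) / 1.5, 0.05)
  # independent cross-check: flexsurv ML fit on the same data
  fs <- flexsurv::flexsurvreg(survival::Surv(t, rep(1, 2000)) ~ 1,
                              dist = "weibull")
  expect_equal(fit$scale, unname(fs$res["scale", "est"]), tolerance = 1e-3)
  expect_equal(fit$shape, unname(fs$res["shape", "est"]), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(logLik(fs)), tolerance = 1e-6)
})

test_that("censored exponential data reproduce the closed-form exponential MLE", {
  set.seed(8)
  lat <- rexp(800, 1 / 3)
  cen <- runif(800, 0, 8)
  t <- pmin(lat, cen)
  d <- as.numeric(lat <= cen)
  fit <- weibmix_fit(t, d, n_components = 1, seed = 2, n_starts = 4)
  expect_equal(fit$shape, 1, tolerance = 0.1)      # k near 1
  mle <- sum(t) / sum(d)                           # exponential MLE
  expect_equal(fit$scale, mle, tolerance = 0.05 * mle)
})

test_that("fitting requires events and rejects events at time zero", {
  expect_error(weibmix_fit(c(1, 2, 3), c(0, 0, 0), 1), "at least one event")
  expect_error(weibmix_fit(c(0, 2, 3), c(1, 1, 1), 1), "time 0")
})

test_that("fit is deterministic given a seed and invariant to row order", {
  set.seed(31)
  t <- rweibull(150, 1.2, 4)
  e <- rbinom(150, 1, 0.8)
  f1 <- weibmix_fit(t, e, n_components = 2, seed = 9, n_starts = 4)
  f2 <- weibmix_fit(t, e, n_components = 2, seed = 9, n_starts = 4)
  expect_identical(coef(f1), coef(f2))
  perm <- sample(150)
  f3 <- weibmix_fit(t[perm], e[perm], n_components = 2, seed = 9,
                    n_starts = 4)
  expect_identical(coef(f1), coef(f3))
  expect_identical(f1$logLik, f3$logLik)
})

test_that("optimum dominates every multi-start initial point", {
  set.seed(5)
  t <- rweibull(120, 1.5, 3)
  e <- rbinom(120, 1, 0.8)
  fit <- weibmix_fit(t, e, n_components = 2, seed = 4, n_starts = 5)
  starts <- attr(fit, "starts")
  expect_true(all(fit$logLik >= starts$logLik - 1e-8))
})

test_that("label switching leaves survival, density and likelihood unchanged", {
  m <- weibmix(c(2, 8, 15), c(0.9, 1.8, 3), c(0.2, 0.5, 0.3))
  mp <- weibmix(m$scale[c(3, 1, 2)], m$shape[c(3, 1, 2)],
                m$weights[c(3, 1, 2)])
  tt <- seq(0.1, 30, length.out = 40)
  expect_equal(predict(m, tt, "survival"), predict(mp, tt, "survival"))
  expect_equal(predict(m, tt, "density"), predict(mp, tt, "density"))
  set.seed(2)
  t <- rweibull(40, 1.3, 5)
  d <- rbinom(40, 1, 0.7)
  expect_equal(weibmix_loglik(m, t, d), weibmix_loglik(mp, t, d))
})

test_that("fitted survival is a valid survival function on a dense grid", {
  set.seed(13)
  sc <- trial_scenario("delayed", n = 400, seed = 13)
  ds <- simulate_trial(sc)
  fit <- weibmix_fit(arm_split(ds)$treatment, n_components = 2, seed = 3,
                     n_starts = 5)
  grid <- seq(0, 80, length.out = 400)
  s <- predict(fit, grid, "survival")
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("BIC selection finds the generating component count", {
  set.seed(17)
  # single Weibull
  t1 <- rweibull(1500, 1.4, 5)
  s1 <- select_components(t1, rep(1, 1500), candidates = 1:2,
                          criterion = "BIC", n_starts = 4, seed = 5)
  expect_equal(s1$J, 1)
  # well-separated two-component mixture
  m2 <- weibmix(c(1, 20), c(1, 1), c(0.5, 0.5))
  t2 <- simulate(m2, 1500, seed = 18)
  s2 <- select_components(t2, rep(1, 1500), candidates = 1:2,
                          criterion = "BIC", n_starts = 4, seed = 6)
  expect_equal(s2$J, 2)
  tab <- attr(s2, "selection")
  expect_equal(names(tab)[4], "BIC")
  expect_equal(nrow(tab), 2)
  # single candidate: no selection, just the fit
  s3 <- select_components(t2, rep(1, 1500), candidates = 2,
                          criterion = "BIC", n_starts = 3, seed = 7)
  expect_equal(s3$J, 2)
})

test_that("simulated draws follow the model distribution", {
  e <- weibmix(1, 1)
  x <- simulate(e, 1e5, seed = 1)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))     # 3 MC se of the mean
  m <- weibmix(c(2, 10), c(1.2, 2.5), c(0.4, 0.6))
  n <- 1e4
  x <- simulate(m, n, seed = 2)
  dkw <- sqrt(log(2 / 0.001) / (2 * n))           # 99.9% DKW band
  for (t0 in c(0.5, 2, 5, 12))
    expect_lt(abs(mean(x > t0) - predict(m, t0, "survival")), dkw)
  # reproducibility at n = 1
  expect_identical(simulate(m, 1, seed = 3), simulate(m, 1, seed = 3))
})
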