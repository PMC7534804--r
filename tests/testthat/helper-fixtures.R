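# shared fixtures built in code

toy_dataset <- function() {
  surv_dataset(time = c(1, 2, 1.5, 3), event = c(1, 0, 1, 1),
               arm = c("A", "A", "B", "B"), control = "A")
}

## uncensored exponential-ish arm as a data frame
uncensored_arm <- function(n, scale = 2, shape = 1.2, seed = 1) {
  set.seed(seed)
  data.frame(time = rweibull(n, shape = shape, scale = scale),
             event = rep(1, n))
}

## random valid mixture model (used by property loops)
random_weibmix <- function() {
  J <- sample(1:3, 1)
  w <- rgamma(J, 2) + 0.05
  weibmix(scale = exp(runif(J, log(0.2), log(20))),
          shape = exp(runif(J, log(0.3), log(4))),
          weights = w / sum(w))
}

## quadrature oracle for restricted moments of a mixture survival function
quad_rmst <- function(model, tau, order = 0) {
  f <- if (order == 0) function(x) predict(model, x, "survival")
       else function(x) x * predict(model, x, "survival")
  stats::integrate(f, 0, tau, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 500L)$value
}
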