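# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. seed = NULL means: use the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## row-wise log(sum(exp(m))) for small column counts; guards -Inf rows
row_logsumexp <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  J <- ncol(m)
  mx <- m[, 1L]
  if (J > 1L) for (j in 2:J) mx <- pmax(mx, m[, j])
  mx[!is.finite(mx)] <- 0  # all -Inf row -> log(0) handled below
  s <- exp(m[, 1L] - mx)
  if (J > 1L) for (j in 2:J) s <- s + exp(m[, j] - mx)
  mx + log(s)
}

## central-difference gradient of scalar f at x
num_grad <- function(f, x, h = 1e-5 * pmax(1, abs(x))) {
  vapply(seq_along(x), function(i) {
    e <- x
    e[i] <- x[i] + h[i]; f1 <- f(e)
    e[i] <- x[i] - h[i]; f0 <- f(e)
    (f1 - f0) / (2 * h[i])
  }, numeric(1))
}

## central-difference Jacobian of vector-valued g at x (used for the Hessian
## as the Jacobian of the analytic score); symmetrized by the caller
num_jacobian <- function(g, x, h = 1e-4 * pmax(1, abs(x))) {
  cols <- lapply(seq_along(x), function(i) {
    e <- x
    e[i] <- x[i] + h[i]; g1 <- g(e)
    e[i] <- x[i] - h[i]; g0 <- g(e)
    (g1 - g0) / (2 * h[i])
  })
  do.call(cbind, cols)
}

z_crit <- function(alpha) stats::qnorm(1 - alpha / 2)

## two-sided normal p-value robust to se = 0
two_sided_p <- function(estimate, se, null = 0) {
  z <- ifelse(se > 0, (estimate - null) / se,
              ifelse(estimate == null, 0, Inf))
  2 * stats::pnorm(-abs(z))
}
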