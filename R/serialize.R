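#' Write a fitted mixture Weibull model to JSON
#'
#' Serializes component parameters on the natural scale, weights, the
#' transformed-scale covariance, log-likelihood, counts and fit metadata so
#' a fit can be archived and reloaded losslessly.
#'
#' @param model a [weibmix].
#' @param path output path.
#' @export
weibmix_write <- function(model, path) {
  stopifnot(inherits(model, "weibmix"))
  doc <- list(weights = model$weights, scale = model$scale,
              shape = model$shape,
              vcov = model$vcov, par_names = names(model$par),
              logLik = model$logLik, n = model$n, n_events = model$n_events,
              convergence = model$convergence,
              n_starts = model$n_starts %||% NA_integer_,
              seed = model$seed %||% NA_integer_)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Read a fitted mixture Weibull model from JSON
#'
#' @param path path written by [weibmix_write].
#' @return a [weibmix].
#' @export
weibmix_read <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- weibmix(doc$scale, doc$shape, doc$weights)
  if (!is.null(doc$vcov)) {
    m$vcov <- matrix(as.numeric(doc$vcov), nrow = length(doc$par_names),
                     dimnames = list(doc$par_names, doc$par_names))
  }
  m$logLik <- doc$logLik %||% NA_real_
  m$n <- doc$n %||% NA_integer_
  m$n_events <- doc$n_events %||% NA_integer_
  m$convergence <- doc$convergence %||% NA_integer_
  m$n_starts <- doc$n_starts
  m$seed <- doc$seed
  m
}
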