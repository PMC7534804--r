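#' Construct a validated two-arm survival dataset
#'
#' A `surv_dataset` is a data frame with columns `time` (follow-up time,
#' study time units), `event` (1 = event observed, 0 = right-censored) and
#' `arm` (exactly two labels), carrying a designated control and treatment
#' arm. Zero follow-up times are allowed and enter the likelihood and
#' Kaplan-Meier machinery as-is.
#'
#' @param time nonnegative numeric vector of follow-up times.
#' @param event event indicators, 0/1 (logical accepted and mapped to 1/0).
#' @param arm arm label per subject; exactly two distinct labels.
#' @param control label of the control arm; default: first label in input
#'   order. The other label becomes the treatment arm.
#' @return A data frame of class `surv_dataset` with attributes `control`
#'   and `treatment`.
#' @examples
#' surv_dataset(c(1, 2, 1.5, 3), c(1, 0, 1, 1), c("A", "A", "B", "B"))
#' @export
surv_dataset <- function(time, event, arm, control = NULL) {
  if (is.logical(event)) event <- as.integer(event)
  time <- as.numeric(time)
  event <- as.numeric(event)
  arm <- as.character(arm)
  n <- length(time)
  if (length(event) != n || length(arm) != n)
    stop("time, event and arm must have equal length", call. = FALSE)

  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("invalid follow-up times (must be finite and >= 0) in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop("event indicator must be 0/1; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)

  labels <- unique(arm)
  if (length(labels) != 2)
    stop("exactly two arm labels required, found ", length(labels), ": ",
         paste(utils::head(labels, 5), collapse = ", "), call. = FALSE)
  control <- as.character(control %||% labels[1])
  if (!control %in% labels)
    stop("control label '", control, "' not present in arm column", call. = FALSE)
  treatment <- setdiff(labels, control)

  for (lab in labels) {
    idx <- arm == lab
    if (sum(idx) < 2)
      stop("arm '", lab, "' has fewer than 2 subjects", call. = FALSE)
    if (sum(event[idx]) < 1)
      stop("arm '", lab, "' has zero observed events", call. = FALSE)
  }

  out <- data.frame(time = time, event = event, arm = arm,
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  attr(out, "treatment") <- treatment
  class(out) <- c("surv_dataset", "data.frame")
  out
}

#' Read a two-arm survival dataset from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param time_col,event_col,arm_col column names (defaults `"time"`,
#'   `"event"`, `"arm"`).
#' @param control control-arm label; default: first label in file order.
#' @param delim field delimiter, default comma.
#' @return A [surv_dataset] with records in file order.
#' @export
read_surv_data <- function(path, time_col = "time", event_col = "event",
                           arm_col = "arm", control = NULL, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(time_col, event_col, arm_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  ev <- df[[event_col]]
  if (is.character(ev)) ev <- as.logical(toupper(ev))  # TRUE/FALSE text
  surv_dataset(df[[time_col]], ev, df[[arm_col]], control = control)
}

#' Write a survival dataset as delimited text
#'
#' Emits the same `time,event,arm` schema [read_surv_data] consumes, so a
#' write/read round trip reproduces the records.
#'
#' @param ds a [surv_dataset].
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_surv_data <- function(ds, path, delim = ",") {
  stopifnot(inherits(ds, "surv_dataset"))
  utils::write.table(as.data.frame(ds)[c("time", "event", "arm")], path,
                     sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a two-arm dataset into control and treatment subsets
#'
#' @param ds a [surv_dataset].
#' @return list with elements `control` and `treatment`, each a data frame
#'   of `time`, `event` for one arm (attribute `arm` holds the label).
#' @export
arm_split <- function(ds) {
  stopifnot(inherits(ds, "surv_dataset"))
  one <- function(lab) {
    sub <- as.data.frame(ds)[ds$arm == lab, c("time", "event")]
    rownames(sub) <- NULL
    attr(sub, "arm") <- lab
    sub
  }
  list(control = one(attr(ds, "control")),
       treatment = one(attr(ds, "treatment")))
}

#' Largest observed follow-up time
#'
#' The largest observed time includes censored times, matching the
#' convention under which the default horizon is taken as the minimum of
#' the two per-arm maxima.
#'
#' @param ds a [surv_dataset].
#' @param per_arm if `TRUE`, return the named pair (control, treatment).
#' @return a single maximum, or a named length-2 vector.
#' @export
max_observed_time <- function(ds, per_arm = FALSE) {
  stopifnot(inherits(ds, "surv_dataset"))
  if (!per_arm) return(max(ds$time))
  s <- arm_split(ds)
  c(control = max(s$control$time), treatment = max(s$treatment$time))
}

#' Default RMST horizon: minimum of the per-arm largest observed times
#'
#' @param ds a [surv_dataset].
#' @return the default restriction time tau.
#' @export
default_tau <- function(ds) min(max_observed_time(ds, per_arm = TRUE))

#' @export
print.surv_dataset <- function(x, ...) {
  s <- arm_split(x)
  cat("Two-arm survival dataset: n =", nrow(x), "\n")
  cat(sprintf("  control   '%s': n = %d, events = %d, max time = %g\n",
              attr(x, "control"), nrow(s$control), sum(s$control$event),
              max(s$control$time)))
  cat(sprintf("  treatment '%s': n = %d, events = %d, max time = %g\n",
              attr(x, "treatment"), nrow(s$treatment), sum(s$treatment$event),
              max(s$treatment$time)))
  cat(sprintf("  default horizon tau = %g\n", default_tau(x)))
  invisible(x)
}
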