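#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm rpois runif sd var median quantile pf pt pchisq qnorm
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Classed conditions so callers can distinguish failure modes.
rqStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "rq_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stopInvalidConfig   <- function(msg) rqStop("rq_invalid_configuration", msg)
stopGeometry        <- function(msg) rqStop("rq_geometry_error", msg)
stopValidation      <- function(msg) rqStop("rq_validation_error", msg)
stopInsufficientLandmarks <- function(msg) rqStop("rq_insufficient_landmarks", msg)
stopInsufficientData <- function(msg) rqStop("rq_insufficient_data", msg)
stopDegenerateInput <- function(msg) rqStop("rq_degenerate_input", msg)
stopFormat          <- function(msg) rqStop("rq_format_error", msg)

# 2D rotation matrix, angle in degrees.
rotationMatrix2 <- function(degrees) {
  th <- degrees * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stopValidation("axis vector has zero length")
  v / n
}

# Unit normal to a 2D unit axis (90 deg counter-clockwise in x-right/y-down
# image coordinates).
normalVector <- function(axis) c(-axis[2L], axis[1L])

`%||%` <- function(a, b) if (is.null(a)) b else a
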