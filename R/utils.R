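# Internal helpers shared across modules.

#' Sensor positions
#'
#' The six body sites instrumented on the infant doll: cranial apex, navel,
#' both wrists and both shins. One model is fitted per position.
#'
#' @return Character vector of the six position names.
#' @export
sensor_positions <- function() {
  c("head", "chest", "left_arm", "right_arm", "left_leg", "right_leg")
}

assert_position <- function(position) {
  if (!is.character(position) || length(position) != 1L ||
      !position %in% sensor_positions()) {
    stop("`position` must be one of: ",
         paste(sensor_positions(), collapse = ", "), call. = FALSE)
  }
  position
}

# Round half away from zero, matching the reporting convention of printed
# metric tables (0.975 -> 0.98, unlike base round()'s banker's rounding).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-recording seed derived from a session seed. Kept within
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k)) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
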