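# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483646L) + 1L
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
species_levels <- function() c("YS", "BS")

biometric_names <- function() {
  c("bill_depth_base", "bill_depth_nostril", "bill_length",
    "head_length", "tarsus_length", "wing_length")
}

isotope_names <- function() {
  c("d15N_P1", "d13C_P1", "d15N_R6", "d13C_R6")
}
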