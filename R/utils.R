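#' Round half away from zero
#'
#' Report-style rounding: exact halves move away from zero, unlike base
#' [round()] which rounds half to even. Used for all printed/exported
#' tables; internal computation always keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.125, -0.125, 2.5), c(2, 2, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# significance code bands used in reported tables (figure convention:
# "+" marks p < 0.1)
sig_codes <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "+",
    TRUE ~ ""
  )
}

# deterministic sub-stream seed: keeps strata independent so that e.g.
# adding genotypes does not reshuffle the noise of existing ones
substream_seed <- function(seed, offset) {
  (as.integer(seed %% 10000019L) * 101L + as.integer(offset)) %% 2147483629L
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", what), class = "sfsi_config_error")
  }
}
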