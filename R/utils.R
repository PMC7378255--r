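#' @importFrom rlang .data %||%
#' @keywords internal
"_PACKAGE"

# deterministic seed derivation for sub-streams, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}
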