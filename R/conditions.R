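#' @title Classed error conditions
#' @description Internal helpers raising classed conditions so callers can
#'   distinguish failure modes (`tryCatch(..., spx_range_error = ...)`).
#'   Every condition also carries the class `spx_error`.
#' @name spectroxy-conditions
#' @keywords internal
NULL

spxStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "spx_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# condition classes used across the package:
#   spx_file_error        missing / unreadable file
#   spx_parse_error       malformed rows or header
#   spx_order_error       non-increasing wavelength or time axis
#   spx_coverage_error    grid does not cover the required window
#   spx_range_error       extrapolation / out-of-span request
#   spx_alignment_error   spectra share no usable common grid
#   spx_domain_error      numeric domain violation (e.g. log of <= 0)
#   spx_normalization_error  all-zero spectrum
#   spx_validation_error  object invariant violated
#   spx_parameter_error   bad argument value
#   spx_phase_error       split time leaves an empty phase
#   spx_profile_error     too few step-down levels
#   spx_undefined_saturation_error  both haemoglobin amplitudes zero
#   spx_infeasible_error  simulated truth absorbance exceeds the lamp
#   spx_config_error      run configuration invalid
#   spx_io_error          unwritable output path
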