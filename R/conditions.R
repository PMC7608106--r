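# Typed conditions so the command-line layer can map error families to
# distinct exit codes (validation -> 1, design failure / insufficient
# overlap -> 2).

fmStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

fmValidationError <- function(msg, ...) fmStop("fm_validation_error", msg, ...)
fmParseError      <- function(msg, ...) fmStop("fm_parse_error", msg, ...)
fmLookupError     <- function(msg, ...) fmStop("fm_lookup_error", msg, ...)
fmDesignError     <- function(msg, ...) fmStop("fm_design_error", msg, ...)
fmOverlapError    <- function(msg, ...) fmStop("fm_overlap_error", msg, ...)
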