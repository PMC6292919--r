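# Classed conditions so callers (and the CLI) can map error classes to exit
# codes instead of string-matching messages.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_validation_error", ...)
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_parse_error", ...)
}

abort_lookup <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_lookup_error", ...)
}

abort_limit <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_limit_error", ...)
}

abort_consistency <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_consistency_error", ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "pathmapr_io_error", ...)
}

warn_pathmapr <- function(msg, class = "pathmapr_warning", ...) {
  rlang::warn(msg, class = class, ...)
}
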