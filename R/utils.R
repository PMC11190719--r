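ril_error <- function(class, message) {
  structure(class = c(class, "ril_error", "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
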