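# Classed error conditions used across the package. Every user-facing
# failure mode carries a condition class so callers (and tests) can
# distinguish format problems from validation or degenerate-input problems.

abort_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ctcprofiler_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

format_error          <- function(msg, ...) abort_with("format_error", msg, ...)
validation_error      <- function(msg, ...) abort_with("validation_error", msg, ...)
io_error              <- function(msg, ...) abort_with("io_error", msg, ...)
missing_genes_error   <- function(msg, ...) abort_with("missing_genes_error", msg, ...)
degenerate_input_error <- function(msg, ...) abort_with("degenerate_input_error", msg, ...)
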