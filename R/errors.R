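# Structured error conditions used across the pipeline. Every stage failure
# carries a condition class so callers (and the CLI) can react per stage.

iop_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "iop_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @export
print.iop_error <- function(x, ...) {
  cat("<", class(x)[1], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}
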