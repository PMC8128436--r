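# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries class c("az_<what>", "az_error", "error", "condition").

az_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "az_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

az_check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    az_stop("az_invalid_alphabet",
            "%s contains non-nucleotide characters (first offender: %s)",
            what, x[bad][1])
  }
  invisible(x)
}
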