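# Classed error conditions so callers and tests can discriminate failure
# modes (UnknownResidue, ParseError, ...) from generic errors.

abort_class <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = call)))
}
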