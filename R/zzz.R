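.latentmol_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  # OpenBabel writes parse diagnostics straight to stderr; generation-mode
  # decoding validity-checks thousands of deliberately malformed strings, so
  # route the toolkit's log into a discarded stream. The stream object is
  # kept alive for the session in the package environment.
  sink_stream <- try(ChemmineOB:::ostreamToString(), silent = TRUE)
  if (!inherits(sink_stream, "try-error")) {
    handler <- try(ChemmineOB:::obErrorLog_get(), silent = TRUE)
    if (!inherits(handler, "try-error")) {
      try(ChemmineOB:::OBMessageHandler_SetOutputStream(handler, sink_stream),
          silent = TRUE)
      .latentmol_env$ob_log_sink <- sink_stream
    }
  }
  invisible()
}
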