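.onLoad <- function(libname, pkgname) {
  registerDemoServices()
  # last-resort hygiene: shut down any still-open worker endpoints when this
  # namespace is garbage collected or R exits; the workers' own linger rule
  # covers abnormal client death.
  reg.finalizer(.endpointTracker, function(e) {
    tryCatch(shutdownAllEndpoints(grace = 2), error = function(err) NULL)
  }, onexit = TRUE)
  invisible(NULL)
}

.onUnload <- function(libpath) {
  tryCatch(closeAllServices(grace = 2), error = function(e) NULL)
  tryCatch(shutdownAllEndpoints(grace = 2), error = function(e) NULL)
  invisible(NULL)
}
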