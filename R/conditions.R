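# Condition classes used throughout the package. Every error raised by
# proxysim carries "proxysimError" plus one specific subclass so callers can
# handle categories with tryCatch()/expect_error(class = ...).

pxCondition <- function(class, message, call = NULL, ...) {
  structure(
    class = c(class, "proxysimError", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

#' @noRd
stopLifecycleOrder <- function(op, status) {
  stop(pxCondition(
    "proxysimLifecycleError",
    sprintf("lifecycle-order error: %s() is not legal in status %s", op, status),
    op = op, status = status
  ))
}

stopContract <- function(missing, what = "implementation") {
  stop(pxCondition(
    "proxysimContractError",
    sprintf("%s does not conform to the service lifecycle contract: missing hook(s) %s",
            what, paste(missing, collapse = ", ")),
    missing = missing
  ))
}

stopSerialization <- function(where, detail) {
  stop(pxCondition(
    "proxysimSerializationError",
    sprintf("value at %s cannot be serialized: %s", where, detail),
    where = where
  ))
}

stopTransport <- function(message, ...) {
  stop(pxCondition("proxysimTransportError", message, ...))
}

stopTimeout <- function(message, ...) {
  stop(pxCondition(c("proxysimTimeoutError", "proxysimTransportError"), message, ...))
}

stopUnknownMember <- function(name) {
  stop(pxCondition(
    "proxysimUnknownMemberError",
    sprintf("unknown member '%s': not in the service manifest or service-function table", name),
    member = name
  ))
}

stopCollision <- function(name, with) {
  stop(pxCondition(
    "proxysimCollisionError",
    sprintf("service-function name '%s' collides with %s", name, with),
    member = name
  ))
}

stopRegistration <- function(message, ...) {
  stop(pxCondition("proxysimRegistrationError", message, ...))
}

stopLookup <- function(name, known) {
  stop(pxCondition(
    "proxysimLookupError",
    sprintf("no service implementation registered under '%s' (known: %s)",
            name, if (length(known)) paste(known, collapse = ", ") else "<none>"),
    name = name
  ))
}

stopSpawn <- function(message, ...) {
  stop(pxCondition("proxysimSpawnError", message, ...))
}

# Re-raise a remote ERROR response client-side. The remote category string is
# prepended to the condition class so handlers written for local conditions
# (e.g. "proxysimLifecycleError") also catch the remote flavour; the original
# condition object is never reconstructed.
stopRemote <- function(category, message, remoteTrace = NULL) {
  cls <- unique(c(category, "proxysimRemoteError"))
  stop(pxCondition(
    cls,
    sprintf("remote error [%s]: %s", category[[1L]], message),
    remoteCategory = category, remoteMessage = message, remoteTrace = remoteTrace
  ))
}
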