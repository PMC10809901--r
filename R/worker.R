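# Worker side of the broker: process entry point and the message-dispatch
# loop. One worker hosts exactly one interface-implementation instance in its
# own address space. Besides the bootstrap connection from the spawning
# client, the worker listens on its own socket so that deserialized proxy
# handles (possibly in other processes) can attach to the same instance.
# Requests are served one at a time, in arrival order across connections: the
# protocol is synchronous per endpoint, and the instance is never entered
# concurrently.

# entry point executed by `Rscript -e 'proxysim:::workerMain(host, port, key)'`
workerMain <- function(host, port, key) {
  con <- socketConnection(host, port = port, blocking = TRUE, open = "a+b",
                          timeout = 60)
  writeFrame(con, encodeFrame(list(version = WIRE_VERSION, key = key,
                                   pid = Sys.getpid())))
  setup <- readFrame(con)
  if (is.null(setup) || !identical(setup$version, WIRE_VERSION)) {
    close(con)
    return(invisible(1L))
  }

  svc <- NULL
  built <- captureRemoteError({
    impl <- unserialize(setup$impl)
    localService(impl, as.list(setup$args))
  })
  if (!built$ok) {
    writeFrame(con, encodeFrame(list(ok = FALSE, error = built$error)))
    close(con)
    return(invisible(1L))
  }
  svc <- built$value

  listen <- withPrivateRNG(openListenSocket())
  writeFrame(con, encodeFrame(list(ok = TRUE, port = listen$port,
                                   pid = Sys.getpid())))

  serveLoop(svc, firstConnection = con, listenSocket = listen$socket,
            key = key, linger = setup$linger %||% 5)
  invisible(0L)
}

# run expr, returning list(ok, value) or list(ok=FALSE, error=descriptor)
# with the remote stack captured at the raise point.
captureRemoteError <- function(expr) {
  calls <- NULL
  tryCatch(
    list(ok = TRUE,
         value = withCallingHandlers(expr,
           error = function(e) calls <<- utils::head(sys.calls(), -2L))),
    error = function(e) list(ok = FALSE, error = errorDescriptor(e, calls))
  )
}

#' Serve the message-dispatch loop for a constructed instance
#'
#' Reads `RequestMessage`s from all live client connections and answers each
#' with exactly one `ResponseMessage`: lifecycle requests go through the state
#' machine, method/property requests through the instance's public members or
#' the service-function table, `MANIFEST` returns the live interface,
#' `REGISTER_FUNCTION` updates the service-function table, and `SHUTDOWN`
#' stops the loop after acknowledging. A failing dispatch target produces an
#' `ERROR` response; the loop itself survives any bad request. The loop exits
#' on `SHUTDOWN` or when no client connection remains and none arrives within
#' the linger window.
#'
#' This function runs inside worker processes; it is exported for services
#' that host nested services and for documentation of the dispatch contract.
#'
#' @param service The hosted `SimService` instance.
#' @param firstConnection Already-open client connection (from spawn).
#' @param listenSocket Server socket accepting reattachment connections.
#' @param key Shared secret new connections must present.
#' @param linger Seconds to keep serving with zero client connections before
#'   exiting.
#' @return Invisibly, `NULL` after the loop ends.
#' @keywords internal
#' @export
serveLoop <- function(service, firstConnection, listenSocket, key, linger = 5) {
  conns <- list(firstConnection)
  on.exit({
    for (cn in conns) tryCatch(close(cn), error = function(e) NULL)
    tryCatch(close(listenSocket), error = function(e) NULL)
    # nested services created by this worker die with it
    tryCatch(closeAllServices(grace = 2), error = function(e) NULL)
  })

  repeat {
    watch <- c(conns, list(listenSocket))
    ready <- socketSelect(watch, timeout = if (length(conns)) NULL else linger)
    if (!any(ready)) {
      if (!length(conns)) return(invisible(NULL))  # lingered out, no clients
      next
    }

    if (ready[[length(watch)]]) {  # pending attach on the listen socket
      newCon <- tryCatch(
        socketAccept(listenSocket, blocking = TRUE, open = "a+b", timeout = 10),
        error = function(e) NULL)
      if (!is.null(newCon)) {
        hello <- tryCatch(readFrame(newCon), error = function(e) NULL)
        if (!is.null(hello) && identical(hello$key, key) &&
            identical(hello$version, WIRE_VERSION)) {
          writeFrame(newCon, encodeFrame(list(ok = TRUE, pid = Sys.getpid())))
          conns[[length(conns) + 1L]] <- newCon
        } else {
          tryCatch(writeFrame(newCon, encodeFrame(list(ok = FALSE))),
                   error = function(e) NULL)
          tryCatch(close(newCon), error = function(e) NULL)
        }
      }
    }

    drop <- integer(0)
    for (i in seq_along(conns)) {
      if (!ready[[i]]) next
      cn <- conns[[i]]
      msg <- tryCatch(readFrame(cn), error = function(e) NULL)
      if (is.null(msg)) {            # client went away
        tryCatch(close(cn), error = function(e) NULL)
        drop <- c(drop, i)
        next
      }
      resp <- dispatchRequest(service, msg)
      sent <- tryCatch({
        writeFrame(cn, encodeFrame(resp, "response payload"))
        TRUE
      }, error = function(e) {
        # unserializable return value: report it instead of dying silently
        errResp <- responseMessage(msg$id, "ERROR", error = list(
          category = c("proxysimSerializationError", "proxysimError"),
          message = conditionMessage(e), trace = NULL))
        tryCatch({ writeFrame(cn, encodeFrame(errResp)); TRUE },
                 error = function(e2) FALSE)
      })
      if (!sent) {
        tryCatch(close(cn), error = function(e) NULL)
        drop <- c(drop, i)
        next
      }
      if (identical(msg$kind, "SHUTDOWN")) return(invisible(NULL))
    }
    if (length(drop)) conns <- conns[-drop]
  }
}

# one request -> one response
dispatchRequest <- function(service, msg) {
  bad <- function(message) {
    responseMessage(msg$id %||% NA_integer_, "ERROR", error = list(
      category = c("proxysimProtocolError", "proxysimError"),
      message = message, trace = NULL))
  }
  if (!identical(msg$version, WIRE_VERSION)) {
    return(bad(sprintf("wire format version mismatch (peer v%s, worker v%d)",
                       format(msg$version), WIRE_VERSION)))
  }
  if (!is.character(msg$kind) || !(msg$kind %in% REQUEST_KINDS)) {
    return(bad(sprintf("unknown request kind '%s'", format(msg$kind))))
  }

  if (msg$kind == "SHUTDOWN") return(responseMessage(msg$id, "OK"))

  res <- captureRemoteError(switch(
    msg$kind,
    LIFECYCLE = dispatchLifecycle(service, msg$target),
    METHOD = callMemberInternal(service, msg$target, as.list(msg$payload), "METHOD"),
    PROPERTY_GET = callMemberInternal(service, msg$target, kind = "PROPERTY_GET"),
    PROPERTY_SET = callMemberInternal(service, msg$target, list(msg$payload),
                                      "PROPERTY_SET"),
    MANIFEST = liveManifest(service),
    REGISTER_FUNCTION = {
      rec <- registerServiceFunction(service, msg$payload$fn, msg$target)
      rec$exposedName
    }
  ))
  if (res$ok) {
    responseMessage(msg$id, "OK", payload = res$value)
  } else {
    responseMessage(msg$id, "ERROR", error = res$error)
  }
}

dispatchLifecycle <- function(service, target) {
  switch(target,
    run = serviceRun(service),
    init = serviceInit(service),
    start = serviceStart(service),
    step = serviceStep(service),
    finish = serviceFinish(service),
    status = serviceStatus(service),
    metrics = serviceMetrics(service),
    stopUnknownMember(target)
  )
}
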