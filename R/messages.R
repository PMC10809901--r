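# Wire contract between client endpoints and workers.
#
# Every message is one length-prefixed frame: a 4-byte big-endian payload
# length followed by the payload, an R serialization of a plain list. Frames
# are written atomically from a pre-serialized raw vector, so a value that
# fails to serialize can never corrupt the stream. The contract is
# synchronous: one outstanding request per endpoint, each request answered by
# exactly one response echoing its id.

WIRE_VERSION <- 1L

REQUEST_KINDS <- c("LIFECYCLE", "METHOD", "PROPERTY_GET", "PROPERTY_SET",
                   "REGISTER_FUNCTION", "MANIFEST", "SHUTDOWN")

requestMessage <- function(id, kind, target = "", payload = NULL) {
  stopifnot(kind %in% REQUEST_KINDS)
  list(version = WIRE_VERSION, id = as.integer(id), kind = kind,
       target = target, payload = payload)
}

responseMessage <- function(id, outcome, payload = NULL, error = NULL) {
  stopifnot(outcome %in% c("OK", "ERROR"))
  # ERROR responses never carry a return value
  if (outcome == "ERROR") payload <- NULL
  list(version = WIRE_VERSION, id = as.integer(id), outcome = outcome,
       payload = payload, error = error)
}

# error descriptor shipped inside an ERROR response: category (condition class
# vector), message, and the remote stack rendered as text.
errorDescriptor <- function(cond, calls = NULL) {
  trace <- NULL
  if (!is.null(calls)) {
    trace <- paste(vapply(calls, function(cl) {
      paste(deparse(cl, nlines = 1L), collapse = "")
    }, character(1)), collapse = "\n")
  }
  list(category = class(cond), message = conditionMessage(cond), trace = trace)
}

# serialize a message to a raw frame; serialization failures surface as
# proxysimSerializationError naming `where`.
encodeFrame <- function(msg, where = "message") {
  tryCatch(
    serialize(msg, NULL, xdr = TRUE),
    error = function(e) stopSerialization(where, conditionMessage(e))
  )
}

writeFrame <- function(con, frame) {
  # header and payload go out in a single write: two small segments per
  # message interact badly with Nagle/delayed-ACK and cost ~80ms a round trip
  header <- writeBin(length(frame), raw(), size = 4L, endian = "big")
  writeBin(c(header, frame), con)
  flush(con)
  invisible(NULL)
}

# blocking read of one frame; returns NULL on orderly EOF.
readFrame <- function(con) {
  len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(len) == 0L) return(NULL)
  if (is.na(len) || len < 0L) stopTransport("corrupt frame header")
  buf <- raw(0)
  while (length(buf) < len) {
    chunk <- readBin(con, "raw", n = len - length(buf))
    if (length(chunk) == 0L) return(NULL)  # peer died mid-frame
    buf <- c(buf, chunk)
  }
  unserialize(buf)
}

checkWireVersion <- function(msg) {
  if (!identical(msg$version, WIRE_VERSION)) {
    stopTransport(sprintf(
      "wire format version mismatch: peer speaks v%s, this build speaks v%d",
      format(msg$version), WIRE_VERSION))
  }
  invisible(msg)
}

# reason a value cannot cross a process boundary, or NULL. Connections and
# external pointers pass serialize() byte-wise but are meaningless in another
# address space, so they are rejected as non-exportable up front.
nonExportableReason <- function(x, depth = 0L) {
  if (depth > 8L) return(NULL)
  if (inherits(x, "connection")) return("is a connection")
  if (typeof(x) == "externalptr") return("is an external pointer")
  if (is.list(x)) {
    for (el in x) {
      r <- nonExportableReason(el, depth + 1L)
      if (!is.null(r)) return(paste("contains a value that", r))
    }
  }
  attrs <- attributes(x)
  if (!is.null(attrs) && depth <= 8L) {
    for (a in attrs[setdiff(names(attrs), c("names", "class", "dim", "dimnames"))]) {
      r <- nonExportableReason(a, depth + 1L)
      if (!is.null(r)) return(paste("has an attribute that", r))
    }
  }
  NULL
}

# verify each element of an argument bundle serializes and is exportable,
# reporting the position of the first offender; runs client-side before any
# worker is involved.
checkSerializable <- function(args, what = "argument") {
  nms <- names(args)
  for (i in seq_along(args)) {
    label <- if (!is.null(nms) && nzchar(nms[[i]])) {
      sprintf("%s '%s'", what, nms[[i]])
    } else {
      sprintf("%s %d", what, i)
    }
    reason <- nonExportableReason(args[[i]])
    if (!is.null(reason)) stopSerialization(label, reason)
    tryCatch(serialize(args[[i]], NULL),
             error = function(e) stopSerialization(label, conditionMessage(e)))
  }
  invisible(args)
}
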