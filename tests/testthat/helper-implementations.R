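# Implementation fixtures and small drivers shared across the suite. Each
# fixture is built inside a function so its closures carry a small local
# environment when serialized to a worker.

`%||%` <- function(a, b) if (is.null(a)) b else a

# hooks count their own invocations; `tally` counts member dispatches
countingImplementation <- function() {
  serviceImplementation(
    "Counting",
    constructor = function(self) {
      self$hookCalls <- c(run = 0, init = 0, start = 0, step = 0, finish = 0)
      self$dispatches <- 0L
    },
    run = function(self) self$hookCalls[["run"]] <- self$hookCalls[["run"]] + 1,
    init = function(self) self$hookCalls[["init"]] <- self$hookCalls[["init"]] + 1,
    start = function(self) self$hookCalls[["start"]] <- self$hookCalls[["start"]] + 1,
    step = function(self) {
      self$hookCalls[["step"]] <- self$hookCalls[["step"]] + 1
      TRUE
    },
    finish = function(self) self$hookCalls[["finish"]] <- self$hookCalls[["finish"]] + 1,
    methods = list(
      hook_calls = function(self) self$hookCalls,
      tally = function(self) {
        self$dispatches <- self$dispatches + 1L
        self$dispatches
      }
    )
  )
}

# pure instance-state simulator: v advances by `inc` per step; used where a
# local twin must coexist with other instances in one process
accumulatorImplementation <- function() {
  serviceImplementation(
    "Accumulator",
    constructor = function(self, v0 = 0, inc = 1) {
      self$v <- v0
      self$inc <- inc
    },
    run = function(self) NULL,
    init = function(self) NULL,
    start = function(self) NULL,
    step = function(self) {
      self$v <- self$v + self$inc
      TRUE
    },
    finish = function(self) NULL,
    methods = list(
      get_value = function(self) self$v,
      set_value = function(self, v) {
        self$v <- v
        invisible(NULL)
      },
      add = function(self, x, scale = 1) {
        self$v <- self$v + x * scale
        self$v
      }
    )
  )
}

# a chosen lifecycle hook raises
failingImplementation <- function(failIn, msg = "deliberate hook failure") {
  mk <- function(op) {
    force(op)
    function(self) {
      if (identical(op, failIn)) stop(msg)
      if (identical(op, "step")) TRUE else NULL
    }
  }
  serviceImplementation(
    paste0("FailIn_", failIn),
    run = mk("run"), init = mk("init"), start = mk("start"),
    step = mk("step"), finish = mk("finish"),
    methods = list(
      boom = function(self, msg2) stop(msg2),
      ok = function(self) "still here"
    )
  )
}

# step hook blocks long enough to look hung
blockingStepImplementation <- function() {
  serviceImplementation(
    "BlockingStep",
    run = function(self) NULL, init = function(self) NULL,
    start = function(self) NULL,
    step = function(self) {
      Sys.sleep(120)
      TRUE
    },
    finish = function(self) NULL
  )
}

# constructor fails on demand
pickyConstructorImplementation <- function() {
  serviceImplementation(
    "PickyConstructor",
    constructor = function(self, mode = "ok") {
      if (identical(mode, "explode")) stop("constructor exploded on purpose")
      self$mode <- mode
    },
    run = function(self) NULL, init = function(self) NULL,
    start = function(self) NULL, step = function(self) TRUE,
    finish = function(self) NULL,
    methods = list(get_mode = function(self) self$mode)
  )
}

minimalImplementation <- function() {
  serviceImplementation(
    "Minimal",
    run = function(self) NULL, init = function(self) NULL,
    start = function(self) NULL, step = function(self) TRUE,
    finish = function(self) NULL
  )
}

# independent oracle for the walker: direct re-execution of the update rule
# outside all service machinery, one seeded sign draw per step
oracleWalk <- function(n, start = 0, step_size = 1, seed = 12345L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pos <- start
  for (i in seq_len(n)) pos <- pos + sample(c(-1, 1), 1L) * step_size
  pos
}

# drive a service or proxy to STARTED
driveToStarted <- function(svc) {
  serviceRun(svc)
  serviceInit(svc)
  serviceStart(svc)
  svc
}

workerPid <- function(proxy) proxy[["handle"]]$pid

expectProcessGone <- function(pid, timeout = 10) {
  deadline <- Sys.time() + timeout
  while (Sys.time() < deadline && proxysim::processAlive(pid)) Sys.sleep(0.1)
  expect_false(proxysim::processAlive(pid))
}

# fixtures used by name through the registry (client-side only: workers get
# the implementation shipped serialized, not looked up)
if (!"Accum" %in% registeredServices()) {
  registerService("Accum", accumulatorImplementation())
}
if (!"Counting" %in% registeredServices()) {
  registerService("Counting", countingImplementation())
}
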