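# interface discovery, proxy transparency, signature fidelity, and proxy
# serialization semantics.

test_that("discovery finds exactly the public extra members, with faithful signatures", {
  m <- discoverInterface(randomWalkerImplementation())
  expect_setequal(manifestNames(m), c("get_pos", "set_pos", "enable_jump"))
  # private (.jump) and lifecycle hooks are absent
  expect_false(".jump" %in% manifestNames(m))
  expect_false(any(lifecycleNames() %in% manifestNames(m)))
  rec <- manifestRecord(m, "set_pos", "METHOD")
  expect_identical(rec$parameterNames, "pos")  # self receiver excluded
  # properties surface as read and write records under one name
  mr <- discoverInterface(fineRelaxerImplementation())
  expect_false(is.null(manifestRecord(mr, "target", "PROPERTY_READ")))
  expect_false(is.null(manifestRecord(mr, "target", "PROPERTY_WRITE")))
  # an implementation adding nothing beyond the base interface
  expect_length(manifestNames(discoverInterface(minimalImplementation())), 0)
})

test_that("a non-conforming implementation is rejected naming its missing hooks", {
  broken <- serviceImplementation("Broken", run = function(self) NULL,
                                  init = function(self) NULL,
                                  start = function(self) NULL,
                                  finish = function(self) NULL)  # no step
  err <- expect_error(discoverInterface(broken), class = "proxysimContractError")
  expect_match(conditionMessage(err), "step")
})

test_that("member names may not shadow the uniform lifecycle interface", {
  expect_error(
    serviceImplementation("Shadow", step = function(self) TRUE,
                          methods = list(status = function(self) 1)),
    class = "proxysimNameError"
  )
})

test_that("proxy calls behave exactly like calls on a local twin instance", {
  px <- createService("Accum", v0 = 10, inc = 2)
  on.exit(closeService(px))
  twin <- localService(accumulatorImplementation(), list(v0 = 10, inc = 2))
  driveToStarted(px)
  driveToStarted(twin)
  # property test over generated call sequences, fixed seed
  set.seed(4242)
  ops <- c("step", "get", "set", "add")
  for (rep in 1:6) {
    for (op in sample(ops, 25, replace = TRUE)) {
      switch(op,
        step = expect_identical(serviceStep(px), serviceStep(twin)),
        get = expect_identical(px$get_value(), callMember(twin, "get_value")),
        set = {
          v <- round(stats::runif(1), 3)
          px$set_value(v)
          callMember(twin, "set_value", v)
        },
        add = {
          x <- sample(-5:5, 1)
          expect_identical(px$add(x, scale = 2), callMember(twin, "add", x, scale = 2))
        })
    }
    expect_identical(px$get_value(), callMember(twin, "get_value"))
  }
})

test_that("proxy get/set are coherent and stepping continues the same seeded stream", {
  w <- randomWalkerService(seed = 5L)
  on.exit(closeService(w))
  driveToStarted(w)
  w$set_pos(5.0)
  expect_identical(w$get_pos(), 5.0)
  for (i in 1:40) serviceStep(w)
  # displacement from the overwritten position replays the seeded sign stream
  expect_identical(w$get_pos() - 5.0, oracleWalk(40L, seed = 5L))
})

test_that("wrong arity fails client-side like on the real member", {
  px <- createService("Accum", v0 = 0)
  on.exit(closeService(px))
  twin <- localService(accumulatorImplementation(), list(v0 = 0))
  viaProxy <- tryCatch(px$add(1, 2, 3), error = function(e) class(e)[[1L]])
  viaTwin <- tryCatch(callMember(twin, "add", 1, 2, 3), error = function(e) class(e)[[1L]])
  expect_identical(viaProxy, "simpleError")
  expect_identical(viaProxy, viaTwin)
  # unknown names dispatch worker-side and name the attempted member
  err <- expect_error(px$definitely_not_there(), class = "proxysimUnknownMemberError")
  expect_match(conditionMessage(err), "definitely_not_there")
})

test_that("properties are remote value accesses, readable and writable", {
  fx <- fineRelaxerService(n_particles = 3L)
  on.exit(closeService(fx))
  driveToStarted(fx)
  expect_identical(fx$target, 0)
  fx$target <- 2.5
  expect_identical(fx$target, 2.5)
  expect_identical(fx$get_target(), 2.5)
})

test_that("a serialized proxy reattaches to the same worker instance", {
  orig <- createService("Accum", v0 = 0)
  on.exit(closeService(orig))
  driveToStarted(orig)
  orig$set_value(7.0)
  bytes <- serializeProxy(orig)
  expect_true(is.raw(bytes))
  copy <- deserializeProxy(bytes)
  expect_identical(copy$get_value(), 7.0)      # state set through the original
  copy$set_value(-1.5)
  expect_identical(orig$get_value(), -1.5)     # and vice versa: one instance
  # manifest preserved across the round trip
  expect_identical(manifestNames(copy[["manifest"]]), manifestNames(orig[["manifest"]]))
  # serialize -> deserialize -> serialize is idempotent
  expect_identical(serializeProxy(deserializeProxy(bytes)), bytes)
})

test_that("parallel client contexts over one serialized proxy observe the same state", {
  skip_if_not_installed("parallel")
  px <- createService("Accum", v0 = 123)
  on.exit(closeService(px))
  bytes <- serializeProxy(px)
  cl <- parallel::makePSOCKcluster(2)
  on.exit(parallel::stopCluster(cl), add = TRUE)
  got <- parallel::parLapply(cl, 1:2, function(i, bytes) {
    library(proxysim)
    p <- deserializeProxy(bytes)
    p$get_value()
  }, bytes = bytes)
  expect_identical(got, list(123, 123))
})

test_that("a rebuilt proxy to a dead worker errors at call time, not build time", {
  px <- createService("Accum", v0 = 1)
  bytes <- serializeProxy(px)
  closeService(px)
  ghost <- deserializeProxy(bytes)   # cheap, no connection yet
  expect_error(ghost$get_value(), class = "proxysimTransportError")
})

test_that("refreshManifest reflects runtime registrations; both proxies see them", {
  w <- randomWalkerService(seed = 1L)
  on.exit(closeService(w))
  m0 <- refreshManifest(w)
  expect_setequal(manifestNames(m0), manifestNames(discoverInterface(randomWalkerImplementation())))
  w2 <- deserializeProxy(serializeProxy(w))
  driveToStarted(w)
  w$enable_jump()   # registers service function "jump" worker-side
  expect_true("jump" %in% manifestNames(refreshManifest(w)))
  expect_true("jump" %in% manifestNames(refreshManifest(w2)))
  expect_true("jump" %in% names(w))
})
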