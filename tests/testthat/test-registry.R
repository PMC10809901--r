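# naming, factories, instance management, and the service-function mechanism.

test_that("duplicate registration is rejected and the first entry stays intact", {
  nm <- "DupTest"
  registerService(nm, accumulatorImplementation())
  expect_error(registerService(nm, minimalImplementation()),
               class = "proxysimRegistrationError")
  px <- createService(nm, v0 = 9)
  on.exit(closeService(px))
  expect_identical(px$get_value(), 9)  # still the accumulator implementation
})

test_that("registering a type missing hooks is a contract error naming them", {
  broken <- serviceImplementation("NoStep", run = function(self) NULL,
                                  init = function(self) NULL,
                                  start = function(self) NULL,
                                  finish = function(self) NULL)
  err <- expect_error(registerService("BrokenReg", broken),
                      class = "proxysimContractError")
  expect_match(conditionMessage(err), "step")
  expect_false("BrokenReg" %in% registeredServices())
})

test_that("creating an unknown service is a lookup error listing known names", {
  err <- expect_error(createService("nope"), class = "proxysimLookupError")
  expect_match(conditionMessage(err), "RandomWalker")
})

test_that("a rejected constructor keyword surfaces as a remote spawn failure", {
  expect_error(createService("Accum", bogus_kwarg = 1),
               class = "proxysimSpawnError")
})

test_that("every create yields a fresh, independent instance", {
  a <- createService("RandomWalker", seed = 1L)
  b <- createService("RandomWalker", seed = 1L)
  on.exit({ closeService(a); closeService(b) })
  driveToStarted(a)
  driveToStarted(b)
  for (i in 1:30) serviceStep(a)   # step only one of them
  expect_identical(a$get_pos(), oracleWalk(30L, seed = 1L))
  expect_identical(b$get_pos(), 0) # the other is untouched
})

test_that("closing one of three live walkers leaves the other two fully functional", {
  ws <- lapply(1:3, function(s) createService("RandomWalker", seed = s))
  on.exit(for (w in ws) tryCatch(closeService(w), error = function(e) NULL))
  for (w in ws) driveToStarted(w)
  expect_true(closeService(ws[[2L]]))
  expect_error(ws[[2L]]$get_pos(), class = "proxysimTransportError")
  for (i in 1:20) { serviceStep(ws[[1L]]); serviceStep(ws[[3L]]) }
  expect_identical(ws[[1L]]$get_pos(), oracleWalk(20L, seed = 1L))
  expect_identical(ws[[3L]]$get_pos(), oracleWalk(20L, seed = 3L))
})

test_that("activeServices snapshots live instances with independent statuses", {
  closeAllServices()
  expect_identical(nrow(activeServices()), 0L)
  a <- createService("Accum")
  b <- createService("Accum")
  c3 <- createService("RandomWalker", seed = 1L)
  on.exit(closeAllServices())
  driveToStarted(a)                 # a STARTED, b CONSTRUCTED, c3 RUNNING
  serviceRun(c3)
  snap <- activeServices()
  expect_identical(nrow(snap), 3L)
  expect_setequal(snap$status, c("STARTED", "CONSTRUCTED", "RUNNING"))
  closeService(b)
  snap2 <- activeServices()
  expect_identical(nrow(snap2), 2L)
  expect_false("CONSTRUCTED" %in% snap2$status)
})

test_that("registry teardown closes every instance and leaves no workers", {
  closeAllServices()
  pxs <- lapply(1:3, function(i) createService("Accum", v0 = i))
  pids <- vapply(pxs, workerPid, integer(1))
  closeAllServices()
  expect_identical(nrow(activeServices()), 0L)
  for (pid in pids) expectProcessGone(pid)
})

test_that("factories mint a fresh service per call", {
  newAccum <- serviceFactory("Accum")
  a <- newAccum(v0 = 1)
  b <- newAccum(v0 = 2)
  on.exit({ closeService(a); closeService(b) })
  expect_identical(a$get_value(), 1)
  expect_identical(b$get_value(), 2)
})

test_that("service functions are exposed under the same or a different name, immediately", {
  px <- createService("Accum", v0 = 0)
  px2 <- deserializeProxy(serializeProxy(px))  # built before any registration
  on.exit(closeService(px))
  double <- function(x) 2 * x
  registerServiceFunction(px, double)                       # callable's own name
  registerServiceFunction(px, function(x) x * x, "square")  # different name
  expect_identical(px$double(21), 42)
  expect_identical(px$square(7), 49)
  # available on the other, already-built proxy without any refresh
  expect_identical(px2$double(4), 8)
})

test_that("service-function name collisions are rejected, lifecycle untouched", {
  px <- createService("Accum", v0 = 5)
  on.exit(closeService(px))
  expect_error(registerServiceFunction(px, function() 1, "step"),
               class = "proxysimCollisionError")
  expect_error(registerServiceFunction(px, function() 1, "get_value"),
               class = "proxysimCollisionError")
  expect_identical(serviceStatus(px), "CONSTRUCTED")  # lifecycle intact
  driveToStarted(px)
  expect_true(serviceStep(px))
  # re-registration of a service-function name replaces, with a message
  registerServiceFunction(px, function() "v1", "probe")
  expect_identical(px$probe(), "v1")
  registerServiceFunction(px, function() "v2", "probe")
  expect_identical(px$probe(), "v2")
})

test_that("a private member can be promoted to a service function from inside the worker", {
  w <- randomWalkerService(seed = 8L)
  on.exit(closeService(w))
  driveToStarted(w)
  expect_error(w$jump(3.0), class = "proxysimUnknownMemberError")
  w$enable_jump()   # the instance registers its private .jump as "jump"
  before <- w$get_pos()
  expect_identical(w$jump(3.0), before + 3.0)
  # in-context twin of the same move
  walkerReset()
  walkerInit(before, 1, seed = 8L)
  walkerSetPos(walkerGetPos() + 3.0)
  expect_identical(w$get_pos(), walkerGetPos())
  walkerReset()
})

test_that("service functions work on local services too, with the same collision rules", {
  svc <- localService(accumulatorImplementation(), list(v0 = 1))
  registerServiceFunction(svc, function(x) x + 1, "succ")
  expect_identical(callMember(svc, "succ", 41), 42)
  expect_error(registerServiceFunction(svc, function() 0, "finish"),
               class = "proxysimCollisionError")
})
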