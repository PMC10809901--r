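# proxysim

Memory-isolated simulation services with interactive proxies, in R.

## The problem

Integrative modeling in systems biology couples several simulators — a
multicellular lattice model, a particle-based subcellular model, ODE
submodels — into one orchestrated computation. Many scientific simulators are
stateful by construction: they keep their working state in module-level or
package-level variables, so a single process can host exactly one instance.
That makes batch execution, sensitivity analysis, model calibration and
co-simulation awkward or impossible without rewriting the simulator.

`proxysim` removes that constraint without touching the simulator. Each
simulation runs as a **service**: one instance of a user-written *interface
implementation*, constructed inside its own operating-system process (a
*worker*) with a fully isolated address space, and controlled exclusively
through an interactive **proxy object** in the client. All services share one
execution lifecycle; everything simulator-specific is discovered
automatically and replicated onto the proxy.

## The architecture

An interface implementation supplies five lifecycle hooks plus any public
methods/properties:

| hook | meaning |
|---|---|
| `run` | simulator startup (allocate resources) |
| `init` | initialize simulation data |
| `start` | apply initial conditions |
| `step` | advance one step in time; returns a continue/stop flag |
| `finish` | store final data, release resources |

The lifecycle is a state machine

```
CONSTRUCTED -> RUNNING -> INITIALIZED -> STARTED -> FINISHED
                         (step: STARTED -> STARTED)        FAILED <- any, on hook error
```

with exactly those transitions legal; anything else raises a lifecycle-order
error and changes nothing. Every proxy call is one synchronous
request/response message exchange with the worker (arguments and results pass
by value through a serialization boundary). Key capabilities:

- **Isolation**: *n* instances of a module-level-state simulator run
  simultaneously, one worker each, with provably no cross-talk.
- **Transparency**: the proxy exposes each discovered member under its own
  name and signature — it can be treated as if it were the implementation
  instance.
- **Service functions**: any R function can be attached to a *running*
  service (same or different name) and becomes a proxy method immediately, on
  every proxy to that worker, without a refresh.
- **Serializable proxies**: `serializeProxy()` yields bytes from which
  another process rebuilds a proxy to the *same* live instance — the basis
  for parallel/batch patterns.

## Worked example

The bundled reference service wraps a 1D random walker that stores its
position in a package-level variable (`pos <- pos ± step_size`, fair seeded
sign). Two instances in one process would trample each other; as services
they cannot:

```r
library(proxysim)

w1 <- randomWalkerService(seed = 1L)   # one worker process each
w2 <- randomWalkerService(seed = 2L)
serviceStatus(w1)
#> [1] "CONSTRUCTED"

for (w in list(w1, w2)) { serviceRun(w); serviceInit(w); serviceStart(w) }
for (i in 1:100) { serviceStep(w1); serviceStep(w2) }
c(w1$get_pos(), w2$get_pos())
#> [1] 2 2      # each equals its own seeded single-instance trajectory

w1$enable_jump()    # the instance registers its private .jump as "jump"
w1$jump(2.5)
#> [1] 4.5

activeServices()
#>    serviceName instanceId  status
#> 1 RandomWalker          1 STARTED
#> 2 RandomWalker          2 STARTED

closeAllServices()  # workers shut down; none outlive their clients
```

That both walkers print `2` here is a seed coincidence, not cross-talk: each
final position is checked in the tests against an independent replay of its
own seed, after fully interleaved stepping.

The discovered interface that was replicated onto the proxies:

```r
discoverInterface(randomWalkerImplementation())
#> <InterfaceManifest RandomWalkerService> 3 record(s)
#>   METHOD         get_pos()
#>   METHOD         set_pos(pos)
#>   METHOD         enable_jump()
```

A two-scale coupled demo (`runCoupledDemo()`, also reachable through the CLI
script `inst/cli/proxysim-demo`) orchestrates a coarse walker service and a
fine particle-relaxation service with `k` substeps per coarse step — the
standard pattern for coupling a discrete-time simulator to a finer-grained
one. With noise off, the fine system's distance to the coarse state contracts
by exactly `(1 - alpha)^k` per coarse step, which the tests verify
analytically.

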