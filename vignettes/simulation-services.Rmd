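---
title: "Simulation services: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation services: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why it is
built the way it is: the service model and its assumptions, the parameters
that matter, the numerical and design choices that were genuinely open, and
what the bundled synthetic simulators do and do not establish about real
simulators.

## The service model

A *simulation service* is one instance of a user-written interface
implementation, hosted in its own operating-system process and controlled
only through messages. The model rests on three contracts.

**Lifecycle.** Every service moves through
`CONSTRUCTED → RUNNING → INITIALIZED → STARTED → FINISHED`, driven by the
five client-visible operations `run`, `init`, `start`, `step`, `finish`,
each of which invokes exactly one implementation-supplied hook. `step` keeps
the service in `STARTED` and may be called any number of times; its hook
returns a continue/stop flag so simulations with natural termination can say
so. `FAILED` is reachable from every state: if a hook raises, the service is
marked failed *before* the error propagates, so an observer can never see a
partially advanced state. Chosen behaviours where the design was open:

- `run()` is an explicit client call, not implicit in creation, so the five
  hooks stay visible one-to-one on the proxy.
- `step()` takes no count argument. Multi-step advancement belongs in
  implementation-specific methods (e.g. "simulation time per step"), where a
  simulator can define what a batch of substeps means for it.
- `finish()` is legal only from `STARTED`. This is the simplest reading of
  "stopping a started simulation"; implementations wanting other teardown
  paths can expose custom methods.
- `FAILED` is sticky. After an arbitrary hook failure the worker's state is
  untrustworthy; offering a recovery transition would promise more than the
  architecture can honor. Status queries (and, from `FINISHED`, ordinary
  interface methods) remain available.
- The uniform interface also carries `metrics`: an optional hook returning a
  name→number vector of performance metrics. No schema is imposed — the
  field has no agreed one — so the contract is deliberately minimal: numeric,
  named, possibly empty.

**Transport.** Client and worker exchange length-prefixed frames (R
serialization) over a local socket: one strictly increasing request id per
endpoint, one response per request, synchronous. The contract is *ordered,
reliable, bidirectional, one client endpoint per connection*; sockets are
merely the mechanism that satisfies it in base R. Each frame is written in a
single system write — header and payload split across two writes interacts
with Nagle/delayed-ACK and costs ~80 ms per round trip; combined, a round
trip is ~0.3 ms. A one-byte-field format version rides in every frame so
mismatched builds fail loudly rather than misparse. There is deliberately no
default call timeout (simulation steps may legitimately run for hours); a
per-service timeout is available, and a timed-out endpoint is poisoned,
since its stream can no longer pair requests with responses.

**Serialization boundary.** All arguments and results cross by value.
Consequences the package documents rather than hides: mutating a returned
structure never writes back; arguments are checked client-side *before* any
worker is involved, and values that cannot meaningfully cross an address
space (connections, external pointers) are rejected with the offending
argument's name, even though base `serialize()` would happily emit bytes for
them. Closures serialize together with their enclosing environments, except
the global environment and package namespaces, which R stores by reference —
so implementations must not lean on ad-hoc globals.

## Proxies and interface discovery

The manifest of an implementation is computed by reflection: every public
method and property beyond the lifecycle, with parameter names and defaults
(minus the `self` receiver). Members whose names start with `.` are private
and excluded — R's native privacy marker, applied to the same purpose that
leading underscores serve in other ecosystems. Proxy methods are synthesized
with the member's own formals, so arity errors fail client-side exactly as
on the real member.

Calls to names outside the cached manifest are *not* rejected client-side:
they are forwarded and resolved worker-side at call time, against the
manifest first and the service-function table second. That resolution order,
plus rejecting (rather than shadowing) collisions at registration, is what
lets a function registered at any moment in a service's life be callable on
every existing proxy instantly; `refreshManifest()` exists purely for
introspection. Collisions with lifecycle names or manifest members are
errors because silently changing the meaning of an existing member under a
running orchestration is the worst available failure mode; re-registering a
service-function name replaces it, with a message, since iterating on a
user-supplied extension is the normal workflow.

Serialized proxies are handles: format version, service name, connection
descriptor (host, port, key), manifest. Deserialization is lazy — no
connection until the first call — and reattaches to the *same* worker
instance, which is the intended sharing mechanism: serialize to share, one
outstanding call per endpoint, requests served in arrival order across
endpoints so the instance is never entered concurrently. Whether two live
proxies *should* drive one service interleaved is a policy the orchestrator
owns; the worker merely guarantees serial execution.

## Worker lifetime and hygiene

Workers are launched as fresh R processes and bootstrapped over a one-shot
socket with a shared key. Teardown is belt and braces:

- `closeService()`/`shutdownWorker()` send `SHUTDOWN`, wait a configurable
  grace period (default 5 s) for a clean exit, then forcibly reap.
- Client-side finalizers attempt clean shutdown of any endpoint still open
  when the namespace is collected or R exits.
- Independently, a worker whose last client connection has dropped exits on
  its own after a linger window (default 5 s). This is the backstop for
  abrupt client death, where no client code runs at all.

The linger rule is also the answer to nested services: a registry exists per
process, workers included, so a service can create and own sub-services; they
are closed when their creating worker shuts down. Lifetime rules beyond
"nested instances die with their owner" are intentionally not invented.

## The synthetic simulators

The generator-side defaults are the study conditions used throughout the
tests and the acceptance script.

**Random walker.** Position `pos` updates by `pos ± step_size` with a fair
seeded sign; defaults start = 0, step_size = 1, seed = 12345. The update rule
and defaults are this package's reconstruction of the classic 1D random walk
(stated as such in the docs). Two properties make it the right probe for this
architecture: its state is module-level, so in-process instances collide by
construction; and its trajectory is a pure function of `(seed, step_size,
start)`, so an independent oracle — direct re-execution of the update rule
outside all service machinery — checks service trajectories *exactly*, not
statistically. The sign stream is drawn from a per-instance RNG state, never
the caller's global stream, so harness randomness cannot perturb it.

**Fine relaxer.** `M` particles relax toward a target `x`:
`y_i ← y_i + α(x − y_i) + σξ_i`, `ξ_i` standard normal from an
instance-owned stream; defaults M = 5, α = 0.5, σ = 0, `y_i,0` spread evenly
on [−1, 1]. With σ = 0 the recurrence has the closed form
`y_i − x = (1 − α)^k (y_i,0 − x)` after `k` substeps — an analytic oracle.

**Coupled demo.** Per coarse step: walker steps once, its position becomes
the fine target, the fine system takes `k` substeps (defaults: 20 coarse
steps, k = 10, seeds (1, 2)). With α = 0.5, k = 10 the per-coarse-step
contraction factor is exactly 2⁻¹⁰, which the tests and the acceptance
script verify at every step, along with byte-identical reproduction of the
CSV under fixed seeds.

What passing these suites shows: the architecture adds *no numerical effect*
— trajectories through the full service stack equal bare in-context
trajectories for identical seeds — and the process machinery (isolation,
dispatch, serialization, teardown) honors its contracts. What it does not
show: behaviour under large payloads, long-running native simulators,
resource acquisition (GPUs, graphics contexts — the implementation's
responsibility by contract), or platforms without POSIX process semantics.

## Problem sizes and statistical checks

The suites run on one CPU: four interleaved walker services × 1000 steps for
isolation; ~150 generated calls for proxy transparency; the full 6 × 5
(state × operation) matrix; 10 coarse × 10 fine steps for the coupled demo.
The walker-statistics check uses 1000 seeded replicates of 100 steps: the
final position has mean 0 and variance n, and the tests require agreement
within four standard errors (for the variance, the SE uses the walk's fourth
moment, `μ₄ = 3n² − 2n`), a band chosen once from the sampling distribution,
not tuned.

## Known limitations

One client endpoint at a time is assumed well-behaved (the protocol is not
hardened against a malicious peer); workers listen on loopback only and are
keyed, but this is process isolation, not a security boundary. Remote
(networked) workers, shared-memory bulk data paths, and multi-client shared
services are out of scope. Error objects are not reconstructed across the
boundary — a wrapper carries category, message and remote stack text —
because the client may not have the classes needed to rebuild them.
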