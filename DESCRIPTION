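Package: proxysim
Title: Memory-Isolated Simulation Services with Interactive Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deploys stateful simulations as memory-isolated services, each
    hosted in its own operating-system process and controlled through an
    interactive proxy object. All services share a uniform execution
    lifecycle (run, init, start, step, finish) while exposing their own
    simulator-specific methods and properties, which are discovered
    automatically and replicated onto proxies with faithful signatures.
    Additional callables ("service functions") can be attached to a running
    service at any time and become proxy methods immediately. Proxies are
    serializable, so a handle to a live simulation can be shipped to
    parallel client contexts. Includes reference services (a seeded 1D
    random walker with module-level state, and a particle relaxation
    system), a two-scale coupled-simulation orchestration demo, and a
    command-line interface for the demos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    utils,
    stats,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    parallel,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
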