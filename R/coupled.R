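# Two-scale coupled-simulation demo: a coarse walker service advanced in
# discrete steps, and a fine particle system that relaxes toward the walker's
# position with several substeps per coarse step. This is the canonical
# orchestration pattern for coupling a discrete-time simulator to a
# continuous-time one: integrate the coarse service, forward its updated
# configuration to the fine service, then integrate the fine service.

#' Configuration for the coupled two-scale demo
#'
#' @param coarse_steps Number of coarse (walker) steps.
#' @param k Fine substeps per coarse step (`k >= 1`).
#' @param alpha Relaxation rate in (0, 1]: the fraction of the remaining gap
#'   closed per substep. With `sigma = 0`, the gap after `k` substeps is
#'   exactly `(1 - alpha)^k` times the pre-step gap.
#' @param sigma Fine-scale noise amplitude (`>= 0`), standard deviation of the
#'   per-substep normal perturbation.
#' @param n_particles Number of fine particles `M`.
#' @param seeds Integer pair: walker seed, fine-noise seed.
#' @param step_size Coarse walker step magnitude.
#' @return A validated `CoupledDemoConfig` list.
#' @export
coupledDemoConfig <- function(coarse_steps = 20L, k = 10L, alpha = 0.5,
                              sigma = 0, n_particles = 5L,
                              seeds = c(1L, 2L), step_size = 1) {
  stopifnot(coarse_steps >= 1L, k >= 1L, alpha > 0, alpha <= 1, sigma >= 0,
            n_particles >= 1L, length(seeds) == 2L, step_size > 0)
  structure(list(coarse_steps = as.integer(coarse_steps), k = as.integer(k),
                 alpha = alpha, sigma = sigma,
                 n_particles = as.integer(n_particles),
                 seeds = as.integer(seeds), step_size = step_size),
            class = "CoupledDemoConfig")
}

#' Run the coupled two-scale demo
#'
#' Launches a coarse walker service and a fine relaxer service, runs both
#' through their lifecycles, and per coarse step: advances the walker one
#' step, forwards its position `x` as the fine system's target, advances the
#' fine system `k` substeps, and records one row for the walker plus one per
#' particle. Both services are finished and closed at the end; if anything
#' fails mid-run, both are closed best-effort and an orchestration error is
#' raised.
#'
#' Given fixed seeds the whole table is deterministic, down to identical CSV
#' bytes when written twice.
#'
#' @param config A [coupledDemoConfig()].
#' @return A `TrajectoryTable`: a data frame with columns `step`, `id`
#'   (`"walker"` or `"particle_<i>"`), `position`; exactly
#'   `coarse_steps * (1 + n_particles)` rows in monotone step order.
#' @examples
#' \dontrun{
#' tab <- runCoupledDemo(coupledDemoConfig(coarse_steps = 5L))
#' head(tab)
#' }
#' @export
runCoupledDemo <- function(config = coupledDemoConfig()) {
  stopifnot(inherits(config, "CoupledDemoConfig"))
  coarse <- NULL
  fine <- NULL
  closeBoth <- function() {
    if (!is.null(coarse)) tryCatch(closeService(coarse), error = function(e) NULL)
    if (!is.null(fine)) tryCatch(closeService(fine), error = function(e) NULL)
  }
  rows <- vector("list", config$coarse_steps)
  ok <- tryCatch({
    coarse <- createService("RandomWalker", start = 0,
                            step_size = config$step_size,
                            seed = config$seeds[[1L]])
    fine <- createService("FineRelaxer", n_particles = config$n_particles,
                          alpha = config$alpha, sigma = config$sigma,
                          seed = config$seeds[[2L]])
    for (svc in list(coarse, fine)) {
      serviceRun(svc); serviceInit(svc); serviceStart(svc)
    }
    pids <- paste0("particle_", seq_len(config$n_particles))
    for (s in seq_len(config$coarse_steps)) {
      serviceStep(coarse)
      x <- coarse$get_pos()
      fine$set_target(x)
      for (j in seq_len(config$k)) serviceStep(fine)
      y <- fine$get_positions()
      rows[[s]] <- data.frame(step = s, id = c("walker", pids),
                              position = c(x, y), stringsAsFactors = FALSE)
    }
    serviceFinish(coarse)
    serviceFinish(fine)
    TRUE
  }, error = function(e) e)
  closeBoth()
  if (!isTRUE(ok)) {
    stop(pxCondition("proxysimOrchestrationError",
                     sprintf("coupled demo failed: %s", conditionMessage(ok)),
                     parent = ok))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("TrajectoryTable", "data.frame")
  out
}

#' Write a trajectory table as CSV
#'
#' Plain-text CSV with a header row and full-precision floating values, for
#' inspectability and byte-stable reproduction under fixed seeds.
#'
#' @param table A `TrajectoryTable` (or any data frame).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeTrajectoryCSV <- function(table, path) {
  df <- as.data.frame(table)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      df[[cl]] <- formatC(df[[cl]], digits = 17, format = "g")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
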