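# the fine relaxer's closed forms, the coupled two-scale demo, and the CLI.

test_that("with sigma = 0 and alpha = 1 one substep lands every particle on the target", {
  svc <- localService(fineRelaxerImplementation(),
                      list(n_particles = 4L, alpha = 1, sigma = 0))
  driveToStarted(svc)
  callMember(svc, "set_target", 3.5)
  serviceStep(svc)
  expect_identical(callMember(svc, "get_positions"), rep(3.5, 4))
})

test_that("with sigma = 0 the gap contracts exactly as (1 - alpha)^k", {
  alpha <- 0.3
  y0 <- c(-2, 0.5, 4)
  svc <- localService(fineRelaxerImplementation(),
                      list(n_particles = 3L, alpha = alpha, sigma = 0, y0 = y0))
  driveToStarted(svc)
  x <- 1.25
  callMember(svc, "set_target", x)
  y <- y0
  for (k in 1:12) {
    serviceStep(svc)
    y <- y + alpha * (x - y)   # independent replay of the recurrence
    expect_equal(callMember(svc, "get_positions"), y, tolerance = 1e-15)
    expect_equal(callMember(svc, "get_positions") - x, (1 - alpha)^k * (y0 - x),
                 tolerance = 1e-12)
  }
})

test_that("with sigma > 0 positions equal an oracle replay of the seeded update rule", {
  alpha <- 0.5; sigma <- 0.2; seed <- 31L; n <- 3L
  y0 <- c(0, 1, 2)
  svc <- localService(fineRelaxerImplementation(),
                      list(n_particles = n, alpha = alpha, sigma = sigma,
                           seed = seed, y0 = y0))
  driveToStarted(svc)
  callMember(svc, "set_target", -1)
  for (k in 1:5) serviceStep(svc)
  # direct re-execution of the update rule with the same draw stream
  set.seed(seed)
  y <- y0
  for (k in 1:5) y <- y + alpha * (-1 - y) + sigma * rnorm(n)
  expect_identical(callMember(svc, "get_positions"), y)
})

test_that("the coupled demo keeps the fine system within the contraction bound each coarse step", {
  cfg <- coupledDemoConfig(coarse_steps = 8L, k = 10L, alpha = 0.5, sigma = 0,
                           n_particles = 5L, seeds = c(1L, 2L))
  tab <- runCoupledDemo(cfg)
  expect_s3_class(tab, "TrajectoryTable")
  expect_identical(nrow(tab), cfg$coarse_steps * (1L + cfg$n_particles))
  expect_true(!is.unsorted(tab$step))
  factor <- (1 - cfg$alpha)^cfg$k   # 2^-10
  yPrev <- seq(-1, 1, length.out = cfg$n_particles)  # relaxer's default y0
  for (s in seq_len(cfg$coarse_steps)) {
    x <- tab$position[tab$step == s & tab$id == "walker"]
    y <- tab$position[tab$step == s & tab$id != "walker"]
    preGap <- max(abs(yPrev - x))
    expect_lte(max(abs(y - x)), factor * preGap + 1e-12)
    yPrev <- y
  }
})

test_that("already-converged fine systems are insensitive to extra substeps", {
  base <- list(coarse_steps = 5L, alpha = 1, sigma = 0, n_particles = 3L,
               seeds = c(9L, 10L))
  t1 <- do.call(runCoupledDemo, list(do.call(coupledDemoConfig, c(base, k = 1L))))
  t2 <- do.call(runCoupledDemo, list(do.call(coupledDemoConfig, c(base, k = 2L))))
  expect_identical(t1$position, t2$position)
})

test_that("the full demo is reproducible to the byte under fixed seeds", {
  cfg <- coupledDemoConfig(coarse_steps = 5L, k = 5L, alpha = 0.5, sigma = 0.1,
                           n_particles = 3L, seeds = c(3L, 4L))
  t1 <- runCoupledDemo(cfg)
  t2 <- runCoupledDemo(cfg)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(t1, f1); writeTrajectoryCSV(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("cli walk writes one row per (step, walker) and reproduces byte-identically", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  args <- c("walk", "--n", "2", "--steps", "50", "--seeds", "1,2")
  expect_identical(cliMain(c(args, "--out", f1)), 0L)
  got <- utils::read.csv(f1)
  expect_identical(nrow(got), 100L)     # 2 walkers x 50 steps
  expect_setequal(unique(got$id), c("walker_1", "walker_2"))
  # each walker's final row equals its independent oracle run
  expect_identical(as.numeric(got$position[got$id == "walker_1" & got$step == 50]),
                   oracleWalk(50L, seed = 1L))
  expect_identical(as.numeric(got$position[got$id == "walker_2" & got$step == 50]),
                   oracleWalk(50L, seed = 2L))
  expect_identical(cliMain(c(args, "--out", f2)), 0L)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("cli couple honors flags and a YAML config, flags taking precedence", {
  f1 <- tempfile(fileext = ".csv")
  cfgFile <- tempfile(fileext = ".yaml")
  writeLines(c("coarse_steps: 3", "k: 4", "alpha: 1.0", "sigma: 0.0",
               "n_particles: 2", "seeds: [5, 6]"), cfgFile)
  expect_identical(cliMain(c("couple", "--config", cfgFile, "--out", f1)), 0L)
  got <- utils::read.csv(f1)
  expect_identical(nrow(got), 3L * (1L + 2L))
  # alpha = 1, sigma = 0: particles sit exactly on the walker each step
  for (s in 1:3) {
    x <- got$position[got$step == s & got$id == "walker"]
    expect_true(all(got$position[got$step == s & got$id != "walker"] == x))
  }
})

test_that("cli rejects bad usage with a nonzero exit and no partial output", {
  expect_identical(cliMain(character(0)), 2L)
  expect_identical(cliMain(c("walk")), 2L)           # missing --out
  f <- tempfile(fileext = ".csv")
  expect_identical(cliMain(c("walk", "--n", "2", "--seeds", "1", "--out", f)), 2L)
  expect_false(file.exists(f))
})
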