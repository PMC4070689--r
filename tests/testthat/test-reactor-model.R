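test_that("nominal HRT follows the volume/feed-rate balance", {
  expect_equal(nominal_hrt(reactor_config()), 8)

  full <- reactor_config(working_volume = 10, feed_volume = 10)
  expect_equal(nominal_hrt(full), sum(full$phases) / 60)  # one cycle length

  doubled <- reactor_config(phases = 2 * c(feed = 5, anaerobic = 55,
                                           aerobic = 120, settle = 45,
                                           decant = 15))
  expect_equal(nominal_hrt(doubled), 16)

  expect_error(reactor_config(feed_volume = 0), "positive")
  expect_error(reactor_config(feed_volume = 11), "exceed")
})

test_that("wastage fraction matches the SRT in both forms", {
  config <- reactor_config()  # 4 h cycle, SRT 10 d
  expect_equal(wastage_fraction_per_cycle(config, "nominal"), 1 / 60)
  w_exact <- wastage_fraction_per_cycle(config)  # exact is the default
  expect_equal(w_exact, 1 - exp(-1 / 60))

  # the two forms differ at order w^2
  expect_lt(abs(w_exact - 1 / 60), (1 / 60)^2)

  long_srt <- reactor_config(srt = 1e6)
  expect_lt(wastage_fraction_per_cycle(long_srt), 1e-6)
})

test_that("the no-growth curve anchors, decays, and matches across modes", {
  config <- reactor_config()
  days <- 41 + 0:20
  cont <- expected_no_growth_curve(30, 41, days, config)
  expect_equal(cont$expected[1], 30)
  expect_true(all(diff(cont$expected) < 0))
  expect_equal(cont$expected[days == 51], 30 * exp(-1), tolerance = 1e-12)

  per <- expected_no_growth_curve(30, 41, days, config, mode = "per_cycle")
  rel_gap <- abs(per$expected / cont$expected - 1)
  expect_lt(max(rel_gap), 0.01)   # whole days are whole cycles: near-exact

  expect_error(expected_no_growth_curve(30, 41, c(40, 42), config), "precede")
  expect_error(expected_no_growth_curve(0, 41, 42, config), "positive")
})

test_that("simulator no-growth trajectories reproduce the washout curve", {
  config <- reactor_config()
  dyn <- dynamics_spec(c(x = 1), constant_growth("x", 0, 20))
  tr <- simulate_dynamics(dyn, config, 20)
  expect_equal(unname(tr$biomass[1, ]), exp(-tr$days / config$srt),
               tolerance = 1e-9)
})

test_that("substrate share follows the steady-state production balance", {
  config <- reactor_config()
  # steady OTU consumes exactly its own fraction of production
  s <- substrate_share(12, 12, dt = 4, config)
  expect_equal(as.numeric(s), 0.12)
  expect_equal(attr(s, "flag"), "ok")

  # the boom: 1.9% -> 29.9% within 3-5 d implies more than half the substrate
  for (dt in seq(3, 5, by = 0.5)) {
    expect_gt(as.numeric(substrate_share(1.9, 29.9, dt, config)), 0.5)
  }

  # decline faster than washout gives a negative, flagged share
  f1 <- 10; dt <- 5
  f2 <- f1 * exp(-dt / config$srt) * 0.5
  s2 <- substrate_share(f1, f2, dt, config)
  expect_lt(as.numeric(s2), 0)
  expect_equal(attr(s2, "flag"), "negative")

  expect_error(substrate_share(10, 20, 0, config), "positive")
  expect_error(substrate_share(0, 20, 5, config), "\\(0, 100\\)")
})

test_that("substrate shares over a closed steady community sum to one", {
  config <- reactor_config()
  taxa <- paste0("t", 1:8)
  g <- constant_growth(taxa, 1 / config$srt, 10)
  # mild reshuffling episodes, community total stays near steady state
  g <- overlay_episode(g, "t1", 2, 8, 0.16)
  g <- overlay_episode(g, "t2", 2, 8, 0.04)
  dyn <- dynamics_spec(setNames(rep(1, 8), taxa), g)
  tr <- simulate_dynamics(dyn, config, 10)
  f <- 100 * sweep(tr$biomass, 2, colSums(tr$biomass), "/")
  i1 <- which.min(abs(tr$days - 2)); i2 <- which.min(abs(tr$days - 8))
  shares <- vapply(taxa, function(tx) {
    as.numeric(substrate_share(f[tx, i1], f[tx, i2], 6, config))
  }, numeric(1))
  expect_equal(sum(shares), 1, tolerance = 0.02)
})

test_that("a planted lysis event is called faster than washout", {
  config <- reactor_config()
  taxa <- sprintf("t%02d", 1:15)
  g <- constant_growth(taxa, 1 / config$srt, 40)
  g <- overlay_episode(g, "t01", 14, 20, 0.5)   # propagate, then get killed
  dyn <- dynamics_spec(setNames(rep(1, 15), taxa), g,
                       lysis = data.frame(taxon_id = "t01", day = 20.5,
                                          survival = 0.05))
  tr <- simulate_dynamics(dyn, config, 40, sampling_days = seq(14, 32, by = 2))
  ser <- compute_fractions(sample_counts(tr, 2000, seed = 55))
  call <- detect_selective_recession(ser, "t01", t0 = 20, config)
  expect_equal(call$verdict, "faster_than_washout")
  expect_true(all(c("day", "observed", "upper", "expected") %in%
                    names(call$evidence)))
})

test_that("a no-growth OTU is (almost) never called selectively killed", {
  config <- reactor_config()
  taxa <- sprintf("t%02d", 1:20)
  verdicts <- vapply(1:8, function(seed) {
    g <- constant_growth(taxa, 1 / config$srt, 40)
    g <- overlay_episode(g, "t01", 20, 40, 0)   # growth stops at day 20
    init <- setNames(rep(1, 20), taxa); init["t01"] <- 0.4
    dyn <- dynamics_spec(init, g)
    tr <- simulate_dynamics(dyn, config, 40, sampling_days = seq(16, 40, by = 2))
    ser <- compute_fractions(sample_counts(tr, 2000, seed = seed))
    detect_selective_recession(ser, "t01", t0 = 20, config,
                               window_days = 12)$verdict
  }, character(1))
  # washout alone is never mistaken for selective killing; and it usually
  # tracks the curve (anchor noise can occasionally read as not receding)
  expect_false(any(verdicts == "faster_than_washout"))
  expect_gte(sum(verdicts == "consistent_with_washout"), 6)
})

test_that("a constant-fraction OTU is not receding and short series are withheld", {
  config <- reactor_config()
  taxa <- c("a", "b")
  dyn <- dynamics_spec(c(a = 1, b = 1), constant_growth(taxa, 1 / config$srt, 30))
  tr <- simulate_dynamics(dyn, config, 30, sampling_days = seq(10, 30, by = 2))
  ser <- compute_fractions(sample_counts(tr, 3000, seed = 57))
  call <- detect_selective_recession(ser, "a", t0 = 10, config)
  expect_equal(call$verdict, "not_receding")

  short <- compute_fractions(sample_counts(
    simulate_dynamics(dyn, config, 30, sampling_days = c(10, 12)),
    3000, seed = 58))
  call2 <- detect_selective_recession(short, "a", t0 = 12, config)
  expect_equal(call2$verdict, "insufficient_data")
})

test_that("reactor config round-trips through its key-value file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  config <- reactor_config(working_volume = 12, feed_volume = 4, srt = 8)
  write_reactor_config(config, path)
  back <- read_reactor_config(path)
  expect_equal(back$working_volume, 12)
  expect_equal(back$srt, 8)
  expect_equal(back$phases, config$phases)
  expect_equal(nominal_hrt(back), nominal_hrt(config))
})
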