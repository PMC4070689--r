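test_that("reference generation honours site fraction, divergence and determinism", {
  one <- generate_reference_sequences(1, site_fraction = 1, seed = 3)
  expect_true(grepl("GTAC", one$sequence, fixed = TRUE))

  two <- generate_reference_sequences(2, site_fraction = 0, seed = 3)
  expect_false(any(grepl("GTAC", two$sequence, fixed = TRUE)))
  expect_lt(pairwise_identity(two$sequence[1], two$sequence[2]), 0.90)

  a <- generate_reference_sequences(30, length_range = c(420, 500), seed = 7)
  b <- generate_reference_sequences(30, length_range = c(420, 500), seed = 7)
  expect_identical(a, b)
  expect_true(all(nchar(a$sequence) >= 420 & nchar(a$sequence) <= 500))
  expect_true(all(grepl("^[ACGT]+$", a$sequence)))

  # planted_trf equals the value recomputed by scanning the sequence
  rescanned <- vapply(a$sequence, function(s) {
    p <- regexpr("GTAC", s, fixed = TRUE)[1]
    if (p > 0) as.integer(p) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(a$planted_trf, rescanned)
  expect_equal(sum(!is.na(a$planted_trf)), 15)  # default site_fraction 0.5
})

test_that("impossible divergence constraints fail explicitly", {
  expect_error(
    generate_reference_sequences(50, length_range = c(100, 100),
                                 max_pairwise_identity = 0.05, max_retries = 3),
    "divergent"
  )
})

test_that("biomass dynamics follow the per-cycle update and closed forms", {
  config <- reactor_config()
  taxa <- c("a", "b", "c")
  # equal growth, no lysis: relative fractions constant over time
  dyn <- dynamics_spec(setNames(c(1, 2, 3), taxa),
                       constant_growth(taxa, 0.2, 10))
  tr <- simulate_dynamics(dyn, config, 10)
  frac <- sweep(tr$biomass, 2, colSums(tr$biomass), "/")
  expect_equal(frac[, ncol(frac)], frac[, 1], tolerance = 1e-12)

  # single taxon growing at 1/SRT exactly balances wastage
  dyn1 <- dynamics_spec(c(x = 5), constant_growth("x", 1 / config$srt, 20))
  tr1 <- simulate_dynamics(dyn1, config, 20)
  expect_equal(unname(tr1$biomass[1, ]), rep(5, ncol(tr1$biomass)),
               tolerance = 1e-9)

  # discrete trajectory equals the continuous closed form on the cycle grid
  mu <- 0.37
  dyn2 <- dynamics_spec(c(x = 1), constant_growth("x", mu, 15))
  tr2 <- simulate_dynamics(dyn2, config, 15)
  expect_equal(unname(tr2$biomass[1, ]),
               exp((mu - 1 / config$srt) * tr2$days), tolerance = 1e-8)

  # lysis with survival 0 is absorbing
  dyn3 <- dynamics_spec(c(x = 1, y = 1),
                        constant_growth(c("x", "y"), 0.1, 20),
                        lysis = data.frame(taxon_id = "x", day = 8,
                                           survival = 0))
  tr3 <- simulate_dynamics(dyn3, config, 20)
  expect_true(all(tr3$biomass["x", tr3$days >= 8.01] == 0))
  expect_true(all(tr3$biomass["y", ] > 0))
  expect_true(all(tr3$biomass >= 0))
})

test_that("malformed dynamics specs are rejected", {
  expect_error(dynamics_spec(c(x = 1),
                             data.frame(taxon_id = "x", start_day = 0,
                                        end_day = 5, rate = NaN)),
               "NaN")
  g <- rbind(data.frame(taxon_id = "x", start_day = 0, end_day = 6, rate = 0.1),
             data.frame(taxon_id = "x", start_day = 4, end_day = 10, rate = 0.2))
  expect_error(dynamics_spec(c(x = 1), g), "overlapping")
  expect_error(dynamics_spec(c(x = -1), constant_growth("x", 0, 5)), "positive")
})

test_that("read counts are multinomially consistent with biomass", {
  config <- reactor_config()
  dyn <- dynamics_spec(c(a = 1, b = 1),
                       constant_growth(c("a", "b"), 1 / config$srt, 2))
  tr <- simulate_dynamics(dyn, config, 2, sampling_days = 1)
  tab <- sample_counts(tr, 10000, seed = 5)
  # equal biomass: each count within 3 binomial SDs of 5000
  expect_true(all(abs(tab$counts - 5000) <= 3 * sqrt(10000 * 0.25)))
  expect_equal(sum(tab$counts), 10000L)
})

test_that("read simulation is deterministic and respects its knobs", {
  fx1 <- fixture_simulation(n_taxa = 3, depth = 15, error_rate = 0.005, seed = 9)
  fx2 <- fixture_simulation(n_taxa = 3, depth = 15, error_rate = 0.005, seed = 9)
  expect_identical(fx1$sim$reads, fx2$sim$reads)

  # error rate 0, one taxon, full length: every insert is recovered exactly
  fx <- fixture_simulation(n_taxa = 1, depth = 10, error_rate = 0,
                           full_length_fraction = 1, days = 3, seed = 13)
  dm <- demultiplex(fx$sim$reads, fx$primers)
  expect_true(all(dm$assigned$insert == fx$taxa$sequence))

  # all reads reverse-complemented: none starts with a forward barcode
  taxa <- generate_reference_sequences(2, seed = 15)
  config <- reactor_config()
  dyn <- dynamics_spec(setNames(c(1, 1), taxa$taxon_id),
                       constant_growth(taxa$taxon_id, 0.1, 3))
  tr <- simulate_dynamics(dyn, config, 3, sampling_days = 2)
  barcodes <- setNames(generate_barcodes(1, seed = 16), "d002")
  primers <- barcoded_primer_set(barcodes)
  spec <- sequencing_spec(reads_per_sample = 50, error_rate = 0,
                          fraction_reverse = 1, seed = 17)
  sim <- sample_reads(tr, taxa, spec, primers)
  expect_false(any(substr(sim$reads, 1, 8) %in% primers$barcodes))
  # and they all demultiplex as reverse orientation
  dm <- demultiplex(sim$reads, primers)
  expect_true(all(dm$assigned$orientation == "reverse"))

  # zero depth is an empty sample, not an error
  spec0 <- sequencing_spec(reads_per_sample = 0, seed = 18)
  sim0 <- sample_reads(tr, taxa, spec0, primers)
  expect_length(sim0$reads, 0)
})

test_that("generated barcodes keep pairwise Hamming distance >= 3", {
  bc <- generate_barcodes(12, seed = 19)
  expect_length(unique(bc), 12)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in 1:11) for (j in (i + 1):12) expect_gte(ham(bc[i], bc[j]), 3)
})

test_that("the default scenario plants the boom-and-lysis taxon as specified", {
  sc <- default_scenario(n_taxa = 12, horizon = 60, n_sampling_points = 10,
                         seed = 23)
  expect_s3_class(sc$dynamics, "dynamics_spec")
  expect_equal(sc$dynamics$lysis$taxon_id, sc$focal)
  expect_equal(sc$dynamics$lysis$survival, 0.05)
  # the focal reference's first restriction site is planted at insert 463
  focal_seq <- sc$taxa$sequence[sc$taxa$taxon_id == sc$focal]
  expect_equal(as.integer(regexpr("GTAC", focal_seq, fixed = TRUE)), 463L)

  # fraction trajectory: ~2% before the boom, ~30% at its peak, collapse after
  tr <- simulate_dynamics(sc$dynamics, sc$reactor, 60,
                          sampling_days = sc$sampling_days)
  frac <- sweep(tr$biomass, 2, colSums(tr$biomass), "/")[sc$focal, ]
  f_pre <- frac[which.min(abs(tr$days - 29))]
  f_peak <- frac[which.min(abs(tr$days - 35))]
  f_post <- frac[which.min(abs(tr$days - 47))]
  expect_gt(f_pre, 0.01); expect_lt(f_pre, 0.04)
  expect_gt(f_peak, 0.25); expect_lt(f_peak, 0.40)
  # collapsed by the lysis event (5% survival, plus renormalization)
  expect_lt(f_post, 0.05)
  expect_lt(f_post, f_peak / 5)
})
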