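test_that("T-RF lengths follow the cut-offset arithmetic and full-length rule", {
  primers <- fixture_primers(1)   # forward primer is 20 nt
  # site starting at overall 0-based position 48 -> cut after GT at 50 bp
  insert <- paste(c(rep("A", 28), "GTAC", rep("C", 60)), collapse = "")
  res <- trf_length(insert, FALSE, primers)
  expect_equal(res$trf, 50L)
  expect_equal(res$status, "cut")

  # no site: full reconstituted length only with a detected reverse primer
  no_site <- paste(rep("A", 100), collapse = "")
  full <- trf_length(no_site, TRUE, primers)
  expect_equal(full$status, "full_length")
  expect_equal(full$trf, 20L + 100L + nchar(primers$reverse))
  excl <- trf_length(no_site, FALSE, primers)
  expect_equal(excl$status, "excluded")
  expect_true(is.na(excl$trf))

  # barcode inclusion shifts sizes by 8
  expect_equal(trf_length(insert, FALSE, primers, include_barcode = TRUE)$trf, 58L)
})

test_that("trf_length agrees with the brute-force scanning oracle", {
  primers <- fixture_primers(1)
  withr::with_seed(51, {
    for (i in 1:200) {
      len <- sample(60:200, 1)
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      had <- runif(1) < 0.5
      got <- trf_length(s, had, primers)
      want <- oracle_trf(s, had, primers$forward, primers$reverse)
      expect_equal(got$status, want$status)
      expect_equal(got$trf, want$trf)
    }
  })
})

test_that("virtual profiles bin reads by fragment size with exact bookkeeping", {
  primers <- fixture_primers(1)
  insert <- paste(c(rep("A", 28), "GTAC", rep("C", 60)), collapse = "")
  reads <- data.frame(sample_id = "S1", insert = insert,
                      had_reverse_primer = FALSE)[rep(1, 10), ]
  prof <- build_virtual_profile(reads, primers)
  expect_equal(prof$sizes, 50L)
  expect_equal(prof$counts, 10L)
  expect_equal(prof$n_excluded, 0L)

  # all site-free, no reverse primer: empty histogram, everything excluded
  no_site <- data.frame(sample_id = "S1",
                        insert = paste(rep("A", 80), collapse = ""),
                        had_reverse_primer = FALSE)[rep(1, 7), ]
  prof0 <- build_virtual_profile(no_site, primers)
  expect_length(prof0$sizes, 0)
  expect_equal(prof0$n_excluded, 7L)
  expect_equal(sum(prof0$counts) + prof0$n_excluded, prof0$n_reads)
})

test_that("per-sample profiles from simulated reads hit the planted sites", {
  fx <- fixture_simulation(n_taxa = 6, depth = 40, error_rate = 0,
                           days = 5, seed = 53, full_length_fraction = 1)
  dm <- demultiplex(fx$sim$reads, fx$primers)
  prof <- build_virtual_profile(dm, fx$primers, sample_id = "d005")
  expect_equal(sum(prof$counts) + prof$n_excluded, nrow(dm$assigned))

  # expected sizes: planted site -> 20 + (site - 1) + 2; else full length
  plen <- nchar(fx$primers$forward); rlen <- nchar(fx$primers$reverse)
  expected <- ifelse(!is.na(fx$taxa$planted_trf),
                     plen + fx$taxa$planted_trf - 1L + 2L,
                     plen + nchar(fx$taxa$sequence) + rlen)
  expect_setequal(prof$sizes, expected)
})

test_that("profile comparison scores and matches behave at the extremes", {
  primers <- fixture_primers(1)
  insert <- paste(c(rep("A", 28), "GTAC", rep("C", 60)), collapse = "")
  reads <- data.frame(sample_id = "S1", insert = insert,
                      had_reverse_primer = FALSE)[rep(1, 10), ]
  virt <- build_virtual_profile(reads, primers)

  same <- experimental_profile(virt$sizes, virt$counts)
  res <- compare_profiles(virt, same)
  expect_equal(res$score, 1)
  expect_equal(nrow(res$matches), length(virt$sizes))

  far <- experimental_profile(virt$sizes + 100, virt$counts)
  res2 <- compare_profiles(virt, far)
  expect_equal(res2$score, 0)
  expect_equal(nrow(res2$matches), 0)

  expect_error(compare_profiles(virt, same, tolerance_bp = -1), "non-negative")
})

test_that("a 484 bp virtual fragment matches a 481 bp experimental peak at 5 bp tolerance", {
  virt <- structure(list(sample_id = "s", sizes = 484L, counts = 20L,
                         n_excluded = 0L, n_reads = 20L),
                    class = "virtual_profile")
  exp_prof <- experimental_profile(c(200, 481), c(5, 40))
  res <- compare_profiles(virt, exp_prof, tolerance_bp = 5)
  expect_equal(res$matches$virtual_size, 484)
  expect_equal(res$matches$experimental_size, 481)
})

test_that("peak tables round-trip and the comparison plot renders", {
  path <- withr::local_tempfile(fileext = ".tsv")
  prof <- experimental_profile(c(100.2, 230.7, 481), c(10, 0, 33.5), "day35")
  write_peak_table(prof, path)
  back <- read_peak_table(path, "day35")
  expect_equal(back$sizes, prof$sizes)
  expect_equal(back$intensities, prof$intensities)
  expect_error(experimental_profile(c(2, 1), c(1, 1)), "increasing")

  virt <- structure(list(sample_id = "s", sizes = c(100L, 484L),
                         counts = c(3L, 20L), n_excluded = 0L, n_reads = 23L),
                    class = "virtual_profile")
  img <- withr::local_tempfile(fileext = ".png")
  plot_profile_comparison(virt, prof, file = img)
  expect_true(file.exists(img) && file.size(img) > 0)
})
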