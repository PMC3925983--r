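test_that("degenerate spectrum yields a perfect array and exact lengths", {
  spec <- array_spec(unit_count = 3, class_spectrum = c(1, 0, 0, 0, 0, 0),
                     seed = 7)
  arr <- generate_array(spec)
  expect_identical(arr$sequence, "TTCCATTCCATTCCA")
  expect_identical(arr$truth$classes, rep(0L, 3))

  arr713 <- generate_array(array_spec(unit_count = 713,
                                      class_spectrum = c(1, 0, 0, 0, 0, 0),
                                      seed = 7))
  expect_identical(nchar(arr713$sequence), 713L * 5L)
})

test_that("spec validation names the offending field", {
  expect_error(array_spec(class_spectrum = c(0.5, 0.5, 0.1, 0, 0, 0)),
               "class_spectrum")
  expect_error(array_spec(unit_count = 0), "unit_count")
  expect_error(array_spec(point_indel_rate = 2), "point_indel_rate")
  expect_error(array_spec(derivative_weights = rep(1, 10)),
               "derivative_weights")
})

test_that("same seed and spec give byte-identical arrays; seeds differ", {
  s <- array_spec(seed = 123, point_indel_rate = 0.01,
                  indel_blocks = data.frame(position = 100, length = 12,
                                            kind = "deletion"))
  expect_identical(generate_array(s), generate_array(s))
  s2 <- s; s2$seed <- 124L
  expect_false(identical(generate_array(s)$sequence,
                         generate_array(s2)$sequence))
})

test_that("generated length equals 5*unit_count plus net indel length", {
  for (seed in 1:5) {
    blocks <- data.frame(position = c(50, 400), length = c(10, 25),
                         kind = c("insertion", "deletion"))
    arr <- generate_array(array_spec(unit_count = 200, seed = seed,
                                     point_indel_rate = 0.02,
                                     indel_blocks = blocks))
    slips <- arr$truth$slips
    net_slips <- sum(slips$kind == "insertion") - sum(slips$kind == "deletion")
    expect_identical(nchar(arr$sequence), 200L * 5L + net_slips + 10L - 25L)
  }
})

test_that("sampled class counts follow the spectrum within 3-sigma multinomial bounds", {
  # class proportions of a real sequenced 3564 bp array unit
  p <- c(235, 290, 142, 33, 9, 1) / 710
  arr <- generate_array(array_spec(unit_count = 710, class_spectrum = p,
                                   seed = 20140204))
  counts <- tabulate(arr$truth$classes + 1L, nbins = 6)
  expected <- 710 * p
  tol <- 3 * sqrt(710 * p * (1 - p))
  expect_true(all(abs(counts - expected) <= pmax(tol, 3)))
  # truth classes agree with direct re-classification of the units
  expect_identical(arr$truth$classes,
                   as.integer(hamming_class(arr$truth$units)))
})

test_that("twin edits: identity, reported 35 bp loss, and insertion round trip", {
  parent <- generate_array(array_spec(unit_count = 720, seed = 5))$sequence

  same <- apply_twin_edits(parent, twin_edit_spec())
  expect_identical(same$sequence, parent)

  te <- twin_edit_spec(deletions = data.frame(position = c(390, 1728),
                                              length = c(20, 15)))
  child <- apply_twin_edits(parent, te)
  expect_identical(nchar(child$sequence), nchar(parent) - 35L)
  expect_identical(child$truth$net_length_change, -35L)

  ins <- apply_twin_edits(parent,
                          twin_edit_spec(insertions = data.frame(position = 1000,
                                                                 length = 10)))
  expect_identical(net_length_difference(ins$sequence, parent), 10L)
})

test_that("edit-log replay reproduces the child sequence exactly", {
  parent <- generate_array(array_spec(unit_count = 500, seed = 9))$sequence
  te <- twin_edit_spec(deletions = data.frame(position = c(120, 900),
                                              length = c(7, 30)),
                       insertions = data.frame(position = c(400, 1500),
                                               length = c(4, 12)),
                       seed = 11)
  child <- apply_twin_edits(parent, te)
  log <- child$truth$edits  # realised sequences recorded
  replay <- apply_twin_edits(parent,
    twin_edit_spec(deletions = log[log$kind == "deletion",
                                   c("position", "length")],
                   insertions = log[log$kind == "insertion",
                                    c("position", "length", "sequence")]))
  expect_identical(replay$sequence, child$sequence)
})

test_that("overlapping or out-of-range edits are rejected", {
  expect_error(twin_edit_spec(deletions = data.frame(position = c(100, 110),
                                                     length = c(20, 5))),
               "overlap")
  expect_error(twin_edit_spec(deletions = data.frame(position = 100, length = 10),
                              insertions = data.frame(position = 105, length = 3)),
               "overlap")
  parent <- strrep("TTCCA", 20)
  expect_error(apply_twin_edits(parent,
                 twin_edit_spec(deletions = data.frame(position = 99,
                                                       length = 10))),
               "beyond")
})

test_that("dilution series follows the Ct model and is deterministic", {
  # perfect doubling: 10-fold dilution shifts Ct by exactly log2(10)
  expect_equal(expected_ct(2e7) - expected_ct(2e8), log2(10), tolerance = 1e-12)

  spec <- dilution_series_spec(noise_sd = 0, seed = 1)
  sim <- simulate_dilution_series(spec)
  expect_identical(nrow(sim), 18L)  # 6 points x 3 replicates
  expect_equal(sim$ct[sim$point == 2][1] - sim$ct[sim$point == 1][1],
               log2(10), tolerance = 1e-12)
  expect_identical(sim, simulate_dilution_series(spec))

  noisy <- simulate_dilution_series(dilution_series_spec(noise_sd = 0.2,
                                                         seed = 31))
  spread <- tapply(noisy$ct, noisy$point, sd)
  expect_true(all(spread >= 0.02 & spread <= 1.0))
})

test_that("dilution spec invariants are enforced", {
  expect_error(dilution_series_spec(start_copies = 0), "start_copies")
  expect_error(dilution_series_spec(fold = 1), "fold")
  expect_error(dilution_series_spec(replicates = 0), "replicates")
  expect_error(dilution_series_spec(efficiency = 1.5), "efficiency")
})

test_that("generation restores the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_array(array_spec(unit_count = 10, seed = 3)))
  expect_identical(.Random.seed, before)
})
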