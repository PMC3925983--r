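test_that("hamming_class counts substitutions against TTCCA", {
  expect_identical(hamming_class("TTCCA"), 0L)
  expect_identical(hamming_class("TTCGA"), 1L)
  expect_identical(hamming_class("GGAAT"), 5L)
  expect_identical(hamming_class(single_bp_derivatives()), rep(1L, 15))
  expect_error(hamming_class("TTCC"), "length 5")
  expect_error(hamming_class("TTCCN"), "non-ACGT")
})

test_that("decomposition handles perfect, substituted and slipped arrays", {
  u <- decompose_array("TTCCATTCCATTCCA")
  expect_identical(nrow(u), 3L)
  expect_identical(u$edit_class, rep(0L, 3))

  u <- decompose_array("TTCCAATCCATTCCA")
  expect_identical(u$sequence, c("TTCCA", "ATCCA", "TTCCA"))
  expect_identical(u$edit_class, c(0L, 1L, 0L))

  # a 1-bp deletion is absorbed by one length-4 frameshift unit
  u <- decompose_array("TTCCATTCATTCCA")
  expect_identical(u$sequence, c("TTCCA", "TTCA", "TTCCA"))
  expect_identical(u$is_frameshift, c(FALSE, TRUE, FALSE))
  expect_identical(attr(u, "total_cost"), 1)
  expect_identical(oracle_tiling_enumerate("TTCCATTCATTCCA"), 1)
})

test_that("perfect arrays decompose to n class-0 units for many n", {
  for (n in c(1, 2, 7, 50, 713)) {
    u <- decompose_array(strrep("TTCCA", n))
    expect_identical(nrow(u), as.integer(n))
    expect_true(all(u$edit_class == 0L))
    expect_identical(attr(u, "total_cost"), 0)
  }
})

test_that("DP cost equals the suffix-recursion oracle on random sequences", {
  set.seed(401)
  for (rep in 1:250) {
    n <- sample(3:40, 1)
    s <- if (rep %% 2 == 0) random_seq(n) else
      substr(random_arrayish(ceiling(n / 5) + 1, noise = 0.25), 1, n)
    u <- decompose_array(s)
    expect_identical(sum(u$length), nchar(s))          # tiling conservation
    expect_identical(u$start, cumsum(c(1L, head(u$length, -1))))  # no gaps/overlaps
    expect_equal(attr(u, "total_cost"), oracle_tiling_cost(s))
  }
})

test_that("DP cost equals exhaustive tiling enumeration on short sequences", {
  set.seed(402)
  for (rep in 1:80) {
    n <- sample(3:15, 1)
    s <- random_seq(n)
    expect_equal(attr(decompose_array(s), "total_cost"),
                 oracle_tiling_enumerate(s))
  }
})

test_that("decomposition is deterministic and respects parameter bounds", {
  set.seed(403)
  s <- random_arrayish(30, noise = 0.2)
  expect_identical(decompose_array(s), decompose_array(s))
  expect_error(decompose_array("TT"), "shorter than min_len")
  expect_error(decomposition_params(consensus = "TTCC"), "length 5")
  # custom penalty discourages non-pentamer units
  u <- decompose_array("TTCCATTCATTCCA",
                       decomposition_params(length_penalty = 0.1))
  expect_identical(sum(u$length), 14L)
})

test_that("profiles recover generator ground truth exactly for mildly diverged arrays", {
  # frame recovery is exact (no indels, units within 1 substitution of
  # TTCCA): every unit remains the cheapest segmentation of itself
  for (seed in c(11, 12)) {
    spec <- array_spec(unit_count = 400,
                       class_spectrum = c(0.45, 0.55, 0, 0, 0, 0),
                       seed = seed)
    arr <- generate_array(spec)
    prof <- build_profile(decompose_array(arr$sequence))
    truth <- tabulate(arr$truth$classes + 1L, nbins = 6)
    expect_identical(prof$ttcca_count, truth[1])
    expect_identical(prof$class1, truth[2])
    expect_identical(prof$frameshift_units, 0L)
    expect_identical(prof$total_units, 400L)
    # per-derivative counts match direct tabulation of the true units
    singles <- arr$truth$units[arr$truth$classes == 1L]
    expect_identical(prof$single_bp,
                     setNames(as.integer(table(factor(singles,
                       levels = single_bp_derivatives()))),
                       single_bp_derivatives()))
  }
})

test_that("full-spectrum arrays are recovered near-exactly and never over cost", {
  # pentamers 3+ substitutions away from TTCCA are close to arbitrary
  # DNA, so minimum-cost tiling may re-frame a few of them; class counts
  # still track the truth to within ~2% of units and the DP tiling can
  # never cost more than the generating segmentation
  for (seed in c(13, 14)) {
    arr <- generate_array(array_spec(unit_count = 710, seed = seed))
    units <- decompose_array(arr$sequence)
    prof <- build_profile(units)
    truth <- tabulate(arr$truth$classes + 1L, nbins = 6)
    got <- c(prof$ttcca_count, prof$class1, prof$class2, prof$class3,
             prof$class4, prof$class5)
    expect_true(all(abs(got - truth) <= 0.025 * 710))
    expect_lte(attr(units, "total_cost"), sum(arr$truth$classes))
  }
})

test_that("build_profile enforces tiling and aggregates singles into class 1", {
  u <- decompose_array(strrep("TTCCA", 20))
  p <- build_profile(u)
  expect_identical(p$ttcca_count, 20L)
  expect_identical(p$class1 + p$class2 + p$class3 + p$class4 + p$class5, 0L)

  broken <- as.data.frame(u)[-2, ]
  expect_error(build_profile(broken, sequence_length = 100L), "tile")

  p2 <- profile_from_counts(ttcca = 10,
                            single_bp = setNames(rep(1L, 15),
                                                 single_bp_derivatives()),
                            class2 = 2, class3 = 1, class4 = 0, class5 = 0)
  expect_identical(p2$class1, 15L)
  expect_identical(p2$total_units, 28L)
  expect_error(profile_from_counts(1, setNames(rep(1L, 15),
                                               c(single_bp_derivatives()[-1], "TTCCA")),
                                   0, 0, 0, 0),
               "Hamming-1")
})

test_that("compare_profiles reports signed per-row differences", {
  profs <- reported_profiles()
  cmp_same <- compare_profiles(profs$MZT1a, profs$MZT1a)
  expect_true(all(cmp_same$difference == 0))
  expect_false(any(cmp_same$changed))

  cmp <- compare_profiles(profs$MZT1a, profs$MZT1b)
  expect_identical(cmp$difference[cmp$row == "TTCCA"], 9L)  # 235 vs 226

  # synthetic pair: one class-1 unit reverted to TTCCA changes exactly
  # the TTCCA row, the class-1 aggregate, one derivative row, and totals
  singles <- setNames(rep(2L, 15), single_bp_derivatives())
  a <- profile_from_counts(100, singles, 5, 2, 1, 0)
  singles_b <- singles; singles_b[["TTCGA"]] <- 1L
  b <- profile_from_counts(101, singles_b, 5, 2, 1, 0)
  cmp2 <- compare_profiles(a, b)
  changed <- cmp2$row[cmp2$changed]
  expect_setequal(changed, c("TTCCA", "1 bp derivatives", "TTCGA"))
  expect_identical(cmp2$difference[cmp2$row == "TTCCA"], -1L)
  expect_identical(cmp2$difference[cmp2$row == "TTCGA"], 1L)
})
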