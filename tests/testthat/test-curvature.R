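test_that("curvature_at matches the complex-sum oracle and handles edge cases", {
  steps16 <- dinucleotide_steps()
  zero_tab <- roll_tilt_table(stats::setNames(numeric(16), steps16),
                              stats::setNames(numeric(16), steps16))
  p <- curvature_params()
  expect_equal(curvature_at(rep("AA", 10), zero_tab, p), 0)

  one_tab <- roll_tilt_table(stats::setNames(rep(1, 16), steps16),
                             stats::setNames(numeric(16), steps16))
  expect_equal(curvature_at(rep("GC", 10), one_tab, p),
               (10.4 / 10) * Mod(sum(exp(2i * pi * (0:9) / 10.4))),
               tolerance = 1e-12)

  # random windows over random tables and window widths
  for (seed in 1:25) {
    tab <- random_table(seed)
    set.seed(seed + 100)
    W <- sample(5:30, 1)
    steps <- sample(steps16, W, replace = TRUE)
    pp <- curvature_params(window = W)
    expect_equal(curvature_at(steps, tab, pp),
                 curvature_oracle(steps, tab, 10.4, W), tolerance = 1e-12)
  }

  expect_error(curvature_at(rep("AA", 9), zero_tab, p), "10 steps")
  bad <- c(rep("AA", 9), "XX")
  expect_error(curvature_at(bad, zero_tab, p), "unknown")
})

test_that("in-phase bending gives a larger modulus than any permutation", {
  p <- curvature_params()
  j <- 0:9
  # with the phase factor exp(+2*pi*i*j/nu0) and the step term rho - i*tau,
  # coherent (in-phase) bending needs rho_j = cos(theta_j), tau_j = +sin(theta_j)
  roll <- cos(2 * pi * j / 10.4)
  tilt <- sin(2 * pi * j / 10.4)
  # per-step table: use 10 distinct steps carrying the phased angles
  steps16 <- dinucleotide_steps()
  steps <- steps16[1:10]
  tab <- roll_tilt_table(
    stats::setNames(c(roll, numeric(6)), c(steps, steps16[11:16])),
    stats::setNames(c(tilt, numeric(6)), c(steps, steps16[11:16])))
  inphase <- curvature_at(steps, tab, p)
  set.seed(4)
  for (i in 1:100) {
    perm <- sample(steps)
    if (identical(perm, steps)) next
    expect_lt(curvature_at(perm, tab, p), inphase)
  }
})

test_that("curvature scales linearly in the roll/tilt angles", {
  tab <- random_table(7)
  k <- 3.25
  tab_k <- roll_tilt_table(tab$roll * k, tab$tilt * k)
  set.seed(7)
  steps <- sample(dinucleotide_steps(), 10, replace = TRUE)
  expect_equal(curvature_at(steps, tab_k, curvature_params()),
               k * curvature_at(steps, tab, curvature_params()))
  seq <- random_genome(200, seed = 3)
  expect_equal(curvature_curve(seq, tab_k)$values,
               k * curvature_curve(seq, tab)$values)
})

test_that("curvature_curve matches the per-window oracle and assigns centers", {
  tab <- random_table(11)
  p <- curvature_params()
  seq <- random_genome(30, seed = 5)
  curve <- curvature_curve(seq, tab, p)
  expect_equal(length(curve$values), 30L - 10L)
  expect_equal(curve$start, 5L)
  chars <- strsplit(seq$seq, "")[[1]]
  steps_all <- paste0(chars[-30], chars[-1])
  for (k in seq_along(curve$values)) {
    expect_equal(curve$values[k],
                 curvature_oracle(steps_all[k:(k + 9)], tab, 10.4, 10),
                 tolerance = 1e-12)
  }

  polyA <- genome_sequence("a", strrep("A", 50))
  cvA <- curvature_curve(polyA, tab, p)
  expect_equal(length(unique(round(cvA$values, 12))), 1L)

  expect_error(curvature_curve(genome_sequence("s", "ACGTACGTAC"), tab, p),
               "shorter")
})

test_that("windows overlapping N are masked and flanking N only pads", {
  tab <- random_table(2)
  core <- random_genome(40, seed = 8)
  padded <- genome_sequence("p", paste0("NNNNN", core$seq, "NNNNN"))
  cv_core <- curvature_curve(core, tab)
  cv_pad <- curvature_curve(padded, tab)
  expect_true(any(cv_pad$mask))
  expect_false(any(cv_core$mask))
  # unmasked interior values agree after aligning genomic positions
  pos_core <- track_positions(cv_core) + 5L
  pos_pad <- track_positions(cv_pad)
  common <- intersect(pos_core, pos_pad[!cv_pad$mask])
  expect_gt(length(common), 20L)
  expect_equal(cv_pad$values[match(common, pos_pad)],
               cv_core$values[match(common, pos_core)])
  expect_true(all(cv_pad$values[cv_pad$mask] == 0))
})

test_that("reverse complement reverses the curve under a strand-symmetric table", {
  tab <- random_symmetric_table(13)
  seq <- random_genome(80, seed = 21)
  rc <- genome_sequence("rc", revcomp(seq$seq))
  expect_equal(curvature_curve(rc, tab)$values,
               rev(curvature_curve(seq, tab)$values), tolerance = 1e-12)
  # also holds for the shipped default table
  expect_equal(curvature_curve(rc, default_roll_tilt())$values,
               rev(curvature_curve(seq, default_roll_tilt())$values),
               tolerance = 1e-12)
})

test_that("build_pattern averages per-sequence curves then normalizes", {
  tab <- random_table(17)
  s1 <- random_genome(146, seed = 31, chrom = "s1")
  s2 <- random_genome(146, seed = 32, chrom = "s2")
  p1 <- build_pattern(list(s1), tab)
  expect_equal(sum(p1$values^2), 1, tolerance = 1e-12)
  expect_equal(mean(p1$values), 0, tolerance = 1e-12)
  c1 <- curvature_curve(s1, tab)$values
  expect_equal(p1$values, (c1 - mean(c1)) / sqrt(sum((c1 - mean(c1))^2)))

  expect_equal(build_pattern(list(s1, s1, s1), tab)$values, p1$values)

  p12 <- build_pattern(list(s1, s2), tab)
  c2 <- curvature_curve(s2, tab)$values
  m <- (c1 + c2) / 2
  expect_equal(p12$values, (m - mean(m)) / sqrt(sum((m - mean(m))^2)))

  expect_error(build_pattern(list(s1, random_genome(147, seed = 1)), tab),
               "same length")
})

test_that("idealized pattern is symmetric, normalized, end-heavy", {
  pat <- idealized_pattern()
  v <- pat$values
  L <- length(v)
  expect_equal(L, 147L)
  expect_equal(pat$dyad_index, 73L)
  expect_equal(v, rev(v), tolerance = 1e-12)
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  raw <- idealized_pattern(normalize = FALSE)$values
  ends <- c(1:50, 98:147)
  expect_gt(mean(raw[ends]), mean(raw[51:97]))
})

test_that("curvature_profile is an exact matched filter", {
  pat <- idealized_pattern()
  # identity: pattern embedded in zeros peaks at the embedding dyad
  n <- 600
  at <- 250L  # embedding start (0-based track position)
  vals <- numeric(n)
  vals[(at + 1):(at + length(pat$values))] <- pat$values
  curve <- score_track("c", 0L, vals)
  prof <- curvature_profile(curve, pat)
  expect_equal(track_positions(prof)[which.max(prof$values)],
               at + pat$dyad_index)
  expect_equal(max(prof$values), 1, tolerance = 1e-9)

  # constant offsets are invisible to the zero-mean pattern
  prof_c <- curvature_profile(score_track("c", 0L, vals + 11.5), pat)
  expect_equal(prof_c$values, prof$values, tolerance = 1e-9)

  # every value equals the explicit sliding dot product on a random curve
  set.seed(77)
  rv <- stats::rnorm(500)
  rcurve <- score_track("c", 0L, rv)
  rprof <- curvature_profile(rcurve, pat)
  L <- length(pat$values)
  oracle <- vapply(seq_len(500 - L + 1), function(k) {
    sum(rv[k:(k + L - 1)] * pat$values)
  }, 0)
  expect_equal(rprof$values, oracle, tolerance = 1e-9)
  expect_equal(rprof$start, pat$dyad_index)

  expect_error(curvature_profile(score_track("c", 0L, numeric(100)), pat),
               "shorter")
})
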