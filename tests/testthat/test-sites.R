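test_that("anchored_profile aligns, flips minus-strand windows and averages", {
  tr <- score_track("c", 0L, as.numeric(1:101))
  one <- data.frame(chrom = "c", pos = 50L, strand = "+", label = "")
  p <- anchored_profile(tr, one, flank = 10)
  expect_equal(p$mean_signal, as.numeric(41:61))
  expect_equal(p$offset, -10:10)

  minus <- data.frame(chrom = "c", pos = 50L, strand = "-", label = "")
  pm <- anchored_profile(tr, minus, flank = 10)
  expect_equal(pm$mean_signal, as.numeric(61:41))

  two <- rbind(one, one)
  p2 <- anchored_profile(tr, two, flank = 10)
  expect_equal(p2$mean_signal, p$mean_signal)
  expect_true(all(p2$n_sites == 2L))
})

test_that("anchored_profile is linear in the track for raw scaling", {
  set.seed(5)
  tr <- score_track("c", 0L, stats::rnorm(400))
  a <- data.frame(chrom = "c", pos = c(100L, 250L), strand = c("+", "-"),
                  label = "")
  p1 <- anchored_profile(tr, a, 30)
  p3 <- anchored_profile(score_track("c", 0L, 3 * tr$values), a, 30)
  expect_equal(p3$mean_signal, 3 * p1$mean_signal)
})

test_that("edge-truncated sites contribute only covered offsets", {
  tr <- score_track("c", 0L, as.numeric(1:50))
  a <- data.frame(chrom = "c", pos = c(5L, 25L), strand = "+", label = "")
  p <- anchored_profile(tr, a, 10)
  expect_equal(p$n_sites[1], 1L)            # offset -10 covered only by pos 25
  expect_equal(p$n_sites[11], 2L)
  ps <- anchored_profile(tr, a, 10, strict = TRUE)
  expect_true(all(ps$n_sites == 1L))
  expect_equal(ps$mean_signal, as.numeric(16:36))
})

test_that("z-scored averaging standardizes each site before pooling", {
  tr <- score_track("c", 0L, c(rep(0, 40), 1:21, rep(0, 40)))
  a <- data.frame(chrom = "c", pos = 50L, strand = "+", label = "")
  p <- anchored_profile(tr, a, 10, scale_mode = "zscore")
  w <- as.numeric(1:21)
  expect_equal(p$mean_signal, (w - mean(w)) / stats::sd(w))
})

test_that("classify_tss separates clear occupancy classes and is stable", {
  n <- 10
  stride <- 500L
  pos <- 200L + stride * (0:(n - 1))
  x <- numeric(max(pos) + 300)
  for (i in seq_len(n)) {
    if (i <= 5) x[pos[i] + (-150:50) + 1L] <- 10
  }
  tr <- score_track("c", 0L, x)
  a <- data.frame(chrom = "c", pos = pos, strand = "+", label = "t")
  cls <- classify_tss(tr, a, seed = 42)
  expect_equal(cls$class, rep(c("I", "II"), each = 5))
  # invariant to site ordering
  perm <- sample(n)
  cls2 <- classify_tss(tr, a[perm, ], seed = 42)
  expect_equal(cls2$class, cls$class[perm])

  expect_warning(
    same <- classify_tss(score_track("c", 0L, rep(2, 3000)),
                         data.frame(chrom = "c", pos = c(500L, 1500L, 2500L),
                                    strand = "+", label = ""), seed = 1),
    "identical")
  expect_equal(length(unique(same$class)), 1L)
})

test_that("classify_tss recovers generator labels on the synthetic fixture", {
  fx <- tss_class_fixture(60, flank = 200L, seed = 9, noise_sd = 0)
  cls <- classify_tss(fx$track, fx$anchors, seed = 5)
  truth <- ifelse(fx$truth$labels == "occupied", "I", "II")
  expect_equal(cls$class, truth)
})

test_that("dinucleotide fraction profiles respect class membership and strand", {
  g <- genome_sequence("c", strrep("A", 101))
  a <- data.frame(chrom = "c", pos = 50L, strand = "+", label = "")
  ww <- dinucleotide_fraction_profile(g, a, 20, "WW")
  expect_true(all(ww$mean_signal == 1))

  g2 <- genome_sequence("c", strrep("AC", 51))
  ww2 <- dinucleotide_fraction_profile(g2, a, 20, "WW")
  expect_true(all(ww2$mean_signal == 0))

  # WW + SS + mixed partition the dinucleotide space
  g3 <- random_genome(301, seed = 4, chrom = "c")
  a3 <- data.frame(chrom = "c", pos = 150L, strand = c("+", "-"), label = "")
  ww3 <- dinucleotide_fraction_profile(g3, a3, 40, "WW")
  ss3 <- dinucleotide_fraction_profile(g3, a3, 40, "SS")
  expect_true(all(ww3$mean_signal + ss3$mean_signal <= 1 + 1e-12))
  expect_true(all(ww3$mean_signal >= 0 & ss3$mean_signal >= 0))
})

test_that("minus-strand sites contribute reverse-complement windows", {
  # place a WW dinucleotide asymmetrically so strand flipping is visible
  seq <- paste0(strrep("C", 48), "AACC", strrep("C", 48))  # AA at 0-based 48
  g <- genome_sequence("c", seq)
  plus <- data.frame(chrom = "c", pos = 50L, strand = "+", label = "")
  minus <- data.frame(chrom = "c", pos = 50L, strand = "-", label = "")
  wp <- dinucleotide_fraction_profile(g, plus, 10, "WW")
  wm <- dinucleotide_fraction_profile(g, minus, 10, "WW")
  expect_equal(wp$mean_signal[wp$offset == -2], 1)   # AA starts at offset -2
  expect_equal(wm$mean_signal[wm$offset == 1], 1)    # rc: TT starts at offset +1
})

test_that("polytract profile flags only pure runs of the minimum length", {
  g <- genome_sequence("c", "AAAATCGC")
  a <- data.frame(chrom = "c", pos = 3L, strand = "+", label = "")
  p <- polytract_fraction_profile(g, a, 3, min_run = 4)
  expect_equal(p$mean_signal, c(1, 1, 1, 1, 0, 0, 0))

  p1 <- polytract_fraction_profile(g, a, 3, min_run = 1)
  expect_equal(p1$mean_signal, c(1, 1, 1, 1, 1, 0, 0))

  g2 <- genome_sequence("c", "CCAATTCC")
  a2 <- data.frame(chrom = "c", pos = 3L, strand = "+", label = "")
  p2 <- polytract_fraction_profile(g2, a2, 3, min_run = 4)
  expect_true(all(p2$mean_signal == 0))
})
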