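test_that("overlap_ratio reproduces the printed formula", {
  expect_equal(overlap_ratio(0), 146 / 147)
  expect_equal(overlap_ratio(73), 73 / 147)
  r <- overlap_ratio(0:73)
  expect_true(all(diff(r) < 0))
  expect_error(overlap_ratio(74), "deviation")
  expect_error(overlap_ratio(-1), "deviation")
})

test_that("matching_ratio counts references with a close-enough prediction", {
  ref <- c(100, 300, 500)
  pred <- c(110, 480)
  expect_equal(matching_ratio(ref, pred, 10), 1 / 3)
  expect_equal(matching_ratio(ref, pred, 20), 2 / 3)
  expect_equal(matching_ratio(ref, ref, 0), 1)
  expect_equal(matching_ratio(ref, numeric(0), 50), 0)
  expect_error(matching_ratio(numeric(0), pred, 10), "empty")
})

test_that("adding predictions never lowers the any-within matching ratio", {
  set.seed(31)
  ref <- sort(sample(1e5, 300))
  pred <- sort(sample(1e5, 200))
  extra <- sort(c(pred, sample(1e5, 100)))
  for (d in c(5, 20, 60)) {
    expect_gte(matching_ratio(ref, extra, d), matching_ratio(ref, pred, d))
  }
})

test_that("match_curve equals the exhaustive pairwise oracle and is monotone", {
  expect_equal(match_curve(c(1, 2, 3), c(1, 2, 3))$matching_ratio, rep(1, 60))

  ref <- seq(1000, 9000, 500)
  mc <- match_curve(ref, ref + 30)
  expect_equal(mc$matching_ratio, rep(c(0, 1), c(29, 31)))

  set.seed(8)
  ref2 <- sort(sample(1e5, 400))
  pred2 <- sort(sample(1e5, 350))
  mc2 <- match_curve(ref2, pred2)
  oracle <- vapply(1:60, function(d) {
    mean(vapply(ref2, function(r) any(abs(pred2 - r) <= d), TRUE))
  }, 0)
  expect_equal(mc2$matching_ratio, oracle)
  expect_true(all(diff(mc2$matching_ratio) >= 0))
})

test_that("one-to-one matching is never more generous than any-within", {
  set.seed(14)
  ref <- sort(sample(5e4, 150))
  pred <- sort(sample(5e4, 150))
  for (d in c(10, 40)) {
    expect_lte(matching_ratio(ref, pred, d, one_to_one = TRUE),
               matching_ratio(ref, pred, d))
  }
  # a single prediction can match only one reference in one-to-one mode
  expect_equal(matching_ratio(c(100, 110), 105, 10, one_to_one = TRUE), 0.5)
  expect_equal(matching_ratio(c(100, 110), 105, 10), 1)
})

test_that("hexamer occupancy classifies occurrences by full containment", {
  g <- genome_sequence("c", "AAAAAATTTTTT")
  tab <- hexamer_occupancy(g, toy_calls("c", 0L, 6L))
  expect_equal(tab$occupancy_ratio[tab$hexamer == "AAAAAA"], 1)
  expect_equal(tab$occupancy_ratio[tab$hexamer == "ATTTTT"], 0)
  expect_equal(tab$total_count[tab$hexamer == "AAAAAT"], 1L)
  expect_false(tab$present[tab$hexamer == "CCCCCC"])

  none <- hexamer_occupancy(g, nucleosome_calls("c", integer(0), numeric(0)))
  expect_true(all(none$occupancy_ratio[none$present] == 0))

  full <- hexamer_occupancy(g, toy_calls("c", 0L, 12L))
  expect_true(all(full$occupancy_ratio[full$present] == 1))
  expect_true(all(full$occupied_count <= full$total_count))
})

test_that("hexamer counts skip N windows and match an interval oracle", {
  set.seed(6)
  g <- random_genome(500, seed = 6, chrom = "c")
  gN <- genome_sequence("c", paste0(substr(g$seq, 1, 200), "N",
                                    substr(g$seq, 202, 500)))
  calls <- toy_calls("c", c(50L, 300L), c(197L, 447L))
  tab <- hexamer_occupancy(gN, calls)
  # independent oracle: enumerate positions directly
  chars <- strsplit(gN$seq, "")[[1]]
  total_o <- integer(4096); occ_o <- integer(4096)
  for (q in 0:(500 - 6)) {
    hx <- paste(chars[(q + 1):(q + 6)], collapse = "")
    if (grepl("N", hx)) next
    i <- match(hx, hexamers())
    total_o[i] <- total_o[i] + 1L
    if (any(calls$start <= q & q + 6 <= calls$end)) occ_o[i] <- occ_o[i] + 1L
  }
  expect_equal(tab$total_count, total_o)
  expect_equal(tab$occupied_count, occ_o)
})

test_that("occupancy correlation follows the textbook Pearson formula", {
  mk <- function(ratios) {
    n <- length(ratios)
    df <- data.frame(hexamer = hexamers()[1:4096],
                     total_count = c(rep(10L, n), rep(0L, 4096 - n)),
                     occupied_count = 0L,
                     occupancy_ratio = c(ratios, rep(NA_real_, 4096 - n)),
                     free_ratio = NA_real_,
                     present = c(rep(TRUE, n), rep(FALSE, 4096 - n)))
    class(df) <- c("hexamer_table", "data.frame")
    df
  }
  a <- c(0.1, 0.4, 0.8, 0.3)
  b <- c(0.2, 0.5, 0.6, 0.1)
  pearson <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(occupancy_correlation(mk(a), mk(b)), pearson, tolerance = 1e-12)
  expect_equal(occupancy_correlation(mk(a), mk(a)), 1)
  expect_equal(occupancy_correlation(mk(a), mk(1 - a)), -1)
  expect_error(occupancy_correlation(mk(a[1:2]), mk(b[1:2])), "fewer than 3")
})
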