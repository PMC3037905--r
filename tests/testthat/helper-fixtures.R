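# Shared test helpers: small constructed tables and scoring utilities.
# Roll/tilt tables used in tests are always built explicitly here, never
# taken from the package's default table's specific values.

# A random but strand-symmetric roll/tilt table: complementary steps share
# roll and negate tilt (self-complementary steps get tilt 0).
random_symmetric_table <- function(seed = 1) {
  set.seed(seed)
  steps <- dinucleotide_steps()
  rc_step <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  roll <- stats::setNames(numeric(16), steps)
  tilt <- stats::setNames(numeric(16), steps)
  done <- character(0)
  for (s in steps) {
    if (s %in% done) next
    r <- rc_step(s)
    roll[s] <- roll[r] <- stats::runif(1, -8, 8)
    if (s == r) {
      tilt[s] <- 0
    } else {
      tilt[s] <- stats::runif(1, -3, 3)
      tilt[r] <- -tilt[s]
    }
    done <- c(done, s, r)
  }
  roll_tilt_table(roll, tilt)
}

# Fully random (not strand-symmetric) table.
random_table <- function(seed = 1) {
  set.seed(seed)
  steps <- dinucleotide_steps()
  roll_tilt_table(stats::setNames(stats::runif(16, -8, 8), steps),
                  stats::setNames(stats::runif(16, -3, 3), steps))
}

# Independent brute-force oracle for the curvature modulus.
curvature_oracle <- function(steps, table, nu0, W) {
  acc <- 0 + 0i
  for (j in seq_along(steps) - 1) {
    s <- steps[j + 1]
    acc <- acc + complex(real = table$roll[s], imaginary = -table$tilt[s]) *
      exp(2i * pi * j / nu0)
  }
  Mod(nu0 / W * acc)
}

# Recovery / false-call fractions of a call set against planted truth.
score_calls <- function(calls, truth, tol) {
  rec <- mean(vapply(truth, function(d) any(abs(calls$dyad - d) <= tol), TRUE))
  fdr <- if (nrow(calls) > 0) {
    mean(vapply(calls$dyad, function(d) !any(abs(truth - d) <= tol), TRUE))
  } else 0
  list(recovery = rec, false_rate = fdr, n = nrow(calls))
}

# Fabricate a call set with arbitrary intervals (for occupancy toys where
# the 147-bp geometry is irrelevant).
toy_calls <- function(chrom, start, end) {
  df <- data.frame(chrom = chrom, dyad = (start + end) %/% 2L,
                   score = 1, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(df) <- c("nucleosome_calls", "data.frame")
  df
}

write_lines_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
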