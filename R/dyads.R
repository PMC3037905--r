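#' MSCWT peak-calling parameters
#'
#' @param scales Ascending wavelet scales in bp; default `seq(25, 100, 5)`,
#'   bracketing half to two-thirds of the 147-bp nucleosome footprint.
#' @param min_distance Minimum separation between accepted dyads in bp;
#'   default 100 (below the 147-bp core, since neighbouring calls may
#'   overlap at large deviations).
#' @param threshold_quantile Quantile of the wavelet spectrum a local
#'   maximum must exceed to be considered; default 0.70. A quantile is used
#'   because matched-filter profiles are in arbitrary units.
#' @return An `mscwt_params` list.
#' @export
mscwt_params <- function(scales = seq(25, 100, by = 5), min_distance = 100L,
                         threshold_quantile = 0.70) {
  scales <- as.numeric(scales)
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be positive and strictly ascending")
  }
  min_distance <- as.integer(min_distance)
  if (min_distance < 1L) stop("min_distance must be >= 1")
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    stop("threshold_quantile must be in (0, 1)")
  }
  structure(list(scales = scales, min_distance = min_distance,
                 threshold_quantile = threshold_quantile),
            class = "mscwt_params")
}

# Mexican-hat (Ricker) mother wavelet, standard L2 normalization.
.ricker <- function(t) {
  (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
}

# Same-length convolution of x with a symmetric kernel via FFT. The signal
# is extended at both ends by replicating the edge value, so a zero-mean
# kernel (Mexican hat) maps constant tracks to exactly zero everywhere —
# no spurious edge response from implicit zero padding. FFT length is a
# power of two so the transform stays fast for arbitrary track sizes.
.conv_same <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  h <- (m - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], m - 1L - h))
  np <- length(xp)
  N <- stats::nextn(np + m - 1L, 2L)
  fx <- stats::fft(c(xp, numeric(N - np)))
  fk <- stats::fft(c(kernel, numeric(N - m)))
  full <- Re(stats::fft(fx * fk, inverse = TRUE)) / N
  full[(2L * h + 1L):(2L * h + n)]
}

#' Maximal spectrum of the continuous wavelet transform
#'
#' Computes the continuous wavelet transform of the track with a Mexican-hat
#' mother wavelet at each requested scale and keeps, per position, the
#' maximum coefficient over scales ("maximal spectrum", MSCWT). The
#' zero-mean wavelet removes baseline; taking the max over a scale range
#' sharpens peaks of nucleosome-sized support regardless of their exact
#' width.
#'
#' @param track A [score_track] (curvature profile or reference occupancy
#'   signal); length must exceed `2 * max(scales)`.
#' @param params An [mscwt_params].
#' @return A [score_track] of the same length and start.
#' @export
mscwt_spectrum <- function(track, params = mscwt_params()) {
  stopifnot(inherits(track, "score_track"))
  x <- track$values
  if (length(x) <= 2 * max(params$scales)) {
    stop("track too short for the largest wavelet scale")
  }
  # the Mexican hat is zero-mean, so the track mean is invisible in exact
  # arithmetic; subtracting it up front makes that exact in floating point
  # (a constant track maps to an identically zero spectrum)
  x <- x - mean(x)
  spec <- rep(-Inf, length(x))
  for (a in params$scales) {
    half <- ceiling(5 * a)
    t <- (-half:half) / a
    kernel <- .ricker(t) / sqrt(a)
    spec <- pmax(spec, .conv_same(x, kernel))
  }
  score_track(track$chrom, track$start, spec)
}

#' Construct a nucleosome call set
#'
#' @param chrom Chromosome identifier (recycled).
#' @param dyad Integer vector of 0-based dyad positions.
#' @param score Numeric score per call.
#' @return A data.frame of class `nucleosome_calls` with columns `chrom`,
#'   `dyad`, `score`, `start` (`dyad - 73`) and `end` (`dyad + 74`), sorted
#'   by dyad.
#' @export
nucleosome_calls <- function(chrom, dyad, score) {
  dyad <- as.integer(dyad)
  df <- data.frame(chrom = as.character(rep_len(chrom, length(dyad))),
                   dyad = dyad, score = as.numeric(score),
                   start = dyad - 73L, end = dyad + 74L,
                   stringsAsFactors = FALSE)
  df <- df[order(df$dyad), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("nucleosome_calls", "data.frame")
  df
}

#' Detect nucleosome dyads from a score track
#'
#' Runs [mscwt_spectrum], finds its strict local maxima above the
#' `threshold_quantile` spectrum quantile, and accepts them greedily in
#' descending spectrum order subject to the `min_distance` exclusion
#' (ties broken leftmost). Accepted positions whose 147-bp nucleosome
#' interval would extend past the track are dropped. The reported score is
#' the input track's value at the dyad.
#'
#' @param track A [score_track], typically a curvature profile.
#' @param params An [mscwt_params].
#' @param chrom Optional chromosome name override (default the track's).
#' @return A `nucleosome_calls` data.frame sorted by dyad.
#' @export
detect_dyads <- function(track, params = mscwt_params(), chrom = track$chrom) {
  spec <- mscwt_spectrum(track, params)
  s <- spec$values
  n <- length(s)
  thr <- stats::quantile(s, params$threshold_quantile, names = FALSE)
  # numerical floor: a quantile of an (almost) everywhere-zero spectrum is
  # floating-point dust; a real peak must also rise above it relative to
  # the global maximum
  floor_ <- 1e-8 * max(abs(s))
  # strict rise on the left, non-strict on the right: the leftmost point of
  # a plateau is the representative maximum
  i <- 2:(n - 1L)
  is_max <- s[i] > s[i - 1L] & s[i] >= s[i + 1L] & s[i] > thr & s[i] > floor_
  cand <- i[is_max]
  if (length(cand) == 0L) return(nucleosome_calls(chrom, integer(0), numeric(0)))
  cand <- cand[order(-s[cand], cand)]
  accepted <- integer(0)
  for (p in cand) {
    if (length(accepted) == 0L || all(abs(accepted - p) >= params$min_distance)) {
      accepted <- c(accepted, p)
    }
  }
  dyads <- track$start + accepted - 1L
  keep <- (dyads - 73L >= track$start) & (dyads + 74L <= track$start + n)
  dyads <- dyads[keep]
  nucleosome_calls(chrom, dyads, track$values[accepted[keep]])
}

#' Spacing statistics of a call set
#'
#' Centre-to-centre (dyad-to-dyad) distances between consecutive calls.
#'
#' @param callset A `nucleosome_calls` data.frame.
#' @param binwidth Histogram bin width in bp (default 10).
#' @return A list with `n_pairs`, `mean`, `median`, and `histogram` (a
#'   data.frame of bin lower bounds and counts). With fewer than 2 calls,
#'   `n_pairs` is 0 and the summary is flagged `empty = TRUE`.
#' @export
spacing_stats <- function(callset, binwidth = 10L) {
  stopifnot(inherits(callset, "nucleosome_calls"))
  if (nrow(callset) < 2L) {
    return(list(empty = TRUE, n_pairs = 0L, mean = NA_real_, median = NA_real_,
                histogram = data.frame(bin = numeric(0), count = integer(0))))
  }
  d <- diff(sort(callset$dyad))
  bins <- floor(d / binwidth) * binwidth
  tab <- table(bins)
  list(empty = FALSE, n_pairs = length(d), mean = mean(d), median = stats::median(d),
       histogram = data.frame(bin = as.numeric(names(tab)),
                              count = as.integer(tab)))
}
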