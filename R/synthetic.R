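# Seeded synthetic-fixture generators: every stage of the pipeline is
# testable against known ground truth without genome downloads. Each
# generator is a pure function of its parameters and seed.

#' Random genome sequence
#'
#' I.i.d. bases with the requested GC fraction split evenly between G and C
#' (and AT evenly between A and T).
#'
#' @param length Sequence length in bp.
#' @param gc_fraction P(G) + P(C), in [0, 1] (default 0.5).
#' @param seed Integer seed.
#' @param chrom Sequence name.
#' @return A [genome_sequence].
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = 1L, chrom = "synth") {
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  genome_sequence(chrom, paste(sample(names(p), length, replace = TRUE, prob = p),
                               collapse = ""))
}

#' Plant a signal template at known dyads in a noisy track
#'
#' Zero baseline plus the template — rescaled to unit peak amplitude, its
#' unit-L2 normalization undone — centered at each dyad, plus i.i.d.
#' Gaussian noise, so `amplitude / noise_sd` is the fixture's SNR. The
#' canonical use plants the model's own (zero-mean) curvature template and
#' recovers the dyads with the matched filter plus MSCWT.
#'
#' @param length Track length.
#' @param pattern A `curvature_pattern` (or numeric vector) to plant; its
#'   `dyad_index` aligns with each planted dyad. Values are scaled so
#'   `max(abs(values))` equals `amplitude`.
#' @param dyads Sorted 0-based dyad positions; at least a template
#'   half-length from both ends and pairwise >= 147 bp apart.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param amplitude Planted peak amplitude (default 1).
#' @param chrom Track name.
#' @return A list with `track` (a [score_track]) and `truth` (a
#'   `fixture_truth` list recording `dyads` and all generation parameters).
#' @export
plant_signal_pattern <- function(length, pattern, dyads, noise_sd = 0, seed = 1L,
                                 amplitude = 1, chrom = "synth") {
  if (is.numeric(pattern)) pattern <- curvature_pattern(pattern)
  vals <- pattern$values
  vals <- amplitude * vals / max(abs(vals))
  L <- base::length(vals)
  dyads <- as.integer(sort(dyads))
  lo <- dyads - pattern$dyad_index
  hi <- lo + L - 1L
  if (any(lo < 0L) || any(hi > length - 1L)) {
    stop("a dyad is closer to a track end than the template half-length")
  }
  if (base::length(dyads) > 1L && any(diff(dyads) < 147L)) {
    stop("planted dyads must be at least 147 bp apart")
  }
  set.seed(seed)
  x <- numeric(length)
  for (k in seq_along(dyads)) {
    idx <- (lo[k] + 1L):(hi[k] + 1L)
    x[idx] <- x[idx] + vals
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length, sd = noise_sd)
  list(track = score_track(chrom, 0L, x),
       truth = structure(list(dyads = dyads, seed = seed, length = length,
                              noise_sd = noise_sd, template_length = L),
                         class = "fixture_truth"))
}

#' Plant nucleosome-favoring sequence cassettes in a random genome
#'
#' Builds a random-background sequence with 147-bp nucleosome cassettes at
#' regularly spaced dyads. Inside each cassette, WW elements are laid on
#' helical phase grids over an alternating-G/C filler: short A tracts
#' (`end_tract` bp, first end) and T tracts (second end) every ~10.3 bp
#' across the two ~50-bp ends, and single AA/TT dinucleotides every
#' ~11.1 bp across the ~47-bp middle. Successive wedge angles of an A (or
#' T) tract add almost in phase, so cassette ends carry strong coherent
#' bending, the sparser middle less, and the alternating-G/C filler and
#' incoherent random background none — the end-heavy curvature signature of
#' core DNA that the matched filter looks for.
#'
#' @param length Total sequence length (>= 2000 bp).
#' @param dyad_spacing Centre-to-centre distance between planted dyads
#'   (default 190 bp, the typical internucleosome repeat).
#' @param seed Integer seed.
#' @param chrom Sequence name.
#' @param end_phase,mid_phase WW grid spacings in bp (defaults 10.3 / 11.1).
#' @param end_tract A/T tract length in the end sections (default 3 bp,
#'   kept below the 4-bp poly(dA:dT) convention).
#' @return A list with `genome` (a [genome_sequence]) and `truth`
#'   (`fixture_truth` with the planted `dyads`).
#' @export
plant_sequence_nucleosomes <- function(length, dyad_spacing = 190L, seed = 1L,
                                       chrom = "synth", end_phase = 10.3,
                                       mid_phase = 11.1, end_tract = 3L) {
  if (length < 2000L) stop("length must be >= 2000")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  dyads <- seq(100L, length - 101L, by = as.integer(dyad_spacing))
  for (dy in dyads) {
    cass <- rep(c("G", "C"), length.out = 147L)
    put <- function(rel, base, n) {
      rel <- rel[rel + n <= 147L]
      for (r in rel) cass[(r + 1L):(r + n)] <<- base
    }
    end_grid <- round(seq(0, 49, by = end_phase))
    mid_grid <- round(seq(50, 96, by = mid_phase))
    put(end_grid, "A", end_tract)
    for (i in seq_along(mid_grid)) {
      put(mid_grid[i], if (i %% 2L == 1L) "A" else "T", 2L)
    }
    put(97L + end_grid, "T", end_tract)
    bases[(dy - 73L + 1L):(dy + 73L + 1L)] <- cass
  }
  list(genome = genome_sequence(chrom, paste(bases, collapse = "")),
       truth = structure(list(dyads = as.integer(dyads), seed = seed,
                              length = length, dyad_spacing = dyad_spacing,
                              end_phase = end_phase, mid_phase = mid_phase),
                         class = "fixture_truth"))
}

#' Synthetic TSS occupancy fixture for classification tests
#'
#' A long score track with `n_sites` TSS anchors laid out along it; a random
#' half of the sites receive an "occupied" raised-cosine bump over the
#' [-150, +50] window (amplitude `+amplitude`), the other half a depleted
#' trough (`-amplitude`), plus Gaussian noise. Default `noise_sd = 1/3`
#' makes the fixture an SNR-3 classification problem.
#'
#' @param n_sites Number of TSS sites (>= 10).
#' @param flank Spacing half-width: sites are placed `2*flank + 100` bp
#'   apart (must be >= 150 so the class window is covered).
#' @param seed Integer seed.
#' @param amplitude Bump/trough amplitude (default 1).
#' @param noise_sd Gaussian noise sd (default 1/3).
#' @param chrom Track name.
#' @return A list with `track`, `anchors` (anchor data.frame, all `+`
#'   strand) and `truth` (`fixture_truth` with `labels`: "occupied" /
#'   "free" per site, in anchor order).
#' @export
tss_class_fixture <- function(n_sites, flank = 200L, seed = 1L, amplitude = 1,
                              noise_sd = 1 / 3, chrom = "synth") {
  if (n_sites < 10L) stop("n_sites must be >= 10")
  if (flank < 150L) stop("flank must be >= 150 to cover the [-150, +50] window")
  set.seed(seed)
  stride <- 2L * flank + 100L
  positions <- flank + stride * (seq_len(n_sites) - 1L)
  len <- positions[n_sites] + flank + 100L
  labels <- sample(rep(c("occupied", "free"), length.out = n_sites))
  x <- stats::rnorm(len, sd = noise_sd)
  rel <- -150:50
  shape <- (1 - cos(2 * pi * (rel + 150) / 200)) / 2    # raised cosine on the window
  for (i in seq_len(n_sites)) {
    sgn <- if (labels[i] == "occupied") 1 else -1
    idx <- positions[i] + rel + 1L
    x[idx] <- x[idx] + sgn * amplitude * shape
  }
  anchors <- data.frame(chrom = chrom, pos = positions, strand = "+",
                        label = "TSS", stringsAsFactors = FALSE)
  list(track = score_track(chrom, 0L, x), anchors = anchors,
       truth = structure(list(labels = labels, positions = positions,
                              seed = seed, n_sites = n_sites,
                              amplitude = amplitude, noise_sd = noise_sd),
                         class = "fixture_truth"))
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat("<fixture_truth>", if (!is.null(x$dyads)) paste(base::length(x$dyads), "planted dyads")
      else paste(base::length(x$labels), "labelled sites"),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}
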