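#' Construct a curvature pattern object
#'
#' The canonical 1-D curvature template of nucleosomal core DNA, with the
#' dyad index marking the nucleosome center within the template.
#'
#' @param values Numeric template values.
#' @param dyad_index 0-based offset of the dyad within the template; default
#'   the center, `floor(length/2)`.
#' @return A `curvature_pattern` object.
#' @export
curvature_pattern <- function(values, dyad_index = length(values) %/% 2L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("pattern values must be finite")
  dyad_index <- as.integer(dyad_index)
  if (dyad_index < 0L || dyad_index >= length(values)) stop("dyad_index out of range")
  structure(list(values = values, dyad_index = dyad_index), class = "curvature_pattern")
}

#' @export
length.curvature_pattern <- function(x) length(x$values)

#' @export
print.curvature_pattern <- function(x, ...) {
  cat(sprintf("<curvature_pattern> length %d, dyad_index %d, mean %.3g, L2 %.3g\n",
              length(x$values), x$dyad_index, mean(x$values),
              sqrt(sum(x$values^2))))
  invisible(x)
}

# Zero-mean, unit-L2 scaling shared by pattern constructors; makes the
# matched filter insensitive to baseline curvature and overall amplitude.
.normalize_pattern <- function(v) {
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("pattern is constant; cannot normalize")
  v / nrm
}

#' Build the curvature pattern from aligned core-DNA sequences
#'
#' Computes the curvature curve of each aligned nucleosomal core sequence
#' (146 or 147 bp, e.g. from crystal structures), averages the curves
#' positionwise, and scales the mean to zero mean and unit L2 norm. The
#' dyad index is the template center.
#'
#' @param core_seqs List of [genome_sequence] objects, all the same length.
#' @param table A `roll_tilt_table`.
#' @param params A [curvature_params].
#' @return A `curvature_pattern` of length `core length - window`.
#' @export
build_pattern <- function(core_seqs, table, params = curvature_params()) {
  if (inherits(core_seqs, "genome_sequence")) core_seqs <- list(core_seqs)
  if (length(core_seqs) < 1L) stop("need at least one core sequence")
  lens <- vapply(core_seqs, length, 0L)
  if (length(unique(lens)) != 1L) stop("core sequences must all have the same length")
  curves <- lapply(core_seqs, function(s) curvature_curve(s, table, params)$values)
  m <- rowMeans(do.call(cbind, curves))
  curvature_pattern(.normalize_pattern(m))
}

#' Idealized nucleosomal curvature template
#'
#' A piecewise template encoding the canonical shape of core-DNA curvature:
#' elevated bending over ~50 bp at each end of the wrapped DNA and lower
#' curvature over the ~47 bp middle, with 5-bp half-cosine ramps between the
#' plateaus. Mirror-symmetric about the dyad. Serves as a bundled stand-in
#' for a pattern built from aligned crystal-structure core sequences.
#'
#' @param params A [curvature_params] (unused by the shape itself; kept for
#'   interface symmetry with [build_pattern]).
#' @param end_len Length in bp of each high-curvature end plateau.
#' @param mid_len Length in bp of the low-curvature middle section.
#' @param high,low Plateau amplitudes before normalization.
#' @param ramp Transition length in bp.
#' @param normalize If `TRUE` (default) apply the zero-mean unit-norm scaling
#'   used by [build_pattern]; `FALSE` returns the raw amplitude-`high` shape
#'   (used e.g. when planting signal in synthetic fixtures).
#' @return A `curvature_pattern` of length `2*end_len + mid_len`.
#' @export
idealized_pattern <- function(params = curvature_params(), end_len = 50L,
                              mid_len = 47L, high = 1.0, low = 0.2,
                              ramp = 5L, normalize = TRUE) {
  end_len <- as.integer(end_len); mid_len <- as.integer(mid_len)
  L <- 2L * end_len + mid_len
  if (L < 100L) stop("template too short: 2*end_len + mid_len must be >= 100")
  half <- numeric(end_len + (mid_len + 1L) %/% 2L)   # left half incl. center for odd L
  half[seq_len(end_len)] <- high
  half[(end_len + 1L):length(half)] <- low
  # half-cosine ramp high -> low over `ramp` positions starting at the boundary
  if (ramp > 0L) {
    t <- seq_len(ramp) / (ramp + 1)
    half[end_len + seq_len(min(ramp, length(half) - end_len))] <-
      low + (high - low) * (1 + cos(pi * t))[seq_len(min(ramp, length(half) - end_len))] / 2
  }
  values <- if (L %% 2L == 1L) c(half, rev(half[-length(half)])) else c(half, rev(half))
  if (normalize) values <- .normalize_pattern(values)
  curvature_pattern(values, dyad_index = L %/% 2L)
}

#' Write / read a curvature pattern as TSV
#'
#' Two columns `offset`, `value`, with a header comment recording the dyad
#' index so the template round-trips exactly.
#'
#' @param pattern A `curvature_pattern`.
#' @param path File path.
#' @return `path` (write) or a `curvature_pattern` (read).
#' @export
write_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dyad_index=%d", pattern$dyad_index), con)
  writeLines("offset\tvalue", con)
  writeLines(sprintf("%d\t%.17g", seq_along(pattern$values) - 1L, pattern$values), con)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  dy <- grep("^#\\s*dyad_index=", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  dyad <- if (length(dy)) as.integer(sub(".*dyad_index=", "", dy[1])) else nrow(df) %/% 2L
  curvature_pattern(df$value, dyad_index = dyad)
}

#' Curvature profile by matched filtering
#'
#' Slides the (zero-mean, unit-norm) curvature pattern along a curvature
#' curve and records the dot product at every placement: the matched-filter
#' response. Where a curve segment resembles the nucleosomal template the
#' profile peaks; each placement's score is assigned to the genomic position
#' aligned with the pattern's dyad index, so profile peaks sit at predicted
#' dyads. Masked curve positions carry value 0 and therefore contribute no
#' weight.
#'
#' @param curve A [score_track] (typically from [curvature_curve]).
#' @param pattern A `curvature_pattern`.
#' @return A [score_track] of matched-filter scores with
#'   `start = curve$start + dyad_index` and `length(curve) - length(pattern)
#'   + 1` values.
#' @export
curvature_profile <- function(curve, pattern) {
  stopifnot(inherits(curve, "score_track"), inherits(pattern, "curvature_pattern"))
  v <- curve$values
  if (!is.null(curve$mask)) v[curve$mask] <- 0
  L <- length(pattern$values)
  n <- length(v)
  if (n < L) stop("curve shorter than the pattern (", L, " values)")
  n_out <- n - L + 1L
  acc <- numeric(n_out)
  for (i in seq_len(L)) {
    acc <- acc + pattern$values[i] * v[i:(i + n_out - 1L)]
  }
  score_track(curve$chrom, start = curve$start + pattern$dyad_index, values = acc)
}
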