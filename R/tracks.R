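#' Per-position score track
#'
#' The toolkit's basic 1-bp-step signal container: a curvature curve, a
#' curvature profile, a wavelet spectrum or a reference occupancy track.
#' Coordinates are 0-based: `values[i]` is the score at genomic position
#' `start + i - 1`.
#'
#' @param chrom Chromosome / sequence identifier.
#' @param start 0-based genomic position of the first value.
#' @param values Numeric vector of per-position scores (finite).
#' @param mask Optional logical vector, `TRUE` where the value is a
#'   placeholder (e.g. a curvature window overlapping an N); masked entries
#'   carry value 0.
#' @return An object of class `"score_track"`.
#' @export
score_track <- function(chrom, start, values, mask = NULL) {
  start <- as.integer(start)
  values <- as.numeric(values)
  if (is.na(start) || start < 0L) stop("track start must be a non-negative integer")
  if (any(!is.finite(values))) stop("track values must be finite")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != length(values)) stop("mask length must equal values length")
  }
  structure(list(chrom = as.character(chrom), start = start,
                 values = values, mask = mask),
            class = "score_track")
}

#' @export
length.score_track <- function(x) length(x$values)

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track> %s:%d-%d (%d values", x$chrom, x$start,
              x$start + length(x$values), length(x$values)))
  if (!is.null(x$mask) && any(x$mask)) cat(sprintf(", %d masked", sum(x$mask)))
  cat(")\n")
  invisible(x)
}

#' Genomic positions covered by a score track
#' @param track A `score_track`.
#' @return Integer vector of 0-based positions, one per value.
#' @export
track_positions <- function(track) {
  track$start + seq_along(track$values) - 1L
}

#' DNA sequence container
#'
#' A named DNA sequence over the alphabet A, C, G, T, N, uppercase-normalized
#' at construction.
#'
#' @param chrom Sequence identifier.
#' @param seq Character scalar; lowercase (soft-masked) letters are accepted
#'   and uppercased.
#' @return An object of class `"genome_sequence"` with fields `chrom`, `seq`
#'   and `length`.
#' @export
genome_sequence <- function(chrom, seq) {
  seq <- toupper(as.character(seq))
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("sequence '%s': illegal character '%s' at position %d (alphabet is A/C/G/T/N)",
                 chrom, substr(seq, bad, bad), bad))
  }
  structure(list(chrom = as.character(chrom), seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
length.genome_sequence <- function(x) x$length

#' @export
print.genome_sequence <- function(x, ...) {
  head <- substr(x$seq, 1L, 60L)
  cat(sprintf("<genome_sequence> %s (%d bp) %s%s\n", x$chrom, x$length, head,
              if (x$length > 60L) "..." else ""))
  invisible(x)
}

#' Reverse complement of a sequence string
#' @param s Character scalar over A/C/G/T/N.
#' @return The reverse complement, N preserved.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Integer encoding A=0 C=1 G=2 T=3, NA for N. Shared by curvature, hexamer
# and PWM code.
.encode_bases <- function(seq) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  unname(codes[chars])
}
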