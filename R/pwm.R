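# PWM promoter scanning: PFM -> log-odds PWM, strand-max scan tracks, and
# the cross-TF cross-promoter average binding-score profile.

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per column, counts are turned into pseudocount-smoothed frequencies
#' `f_b = (count_b + pseudocount) / (colsum + 4*pseudocount)` and scored as
#' base-2 log odds against the background: `log2(f_b / background_b)`.
#'
#' @param pfm A PFM record (list with `tf_name` and a 4 x L `counts` matrix,
#'   rows A, C, G, T), e.g. from [read_jaspar_pfm].
#' @param pseudocount Additive count per cell (default 0.5).
#' @param background Background base probabilities (A, C, G, T), summing to
#'   1; default uniform.
#' @return A `pwm` object: list with `tf_name`, `log_odds` (4 x L),
#'   `background`, `pseudocount`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.5, background = rep(0.25, 4)) {
  counts <- pfm$counts
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (any(background <= 0)) stop("background probabilities must be positive")
  if (pseudocount == 0 && any(colSums(counts) == 0)) {
    stop("zero-sum column with pseudocount 0")
  }
  freq <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(freq / background)
  rownames(lo) <- c("A", "C", "G", "T")
  structure(list(tf_name = pfm$tf_name, log_odds = lo,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' Motif width of a PWM
#' @param x A `pwm`.
#' @export
length.pwm <- function(x) ncol(x$log_odds)

# Reverse-complement a log-odds matrix: reverse columns, swap A<->T, C<->G.
.rc_pwm_matrix <- function(lo) {
  lo[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(lo))), drop = FALSE]
}

#' Scan a sequence with a PWM
#'
#' At each placement the score is the sum of the log-odds entries of the
#' aligned bases; the reported per-position value is the maximum of the
#' forward score and the reverse-complement-strand score at the same
#' placement. Placements whose window contains an N are masked (value 0).
#' Values are anchored at the placement's first base.
#'
#' @param seq A [genome_sequence], at least as long as the motif.
#' @param pwm A `pwm`.
#' @return A [score_track] with `length(seq) - L + 1` values.
#' @export
scan_scores <- function(seq, pwm) {
  stopifnot(inherits(seq, "genome_sequence"), inherits(pwm, "pwm"))
  L <- ncol(pwm$log_odds)
  n <- seq$length
  if (n < L) stop("sequence shorter than the motif (", L, " bp)")
  code <- .encode_bases(seq$seq)
  n_out <- n - L + 1L
  score_one <- function(lo) {
    s <- numeric(n_out)
    for (j in seq_len(L)) {
      b <- code[j:(j + n_out - 1L)]
      v <- lo[cbind(b + 1L, j)]
      v[is.na(b)] <- NA_real_
      s <- s + v
    }
    s
  }
  fwd <- score_one(pwm$log_odds)
  rev_ <- score_one(.rc_pwm_matrix(pwm$log_odds))
  vals <- pmax(fwd, rev_)
  mask <- is.na(vals)
  vals[mask] <- 0
  score_track(seq$chrom, 0L, vals, mask = mask)
}

#' Average binding-score profile across TFs and promoters
#'
#' For every (PWM, promoter) pair: scan the promoter, min-max normalize the
#' scores to [0, 1] across that promoter (so TFs with different log-odds
#' ranges weigh equally), then average all normalized tracks positionwise.
#' Offsets are reported relative to the stated TSS position within the
#' aligned promoters. A pair whose scan is constant contributes 0.5
#' everywhere, with a warning.
#'
#' @param promoters List of [genome_sequence] objects, all the same length,
#'   aligned so the TSS sits at the same offset in each.
#' @param pwms List of `pwm` objects.
#' @param tss_offset 0-based offset of the TSS within each promoter
#'   (default 0).
#' @return A data.frame of class `binding_profile` with columns `offset`
#'   (bp relative to TSS), `mean_score` (in [0, 1]) and `n_pairs`.
#' @export
average_binding_profile <- function(promoters, pwms, tss_offset = 0L) {
  if (inherits(promoters, "genome_sequence")) promoters <- list(promoters)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (length(promoters) < 1L || length(pwms) < 1L) {
    stop("need at least one promoter and one PWM")
  }
  plen <- unique(vapply(promoters, length, 0L))
  if (length(plen) != 1L) stop("promoters must all have the same length")
  n_out_min <- plen - max(vapply(pwms, length, 0L)) + 1L
  if (n_out_min < 1L) stop("a motif is longer than the promoters")
  acc <- NULL; nn <- NULL
  for (pwm in pwms) {
    for (prom in promoters) {
      tr <- scan_scores(prom, pwm)
      v <- tr$values
      v[tr$mask] <- NA_real_
      rng <- range(v, na.rm = TRUE)
      if (!is.finite(rng[1]) || rng[2] == rng[1]) {
        warning("constant scan for ", pwm$tf_name, " on ", prom$chrom,
                "; contributing 0.5")
        v <- rep(0.5, length(v))
      } else {
        v <- (v - rng[1]) / (rng[2] - rng[1])
      }
      if (is.null(acc)) {
        acc <- numeric(plen); nn <- integer(plen)
      }
      idx <- seq_along(v)
      ok <- !is.na(v)
      acc[idx[ok]] <- acc[idx[ok]] + v[ok]
      nn[idx[ok]] <- nn[idx[ok]] + 1L
    }
  }
  keep <- nn > 0L
  structure(data.frame(offset = (which(keep) - 1L) - tss_offset,
                       mean_score = acc[keep] / nn[keep],
                       n_pairs = nn[keep]),
            class = c("binding_profile", "data.frame"))
}

#' Consensus sequence of a PWM
#' @param pwm A `pwm`.
#' @return Character scalar: the top-scoring base per column.
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$log_odds, 2L, which.max)], collapse = "")
}
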