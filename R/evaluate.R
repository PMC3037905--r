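#' Overlap ratio of two 147-bp nucleosomes at a given dyad deviation
#'
#' Returns `(2*(73 - deviation) + deviation) / 147`, the published degree of
#' overlap between a predicted and a reference nucleosome whose dyads differ
#' by `deviation` bp. (The natural geometric overlap of two 147-bp intervals
#' offset by d is (147 - d)/147; the published formula is kept as printed.)
#'
#' @param deviation Dyad distance in bp, 0..73 (vectorized).
#' @return Overlap fraction(s) in (0, 1].
#' @export
overlap_ratio <- function(deviation) {
  if (any(deviation < 0 | deviation > 73)) stop("deviation must be in [0, 73]")
  (2 * (73 - deviation) + deviation) / 147
}

#' Matching ratio between reference and predicted dyads
#'
#' Fraction of reference dyads that have at least one predicted dyad within
#' `deviation` bp (any-within matching: one predicted dyad may match several
#' reference dyads). With `one_to_one = TRUE`, matches are instead formed
#' greedily by increasing pair distance and each predicted dyad is consumed
#' by at most one reference dyad.
#'
#' @param reference Integer vector of reference (e.g. experimentally
#'   determined) dyad positions; must be nonempty.
#' @param predicted Integer vector of predicted dyad positions.
#' @param deviation Maximum allowed dyad distance in bp.
#' @param one_to_one Use the stricter one-to-one pairing (default `FALSE`).
#' @return The matching ratio in [0, 1].
#' @export
matching_ratio <- function(reference, predicted, deviation, one_to_one = FALSE) {
  reference <- sort(as.numeric(reference))
  predicted <- sort(as.numeric(predicted))
  if (length(reference) == 0L) stop("reference dyad set is empty")
  if (length(predicted) == 0L) return(0)
  if (!one_to_one) {
    # nearest predicted dyad per reference dyad via sorted insertion
    idx <- findInterval(reference, predicted)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(predicted))
    nearest <- pmin(abs(reference - predicted[left]),
                    abs(reference - predicted[right]))
    return(mean(nearest <= deviation))
  }
  pairs <- expand.grid(r = seq_along(reference), p = seq_along(predicted))
  pairs$d <- abs(reference[pairs$r] - predicted[pairs$p])
  pairs <- pairs[pairs$d <= deviation, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$r, pairs$p), , drop = FALSE]
  used_r <- logical(length(reference)); used_p <- logical(length(predicted))
  matched <- 0L
  for (k in seq_len(nrow(pairs))) {
    r <- pairs$r[k]; p <- pairs$p[k]
    if (!used_r[r] && !used_p[p]) {
      used_r[r] <- TRUE; used_p[p] <- TRUE; matched <- matched + 1L
    }
  }
  matched / length(reference)
}

#' Matching-ratio curve over a deviation sweep
#'
#' Evaluates [matching_ratio] at every deviation 1..`d_max` bp.
#'
#' @inheritParams matching_ratio
#' @param d_max Largest deviation (default 60).
#' @return A data.frame of class `match_curve` with columns `deviation` and
#'   `matching_ratio` (nondecreasing in deviation).
#' @export
match_curve <- function(reference, predicted, d_max = 60L, one_to_one = FALSE) {
  devs <- seq_len(d_max)
  mr <- vapply(devs, function(d) matching_ratio(reference, predicted, d, one_to_one), 0)
  structure(data.frame(deviation = devs, matching_ratio = mr),
            class = c("match_curve", "data.frame"))
}

# ---- hexamer occupancy ------------------------------------------------------

#' All 4096 hexamers in lexicographic order
#' @return Character vector of length 4096.
#' @export
hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b6 = bases, b5 = bases, b4 = bases, b3 = bases,
                   b2 = bases, b1 = bases, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3, g$b4, g$b5, g$b6)
}

#' Hexamer occupancy table for a call set
#'
#' Enumerates every forward-strand hexamer occurrence in the genome
#' (positions whose 6-bp window contains an N are skipped) and classifies
#' it as nucleosome-occupied iff the window lies entirely inside at least
#' one call's 147-bp interval. The occupancy ratio of a hexamer is
#' occupied occurrences / total occurrences.
#'
#' @param genome A [genome_sequence].
#' @param callset A `nucleosome_calls` data.frame on the same chromosome.
#' @param collapse_rc If `TRUE`, pool each hexamer's counts with its reverse
#'   complement's before computing ratios (default `FALSE`: no collapsing).
#' @return A data.frame of class `hexamer_table` with one row per hexamer:
#'   `hexamer`, `total_count`, `occupied_count`, `occupancy_ratio`,
#'   `free_ratio`, `present` (total_count > 0). Ratios are `NA` for absent
#'   hexamers.
#' @export
hexamer_occupancy <- function(genome, callset, collapse_rc = FALSE) {
  stopifnot(inherits(genome, "genome_sequence"),
            inherits(callset, "nucleosome_calls"))
  n <- genome$length
  code <- .encode_bases(genome$seq)
  n_pos <- n - 5L
  if (n_pos < 1L) stop("genome shorter than 6 bp")
  # hexamer id at each start position (1-based), NA if the window has an N
  id <- integer(n_pos)
  for (k in 0:5) id <- id * 4L + code[(1L + k):(n_pos + k)]
  # position p (1-based) is "coverable" iff some call fully contains
  # [p-1, p+5): call$start <= p-1 and p+5 <= call$end
  ok_start <- rep(FALSE, n_pos)
  if (nrow(callset) > 0L) {
    lo <- pmax(callset$start + 1L, 1L)          # 1-based first allowed start
    hi <- pmin(callset$end - 5L, n_pos)         # 1-based last allowed start
    for (k in seq_len(nrow(callset))) {
      if (lo[k] <= hi[k]) ok_start[lo[k]:hi[k]] <- TRUE
    }
  }
  valid <- !is.na(id)
  total <- tabulate(id[valid] + 1L, nbins = 4096L)
  occ <- tabulate(id[valid & ok_start] + 1L, nbins = 4096L)
  hx <- hexamers()
  if (collapse_rc) {
    rc <- vapply(hx, revcomp, "")
    rc_idx <- match(rc, hx)
    total <- total + total[rc_idx]
    occ <- occ + occ[rc_idx]
  }
  ratio <- ifelse(total > 0L, occ / total, NA_real_)
  structure(data.frame(hexamer = hx, total_count = total, occupied_count = occ,
                       occupancy_ratio = ratio, free_ratio = 1 - ratio,
                       present = total > 0L, stringsAsFactors = FALSE),
            class = c("hexamer_table", "data.frame"))
}

#' Correlation between two hexamer occupancy tables
#'
#' Pearson correlation of the occupancy-ratio vectors over hexamers present
#' (total_count > 0) in both tables — the sequence-dependence statistic
#' comparing predicted and reference nucleosome sets.
#'
#' @param table_a,table_b `hexamer_table` data.frames over the same hexamer
#'   universe.
#' @return Pearson r.
#' @export
occupancy_correlation <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "hexamer_table"), inherits(table_b, "hexamer_table"))
  if (!identical(table_a$hexamer, table_b$hexamer)) {
    stop("tables must cover the same hexamer universe in the same order")
  }
  shared <- table_a$present & table_b$present
  if (sum(shared) < 3L) stop("fewer than 3 hexamers present in both tables")
  stats::cor(table_a$occupancy_ratio[shared], table_b$occupancy_ratio[shared])
}
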