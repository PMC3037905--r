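# Site-centered analyses: anchored average profiles, two-class k-means TSS
# classification, sequence-composition profiles.

# Extract the per-site signal window (offsets -flank..+flank, strand-aware)
# as a numeric vector with NA outside the track.
.site_window <- function(track, pos, strand, flank) {
  offs <- -flank:flank
  gpos <- pos + offs                      # genomic positions, plus strand
  idx <- gpos - track$start + 1L
  v <- rep(NA_real_, length(offs))
  inside <- idx >= 1L & idx <= length(track$values)
  v[inside] <- track$values[idx[inside]]
  if (strand == "-") v <- rev(v)
  v
}

#' Anchored average signal profile
#'
#' Aligns a score track on a set of anchor sites (TSSs, SNPs, miRNA target
#' sites, ...), flips windows from minus-strand sites so that positive
#' offsets always point downstream, optionally z-scores each site's window,
#' and averages positionwise. Offsets a site cannot cover (chromosome edge)
#' are simply not contributed (tracked by `n_sites`), rather than the site
#' being discarded; set `strict = TRUE` to keep only fully covered sites.
#'
#' @param track A [score_track].
#' @param anchors Anchor data.frame from [read_anchor_table] (columns
#'   `chrom`, `pos`, `strand`); rows on other chromosomes are ignored.
#' @param flank Half-width of the window in bp.
#' @param scale_mode `"none"` (raw signal) or `"zscore"` (per-site
#'   standardization, for cross-track comparability of "scaled signal"
#'   averages).
#' @param strict Drop sites without full window coverage (default `FALSE`).
#' @return An `anchored_profile` data.frame with columns `offset`,
#'   `mean_signal`, `n_sites`.
#' @export
anchored_profile <- function(track, anchors, flank,
                             scale_mode = c("none", "zscore"),
                             strict = FALSE) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(inherits(track, "score_track"), flank >= 1)
  anchors <- anchors[anchors$chrom == track$chrom, , drop = FALSE]
  if (nrow(anchors) == 0L) stop("no anchors on chromosome ", track$chrom)
  offs <- -flank:flank
  acc <- numeric(length(offs)); nn <- integer(length(offs))
  used <- 0L
  for (i in seq_len(nrow(anchors))) {
    w <- .site_window(track, anchors$pos[i], anchors$strand[i], flank)
    if (all(is.na(w))) next
    if (strict && anyNA(w)) next
    if (scale_mode == "zscore") {
      mu <- mean(w, na.rm = TRUE)
      sd <- stats::sd(w, na.rm = TRUE)
      w <- if (is.na(sd) || sd == 0) w - mu else (w - mu) / sd
    }
    ok <- !is.na(w)
    acc[ok] <- acc[ok] + w[ok]
    nn[ok] <- nn[ok] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no anchor has any in-track coverage")
  structure(data.frame(offset = offs,
                       mean_signal = ifelse(nn > 0L, acc / nn, NA_real_),
                       n_sites = nn),
            class = c("anchored_profile", "data.frame"))
}

#' Two-class k-means classification of TSSs by local signal
#'
#' Clusters the per-site signal vectors over a window around each TSS
#' (default 150 bp upstream to 50 bp downstream) into two classes with
#' k-means (Euclidean, `nstart` seeded restarts). The cluster with the
#' higher mean signal is class `"I"` (nucleosome-occupied), the other
#' `"II"` (nucleosome-free), so the labels are stable across seeds. Only
#' sites with full window coverage are used. Raw (unscaled) vectors are
#' clustered.
#'
#' @param track A [score_track] of occupancy-like signal.
#' @param anchors Anchor data.frame (TSSs; strand-aware windows).
#' @param window Length-2 integer vector of offsets relative to the TSS,
#'   default `c(-150, 50)`.
#' @param k Number of classes (fixed at 2 for the I/II scheme).
#' @param seed Integer seed for the k-means initialization.
#' @param nstart Number of random restarts (default 20).
#' @return A data.frame of class `tss_classes` with columns `chrom`, `pos`,
#'   `strand`, `label`, `class` ("I"/"II") for every usable site, plus an
#'   attribute `centers` (the 2 cluster mean vectors).
#' @export
classify_tss <- function(track, anchors, window = c(-150L, 50L), k = 2L,
                         seed = 1L, nstart = 20L) {
  stopifnot(inherits(track, "score_track"), k == 2L, length(window) == 2L)
  anchors <- anchors[anchors$chrom == track$chrom, , drop = FALSE]
  offs <- window[1]:window[2]
  rows <- vector("list", nrow(anchors))
  keep <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    flank_max <- max(abs(window))
    w <- .site_window(track, anchors$pos[i], anchors$strand[i], flank_max)
    w <- w[offs + flank_max + 1L]
    if (!anyNA(w)) { rows[[i]] <- w; keep[i] <- TRUE }
  }
  if (sum(keep) < 2L) stop("fewer than 2 TSSs with full window coverage")
  m <- do.call(rbind, rows[keep])
  anchors <- anchors[keep, , drop = FALSE]
  if (all(apply(m, 2L, function(col) length(unique(col)) == 1L)) &&
      nrow(unique(m)) == 1L) {
    warning("all site vectors identical; assigning a single class")
    cls <- rep("I", nrow(m))
    centers <- rbind(m[1, ], m[1, ])
  } else {
    set.seed(seed)
    km <- stats::kmeans(m, centers = 2L, nstart = nstart, iter.max = 100L)
    occ_first <- mean(km$centers[1, ]) >= mean(km$centers[2, ])
    map <- if (occ_first) c("I", "II") else c("II", "I")
    cls <- map[km$cluster]
    centers <- if (occ_first) km$centers else km$centers[2:1, ]
  }
  out <- data.frame(chrom = anchors$chrom, pos = anchors$pos,
                    strand = anchors$strand, label = anchors$label,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "centers") <- centers
  class(out) <- c("tss_classes", "data.frame")
  out
}

# Strand-aware sequence window: bases at offsets -flank..(+flank+extra) from
# the site, reverse-complemented for minus-strand sites. NA-padded at edges.
.seq_window <- function(genome, pos, strand, flank, extra = 0L) {
  if (strand == "+") {
    lo <- pos - flank; hi <- pos + flank + extra
    chars <- rep(NA_character_, hi - lo + 1L)
    ok <- (lo:hi) >= 0L & (lo:hi) <= genome$length - 1L
    if (any(ok)) {
      r <- range(which(ok))
      chars[r[1]:r[2]] <- strsplit(substr(genome$seq, lo + r[1], lo + r[2]),
                                   "", fixed = TRUE)[[1]]
    }
  } else {
    # offset x on the minus strand reads the complement of base pos - x
    lo <- pos - flank - extra; hi <- pos + flank
    chars <- rep(NA_character_, hi - lo + 1L)
    ok <- (lo:hi) >= 0L & (lo:hi) <= genome$length - 1L
    if (any(ok)) {
      r <- range(which(ok))
      sub <- substr(genome$seq, lo + r[1], lo + r[2])
      chars[r[1]:r[2]] <- strsplit(sub, "", fixed = TRUE)[[1]]
    }
    chars <- rev(chartr("ACGTN", "TGCAN", chars))
  }
  chars
}

#' Dinucleotide-class fraction profile around anchor sites
#'
#' At each offset from the aligned sites, the fraction of sites whose
#' dinucleotide starting there belongs to the class: WW = AA/AT/TA/TT,
#' SS = CC/CG/GC/GG. Minus-strand sites contribute their reverse-complement
#' window (both classes are closed under reverse complement). Dinucleotides
#' containing N are not counted.
#'
#' @param genome A [genome_sequence].
#' @param anchors Anchor data.frame (rows on other chromosomes ignored).
#' @param flank Half-width in bp; offsets run -flank..+flank.
#' @param dinuc_class `"WW"` or `"SS"`.
#' @return An `anchored_profile` data.frame (`mean_signal` is the fraction).
#' @export
dinucleotide_fraction_profile <- function(genome, anchors, flank,
                                          dinuc_class = c("WW", "SS")) {
  dinuc_class <- match.arg(dinuc_class)
  members <- if (dinuc_class == "WW") c("AA", "AT", "TA", "TT")
             else c("CC", "CG", "GC", "GG")
  .composition_profile(genome, anchors, flank, extra = 1L, function(chars) {
    d <- paste0(chars[-length(chars)], chars[-1L])
    ifelse(is.na(chars[-length(chars)]) | is.na(chars[-1L]), NA, d %in% members)
  })
}

#' Poly(dA:dT) tract fraction profile around anchor sites
#'
#' At each offset, the fraction of sites where the base lies inside a pure
#' homopolymer run of A, or of T, of length at least `min_run` (mixed A/T
#' stretches do not qualify).
#'
#' @inheritParams dinucleotide_fraction_profile
#' @param min_run Minimum run length (default 4).
#' @return An `anchored_profile` data.frame.
#' @export
polytract_fraction_profile <- function(genome, anchors, flank, min_run = 4L) {
  if (min_run < 1L) stop("min_run must be >= 1")
  .composition_profile(genome, anchors, flank, extra = 0L, function(chars) {
    in_run <- rep(FALSE, length(chars))
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- !is.na(r$values) & r$values %in% c("A", "T") & r$lengths >= min_run
    for (k in which(hit)) in_run[starts[k]:ends[k]] <- TRUE
    in_run[is.na(chars)] <- NA
    in_run
  })
}

# Shared driver: per-site boolean feature vector over the window -> fraction
# of sites per offset.
.composition_profile <- function(genome, anchors, flank, extra, feature_fn) {
  stopifnot(inherits(genome, "genome_sequence"), flank >= 1)
  anchors <- anchors[anchors$chrom == genome$chrom, , drop = FALSE]
  if (nrow(anchors) == 0L) stop("no anchors on chromosome ", genome$chrom)
  offs <- -flank:flank
  acc <- numeric(length(offs)); nn <- integer(length(offs))
  used <- 0L
  for (i in seq_len(nrow(anchors))) {
    chars <- .seq_window(genome, anchors$pos[i], anchors$strand[i], flank, extra)
    f <- feature_fn(chars)[seq_along(offs)]
    if (all(is.na(f))) next
    ok <- !is.na(f)
    acc[ok] <- acc[ok] + as.numeric(f[ok])
    nn[ok] <- nn[ok] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no anchor has any in-genome coverage")
  structure(data.frame(offset = offs,
                       mean_signal = ifelse(nn > 0L, acc / nn, NA_real_),
                       n_sites = nn),
            class = c("anchored_profile", "data.frame"))
}
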