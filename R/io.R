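#' Read a FASTA file
#'
#' Reads every record of a FASTA file into [genome_sequence] objects.
#' Sequences are uppercased (soft-masking is ignored); any character outside
#' A/C/G/T/N is an error naming the record and offending position.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [genome_sequence] objects, one per record, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- genome_sequence(ids[i], as.character(set[[i]]))
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#' @param seqs A list of [genome_sequence] objects (or a single one).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$chrom), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$seq, starts, pmin(starts + width - 1L, s$length)), con)
  }
  invisible(path)
}

#' Read an anchor-site table
#'
#' Tab-separated columns `chrom`, `pos`, `strand`, `label`; `pos` is a
#' 0-based coordinate of the anchored base (e.g. the TSS base, a SNP, a
#' miRNA target site). Strand defaults to `"+"` and label to `""` when the
#' columns are absent. Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `chrom`, `pos` (integer), `strand`,
#'   `label`, in file order.
#' @export
read_anchor_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("anchor table '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(i) {
    f <- parts[[i]]
    if (length(f) < 2L) stop("anchor table line ", i, ": need at least chrom and pos")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("anchor table line ", i, ": non-integer position '", f[2], "'")
    if (pos < 0L) stop("anchor table line ", i, ": negative position")
    strand <- if (length(f) >= 3L && nzchar(f[3])) f[3] else "+"
    if (!strand %in% c("+", "-")) stop("anchor table line ", i, ": bad strand '", strand, "'")
    list(chrom = f[1], pos = pos, strand = strand,
         label = if (length(f) >= 4L) f[4] else "")
  }
  rows <- lapply(seq_along(parts), parse_row)
  data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
             pos = vapply(rows, `[[`, 0L, "pos"),
             strand = vapply(rows, `[[`, "", "strand"),
             label = vapply(rows, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

#' Read a score track
#'
#' Two dialects:
#' \describe{
#'   \item{`two_column`}{position\\tscore rows, positions 0-based and sorted
#'     ascending; gaps between listed positions are filled with 0 (no
#'     evidence), as for sparse reference nucleosome-score tracks published
#'     as position/score pairs.}
#'   \item{`fixed_step`}{a header line `fixedStep chrom=<id> start=<int>`
#'     followed by one score per line at 1-bp step.}
#' }
#'
#' Whether a two-column position indexes a fragment start or midpoint is not
#' defined by the dialect; the value is taken as "the position of the score".
#'
#' @param path Path to the track file.
#' @param dialect `"two_column"` or `"fixed_step"`.
#' @param chrom Chromosome name for `two_column` input (the dialect carries
#'   none); default `"chr"`.
#' @return A [score_track].
#' @export
read_score_track <- function(path, dialect = c("two_column", "fixed_step"),
                             chrom = "chr") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (dialect == "fixed_step") {
    hdr <- lines[1]
    if (!grepl("^fixedStep", hdr)) stop("fixed_step track must begin with a 'fixedStep' header")
    get <- function(key, default = NA_character_) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^ \t]+)"), hdr))[[1]]
      if (length(m) == 2L) m[2] else default
    }
    chrom <- get("chrom", chrom)
    start <- as.integer(get("start", "0"))
    vals <- as.numeric(lines[-1])
    if (any(is.na(vals))) stop("non-numeric score in fixed_step track")
    return(score_track(chrom, start, vals))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (any(is.na(pos))) stop("non-integer position in two_column track")
  if (any(is.na(val))) stop("non-numeric score in two_column track")
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("two_column track positions must be strictly increasing")
  }
  start <- pos[1]
  values <- numeric(pos[length(pos)] - start + 1L)
  values[pos - start + 1L] <- val
  score_track(chrom, start, values)
}

#' Write a score track in fixed-step format
#' @param track A [score_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=%d step=1", track$chrom, track$start), con)
  writeLines(format(track$values, trim = TRUE, digits = 10), con)
  invisible(path)
}

#' Write nucleosome calls as BED6
#'
#' Each call becomes `chrom, dyad-73, dyad+74` (0-based half-open, span 147),
#' name `nuc<i>`, score min-max scaled to 0-1000 integers, strand `"."`.
#' Calls whose interval would leave the chromosome start (dyad < 73) are
#' dropped with a warning, never clipped.
#'
#' @param callset A `nucleosome_calls` object (see [detect_dyads]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(callset, path) {
  stopifnot(inherits(callset, "nucleosome_calls"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6 nucleosome calls: start=dyad-73, end=dyad+74 (147 bp)", con)
  if (nrow(callset) == 0L) return(invisible(path))
  drop <- callset$dyad < 73L
  if (any(drop)) {
    warning(sum(drop), " call(s) with dyad < 73 dropped (147-bp interval would leave the chromosome)")
    callset <- callset[!drop, , drop = FALSE]
  }
  if (nrow(callset) == 0L) return(invisible(path))
  s <- callset$score
  rng <- range(s)
  scaled <- if (rng[2] > rng[1]) round(1000 * (s - rng[1]) / (rng[2] - rng[1])) else rep(1000, length(s))
  writeLines(sprintf("%s\t%d\t%d\tnuc%d\t%d\t.",
                     callset$chrom, callset$dyad - 73L, callset$dyad + 74L,
                     seq_len(nrow(callset)), as.integer(scaled)), con)
  invisible(path)
}

#' Read nucleosome calls from BED6
#'
#' Inverse of [write_calls_bed]: dyad = start + 73. BED scores (0-1000) are
#' kept as the call score.
#'
#' @param path Path to a BED file.
#' @return A `nucleosome_calls` data.frame.
#' @export
read_calls_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(nucleosome_calls(character(0), integer(0), numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  if (any(is.na(start)) || any(is.na(end))) stop("non-integer BED coordinates")
  if (any(end - start != 147L)) stop("BED intervals must span exactly 147 bp")
  score <- if (all(lengths(parts) >= 5L)) as.numeric(vapply(parts, `[[`, "", 5L)) else rep(0, length(start))
  nucleosome_calls(chrom, start + 73L, score)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses JASPAR 2010-style text: a `>ID NAME` header followed by four rows
#' in the order A, C, G, T, with counts optionally wrapped in brackets
#' (`A [ 8 0 ... ]`) or bare. Multiple records per file are supported.
#'
#' @param path Path to the PFM file.
#' @return A list of PFM records, each a list with `tf_name` and `counts`
#'   (a 4 x L numeric matrix with rownames A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no JASPAR '>' header found in ", path)
  bounds <- c(hdr_idx, length(lines) + 1L)
  records <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L) {
      stop("JASPAR record ", k, ": expected 4 matrix rows (A,C,G,T), got ", length(block))
    }
    hdr <- sub("^>\\s*", "", lines[hdr_idx[k]])
    name <- strsplit(hdr, "\\s+")[[1]]
    tf_name <- if (length(name) >= 2L) name[2] else name[1]
    parse_row <- function(row) {
      row <- gsub("^\\s*[ACGT]\\s*", "", row)   # optional base letter prefix
      row <- gsub("[][]", " ", row)             # optional brackets
      v <- suppressWarnings(as.numeric(strsplit(trimws(row), "\\s+")[[1]]))
      if (any(is.na(v))) stop("JASPAR record ", k, ": non-numeric count in row '", row, "'")
      v
    }
    vals <- lapply(block, parse_row)
    if (length(unique(lengths(vals))) != 1L) {
      stop("JASPAR record ", k, ": ragged matrix rows")
    }
    counts <- do.call(rbind, vals)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("JASPAR record ", k, ": negative count")
    if (any(colSums(counts) <= 0)) stop("JASPAR record ", k, ": zero-sum column")
    records[[k]] <- list(tf_name = tf_name, counts = counts)
  }
  names(records) <- vapply(records, `[[`, "", "tf_name")
  records
}
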