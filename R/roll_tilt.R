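#' Read a dinucleotide roll/tilt angle table
#'
#' The table drives the wedge-model curvature sum: one roll and one tilt
#' angle (degrees) per dinucleotide step. Format: TSV with a header
#' `step roll_deg tilt_deg` and exactly 16 rows covering AA..TT.
#'
#' @param path Path to the TSV.
#' @return A `roll_tilt_table`: a list with numeric vectors `roll` and
#'   `tilt`, each named by the 16 dinucleotide steps.
#' @export
read_roll_tilt <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("step", "roll_deg", "tilt_deg") %in% names(df))) {
    stop("roll/tilt table needs columns step, roll_deg, tilt_deg")
  }
  roll_tilt_table(stats::setNames(df$roll_deg, df$step),
                  stats::setNames(df$tilt_deg, df$step))
}

#' Construct a roll/tilt table
#'
#' @param roll Named numeric vector of roll angles (degrees), one per
#'   dinucleotide step AA..TT.
#' @param tilt Named numeric vector of tilt angles (degrees), same names.
#' @return A `roll_tilt_table` object.
#' @export
roll_tilt_table <- function(roll, tilt) {
  steps <- dinucleotide_steps()
  if (!setequal(names(roll), steps) || !setequal(names(tilt), steps)) {
    stop("roll/tilt table must cover exactly the 16 dinucleotide steps")
  }
  roll <- roll[steps]; tilt <- tilt[steps]
  if (any(!is.finite(roll)) || any(!is.finite(tilt))) stop("roll/tilt angles must be finite")
  structure(list(roll = roll, tilt = tilt), class = "roll_tilt_table")
}

#' The 16 dinucleotide steps in canonical order
#' @return Character vector AA, AC, ..., TT.
#' @export
dinucleotide_steps <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(t(outer(bases, bases, paste0)))
}

#' Default roll/tilt wedge angles
#'
#' Loads the dinucleotide wedge-model roll/tilt set shipped with the package
#' (`inst/extdata/roll_tilt_wedge.tsv`), a published curvature-model table in
#' which complementary steps share the roll angle and negate the tilt. Any
#' other table in the same TSV format can be used via [read_roll_tilt].
#'
#' @return A `roll_tilt_table`.
#' @export
default_roll_tilt <- function() {
  path <- system.file("extdata", "roll_tilt_wedge.tsv", package = "nucurve",
                      mustWork = TRUE)
  read_roll_tilt(path)
}

#' @export
print.roll_tilt_table <- function(x, ...) {
  cat("<roll_tilt_table> 16 dinucleotide steps (degrees)\n")
  print(data.frame(step = names(x$roll), roll = unname(x$roll),
                   tilt = unname(x$tilt)), row.names = FALSE)
  invisible(x)
}
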