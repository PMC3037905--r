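#' Curvature-profile nucleosome positioning model
#'
#' The package's main entry point. Builds (or accepts) the canonical
#' nucleosomal curvature template and bundles it with the roll/tilt angle
#' table, the curvature parameters and the wavelet peak-calling parameters
#' into a single model object. [predict.nucleosome_model] then maps DNA
#' sequence to nucleosome calls: curvature curve -> matched-filter profile
#' -> MSCWT dyad detection.
#'
#' If `core_seqs` is supplied the template is estimated from those aligned
#' nucleosomal core sequences via [build_pattern]; otherwise the bundled
#' [idealized_pattern] (high curvature over ~50 bp at each end, lower over
#' the ~47-bp middle) is used.
#'
#' @param core_seqs Optional list of aligned 146/147-bp
#'   [genome_sequence] core sequences to estimate the template from.
#' @param roll_tilt A `roll_tilt_table` (default [default_roll_tilt]).
#' @param params A [curvature_params].
#' @param pattern Optionally a ready-made `curvature_pattern`, overriding
#'   both `core_seqs` and the idealized template.
#' @param peak_params An [mscwt_params].
#' @return An object of class `"nucleosome_model"`.
#' @seealso [predict.nucleosome_model], [simulate.nucleosome_model]
#' @examples
#' mod <- nucleosome_model()
#' fx <- simulate(mod, length = 5000, seed = 7)
#' calls <- predict(mod, fx$genome)
#' summary(calls)
#' @export
nucleosome_model <- function(core_seqs = NULL, roll_tilt = default_roll_tilt(),
                             params = curvature_params(), pattern = NULL,
                             peak_params = mscwt_params()) {
  stopifnot(inherits(roll_tilt, "roll_tilt_table"),
            inherits(params, "curvature_params"),
            inherits(peak_params, "mscwt_params"))
  if (is.null(pattern)) {
    pattern <- if (is.null(core_seqs)) idealized_pattern(params)
               else build_pattern(core_seqs, roll_tilt, params)
    source <- if (is.null(core_seqs)) "idealized" else
      sprintf("estimated from %d core sequences", length(core_seqs))
  } else {
    stopifnot(inherits(pattern, "curvature_pattern"))
    source <- "user-supplied"
  }
  structure(list(pattern = pattern, roll_tilt = roll_tilt, params = params,
                 peak_params = peak_params, pattern_source = source),
            class = "nucleosome_model")
}

#' @export
print.nucleosome_model <- function(x, ...) {
  cat("Curvature-profile nucleosome positioning model\n")
  cat(sprintf("  template: %s, length %d, dyad index %d\n", x$pattern_source,
              length(x$pattern), x$pattern$dyad_index))
  cat(sprintf("  curvature: nu0 = %.2f bp/turn, window = %d steps\n",
              x$params$nu0, x$params$window))
  cat(sprintf("  peak calling: %d wavelet scales (%g-%g bp), min spacing %d bp, q = %.2f\n",
              length(x$peak_params$scales), min(x$peak_params$scales),
              max(x$peak_params$scales), x$peak_params$min_distance,
              x$peak_params$threshold_quantile))
  invisible(x)
}

#' @export
summary.nucleosome_model <- function(object, ...) {
  print(object)
  v <- object$pattern$values
  cat(sprintf("  template stats: mean %.3g, L2 norm %.6f, range [%.3f, %.3f]\n",
              mean(v), sqrt(sum(v^2)), min(v), max(v)))
  invisible(object)
}

#' @export
coef.nucleosome_model <- function(object, ...) object$pattern$values

#' Predict nucleosome positions
#'
#' Runs the full pipeline on a DNA sequence (or directly on a precomputed
#' curvature curve / score track): curvature curve from the roll/tilt wedge
#' model, matched-filter curvature profile against the model's template,
#' and MSCWT dyad detection.
#'
#' @param object A [nucleosome_model].
#' @param newdata A [genome_sequence], or a [score_track] already on the
#'   curvature-curve scale.
#' @param what `"calls"` (default) returns the `nucleosome_calls` with the
#'   profile attached as attribute `"profile"`; `"profile"` returns the
#'   matched-filter [score_track] itself.
#' @param ... Unused.
#' @return See `what`.
#' @export
predict.nucleosome_model <- function(object, newdata,
                                     what = c("calls", "profile"), ...) {
  what <- match.arg(what)
  curve <- if (inherits(newdata, "genome_sequence")) {
    curvature_curve(newdata, object$roll_tilt, object$params)
  } else if (inherits(newdata, "score_track")) {
    newdata
  } else stop("newdata must be a genome_sequence or a score_track")
  profile <- curvature_profile(curve, object$pattern)
  if (what == "profile") return(profile)
  calls <- detect_dyads(profile, object$peak_params)
  attr(calls, "profile") <- profile
  calls
}

#' @export
summary.nucleosome_calls <- function(object, ...) {
  cat(sprintf("%d nucleosome calls", nrow(object)))
  if (nrow(object)) {
    cat(sprintf(" on %s, dyads %d-%d", object$chrom[1], min(object$dyad),
                max(object$dyad)))
    sp <- spacing_stats(object)
    if (!sp$empty) cat(sprintf("; mean spacing %.1f bp (median %.0f)", sp$mean,
                               sp$median))
  }
  cat("\n")
  invisible(object)
}

#' Plot a nucleosome model's curvature template
#'
#' @param x A [nucleosome_model].
#' @param ... Passed to [graphics::plot].
#' @export
plot.nucleosome_model <- function(x, ...) {
  v <- x$pattern$values
  graphics::plot(seq_along(v) - 1L - x$pattern$dyad_index, v, type = "l",
                 xlab = "offset from dyad (bp)",
                 ylab = "normalized curvature template", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Simulate a sequence-level nucleosome fixture from the model
#'
#' Delegates to [plant_sequence_nucleosomes]: a random genome carrying
#' phased-WW nucleosome cassettes at regular dyads, with the ground truth
#' recorded, so model predictions can be scored against a known answer.
#'
#' @param object A [nucleosome_model].
#' @param nsim Number of fixtures (default 1; a list is returned if > 1).
#' @param seed Integer seed.
#' @param length Sequence length (default 20000).
#' @param dyad_spacing Planted dyad spacing (default 190).
#' @param ... Unused.
#' @return A list with `genome` and `truth` (or a list of such lists).
#' @export
simulate.nucleosome_model <- function(object, nsim = 1, seed = 1L,
                                      length = 20000L, dyad_spacing = 190L, ...) {
  fixtures <- lapply(seq_len(nsim), function(i) {
    plant_sequence_nucleosomes(length, dyad_spacing, seed = seed + i - 1L)
  })
  if (nsim == 1) fixtures[[1]] else fixtures
}
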