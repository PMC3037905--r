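#' Curvature model parameters
#'
#' @param nu0 Helical periodicity in bp per turn; default 10.4, the average
#'   periodicity of the B-DNA double helix.
#' @param window Number of dinucleotide steps integrated per curvature value
#'   (the `n2 - n1` of the curvature sum); default 10, about one helical
#'   turn at `nu0 = 10.4`.
#' @param exp_convention Phase convention of the helical factor:
#'   `"per_step"` (default) uses `exp(2*pi*1i*j/nu0)` so the phase advances a
#'   full turn every `nu0` steps; `"literal"` uses `exp(2*pi*1i*j*nu0)`, the
#'   typographical alternative, retained for comparison only.
#' @return A `curvature_params` list.
#' @export
curvature_params <- function(nu0 = 10.4, window = 10L,
                             exp_convention = c("per_step", "literal")) {
  exp_convention <- match.arg(exp_convention)
  if (!is.finite(nu0) || nu0 <= 0) stop("nu0 must be positive")
  window <- as.integer(window)
  if (is.na(window) || window < 2L) stop("window must be an integer >= 2")
  structure(list(nu0 = nu0, window = window, exp_convention = exp_convention),
            class = "curvature_params")
}

# Complex helical phase weights for window offsets j = 0..W-1.
.phase_weights <- function(params) {
  j <- seq_len(params$window) - 1
  if (params$exp_convention == "per_step") {
    exp(2i * pi * j / params$nu0)
  } else {
    exp(2i * pi * j * params$nu0)
  }
}

#' Curvature modulus of one window of dinucleotide steps
#'
#' The wedge-model curvature vector over a window of W steps is
#' \deqn{C = \frac{\nu_0}{W} \sum_{j=0}^{W-1} (\rho_j - i\,\tau_j)\,
#'   e^{2\pi i j/\nu_0},}
#' with roll \eqn{\rho} and tilt \eqn{\tau} in degrees and \eqn{\nu_0} the
#' helical periodicity. The returned modulus \eqn{|C|} measures the local
#' deviation of the helix axis from straight B-DNA: roll/tilt wedges that
#' recur in helical phase add coherently and give large \eqn{|C|}.
#'
#' @param steps Character vector of `params$window` dinucleotide steps.
#' @param table A `roll_tilt_table`.
#' @param params A [curvature_params].
#' @return The curvature modulus (non-negative scalar, degrees per averaged
#'   step).
#' @export
curvature_at <- function(steps, table, params = curvature_params()) {
  stopifnot(inherits(table, "roll_tilt_table"))
  if (length(steps) != params$window) {
    stop("expected ", params$window, " steps, got ", length(steps))
  }
  unknown <- setdiff(steps, names(table$roll))
  if (length(unknown)) stop("unknown dinucleotide step(s): ", paste(unknown, collapse = ", "))
  z <- complex(real = table$roll[steps], imaginary = -table$tilt[steps])
  Mod(params$nu0 / params$window * sum(z * .phase_weights(params)))
}

#' Curvature curve of a DNA sequence
#'
#' Slides the curvature window along the sequence and assigns each window's
#' curvature modulus to the window's center base (`start + floor(window/2)`
#' in 0-based coordinates). The track has `length(seq) - window` values.
#' Windows whose bases include an N are masked: their value is 0 and the
#' track's `mask` is `TRUE` there (no evidence is not faked as signal).
#'
#' @param seq A [genome_sequence] (length at least `window + 1`).
#' @param table A `roll_tilt_table`.
#' @param params A [curvature_params].
#' @return A [score_track] of curvature moduli, `mask` set where windows
#'   overlap N.
#' @export
curvature_curve <- function(seq, table, params = curvature_params()) {
  stopifnot(inherits(seq, "genome_sequence"), inherits(table, "roll_tilt_table"))
  W <- params$window
  n <- seq$length
  if (n < W + 1L) stop("sequence shorter than window + 1 (", W + 1L, " bp)")
  code <- .encode_bases(seq$seq)
  # step index = 4*first + second + 1 into the canonical AA..TT order
  step_idx <- 4L * code[-n] + code[-1L] + 1L            # NA where a base is N
  roll <- unname(table$roll)[step_idx]
  tilt <- unname(table$tilt)[step_idx]
  z <- complex(real = roll, imaginary = -tilt)
  z_ok <- z
  z_ok[is.na(z)] <- 0 + 0i
  w <- .phase_weights(params)
  n_win <- (n - 1L) - W + 1L                            # = n - W
  acc <- complex(n_win)
  bad <- integer(n_win)
  na_step <- as.integer(is.na(step_idx))
  for (j in seq_len(W)) {
    idx <- j:(j + n_win - 1L)
    acc <- acc + z_ok[idx] * w[j]
    bad <- bad + na_step[idx]
  }
  vals <- Mod(params$nu0 / W * acc)
  mask <- bad > 0L
  vals[mask] <- 0
  score_track(seq$chrom, start = W %/% 2L, values = vals, mask = mask)
}
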