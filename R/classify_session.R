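#' Classify a whole session end to end
#'
#' Convenience wrapper running the full chain: preprocessing (resampling to
#' the working rate, gravity alignment of the ski sensors), motion-component
#' estimation, per-sample decision functions, cycle segmentation from the
#' left-arm angle, and cycle-level majority labelling.
#'
#' @param session a [ski_session] with the four extremity sensors.
#' @param params a [ski_tolerances].
#' @param preprocess run [preprocess_session()] first (default `TRUE`; set
#'   `FALSE` for sessions already on the common clock and aligned).
#' @param leg_gate see [decision_functions()].
#' @return object of class `ski_classification`: list with `components`
#'   (`ski_components`), `samples` (`ski_labels`), `cycles` (`ski_cycles`),
#'   `arm_frequency` (session-level cycle-frequency estimate) and `params`.
#' @export
classify_session <- function(session, params = ski_tolerances(),
                             preprocess = TRUE,
                             leg_gate = c("legMoS", "legMoST")) {
  stopifnot(inherits(session, "ski_session"))
  if (preprocess) session <- preprocess_session(session, params)
  comp <- assemble_components(session, params)
  samples <- classify_series(comp, params, leg_gate)
  la <- session$recordings$left_arm
  intervals <- segment_cycles(la$gyro[, 2], params$fs,
                              band = c(params$lowB, params$highB), t = la$t)
  cycles <- cycle_majority_label(samples, intervals)
  freq <- arm_frequency(la$gyro[, 2],
                        session$recordings$right_arm$gyro[, 2], params$fs)
  structure(list(components = comp, samples = samples, cycles = cycles,
                 arm_frequency = freq, params = params),
            class = "ski_classification")
}

#' @export
print.ski_classification <- function(x, ...) {
  cat("<ski_classification>", nrow(x$samples), "samples,",
      nrow(x$cycles), "cycles\n")
  cat("cycle labels:\n")
  print(table(x$cycles$label))
  if (!is.na(x$arm_frequency))
    cat(sprintf("session arm frequency: %.2f cycles/s\n", x$arm_frequency))
  invisible(x)
}

#' @export
summary.ski_classification <- function(object, ...) {
  print(object)
  cat("\nsample-level distribution:\n")
  d <- distribution_summary(object$cycles, object$samples)
  print(d, digits = 3)
  invisible(d)
}

#' @export
plot.ski_classification <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  lev <- seq_along(TECH_LEVELS)
  graphics::plot(x$samples$t, as.integer(x$samples$label), type = "p",
                 pch = ".", yaxt = "n", xlab = "time (s)",
                 ylab = "per-sample label", ...)
  graphics::axis(2, at = lev, labels = TECH_LEVELS, las = 1, cex.axis = 0.7)
  mid <- (x$cycles$start + x$cycles$stop) / 2
  graphics::plot(mid, as.integer(x$cycles$label), type = "s", yaxt = "n",
                 xlab = "time (s)", ylab = "cycle label", ...)
  graphics::axis(2, at = lev, labels = TECH_LEVELS, las = 1, cex.axis = 0.7)
  invisible(x)
}
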