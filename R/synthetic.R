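# Synthetic multi-sensor session generator.  The field data behind the
# method is not publicly available, so every other module is exercised on
# simulated sessions whose kinematic structure matches the sub-technique
# definitions: anti-phase vs in-phase sinusoidal arm angular rate about the
# lateral axis, independent sagittal/transversal leg motion, vertical-axis
# kick rotation, and gravity-consistent ski accelerometer signals under
# prescribed roll and pitch.

#' Specification of one synthetic technique segment
#'
#' Defaults state realistic conditions for a high-level skier: cycle
#' frequencies per technique in the 0.55--1.0 cycles/s range, arm angular
#' rates of 180 deg/s amplitude (summed windowed variance 32400 (deg/s)^2,
#' well above the 1e4 arm-motion tolerance), sagittal ski-angle amplitudes of
#' 6 deg, vertical kick-rotation amplitudes of 18 deg, a herringbone roll
#' split of 0.35 rad on a 0.15 rad incline, and Gaussian sensor noise of
#' 5 deg/s (gyro) and 0.3 m/s^2 (accel).
#'
#' @param technique one of `DIA, DP, DK, DPrK, rK, HRB, noTech, TCK`.
#' @param duration segment length (s); must exceed 3 cycles.
#' @param cycle_freq cycle frequency (cycles/s); technique default when `NULL`.
#' @param arm_amp lateral-axis arm angular-rate amplitude (deg/s).
#' @param leg_amp sagittal ski/leg angle amplitude (deg).
#' @param kick_rot_amp vertical-axis angle-difference amplitude (deg).
#' @param ski_roll_split inter-ski roll difference (rad).
#' @param pitch terrain incline per ski (rad); positive is uphill.
#' @param hrb_armCorr target arm correlation for HRB (between the DIA and
#'   HRB correlation bounds: the herringbone arm swing is less
#'   anti-synchronized than the diagonal stride).
#' @param noise_sd_gyro,noise_sd_accel per-channel Gaussian noise sd.
#' @param seed integer fixing the randomness of [generate_segment()].
#' @return classed list (`ski_motif`).
#' @export
technique_motif <- function(technique, duration = 60, cycle_freq = NULL,
                            arm_amp = NULL, leg_amp = NULL,
                            kick_rot_amp = NULL, ski_roll_split = NULL,
                            pitch = NULL, hrb_armCorr = -0.45,
                            noise_sd_gyro = 5, noise_sd_accel = 0.3,
                            seed = 1L) {
  technique <- match.arg(technique, c(TECH_LEVELS, "TCK"))
  def <- switch(technique,
    DIA  = list(freq = 0.77, arm = 180, leg = 6, kick = 0, split = 0, pit = 0),
    DP   = list(freq = 0.70, arm = 180, leg = 0, kick = 0, split = 0, pit = 0),
    DK   = list(freq = 0.65, arm = 180, leg = 6, kick = 0, split = 0, pit = 0),
    DPrK = list(freq = 0.75, arm = 180, leg = 6, kick = 18, split = 0, pit = 0),
    rK   = list(freq = 0.55, arm = 20, leg = 6, kick = 18, split = 0, pit = 0),
    HRB  = list(freq = 1.00, arm = 180, leg = 6, kick = 0, split = 0.35,
                pit = 0.15),
    list(freq = 0.70, arm = 0, leg = 0, kick = 0, split = 0, pit = 0))
  spec <- list(technique = technique, duration = duration,
               cycle_freq = if (is.null(cycle_freq)) def$freq else cycle_freq,
               arm_amp = if (is.null(arm_amp)) def$arm else arm_amp,
               leg_amp = if (is.null(leg_amp)) def$leg else leg_amp,
               kick_rot_amp = if (is.null(kick_rot_amp)) def$kick else kick_rot_amp,
               ski_roll_split = if (is.null(ski_roll_split)) def$split else ski_roll_split,
               pitch = if (is.null(pitch)) def$pit else pitch,
               hrb_armCorr = hrb_armCorr,
               noise_sd_gyro = noise_sd_gyro, noise_sd_accel = noise_sd_accel,
               seed = as.integer(seed))
  if (any(c(spec$arm_amp, spec$leg_amp, spec$kick_rot_amp) < 0))
    stop("amplitudes must be >= 0")
  if (spec$duration <= 3 / spec$cycle_freq)
    stop("duration must exceed 3 cycles (", 3 / spec$cycle_freq, " s)")
  structure(spec, class = "ski_motif")
}

# Nominal (noise-free, unfiltered) motion-component values implied by a
# motif's amplitudes; used to assert construction validity.
nominal_components <- function(spec) {
  two_leg <- spec$technique %in% c("DIA", "HRB")
  th_amp <- if (two_leg) 2 * spec$leg_amp else spec$leg_amp
  legMoS <- th_amp^2 / 2
  var_psi <- spec$kick_rot_amp^2 / 2
  armCorr <- switch(spec$technique,
                    DIA = -1, HRB = spec$hrb_armCorr,
                    DP = 1, DK = 1, DPrK = 1, rK = 1, 0)
  if (spec$arm_amp == 0) armCorr <- 0
  list(armMo = spec$arm_amp^2,
       armCorr = armCorr,
       legMoS = legMoS,
       legMoST = legMoS + var_psi,
       kickRot = if (legMoS > 0) sqrt(var_psi / legMoS)
                 else if (var_psi > 0) Inf else 0,
       epsi = spec$ski_roll_split * 2 * spec$pitch)
}

# Assert that the clean motif satisfies its technique's defining
# inequalities with at least a 20% margin; error names the violation.
assert_motif_valid <- function(spec, tol = ski_tolerances(), margin = 1.2) {
  nom <- nominal_components(spec)
  req <- list()
  gt <- function(val, thr, what)
    if (!(val > margin * thr))
      stop(sprintf("unsatisfiable spec (%s): %s = %g does not exceed %g with 20%% margin",
                   spec$technique, what, val, thr))
  lt <- function(val, thr, what)
    if (!(val < thr / margin))
      stop(sprintf("unsatisfiable spec (%s): %s = %g not below %g with 20%% margin",
                   spec$technique, what, val, thr))
  ltneg <- function(val, thr, what)     # strict negative bound, e.g. corr < -0.4
    if (!(val < margin * thr))
      stop(sprintf("unsatisfiable spec (%s): %s = %g not below %g with 20%% margin",
                   spec$technique, what, val, thr))
  switch(spec$technique,
    DIA = { gt(nom$armMo, tol$tol_armMo, "armMo")
            ltneg(nom$armCorr, tol$tol_armDiagD, "armCorr")
            gt(nom$legMoS, tol$tol_legMoS, "legMoS")
            lt(nom$epsi, tol$tol_epsi, "epsi") },
    DP  = { gt(nom$armMo, tol$tol_armMo, "armMo")
            gt(nom$armCorr, tol$tol_armPole, "armCorr")
            lt(nom$legMoS, tol$tol_legMoS, "legMoS")
            lt(nom$legMoST, tol$tol_legMoST, "legMoST") },
    DK  = { gt(nom$armMo, tol$tol_armMo, "armMo")
            gt(nom$armCorr, tol$tol_armPole, "armCorr")
            gt(nom$legMoS, tol$tol_legMoS, "legMoS")
            if (nom$kickRot > tol$tol_kickRot / margin &&
                nom$legMoST > tol$tol_legMoST / margin)
              stop("unsatisfiable spec (DK): kick rotation makes this DPrK") },
    DPrK = { gt(nom$armMo, tol$tol_armMo, "armMo")
             gt(nom$armCorr, tol$tol_armPole, "armCorr")
             gt(nom$kickRot, tol$tol_kickRot, "kickRot")
             gt(nom$legMoST, tol$tol_legMoST, "legMoST") },
    rK  = { lt(nom$armMo, tol$tol_armMo, "armMo")
            gt(nom$kickRot, tol$tol_kickRot, "kickRot")
            gt(nom$legMoST, tol$tol_legMoST, "legMoST") },
    HRB = { gt(nom$armMo, tol$tol_armMo, "armMo")
            ltneg(nom$armCorr, tol$tol_armDiagHrb, "armCorr")
            gt(nom$legMoS, tol$tol_legMoS, "legMoS")
            gt(nom$epsi, tol$tol_epsi, "epsi") },
    { lt(nom$armMo, tol$tol_armMo, "armMo")
      lt(nom$legMoST, tol$tol_legMoST, "legMoST") })
  invisible(nom)
}

# Core signal synthesis for one segment on the grid t = 0, 1/fs, ...
# Returns channel matrices for the four sensors plus truth cycle boundaries.
synth_channels <- function(spec, fs) {
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  w <- 2 * pi * spec$cycle_freq
  A <- spec$arm_amp
  sinwt <- sin(w * t); coswt <- cos(w * t)

  arm_left <- A * sinwt
  arm_right <- switch(spec$technique,
    DIA = -arm_left,
    HRB = {
      a <- -spec$hrb_armCorr
      A * (-a * sinwt + sqrt(max(0, 1 - a^2)) * coswt)
    },
    A * sinwt)

  # sagittal ski angles (deg): two-leg alternation for diagonal-type
  # techniques, single-leg kick for the poling-with-kick family
  th_left <- th_right <- numeric(n)
  if (spec$leg_amp > 0) {
    if (spec$technique %in% c("DIA", "HRB")) {
      th_left <- spec$leg_amp * sinwt
      th_right <- -spec$leg_amp * sinwt
    } else if (spec$technique %in% c("DK", "DPrK", "rK")) {
      th_left <- spec$leg_amp * sinwt
    }
  }
  # vertical-axis rotation (deg), carried by the kicking (left) ski
  psi_left <- if (spec$kick_rot_amp > 0) spec$kick_rot_amp * sinwt
              else numeric(n)

  deg2rad <- pi / 180
  roll_left <- rep(spec$ski_roll_split / 2, n)
  roll_right <- rep(-spec$ski_roll_split / 2, n)
  pitch_left <- spec$pitch + th_left * deg2rad
  pitch_right <- spec$pitch + th_right * deg2rad

  drate <- function(angle) c(0, diff(angle)) * fs    # deg -> deg/s
  list(t = t, n = n,
       arm_left = arm_left, arm_right = arm_right,
       ski_left_gy = drate(th_left), ski_right_gy = drate(th_right),
       ski_left_gx = drate(psi_left), ski_right_gx = numeric(n),
       accel_left = gravity_forward(roll_left, pitch_left),
       accel_right = gravity_forward(roll_right, pitch_right),
       cycles = synth_true_cycles(spec))
}

# True cycle boundaries: instants of maximal backward extension of the limb
# that defines the cycle (left arm, or the active leg for rK).
synth_true_cycles <- function(spec) {
  f <- spec$cycle_freq
  if (spec$technique %in% c("noTech", "TCK") || spec$arm_amp == 0 &&
      spec$leg_amp == 0)
    return(data.frame(start = numeric(0), stop = numeric(0)))
  phase0 <- if (spec$technique == "rK") 0.25 else 0.5  # angle maxima of sin drive
  b <- seq(phase0 / f, spec$duration, by = 1 / f)
  b <- b[b < spec$duration]
  if (length(b) < 2L) return(data.frame(start = numeric(0), stop = numeric(0)))
  data.frame(start = b[-length(b)], stop = b[-1L])
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate one labelled synthetic technique segment
#'
#' Synthesizes the four extremity sensor streams for one technique motif,
#' adds seeded Gaussian noise, and returns the recordings together with the
#' ground-truth per-sample labels and true cycle boundaries.  Before
#' generating, the motif's amplitudes are checked against the technique's
#' defining inequalities with a 20% margin; an impossible motif (e.g. a DP
#' spec with strong independent leg motion) errors, naming the violated
#' inequality.
#'
#' @param spec a [technique_motif()].
#' @param fs sampling frequency (samples/s), default 20.
#' @param tol tolerances used for the validity assertion.
#' @return list with `recordings` (named list of four [ski_recording]s),
#'   `labels` (data frame `t`, `label`), and `cycles` (true boundaries with
#'   per-cycle label).
#' @export
generate_segment <- function(spec, fs = 20, tol = ski_tolerances()) {
  stopifnot(inherits(spec, "ski_motif"))
  assert_motif_valid(spec, tol)
  ch <- with_seed(spec$seed, {
    ch <- synth_channels(spec, fs)
    ch$noise <- list(g = matrix(stats::rnorm(ch$n * 12, 0, spec$noise_sd_gyro),
                                ch$n, 12),
                     a = matrix(stats::rnorm(ch$n * 12, 0, spec$noise_sd_accel),
                                ch$n, 12))
    ch
  })
  n <- ch$n
  z <- numeric(n)
  g <- ch$noise$g; a <- ch$noise$a
  mk <- function(pl, gx, gy, gz, acc, k) {
    ski_recording(pl, ch$t,
                  cbind(gx, gy, gz) + g[, (3 * k - 2):(3 * k)],
                  acc + a[, (3 * k - 2):(3 * k)], fs)
  }
  flat_acc <- cbind(z, z, rep(-STANDARD_GRAVITY, n))
  recs <- list(
    left_arm = mk("left_arm", z, ch$arm_left, z, flat_acc, 1L),
    right_arm = mk("right_arm", z, ch$arm_right, z, flat_acc, 2L),
    left_ski = mk("left_ski", ch$ski_left_gx, ch$ski_left_gy, z,
                  ch$accel_left, 3L),
    right_ski = mk("right_ski", ch$ski_right_gx, ch$ski_right_gy, z,
                   ch$accel_right, 4L))
  truth_label <- if (spec$technique == "TCK") "noTech" else spec$technique
  cyc <- ch$cycles
  if (nrow(cyc)) cyc$label <- factor(truth_label, levels = TECH_LEVELS)
  list(recordings = recs,
       labels = data.frame(t = ch$t,
                           label = factor(truth_label, levels = TECH_LEVELS)),
       cycles = cyc)
}

#' Generate a labelled multi-segment synthetic session
#'
#' Concatenates technique segments into one session.  At each junction the
#' signals are cross-faded with half-cosine ramps over `fade` seconds, and
#' ground-truth samples (and true cycles touching the junction) within
#' `fade/2` of it are flagged as transitions; transition cycles are excluded
#' from accuracy accounting, mirroring the ambiguity of expert-labelled
#' transition cycles.
#'
#' @param specs list of [technique_motif()]s (>= 1).
#' @param fs sampling frequency (samples/s).
#' @param seed root seed; segment seeds are derived from it, so a fixed seed
#'   makes the output fully reproducible.
#' @param fade transition cross-fade length (s).
#' @param tol tolerances for the per-motif validity assertion.
#' @return list of class `ski_synthetic` with elements `session`
#'   ([ski_session]), `labels` (data frame `t`, `label`, `transition`) and
#'   `cycles` (data frame `start`, `stop`, `label`, `transition`).
#' @export
generate_session <- function(specs, fs = 20, seed = 1L, fade = 1,
                             tol = ski_tolerances()) {
  if (!length(specs)) stop("need at least one motif spec")
  if (inherits(specs, "ski_motif")) specs <- list(specs)
  specs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    s$seed <- (as.integer(seed) * 1000L + i) %% .Machine$integer.max
    s
  })
  segs <- lapply(specs, generate_segment, fs = fs, tol = tol)

  half <- fade / 2
  nseg <- length(segs)
  offs <- cumsum(c(0, vapply(specs, `[[`, numeric(1L), "duration")))[1:nseg]
  total_n <- sum(vapply(segs, function(s) nrow(s$labels), integer(1L)))

  taper <- function(x, t_local, dur, first, last) {
    w <- rep(1, length(x))
    if (!first) {
      i <- t_local < half
      w[i] <- 0.5 - 0.5 * cos(pi * t_local[i] / half)
    }
    if (!last) {
      i <- t_local > dur - half
      w[i] <- pmin(w[i], 0.5 - 0.5 * cos(pi * (dur - t_local[i]) / half))
    }
    x * w
  }

  recs_out <- lapply(PLACEMENTS[1:4], function(pl) {
    t_all <- numeric(0); gy <- acc <- NULL
    for (i in seq_len(nseg)) {
      r <- segs[[i]]$recordings[[pl]]
      dur <- specs[[i]]$duration
      gmat <- apply(r$gyro, 2, taper, t_local = r$t, dur = dur,
                    first = i == 1L, last = i == nseg)
      grav <- colMeans(r$accel)   # keep the gravity component through fades
      amat <- apply(sweep(r$accel, 2, grav), 2, taper, t_local = r$t,
                    dur = dur, first = i == 1L, last = i == nseg)
      amat <- sweep(amat, 2, grav, `+`)
      t_all <- c(t_all, r$t + offs[i])
      gy <- rbind(gy, gmat); acc <- rbind(acc, amat)
    }
    ski_recording(pl, t_all, gy, acc, fs)
  })
  names(recs_out) <- PLACEMENTS[1:4]

  junctions <- offs[-1L]
  labels <- do.call(rbind, lapply(seq_len(nseg), function(i) {
    d <- segs[[i]]$labels
    d$t <- d$t + offs[i]
    d
  }))
  labels$transition <- Reduce(`|`, lapply(junctions, function(j)
    abs(labels$t - j) < half), rep(FALSE, nrow(labels)))

  cycles <- do.call(rbind, lapply(seq_len(nseg), function(i) {
    cyc <- segs[[i]]$cycles
    if (!nrow(cyc)) return(cyc)
    cyc$start <- cyc$start + offs[i]
    cyc$stop <- cyc$stop + offs[i]
    cyc
  }))
  if (is.null(cycles) || !nrow(cycles)) {
    cycles <- data.frame(start = numeric(0), stop = numeric(0),
                         label = factor(character(0), levels = TECH_LEVELS),
                         transition = logical(0))
  } else {
    cycles$transition <- Reduce(`|`, lapply(junctions, function(j)
      cycles$start < j + half & cycles$stop > j - half),
      rep(FALSE, nrow(cycles)))
  }

  structure(list(session = ski_session(recs_out),
                 labels = labels, cycles = cycles),
            class = "ski_synthetic")
}

#' @export
print.ski_synthetic <- function(x, ...) {
  cat("<ski_synthetic> session of", nrow(x$labels), "samples;",
      nrow(x$cycles), "true cycles\n")
  print(table(ground_truth = x$labels$label,
              transition = x$labels$transition))
  invisible(x)
}
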