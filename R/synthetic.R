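## Synthetic cohort simulator: paired load-cell (BCG) + BP recordings with
## the statistical structure the regression method assumes.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' previous RNG state afterwards, so simulation functions are pure in
#' (arguments, seed) and do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-participant seed from a master seed
#'
#' Deterministic integer mixing (two rounds of a Lehmer-style congruential
#' step, all arithmetic exact in doubles below 2^53) so that cohort
#' generation is a pure function of the master seed and the participant
#' index, stable across platforms.
#'
#' @param masterSeed integer master seed.
#' @param index participant index (1-based).
#' @return An integer in `[0, 2^31 - 1]`.
#' @examples
#' deriveSeed(7, 1:3)
#' @export
deriveSeed <- function(masterSeed, index) {
  m <- 2^31
  x <- (abs(as.numeric(masterSeed)) %% m)
  out <- vapply(as.numeric(index), function(i) {
    y <- (x * 69069 + i * 12345 + 1) %% m
    y <- (y * 69069 + 1) %% m
    y
  }, 0)
  as.integer(out)
}

#' Participant-level simulation parameters
#'
#' Bundles the physiological and instrumental parameters of one simulated
#' participant. Defaults describe a normotensive adult at rest; systolic
#' and diastolic levels must lie inside the extrema-detection amplitude
#' gates ((100, 150) and (60, 100) mmHg) so downstream SBP/DBP extraction
#' accepts every beat.
#'
#' @param participant_id identifier string.
#' @param sbp_level,dbp_level systolic / diastolic level, mmHg.
#' @param heart_rate mean heart rate, beats/min.
#' @param hr_jitter_sd SD of the per-beat heart-rate jitter, beats/min.
#' @param resp_rate respiratory rate, breaths/min.
#' @param resp_amplitude amplitude of the respiratory BP modulation, mmHg
#'   (the load-cell respiratory component is fixed at 0.1 signal units).
#' @param channel_gains numeric length 4, dimensionless per-channel gains.
#' @param noise_sd per-channel white-noise SD, signal units.
#' @param drift_amplitude amplitude of the slow (90 s period) drift of
#'   the pressure levels, mmHg; the load-cell wavelet amplitudes track
#'   the drifting level beat by beat, and a small fixed baseline drift
#'   (0.2 signal units) is added to each channel whenever drift is on.
#' @param seed integer seed making the participant's recording
#'   deterministic.
#' @return A validated list of class `ParticipantParams`.
#' @examples
#' p <- participantParams("P01", sbp_level = 125, dbp_level = 75)
#' rec <- simulateParticipant(p, duration = 10, fs = 100)
#' @export
participantParams <- function(participant_id = "P01",
                              sbp_level = 120, dbp_level = 80,
                              heart_rate = 65, hr_jitter_sd = 1.5,
                              resp_rate = 14, resp_amplitude = 2,
                              channel_gains = c(1, 0.95, 1.05, 0.9),
                              noise_sd = 0.05, drift_amplitude = 4,
                              seed = 1L) {
  p <- list(
    participant_id = as.character(participant_id),
    sbp_level = sbp_level, dbp_level = dbp_level,
    heart_rate = heart_rate, hr_jitter_sd = hr_jitter_sd,
    resp_rate = resp_rate, resp_amplitude = resp_amplitude,
    channel_gains = channel_gains, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, seed = as.integer(seed)
  )
  if (p$sbp_level <= p$dbp_level)
    stop("sbp_level must exceed dbp_level")
  if (p$sbp_level <= 100 || p$sbp_level >= 150)
    stop("sbp_level must lie in (100, 150) mmHg")
  if (p$dbp_level <= 60 || p$dbp_level >= 100)
    stop("dbp_level must lie in (60, 100) mmHg")
  if (p$heart_rate <= 0 || p$resp_rate <= 0)
    stop("heart_rate and resp_rate must be positive")
  if (p$noise_sd < 0 || p$hr_jitter_sd < 0)
    stop("noise_sd and hr_jitter_sd must be non-negative")
  if (length(p$channel_gains) != 4L)
    stop("channel_gains must have length 4")
  class(p) <- "ParticipantParams"
  p
}

## Biphasic BCG-like wavelets mimicking the ringing I-J-K complex, shared
## by all participants so the load-cell-to-BP mapping transfers across
## individuals. Each beat emits three superposed damped oscillations in
## distinct bands: a pulse wavelet carrying the beat's pulse pressure, an
## 8 Hz wavelet carrying the instantaneous diastolic level (a
## stiffness-like association), and a fixed-amplitude 12 Hz pilot
## (mass-driven recoil) against which amplitude ratios cancel the unknown
## channel gain. The ~0.7 s support keeps every 0.5-s input window
## informative about the most recent beat, and the spectral separation
## makes the quantities separately decodable.
bcgKernels <- function(fs) {
  tau <- seq(0, 0.7, by = 1 / fs)
  # pulse wavelet: the ejection force is modeled as the rate of change of
  # the pressure template (biphasic by construction), with a superposed
  # 4.5 Hz ring; its amplitude carries the beat's pulse pressure
  g <- beatShape(tau)
  dg <- c(0, diff(g)) * fs
  pulse <- dg / max(abs(dg)) + 0.5 * sin(2 * pi * 4.5 * tau) * exp(-tau / 0.15)
  list(
    pulse = pulse,
    level = sin(2 * pi * 8 * tau) * exp(-tau / 0.12),
    # pilot: a recoil component of fixed amplitude (mass-driven, not
    # pressure-driven); ratios against it cancel the unknown channel gain
    pilot = sin(2 * pi * 12 * tau) * exp(-tau / 0.10)
  )
}

## Fixed-duration beat template on phase tau: raised-cosine upstroke from
## DBP to SBP over 0.15 s, shifted-exponential relaxation back to DBP over
## the next 0.35 s, then a diastolic plateau until the next onset
## (continuous, max = SBP, min = DBP). The fixed shape makes the pressure
## waveform a true convolution of the beat impulse train, so the
## load-cell-to-BP mapping is the same linear-time-invariant relation for
## every participant regardless of heart rate.
beatShape <- function(tau, upstroke = 0.15, relax = 0.35) {
  s <- (tau - upstroke) / relax
  k <- 5
  out <- numeric(length(tau))
  up <- tau < upstroke
  dn <- !up & tau < upstroke + relax
  out[up] <- (1 - cos(pi * tau[up] / upstroke)) / 2
  out[dn] <- (exp(-k * s[dn]) - exp(-k)) / (1 - exp(-k))
  out
}

#' Simulate one participant's paired load-cell + BP recording
#'
#' Generates a beat-by-beat arterial pressure waveform (raised-cosine
#' upstroke, exponential relaxation to a diastolic plateau, respiratory
#' modulation and a slow drift of the pressure levels) and four BCG-like
#' load-cell channels: a cardiac impulse train at the beat onsets
#' convolved with three superposed biphasic damped-oscillation wavelets —
#' a pulse component scaled affinely by the beat's pulse pressure
#' (sbp - dbp), an 8 Hz component scaled by the instantaneous diastolic
#' level, and a fixed-amplitude 12 Hz pilot — plus a respiratory
#' component, white noise and baseline drift, each channel scaled by its
#' own gain and delayed by 10 ms per channel index. The spectral
#' separation of the wavelets, and ratios against the pilot, make the
#' mapping from a 0.5-s load-cell window to the concurrent BP sample
#' learnable by construction. Deterministic given `params$seed`.
#'
#' @param params a [participantParams()] object.
#' @param duration recording length, seconds.
#' @param fs sampling frequency, 100 or 1000 Hz.
#' @return A [LoadCellRecording-class].
#' @examples
#' rec <- simulateParticipant(participantParams(seed = 3), duration = 20)
#' range(bpWaveform(rec))
#' @export
simulateParticipant <- function(params, duration = 480, fs = 100) {
  if (!inherits(params, "ParticipantParams"))
    stop("params must come from participantParams()")
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!fs %in% c(100, 1000))
    stop("fs must be 100 or 1000 Hz")
  withSeed(params$seed, {
    L <- round(duration * fs)
    t <- (seq_len(L) - 1) / fs

    ## beat onsets: inter-beat interval 60 / (HR + jitter), instantaneous
    ## HR clamped to [30, 105] so beats never overlap the 0.5 s template
    onsets <- 0
    while (tail(onsets, 1) < duration + 2) {
      hr <- min(105, max(30,
        params$heart_rate + rnorm(1, 0, params$hr_jitter_sd)))
      onsets <- c(onsets, tail(onsets, 1) + 60 / hr)
    }

    ## beat onsets snap to the sample grid so the force encoding and the
    ## pressure waveform share one clock
    onsets <- round(onsets * fs) / fs

    ## slow drift of the pressure level (vasomotor-like, 90 s period),
    ## shared by the systolic and diastolic levels
    phiR <- runif(1, 0, 2 * pi)
    levelDrift <- params$drift_amplitude * sin(2 * pi * t / 90 + phiR)

    ## BP waveform
    k <- findInterval(t, onsets)
    tau <- t - onsets[k]
    pp <- params$sbp_level - params$dbp_level
    bp <- params$dbp_level + levelDrift + pp * beatShape(tau)
    bp <- bp + params$resp_amplitude * sin(2 * pi * params$resp_rate / 60 * t)

    ## load-cell channels: per-beat wavelet amplitudes track the
    ## instantaneous pressure levels at the beat onset
    kerns <- bcgKernels(fs)
    beatIdx <- round(onsets * fs) + 1
    beatIdx <- beatIdx[beatIdx >= 1 & beatIdx <= L]
    impP <- numeric(L)
    impP[beatIdx] <- pp / 50
    impL <- numeric(L)
    impL[beatIdx] <- (params$dbp_level + levelDrift[beatIdx] - 60) / 40
    impC <- numeric(L)
    impC[beatIdx] <- 0.6
    causalConv <- function(x, kern) {
      K <- length(kern)
      xpad <- c(numeric(K - 1), x)
      as.numeric(stats::filter(xpad, kern,
        method = "convolution", sides = 1))[K:(K + L - 1)]
    }
    pulse <- causalConv(impP, kerns$pulse) + causalConv(impL, kerns$level) +
      causalConv(impC, kerns$pilot)

    lc <- matrix(0, 4, L)
    for (j in 1:4) {
      d <- round((j - 1) * 0.01 * fs)  # 10 ms inter-channel delay
      pj <- c(numeric(d), pulse)[seq_len(L)]
      # respiration on the load cells is phase-locked to the breath that
      # modulates BP, with a fixed per-channel mechanical phase offset
      psi <- (j - 1) * pi / 4
      phiD <- runif(1, 0, 2 * pi)
      baseDrift <- if (params$drift_amplitude > 0) 0.2 else 0
      lc[j, ] <- params$channel_gains[j] * pj +
        0.1 * sin(2 * pi * params$resp_rate / 60 * t + psi) +
        baseDrift * sin(2 * pi * t / 90 + phiD) +
        rnorm(L, 0, params$noise_sd)
    }
    loadCellRecording(params$participant_id, fs, lc, bp)
  })
}

#' Simulate a cohort of participants
#'
#' Draws per-participant parameters from fixed population distributions
#' (SBP ~ U(108, 142), DBP ~ U(68, 92) mmHg, heart rate ~ N(65, 8)
#' truncated above 40 beats/min, respiratory rate ~ U(10, 18) breaths/min,
#' channel gains ~ U(0.9, 1.1)) and simulates one recording per
#' participant. Per-participant seeds are derived deterministically from
#' `masterSeed` via [deriveSeed()], so the whole cohort is a pure function
#' of its arguments.
#'
#' @param n_participants number of participants (>= 1).
#' @param duration recording length per participant, seconds.
#' @param fs sampling frequency, 100 or 1000 Hz.
#' @param masterSeed integer master seed.
#' @param noise_sd,drift_amplitude,hr_jitter_sd,resp_amplitude overrides of
#'   the corresponding [participantParams()] fields, applied to every
#'   participant.
#' @param return_params if `TRUE`, attach the drawn parameter list as
#'   attribute `"params"`.
#' @return A list of [LoadCellRecording-class] objects named by
#'   participant id.
#' @examples
#' cohort <- simulateCohort(3, duration = 10, masterSeed = 7)
#' names(cohort)
#' @export
simulateCohort <- function(n_participants, duration = 480, fs = 100,
                           masterSeed = 1L, noise_sd = 0.05,
                           drift_amplitude = 4, hr_jitter_sd = 1.5,
                           resp_amplitude = 2, return_params = FALSE) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  ids <- sprintf("P%02d", seq_len(n_participants))
  seeds <- deriveSeed(masterSeed, seq_len(n_participants))
  params <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    params[[i]] <- withSeed(seeds[i], {
      hr <- 0
      while (hr <= 40) hr <- rnorm(1, 65, 8)
      participantParams(
        participant_id = ids[i],
        sbp_level = runif(1, 108, 142),
        dbp_level = runif(1, 68, 92),
        heart_rate = hr,
        hr_jitter_sd = hr_jitter_sd,
        resp_rate = runif(1, 10, 18),
        resp_amplitude = resp_amplitude,
        channel_gains = runif(4, 0.9, 1.1),
        noise_sd = noise_sd,
        drift_amplitude = drift_amplitude,
        seed = deriveSeed(seeds[i], 1L)
      )
    })
  }
  cohort <- lapply(params, simulateParticipant, duration = duration, fs = fs)
  names(cohort) <- ids
  if (return_params) attr(cohort, "params") <- setNames(params, ids)
  cohort
}
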