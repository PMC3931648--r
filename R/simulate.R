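#' Behaviour template for the signal simulator
#'
#' A template describes the characteristic acceleration signature of one
#' behaviour as the sum of a static (postural) component — the 1-g gravity
#' vector as seen by a device held at a given pitch and roll — plus zero or
#' more dynamic (movement) sinusoids on individual axes, plus i.i.d.
#' Gaussian sensor noise per axis.
#'
#' Orientation convention: an upright device reads `(0, 0, -1)` g; `pitch`
#' rotates about the x-axis, then `roll` about the y-axis, both in degrees.
#'
#' @param name Behaviour name (non-empty string).
#' @param pitch,roll Device posture relative to gravity, in degrees.
#' @param components Dynamic components: a list of lists/vectors with
#'   fields `axis` (one of `"x"`, `"y"`, `"z"`), `freq` (Hz), `amp`
#'   (amplitude in g, >= 0) and optional `phase` (radians, default 0).
#' @param noise_sd Standard deviation of the per-axis Gaussian noise, in g.
#' @return An object of class `behavior_template`.
#' @examples
#' walk <- behavior_template("Walk", pitch = 15, roll = 0,
#'   components = list(list(axis = "z", freq = 2, amp = 0.25)),
#'   noise_sd = 0.05)
#' @export
behavior_template <- function(name, pitch = 0, roll = 0,
                              components = list(), noise_sd = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a non-empty string", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  comps <- lapply(components, function(cm) {
    cm <- as.list(cm)
    if (is.null(cm$axis) || !cm$axis %in% c("x", "y", "z"))
      stop("component axis must be one of x, y, z", call. = FALSE)
    freq <- as.numeric(cm$freq); amp <- as.numeric(cm$amp)
    phase <- if (is.null(cm$phase)) 0 else as.numeric(cm$phase)
    if (!is.finite(freq) || freq <= 0)
      stop("component freq must be a positive frequency in Hz",
           call. = FALSE)
    if (!is.finite(amp) || amp < 0)
      stop("component amp must be >= 0 g", call. = FALSE)
    list(axis = cm$axis, freq = freq, amp = amp, phase = phase)
  })
  structure(list(name = name, pitch = as.numeric(pitch),
                 roll = as.numeric(roll), components = comps,
                 noise_sd = as.numeric(noise_sd)),
            class = "behavior_template")
}

# Static gravity vector for a device pitched then rolled from upright
# (upright reads (0, 0, -1) g); angles in degrees.
static_gravity <- function(pitch, roll) {
  p <- pitch * pi / 180; r <- roll * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(p), -sin(p),
                 0, sin(p), cos(p)), 3L, 3L, byrow = TRUE)
  ry <- matrix(c(cos(r), 0, sin(r),
                 0, 1, 0,
                 -sin(r), 0, cos(r)), 3L, 3L, byrow = TRUE)
  as.vector(ry %*% rx %*% c(0, 0, -1))
}

#' Simulate one labelled behaviour segment
#'
#' Generates `round(seconds * sample_rate)` samples of the template's
#' signal: sample at time t is the static gravity vector plus the sum of
#' the template's sinusoids `amp * sin(2 * pi * freq * t + phase)` on their
#' axes, plus independent Gaussian noise per axis.  Every component
#' frequency must lie below the Nyquist limit `sample_rate / 2` (the
#' sample rate must be at least twice the fastest movement present).
#'
#' @param template A [behavior_template].
#' @param seconds Segment duration in seconds (> 0).
#' @param sample_rate Sampling frequency in Hz.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A fully labelled [accel_dataset] carrying the template name.
#' @export
simulate_segment <- function(template, seconds, sample_rate, seed = NULL) {
  stopifnot(inherits(template, "behavior_template"))
  if (!is.numeric(seconds) || seconds <= 0)
    stop("seconds must be positive", call. = FALSE)
  for (cm in template$components)
    if (cm$freq >= sample_rate / 2)
      stop("component frequency ", cm$freq, " Hz violates the Nyquist ",
           "limit at ", sample_rate, " Hz sampling", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(seconds * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  g <- static_gravity(template$pitch, template$roll)
  sig <- matrix(rep(g, each = n), n, 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  for (cm in template$components)
    sig[, cm$axis] <- sig[, cm$axis] +
      cm$amp * sin(2 * pi * cm$freq * t + cm$phase)
  if (template$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(3L * n, sd = template$noise_sd), n, 3L)
  accel_dataset(x = sig[, "x"], y = sig[, "y"], z = sig[, "z"],
                sample_rate = sample_rate, t = t,
                label = rep(template$name, n))
}

#' Simulation specification: an ethogram of behaviour templates
#'
#' Bundles the behaviour templates with the recording design: how many
#' seconds of each behaviour to generate, at what sample rate, and under
#' which seed.  The default design — 10 s per behaviour — yields 200
#' samples per behaviour at 20 Hz, so a five-behaviour ethogram gives a
#' 1000-sample set at 20 Hz and a 2000-sample set at 40 Hz.
#'
#' @param templates List of [behavior_template]s with distinct names.
#' @param seconds_per_behavior Seconds of signal per behaviour (default 10).
#' @param sample_rate Sampling frequency in Hz (default 20).
#' @param seed Integer seed (default 1).
#' @param phase_jitter If `TRUE`, each dynamic component's phase is offset
#'   by an independent uniform draw on `[0, 2 * pi)` per generated segment,
#'   so training and testing segments are not trivially identical periodic
#'   traces.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(templates, seconds_per_behavior = 10,
                     sample_rate = 20, seed = 1L, phase_jitter = FALSE) {
  if (length(templates) < 1L ||
      !all(vapply(templates, inherits, TRUE, "behavior_template")))
    stop("templates must be a non-empty list of behavior_template",
         call. = FALSE)
  nm <- vapply(templates, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate template names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (seconds_per_behavior <= 0 || sample_rate <= 0)
    stop("seconds_per_behavior and sample_rate must be positive",
         call. = FALSE)
  structure(list(templates = templates,
                 seconds_per_behavior = as.numeric(seconds_per_behavior),
                 sample_rate = as.numeric(sample_rate),
                 seed = as.integer(seed),
                 phase_jitter = isTRUE(phase_jitter)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d behaviours x %g s at %g Hz (seed %d)\n",
              length(x$templates), x$seconds_per_behavior, x$sample_rate,
              x$seed))
  for (tp in x$templates)
    cat(sprintf("  %-8s pitch %5.1f roll %5.1f, %d dynamic component(s), noise %g g\n",
                tp$name, tp$pitch, tp$roll, length(tp$components),
                tp$noise_sd))
  invisible(x)
}

#' Simulate matched training and testing recordings
#'
#' Emulates obtaining data on two separate occasions: two datasets with the
#' identical behaviour schedule (one segment per template, in template
#' order, each `seconds_per_behavior` long) but independent noise and
#' phase-jitter draws — the training set from `spec$seed`, the testing set
#' from `spec$seed + 1`.  Both retain true labels; the testing labels are
#' for later verification of the classifier output.
#'
#' `posture_offset` adds a fixed number of degrees to every test template's
#' pitch and roll before generation, emulating a device that shifted
#' position between the training and testing occasions (e.g. a rotated
#' collar); the training set is never offset.
#'
#' @param spec A [sim_spec].
#' @param posture_offset Degrees added to test-set template pitch and roll:
#'   a single number (applied to both) or a length-2 vector
#'   `c(pitch, roll)`.  Default 0.
#' @return A list with fully labelled [accel_dataset]s `training` and
#'   `testing`.
#' @examples
#' sets <- simulate_dataset(default_ethogram(seed = 3))
#' nrow(sets$training)  # 5 behaviours x 10 s x 20 Hz = 1000
#' @export
simulate_dataset <- function(spec, posture_offset = 0) {
  stopifnot(inherits(spec, "sim_spec"))
  off <- rep(as.numeric(posture_offset), length.out = 2L)
  gen <- function(seed, templates) {
    set.seed(seed)
    segs <- vector("list", length(templates))
    for (i in seq_along(templates)) {
      tp <- templates[[i]]
      if (spec$phase_jitter && length(tp$components) > 0L)
        tp$components <- lapply(tp$components, function(cm) {
          cm$phase <- cm$phase + stats::runif(1L, 0, 2 * pi)
          cm
        })
      segs[[i]] <- simulate_segment(tp, spec$seconds_per_behavior,
                                    spec$sample_rate, seed = NULL)
    }
    bind_segments(segs, spec)
  }
  offset_templates <- lapply(spec$templates, function(tp) {
    tp$pitch <- tp$pitch + off[1L]
    tp$roll <- tp$roll + off[2L]
    tp
  })
  list(training = gen(spec$seed, spec$templates),
       testing = gen(spec$seed + 1L, offset_templates))
}

# Concatenate per-behaviour segments into one dataset with a continuous
# global time axis.
bind_segments <- function(segs, spec) {
  shift <- 0
  for (i in seq_along(segs)) {
    segs[[i]]$t <- segs[[i]]$t + shift
    shift <- shift + spec$seconds_per_behavior
  }
  all <- do.call(rbind, lapply(segs, as.data.frame))
  accel_dataset(x = all$x, y = all$y, z = all$z,
                sample_rate = spec$sample_rate, t = all$t,
                label = all$label)
}

#' Packaged five-behaviour ethogram
#'
#' A ready-made simulation spec with the five human behaviours Stand,
#' Lying, Walk, Run and Crawl, 10 s each at 20 Hz.  The templates are
#' synthetic fixture choices (no published signal parameters exist for
#' these behaviours) designed to be well separated in the raw (x, y, z)
#' feature space: postures at least 15 degrees apart, Walk and Run
#' distinguished by both lean and gait frequency/amplitude, and modest
#' sensor noise (0.05 g) relative to those separations.
#'
#' @param sample_rate Sampling frequency in Hz (default 20).
#' @param seconds_per_behavior Seconds per behaviour (default 10).
#' @param seed Integer seed (default 1).
#' @param noise_sd Per-axis Gaussian noise sd in g for every behaviour
#'   (default 0.05).
#' @param phase_jitter Randomize dynamic-component phases per segment
#'   (default `TRUE`, so training and testing gait traces are out of
#'   phase as on two real occasions).
#' @return A [sim_spec] with five templates.
#' @export
default_ethogram <- function(sample_rate = 20, seconds_per_behavior = 10,
                             seed = 1L, noise_sd = 0.05,
                             phase_jitter = TRUE) {
  tpl <- list(
    behavior_template("Stand", pitch = 0, roll = 0, noise_sd = noise_sd),
    behavior_template("Lying", pitch = 90, roll = 0, noise_sd = noise_sd),
    behavior_template("Walk", pitch = 15, roll = 0, noise_sd = noise_sd,
      components = list(list(axis = "z", freq = 2, amp = 0.25),
                        list(axis = "x", freq = 2, amp = 0.1,
                             phase = pi / 2))),
    behavior_template("Run", pitch = 30, roll = 0, noise_sd = noise_sd,
      components = list(list(axis = "z", freq = 3.5, amp = 0.5),
                        list(axis = "x", freq = 3.5, amp = 0.2,
                             phase = pi / 2))),
    behavior_template("Crawl", pitch = 60, roll = 20, noise_sd = noise_sd,
      components = list(list(axis = "z", freq = 1, amp = 0.15))))
  sim_spec(tpl, seconds_per_behavior = seconds_per_behavior,
           sample_rate = sample_rate, seed = seed,
           phase_jitter = phase_jitter)
}

#' Read a simulation spec from a YAML config file
#'
#' The config is a plain-text YAML document with optional top-level keys
#' `sample_rate`, `seconds_per_behavior`, `seed`, `phase_jitter` and a
#' required `behaviors` list; each behaviour has `name`, `pitch`, `roll`,
#' `noise_sd` and an optional `components` list of `{axis, freq, amp,
#' phase}` entries.  See `system.file("extdata", "ethogram_default.yml",
#' package = "accelknn")` for a complete example.
#'
#' @param path Path to the YAML file.
#' @param seed Seed overriding any `seed` key in the file (optional).
#' @return A [sim_spec].
#' @export
read_sim_spec <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$behaviors) || length(cfg$behaviors) == 0L)
    stop("config must define a non-empty 'behaviors' list", call. = FALSE)
  tpl <- lapply(cfg$behaviors, function(b) {
    if (is.null(b$name)) stop("behaviour entry lacks a name", call. = FALSE)
    behavior_template(name = b$name,
                      pitch = if (is.null(b$pitch)) 0 else b$pitch,
                      roll = if (is.null(b$roll)) 0 else b$roll,
                      components = if (is.null(b$components)) list()
                                   else b$components,
                      noise_sd = if (is.null(b$noise_sd)) 0 else b$noise_sd)
  })
  sim_spec(tpl,
           seconds_per_behavior = if (is.null(cfg$seconds_per_behavior)) 10
                                  else cfg$seconds_per_behavior,
           sample_rate = if (is.null(cfg$sample_rate)) 20
                         else cfg$sample_rate,
           seed = if (!is.null(seed)) seed
                  else if (!is.null(cfg$seed)) cfg$seed else 1L,
           phase_jitter = isTRUE(cfg$phase_jitter))
}
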