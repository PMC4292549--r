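#' Exact stochastic simulation of the gating chain
#'
#' Gillespie simulation of the continuous-time Markov chain: the holding
#' time in state i is Exponential with rate equal to the total exit rate,
#' and the next state is drawn with probability proportional to the
#' outgoing rate.  The initial state is drawn from the stationary
#' distribution by default.
#'
#' @param model A [gating_model()].
#' @param duration Total simulated time in ms (ignored if `n_events` given
#'   without it).
#' @param n_events Optional cap on the number of sojourns; simulate exactly
#'   this many when `duration` is `NULL`.
#' @param seed Optional integer seed for reproducibility.
#' @param init Initial state name, or `NULL` (default) for a stationary
#'   draw.
#' @return Object of class `"state_path"`: data.frame with columns `state`,
#'   `t_entry`, `t_exit` (ms) plus attributes `duration` and `truncated`
#'   (last sojourn cut by the duration limit).
#' @export
gillespie_path <- function(model, duration = NULL, n_events = NULL,
                           seed = NULL, init = NULL) {
  stopifnot(inherits(model, "gating_model"))
  if (is.null(duration) && is.null(n_events)) {
    stop("give 'duration' and/or 'n_events'", call. = FALSE)
  }
  if (!is.null(duration) &&
      (!is.numeric(duration) || duration <= 0 || !is.finite(duration))) {
    stop("'duration' must be a positive time in ms", call. = FALSE)
  }
  Q <- build_generator(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    pi_ <- stationary_distribution(Q)
    init <- sample(model$states, 1L, prob = pi_)
  } else {
    if (!init %in% model$states) stop("unknown initial state", call. = FALSE)
  }
  dur <- if (is.null(duration)) Inf else duration
  nev <- if (is.null(n_events)) .Machine$integer.max else n_events
  res <- cpp_gillespie(Q, dur, match(init, model$states) - 1L, nev)
  path <- data.frame(state = model$states[res$state],
                     t_entry = res$t_entry, t_exit = res$t_exit,
                     stringsAsFactors = FALSE)
  attr(path, "duration") <- if (is.finite(dur)) dur else
    path$t_exit[nrow(path)]
  attr(path, "truncated") <- isTRUE(res$truncated)
  class(path) <- c("state_path", "data.frame")
  path
}

#' Discretize a state path at a fixed sampling interval
#'
#' Maps the state occupied at each sampling instant k * tau
#' (k = 0, 1, ..., N - 1, N = floor(duration / tau)) through the model's
#' conductance classes and run-length encodes the result.  Sojourns shorter
#' than the sampling interval can fall between grid points and leave no
#' trace, just as brief events escape detection in real recordings.
#'
#' @param path A [gillespie_path()] result (or a data.frame with the same
#'   columns).
#' @param tau Sampling interval in ms, > 0.
#' @param model The [gating_model()] supplying the class map.
#' @return An [event_sequence()].
#' @export
discretize <- function(path, tau, model) {
  stopifnot(inherits(model, "gating_model"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("'tau' must be a single positive sampling interval (ms)",
         call. = FALSE)
  }
  duration <- attr(path, "duration")
  if (is.null(duration)) duration <- max(path$t_exit)
  N <- floor(duration / tau + 1e-9)
  if (N < 1L) stop("duration shorter than one sampling interval",
                   call. = FALSE)
  # samples k*tau with entry <= k*tau < exit:
  # first index ceil(entry/tau), last index ceil(exit/tau) - 1
  first <- ceiling(path$t_entry / tau - 1e-9)
  last <- pmin(ceiling(path$t_exit / tau - 1e-9) - 1, N - 1)
  cnt <- pmax(last - first + 1, 0)
  keep <- cnt > 0
  cls <- unname(model$classes[path$state[keep]])
  event_sequence(cls, cnt[keep], tau)
}

#' Continuous dwell times per conductance class of a state path
#'
#' Merges consecutive sojourns sharing a conductance class and returns the
#' resulting dwell durations per class.  The first and last aggregated
#' dwells are dropped: the last is duration-censored and the first starts
#' from the simulation's initial draw rather than a class entry.
#'
#' @param path A [gillespie_path()] result.
#' @param model The [gating_model()] supplying the class map.
#' @return Named list with one numeric vector of durations (ms) per class.
#' @export
class_dwells <- function(path, model) {
  stopifnot(inherits(model, "gating_model"))
  cls <- unname(model$classes[path$state])
  new_run <- c(TRUE, cls[-1L] != cls[-length(cls)])
  grp <- cumsum(new_run)
  dur <- as.numeric(tapply(path$t_exit - path$t_entry, grp, sum))
  rcls <- cls[new_run]
  if (length(dur) > 2L) {
    dur <- dur[-c(1L, length(dur))]
    rcls <- rcls[-c(1L, length(rcls))]
  }
  lapply(setNames(.classes, .classes), function(cl) dur[rcls == cl])
}

#' Rendering specification for synthetic traces
#'
#' Maps conductance classes to fixed current levels (pA) and sets the
#' additive Gaussian measurement-noise standard deviation.
#'
#' @param levels Named numeric vector `c(O = ..., O_S = ..., C = ...)` with
#'   `|levels["O"]| > |levels["O_S"]| > |levels["C"]|`.
#' @param noise_sd Noise standard deviation in pA (>= 0, default 0.5).
#' @return Object of class `"render_spec"`.
#' @export
render_spec <- function(levels, noise_sd = 0.5) {
  if (!all(.classes %in% names(levels))) {
    stop("'levels' needs entries O, O_S, C", call. = FALSE)
  }
  levels <- levels[.classes]
  mags <- abs(levels)
  if (!(mags["O"] > mags["O_S"] && mags["O_S"] > mags["C"])) {
    stop("need |level(O)| > |level(O_S)| > |level(C)|", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  structure(list(levels = levels, noise_sd = noise_sd),
            class = "render_spec")
}

#' Default current levels consistent with a threshold pair
#'
#' Places the sub-conductance level midway between the two threshold
#' magnitudes, the open level 5 pA beyond the open threshold and the closed
#' level below the closed threshold, all on the negative-current branch
#' (open-channel events deflect downward at negative holding potentials).
#'
#' @param thr A [threshold_spec()].
#' @return Named numeric vector of levels in pA.
#' @export
default_levels <- function(thr) {
  stopifnot(inherits(thr, "threshold_spec"))
  c(O = -(thr$open_mag + 5),
    O_S = -(thr$open_mag + thr$closed_mag) / 2,
    C = -max(thr$closed_mag - 5, thr$closed_mag / 2))
}

#' Render an event sequence as a noisy current trace
#'
#' Each sample's current is the fixed level of its conductance class plus
#' independent Gaussian noise; `noise_sd = 0` reproduces noise-free model
#' traces.
#'
#' @param seq An [event_sequence()].
#' @param spec A [render_spec()].
#' @param seed Optional integer seed.
#' @param meta Metadata list stored on the trace.
#' @return A [trace_record()].
#' @export
render_trace <- function(seq, spec, seed = NULL, meta = list()) {
  stopifnot(inherits(seq, "event_sequence"), inherits(spec, "render_spec"))
  if (!is.null(seed)) set.seed(seed)
  cur <- unname(spec$levels[expand_classes(seq)])
  if (spec$noise_sd > 0) cur <- cur + rnorm(length(cur), 0, spec$noise_sd)
  trace_record(cur, seq$tau, meta)
}

#' Synthetic single-channel recording for a published condition
#'
#' End-to-end fixture generator: simulates the five-state gating chain with
#' the published rate constants of the requested condition, discretizes at
#' the recording sampling interval (0.2 ms, i.e. 5 kHz), and renders a
#' noisy current trace at levels consistent with that condition's
#' idealization thresholds.  Ground truth (continuous path and discretized
#' event sequence) is returned alongside the trace.
#'
#' @inheritParams vdac_model
#' @param duration Recording length in ms (default 100000 ms = 100 s, i.e.
#'   500,000 samples at 0.2 ms).
#' @param seed Optional integer seed.
#' @param noise_sd Measurement noise SD in pA (default 0.5; 0 for noiseless
#'   model traces).
#' @param tau Sampling interval in ms (default 0.2).
#' @return List with elements `trace` ([trace_record()]), `path`
#'   ([gillespie_path()] ground truth), `events` ([event_sequence()] ground
#'   truth), `model`, `thresholds`, `levels`.
#' @export
make_fixture <- function(condition = c("WT", "PPN25", "PPN100",
                                       "rVDAC", "S137E"),
                         duration = 1e5, seed = NULL, noise_sd = 0.5,
                         tau = 0.2) {
  condition <- match.arg(condition)
  model <- vdac_model(condition)
  thr <- vdac_thresholds(condition)
  spec <- render_spec(default_levels(thr), noise_sd)
  path <- gillespie_path(model, duration = duration, seed = seed)
  events <- discretize(path, tau, model)
  trace <- render_trace(events, spec,
                        meta = list(condition = condition,
                                    holding_mV = -10, synthetic = TRUE))
  list(trace = trace, path = path, events = events, model = model,
       thresholds = thr, levels = spec$levels)
}
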