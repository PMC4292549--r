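#' Theoretical dwell-time density of a conductance class
#'
#' Colquhoun-Hawkes density of the time spent within a conductance class A
#' before leaving it: `f(t) = phi0 exp(Q_AA t) (-Q_AA) u_A`, where `Q_AA`
#' is the sub-generator on the class states, `u_A` a ones vector, and the
#' entry vector `phi0 = pi_B Q_BA / (pi_B Q_BA u_A)` distributes class
#' entries according to the stationary flux from the complement B.  When
#' the class has a single state the density reduces to an exponential with
#' rate equal to that state's total exit rate.  The density is represented
#' as a (possibly signed-weight) mixture of exponentials from the
#' eigendecomposition of `-Q_AA`.
#'
#' @param model A [gating_model()].
#' @param cls Conductance class, one of `"O"`, `"O_S"`, `"C"` (must be
#'   non-empty and have a non-empty complement).
#' @param Q Optional generator (ms^-1); defaults to
#'   `build_generator(model)`.
#' @return Object of class `"dwell_density"`: list with `class`, `phi0`,
#'   `Qaa`, `components` (data.frame of exponential `rate` (ms^-1) and
#'   `weight`), `mean` (ms).
#' @export
dwell_density <- function(model, cls, Q = build_generator(model)) {
  stopifnot(inherits(model, "gating_model"))
  cls <- match.arg(cls, .classes)
  check_generator(Q)
  A <- which(model$classes[model$states] == cls)
  B <- setdiff(seq_along(model$states), A)
  if (length(A) == 0L) stop("class ", cls, " has no states", call. = FALSE)
  if (length(B) == 0L) stop("class ", cls, " has no complement",
                            call. = FALSE)
  Qaa <- Q[A, A, drop = FALSE]
  exit_rates <- -rowSums(Qaa)  # rate of leaving the class from each state
  if (all(exit_rates <= 1e-300)) {
    stop("absorbing class: no exit rates out of ", cls, call. = FALSE)
  }
  piB <- stationary_distribution(Q)[B]
  Qba <- Q[B, A, drop = FALSE]
  flux <- as.numeric(piB %*% Qba)
  tot <- sum(flux)
  if (tot <= 0) stop("no stationary flux into class ", cls, call. = FALSE)
  phi0 <- flux / tot

  eg <- eigen(Qaa)
  if (max(abs(Im(eg$values))) > 1e-9 * max(abs(eg$values))) {
    stop("complex dwell spectrum: class sub-generator is not reversible",
         call. = FALSE)
  }
  lam <- Re(eg$values)
  V <- Re(eg$vectors)
  condV <- tryCatch(kappa(V, exact = TRUE), error = function(e) Inf)
  uA <- rep(1, length(A))
  if (is.finite(condV) && condV < 1e8) {
    # f(t) = sum_k c_k exp(lam_k t), c_k = (phi0 V)_k (V^-1 (-Qaa) uA)_k
    left <- as.numeric(phi0 %*% V)
    right <- as.numeric(solve(V, -Qaa %*% uA))
    comp <- data.frame(rate = -lam, weight = left * right / (-lam))
  } else {
    comp <- NULL  # fall back to Pade evaluation of exp(Qaa t)
  }
  mean_dwell <- as.numeric(-phi0 %*% solve(Qaa, uA))
  structure(
    list(class = cls, states = model$states[A], phi0 = phi0, Qaa = Qaa,
         components = comp, mean = mean_dwell),
    class = "dwell_density"
  )
}

#' @export
print.dwell_density <- function(x, ...) {
  cat(sprintf("Dwell-time density, class %s (%s): mean %.4g ms\n",
              x$class, paste(x$states, collapse = ", "), x$mean))
  if (!is.null(x$components)) print(x$components, digits = 4)
  invisible(x)
}

#' Evaluate a dwell-time density or its survival function
#'
#' `ddwell()` evaluates the density f(t), `sdwell()` the survival function
#' `S(t) = P(dwell > t)`, at times `t` in ms.  Uses the exponential-mixture
#' form when the eigendecomposition is well-conditioned, otherwise the Pade
#' matrix exponential of the class sub-generator.
#'
#' @param t Numeric vector of times in ms (>= 0).
#' @param dens A [dwell_density()].
#' @return Numeric vector of density (ms^-1) or survival values.
#' @export
ddwell <- function(t, dens) {
  stopifnot(inherits(dens, "dwell_density"))
  if (any(t < 0)) stop("dwell times are non-negative", call. = FALSE)
  if (!is.null(dens$components)) {
    w <- dens$components$weight
    r <- dens$components$rate
    return(vapply(t, function(ti) sum(w * r * exp(-r * ti)), 0))
  }
  uA <- rep(1, nrow(dens$Qaa))
  vapply(t, function(ti) {
    as.numeric(dens$phi0 %*% cpp_expm(dens$Qaa * ti) %*% (-dens$Qaa) %*% uA)
  }, 0)
}

#' @rdname ddwell
#' @export
sdwell <- function(t, dens) {
  stopifnot(inherits(dens, "dwell_density"))
  if (any(t < 0)) stop("dwell times are non-negative", call. = FALSE)
  if (!is.null(dens$components)) {
    w <- dens$components$weight
    r <- dens$components$rate
    return(vapply(t, function(ti) sum(w * exp(-r * ti)), 0))
  }
  uA <- rep(1, nrow(dens$Qaa))
  vapply(t, function(ti) {
    as.numeric(dens$phi0 %*% cpp_expm(dens$Qaa * ti) %*% uA)
  }, 0)
}

#' Mean dwell time of a class
#'
#' Closed form `-phi0 Qaa^-1 u_A`; for a single-state class this is one
#' over the state's total exit rate.
#'
#' @param dens A [dwell_density()].
#' @return Mean dwell time in ms.
#' @export
mean_dwell <- function(dens) {
  stopifnot(inherits(dens, "dwell_density"))
  dens$mean
}

#' Empirical dwell-time histogram of a conductance class
#'
#' Bins the durations (run length times sampling interval) of all maximal
#' runs of the class, with the conventional 0.5 ms bin width.  Counts are
#' stored untransformed; the square-root frequency scale used for display
#' is applied only by [plot.dwell_histogram()].
#'
#' @param seq An [event_sequence()].
#' @param cls Conductance class.
#' @param bin_width Bin width in ms (> 0, default 0.5).
#' @return Object of class `"dwell_histogram"`: list with `class`,
#'   `bin_edges` (ms), `counts`, `eta` (total event count).
#' @export
empirical_dwell_histogram <- function(seq, cls, bin_width = 0.5) {
  stopifnot(inherits(seq, "event_sequence"))
  cls <- match.arg(cls, .classes)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("'bin_width' must be a single positive width (ms)", call. = FALSE)
  }
  dur <- seq$lengths[seq$classes == cls] * seq$tau
  eta <- length(dur)
  if (eta == 0L) {
    edges <- c(0, bin_width)
    counts <- 0L
  } else {
    edges <- seq(0, (floor(max(dur) / bin_width) + 1) * bin_width,
                 by = bin_width)
    counts <- as.integer(
      table(cut(dur, breaks = edges, right = FALSE, labels = FALSE))
      [as.character(seq_len(length(edges) - 1L))]
    )
    counts[is.na(counts)] <- 0L
  }
  structure(list(class = cls, bin_edges = edges, counts = counts,
                 eta = eta),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("Dwell histogram, class %s: %d events in %d bins of %g ms\n",
              x$class, x$eta, length(x$counts),
              diff(x$bin_edges[1:2])))
  invisible(x)
}

#' Plot a dwell histogram with optional theoretical overlay
#'
#' Frequencies are drawn on a square-root ordinate, the conventional
#' display for dwell-time distributions.
#'
#' @param x A [dwell_histogram()].
#' @param dens Optional [dwell_density()] to overlay as eta * f(t).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dwell_histogram <- function(x, dens = NULL, ...) {
  mids <- head(x$bin_edges, -1L) + diff(x$bin_edges) / 2
  graphics::plot(mids, sqrt(x$counts), type = "h", lwd = 3,
                 xlab = "dwell time (ms)", ylab = "sqrt(frequency)",
                 main = paste("Class", x$class), ...)
  if (!is.null(dens)) {
    exp_counts <- overlay_theoretical(x, dens)$expected
    graphics::lines(mids, sqrt(exp_counts), lty = 2)
  }
  invisible(x)
}

#' Expected per-bin counts from a theoretical dwell density
#'
#' Expected count in bin `[a, b)` is `eta * (S(a) - S(b))` with S the
#' survival function, i.e. eta times the exact bin integral of f(t).
#'
#' @param hist A [empirical_dwell_histogram()].
#' @param dens A [dwell_density()] of the same class.
#' @return data.frame with `bin_lo`, `bin_hi`, `observed`, `expected`.
#' @export
overlay_theoretical <- function(hist, dens) {
  stopifnot(inherits(hist, "dwell_histogram"),
            inherits(dens, "dwell_density"))
  if (hist$class != dens$class) {
    stop("histogram and density are for different classes", call. = FALSE)
  }
  lo <- head(hist$bin_edges, -1L)
  hi <- tail(hist$bin_edges, -1L)
  expected <- hist$eta * (sdwell(lo, dens) - sdwell(hi, dens))
  data.frame(bin_lo = lo, bin_hi = hi, observed = hist$counts,
             expected = expected)
}

#' Chi-squared goodness of fit of dwell times to a theoretical density
#'
#' Bins observed dwell durations into `nbins` equal-probability bins of the
#' theoretical distribution (edges found by inverting the survival
#' function) and computes Pearson's chi-squared statistic against the
#' uniform expected counts.
#'
#' @param dwells Numeric vector of dwell durations (ms).
#' @param dens A [dwell_density()].
#' @param nbins Number of equal-probability bins (default 50).
#' @return List with `statistic`, `df`, `p.value`, `nbins`.
#' @export
dwell_gof <- function(dwells, dens, nbins = 50) {
  stopifnot(inherits(dens, "dwell_density"))
  n <- length(dwells)
  if (n < 10 * nbins) nbins <- max(5L, n %/% 10L)
  probs <- seq_len(nbins - 1L) / nbins
  # invert S(t) = 1 - p on a bracket that surely covers the quantile
  upper <- dens$mean
  while (sdwell(upper, dens) > 1 / (2 * nbins)) upper <- upper * 2
  edges <- vapply(probs, function(p) {
    uniroot(function(t) sdwell(t, dens) - (1 - p),
            lower = 0, upper = upper, tol = 1e-12)$root
  }, 0)
  obs <- as.numeric(table(cut(dwells, breaks = c(0, edges, Inf),
                              right = FALSE, labels = FALSE)))
  if (length(obs) < nbins) obs <- c(obs, rep(0, nbins - length(obs)))
  expd <- rep(n / nbins, nbins)
  stat <- sum((obs - expd)^2 / expd)
  df <- nbins - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), nbins = nbins)
}
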