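#' Construct a gating model
#'
#' A gating model is a continuous-time Markov chain on hidden conformational
#' states, observed only through a many-to-one map from states to conductance
#' classes (`"O"` open, `"O_S"` sub-conductance, `"C"` closed).  Each
#' undirected edge of the state graph carries two directed transition rates.
#' All rates are in ms^-1.
#'
#' @param states Character vector of state names (length >= 2), e.g.
#'   `c("S1", ..., "S5")`.
#' @param classes Named character vector mapping every state to one of
#'   `"O"`, `"O_S"`, `"C"`.
#' @param edges Two-column matrix or data.frame of state-name pairs; the
#'   undirected graph must be connected.
#' @param rates Named numeric vector of directed rates in ms^-1; names are
#'   `"<from>-><to>"` for both directions of every edge.  Missing directions
#'   default to 0.
#' @param acyclic Logical; if `TRUE` (default) the edge graph must be a tree
#'   (n - 1 edges, no cycle), which makes detailed balance automatic and all
#'   rates free parameters.
#' @return An object of class `"gating_model"`.
#' @examples
#' m <- gating_model(
#'   states  = c("A", "B"),
#'   classes = c(A = "O", B = "C"),
#'   edges   = cbind("A", "B"),
#'   rates   = c("A->B" = 1, "B->A" = 2)
#' )
#' build_generator(m)
#' @export
gating_model <- function(states, classes, edges, rates, acyclic = TRUE) {
  states <- as.character(states)
  if (length(states) < 2L || anyDuplicated(states)) {
    stop("'states' must be >= 2 distinct state names", call. = FALSE)
  }
  classes <- classes[states]
  if (any(is.na(classes)) || !all(classes %in% .classes)) {
    stop("every state needs a conductance class in {O, O_S, C}",
         call. = FALSE)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (!all(edges %in% states)) {
    stop("edge endpoints must be model states", call. = FALSE)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loop edges are not allowed", call. = FALSE)
  }
  key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "|"))
  if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)

  wanted <- c(rate_name(edges[, 1L], edges[, 2L]),
              rate_name(edges[, 2L], edges[, 1L]))
  extra <- setdiff(names(rates), wanted)
  if (length(extra)) {
    stop("rates given for non-edges: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  full <- setNames(numeric(length(wanted)), wanted)
  full[names(rates)] <- as.numeric(rates)
  if (any(!is.finite(full)) || any(full < 0)) {
    stop("invalid model: all rates must be finite and >= 0", call. = FALSE)
  }

  if (!is_connected(states, edges)) {
    stop("invalid model: state graph is not connected", call. = FALSE)
  }
  if (acyclic && nrow(edges) != length(states) - 1L) {
    stop("invalid model: acyclic model must have exactly n - 1 edges",
         call. = FALSE)
  }

  structure(
    list(states = states, classes = classes, edges = edges,
         rates = full, acyclic = acyclic),
    class = "gating_model"
  )
}

rate_name <- function(from, to) paste0(from, "->", to)

# connectivity of the undirected edge graph (breadth-first search)
is_connected <- function(states, edges) {
  n <- length(states)
  adj <- lapply(setNames(vector("list", n), states), function(x) character())
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(logical(n), states)
  queue <- states[1L]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[cur]][!seen[adj[[cur]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.gating_model <- function(x, ...) {
  cat("Gating model:", length(x$states), "states,",
      nrow(x$edges), "edges", if (x$acyclic) "(acyclic)", "\n")
  cls <- split(x$states, x$classes[x$states])
  for (cl in intersect(.classes, names(cls))) {
    cat(sprintf("  %-4s: %s\n", cl, paste(cls[[cl]], collapse = ", ")))
  }
  cat("Rates (ms^-1):\n")
  print(x$rates)
  invisible(x)
}

#' Extract or replace the free rate constants of a model
#'
#' The free parameters of an acyclic gating model are the two directed rates
#' on every edge (detailed balance holds automatically, so none is
#' constrained away).
#'
#' @param model A [gating_model()].
#' @param rates Named numeric vector (ms^-1) with the same names as
#'   `model_rates(model)`.
#' @return `model_rates()` returns the named rate vector;
#'   `set_model_rates()` returns the updated model.
#' @export
model_rates <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  model$rates
}

#' @rdname model_rates
#' @export
set_model_rates <- function(model, rates) {
  stopifnot(inherits(model, "gating_model"))
  if (!all(names(rates) %in% names(model$rates))) {
    stop("unknown rate names", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  model$rates[names(rates)] <- as.numeric(rates)
  model
}

#' Build the infinitesimal generator of a gating model
#'
#' Assembles the n x n rate matrix Q (ms^-1): entry (i, j), i != j, is the
#' directed rate from state i to state j (zero when \{i, j\} is not an edge)
#' and each diagonal entry is minus the sum of the other entries in its row,
#' so that every row sums to zero.
#'
#' @param model A [gating_model()].
#' @return Numeric n x n matrix with state names as dimnames.
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  n <- length(model$states)
  Q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  from <- sub("->.*$", "", names(model$rates))
  to <- sub("^.*->", "", names(model$rates))
  Q[cbind(from, to)] <- model$rates
  diag(Q) <- -rowSums(Q)
  Q
}

# validate an externally supplied generator
check_generator <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || any(!is.finite(Q))) {
    stop("Q must be a finite square matrix", call. = FALSE)
  }
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of Q must be >= 0",
                         call. = FALSE)
  if (max(abs(rowSums(Q))) > 1e-9 * max(1, max(abs(Q)))) {
    stop("rows of Q must sum to zero", call. = FALSE)
  }
  invisible(Q)
}

#' Transition matrix over a sampling interval
#'
#' Computes `A_tau = exp(Q * tau)` by the scaling-and-squaring Pade
#' approximation.  `A_tau[i, j]` is the probability that a chain in state i
#' is found in state j a time `tau` later.
#'
#' @param Q Generator matrix (ms^-1), e.g. from [build_generator()].
#' @param tau Time step in ms, > 0.
#' @return Row-stochastic n x n matrix.
#' @export
transition_matrix <- function(Q, tau) {
  check_generator(Q)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a single positive number (ms)", call. = FALSE)
  }
  A <- cpp_expm(Q * tau)
  dimnames(A) <- dimnames(Q)
  A
}

#' Propagate a state-probability vector through time
#'
#' Solves the master equation for the state occupancy: with the row
#' convention used throughout this package, `p(t) = p0 %*% exp(Q t)`.
#'
#' @param Q Generator matrix (ms^-1).
#' @param p0 Initial probability vector over states (sums to 1).
#' @param t Time in ms, >= 0.
#' @return Probability vector at time `t`.
#' @export
propagate <- function(Q, p0, t) {
  check_generator(Q)
  p0 <- as.numeric(p0)
  if (length(p0) != nrow(Q) || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8) {
    stop("'p0' must be a probability vector over the states", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("'t' must be a single non-negative time (ms)", call. = FALSE)
  }
  if (t == 0) return(setNames(p0, rownames(Q)))
  p <- as.numeric(p0 %*% cpp_expm(Q * t))
  setNames(p, rownames(Q))
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by replacing one equation of the
#' transposed linear system with the normalization constraint; falls back to
#' the singular-value null space when the replaced system is
#' ill-conditioned.  For acyclic models the result coincides with the
#' closed form obtained by chaining detailed balance
#' (`pi_i q_ij = pi_j q_ji`) along the tree; see
#' [detailed_balance_distribution()].
#'
#' @param Q Generator matrix (ms^-1) of a connected chain.
#' @return Named probability vector over states.
#' @export
stationary_distribution <- function(Q) {
  check_generator(Q)
  n <- nrow(Q)
  M <- t(Q)
  M[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi_ <- NULL
  if (rcond(M) > 1e-13) {
    pi_ <- tryCatch(solve(M, b), error = function(e) NULL)
  }
  if (is.null(pi_)) {
    # SVD null space of t(Q)
    sv <- svd(t(Q))
    if (sv$d[n] > 1e-10 * max(sv$d, 1)) {
      stop("singular-system error: generator has no one-dimensional null ",
           "space (zero-rate edge may disconnect the chain)", call. = FALSE)
    }
    pi_ <- sv$u[, n]
    pi_ <- pi_ / sum(pi_)
  }
  if (any(pi_ < -1e-8)) {
    stop("singular-system error: stationary solve returned negative mass ",
         "(is the chain effectively disconnected?)", call. = FALSE)
  }
  pi_ <- pmax(pi_, 0)
  setNames(pi_ / sum(pi_), rownames(Q))
}

#' Stationary distribution by detailed-balance chaining
#'
#' For an acyclic (tree) model, detailed balance `pi_i q_ij = pi_j q_ji`
#' holds automatically and the stationary distribution follows in closed
#' form by chaining the relation along tree edges from a reference state.
#' Used as an independent cross-check of [stationary_distribution()].
#'
#' @param model An acyclic [gating_model()].
#' @return Named probability vector over states.
#' @export
detailed_balance_distribution <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  if (!model$acyclic) {
    stop("detailed-balance chaining requires an acyclic model",
         call. = FALSE)
  }
  states <- model$states
  w <- setNames(rep(NA_real_, length(states)), states)
  w[states[1L]] <- 1
  edges <- model$edges
  repeat {
    done <- TRUE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      if (is.na(w[a]) == is.na(w[b])) next
      done <- FALSE
      if (is.na(w[b])) { from <- a; to <- b } else { from <- b; to <- a }
      fwd <- model$rates[rate_name(from, to)]
      rev <- model$rates[rate_name(to, from)]
      if (rev <= 0) {
        stop("singular-system error: zero return rate on edge ",
             from, "-", to, call. = FALSE)
      }
      w[to] <- w[from] * fwd / rev
    }
    if (done) break
  }
  w / sum(w)
}

#' Restrict and renormalize a stationary distribution
#'
#' Drops all states outside `keep` and renormalizes the remaining mass to
#' one, e.g. to compare occupancies among the non-dominant states after
#' excluding a dominant dwell state.
#'
#' @param pi Named probability vector (e.g. from
#'   [stationary_distribution()]).
#' @param keep Character or integer subset of states to retain (non-empty).
#' @return Named probability vector over `keep`.
#' @export
restricted_stationary <- function(pi, keep) {
  if (length(keep) == 0L) stop("'keep' must be non-empty", call. = FALSE)
  sub <- pi[keep]
  if (any(is.na(sub))) stop("unknown states in 'keep'", call. = FALSE)
  tot <- sum(sub)
  if (tot <= 0) stop("retained states carry no stationary mass",
                     call. = FALSE)
  sub / tot
}

#' Read or write a model-topology file
#'
#' Plain-text (YAML) description of a gating model: state names with
#' conductance-class labels and edges with their two directed rates.  Rates
#' in the file are in s^-1 (the conventional reporting unit) and are
#' converted to the internal ms^-1 on read; `units: ms^-1` in the file
#' suppresses the conversion.
#'
#' @param path File path.
#' @param model A [gating_model()] (for writing).
#' @param units Unit written to file, `"s^-1"` (default) or `"ms^-1"`.
#' @return `read_model_file()` returns a [gating_model()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("states", "edges")
  if (!all(need %in% names(y))) {
    stop("model file needs 'states' and 'edges' entries", call. = FALSE)
  }
  states <- vapply(y$states, function(s) as.character(s$name), "")
  classes <- setNames(vapply(y$states, function(s) as.character(s$class), ""),
                      states)
  edges <- t(vapply(y$edges, function(e) c(e$from, e$to), c("", "")))
  scale <- if (identical(y$units, "ms^-1")) 1 else 1e-3
  rates <- unlist(lapply(y$edges, function(e) {
    setNames(c(e$rate_fwd, e$rate_rev) * scale,
             c(rate_name(e$from, e$to), rate_name(e$to, e$from)))
  }))
  gating_model(states, classes, edges, rates,
               acyclic = !isFALSE(y$acyclic))
}

#' @rdname read_model_file
#' @export
write_model_file <- function(model, path, units = c("s^-1", "ms^-1")) {
  stopifnot(inherits(model, "gating_model"))
  units <- match.arg(units)
  scale <- if (units == "s^-1") 1e3 else 1
  y <- list(
    units = units,
    acyclic = model$acyclic,
    states = lapply(model$states, function(s) {
      list(name = s, class = unname(model$classes[s]))
    }),
    edges = lapply(seq_len(nrow(model$edges)), function(k) {
      a <- model$edges[k, 1L]; b <- model$edges[k, 2L]
      list(from = a, to = b,
           rate_fwd = unname(model$rates[rate_name(a, b)]) * scale,
           rate_rev = unname(model$rates[rate_name(b, a)]) * scale)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
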