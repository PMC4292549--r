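# Shared fixtures and independent oracles used across the suite.

two_state_model <- function(q12 = 1, q21 = 2,
                            classes = c(A = "O", B = "C")) {
  gating_model(c("A", "B"), classes, cbind("A", "B"),
               c("A->B" = q12, "B->A" = q21))
}

# closed-form 2-state transition matrix exp(Q tau)
A2_closed_form <- function(q12, q21, tau) {
  s <- q12 + q21
  e <- exp(-s * tau)
  matrix(c((q21 + q12 * e) / s, q12 * (1 - e) / s,
           q21 * (1 - e) / s, (q12 + q21 * e) / s),
         2, 2, byrow = TRUE)
}

# event sequence from a per-sample class string
seq_from_string <- function(cls, tau = 0.2) {
  r <- rle(cls)
  event_sequence(r$values, r$lengths, tau)
}

# exhaustive path-enumeration likelihood oracle: sums p0 * prod(A) over
# every hidden state path consistent with the per-sample class string,
# conditioning on the first event exactly as the forward filter does
brute_force_loglik <- function(cls, model, tau = 0.2, A = NULL,
                               pi_ = NULL) {
  Q <- build_generator(model)
  if (is.null(A)) A <- transition_matrix(Q, tau)
  if (is.null(pi_)) pi_ <- stationary_distribution(Q)
  state_class <- model$classes[model$states]
  allowed <- lapply(cls, function(cl) which(state_class == cl))
  if (any(lengths(allowed) == 0L)) return(-Inf)
  p0 <- rep(0, length(model$states))
  p0[allowed[[1L]]] <- pi_[allowed[[1L]]]
  p0 <- p0 / sum(p0)
  paths <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))
  pr <- p0[paths[, 1L]]
  if (length(cls) > 1L) {
    for (k in 2:length(cls)) {
      pr <- pr * A[cbind(paths[, k - 1L], paths[, k])]
    }
  }
  log(sum(pr))
}

# every class string of a given length over an alphabet
all_class_strings <- function(alphabet, n) {
  g <- do.call(expand.grid,
               c(rep(list(alphabet), n),
                 list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
}

# random acyclic (tree) gating model for property-style loops
random_tree_model <- function(n = 4, seed = 1) {
  set.seed(seed)
  states <- paste0("S", seq_len(n))
  parent <- c(NA, vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L))
  edges <- cbind(states[parent[-1L]], states[2:n])
  classes <- setNames(sample(c("O", "O_S", "C"), n, replace = TRUE), states)
  # ensure all three classes appear when n allows
  if (n >= 3) classes[1:3] <- c("O", "O_S", "C")
  rates <- runif(2 * (n - 1L), 0.01, 0.5)
  names(rates) <- c(rate_name_vec(edges[, 1L], edges[, 2L]),
                    rate_name_vec(edges[, 2L], edges[, 1L]))
  gating_model(states, classes, edges, rates)
}

rate_name_vec <- function(from, to) paste0(from, "->", to)

# manual hand-rolled state path for discretization fixtures
manual_path <- function(states, t_entry, t_exit, duration = max(t_exit)) {
  p <- data.frame(state = states, t_entry = t_entry, t_exit = t_exit,
                  stringsAsFactors = FALSE)
  attr(p, "duration") <- duration
  class(p) <- c("state_path", "data.frame")
  p
}
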