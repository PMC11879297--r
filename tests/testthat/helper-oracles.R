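# Independent oracles, kept deliberately naive and separate from the package's
# code paths.

# logistic regression by hand-rolled Newton (IRLS) iteration
oracle_logistic_fit <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    step <- solve(t(X) %*% (X * w), t(X) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  drop(1 / (1 + exp(-(X %*% beta))))
}

# greedy 1:1 nearest-neighbour matching, written independently with plain loops
oracle_greedy_match <- function(t_scores, c_scores, caliper = NULL) {
  t_order <- order(t_scores, decreasing = TRUE)
  used <- logical(length(c_scores))
  pairs <- list()
  for (i in t_order) {
    best_j <- 0L
    best_d <- Inf
    for (j in seq_along(c_scores)) {
      if (used[j]) next
      d <- abs(c_scores[j] - t_scores[i])
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    if (best_j == 0L) next
    if (!is.null(caliper) && best_d > caliper) next
    used[best_j] <- TRUE
    pairs[[length(pairs) + 1L]] <-
      c(treated = names(t_scores)[i], control = names(c_scores)[best_j])
  }
  if (!length(pairs)) {
    return(data.frame(treated = character(), control = character()))
  }
  as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
}

# brute-force horizon filter: per-event loop
oracle_horizon_keep <- function(events, horizon) {
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) keep[i] <- events$day[i] <= horizon
  events[keep, , drop = FALSE]
}

# brute-force break-even: first n with burden + n * vw_var <= n * sc_pp
oracle_breakeven_scan <- function(burden, vw_var, sc_pp, n_max = 10000L) {
  for (n in seq_len(n_max)) {
    if (burden + n * vw_var <= n * sc_pp) return(n)
  }
  NA_integer_
}
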