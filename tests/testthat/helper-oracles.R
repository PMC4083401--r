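# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / closed form, not by calling the code under test.

# Exhaustive minimum-within-SS threshold split of a 1-D vector into two
# clusters; ties broken toward the larger lower (DOWN) cluster, mirroring
# the documented convention. Returns labels in input order.
brute_force_two_means <- function(x, min_cluster_size = 1L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  best_ss <- Inf
  best_k <- NA_integer_
  for (k in seq_len(n - 1L)) {
    if (xs[k] == xs[k + 1L]) next
    if (min(k, n - k) < min_cluster_size) next
    lo <- xs[seq_len(k)]
    hi <- xs[(k + 1L):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss - 1e-12 ||
        (abs(ss - best_ss) <= 1e-12 && k > best_k)) {
      best_ss <- ss
      best_k <- k
    }
  }
  if (is.na(best_k)) return(NULL)
  labels <- character(n)
  labels[ord] <- rep(c("DOWN", "UP"), c(best_k, n - best_k))
  labels
}

# Closed-form censored-exponential log-likelihood at given rate.
oracle_exp_loglik <- function(rate, time, event) {
  if (rate == 0) return(0)
  sum(event) * log(rate) - rate * sum(time)
}

# Closed-form exponential LRT evaluated from scratch (separate MLEs vs
# pooled MLE), independent of the package's internals.
oracle_exp_lrt <- function(time, event, is_up) {
  ll <- function(t, e) {
    d <- sum(e)
    if (d == 0) return(0)
    lam <- d / sum(t)
    d * log(lam) - lam * sum(t)
  }
  2 * (ll(time[is_up], event[is_up]) + ll(time[!is_up], event[!is_up]) -
         ll(time, event))
}

# Small clinical frame builder for scoring tests.
make_clinical <- function(time, event, endpoint = "survival",
                          ids = sprintf("S%03d", seq_along(time)),
                          stage = NULL) {
  out <- data.frame(sample_id = ids, endpoint = endpoint, time = time,
                    event = event, stringsAsFactors = FALSE)
  if (!is.null(stage)) out$stage <- stage
  out
}
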