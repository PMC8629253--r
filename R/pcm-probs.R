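# Weighted partial credit model category probabilities and moments.
#
# An item with categories k = 0..m, step parameters delta_1..delta_m
# (logits) and category weight w (score points per category step) has
#   P(K = k | theta)  propto  exp(k * w * theta - sum_{j<=k} delta_j),
# the usual PCM with the person term scaled by the category weight so
# that polytomous "super-items" contribute w score points per step
# (dichotomous items: m = 1, w = 1, delta_1 = item difficulty).

# Category probabilities for one item at a vector of abilities.
# Returns length(theta) x (m+1) matrix.
pcm_prob <- function(theta, delta, weight = 1) {
  m <- length(delta)
  k <- 0:m
  eta <- tcrossprod(theta * weight, k)
  eta <- eta - rep(c(0, cumsum(delta)), each = length(theta))
  eta <- eta - row_max(eta)
  p <- exp(eta)
  p / rowSums(p)
}

# Category probabilities and first two moments at a single ability,
# allocation-light for the EM inner loops.
pcm_scalar_moments <- function(theta, delta, weight = 1) {
  k <- 0:length(delta)
  eta <- k * (weight * theta) - c(0, cumsum(delta))
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  e1 <- sum(p * k)
  list(E = e1, V = max(sum(p * k * k) - e1 * e1, 0))
}

# First three moments of the category score K under the item model.
# Returns list(E, V, M3): mean, variance and third central moment of K
# (on the raw category scale, not yet weighted).
pcm_moments <- function(theta, delta, weight = 1) {
  p <- pcm_prob(theta, delta, weight)
  k <- 0:length(delta)
  e1 <- drop(p %*% k)
  e2 <- drop(p %*% k^2)
  e3 <- drop(p %*% k^3)
  v <- pmax(e2 - e1^2, 0)
  list(E = e1, V = v, M3 = e3 - 3 * e1 * e2 + 2 * e1^3)
}

# Newton update of one item's step parameters given expected category
# counts at a set of ability nodes. `counts` is (m+1) x Q; `theta` the
# Q node locations. The expected log-likelihood is concave in delta,
# so damped Newton converges; returns list(delta, hessian, converged).
pcm_item_newton <- function(delta, counts, theta, weight = 1,
                            max_steps = 60L, tol = 1e-10) {
  m <- length(delta)
  nq <- colSums(counts)
  # observed (expected) count of responses in category >= j
  t_obs <- sapply(1:m, function(j) sum(counts[(j + 1L):(m + 1L), , drop = FALSE]))

  objective <- function(d) {
    lp <- log(pcm_prob(theta, d, weight))
    sum(counts * t(lp))
  }
  obj <- objective(delta)
  H <- NULL
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    p <- pcm_prob(theta, delta, weight)         # Q x (m+1)
    # P(K >= j | theta_q), Q x m
    pj <- sapply(1:m, function(j) rowSums(p[, (j + 1L):(m + 1L), drop = FALSE]))
    pj <- matrix(pj, nrow = length(theta))
    grad <- colSums(nq * pj) - t_obs
    # Hessian: -sum_q Nq * Cov_q(1(K>=j), 1(K>=l));
    # Cov_q(j,l) = P(K >= max(j,l)) - P(K>=j) P(K>=l)
    H <- matrix(0, m, m)
    for (j in 1:m) for (l in j:m) {
      cov_q <- pj[, max(j, l)] - pj[, j] * pj[, l]
      H[j, l] <- H[l, j] <- -sum(nq * cov_q)
    }
    dir <- tryCatch(solve(H + diag(-1e-10, m), grad),
                    error = function(e) grad / (abs(diag(H)) + 1e-8))
    dir <- -dir  # ascent direction for concave objective
    if (max(abs(grad)) < tol * (1 + abs(obj))) { converged <- TRUE; break }
    lambda <- 1
    repeat {
      cand <- delta + lambda * dir
      ocand <- objective(cand)
      if (is.finite(ocand) && ocand >= obj - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { cand <- delta; ocand <- obj; break }
    }
    if (abs(ocand - obj) < tol * (1 + abs(obj)) && step > 1L) {
      delta <- cand; obj <- ocand; converged <- TRUE; break
    }
    delta <- cand; obj <- ocand
  }
  list(delta = delta, hessian = H, converged = converged)
}
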