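#' Fit a weighted partial credit model by marginal maximum likelihood
#'
#' EM estimation of the unidimensional (weighted) partial credit model
#' with a normal latent ability distribution whose mean is fixed to 0
#' for identification and whose standard deviation is estimated.
#' Polytomous items enter with their configured category weight (0.5
#' score points per step for the reading super-items emulated here).
#' The latent density is handled on a fixed quadrature grid with
#' normalized normal weights, which makes each latent-scale update an
#' exact M-step, so the marginal log-likelihood is non-decreasing over
#' iterations.
#'
#' @param rm a `response_matrix`.
#' @param bank_skeleton an [item_bank] giving item types, category
#'   counts and weights (its step parameters are used only as starting
#'   values if finite).
#' @param n_nodes number of quadrature nodes (default 61 on
#'   `[-8, 8]`).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `pcm_fit`: the estimated item bank, the
#'   latent standard deviation, per-item standard errors, the
#'   log-likelihood trace and a convergence flag.
#' @export
fit_pcm <- function(rm, bank_skeleton, n_nodes = 61L, max_iter = 500L,
                    tol = 1e-7) {
  stopifnot(inherits(rm, "response_matrix"), inherits(bank_skeleton, "item_bank"))
  if (ncol(rm) != nrow(bank_skeleton))
    stop("response matrix and item bank dimensions differ")
  prep <- collapse_unobserved(rm, bank_skeleton)
  rm <- prep$rm; bank <- prep$bank
  n <- nrow(rm); nitems <- nrow(bank)
  grid <- seq(-8, 8, length.out = n_nodes)
  sigma <- 1
  delta <- init_deltas(rm, bank)
  weights <- bank$category_weight
  ll_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    prior <- stats::dnorm(grid, 0, sigma)
    prior <- prior / sum(prior)
    lp <- matrix(log(prior), n, n_nodes, byrow = TRUE)
    for (i in seq_len(nitems)) {
      lpi <- t(log(pcm_prob(grid, delta[[i]], weights[i])))  # ncat x Q
      xi <- rm[, i]
      obs <- which(!is.na(xi))
      lp[obs, ] <- lp[obs, ] + lpi[xi[obs] + 1L, , drop = FALSE]
    }
    llv <- logsumexp_rows(lp)
    ll <- sum(llv)
    ll_trace <- c(ll_trace, ll)
    post <- exp(lp - llv)

    # M-step: item steps from expected category counts at the nodes
    hess <- vector("list", nitems)
    for (i in seq_len(nitems)) {
      xi <- rm[, i]
      obs <- which(!is.na(xi))
      counts <- rowsum_all_levels(post[obs, , drop = FALSE], xi[obs],
                                  0:(bank$n_categories[i] - 1L))
      up <- pcm_item_newton(delta[[i]], counts, grid, weights[i],
                            max_steps = 4L)
      delta[[i]] <- up$delta
      hess[[i]] <- up$hessian
    }
    # M-step: latent sd (discretized normal prior on the fixed grid;
    # log-space to stay finite at small sd)
    nq <- colSums(post)
    sigma <- stats::optimize(function(s) {
      lw <- stats::dnorm(grid, 0, s, log = TRUE)
      mx <- max(lw)
      sum(nq * (lw - mx - log(sum(exp(lw - mx)))))
    }, c(0.02, 6), maximum = TRUE, tol = 1e-7)$maximum

    if (iter > 1L) {
      rel <- abs(ll - ll_trace[iter - 1L]) / (abs(ll) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("PCM EM did not converge in ", max_iter,
            " iterations; returning partial result")

  se <- lapply(hess, function(H) {
    if (is.null(H)) return(NA_real_)
    v <- tryCatch(diag(solve(-H)), error = function(e) rep(NA_real_, nrow(H)))
    sqrt(pmax(v, 0))
  })
  est_bank <- item_bank(bank$item_id, bank$item_type, delta,
                        bank$category_weight)
  structure(list(bank = est_bank, latent_mean = 0, latent_sd = sigma,
                 item_se = se, loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_nodes = n_nodes,
                 nodes = grid, n_persons = n, converged = converged,
                 collapsed = prep$collapsed),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("Weighted PCM fit: %d items, %d persons\n",
              nrow(x$bank), x$n_persons))
  cat(sprintf("  logLik %.2f | latent mean 0 (fixed), sd %.3f | %s\n",
              x$loglik, x$latent_sd,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Drop unobserved response categories (collapse codes downward) so the
# step parameters stay estimable; warns when it does so.
collapse_unobserved <- function(rm, bank) {
  collapsed <- character(0)
  x <- unclass(rm)
  steps <- bank$step_params
  types <- bank$item_type
  weights <- bank$category_weight
  for (i in seq_len(nrow(bank))) {
    ncat <- bank$n_categories[i]
    seen <- sort(unique(x[!is.na(x[, i]), i]))
    if (length(seen) < 2L)
      stop("item ", bank$item_id[i], " has a constant (or empty) response column")
    if (length(seen) < ncat || max(seen) > ncat - 1L) {
      collapsed <- c(collapsed, bank$item_id[i])
      x[, i] <- match(x[, i], seen) - 1L
      m <- length(seen) - 1L
      steps[[i]] <- rep(mean(steps[[i]]), m)
      if (m == 1L) { types[i] <- "dichotomous"; weights[i] <- 1 }
    }
  }
  if (length(collapsed))
    warning("collapsed unobserved categories for item(s): ",
            paste(collapsed, collapse = ", "))
  bank2 <- item_bank(bank$item_id, types, steps, weights)
  list(rm = response_matrix(x, person_id = attr(rm, "person_id"),
                            true_theta = attr(rm, "true_theta"),
                            true_class = attr(rm, "true_class")),
       bank = bank2, collapsed = collapsed)
}

# Marginal log-likelihood of a response matrix under given item
# parameters and latent sd, on the same quadrature as fit_pcm.
pcm_marginal_loglik <- function(rm, bank, latent_sd, n_nodes = 61L) {
  grid <- seq(-8, 8, length.out = n_nodes)
  prior <- stats::dnorm(grid, 0, latent_sd)
  prior <- prior / sum(prior)
  lp <- matrix(log(prior), nrow(rm), n_nodes, byrow = TRUE)
  for (i in seq_len(nrow(bank))) {
    lpi <- t(log(pcm_prob(grid, bank$step_params[[i]],
                          bank$category_weight[i])))
    xi <- rm[, i]
    obs <- which(!is.na(xi))
    lp[obs, ] <- lp[obs, ] + lpi[xi[obs] + 1L, , drop = FALSE]
  }
  sum(logsumexp_rows(lp))
}

# Moment starting values: item location from the logit of the mean
# relative score, steps flat around it.
init_deltas <- function(rm, bank) {
  lapply(seq_len(nrow(bank)), function(i) {
    xi <- rm[, i]
    m <- bank$n_categories[i] - 1L
    p <- mean(xi, na.rm = TRUE) / m
    p <- min(max(p, 0.02), 0.98)
    loc <- log((1 - p) / p)
    rep(bank$category_weight[i] * loc, m)
  })
}
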