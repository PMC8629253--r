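#' Fit a constrained mixture Rasch model
#'
#' Estimates a discrete latent proficiency-class model: `G` latent
#' classes with class proportions `pi_g` and ability locations
#' `theta_g` (zero within-class variance), sharing one set of item
#' parameters across classes. The observed-data log-likelihood
#' `sum_v log sum_g pi_g prod_i P(x_vi | theta_g, item i)` is
#' maximized by EM (an ECM variant: proportions, class locations and
#' item steps are updated in turn, each to its conditional maximum, so
#' the likelihood is non-decreasing every iteration). Missing
#' responses are skipped in the per-person product. For
#' identification the proportion-weighted mean of the class locations
#' is fixed to 0, mirroring the latent-mean-0 constraint of the
#' continuous Rasch scaling; classes are returned in ascending
#' location order so class 1 is always the lowest-proficiency (low
#' literacy) class.
#'
#' Local maxima are handled by a two-stage multistart scheme: `n_starts`
#' short EM runs from random starting values, of which the `n_final`
#' best are run to full convergence. A run that collapses a class
#' below one person is discarded and replaced by a fresh start.
#'
#' @param rm a `response_matrix`.
#' @param bank_skeleton an [item_bank] giving item structure.
#' @param G number of latent classes (>= 1).
#' @param n_starts,n_final multistart counts (short runs / full runs).
#' @param seed integer seed for the random starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per full run.
#' @param short_iter iterations used in the screening stage.
#' @param init optional list(pi, theta, delta) of starting values; if
#'   supplied it is used as one additional (first) start.
#' @return An object of class `cmrm_fit` with elements `G`, `pi`,
#'   `theta`, `bank` (shared item parameters), `loglik`,
#'   `loglik_trace`, `n_params`, `posteriors`, `converged`,
#'   `n_starts_used`, `best_start_seed`.
#' @export
fit_cmrm <- function(rm, bank_skeleton, G, n_starts = 50L, n_final = 10L,
                     seed = 1L, tol = 1e-8, max_iter = 2000L,
                     short_iter = 15L, init = NULL) {
  stopifnot(inherits(rm, "response_matrix"), G >= 1L)
  prep <- collapse_unobserved(rm, bank_skeleton)
  rm <- prep$rm; bank <- prep$bank
  n <- nrow(rm)
  n_params <- sum(bank$n_categories - 1L) + 2L * (G - 1L)
  if (n <= n_params)
    stop("sample size must exceed the number of free parameters")
  delta0 <- init_deltas(rm, bank)

  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- c(init, list(start_seed = 0L))
  draw_start <- function(s) {
    set.seed(stage_seed(seed, paste0("start", s)))
    theta0 <- if (G == 1L) 0 else sort(stats::rnorm(G, 0, 1.5))
    p0 <- stats::rgamma(G, 3, 1); p0 <- p0 / sum(p0)
    list(pi = p0, theta = theta0, delta = delta0, start_seed = s)
  }
  for (s in seq_len(n_starts)) starts[[length(starts) + 1L]] <- draw_start(s)

  # screening stage
  extra <- 0L; max_extra <- 3L * n_starts
  screened <- list()
  s_idx <- 1L
  while (s_idx <= length(starts)) {
    st <- starts[[s_idx]]
    run <- cmrm_em(rm, bank, st$pi, st$theta, st$delta,
                   max_iter = short_iter, tol = 0)
    if (run$degenerate && extra < max_extra) {
      extra <- extra + 1L
      starts[[length(starts) + 1L]] <- draw_start(n_starts + extra)
    } else if (!run$degenerate) {
      run$start_seed <- st$start_seed
      screened[[length(screened) + 1L]] <- run
    }
    s_idx <- s_idx + 1L
  }
  if (length(screened) == 0L)
    stop("all cMRM starts degenerated (empty class); G = ", G,
         " is likely too large for these data")

  ord <- order(vapply(screened, `[[`, 1, "loglik"), decreasing = TRUE)
  finalists <- screened[ord[seq_len(min(n_final, length(screened)))]]
  best <- NULL
  for (f in finalists) {
    run <- cmrm_em(rm, bank, f$pi, f$theta, f$delta,
                   max_iter = max_iter, tol = tol)
    if (run$degenerate) next
    run$start_seed <- f$start_seed
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("all finalist cMRM runs degenerated (empty class) for G = ", G)

  # canonical ascending-location order
  ordg <- order(best$theta)
  pi_g <- best$pi[ordg]; theta_g <- best$theta[ordg]
  post <- best$post[, ordg, drop = FALSE]
  est_bank <- item_bank(bank$item_id, bank$item_type, best$delta,
                        bank$category_weight)
  structure(list(G = G, pi = pi_g, theta = theta_g, bank = est_bank,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n_params = n_params, posteriors = post,
                 n_persons = n, converged = best$converged,
                 n_starts_used = length(starts),
                 best_start_seed = best$start_seed,
                 collapsed = prep$collapsed),
            class = "cmrm_fit")
}

# Core ECM loop. Returns pi/theta/delta/post/loglik/trace and flags.
cmrm_em <- function(rm, bank, pi_g, theta_g, delta, max_iter, tol) {
  n <- nrow(rm); G <- length(pi_g)
  x <- unclass(rm)
  obs <- !is.na(x)
  obs_num <- obs * 1
  x0 <- ifelse(obs, x, 0L)
  obs_idx <- lapply(seq_len(ncol(x)), function(i) which(obs[, i]))
  cat_idx <- lapply(seq_len(ncol(x)), function(i) {
    xi <- x[, i]
    lapply(0:(bank$n_categories[i] - 1L), function(k) which(!is.na(xi) & xi == k))
  })
  w <- bank$category_weight
  trace <- numeric(0)
  converged <- FALSE; degenerate <- FALSE
  post <- NULL; ll <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step
    lp <- matrix(log(pi_g), n, G, byrow = TRUE)
    for (i in seq_len(ncol(x))) {
      lpi <- t(log(pcm_prob(theta_g, delta[[i]], w[i])))  # ncat x G
      oi <- obs_idx[[i]]
      lp[oi, ] <- lp[oi, ] + lpi[x[oi, i] + 1L, , drop = FALSE]
    }
    llv <- logsumexp_rows(lp)
    ll_new <- sum(llv)
    trace <- c(trace, ll_new)
    post <- exp(lp - llv)

    # M-step: proportions
    pi_g <- colMeans(post)
    if (any(pi_g * n < 1)) { degenerate <- TRUE; break }
    # M-step: class locations given current item parameters
    S <- crossprod(x0, post)          # I x G sum of p_vg * x_vi (observed)
    Nobs <- crossprod(obs_num, post)  # I x G sum of p_vg over observed
    for (g in seq_len(G)) {
      theta_g[g] <- solve_class_location(S[, g], Nobs[, g], delta, w,
                                         theta_g[g])
    }
    # M-step: item steps given updated locations (a few damped Newton
    # steps per iteration suffice; step-halving keeps the expected
    # objective non-decreasing, so the EM stays monotone)
    for (i in seq_len(ncol(x))) {
      ncat <- bank$n_categories[i]
      counts <- matrix(0, ncat, G)
      for (k in seq_len(ncat)) {
        sel <- cat_idx[[i]][[k]]
        if (length(sel))
          counts[k, ] <- colSums(post[sel, , drop = FALSE])
      }
      delta[[i]] <- pcm_item_newton(delta[[i]], counts, theta_g, w[i],
                                    max_steps = 4L)$delta
    }
    # identification: proportion-weighted location mean = 0
    shift <- sum(pi_g * theta_g)
    theta_g <- theta_g - shift
    delta <- lapply(seq_along(delta),
                    function(i) delta[[i]] - w[i] * shift)

    if (iter > 1L &&
        abs(ll_new - ll) < tol * (abs(ll_new) + 1e-12)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  list(pi = pi_g, theta = theta_g, delta = delta, post = post,
       loglik = trace[length(trace)], trace = trace,
       converged = converged, degenerate = degenerate)
}

# Solve sum_i w_i (S_i - N_i * E_i(theta)) = 0 for one class location.
# The left side is strictly decreasing in theta; Newton with a
# bisection fallback on [-12, 12].
solve_class_location <- function(S, Nobs, deltas, weights, start) {
  nI <- length(deltas)
  g <- function(theta) {
    e <- numeric(nI)
    for (i in seq_len(nI))
      e[i] <- pcm_scalar_moments(theta, deltas[[i]], weights[i])$E
    sum(weights * (S - Nobs * e))
  }
  theta <- start
  for (step in 1:8) {
    e <- v <- numeric(nI)
    for (i in seq_len(nI)) {
      mom <- pcm_scalar_moments(theta, deltas[[i]], weights[i])
      e[i] <- mom$E; v[i] <- mom$V
    }
    val <- sum(weights * (S - Nobs * e))
    slope <- -sum(weights^2 * Nobs * v)
    if (abs(slope) < 1e-12) break
    delta_step <- val / slope
    theta_new <- theta - delta_step
    theta_new <- min(max(theta_new, -12), 12)
    if (abs(theta_new - theta) < 1e-10) { theta <- theta_new; break }
    theta <- theta_new
  }
  if (abs(g(theta)) > 1e-6) {
    gl <- g(-12); gu <- g(12)
    if (gl <= 0) theta <- -12
    else if (gu >= 0) theta <- 12
    else theta <- stats::uniroot(g, c(-12, 12), tol = 1e-10)$root
  }
  theta
}

#' @export
print.cmrm_fit <- function(x, ...) {
  cat(sprintf("Constrained mixture Rasch model: G = %d classes, %d persons\n",
              x$G, x$n_persons))
  cat(sprintf("  logLik %.2f (%d free parameters)%s\n", x$loglik,
              x$n_params, if (x$converged) "" else " [NOT converged]"))
  cat("  class   pi      theta\n")
  for (g in seq_len(x$G))
    cat(sprintf("  %5d   %.3f  %+.3f\n", g, x$pi[g], x$theta[g]))
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Bayes posteriors `pi_g P(x_v | theta_g) / sum_h pi_h P(x_v |
#' theta_h)`. A person with no observed responses gets the prior
#' proportions.
#'
#' @param fit a [fit_cmrm] result.
#' @param rm a `response_matrix` on the same items.
#' @return N x G matrix with rows summing to 1.
#' @export
cmrm_posteriors <- function(fit, rm) {
  stopifnot(inherits(fit, "cmrm_fit"))
  n <- nrow(rm); G <- fit$G
  x <- unclass(rm); obs <- !is.na(x)
  lp <- matrix(log(fit$pi), n, G, byrow = TRUE)
  for (i in seq_len(ncol(x))) {
    lpi <- t(log(pcm_prob(fit$theta, fit$bank$step_params[[i]],
                          fit$bank$category_weight[i])))
    oi <- which(obs[, i])
    lp[oi, ] <- lp[oi, ] + lpi[x[oi, i] + 1L, , drop = FALSE]
  }
  exp(lp - logsumexp_rows(lp))
}

#' Modal class assignment
#'
#' Assigns each person to the most probable class; exact posterior
#' ties break toward the lower class index, so borderline persons fall
#' into the lower-proficiency class. Class 1 (lowest location) is the
#' low-literacy class.
#'
#' @param fit a [fit_cmrm] result.
#' @param post optional posterior matrix (defaults to the fit's).
#' @return Integer vector of class labels in `1..G`.
#' @export
cmrm_classify <- function(fit, post = NULL) {
  if (is.null(post)) post <- fit$posteriors
  max.col(post, ties.method = "first")
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_v sum_g (-p_vg log p_vg) / (N log G)`; 1 for a perfectly
#' sharp classification, 0 for uniform posteriors. Values above .80
#' are conventionally read as high class separation, above .60 as
#' medium, above .40 as low.
#'
#' @param post an N x G posterior probability matrix with G >= 2.
#' @return A value in `[0, 1]`.
#' @export
relative_entropy <- function(post) {
  G <- ncol(post)
  if (is.null(G) || G < 2L)
    stop("relative entropy is undefined for G = 1")
  p <- pmax(post, 0)
  e <- ifelse(p > 0, -p * log(p), 0)
  1 - sum(e) / (nrow(post) * log(G))
}

#' Average posterior class probabilities (ACP)
#'
#' Mean posterior probability of class `g` among persons modally
#' assigned to `g`. Values below .70 are conventionally flagged as an
#' uncertain classification; a class with no modally assigned persons
#' gets `NA` and is flagged.
#'
#' @param post an N x G posterior matrix.
#' @param labels optional modal assignments (defaults to row-wise
#'   argmax with ties toward the lower class).
#' @param flag_below flag threshold (default .70).
#' @return Data frame with columns `class`, `n`, `acp`, `flagged`.
#' @export
acp <- function(post, labels = NULL, flag_below = 0.70) {
  if (is.null(labels)) labels <- max.col(post, ties.method = "first")
  G <- ncol(post)
  out <- data.frame(class = seq_len(G), n = 0L, acp = NA_real_,
                    flagged = TRUE)
  for (g in seq_len(G)) {
    sel <- labels == g
    out$n[g] <- sum(sel)
    if (any(sel)) out$acp[g] <- mean(post[sel, g])
  }
  out$flagged <- is.na(out$acp) | out$acp < flag_below
  out
}

#' Serialize a cMRM fit to JSON
#'
#' @param fit a [fit_cmrm] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cmrm_fit <- function(fit, path) {
  jsonlite::write_json(list(
    G = fit$G, pi = fit$pi, theta = fit$theta,
    item_id = fit$bank$item_id, step_params = fit$bank$step_params,
    category_weight = fit$bank$category_weight,
    loglik = fit$loglik, n_params = fit$n_params,
    converged = fit$converged, n_starts_used = fit$n_starts_used,
    best_start_seed = fit$best_start_seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
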