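#' Information criteria for a fitted class solution
#'
#' `AIC = -2L + 2p`, `BIC = -2L + p log N`, and the sample-adjusted
#' BIC `aBIC = -2L + p log((N + 2) / 24)` (Sclove's effective sample
#' size). `p` counts free parameters after the identification
#' constraints: one step parameter per category step, plus `G - 1`
#' free proportions and `G - 1` free locations (the weighted location
#' mean is fixed to 0).
#'
#' @param fit a [fit_cmrm] result.
#' @param N sample size (defaults to the fit's).
#' @return Named list `AIC`, `BIC`, `aBIC`, `n_params`.
#' @export
information_criteria <- function(fit, N = fit$n_persons) {
  p <- fit$n_params
  m2l <- -2 * fit$loglik
  list(AIC = m2l + 2 * p, BIC = m2l + p * log(N),
       aBIC = m2l + p * log((N + 2) / 24), n_params = p)
}

#' Minimum class-size check
#'
#' Flags classes whose modal-assignment share falls below `min_prop`
#' (default 5% of the sample, inclusive: a share of exactly
#' `min_prop` passes). Solutions with under-populated classes are
#' unlikely to replicate and are dropped from consideration.
#'
#' @param fit a [fit_cmrm] result.
#' @param min_prop minimum acceptable class proportion.
#' @return Data frame with `class`, `prop`, `pass`, plus attribute
#'   `all_pass`.
#' @export
class_size_check <- function(fit, min_prop = 0.05) {
  labels <- cmrm_classify(fit)
  prop <- tabulate(labels, nbins = fit$G) / length(labels)
  out <- data.frame(class = seq_len(fit$G), prop = prop,
                    pass = prop >= min_prop)
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Bootstrapped likelihood ratio test for G vs G - 1 classes
#'
#' Parametric bootstrap: `B` datasets are simulated from the fitted
#' `(G-1)`-class model, both models are refitted on each, and the
#' observed likelihood-ratio statistic is referred to the bootstrap
#' distribution with the add-one estimator
#' `p = (1 + #\{LR_b >= LR_obs\}) / (B + 1)`.
#'
#' All likelihood ratios entering the comparison — the observed one
#' included — are computed by one and the same warm-started refit
#' procedure (null model seeded by the parent estimates, alternative
#' seeded by a class split of that null refit, plus random starts), so
#' observed and bootstrap statistics are exchangeable under the null
#' and the add-one p-value is calibrated. An alternative refit that
#' degenerates (empty class) contributes LR = 0, the value of a
#' non-improving extra class; ratios are clamped at 0 on both sides.
#' Replicates whose null refit fails are dropped and counted, with a
#' warning above 10% drop.
#'
#' @param rm the observed `response_matrix`.
#' @param bank_skeleton the [item_bank] structure.
#' @param G number of classes under the alternative (>= 2).
#' @param B bootstrap replicates (>= 19; default 99).
#' @param seed RNG seed.
#' @param alpha decision level (default .001).
#' @param fit_G,fit_Gm1 optional pre-computed fits on the observed
#'   data (avoids refitting during class enumeration).
#' @param n_starts,n_final multistart counts for the observed-data
#'   fits (bootstrap refits use the parent solution plus 2 starts).
#' @return List with `LR_obs`, `p_value`, `significant`, `B_used`,
#'   `B_dropped`, and the bootstrap `LR` values.
#' @export
blrt <- function(rm, bank_skeleton, G, B = 99L, seed = 1L, alpha = 0.001,
                 fit_G = NULL, fit_Gm1 = NULL,
                 n_starts = 20L, n_final = 5L) {
  stopifnot(G >= 2L, B >= 19L)
  if (is.null(fit_Gm1))
    fit_Gm1 <- fit_cmrm(rm, bank_skeleton, G - 1L, n_starts, n_final,
                        seed = stage_seed(seed, "blrt_null"))
  if (is.null(fit_G))
    fit_G <- tryCatch(
      fit_cmrm(rm, bank_skeleton, G, n_starts, n_final,
               seed = stage_seed(seed, "blrt_alt"),
               init = nested_init(fit_Gm1)),
      error = function(e) NULL)

  # one refit procedure for every LR entering the comparison
  lr_pair <- function(data, b) {
    f0 <- refit_warm(data, fit_Gm1, G - 1L, seed, b)
    f1 <- tryCatch(refit_warm(data, f0, G, seed, b),
                   error = function(e) NULL)
    if (is.null(f1)) 0 else max(0, 2 * (f1$loglik - f0$loglik))
  }
  lr_obs <- lr_pair(rm, 0L)

  null_ability <- boot_ability(fit_Gm1)
  lr_boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    cfg <- synthetic_config(nrow(rm), null_ability,
                            seed = stage_seed(seed, paste0("blrt_b", b)))
    sim <- simulate_responses(fit_Gm1$bank, cfg)
    lr_boot[b] <- tryCatch(lr_pair(sim, b), error = function(e) NA_real_)
  }
  dropped <- sum(is.na(lr_boot))
  if (dropped > 0.1 * B)
    warning(sprintf("BLRT: %d of %d bootstrap replicates dropped", dropped, B))
  lr_ok <- lr_boot[!is.na(lr_boot)]
  b_used <- length(lr_ok)
  p <- (1 + sum(lr_ok >= lr_obs)) / (b_used + 1)
  list(LR_obs = lr_obs, p_value = p, significant = p <= alpha,
       alpha = alpha, B_used = b_used, B_dropped = dropped, LR = lr_ok,
       loglik_G = if (!is.null(fit_G)) fit_G$loglik else NA_real_,
       loglik_Gm1 = fit_Gm1$loglik)
}

# Discrete mixture ability model from a fitted cMRM; a single class
# degenerates to a point mass, which ability_mixture() accepts.
boot_ability <- function(fit) {
  ability_mixture(fit$pi, fit$theta)
}

# Starting values for a (G+1)-class fit nested above a G-class fit:
# split the largest class into two slightly offset locations. EM from
# here starts essentially at the parent likelihood, so the
# best-of-restarts likelihood is non-decreasing in G.
nested_init <- function(parent) {
  g <- which.max(parent$pi)
  pi_new <- append(parent$pi[-g], rep(parent$pi[g] / 2, 2), after = g - 1L)
  th_new <- append(parent$theta[-g], parent$theta[g] + c(-0.1, 0.1),
                   after = g - 1L)
  list(pi = pi_new, theta = th_new, delta = parent$bank$step_params)
}

# Warm-started refit for bootstrap replicates: parent estimates (or a
# class-split thereof) plus two random starts.
refit_warm <- function(sim, parent, G, seed, b) {
  init <- if (parent$G == G) {
    list(pi = parent$pi, theta = parent$theta,
         delta = parent$bank$step_params)
  } else if (parent$G == G - 1L) {
    nested_init(parent)
  } else NULL
  fit_cmrm(sim, parent$bank, G, n_starts = 2L, n_final = 1L,
           seed = stage_seed(seed, paste0("refit", G, "_", b)),
           tol = 1e-6, max_iter = 200L, init = init)
}

#' Enumerate class solutions and build a selection report
#'
#' Fits the constrained mixture Rasch model for `G = 1..G_max` and
#' collects, per G: log-likelihood, parameter count, AIC/BIC/aBIC,
#' BLRT p-value (optional), minimum modal class proportion, relative
#' entropy and minimum ACP.
#'
#' @param rm a `response_matrix`.
#' @param bank_skeleton the [item_bank] structure.
#' @param G_max largest class count to consider.
#' @param n_starts,n_final multistart counts per fit.
#' @param seed RNG seed.
#' @param blrt_B bootstrap replicates for the BLRT; `0` skips the
#'   BLRT (its column becomes `NA`).
#' @param alpha BLRT significance level.
#' @param min_prop minimum class-size proportion.
#' @param blrt_skip_small if `TRUE`, skip the (expensive) BLRT for
#'   solutions that already fail the class-size rule — the selection
#'   rule drops them before the BLRT is consulted.
#' @return An object of class `selection_report`: a data frame with
#'   one row per G, the fits in `attr(, "fits")`, and the applied
#'   thresholds as attributes.
#' @export
enumerate_classes <- function(rm, bank_skeleton, G_max, n_starts = 50L,
                              n_final = 10L, seed = 1L, blrt_B = 99L,
                              alpha = 0.001, min_prop = 0.05,
                              blrt_skip_small = FALSE) {
  stopifnot(G_max >= 1L)
  fits <- vector("list", G_max)
  rows <- vector("list", G_max)
  for (G in seq_len(G_max)) {
    fit <- fit_cmrm(rm, bank_skeleton, G, n_starts, n_final,
                    seed = stage_seed(seed, paste0("enum", G)),
                    init = if (G >= 2L) nested_init(fits[[G - 1L]]))
    fits[[G]] <- fit
    ic <- information_criteria(fit)
    csc <- class_size_check(fit, min_prop)
    ent <- if (G >= 2L) relative_entropy(fit$posteriors) else NA_real_
    min_acp <- if (G >= 2L) min(acp(fit$posteriors)$acp, na.rm = TRUE)
               else NA_real_
    p_blrt <- NA_real_
    if (G >= 2L && blrt_B > 0L &&
        !(blrt_skip_small && !attr(csc, "all_pass"))) {
      p_blrt <- blrt(rm, bank_skeleton, G, B = blrt_B,
                     seed = stage_seed(seed, paste0("blrtG", G)),
                     alpha = alpha, fit_G = fit,
                     fit_Gm1 = fits[[G - 1L]])$p_value
    }
    rows[[G]] <- data.frame(
      G = G, loglik = fit$loglik, n_params = fit$n_params,
      AIC = ic$AIC, BIC = ic$BIC, aBIC = ic$aBIC, BLRT_p = p_blrt,
      min_class_prop = min(csc$prop), entropy = ent, min_ACP = min_acp)
  }
  report <- do.call(rbind, rows)
  attr(report, "fits") <- fits
  attr(report, "alpha") <- alpha
  attr(report, "min_prop") <- min_prop
  class(report) <- c("selection_report", "data.frame")
  report
}

#' Select the number of latent classes
#'
#' Deterministic codification of the selection hierarchy: (1) drop
#' solutions with a modal class share below the minimum (5% rule);
#' (2) among the survivors prefer the largest G whose BLRT is
#' significant at `alpha`; (3) break remaining ties by the lowest
#' aBIC; (4) entropy and ACP are recorded as advisory flags only.
#' If every solution fails the class-size rule, G = 1 is returned
#' with a warning.
#'
#' @param report a [enumerate_classes] report (or any data frame with
#'   columns `G`, `aBIC`, `BLRT_p`, `min_class_prop`).
#' @param alpha BLRT significance level (default .001).
#' @param min_prop minimum class proportion (default .05, inclusive).
#' @return List with `chosen_G` and `rationale`, an ordered character
#'   vector of the applied rules.
#' @export
select_solution <- function(report, alpha = 0.001, min_prop = 0.05) {
  stopifnot(all(c("G", "aBIC", "BLRT_p", "min_class_prop") %in% names(report)))
  rationale <- character(0)
  ok <- report$min_class_prop >= min_prop
  rationale <- c(rationale, sprintf(
    "class-size rule (>= %.0f%%): dropped G in {%s}", 100 * min_prop,
    paste(report$G[!ok], collapse = ", ")))
  surv <- report[ok, , drop = FALSE]
  if (nrow(surv) == 0L) {
    warning("all class solutions fail the minimum class-size rule; returning G = 1")
    return(list(chosen_G = 1L,
                rationale = c(rationale, "all G failed the class-size rule: fallback G = 1")))
  }
  if (nrow(surv) == 1L) {
    return(list(chosen_G = surv$G[1L],
                rationale = c(rationale, sprintf("single surviving solution: G = %d", surv$G[1L]))))
  }
  sig <- !is.na(surv$BLRT_p) & surv$BLRT_p <= alpha
  if (any(sig)) {
    gsig <- max(surv$G[sig])
    cand <- surv[surv$G == gsig, , drop = FALSE]
    rationale <- c(rationale, sprintf(
      "BLRT rule (alpha = %g): largest surviving G with significant BLRT is %d",
      alpha, gsig))
  } else {
    cand <- surv
    rationale <- c(rationale,
                   "BLRT rule: no surviving G significant (or BLRT unavailable); falling back to aBIC")
  }
  chosen <- cand$G[which.min(cand$aBIC)]
  rationale <- c(rationale, sprintf("aBIC tie-break: chose G = %d", chosen))
  list(chosen_G = chosen, rationale = rationale)
}

#' Write a selection report
#'
#' @param report a [enumerate_classes] result.
#' @param path_csv,path_json optional output paths.
#' @param selection optional [select_solution] result to embed in the
#'   JSON output.
#' @return The report, invisibly.
#' @export
write_selection_report <- function(report, path_csv = NULL,
                                   path_json = NULL, selection = NULL) {
  df <- as.data.frame(report)
  if (!is.null(path_csv)) utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(table = df, chosen_G = selection$chosen_G,
                              rationale = selection$rationale),
                         path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  invisible(report)
}
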