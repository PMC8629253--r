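# Constrained mixture Rasch model: EM behaviour, posteriors,
# classification and classification-quality summaries.

test_that("a 1-class model reduces to the Rasch likelihood at ability 0", {
  bank <- test_bank_dichot(8)
  rm <- simulate_responses(bank, synthetic_config(
    400, ability_continuous(0, 1), seed = 61))
  fit <- fit_cmrm(rm, bank, G = 1, n_starts = 3, n_final = 1, seed = 1)
  expect_equal(fit$pi, 1)
  expect_equal(fit$theta, 0)
  # direct likelihood of the data at theta = 0 under the estimated items
  ll <- 0
  for (i in seq_len(nrow(bank))) {
    p <- oracle_pcm(0, fit$bank$step_params[[i]], fit$bank$category_weight[i])
    ll <- ll + sum(log(p[rm[, i] + 1L]))
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and classes come out ordered", {
  bank <- test_bank_dichot(12)
  rm <- simulate_responses(bank, synthetic_config(
    800, adult_like_mixture(), seed = 62, missing_rate = 0.05))
  fit <- fit_cmrm(rm, bank, G = 3, n_starts = 10, n_final = 3, seed = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(all(diff(fit$theta) > 0))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
  expect_equal(sum(fit$pi * fit$theta), 0, tolerance = 1e-8)
  expect_equal(rowSums(fit$posteriors), rep(1, 800), tolerance = 1e-10)
})

test_that("parameters of a 2-class world are recovered", {
  bank <- test_bank_dichot(15, range = c(-2, 2))
  truth_pi <- c(.4, .6); truth_th <- c(-1.2, 1.0)
  rm <- simulate_responses(bank, synthetic_config(
    1500, ability_mixture(truth_pi, truth_th), seed = 63))
  fit <- fit_cmrm(rm, bank, G = 2, n_starts = 10, n_final = 3, seed = 3)
  # align the truth with the weighted-mean-0 identification
  shift <- sum(truth_pi * truth_th)
  expect_lt(max(abs(fit$pi - truth_pi)), 0.05)
  expect_lt(max(abs(fit$theta - (truth_th - shift))), 0.15)
})

test_that("the best-of-restarts likelihood is non-decreasing in G", {
  bank <- test_bank_dichot(10)
  rm <- simulate_responses(bank, synthetic_config(
    500, adult_like_mixture(), seed = 64))
  lls <- numeric(3)
  prev <- NULL
  for (G in 1:3) {
    init <- if (G > 1) raschcut:::nested_init(prev)
    prev <- fit_cmrm(rm, bank, G, n_starts = 8, n_final = 2, seed = 4,
                     init = init)
    lls[G] <- prev$loglik
  }
  expect_true(all(diff(lls) > -1e-6))
})

test_that("posteriors match a hand-computed two-item case", {
  # 2 dichotomous items b = (0, 1); classes at theta -1 / +1 with
  # pi = (.4, .6); person answered item1 correct, item2 wrong.
  bank <- item_bank(c("i1", "i2"), rep("dichotomous", 2),
                    list(0, 1), c(1, 1))
  fit <- structure(list(G = 2L, pi = c(.4, .6), theta = c(-1, 1),
                        bank = bank), class = "cmrm_fit")
  rm <- response_matrix(matrix(c(1L, 0L), 1, 2,
                               dimnames = list(NULL, c("i1", "i2"))))
  post <- cmrm_posteriors(fit, rm)
  p1 <- plogis(-1 - 0) * (1 - plogis(-1 - 1))
  p2 <- plogis(1 - 0) * (1 - plogis(1 - 1))
  expect_equal(post[1, 1], .4 * p1 / (.4 * p1 + .6 * p2), tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("an all-missing person gets the prior as posterior", {
  bank <- test_bank_dichot(6)
  rm <- simulate_responses(bank, synthetic_config(
    300, adult_like_mixture(), seed = 65))
  fit <- fit_cmrm(rm, bank, G = 2, n_starts = 6, n_final = 2, seed = 5)
  x <- unclass(rm); x[1, ] <- NA_integer_
  post <- cmrm_posteriors(fit, response_matrix(x))
  expect_equal(post[1, ], fit$pi, tolerance = 1e-12)
})

test_that("G = 1 posteriors are unity and entropy is undefined", {
  bank <- test_bank_dichot(5)
  rm <- simulate_responses(bank, synthetic_config(
    200, ability_continuous(0, 1), seed = 66))
  fit <- fit_cmrm(rm, bank, G = 1, n_starts = 2, n_final = 1, seed = 6)
  expect_true(all(fit$posteriors == 1))
  expect_error(relative_entropy(fit$posteriors), "G = 1")
})

test_that("modal classification breaks ties toward the lower class", {
  post <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9))
  fit <- structure(list(posteriors = post), class = "cmrm_fit")
  expect_equal(cmrm_classify(fit), c(1L, 1L, 2L))
})

test_that("relative entropy spans its defining extremes", {
  hard <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(relative_entropy(hard), 1)
  flat <- matrix(1 / 3, 5, 3)
  expect_equal(relative_entropy(flat), 0)
})

test_that("ACP matches hand arithmetic and flags weak classes", {
  post <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  a <- acp(post)
  expect_equal(a$acp, c((0.9 + 0.6) / 2, NA_real_))
  expect_true(a$flagged[2])  # empty class
  expect_false(a$flagged[1])
  degenerate <- rbind(c(1, 0), c(0, 1))
  expect_equal(acp(degenerate)$acp, c(1, 1))
})

test_that("class separation on an adult-like profile gives the reported quality", {
  bank <- test_bank_mixed()
  rm <- simulate_responses(bank, synthetic_config(
    2000, adult_like_mixture(), seed = 67))
  fit <- fit_cmrm(rm, bank, G = 3, n_starts = 10, n_final = 3, seed = 7)
  ent <- relative_entropy(fit$posteriors)
  expect_gt(ent, 0.6)
  expect_lt(ent, 0.85)
  expect_true(all(acp(fit$posteriors)$acp > 0.8))
})

test_that("cMRM fits serialize to JSON", {
  bank <- test_bank_dichot(5)
  rm <- simulate_responses(bank, synthetic_config(
    300, adult_like_mixture(), seed = 68))
  fit <- fit_cmrm(rm, bank, G = 2, n_starts = 5, n_final = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_cmrm_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$G, 2)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
})
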