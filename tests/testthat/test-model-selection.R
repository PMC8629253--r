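test_that("information criteria follow their closed forms", {
  fake <- structure(list(loglik = -100, n_params = 5, n_persons = 1000),
                    class = "cmrm_fit")
  ic <- information_criteria(fake)
  expect_equal(ic$AIC, 210)
  expect_equal(ic$BIC, 200 + 5 * log(1000))
  expect_equal(ic$aBIC, 200 + 5 * log(1002 / 24))
})

test_that("aBIC penalizes less than BIC at realistic sample sizes", {
  fake <- structure(list(loglik = -50, n_params = 3), class = "cmrm_fit")
  for (N in c(23, 100, 3145, 13897)) {
    ic <- information_criteria(fake, N = N)
    expect_lt(ic$aBIC, ic$BIC)
  }
  # the effective sample size (N+2)/24 reaches 1 at N = 22
  expect_equal(information_criteria(fake, N = 22)$aBIC, 100)
})

test_that("the free-parameter count reflects the identification constraints", {
  bank <- test_bank_dichot(25)
  rm <- simulate_responses(bank, synthetic_config(
    600, adult_like_mixture(), seed = 71))
  fit <- fit_cmrm(rm, bank, G = 3, n_starts = 6, n_final = 2, seed = 9)
  # 25 item difficulties + (G-1) proportions + (G-1) free locations
  expect_equal(fit$n_params, 25 + 2 + 2)
})

test_that("the class-size rule is inclusive at the boundary", {
  mk <- function(props) {
    n <- 1000
    labels <- rep(seq_along(props), round(props * n))
    post <- matrix(0, length(labels), length(props))
    post[cbind(seq_along(labels), labels)] <- 1
    structure(list(G = length(props), posteriors = post),
              class = "cmrm_fit")
  }
  fail <- class_size_check(mk(c(.04, .96)))
  expect_false(attr(fail, "all_pass"))
  expect_equal(fail$pass, c(FALSE, TRUE))
  pass <- class_size_check(mk(c(.05, .95)))
  expect_true(attr(pass, "all_pass"))
})

test_that("select_solution applies its rules in the documented order", {
  mk_report <- function(...) {
    df <- data.frame(...)
    class(df) <- c("selection_report", "data.frame")
    df
  }
  # student-like: 5% rule holds through G = 4, BLRT significant throughout
  student <- mk_report(G = 1:5, aBIC = c(500, 450, 420, 410, 405),
                       BLRT_p = c(NA, .001, .001, .001, .001),
                       min_class_prop = c(1, .3, .15, .08, .03))
  expect_equal(select_solution(student, alpha = .001)$chosen_G, 4L)
  # adult-like: 5% rule fails from G = 4 onward, BLRT significant to 5
  adult <- mk_report(G = 1:5, aBIC = c(400, 360, 340, 335, 333),
                     BLRT_p = c(NA, .0001, .0001, .0001, .0001),
                     min_class_prop = c(1, .4, .14, .04, .02))
  expect_equal(select_solution(adult, alpha = .001)$chosen_G, 3L)
  # single row: returned as-is
  single <- mk_report(G = 1, aBIC = 100, BLRT_p = NA,
                      min_class_prop = 1)
  expect_equal(select_solution(single)$chosen_G, 1L)
  # nothing significant: lowest aBIC among survivors
  none <- mk_report(G = 1:3, aBIC = c(300, 290, 295),
                    BLRT_p = c(NA, .5, .9),
                    min_class_prop = c(1, .4, .2))
  sel <- select_solution(none, alpha = .001)
  expect_equal(sel$chosen_G, 2L)
  expect_true(any(grepl("aBIC", sel$rationale)))
  # everything fails the 5% rule
  bad <- mk_report(G = 2:3, aBIC = c(10, 5), BLRT_p = c(.001, .001),
                   min_class_prop = c(.01, .02))
  expect_warning(sel_bad <- select_solution(bad), "fail")
  expect_equal(sel_bad$chosen_G, 1L)
})

test_that("BLRT p-values respect the add-one bounds and the null", {
  bank <- test_bank_dichot(8)
  rm <- simulate_responses(bank, synthetic_config(
    300, ability_mixture(1, 0), seed = 73))
  b <- blrt(rm, bank, G = 2, B = 19, seed = 11, alpha = .05,
            n_starts = 6, n_final = 2)
  expect_gte(b$p_value, 1 / (b$B_used + 1))
  expect_lte(b$p_value, 1)
  expect_gt(b$LR_obs, -1e-3)   # nested warm start keeps LR >= ~0
  expect_lt(b$LR_obs, 20)      # no spurious class structure under the null
  expect_equal(b$B_dropped, 0L)
})

test_that("BLRT detects a strongly two-class structure", {
  bank <- test_bank_dichot(10)
  rm <- simulate_responses(bank, synthetic_config(
    600, ability_mixture(c(.4, .6), c(-1.3, 1.1)), seed = 74))
  b <- blrt(rm, bank, G = 2, B = 99, seed = 12, alpha = .01,
            n_starts = 6, n_final = 2)
  expect_lte(b$p_value, .01)
  expect_true(b$significant)
  expect_gt(b$LR_obs, 100)
})

test_that("enumerate_classes produces a coherent report", {
  bank <- test_bank_dichot(10)
  rm <- simulate_responses(bank, synthetic_config(
    500, ability_mixture(c(.45, .55), c(-1.2, 1.0)), seed = 75))
  rep <- enumerate_classes(rm, bank, G_max = 3, n_starts = 6,
                           n_final = 2, seed = 13, blrt_B = 19,
                           alpha = .05, blrt_skip_small = TRUE)
  expect_equal(rep$G, 1:3)
  expect_true(all(diff(rep$n_params) > 0))
  expect_true(all(diff(rep$loglik) > -1e-6))
  expect_true(is.na(rep$BLRT_p[1]))
  sel <- select_solution(rep, alpha = .05)
  expect_equal(sel$chosen_G, 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep, path_json = path, selection = sel)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$chosen_G, 2)
})
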