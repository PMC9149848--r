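sim_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    bad_performances = rpois(n, 1),
    total_mistakes = rpois(n, 10),
    mistakes_good = rpois(n, 8),
    mean_rt = rnorm(n, 380, 90),
    sd_rt = rnorm(n, 70, 20),
    age1 = sample(50:85, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    education = sample(c("primary/none", "secondary", "third/higher"),
                       n, replace = TRUE),
    anxiety1 = rpois(n, 5), depression1 = rpois(n, 5),
    antihypertensives = runif(n) < 0.3, diabetes = runif(n) < 0.1,
    smoker = sample(c("never", "past", "current"), n, replace = TRUE),
    drinking = sample(c("no", "dont_know", "yes"), n, replace = TRUE),
    ugs1 = rnorm(n, 135, 20),
    ipaq = sample(c("low", "medium", "high"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("model tiers are nested and carry one main predictor", {
  specs <- lapply(1:4, function(t) model_spec("bad_performances", t))
  for (t in 2:4) {
    expect_true(all(specs[[t - 1]]$terms %in% specs[[t]]$terms))
  }
  expect_equal(specs[[1]]$terms, "bad_performances")
  expect_false("total_mistakes" %in% specs[[4]]$terms)
})

test_that("logistic fit recovers a known odds ratio", {
  set.seed(42)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * x))
  fit <- fit_blr(y, data.frame(bad_performances = x),
                 model_spec("bad_performances", 1))
  row <- fit$results[fit$results$term == "bad_performances", ]
  expect_true(row$ci_low <= exp(0.3) && exp(0.3) <= row$ci_high)
  expect_equal(row$or, exp(row$estimate))
  expect_equal(fit$n_used, n)
  expect_true(fit$converged)
})

test_that("degenerate outcomes and separation fail explicitly", {
  d <- data.frame(bad_performances = rnorm(20))
  expect_error(fit_blr(rep(1, 20), d, model_spec("bad_performances", 1)),
               "both classes")
  xs <- c(rnorm(30, -5), rnorm(30, 5))
  ys <- as.integer(xs > 0)
  suppressWarnings(expect_error(
    fit_blr(ys, data.frame(bad_performances = xs),
            model_spec("bad_performances", 1)),
    "separation"))
})

test_that("Wald p-values and confidence intervals agree about the null", {
  d <- sim_design(800, 10)
  set.seed(11)
  y <- rbinom(800, 1, plogis(-1.5 + 0.4 * d$bad_performances + 0.02 *
                               (d$age1 - 65)))
  fit <- fit_blr(y, d, model_spec("bad_performances", 4))
  sig <- fit$results$p_value < 0.05
  excl <- fit$results$ci_low > 1 | fit$results$ci_high < 1
  expect_equal(sig[-1], excl[-1])   # every term except the intercept
})

test_that("tier log-likelihoods are monotone on identical data", {
  d <- sim_design(600, 12)
  set.seed(13)
  y <- rbinom(600, 1, plogis(-1 + 0.3 * d$bad_performances))
  ll <- vapply(1:4, function(t) {
    fit_blr(y, d, model_spec("bad_performances", t))$log_lik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("multicollinearity screen flags rank-correlated columns", {
  set.seed(14)
  d <- data.frame(a = rnorm(300), b = rnorm(300))
  ok <- multicollinearity_screen(d)
  expect_true(ok$pass)
  expect_lt(ok$max_abs_rho, 0.2)

  dup <- data.frame(a = d$a, b = d$a)
  expect_false(multicollinearity_screen(dup)$pass)
  expect_equal(multicollinearity_screen(dup)$max_abs_rho, 1)

  mono <- data.frame(a = d$a, b = exp(d$a))   # rank-invariant transform
  expect_equal(multicollinearity_screen(mono)$max_abs_rho, 1)
})

test_that("null predictors show approximately nominal CI coverage", {
  covered <- 0
  for (i in 1:100) {
    set.seed(800 + i)
    x <- rnorm(500)
    y <- rbinom(500, 1, 0.3)
    fit <- fit_blr(y, data.frame(bad_performances = x),
                   model_spec("bad_performances", 1))
    row <- fit$results[fit$results$term == "bad_performances", ]
    if (row$ci_low <= 1 && 1 <= row$ci_high) covered <- covered + 1
  }
  expect_gte(covered / 100, 0.88)
})

test_that("the driving predictor earns the largest odds ratio", {
  wins <- 0
  for (i in 1:50) {
    set.seed(900 + i)
    n <- 800
    bp1 <- rpois(n, 1)
    d <- sim_design(n, 900 + i)
    d$bad_performances <- bp1
    d$total_mistakes <- 5 * bp1 + rpois(n, 8)      # noisy proxies
    d$mistakes_good <- 3 * bp1 + rpois(n, 6)
    y <- rbinom(n, 1, plogis(-2 + 0.8 * bp1))
    tab <- compare_predictors(y, d)
    t1 <- tab[tab$tier == 1 & tab$available, ]
    if (t1$or[t1$predictor == "bad_performances"] == max(t1$or)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins / 50, 0.9)
})

test_that("the comparison table reports CI overlap consistently", {
  d <- sim_design(600, 15)
  set.seed(16)
  y <- rbinom(600, 1, plogis(-1.5 + 0.5 * d$bad_performances))
  tab <- compare_predictors(y, d)
  expect_equal(nrow(tab), 12)
  for (t in 1:4) {
    rows <- tab[tab$tier == t & tab$available, ]
    expect_equal(unique(rows$ci_overlap),
                 max(rows$ci_low) <= min(rows$ci_high))
  }
})
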