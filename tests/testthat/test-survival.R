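# independent Efron/Breslow-free partial likelihood for the no-ties case,
# used as a brute-force oracle for the Cox fit
plik_noties <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- kmEstimate(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))
  # no events: flat at 1
  km2 <- kmEstimate(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # censoring after the last event leaves S unchanged
  km3 <- kmEstimate(c(1, 2, 9), c(1, 1, 0))
  expect_equal(km3$surv, c(2 / 3, 1 / 3, 1 / 3))
  # survival starts at 1 and is non-increasing, per group
  set.seed(4)
  t <- rexp(40); e <- rbinom(40, 1, 0.6); g <- rep(c("a", "b"), 20)
  km4 <- kmEstimate(t, e, g)
  for (gg in c("a", "b")) {
    s <- km4$surv[km4$group == gg]
    expect_true(all(diff(s) <= 0) && s[1] <= 1)
  }
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test matches hand computation and the survival package", {
  # identical groups (duplicated data): chi-squared 0, p = 1
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 1)
  res0 <- logrankTest(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # 2x2 toy: A events at 1,2; B events at 3,4
  # hand computation: O_A = 2; E_A = 2/4 + 1/3 = 5/6;
  # V = sum d(n-d)/(n-1) * nA*nB/n^2 = 1*3/3*(4/16) + 1*2/2*(2/9) + 0 + 0
  toy <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(toy$chisq, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-10)
  skip_if_not_installed("survival")
  set.seed(5)
  tt <- round(rexp(60, 0.1), 1) + 0.1
  ee <- rbinom(60, 1, 0.7)
  gg <- rep(c("x", "y", "z"), 20)
  mine <- logrankTest(tt, ee, gg)
  ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
  expect_equal(mine$df, 2)
})

test_that("log-rank rejects at the nominal rate under the null", {
  set.seed(99)
  rej <- vapply(1:500, function(i) {
    t <- rexp(24); e <- rbinom(24, 1, 0.8); g <- rep(c("a", "b"), 12)
    logrankTest(t, e, g)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("Cox fit maximizes the partial likelihood (brute-force oracle)", {
  # single binary covariate, 6 subjects, no ties
  t <- c(4, 3, 1, 2, 6, 5); e <- c(1, 1, 1, 0, 1, 1)
  x <- c(0, 1, 1, 0, 0, 1)
  fit <- coxFit(t, e, cbind(x = x))
  opt <- optimize(function(b) plik_noties(b, t, e, x - mean(x)),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(coef(fit)), opt$maximum, tolerance = 1e-4)
  expect_equal(fit@loglik[2], opt$objective, tolerance = 1e-8)
  expect_equal(fit@loglik[1], plik_noties(0, t, e, x), tolerance = 1e-10)
})

test_that("Cox fit agrees with the survival package under Efron ties", {
  skip_if_not_installed("survival")
  set.seed(6)
  n <- 120
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  t <- round(rexp(n, exp(0.5 * x1 - 0.7 * x2) / 20)) + 1  # heavy ties
  e <- rbinom(n, 1, 0.7)
  fit <- coxFit(t, e, cbind(a = x1, b = x2))
  ref <- survival::coxph(survival::Surv(t, e) ~ x1 + x2, ties = "efron")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit@se), unname(sqrt(diag(ref$var))), tolerance = 1e-6)
  expect_equal(unname(fit@loglik), unname(ref$loglik), tolerance = 1e-6)
  expect_equal(concordanceIndex(fit),
               unname(summary(ref)$concordance[1]), tolerance = 1e-8)
  hr <- hazardRatios(fit)
  expect_equal(hr$HR, unname(exp(coef(ref))), tolerance = 1e-6)
})

test_that("Cox partial likelihood is shift-invariant and scale-equivariant", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  t <- rexp(n, exp(0.4 * x) / 10); e <- rbinom(n, 1, 0.8)
  f1 <- coxFit(t, e, cbind(x = x))
  f2 <- coxFit(t, e, cbind(x = x + 100))
  f3 <- coxFit(t, e, cbind(x = 2 * x))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-6)
  expect_equal(unname(coef(f3)), unname(coef(f1)) / 2, tolerance = 1e-6)
})

test_that("Cox null coverage: coefficient within 2 SE of 0 in >= 95% of seeds", {
  cover <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 50
    t <- rexp(n); e <- rbinom(n, 1, 0.7); x <- rnorm(n)
    f <- coxFit(t, e, cbind(x = x))
    abs(coef(f)) < 2 * f@se
  }, logical(1))
  expect_gte(mean(cover), 0.95 - 0.035)  # binomial slack at 200 draws
})

test_that("concordance is 1 under perfect separation and matches score-test logic", {
  # risk order exactly reverses event-time order, all events
  t <- c(5, 4, 3, 2, 1); e <- rep(1, 5); risk <- 1:5
  expect_equal(concordanceIndexOf(t, e, risk), 1)
  expect_equal(concordanceIndexOf(t, e, -risk), 0)
  # score test at beta=0 on a binary group ~ log-rank chi-squared
  set.seed(8)
  n <- 40
  tt <- rexp(n) * 10; tt <- tt + seq_len(n) * 1e-6  # no ties
  ee <- rbinom(n, 1, 0.8); gg <- rep(0:1, n / 2)
  f <- coxFit(tt, ee, cbind(g = gg))
  lr <- logrankTest(tt, ee, gg)
  expect_equal(signif(f@score_test, 2), signif(lr$chisq, 2))
})

test_that("LR test compares nested fits on the chi-squared scale", {
  set.seed(9)
  n <- 80
  x <- rnorm(n); z <- rnorm(n)
  t <- rexp(n, exp(0.6 * x) / 10); e <- rbinom(n, 1, 0.8)
  f1 <- coxFit(t, e, cbind(x = x))
  f2 <- coxFit(t, e, cbind(x = x, z = z))
  lr <- lrTest(f1, f2)
  expect_equal(lr$df, 1)
  expect_equal(lr$chisq, 2 * (f2@loglik[2] - f1@loglik[2]), tolerance = 1e-10)
  # identical models: chi-squared 0, p 1
  same <- lrTest(f1, f1)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  # non-nested pairs refuse
  f3 <- coxFit(t, e, cbind(w = z))
  expect_error(lrTest(f3, f2), "nested")
})

test_that("quartile stratification follows the interpolation-quantile convention", {
  q <- quartileStratify(1:8)
  expect_equal(as.character(q$labels)[1:2], c("Q1", "Q1"))
  expect_equal(as.character(q$labels)[7:8], c("Q4", "Q4"))
  expect_equal(q$cutpoints, quantile(1:8, c(.25, .5, .75), names = FALSE))
  # all-distinct n = 100: 25 per quartile
  set.seed(10)
  s <- rnorm(100)
  q2 <- quartileStratify(s)
  expect_equal(unname(table(q2$labels)), rep(25L, 4), ignore_attr = TRUE)
  # invariant under monotone transform
  q3 <- quartileStratify(exp(s))
  expect_equal(as.character(q2$labels), as.character(q3$labels))
  expect_error(quartileStratify(rep(1, 20)), "constant")
  expect_error(quartileStratify(1:5), "at least 8")
})

test_that("median risk split uses the linear predictor with ties to low risk", {
  set.seed(11)
  n <- 50
  x <- rnorm(n)
  t <- rexp(n, exp(x) / 5); e <- rep(1, n)
  f <- coxFit(t, e, cbind(x = x))
  rs <- riskScoreSplit(f)
  # single positive-coefficient covariate: split equals median split of x
  expect_gt(unname(coef(f)), 0)
  expect_equal(rs$labels, ifelse(x <= median(x), "low", "high"),
               ignore_attr = TRUE)
  expect_equal(sum(rs$labels == "low"), 25)
  # high-risk stratum must have worse survival here (all events)
  km <- kmEstimate(t, e, rs$labels)
  s_end <- vapply(c("high", "low"), function(g)
    min(km$surv[km$group == g]), numeric(1))
  expect_true(mean(t[rs$labels == "high"]) < mean(t[rs$labels == "low"]))
})
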