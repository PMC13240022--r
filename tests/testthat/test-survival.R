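test_that("signature scores follow the gene-wise z construction", {
  # one gene, two patients: population-SD z of two points is (+1, -1)
  expr <- matrix(c(3, 7), 1, 2, dimnames = list("g1", c("p1", "p2")))
  expect_equal(unname(signature_score(expr, "g1")), c(-1, 1))
  # a gene listed twice in the signature counts once
  expr2 <- rbind(expr, g3 = c(10, 2))
  s_dup <- signature_score(expr2, c("g1", "g1", "g3"))
  s_once <- signature_score(expr2, c("g1", "g3"))
  expect_equal(s_dup, s_once)
  # scores average to zero across patients
  set.seed(7)
  big <- matrix(stats::rnorm(50), 5, 10,
                dimnames = list(paste0("g", 1:5), paste0("p", 1:10)))
  expect_equal(mean(signature_score(big, rownames(big))), 0,
               tolerance = 1e-9)
})

test_that("a hand-computed 5x4 fixture matches exactly", {
  expr <- matrix(c(1, 2, 3, 4,
                   2, 2, 4, 4,
                   0, 1, 0, 1,
                   5, 5, 5, 7,
                   1, 3, 5, 7), 5, 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("p", 1:4)))
  z <- t(apply(expr, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  expect_equal(signature_score(expr, rownames(expr)), colMeans(z))
})

test_that("signature scoring validates genes and is affine-invariant per row", {
  expr <- matrix(c(1, 2, 3, 4, 2, 2, 2, 2), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "flat"), paste0("p", 1:4)))
  expect_warning(s <- signature_score(expr, c("g1", "flat")), "zero-variance")
  expect_equal(s, signature_score(expr["g1", , drop = FALSE], "g1"))
  expect_error(suppressMessages(signature_score(expr, "absent")),
               "no signature gene")
  # affine rescaling of a gene row leaves the scores unchanged
  set.seed(11)
  e <- matrix(stats::rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("p", 1:10)))
  e2 <- e; e2[2, ] <- 100 * e2[2, ] - 7
  expect_equal(signature_score(e, rownames(e)), signature_score(e2, rownames(e2)))
})

test_that("quartile stratification cuts at interpolated percentiles", {
  q <- stratify_quartiles(1:8)
  expect_equal(as.character(q[c(1, 2)]), c("Q1", "Q1"))
  expect_equal(as.character(q[c(7, 8)]), c("Q4", "Q4"))
  expect_equal(as.vector(table(q)), c(2, 2, 2, 2))
  expect_error(stratify_quartiles(rep(1, 10)), "degenerate")
  expect_error(stratify_quartiles(1:3), "at least 4")
  # distinct values at n = 100 split 25/25/25/25
  set.seed(13)
  for (s in 1:5) {
    expect_equal(as.vector(table(stratify_quartiles(stats::rnorm(100)))),
                 rep(25, 4))
  }
})

test_that("log-rank statistic matches the O/E/V sums and survdiff", {
  # identical survival experience -> statistic 0, p 1
  r0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # worked two-by-two case: O/E/V sums give 0.6154
  r <- logrank_test(c(1, 3, 2, 4), c(1, 1, 1, 1), c("g1", "g1", "g2", "g2"))
  expect_equal(r$statistic, 0.615, tolerance = 1e-3)
  # cross-check against the standard survival implementation
  sd <- survival::survdiff(survival::Surv(c(1, 3, 2, 4), rep(1, 4)) ~
                             rep(c("g1", "g2"), each = 2))
  expect_equal(r$statistic, sd$chisq, tolerance = 1e-12)
  # larger random cross-check
  set.seed(17)
  tm <- stats::rexp(60); ev <- stats::rbinom(60, 1, 0.8)
  gr <- rep(c("a", "b"), 30)
  expect_equal(logrank_test(tm, ev, gr)$statistic,
               survival::survdiff(survival::Surv(tm, ev) ~ gr)$chisq,
               tolerance = 1e-9)
  expect_warning(rn <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_equal(rn$p.value, 1)
})

test_that("log-rank is invariant to monotone time transforms and label swaps", {
  set.seed(19)
  tm <- stats::rexp(40); ev <- stats::rbinom(40, 1, 0.7)
  gr <- rep(c("a", "b"), 20)
  s1 <- logrank_test(tm, ev, gr)$statistic
  expect_equal(logrank_test(log1p(tm), ev, gr)$statistic, s1)
  expect_equal(logrank_test(tm, ev, ifelse(gr == "a", "b", "a"))$statistic, s1)
})

test_that("proportional-hazards fit validates input and recovers structure", {
  set.seed(23)
  coh <- generate_survival_cohort(300L, paste0("g", 1:5), beta = 0.8,
                                  censoring_rate = 0.2, seed = 5)
  fit <- cox_ph_fit(coh$survival$time, coh$survival$event,
                    data.frame(score = coh$latent))
  expect_gt(fit$hr[1], 1)
  expect_lt(fit$p[1], 1e-6)
  expect_true(fit$ci_lower[1] < fit$hr[1] && fit$hr[1] < fit$ci_upper[1])
  expect_error(cox_ph_fit(coh$survival$time, coh$survival$event,
                          data.frame(flat = rep(1, 300))), "zero-variance")
  expect_error(cox_ph_fit(c(1, 2), c(1, 0), data.frame(x = c(1, 2))),
               "two events")
  # multivariable design expands the stage factor
  multi <- cox_ph_fit(coh$survival$time, coh$survival$event,
                      data.frame(score = coh$latent,
                                 stage = factor(coh$survival$stage),
                                 age = coh$survival$age))
  expect_true(any(grepl("stage", multi$variable)))
})

test_that("null Cox confidence intervals cover HR = 1 near nominally", {
  cover <- vapply(1:60, function(s) {
    coh <- generate_survival_cohort(120L, "g1", beta = 0,
                                    censoring_rate = 0.2, seed = s)
    fit <- cox_ph_fit(coh$survival$time, coh$survival$event,
                      data.frame(score = coh$latent))
    fit$ci_lower[1] <= 1 && 1 <= fit$ci_upper[1]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("stage association reduces to the rank-sum test for two groups", {
  set.seed(29)
  sc <- stats::rnorm(40)
  st <- rep(c("I", "II"), 20)
  ka <- stage_association(sc, st)
  # Kruskal-Wallis with k = 2 is the (tie-corrected) rank-sum test
  kw <- stats::kruskal.test(sc, factor(st))
  expect_equal(ka$statistic, unname(kw$statistic))
  wt <- wilcoxon_rank_sum(sc[st == "I"], sc[st == "II"])
  expect_equal(stats::pchisq(ka$statistic, 1, lower.tail = FALSE), wt$p.value,
               tolerance = 0.02)
  expect_error(stage_association(sc, rep("I", 40)), "two stage")
  # planted stage shift is detected
  sc2 <- sc + (st == "II") * 1.5
  expect_lt(stage_association(sc2, st)$p.value, 0.001)
})
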