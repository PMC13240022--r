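test_that("rank-sum test matches its analytic anchor cases", {
  # identical multisets: symmetric null, two-sided p = 1
  x <- c(1, 5, 9)
  expect_equal(wilcoxon_rank_sum(x, x)$p.value, 1.0)
  # complete separation at n1 = n2 = 3: U = 9, exact two-sided p = 2/20
  r <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$statistic, 9)
  expect_equal(r$p.value, 0.1)
  # swapping the groups flips the one-sided tails
  a <- stats::runif(8); b <- stats::runif(6) + 0.3
  expect_equal(wilcoxon_rank_sum(a, b, "greater")$p.value,
               wilcoxon_rank_sum(b, a, "less")$p.value)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum matches exhaustive enumeration for all small no-tie cases", {
  set.seed(71)
  for (n1 in 1:5) for (n2 in 1:5) {
    if (n1 + n2 > 10) next
    for (rep in 1:3) {
      x <- sample(stats::rnorm(50), n1)
      y <- sample(stats::rnorm(50), n2)
      for (alt in c("two.sided", "greater", "less")) {
        got <- wilcoxon_rank_sum(x, y, alt)$p.value
        expect_equal(got, oracle_ranksum(x, y, alt),
                     info = sprintf("n1=%d n2=%d alt=%s", n1, n2, alt))
      }
    }
  }
})

test_that("state-mean z-scores follow their closed forms", {
  # three states with means (1, 0, 0): population-SD z
  act <- matrix(c(rep(1, 4), rep(0, 8)), ncol = 1,
                dimnames = list(NULL, "R"))
  lab <- rep(c("s1", "s2", "s3"), each = 4)
  sm <- state_mean_zscore(act, lab, z_mode = "states")
  expect_equal(unname(sm$z[1, ]), c(1.41421, -0.70711, -0.70711),
               tolerance = 1e-5)
  # the "states" z rows have mean 0 and population SD 1, max |z| = sqrt(2)
  expect_equal(mean(sm$z[1, ]), 0)
  expect_equal(sqrt(mean((sm$z[1, ])^2)), 1)
  expect_lte(max(abs(sm$z[1, ])), sqrt(2) + 1e-12)
  # constant regulon -> all-zero z in both modes
  cst <- matrix(1, 12, 1, dimnames = list(NULL, "R"))
  expect_equal(unname(state_mean_zscore(cst, lab, "states")$z[1, ]),
               rep(0, 3))
  expect_equal(unname(state_mean_zscore(cst, lab, "cellwise")$z[1, ]),
               rep(0, 3))
  expect_error(state_mean_zscore(act, rep("s1", 12)), "two states")
})

test_that("cellwise z of a Bernoulli column equals sqrt((1-p)/p) in its state", {
  # active (1) exactly in a state holding 20% of cells
  act <- matrix(c(rep(1, 20), rep(0, 80)), ncol = 1,
                dimnames = list(NULL, "R"))
  lab <- c(rep("home", 20), rep(c("a", "b"), 40))
  sm <- state_mean_zscore(act, lab, z_mode = "cellwise")
  expect_equal(sm$z["R", "home"], 2.0)
})

test_that("cellwise state-mean z is bounded by sqrt((1-p)/p)", {
  # Cauchy-Schwarz: mean_S z = cov(z, 1_S)/p <= sd(1_S)/p; checked over
  # random activity profiles
  set.seed(55)
  lab <- sample(c("s1", "s2", "s3"), 200, replace = TRUE, prob = c(.4, .35, .25))
  act <- matrix(stats::runif(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("R", 1:10)))
  sm <- state_mean_zscore(act, lab, "cellwise")
  for (s in colnames(sm$z)) {
    p <- mean(lab == s)
    expect_true(all(sm$z[, s] <= sqrt((1 - p) / p) + 1e-9))
  }
})

test_that("state-regulon selection honours thresholds, warnings and uniqueness", {
  d <- small_design(seed = 19L)
  sc <- generate_single_cell_dataset(d)
  r <- rank_genes_per_cell(sc$expression, seed = 1)
  act <- score_gene_sets(r, sc$regulons)
  # the row-normalized "states" mode provably selects nothing at 1.5
  expect_warning(
    calls_states <- identify_state_regulons(act, sc$cells$state,
                                            z_threshold = 1.5,
                                            z_mode = "states"),
    "unattainable")
  expect_false(any(calls_states$selected))
  # alpha = 0 -> empty selection
  calls0 <- identify_state_regulons(act, sc$cells$state, alpha = 0)
  expect_false(any(calls0$selected))
  # cellwise defaults: whatever is selected is planted, one state per regulon
  calls <- identify_state_regulons(act, sc$cells$state)
  sel <- calls[calls$selected, ]
  expect_true(all(table(sel$regulon) == 1))
  expect_true(all(sel$z > 1.5 & sel$p < 0.05))
  planted_pairs <- unlist(lapply(names(sc$truth$state_specific_regulons),
    function(s) paste(sc$truth$state_specific_regulons[[s]], s)))
  expect_true(all(paste(sel$regulon, sel$state) %in% planted_pairs))
})

test_that("selection is monotone in its thresholds", {
  d <- small_design(seed = 29L)
  sc <- generate_single_cell_dataset(d)
  r <- rank_genes_per_cell(sc$expression, seed = 1)
  act <- score_gene_sets(r, sc$regulons)
  strict <- identify_state_regulons(act, sc$cells$state,
                                    z_threshold = 1.6, alpha = 0.01)
  loose <- identify_state_regulons(act, sc$cells$state,
                                   z_threshold = 1.2, alpha = 0.05)
  key <- function(df) paste(df$regulon, df$state)[df$selected]
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("program comparisons find planted shifts and behave under the null", {
  set.seed(61)
  lab <- rep(c("fate0", "fate1", "fate2"), c(400, 350, 250))
  # planted: program shifted up 1 SD in fate0
  prog <- matrix(stats::rnorm(1000), ncol = 1, dimnames = list(NULL, "AH"))
  prog[lab == "fate0", 1] <- prog[lab == "fate0", 1] + 1
  tab <- compare_program_activity(prog, lab)
  expect_true(all(tab$p[tab$state1 == "fate0" | tab$state2 == "fate0"] < 0.001))
  # a single shared value gives p = 1 everywhere
  flat <- matrix(1, 60, 1, dimnames = list(NULL, "P"))
  tabf <- compare_program_activity(flat, rep(c("a", "b", "c"), each = 20))
  expect_true(all(tabf$p == 1))
  # a state with < 2 cells is skipped with a warning
  expect_warning(
    compare_program_activity(prog[1:401, , drop = FALSE],
                             c(rep("a", 400), "b")), "skipped")
})

test_that("null program comparisons reject at the nominal rate", {
  set.seed(67)
  rej <- mean(replicate(400, {
    x <- stats::rnorm(60)
    wilcoxon_rank_sum(x[1:30], x[31:60])$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("expression summaries match a direct group-by on a hand fixture", {
  expr <- matrix(c(1, 0, 2, 0, 3, 0, 0, 0, 0, 1,   # gene A
                   0, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # gene B
                 nrow = 10,
                 dimnames = list(paste0("c", 1:10), c("A", "B")))
  lab <- rep(c("s1", "s2"), each = 5)
  out <- state_expression_summary(expr, c("A", "B"), lab)
  get <- function(g, s, col) out[out$gene == g & out$state == s, col]
  expect_equal(get("A", "s1", "mean_expression"), mean(c(1, 0, 2, 0, 3)))
  expect_equal(get("A", "s1", "prevalence"), 3 / 5)
  expect_equal(get("A", "s2", "prevalence"), 1 / 5)
  expect_equal(get("B", "s1", "mean_expression"), 0)
  expect_equal(get("B", "s2", "prevalence"), 0)
  # gene expressed in every cell of exactly one state
  expr2 <- cbind(expr, C = c(rep(0, 5), rep(1, 5)))
  out2 <- state_expression_summary(expr2, "C", lab)
  expect_equal(out2$prevalence[order(out2$state)], c(0, 1))
  expect_warning(state_expression_summary(expr, c("A", "nope"), lab),
                 "unknown gene")
})
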