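#' Per-patient signature score
#'
#' Each signature gene's expression row is z-scored across patients
#' (population SD) and the per-patient score is the mean over the genes
#' present; the scores therefore average to zero across the cohort. Genes
#' absent from the matrix are dropped with a message; zero-variance genes
#' are excluded with a warning.
#'
#' @param expr genes x patients bulk expression matrix.
#' @param genes signature gene list.
#' @return named numeric vector, one score per patient.
#' @export
signature_score <- function(expr, genes) {
  if (ncol(expr) < 2L)
    stop("validation error: need at least two patients", call. = FALSE)
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes))
    message(sprintf("signature genes absent from matrix: %s",
                    paste(setdiff(genes, present), collapse = ", ")))
  if (length(present) == 0L)
    stop("validation error: no signature gene present in the matrix",
         call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  v <- apply(sub, 1, function(r) mean((r - mean(r))^2))
  if (any(v == 0)) {
    warning(sprintf("zero-variance gene(s) excluded: %s",
                    paste(present[v == 0], collapse = ", ")))
    sub <- sub[v > 0, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("validation error: no non-degenerate signature gene",
           call. = FALSE)
  }
  z <- t(apply(sub, 1, zscore_pop))
  colMeans(z)
}

#' Quartile stratification of signature scores
#'
#' Cuts at the empirical 25/50/75 percentiles (linear-interpolation
#' convention); values equal to a cut point fall in the lower quartile.
#'
#' @param scores numeric vector (n >= 4, not all equal).
#' @return factor with levels Q1..Q4.
#' @export
stratify_quartiles <- function(scores) {
  if (length(scores) < 4L)
    stop("validation error: need at least 4 scores", call. = FALSE)
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (length(unique(qs)) < 3L || diff(range(scores)) == 0)
    stop("validation error: degenerate quartiles", call. = FALSE)
  cut(scores, breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4),
      right = TRUE)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed-minus-expected event count in
#' group 1 is accumulated together with its hypergeometric variance; the
#' statistic (sum O - sum E)^2 / sum V is referred to a chi-square with one
#' degree of freedom. Risk sets of size 1 contribute zero variance.
#'
#' @param times event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level group labels.
#' @return list with `statistic`, `p.value`, and the `observed`/`expected`
#'   event counts per group.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("validation error: exactly two groups required", call. = FALSE)
  if (any(table(groups) == 0))
    stop("validation error: both groups must be non-empty", call. = FALSE)
  if (sum(events) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, p.value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  g1 <- groups == lev[1]
  o_sum <- e_sum <- v_sum <- 0
  obs <- c(0, 0)
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    o_sum <- o_sum + d1
    e_sum <- e_sum + d * n1 / n
    if (n > 1)
      v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    obs <- obs + c(d1, d - d1)
  }
  stat <- if (v_sum > 0) (o_sum - e_sum)^2 / v_sum else 0
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = obs,
       expected = c(e_sum, sum(obs) - e_sum))
}

#' Cox proportional-hazards fit for the signature model
#'
#' Partial-likelihood fit (Efron tie handling) of survival on the covariates
#' given; typically the z-scaled signature score alone (univariable) or with
#' a stage factor and age (the multivariable design). Returns hazard ratios,
#' Wald 95% confidence intervals, and p-values per coefficient.
#'
#' @param times,events survival outcome.
#' @param covariates data.frame of covariates; factors expand to dummies.
#' @return data.frame (variable, coef, hr, ci_lower, ci_upper, p).
#' @export
cox_ph_fit <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (sum(events) < 2L)
    stop("validation error: need at least two events", call. = FALSE)
  num <- vapply(covariates, is.numeric, logical(1))
  for (v in names(covariates)[num]) {
    x <- covariates[[v]]
    if (!all(is.finite(x)))
      stop(sprintf("validation error: non-finite covariate '%s'", v),
           call. = FALSE)
    if (stats::var(x) == 0)
      stop(sprintf("validation error: zero-variance covariate '%s'", v),
           call. = FALSE)
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  data.frame(
    variable = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Signature-by-stage association (Kruskal-Wallis)
#'
#' Rank-based k-group test of signature scores across pathological stages.
#'
#' @param scores per-patient signature scores.
#' @param stages per-patient stage labels (>= 2 observed stages).
#' @return list with `statistic`, `p.value`, `df`.
#' @export
stage_association <- function(scores, stages) {
  stages <- factor(stages)
  if (nlevels(droplevels(stages)) < 2L)
    stop("validation error: need at least two stage groups", call. = FALSE)
  kt <- stats::kruskal.test(scores, droplevels(stages))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}
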