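#' Tie-corrected Mann-Whitney test (normal approximation)
#'
#' Rank-sum test using midranks, with the tie-corrected variance
#' `Var(U) = (n1*n2/12) * ((N+1) - sum(t^3 - t) / (N*(N-1)))`
#' and a two-sided p-value from the normal approximation WITHOUT
#' continuity correction. This variant is exact enough to reproduce
#' published p-values computed on heavily tied (e.g. binary count) data,
#' which a continuity-corrected or exact-permutation variant does not.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return An `AssociationReport` list: `test`, `statistic` (U for group
#'   a), `p`, `n` (group sizes). `U_a + U_b = n1*n2` is asserted. When all
#'   values are tied the variance is zero and `p = 1` with a warning.
#' @export
mann_whitney_tiecorrected <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  x <- c(group_a, group_b)
  if (any(!is.finite(x))) stop("values must be finite")
  n1 <- length(group_a); n2 <- length(group_b); N <- n1 + n2
  r <- rank(x)
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_b <- sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2
  stopifnot(abs(U_a + U_b - n1 * n2) < 1e-9)
  tt <- table(x)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    warning("all values tied: zero variance, p = 1", call. = FALSE)
    p <- 1
  } else {
    z <- (U_a - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  association_report("Mann-Whitney (tie-corrected, no continuity correction)",
                     statistic = U_a, p = p, n = c(n1, n2))
}

association_report <- function(test, statistic, p, n, df = NA_real_,
                               extra = NULL) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p = unname(p), n = unname(n)), extra),
            class = "AssociationReport")
}

#' @export
print.AssociationReport <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

# probability of a 2xK table with fixed margins (multivariate hypergeometric
# factorization over columns), on the log scale
log_p_table_2xk <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  sum(lchoose(cs, tab[1L, ])) - lchoose(N, rs[1L])
}

enumerate_2xk_count <- function(cs, r1) {
  # number of first-row vectors with sum r1 and 0 <= a_j <= cs_j
  prod(pmin(cs, r1) + 1)  # cheap upper bound used for the switch only
}

#' Fisher's exact test for 2x2 and 2xK tables
#'
#' For 2x2 tables the exact two-sided p is the hypergeometric sum of all
#' tables (fixed margins) whose probability does not exceed the observed
#' table's. For 2xK tables the same probability-ordering p is computed by
#' full enumeration when the enumeration cost is below `max_enumeration`,
#' and otherwise by seeded Monte-Carlo sampling of tables with fixed
#' margins.
#'
#' @param tab A 2-row matrix of non-negative integer counts.
#' @param mc_iterations Monte-Carlo sample size for large 2xK tables
#'   (default 1e5).
#' @param seed Seed for the Monte-Carlo branch.
#' @param max_enumeration Enumeration cost cutoff (default 1e6).
#' @return An `AssociationReport` with `p` and, for the Monte-Carlo
#'   branch, `mc_se` (binomial standard error).
#' @export
fisher_exact <- function(tab, mc_iterations = 1e5L, seed = 1L,
                         max_enumeration = 1e6) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("table must have 2 rows")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin")
  }
  K <- ncol(tab)
  lp_obs <- log_p_table_2xk(tab)
  eps <- 1e-7
  mc_se <- NA_real_
  if (K == 2L) {
    m <- colSums(tab)[1L]; nn <- colSums(tab)[2L]; k <- rowSums(tab)[1L]
    a <- max(0, k - nn):min(m, k)
    lp <- stats::dhyper(a, m, nn, k, log = TRUE)
    p <- sum(exp(lp[lp <= lp_obs + eps]))
    method <- "Fisher exact (2x2)"
  } else {
    cs <- colSums(tab); r1 <- rowSums(tab)[1L]
    if (enumerate_2xk_count(cs, r1) <= max_enumeration) {
      p <- enumerate_fisher_2xk(cs, r1, lp_obs + eps)
      method <- sprintf("Fisher exact (2x%d, enumeration)", K)
    } else {
      set.seed(seed)
      sims <- stats::r2dtable(mc_iterations, rowSums(tab), cs)
      lps <- vapply(sims, log_p_table_2xk, numeric(1L))
      hits <- sum(lps <= lp_obs + eps)
      # include the observed table (standard MC correction)
      p <- (hits + 1) / (mc_iterations + 1)
      mc_se <- sqrt(p * (1 - p) / mc_iterations)
      method <- sprintf("Fisher exact (2x%d, Monte-Carlo)", K)
    }
  }
  association_report(method, statistic = lp_obs, p = min(p, 1),
                     n = colSums(tab),
                     extra = list(mc_se = mc_se))
}

# exact probability-ordering p for a 2xK table by recursive enumeration of
# first-row vectors with fixed column sums cs and first-row sum r1
enumerate_fisher_2xk <- function(cs, r1, lp_cut) {
  K <- length(cs)
  N <- sum(cs)
  lden <- lchoose(N, r1)
  total <- 0
  recurse <- function(j, rem, lp_acc) {
    if (j == K) {
      if (rem <= cs[K]) {
        lp <- lp_acc + lchoose(cs[K], rem) - lden
        if (lp <= lp_cut) total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (a in 0:min(cs[j], rem)) {
      recurse(j + 1L, rem - a, lp_acc + lchoose(cs[j], a))
    }
  }
  recurse(1L, r1, 0)
  total
}

#' Proportional-odds association of an ordinal outcome with a binary class
#'
#' Fits an ordinal logistic (proportional-odds) regression of the outcome
#' on the class by maximum likelihood and reports the 1-df
#' likelihood-ratio test against the intercepts-only model. Convergence
#' problems (e.g. complete separation) are flagged: the LRT p is still
#' reported, together with `converged = FALSE` and a warning.
#'
#' @param outcome Ordinal outcome (integer codes or ordered factor) with
#'   at least 2 observed levels.
#' @param class Binary class (factor or 2-level vector); both levels must
#'   be present.
#' @return An `AssociationReport` with `statistic` (LRT chi-square), `df`,
#'   `p`, `log_odds` (the class coefficient) and `loglik` (maximized
#'   log-likelihood of the class model).
#' @export
proportional_odds_assoc <- function(outcome, class) {
  keep <- !is.na(outcome) & !is.na(class)
  outcome <- outcome[keep]; class <- class[keep]
  y <- factor(outcome, ordered = TRUE)
  g <- factor(class)
  if (nlevels(y) < 2L) stop("outcome needs >= 2 observed levels")
  if (nlevels(g) != 2L) stop("class must have exactly 2 observed levels")
  converged <- TRUE
  fit1 <- withCallingHandlers(
    suppressWarnings(MASS::polr(y ~ g, Hess = FALSE)),
    error = function(e) stop("proportional-odds fit failed: ",
                             conditionMessage(e)))
  fit0 <- suppressWarnings(MASS::polr(y ~ 1, Hess = FALSE))
  beta <- unname(stats::coef(fit1)[[1L]])
  if (abs(beta) > 15) {
    converged <- FALSE
    warning("possible complete separation in proportional-odds fit",
            call. = FALSE)
  }
  lrt <- fit0$deviance - fit1$deviance
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  association_report("proportional-odds LRT", statistic = lrt, p = p,
                     n = as.integer(table(g)), df = 1,
                     extra = list(log_odds = beta, converged = converged,
                                  loglik = -fit1$deviance / 2))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return An `AssociationReport` with `statistic` (t), `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 values")
  }
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  n1 <- length(group_a); n2 <- length(group_b)
  if (v1 == 0 && v2 == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(association_report("Welch t", statistic = 0, p = 1,
                                n = c(n1, n2), df = n1 + n2 - 2))
    }
    stop("zero variance in both groups with unequal means")
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  association_report("Welch t", statistic = t, p = p, n = c(n1, n2),
                     df = df)
}

#' Two-group log-rank test
#'
#' Chi-square statistic from the observed-minus-expected event counts with
#' hypergeometric variance at each distinct event time, 1 df.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Two-level group labels.
#' @return An `AssociationReport` with `statistic` (chi-square), `df = 1`,
#'   `p`. With no events at all, `p = 1` with a warning.
#' @export
logrank_test <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- factor(group[keep])
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("events must be 0/1")
  if (sum(event) == 0) {
    warning("no events: log-rank undefined, p = 1", call. = FALSE)
    return(association_report("log-rank", statistic = 0, p = 1,
                              n = as.integer(table(group)), df = 1))
  }
  g1 <- levels(group)[[1L]]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == g1)
    d_t <- sum(time == tt & event == 1)
    d1_t <- sum(time == tt & event == 1 & group == g1)
    O <- O + d1_t
    E <- E + d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) *
        (n_t - d_t) / (n_t - 1)
    }
  }
  if (V <= 0) {
    warning("zero log-rank variance, p = 1", call. = FALSE)
    return(association_report("log-rank", statistic = 0, p = 1,
                              n = as.integer(table(group)), df = 1))
  }
  chi <- (O - E)^2 / V
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  association_report("log-rank", statistic = chi, p = p,
                     n = as.integer(table(group)), df = 1,
                     extra = list(observed = O, expected = E, variance = V))
}

#' Cox proportional-hazards regression
#'
#' Multivariate Cox model (partial likelihood, Efron tie handling,
#' Newton-Raphson to 1e-9) reporting a hazard ratio and Wald p per
#' covariate. Monotone-likelihood situations (e.g. a class with no
#' events) are flagged with a warning and `converged = FALSE`.
#'
#' @param time,event Follow-up times (> 0) and 0/1 indicators.
#' @param covariates Data.frame of covariates (the class indicator plus
#'   any adjusters: grade, stage, serous flag, age, residual disease).
#' @return List of class `CoxReport`: data.frame `table` with per-covariate
#'   `coef`, `hr`, `se`, `z`, `p`; plus `loglik`, `score_test` (the global
#'   score chi-square at beta = 0) and `converged`.
#' @export
cox_ph <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- stats::complete.cases(covariates) & !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]
  covariates <- covariates[keep, , drop = FALSE]
  if (sum(event) < 1) stop("at least one event required")
  if (any(time <= 0)) stop("times must be positive")
  X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  fit <- survival::coxph(
    survival::Surv(time, event) ~ X, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  converged <- TRUE
  s <- summary(fit)
  if (any(abs(stats::coef(fit)) > 15)) {
    converged <- FALSE
    warning("monotone partial likelihood suspected (|coef| > 15)",
            call. = FALSE)
  }
  tab <- data.frame(
    covariate = sub("^X", "", rownames(s$coefficients)),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[[2L]],
                 score_test = unname(fit$score), n = length(time),
                 n_events = sum(event), converged = converged),
            class = "CoxReport")
}

#' @export
print.CoxReport <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties), n = %d, events = %d\n",
              x$n, x$n_events))
  print(x$table, digits = 4)
  invisible(x)
}

#' Permuted-signature null control
#'
#' Repeats the score-classify-associate chain with random +1/-1
#' signatures drawn from the annotated probeset universe, and reports how
#' often each clinical association reaches `p < alpha`. A real
#' cell-of-origin signature should look nothing like this ensemble; when
#' clinical covariates are independent of expression the per-test
#' fractions calibrate to `alpha`.
#'
#' @param x Normalized `ExpressionMatrix`.
#' @param clinical Clinical data.frame (needs `sample_id` and whichever of
#'   `subtype`, `grade`, `stage` are to be tested).
#' @param k_per_direction Signature size per direction (default 5).
#' @param n_permutations Number of random signatures (default 1000).
#' @param alpha Significance level for the summary fraction (default 0.05).
#' @param seed Base seed; permutation `i` uses `seed + i`.
#' @param tests Which associations to run (default subtype, grade, stage).
#' @param variance_mode,n_restarts Passed to the mixture fit.
#' @param mc_iterations Monte-Carlo size for the Fisher subtype test inside
#'   the ensemble (default 1e4; p resolution 1e-4 is ample for an alpha of
#'   0.05 summarized over permutations).
#' @return A `PermutationNullResult` list: data.frame `p_values` (one row
#'   per successful permutation), `fraction_significant` (named, per
#'   test), `n_permutations`, `n_failed`, `alpha`.
#' @export
permutation_signature_null <- function(x, clinical, k_per_direction = 5L,
                                       n_permutations = 1000L, alpha = 0.05,
                                       seed = 1L,
                                       tests = c("subtype", "grade",
                                                 "stage"),
                                       variance_mode = "shared",
                                       n_restarts = 5L,
                                       mc_iterations = 1e4L) {
  stopifnot_normalized(x, "permutation_signature_null")
  tests <- match.arg(tests, several.ok = TRUE)
  tests <- intersect(tests, names(clinical))
  if (length(tests) == 0L) stop("no requested clinical column present")
  al <- align_samples(x, clinical)
  universe <- data.frame(probeset_id = rownames(x$values),
                         symbol = unname(x$annotation),
                         stringsAsFactors = FALSE)
  n_failed <- 0L
  rows <- vector("list", n_permutations)
  if (n_permutations > 0L) for (i in seq_len(n_permutations)) {
    res <- tryCatch({
      sig <- random_signature(universe, k_per_direction, seed = seed + i)
      sc <- score_samples(al$matrix, sig)
      model <- fit_two_component_mixture(
        sc$score, variance_mode = variance_mode, seed = seed + i,
        n_restarts = n_restarts)
      labels <- model$labels
      if (nlevels(droplevels(labels)) < 2L) stop("single-class labeling")
      ps <- vapply(tests, function(tn) {
        if (tn == "subtype") {
          tab <- table(al$clinical[[tn]], labels)
          fisher_exact(t(tab), mc_iterations = mc_iterations,
                       seed = seed + i)$p
        } else {
          proportional_odds_assoc(al$clinical[[tn]], labels)$p
        }
      }, numeric(1L))
      as.list(ps)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  p_values <- if (length(rows)) {
    do.call(rbind, lapply(rows, as.data.frame))
  } else {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(tests)),
                                  tests))
  }
  frac <- vapply(tests, function(tn) {
    if (nrow(p_values) == 0L) NA_real_ else
      mean(p_values[[tn]] < alpha)
  }, numeric(1L))
  structure(list(p_values = p_values, fraction_significant = frac,
                 n_permutations = as.integer(n_permutations),
                 n_failed = n_failed, alpha = alpha),
            class = "PermutationNullResult")
}

#' @export
print.PermutationNullResult <- function(x, ...) {
  cat(sprintf("Permuted-signature null: %d permutations (%d failed)\n",
              x$n_permutations, x$n_failed))
  for (tn in names(x$fraction_significant)) {
    cat(sprintf("  %s: fraction p < %g = %.3f\n", tn, x$alpha,
                x$fraction_significant[[tn]]))
  }
  invisible(x)
}

#' Kaplan-Meier curve coordinates
#'
#' Product-limit survival estimates per group, exported as a plain table
#' (time, survival, at-risk) for plotting.
#'
#' @inheritParams logrank_test
#' @return Data.frame with `group`, `time`, `survival`, `n_risk`,
#'   `n_event`.
#' @export
km_curves <- function(time, event, group) {
  group <- factor(group)
  out <- lapply(levels(group), function(g) {
    tt <- time[group == g]; ee <- event[group == g]
    ts <- sort(unique(tt[ee == 1]))
    surv <- 1
    rows <- lapply(ts, function(t0) {
      n_risk <- sum(tt >= t0)
      n_event <- sum(tt == t0 & ee == 1)
      surv <<- surv * (1 - n_event / n_risk)
      data.frame(group = g, time = t0, survival = surv,
                 n_risk = n_risk, n_event = n_event,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(list(data.frame(group = g, time = 0, survival = 1,
                                     n_risk = length(tt), n_event = 0L,
                                     stringsAsFactors = FALSE)), rows))
  })
  do.call(rbind, out)
}
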