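#' Configuration for the paired cell-line simulator
#'
#' Describes the paired two-cell-type design the differential-expression
#' stage assumes: each patient contributes one fallopian-tube non-ciliated
#' epithelial (FNE) and one ovarian surface epithelial (OCE) line, arrays
#' within a patient share an intra-patient correlation, and a planted set of
#' probesets differs between the cell types. Gene-level residual variances
#' are drawn from a scaled inverse-chi-square prior so the empirical-Bayes
#' moderation model holds exactly, which makes prior recovery a valid test.
#'
#' @param n_probesets Number of probesets (default 54675, the size of the
#'   HG-U133 Plus 2.0 array family the design uses).
#' @param n_patients Number of patient blocks (default 2).
#' @param replicates Arrays per patient-by-cell-type cell (default 1).
#' @param rho Intra-patient correlation of residuals, in (-1, 1)
#'   (default 0.5, a typical consensus correlation for shared-donor lines).
#' @param n_de_per_direction Number of planted FNE-up probesets and,
#'   equally, OCE-up probesets (default 600, matching the order of magnitude
#'   of the significant probeset lists the design was built to detect).
#' @param delta Planted log2 effect size (default 2, a strong cell-type
#'   difference).
#' @param d0_true,s0sq_true Degrees of freedom and scale of the scaled
#'   inverse-chi-square variance prior (defaults 4 and 0.05).
#' @param baseline_mean,baseline_sd Mean and SD of per-probeset baseline
#'   log2 intensity (defaults 8 and 1.5).
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A `CellLineSimConfig` list.
#' @export
cell_line_sim_config <- function(n_probesets = 54675L, n_patients = 2L,
                                 replicates = 1L, rho = 0.5,
                                 n_de_per_direction = 600L, delta = 2,
                                 d0_true = 4, s0sq_true = 0.05,
                                 baseline_mean = 8, baseline_sd = 1.5,
                                 seed = 1L) {
  if (n_probesets < 1L || n_patients < 1L || replicates < 1L) {
    stop("dimensions must be positive")
  }
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (n_de_per_direction < 0L) stop("n_de_per_direction must be >= 0")
  if (2L * n_de_per_direction > n_probesets) {
    stop("2 * n_de_per_direction must not exceed n_probesets")
  }
  if (d0_true <= 0 || s0sq_true <= 0) stop("variance prior must be positive")
  structure(list(n_probesets = as.integer(n_probesets),
                 n_patients = as.integer(n_patients),
                 replicates = as.integer(replicates),
                 rho = rho, n_de_per_direction = as.integer(n_de_per_direction),
                 delta = delta, d0_true = d0_true, s0sq_true = s0sq_true,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "CellLineSimConfig")
}

#' Simulate a paired FNE/OCE cell-line expression matrix
#'
#' Generates a normalized (log2-scale) probeset-by-array matrix with the
#' block structure of a paired design: per probeset, a true residual
#' variance `sigma^2_g ~ d0 * s0^2 / chisq(d0)`, arrays within a patient
#' correlated at `rho` through an equicorrelated block covariance, and the
#' first `2 * n_de_per_direction` probesets shifted by `+delta` (FNE-up)
#' or `-delta` (OCE-up) between cell types.
#'
#' @param config A [cell_line_sim_config()].
#' @return List with `matrix` (an `ExpressionMatrix`, normalized scale,
#'   symbols `SYM<g>`), `design` (data.frame `sample_id`, `patient_block`,
#'   `cell_type`) and `truth` (data.frame of planted probesets with their
#'   direction, empty when `delta == 0` or no probesets are planted).
#' @export
simulate_paired_cell_lines <- function(config) {
  stopifnot(inherits(config, "CellLineSimConfig"))
  set.seed(config$seed)
  G <- config$n_probesets
  P <- config$n_patients
  R <- config$replicates
  m <- 2L * R           # arrays per patient block
  n <- P * m

  design <- data.frame(
    sample_id = character(n), patient_block = character(n),
    cell_type = character(n), stringsAsFactors = FALSE)
  k <- 0L
  for (p in seq_len(P)) for (ct in c("FNE", "OCE")) for (r in seq_len(R)) {
    k <- k + 1L
    design$sample_id[k] <- sprintf("P%d_%s%s", p, ct,
                                   if (R > 1L) sprintf("_r%d", r) else "")
    design$patient_block[k] <- sprintf("P%d", p)
    design$cell_type[k] <- ct
  }

  sigma2 <- config$d0_true * config$s0sq_true /
    stats::rchisq(G, df = config$d0_true)
  mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)

  # equicorrelated residuals within each patient block
  rho <- config$rho
  if (rho <= -1 / (m - 1)) {
    stop("rho = ", rho, " is not a valid equicorrelation for blocks of size ",
         m)
  }
  Sigma_blk <- matrix(rho, m, m); diag(Sigma_blk) <- 1
  L <- chol(Sigma_blk)
  resid <- matrix(0, G, n)
  for (p in seq_len(P)) {
    idx <- which(design$patient_block == sprintf("P%d", p))
    z <- matrix(stats::rnorm(G * m), G, m)
    resid[, idx] <- z %*% L
  }
  resid <- resid * sqrt(sigma2)

  values <- matrix(mu, G, n) + resid
  nde <- config$n_de_per_direction
  fne_idx <- if (nde > 0L) seq_len(nde) else integer(0)
  oce_idx <- if (nde > 0L) nde + seq_len(nde) else integer(0)
  is_fne <- design$cell_type == "FNE"
  half <- config$delta / 2
  values[fne_idx, is_fne] <- values[fne_idx, is_fne] + half
  values[fne_idx, !is_fne] <- values[fne_idx, !is_fne] - half
  values[oce_idx, is_fne] <- values[oce_idx, is_fne] - half
  values[oce_idx, !is_fne] <- values[oce_idx, !is_fne] + half

  probes <- sprintf("PS%06d_at", seq_len(G))
  rownames(values) <- probes
  colnames(values) <- design$sample_id
  ann <- sprintf("SYM%06d", seq_len(G))
  names(ann) <- probes

  truth <- data.frame(probeset_id = probes[c(fne_idx, oce_idx)],
                      direction = rep(c("FNE-up", "OCE-up"),
                                      c(length(fne_idx), length(oce_idx))),
                      stringsAsFactors = FALSE)
  if (config$delta == 0) truth <- truth[0, ]

  list(matrix = expression_matrix(values, scale = "normalized",
                                  annotation = ann),
       design = design, truth = truth)
}

#' Configuration for the tumor cohort simulator
#'
#' Describes a cohort whose signature scores follow a two-component
#' Gaussian mixture (a latent FT-like/OV-like class), with class-linked
#' ordinal clinical covariates drawn from proportional-odds models,
#' class-linked histologic subtype, and class-linked exponential survival
#' under proportional hazards with independent censoring.
#'
#' With `k` signature probesets each shifted by `w_i * delta / 2` per
#' class and per-probeset noise SD `sigma`, the score separation is
#' `sqrt(k) * delta / sigma` score-scale standard deviations.
#'
#' @param n_tumors Cohort size (default 100, the scale of the smaller
#'   validation cohort).
#' @param pi_true Mixing proportion of the FT-like class (default 0.6:
#'   serous tumors dominate typical ovarian cancer cohorts and
#'   overwhelmingly score FT-like).
#' @param delta Per-signature-probeset class mean shift in log2 units
#'   (default 1).
#' @param sigma Per-probeset noise SD (default 0.5; with the 10-probeset
#'   default signature this gives a clearly bimodal ~6.3 SD separation).
#' @param hazard_ratio Hazard ratio of FT-like versus OV-like (default 2,
#'   FT-like tumors faring worse).
#' @param censoring_rate Target fraction censored, in [0, 1) (default 0.3).
#' @param clinical_odds Named positive vector of odds ratios linking the
#'   FT-like class to higher grade, higher stage and serous subtype
#'   (defaults `c(grade = 4, stage = 4, subtype = 8)`).
#' @param n_probesets Total probesets in the simulated matrix
#'   (default 2000; non-signature rows are class-independent noise).
#' @param baseline_hazard Event rate per month for the OV-like class
#'   (default `log(2) / 36`, i.e. a 36-month median).
#' @param seed Integer seed.
#' @return A `CohortSimConfig` list.
#' @export
cohort_sim_config <- function(n_tumors = 100L, pi_true = 0.6, delta = 1,
                              sigma = 0.5, hazard_ratio = 2,
                              censoring_rate = 0.3,
                              clinical_odds = c(grade = 4, stage = 4,
                                                subtype = 8),
                              n_probesets = 2000L,
                              baseline_hazard = log(2) / 36, seed = 1L) {
  if (n_tumors < 1L) stop("n_tumors must be positive")
  if (pi_true <= 0 || pi_true >= 1) stop("pi_true must be in (0,1)")
  if (sigma <= 0) stop("sigma must be positive")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0,1)")
  }
  if (any(clinical_odds <= 0)) stop("clinical_odds must be positive")
  structure(list(n_tumors = as.integer(n_tumors), pi_true = pi_true,
                 delta = delta, sigma = sigma, hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate,
                 clinical_odds = clinical_odds,
                 n_probesets = as.integer(n_probesets),
                 baseline_hazard = baseline_hazard, seed = as.integer(seed)),
            class = "CohortSimConfig")
}

# proportional-odds draw of an ordinal outcome given a linear predictor:
# cumulative logits alpha_j - eta, highest level most likely when eta large
r_prop_odds <- function(eta, cutpoints) {
  cum <- stats::plogis(outer(cutpoints, eta, "-"))     # P(Y <= j | eta)
  u <- stats::runif(length(eta))
  1L + colSums(cum < rep(u, each = length(cutpoints)))
}

#' Simulate a tumor cohort with a latent FT-like/OV-like class
#'
#' Signature probesets are shifted by `w_i * delta / 2` towards the
#' FT-like pole for FT-like tumors and away from it for OV-like tumors, so
#' the +1/-1-weighted score is an exact two-Gaussian mixture; all other
#' probesets are class-independent noise. Grade (3 levels) and stage
#' (4 levels) are proportional-odds draws with class log-odds
#' `log(clinical_odds)`, subtype is serous with class-dependent odds and
#' otherwise split across non-serous categories, and disease-free and
#' overall survival are exponential with hazard multiplied by
#' `hazard_ratio` for FT-like tumors. Censoring times are exponential with
#' the rate giving the target expected censored fraction.
#'
#' @param config A [cohort_sim_config()].
#' @param signature A `Signature` (see [select_signature()]).
#' @return List with `matrix` (normalized `ExpressionMatrix` containing all
#'   signature probesets), `clinical` (data.frame with `sample_id`, `grade`,
#'   `stage`, `subtype`, `age`, `residual_disease`, `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event`) and `latent` (factor of true class labels,
#'   levels `OV-like` < `FT-like`).
#' @export
simulate_tumor_cohort <- function(config, signature) {
  stopifnot(inherits(config, "CohortSimConfig"))
  signature <- validate_signature(signature)
  if (nrow(signature) == 0L) stop("signature must be non-empty")
  set.seed(config$seed)
  n <- config$n_tumors
  k <- nrow(signature)
  G <- max(config$n_probesets, k)

  cls <- stats::rbinom(n, 1L, config$pi_true)   # 1 = FT-like
  latent <- factor(ifelse(cls == 1L, "FT-like", "OV-like"),
                   levels = c("OV-like", "FT-like"))
  samples <- sprintf("T%03d", seq_len(n))

  probes <- unique(c(signature$probeset_id,
                     sprintf("BG%06d_at", seq_len(G))))[seq_len(G)]
  values <- matrix(stats::rnorm(G * n, mean = 8, sd = 1), G, n,
                   dimnames = list(probes, samples))
  shift <- config$delta / 2
  for (i in seq_len(k)) {
    w <- signature$weight[i]
    values[signature$probeset_id[i], ] <- 8 +
      w * shift * ifelse(cls == 1L, 1, -1) +
      stats::rnorm(n, 0, config$sigma)
  }
  ann <- c(stats::setNames(toupper(signature$symbol), signature$probeset_id),
           stats::setNames(sprintf("BGSYM%06d", seq_len(G)), probes))
  ann <- ann[!duplicated(names(ann))][probes]

  odds <- config$clinical_odds
  eta <- ifelse(cls == 1L, 1, 0)
  grade <- r_prop_odds(eta * log(odds[["grade"]]), c(-0.5, 1.0))
  stage <- r_prop_odds(eta * log(odds[["stage"]]), c(-1.0, 0.0, 1.5))
  p_serous <- stats::plogis(stats::qlogis(0.35) + eta * log(odds[["subtype"]]))
  serous <- stats::rbinom(n, 1L, p_serous) == 1L
  other_levels <- c("endometrioid", "clear cell", "mucinous", "other")
  subtype <- ifelse(serous, "serous",
                    sample(other_levels, n, replace = TRUE,
                           prob = c(0.4, 0.25, 0.2, 0.15)))
  age <- round(stats::rnorm(n, 60, 10), 1)
  residual <- stats::rbinom(n, 1L, stats::plogis(-0.5 + 0.8 * eta))

  lam <- config$baseline_hazard *
    ifelse(cls == 1L, config$hazard_ratio, 1)
  draw_surv <- function() {
    ev_t <- stats::rexp(n, rate = lam)
    cr <- config$censoring_rate
    if (cr > 0) {
      mu_c <- mean(lam) * cr / (1 - cr)
      cn_t <- stats::rexp(n, rate = mu_c)
      list(time = pmin(ev_t, cn_t), event = as.integer(ev_t <= cn_t))
    } else {
      list(time = ev_t, event = rep(1L, n))
    }
  }
  dfs <- draw_surv()
  os <- draw_surv()

  clinical <- data.frame(
    sample_id = samples, grade = grade, stage = stage, subtype = subtype,
    age = age, residual_disease = residual,
    dfs_time = dfs$time, dfs_event = dfs$event,
    os_time = os$time, os_event = os$event, stringsAsFactors = FALSE)

  list(matrix = expression_matrix(values, scale = "normalized",
                                  annotation = ann),
       clinical = clinical, latent = latent)
}
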