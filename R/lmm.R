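#' Specify a family-nested linear mixed model
#'
#' One analysis cell of the association grid: a connectivity feature (or
#' any numeric column) as outcome, one score as predictor of interest,
#' covariates, and a random intercept per family. With
#' `standardize = TRUE` (default) the outcome and all continuous
#' predictors are z-scored on the analysis sample and sex is contrast
#' coded -0.5/+0.5, so coefficients are standardized betas.
#'
#' @param outcome outcome column name.
#' @param predictor predictor-of-interest column name.
#' @param covariates covariate column names; default youth age and sex.
#' @param family_col grouping column name; default `"family_id"`.
#' @param standardize report standardized coefficients.
#' @return an `lmm_spec`.
#' @export
lmm_spec <- function(outcome, predictor, covariates = c("age", "sex"),
                     family_col = "family_id", standardize = TRUE) {
  structure(list(outcome = outcome, predictor = predictor,
                 covariates = covariates, family_col = family_col,
                 standardize = standardize), class = "lmm_spec")
}

# design construction shared by both engines: complete cases, z-scoring,
# sex contrast coding, 0-based family index
build_lmm_frame <- function(spec, data) {
  cols <- c(spec$outcome, spec$predictor, spec$covariates, spec$family_col)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[, cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0) stop("no complete cases")
  fam <- factor(d[[spec$family_col]])
  if (nlevels(fam) < 2) stop("need at least 2 families")
  prep <- function(cc) {
    v <- d[[cc]]
    if (cc == "sex") return(sex_code(v))
    v <- as.numeric(v)
    if (spec$standardize) zscore(v, cc) else v
  }
  y <- prep(spec$outcome)
  terms <- c(spec$predictor, spec$covariates)
  X <- cbind(`(Intercept)` = 1, sapply(terms, prep))
  colnames(X) <- c("(Intercept)", terms)
  list(y = y, X = X, group = as.integer(fam) - 1L, ngrp = nlevels(fam),
       n = nrow(d), frame = d)
}

#' Fit a family-nested linear mixed model
#'
#' Fits `outcome ~ predictor + covariates + (1 | family)`. The default
#' engine is lme4 (REML); `engine = "fast"` uses the package's compiled
#' profiled-deviance fitter for the same model, which the bootstrap and the
#' simulation studies rely on (the two engines agree to optimizer
#' tolerance; see the test suite).
#'
#' @param spec an [lmm_spec()].
#' @param data cohort table.
#' @param engine `"lmer"` or `"fast"`.
#' @param reml use REML (default) or ML.
#' @return a `family_lmm` list: `coefficients` (term/estimate/se/t),
#'   `sigma2`, `tau2` (family random-intercept variance), `loglik_ml`, `n`,
#'   `n_families`, `converged`, and the design pieces reused by
#'   [bootstrap_inference()].
#' @export
fit_family_lmm <- function(spec, data, engine = c("lmer", "fast"),
                           reml = TRUE) {
  engine <- match.arg(engine)
  fr <- build_lmm_frame(spec, data)
  if (engine == "fast") {
    fit <- ri_lmm_cpp(fr$X, fr$y, fr$group, fr$ngrp, reml)
    coefs <- data.frame(term = colnames(fr$X), estimate = drop(fit$beta),
                        se = drop(fit$se),
                        t = drop(fit$beta) / drop(fit$se),
                        stringsAsFactors = FALSE)
    out <- list(coefficients = coefs, sigma2 = fit$sigma2, tau2 = fit$tau2,
                loglik_ml = fit$loglik_ml, converged = TRUE)
  } else {
    df <- data.frame(.y = fr$y, fr$X[, -1, drop = FALSE],
                     .fam = factor(fr$group), check.names = FALSE)
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf("`%s`", colnames(fr$X)[-1]), collapse = " + "),
      "+ (1 | .fam)"))
    msgs <- character(0)
    mod <- withCallingHandlers(
      lme4::lmer(fml, data = df, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (length(msgs) > 0) {
      warning("lmer reported: ", paste(msgs, collapse = "; "))
    }
    est <- lme4::fixef(mod)
    se <- sqrt(diag(as.matrix(stats::vcov(mod))))
    coefs <- data.frame(term = colnames(fr$X), estimate = unname(est),
                        se = unname(se), t = unname(est / se),
                        stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(mod))
    out <- list(coefficients = coefs,
                sigma2 = vc$vcov[vc$grp == "Residual"],
                tau2 = vc$vcov[vc$grp == ".fam"],
                loglik_ml = if (reml) {
                  as.numeric(stats::logLik(lme4::refitML(mod)))
                } else as.numeric(stats::logLik(mod)),
                converged = length(msgs) == 0)
  }
  out$spec <- spec
  out$engine <- engine
  out$reml <- reml
  out$n <- fr$n
  out$n_families <- fr$ngrp
  out$design <- fr
  class(out) <- "family_lmm"
  out
}

#' @export
print.family_lmm <- function(x, ...) {
  cat(sprintf("family-nested LMM (%s, %s): %s ~ %s, n = %d, %d families\n",
              x$engine, if (x$reml) "REML" else "ML", x$spec$outcome,
              paste(c(x$spec$predictor, x$spec$covariates), collapse = " + "),
              x$n, x$n_families))
  print(x$coefficients, row.names = FALSE)
  cat(sprintf("family variance %.4g, residual variance %.4g\n",
              x$tau2, x$sigma2))
  invisible(x)
}

#' Cluster-bootstrap inference for a mixed-model coefficient
#'
#' Resamples whole families with replacement (case bootstrap, default),
#' refits the model on each resample, and reports the percentile 95%
#' confidence interval and a two-sided bootstrap p-value
#' `2 * min(share of draws <= 0, share >= 0)` with the `(1 + count)/(B + 1)`
#' correction. Residual and parametric schemes resample/redraw family
#' effects and residuals from the fitted model instead. Fully reproducible
#' given `seed`.
#'
#' @param spec an [lmm_spec()].
#' @param data cohort table.
#' @param B number of bootstrap iterations (>= 100).
#' @param seed RNG seed.
#' @param scheme `"case"` (family-level, default), `"residual"`, or
#'   `"parametric"`.
#' @param reml refit criterion for the resamples.
#' @param conf confidence level.
#' @return list with `estimate`, `ci` (length 2), `p`, the predictor's
#'   bootstrap draws `boot`, `n_failed`, and `flagged` (TRUE when more than
#'   5% of resampled fits failed).
#' @export
bootstrap_inference <- function(spec, data, B = 1000, seed = 1,
                                scheme = c("case", "residual", "parametric"),
                                reml = TRUE, conf = 0.95) {
  scheme <- match.arg(scheme)
  if (B < 100) stop("B must be at least 100")
  fr <- build_lmm_frame(spec, data)
  fit <- ri_lmm_cpp(fr$X, fr$y, fr$group, fr$ngrp, reml)
  k <- match(spec$predictor, colnames(fr$X))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (scheme == "case") {
    draws <- ri_boot_cpp(fr$X, fr$y, fr$group, fr$ngrp, B, reml)[, k]
  } else {
    mu <- drop(fr$X %*% fit$beta)
    draws <- numeric(B)
    for (b in seq_len(B)) {
      if (scheme == "parametric") {
        u <- stats::rnorm(fr$ngrp, 0, sqrt(fit$tau2))
        e <- stats::rnorm(fr$n, 0, sqrt(fit$sigma2))
      } else {
        # residual scheme: resample empirical family effects and residuals
        resid <- fr$y - mu
        fam_eff <- tapply(resid, fr$group, mean)
        u <- sample(fam_eff - mean(fam_eff), fr$ngrp, replace = TRUE)
        ehat <- resid - fam_eff[fr$group + 1L]
        e <- sample(ehat - mean(ehat), fr$n, replace = TRUE)
      }
      yb <- mu + u[fr$group + 1L] + e
      fb <- tryCatch(ri_lmm_cpp(fr$X, yb, fr$group, fr$ngrp, reml),
                     error = function(err) NULL)
      draws[b] <- if (is.null(fb)) NA_real_ else fb$beta[k]
    }
  }
  ok <- draws[is.finite(draws)]
  if (length(ok) == 0) stop("all bootstrap refits failed")
  n_failed <- B - length(ok)
  alpha <- 1 - conf
  ci <- unname(stats::quantile(ok, c(alpha / 2, 1 - alpha / 2)))
  Bk <- length(ok)
  p <- 2 * min((1 + sum(ok <= 0)) / (Bk + 1), (1 + sum(ok >= 0)) / (Bk + 1))
  list(estimate = fit$beta[k], ci = ci, p = min(p, 1), boot = draws,
       n_failed = n_failed, flagged = n_failed > 0.05 * B)
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: step-up
#' false-discovery-rate adjusted p-values, order-preserving and clipped at
#' 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the scale-by-measure association grid
#'
#' Fits one family-nested mixed model per (psychopathology scale,
#' connectivity measure) cell — connectivity is always the outcome — with
#' cluster-bootstrap inference per cell and a single FDR correction over
#' the grid. `direction = "parent_to_connectivity"` uses the parental
#' baseline scales as predictors (the main analysis);
#' `direction = "connectivity_to_youth"` uses the youth follow-up scales
#' (the exploratory analysis).
#'
#' @param data cohort table with features and phenotypes joined.
#' @param scales predictor score columns; defaults depend on `direction`.
#' @param measures connectivity feature columns; default all 10.
#' @param direction which score set predicts connectivity.
#' @param covariates covariates; default age and sex.
#' @param B bootstrap iterations per cell.
#' @param seed grid seed (per-cell seeds are derived deterministically).
#' @param fdr `"pooled"` (one BH family over the whole grid, default) or
#'   `"per_scale"`.
#' @param engine model engine passed to [fit_family_lmm()]; default
#'   `"fast"` (the grid refits each cell hundreds of times).
#' @param scheme bootstrap scheme.
#' @return `result table` data frame with one row per cell: scale, measure,
#'   n, beta, se, t, bootstrap CI and p, FDR-adjusted p, family
#'   random-intercept variance, bootstrap failure count and flag.
#' @export
run_association_grid <- function(data, scales = NULL,
                                 measures = feature_keys(),
                                 direction = c("parent_to_connectivity",
                                               "connectivity_to_youth"),
                                 covariates = c("age", "sex"), B = 1000,
                                 seed = 1, fdr = c("pooled", "per_scale"),
                                 engine = c("fast", "lmer"),
                                 scheme = "case") {
  direction <- match.arg(direction)
  fdr <- match.arg(fdr)
  engine <- match.arg(engine)
  if (is.null(scales)) {
    scales <- if (direction == "parent_to_connectivity") {
      c("int_p", "ext_p", "tot_p")
    } else c("int_y", "ext_y", "tot_y")
  }
  cells <- expand.grid(scale = scales, measure = measures,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- cells$scale[i]
    ms <- cells$measure[i]
    spec <- lmm_spec(outcome = ms, predictor = sc, covariates = covariates)
    fit <- fit_family_lmm(spec, data, engine = engine)
    boot <- bootstrap_inference(spec, data, B = B,
                                seed = derive_seed(seed, i), scheme = scheme)
    ce <- fit$coefficients[fit$coefficients$term == sc, ]
    rows[[i]] <- data.frame(
      scale = sc, measure = ms, kind = feature_kind(ms), n = fit$n,
      n_families = fit$n_families, beta = ce$estimate, se = ce$se, t = ce$t,
      ci_lower = boot$ci[1], ci_upper = boot$ci[2], p_boot = boot$p,
      re_var = fit$tau2, n_boot_failed = boot$n_failed,
      flagged = boot$flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- if (fdr == "pooled") {
    bh_adjust(out$p_boot)
  } else {
    stats::ave(out$p_boot, out$scale, FUN = bh_adjust)
  }
  rownames(out) <- NULL
  out
}
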