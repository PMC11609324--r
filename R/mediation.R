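#' Between/within family decomposition
#'
#' Splits a child-level variable into the observed family mean (the
#' between-family component) and each child's deviation from their own
#' family mean (the within-family component). The decomposition is exact:
#' `between + within` reconstructs the input, and the within components
#' sum to zero inside every family. Singleton families are legal (their
#' within component is 0).
#'
#' @param values numeric child-level vector.
#' @param family_ids family id per child.
#' @return list with numeric vectors `between` and `within`.
#' @export
family_decompose <- function(values, family_ids) {
  if (length(values) != length(family_ids)) {
    stop("values and family_ids must have equal length")
  }
  if (anyNA(family_ids)) stop("every child needs a family id")
  between <- stats::ave(values, family_ids, FUN = mean)
  list(between = between, within = values - between)
}

# one random-intercept fit through either engine, normalized output
ri_fit <- function(y, X, group, ngrp, engine = "fast", reml = FALSE) {
  if (engine == "fast") {
    f <- ri_lmm_cpp(X, y, group, ngrp, reml)
    return(list(beta = setNames(drop(f$beta), colnames(X)),
                se = setNames(drop(f$se), colnames(X)),
                vcov = f$vcov, sigma2 = f$sigma2, tau2 = f$tau2,
                loglik_ml = f$loglik_ml))
  }
  df <- data.frame(.y = y, X[, -1, drop = FALSE], .fam = factor(group),
                   check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + "),
    "+ (1 | .fam)"))
  mod <- suppressWarnings(
    lme4::lmer(fml, data = df, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(mod))
  est <- lme4::fixef(mod)
  list(beta = setNames(unname(est), colnames(X)),
       se = setNames(sqrt(diag(as.matrix(stats::vcov(mod)))), colnames(X)),
       vcov = as.matrix(stats::vcov(mod)),
       sigma2 = vc$vcov[vc$grp == "Residual"],
       tau2 = vc$vcov[vc$grp == ".fam"],
       loglik_ml = as.numeric(stats::logLik(
         if (reml) lme4::refitML(mod) else mod)))
}

#' Multilevel mediation with within/between-family paths
#'
#' Two-equation mediation for a family-level exposure `x` (parental
#' score), child-level mediator `m` (connectivity feature) and child-level
#' outcome `y` (youth follow-up score): the mediator is regressed on the
#' exposure (`a` path), and the outcome on the exposure (`c'` path) plus
#' the mediator's observed family mean (`b_between`) and within-family
#' deviation (`b_within`), each with a family random intercept, estimated
#' by maximum likelihood so that constrained and free fits are comparable
#' by likelihood-ratio test. The indirect effect is `a * b_between`
#' (exposure is family-constant, so transmission can only run through the
#' between-family component) and the total effect is `c' + indirect`.
#'
#' The exposure must be constant within family; rows violating this are an
#' error (see [subsample_one_per_family()]). If every family is a
#' singleton the within-family deviations are identically zero, so
#' `b_within` is inestimable: it is reported as `NA` with a warning and
#' the outcome model drops the term.
#'
#' @param data cohort table.
#' @param x,m,y column names of exposure, mediator, outcome.
#' @param covariates covariate columns; default youth age and sex.
#' @param family_col family id column.
#' @param constrain_b force the within- and between-family mediator
#'   coefficients to be equal (the null model of [compare_b_paths()]).
#' @param standardize z-score x, m, y and continuous covariates; sex is
#'   contrast coded.
#' @param engine `"lmer"` (default) or the compiled `"fast"` fitter.
#' @return a `mediation_result` with paths `a`, `b_between`, `b_within`,
#'   `c_prime`, `indirect`, `total`, their SEs and Wald CIs, the ML
#'   log-likelihoods of both equations, and bookkeeping fields.
#' @export
fit_mediation <- function(data, x, m, y, covariates = c("age", "sex"),
                          family_col = "family_id", constrain_b = FALSE,
                          standardize = TRUE,
                          engine = c("lmer", "fast")) {
  engine <- match.arg(engine)
  cols <- c(x, m, y, covariates, family_col)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  if (nrow(d) == 0) stop("no complete cases")
  fam <- factor(d[[family_col]])
  if (nlevels(fam) < 2) stop("need at least 2 families")
  x_range <- tapply(as.numeric(d[[x]]), fam, function(v) diff(range(v)))
  if (any(x_range > 0)) {
    stop("exposure '", x, "' varies within family for ",
         sum(x_range > 0), " families; resolve discrepant parental ",
         "reports first (see subsample_one_per_family())")
  }
  prep <- function(cc) {
    v <- d[[cc]]
    if (cc == "sex") return(sex_code(v))
    v <- as.numeric(v)
    if (standardize) zscore(v, cc) else v
  }
  xv <- prep(x); mv <- prep(m); yv <- prep(y)
  CV <- if (length(covariates)) {
    cv <- sapply(covariates, prep)
    colnames(cv) <- covariates
    cv
  } else NULL
  group <- as.integer(fam) - 1L
  ngrp <- nlevels(fam)

  Xm <- cbind(1, xv, CV)
  colnames(Xm) <- c("(Intercept)", x, covariates)
  fit_m <- ri_fit(mv, Xm, group, ngrp, engine)

  dec <- family_decompose(mv, as.integer(fam))
  singleton_only <- stats::sd(dec$within) == 0
  if (constrain_b) {
    Xy <- cbind(1, xv, mv, CV)
    colnames(Xy) <- c("(Intercept)", x, "m", covariates)
  } else if (singleton_only) {
    warning("all families are singletons: within-family mediator ",
            "deviations are identically zero, b_within is inestimable")
    Xy <- cbind(1, xv, dec$between, CV)
    colnames(Xy) <- c("(Intercept)", x, "m_between", covariates)
  } else {
    Xy <- cbind(1, xv, dec$between, dec$within, CV)
    colnames(Xy) <- c("(Intercept)", x, "m_between", "m_within", covariates)
  }
  fit_y <- ri_fit(yv, Xy, group, ngrp, engine)

  Xt <- cbind(1, xv, CV)
  colnames(Xt) <- c("(Intercept)", x, covariates)
  fit_t <- ri_fit(yv, Xt, group, ngrp, engine)

  a <- fit_m$beta[[x]]
  se_a <- fit_m$se[[x]]
  if (constrain_b) {
    b_between <- b_within <- fit_y$beta[["m"]]
    se_b_between <- se_b_within <- fit_y$se[["m"]]
  } else {
    b_between <- fit_y$beta[["m_between"]]
    se_b_between <- fit_y$se[["m_between"]]
    b_within <- if (singleton_only) NA_real_ else fit_y$beta[["m_within"]]
    se_b_within <- if (singleton_only) NA_real_ else fit_y$se[["m_within"]]
  }
  c_prime <- fit_y$beta[[x]]
  se_c <- fit_y$se[[x]]
  zq <- stats::qnorm(0.975)
  res <- list(
    a = a, se_a = se_a, ci_a = a + c(-1, 1) * zq * se_a,
    b_between = b_between, se_b_between = se_b_between,
    ci_b_between = b_between + c(-1, 1) * zq * se_b_between,
    b_within = b_within, se_b_within = se_b_within,
    ci_b_within = b_within + c(-1, 1) * zq * se_b_within,
    c_prime = c_prime, se_c_prime = se_c,
    ci_c_prime = c_prime + c(-1, 1) * zq * se_c,
    indirect = a * b_between,
    total = c_prime + a * b_between,
    total_xy = fit_t$beta[[x]],
    loglik_m = fit_m$loglik_ml, loglik_y = fit_y$loglik_ml,
    constrained = constrain_b, singleton_only = singleton_only,
    n = nrow(d), n_families = ngrp, engine = engine, ml = TRUE,
    vars = list(x = x, m = m, y = y, covariates = covariates,
                family_col = family_col),
    frame = list(x = xv, m = mv, y = yv, CV = CV, group = group,
                 ngrp = ngrp))
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "multilevel mediation (%s%s): %s -> %s -> %s, n = %d, %d families\n",
    x$engine, if (x$constrained) ", constrained b" else "",
    x$vars$x, x$vars$m, x$vars$y, x$n, x$n_families))
  cat(sprintf("  a = %.4f (SE %.4f)\n", x$a, x$se_a))
  cat(sprintf("  b_between = %.4f (SE %.4f), b_within = %.4f (SE %.4f)\n",
              x$b_between, x$se_b_between, x$b_within, x$se_b_within))
  cat(sprintf("  c' = %.4f, indirect = %.4f, total = %.4f\n",
              x$c_prime, x$indirect, x$total))
  invisible(x)
}

#' Confidence interval for the indirect effect
#'
#' `"montecarlo"` (default) samples the `a` and `b_between` paths from
#' their asymptotic sampling distributions (they come from separate
#' equations, so they are sampled independently) and takes percentile
#' quantiles of the product. `"bootstrap"` resamples whole families,
#' refits both equations, and takes percentile quantiles of the resampled
#' products.
#'
#' @param result a [fit_mediation()] result.
#' @param method `"montecarlo"` or `"bootstrap"`.
#' @param B number of draws/resamples.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `ci`, a two-sided `p` for the indirect effect, and
#'   the product draws.
#' @export
indirect_ci <- function(result, method = c("montecarlo", "bootstrap"),
                        B = 1000, seed = 1, conf = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(result, "mediation_result"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (method == "montecarlo") {
    if (!is.finite(result$se_a) || !is.finite(result$se_b_between)) {
      stop("missing standard errors for Monte-Carlo interval")
    }
    a_draw <- stats::rnorm(B, result$a, result$se_a)
    b_draw <- stats::rnorm(B, result$b_between, result$se_b_between)
    prod_draw <- a_draw * b_draw
  } else {
    fr <- result$frame
    rows_by_fam <- split(seq_along(fr$group), fr$group)
    prod_draw <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      fams <- sample.int(fr$ngrp, fr$ngrp, replace = TRUE)
      idx <- unlist(rows_by_fam[fams], use.names = FALSE)
      grp <- rep.int(seq_along(fams) - 1L,
                     lengths(rows_by_fam[fams]))
      Xm <- cbind(1, fr$x[idx], fr$CV[idx, , drop = FALSE])
      am <- tryCatch(ri_lmm_cpp(Xm, fr$m[idx], grp, fr$ngrp, FALSE)$beta[2],
                     error = function(e) NA_real_)
      dec <- family_decompose(fr$m[idx], grp)
      Xy <- cbind(1, fr$x[idx], dec$between, dec$within,
                  fr$CV[idx, , drop = FALSE])
      bm <- tryCatch(ri_lmm_cpp(Xy, fr$y[idx], grp, fr$ngrp, FALSE)$beta[3],
                     error = function(e) NA_real_)
      prod_draw[b] <- am * bm
    }
    prod_draw <- prod_draw[is.finite(prod_draw)]
    if (length(prod_draw) == 0) stop("all bootstrap refits failed")
  }
  alpha <- 1 - conf
  ci <- unname(stats::quantile(prod_draw, c(alpha / 2, 1 - alpha / 2)))
  Bk <- length(prod_draw)
  p <- 2 * min((1 + sum(prod_draw <= 0)) / (Bk + 1),
               (1 + sum(prod_draw >= 0)) / (Bk + 1))
  list(ci = ci, p = min(p, 1), draws = prod_draw)
}

#' Likelihood-ratio comparison of within vs between family paths
#'
#' Chi-squared difference test of the free outcome model (separate
#' `b_within` and `b_between`) against the constrained one (single
#' coefficient): `2 * (loglik_free - loglik_constrained)` on 1 degree of
#' freedom. Both fits must be maximum likelihood on the same sample.
#'
#' @param free unconstrained [fit_mediation()] result.
#' @param constrained result fitted with `constrain_b = TRUE`.
#' @return list with `statistic`, `df` (always 1), and `p`.
#' @export
compare_b_paths <- function(free, constrained) {
  stopifnot(inherits(free, "mediation_result"),
            inherits(constrained, "mediation_result"))
  if (constrained$constrained == free$constrained) {
    stop("need one free and one constrained fit")
  }
  if (free$constrained) {
    tmp <- free; free <- constrained; constrained <- tmp
  }
  if (!isTRUE(free$ml) || !isTRUE(constrained$ml)) {
    stop("likelihood comparison requires ML fits")
  }
  if (free$n != constrained$n) {
    stop("fits are not on identical samples (n differs)")
  }
  if (free$singleton_only) {
    stop("b_within is inestimable with singleton-only families")
  }
  stat <- max(0, 2 * (free$loglik_y - constrained$loglik_y))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Run the mediation grid over scales and connectivity measures
#'
#' One multilevel mediation model per (psychopathology scale, connectivity
#' measure): parental scale at baseline as exposure, the feature as
#' mediator, the matching youth follow-up scale as outcome. The FDR
#' family is the grid's indirect-effect p-values. With
#' `adjust_baseline = TRUE` the matching parent-reported youth baseline
#' score (`<scale>_y_bl`) is added as a covariate.
#'
#' @param data cohort table.
#' @param scales scale stems; default `c("int", "ext", "tot")`, pairing
#'   `<stem>_p` with `<stem>_y`.
#' @param measures mediator feature columns; default all 10.
#' @param covariates base covariates.
#' @param adjust_baseline add the matching youth baseline score.
#' @param B Monte-Carlo draws for the indirect CI.
#' @param seed grid seed.
#' @param fdr `"pooled"` or `"per_scale"` FDR family.
#' @param engine model engine; default `"fast"`.
#' @return data frame with one row per cell: paths, indirect and total
#'   effects, indirect CI and p, FDR-adjusted p, and the within-vs-between
#'   likelihood-ratio comparison.
#' @export
run_mediation_grid <- function(data, scales = c("int", "ext", "tot"),
                               measures = feature_keys(),
                               covariates = c("age", "sex"),
                               adjust_baseline = FALSE, B = 1000, seed = 1,
                               fdr = c("pooled", "per_scale"),
                               engine = c("fast", "lmer")) {
  fdr <- match.arg(fdr)
  engine <- match.arg(engine)
  cells <- expand.grid(scale = scales, measure = measures,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    st <- cells$scale[i]
    ms <- cells$measure[i]
    covs <- covariates
    if (adjust_baseline) covs <- c(covs, paste0(st, "_y_bl"))
    free <- fit_mediation(data, x = paste0(st, "_p"), m = ms,
                          y = paste0(st, "_y"), covariates = covs,
                          engine = engine)
    constr <- fit_mediation(data, x = paste0(st, "_p"), m = ms,
                            y = paste0(st, "_y"), covariates = covs,
                            constrain_b = TRUE, engine = engine)
    cmp <- if (free$singleton_only) {
      list(statistic = NA_real_, df = 1L, p = NA_real_)
    } else compare_b_paths(free, constr)
    ici <- indirect_ci(free, method = "montecarlo", B = B,
                       seed = derive_seed(seed, i))
    rows[[i]] <- data.frame(
      scale = st, measure = ms, n = free$n, n_families = free$n_families,
      a = free$a, b_between = free$b_between, b_within = free$b_within,
      c_prime = free$c_prime, indirect = free$indirect, total = free$total,
      indirect_ci_lower = ici$ci[1], indirect_ci_upper = ici$ci[2],
      p_indirect = ici$p, chisq_diff = cmp$statistic, chisq_df = cmp$df,
      chisq_p = cmp$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- if (fdr == "pooled") {
    bh_adjust(out$p_indirect)
  } else {
    stats::ave(out$p_indirect, out$scale, FUN = bh_adjust)
  }
  rownames(out) <- NULL
  out
}
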