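#' Fit a parametric empirical-Bayes batch-effect model
#'
#' ComBat-type location/scale harmonization for the connectivity features:
#' each feature is modelled with batch (site/scanner) intercepts plus
#' biological covariates, standardized by the pooled residual scale, and
#' per-batch means and variances are shrunk towards a normal and an
#' inverse-gamma prior via the usual iterative moment updates. Covariate
#' effects are estimated once and preserved; the covariate design must not
#' contain batch indicators.
#'
#' @param features numeric matrix or data frame, observations x features
#'   (at least 2 features, needed for the empirical-Bayes priors).
#' @param batch batch (site) labels, one per observation.
#' @param covariates optional numeric design matrix of covariates to
#'   preserve (no intercept column).
#' @param conv absolute convergence tolerance of the EB updates.
#' @param max_iter iteration cap for the EB updates.
#' @return a `combat_model` with the per-feature grand intercept, covariate
#'   coefficients, pooled scale, and per-batch shrunk location/scale.
#' @export
fit_combat <- function(features, batch, covariates = NULL, conv = 1e-6,
                       max_iter = 100) {
  Y <- as.matrix(features)
  if (!is.numeric(Y)) stop("features must be numeric")
  if (ncol(Y) < 2) stop("empirical-Bayes fitting needs at least 2 features")
  n <- nrow(Y)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length must match rows of features")
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("singleton batch(es): ",
         paste(names(nb)[nb < 2], collapse = ", "))
  }
  X <- NULL
  if (!is.null(covariates)) {
    X <- as.matrix(covariates)
    if (nrow(X) != n) stop("covariates rows must match features")
  }
  # cell-means batch design (model.matrix chokes on single-level factors)
  Bm <- sapply(levels(batch), function(l) as.numeric(batch == l))
  D <- cbind(Bm, X)
  if (qr(D)$rank < ncol(D)) {
    stop("rank-deficient design: covariates are collinear with batch or ",
         "each other")
  }
  coefs <- solve(crossprod(D), crossprod(D, Y))     # (B + q) x G
  nbatch <- nlevels(batch)
  batch_int <- coefs[seq_len(nbatch), , drop = FALSE]
  beta_cov <- if (is.null(X)) NULL else {
    coefs[-seq_len(nbatch), , drop = FALSE]
  }
  alpha <- drop((as.numeric(nb) / n) %*% batch_int) # weighted grand mean
  resid <- Y - D %*% coefs
  var_pooled <- colMeans(resid^2)
  if (any(var_pooled <= 0)) stop("zero pooled residual variance")

  stand_mean <- matrix(alpha, n, ncol(Y), byrow = TRUE)
  if (!is.null(X)) stand_mean <- stand_mean + X %*% beta_cov
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE)

  gamma_star <- matrix(0, nbatch, ncol(Y))
  delta_star <- matrix(1, nbatch, ncol(Y))
  if (nbatch > 1) {
    gamma_hat <- apply(Z, 2, function(col) tapply(col, batch, mean))
    delta_hat <- apply(Z, 2, function(col) tapply(col, batch, stats::var))
    for (b in seq_len(nbatch)) {
      gh <- gamma_hat[b, ]
      dh <- delta_hat[b, ]
      g_bar <- mean(gh)
      t2 <- stats::var(gh)
      m <- mean(dh)
      s2 <- stats::var(dh)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      zb <- Z[batch == levels(batch)[b], , drop = FALSE]
      n_b <- nrow(zb)
      g_old <- gh
      d_old <- dh
      for (it in seq_len(max_iter)) {
        g_new <- (n_b * t2 * gh + d_old * g_bar) / (n_b * t2 + d_old)
        sum2 <- colSums((zb - matrix(g_new, n_b, length(g_new),
                                     byrow = TRUE))^2)
        d_new <- (b_prior + 0.5 * sum2) / (n_b / 2 + a_prior - 1)
        delta <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new
        d_old <- d_new
        if (delta < conv) break
      }
      gamma_star[b, ] <- g_old
      delta_star[b, ] <- d_old
    }
  }
  structure(list(alpha = alpha, beta_cov = beta_cov,
                 var_pooled = var_pooled, gamma_star = gamma_star,
                 delta_star = delta_star, batch_levels = levels(batch),
                 n_batch = as.numeric(nb),
                 feature_names = colnames(Y),
                 covariate_names = colnames(X)),
            class = "combat_model")
}

#' Apply a fitted batch-effect model
#'
#' Adjusts features with the shrunk per-batch location and scale:
#' `y_adj = sigma * (z - gamma*) / sqrt(delta*) + alpha + X beta`.
#' Deterministic given the model; only batches seen at fit time are
#' accepted.
#'
#' @param model a [fit_combat()] result.
#' @param features observations x features matrix (same feature order as at
#'   fit time).
#' @param batch batch labels.
#' @param covariates covariate design matching the fit.
#' @return adjusted feature matrix.
#' @export
apply_combat <- function(model, features, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  Y <- as.matrix(features)
  n <- nrow(Y)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen) > 0) {
    stop("batch label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "))
  }
  bi <- match(batch, model$batch_levels)
  stand_mean <- matrix(model$alpha, n, ncol(Y), byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    X <- as.matrix(covariates)
    if (is.null(covariates) || nrow(X) != n ||
        ncol(X) != nrow(model$beta_cov)) {
      stop("covariate design must match the one used at fit time")
    }
    stand_mean <- stand_mean + X %*% model$beta_cov
  }
  sig <- matrix(sqrt(model$var_pooled), n, ncol(Y), byrow = TRUE)
  Z <- (Y - stand_mean) / sig
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- sig * Zadj + stand_mean
  dimnames(out) <- dimnames(Y)
  out
}

#' Harmonize the connectivity features of a cohort table
#'
#' Pipeline wrapper: fits [fit_combat()] on the 10 connectivity features
#' with site as batch and the default covariate set — youth age, sex, and
#' the six parental/youth psychopathology sum scores — then replaces the
#' feature columns by their adjusted values.
#'
#' @param cohort a cohort table (see [simulate_cohort()]).
#' @param features feature column names; default [feature_keys()].
#' @param batch_col batch column name; default `"site_id"`.
#' @param covariate_cols covariate column names; `"sex"` is contrast-coded
#'   as -0.5/+0.5, all others used as numeric.
#' @return the cohort with adjusted features; the fitted model is attached
#'   as the `combat_model` attribute.
#' @export
harmonize_features <- function(cohort, features = feature_keys(),
                               batch_col = "site_id",
                               covariate_cols = c("age", "sex", "int_p",
                                                  "ext_p", "tot_p", "int_y",
                                                  "ext_y", "tot_y")) {
  covariate_cols <- intersect(covariate_cols, names(cohort))
  X <- NULL
  if (length(covariate_cols) > 0) {
    X <- sapply(covariate_cols, function(cc) {
      if (cc == "sex") sex_code(cohort[[cc]]) else as.numeric(cohort[[cc]])
    })
    colnames(X) <- covariate_cols
  }
  model <- fit_combat(cohort[, features, drop = FALSE],
                      batch = cohort[[batch_col]], covariates = X)
  adj <- apply_combat(model, cohort[, features, drop = FALSE],
                      batch = cohort[[batch_col]], covariates = X)
  cohort[, features] <- adj
  attr(cohort, "combat_model") <- model
  cohort
}

#' Serialize and restore a batch-effect model
#'
#' @param model a `combat_model`.
#' @param path JSON file path.
#' @return `write_combat_model()` returns `path` invisibly;
#'   `read_combat_model()` returns the model.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("gamma_star", "delta_star")) obj[[nm]] <- as.matrix(obj[[nm]])
  if (!is.null(obj$beta_cov)) obj$beta_cov <- as.matrix(obj$beta_cov)
  structure(obj, class = "combat_model")
}
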