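#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults are
#' the study conditions the package is designed around: ~3952 families
#' with the observed 1/2/3-sibling mix, 21 acquisition sites with additive
#' and multiplicative scanner effects, right-skewed count-like ASR/BPM sum
#' scores with a parent-youth correlation of 0.15, stronger within- than
#' between-network connectivity on the Fisher-z scale, small planted
#' standardized effects (|beta| = 0.04-0.05) on the cells reported
#' significant in the source cohort, and a family random intercept. Any
#' field can be overridden; `planted_effects = NULL` and
#' `mediation = NULL` give null generators.
#'
#' @param n_families number of families.
#' @param sibling_probs probabilities of 1, 2, 3 children per family.
#' @param n_sites number of acquisition sites (families nested in sites).
#' @param age_mean,age_sd youth age distribution (years).
#' @param p_female probability of female youth.
#' @param score_mu,score_size negative-binomial mean and dispersion per
#'   scale (named: `int_p`, `ext_p`, `tot_p`, `int_y`, `ext_y`, `tot_y`).
#' @param parent_youth_cor target Pearson correlation between matching
#'   parent and youth sum scores.
#' @param scale_cor correlation between the int/ext/tot latents of one
#'   informant.
#' @param sibling_cor share of the youth latent shared by siblings.
#' @param baseline_cor correlation of youth baseline with follow-up
#'   latents.
#' @param within_mean,between_mean Fisher-z connectivity means (within >
#'   between, the typical network pattern).
#' @param family_sd SD of the per-family connectivity intercept (z units).
#' @param noise_sd SD of subject-level feature noise (z units).
#' @param site_sd SD of additive site offsets (z units).
#' @param site_scale_range range of multiplicative site noise factors;
#'   `c(1, 1)` disables them.
#' @param pair_sd SD of parcel-pair noise around a subject's feature value
#'   (matrix mode only).
#' @param planted_effects data frame with columns `scale`, `measure`,
#'   `beta` of planted standardized effects, or `NULL` for a global null.
#' @param mediation `NULL`, or a list with `scale` (stem, e.g. `"int"`),
#'   `measure`, and paths `a`, `b_between`, `b_within`, `c_prime`: the
#'   matching youth follow-up score is then rebuilt from the planted
#'   mediation model (on a standardized continuous scale).
#' @param seed integer seed; the full generator is deterministic given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 3952,
                       sibling_probs = c(3709, 236, 7) / 3952,
                       n_sites = 21, age_mean = 10.0, age_sd = 0.6,
                       p_female = 0.509,
                       score_mu = c(int_p = 8, ext_p = 6, tot_p = 25,
                                    int_y = 3, ext_y = 3, tot_y = 7),
                       score_size = c(int_p = 1.2, ext_p = 1.2,
                                      tot_p = 1.5, int_y = 1.0,
                                      ext_y = 1.0, tot_y = 1.2),
                       parent_youth_cor = 0.15, scale_cor = 0.6,
                       sibling_cor = 0.3, baseline_cor = 0.5,
                       within_mean = 0.35, between_mean = 0.12,
                       family_sd = 0.03, noise_sd = 0.07, site_sd = 0.05,
                       site_scale_range = c(0.8, 1.25), pair_sd = 0.05,
                       planted_effects = default_planted_effects(),
                       mediation = NULL, seed = 1) {
  cfg <- list(n_families = n_families, sibling_probs = sibling_probs,
              n_sites = n_sites, age_mean = age_mean, age_sd = age_sd,
              p_female = p_female, score_mu = score_mu,
              score_size = score_size, parent_youth_cor = parent_youth_cor,
              scale_cor = scale_cor, sibling_cor = sibling_cor,
              baseline_cor = baseline_cor, within_mean = within_mean,
              between_mean = between_mean, family_sd = family_sd,
              noise_sd = noise_sd, site_sd = site_sd,
              site_scale_range = site_scale_range, pair_sd = pair_sd,
              planted_effects = planted_effects, mediation = mediation,
              seed = seed)
  if (cfg$n_families < 1) stop("need at least 1 family")
  if (abs(sum(cfg$sibling_probs) - 1) > 1e-8) {
    stop("sibling probabilities must sum to 1")
  }
  sds <- c(cfg$age_sd, cfg$family_sd, cfg$noise_sd, cfg$site_sd,
           cfg$pair_sd)
  if (any(sds < 0)) stop("SDs must be non-negative")
  if (!is.null(cfg$planted_effects) &&
      any(abs(cfg$planted_effects$beta) >= 1)) {
    stop("planted standardized |beta| must be < 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @details `default_planted_effects()` returns the study-flavoured default
#'   effect map: the eight (scale, measure) cells with standardized betas
#'   of -0.05 to 0.04.
#' @export
default_planted_effects <- function() {
  data.frame(
    scale = c("int_p", "int_p", "int_p", "ext_p", "tot_p", "tot_p",
              "tot_p", "tot_p"),
    measure = c("ERN3", "ERN12", "ERN24", "ERN4", "ERN3", "ERN4", "ERN12",
                "ERN24"),
    beta = c(-0.04, -0.04, 0.04, -0.05, -0.04, -0.04, -0.05, 0.04),
    stringsAsFactors = FALSE)
}

# correlated standard-normal draws with an exchangeable-ish scale
# correlation among int/ext/tot (chol of the 3x3 matrix)
draw_scale_latent <- function(n, rho) {
  S <- matrix(rho, 3, 3)
  diag(S) <- 1
  matrix(stats::rnorm(3 * n), n, 3) %*% chol(S)
}

# Gaussian-copula -> negative-binomial marginal
latent_to_score <- function(z, mu, size) {
  stats::qnbinom(stats::pnorm(z), size = size, mu = mu)
}

# copula attenuation: Pearson correlation survives the normal -> NB
# quantile map only partially; this inflation factor (measured once on
# large simulations of the default score marginals) keeps the observed
# parent-youth correlation on target
COPULA_INFLATION <- 1.18

#' Simulate a family-nested cohort
#'
#' Draws families with the configured sibling mix, nests them in sites,
#' and generates demographics plus parental baseline and youth
#' baseline/follow-up internalizing, externalizing, and total problem sum
#' scores from a Gaussian copula with negative-binomial margins. Parental
#' scores are family-constant; sibling youth scores share a family
#' component; the matching parent-youth score correlation is calibrated to
#' `cfg$parent_youth_cor`.
#'
#' @param cfg a [sim_config()].
#' @return cohort data frame (one row per subject) without connectivity
#'   features.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed) %% .Machine$integer.max)
  nf <- cfg$n_families
  n_kids <- sample.int(3, nf, replace = TRUE, prob = cfg$sibling_probs)
  n <- sum(n_kids)
  family_id <- rep(sprintf("F%05d", seq_len(nf)), n_kids)
  site_fam <- sample.int(cfg$n_sites, nf, replace = TRUE)
  site_id <- sprintf("site%02d", rep(site_fam, n_kids))
  fam_index <- rep(seq_len(nf), n_kids)

  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$p_female, "F", "M")

  # latent scores: parent per family, youth per child with shared family
  # component; matching-scale parent-youth correlation = rho (inflated to
  # survive the copula's marginal transform)
  rho <- min(0.98, cfg$parent_youth_cor * COPULA_INFLATION)
  p_lat <- draw_scale_latent(nf, cfg$scale_cor)
  fam_lat <- draw_scale_latent(nf, cfg$scale_cor)
  kid_lat <- draw_scale_latent(n, cfg$scale_cor)
  shared <- sqrt(cfg$sibling_cor) * fam_lat[fam_index, ] +
    sqrt(1 - cfg$sibling_cor) * kid_lat
  y_lat <- rho * p_lat[fam_index, ] + sqrt(1 - rho^2) * shared
  bl_extra <- draw_scale_latent(n, cfg$scale_cor)
  bl_lat <- cfg$baseline_cor * y_lat +
    sqrt(1 - cfg$baseline_cor^2) * bl_extra

  stems <- c("int", "ext", "tot")
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    family_id = family_id, site_id = site_id, age = age,
                    sex = sex, stringsAsFactors = FALSE)
  for (k in 1:3) {
    pk <- paste0(stems[k], "_p")
    yk <- paste0(stems[k], "_y")
    out[[pk]] <- latent_to_score(p_lat[fam_index, k], cfg$score_mu[[pk]],
                                 cfg$score_size[[pk]])
    out[[yk]] <- latent_to_score(y_lat[, k], cfg$score_mu[[yk]],
                                 cfg$score_size[[yk]])
    out[[paste0(yk, "_bl")]] <- latent_to_score(
      bl_lat[, k], cfg$score_mu[[yk]], cfg$score_size[[yk]])
  }
  attr(out, "sim_config") <- cfg
  out
}

#' Simulate connectivity for a cohort
#'
#' Builds the 10 within/between-network Fisher-z features: network-level
#' means (within > between), planted standardized score effects, a family
#' random intercept, additive site offsets, and site-scaled subject noise.
#' With `mode = "matrices"` full parcel-by-parcel matrices are emitted
#' around the same feature values (plus parcel-pair noise), exercising
#' [extract_features()]; `mode = "features"` appends the features
#' directly. If the config plants mediation paths, the matching youth
#' follow-up score is rebuilt from the planted model afterwards.
#'
#' @param cohort a [simulate_cohort()] table.
#' @param cfg the same [sim_config()].
#' @param mode `"features"` or `"matrices"`.
#' @param map a network-parcel map, required for `mode = "matrices"`.
#' @return for `"features"`: the cohort with 10 feature columns and a
#'   `truth` attribute holding the planted effect map; for `"matrices"`:
#'   list with elements `cohort` (same) and `matrices` (named list of
#'   [connectivity_matrix()] objects).
#' @export
simulate_connectivity <- function(cohort, cfg, mode = c("features",
                                                        "matrices"),
                                  map = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  set.seed(derive_seed(cfg$seed, 7919L))
  n <- nrow(cohort)
  fam <- factor(cohort$family_id)
  site <- factor(cohort$site_id)
  keys <- feature_keys()
  mu <- ifelse(keys %in% network_keys(), cfg$within_mean, cfg$between_mean)
  names(mu) <- keys
  sigma_f <- sqrt(cfg$family_sd^2 + cfg$noise_sd^2)

  fam_int <- matrix(stats::rnorm(nlevels(fam) * 10, 0, cfg$family_sd),
                    nlevels(fam), 10)
  site_off <- matrix(stats::rnorm(nlevels(site) * 10, 0, cfg$site_sd),
                     nlevels(site), 10)
  site_scale <- matrix(stats::runif(nlevels(site) * 10,
                                    cfg$site_scale_range[1],
                                    cfg$site_scale_range[2]),
                       nlevels(site), 10)

  planted <- cfg$planted_effects
  if (!is.null(cfg$mediation)) {
    med <- cfg$mediation
    extra <- data.frame(scale = paste0(med$scale, "_p"),
                        measure = med$measure, beta = med$a,
                        stringsAsFactors = FALSE)
    planted <- rbind(planted, extra)
  }
  feats <- matrix(0, n, 10, dimnames = list(NULL, keys))
  for (j in seq_along(keys)) {
    eff <- 0
    if (!is.null(planted)) {
      pj <- planted[planted$measure == keys[j], , drop = FALSE]
      for (r in seq_len(nrow(pj))) {
        # plant on the standardized scale: the raw slope b*sigma_f with
        # b = beta / sqrt(1 - beta^2) makes the standardized coefficient
        # exactly beta after the planted term inflates the feature SD
        b <- pj$beta[r] / sqrt(1 - pj$beta[r]^2)
        eff <- eff + b * sigma_f *
          zscore(as.numeric(cohort[[pj$scale[r]]]), pj$scale[r])
      }
    }
    noise <- stats::rnorm(n, 0, cfg$noise_sd) *
      site_scale[as.integer(site), j]
    feats[, j] <- mu[j] + eff + fam_int[as.integer(fam), j] +
      site_off[as.integer(site), j] + noise
  }
  cohort[, keys] <- feats

  if (!is.null(cfg$mediation)) {
    med <- cfg$mediation
    xz <- zscore(as.numeric(cohort[[paste0(med$scale, "_p")]]))
    mz <- zscore(feats[, med$measure])
    dec <- family_decompose(mz, cohort$family_id)
    u_y <- stats::rnorm(nlevels(fam), 0, sqrt(0.1))
    sys <- med$c_prime * xz + med$b_between * dec$between +
      med$b_within * dec$within + u_y[as.integer(fam)]
    resid_sd <- sqrt(max(0.05, 1 - stats::var(sys)))
    cohort[[paste0(med$scale, "_y")]] <- sys +
      stats::rnorm(n, 0, resid_sd)
  }
  attr(cohort, "truth") <- planted
  attr(cohort, "sim_config") <- cfg

  if (mode == "features") return(cohort)

  if (is.null(map)) stop("matrix mode needs a network-parcel map")
  ids <- map$parcel_id
  net_of <- map$network_id
  P <- length(ids)
  pair_key <- matrix("", P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (net_of[i] == net_of[j]) {
        pair_key[i, j] <- net_of[i]
      } else {
        a <- sort(match(c(net_of[i], net_of[j]), network_keys()))
        pair_key[i, j] <- paste0("ERN", a[1], a[2])
      }
    }
  }
  matrices <- vector("list", n)
  for (s in seq_len(n)) {
    base <- matrix(feats[s, ][pair_key], P, P)
    eps <- matrix(stats::rnorm(P * P, 0, cfg$pair_sd), P, P)
    eps <- (eps + t(eps)) / sqrt(2)
    mvals <- base + eps
    diag(mvals) <- 0
    matrices[[s]] <- connectivity_matrix(mvals, parcel_ids = ids)
  }
  names(matrices) <- cohort$subject_id
  list(cohort = cohort, matrices = matrices)
}

#' Simulate a toy labelled volume with known network structure
#'
#' Tiles a grid into `n_parcels` contiguous parcels (Voronoi cells of
#' random seed voxels), assigns parcels to the four networks round-robin,
#' and places one ROI peak at each parcel's seed voxel centre, so the
#' expected overlap table is known by construction.
#'
#' @param dims grid dimensions; default `c(20, 20, 20)`.
#' @param n_parcels number of parcels (>= 4 so each network gets one).
#' @param voxel_mm isotropic voxel size in millimetres.
#' @param seed RNG seed.
#' @return list with `vol` (a [label_volume()]), `nets` (a
#'   `network_definition` with one peak per parcel), and `truth` (the
#'   planted parcel-to-network table).
#' @export
simulate_label_volume <- function(dims = c(20, 20, 20), n_parcels = 6,
                                  voxel_mm = 2, seed = 1) {
  if (n_parcels > prod(dims)) stop("more parcels than voxels")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (dims - 1) / 2   # roughly centred origin
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  seeds <- idx[sample.int(nrow(idx), n_parcels), , drop = FALSE]
  d2 <- vapply(seq_len(n_parcels), function(p) {
    (idx[, 1] - seeds[p, 1])^2 + (idx[, 2] - seeds[p, 2])^2 +
      (idx[, 3] - seeds[p, 3])^2
  }, numeric(nrow(idx)))
  lab <- max.col(-d2, ties.method = "first")
  grid <- array(as.integer(lab), dim = dims)
  vol <- label_volume(grid, affine)
  nets <- rep_len(network_keys(), n_parcels)
  peak_mm <- vox_to_mm(seeds, affine)
  def <- data.frame(network = nets,
                    label = sprintf("parcel%02d_peak", seq_len(n_parcels)),
                    x = peak_mm[, 1], y = peak_mm[, 2], z = peak_mm[, 3],
                    stringsAsFactors = FALSE)
  class(def) <- c("network_definition", "data.frame")
  truth <- data.frame(parcel_id = seq_len(n_parcels), network_id = nets,
                      stringsAsFactors = FALSE)
  list(vol = vol, nets = def, truth = truth)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a subject-by-item score table:
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the sum)`.
#'
#' @param items numeric matrix or data frame, subjects in rows, items in
#'   columns (>= 2 of each).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  X <- as.matrix(items)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 subjects and >= 2 items")
  total_var <- stats::var(rowSums(X))
  if (total_var <= 0) stop("zero total-score variance")
  k <- ncol(X)
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / total_var)
}

#' Keep one child per family where parental reports disagree
#'
#' Families whose parental scores are not constant across siblings violate
#' the family-constant exposure assumption of the mediation models; this
#' utility randomly keeps one child from each such family (all other
#' families are untouched).
#'
#' @param data cohort table.
#' @param parent_cols parental score columns to check.
#' @param family_col family id column.
#' @param seed RNG seed for the random selection.
#' @return the subsetted cohort.
#' @export
subsample_one_per_family <- function(data,
                                     parent_cols = c("int_p", "ext_p",
                                                     "tot_p"),
                                     family_col = "family_id", seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fam <- data[[family_col]]
  bad <- vapply(split(seq_len(nrow(data)), fam), function(ix) {
    any(vapply(parent_cols, function(cc) {
      length(unique(data[[cc]][ix])) > 1
    }, logical(1)))
  }, logical(1))
  drop_rows <- unlist(lapply(split(seq_len(nrow(data)), fam)[bad],
                             function(ix) ix[-sample.int(length(ix), 1)]))
  if (length(drop_rows) > 0) data <- data[-drop_rows, , drop = FALSE]
  rownames(data) <- NULL
  data
}
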