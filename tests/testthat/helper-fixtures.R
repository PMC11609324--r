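# Shared fixtures: everything is generated in code at test time.

# independent per-voxel oracle for compute_overlap (peak mode): loops over
# every voxel of the grid, tests membership in each ROI sphere, and counts
# each voxel once per network (union over the network's ROIs)
brute_overlap <- function(nets, vol, radius_mm) {
  dims <- dim(vol$grid)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  mm <- t(vol$affine[1:3, 1:3] %*% t(idx) + vol$affine[1:3, 4])
  labs <- as.vector(vol$grid)
  rows <- list()
  for (net in intersect(paste0("ERN", 1:4), unique(nets$network))) {
    sub <- nets[nets$network == net, , drop = FALSE]
    member <- rep(FALSE, nrow(idx))
    for (r in seq_len(nrow(sub))) {
      d2 <- (mm[, 1] - sub$x[r])^2 + (mm[, 2] - sub$y[r])^2 +
        (mm[, 3] - sub$z[r])^2
      member <- member | (d2 <= radius_mm^2 + 1e-9)
    }
    hit <- labs[member & labs > 0]
    if (length(hit) == 0) next
    tab <- table(hit)
    rows[[net]] <- data.frame(network_id = net,
                              parcel_id = as.integer(names(tab)),
                              voxel_count = as.integer(tab),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# a hand-built parcel map: parcels 1..sum(sizes), networks in order
toy_map <- function(sizes = c(2, 2, 2, 2)) {
  stopifnot(length(sizes) == 4)
  tab <- data.frame(parcel_id = seq_len(sum(sizes)),
                    network_id = rep(network_keys(), sizes),
                    voxel_count = 10L, stringsAsFactors = FALSE)
  attr(tab, "overlap") <- tab
  class(tab) <- c("network_parcel_map", "data.frame")
  tab
}

# random symmetric z-scale connectivity matrix over given parcel ids
rand_conn <- function(parcel_ids, seed = 1, mean = 0.2, sd = 0.1) {
  set.seed(seed)
  p <- length(parcel_ids)
  m <- matrix(rnorm(p * p, mean, sd), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectivity_matrix(m, parcel_ids = parcel_ids)
}

# small cohort + features for model tests
quick_cohort <- function(n_families = 400, seed = 1, beta_map = NULL,
                         site_sd = 0, site_scale = c(1, 1),
                         mediation = NULL,
                         sibling_probs = c(0.7, 0.25, 0.05)) {
  cfg <- sim_config(n_families = n_families, seed = seed,
                    sibling_probs = sibling_probs,
                    planted_effects = beta_map, site_sd = site_sd,
                    site_scale_range = site_scale, mediation = mediation)
  simulate_connectivity(simulate_cohort(cfg), cfg, mode = "features")
}
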