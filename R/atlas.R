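#' Load an emotion-regulation network definition table
#'
#' Reads a tab-separated table of meta-analytic regions of interest, one row
#' per ROI, with columns `network` (one of `ERN1`..`ERN4`), `label` (region
#' name, unique within a network), and `x`, `y`, `z` peak coordinates in MNI
#' millimetres. An optional `mask_path` column points at per-ROI cluster
#' mask volumes for cluster-to-parcel mapping.
#'
#' The packaged default (`system.file("extdata",
#' "ern_networks_synthetic.tsv", package = "ernfc")`) is a synthetic
#' stand-in: 36 ROIs whose anatomical labels follow the published network
#' composition, with canonical MNI coordinates for those structures rather
#' than the original meta-analytic peaks.
#'
#' @param path path to the TSV file.
#' @return a `network_definition` data frame with row order preserved.
#' @export
load_network_definition <- function(path) {
  def <- read_tsv_table(path)
  required <- c("network", "label", "x", "y", "z")
  missing_cols <- setdiff(required, names(def))
  if (length(missing_cols) > 0) {
    stop("network definition is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_net <- setdiff(unique(def$network), network_keys())
  if (length(bad_net) > 0) {
    stop("unknown network id(s): ", paste(bad_net, collapse = ", "))
  }
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(def[[cc]]))
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-numeric or non-finite peak coordinate in column ", cc)
    }
    def[[cc]] <- v
  }
  dup <- duplicated(def[, c("network", "label")])
  if (any(dup)) {
    stop("duplicate ROI label within a network: ",
         paste(unique(def$label[dup]), collapse = ", "))
  }
  class(def) <- c("network_definition", "data.frame")
  def
}

#' Construct a labelled parcellation volume
#'
#' A label volume is a 3-D integer grid (0 = background, positive integers =
#' parcel ids) plus the 4x4 affine mapping 0-based voxel indices to
#' millimetre coordinates. The affine is the single source of truth for
#' voxel/mm conversion.
#'
#' @param grid 3-D integer array of parcel labels.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param parcel_kind optional named character vector mapping parcel id to
#'   `"cortical"`/`"subcortical"`.
#' @return a `label_volume` object.
#' @export
label_volume <- function(grid, affine, parcel_kind = NULL) {
  if (length(dim(grid)) != 3 || any(dim(grid) < 1)) {
    stop("grid must be a 3-D array with positive dimensions")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("affine must be an invertible 4x4 transform")
  }
  if (any(grid < 0) || any(grid != round(grid))) {
    stop("parcel labels must be non-negative integers")
  }
  structure(list(grid = grid, affine = affine, parcel_kind = parcel_kind),
            class = "label_volume")
}

#' @rdname label_volume
#' @param path path to a NIfTI-1 file with integer labels.
#' @export
load_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), dimnames = NULL)
  grid <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  label_volume(grid, affine)
}

# mm coordinates of 0-based voxel index matrix (n x 3)
vox_to_mm <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

mm_to_vox <- function(mm, affine) {
  mm <- matrix(mm, ncol = 3)
  t(solve(affine[1:3, 1:3]) %*% (t(mm) - affine[1:3, 4]))
}

#' Voxels inside a millimetre sphere
#'
#' Returns the 0-based indices of all in-grid voxels whose centres lie at
#' Euclidean distance at most `radius_mm` from `center_mm`. Membership is
#' decided by the voxel centre, not any corner.
#'
#' @param center_mm length-3 MNI millimetre coordinate.
#' @param radius_mm sphere radius in millimetres (>= 0).
#' @param vol a [label_volume()].
#' @return integer matrix with columns `i`, `j`, `k` of 0-based voxel
#'   indices; zero rows (with a warning) if the sphere misses the grid.
#' @export
sphere_voxels <- function(center_mm, radius_mm, vol) {
  stopifnot(inherits(vol, "label_volume"), length(center_mm) == 3)
  if (!all(is.finite(center_mm))) stop("non-finite sphere centre")
  if (radius_mm < 0) stop("radius must be non-negative")
  dims <- dim(vol$grid)
  A <- vol$affine
  cv <- drop(mm_to_vox(center_mm, A))
  # conservative per-axis half-width in voxel units: a displacement of r mm
  # cannot move a voxel index by more than r / sigma_min(A3)
  sv <- svd(A[1:3, 1:3])$d
  pad <- radius_mm / min(sv) + 1e-9
  lo <- pmax(0L, floor(cv - pad))
  hi <- pmin(dims - 1L, ceiling(cv + pad))
  if (any(lo > hi)) {
    warning("sphere lies outside the volume grid; returning no voxels")
    return(matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "k"))))
  }
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- vox_to_mm(cand, A)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  out <- cand[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("sphere contains no in-grid voxel centres")
  }
  storage.mode(out) <- "integer"
  colnames(out) <- c("i", "j", "k")
  out
}

# nearest-neighbour resample of a mask volume onto the label grid:
# TRUE where the mask voxel nearest to each label-grid voxel centre is > 0
resample_mask_nn <- function(mask_vol, vol) {
  dims <- dim(vol$grid)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  mm <- vox_to_mm(idx, vol$affine)
  mv <- round(mm_to_vox(mm, mask_vol$affine))
  md <- dim(mask_vol$grid)
  inb <- mv[, 1] >= 0 & mv[, 1] < md[1] & mv[, 2] >= 0 & mv[, 2] < md[2] &
    mv[, 3] >= 0 & mv[, 3] < md[3]
  hit <- logical(nrow(idx))
  if (any(inb)) {
    lin <- mv[inb, 1] + md[1] * (mv[inb, 2] + md[2] * mv[inb, 3]) + 1
    hit[inb] <- mask_vol$grid[lin] > 0
  }
  idx[hit, , drop = FALSE]
}

#' Overlap of network ROIs with parcellation labels
#'
#' Maps each network's ROIs onto the label volume — 6 mm peak spheres by
#' default, or resampled cluster masks — and tallies, per (network, parcel)
#' pair, the number of ROI voxels landing in that parcel. Voxels covered by
#' several ROIs of the same network are counted once (the network's voxel
#' set is the union of its ROI voxel sets). Background hits are reported via
#' the `background_voxels` attribute, and ROIs falling entirely into
#' background or off the grid raise a warning.
#'
#' @param nets a [load_network_definition()] table.
#' @param vol a [label_volume()].
#' @param mode `"peak"` (spheres around peak coordinates) or `"cluster"`
#'   (per-ROI mask volumes from `nets$cluster_mask` or `nets$mask_path`).
#' @param radius_mm sphere radius for peak mode; default 6 mm.
#' @return an `overlap_table` data frame with columns `network_id`,
#'   `parcel_id`, `voxel_count` (only rows with `voxel_count >= 1`).
#' @export
compute_overlap <- function(nets, vol, mode = c("peak", "cluster"),
                            radius_mm = 6) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "label_volume"))
  dims <- dim(vol$grid)
  rows <- list()
  background <- 0L
  for (net in intersect(network_keys(), unique(nets$network))) {
    sub <- nets[nets$network == net, , drop = FALSE]
    vox_keys <- integer(0)
    for (r in seq_len(nrow(sub))) {
      if (mode == "peak") {
        vx <- withCallingHandlers(
          sphere_voxels(c(sub$x[r], sub$y[r], sub$z[r]), radius_mm, vol),
          warning = function(w) invokeRestart("muffleWarning"))
      } else {
        mask <- sub$cluster_mask[[r]]
        if (is.null(mask) && "mask_path" %in% names(sub)) {
          mask <- load_label_volume(sub$mask_path[r])
        }
        if (is.null(mask)) {
          stop("cluster mode requires a cluster mask for ROI '", sub$label[r],
               "'")
        }
        vx <- resample_mask_nn(mask, vol)
      }
      lin <- vx[, 1] + dims[1] * (vx[, 2] + dims[2] * vx[, 3]) + 1
      labs <- vol$grid[lin]
      if (length(lin) == 0 || all(labs == 0)) {
        warning("ROI '", sub$label[r], "' (", net,
                ") maps entirely to background or off-grid; skipped")
      }
      vox_keys <- c(vox_keys, lin)
    }
    vox_keys <- unique(vox_keys)
    if (length(vox_keys) == 0) next
    labs <- vol$grid[vox_keys]
    background <- background + sum(labs == 0)
    labs <- labs[labs > 0]
    if (length(labs) == 0) next
    tab <- table(labs)
    rows[[net]] <- data.frame(network_id = net,
                              parcel_id = as.integer(names(tab)),
                              voxel_count = as.integer(tab),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(network_id = character(0), parcel_id = integer(0),
               voxel_count = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "background_voxels") <- background
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Filter an overlap table by voxel count
#'
#' Drops weakly overlapping (network, parcel) rows. Under the `"quartile"`
#' rule, rows whose `voxel_count` is at or below the first quartile of the
#' pooled count distribution are removed (quartile computed with the
#' linear-interpolation convention, [stats::quantile()] type 7; set
#' `scope = "network"` to compute the quartile within each network
#' instead). Under the `"fixed"` rule, rows with `voxel_count <= fixed_min`
#' are removed.
#'
#' @param table an `overlap_table`.
#' @param rule `"quartile"` or `"fixed"`.
#' @param fixed_min count threshold for the fixed rule (default 5, i.e.
#'   drop parcels of five voxels or fewer).
#' @param scope quartile pooling: `"pooled"` across all rows (default) or
#'   per `"network"`.
#' @return the filtered `overlap_table`; the threshold(s) used are attached
#'   as the `threshold` attribute.
#' @export
filter_overlap <- function(table, rule = c("quartile", "fixed"),
                           fixed_min = 5, scope = c("pooled", "network")) {
  rule <- match.arg(rule)
  scope <- match.arg(scope)
  if (nrow(table) == 0) stop("overlap table is empty")
  if (rule == "fixed") {
    thr <- fixed_min
    keep <- table$voxel_count > thr
  } else if (scope == "pooled") {
    thr <- stats::quantile(table$voxel_count, 0.25, type = 7, names = FALSE)
    keep <- table$voxel_count > thr
  } else {
    thr <- vapply(split(table$voxel_count, table$network_id),
                  stats::quantile, numeric(1), probs = 0.25, type = 7,
                  names = FALSE)
    keep <- table$voxel_count > thr[table$network_id]
  }
  out <- table[keep, , drop = FALSE]
  nets_in <- unique(table$network_id)
  n_left <- vapply(nets_in, function(nt) sum(out$network_id == nt),
                   integer(1))
  if (any(n_left < 2)) {
    stop("filtering leaves network(s) with fewer than 2 parcels: ",
         paste(nets_in[n_left < 2], collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Assign each parcel to a single network
#'
#' Every parcel appearing in the (filtered) overlap table is assigned to
#' the network with the largest voxel overlap; ties are broken towards the
#' lowest network index with a warning. The result must leave every network
#' represented in the input with at least two parcels, since within-network
#' mean connectivity is undefined otherwise.
#'
#' @param table a filtered `overlap_table`.
#' @return a `network_parcel_map` data frame with columns `parcel_id`,
#'   `network_id`, `voxel_count` (the winning overlap) and the full input
#'   table in the `overlap` attribute.
#' @export
assign_parcels <- function(table) {
  if (nrow(table) == 0) stop("overlap table is empty")
  parts <- split(seq_len(nrow(table)), table$parcel_id)
  rows <- lapply(parts, function(ix) {
    sub <- table[ix, , drop = FALSE]
    best <- which(sub$voxel_count == max(sub$voxel_count))
    if (length(best) > 1) {
      # deterministic tie-break: lowest network index
      ord <- order(match(sub$network_id[best], network_keys()))
      warning("parcel ", sub$parcel_id[1], " overlaps networks ",
              paste(sub$network_id[best], collapse = "/"),
              " equally; assigned to ", sub$network_id[best[ord[1]]])
      best <- best[ord[1]]
    }
    sub[best, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$parcel_id), c("parcel_id", "network_id", "voxel_count")]
  rownames(out) <- NULL
  nets_in <- unique(table$network_id)
  n_parc <- vapply(nets_in, function(nt) sum(out$network_id == nt),
                   integer(1))
  if (any(n_parc < 2)) {
    stop("network(s) retain fewer than 2 parcels after assignment: ",
         paste(nets_in[n_parc < 2], collapse = ", "))
  }
  attr(out, "overlap") <- table
  class(out) <- c("network_parcel_map", "data.frame")
  out
}

#' Parcels mapped to one network
#'
#' @param map a [assign_parcels()] result.
#' @param net a network key.
#' @return integer vector of parcel ids.
#' @export
network_parcels <- function(map, net) {
  net <- match.arg(net, network_keys())
  map$parcel_id[map$network_id == net]
}

#' Run the full atlas-mapping stage
#'
#' Convenience composition of [compute_overlap()], [filter_overlap()] and
#' [assign_parcels()].
#'
#' @inheritParams compute_overlap
#' @inheritParams filter_overlap
#' @return a `network_parcel_map`.
#' @export
map_networks_to_parcels <- function(nets, vol, mode = "peak", radius_mm = 6,
                                    rule = "quartile", fixed_min = 5,
                                    scope = "pooled") {
  overlap <- compute_overlap(nets, vol, mode = mode, radius_mm = radius_mm)
  assign_parcels(filter_overlap(overlap, rule = rule, fixed_min = fixed_min,
                                scope = scope))
}
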