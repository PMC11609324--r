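#' Fisher variance stabilization of correlations
#'
#' `variance_stabilize()` applies the inverse hyperbolic tangent
#' (Fisher z transform), `z = atanh(r)`; `variance_unstabilize()` inverts
#' it. All connectivity summaries in this package are computed on the z
#' scale and never transformed back.
#'
#' @param r correlation value(s), strictly inside (-1, 1).
#' @param z Fisher-z value(s).
#' @return transformed numeric vector.
#' @export
variance_stabilize <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("correlations must be finite and strictly inside (-1, 1)")
  }
  atanh(r)
}

#' @rdname variance_stabilize
#' @export
variance_unstabilize <- function(z) {
  if (any(!is.finite(z))) stop("z values must be finite")
  tanh(z)
}

#' Construct a subject connectivity matrix
#'
#' A symmetric parcel-by-parcel matrix of variance-stabilized (Fisher z)
#' correlations, keyed by parcel id. Asymmetry beyond `tol` is an error —
#' never silently symmetrized — and the diagonal is ignored by every
#' summary.
#'
#' @param values square numeric matrix.
#' @param parcel_ids parcel ids for the rows/columns; defaults to integer
#'   dimnames of `values`.
#' @param tol symmetry tolerance.
#' @return a `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, parcel_ids = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (is.null(parcel_ids)) {
    if (is.null(rownames(values))) stop("parcel ids required")
    parcel_ids <- as.integer(rownames(values))
  }
  if (length(parcel_ids) != nrow(values)) {
    stop("parcel_ids length must match matrix dimension")
  }
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off))) {
    stop("non-finite off-diagonal connectivity values")
  }
  if (max(abs(values - t(values))) > tol) {
    stop("connectivity matrix is asymmetric beyond tolerance ", tol)
  }
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(values, parcel_ids = as.integer(parcel_ids),
            class = c("connectivity_matrix", "matrix"))
}

#' @rdname connectivity_matrix
#' @param path dense square TSV with parcel-id header row and first column.
#' @export
read_connectivity_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  connectivity_matrix(as.matrix(tab), parcel_ids = as.integer(rownames(tab)))
}

# rows/cols of m for the parcels mapped to net, with presence checks
matrix_indices <- function(m, map, net) {
  ids <- network_parcels(map, net)
  pos <- match(ids, attr(m, "parcel_ids"))
  if (anyNA(pos)) {
    stop("parcel(s) in map missing from matrix: ",
         paste(ids[is.na(pos)], collapse = ", "))
  }
  pos
}

#' Mean connectivity within one network
#'
#' Mean of the k(k-1)/2 unique off-diagonal entries among the parcels of
#' one network (diagonal excluded).
#'
#' @param m a [connectivity_matrix()].
#' @param map a network-parcel map from [assign_parcels()].
#' @param net network key.
#' @return scalar mean z connectivity.
#' @export
within_network_mean <- function(m, map, net) {
  pos <- matrix_indices(m, map, net)
  if (length(pos) < 2) {
    stop("network ", net, " has fewer than 2 parcels in the matrix")
  }
  sub <- unclass(m)[pos, pos, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Mean connectivity between two networks
#'
#' Mean over all k_a x k_b cross pairs between two distinct networks.
#'
#' @inheritParams within_network_mean
#' @param a,b distinct network keys.
#' @return scalar mean z connectivity.
#' @export
between_network_mean <- function(m, map, a, b) {
  if (identical(a, b)) {
    stop("a and b must differ; use within_network_mean() for one network")
  }
  pa <- matrix_indices(m, map, a)
  pb <- matrix_indices(m, map, b)
  if (length(pa) == 0 || length(pb) == 0) stop("empty network in matrix")
  mean(unclass(m)[pa, pb, drop = FALSE])
}

#' Ten-feature connectivity summary of one subject
#'
#' Reduces a parcel-level matrix to the fixed-order feature vector: four
#' within-network means (`ERN1`..`ERN4`) then six between-network means
#' (`ERN12`..`ERN34`).
#'
#' @inheritParams within_network_mean
#' @return named numeric vector of length 10 in [feature_keys()] order.
#' @export
extract_features <- function(m, map) {
  keys <- feature_keys()
  out <- setNames(numeric(length(keys)), keys)
  for (key in keys) {
    if (feature_kind(key) == "within") {
      out[key] <- within_network_mean(m, map, key)
    } else {
      nets <- between_pair(key)
      out[key] <- between_network_mean(m, map, nets[1], nets[2])
    }
  }
  out
}

#' Extract features for a set of subjects
#'
#' @param matrices named list of [connectivity_matrix()] objects (names are
#'   subject ids), or a directory of `<subject>.tsv` matrix files.
#' @param map a network-parcel map.
#' @return data frame with `subject_id` and the 10 feature columns.
#' @export
extract_features_table <- function(matrices, map) {
  if (is.character(matrices) && length(matrices) == 1) {
    files <- list.files(matrices, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0) stop("no .tsv matrices found in ", matrices)
    matrices <- setNames(lapply(files, read_connectivity_matrix),
                         sub("\\.tsv$", "", basename(files)))
  }
  feats <- t(vapply(matrices, extract_features, numeric(10), map = map))
  out <- data.frame(subject_id = names(matrices), feats, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}
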