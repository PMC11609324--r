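test_that("sphere membership follows the voxel-centre rule", {
  vol1 <- label_volume(array(1L, dim = c(15, 15, 15)), diag(4))
  # radius 0 at a voxel centre is exactly that voxel
  vx <- sphere_voxels(c(7, 7, 7), 0, vol1)
  expect_equal(nrow(vx), 1L)
  expect_equal(as.vector(vx), c(7L, 7L, 7L))

  # 1 mm isotropic grid, radius 6: count equals the exhaustive number of
  # integer lattice points with x^2 + y^2 + z^2 <= 36
  lattice <- expand.grid(x = -6:6, y = -6:6, z = -6:6)
  k_expected <- sum(lattice$x^2 + lattice$y^2 + lattice$z^2 <= 36)
  expect_equal(nrow(sphere_voxels(c(7, 7, 7), 6, vol1)), k_expected)

  # 2 mm grid: brute-force per-voxel check
  aff2 <- diag(c(2, 2, 2, 1))
  vol2 <- label_volume(array(1L, dim = c(15, 15, 15)), aff2)
  center <- c(14, 14, 14)
  vx2 <- sphere_voxels(center, 6, vol2)
  all_idx <- as.matrix(expand.grid(i = 0:14, j = 0:14, k = 0:14))
  mm <- all_idx * 2
  inside <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
    (mm[, 3] - center[3])^2 <= 36
  expect_equal(nrow(vx2), sum(inside))
})

test_that("sphere voxel sets grow monotonically with radius", {
  vol <- label_volume(array(1L, dim = c(12, 12, 12)), diag(c(2, 2, 2, 1)))
  center <- c(10, 10, 10)
  prev <- character(0)
  for (r in c(0, 2, 4, 6, 8)) {
    vx <- sphere_voxels(center, r, vol)
    keys <- apply(vx, 1, paste, collapse = ",")
    expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("spheres fully off the grid return no voxels with a warning", {
  vol <- label_volume(array(1L, dim = c(10, 10, 10)), diag(4))
  expect_warning(vx <- sphere_voxels(c(100, 100, 100), 3, vol),
                 "outside|no in-grid")
  expect_equal(nrow(vx), 0L)
})

test_that("overlap tallies match trivial and straddling constructions", {
  # whole grid one parcel: every network's count is its ROI voxel total
  vol <- label_volume(array(1L, dim = c(20, 20, 20)), diag(4))
  nets <- data.frame(network = c("ERN1", "ERN2"),
                     label = c("a", "b"), x = c(5, 14), y = c(5, 14),
                     z = c(5, 14), stringsAsFactors = FALSE)
  ov <- compute_overlap(nets, vol, mode = "peak", radius_mm = 3)
  expect_equal(nrow(ov), 2L)
  k3 <- nrow(sphere_voxels(c(5, 5, 5), 3, vol))
  expect_equal(ov$voxel_count, c(k3, k3))

  # two-parcel half split, sphere straddling the boundary: counts sum to
  # the sphere's voxel count
  grid <- array(1L, dim = c(20, 20, 20))
  grid[11:20, , ] <- 2L
  vol2 <- label_volume(grid, diag(4))
  nets2 <- data.frame(network = "ERN1", label = "straddle", x = 9.5,
                      y = 10, z = 10, stringsAsFactors = FALSE)
  ov2 <- compute_overlap(nets2, vol2, mode = "peak", radius_mm = 4)
  expect_equal(sum(ov2$voxel_count),
               nrow(sphere_voxels(c(9.5, 10, 10), 4, vol2)))
  expect_equal(sort(ov2$parcel_id), c(1L, 2L))
})

test_that("peaks landing in background are dropped with a warning", {
  grid <- array(0L, dim = c(20, 20, 20))
  grid[1:4, 1:4, 1:4] <- 1L
  vol <- label_volume(grid, diag(4))
  nets <- data.frame(network = c("ERN1", "ERN2"), label = c("in", "out"),
                     x = c(1, 15), y = c(1, 15), z = c(1, 15),
                     stringsAsFactors = FALSE)
  expect_warning(ov <- compute_overlap(nets, vol, radius_mm = 1),
                 "background")
  expect_equal(unique(ov$network_id), "ERN1")
})

test_that("overlap equals the exhaustive per-voxel oracle on random toys", {
  for (s in 1:5) {
    toy <- simulate_label_volume(dims = c(14, 14, 14), n_parcels = 5,
                                 voxel_mm = 2, seed = s)
    ov <- compute_overlap(toy$nets, toy$vol, radius_mm = 5)
    ref <- brute_overlap(toy$nets, toy$vol, 5)
    o1 <- ov[order(ov$network_id, ov$parcel_id), ]
    o2 <- ref[order(ref$network_id, ref$parcel_id), ]
    expect_equal(o1$voxel_count, o2$voxel_count)
    expect_equal(o1$parcel_id, o2$parcel_id)
  }
})

test_that("overlap is invariant to a common translation of affine and peaks", {
  toy <- simulate_label_volume(dims = c(16, 16, 16), n_parcels = 6,
                               voxel_mm = 2, seed = 9)
  shift <- c(13.5, -7, 22)
  vol2 <- toy$vol
  vol2$affine[1:3, 4] <- vol2$affine[1:3, 4] + shift
  nets2 <- toy$nets
  nets2$x <- nets2$x + shift[1]
  nets2$y <- nets2$y + shift[2]
  nets2$z <- nets2$z + shift[3]
  ov1 <- compute_overlap(toy$nets, toy$vol, radius_mm = 5)
  ov2 <- compute_overlap(nets2, vol2, radius_mm = 5)
  expect_equal(ov1$voxel_count, ov2$voxel_count)
  expect_equal(ov1$parcel_id, ov2$parcel_id)
})

test_that("quartile and fixed filters drop the documented rows", {
  tab <- data.frame(network_id = rep("ERN1", 4), parcel_id = 1:4,
                    voxel_count = c(2L, 5L, 8L, 11L),
                    stringsAsFactors = FALSE)
  class(tab) <- c("overlap_table", "data.frame")
  # type-7 Q1 of {2,5,8,11} is 4.25, so only the count-2 row goes
  f <- filter_overlap(tab, rule = "quartile")
  expect_equal(f$voxel_count, c(5L, 8L, 11L))
  expect_equal(attr(f, "threshold"), 4.25)
  # fixed rule at 5: counts <= 5 go
  f2 <- filter_overlap(tab, rule = "fixed", fixed_min = 5)
  expect_equal(f2$voxel_count, c(8L, 11L))
  # all counts equal: quartile would empty every network
  tab3 <- tab
  tab3$voxel_count <- rep(7L, 4)
  expect_error(filter_overlap(tab3, rule = "quartile"), "fewer than 2")
  # error names the offending network
  tab4 <- rbind(tab,
                data.frame(network_id = "ERN2", parcel_id = 5:6,
                           voxel_count = c(1L, 2L)))
  class(tab4) <- c("overlap_table", "data.frame")
  expect_error(filter_overlap(tab4, rule = "fixed", fixed_min = 5), "ERN2")
})

test_that("parcel assignment keeps the largest overlap and breaks ties low", {
  tab <- data.frame(
    network_id = c("ERN1", "ERN3", "ERN1", "ERN1", "ERN3", "ERN3"),
    parcel_id = c(7L, 7L, 1L, 2L, 3L, 4L),
    voxel_count = c(10L, 3L, 8L, 9L, 7L, 6L), stringsAsFactors = FALSE)
  class(tab) <- c("overlap_table", "data.frame")
  map <- assign_parcels(tab)
  expect_equal(map$network_id[map$parcel_id == 7], "ERN1")

  # exact tie goes to the lower network index, with a warning
  tie <- tab
  tie$voxel_count[2] <- 10L
  expect_warning(map2 <- assign_parcels(tie), "equally")
  expect_equal(map2$network_id[map2$parcel_id == 7], "ERN1")

  # disjoint overlaps: assignment is the identity, in any row order
  dis <- tab[-(1:2), ]
  set.seed(3)
  shuffled <- dis[sample(nrow(dis)), ]
  class(shuffled) <- c("overlap_table", "data.frame")
  m1 <- assign_parcels(dis)
  m2 <- assign_parcels(shuffled)
  expect_equal(m1$parcel_id, m2$parcel_id)
  expect_equal(m1$network_id, m2$network_id)
  expect_equal(m1$network_id, dis$network_id[order(dis$parcel_id)])
  # a parcel never sits under two networks
  expect_false(any(duplicated(m1$parcel_id)))
})

test_that("network definitions parse, validate, and the packaged table has 36 ROIs", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("network\tlabel\tx\ty\tz",
               "ERN1\tfoo\t-20\t30\t44", "ERN2\tbar\t50\t26\t6",
               "ERN3\tbaz\t-22\t-4\t-18", "ERN4\tqux\t-44\t-26\t50"), tmp)
  def <- load_network_definition(tmp)
  expect_equal(nrow(def), 4L)
  expect_equal(def$label, c("foo", "bar", "baz", "qux"))

  packaged <- load_network_definition(
    system.file("extdata", "ern_networks_synthetic.tsv", package = "ernfc"))
  expect_equal(nrow(packaged), 36L)
  expect_setequal(unique(packaged$network), network_keys())

  writeLines(c("network\tlabel\tx\ty\tz", "ERN5\tnope\t0\t0\t0"), tmp)
  expect_error(load_network_definition(tmp), "unknown network")
  writeLines(c("network\tlabel\tx\ty", "ERN1\tfoo\t0\t0"), tmp)
  expect_error(load_network_definition(tmp), "missing column")
  writeLines(c("network\tlabel\tx\ty\tz", "ERN1\tfoo\t0\tNA\t0"), tmp)
  expect_error(load_network_definition(tmp), "coordinate")
})

test_that("cluster-mode mapping accepts resampled masks", {
  toy <- simulate_label_volume(dims = c(12, 12, 12), n_parcels = 4,
                               voxel_mm = 2, seed = 21)
  # build a mask around each peak on a finer 1 mm grid
  nets <- toy$nets
  nets$cluster_mask <- lapply(seq_len(nrow(nets)), function(r) {
    g <- array(0L, dim = c(24, 24, 24))
    aff <- diag(c(1, 1, 1, 1))
    aff[1:3, 4] <- toy$vol$affine[1:3, 4]
    mvol <- label_volume(g, aff)
    vx <- sphere_voxels(c(nets$x[r], nets$y[r], nets$z[r]), 3, mvol)
    g[vx + 1L] <- 1L   # single-voxel-column indexing needs linear index
    lin <- vx[, 1] + 24 * (vx[, 2] + 24 * vx[, 3]) + 1
    g <- array(0L, dim = c(24, 24, 24))
    g[lin] <- 1L
    label_volume(g, aff)
  })
  ov <- compute_overlap(nets, toy$vol, mode = "cluster")
  expect_gt(nrow(ov), 0)
  expect_true(all(ov$voxel_count >= 1))
  # missing mask errors
  nets$cluster_mask[2] <- list(NULL)
  expect_error(compute_overlap(nets, toy$vol, mode = "cluster"),
               "cluster mode requires")
})
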