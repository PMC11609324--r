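#!/usr/bin/env Rscript
# Stage 1 - map the four emotion-regulation networks onto a parcellation.
#
# The packaged 36-ROI definition (synthetic peak coordinates, see the
# package docs) is mapped onto a synthetic MNI-space label volume via 6 mm
# peak spheres, weak overlaps are dropped at the pooled first quartile,
# and each parcel is assigned to the network with the largest overlap.

suppressPackageStartupMessages(library(ernfc))
dir.create("results", showWarnings = FALSE)

nets <- load_network_definition(
  system.file("extdata", "ern_networks_synthetic.tsv", package = "ernfc"))
cat(sprintf("network definition: %d ROIs across %d networks\n",
            nrow(nets), length(unique(nets$network))))

# synthetic whole-brain-sized label volume: 60 contiguous parcels on a
# 4 mm grid whose affine covers the MNI bounding box
toy <- simulate_label_volume(dims = c(46, 55, 46), n_parcels = 60,
                             voxel_mm = 4, seed = 101)

overlap <- compute_overlap(nets, toy$vol, mode = "peak", radius_mm = 6)
cat(sprintf("raw overlap: %d (network, parcel) pairs, %d background voxels\n",
            nrow(overlap), attr(overlap, "background_voxels")))

filtered <- filter_overlap(overlap, rule = "quartile")
cat(sprintf("quartile filter at <= %.2f voxels kept %d pairs\n",
            attr(filtered, "threshold"), nrow(filtered)))

map <- assign_parcels(filtered)
print(table(map$network_id))
write_tsv_table(map, "results/network_parcel_map.tsv")
cat("wrote results/network_parcel_map.tsv\n")
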