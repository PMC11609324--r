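#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates every stage end to end on generated data: toy atlas +
#' network definition, network-to-parcel mapping, per-subject connectivity
#' (optionally full matrices fed through feature extraction),
#' harmonization, the association grid, and the mediation grid. Each stage
#' writes a plain TSV with a header into `out_dir` and never mutates its
#' inputs; a JSON manifest (config echo, seeds, package version, row
#' counts) is written last and suffices to reproduce the run. With
#' `skip_existing = TRUE` stages whose output file already exists are
#' loaded instead of recomputed.
#'
#' @param out_dir output directory (created if missing).
#' @param cfg a [sim_config()].
#' @param B bootstrap iterations for the association grid and Monte-Carlo
#'   draws for mediation.
#' @param seed pipeline seed; overrides `cfg$seed`.
#' @param mode connectivity emission mode, `"features"` or `"matrices"`
#'   (the latter exercises atlas mapping and feature extraction).
#' @param atlas list of toy-atlas parameters: `dims`, `n_parcels`,
#'   `voxel_mm`, `radius`, `rule`, `fixed_min`.
#' @param adjust_baseline pass-through to [run_mediation_grid()].
#' @param fdr FDR family, `"pooled"` or `"per_scale"`.
#' @param engine model engine for both grids.
#' @param skip_existing reuse stage outputs already present in `out_dir`.
#' @return invisibly, a list with all stage objects and the manifest.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), B = 1000,
                         seed = cfg$seed, mode = c("features", "matrices"),
                         atlas = list(dims = c(20, 20, 20), n_parcels = 12,
                                      voxel_mm = 2, radius = 4,
                                      rule = "fixed", fixed_min = 5),
                         adjust_baseline = FALSE, fdr = "pooled",
                         engine = "fast", skip_existing = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg$seed <- seed
  counts <- list()
  stage_file <- function(name) file.path(out_dir, name)
  run_stage <- function(name, file, compute, write, read) {
    path <- stage_file(file)
    if (skip_existing && file.exists(path)) {
      message("pipeline: reusing ", name, " from ", path)
      return(read(path))
    }
    obj <- tryCatch(compute(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    write(obj, path)
    obj
  }

  toy <- simulate_label_volume(dims = atlas$dims,
                               n_parcels = atlas$n_parcels,
                               voxel_mm = atlas$voxel_mm,
                               seed = derive_seed(seed, 1L))
  map <- run_stage(
    "map-atlas", "network_parcel_map.tsv",
    compute = function() {
      map_networks_to_parcels(toy$nets, toy$vol, mode = "peak",
                              radius_mm = atlas$radius, rule = atlas$rule,
                              fixed_min = atlas$fixed_min)
    },
    write = function(obj, path) write_tsv_table(obj, path),
    read = function(path) {
      tab <- read_tsv_table(path)
      class(tab) <- c("network_parcel_map", "data.frame")
      tab
    })
  counts$parcels_retained <- nrow(map)

  cohort <- run_stage(
    "simulate", "pheno.tsv",
    compute = function() simulate_cohort(cfg),
    write = write_tsv_table, read = read_tsv_table)
  counts$subjects <- nrow(cohort)
  counts$families <- length(unique(cohort$family_id))

  features <- run_stage(
    "extract", "features.tsv",
    compute = function() {
      if (mode == "matrices") {
        sim <- simulate_connectivity(cohort, cfg, mode = "matrices",
                                     map = map)
        feats <- extract_features_table(sim$matrices, map)
        merge(sim$cohort[, setdiff(names(sim$cohort), feature_keys())],
              feats, by = "subject_id", sort = FALSE)
      } else {
        simulate_connectivity(cohort, cfg, mode = "features")
      }
    },
    write = write_tsv_table, read = read_tsv_table)

  harmonized <- run_stage(
    "harmonize", "features_harmonized.tsv",
    compute = function() harmonize_features(features),
    write = function(obj, path) {
      write_tsv_table(obj, path)
      model <- attr(obj, "combat_model")
      if (!is.null(model)) {
        write_combat_model(model, stage_file("combat_model.json"))
      }
    },
    read = read_tsv_table)

  assoc <- run_stage(
    "associate", "associations.tsv",
    compute = function() {
      run_association_grid(harmonized, B = B, seed = derive_seed(seed, 2L),
                           fdr = fdr, engine = engine)
    },
    write = write_tsv_table, read = read_tsv_table)
  counts$association_rows <- nrow(assoc)

  med <- run_stage(
    "mediate", "mediation.tsv",
    compute = function() {
      run_mediation_grid(harmonized, adjust_baseline = adjust_baseline,
                         B = B, seed = derive_seed(seed, 3L), fdr = fdr,
                         engine = engine)
    },
    write = write_tsv_table, read = read_tsv_table)
  counts$mediation_rows <- nrow(med)

  manifest <- list(
    package = "ernfc",
    version = as.character(utils::packageVersion("ernfc")),
    seed = seed, B = B, mode = mode, fdr = fdr, engine = engine,
    adjust_baseline = adjust_baseline, atlas = atlas, counts = counts,
    config = unclass(cfg)[setdiff(names(cfg), "mediation")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, stage_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(map = map, cohort = cohort, features = features,
                 harmonized = harmonized, associations = assoc,
                 mediation = med, manifest = manifest))
}
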