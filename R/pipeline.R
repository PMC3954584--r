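#' Pipeline configuration
#'
#' Bundles every stage default into one serializable list: preprocessing
#' (threshold rule, canonical frame), feature extraction, KNN and naive
#' Bayes settings. Round-trips through JSON unchanged.
#'
#' @param manifest Path to the label manifest CSV.
#' @param out_dir Output directory for the report bundle.
#' @param threshold_rule `"half_mean"` or `"mean"` for [artifact_mask()].
#' @param mask_first Mask before geometry standardization.
#' @param target_side,target_pixel_um Canonical frame.
#' @param abs_coeffs Moments on absolute DCT coefficients.
#' @param knn_k,knn_subset_size,knn_distance_weighting,knn_prior_weighting
#'   KNN stage settings (`knn_k = NULL` sweeps 1..25 via [knn_search()]).
#' @param nb_bins,nb_subset_size,nb_allowed_misses Naive Bayes settings.
#' @param seed Seed for any stochastic stage.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(manifest, out_dir,
                            threshold_rule = "half_mean", mask_first = TRUE,
                            target_side = 1024L, target_pixel_um = 200,
                            abs_coeffs = FALSE,
                            knn_k = NULL, knn_subset_size = 3L,
                            knn_distance_weighting = FALSE,
                            knn_prior_weighting = TRUE,
                            nb_bins = 12L, nb_subset_size = 1L,
                            nb_allowed_misses = 0L, seed = 1L) {
  structure(list(manifest = manifest, out_dir = out_dir,
                 threshold_rule = threshold_rule, mask_first = mask_first,
                 target_side = as.integer(target_side),
                 target_pixel_um = target_pixel_um, abs_coeffs = abs_coeffs,
                 knn_k = knn_k, knn_subset_size = as.integer(knn_subset_size),
                 knn_distance_weighting = knn_distance_weighting,
                 knn_prior_weighting = knn_prior_weighting,
                 nb_bins = as.integer(nb_bins),
                 nb_subset_size = as.integer(nb_subset_size),
                 nb_allowed_misses = as.integer(nb_allowed_misses),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the whole triage pipeline
#'
#' Executes the four stages in order — preprocess, transform/extract,
#' classify (KNN and naive Bayes), report — and writes a bundle to
#' `config$out_dir`: `features.csv`, `knn_report.json`, `bayes_report.json`,
#' `bayes_roc.csv` and `config.json`. Feature extraction is cached: if a
#' `features_<hash>.csv` matching the manifest content and the extraction
#' settings already exists in `out_dir` it is reused, which lets the
#' subset searches rerun without re-transforming images.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `knn` (search tibble), `bayes`
#'   (report), `roc` (sweep tibble) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  man <- stage("preprocess", read_manifest(config$manifest))
  feats <- stage("extract", cached_features(man, config))
  feat_path <- file.path(config$out_dir, "features.csv")
  utils::write.csv(feats, feat_path, row.names = FALSE)

  cfg <- knn_config(k = config$knn_k %||% 2L,
                    distance_weighting = config$knn_distance_weighting,
                    prior_weighting = config$knn_prior_weighting)
  knn_res <- stage("classify_knn",
                   knn_search(feats, subset_size = config$knn_subset_size,
                              k_range = if (is.null(config$knn_k)) 1:25
                                        else config$knn_k,
                              cfg = cfg))

  nb_res <- stage("classify_bayes", {
    srch <- nb_search(feats, subset_size = config$nb_subset_size,
                      n_bins = config$nb_bins,
                      allowed_misses = config$nb_allowed_misses, top = 1)
    pp <- nb_loocv(feats, srch$subset[[1]], n_bins = config$nb_bins)
    list(search = srch, pp = pp,
         report = nb_report(pp, nb_threshold(pp, config$nb_allowed_misses)))
  })
  roc <- stage("report", roc_sweep(nb_res$pp))

  snap <- unclass(config)
  write_json <- function(x, file) {
    jsonlite::write_json(x, file.path(config$out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  write_json(list(config = snap,
                  per_k = lapply(seq_len(nrow(knn_res)), function(i) list(
                    k = knn_res$k[i], subset = knn_res$subset[[i]],
                    sensitivity = knn_res$sensitivity[i],
                    specificity = knn_res$specificity[i]))),
             "knn_report.json")
  write_json(list(config = snap,
                  subset = nb_res$search$subset[[1]],
                  threshold = nb_res$search$threshold[1],
                  metrics = as.list(glance(nb_res$report))),
             "bayes_report.json")
  utils::write.csv(roc, file.path(config$out_dir, "bayes_roc.csv"),
                   row.names = FALSE)
  write_json(snap, "config.json")

  invisible(list(features = feats, knn = knn_res, bayes = nb_res$report,
                 roc = roc, out_dir = config$out_dir))
}

cached_features <- function(man, config) {
  key <- rlang::hash(list(
    sums = vapply(man$path, function(p) unname(tools::md5sum(p)), character(1)),
    ids = man$source_id, labels = man$label,
    side = config$target_side, um = config$target_pixel_um,
    rule = config$threshold_rule, mask_first = config$mask_first,
    abs = config$abs_coeffs))
  cache <- file.path(config$out_dir, paste0("features_", key, ".csv"))
  if (file.exists(cache)) {
    return(tibble::as_tibble(utils::read.csv(cache, stringsAsFactors = FALSE)))
  }
  recs <- purrr::pmap(man, function(source_id, path, pixel_size_um, label, ...) {
    read_image(path, pixel_size_um, label = label, source_id = source_id)
  })
  recs <- purrr::map(recs, preprocess_image, rule = config$threshold_rule,
                     target_pixel_um = config$target_pixel_um,
                     target_side = config$target_side,
                     mask_first = config$mask_first)
  feats <- feature_table(recs, preprocess = FALSE,
                         abs_coeffs = config$abs_coeffs)
  utils::write.csv(feats, cache, row.names = FALSE)
  feats
}
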