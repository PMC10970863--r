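#' Batch run configuration
#'
#' Collects every tunable of the batch pipeline in one validated record,
#' persisted as YAML next to the outputs for provenance.
#'
#' @param metadata path to a metadata CSV with columns `sample_id`,
#'   `condition` (IS/OOS), `image_path` and optionally `weight_g`.
#' @param out_dir output directory (created if missing).
#' @param sweep_start,sweep_stop,sweep_step binarization threshold sweep.
#' @param glcm_d,glcm_ng GLCM pixel distance and gray-level count.
#' @param entropy_base entropy logarithm base.
#' @param scale_range optional box-size band (pixels) for FD summaries.
#' @param um_per_px spatial calibration.
#' @param pca_components components to retain in PCA reports (`NULL` =
#'   full rank).
#' @param summary_thresholds thresholds reported in the per-sample FD
#'   summary table.
#' @param seed integer seed for stochastic stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(metadata = NULL, out_dir = "powdertex_out",
                       sweep_start = 0, sweep_stop = 255, sweep_step = 5,
                       glcm_d = 1, glcm_ng = 256, entropy_base = exp(1),
                       scale_range = NULL, um_per_px = 1.7,
                       pca_components = NULL,
                       summary_thresholds = c(50, 90, 135, 180, 205, 230),
                       seed = 1) {
  if (sweep_start > sweep_stop || sweep_step < 1) {
    stop("invalid threshold sweep")
  }
  if (glcm_d < 1 || glcm_ng < 2 || glcm_ng > 256) {
    stop("invalid GLCM parameters")
  }
  if (um_per_px <= 0) stop("um_per_px must be positive")
  structure(list(metadata = metadata, out_dir = out_dir,
                 sweep_start = sweep_start, sweep_stop = sweep_stop,
                 sweep_step = sweep_step, glcm_d = glcm_d,
                 glcm_ng = glcm_ng, entropy_base = entropy_base,
                 scale_range = scale_range, um_per_px = um_per_px,
                 pca_components = pca_components,
                 summary_thresholds = summary_thresholds,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write a run configuration as YAML
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

.read_metadata <- function(config) {
  if (is.null(config$metadata)) stop("config has no metadata path")
  md <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "image_path")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(md) == 0L) stop("metadata table is empty")
  md
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

# load every image in the metadata table, recording a manifest of outcomes
.load_batch <- function(md) {
  images <- vector("list", nrow(md))
  manifest <- data.frame(image_path = md$image_path,
                         sample_id = md$sample_id,
                         status = "ok", message = "",
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(md))) {
    res <- tryCatch(load_image(md$image_path[i]), error = identity)
    if (inherits(res, "error")) {
      manifest$status[i] <- "skipped"
      manifest$message[i] <- conditionMessage(res)
    } else {
      images[[i]] <- res
    }
  }
  list(images = images, manifest = manifest)
}

#' Batch fractal-dimension analysis
#'
#' For every readable image in the metadata table: the FD-vs-threshold
#' signature; then per-sample mean curves (unweighted mean over the sample's
#' images at each threshold) and a per-sample summary table of mean FD and
#' its standard deviation at the configured report thresholds. Unreadable
#' images are logged in the manifest and skipped; the run fails only if no
#' image is readable.
#'
#' @param config a [run_config()] with a `metadata` path.
#' @return Invisibly, a list with `per_image` (long data frame), `per_sample`
#'   (threshold x sample mean-FD matrix as a long data frame), `summary`
#'   (per-sample FD / Std FD at report thresholds), `manifest`, and the
#'   output file paths. CSVs and the config YAML are written to
#'   `config$out_dir`.
#' @export
run_fd <- function(config) {
  stopifnot(inherits(config, "run_config"))
  md <- .read_metadata(config)
  batch <- .load_batch(md)
  if (all(batch$manifest$status != "ok")) {
    stop("no readable images in batch")
  }
  out_dir <- .ensure_dir(config$out_dir)
  per_image <- do.call(rbind, lapply(seq_len(nrow(md)), function(i) {
    if (batch$manifest$status[i] != "ok") return(NULL)
    cur <- fd_threshold_curve(batch$images[[i]],
                              start = config$sweep_start,
                              stop = config$sweep_stop,
                              step = config$sweep_step,
                              scale_range = config$scale_range)
    data.frame(image_path = md$image_path[i], sample_id = md$sample_id[i],
               condition = md$condition[i], cur)
  }))
  per_sample <- stats::aggregate(
    cbind(mean_fd, std_fd) ~ sample_id + condition + threshold,
    data = per_image, FUN = mean)
  per_sample <- per_sample[order(per_sample$sample_id,
                                 per_sample$threshold), ]
  summary_tab <- per_sample[per_sample$threshold %in%
                              config$summary_thresholds, ]
  paths <- list(
    per_image = file.path(out_dir, "fd_per_image.csv"),
    per_sample = file.path(out_dir, "fd_per_sample.csv"),
    summary = file.path(out_dir, "fd_summary.csv"),
    manifest = file.path(out_dir, "manifest_fd.csv"),
    config = file.path(out_dir, "config_fd.yaml"))
  utils::write.csv(per_image, paths$per_image, row.names = FALSE)
  utils::write.csv(per_sample, paths$per_sample, row.names = FALSE)
  utils::write.csv(summary_tab, paths$summary, row.names = FALSE)
  utils::write.csv(batch$manifest, paths$manifest, row.names = FALSE)
  write_run_config(config, paths$config)
  invisible(list(per_image = per_image, per_sample = per_sample,
                 summary = summary_tab, manifest = batch$manifest,
                 paths = paths))
}

#' Batch Haralick texture analysis
#'
#' Per-image four-direction descriptors, aggregated image -> sample ->
#' condition by unweighted means (see [aggregate_haralick()]). Tables at all
#' three levels are written as CSVs with 3-decimal half-up rounding; the
#' returned data frames keep full precision.
#'
#' @param config a [run_config()].
#' @return Invisibly: `per_image`, `per_sample`, `per_condition` (long data
#'   frames), `manifest`, `paths`.
#' @export
run_texture <- function(config) {
  stopifnot(inherits(config, "run_config"))
  md <- .read_metadata(config)
  batch <- .load_batch(md)
  if (all(batch$manifest$status != "ok")) {
    stop("no readable images in batch")
  }
  out_dir <- .ensure_dir(config$out_dir)
  feats <- lapply(seq_len(nrow(md)), function(i) {
    if (batch$manifest$status[i] != "ok") return(NULL)
    haralick_all_directions(batch$images[[i]], D = config$glcm_d,
                            Ng = config$glcm_ng,
                            entropy_base = config$entropy_base)
  })
  ok <- !vapply(feats, is.null, logical(1))
  per_image <- do.call(rbind, lapply(which(ok), function(i) {
    data.frame(image_path = md$image_path[i], sample_id = md$sample_id[i],
               condition = md$condition[i], feats[[i]])
  }))
  sample_ids <- unique(md$sample_id[ok])
  per_sample <- do.call(rbind, lapply(sample_ids, function(s) {
    idx <- which(ok & md$sample_id == s)
    agg <- aggregate_haralick(feats[idx], level = "sample")
    data.frame(sample_id = s, condition = md$condition[idx[1]], agg,
               n_images = length(idx))
  }))
  conds <- unique(per_sample$condition)
  per_condition <- do.call(rbind, lapply(conds, function(cc) {
    rows <- per_sample[per_sample$condition == cc, ]
    tabs <- lapply(unique(rows$sample_id), function(s) {
      r <- rows[rows$sample_id == s, ]
      structure(r[, c("feature", "deg0", "deg45", "deg90", "deg135", "mu")],
                class = c("haralick_features", "data.frame"))
    })
    agg <- aggregate_haralick(tabs, level = "condition")
    data.frame(condition = cc, agg, n_samples = length(tabs))
  }))
  paths <- list(per_image = file.path(out_dir, "haralick_per_image.csv"),
                per_sample = file.path(out_dir, "haralick_per_sample.csv"),
                per_condition = file.path(out_dir, "haralick_per_condition.csv"),
                manifest = file.path(out_dir, "manifest_texture.csv"),
                config = file.path(out_dir, "config_texture.yaml"))
  num <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col))
      round_half_up(col, 3) else col)
    df
  }
  utils::write.csv(num(per_image), paths$per_image, row.names = FALSE)
  utils::write.csv(num(per_sample), paths$per_sample, row.names = FALSE)
  utils::write.csv(num(per_condition), paths$per_condition, row.names = FALSE)
  utils::write.csv(batch$manifest, paths$manifest, row.names = FALSE)
  write_run_config(config, paths$config)
  invisible(list(per_image = per_image, per_sample = per_sample,
                 per_condition = per_condition, manifest = batch$manifest,
                 paths = paths))
}

#' PCA report over a per-sample curve matrix
#'
#' Assembles a samples x variables matrix from a long per-sample table (one
#' row per sample and variable value, e.g. the output of [run_fd()]),
#' autoscales it, fits PCA, and writes scores (with condition labels),
#' loadings, explained variance, per-group 95% ellipse parameters and a
#' PC1 separation summary.
#'
#' @param config a [run_config()].
#' @param per_sample long data frame with columns `sample_id`, `condition`,
#'   a variable column and a value column; or the path of such a CSV.
#' @param variable,value names of the variable and value columns (defaults
#'   `"threshold"` and `"mean_fd"`, matching [run_fd()] output).
#' @return Invisibly: `model` ([fit_pca()] result), `report`
#'   ([separation_report()]), `ellipses`, `labels`, `paths`.
#' @export
run_pca <- function(config, per_sample, variable = "threshold",
                    value = "mean_fd") {
  stopifnot(inherits(config, "run_config"))
  if (is.character(per_sample)) {
    per_sample <- utils::read.csv(per_sample, stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "condition", variable, value)
  if (!all(need %in% names(per_sample))) {
    stop("per-sample table must have columns: ", paste(need, collapse = ", "))
  }
  wide <- stats::reshape(
    per_sample[, need], direction = "wide",
    idvar = c("sample_id", "condition"), timevar = variable)
  X <- as.matrix(wide[, -(1:2), drop = FALSE])
  colnames(X) <- sub(paste0("^", value, "\\."), "", colnames(X))
  rownames(X) <- wide$sample_id
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples")
  labels <- wide$condition
  sc <- autoscale(X)
  model <- fit_pca(sc, n_components = config$pca_components)
  report <- if (length(unique(labels)) >= 2L) {
    separation_report(model, labels)
  } else NULL
  ell <- if (ncol(model$scores) >= 2L) {
    suppressWarnings(ellipse95(model$scores, labels))
  } else list()
  out_dir <- .ensure_dir(config$out_dir)
  paths <- list(scores = file.path(out_dir, "pca_scores.csv"),
                loadings = file.path(out_dir, "pca_loadings.csv"),
                variance = file.path(out_dir, "pca_variance.csv"))
  utils::write.csv(data.frame(sample_id = rownames(model$scores),
                              condition = labels, model$scores),
                   paths$scores, row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(model$loadings),
                              model$loadings),
                   paths$loadings, row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(model$explained_variance_pct),
                              explained_variance_pct = model$explained_variance_pct),
                   paths$variance, row.names = FALSE)
  invisible(list(model = model, report = report, ellipses = ell,
                 labels = labels, X = X, paths = paths))
}

#' Generate and write a synthetic two-condition image set
#'
#' Runs [synth_ensemble()] for both conditions, writes each image as an
#' 8-bit PNG, a metadata CSV compatible with [run_fd()]/[run_texture()],
#' and a per-sample volume-based PSD table readable by [read_psd_table()].
#'
#' @param config a [run_config()] (uses `out_dir`, `um_per_px`, `seed`).
#' @param n_samples,images_per_sample ensemble shape per condition.
#' @param n_particles particles per image.
#' @param psd_bins PSD bin edges in um.
#' @return Invisibly: `metadata` (data frame), `paths`.
#' @export
run_synth <- function(config, n_samples = 3, images_per_sample = 2,
                      n_particles = 60,
                      psd_bins = c(1, 2, 5, 10, 20, 40, 80, 120, 180, 280, 400)) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- .ensure_dir(config$out_dir)
  img_dir <- .ensure_dir(file.path(out_dir, "images"))
  scene <- scene_spec(um_per_px = config$um_per_px)
  rows <- list(); psd_rows <- list()
  for (cond in c("IS", "OOS")) {
    ens <- synth_ensemble(cond, n_samples = n_samples,
                          images_per_sample = images_per_sample,
                          seed = config$seed, scene = scene,
                          n_particles = n_particles)
    for (s in ens) {
      for (im in seq_along(s$images)) {
        p <- file.path(img_dir, sprintf("%s_I%02d.png", s$sample_id, im))
        write_gray_png(s$images[[im]], p)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s$sample_id, condition = cond, image_path = p,
          weight_g = NA_real_)
      }
      psd <- psd_from_diameters(s$diameters, psd_bins)
      psd_rows[[length(psd_rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, condition = cond, t(psd),
        check.names = FALSE)
    }
  }
  metadata <- do.call(rbind, rows)
  psd_tab <- do.call(rbind, psd_rows)
  paths <- list(metadata = file.path(out_dir, "metadata.csv"),
                psd = file.path(out_dir, "psd.csv"))
  utils::write.csv(metadata, paths$metadata, row.names = FALSE)
  utils::write.csv(psd_tab, paths$psd, row.names = FALSE)
  invisible(list(metadata = metadata, psd = psd_tab, paths = paths))
}
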