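# Study I/O: NIfTI cohorts + CSV manifests, feature tables as CSV with a
# JSON provenance sidecar, and the JSON run configuration.

# atomic write: render to a temp file in the same directory, then rename
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' Emits `<subject>_<sequence>.nii.gz` and
#' `<subject>_<sequence>_<tissue>_mask.nii.gz` per subject plus a
#' `manifest.csv` (subject_id, label, covariates, sequence, tissue, volume
#' and mask paths).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$volumes, function(v) {
    vol_file <- paste0(v$subject_id, "_", v$sequence_tag, ".nii.gz")
    mask_file <- paste0(v$subject_id, "_", v$sequence_tag, "_",
                        v$tissue_tag, "_mask.nii.gz")
    write_nifti(v$intensities, file.path(dir, vol_file), datatype = 64L)
    write_nifti(v$mask, file.path(dir, mask_file), datatype = 2L)
    data.frame(subject_id = v$subject_id, sequence = v$sequence_tag,
               tissue = v$tissue_tag, volume = vol_file, mask = mask_file,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest <- merge(cohort$covariates, manifest, by = "subject_id", sort = FALSE)
  path <- file.path(dir, "manifest.csv")
  write_atomic(path, function(p) write.csv(manifest, p, row.names = FALSE))
  path
}

#' Load a study from a manifest
#'
#' The manifest is a CSV with one row per (subject, sequence, tissue):
#' columns `subject_id`, `label`, `sequence`, `tissue`, `volume`, `mask`
#' (paths relative to the manifest directory or absolute) and optional
#' covariate columns (any other name). Masks are binarised at `> 0`. A
#' shape or affine mismatch between a volume and its mask is an error naming
#' the offending subject.
#'
#' @param manifest_path path to the manifest CSV.
#' @return list with `volumes` (list of [volume_with_mask()]), `labels`
#'   (named integer vector per subject), and `covariates` (data.frame).
#' @export
load_study <- function(manifest_path) {
  if (!file.exists(manifest_path))
    rt_error(paste0("manifest not found: ", manifest_path), "radtex_io_error")
  mf <- read.csv(manifest_path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("subject_id", "label", "sequence", "tissue", "volume", "mask")
  if (!all(need %in% names(mf)))
    rt_error(paste0("manifest must contain columns: ",
                    paste(need, collapse = ", ")), "radtex_io_error")
  if (anyDuplicated(mf[, c("subject_id", "sequence", "tissue")]))
    rt_error("duplicate (subject, sequence, tissue) rows", "radtex_io_error")
  if (!all(mf$label %in% c(0L, 1L)))
    rt_error("labels must be binary 0/1", "radtex_io_error")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  vols <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    sid <- mf$subject_id[i]
    v <- read_nifti(resolve(mf$volume[i]))
    m <- read_nifti(resolve(mf$mask[i]))
    if (!identical(v$dim, m$dim))
      rt_error(paste0("volume/mask shape mismatch for subject ", sid),
               "radtex_shape_mismatch")
    if (max(abs(v$affine - m$affine)) > 1e-4)
      rt_error(paste0("volume/mask affine mismatch for subject ", sid),
               "radtex_affine_mismatch")
    vols[[i]] <- volume_with_mask(v$data, array(as.integer(m$data > 0), m$dim),
                                  subject_id = sid,
                                  sequence_tag = mf$sequence[i],
                                  tissue_tag = mf$tissue[i])
  }
  subj <- unique(mf$subject_id)
  labels <- stats::setNames(
    as.integer(mf$label[match(subj, mf$subject_id)]), subj)
  covcols <- setdiff(names(mf), c(need))
  covariates <- unique(mf[, c("subject_id", "label", covcols), drop = FALSE])
  list(volumes = vols, labels = labels, covariates = covariates)
}

#' Write a feature table as CSV plus JSON sidecar
#'
#' The CSV holds `subject_id`, `label` and one column per feature; the
#' sidecar (`<path>.json`) records column metadata, cleaning provenance and
#' any standardization parameters. A `# config_hash:` comment line prefixes
#' the CSV when a hash is supplied.
#'
#' @param t a [feature_table()].
#' @param path output CSV path.
#' @param extra named list merged into the sidecar (e.g. standardization
#'   parameters).
#' @param config_hash optional hash string embedded in the file header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path, extra = list(), config_hash = NULL) {
  df <- data.frame(subject_id = t$row_ids, label = t$labels,
                   t$matrix, check.names = FALSE, stringsAsFactors = FALSE)
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    if (!is.null(config_hash))
      writeLines(paste0("# config_hash: ", config_hash), con)
    write.csv(df, con, row.names = FALSE)
  })
  side <- c(list(col_info = t$col_info, provenance = as.list(t$provenance)),
            extra)
  write_atomic(paste0(path, ".json"), function(p)
    jsonlite::write_json(side, p, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path the CSV path (expects `<path>.json` alongside).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ci <- as.data.frame(side$col_info, stringsAsFactors = FALSE)
  M <- as.matrix(df[, ci$name, drop = FALSE])
  feature_table(M, df$subject_id, ci, df$label,
                unlist(side$provenance)[ci$name])
}

#' Assemble and extract features for a loaded study
#'
#' Convenience wrapper: runs [extract_volume_features()] on every volume of
#' a [load_study()] result and assembles the [feature_table()].
#'
#' @param study a [load_study()] (or [generate_cohort()]-shaped) list.
#' @param cfg a [texture_config()].
#' @return a [feature_table()].
#' @export
extract_study_features <- function(study, cfg = texture_config()) {
  vectors <- lapply(study$volumes, function(v)
    list(subject = v$subject_id, sequence = v$sequence_tag,
         tissue = v$tissue_tag, fv = extract_volume_features(v, cfg)))
  labels <- study$labels
  if (is.null(names(labels)))
    labels <- stats::setNames(as.integer(labels),
                              vapply(study$volumes, `[[`, "", "subject_id"))
  assemble_table(vectors, labels)
}

default_run_config <- function() {
  list(
    phantom = list(volume_shape = c(32L, 32L, 12L), mask_kind = "blob",
                   mask_fraction = 0.15, base_intensity = 100, noise_sd = 2,
                   smoothing_scale = 0.8, contrast = 10, effect_size = 1,
                   subject_jitter_sd = 0.05, n_per_class = 10L),
    texture = list(Ng = 32L, d = 1L, dwt_levels = 3L,
                   min_mask_pixels = 16L, range_policy = "volume"),
    cleaning = list(nzv_freq_ratio = 19, nzv_unique_pct = 10),
    screening = list(alpha = 0.05, family = "per_dataset"),
    cv = list(k = 5L, R = 10L),
    grid = list(svm_C = 2^(-3:3), rf_mtry = c(2L, 4L, 6L, 8L, 10L, 12L),
                rf_ntree = 250L),
    ranking = list(method = "mic", mic_grid_exponent = 0.6),
    seed = 1L,
    out_dir = "radtex_out")
}

#' Load and validate a JSON run configuration
#'
#' Unknown keys (top level or nested) are rejected; missing keys fall back
#' to defaults. The configuration round-trips losslessly through
#' [save_run_config()].
#'
#' @param path JSON file, or `NULL` for the defaults.
#' @return named list of class `run_config` with a `hash` attribute.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      rt_error(paste0("config not found: ", path), "radtex_io_error")
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      rt_error(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
               "radtex_invalid_config")
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]]))) {
        badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badk))
          rt_error(paste0("unknown config keys in ", k, ": ",
                          paste(badk, collapse = ", ")),
                   "radtex_invalid_config")
        cfg[[k]] <- utils::modifyList(cfg[[k]], as.list(user[[k]]))
      } else cfg[[k]] <- user[[k]]
    }
  }
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as JSON
#' @param cfg a `run_config` (or plain named list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  attributes(cfg)[c("hash", "class")] <- NULL
  write_atomic(path, function(p)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(path)
}

# md5 of the canonical JSON rendering
config_hash <- function(cfg) {
  attributes(cfg)[c("hash", "class")] <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
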