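# Format adapters: TSV tables (UTF-8, tab-delimited, header row), NIfTI-1
# volumes, YAML configuration. Units are encoded in column names
# (K_per_min, glucose_mM, ...) and table shapes are validated on read.

read_tsv_checked <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(required_cols) && !all(required_cols %in% names(d)))
    stop("malformed table ", basename(path), ": expected columns ",
         paste(required_cols, collapse = ", "))
  d
}

#' Write a table as TSV with a configuration-hash header comment
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config_hash Optional hash string recorded as a `# config_hash:`
#'   comment line so every output is traceable to its resolved configuration.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#' @param path File path.
#' @param required_cols Optional column names that must be present.
#' @return Data frame. `#`-prefixed header comments are skipped.
#' @export
read_tsv <- function(path, required_cols = NULL) read_tsv_checked(path, required_cols)

#' Write a 3D or 4D volume as NIfTI-1
#' @param image Numeric array (3D or 4D).
#' @param path Output path (`.nii` recommended for reproducible bytes).
#' @param voxel_size Isotropic voxel edge length (mm).
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(image, path, voxel_size = 2) {
  RNifti::writeNifti(RNifti::asNifti(image, pixdim = rep(voxel_size,
                                                         min(3L, length(dim(image))))),
                     path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#' @param path File path.
#' @return Numeric array with a `voxel_size` attribute (mm, first spatial axis).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1L]
  out
}

#' Write a dynamic image with its frame-timing sidecar
#' @param image 4D array `(x, y, z, frame)`.
#' @param schedule A [frame_schedule()] with one row per frame.
#' @param path Output NIfTI path; the sidecar is written next to it as
#'   `<path>_timing.tsv` with columns `start_min`, `end_min`.
#' @param voxel_size Voxel edge length (mm).
#' @return Paths of the two files, invisibly.
#' @export
write_dynamic_image <- function(image, schedule, path, voxel_size = 2) {
  stopifnot(length(dim(image)) == 4L, inherits(schedule, "frame_schedule"))
  if (dim(image)[4L] != nrow(schedule))
    stop("frame count mismatch between image (", dim(image)[4L],
         ") and schedule (", nrow(schedule), ")")
  write_nifti_volume(image, path, voxel_size)
  timing <- paste0(tools::file_path_sans_ext(path), "_timing.tsv")
  write_tsv(data.frame(start_min = schedule$start, end_min = schedule$end), timing)
  invisible(c(path, timing))
}

#' Read a dynamic image and its frame-timing sidecar
#' @param path NIfTI path of the 4D image.
#' @param timing_path Timing TSV (`start_min`, `end_min`); default the sidecar
#'   written by [write_dynamic_image()].
#' @return A list: `image` (4D array), `schedule` ([frame_schedule()]).
#' @export
read_dynamic_image <- function(path,
                               timing_path = paste0(tools::file_path_sans_ext(path),
                                                    "_timing.tsv")) {
  img <- read_nifti_volume(path)
  if (length(dim(img)) != 4L) stop("expected a 4D dynamic image")
  tm <- read_tsv_checked(timing_path, c("start_min", "end_min"))
  if (nrow(tm) != dim(img)[4L])
    stop("frame count mismatch: image has ", dim(img)[4L], " frames, timing file ",
         nrow(tm), " rows")
  list(image = img, schedule = frame_schedule(tm$start_min, tm$end_min))
}

#' Default pipeline configuration
#'
#' Tracer constants default to the standard values: lumped constant 0.8 for
#' FDG/glucose and 1.0 for acetoacetate; Patlak linear-phase onset 10 min for
#' the 60-min glucose protocol and 3 min for the 10-min acetoacetate protocol;
#' plasma substrate levels 5.1 mM glucose and 0.12 mM acetoacetate; PVC with a
#' 6-mm PSF and 0.3 gray-matter threshold; FDR level 0.05.
#'
#' @param seed Master seed; every random stage derives from it.
#' @return A nested list usable by [run_pipeline()].
#' @export
default_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    tracers = list(
      glucose = list(lc = 0.8, t_star = 10, cp_met = 5.1, schedule = "fdg"),
      acac = list(lc = 1.0, t_star = 3, cp_met = 0.12, schedule = "acac")
    ),
    pvc = list(fwhm_mm = 6, gm_threshold = 0.3, wm_reference = "auto"),
    phantom = list(shape = c(32L, 32L, 32L), voxel_size = 2),
    fdr = list(q = 0.05),
    weighting = "uniform"
  )
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path or a nested list; missing keys are filled
#'   from [default_config()].
#' @return The fully resolved, validated configuration list with a
#'   `config_hash` field (MD5 of its canonical YAML serialization).
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop("config must be a YAML path or a list")
  merged <- utils::modifyList(base, user)
  if (!is.null(user$seed)) merged$seed <- as.integer(user$seed)
  for (tr in names(merged$tracers)) {
    tc <- merged$tracers[[tr]]
    if (!is.finite(tc$lc) || tc$lc <= 0)
      stop("invalid config: lumped constant for ", tr, " must be positive")
    if (!is.finite(tc$cp_met) || tc$cp_met <= 0)
      stop("invalid config: cp_met for ", tr, " must be positive")
    if (tc$t_star < 0) stop("invalid config: t_star must be non-negative")
  }
  if (merged$pvc$fwhm_mm < 0) stop("invalid config: pvc.fwhm_mm must be >= 0")
  if (merged$fdr$q <= 0 || merged$fdr$q >= 1)
    stop("invalid config: fdr.q must be in (0, 1)")
  merged$config_hash <- config_hash(merged)
  merged
}

config_hash <- function(config) {
  config$config_hash <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}
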