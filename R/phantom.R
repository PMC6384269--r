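# Digital brain phantoms: an ellipsoidal brain with a white-matter core, a
# gray-matter shell parcellated into the atlas regions, and a thin CSF rim.
# These stand in for a T1w segmentation plus anatomical labelling when testing
# partial-volume correction and regional extraction.

#' Generate a digital brain phantom
#'
#' Builds, inside an ellipsoidal brain mask, a white-matter core
#' (normalized ellipsoidal radius <= 0.62), a gray-matter shell
#' (0.62-0.95) and a CSF rim (> 0.95). The gray-matter shell is parcellated
#' into one compact patch per atlas region by nearest-seed assignment from
#' seed voxels drawn within the shell (minimum-separation rejection sampling,
#' deterministic for a fixed seed).
#'
#' @param shape Grid dimensions, e.g. `c(48, 48, 48)`. Must be large enough
#'   that every region receives at least 8 voxels.
#' @param atlas Region atlas data frame (default [load_atlas()]).
#' @param seed Integer seed controlling seed-voxel placement.
#' @param voxel_size Isotropic voxel edge length (mm), default 2 as typical
#'   for brain PET.
#' @return An object of class `digital_phantom`: `gm_map`, `wm_map`, `csf_map`
#'   (3D probability grids), `labels` (3D integer grid of region ids),
#'   `brain_mask`, `voxel_size` (mm) and `icv` (mL).
#' @export
make_phantom <- function(shape = c(48, 48, 48), atlas = load_atlas(),
                         seed = 1L, voxel_size = 2) {
  if (length(shape) != 3L || any(shape < 16))
    stop("shape must be three dimensions of at least 16 voxels")
  ctr <- (shape + 1) / 2
  semi <- 0.44 * shape
  ax <- (seq_len(shape[1L]) - ctr[1L]) / semi[1L]
  ay <- (seq_len(shape[2L]) - ctr[2L]) / semi[2L]
  az <- (seq_len(shape[3L]) - ctr[3L]) / semi[3L]
  r <- sqrt(outer(outer(ax^2, ay^2, `+`), az^2, `+`))
  dim(r) <- shape

  brain <- r <= 1
  wm <- r <= 0.62
  gm <- r > 0.62 & r <= 0.95
  csf <- r > 0.95 & brain

  gm_idx <- which(gm)
  n_reg <- nrow(atlas)
  if (length(gm_idx) < 8L * n_reg)
    stop("shape too small: gray-matter shell cannot host ", n_reg,
         " regions with >= 8 voxels each")
  coords <- arrayInd(gm_idx, shape)

  labels <- with_seed(seed, {
    lab <- NULL
    for (attempt in 1:10) {
      # spread seeds through the shell with a minimum-separation draw;
      # the separation relaxes geometrically if placement fails
      min_sep <- (length(gm_idx) / n_reg)^(1 / 3) * 0.85^(attempt - 1L)
      seeds <- matrix(NA_real_, n_reg, 3L)
      placed <- 0L
      for (draw in seq_len(5000L)) {
        cand <- coords[sample.int(nrow(coords), 1L), ]
        if (placed == 0L ||
            min(sqrt(rowSums((seeds[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 3L, byrow = TRUE))^2))) >= min_sep) {
          placed <- placed + 1L
          seeds[placed, ] <- cand
          if (placed == n_reg) break
        }
      }
      if (placed < n_reg) next
      d2 <- matrix(0, nrow(coords), n_reg)
      for (j in 1:3) d2 <- d2 + outer(coords[, j], seeds[, j], `-`)^2
      assign_r <- max.col(-d2, ties.method = "first")
      if (min(tabulate(assign_r, n_reg)) >= 8L) { lab <- assign_r; break }
    }
    lab
  })
  if (is.null(labels))
    stop("shape too small: could not place all ", n_reg,
         " regions with >= 8 voxels each")

  label_vol <- array(0L, shape)
  label_vol[gm_idx] <- atlas$id[labels]

  gm_map <- array(0, shape); gm_map[gm] <- 1
  wm_map <- array(0, shape); wm_map[wm] <- 1
  csf_map <- array(0, shape); csf_map[csf] <- 1
  icv <- sum(brain) * voxel_size^3 / 1000

  structure(list(gm_map = gm_map, wm_map = wm_map, csf_map = csf_map,
                 labels = label_vol, brain_mask = brain,
                 voxel_size = voxel_size, icv = icv, seed = seed),
            class = "digital_phantom")
}

#' Paint a dynamic PET image onto a phantom
#'
#' Assigns a gray-matter time-activity curve (either one curve for all regions
#' or a named list with one curve per region) and a white-matter curve, frame
#' by frame, yielding a noiseless 4D dynamic image aligned with the phantom.
#'
#' @param phantom A [make_phantom()] result.
#' @param gm_tac A [tac()], or a named list of [tac()]s keyed by region name
#'   (names matching the atlas used to build the phantom).
#' @param wm_tac Optional [tac()] for white matter; default zero activity.
#' @param atlas Atlas used when `gm_tac` is a per-region list.
#' @return A 4D array `(x, y, z, frame)`.
#' @export
phantom_dynamic_image <- function(phantom, gm_tac, wm_tac = NULL,
                                  atlas = load_atlas()) {
  stopifnot(inherits(phantom, "digital_phantom"))
  per_region <- is.list(gm_tac) && !inherits(gm_tac, "tac")
  sched <- if (per_region) gm_tac[[1L]]$schedule else gm_tac$schedule
  n_fr <- nrow(sched)
  shape <- dim(phantom$labels)
  img <- array(0, c(shape, n_fr))
  wm_sel <- phantom$wm_map >= 0.5
  for (f in seq_len(n_fr)) {
    vol <- array(0, shape)
    if (per_region) {
      for (i in seq_len(nrow(atlas))) {
        cur <- gm_tac[[atlas$name[i]]]
        if (!is.null(cur)) vol[phantom$labels == atlas$id[i]] <- cur$values[f]
      }
    } else {
      vol[phantom$labels > 0L] <- gm_tac$values[f]
    }
    if (!is.null(wm_tac)) vol[wm_sel] <- wm_tac$values[f]
    img[, , , f] <- vol
  }
  img
}
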