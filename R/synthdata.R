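#' Specification for the synthetic labelled-volume generator
#'
#' Describes a dataset of greyscale 3D cubes emulating resized brain MRI:
#' a dark, slightly noisy background with a bright class-dependent
#' structure. Each class draws a concentric spherical shell whose radius,
#' thickness and intensity differ by class (loosely evoking
#' atrophy/ventricle differences between diagnostic groups); the shell
#' centre jitters per volume.
#'
#' @param n_per_class volumes generated per class, default 20.
#' @param edge cube edge length, default 16 (64 matches the reference
#'   network input).
#' @param background mean background intensity, default 0.05.
#' @param noise_sd additive Gaussian noise s.d., default 0.02.
#' @param classes class label names.
#' @param radius_frac per-class shell radius as a fraction of `edge / 2`.
#' @param thickness_frac per-class shell thickness fraction of `edge / 2`.
#' @param intensity per-class shell intensity.
#' @param jitter_frac centre jitter s.d. as a fraction of `edge`, default
#'   0.02.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   spec.
#' @return object of class `sgt_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 20L, edge = 16L,
                           background = 0.05, noise_sd = 0.02,
                           classes = c("AD", "CN", "MCI"),
                           radius_frac = c(0.35, 0.55, 0.75),
                           thickness_frac = c(0.18, 0.18, 0.18),
                           intensity = c(0.8, 0.8, 0.8),
                           jitter_frac = 0.02, seed = 1L) {
  K <- length(classes)
  stopifnot(n_per_class >= 1L, edge >= 4L, noise_sd >= 0,
            length(radius_frac) == K, length(thickness_frac) == K,
            length(intensity) == K, all(radius_frac < 1))
  structure(
    list(n_per_class = as.integer(n_per_class), edge = as.integer(edge),
         background = background, noise_sd = noise_sd, classes = classes,
         radius_frac = radius_frac, thickness_frac = thickness_frac,
         intensity = intensity, jitter_frac = jitter_frac,
         seed = as.integer(seed)),
    class = "sgt_synthetic_spec"
  )
}

radial_distance <- function(edge, centre) {
  ax <- seq_len(edge)
  dx2 <- (ax - centre[1L])^2
  dy2 <- (ax - centre[2L])^2
  dz2 <- (ax - centre[3L])^2
  sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
}

#' Generate a synthetic labelled dataset
#'
#' Draws `n_per_class` volumes for each class per the spec. Every volume is
#' `background + N(0, noise_sd)` noise plus a bright spherical shell of the
#' class's radius/thickness/intensity centred near the cube middle
#' (Gaussian jitter). Deterministic given the spec's seed.
#'
#' @param spec an [synthetic_spec()].
#' @return list of records, each with `voxels` (3D array), `label`
#'   (factor), `class` (1-based integer), and `id`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_per_class = 2, edge = 8))
#' length(ds)  # 6
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sgt_synthetic_spec"))
  set.seed(spec$seed)
  e <- spec$edge
  half <- e / 2
  mid <- (e + 1) / 2
  records <- list()
  for (cl in seq_along(spec$classes)) {
    for (i in seq_len(spec$n_per_class)) {
      centre <- mid + stats::rnorm(3L, 0, spec$jitter_frac * e)
      r <- radial_distance(e, centre)
      shell <- abs(r - spec$radius_frac[cl] * half) <
        spec$thickness_frac[cl] * half / 2
      vox <- array(spec$background, dim = c(e, e, e))
      if (spec$noise_sd > 0) {
        vox <- vox + array(stats::rnorm(e^3, 0, spec$noise_sd), dim = c(e, e, e))
      }
      vox[shell] <- vox[shell] + spec$intensity[cl]
      records[[length(records) + 1L]] <- list(
        voxels = vox,
        label = factor(spec$classes[cl], levels = spec$classes),
        class = cl,
        id = sprintf("%s_%03d", spec$classes[cl], i)
      )
    }
  }
  records
}

#' Read / write a volume in NIfTI format
#'
#' Thin wrappers over the RNifti reader/writer. Reading a 4D file keeps the
#' first 3D frame with a warning. Writing then reading restores voxels
#' bit-exactly for double-precision data.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns a record list with `voxels`, `dim` and
#'   `pixdim`; `write_nifti` returns `path` invisibly.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) > 3L) {
    warning("read_nifti: ", length(dim(vox)), "D image; keeping first 3D frame")
    vox <- array(vox[, , , 1L], dim = dim(vox)[1:3])
  }
  list(voxels = vox, dim = dim(vox),
       pixdim = RNifti::pixdim(img), path = path)
}

#' @rdname read_nifti
#' @param record a list with a `voxels` 3D array (extra fields ignored), or
#'   a bare 3D array.
#' @export
write_nifti <- function(record, path) {
  vox <- if (is.list(record)) record$voxels else record
  stopifnot(length(dim(vox)) == 3L)
  RNifti::writeNifti(RNifti::asNifti(vox), path)
  invisible(path)
}

#' Trilinear resize to a cube
#'
#' Resamples a 3D volume to `edge^3` voxels by trilinear interpolation
#' under the pixel-center convention (an identity-size resample returns the
#' input unchanged). Output intensities stay within the input range.
#'
#' @param voxels 3D numeric array.
#' @param edge target edge length, default 64.
#' @return `edge^3` array.
#' @export
resize_to_cube <- function(voxels, edge = 64L) {
  stopifnot(length(dim(voxels)) == 3L, edge >= 2L)
  d <- dim(voxels)
  coord <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(x, 1), n_in)
  }
  cx <- coord(edge, d[1L]); cy <- coord(edge, d[2L]); cz <- coord(edge, d[3L])
  lo <- function(c_, n) pmin(floor(c_), n - 1L)
  lx <- lo(cx, d[1L]); ly <- lo(cy, d[2L]); lz <- lo(cz, d[3L])
  fx <- cx - lx; fy <- cy - ly; fz <- cz - lz
  out <- array(0, dim = c(edge, edge, edge))
  g <- expand.grid(i = seq_len(edge), j = seq_len(edge), k = seq_len(edge))
  acc <- numeric(nrow(g))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx[g$i] else 1 - fx[g$i]) *
         (if (dy) fy[g$j] else 1 - fy[g$j]) *
         (if (dz) fz[g$k] else 1 - fz[g$k])
    acc <- acc + w * voxels[cbind(lx[g$i] + dx, ly[g$j] + dy, lz[g$k] + dz)]
  }
  out[cbind(g$i, g$j, g$k)] <- acc
  out
}

#' Zero-center normalization against the training subset
#'
#' Computes the per-voxel mean map over the training records only and
#' subtracts it from every record (train, validation and test alike), the
#' input normalization used by the network's image-input layer. The mean
#' map is returned so it can be serialized with checkpoints and applied to
#' new data.
#'
#' @param records list of records with `voxels` arrays of identical shape.
#' @param train_idx integer indices of the training records.
#' @param mean_map optionally, a precomputed mean map to apply instead.
#' @return list with `records` (normalized) and `mean_map`.
#' @export
zero_center <- function(records, train_idx = seq_along(records),
                        mean_map = NULL) {
  stopifnot(length(records) >= 1L)
  d <- dim(records[[1L]]$voxels)
  if (is.null(mean_map)) {
    if (!length(train_idx)) stop("zero_center: empty training subset")
    mean_map <- array(0, dim = d)
    for (i in train_idx) mean_map <- mean_map + records[[i]]$voxels
    mean_map <- mean_map / length(train_idx)
  }
  if (!identical(dim(mean_map), d)) {
    stop("zero_center: mean map shape does not match records")
  }
  for (i in seq_along(records)) {
    if (!identical(dim(records[[i]]$voxels), d)) {
      stop("zero_center: record ", i, " shape mismatch")
    }
    records[[i]]$voxels <- records[[i]]$voxels - mean_map
  }
  list(records = records, mean_map = mean_map)
}

#' Dataset manifest as a tibble
#'
#' @param records list of generated or loaded records.
#' @param subset optional subset tags aligned with `records`.
#' @return tibble with `id`, `label`, `class` and `subset` columns.
#' @export
dataset_manifest <- function(records, subset = NULL) {
  tibble::tibble(
    id = vapply(records, function(r) r$id %||% NA_character_, ""),
    label = vapply(records, function(r) as.character(r$label), ""),
    class = vapply(records, function(r) as.integer(r$class), 1L),
    subset = if (is.null(subset)) NA_character_ else subset
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
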