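#' Specify a synthetic phantom cohort
#'
#' Defines a multi-batch, two-class cohort of 3D volumes with ellipsoidal
#' lesions. Benign lesions carry a near-constant signal with low-amplitude
#' correlated noise; malignant lesions add high-contrast internal structure
#' (hyperintense nodular inclusions and hypointense septum-like planes) whose
#' amplitude scales with `class_texture_gap`. Each batch then applies an
#' acquisition-style perturbation to the whole volume: a multiplicative gain,
#' an additive offset, and a Gaussian blur — the kind of protocol differences
#' (e.g. fat-suppression technique, field strength) that confound raw
#' radiomic features in multicentre MRI studies.
#'
#' Class labels and batch assignments are fixed deterministically at
#' construction time. With `confounding = 0`, batches are dealt round-robin
#' within each class, so class and batch are independent by construction.
#' With `confounding > 0`, each case is moved with that probability to its
#' class-preferred batch (malignant cases prefer the last batch), inducing a
#' class–batch correlation as in a cohort where site case-mix differs.
#'
#' @param n_cases number of cases.
#' @param class_balance fraction of malignant cases, in (0, 1).
#' @param n_batches number of acquisition batches.
#' @param class_texture_gap non-negative scale of the malignant internal
#'   texture (0 makes the class label uninformative).
#' @param batch_gain,batch_offset,batch_blur_sigma numeric vectors of length
#'   `n_batches`: per-batch multiplicative gain, additive offset, and Gaussian
#'   blur width (voxels).
#' @param confounding probability in \[0, 1\] that a case is reassigned to its
#'   class-preferred batch.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @param grid_shape integer vector of 3 volume dimensions (voxels).
#' @param voxel_spacing numeric vector of 3 voxel spacings (mm).
#' @param lesion_semiaxes length-2 range (voxels) for the ellipsoid semi-axes.
#' @param lesion_base,lesion_base_sd,noise_sd,background_level intensity model
#'   parameters (arbitrary MR units): lesion mean signal and its per-case SD,
#'   within-lesion correlated-noise SD, and background level.
#' @param case_gain_sd,case_offset_sd,case_blur_sd scanner-level jitter of
#'   the acquisition parameters around their batch means (log-normal SD for
#'   gain, additive SDs for offset and blur): each batch pools many
#'   centres/systems, so cases within a batch share the batch tendency but
#'   not an identical protocol.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_case()], [generate_cohort()], [phantom_preset()]
#' @export
phantom_spec <- function(n_cases = 85,
                         class_balance = 45 / 85,
                         n_batches = 2,
                         class_texture_gap = 1.2,
                         batch_gain = seq(1, 1.5, length.out = n_batches),
                         batch_offset = seq(0, 30, length.out = n_batches),
                         batch_blur_sigma = seq(0.2, 1.2, length.out = n_batches),
                         confounding = 0,
                         seed = 1L,
                         grid_shape = c(48L, 48L, 48L),
                         voxel_spacing = c(1, 1, 1),
                         lesion_semiaxes = c(7, 14),
                         lesion_base = 300,
                         lesion_base_sd = 60,
                         noise_sd = 12,
                         background_level = 40,
                         case_gain_sd = 0.3,
                         case_offset_sd = 15,
                         case_blur_sd = 0.35) {
  stopifnot(n_cases >= 1, class_balance > 0, class_balance < 1, n_batches >= 1,
            class_texture_gap >= 0, confounding >= 0, confounding <= 1,
            length(grid_shape) == 3, all(grid_shape >= 8),
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            length(lesion_semiaxes) == 2, lesion_semiaxes[1] >= 2,
            diff(lesion_semiaxes) >= 0)
  batch_gain <- rep_len(batch_gain, n_batches)
  batch_offset <- rep_len(batch_offset, n_batches)
  batch_blur_sigma <- rep_len(batch_blur_sigma, n_batches)

  n_mal <- round(n_cases * class_balance)
  n_mal <- min(max(n_mal, 1L), n_cases - 1L)
  assign <- with_seed(seed, {
    label <- rep("benign", n_cases)
    label[sample.int(n_cases, n_mal)] <- "malignant"
    batch <- integer(n_cases)
    # round-robin within class in randomized case order: stratified, so
    # independent of class when confounding = 0
    for (cl in c("benign", "malignant")) {
      idx <- which(label == cl)
      batch[idx] <- 1L + (seq_along(idx) - 1L) %% n_batches
    }
    if (confounding > 0 && n_batches > 1) {
      move <- stats::runif(n_cases) < confounding
      pref <- ifelse(label == "malignant", n_batches, 1L)
      batch[move] <- pref[move]
    }
    list(label = label, batch = batch)
  })

  structure(list(
    n_cases = as.integer(n_cases), class_balance = class_balance,
    n_batches = as.integer(n_batches), class_texture_gap = class_texture_gap,
    batch_gain = batch_gain, batch_offset = batch_offset,
    batch_blur_sigma = batch_blur_sigma, confounding = confounding,
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    lesion_semiaxes = lesion_semiaxes, lesion_base = lesion_base,
    lesion_base_sd = lesion_base_sd, noise_sd = noise_sd,
    background_level = background_level, case_gain_sd = case_gain_sd,
    case_offset_sd = case_offset_sd, case_blur_sd = case_blur_sd,
    label = assign$label, batch_assignment = assign$batch
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom cohort spec:", x$n_cases, "cases,",
      sum(x$label == "malignant"), "malignant /",
      sum(x$label == "benign"), "benign,",
      x$n_batches, "batch(es)\n")
  cat("  grid", paste(x$grid_shape, collapse = "x"),
      " spacing", paste(x$voxel_spacing, collapse = "x"), "mm\n")
  cat("  texture gap", x$class_texture_gap,
      " confounding", x$confounding, " seed", x$seed, "\n")
  cat("  batch gain", paste(signif(x$batch_gain, 3), collapse = "/"),
      " offset", paste(signif(x$batch_offset, 3), collapse = "/"),
      " blur", paste(signif(x$batch_blur_sigma, 3), collapse = "/"), "\n")
  invisible(x)
}

#' Named phantom presets
#'
#' `"paper-like"` emulates a two-batch multicentre cohort at the scale of the
#' motivating study design (85 training-sized + 60 validation-sized cases,
#' moderate class–batch confounding, gain/offset/blur protocol differences).
#' `"small"` is a fast cohort for examples and tests.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides passed on to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
phantom_preset <- function(name = c("paper-like", "small"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "paper-like" = list(n_cases = 145, class_balance = 77 / 145, n_batches = 2,
                        confounding = 0.1, seed = seed,
                        grid_shape = c(64L, 64L, 48L),
                        voxel_spacing = c(1, 1, 2),
                        lesion_semiaxes = c(8, 18)),
    "small" = list(n_cases = 20, class_balance = 0.5, n_batches = 2,
                   confounding = 0, seed = seed,
                   grid_shape = c(28L, 28L, 26L),
                   voxel_spacing = c(1, 1, 1),
                   lesion_semiaxes = c(5, 8))
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# Random 3D rotation matrix (uniform Euler-ish; adequate for phantom variety).
random_rotation <- function() {
  a <- stats::runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Generate one phantom case
#'
#' Deterministic in `(spec$seed, case_index)`: the same call always returns
#' bit-identical arrays.
#'
#' @param spec a [phantom_spec()].
#' @param case_index case number in `1..spec$n_cases`.
#' @return a list of class `volume_with_mask` with elements `intensities`
#'   (3D array), `mask` (3D logical), `spacing` (mm), plus `case_id`, `batch`
#'   and `label`.
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"),
            case_index >= 1, case_index <= spec$n_cases)
  d <- spec$grid_shape
  batch <- spec$batch_assignment[case_index]
  label <- spec$label[case_index]
  case_seed <- derive_seed(spec$seed, case_index)

  res <- with_seed(case_seed, {
    centre <- d / 2 + stats::runif(3, -2, 2)
    ax <- stats::runif(3, spec$lesion_semiaxes[1], spec$lesion_semiaxes[2])
    for (k in 1:3) {
      if (centre[k] - ax[k] < 2 || centre[k] + ax[k] > d[k] - 1)
        stop(sprintf("lesion does not fit in grid_shape along axis %d (semi-axis %.1f, extent %d)",
                     k, ax[k], d[k]))
    }
    R <- random_rotation()
    # lesion bounding box: ellipsoid evaluated only there
    rad <- ceiling(max(ax)) + 1L
    lo <- pmax(floor(centre - rad), 1)
    hi <- pmin(ceiling(centre + rad), d)
    bd <- hi - lo + 1L
    bx <- (lo[1]:hi[1]) - centre[1]
    by <- (lo[2]:hi[2]) - centre[2]
    bz <- (lo[3]:hi[3]) - centre[3]
    gx <- array(bx, bd)
    gy <- array(rep(by, each = bd[1]), bd)
    gz <- array(rep(bz, each = bd[1] * bd[2]), bd)
    u1 <- R[1, 1] * gx + R[2, 1] * gy + R[3, 1] * gz
    u2 <- R[1, 2] * gx + R[2, 2] * gy + R[3, 2] * gz
    u3 <- R[1, 3] * gx + R[2, 3] * gy + R[3, 3] * gz
    mask_box <- (u1 / ax[1])^2 + (u2 / ax[2])^2 + (u3 / ax[3])^2 <= 1
    dim(mask_box) <- bd
    mask <- array(FALSE, d)
    mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mask_box
    mv <- which(mask_box)
    gxm <- gx[mv]; gym <- gy[mv]; gzm <- gz[mv]

    base <- stats::rnorm(1, spec$lesion_base, spec$lesion_base_sd)
    # benign heterogeneity varies from lesion to lesion (correlated noise of
    # case-specific amplitude), as benign lipomas are not uniformly bland
    noise_amp <- spec$noise_sd * stats::runif(1, 0.7, 1.8)
    corr_noise <- gaussian_blur_3d(array(stats::rnorm(prod(bd)), bd), 1.2)
    corr_noise <- corr_noise / stats::sd(corr_noise) * noise_amp
    lesion_val <- base + corr_noise[mv]

    if (label == "malignant" && spec$class_texture_gap > 0) {
      # per-case severity: malignant internal structure ranges from subtle
      # to florid, so no single feature separates the classes on its own
      gap <- spec$class_texture_gap * stats::runif(1, 0.3, 1)
      n_blob <- sample(2:8, 1)
      for (b in seq_len(n_blob)) {
        # blob centre uniform inside the ellipsoid (rejection sampling)
        repeat {
          p <- stats::runif(3, -1, 1)
          if (sum(p^2) <= 1) break
        }
        bc <- as.vector(R %*% (p * ax * 0.8))
        bs <- stats::runif(1, 1.5, 4)
        amp <- gap * stats::runif(1, 40, 100)
        lesion_val <- lesion_val + amp *
          exp(-((gxm - bc[1])^2 + (gym - bc[2])^2 + (gzm - bc[3])^2) / (2 * bs^2))
      }
      n_sep <- sample(1:3, 1)
      for (s in seq_len(n_sep)) {
        nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
        off <- stats::runif(1, -0.4, 0.4) * min(ax)
        dist <- nrm[1] * gxm + nrm[2] * gym + nrm[3] * gzm - off
        th <- stats::runif(1, 0.8, 1.6)
        amp <- gap * stats::runif(1, 50, 90)
        lesion_val <- lesion_val - amp * exp(-(dist / th)^2)
      }
    }

    img <- array(stats::rnorm(prod(d), spec$background_level, 4), d)
    img[mask] <- lesion_val

    # per-case acquisition parameters: batch mean plus scanner-level jitter
    gain <- spec$batch_gain[batch] * exp(stats::rnorm(1, 0, spec$case_gain_sd))
    offset <- spec$batch_offset[batch] + stats::rnorm(1, 0, spec$case_offset_sd)
    blur <- max(0, spec$batch_blur_sigma[batch] +
                  stats::rnorm(1, 0, spec$case_blur_sd))
    img <- gain * img + offset
    if (blur > 0.05) img <- gaussian_blur_3d(img, blur)
    list(img = img, mask = mask)
  })

  structure(list(intensities = res$img, mask = res$mask,
                 spacing = spec$voxel_spacing,
                 case_id = sprintf("case_%03d", case_index),
                 batch = batch, label = label),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  cat("Volume", paste(dim(x$intensities), collapse = "x"),
      "voxels @", paste(signif(x$spacing, 3), collapse = "x"), "mm;",
      sum(x$mask), "masked voxels")
  if (!is.null(x$case_id)) cat(";", x$case_id, paste0("(", x$label, ", batch ", x$batch, ")"))
  cat("\n")
  invisible(x)
}

#' Generate and write a full phantom cohort
#'
#' Writes one image and one mask NIfTI per case (affines carry the voxel
#' spacing) plus a `cohort.csv` metadata table with header
#' `case_id,batch,label`.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite existing case files; if `FALSE` (default), any
#'   collision is an error.
#' @return invisibly, the manifest data frame with columns `case_id`, `batch`,
#'   `label`, `image`, `mask`.
#' @export
generate_cohort <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("case_%03d", seq_len(spec$n_cases))
  img_files <- file.path(out_dir, paste0(ids, "_image.nii.gz"))
  mask_files <- file.path(out_dir, paste0(ids, "_mask.nii.gz"))
  existing <- c(img_files, mask_files)[file.exists(c(img_files, mask_files))]
  if (length(existing) && !overwrite)
    stop("refusing to overwrite existing files (use overwrite = TRUE): ",
         existing[1])
  for (i in seq_len(spec$n_cases)) {
    v <- generate_case(spec, i)
    write_nifti_volume(v$intensities, v$spacing, img_files[i])
    write_nifti_volume(v$mask * 1L, v$spacing, mask_files[i])
  }
  manifest <- data.frame(case_id = ids, batch = spec$batch_assignment,
                         label = spec$label, image = img_files,
                         mask = mask_files, stringsAsFactors = FALSE)
  utils::write.csv(manifest[, c("case_id", "batch", "label")],
                   file.path(out_dir, "cohort.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest written by [generate_cohort()]
#'
#' @param dir cohort directory containing `cohort.csv`.
#' @return manifest data frame with resolved `image`/`mask` paths.
#' @export
read_cohort_manifest <- function(dir) {
  m <- utils::read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  m$image <- file.path(dir, paste0(m$case_id, "_image.nii.gz"))
  m$mask <- file.path(dir, paste0(m$case_id, "_mask.nii.gz"))
  m
}

write_nifti_volume <- function(arr, spacing, path) {
  n <- RNifti::asNifti(arr)
  RNifti::pixdim(n) <- spacing
  RNifti::writeNifti(n, path)
  invisible(path)
}

#' Read an image/mask pair into a `volume_with_mask`
#'
#' @param image_path,mask_path NIfTI file paths.
#' @param case_id,batch,label optional metadata carried along.
#' @return a `volume_with_mask`.
#' @export
read_case <- function(image_path, mask_path, case_id = NULL, batch = NULL,
                      label = NULL) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop("image and mask dimensions differ for ", image_path)
  structure(list(intensities = array(as.numeric(img), dim(img)),
                 mask = array(as.numeric(msk) > 0.5, dim(msk)),
                 spacing = as.numeric(RNifti::pixdim(img))[1:3],
                 case_id = case_id, batch = batch, label = label),
            class = "volume_with_mask")
}
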