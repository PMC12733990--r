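# Synthetic contrast-CT kidney phantoms.
#
# Each phantom is one smooth ellipsoidal kidney embedded in soft-tissue
# background, optionally carrying lesions of a single designated pathology
# class: hypodense spherical cysts with smooth borders, irregular tumors
# (low-order spherical-harmonic radius perturbation, spatially mixed
# enhancement), or small hyperdense stones.  Intensities are Hounsfield-like
# conventions chosen for class separability under noise, not measured CT
# values.  Everything is a pure function of (spec, seed, patient id).

#' Default per-tissue intensity statistics (HU-like mean and sd)
#' @keywords internal
default_hu_params <- function() list(
  background = c(mean = -80, sd = 20),
  kidney     = c(mean = 110, sd = 15),
  cyst       = c(mean = 10,  sd = 8),
  tumor_low  = c(mean = 60,  sd = 20),
  tumor_high = c(mean = 140, sd = 20),
  stone      = c(mean = 700, sd = 150)
)

#' Default pathology class mixture of the emulated cohort
#'
#' Proportions follow the class distribution of the public CT kidney cohort
#' the package emulates (1448 normal, 1078 cyst, 638 tumor, 393 stone
#' patients), normalized to sum to one.
#' @return Named numeric vector over normal/cyst/tumor/stone.
#' @export
defaultClassMix <- function() {
  counts <- c(normal = 1448, cyst = 1078, tumor = 638, stone = 393)
  counts / sum(counts)
}

#' Construct a phantom specification
#'
#' @param volumeShape voxel grid, default desk-scale 64 x 64 x 16
#'   (a full-scale 96 x 96 x 32 grid is available by configuration).
#' @param spacing voxel spacing in mm, default 1 x 1 x 2.5.
#' @param classMix named proportions over normal/cyst/tumor/stone.
#' @param lesionRadiusRange named list of `c(min, max)` radii in mm.
#' @param huParams per-tissue `c(mean, sd)` intensity list.
#' @param noiseStd global noise multiplier.
#' @param nLesions lesions per pathological patient (1--3).
#' @param seed integer base seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(volumeShape = c(64L, 64L, 16L),
                        spacing = c(1, 1, 2.5),
                        classMix = defaultClassMix(),
                        lesionRadiusRange = list(cyst = c(4, 8),
                                                 tumor = c(5, 8),
                                                 stone = c(3, 5)),
                        huParams = default_hu_params(),
                        noiseStd = 1,
                        nLesions = 1L,
                        seed = 42L) {
  new("PhantomSpec", volumeShape = as.integer(volumeShape),
      spacing = as.numeric(spacing),
      classMix = classMix[PATHOLOGY_CLASSES],
      lesionRadiusRange = lesionRadiusRange, huParams = huParams,
      noiseStd = noiseStd, nLesions = as.integer(nLesions),
      seed = as.integer(seed))
}

# Real spherical harmonics (unnormalized) up to degree 3, evaluated at unit
# directions; used as a smooth low-order basis for tumor margin
# irregularity.
real_sh_basis <- function(ct, st, phi) {
  cbind(
    ct,                      # l=1
    st * cos(phi), st * sin(phi),
    (3 * ct^2 - 1) / 2,      # l=2
    ct * st * cos(phi), ct * st * sin(phi),
    st^2 * cos(2 * phi), st^2 * sin(2 * phi),
    (5 * ct^3 - 3 * ct) / 2, # l=3
    (5 * ct^2 - 1) * st * cos(phi), (5 * ct^2 - 1) * st * sin(phi),
    ct * st^2 * cos(2 * phi), ct * st^2 * sin(2 * phi),
    st^3 * cos(3 * phi), st^3 * sin(3 * phi)
  )
}

# voxel-center coordinates in mm for a grid
grid_mm <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

#' Generate one synthetic kidney phantom
#'
#' @param spec a [PhantomSpec-class].
#' @param patientId character id; combined with the spec seed it fully
#'   determines the volume.
#' @param lesionClass `NULL` to draw the class from `classMix`, otherwise
#'   one of "normal", "cyst", "tumor", "stone".
#' @return A [LabeledVolume-class]; `@meta$lesions` holds the analytic
#'   parameters (center mm, radius mm, class) of every implanted lesion.
#' @export
generatePhantom <- function(spec, patientId, lesionClass = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  seed <- deriveSeed(spec@seed, patientId)
  with_seed(seed, {
    shape <- spec@volumeShape
    sp <- spec@spacing
    hu <- spec@huParams
    ns <- spec@noiseStd
    if (is.null(lesionClass))
      lesionClass <- sample(PATHOLOGY_CLASSES, 1, prob = spec@classMix)

    g <- grid_mm(shape, sp)
    ext <- c(max(g$x), max(g$y), max(g$z))
    center <- ext / 2 + runif(3, -3, 3)
    # kidney semi-axes in mm, bounded by the field of view
    axes <- c(runif(1, 16, 22), runif(1, 11, 15), runif(1, 12, 16))
    axes <- pmin(axes, ext / 2 - 2)

    X <- array(g$x, shape)
    Y <- array(rep(g$y, each = shape[1]), shape)
    Z <- array(rep(g$z, each = shape[1] * shape[2]), shape)
    rho <- sqrt(((X - center[1]) / axes[1])^2 + ((Y - center[2]) / axes[2])^2 +
                ((Z - center[3]) / axes[3])^2)
    mask <- array(0L, shape)
    mask[rho <= 1] <- 1L

    img <- array(rnorm(prod(shape), hu$background["mean"],
                       hu$background["sd"] * ns), shape)
    kid <- mask == 1L
    img[kid] <- rnorm(sum(kid), hu$kidney["mean"], hu$kidney["sd"] * ns)

    lesions <- list()
    if (lesionClass != "normal") {
      rr <- spec@lesionRadiusRange[[lesionClass]]
      lab <- MASK_LEVELS[[lesionClass]]
      for (li in seq_len(spec@nLesions)) {
        r0 <- runif(1, rr[1], rr[2])
        r_max <- if (lesionClass == "tumor") 1.3 * r0 else r0
        r_eff <- r_max / min(axes)
        if (r_eff >= 1)
          nx_stop("lesion radius ", round(r_max, 1),
                  " mm exceeds the kidney extent; reduce lesionRadiusRange")
        # uniform point inside the ellipsoid shrunk so the lesion fits
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        rad <- (1 - r_eff) * runif(1)^(1 / 3)
        lcen <- center + u * rad * axes

        dxm <- X - lcen[1]; dym <- Y - lcen[2]; dzm <- Z - lcen[3]
        dist <- sqrt(dxm^2 + dym^2 + dzm^2)
        if (lesionClass == "tumor") {
          coef <- rnorm(15)
          amp <- runif(1, 0.15, 0.30)
          ct <- ifelse(dist > 0, dzm / dist, 1)
          st <- sqrt(pmax(0, 1 - ct^2))
          phi <- atan2(dym, dxm)
          f <- as.vector(real_sh_basis(as.vector(ct), as.vector(st),
                                       as.vector(phi)) %*% coef)
          f <- f / max(abs(f), 1e-12) * amp
          rdir <- r0 * (1 + array(f, shape))
          inside <- dist <= rdir
          lesions[[li]] <- list(class = lesionClass, center = lcen, radius = r0,
                                sh_coef = coef, sh_amp = amp)
        } else {
          inside <- dist <= r0
          lesions[[li]] <- list(class = lesionClass, center = lcen, radius = r0)
        }
        inside <- inside & kid  # anatomical containment
        mask[inside] <- lab
        nin <- sum(inside)
        if (lesionClass == "cyst") {
          img[inside] <- rnorm(nin, hu$cyst["mean"], hu$cyst["sd"] * ns)
        } else if (lesionClass == "stone") {
          img[inside] <- rnorm(nin, hu$stone["mean"], hu$stone["sd"] * ns)
        } else {
          # heterogeneous enhancement: a smooth random field splits the
          # tumor into low- and high-attenuation patches
          coarse <- array(rnorm(prod(pmax(2L, shape %/% 8L))),
                          c(1L, pmax(2L, shape %/% 8L)))
          field <- resize3d_fwd_cpp(coarse, as.integer(shape))[1, , , ]
          hi <- field > 0
          vals <- numeric(nin)
          hii <- hi[inside]
          vals[hii] <- rnorm(sum(hii), hu$tumor_high["mean"],
                             hu$tumor_high["sd"] * ns)
          vals[!hii] <- rnorm(sum(!hii), hu$tumor_low["mean"],
                              hu$tumor_low["sd"] * ns)
          img[inside] <- vals
        }
        lesions[[li]]$voxels <- nin
      }
    }
    LabeledVolume(img, mask, sp, patientId,
                  meta = list(lesionClass = lesionClass, lesions = lesions,
                              kidney = list(center = center, axes = axes)))
  })
}

#' Generate a cohort of phantoms
#'
#' Pathology classes are assigned multinomially from the spec's `classMix`
#' under the spec seed; each patient's volume then derives its own stream.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPatients number of patients (>= 1).
#' @return List of [LabeledVolume-class] objects with unique patient ids.
#' @export
generateCohort <- function(spec, nPatients) {
  if (nPatients < 1) nx_stop("nPatients must be >= 1")
  ids <- sprintf("P%05d", seq_len(nPatients))
  classes <- with_seed(spec@seed,
    sample(PATHOLOGY_CLASSES, nPatients, replace = TRUE, prob = spec@classMix))
  mapply(function(id, cl) generatePhantom(spec, id, lesionClass = cl),
         ids, classes, SIMPLIFY = FALSE)
}

#' Patient-level train/validation/test split
#'
#' Validation and test sizes are `round(f * n)` for the stated fractions;
#' training receives the remainder.  Assignment is a seeded shuffle, so the
#' same ids and seed always give the same partition.
#'
#' @param ids character patient ids.
#' @param fractions train/val/test proportions summing to one.
#' @param seed integer seed (default 42, the conventional split seed).
#' @return A [DatasetSplit-class].
#' @export
splitPatients <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 42L) {
  n <- length(ids)
  if (n < 3) nx_stop("need at least 3 patients to split")
  if (abs(sum(fractions) - 1) > 1e-9) nx_stop("fractions must sum to 1")
  if (anyDuplicated(ids)) nx_stop("patient ids must be unique")
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  perm <- with_seed(seed, sample(ids))
  new("DatasetSplit",
      trainIds = perm[seq_len(n - n_val - n_test)],
      valIds = perm[n - n_val - n_test + seq_len(n_val)],
      testIds = perm[n - n_test + seq_len(n_test)])
}

# separable Gaussian smoothing of a 3D array (via the conv kernel)
gauss_smooth3d <- function(arr, sigma) {
  sm <- array(arr, c(1L, dim(arr)))
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    half <- max(1L, ceiling(3 * sigma[ax]))
    k <- stats::dnorm(seq(-half, half), sd = sigma[ax])
    k <- k / sum(k)
    wd <- c(1L, 1L, 1L, 1L, 1L)
    wd[2 + ax] <- length(k)
    w <- array(k, wd)
    pad <- c(0L, 0L, 0L)
    pad[ax] <- half
    sm <- conv3d_fwd_cpp(sm, w, 0, c(1L, 1L, 1L), c(1L, 1L, 1L),
                         as.integer(pad), 1L)
  }
  array(sm, dim(arr))
}

#' Randomized augmentation of a labelled volume
#'
#' In-plane rotation (uniform in +/- 15 degrees, trilinear for the image
#' and nearest neighbor for the mask), a Gaussian-smoothed random elastic
#' displacement field, multiplicative intensity scaling in [0.9, 1.1] and
#' gamma correction in [0.8, 1.2] applied on min-max-rescaled intensities.
#'
#' @param v a [LabeledVolume-class].
#' @param seed integer seed.
#' @param params optional explicit transform parameters (list with
#'   `angle_deg`, `scale`, `gamma`, `elastic` displacement array
#'   (3, X, Y, Z)); when given, no sampling happens.
#' @param elastic_amp peak elastic displacement in voxels.
#' @param elastic_sigma smoothness (voxels) of the displacement field.
#' @return The augmented [LabeledVolume-class].
#' @export
augmentVolume <- function(v, seed = 1L, params = NULL, elastic_amp = 2,
                          elastic_sigma = 4) {
  d <- dim(v@image)
  if (is.null(params)) {
    params <- with_seed(seed, {
      el <- array(rnorm(3 * prod(d)), c(3, d))
      for (a in 1:3) {
        f <- gauss_smooth3d(el[a, , , ], rep(elastic_sigma, 3))
        el[a, , , ] <- f / max(abs(f), 1e-12) * elastic_amp
      }
      list(angle_deg = runif(1, -15, 15), scale = runif(1, 0.9, 1.1),
           gamma = runif(1, 0.8, 1.2), elastic = el)
    })
  }
  th <- params$angle_deg * pi / 180
  cx <- (d[1] - 1) / 2
  cy <- (d[2] - 1) / 2
  ix <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  # inverse in-plane rotation about the volume center
  sx <- cx + cos(th) * (ix - cx) + sin(th) * (iy - cy)
  sy <- cy - sin(th) * (ix - cx) + cos(th) * (iy - cy)
  sz <- iz
  if (!is.null(params$elastic)) {
    sx <- sx + as.vector(params$elastic[1, , , ])
    sy <- sy + as.vector(params$elastic[2, , , ])
    sz <- sz + as.vector(params$elastic[3, , , ])
  }
  pts <- rbind(sx, sy, sz)
  fill <- min(v@image)
  img <- array(sample3d_cpp(v@image, pts, fill, 0L), d)
  msk <- array(as.integer(sample3d_cpp(v@mask + 0.0, pts, 0, 1L)), d)
  img <- img * params$scale
  mn <- min(img); mx <- max(img)
  if (mx > mn) img <- ((img - mn) / (mx - mn))^params$gamma * (mx - mn) + mn
  LabeledVolume(img, msk, v@spacing, v@patientId,
                meta = c(v@meta, list(augmented = TRUE)))
}

#' Write a phantom cohort to NIfTI files with a CSV manifest
#'
#' One image and one mask file per patient (`.nii.gz`, voxel spacing in the
#' header) plus `manifest.csv` with patient id, split membership, lesion
#' class and file paths.
#'
#' @param volumes list of [LabeledVolume-class].
#' @param split a [DatasetSplit-class] covering the patient ids.
#' @param outDir output directory (created if missing).
#' @return The manifest as a data.frame, invisibly; also written as CSV.
#' @export
writeDataset <- function(volumes, split, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    nx_stop("cannot create output directory ", outDir)
  membership <- function(id) {
    if (id %in% split@trainIds) "train"
    else if (id %in% split@valIds) "val"
    else if (id %in% split@testIds) "test"
    else NA_character_
  }
  rows <- lapply(volumes, function(v) {
    id <- v@patientId
    img_path <- file.path(outDir, paste0(id, "_image.nii.gz"))
    msk_path <- file.path(outDir, paste0(id, "_mask.nii.gz"))
    im <- RNifti::asNifti(v@image)
    RNifti::pixdim(im) <- v@spacing
    mk <- RNifti::asNifti(v@mask)
    RNifti::pixdim(mk) <- v@spacing
    RNifti::writeNifti(im, img_path)
    RNifti::writeNifti(mk, msk_path)
    data.frame(patient_id = id, split = membership(id),
               class = v@meta$lesionClass %||% NA_character_,
               image_path = img_path, mask_path = msk_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one labelled volume back from a manifest row
#' @param row one row of the manifest written by [writeDataset()].
#' @return A [LabeledVolume-class].
#' @export
readVolume <- function(row) {
  img <- RNifti::readNifti(row$image_path)
  msk <- RNifti::readNifti(row$mask_path)
  sp <- RNifti::pixdim(img)
  LabeledVolume(array(as.numeric(img), dim(img)),
                array(as.integer(msk), dim(msk)), sp, row$patient_id,
                meta = list(lesionClass = row$class))
}
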