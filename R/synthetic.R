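# Seeded synthetic lesion-image generator.
#
# Emulates the *shape* of a two-modality (mammography / ultrasound) benign vs
# malignant lesion dataset so every downstream stage can be exercised without
# external image collections. Benign lesions are smooth ellipses; malignant
# lesions have a spiculated, star-shaped boundary. Mammogram-like images (MGI)
# put the lesion on a smooth low-frequency background with additive Gaussian
# noise; ultrasound-like images (USI) use a darker background and
# multiplicative unit-mean speckle.

# Run expr with a temporary RNG state seeded at `seed`; restores the caller's
# RNG stream afterwards. seed = NULL runs expr against the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Lesion specification
#'
#' Geometric description of a single synthetic lesion. Benign lesions must
#' have zero spicule amplitude; malignant lesions need at least 5 spicules and
#' a positive amplitude.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param modality `"MGI"` or `"USI"`.
#' @param center `(row, col)` center in pixels.
#' @param radii `(a, b)` ellipse semi-axes in pixels, both positive.
#' @param spicule_count integer >= 0; number of boundary lobes.
#' @param spicule_amplitude radial amplitude of the lobes, in pixels.
#' @param rotation ellipse rotation in radians.
#' @param phase angular phase of the spicule pattern in radians.
#' @return A `lwunet_lesion_spec` list.
#' @export
lesion_spec <- function(label, modality, center, radii, spicule_count = 0L,
                        spicule_amplitude = 0, rotation = 0, phase = 0) {
  lw_assert(label %in% LWUNET_LABELS, "unknown label: ", label,
            class = "lwunet_input_error")
  lw_assert(modality %in% LWUNET_MODALITIES, "unknown modality: ", modality,
            class = "lwunet_input_error")
  lw_assert(length(radii) == 2 && all(radii > 0), "radii must be two positives",
            class = "lwunet_input_error")
  if (label == "benign") {
    lw_assert(spicule_amplitude == 0, "benign lesions have no spicules",
              class = "lwunet_input_error")
  } else {
    lw_assert(spicule_count >= 5 && spicule_amplitude > 0,
              "malignant lesions need >= 5 spicules and positive amplitude",
              class = "lwunet_input_error")
  }
  structure(list(label = label, modality = modality,
                 center = as.numeric(center), radii = as.numeric(radii),
                 spicule_count = as.integer(spicule_count),
                 spicule_amplitude = as.numeric(spicule_amplitude),
                 rotation = as.numeric(rotation), phase = as.numeric(phase)),
            class = "lwunet_lesion_spec")
}

# Draw a randomized lesion spec from the generator's documented parameter
# ranges, using the current RNG stream.
sample_lesion_spec <- function(label, modality, size) {
  center <- size / 2 + stats::runif(2, -0.06, 0.06) * size
  radii <- stats::runif(2, 0.14, 0.22) * size
  if (label == "malignant") {
    k <- sample(8:12, 1)
    amp <- stats::runif(1, 0.25, 0.45) * mean(radii)
  } else {
    k <- 0L; amp <- 0
  }
  lesion_spec(label, modality, center, radii, k, amp,
              rotation = stats::runif(1, 0, 2 * pi),
              phase = stats::runif(1, 0, 2 * pi))
}

#' Rasterize a lesion mask
#'
#' Renders the lesion boundary `r(phi) = r_ellipse(phi) * (1 + a*cos(k*phi +
#' phase))` onto a `size x size` binary grid. Benign specs (amplitude 0) give
#' a plain ellipse. The mask is a deterministic function of the spec.
#'
#' @param spec a [lesion_spec()].
#' @param size image edge length in pixels.
#' @return `size x size` 0/1 matrix.
#' @export
make_lesion_mask <- function(spec, size) {
  lw_assert(inherits(spec, "lwunet_lesion_spec"), "spec must be a lesion_spec",
            class = "lwunet_input_error")
  a <- spec$radii[1]; b <- spec$radii[2]
  amp_frac <- if (spec$spicule_amplitude > 0)
    spec$spicule_amplitude / mean(spec$radii) else 0
  r_max <- max(a, b) * (1 + amp_frac)
  fits <- all(spec$center - r_max >= 1) && all(spec$center + r_max <= size)
  lw_assert(fits, "lesion does not fit within the image",
            class = "lwunet_spec_error")
  ij <- expand.grid(i = seq_len(size), j = seq_len(size))
  dy <- ij$i - spec$center[1]
  dx <- ij$j - spec$center[2]
  ct <- cos(spec$rotation); st <- sin(spec$rotation)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  m <- 1 + amp_frac * cos(spec$spicule_count * phi + spec$phase)
  matrix(as.numeric(rho <= m), size, size)
}

# 3x3 box blur with replicated edges; `passes` repeats.
box_blur3 <- function(x, passes = 1) {
  for (p in seq_len(passes)) {
    h <- nrow(x); w <- ncol(x)
    xp <- x[c(1, 1:h, h), , drop = FALSE][, c(1, 1:w, w), drop = FALSE]
    acc <- matrix(0, h, w)
    for (dy in 0:2) for (dx in 0:2)
      acc <- acc + xp[dy + 1:h, dx + 1:w]
    x <- acc / 9
  }
  x
}

#' Boundary irregularity of a binary mask
#'
#' Digital isoperimetric quotient `perimeter^2 / (4 * pi * area)`, with the
#' perimeter taken as the number of exposed 4-neighbor faces of mask pixels.
#' A disc scores lowest; spiculated shapes score strictly higher at equal
#' radii, which is the signal separating the two synthetic classes.
#'
#' @param mask 0/1 matrix.
#' @return Scalar irregularity (>= ~1 up to digitization effects).
#' @export
mask_irregularity <- function(mask) {
  area <- sum(mask)
  lw_assert(area > 0, "empty mask", class = "lwunet_input_error")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  per <- sum(core * (1 - pad[1:h, 2:(w + 1)])) +
    sum(core * (1 - pad[3:(h + 2), 2:(w + 1)])) +
    sum(core * (1 - pad[2:(h + 1), 1:w])) +
    sum(core * (1 - pad[2:(h + 1), 3:(w + 2)]))
  per^2 / (4 * pi * area)
}

# Label 4-connected components of a binary matrix by stack-based flood fill;
# returns the largest one.
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- integer(h * w)
  cur <- 0L
  stack <- integer(h * w)
  for (s in which(mask == 1)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    stack[1] <- s
    top <- 1L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- (p - 1L) %% h + 1L
      j <- (p - 1L) %/% h + 1L
      if (i > 1L && mask[p - 1L] == 1 && lab[p - 1L] == 0L) {
        lab[p - 1L] <- cur; top <- top + 1L; stack[top] <- p - 1L
      }
      if (i < h && mask[p + 1L] == 1 && lab[p + 1L] == 0L) {
        lab[p + 1L] <- cur; top <- top + 1L; stack[top] <- p + 1L
      }
      if (j > 1L && mask[p - h] == 1 && lab[p - h] == 0L) {
        lab[p - h] <- cur; top <- top + 1L; stack[top] <- p - h
      }
      if (j < w && mask[p + h] == 1 && lab[p + h] == 0L) {
        lab[p + h] <- cur; top <- top + 1L; stack[top] <- p + h
      }
    }
  }
  if (cur == 0L) return(mask)
  best <- which.max(tabulate(lab[lab > 0L]))
  matrix(as.numeric(lab == best), h, w)
}

# Fill interior holes: background not reachable from the image border becomes
# foreground.
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- mask == 0
  reach <- matrix(FALSE, h, w)
  stack <- integer(h * w)
  top <- 0L
  border <- unique(c(which(row(mask) == 1 | row(mask) == h),
                     which(col(mask) == 1 | col(mask) == w)))
  for (p in border) {
    if (bg[p] && !reach[p]) { reach[p] <- TRUE; top <- top + 1L; stack[top] <- p }
  }
  while (top > 0L) {
    p <- stack[top]; top <- top - 1L
    i <- (p - 1L) %% h + 1L
    j <- (p - 1L) %/% h + 1L
    if (i > 1L && bg[p - 1L] && !reach[p - 1L]) {
      reach[p - 1L] <- TRUE; top <- top + 1L; stack[top] <- p - 1L
    }
    if (i < h && bg[p + 1L] && !reach[p + 1L]) {
      reach[p + 1L] <- TRUE; top <- top + 1L; stack[top] <- p + 1L
    }
    if (j > 1L && bg[p - h] && !reach[p - h]) {
      reach[p - h] <- TRUE; top <- top + 1L; stack[top] <- p - h
    }
    if (j < w && bg[p + h] && !reach[p + h]) {
      reach[p + h] <- TRUE; top <- top + 1L; stack[top] <- p + h
    }
  }
  mask[bg & !reach] <- 1
  mask
}

#' Segment the lesion in a synthetic image
#'
#' Quick intensity-based segmentation used to check that the generated classes
#' are separable from the images alone: blur, threshold at an upper intensity
#' quantile (lesions are rendered brighter than background in both
#' modalities), keep the largest connected component, and fill interior holes.
#'
#' @param img `H x W` or `H x W x C` intensity array.
#' @param q quantile cut (default 0.9, roughly the lesion area fraction).
#' @param blur_passes 3x3 box-blur passes applied first (default 3).
#' @return 0/1 matrix.
#' @export
segment_lesion <- function(img, q = 0.9, blur_passes = 3) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  s <- box_blur3(img, blur_passes)
  fill_holes(largest_component((s > stats::quantile(s, q)) * 1))
}

#' Render a lesion mask in a given modality
#'
#' MGI: a fixed smooth low-frequency background plus `+85` lesion contrast
#' (soft-edged) and additive Gaussian noise of standard deviation `noise_sd`.
#' USI: darker background (55) with lesion plateau at 150, multiplied by
#' unit-mean gamma speckle with shape `speckle_shape`. Output is clipped to
#' `[0, 255]`. With `noise_sd = 0`, the MGI render is a deterministic function
#' of the mask.
#'
#' @param mask 0/1 matrix from [make_lesion_mask()].
#' @param modality `"MGI"` or `"USI"`.
#' @param noise_sd additive noise sd for MGI (default 8).
#' @param speckle_shape gamma shape of USI speckle (default 4; unit mean).
#' @param seed optional integer; when given, rendering noise is drawn from a
#'   temporary RNG stream seeded with it.
#' @return `H x W` intensity matrix in `[0, 255]`.
#' @export
render_modality <- function(mask, modality, noise_sd = 8, speckle_shape = 4,
                            seed = NULL) {
  lw_assert(is.matrix(mask) && all(mask %in% c(0, 1)), "mask must be binary",
            class = "lwunet_input_error")
  lw_assert(modality %in% LWUNET_MODALITIES, "unknown modality tag: ", modality,
            class = "lwunet_input_error")
  h <- nrow(mask); w <- ncol(mask)
  soft <- box_blur3(mask, 2)
  with_seed(seed, {
    if (modality == "MGI") {
      ii <- matrix(seq_len(h), h, w)
      jj <- matrix(seq_len(w), h, w, byrow = TRUE)
      bg <- 110 + 25 * sin(2 * pi * (0.6 * ii + 0.25 * jj) / h) +
        20 * cos(2 * pi * (0.3 * ii - 0.5 * jj) / h + 1)
      img <- bg + 85 * soft
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    } else {
      img <- (55 + 95 * soft) *
        matrix(stats::rgamma(h * w, shape = speckle_shape,
                             rate = speckle_shape), h, w)
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Generate a synthetic multimodal lesion dataset
#'
#' Writes `n_per_class_per_modality` images for every class x modality cell
#' (8-bit RGB PNG; the grayscale render replicated to three planes), splits
#' them into train/test stratified by class x modality, and writes the CSV
#' manifest plus a JSON sidecar echoing the generation config. Fully seeded:
#' the same seed reproduces identical manifests and image bytes.
#'
#' @param n_per_class_per_modality images per class per modality (>= 1).
#' @param size image edge length in pixels (default 256).
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param train_fraction fraction assigned to the train split (default 0.8).
#' @param modalities which modalities to generate (default both).
#' @return The generated `lwunet_manifest`.
#' @export
generate_dataset <- function(n_per_class_per_modality, size = 256, seed = 1,
                             out_dir, train_fraction = 0.8,
                             modalities = LWUNET_MODALITIES) {
  n <- n_per_class_per_modality
  lw_assert(n >= 1, "n_per_class_per_modality must be >= 1",
            class = "lwunet_input_error")
  lw_assert(train_fraction > 0 && train_fraction < 1,
            "train_fraction must be in (0, 1)", class = "lwunet_input_error")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lw_assert(dir.exists(out_dir), "cannot create out_dir: ", out_dir,
            class = "lwunet_io_error")
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  rows <- list()
  with_seed(seed, {
    for (mod in modalities) {
      for (lab in LWUNET_LABELS) {
        n_train <- round(n * train_fraction)
        split <- c(rep("train", n_train), rep("test", n - n_train))
        for (i in seq_len(n)) {
          spec <- sample_lesion_spec(lab, mod, size)
          mask <- make_lesion_mask(spec, size)
          img <- render_modality(mask, mod)
          rgb <- array(img, dim = c(size, size, 3))
          p <- file.path(img_dir, sprintf("%s_%s_%04d.png", mod, lab, i))
          write_image_png(rgb, p)
          rows[[length(rows) + 1]] <- data.frame(
            path = p, modality = mod, label = lab, split = split[i],
            fold = "none", stringsAsFactors = FALSE)
        }
      }
    }
  })
  m <- manifest(do.call(rbind, rows), image_size = size, seed = seed)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  cfg <- list(n_per_class_per_modality = n, size = size, seed = seed,
              train_fraction = train_fraction, modalities = modalities)
  jsonlite::write_json(cfg, file.path(out_dir, "generation.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  m
}
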