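# Synthetic section images and autoradiographs with known ground truth.

# Pixel-center coordinate grids for an nrow x ncol image (1-based).
pixel_grid <- function(shape) {
  list(
    row = matrix(seq_len(shape[1]), shape[1], shape[2]),
    col = matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  )
}

# Mask of pixels within `radius` of the segment (r0,c0)-(r1,c1).
tube_mask <- function(shape, r0, c0, r1, c1, radius, grid = pixel_grid(shape)) {
  dr <- r1 - r0
  dc <- c1 - c0
  len2 <- dr^2 + dc^2
  if (len2 == 0) {
    d2 <- (grid$row - r0)^2 + (grid$col - c0)^2
  } else {
    t <- ((grid$row - r0) * dr + (grid$col - c0) * dc) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (grid$row - (r0 + t * dr))^2 + (grid$col - (c0 + t * dc))^2
  }
  d2 <= radius^2
}

#' Random vessel specification for the section generator
#'
#' Places short straight vessel segments of random orientation, rejecting
#' placements that would overlap an existing vessel so per-vessel ground
#' truth stays exact. Vessels of class `"btb"` are placed inside lesions,
#' class `"bbb"` outside. Per-vessel marker intensities are drawn
#' `N(mean, sd)` and truncated at 1.
#'
#' @param n_bbb,n_btb number of vessels per class.
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param lesions lesion specification (see [generate_section()]); required
#'   when `n_btb > 0`.
#' @param radius_range vessel radius range in pixels.
#' @param length_range segment length range in pixels.
#' @param mean_bbb,mean_btb,sd per-class mean and common SD of the
#'   per-vessel transporter intensity (arbitrary units).
#' @param seed integer seed.
#' @return data.frame with one row per vessel: `vessel_id`, `class`,
#'   `r0`, `c0`, `r1`, `c1`, `radius_px`, `pgp_intensity`.
#' @export
random_vessel_spec <- function(n_bbb = 20, n_btb = 12, shape = c(224, 224),
                               lesions = NULL, radius_range = c(1.5, 3),
                               length_range = c(6, 14),
                               mean_bbb = 22.6, mean_btb = 22.9, sd = 10,
                               seed = 1) {
  if (n_btb > 0 && is.null(lesions)) {
    stop("`lesions` required to place btb vessels", call. = FALSE)
  }
  grid <- pixel_grid(shape)
  lesion_px <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      lesion_px <- lesion_px |
        ((grid$row - lesions$cr[i])^2 + (grid$col - lesions$cc[i])^2 <=
           lesions$radius_px[i]^2)
    }
  }
  with_seed(substream_seed(seed, "vessels"), {
    occupied <- matrix(FALSE, shape[1], shape[2])
    rows <- list()
    classes <- c(rep("bbb", n_bbb), rep("btb", n_btb))
    means <- c(rep(mean_bbb, n_bbb), rep(mean_btb, n_btb))
    id <- 0L
    for (k in seq_along(classes)) {
      placed <- FALSE
      for (try in 1:200) {
        rad <- stats::runif(1, radius_range[1], radius_range[2])
        ang <- stats::runif(1, 0, pi)
        if (classes[k] == "btb") {
          # sample the whole segment inside one lesion: midpoint within the
          # lesion center's safe disc, half-length bounded by what fits
          li <- sample.int(nrow(lesions), 1)
          slack <- lesions$radius_px[li] - rad - 1
          if (slack <= 1) next
          len <- stats::runif(1, min(length_range[1], slack),
                              min(length_range[2], 2 * slack))
          dmax <- max(slack - len / 2, 0)
          u <- stats::runif(1, 0, dmax^2)
          th <- stats::runif(1, 0, 2 * pi)
          rm <- lesions$cr[li] + sqrt(u) * cos(th)
          cm <- lesions$cc[li] + sqrt(u) * sin(th)
        } else {
          len <- stats::runif(1, length_range[1], length_range[2])
          rm <- stats::runif(1, rad + 1 + len / 2, shape[1] - rad - 1 - len / 2)
          cm <- stats::runif(1, rad + 1 + len / 2, shape[2] - rad - 1 - len / 2)
        }
        r0 <- rm - len / 2 * cos(ang)
        c0 <- cm - len / 2 * sin(ang)
        r1 <- rm + len / 2 * cos(ang)
        c1 <- cm + len / 2 * sin(ang)
        m <- tube_mask(shape, r0, c0, r1, c1, rad + 1, grid)
        inside <- mean(lesion_px[tube_mask(shape, r0, c0, r1, c1, rad, grid)])
        ok_class <- if (classes[k] == "btb") inside == 1 else inside == 0
        if (ok_class && !any(occupied & m)) {
          occupied <- occupied | m
          id <- id + 1L
          rows[[id]] <- data.frame(
            vessel_id = id, class = classes[k],
            r0 = r0, c0 = c0, r1 = r1, c1 = c1, radius_px = rad,
            pgp_intensity = max(1, stats::rnorm(1, means[k], sd))
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warning(sprintf("could not place a %s vessel without overlap; skipped",
                        classes[k]))
      }
    }
    do.call(rbind, rows)
  })
}

#' Random lesion specification for the section generator
#'
#' Circular metastatic lesions with per-tracer amplification factors over
#' surrounding tissue. Lesions are placed without mutual overlap.
#'
#' @param n number of lesions.
#' @param shape image dimensions.
#' @param radius_range lesion radius range in pixels.
#' @param fold_aib,fold_r123 amplification of the passive tracer and of the
#'   efflux-substrate fluorescence inside each lesion; scalars are recycled.
#' @param seed integer seed.
#' @return data.frame with columns `lesion_id`, `cr`, `cc`, `radius_px`,
#'   `fold_r123`, `fold_aib`.
#' @export
random_lesion_spec <- function(n = 4, shape = c(224, 224),
                               radius_range = c(14, 22),
                               fold_aib = 4.9, fold_r123 = 0.98, seed = 1) {
  fold_aib <- rep_len(fold_aib, n)
  fold_r123 <- rep_len(fold_r123, n)
  with_seed(substream_seed(seed, "lesions"), {
    out <- NULL
    for (k in seq_len(n)) {
      for (try in 1:500) {
        rad <- stats::runif(1, radius_range[1], radius_range[2])
        cr <- stats::runif(1, rad + 2, shape[1] - rad - 2)
        cc <- stats::runif(1, rad + 2, shape[2] - rad - 2)
        clear <- is.null(out) ||
          all(sqrt((out$cr - cr)^2 + (out$cc - cc)^2) > out$radius_px + rad + 4)
        if (clear) {
          out <- rbind(out, data.frame(
            lesion_id = k, cr = cr, cc = cc, radius_px = rad,
            fold_r123 = fold_r123[k], fold_aib = fold_aib[k]
          ))
          break
        }
      }
    }
    out
  })
}

#' Simulate a stained, perfused brain section with ground-truth masks
#'
#' Renders a four-channel section (`nuclei`, `endothelial`, `pgp`, `r123`)
#' on one pixel grid. Vessels are constant-intensity tubes: the endothelial
#' marker channel is nonzero only on vessel tubes, and the transporter
#' channel carries each vessel's configured intensity on its tube (plus an
#' optional pericellular rim just inside lesion boundaries). The
#' efflux-substrate fluorescence channel equals the background tissue level
#' times each lesion's amplification factor inside lesion masks. Optical
#' blur (Gaussian) and additive Gaussian noise are applied last, so with
#' both at zero every region statistic equals its configured ground truth
#' exactly. True label masks are returned alongside the image.
#'
#' @param shape image dimensions `c(nrow, ncol)`.
#' @param pixel_size lateral pixel size, um/pixel.
#' @param thickness section thickness, um.
#' @param vessels vessel specification (see [random_vessel_spec()]); rows
#'   with `radius_px < 1` are skipped with a warning.
#' @param lesions lesion specification (see [random_lesion_spec()]);
#'   duplicated `lesion_id`s or overlapping lesions are an error.
#' @param tissue_level background tissue fluorescence in the `r123` channel.
#' @param endothelial_intensity tube intensity of the endothelial marker.
#' @param nuclei_level base nuclei-channel level; inside lesions it is
#'   multiplied by `nuclei_lesion_fold` (tumors are nuclei-dense).
#' @param nuclei_lesion_fold nuclear density amplification inside lesions.
#' @param lesion_pgp_rim intensity of a 2-px transporter rim just inside
#'   each lesion boundary (0 disables; models transporter on tumor cells
#'   adjacent to the vasculature).
#' @param blur_sigma Gaussian optical blur SD in pixels (0 disables).
#' @param noise_sd additive Gaussian noise SD (0 disables); negative pixels
#'   are clamped to 0.
#' @param exposure_tag acquisition label stored on the image.
#' @param seed integer seed.
#' @return list with elements `image` (a [section_image()]), `vessel_mask`
#'   and `lesion_mask` (integer label matrices, 0 = background), and
#'   `ground_truth` (the specifications and levels used).
#' @export
generate_section <- function(shape = c(224, 224), pixel_size = 2,
                             thickness = 20,
                             vessels = NULL, lesions = NULL,
                             tissue_level = 10, endothelial_intensity = 100,
                             nuclei_level = 20, nuclei_lesion_fold = 3,
                             lesion_pgp_rim = 0,
                             blur_sigma = 0, noise_sd = 0,
                             exposure_tag = "simulated_15ms_gain615",
                             seed = 1) {
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(blur_sigma, "blur_sigma", strict = FALSE)
  grid <- pixel_grid(shape)
  zero <- matrix(0, shape[1], shape[2])

  lesion_mask <- zero
  if (!is.null(lesions) && nrow(lesions)) {
    if (anyDuplicated(lesions$lesion_id)) {
      stop("duplicated lesion ids", call. = FALSE)
    }
    for (i in seq_len(nrow(lesions))) {
      m <- (grid$row - lesions$cr[i])^2 + (grid$col - lesions$cc[i])^2 <=
        lesions$radius_px[i]^2
      if (any(lesion_mask[m] != 0)) {
        stop("overlapping lesions", call. = FALSE)
      }
      lesion_mask[m] <- lesions$lesion_id[i]
    }
  }

  vessel_mask <- zero
  pgp <- zero
  endo <- zero
  if (!is.null(vessels) && nrow(vessels)) {
    small <- vessels$radius_px < 1
    if (any(small)) {
      warning(sprintf("%d vessel(s) with radius < 1 px skipped", sum(small)))
      vessels <- vessels[!small, , drop = FALSE]
    }
    for (i in seq_len(nrow(vessels))) {
      m <- tube_mask(shape, vessels$r0[i], vessels$c0[i],
                     vessels$r1[i], vessels$c1[i], vessels$radius_px[i], grid)
      vessel_mask[m] <- vessels$vessel_id[i]
      pgp[m] <- vessels$pgp_intensity[i]
      endo[m] <- endothelial_intensity
    }
  }
  if (lesion_pgp_rim > 0 && !is.null(lesions) && nrow(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      d2 <- (grid$row - lesions$cr[i])^2 + (grid$col - lesions$cc[i])^2
      rim <- d2 <= lesions$radius_px[i]^2 &
        d2 > (lesions$radius_px[i] - 2)^2
      rim <- rim & vessel_mask == 0
      pgp[rim] <- lesion_pgp_rim
    }
  }

  fold_r123 <- matrix(1, shape[1], shape[2])
  nuc_fold <- matrix(1, shape[1], shape[2])
  if (!is.null(lesions) && nrow(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      inside <- lesion_mask == lesions$lesion_id[i]
      fold_r123[inside] <- lesions$fold_r123[i]
      nuc_fold[inside] <- nuclei_lesion_fold
    }
  }
  r123 <- tissue_level * fold_r123
  nuclei <- nuclei_level * nuc_fold

  channels <- list(nuclei = nuclei, endothelial = endo, pgp = pgp,
                   r123 = r123)
  if (blur_sigma > 0) {
    channels <- lapply(channels, function(ch) {
      as.matrix(EBImage::gblur(EBImage::Image(ch), sigma = blur_sigma))
    })
  }
  if (noise_sd > 0) {
    channels <- with_seed(substream_seed(seed, "section_noise"), {
      lapply(channels, function(ch) {
        pmax(ch + matrix(stats::rnorm(length(ch), 0, noise_sd), nrow(ch)), 0)
      })
    })
  }

  list(
    image = section_image(channels, pixel_size, thickness, exposure_tag),
    vessel_mask = vessel_mask,
    lesion_mask = lesion_mask,
    ground_truth = list(
      vessels = vessels, lesions = lesions, tissue_level = tissue_level,
      endothelial_intensity = endothelial_intensity,
      nuclei_level = nuclei_level, nuclei_lesion_fold = nuclei_lesion_fold,
      blur_sigma = blur_sigma, noise_sd = noise_sd, seed = seed
    )
  )
}

# Block-mean downsample, padding with `fill` up to a multiple of `f`.
block_mean <- function(x, f, fill) {
  if (f == 1) return(x)
  nr <- ceiling(nrow(x) / f) * f
  nc <- ceiling(ncol(x) / f) * f
  p <- matrix(fill, nr, nc)
  p[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  ri <- (seq_len(nr) - 1L) %/% f
  ci <- (seq_len(nc) - 1L) %/% f
  out <- t(rowsum(t(rowsum(p, ri)), ci) / f^2)
  dimnames(out) <- NULL
  out
}

#' Simulate a quantitative autoradiograph of a sectioned brain
#'
#' Builds the passive-tracer activity image on the section's pixel grid
#' (background activity times each lesion's amplification inside its mask),
#' optionally displaces it by a known integer shift (in section-grid
#' pixels), then block-averages down to the coarser autoradiography
#' resolution. Before noise, the lesion-region mean divided by the
#' background mean equals the configured fold exactly. The output's
#' dimensions are `ceiling(section_dim / downsample_factor)`.
#'
#' @param section output of [generate_section()] (its lesion mask and
#'   lesion table define the activity layout).
#' @param downsample_factor integer >= 1, autoradiograph pixel =
#'   `downsample_factor` section pixels.
#' @param fold_map optional named numeric vector (`lesion_id` -> fold)
#'   overriding the section's `fold_aib` values.
#' @param background background activity level (arbitrary units > 0).
#' @param shift_px known integer displacement `c(dy, dx)` of the activity
#'   relative to the section grid, for registration tests; exposed in the
#'   returned metadata.
#' @param noise_sd additive Gaussian noise SD applied after downsampling.
#' @param seed integer seed.
#' @return object of class `autoradiograph`: list with `activity` matrix,
#'   `downsample_factor`, `pixel_size` (um/px), `shift_px`, `background`.
#' @export
generate_autoradiograph <- function(section, downsample_factor = 4,
                                    fold_map = NULL, background = 50,
                                    shift_px = c(0L, 0L), noise_sd = 0,
                                    seed = 1) {
  if (downsample_factor < 1 || downsample_factor != round(downsample_factor)) {
    stop("`downsample_factor` must be an integer >= 1", call. = FALSE)
  }
  check_positive(background, "background")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  shift_px <- as.integer(round(shift_px))
  lesions <- section$ground_truth$lesions
  act <- matrix(background, nrow(section$lesion_mask),
                ncol(section$lesion_mask))
  if (!is.null(lesions) && nrow(lesions)) {
    folds <- lesions$fold_aib
    names(folds) <- as.character(lesions$lesion_id)
    if (!is.null(fold_map)) folds[names(fold_map)] <- fold_map
    for (i in seq_len(nrow(lesions))) {
      id <- as.character(lesions$lesion_id[i])
      act[section$lesion_mask == lesions$lesion_id[i]] <-
        background * folds[[id]]
    }
  }
  if (any(shift_px != 0L)) {
    shifted <- matrix(background, nrow(act), ncol(act))
    src_r <- seq_len(nrow(act)) - shift_px[1]
    src_c <- seq_len(ncol(act)) - shift_px[2]
    ok_r <- src_r >= 1 & src_r <= nrow(act)
    ok_c <- src_c >= 1 & src_c <= ncol(act)
    shifted[ok_r, ok_c] <- act[src_r[ok_r], src_c[ok_c]]
    act <- shifted
  }
  act <- block_mean(act, downsample_factor, fill = background)
  if (noise_sd > 0) {
    act <- with_seed(substream_seed(seed, "autorad_noise"), {
      pmax(act + matrix(stats::rnorm(length(act), 0, noise_sd), nrow(act)), 0)
    })
  }
  structure(
    list(activity = act, downsample_factor = as.integer(downsample_factor),
         pixel_size = section$image$pixel_size * downsample_factor,
         shift_px = shift_px, background = background),
    class = "autoradiograph"
  )
}

#' @export
print.autoradiograph <- function(x, ...) {
  cat(sprintf(
    "autoradiograph: %d x %d px (x%d downsample, %g um/px), shift (%d, %d)\n",
    nrow(x$activity), ncol(x$activity), x$downsample_factor, x$pixel_size,
    x$shift_px[1], x$shift_px[2]))
  invisible(x)
}
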