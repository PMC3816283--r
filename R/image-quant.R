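# Per-vessel expression, lesion fold changes, and modality co-registration.

# 8-connected component labeling (breadth-first frontier expansion).
# EBImage's labeling is 4-connected; diagonal continuity matters for thin
# angled vessel tubes, so labeling is done here with the 8-neighborhood.
label_components8 <- function(bin) {
  nr <- nrow(bin)
  nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  remaining <- bin
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  next_lab <- 0L
  for (s in which(bin)) {
    if (!remaining[s]) next
    next_lab <- next_lab + 1L
    lab[s] <- next_lab
    remaining[s] <- FALSE
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc0 <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (o in 1:8) {
        rr <- r + dr[o]
        cc <- cc0 + dc[o]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr[remaining[nbr]])
      if (length(nbr)) {
        lab[nbr] <- next_lab
        remaining[nbr] <- FALSE
      }
      frontier <- nbr
    }
  }
  lab
}

#' Segment vessels from an endothelial-marker channel
#'
#' Thresholds the endothelial channel (Otsu's method by default, or a
#' manual threshold) and labels 8-connected components; components smaller
#' than `min_size` pixels are dropped and counted. An all-constant channel
#' yields an empty mask (0 vessels), not an error.
#'
#' @param channel 2-D numeric matrix (endothelial marker intensities).
#' @param min_size minimum component size in pixels (default 10).
#' @param method `"otsu"` or `"manual"`.
#' @param threshold numeric threshold, required for `method = "manual"`;
#'   pixels strictly above it are foreground.
#' @return object of class `vessel_mask`: `labels` (integer matrix, 0 =
#'   background), `n_vessels`, `sizes` (pixels per vessel), `threshold`,
#'   `method`, `min_size`, `n_dropped` (undersized components rejected).
#' @export
segment_vessels <- function(channel, min_size = 10, method = c("otsu", "manual"),
                            threshold = NULL) {
  stopifnot(is.matrix(channel))
  method <- match.arg(method)
  rng <- range(channel)
  if (method == "otsu") {
    if (rng[1] == rng[2]) {
      # constant image: nothing to threshold
      return(structure(
        list(labels = matrix(0L, nrow(channel), ncol(channel)),
             n_vessels = 0L, sizes = integer(0), threshold = NA_real_,
             method = method, min_size = min_size, n_dropped = 0L),
        class = "vessel_mask"))
    }
    threshold <- EBImage::otsu(EBImage::Image(channel), range = rng,
                               levels = 256)
  } else if (is.null(threshold)) {
    stop("`threshold` required for manual method", call. = FALSE)
  }
  bin <- channel > threshold
  lab <- label_components8(bin)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  n_dropped <- sum(sizes > 0) - length(keep)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  fg <- lab > 0L
  out[fg] <- relab[lab[fg]]
  structure(
    list(labels = out, n_vessels = length(keep),
         sizes = sizes[keep], threshold = as.numeric(threshold),
         method = method, min_size = min_size, n_dropped = n_dropped),
    class = "vessel_mask"
  )
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("vessel_mask: %d vessel(s) (%s threshold %.4g, min %d px, %d dropped)\n",
              x$n_vessels, x$method, x$threshold, x$min_size, x$n_dropped))
  invisible(x)
}

#' Per-vessel mean intensity of a target channel
#'
#' Averages the target channel (e.g. the transporter stain) over each
#' labeled vessel region, and summarizes per vessel class (BBB vs BTB) as
#' mean +/- SEM of the per-vessel means when class labels are supplied.
#'
#' @param channel 2-D target channel, same shape as the mask.
#' @param mask a [segment_vessels()] result, or an integer label matrix
#'   (0 = background).
#' @param classes optional data.frame with columns `vessel_id`, `class`
#'   assigning each vessel to a group.
#' @return list with `per_vessel` (data.frame `vessel_id`, `class`,
#'   `mean_intensity`, `n_pixels`) and `summary` (per-class `mean`, `sem`,
#'   `n`; NULL without classes).
#' @export
vessel_expression <- function(channel, mask, classes = NULL) {
  labels <- if (inherits(mask, "vessel_mask")) mask$labels else mask
  if (!all(dim(channel) == dim(labels))) {
    stop("channel and mask shapes differ", call. = FALSE)
  }
  ids <- sort(unique(labels[labels > 0]))
  per <- data.frame(
    vessel_id = ids,
    class = NA_character_,
    mean_intensity = vapply(ids, function(k) mean(channel[labels == k]),
                            numeric(1)),
    n_pixels = vapply(ids, function(k) sum(labels == k), numeric(1))
  )
  summary <- NULL
  if (!is.null(classes)) {
    per$class <- classes$class[match(per$vessel_id, classes$vessel_id)]
    summary <- do.call(rbind, lapply(split(per, per$class), function(d) {
      data.frame(class = d$class[1], mean = mean(d$mean_intensity),
                 sem = sem(d$mean_intensity), n = nrow(d))
    }))
    rownames(summary) <- NULL
  }
  list(per_vessel = per, summary = summary)
}

#' Brain-distant-to-tumor reference mask
#'
#' Normal-appearing tissue used as the fold-change denominator: all
#' non-lesion pixels at least `margin_px` pixels (Euclidean) from any
#' lesion pixel.
#'
#' @param lesion_mask integer lesion label matrix (0 = background).
#' @param margin_px exclusion margin around lesions in pixels (default 50).
#' @return logical matrix.
#' @export
bdt_mask <- function(lesion_mask, margin_px = 50) {
  if (all(lesion_mask == 0)) {
    return(matrix(TRUE, nrow(lesion_mask), ncol(lesion_mask)))
  }
  d <- as.matrix(EBImage::distmap(EBImage::Image(lesion_mask == 0)))
  lesion_mask == 0 & d >= margin_px
}

#' Per-lesion tracer fold change over brain distant to tumor
#'
#' For each lesion, the mean signal inside the lesion divided by the mean
#' over the brain-distant-to-tumor (BDT) reference region, plus the lesion
#' area from its pixel count.
#'
#' @param signal 2-D tracer image (fluorescence or upsampled activity).
#' @param lesion_mask integer lesion label matrix.
#' @param bdt logical BDT mask (e.g. [bdt_mask()]); must not intersect
#'   lesions and must have positive mean signal.
#' @param pixel_size um/pixel, for areas in mm^2.
#' @return data.frame with `lesion_id`, `n_pixels`, `area_mm2`, `fold`.
#' @export
lesion_fold_change <- function(signal, lesion_mask, bdt, pixel_size) {
  stopifnot(all(dim(signal) == dim(lesion_mask)),
            all(dim(signal) == dim(bdt)))
  check_positive(pixel_size, "pixel_size")
  if (any(bdt & lesion_mask > 0)) {
    stop("BDT mask overlaps lesions", call. = FALSE)
  }
  if (!any(bdt)) stop("empty BDT mask", call. = FALSE)
  bdt_mean <- mean(signal[bdt])
  if (bdt_mean <= 0) stop("BDT mean signal must be > 0", call. = FALSE)
  ids <- sort(unique(lesion_mask[lesion_mask > 0]))
  n_px <- vapply(ids, function(k) sum(lesion_mask == k), numeric(1))
  data.frame(
    lesion_id = ids,
    n_pixels = n_px,
    area_mm2 = n_px * pixel_size^2 * 1e-6,
    fold = vapply(ids, function(k) mean(signal[lesion_mask == k]),
                  numeric(1)) / bdt_mean
  )
}

#' Co-register an autoradiograph to a fluorescence section
#'
#' Upsamples the coarse activity image onto the section grid using its
#' downsample metadata (pixel replication), then finds the integer
#' translation of the autoradiograph content relative to the section that
#' maximizes the Pearson correlation over the overlap, by exhaustive search
#' within `+/- max_shift` pixels. Same-slice modalities share orientation,
#' so only translation is searched.
#'
#' @param reference 2-D section-grid image carrying the landmarks (e.g. the
#'   nuclei channel: lesions are nuclei-dense and activity-bright).
#' @param autorad an [generate_autoradiograph()] object, or a matrix
#'   already on the section grid.
#' @param max_shift search window half-width in section pixels.
#' @return list with `shift` (`c(dy, dx)`: displacement of the
#'   autoradiograph content relative to the reference), `correlation` at
#'   the optimum, and the full `correlation_grid`. A flat input is an
#'   error; a best correlation below 0.2 raises a warning.
#' @export
register_modalities <- function(reference, autorad, max_shift = 10) {
  up <- if (inherits(autorad, "autoradiograph")) {
    f <- autorad$downsample_factor
    u <- autorad$activity[rep(seq_len(nrow(autorad$activity)), each = f),
                          rep(seq_len(ncol(autorad$activity)), each = f)]
    u[seq_len(nrow(reference)), seq_len(ncol(reference)), drop = FALSE]
  } else {
    autorad
  }
  if (!all(dim(up) == dim(reference))) {
    stop("autoradiograph does not cover the section grid", call. = FALSE)
  }
  if (stats::sd(reference) == 0 || stats::sd(up) == 0) {
    stop("cannot register a flat (zero-variance) image", call. = FALSE)
  }
  nr <- nrow(reference)
  nc <- ncol(reference)
  shifts <- -max_shift:max_shift
  cg <- matrix(NA_real_, length(shifts), length(shifts),
               dimnames = list(dy = shifts, dx = shifts))
  for (iy in seq_along(shifts)) {
    for (ix in seq_along(shifts)) {
      dy <- shifts[iy]
      dx <- shifts[ix]
      r1 <- max(1, 1 - dy):min(nr, nr - dy)
      c1 <- max(1, 1 - dx):min(nc, nc - dx)
      a <- reference[r1, c1]
      b <- up[r1 + dy, c1 + dx]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) {
        cg[iy, ix] <- stats::cor(as.vector(a), as.vector(b))
      }
    }
  }
  best <- which(cg == max(cg, na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(shift = c(dy = shifts[best[1]], dx = shifts[best[2]]),
              correlation = cg[best[1], best[2]],
              correlation_grid = cg)
  if (out$correlation < 0.2) {
    warning(sprintf("low registration correlation (%.3f); %s",
                    out$correlation, "alignment is unreliable"))
  }
  out
}

#' Squared Pearson correlation and OLS slope of y on x
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r_squared`, `slope`, `n`.
#' @examples
#' correlate(c(0, 1, 2), c(0, 1, 0))  # r_squared 0, slope 0
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  list(r_squared = stats::cor(x, y)^2,
       slope = stats::cov(x, y) / stats::var(x),
       n = length(x))
}
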