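## Ex vivo mucus quantification: growth rate from timed thickness
## measurements and penetrability from 3D bead clouds over an epithelial
## height field.

#' Mucus growth rate per mouse
#'
#' For each mouse, the per-timepoint thickness is the mean over measurement
#' sites (five per explant by convention), and the growth rate is the change
#' in that mean thickness per minute between the first and last timepoint:
#' `(mean(T_45) - mean(T_0)) / 45` for the standard 0/45-min design.
#'
#' @param series data.frame with columns `mouse_id`, `site`, `time_min`,
#'   `thickness_um` (and optionally `group`). Each mouse needs both
#'   timepoints.
#' @return data.frame with `mouse_id`, `rate_um_min` (and `group` if
#'   present).
#' @examples
#' s <- data.frame(mouse_id = "m1", site = rep(1:5, 2),
#'                 time_min = rep(c(0, 45), each = 5),
#'                 thickness_um = c(100, 110, 90, 105, 95,
#'                                  190, 200, 180, 195, 185))
#' growthRate(s)  # 2 um/min
#' @export
growthRate <- function(series) {
  need <- c("mouse_id", "site", "time_min", "thickness_um")
  stopIfNot(is.data.frame(series) && all(need %in% names(series)),
            "series needs columns: ", paste(need, collapse = ", "))
  stopIfNot(all(is.finite(series$thickness_um)) && all(series$thickness_um >= 0),
            "thickness must be finite and nonnegative")
  perMouse <- lapply(split(series, series$mouse_id), function(m) {
    times <- sort(unique(m$time_min))
    if (length(times) < 2) {
      stop("mouse ", m$mouse_id[1], " lacks a second timepoint", call. = FALSE)
    }
    t0 <- min(times); t1 <- max(times)
    m0 <- mean(m$thickness_um[m$time_min == t0])
    m1 <- mean(m$thickness_um[m$time_min == t1])
    data.frame(mouse_id = m$mouse_id[1],
               group = if ("group" %in% names(m)) m$group[1] else NA_character_,
               rate_um_min = (m1 - m0) / (t1 - t0))
  })
  out <- do.call(rbind, c(perMouse, list(make.row.names = FALSE)))
  if (all(is.na(out$group))) out$group <- NULL
  out
}

# Epithelial height under a bead: constant plane or bilinear interpolation of
# the gridded field. Beads outside the grid footprint are an error.
epithelialHeight <- function(epi, x, y) {
  if (is.numeric(epi) && length(epi) == 1) return(rep(epi, length(x)))
  stopIfNot(is.list(epi) && all(c("x", "y", "h") %in% names(epi)),
            "epithelium must be a plane height or list(x, y, h)")
  outside <- x < min(epi$x) | x > max(epi$x) | y < min(epi$y) | y > max(epi$y)
  if (any(outside)) {
    stop(sum(outside), " bead(s) fall outside the epithelial height-field domain",
         call. = FALSE)
  }
  # pracma::interp2 interpolates Z with rows ~ y and columns ~ x
  pracma::interp2(epi$x, epi$y, t(epi$h), x, y, method = "linear")
}

#' Per-bead vertical distance to the epithelium
#'
#' `distance = z_bead - h(x_bead, y_bead)`, the vertical distance to the
#' (interpolated) epithelial height, matching z-stack acquisition geometry.
#' Negative distances (beads below the detected epithelium) are returned but
#' flagged in the `below_epithelium` column rather than silently kept.
#'
#' @param cloud a [BeadCloud-class].
#' @return data.frame: `image_id`, `mouse_id`, `distance_um`,
#'   `below_epithelium`.
#' @export
beadDistances <- function(cloud) {
  stopIfNot(is(cloud, "BeadCloud"), "cloud must be a BeadCloud")
  b <- beads(cloud)
  h <- epithelialHeight(epithelium(cloud), b$x_um, b$y_um)
  d <- b$z_um - h
  data.frame(image_id = b$image_id, mouse_id = b$mouse_id,
             distance_um = d, below_epithelium = d < 0)
}

#' Mucus surface from the bead-density mode
#'
#' The mucus surface of an image is the location of highest bead density: the
#' center of the modal bin of the distance histogram (bin width `binUm`,
#' bins anchored at 0). Ties are broken toward the larger distance (the
#' outermost mode), so a surface accumulation of beads wins over a
#' crypt-floor artifact. Negative distances are excluded from the histogram.
#'
#' @param distances numeric vector of per-bead distances (um) for one image.
#' @param binUm histogram bin width in um (default 5, the confocal z-step).
#' @param minBeads minimum number of nonnegative-distance beads required
#'   (default 50); below this the mode is unreliable and an error asks for an
#'   externally supplied surface height instead.
#' @return surface distance above the epithelium (um).
#' @export
mucusSurface <- function(distances, binUm = 5, minBeads = 50L) {
  stopIfNot(binUm > 0, "binUm must be positive")
  d <- distances[is.finite(distances) & distances >= 0]
  if (length(d) < minBeads) {
    stop("only ", length(d), " usable beads (need >= ", minBeads,
         "); supply the mucus surface z-position explicitly via the ",
         "`surface` argument of penetrability()", call. = FALSE)
  }
  bin <- floor(d / binUm)
  tab <- table(bin)
  top <- as.numeric(names(tab)[tab == max(tab)])
  (max(top) + 0.5) * binUm
}

#' Mucus penetrability from a bead cloud
#'
#' Per image: per-bead distances to the epithelium, the mucus surface (bead
#' density mode, unless supplied), the beads within the mucus layer
#' (`0 <= distance <= surface`; beads above the surface are excess unwashed
#' beads, beads below the epithelium go to the QC count) and the fraction of
#' in-mucus beads within `zoneUm` of the epithelium. The per-mouse value is
#' the mean of its image fractions.
#'
#' @param cloud a [BeadCloud-class] (may hold several images).
#' @param zoneUm near-epithelium zone (default 10 um).
#' @param binUm histogram bin width for the surface mode (default 5 um).
#' @param surface optional fixed mucus surface height (um above the
#'   epithelium) used for every image instead of the bead-density mode.
#' @param minBeads floor for the mode estimate, see [mucusSurface()].
#' @return list with `images` (per-image data.frame: `image_id`, `mouse_id`,
#'   `mucus_surface_um`, `n_beads_in_mucus`, `n_below_epithelium`,
#'   `n_above_surface`, `fraction_within_zone`), `perMouse` (data.frame
#'   `mouse_id`, `fraction_within_zone`), and `distances` (the per-bead
#'   distance table).
#' @export
penetrability <- function(cloud, zoneUm = 10, binUm = 5, surface = NULL,
                          minBeads = 50L) {
  dists <- beadDistances(cloud)
  perImage <- lapply(split(dists, dists$image_id), function(img) {
    surf <- if (is.null(surface)) {
      mucusSurface(img$distance_um, binUm = binUm, minBeads = minBeads)
    } else {
      surface
    }
    inMucus <- img$distance_um >= 0 & img$distance_um <= surf
    n <- sum(inMucus)
    frac <- if (n == 0) NA_real_ else {
      sum(img$distance_um[inMucus] <= zoneUm) / n
    }
    data.frame(image_id = img$image_id[1], mouse_id = img$mouse_id[1],
               mucus_surface_um = surf, n_beads_in_mucus = n,
               n_below_epithelium = sum(img$distance_um < 0),
               n_above_surface = sum(img$distance_um > surf),
               fraction_within_zone = frac)
  })
  images <- do.call(rbind, c(perImage, list(make.row.names = FALSE)))
  perMouse <- aggregate(fraction_within_zone ~ mouse_id, data = images,
                        FUN = mean, na.action = stats::na.pass)
  list(images = images, perMouse = perMouse, distances = dists)
}

#' Median and quartiles of pooled bead distances
#'
#' Pools the in-range (nonnegative) per-bead distances and summarizes them as
#' median and quartiles per group or per mouse, using the linear-interpolation
#' quantile convention.
#'
#' @param distances per-bead distance table as returned in
#'   `penetrability()$distances`, optionally with a `group` column.
#' @param by `"mouse"` or `"group"`.
#' @return data.frame with `median`, `q1`, `q3` and `n` per level.
#' @export
distanceDistribution <- function(distances, by = c("mouse", "group")) {
  by <- match.arg(by)
  key <- if (by == "mouse") "mouse_id" else "group"
  stopIfNot(key %in% names(distances), "distances lacks a '", key, "' column")
  stopIfNot(nrow(distances) >= 1, "no distances supplied")
  d <- distances[distances$distance_um >= 0, , drop = FALSE]
  res <- lapply(split(d$distance_um, d[[key]]), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(q1 = q[1], median = q[2], q3 = q[3], n = length(v))
  })
  out <- do.call(rbind, res)
  out <- cbind(setNames(data.frame(rownames(out)), key), out)
  rownames(out) <- NULL
  out
}
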