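# Pore region definition, water counting and tracking, residence times,
# z-binned water density profiles, hydrophobic length from inflection
# points of the second derivative, and wet/dry frame classification.

#' Define the per-frame pore region
#'
#' The pore volume is approximated by the convex hull of the C-alpha
#' positions of two anchor residues (default 5 and 22) on all five chains:
#' ten points forming a pentagonal prism in an ideal bundle. Membership is
#' closed (a point on the hull is inside).
#'
#' @param traj a [traj_frames] object.
#' @param anchors length-2 residue numbers (default `c(5, 22)`).
#' @return object of class `pore_region`: per-frame halfspace systems plus
#'   the anchor points.
#' @export
define_pore_region <- function(traj, anchors = c(5, 22)) {
  stopifnot(inherits(traj, "traj_frames"), length(anchors) == 2L)
  a <- traj$atoms
  sel <- a$resid %in% anchors & a$atomname == "CA"
  anchor_atoms <- a[sel, ]
  frames <- 0:(traj$n_frames - 1L)
  per_frame <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    p <- anchor_atoms[anchor_atoms$frame == f, ]
    if (nrow(p) != 10L) {
      have <- paste(p$chain, p$resid)
      stop(sprintf(
        "define_pore_region: frame %d has %d anchor CA atoms (need 10: residues %d/%d on 5 chains)",
        f, nrow(p), anchors[1], anchors[2]), call. = FALSE)
    }
    pts <- as.matrix(p[, c("x", "y", "z")])
    per_frame[[i]] <- list(halfspaces = hull_halfspaces(pts), points = pts)
  }
  structure(list(frames = frames, regions = per_frame, anchors = anchors),
            class = "pore_region")
}

#' Is a point inside the pore region of a frame?
#'
#' @param region a `pore_region` object.
#' @param frame frame index (0-based).
#' @param pts numeric matrix (n x 3) or length-3 vector.
#' @return logical vector.
#' @export
in_pore <- function(region, frame, pts) {
  i <- match(frame, region$frames)
  if (is.na(i)) stop("in_pore: unknown frame ", frame, call. = FALSE)
  in_hull(region$regions[[i]]$halfspaces, pts)
}

#' Count and track pore waters
#'
#' Waters are identified by residue name (oxygen atom position stands for
#' the molecule) and tested for membership in the per-frame pore region.
#'
#' @param traj a [traj_frames] object.
#' @param region a `pore_region` from [define_pore_region()].
#' @param water_resnames residue names treated as water.
#' @return object of class `water_occupancy`: `counts` (data.frame frame,
#'   n), `inside` (data.frame frame, water_id), `water_ids`, `n_frames`,
#'   `dt`.
#' @export
count_pore_waters <- function(traj, region,
                              water_resnames = WATER_RESNAMES) {
  stopifnot(inherits(traj, "traj_frames"), inherits(region, "pore_region"))
  a <- traj$atoms
  w <- a[a$resname %in% water_resnames &
           a$atomname %in% c("O", "OW", "OH2"), ]
  frames <- 0:(traj$n_frames - 1L)
  inside_list <- vector("list", length(frames))
  counts <- integer(length(frames))
  if (nrow(w)) {
    w$water_id <- paste0(w$chain, w$resid)
    for (i in seq_along(frames)) {
      wf <- w[w$frame == frames[i], ]
      if (!nrow(wf)) next
      ok <- in_pore(region, frames[i], as.matrix(wf[, c("x", "y", "z")]))
      counts[i] <- sum(ok)
      if (any(ok))
        inside_list[[i]] <- data.frame(frame = frames[i],
                                       water_id = wf$water_id[ok],
                                       z = wf$z[ok],
                                       stringsAsFactors = FALSE)
    }
  }
  inside <- if (any(!vapply(inside_list, is.null, logical(1))))
    do.call(rbind, inside_list)
  else data.frame(frame = integer(0), water_id = character(0),
                  z = numeric(0))
  structure(list(counts = data.frame(frame = frames, n = counts),
                 inside = inside,
                 water_ids = sort(unique(w$water_id %||% character(0))),
                 n_frames = traj$n_frames, dt = traj$dt),
            class = "water_occupancy")
}

#' Residence intervals and times of pore waters
#'
#' Maximal runs of consecutive inside-frames per water. Duration is the run
#' length in frames times dt, reported in nanoseconds. Intervals touching
#' the first or last frame are flagged as censored.
#'
#' @param occupancy a `water_occupancy` object.
#' @return data.frame with columns `water_id`, `entry_frame`, `exit_frame`
#'   (inclusive), `n_frames`, `duration_ns`, `censored_start`,
#'   `censored_end`.
#' @export
residence_times <- function(occupancy) {
  stopifnot(inherits(occupancy, "water_occupancy"))
  inside <- occupancy$inside
  out <- list()
  last_frame <- occupancy$n_frames - 1L
  for (wid in unique(inside$water_id)) {
    fr <- sort(unique(inside$frame[inside$water_id == wid]))
    run_id <- cumsum(c(1L, diff(fr) != 1L))
    for (r in unique(run_id)) {
      ff <- fr[run_id == r]
      out[[length(out) + 1L]] <- data.frame(
        water_id = wid,
        entry_frame = ff[1L], exit_frame = ff[length(ff)],
        n_frames = length(ff),
        duration_ns = length(ff) * occupancy$dt / 1000,
        censored_start = ff[1L] == 0L,
        censored_end = ff[length(ff)] == last_frame,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(water_id = character(0), entry_frame = integer(0),
                      exit_frame = integer(0), n_frames = integer(0),
                      duration_ns = numeric(0), censored_start = logical(0),
                      censored_end = logical(0)))
  res <- do.call(rbind, out)
  res[order(res$water_id, res$entry_frame), ]
}

# Savitzky-Golay smoothing that degrades gracefully for short profiles.
smooth_profile <- function(y, window, order) {
  if (window %% 2L == 0L) window <- window + 1L
  if (length(y) < window || window <= order + 1L) return(y)
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

#' Time-averaged water density profile along z
#'
#' Per frame, pore-water z positions are histogrammed in `bin_width` bins
#' spanning the anchor region; densities are counts per Angstrom so the
#' integral over z equals the per-frame pore water count. The per-frame
#' profiles are averaged, smoothed (Savitzky-Golay, default window 11 bins,
#' order 3) and differentiated twice by central differences.
#'
#' @param traj a [traj_frames] object.
#' @param region a `pore_region` object.
#' @param bin_width bin width along z, Angstrom (default 0.5).
#' @param smooth_window,smooth_order smoothing parameters (bins / polynomial
#'   order).
#' @param water_resnames residue names treated as water.
#' @return object of class `density_profile`: data.frame with columns `z`,
#'   `density`, `density_smooth`, `d2`; attributes `bin_width`,
#'   `mean_count`.
#' @export
density_profile <- function(traj, region, bin_width = 0.5,
                            smooth_window = 11L, smooth_order = 3L,
                            water_resnames = WATER_RESNAMES) {
  occ <- count_pore_waters(traj, region, water_resnames)
  zr <- range(vapply(region$regions, function(r) range(r$points[, 3]),
                     numeric(2)))
  breaks <- seq(floor(zr[1] / bin_width) * bin_width,
                ceiling(zr[2] / bin_width) * bin_width, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n_frames <- occ$n_frames
  total <- numeric(length(mids))
  if (nrow(occ$inside)) {
    zc <- pmin(pmax(occ$inside$z, breaks[1]), breaks[length(breaks)])
    idx <- findInterval(zc, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tab <- table(factor(idx, levels = seq_along(mids)))
    total <- as.numeric(tab)
  }
  dens <- total / n_frames / bin_width
  profile_from_density(mids, dens, bin_width, smooth_window, smooth_order,
                       mean_count = sum(occ$counts$n) / n_frames)
}

#' Build a density profile from given density values
#'
#' Applies the same smoothing and differentiation as [density_profile()] to
#' an externally supplied curve (analytic fixtures, pre-computed profiles).
#'
#' @param z bin centres, Angstrom (equally spaced).
#' @param density water density per Angstrom at each bin.
#' @inheritParams density_profile
#' @return a `density_profile` object.
#' @export
density_profile_from_values <- function(z, density, bin_width = NULL,
                                        smooth_window = 11L,
                                        smooth_order = 3L) {
  stopifnot(length(z) == length(density), length(z) >= 3L)
  if (is.null(bin_width)) bin_width <- stats::median(diff(z))
  profile_from_density(z, density, bin_width, smooth_window, smooth_order,
                       mean_count = sum(density) * bin_width)
}

profile_from_density <- function(z, density, bin_width, smooth_window,
                                 smooth_order, mean_count) {
  sm <- smooth_profile(density, smooth_window, smooth_order)
  n <- length(sm)
  d2 <- rep(NA_real_, n)
  if (n >= 3L)
    d2[2:(n - 1L)] <- (sm[3:n] - 2 * sm[2:(n - 1L)] + sm[1:(n - 2L)]) /
      bin_width^2
  structure(data.frame(z = z, density = density, density_smooth = sm,
                       d2 = d2),
            class = c("density_profile", "data.frame"),
            bin_width = bin_width, mean_count = mean_count)
}

#' Hydrophobic spans from second-derivative inflection points
#'
#' Inflection points are the z positions where the smoothed second
#' derivative changes sign (linear interpolation between bins). Gaps between
#' consecutive inflection points qualify as hydrophobic spans when their
#' interior mean (smoothed) density is below `low_density_frac` of the
#' profile maximum; the effective hydrophobic length is the longest
#' qualifying span.
#'
#' @param profile a `density_profile` object.
#' @param low_density_frac dryness criterion as a fraction of the maximum
#'   smoothed density (default 0.25).
#' @return list with `inflection_points` (z, Angstrom), `spans`
#'   (data.frame z_start, z_end, length, mean_density, qualifies) and
#'   `effective_length` (Angstrom; 0 when no span qualifies).
#' @export
hydrophobic_length <- function(profile, low_density_frac = 0.25) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$z
  d2 <- profile$d2
  ok <- !is.na(d2)
  z <- z[ok]; d2 <- d2[ok]
  sm <- profile$density_smooth[ok]
  infl <- numeric(0)
  if (length(d2) >= 2L) {
    for (i in seq_len(length(d2) - 1L)) {
      if (d2[i] == 0 || d2[i + 1L] == 0) next
      if (sign(d2[i]) != sign(d2[i + 1L])) {
        # linear interpolation of the zero crossing
        frac <- d2[i] / (d2[i] - d2[i + 1L])
        infl <- c(infl, z[i] + frac * (z[i + 1L] - z[i]))
      }
    }
  }
  max_dens <- max(profile$density_smooth, na.rm = TRUE)
  spans <- data.frame(z_start = numeric(0), z_end = numeric(0),
                      length = numeric(0), mean_density = numeric(0),
                      qualifies = logical(0))
  if (length(infl) >= 2L) {
    for (i in seq_len(length(infl) - 1L)) {
      z0 <- infl[i]; z1 <- infl[i + 1L]
      interior <- z > z0 & z < z1
      md <- if (any(interior)) mean(sm[interior]) else
        stats::approx(z, sm, xout = (z0 + z1) / 2)$y
      spans <- rbind(spans, data.frame(
        z_start = z0, z_end = z1, length = z1 - z0, mean_density = md,
        qualifies = is.finite(md) && max_dens > 0 &&
          md < low_density_frac * max_dens))
    }
  }
  eff <- if (any(spans$qualifies)) max(spans$length[spans$qualifies]) else 0
  list(inflection_points = infl, spans = spans, effective_length = eff)
}

#' Classify frames as dry, wet or transition
#'
#' Hysteresis rule: scanning frames in order, the state becomes wet at the
#' first frame with `n >= wet_min` and stays wet until a frame with
#' `n <= dry_max`, at which it becomes dry (and vice versa). Frames with
#' intermediate counts inherit the current state; intermediate frames seen
#' before any threshold crossing are labelled `transition`.
#'
#' @param occupancy a `water_occupancy` object.
#' @param dry_max maximum count of a dry frame (default 1).
#' @param wet_min count at which a wet episode starts (default 10).
#' @return data.frame with columns `frame`, `n`, `label`
#'   (factor dry/transition/wet).
#' @export
classify_wet_dry <- function(occupancy, dry_max = 1L, wet_min = 10L) {
  stopifnot(inherits(occupancy, "water_occupancy"), dry_max < wet_min)
  n <- occupancy$counts$n
  lab <- character(length(n))
  cur <- NA_character_
  for (i in seq_along(n)) {
    if (n[i] >= wet_min) cur <- "wet"
    else if (n[i] <= dry_max) cur <- "dry"
    lab[i] <- if (is.na(cur)) "transition" else cur
  }
  data.frame(frame = occupancy$counts$frame, n = n,
             label = factor(lab, levels = c("dry", "transition", "wet")))
}
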