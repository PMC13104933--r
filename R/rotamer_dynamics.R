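# Glutamine sidechain orientation, state classification, pairwise state
# agreement, chi1/chi2 dihedrals, rotamer clustering and background KDE
# contours.
#
# The orientation vector runs from a Gln's C-alpha to its NE2 amide
# nitrogen; its z-offset is measured relative to the plane z = mean z of the
# five Gln C-alpha atoms of that frame (trajectory must be pore-axis
# oriented first). z-offsets are classified into down / neutral / up states
# and compared pairwise across the five chains to quantify channel symmetry.

#' Compute Gln orientation vectors and z-offsets
#'
#' @param traj an oriented [traj_frames] object.
#' @param gln_resid residue number of the pore-lining Gln (e.g. 10 or 17).
#' @return data.frame of class `gln_vectors` with columns `frame`, `chain`,
#'   `vx`, `vy`, `vz`, `z_offset`; attributes `resid`, `dt`,
#'   `n_frames`, `replicate_id`.
#' @export
compute_gln_vectors <- function(traj, gln_resid) {
  stopifnot(inherits(traj, "traj_frames"))
  a <- traj$atoms
  ca <- a[a$resid == gln_resid & a$atomname == "CA", ]
  ne2 <- a[a$resid == gln_resid & a$atomname == "NE2", ]
  chains <- sort(unique(ca$chain))
  if (length(chains) != 5L)
    stop(sprintf("compute_gln_vectors: residue %d found on %d chains (need 5)",
                 gln_resid, length(chains)), call. = FALSE)
  per_frame_ca <- table(ca$frame)
  if (any(per_frame_ca != 5L) || length(per_frame_ca) != traj$n_frames)
    stop("compute_gln_vectors: missing CA atom for residue ", gln_resid,
         call. = FALSE)
  key <- function(d) paste(d$frame, d$chain)
  m <- match(key(ca), key(ne2))
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop(sprintf("compute_gln_vectors: missing NE2 for frame %d chain %s",
                 ca$frame[bad], ca$chain[bad]), call. = FALSE)
  }
  ne2 <- ne2[m, ]
  plane_z <- stats::ave(ca$z, ca$frame)  # mean CA z per frame
  out <- data.frame(frame = ca$frame, chain = ca$chain,
                    vx = ne2$x - ca$x, vy = ne2$y - ca$y, vz = ne2$z - ca$z,
                    z_offset = ne2$z - plane_z,
                    stringsAsFactors = FALSE)
  vlen <- sqrt(out$vx^2 + out$vy^2 + out$vz^2)
  if (any(vlen <= 0))
    stop("compute_gln_vectors: zero-length CA->NE2 vector", call. = FALSE)
  out <- out[order(out$frame, out$chain), ]
  rownames(out) <- NULL
  structure(out, class = c("gln_vectors", "data.frame"),
            resid = gln_resid, dt = traj$dt, n_frames = traj$n_frames,
            replicate_id = traj$replicate_id)
}

#' Pool orientation-vector series from several replicates
#'
#' @param ... `gln_vectors` objects (or a single list of them).
#' @return a `gln_vectors` data.frame with a `replicate` column; attribute
#'   `n_replicates`.
#' @export
pool_gln_vectors <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "data.frame")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  out <- do.call(rbind, lapply(seq_along(xs), function(i) {
    d <- as.data.frame(xs[[i]])
    d$replicate <- attr(xs[[i]], "replicate_id") %||% paste0("run", i)
    d
  }))
  rownames(out) <- NULL
  structure(out, class = c("gln_vectors", "data.frame"),
            resid = attr(xs[[1]], "resid"), dt = attr(xs[[1]], "dt"),
            n_replicates = length(xs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify z-offsets into down / neutral / up states
#'
#' Half-open boundary convention: `z < t_low` is down, `t_low <= z < t_high`
#' is neutral, `z >= t_high` is up. Defaults (0.0, 2.5) Angstrom; 2.4 is the
#' commonly used alternative upper threshold.
#'
#' @param vectors a `gln_vectors` data.frame (needs `frame`, `chain`,
#'   `z_offset`).
#' @param thresholds numeric length-2 `(t_low, t_high)`, Angstrom.
#' @return data.frame of class `state_series` with columns `frame`, `chain`,
#'   `state` (factor down/neutral/up) plus any `replicate` column present.
#' @export
classify_states <- function(vectors, thresholds = c(0, 2.5)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  z <- vectors$z_offset
  st <- ifelse(z < thresholds[1], "down",
               ifelse(z < thresholds[2], "neutral", "up"))
  out <- data.frame(frame = vectors$frame, chain = vectors$chain,
                    state = factor(st, levels = c("down", "neutral", "up")),
                    stringsAsFactors = FALSE)
  if (!is.null(vectors$replicate)) out$replicate <- vectors$replicate
  structure(out, class = c("state_series", "data.frame"),
            thresholds = thresholds)
}

#' Pairwise state-agreement matrix
#'
#' For every unordered chain pair, the fraction of frames in which both
#' chains occupy the same state, pooled over all frames supplied (rbind
#' state series from several replicates to pool runs). Symmetric with unit
#' diagonal.
#'
#' @param states a `state_series` data.frame (5 chains).
#' @return 5 x 5 numeric matrix of class `agreement_matrix` with chain
#'   dimnames; attribute `n_frames_used`.
#' @export
pairwise_agreement <- function(states) {
  if (nrow(states) == 0L)
    stop("pairwise_agreement: empty frame set", call. = FALSE)
  chains <- sort(unique(as.character(states$chain)))
  if (length(chains) != 5L)
    stop("pairwise_agreement: need exactly 5 chains, got ",
         length(chains), call. = FALSE)
  grp <- if (is.null(states$replicate)) states$frame else
    paste(states$replicate, states$frame)
  wide <- tapply(as.character(states$state), list(grp, states$chain),
                 function(s) s[1L])
  if (anyNA(wide))
    stop("pairwise_agreement: missing (frame, chain) entries", call. = FALSE)
  n <- nrow(wide)
  m <- matrix(1, 5, 5, dimnames = list(chains, chains))
  for (i in 1:4) for (j in (i + 1):5) {
    agree <- mean(wide[, chains[i]] == wide[, chains[j]])
    m[i, j] <- agree
    m[j, i] <- agree
  }
  structure(m, class = c("agreement_matrix", class(m)), n_frames_used = n)
}

#' Extract chi1/chi2 sidechain dihedrals
#'
#' chi1 is the N-CA-CB-CG torsion and chi2 the CA-CB-CG-CD torsion, both in
#' degrees in (-180, 180] (IUPAC sign convention, computed by
#' [torsion_angle()]).
#'
#' @inheritParams compute_gln_vectors
#' @return data.frame of class `dihedral_series` with columns `frame`,
#'   `chain`, `chi1`, `chi2`.
#' @export
compute_dihedrals <- function(traj, gln_resid) {
  stopifnot(inherits(traj, "traj_frames"))
  a <- traj$atoms[traj$atoms$resid == gln_resid, ]
  get <- function(an) {
    d <- a[a$atomname == an, ]
    d[order(d$frame, d$chain), ]
  }
  n <- get("N"); ca <- get("CA"); cb <- get("CB")
  cg <- get("CG"); cd <- get("CD")
  sizes <- vapply(list(N = n, CA = ca, CB = cb, CG = cg, CD = cd), nrow,
                  integer(1))
  if (length(unique(sizes)) != 1L || sizes[1L] == 0L) {
    missing_atom <- names(sizes)[which.min(sizes)]
    stop(sprintf("compute_dihedrals: missing %s atoms for residue %d",
                 missing_atom, gln_resid), call. = FALSE)
  }
  xyz <- function(d) as.matrix(d[, c("x", "y", "z")])
  chi1 <- torsion_angle(xyz(n), xyz(ca), xyz(cb), xyz(cg))
  chi2 <- torsion_angle(xyz(ca), xyz(cb), xyz(cg), xyz(cd))
  structure(data.frame(frame = n$frame, chain = n$chain,
                       chi1 = chi1, chi2 = chi2, stringsAsFactors = FALSE),
            class = c("dihedral_series", "data.frame"),
            resid = gln_resid, replicate_id = traj$replicate_id)
}

# ---- DBSCAN on the torus -------------------------------------------------

# Classic DBSCAN (region-query + cluster expansion) on a points-by-features
# matrix with Euclidean metric. Returns integer labels: 0 = noise, clusters
# numbered 1..k in order of discovery. Implemented here because no DBSCAN
# routine ships with the installed stack; the algorithm is the textbook one.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  Xt <- t(X)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  eps2 <- eps^2
  region <- function(i) which(colSums((Xt - X[i, ])^2) <= eps2)
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    nb <- region(i)
    if (length(nb) < min_pts) {
      labels[i] <- 0L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    # pointer-based FIFO with a queued marker keeps the expansion linear
    queued <- logical(n)
    queue <- nb[nb != i]
    queued[queue] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      if (!is.na(labels[j])) {
        if (labels[j] == 0L) labels[j] <- cl  # noise becomes border
        next
      }
      labels[j] <- cl
      nb_j <- region(j)
      if (length(nb_j) >= min_pts) {
        new <- nb_j[!queued[nb_j] & (is.na(labels[nb_j]) |
                                       labels[nb_j] == 0L)]
        queued[new] <- TRUE
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Cluster rotamers with DBSCAN on a periodic embedding
#'
#' Angles are embedded as (sin chi1, cos chi1, sin chi2, cos chi2) so the
#' +-180 degree seam is continuous; `eps` is stated in degrees of arc and
#' converted to the equivalent chord length `2 sin(eps/2)` per angle
#' coordinate. Clusters are relabelled in descending membership order
#' (1 = largest); label 0 is noise.
#'
#' @param dihedrals a `dihedral_series` data.frame.
#' @param eps neighbourhood radius, degrees of arc (default 20).
#' @param min_samples minimum neighbourhood size; default
#'   `max(10, 0.5%% of points)`.
#' @return the input data.frame with a `cluster` column and attribute
#'   `fractions`: data.frame(cluster, n, fraction, fraction_clustered) where
#'   `fraction` uses all points (noise included in the denominator) and
#'   `fraction_clustered` excludes noise; noise is reported as cluster 0.
#' @export
cluster_rotamers <- function(dihedrals, eps = 20, min_samples = NULL) {
  n <- nrow(dihedrals)
  if (is.null(min_samples)) min_samples <- max(10L, ceiling(0.005 * n))
  if (n < min_samples)
    stop("cluster_rotamers: fewer points than min_samples", call. = FALSE)
  rad <- pi / 180
  X <- cbind(sin(dihedrals$chi1 * rad), cos(dihedrals$chi1 * rad),
             sin(dihedrals$chi2 * rad), cos(dihedrals$chi2 * rad))
  eps_chord <- 2 * sin(eps * rad / 2)
  raw <- dbscan_labels(X, eps_chord, min_samples)
  # relabel clusters by descending size
  tab <- sort(table(raw[raw > 0L]), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  lab <- ifelse(raw == 0L, 0L, map[as.character(raw)])
  out <- dihedrals
  out$cluster <- as.integer(lab)
  counts <- table(factor(out$cluster, levels = c(sort(unique(out$cluster)))))
  frac <- data.frame(cluster = as.integer(names(counts)),
                     n = as.integer(counts),
                     fraction = as.numeric(counts) / n)
  n_clustered <- sum(frac$n[frac$cluster > 0L])
  frac$fraction_clustered <- ifelse(frac$cluster == 0L, NA_real_,
                                    frac$n / max(1L, n_clustered))
  frac <- frac[order(frac$cluster == 0L, -frac$n), ]
  rownames(frac) <- NULL
  attr(out, "fractions") <- frac
  attr(out, "eps") <- eps
  attr(out, "min_samples") <- min_samples
  out
}

# ---- periodic KDE background ---------------------------------------------

#' Periodic 2-D Gaussian KDE with probability-mass contours
#'
#' Builds a Gaussian kernel density estimate over (chi1, chi2) treated as a
#' torus: reference points are replicated at +-360 degree shifts within
#' `margin` of the domain edges so density leaks correctly across the seam.
#' Bandwidths follow Scott's rule per coordinate. The returned thresholds
#' `d70`/`d90` are density levels whose superlevel regions
#' `{density >= d_p}` enclose approximately 70% / 90% of the reference
#' probability mass (highest-density-region construction: the (1-p)
#' empirical quantile of the density evaluated at the reference points).
#'
#' @param reference data.frame with columns `chi1`, `chi2` (degrees).
#' @param probs probability masses for the contours (default 0.70, 0.90).
#' @param bw optional length-2 bandwidth (degrees); default Scott's rule.
#' @param margin replication margin in degrees (default 90).
#' @return list of class `kde_background`: `density(chi1, chi2)` function,
#'   `thresholds` (named, decreasing with mass), `bw`, `n`.
#' @export
kde_background <- function(reference, probs = c(0.70, 0.90), bw = NULL,
                           margin = 90) {
  stopifnot(all(c("chi1", "chi2") %in% names(reference)))
  x <- reference$chi1
  y <- reference$chi2
  n <- length(x)
  if (n < 25L)
    stop("kde_background: need at least 25 reference points", call. = FALSE)
  if (stats::sd(x) < 1e-9 || stats::sd(y) < 1e-9)
    stop("kde_background: degenerate reference (zero spread)", call. = FALSE)
  if (is.null(bw)) {
    bw <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)  # Scott, d = 2
  }
  # replicate across the +-180 seam
  reps <- list(c(0, 0))
  for (sx in c(-360, 0, 360)) for (sy in c(-360, 0, 360)) {
    if (sx == 0 && sy == 0) next
    reps <- c(reps, list(c(sx, sy)))
  }
  keep_x <- c(); keep_y <- c()
  for (s in reps) {
    xs <- x + s[1]; ys <- y + s[2]
    keep <- xs >= -180 - margin & xs <= 180 + margin &
      ys >= -180 - margin & ys <= 180 + margin
    keep_x <- c(keep_x, xs[keep]); keep_y <- c(keep_y, ys[keep])
  }
  dens <- function(chi1, chi2) {
    stopifnot(length(chi1) == length(chi2))
    out <- numeric(length(chi1))
    for (i in seq_along(chi1)) {
      out[i] <- sum(stats::dnorm(chi1[i], keep_x, bw[1]) *
                      stats::dnorm(chi2[i], keep_y, bw[2])) / n
    }
    out
  }
  d_at_ref <- dens(x, y)
  thr <- stats::quantile(d_at_ref, 1 - probs, names = FALSE, type = 7)
  names(thr) <- paste0("d", round(probs * 100))
  structure(list(density = dens, thresholds = thr, bw = bw, n = n),
            class = "kde_background")
}

#' Histogram of pooled z-offsets
#'
#' Pools the z-offsets of all chains, frames and supplied replicates; the
#' total count is `5 x n_frames x n_replicates`.
#'
#' @param vectors a `gln_vectors` data.frame (possibly pooled with
#'   [pool_gln_vectors()]).
#' @param bin_width histogram bin width, Angstrom (default 0.25).
#' @return data.frame with columns `z_mid`, `count`; attribute `total`.
#' @export
z_histogram <- function(vectors, bin_width = 0.25) {
  z <- vectors$z_offset
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- hist(z, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  out <- data.frame(z_mid = h$mids, count = h$counts)
  structure(out, total = sum(h$counts), bin_width = bin_width)
}
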