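# Reading, validation and normalisation of multi-frame coordinate data.
#
# All downstream analyses consume the `traj_frames` container produced here:
# a long-format atom table (frame, chain, resid, resname, atomname, x, y, z)
# with an attached frame spacing dt in picoseconds. Coordinates are Angstrom
# throughout; frames are numbered 0 .. n_frames-1.

#' Default residue names identifying water molecules
#' @export
WATER_RESNAMES <- c("HOH", "SOL", "TIP3", "WAT")

#' Construct a trajectory container from an atom table
#'
#' @param atoms data.frame with columns `frame`, `chain`, `resid`,
#'   `resname`, `atomname`, `x`, `y`, `z`. Frames must be contiguous
#'   integers; they are renumbered to start at 0.
#' @param dt time between saved frames, picoseconds.
#' @param replicate_id optional label for the production run.
#' @return object of class `traj_frames` with elements `atoms`, `dt`,
#'   `n_frames`, `replicate_id`.
#' @export
traj_frames <- function(atoms, dt = 200, replicate_id = "run1") {
  need <- c("frame", "chain", "resid", "resname", "atomname", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("traj_frames: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("traj_frames: dt must be a positive scalar (ps)", call. = FALSE)
  atoms <- as.data.frame(atoms)[, need]
  atoms$frame <- as.integer(atoms$frame)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  atoms$resname <- as.character(atoms$resname)
  atoms$atomname <- as.character(atoms$atomname)
  if (any(atoms$resid < 1L))
    stop("traj_frames: residue numbers must be >= 1", call. = FALSE)
  if (any(!nzchar(atoms$atomname)))
    stop("traj_frames: empty atom name", call. = FALSE)
  fr <- sort(unique(atoms$frame))
  if (length(fr) > 1L && any(diff(fr) != 1L))
    stop("traj_frames: non-contiguous frame indices: ",
         paste(utils::head(fr, 10L), collapse = ","), call. = FALSE)
  atoms$frame <- atoms$frame - fr[1L]
  atoms <- atoms[order(atoms$frame, atoms$chain, atoms$resid, atoms$atomname), ]
  rownames(atoms) <- NULL
  check_roster(atoms)
  structure(list(atoms = atoms, dt = dt,
                 n_frames = length(fr), replicate_id = replicate_id),
            class = "traj_frames")
}

# Enforce an identical (chain, resid, atomname) roster in every frame.
check_roster <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$atomname, sep = "|")
  ref_frame <- atoms$frame == atoms$frame[1L]
  ref <- sort(key[ref_frame])
  split_keys <- split(key, atoms$frame)
  for (f in names(split_keys)) {
    k <- sort(split_keys[[f]])
    if (length(k) != length(ref) || any(k != ref)) {
      off <- c(setdiff(ref, k), setdiff(k, ref))
      stop(sprintf(
        "inconsistent atom roster at frame %s (first difference: %s)",
        f, off[1L]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf("traj_frames: %d frames x %d atoms, dt = %g ps (%s)\n",
              x$n_frames, nrow(x$atoms) / max(1L, x$n_frames), x$dt,
              x$replicate_id))
  invisible(x)
}

# Atom rows of one frame as a data.frame.
frame_atoms <- function(traj, frame) {
  traj$atoms[traj$atoms$frame == frame, , drop = FALSE]
}

#' Read a delimited per-frame atom table
#'
#' Expects a CSV/TSV with header
#' `frame,chain,resid,resname,atomname,x,y,z`. Frame indices must be
#' contiguous.
#'
#' @param path file path.
#' @param dt frame spacing, ps.
#' @param units `"angstrom"` (default) or `"nm"`; nm inputs are converted
#'   by a factor of 10.
#' @param replicate_id label attached to the trajectory.
#' @return a [traj_frames] object.
#' @export
read_frame_table <- function(path, dt = 200, units = c("angstrom", "nm"),
                             replicate_id = "run1") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("frame", "chain", "resid", "resname", "atomname", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_frame_table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (units == "nm") df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] * 10
  traj_frames(df, dt = dt, replicate_id = replicate_id)
}

#' Write a trajectory as a frame-table CSV
#'
#' Inverse of [read_frame_table()]; coordinates are written with three
#' decimals (0.001 Angstrom), matching PDB precision.
#'
#' @param traj a [traj_frames] object.
#' @param path output file path.
#' @export
write_frame_table <- function(traj, path) {
  stopifnot(inherits(traj, "traj_frames"))
  out <- traj$atoms
  out$x <- sprintf("%.3f", out$x)
  out$y <- sprintf("%.3f", out$y)
  out$z <- sprintf("%.3f", out$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' Parses fixed-column ATOM/HETATM records; each MODEL/ENDMDL block becomes
#' one frame (a file without MODEL records yields a single frame). Every
#' model must carry the same (chain, residue, atom) roster.
#'
#' @inheritParams read_frame_table
#' @return a [traj_frames] object.
#' @export
read_multimodel_pdb <- function(path, dt = 200, units = c("angstrom", "nm"),
                                replicate_id = "run1") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  model <- 0L
  seen_model <- FALSE
  recs <- vector("list", length(lines))
  nrec <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      model <- model + 1L
      seen_model <- TRUE
    } else if (tag == "ATOM  " || tag == "HETATM") {
      m <- if (seen_model) model else 1L
      atomname <- trimws(substr(ln, 13, 16))
      resname <- trimws(substr(ln, 18, 20))
      chain <- trimws(substr(ln, 22, 22))
      resid <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
      x <- suppressWarnings(as.numeric(trimws(substr(ln, 31, 38))))
      y <- suppressWarnings(as.numeric(trimws(substr(ln, 39, 46))))
      z <- suppressWarnings(as.numeric(trimws(substr(ln, 47, 54))))
      if (is.na(resid) || is.na(x) || is.na(y) || is.na(z) ||
          !nzchar(atomname))
        stop(sprintf("read_multimodel_pdb: unparseable ATOM record at line %d",
                     i), call. = FALSE)
      nrec <- nrec + 1L
      recs[[nrec]] <- list(frame = m - 1L, chain = chain, resid = resid,
                           resname = resname, atomname = atomname,
                           x = x, y = y, z = z)
    }
  }
  if (nrec == 0L)
    stop("read_multimodel_pdb: no ATOM/HETATM records in ", path,
         call. = FALSE)
  recs <- recs[seq_len(nrec)]
  df <- data.frame(
    frame = vapply(recs, `[[`, integer(1), "frame"),
    chain = vapply(recs, `[[`, character(1), "chain"),
    resid = vapply(recs, `[[`, integer(1), "resid"),
    resname = vapply(recs, `[[`, character(1), "resname"),
    atomname = vapply(recs, `[[`, character(1), "atomname"),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    z = vapply(recs, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE)
  if (units == "nm") df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] * 10
  # roster check with a model-numbered message before the generic one
  key <- paste(df$chain, df$resid, df$atomname, sep = "|")
  ref <- sort(key[df$frame == 0L])
  for (f in sort(unique(df$frame))) {
    k <- sort(key[df$frame == f])
    if (length(k) != length(ref) || any(k != ref))
      stop(sprintf("read_multimodel_pdb: atom roster of MODEL %d differs from MODEL 1",
                   f + 1L), call. = FALSE)
  }
  traj_frames(df, dt = dt, replicate_id = replicate_id)
}

#' Orient the pore axis along +z
#'
#' Rigidly rotates each frame so that the principal axis (largest-variance
#' eigenvector of the covariance) of the selected C-alpha atoms lies along
#' +z, and translates the selection centroid to the origin. The sign of +z
#' is fixed so that it points from the C-alpha centroid of
#' `sign_anchors[1]` towards that of `sign_anchors[2]` (defaults: from
#' residue 22 towards residue 5, i.e. N-terminal side up).
#'
#' @param traj a [traj_frames] object.
#' @param sel_atom atom name used for the selection (default `"CA"`).
#' @param sel_resid optional residue numbers to restrict the selection.
#' @param sign_anchors length-2 residue numbers fixing the +z direction.
#' @return a [traj_frames] object with transformed coordinates.
#' @export
orient_pore_axis <- function(traj, sel_atom = "CA", sel_resid = NULL,
                             sign_anchors = c(22, 5)) {
  stopifnot(inherits(traj, "traj_frames"))
  atoms <- traj$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rows_by_frame <- split(seq_len(nrow(atoms)), atoms$frame)
  is_sel_atom <- atoms$atomname == sel_atom
  for (f in 0:(traj$n_frames - 1L)) {
    in_f <- logical(nrow(atoms))
    in_f[rows_by_frame[[as.character(f)]]] <- TRUE
    sel <- in_f & is_sel_atom
    if (!is.null(sel_resid)) sel <- sel & atoms$resid %in% sel_resid
    if (sum(sel) < 3L)
      stop(sprintf("orient_pore_axis: selection matches %d atoms in frame %d (need >= 3)",
                   sum(sel), f), call. = FALSE)
    pts <- xyz[sel, , drop = FALSE]
    ctr <- colMeans(pts)
    cc <- sweep(pts, 2, ctr)
    cv <- crossprod(cc) / nrow(cc)
    if (max(abs(cv)) < 1e-16)
      stop(sprintf("orient_pore_axis: zero-extent selection in frame %d", f),
           call. = FALSE)
    ev <- eigen(cv, symmetric = TRUE)
    axis <- ev$vectors[, 1L]
    R <- rotation_between(axis, c(0, 0, 1))
    new_xyz <- sweep(xyz[in_f, , drop = FALSE], 2, ctr) %*% t(R)
    # sign convention from the anchor residues' CA centroids
    a1 <- in_f & atoms$atomname == sel_atom & atoms$resid == sign_anchors[1]
    a2 <- in_f & atoms$atomname == sel_atom & atoms$resid == sign_anchors[2]
    if (any(a1) && any(a2)) {
      rows_f <- which(in_f)
      z1 <- mean(new_xyz[match(which(a1), rows_f), 3L])
      z2 <- mean(new_xyz[match(which(a2), rows_f), 3L])
      if (z2 < z1) {
        # flip 180 degrees about x: keeps the axis on z, reverses its sign
        new_xyz[, 2L] <- -new_xyz[, 2L]
        new_xyz[, 3L] <- -new_xyz[, 3L]
      }
    }
    xyz[in_f, ] <- new_xyz
  }
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  out <- traj
  out$atoms <- atoms
  out
}

#' Select the frames of a time window
#'
#' Keeps frames whose midpoint time lies in `(t_min, t_max]` nanoseconds,
#' where frame f spans `(f*dt, (f+1)*dt]` ps. The standard network-analysis
#' window (100-200 ns of a 200-ns run saved every 200 ps) selects frames
#' 500..999, i.e. 500 frames.
#'
#' @param traj a [traj_frames] object.
#' @param t_min,t_max window bounds in nanoseconds.
#' @return a [traj_frames] object containing only the window frames
#'   (renumbered from 0).
#' @export
frame_window <- function(traj, t_min, t_max) {
  stopifnot(inherits(traj, "traj_frames"))
  t_end <- (seq_len(traj$n_frames)) * traj$dt / 1000  # ns at frame end
  keep <- which(t_end > t_min & t_end <= t_max) - 1L
  if (!length(keep)) stop("frame_window: empty window", call. = FALSE)
  atoms <- traj$atoms[traj$atoms$frame %in% keep, , drop = FALSE]
  traj_frames(atoms, dt = traj$dt, replicate_id = traj$replicate_id)
}
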