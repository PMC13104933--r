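# Geometric hydrogen-bond detection, water-bridged residue interactions,
# occupancy-filtered network graphs and interaction-type fractions.
#
# Donor/acceptor chemistry covered: Gln NE2 (donor) / OE1 (acceptor), Ser OG
# (both), backbone O (acceptor), water O (both). When hydrogens are present
# the D-H...A angle criterion applies; hydrogen-free frames fall back to a
# distance-only mode, flagged in the output.

hb_roles <- function(resname, atomname, water_resnames = WATER_RESNAMES) {
  is_w <- resname %in% water_resnames
  role <- rep(NA_character_, length(resname))
  role[is_w & atomname %in% c("O", "OW", "OH2")] <- "both"
  role[!is_w & resname == "GLN" & atomname == "NE2"] <- "donor"
  role[!is_w & resname == "GLN" & atomname == "OE1"] <- "acceptor"
  role[!is_w & resname == "SER" & atomname == "OG"] <- "both"
  role[!is_w & atomname == "O"] <- "acceptor"  # backbone carbonyl
  role
}

#' Detect hydrogen bonds in one frame
#'
#' A bond is recorded when the donor-acceptor heavy-atom distance is at
#' most `d_max` and, when a hydrogen bound to the donor is present (within
#' 1.25 Angstrom, same residue), the D-H...A angle is at least `angle_min`.
#' Frames without hydrogens are evaluated distance-only and flagged
#' (`mode = "distance"`). Each unordered heavy-atom pair is reported once.
#'
#' @param atoms data.frame of one frame's atoms (columns chain, resid,
#'   resname, atomname, x, y, z).
#' @param d_max heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff, degrees (default 150).
#' @param water_resnames residue names treated as water.
#' @return data.frame with one row per bond: donor/acceptor chain, resid,
#'   resname, atom, `distance`, `angle` (NA in distance mode), `mode`.
#' @export
detect_hbonds <- function(atoms, d_max = 3.5, angle_min = 150,
                          water_resnames = WATER_RESNAMES) {
  atoms <- as.data.frame(atoms)
  role <- hb_roles(atoms$resname, atoms$atomname, water_resnames)
  polar <- which(!is.na(role))
  if (!length(polar))
    return(empty_hbonds())
  p <- atoms[polar, ]
  p$role <- role[polar]
  p$res_key <- paste(p$chain, p$resid, sep = ":")
  xyz <- as.matrix(p[, c("x", "y", "z")])
  hyd <- atoms[grepl("^H", atoms$atomname) |
                 grepl("^[0-9]H", atoms$atomname), ]
  has_h <- nrow(hyd) > 0L
  hxyz <- if (has_h) as.matrix(hyd[, c("x", "y", "z")]) else NULL
  hkey <- if (has_h) paste(hyd$chain, hyd$resid, sep = ":") else NULL
  bonds <- list()
  np <- nrow(p)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if (p$res_key[i] == p$res_key[j]) next  # intra-residue excluded
    dvec <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(dvec^2))
    if (d > d_max) next
    # orient donor -> acceptor; needs one donor-capable and one
    # acceptor-capable endpoint (either orientation)
    ok_ij <- p$role[i] %in% c("donor", "both") &&
      p$role[j] %in% c("acceptor", "both")
    ok_ji <- p$role[j] %in% c("donor", "both") &&
      p$role[i] %in% c("acceptor", "both")
    if (!ok_ij && !ok_ji) next
    ang <- NA_real_
    mode <- "distance"
    if (has_h) {
      best <- -Inf
      for (ord in list(c(i, j), c(j, i))) {
        if (ord[1] == i && !ok_ij) next
        if (ord[1] == j && !ok_ji) next
        hs <- which(hkey == p$res_key[ord[1]])
        if (!length(hs)) next
        dh <- sqrt(rowSums((hxyz[hs, , drop = FALSE] -
                              matrix(xyz[ord[1], ], length(hs), 3,
                                     byrow = TRUE))^2))
        hs <- hs[dh <= 1.25]
        for (h in hs) {
          v1 <- xyz[ord[1], ] - hxyz[h, ]
          v2 <- xyz[ord[2], ] - hxyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          best <- max(best, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
        }
      }
      if (is.finite(best)) {
        mode <- "angle"
        ang <- best
        if (ang < angle_min) next
      }
    }
    di <- if (ok_ij) i else j
    ai <- if (ok_ij) j else i
    bonds[[length(bonds) + 1L]] <- data.frame(
      donor_chain = p$chain[di], donor_resid = p$resid[di],
      donor_resname = p$resname[di], donor_atom = p$atomname[di],
      acceptor_chain = p$chain[ai], acceptor_resid = p$resid[ai],
      acceptor_resname = p$resname[ai], acceptor_atom = p$atomname[ai],
      distance = d, angle = ang, mode = mode, stringsAsFactors = FALSE)
  }
  if (!length(bonds)) return(empty_hbonds())
  do.call(rbind, bonds)
}

empty_hbonds <- function() {
  data.frame(donor_chain = character(0), donor_resid = integer(0),
             donor_resname = character(0), donor_atom = character(0),
             acceptor_chain = character(0), acceptor_resid = integer(0),
             acceptor_resname = character(0), acceptor_atom = character(0),
             distance = numeric(0), angle = numeric(0),
             mode = character(0), stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds over a set of frames
#'
#' @param traj a [traj_frames] object.
#' @param frames frame indices (default all).
#' @inheritParams detect_hbonds
#' @return the per-frame bond tables row-bound with a `frame` column.
#' @export
frame_hbonds <- function(traj, frames = NULL, d_max = 3.5, angle_min = 150,
                         water_resnames = WATER_RESNAMES) {
  stopifnot(inherits(traj, "traj_frames"))
  if (is.null(frames)) frames <- 0:(traj$n_frames - 1L)
  by_frame <- split(traj$atoms, traj$atoms$frame)
  out <- lapply(frames, function(f) {
    b <- detect_hbonds(by_frame[[as.character(f)]], d_max, angle_min,
                       water_resnames)
    b$frame <- rep(f, nrow(b))
    b
  })
  do.call(rbind, out)
}

#' Water-bridged residue-residue interactions per frame
#'
#' Breadth-first search over the per-frame hydrogen-bond graph, expanding
#' through water nodes only: two residues interact in a frame when they are
#' connected by a path whose interior nodes are at most `max_waters`
#' waters. The bridge length is the minimum interior water count among such
#' paths (0 = direct bond). Each unordered residue pair is reported once
#' per frame.
#'
#' @param bonds a bond table from [frame_hbonds()] (must carry `frame`), or
#'   from [detect_hbonds()] for a single frame.
#' @param max_waters maximum number of bridging waters (default 5).
#' @param water_resnames residue names treated as water.
#' @return data.frame with columns `frame`, `chain_i`, `resid_i`,
#'   `chain_j`, `resid_j`, `bridge_waters`.
#' @export
water_bridges <- function(bonds, max_waters = 5L,
                          water_resnames = WATER_RESNAMES) {
  if (is.null(bonds$frame)) bonds$frame <- rep(0L, nrow(bonds))
  out <- lapply(split(bonds, bonds$frame), function(b) {
    res <- bridge_search_frame(b, max_waters, water_resnames)
    if (nrow(res)) res$frame <- b$frame[1L]
    res
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res))
    return(data.frame(frame = integer(0), chain_i = character(0),
                      resid_i = integer(0), chain_j = character(0),
                      resid_j = integer(0), bridge_waters = integer(0)))
  rownames(res) <- NULL
  res[, c("frame", "chain_i", "resid_i", "chain_j", "resid_j",
          "bridge_waters")]
}

bridge_search_frame <- function(bonds, max_waters, water_resnames) {
  empty <- data.frame(chain_i = character(0), resid_i = integer(0),
                      chain_j = character(0), resid_j = integer(0),
                      bridge_waters = integer(0))
  if (!nrow(bonds)) return(empty)
  nid_d <- paste(bonds$donor_chain, bonds$donor_resid, sep = ":")
  nid_a <- paste(bonds$acceptor_chain, bonds$acceptor_resid, sep = ":")
  isw_d <- bonds$donor_resname %in% water_resnames
  isw_a <- bonds$acceptor_resname %in% water_resnames
  nodes <- unique(data.frame(
    id = c(nid_d, nid_a),
    water = c(isw_d, isw_a),
    chain = c(bonds$donor_chain, bonds$acceptor_chain),
    resid = c(bonds$donor_resid, bonds$acceptor_resid),
    stringsAsFactors = FALSE))
  adj <- split(c(nid_a, nid_d), c(nid_d, nid_a))
  adj <- lapply(adj, unique)
  residues <- nodes[!nodes$water, , drop = FALSE]
  is_water_node <- stats::setNames(nodes$water, nodes$id)
  found <- list()
  for (r in seq_len(nrow(residues))) {
    src <- residues$id[r]
    # BFS: expand through water nodes only; residue nodes terminate a path
    depth <- stats::setNames(0L, src)
    frontier <- src
    reached <- stats::setNames(integer(0), character(0))
    d <- 0L
    while (length(frontier) && d <= max_waters) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in adj[[v]] %||% character(0)) {
          if (!is_water_node[[u]]) {
            if (u != src && !(u %in% names(reached)))
              reached[u] <- d  # interior waters so far
          } else if (!(u %in% names(depth))) {
            depth[u] <- d + 1L
            if (d + 1L <= max_waters) nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      d <- d + 1L
    }
    for (tgt in names(reached)) {
      if (src < tgt) {
        ni <- nodes[nodes$id == src, ][1L, ]
        nj <- nodes[nodes$id == tgt, ][1L, ]
        found[[paste(src, tgt)]] <- data.frame(
          chain_i = ni$chain, resid_i = ni$resid,
          chain_j = nj$chain, resid_j = nj$resid,
          bridge_waters = unname(reached[tgt]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) return(empty)
  do.call(rbind, found)
}

#' Build the occupancy-filtered hydrogen-bond network
#'
#' Edge occupancy is the fraction of window frames in which the residue
#' pair interacts (directly or water-bridged); edges below `occupancy_min`
#' and nodes outside the core residue range are removed.
#' `mean_bridge_waters` averages the per-frame minimum bridge length over
#' the frames where the interaction exists.
#'
#' @param interactions output of [water_bridges()] over the analysis
#'   window.
#' @param n_frames_window number of frames in the window (occupancy
#'   denominator).
#' @param occupancy_min minimum retained occupancy (default 0.10).
#' @param core inclusive residue range kept in the network (default
#'   `c(6, 20)`).
#' @return object of class `hbond_graph`: `edges` data.frame (chain_i,
#'   resid_i, chain_j, resid_j, occupancy, mean_bridge_waters, n_frames)
#'   and `nodes` data.frame.
#' @export
build_network <- function(interactions, n_frames_window,
                          occupancy_min = 0.10, core = c(6, 20)) {
  if (n_frames_window < 1L)
    stop("build_network: empty frame window", call. = FALSE)
  x <- interactions
  keep <- x$resid_i >= core[1] & x$resid_i <= core[2] &
    x$resid_j >= core[1] & x$resid_j <= core[2]
  x <- x[keep, , drop = FALSE]
  if (nrow(x)) {
    pair <- paste(x$chain_i, x$resid_i, x$chain_j, x$resid_j, sep = "|")
    agg_n <- tapply(x$frame, pair, function(f) length(unique(f)))
    agg_b <- tapply(x$bridge_waters, pair, mean)
    parts <- strsplit(names(agg_n), "|", fixed = TRUE)
    edges <- data.frame(
      chain_i = vapply(parts, `[`, "", 1L),
      resid_i = as.integer(vapply(parts, `[`, "", 2L)),
      chain_j = vapply(parts, `[`, "", 3L),
      resid_j = as.integer(vapply(parts, `[`, "", 4L)),
      occupancy = as.numeric(agg_n) / n_frames_window,
      mean_bridge_waters = as.numeric(agg_b),
      n_frames = as.integer(agg_n),
      stringsAsFactors = FALSE)
    edges <- edges[edges$occupancy >= occupancy_min, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(chain_i = character(0), resid_i = integer(0),
                        chain_j = character(0), resid_j = integer(0),
                        occupancy = numeric(0),
                        mean_bridge_waters = numeric(0),
                        n_frames = integer(0))
  }
  nodes <- unique(data.frame(
    chain = c(edges$chain_i, edges$chain_j),
    resid = c(edges$resid_i, edges$resid_j), stringsAsFactors = FALSE))
  structure(list(edges = edges, nodes = nodes,
                 n_frames_window = n_frames_window,
                 occupancy_min = occupancy_min, core = core),
            class = "hbond_graph")
}

#' Fractions of hydrogen-bond interaction types in the pore
#'
#' Bonds are classified by their endpoint types over {Gln sidechain, Ser
#' sidechain, water}: Gln-Gln, Gln-Ser, Ser-Ser, Gln-water, Ser-water.
#' Counted bonds are those whose endpoints are both of these types with at
#' least one pore-facing sidechain atom (Gln NE2/OE1 or Ser OG with residue
#' number inside the core); water-water bonds and bonds to other atoms
#' (e.g. backbone carbonyls) are not counted.
#'
#' @param bonds a bond table from [frame_hbonds()] pooled over the frames
#'   of interest.
#' @param core inclusive residue range of the pore core (default
#'   `c(6, 20)`).
#' @param water_resnames residue names treated as water.
#' @return named numeric vector of fractions summing to 1; attribute
#'   `counts` carries the raw counts.
#' @export
interaction_fractions <- function(bonds, core = c(6, 20),
                                  water_resnames = WATER_RESNAMES) {
  end_type <- function(resname, atomname, resid) {
    ifelse(resname %in% water_resnames, "water",
           ifelse(resname == "GLN" & atomname %in% c("NE2", "OE1") &
                    resid >= core[1] & resid <= core[2], "Gln",
                  ifelse(resname == "SER" & atomname == "OG" &
                           resid >= core[1] & resid <= core[2], "Ser",
                         NA_character_)))
  }
  t1 <- end_type(bonds$donor_resname, bonds$donor_atom, bonds$donor_resid)
  t2 <- end_type(bonds$acceptor_resname, bonds$acceptor_atom,
                 bonds$acceptor_resid)
  ok <- !is.na(t1) & !is.na(t2) & !(t1 == "water" & t2 == "water")
  if (!any(ok))
    stop("interaction_fractions: no counted pore hydrogen bonds",
         call. = FALSE)
  # order endpoints Gln < Ser < water for stable class names
  ordset <- c("Gln", "Ser", "water")
  cls <- apply(cbind(t1[ok], t2[ok]), 1L, function(p) {
    p <- p[order(match(p, ordset))]
    paste(p, collapse = "-")
  })
  levels <- c("Gln-Gln", "Gln-Ser", "Ser-Ser", "Gln-water", "Ser-water")
  counts <- table(factor(cls, levels = levels))
  frac <- as.numeric(counts) / sum(counts)
  names(frac) <- levels
  attr(frac, "counts") <- counts
  frac
}
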