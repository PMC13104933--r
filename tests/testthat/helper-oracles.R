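# Independent oracles and fixture builders shared by the suite. These are
# deliberately coded differently from the package implementations they
# check.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Torsion oracle: the "praxeolitic" single-atan2 formulation built from
# plane normals, independent of torsion_angle()'s arrangement.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b2 <- p3 - p2
  b3 <- p4 - p3
  b2u <- b2 / sqrt(sum(b2^2))
  v <- b0 - sum(b0 * b2u) * b2u
  w <- b3 - sum(b3 * b2u) * b2u
  x <- sum(v * w)
  y <- sum(cross3(b2u, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180 + 1e-12) ang <- 180
  ang
}

# Brute-force water-bridge oracle: enumerate all simple paths between two
# residue nodes whose interior nodes are all waters, return the minimum
# interior count (Inf when none within max_waters). `edges` is a 2-column
# matrix of node ids; `is_water` a named logical.
oracle_min_bridge <- function(edges, is_water, src, dst, max_waters = 5L) {
  adj <- list()
  add <- function(a, b) {
    adj[[a]] <<- unique(c(adj[[a]], b))
    adj[[b]] <<- unique(c(adj[[b]], a))
  }
  for (i in seq_len(nrow(edges))) add(edges[i, 1], edges[i, 2])
  best <- Inf
  recurse <- function(node, visited, interior) {
    for (nb in adj[[node]]) {
      if (nb == dst) {
        best <<- min(best, interior)
      } else if (is_water[[nb]] && !(nb %in% visited) &&
                 interior < max_waters) {
        recurse(nb, c(visited, nb), interior + 1L)
      }
    }
  }
  recurse(src, character(0), 0L)
  best
}

# Henderson-Hasselbalch speciation oracle: fraction of monobasic phosphate
# in the protonated form at a given pH, plus free protons.
oracle_total_proton <- function(pH, Ka, P_total) {
  pKa <- -log10(Ka)
  frac_protonated <- 1 / (1 + 10^(pH - pKa))
  10^(-pH) + P_total * frac_protonated
}

# Hand one-way ANOVA by textbook sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - gm)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  k <- length(unique(groups))
  n <- length(values)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# A random proper rigid transform (rotation + translation), seeded by the
# caller.
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 5))
}

# Minimal ideal pentamer atom table: CA atoms of residues 1..25 on five
# chains, pore along z, N-terminal side up (the generator's scaffold
# geometry, built independently here).
ideal_bundle_atoms <- function(n_frames = 1, radius = 8) {
  chains <- LETTERS[1:5]
  rows <- list()
  for (f in 0:(n_frames - 1)) for (k in 1:5) {
    th <- 2 * pi * (k - 1) / 5
    for (r in 1:25) {
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, chain = chains[k], resid = r, resname = "LEU",
        atomname = "CA", x = radius * cos(th), y = radius * sin(th),
        z = (13 - r) * 1.5, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Write a small multi-model PDB from an atom table (fixed columns).
write_toy_pdb <- function(atoms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in sort(unique(atoms$frame))) {
    writeLines(sprintf("MODEL %8d", f + 1), con)
    a <- atoms[atoms$frame == f, ]
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, a$atomname[i], a$resname[i], a$chain[i], a$resid[i],
        a$x[i], a$y[i], a$z[i]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Random bond table among invented residue/water nodes (for bridge-oracle
# equivalence). Returns list(bonds=..., nodes=..., is_water=...).
random_bond_table <- function(n_res, n_wat, p_edge, frame = 0L) {
  res_ids <- paste0("R", seq_len(n_res))
  wat_ids <- paste0("W", seq_len(n_wat))
  ids <- c(res_ids, wat_ids)
  is_water <- stats::setNames(c(rep(FALSE, n_res), rep(TRUE, n_wat)), ids)
  rows <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    if (stats::runif(1) > p_edge) next
    di <- ids[i]; aj <- ids[j]
    rows[[length(rows) + 1]] <- data.frame(
      donor_chain = substr(di, 1, 1), donor_resid = as.integer(substring(di, 2)),
      donor_resname = if (is_water[[di]]) "HOH" else "GLN",
      donor_atom = if (is_water[[di]]) "O" else "NE2",
      acceptor_chain = substr(aj, 1, 1),
      acceptor_resid = as.integer(substring(aj, 2)),
      acceptor_resname = if (is_water[[aj]]) "HOH" else "GLN",
      acceptor_atom = if (is_water[[aj]]) "O" else "OE1",
      distance = 2.8, angle = NA_real_, mode = "distance",
      frame = frame, stringsAsFactors = FALSE)
  }
  bonds <- if (length(rows)) do.call(rbind, rows) else {
    b <- poresym:::empty_hbonds()
    b$frame <- integer(0)
    b
  }
  edges <- if (nrow(bonds))
    cbind(paste0(bonds$donor_chain, bonds$donor_resid),
          paste0(bonds$acceptor_chain, bonds$acceptor_resid))
  else matrix(character(0), 0, 2)
  list(bonds = bonds, edges = edges, is_water = is_water,
       res_ids = res_ids)
}
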