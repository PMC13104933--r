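# Ground-truth-labelled synthetic inputs: ideal C5 pentamer trajectories
# with scripted Gln rotamer states, water occupancy schedules and bridge
# patterns, analytic density fixtures, and plate-reader fluorescence traces
# forward-generated from a known pH(t).
#
# The generator is deliberately unphysical (no forcefield, no thermal
# water dynamics): its purpose is exact, recoverable ground truth for every
# pipeline stage.

#' Specification for a synthetic pentamer trajectory
#'
#' @param n_frames frames per run (default 1000, i.e. 200 ns at 200 ps).
#' @param dt frame spacing, ps (default 200).
#' @param bundle_radius C-alpha circle radius, Angstrom (default 8).
#' @param gln_resid pore-lining Gln position (default 10).
#' @param ser_resids residue numbers carrying a Ser OG (default none).
#' @param state_script either a list/matrix of per-chain state sequences
#'   over c("down","neutral","up"), or NULL to simulate a Markov chain.
#' @param stay_prob Markov per-frame stay probability (default 0.98;
#'   1/3 with the symmetric transition kernel gives i.i.d. uniform states).
#' @param init_probs initial state distribution (default uniform).
#' @param state_z_map target NE2 z-offsets per state, Angstrom
#'   (defaults down -1.0, neutral 1.2, up 3.3).
#' @param thresholds classification thresholds the z targets must clear by
#'   >= 0.5 Angstrom (default c(0, 2.5)).
#' @param water_schedule data.frame of per-water residence intervals with
#'   columns `entry`, `exit` (inclusive 0-based frames) and optionally
#'   `water` (integer id; repeated ids give multiple intervals), or NULL.
#' @param hbond_script list of scripted bridges, each
#'   `list(chain_i=, chain_j=, frames=, n_waters=)`, or NULL.
#' @param noise_sd positional jitter s.d., Angstrom (default 0).
#' @param seed RNG seed.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 1000L, dt = 200, bundle_radius = 8,
                            gln_resid = 10L, ser_resids = integer(0),
                            state_script = NULL, stay_prob = 0.98,
                            init_probs = c(1, 1, 1) / 3,
                            state_z_map = c(down = -1.0, neutral = 1.2,
                                            up = 3.3),
                            thresholds = c(0, 2.5),
                            water_schedule = NULL, hbond_script = NULL,
                            noise_sd = 0, seed = 1L) {
  stopifnot(n_frames >= 1L, dt > 0, bundle_radius > 0)
  states <- c("down", "neutral", "up")
  if (!all(states %in% names(state_z_map)))
    stop("trajectory_spec: state_z_map must name down/neutral/up",
         call. = FALSE)
  for (s in states) {
    z <- state_z_map[[s]]
    if (min(abs(z - thresholds)) < 0.5)
      stop(sprintf(
        "trajectory_spec: z target for '%s' (%.2f) is within 0.5 A of a threshold",
        s, z), call. = FALSE)
    implied <- if (z < thresholds[1]) "down" else
      if (z < thresholds[2]) "neutral" else "up"
    if (implied != s)
      stop(sprintf(
        "trajectory_spec: z target for '%s' (%.2f) classifies as '%s'",
        s, z, implied), call. = FALSE)
  }
  if (!is.null(water_schedule)) {
    ws <- water_schedule
    stopifnot(all(c("entry", "exit") %in% names(ws)))
    if (any(ws$entry < 0L) || any(ws$exit >= n_frames) ||
        any(ws$entry > ws$exit))
      stop("trajectory_spec: water schedule outside [0, n_frames) or entry > exit",
           call. = FALSE)
    if (is.null(ws$water)) ws$water <- seq_len(nrow(ws))
    # intervals of one water must be disjoint
    for (w in unique(ws$water)) {
      iv <- ws[ws$water == w, ]
      iv <- iv[order(iv$entry), ]
      if (nrow(iv) > 1L && any(iv$entry[-1L] <= iv$exit[-nrow(iv)]))
        stop("trajectory_spec: overlapping intervals for water ", w,
             call. = FALSE)
    }
    water_schedule <- ws
  }
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 bundle_radius = bundle_radius, n_chains = 5L,
                 gln_resid = as.integer(gln_resid),
                 ser_resids = as.integer(ser_resids),
                 state_script = state_script, stay_prob = stay_prob,
                 init_probs = init_probs, state_z_map = state_z_map,
                 thresholds = thresholds, water_schedule = water_schedule,
                 hbond_script = hbond_script, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

# Run a function with a private, seeded RNG stream, restoring the caller's.
with_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Simulate per-chain state sequences
#'
#' Markov chain over down/neutral/up with a symmetric transition kernel:
#' stay with probability `stay_prob`, otherwise move to either other state
#' with equal probability. `stay_prob = 1/3` yields i.i.d. uniform states.
#'
#' @param n_frames number of frames.
#' @param n_chains number of chains (default 5).
#' @param stay_prob per-frame stay probability.
#' @param init_probs initial distribution over (down, neutral, up).
#' @param seed RNG seed.
#' @return a `state_series` data.frame (frame, chain, state).
#' @export
simulate_state_sequences <- function(n_frames, n_chains = 5L,
                                     stay_prob = 0.98,
                                     init_probs = c(1, 1, 1) / 3,
                                     seed = 1L) {
  states <- c("down", "neutral", "up")
  chains <- LETTERS[seq_len(n_chains)]
  sim <- with_seed(seed, function() {
    out <- matrix(NA_character_, n_frames, n_chains)
    for (k in seq_len(n_chains)) {
      s <- sample(3L, 1L, prob = init_probs)
      out[1L, k] <- states[s]
      if (n_frames > 1L) for (f in 2L:n_frames) {
        if (stats::runif(1) >= stay_prob)
          s <- sample(setdiff(1:3, s), 1L)
        out[f, k] <- states[s]
      }
    }
    out
  })
  df <- data.frame(frame = rep(0:(n_frames - 1L), times = n_chains),
                   chain = rep(chains, each = n_frames),
                   state = factor(c(sim), levels = states),
                   stringsAsFactors = FALSE)
  df <- df[order(df$frame, df$chain), ]
  rownames(df) <- NULL
  structure(df, class = c("state_series", "data.frame"))
}

# ---- sidechain geometry --------------------------------------------------

# Chain-0 backbone scaffold position of a residue's CA: a straight helix
# proxy on a circle of the bundle radius, z decreasing with residue number
# (N-terminal side up, matching the orientation convention).
scaffold_ca <- function(resid, bundle_radius) {
  c(bundle_radius, 0, (13 - resid) * 1.5)
}

# Build the chain-0 Gln residue atoms (N, CA, CB, CG, CD, NE2, OE1) for
# given chi1/chi2 (degrees). chi3 fixed. Returns a 7 x 3 matrix with
# rownames.
gln_template <- function(ca, chi1, chi2, chi3 = 0) {
  nrm <- function(v) v / sqrt(sum(v^2))
  N <- ca + 1.46 * nrm(c(0.20, 0.45, -1.35))
  CB <- ca + 1.53 * nrm(c(-0.62, 0.25, 0.74))
  CG <- place_atom(N, ca, CB, 1.52, 113, chi1)
  CD <- place_atom(ca, CB, CG, 1.52, 113, chi2)
  NE2 <- place_atom(CB, CG, CD, 1.33, 120, chi3)
  OE1 <- place_atom(CB, CG, CD, 1.23, 121, chi3 + 180)
  m <- rbind(N = N, CA = ca, CB = CB, CG = CG, CD = CD, NE2 = NE2,
             OE1 = OE1)
  colnames(m) <- c("x", "y", "z")
  m
}

# Solve chi1 so the NE2 z equals ca_z + target (the five Gln CA share one
# z, so the CA-plane mean is ca_z). chi2 is fixed per state. Errors when
# the target is outside the reachable range.
solve_chi1 <- function(ca, target_z_offset, chi2, state) {
  f <- function(chi1)
    gln_template(ca, chi1, chi2)["NE2", "z"] - ca[3] - target_z_offset
  grid <- seq(-180, 180, by = 2)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) {
    if (any(vals == 0)) return(grid[which(vals == 0)[1L]])
    stop(sprintf(
      "generate_trajectory: z target %.2f A for state '%s' unrealizable (reachable %.2f..%.2f)",
      target_z_offset, state,
      min(vals) + target_z_offset, max(vals) + target_z_offset),
      call. = FALSE)
  }
  i <- cross[1L]
  stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-10)$root
}

# Per-state chi2 constants: well separated on the torus so the scripted
# states form distinct rotamer clusters.
STATE_CHI2 <- c(down = 60, neutral = -60, up = 180)

#' Generate a synthetic pentamer trajectory with ground truth
#'
#' Builds an ideal C5-symmetric scaffold (5 chains, residues 1-25 on a
#' circle, 1.5 Angstrom rise per residue, pore along z, N-terminal side
#' up), realises each frame's scripted Gln state by solving chi1 for the
#' state's target NE2 z-offset (chi2 fixed per state), places waters per
#' schedule inside the anchor hull (on-axis, +-1 Angstrom jitter) or parked
#' far outside it, optionally places scripted water bridges between Gln
#' sidechains, and adds seeded Gaussian jitter.
#'
#' @param spec a [trajectory_spec()].
#' @param replicate_id label for the run (default "run1").
#' @return list with elements `traj` (a [traj_frames]) and `truth`:
#'   `states` (frame, chain, state, z_target), `chi` (state, chi1, chi2),
#'   `water_intervals`, `counts` (per-frame scripted pore water count),
#'   `bridges` (echo of the script).
#' @export
generate_trajectory <- function(spec, replicate_id = "run1") {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_frames <- spec$n_frames
  chains <- LETTERS[1:5]
  states <- c("down", "neutral", "up")

  # -- scripted states
  if (is.null(spec$state_script)) {
    st <- simulate_state_sequences(n_frames, 5L, spec$stay_prob,
                                   spec$init_probs, seed = spec$seed)
    smat <- matrix(as.character(st$state[order(st$chain, st$frame)]),
                   n_frames, 5L)
  } else {
    sc <- spec$state_script
    if (is.list(sc) && !is.matrix(sc)) sc <- do.call(cbind, sc)
    if (is.character(sc) && !is.matrix(sc))
      sc <- matrix(sc, n_frames, 5L)
    if (nrow(sc) == 1L) sc <- sc[rep(1L, n_frames), , drop = FALSE]
    stopifnot(nrow(sc) == n_frames, ncol(sc) == 5L,
              all(sc %in% states))
    smat <- sc
  }

  # -- per-state sidechain templates (chain 0)
  ca0 <- scaffold_ca(spec$gln_resid, spec$bundle_radius)
  chi_truth <- data.frame(state = states, chi1 = NA_real_,
                          chi2 = unname(STATE_CHI2[states]),
                          z_offset = unname(spec$state_z_map[states]))
  templates <- list()
  for (s in states) {
    chi1 <- solve_chi1(ca0, spec$state_z_map[[s]], STATE_CHI2[[s]], s)
    chi_truth$chi1[chi_truth$state == s] <- chi1
    templates[[s]] <- gln_template(ca0, chi1, STATE_CHI2[[s]])
  }

  # -- assemble atoms
  theta <- 2 * pi * (0:4) / 5
  rot <- lapply(theta, rotation_z)
  blocks <- list()

  # backbone CA scaffold (all residues, all chains; constant over frames)
  resids <- 1:25
  resname_of <- ifelse(resids == spec$gln_resid, "GLN",
                       ifelse(resids %in% spec$ser_resids, "SER", "LEU"))
  ca_chain0 <- t(vapply(resids, scaffold_ca, numeric(3),
                        bundle_radius = spec$bundle_radius))
  for (k in 1:5) {
    pos <- ca_chain0 %*% t(rot[[k]])
    blocks[[length(blocks) + 1L]] <- data.frame(
      frame = rep(0:(n_frames - 1L), each = length(resids)),
      chain = chains[k], resid = rep(resids, n_frames),
      resname = rep(resname_of, n_frames), atomname = "CA",
      x = rep(pos[, 1], n_frames), y = rep(pos[, 2], n_frames),
      z = rep(pos[, 3], n_frames), stringsAsFactors = FALSE)
  }

  # Gln sidechain + backbone N (replace the CA row coordinates are already
  # in the scaffold; sidechain atoms added here)
  side_atoms <- c("N", "CB", "CG", "CD", "NE2", "OE1")
  for (k in 1:5) {
    tmpl_k <- lapply(templates, function(m) m %*% t(rot[[k]]))
    coords <- array(NA_real_, c(length(side_atoms), 3L, n_frames))
    for (s in states) {
      fidx <- which(smat[, k] == s)
      if (!length(fidx)) next
      coords[, , fidx] <- tmpl_k[[s]][side_atoms, ]
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      frame = rep(0:(n_frames - 1L), each = length(side_atoms)),
      chain = chains[k], resid = spec$gln_resid, resname = "GLN",
      atomname = rep(side_atoms, n_frames),
      x = c(aperm(coords, c(1, 3, 2))[, , 1]),
      y = c(aperm(coords, c(1, 3, 2))[, , 2]),
      z = c(aperm(coords, c(1, 3, 2))[, , 3]), stringsAsFactors = FALSE)
  }

  # Ser OG + CB on scripted residues (fixed inward geometry)
  nrm <- function(v) v / sqrt(sum(v^2))
  for (r in spec$ser_resids) {
    car <- scaffold_ca(r, spec$bundle_radius)
    cb <- car + 1.53 * nrm(c(-0.62, 0.25, 0.74))
    og <- cb + 1.42 * nrm(c(-0.80, 0.10, 0.35))
    for (k in 1:5) {
      pos <- rbind(cb, og) %*% t(rot[[k]])
      blocks[[length(blocks) + 1L]] <- data.frame(
        frame = rep(0:(n_frames - 1L), each = 2L),
        chain = chains[k], resid = r, resname = "SER",
        atomname = rep(c("CB", "OG"), n_frames),
        x = rep(pos[, 1], n_frames), y = rep(pos[, 2], n_frames),
        z = rep(pos[, 3], n_frames), stringsAsFactors = FALSE)
    }
  }

  # -- waters on schedule
  truth_counts <- integer(n_frames)
  water_intervals <- NULL
  z_top <- (13 - 5) * 1.5      # anchor residue 5
  z_bot <- (13 - 22) * 1.5     # anchor residue 22
  park_r <- spec$bundle_radius + 15
  if (!is.null(spec$water_schedule)) {
    ws <- spec$water_schedule
    water_ids <- sort(unique(ws$water))
    inside_z <- with_seed(spec$seed + 1L, function() {
      stats::runif(length(water_ids) * n_frames, z_bot + 1.5, z_top - 1.5)
    })
    inside_xy <- with_seed(spec$seed + 2L, function() {
      stats::runif(2L * length(water_ids) * n_frames, -1, 1)
    })
    wblocks <- vector("list", length(water_ids))
    for (wi in seq_along(water_ids)) {
      w <- water_ids[wi]
      iv <- ws[ws$water == w, , drop = FALSE]
      inside <- rep(FALSE, n_frames)
      for (r in seq_len(nrow(iv)))
        inside[(iv$entry[r]:iv$exit[r]) + 1L] <- TRUE
      truth_counts <- truth_counts + inside
      base <- (wi - 1L) * n_frames
      xs <- ifelse(inside, inside_xy[2 * (base + 1:n_frames) - 1],
                   park_r + 6 * wi)
      ys <- ifelse(inside, inside_xy[2 * (base + 1:n_frames)], 0)
      zs <- ifelse(inside, inside_z[base + 1:n_frames], 0)
      wblocks[[wi]] <- data.frame(
        frame = 0:(n_frames - 1L), chain = "W", resid = 1000L + w,
        resname = "HOH", atomname = "O", x = xs, y = ys, z = zs,
        stringsAsFactors = FALSE)
    }
    blocks <- c(blocks, wblocks)
    water_intervals <- ws[order(ws$water, ws$entry),
                          c("water", "entry", "exit")]
  }

  # -- scripted bridges between Gln sidechains
  if (!is.null(spec$hbond_script)) {
    next_wid <- 5000L
    for (b in spec$hbond_script) {
      ki <- match(b$chain_i, chains)
      kj <- match(b$chain_j, chains)
      stopifnot(!is.na(ki), !is.na(kj), b$n_waters >= 1L)
      nw <- b$n_waters
      for (m in seq_len(nw)) {
        wid <- next_wid
        next_wid <- next_wid + 1L
        xs <- rep(park_r + 6 * (wid - 5000L) + 3, n_frames)
        ys <- rep(-park_r, n_frames)
        zs <- rep(0, n_frames)
        for (f in b$frames) {
          si <- smat[f + 1L, ki]
          sj <- smat[f + 1L, kj]
          p1 <- (templates[[si]] %*% t(rot[[ki]]))["NE2", ]
          p2 <- (templates[[sj]] %*% t(rot[[kj]]))["OE1", ]
          gap <- sqrt(sum((p2 - p1)^2)) / (nw + 1)
          if (gap > 3.5)
            stop(sprintf(
              "generate_trajectory: bridge %s-%s needs spacing %.2f A > 3.5 A; use more waters",
              b$chain_i, b$chain_j, gap), call. = FALSE)
          pos <- p1 + (p2 - p1) * m / (nw + 1)
          xs[f + 1L] <- pos[1]; ys[f + 1L] <- pos[2]; zs[f + 1L] <- pos[3]
        }
        blocks[[length(blocks) + 1L]] <- data.frame(
          frame = 0:(n_frames - 1L), chain = "W", resid = wid,
          resname = "HOH", atomname = "O", x = xs, y = ys, z = zs,
          stringsAsFactors = FALSE)
      }
    }
  }

  atoms <- do.call(rbind, blocks)
  if (spec$noise_sd > 0) {
    jit <- with_seed(spec$seed + 3L, function()
      stats::rnorm(3L * nrow(atoms), 0, spec$noise_sd))
    atoms$x <- atoms$x + jit[seq_len(nrow(atoms))]
    atoms$y <- atoms$y + jit[nrow(atoms) + seq_len(nrow(atoms))]
    atoms$z <- atoms$z + jit[2L * nrow(atoms) + seq_len(nrow(atoms))]
  }
  traj <- traj_frames(atoms, dt = spec$dt, replicate_id = replicate_id)

  truth_states <- data.frame(
    frame = rep(0:(n_frames - 1L), times = 5L),
    chain = rep(chains, each = n_frames),
    state = factor(c(smat), levels = states),
    z_target = unname(spec$state_z_map[c(smat)]),
    stringsAsFactors = FALSE)
  truth_states <- truth_states[order(truth_states$frame,
                                     truth_states$chain), ]
  rownames(truth_states) <- NULL

  list(traj = traj,
       truth = list(states = truth_states, chi = chi_truth,
                    water_intervals = water_intervals,
                    counts = data.frame(frame = 0:(n_frames - 1L),
                                        n = truth_counts),
                    bridges = spec$hbond_script))
}

#' Water schedule realising per-frame target counts
#'
#' Greedily opens/closes single-interval waters so the in-pore count equals
#' `counts[f]` at frame f (0-based frame f = position f+1 of the vector).
#'
#' @param counts integer vector of per-frame target pore water counts.
#' @return data.frame with columns `water`, `entry`, `exit` usable as a
#'   [trajectory_spec()] water schedule.
#' @export
schedule_from_counts <- function(counts) {
  n <- length(counts)
  open <- list()   # water id -> entry frame
  rows <- list()
  next_id <- 1L
  for (f in seq_len(n)) {
    want <- counts[f]
    while (length(open) < want) {
      open[[as.character(next_id)]] <- f - 1L
      next_id <- next_id + 1L
    }
    while (length(open) > want) {
      id <- names(open)[length(open)]
      rows[[length(rows) + 1L]] <- data.frame(
        water = as.integer(id), entry = open[[id]], exit = f - 2L)
      open[[id]] <- NULL
    }
  }
  for (id in names(open))
    rows[[length(rows) + 1L]] <- data.frame(
      water = as.integer(id), entry = open[[id]], exit = n - 1L)
  if (!length(rows))
    return(data.frame(water = integer(0), entry = integer(0),
                      exit = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$water, out$entry), ]
}

# ---- analytic density fixture --------------------------------------------

#' Analytic density fixture with known inflection points
#'
#' Sums logistic steps so that the curve's second derivative changes sign
#' exactly at the requested positions (alternating falling/rising steps:
#' the profile starts high, drops after the first inflection, rises after
#' the second, and so on). Steps must be separated by more than 4 x scale.
#'
#' @param inflection_zs sorted z positions of the inflection points,
#'   Angstrom (may be empty: flat profile).
#' @param scale logistic scale parameter, Angstrom (default 0.8).
#' @param bin_width output bin width (default 0.5).
#' @param z_range range of the profile (default spans the inflections with
#'   a 10 Angstrom margin, or c(-15, 15) when empty).
#' @param amplitude high-density level (default 1).
#' @return a `density_profile` object (built via
#'   [density_profile_from_values()]); attribute `true_inflections`.
#' @export
generate_density_fixture <- function(inflection_zs, scale = 0.8,
                                     bin_width = 0.5, z_range = NULL,
                                     amplitude = 1) {
  zi <- sort(inflection_zs)
  if (length(zi) >= 2L && any(diff(zi) <= 4 * scale))
    stop("generate_density_fixture: inflection points closer than 4*scale",
         call. = FALSE)
  if (is.null(z_range)) {
    z_range <- if (length(zi)) range(zi) + c(-10, 10) else c(-15, 15)
  }
  z <- seq(z_range[1], z_range[2], by = bin_width)
  dens <- rep(amplitude, length(z))
  if (length(zi)) {
    sgn <- rep(c(-1, 1), length.out = length(zi))
    for (i in seq_along(zi))
      dens <- dens + sgn[i] * amplitude / (1 + exp(-(z - zi[i]) / scale))
  }
  dens <- pmax(dens, 0)
  prof <- density_profile_from_values(z, dens, bin_width = bin_width)
  attr(prof, "true_inflections") <- zi
  prof
}

# ---- synthetic flux traces -----------------------------------------------

#' Specification for synthetic plate-reader traces
#'
#' Ground-truth intraliposomal pH follows
#' `pH(t) = pH0 - a * (1 - exp(-(t - t_val)/tau))` after valinomycin
#' addition and `pH0` before it.
#'
#' @param pH0 starting pH (default 7.5).
#' @param amplitude total pH drop `a` (default 0.3).
#' @param tau decay constant, seconds (default 240).
#' @param t_val valinomycin addition time, s (default 120).
#' @param t_end trace end, s (default 720).
#' @param sampling_s sampling interval, s (default 10).
#' @param calib a `calibration_curve` used for the forward map.
#' @param ratio_noise_sd multiplicative ratio noise s.d. (default 0.002).
#' @param n_biological,n_technical replicate structure (defaults 8 and 3).
#' @param F417 pH-independent channel intensity (default 1000).
#' @param seed RNG seed.
#' @return object of class `flux_spec`.
#' @export
flux_spec <- function(pH0 = 7.5, amplitude = 0.3, tau = 240, t_val = 120,
                      t_end = 720, sampling_s = 10,
                      calib = calibration_curve(), ratio_noise_sd = 1e-10,
                      n_biological = 8L, n_technical = 3L, F417 = 1000,
                      seed = 1L) {
  if (pH0 < 3 || pH0 > 9 || (pH0 - amplitude) < 3 || (pH0 - amplitude) > 9)
    stop("flux_spec: pH(t) leaves the calibration range [3, 9]",
         call. = FALSE)
  structure(list(pH0 = pH0, amplitude = amplitude, tau = tau,
                 t_val = t_val, t_end = t_end, sampling_s = sampling_s,
                 calib = calib, ratio_noise_sd = ratio_noise_sd,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical), F417 = F417,
                 seed = as.integer(seed)),
            class = "flux_spec")
}

# Ground-truth pH(t) of a flux_spec.
flux_pH <- function(spec, t) {
  ifelse(t <= spec$t_val, spec$pH0,
         spec$pH0 - spec$amplitude * (1 - exp(-(t - spec$t_val) / spec$tau)))
}

#' Generate synthetic plate-reader traces with ground truth
#'
#' Forward-maps the scripted pH(t) to the fluorescence ratio through the
#' inverse calibration, applies seeded multiplicative noise to the ratio
#' (carried by the F460 channel; F417 is constant), and computes the
#' ground-truth initial rate as the OLS slope of the noiseless total proton
#' concentration over the rate window.
#'
#' @param spec a [flux_spec()].
#' @param variant variant label written to the layout (default "synthetic").
#' @param buffer a `buffer_model` used for the ground-truth rate.
#' @param window rate window, s (default 60).
#' @return list with `plate` (time_s, well, F460, F417), `layout`,
#'   `truth`: list(rate = analytic window slope in M/s, pH_fun, t_val).
#' @export
generate_flux_traces <- function(spec, variant = "synthetic",
                                 buffer = buffer_model(), window = 60) {
  stopifnot(inherits(spec, "flux_spec"))
  times <- seq(0, spec$t_end, by = spec$sampling_s)
  pH_true <- flux_pH(spec, times)
  ratio_true <- pH_to_ratio(pH_true, spec$calib)
  n_wells <- spec$n_biological * spec$n_technical
  noise <- with_seed(spec$seed, function()
    stats::rnorm(n_wells * length(times), 0, spec$ratio_noise_sd))
  plate <- list()
  layout <- list()
  w <- 0L
  for (b in seq_len(spec$n_biological)) for (tech in
                                             seq_len(spec$n_technical)) {
    w <- w + 1L
    well <- sprintf("%s%02d", LETTERS[(w - 1L) %/% 12L + 1L],
                    (w - 1L) %% 12L + 1L)
    idx <- (w - 1L) * length(times) + seq_along(times)
    ratio_obs <- ratio_true * (1 + noise[idx])
    plate[[w]] <- data.frame(time_s = times, well = well,
                             F460 = ratio_obs * spec$F417,
                             F417 = spec$F417, stringsAsFactors = FALSE)
    layout[[w]] <- data.frame(well = well, variant = variant,
                              biological_replicate = b,
                              technical_replicate = tech,
                              stringsAsFactors = FALSE)
  }
  # analytic ground-truth rate: OLS slope of the exact H_total(t) at the
  # window sample points
  sel <- times > spec$t_val & times <= spec$t_val + window
  H <- total_proton(pH_true[sel], buffer)
  tt <- times[sel]
  rate <- sum((tt - mean(tt)) * (H - mean(H))) / sum((tt - mean(tt))^2)
  list(plate = do.call(rbind, plate), layout = do.call(rbind, layout),
       truth = list(rate = rate, t_val = spec$t_val, window = window,
                    pH_fun = function(t) flux_pH(spec, t)))
}
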