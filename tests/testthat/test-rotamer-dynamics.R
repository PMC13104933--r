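# Construct a minimal 5-chain trajectory carrying CA and NE2 for residue 10
# with prescribed z values.
vector_fixture <- function(ca_z, ne2_z, n_frames = 1) {
  chains <- LETTERS[1:5]
  rows <- list()
  for (f in 0:(n_frames - 1)) for (k in 1:5) {
    rows[[length(rows) + 1]] <- data.frame(
      frame = f, chain = chains[k], resid = 10, resname = "GLN",
      atomname = c("CA", "NE2"),
      x = c(cos(2 * pi * k / 5) * 8, cos(2 * pi * k / 5) * 8 + 1),
      y = c(sin(2 * pi * k / 5) * 8, sin(2 * pi * k / 5) * 8),
      z = c(ca_z[k], ne2_z[k]), stringsAsFactors = FALSE)
  }
  traj_frames(do.call(rbind, rows), dt = 200)
}

test_that("Gln vectors and z-offsets follow the CA-plane definition", {
  # all five CA at z = 0, one NE2 3 A above: v = NE2 - CA, z_offset = 3
  traj <- vector_fixture(ca_z = rep(0, 5), ne2_z = c(3, 0, 0, 0, 0))
  v <- compute_gln_vectors(traj, 10)
  expect_equal(nrow(v), 5L)
  a <- v[v$chain == "A", ]
  expect_equal(c(a$vx, a$vy, a$vz), c(1, 0, 3))
  expect_equal(a$z_offset, 3.0)
  # NE2 coincident with the plane mean -> 0
  expect_equal(v$z_offset[v$chain == "B"], 0.0)

  # tilted CA plane: z = {-0.2,-0.1,0,0.1,0.2} has mean 0, NE2 at 1 -> 1.0
  traj2 <- vector_fixture(ca_z = c(-0.2, -0.1, 0, 0.1, 0.2),
                          ne2_z = c(1, 0, 0, 0, 0))
  v2 <- compute_gln_vectors(traj2, 10)
  expect_equal(v2$z_offset[v2$chain == "A"], 1.0)

  # missing NE2 -> error naming frame and chain
  broken <- traj$atoms[!(traj$atoms$chain == "C" &
                           traj$atoms$atomname == "NE2"), ]
  expect_error(compute_gln_vectors(traj_frames(broken, dt = 200), 10),
               "roster|NE2")
})

test_that("state classification uses half-open boundaries", {
  z <- c(-1.0, 1.2, 0.0, 2.5, 2.49999, -1e-9)
  fake <- data.frame(frame = 0:5, chain = "A", z_offset = z)
  st <- classify_states(fake)
  expect_equal(as.character(st$state),
               c("down", "neutral", "neutral", "up", "neutral", "down"))
  # alternative threshold 2.4 reclassifies the band between 2.4 and 2.5
  st24 <- classify_states(fake, thresholds = c(0, 2.4))
  expect_equal(as.character(st24$state[5]), "up")
  expect_error(classify_states(fake, thresholds = c(2, 1)))
})

test_that("pairwise agreement matches hand-enumerated fractions", {
  mk <- function(states_by_frame) {
    # states_by_frame: list of length-5 character vectors
    do.call(rbind, lapply(seq_along(states_by_frame), function(f)
      data.frame(frame = f - 1, chain = LETTERS[1:5],
                 state = states_by_frame[[f]], stringsAsFactors = FALSE)))
  }
  # all chains up in all frames -> all entries 1
  m1 <- pairwise_agreement(mk(list(rep("up", 5), rep("up", 5))))
  expect_true(all(m1 == 1))

  # chain A always up, B always down -> entry(A,B) = 0
  s <- rep("neutral", 5)
  f1 <- s; f1[1] <- "up"; f1[2] <- "down"
  m2 <- pairwise_agreement(mk(list(f1, f1)))
  expect_equal(m2["A", "B"], 0)

  # A and B share a state in exactly 2 of 3 frames -> 2/3
  fa <- c("up", "up", "x3", "x4", "x5")
  fb <- c("up", "up", "x3", "x4", "x5")
  fc <- c("up", "down", "x3", "x4", "x5")
  m3 <- pairwise_agreement(mk(list(fa, fb, fc)))
  expect_equal(m3["A", "B"], 2 / 3)
  expect_equal(attr(m3, "n_frames_used"), 3L)

  empty <- data.frame(frame = integer(0), chain = character(0),
                      state = character(0))
  expect_error(pairwise_agreement(empty), "empty")
})

test_that("agreement matrices are symmetric, unit-diagonal and in [0,1] on random inputs", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    st <- data.frame(frame = rep(0:(n - 1), each = 5),
                     chain = rep(LETTERS[1:5], n),
                     state = sample(c("down", "neutral", "up"), 5 * n,
                                    replace = TRUE))
    m <- pairwise_agreement(st)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 5))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("off-diagonal agreement of independent chains approaches sum(p^2)", {
  # i.i.d. uniform states: expected agreement 1/3
  st <- simulate_state_sequences(30000, stay_prob = 1 / 3, seed = 5)
  m <- pairwise_agreement(st)
  off <- m[upper.tri(m)]
  expect_true(all(abs(off - 1 / 3) < 0.02))
})

test_that("dihedral extraction matches the independent atan2 oracle", {
  # planar cis / trans
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(torsion_angle(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  expect_equal(abs(torsion_angle(trans[1, ], trans[2, ], trans[3, ],
                                 trans[4, ])), 180)

  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    if (sqrt(sum((p[2, ] - p[3, ])^2)) < 0.3) next
    a <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    b <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    d <- abs(a - b)
    worst <- max(worst, min(d, 360 - d))
  }
  expect_lt(worst, 1e-9)

  # collinear triplet -> error
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "collinear")
})

test_that("compute_dihedrals reports chi1/chi2 and flags missing atoms", {
  spec <- trajectory_spec(n_frames = 4, state_script = matrix("up", 4, 5))
  g <- generate_trajectory(spec)
  d <- compute_dihedrals(g$traj, 10)
  expect_equal(nrow(d), 20L)
  expect_true(all(abs(d$chi2 - 180) < 1e-8 | abs(d$chi2 + 180) < 1e-8))
  chopped <- g$traj$atoms[g$traj$atoms$atomname != "CD", ]
  expect_error(compute_dihedrals(traj_frames(chopped, dt = 200), 10),
               "CD")
})

test_that("rotamer clustering separates blobs, absorbs the periodic seam, and reports fractions", {
  set.seed(3)
  blob <- function(c1, c2, n, sd = 4)
    data.frame(frame = seq_len(n), chain = "A",
               chi1 = c1 + stats::rnorm(n, sd = sd),
               chi2 = c2 + stats::rnorm(n, sd = sd))
  two <- rbind(blob(-60, -60, 100), blob(180, 60, 100))
  cl <- cluster_rotamers(two, eps = 20)
  fr <- attr(cl, "fractions")
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$cluster %in% 1:2], c(0.5, 0.5))
  expect_equal(sort(unique(cl$cluster[cl$cluster > 0])), 1:2)

  # identical points: one cluster, fraction 1
  same <- data.frame(frame = 1:50, chain = "A", chi1 = 10, chi2 = -20)
  cls <- cluster_rotamers(same, eps = 20)
  expect_equal(attr(cls, "fractions")$fraction[1], 1)
  expect_true(all(cls$cluster == 1))

  # blob straddling +-180 in chi2: single cluster via the embedding
  wrap <- blob(-60, 180, 120, sd = 6)
  wrap$chi2 <- ((wrap$chi2 + 180) %% 360) - 180
  clw <- cluster_rotamers(wrap, eps = 20)
  expect_equal(max(clw$cluster), 1L)
  expect_true(all(clw$cluster == 1L))
})

test_that("KDE background contours enclose the stated probability mass", {
  set.seed(9)
  ref <- data.frame(chi1 = stats::rnorm(1500, 0, 30),
                    chi2 = stats::rnorm(1500, 20, 25))
  kb <- kde_background(ref)
  expect_true(kb$thresholds["d90"] <= kb$thresholds["d70"])
  fresh <- data.frame(chi1 = stats::rnorm(10000, 0, 30),
                      chi2 = stats::rnorm(10000, 20, 25))
  dens <- kb$density(fresh$chi1, fresh$chi2)
  expect_lt(abs(mean(dens >= kb$thresholds["d70"]) - 0.70), 0.03)
  expect_lt(abs(mean(dens >= kb$thresholds["d90"]) - 0.90), 0.03)

  expect_error(kde_background(data.frame(chi1 = rep(1, 40),
                                         chi2 = rep(2, 40))),
               "degenerate")
  expect_error(kde_background(data.frame(chi1 = 1:10, chi2 = 1:10)),
               "25")
})

test_that("z histograms pool chains, frames and replicates", {
  spec <- trajectory_spec(n_frames = 10, seed = 2)
  runs <- lapply(1:3, function(r)
    compute_gln_vectors(generate_trajectory(
      trajectory_spec(n_frames = 10, seed = r),
      replicate_id = paste0("run", r))$traj, 10))
  pooled <- pool_gln_vectors(runs)
  h <- z_histogram(pooled)
  expect_equal(attr(h, "total"), 5L * 10L * 3L)
  h1 <- z_histogram(runs[[1]])
  expect_equal(attr(h1, "total"), 50L)

  const <- data.frame(z_offset = rep(1.7, 30))
  hc <- z_histogram(const)
  expect_equal(sum(hc$count > 0), 1L)
})
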