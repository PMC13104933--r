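water_pair <- function(d, with_h = FALSE, angle = 180) {
  # two waters separated by d along x; optional donor hydrogen placed so
  # the D-H...A angle equals `angle`
  at <- data.frame(frame = 0,
                   chain = "W", resid = c(1, 2), resname = "HOH",
                   atomname = "O", x = c(0, d), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  if (with_h) {
    # H at 1.0 A from donor O; position set by the required angle at H
    th <- (180 - angle) * pi / 180
    at <- rbind(at, data.frame(frame = 0, chain = "W", resid = 1,
                               resname = "HOH", atomname = "H1",
                               x = cos(th), y = sin(th), z = 0,
                               stringsAsFactors = FALSE))
  }
  at
}

test_that("hydrogen bonds follow distance and angle criteria", {
  # O-O 2.8 A, no hydrogens: distance-only bond, flagged
  b1 <- detect_hbonds(water_pair(2.8))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$mode, "distance")
  expect_equal(b1$distance, 2.8)

  # O-O 4.0 A: no bond
  expect_equal(nrow(detect_hbonds(water_pair(4.0))), 0L)

  # ideal near-linear hydrogen: bond in angle mode
  b2 <- detect_hbonds(water_pair(2.8, with_h = TRUE, angle = 175))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$mode, "angle")
  expect_gt(b2$angle, 170)

  # bent geometry (90 degrees at H): rejected despite the short distance
  expect_equal(nrow(detect_hbonds(water_pair(2.8, with_h = TRUE,
                                             angle = 90))), 0L)

  # decreasing d_max never adds bonds (monotonicity)
  set.seed(31)
  for (i in 1:20) {
    at <- data.frame(frame = 0, chain = "W", resid = 1:6,
                     resname = "HOH", atomname = "O",
                     x = stats::runif(6, 0, 8), y = stats::runif(6, 0, 8),
                     z = stats::runif(6, 0, 8), stringsAsFactors = FALSE)
    n_wide <- nrow(detect_hbonds(at, d_max = 3.5))
    n_narrow <- nrow(detect_hbonds(at, d_max = 2.7))
    expect_lte(n_narrow, n_wide)
  }
})

test_that("Gln/Ser donor-acceptor chemistry is respected", {
  # NE2 (donor only) cannot accept from a water donor side, but the
  # water(both)-NE2(donor) pair is still a valid bond with water accepting
  at <- data.frame(frame = 0,
                   chain = c("A", "A", "W"), resid = c(10, 10, 1),
                   resname = c("GLN", "GLN", "HOH"),
                   atomname = c("NE2", "OE1", "O"),
                   x = c(0, 10, 2.9), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  b <- detect_hbonds(at)
  expect_equal(nrow(b), 1L)
  expect_equal(b$donor_atom, "NE2")
  expect_equal(b$acceptor_atom, "O")

  # two NE2 atoms close together: donor-donor, no bond
  dd <- data.frame(frame = 0, chain = c("A", "B"), resid = 10,
                   resname = "GLN", atomname = "NE2",
                   x = c(0, 2.9), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_equal(nrow(detect_hbonds(dd)), 0L)
})

test_that("water bridges match hand-built chains", {
  # residue - water - residue: bridge length 1
  chain3 <- data.frame(frame = 0,
                       chain = c("A", "W", "B"), resid = c(10, 1, 10),
                       resname = c("GLN", "HOH", "GLN"),
                       atomname = c("OE1", "O", "OE1"),
                       x = c(0, 2.8, 5.6), y = 0, z = 0,
                       stringsAsFactors = FALSE)
  br <- water_bridges(detect_hbonds(chain3))
  expect_equal(nrow(br), 1L)
  expect_equal(br$bridge_waters, 1L)

  # direct residue-residue bond (NE2 donor to OE1 acceptor): length 0
  direct <- chain3[c(1, 3), ]
  direct$atomname <- c("NE2", "OE1")
  direct$x <- c(0, 3.2)
  br0 <- water_bridges(detect_hbonds(direct))
  expect_equal(br0$bridge_waters, 0L)

  # chain of 6 interior waters: beyond the cutoff, no interaction
  n_w <- 6
  chain8 <- data.frame(frame = 0,
                       chain = c("A", rep("W", n_w), "B"),
                       resid = c(10, 1:n_w, 10),
                       resname = c("GLN", rep("HOH", n_w), "GLN"),
                       atomname = c("OE1", rep("O", n_w), "OE1"),
                       x = seq(0, by = 2.8, length.out = n_w + 2),
                       y = 0, z = 0, stringsAsFactors = FALSE)
  expect_equal(nrow(water_bridges(detect_hbonds(chain8))), 0L)
  # ... but it is found when max_waters is raised
  expect_equal(water_bridges(detect_hbonds(chain8),
                             max_waters = 6L)$bridge_waters, 6L)
})

test_that("bridge search equals brute-force path enumeration on random graphs", {
  set.seed(17)
  for (rep in 1:30) {
    g <- random_bond_table(n_res = sample(2:4, 1),
                           n_wat = sample(4:8, 1),
                           p_edge = stats::runif(1, 0.1, 0.35))
    if (!nrow(g$bonds)) next
    got <- water_bridges(g$bonds, max_waters = 5L)
    got$id_i <- paste0(got$chain_i, got$resid_i)
    got$id_j <- paste0(got$chain_j, got$resid_j)
    for (i in seq_along(g$res_ids)) for (j in seq_along(g$res_ids)) {
      if (j <= i) next
      a <- g$res_ids[i]; b <- g$res_ids[j]
      want <- oracle_min_bridge(g$edges, g$is_water, a, b, 5L)
      row <- got[(got$id_i == a & got$id_j == b) |
                   (got$id_i == b & got$id_j == a), ]
      if (is.infinite(want)) {
        expect_equal(nrow(row), 0L)
      } else {
        expect_equal(nrow(row), 1L)
        expect_equal(row$bridge_waters, want)
      }
    }
    # monotonicity in max_waters: growing the budget never loses a pair
    for (mw in 0:4) {
      lo <- water_bridges(g$bonds, max_waters = mw)
      hi <- water_bridges(g$bonds, max_waters = mw + 1L)
      key <- function(d) paste(d$chain_i, d$resid_i, d$chain_j, d$resid_j)
      expect_true(all(key(lo) %in% key(hi)))
    }
  }
})

test_that("network building applies occupancy and core filters", {
  mk_inter <- function(frames, resid_i = 10, resid_j = 17)
    data.frame(frame = frames, chain_i = "A", resid_i = resid_i,
               chain_j = "B", resid_j = resid_j, bridge_waters = 1L,
               stringsAsFactors = FALSE)
  # 40 of 500 frames -> occupancy 0.08 < 0.10 -> dropped
  net <- build_network(mk_inter(0:39), n_frames_window = 500)
  expect_equal(nrow(net$edges), 0L)
  # present in all 500 -> occupancy 1, retained
  net2 <- build_network(mk_inter(0:499), n_frames_window = 500)
  expect_equal(net2$edges$occupancy, 1.0)
  # residue 22 outside the 6-20 core -> excluded
  net3 <- build_network(mk_inter(0:499, resid_j = 22),
                        n_frames_window = 500)
  expect_equal(nrow(net3$edges), 0L)
  expect_error(build_network(mk_inter(0), 0), "empty")

  # re-filtering a filtered network is the identity
  x <- rbind(mk_inter(0:59), mk_inter(0:499, resid_i = 8))
  netA <- build_network(x, 500)
  again <- netA$edges
  expect_true(all(again$occupancy >= 0.10 & again$occupancy <= 1))
  netB <- build_network(x[x$frame < 500, ], 500)
  expect_equal(netA$edges, netB$edges)
})

test_that("interaction-type fractions count pore sidechain bonds", {
  gln_bond <- function(partner_resname, partner_atom, partner_resid = 13) {
    data.frame(donor_chain = "A", donor_resid = 10L,
               donor_resname = "GLN", donor_atom = "NE2",
               acceptor_chain = "B", acceptor_resid = partner_resid,
               acceptor_resname = partner_resname,
               acceptor_atom = partner_atom,
               distance = 2.9, angle = NA_real_, mode = "distance",
               frame = 0L, stringsAsFactors = FALSE)
  }
  only_gg <- rbind(gln_bond("GLN", "OE1", 17))
  f1 <- interaction_fractions(only_gg)
  expect_equal(unname(f1["Gln-Gln"]), 1.0)

  # 3 Gln-water + 1 Gln-Gln per frame -> 0.75 / 0.25
  mixed <- rbind(gln_bond("HOH", "O", 1), gln_bond("HOH", "O", 2),
                 gln_bond("HOH", "O", 3), gln_bond("GLN", "OE1", 17))
  f2 <- interaction_fractions(mixed)
  expect_equal(unname(f2["Gln-water"]), 0.75)
  expect_equal(unname(f2["Gln-Gln"]), 0.25)
  expect_equal(sum(f2), 1.0)

  # water-water-only input: nothing countable
  ww <- detect_hbonds(water_pair(2.8))
  ww$frame <- 0L
  expect_error(interaction_fractions(ww), "no counted")
})

test_that("scripted bridge schedules are recovered with exact occupancy", {
  spec <- trajectory_spec(
    n_frames = 20, state_script = matrix("up", 20, 5),
    hbond_script = list(list(chain_i = "A", chain_j = "C",
                             frames = 0:9, n_waters = 3),
                        list(chain_i = "B", chain_j = "D",
                             frames = 10:14, n_waters = 3)))
  g <- generate_trajectory(spec)
  bonds <- frame_hbonds(g$traj)
  br <- water_bridges(bonds)
  net <- build_network(br, n_frames_window = 20, occupancy_min = 0.10)
  key <- paste(net$edges$chain_i, net$edges$chain_j)
  expect_setequal(key, c("A C", "B D"))
  expect_equal(net$edges$occupancy[key == "A C"], 10 / 20)
  expect_equal(net$edges$occupancy[key == "B D"], 5 / 20)
  expect_equal(net$edges$mean_bridge_waters, c(3, 3))
})
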