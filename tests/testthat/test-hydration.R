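bundle_traj <- function(n_frames = 1) {
  traj_frames(ideal_bundle_atoms(n_frames), dt = 200)
}

test_that("the pore region is the closed hull of the ten anchor CA atoms", {
  traj <- bundle_traj()
  region <- define_pore_region(traj)
  expect_true(in_pore(region, 0, c(0, 0, 0)))           # centroid
  expect_false(in_pore(region, 0, c(60, 0, 0)))         # 50+ A outside
  anchor <- region$regions[[1]]$points[1, ]
  expect_true(in_pore(region, 0, anchor))               # vertex on hull

  # missing anchors -> error naming the frame
  chopped <- traj$atoms[traj$atoms$resid != 5, ]
  expect_error(define_pore_region(traj_frames(chopped, dt = 200)),
               "frame 0")
})

test_that("pore water counting follows the scripted schedule", {
  # no waters at all
  occ0 <- count_pore_waters(bundle_traj(3),
                            define_pore_region(bundle_traj(3)))
  expect_equal(occ0$counts$n, rep(0L, 3))

  # one water inside frames 3..7 of 10
  spec <- trajectory_spec(n_frames = 10,
                          water_schedule = data.frame(entry = 3, exit = 7))
  g <- generate_trajectory(spec)
  reg <- define_pore_region(g$traj)
  occ <- count_pore_waters(g$traj, reg)
  expect_equal(occ$counts$n, as.integer(0:9 %in% 3:7))
  expect_equal(occ$counts$n, g$truth$counts$n)

  # 12 waters in a single frame
  spec12 <- trajectory_spec(n_frames = 2,
                            water_schedule = data.frame(entry = rep(1, 12),
                                                        exit = rep(1, 12)))
  g12 <- generate_trajectory(spec12)
  occ12 <- count_pore_waters(g12$traj, define_pore_region(g12$traj))
  expect_equal(occ12$counts$n, c(0L, 12L))
})

test_that("residence intervals and durations match hand traces", {
  # inside frames 10..19 at dt = 200 ps -> one 2.0 ns interval
  spec <- trajectory_spec(n_frames = 30,
                          water_schedule = data.frame(entry = 10,
                                                      exit = 19))
  g <- generate_trajectory(spec)
  occ <- count_pore_waters(g$traj, define_pore_region(g$traj))
  rt <- residence_times(occ)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$entry_frame, 10L)
  expect_equal(rt$exit_frame, 19L)
  expect_equal(rt$duration_ns, 2.0)
  expect_false(rt$censored_start || rt$censored_end)

  # two intervals 0..4 and 8..9; the second one is end-censored
  spec2 <- trajectory_spec(
    n_frames = 10,
    water_schedule = data.frame(water = c(1, 1), entry = c(0, 8),
                                exit = c(4, 9)))
  g2 <- generate_trajectory(spec2)
  occ2 <- count_pore_waters(g2$traj, define_pore_region(g2$traj))
  rt2 <- residence_times(occ2)
  expect_equal(rt2$n_frames, c(5L, 2L))
  expect_equal(rt2$censored_start, c(TRUE, FALSE))
  expect_equal(rt2$censored_end, c(FALSE, TRUE))

  # water never inside -> no rows
  expect_equal(nrow(residence_times(occ0_global <- count_pore_waters(
    bundle_traj(2), define_pore_region(bundle_traj(2))))), 0L)
})

test_that("residence-interval frame counts conserve the occupancy schedule", {
  set.seed(14)
  for (i in 1:5) {
    n_frames <- 40
    n_waters <- 6
    sched <- do.call(rbind, lapply(seq_len(n_waters), function(w) {
      # sequential intervals separated by >= 2 frames so scripted runs
      # stay distinct after tracking
      rows <- list()
      pos <- sample(0:3, 1)
      while (pos < n_frames - 4) {
        entry <- pos
        exit <- min(entry + sample(0:5, 1), n_frames - 1)
        rows[[length(rows) + 1]] <- data.frame(water = w, entry = entry,
                                               exit = exit)
        pos <- exit + 2 + sample(0:4, 1)
      }
      do.call(rbind, rows)
    }))
    g <- generate_trajectory(trajectory_spec(n_frames = n_frames,
                                             water_schedule = sched,
                                             seed = i))
    occ <- count_pore_waters(g$traj, define_pore_region(g$traj))
    rt <- residence_times(occ)
    # per water: sum of interval lengths == frames inside
    for (w in unique(occ$inside$water_id)) {
      expect_equal(sum(rt$n_frames[rt$water_id == w]),
                   sum(occ$inside$water_id == w))
    }
    # and the scripted schedule is recovered exactly
    sched$water_id <- paste0("W", 1000 + sched$water)
    m <- merge(rt, sched,
               by.x = c("water_id", "entry_frame", "exit_frame"),
               by.y = c("water_id", "entry", "exit"))
    expect_equal(nrow(m), nrow(rt))
  }
})

test_that("density profiles integrate to the mean pore water count", {
  set.seed(4)
  counts <- sample(0:14, 25, replace = TRUE)
  g <- generate_trajectory(trajectory_spec(
    n_frames = 25, water_schedule = schedule_from_counts(counts)))
  reg <- define_pore_region(g$traj)
  prof <- density_profile(g$traj, reg)
  expect_equal(sum(prof$density) * attr(prof, "bin_width"),
               mean(counts), tolerance = 1e-9)
  expect_equal(attr(prof, "mean_count"), mean(counts))

  # no waters: all-zero profile, no inflection points
  empty <- density_profile(bundle_traj(2), define_pore_region(bundle_traj(2)))
  expect_true(all(empty$density == 0))
  hl <- hydrophobic_length(empty)
  expect_equal(length(hl$inflection_points), 0L)
  expect_equal(hl$effective_length, 0)
})

test_that("second derivatives of an analytic profile match the closed form", {
  # double-logistic profile: d(z) = 1 - s(z+6) + s(z-6), s logistic
  s <- 1.5
  bin <- 0.25
  z <- seq(-15, 15, by = bin)
  sig <- function(u) 1 / (1 + exp(-u / s))
  dens <- 1 - sig(z + 6) + sig(z - 6)
  # analytic second derivative
  d2sig <- function(u) {
    p <- sig(u)
    p * (1 - p) * (1 - 2 * p) / s^2
  }
  d2_true <- -d2sig(z + 6) + d2sig(z - 6)
  prof <- density_profile_from_values(z, dens, bin_width = bin)
  ok <- !is.na(prof$d2)
  expect_lt(max(abs(prof$d2[ok] - d2_true[ok])),
            0.05 * max(abs(d2_true)))
})

test_that("hydrophobic lengths recover constructed inflection distances", {
  # analytic fixture with inflections at +-6 -> effective length ~12
  prof <- generate_density_fixture(c(-6, 6), scale = 0.8, bin_width = 0.5)
  hl <- hydrophobic_length(prof)
  truth <- attr(prof, "true_inflections")
  for (tz in truth) {
    expect_lt(min(abs(hl$inflection_points - tz)), 0.5)
  }
  expect_lt(abs(hl$effective_length - 12), 0.5)

  # constant profile -> no spans
  flat <- density_profile_from_values(seq(-10, 10, 0.5),
                                      rep(1, 41), bin_width = 0.5)
  expect_equal(hydrophobic_length(flat)$effective_length, 0)

  # alternating wet/dry/wet/dry/wet pattern: the two 8-A dry spans
  # qualify, the fully hydrated 12-A centre span does not
  prof2 <- generate_density_fixture(c(-14, -6, 6, 14), scale = 1,
                                    bin_width = 0.5)
  hl2 <- hydrophobic_length(prof2)
  for (tz in attr(prof2, "true_inflections"))
    expect_lt(min(abs(hl2$inflection_points - tz)), 0.5)
  q <- hl2$spans[hl2$spans$qualifies, ]
  expect_equal(nrow(q), 2L)
  expect_equal(q$length, c(8, 8), tolerance = 0.05)
  expect_lt(abs(hl2$effective_length - 8), 0.5)
})

test_that("wet/dry classification applies the hysteresis rule", {
  mk_occ <- function(counts) {
    structure(list(counts = data.frame(frame = seq_along(counts) - 1,
                                       n = counts),
                   inside = data.frame(frame = integer(0),
                                       water_id = character(0),
                                       z = numeric(0)),
                   water_ids = character(0),
                   n_frames = length(counts), dt = 200),
              class = "water_occupancy")
  }
  lab <- classify_wet_dry(mk_occ(c(0, 0, 12, 11, 5, 0)))
  expect_equal(as.character(lab$label),
               c("dry", "dry", "wet", "wet", "wet", "dry"))
  expect_equal(as.character(classify_wet_dry(mk_occ(c(0, 0, 0)))$label),
               rep("dry", 3))
  expect_equal(as.character(classify_wet_dry(mk_occ(c(3, 3, 3)))$label),
               rep("transition", 3))

  # property: every frame labelled; wet frames only at/after first n >= 10
  set.seed(8)
  for (i in 1:10) {
    counts <- sample(0:15, 50, replace = TRUE)
    lab <- classify_wet_dry(mk_occ(counts))
    expect_false(anyNA(lab$label))
    wet_idx <- which(lab$label == "wet")
    if (length(wet_idx))
      expect_gte(min(wet_idx), min(which(counts >= 10)))
  }
})
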