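static_traj <- function(xyz, elements, n_frames = 1, names = NULL) {
  if (is.null(names)) names <- paste0(elements, seq_along(elements))
  trajectory(data.frame(name = names, element = elements),
             rep(list(xyz), n_frames), dt = 10)
}

test_that("ring perception sizes cycles and returns 0 for acyclic graphs", {
  hexane <- cbind(1:6, c(2:6, 1))
  expect_equal(largest_ring_size(hexane, 6), 6)
  chain <- cbind(1:5, 2:6)
  expect_equal(largest_ring_size(chain, 6), 0)
  # fused bicyclic (naphthalene-like): largest smallest ring is 6
  naph <- rbind(cbind(1:6, c(2:6, 1)), cbind(c(1, 7, 8, 9), c(7, 8, 9, 6)))
  expect_equal(largest_ring_size(naph, 9), 6)
})

test_that("hydrogen-bond detection applies the distance window and angle cutoff", {
  # linear N-H...N geometry, H...acceptor 2.0 A
  xyz <- matrix(c(0, 0, 0,    # N donor
                  1, 0, 0,    # H
                  3, 0, 0),   # N acceptor
                ncol = 3, byrow = TRUE)
  tr <- static_traj(xyz, c("N", "H", "N"))
  hb <- hbond_series(tr, donor_h = 2, acceptor = 3)
  expect_true(hb$flags[1])
  expect_equal(hb$values[1], 2.0)
  expect_equal(hb$frequency, 1)
  # 3.0 A is outside the 1.5-2.5 A window
  far <- xyz; far[3, 1] <- 4.0
  expect_false(hbond_series(static_traj(far, c("N", "H", "N")),
                            donor_h = 2, acceptor = 3)$flags[1])
  # bent arrangement below the 120 degree cutoff is not a bond
  bent <- xyz; bent[3, ] <- c(1.4, 1.8, 0)  # ~66 deg at H, d ~ 1.84 A
  expect_false(hbond_series(static_traj(bent, c("N", "H", "N")),
                            donor_h = 2, acceptor = 3)$flags[1])
  expect_error(hbond_series(tr, donor_h = 1, acceptor = 3),
               "not a hydrogen")
})

test_that("planted contact schedules are recovered at exact frequency", {
  xyz <- matrix(c(0, 0, 0, 1, 0, 0, 5, 0, 0), ncol = 3, byrow = TRUE)
  tr <- static_traj(xyz, c("N", "H", "N"), n_frames = 1000)
  planted <- plant_contact_events(tr, mobile = 3, anchor = 2,
                                  window = c(1.5, 2.5),
                                  target_frequency = 0.6, seed = 5,
                                  direction_from = 1)
  expect_equal(sum(planted$flags), 600)
  hb <- hbond_series(planted$trajectory, donor_h = 2, acceptor = 3)
  expect_equal(hb$frequency, 0.6)
  expect_equal(hb$flags, planted$flags)
  none <- plant_contact_events(tr, 3, 2, c(1.5, 2.5), 0, seed = 5,
                               direction_from = 1)
  expect_equal(sum(none$flags), 0)
})

test_that("NH-pi distance uses the unweighted ring centroid and its window", {
  hexagon <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    1.39 * c(cos(a), sin(a), 0)
  }, numeric(3)))
  place_n <- function(z) rbind(hexagon, c(0, 0, z))
  tr <- static_traj(place_n(3.2), c(rep("C", 6), "N"))
  s <- nh_pi_series(tr, n_atom = 7, ring_atoms = 1:6)
  expect_equal(s$values[1], 3.2)  # centroid of a regular hexagon is its center
  expect_true(s$flags[1])
  expect_false(nh_pi_series(static_traj(place_n(4.5), c(rep("C", 6), "N")),
                            7, 1:6)$flags[1])
  expect_error(nh_pi_series(tr, 7, c(1, 2, 99)), "outside topology")
  expect_error(nh_pi_series(tr, 7, 1:2), ">= 3 ring atoms")
})

test_that("dihedrals follow the signed IUPAC convention and an independent oracle", {
  cis <- matrix(c(1, 1, 0, 1, 0, 0, 2, 0, 0, 2, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(dihedral_series(static_traj(cis, rep("C", 4)), 1, 2, 3, 4)$values,
               0)
  trans <- cis; trans[4, ] <- c(2, -1, 0)
  expect_equal(abs(dihedral_series(static_traj(trans, rep("C", 4)),
                                   1, 2, 3, 4)$values), 180)
  for (s in 1:20) {
    p <- rand_xyz(4, s, spread = 2)
    got <- dihedral_series(static_traj(p, rep("C", 4)), 1, 2, 3, 4)$values
    expect_equal(got, dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 2, 1, 0),
                      ncol = 3, byrow = TRUE)
  expect_error(dihedral_series(static_traj(collinear, rep("C", 4)),
                               1, 2, 3, 4), "frame 1.*collinear")
  expect_error(dihedral_series(static_traj(cis, rep("C", 4)), 1, 2, 3, 3),
               "distinct")
})

test_that("RMSD series is zero for the reference and for rigid motions of it", {
  ref <- rand_conformer(10, 5)
  frames <- lapply(1:6, function(i) {
    set.seed(i)
    rigid_transform(ref$xyz,
                    euler_rotation(stats::runif(1, 0, 2 * pi),
                                   stats::runif(1, 0, pi),
                                   stats::runif(1, 0, 2 * pi)),
                    stats::rnorm(3, sd = 10))
  })
  tr <- trajectory(ref$atoms, c(list(ref$xyz), frames), dt = 10)
  s <- rmsd_series(tr, ref)
  expect_equal(s$values, rep(0, 7), tolerance = 1e-9)
})

test_that("geometric descriptors are invariant under global rigid motion", {
  sc <- build_macrocycle_scaffold()
  sim <- simulate_two_state_trajectory(sc, c(0.6, 0.4), n_frames = 40,
                                       jitter = 0.05, seed = 3)
  tr <- sim$trajectory
  set.seed(77)
  moved <- tr
  moved$frames <- lapply(tr$frames, function(fr)
    rigid_transform(fr,
                    euler_rotation(stats::runif(1, 0, 2 * pi),
                                   stats::runif(1, 0, pi),
                                   stats::runif(1, 0, 2 * pi)),
                    stats::rnorm(3, sd = 20)))
  nh <- sc$substituent_atoms$sub1
  phe <- sc$substituent_atoms$sub10
  expect_equal(nh_pi_series(moved, nh, phe)$values,
               nh_pi_series(tr, nh, phe)$values, tolerance = 1e-9)
  expect_equal(hbond_series(moved, donor_h = nh, acceptor = 7)$values,
               hbond_series(tr, donor_h = nh, acceptor = 7)$values,
               tolerance = 1e-9)
  expect_equal(dihedral_series(moved, 1, 2, 3, 4)$values,
               dihedral_series(tr, 1, 2, 3, 4)$values, tolerance = 1e-8)
  expect_equal(rmsd_series(moved, sc$conformer)$values,
               rmsd_series(tr, sc$conformer)$values, tolerance = 1e-9)
})

test_that("widening a detection window never decreases the contact frequency", {
  sc <- build_macrocycle_scaffold()
  sim <- simulate_two_state_trajectory(sc, c(0.5, 0.5), n_frames = 60,
                                       jitter = 0.3, seed = 9)
  nh <- sc$substituent_atoms$sub1
  phe <- sc$substituent_atoms$sub10
  windows <- list(c(3.0, 3.3), c(2.9, 3.6), c(2.5, 4.5), c(0, 50))
  freqs <- vapply(windows, function(w)
    nh_pi_series(sim$trajectory, nh, phe, window = w)$frequency, numeric(1))
  expect_true(all(diff(freqs) >= 0))
  expect_true(all(freqs >= 0 & freqs <= 1))
})

test_that("two-state classifiers recover planted populations and agree", {
  sc <- build_macrocycle_scaffold()
  sim <- simulate_two_state_trajectory(sc, c(0.7, 0.3), n_frames = 400,
                                       jitter = 0, seed = 21)
  sa <- classify_states(rmsd_series(sim$trajectory, sc$conformer))
  expect_equal(sa$populations, c(0.7, 0.3))
  expect_equal(sa$labels, sim$labels)
  sf <- classify_states_faces(sim$trajectory, sc$ring_atoms,
                              nh1 = c(1, sc$substituent_atoms$sub1),
                              nh2 = c(7, sc$substituent_atoms$sub7))
  expect_equal(sf$populations, c(0.7, 0.3))
  expect_gte(mean(sf$labels == sa$labels), 0.95)
  expect_equal(sum(sa$populations), 1)
})

test_that("degenerate state inputs give single-state assignments", {
  expect_warning(sa <- classify_states(rep(1.25, 10)), "single")
  expect_equal(sa$populations, c(1, 0))
  # unimodal noise must not be split into two states
  set.seed(33)
  expect_warning(sg <- classify_states(stats::rnorm(500, 1, 0.05)),
                 "unimodal")
  expect_equal(sg$populations, c(1, 0))
  expect_warning(su <- classify_states(stats::runif(500)), "unimodal")
  expect_equal(su$populations, c(1, 0))
  # mirror-image NH vectors across the ring plane are state 1
  sc <- build_macrocycle_scaffold()
  tr <- trajectory(sc$conformer$atoms, rep(list(sc$conformer$xyz), 3), dt = 10)
  sf <- classify_states_faces(tr, sc$ring_atoms,
                              nh1 = c(1, sc$substituent_atoms$sub1),
                              nh2 = c(7, sc$substituent_atoms$sub7))
  expect_equal(sf$labels, rep(1L, 3))
  # both on the same face is state 2
  sf2 <- classify_states_faces(tr, sc$ring_atoms,
                               nh1 = c(1, sc$substituent_atoms$sub1),
                               nh2 = c(13, sc$substituent_atoms$sub13))
  expect_equal(sf2$labels, rep(2L, 3))
})
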