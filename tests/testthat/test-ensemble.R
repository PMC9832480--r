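test_that("superposition recovers rigid motions and matches independent oracles", {
  x <- rand_xyz(8, 1)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  # 90 degree rotation about z plus translation: rigid, so rmsd 0
  rot90 <- euler_rotation(pi / 2, 0, 0)
  y <- rigid_transform(x, rot90, c(3, -2, 7))
  sp <- superpose(x, y)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
  expect_equal(apply_superposition(y, sp), x, ignore_attr = TRUE,
               tolerance = 1e-9)

  # 4-point asymmetric fixture, one atom displaced 1 A: grid-search oracle
  x4 <- matrix(c(0, 0, 0, 1.6, 0, 0, 0.4, 1.9, 0, 0.3, 0.5, 1.7),
               ncol = 3, byrow = TRUE)
  y4 <- x4
  y4[3, ] <- y4[3, ] + c(1, 0, 0)
  y4 <- rigid_transform(y4, euler_rotation(0.9, 1.3, 0.2), c(1, 2, 3))
  expect_equal(superpose(x4, y4)$rmsd, grid_superpose_rmsd(x4, y4),
               tolerance = 1e-3)

  # cross-check against bio3d's fitted rmsd on random pairs
  for (s in 1:5) {
    a <- rand_xyz(10, s)
    b <- a + rand_xyz(10, s + 100, spread = 0.5)
    expect_equal(superpose(a, b)$rmsd,
                 bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE),
                 tolerance = 1e-3)
  }
})

test_that("superposition is symmetric and rejects degenerate selections", {
  a <- rand_xyz(9, 3)
  b <- rand_xyz(9, 4)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd, tolerance = 1e-9)
  line <- cbind(seq_len(5), 2 * seq_len(5), -seq_len(5))
  expect_error(superpose(line, line + 0.1), "collinear")
  expect_error(superpose(a, b, selection = 1:2), ">= 3")
})

test_that("deduplication absorbs rigid copies, conserves degeneracy mass", {
  ens <- planted_duplicate_ensemble()
  out <- deduplicate(ens, rmsd_threshold = 0.75)
  expect_length(out$conformers, 3)
  expect_equal(conformer_ids(out), c("conf1", "conf3", "conf5"))
  expect_equal(out$degeneracy, c(3L, 1L, 1L))
  expect_equal(sum(out$degeneracy), length(ens$conformers))
  # threshold 0 keeps all distinct inputs with unit degeneracy
  distinct <- ensemble(lapply(1:5, function(i)
    rand_conformer(8, i * 7, id = paste0("conf", i))))
  out0 <- deduplicate(distinct, rmsd_threshold = 0)
  expect_length(out0$conformers, 5)
  expect_equal(out0$degeneracy, rep(1L, 5))
})

test_that("deduplication matches a greedy O(n^2) oracle on a random 12-conformer set", {
  set.seed(11)
  base <- rand_xyz(8, 99)
  confs <- lapply(1:12, function(i) {
    pert <- base + matrix(stats::rnorm(24, sd = stats::runif(1, 0.05, 1.2)),
                          ncol = 3)
    conformer(data.frame(name = paste0("C", 1:8), element = "C"),
              pert, conformer_id = paste0("conf", i))
  })
  ens <- ensemble(confs, compound_id = "oracle-fixture")
  out <- deduplicate(ens, rmsd_threshold = 0.75, heavy_only = FALSE)

  # independent oracle: greedy in-order clustering with bio3d fitted RMSD
  reps <- integer(0); deg <- integer(0)
  for (i in 1:12) {
    hit <- 0L
    for (k in seq_along(reps)) {
      r <- bio3d::rmsd(as.vector(t(confs[[reps[k]]]$xyz)),
                       as.vector(t(confs[[i]]$xyz)), fit = TRUE)
      if (r <= 0.75) { hit <- k; break }
    }
    if (hit) deg[hit] <- deg[hit] + 1L
    else { reps <- c(reps, i); deg <- c(deg, 1L) }
  }
  expect_equal(conformer_ids(out), paste0("conf", reps))
  expect_equal(out$degeneracy, deg)
  # retained set is pairwise separated beyond the threshold
  for (i in seq_along(out$conformers))
    for (j in seq_len(i - 1))
      expect_gt(superpose(out$conformers[[i]], out$conformers[[j]])$rmsd, 0.75)
})

test_that("top-degeneracy selection keeps 10, breaking ties by energy then order", {
  confs <- lapply(1:25, function(i)
    rand_conformer(5, i, id = paste0("conf", i)))
  ens <- ensemble(confs, degeneracy = sample(1:100, 25))
  top <- select_top_degeneracy(ens, n = 10)
  expect_length(top$conformers, 10)
  expect_equal(sort(top$degeneracy, decreasing = TRUE), top$degeneracy)
  expect_equal(min(top$degeneracy), sort(ens$degeneracy, decreasing = TRUE)[10])
  expect_length(select_top_degeneracy(ens, n = 1)$conformers, 1)
  expect_equal(select_top_degeneracy(ens, n = 1)$degeneracy,
               max(ens$degeneracy))

  # all-equal degeneracies: stable sort on (-degeneracy, energy, index)
  e <- c(5, 1, 3, 3, 2)
  ens2 <- ensemble(lapply(1:5, function(i)
    conformer(confs[[i]]$atoms, confs[[i]]$xyz, energy = e[i],
              conformer_id = paste0("conf", i))))
  ord <- order(-rep(1, 5), e, seq_len(5))
  expect_equal(conformer_ids(select_top_degeneracy(ens2, 3)),
               paste0("conf", ord[1:3]))
  expect_warning(select_top_degeneracy(ens2, 10), "returning all")
})

test_that("energy window filtering keeps the MEC and is monotone in the window", {
  e <- c(0, 4, 9, 11)
  ens <- ensemble(lapply(1:4, function(i)
    conformer(data.frame(name = paste0("C", 1:5), element = "C"),
              rand_xyz(5, i), energy = e[i], conformer_id = paste0("conf", i))))
  expect_length(energy_window_filter(ens, 10)$conformers, 3)
  expect_equal(conformer_ids(energy_window_filter(ens, 0)), "conf1")
  expect_length(energy_window_filter(ens, Inf)$conformers, 4)
  kept <- lapply(c(0, 2, 5, 9, 10, 11, Inf),
                 function(w) conformer_ids(energy_window_filter(ens, w)))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
})

test_that("MEC selection takes the energy minimum, first on ties", {
  mk <- function(e) ensemble(lapply(seq_along(e), function(i)
    conformer(data.frame(name = paste0("C", 1:4), element = "C"),
              rand_xyz(4, i), energy = e[i], conformer_id = paste0("conf", i))))
  expect_equal(minimum_energy_conformer(mk(c(3.2, 0.0, 5.1)))$conformer_id,
               "conf2")
  expect_message(mec <- minimum_energy_conformer(mk(c(0.0, 0.0))), "tie")
  expect_equal(mec$conformer_id, "conf1")
  expect_equal(minimum_energy_conformer(mk(2.5))$conformer_id, "conf1")
})

test_that("Boltzmann weights follow the closed form and its limits", {
  expect_equal(boltzmann_weights(rep(1.5, 4)), rep(0.25, 4))
  R <- 1.98720425e-3
  w <- boltzmann_weights(c(0, R * 300 * log(2)), temperature = 300)
  expect_equal(w, c(2 / 3, 1 / 3), tolerance = 1e-12)
  whot <- boltzmann_weights(c(0, 0.3, 0.7), temperature = 1e9)
  expect_equal(whot, rep(1 / 3, 3), tolerance = 1e-6)
  # weight ordering matches energy ordering
  e <- c(4.2, 0.1, 2.2, 9.9)
  w2 <- boltzmann_weights(e)
  expect_equal(order(w2), order(-e))
  expect_equal(sum(w2), 1)
  expect_error(boltzmann_weights(numeric(0)), "no energies")
  expect_error(boltzmann_weights(c(1, 2), temperature = 0), "> 0 K")
})

test_that("stride subsampling is tail-aligned with floor arithmetic", {
  topo <- data.frame(name = paste0("C", 1:3), element = "C")
  traj7 <- trajectory(topo, lapply(1:7, function(i) rand_xyz(3, i)), dt = 10)
  sub <- subsample_every(traj7, 3)
  expect_length(sub$conformers, 2)
  expect_equal(conformer_ids(sub), c("frame3", "frame6"))
  expect_equal(sub$conformers[[1]]$xyz, traj7$frames[[3]],
               ignore_attr = TRUE)
  expect_length(subsample_every(traj7, 1)$conformers, 7)
  expect_error(subsample_every(traj7, 8), "exceeds trajectory length")
})
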