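# Shared fixture builders and independent oracles.

rand_xyz <- function(n, seed, spread = 3) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = spread), ncol = 3)
}

rand_conformer <- function(n, seed, id = paste0("conf", seed),
                           elements = NULL) {
  if (is.null(elements)) elements <- rep("C", n)
  conformer(data.frame(name = paste0(elements, seq_len(n)),
                       element = elements, stringsAsFactors = FALSE),
            rand_xyz(n, seed), conformer_id = id)
}

euler_rotation <- function(a, b, c) {
  # z-y-z convention, angles in radians
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

rigid_transform <- function(xyz, rot, shift) {
  sweep(xyz %*% t(rot), 2, shift, `+`)
}

# Brute-force superposition oracle: centered coordinates, nested grid
# search over z-y-z Euler angles, refined three times.
grid_superpose_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  score <- function(a, b, c) {
    fit <- yc %*% t(euler_rotation(a, b, c))
    sqrt(mean(rowSums((fit - xc)^2)))
  }
  ctr <- c(pi, pi / 2, pi)
  half <- c(pi, pi / 2, pi)
  best <- Inf
  for (round in 1:4) {
    grid <- expand.grid(a = seq(ctr[1] - half[1], ctr[1] + half[1], length.out = 13),
                        b = seq(ctr[2] - half[2], ctr[2] + half[2], length.out = 13),
                        c = seq(ctr[3] - half[3], ctr[3] + half[3], length.out = 13))
    vals <- mapply(score, grid$a, grid$b, grid$c)
    i <- which.min(vals)
    best <- vals[i]
    ctr <- as.numeric(grid[i, ])
    half <- half / 5
  }
  best
}

# Independent dihedral oracle: angle between the two bond planes from
# normalized normals, signed by the triple product with the central bond.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(min(1, max(-1, sum(n1 * n2)))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

write_pdb_models <- function(coords_list, elements, path) {
  lines <- character(0)
  for (m in seq_along(coords_list)) {
    xyz <- coords_list[[m]]
    lines <- c(lines, sprintf("MODEL     %4d", m),
               sprintf("ATOM  %5d  %-3s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(xyz)),
                       paste0(elements, seq_len(nrow(xyz))),
                       xyz[, 1], xyz[, 2], xyz[, 3], elements),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

write_sdf_record <- function(xyz, elements, path, energy = NULL) {
  n <- nrow(xyz)
  lines <- c("fixture", "  macrochameleon-tests", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, n - 1),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     xyz[, 1], xyz[, 2], xyz[, 3], elements),
             sprintf("%3d%3d  1  0", seq_len(n - 1), 2:n),
             "M  END")
  if (!is.null(energy))
    lines <- c(lines, "> <energy>", format(energy), "")
  writeLines(c(lines, "$$$$"), path)
  path
}

write_xyz_text <- function(blocks, path) {
  writeLines(unlist(blocks), path)
  path
}

# Small curated ensemble: k base geometries, some repeated under random
# rigid motions (exact duplicates up to rigid transformation).
planted_duplicate_ensemble <- function(seed = 42) {
  base <- rand_conformer(8, seed, id = "conf1")
  set.seed(seed + 1)
  copy_of <- function(cf, id) {
    rot <- euler_rotation(stats::runif(1, 0, 2 * pi),
                          stats::runif(1, 0, pi),
                          stats::runif(1, 0, 2 * pi))
    conformer(cf$atoms, rigid_transform(cf$xyz, rot, stats::rnorm(3, sd = 5)),
              conformer_id = id)
  }
  c2 <- copy_of(base, "conf2")
  c3 <- rand_conformer(8, seed + 10, id = "conf3")
  c4 <- copy_of(base, "conf4")
  c5 <- rand_conformer(8, seed + 20, id = "conf5")
  ensemble(list(base, c2, c3, c4, c5), compound_id = "dup-fixture")
}
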