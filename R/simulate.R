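#' @title Seeded fixture generators
#' @description Every generator draws from its own pseudo-random stream,
#'   derived from (seed, generator name), and restores the caller's RNG
#'   state on exit; identical seeds give byte-identical outputs. Each
#'   generator returns a truth record sufficient to score downstream
#'   operations without re-deriving anything.
#' @name fixtures
NULL

fixture_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

with_fixture_seed <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(fixture_seed(seed, name))
  force(code)
}

#' Build an idealized macrocycle scaffold
#'
#' A closed ring of `ring_size` atoms on a circle with 1.5 Angstrom
#' edges in the xy-plane, decorated with substituents: single atoms
#' placed axially (perpendicular to the ring plane, 1.0 Angstrom) or
#' equatorially (radially outward in-plane, 1.5 Angstrom), or a phenyl
#' ring attached equatorially. The default spec emulates an 18-membered
#' semipeptidic macrocycle: amide-like nitrogens at ring positions 1, 7
#' and 13 carrying axial N-H hydrogens (positions 1 and 13 up, 7 down),
#' and a phenyl side-chain at position 10. Geometries are chemically
#' idealized, not force-field minimized.
#'
#' @param ring_size number of ring atoms (>= 3; default 18).
#' @param substituents list of specs, each `list(position =, group =
#'   "H"|"phenyl"|<element>, mode = "axial_up"|"axial_down"|"equatorial")`;
#'   `NULL` gives the default decoration above (plain ring for
#'   `ring_size != 18`).
#' @param bond_length ring edge length, Angstrom (default 1.5).
#' @return list of class `"scaffold"`: `conformer`, `bonds` (2-column
#'   index matrix), `ring_atoms` (indices 1..ring_size), `substituent_atoms`
#'   (named list: atom indices per substituent, `"sub<position>"`).
#' @export
build_macrocycle_scaffold <- function(ring_size = 18, substituents = NULL,
                                      bond_length = 1.5) {
  if (ring_size < 3L) stop("ring_size must be >= 3")
  if (is.null(substituents)) {
    substituents <- if (ring_size == 18)
      list(list(position = 1, group = "H", mode = "axial_up"),
           list(position = 7, group = "H", mode = "axial_down"),
           list(position = 13, group = "H", mode = "axial_up"),
           list(position = 10, group = "phenyl", mode = "equatorial"))
    else list()
  }
  R <- bond_length / (2 * sin(pi / ring_size))
  theta <- 2 * pi * (seq_len(ring_size) - 1) / ring_size
  xyz <- cbind(R * cos(theta), R * sin(theta), 0)
  elem <- rep("C", ring_size)
  n_positions <- vapply(substituents, function(s)
    s$group == "H", logical(1))
  elem[vapply(substituents[n_positions], `[[`, numeric(1), "position")] <- "N"
  name <- paste0(elem, seq_len(ring_size))
  bonds <- cbind(seq_len(ring_size),
                 c(seq_len(ring_size)[-1], 1L))
  sub_atoms <- list()
  for (s in substituents) {
    p <- s$position
    u_rad <- c(cos(theta[p]), sin(theta[p]), 0)
    if (identical(s$group, "phenyl")) {
      # coplanar hexagon, 1.39 A edges, bonded radially outward
      rp <- 1.39
      cen <- xyz[p, ] + u_rad * (bond_length + rp)
      ang0 <- atan2(u_rad[2], u_rad[1]) + pi  # vertex 1 faces the ring
      ph <- t(vapply(0:5, function(k) {
        a <- ang0 + k * pi / 3
        cen + rp * c(cos(a), sin(a), 0)
      }, numeric(3)))
      i0 <- nrow(xyz)
      xyz <- rbind(xyz, ph)
      elem <- c(elem, rep("C", 6))
      name <- c(name, paste0("CP", p, letters[1:6]))
      bonds <- rbind(bonds, c(p, i0 + 1L),
                     cbind(i0 + 1:6, i0 + c(2:6, 1L)))
      sub_atoms[[paste0("sub", p)]] <- i0 + 1:6
    } else {
      offset <- switch(s$mode,
                       axial_up = c(0, 0, 1),
                       axial_down = c(0, 0, -1),
                       equatorial = u_rad * bond_length,
                       stop("unknown substituent mode: ", s$mode))
      if (s$mode != "equatorial") offset <- offset * 1.0  # N-H ~ 1.0 A
      i0 <- nrow(xyz)
      xyz <- rbind(xyz, xyz[p, ] + offset)
      elem <- c(elem, s$group)
      name <- c(name, paste0(s$group, "S", p))
      bonds <- rbind(bonds, c(p, i0 + 1L))
      sub_atoms[[paste0("sub", p)]] <- i0 + 1L
    }
  }
  cf <- conformer(data.frame(name = name, element = elem,
                             stringsAsFactors = FALSE),
                  xyz, conformer_id = "scaffold")
  structure(list(conformer = cf, bonds = bonds,
                 ring_atoms = seq_len(ring_size),
                 substituent_atoms = sub_atoms),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf("<scaffold> %d-membered ring, %d atoms total, %d substituent group(s)\n",
              length(x$ring_atoms), n_atoms(x$conformer),
              length(x$substituent_atoms)))
  invisible(x)
}

#' Simulate a two-state switching trajectory
#'
#' Emulates a macrocycle switching between two major ring conformations
#' by an amide-flip analog: state 2 reflects the `flip_atoms` through
#' the ring plane (z = 0 of the idealized scaffold). Frames follow an
#' alternating run (dwell) structure whose run lengths are drawn
#' multinomially within an exact per-state frame budget, so the planted
#' label fractions equal the requested populations at frame resolution;
#' Gaussian coordinate jitter is added on top. True labels are returned.
#'
#' @param scaffold a [build_macrocycle_scaffold()] result.
#' @param populations length-2 fractions summing to 1 (state1, state2).
#' @param n_frames number of frames (>= 2).
#' @param dwell target mean dwell time of state 1, frames.
#' @param jitter per-coordinate Gaussian jitter sd, Angstrom.
#' @param seed integer seed.
#' @param flip_atoms atom indices reflected in state 2; default the
#'   first single-atom substituent of the scaffold.
#' @param dt frame spacing, ps (default 10).
#' @return list: `trajectory`, `labels` (integer 1/2 per frame),
#'   `populations` (realized fractions), `flip_atoms`.
#' @export
simulate_two_state_trajectory <- function(scaffold, populations = c(0.7, 0.3),
                                          n_frames = 5000, dwell = 25,
                                          jitter = 0.02, seed = 1,
                                          flip_atoms = NULL, dt = 10) {
  if (abs(sum(populations) - 1) > 1e-9)
    stop("populations must sum to 1")
  if (n_frames < 2L) stop("need n_frames >= 2")
  if (is.null(flip_atoms)) {
    single <- Filter(function(a) length(a) == 1L, scaffold$substituent_atoms)
    if (length(single) == 0L)
      stop("scaffold has no single-atom substituent; pass `flip_atoms`")
    flip_atoms <- single[[1]]
  }
  cf <- scaffold$conformer
  templ <- list(cf$xyz, cf$xyz)
  templ[[2]][flip_atoms, 3] <- -templ[[2]][flip_atoms, 3]
  n1 <- round(populations[1] * n_frames)
  n2 <- n_frames - n1
  labels <- with_fixture_seed(seed, "two_state_trajectory", {
    if (n1 == 0L || n2 == 0L) {
      rep(if (n1 == 0L) 2L else 1L, n_frames)
    } else {
      k <- max(1L, min(round(n1 / dwell), n2))
      len1 <- as.integer(stats::rmultinom(1, n1 - k, rep(1, k))) + 1L
      len2 <- as.integer(stats::rmultinom(1, n2 - k, rep(1, k))) + 1L
      unlist(lapply(seq_len(k), function(i)
        c(rep(1L, len1[i]), rep(2L, len2[i]))))
    }
  })
  frames <- with_fixture_seed(seed, "two_state_jitter", {
    lapply(labels, function(s) {
      fr <- templ[[s]]
      if (jitter > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), sd = jitter), ncol = 3)
      fr
    })
  })
  list(trajectory = trajectory(cf$atoms, frames, dt = dt),
       labels = labels,
       populations = c(n1, n2) / n_frames,
       flip_atoms = flip_atoms)
}

#' Plant contact events in a trajectory at an exact frequency
#'
#' Rewrites the position of one mobile atom per frame so that its
#' distance to an anchor point (an atom or the centroid of an atom set)
#' sits inside the detection window in exactly
#' `round(target_frequency * n_frames)` seeded-random frames and outside
#' it in the rest. When `direction_from` is given, the mobile atom is
#' placed on the extension of the `direction_from -> anchor` line (so a
#' planted hydrogen bond is perfectly linear); otherwise along the
#' mobile atom's current direction from the anchor.
#'
#' @param traj trajectory.
#' @param mobile atom index to reposition.
#' @param anchor atom index (or indices, whose centroid is used).
#' @param window detection window, Angstrom.
#' @param target_frequency fraction of frames inside the window.
#' @param seed integer seed.
#' @param direction_from optional atom index defining the placement
#'   direction.
#' @param inside_distance,outside_distance planted distances; defaults
#'   mid-window and 1.5 Angstrom beyond the upper edge.
#' @return list: `trajectory`, `flags` (true per-frame contact state),
#'   `frequency` (realized, equals the rounded target).
#' @export
plant_contact_events <- function(traj, mobile, anchor, window,
                                 target_frequency, seed = 1,
                                 direction_from = NULL,
                                 inside_distance = mean(window),
                                 outside_distance = window[2] + 1.5) {
  n <- length(traj$frames)
  n_in <- round(target_frequency * n)
  flags <- rep(FALSE, n)
  if (n_in > 0)
    flags[with_fixture_seed(seed, "plant_contact_events",
                            sample.int(n, n_in))] <- TRUE
  for (f in seq_len(n)) {
    fr <- traj$frames[[f]]
    ap <- colMeans(fr[anchor, , drop = FALSE])
    u <- if (!is.null(direction_from)) ap - fr[direction_from, ]
         else fr[mobile, ] - ap
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-9) c(0, 0, 1) else u / nu
    d <- if (flags[f]) inside_distance else outside_distance
    fr[mobile, ] <- ap + u * d
    traj$frames[[f]] <- fr
  }
  list(trajectory = traj, flags = flags, frequency = mean(flags))
}

#' Simulate NOESY build-up curves from known distances
#'
#' Inverts the distance calibration: each pair's build-up rate is
#' `sigma = sigma_ref * (r_ref / r)^6`, and its normalized intensity
#' grows as `eta(tau) = sigma * tau_eff` with `tau_eff = min(tau,
#' tau_sat)` (linear initial build-up that flattens beyond the
#' saturation mixing time). A reference pair at exactly `r_ref` (named
#' `gemA`/`gemB`, the geminal analog) is always included. Integrals are
#' emitted consistent with the geminal-diagonal normalization
#' convention: constant diagonals `diagonal_integral`, cross peaks
#' `eta * sqrt(I_diag_i * I_diag_j)`, with optional multiplicative
#' Gaussian noise on the cross peaks.
#'
#' @param true_distances data.frame with columns `proton_i`, `proton_j`,
#'   `r` (Angstrom), or a named numeric vector (`"HA-HB" = 3.0`).
#' @param sigma_ref build-up rate of the reference pair, 1/ms.
#' @param r_ref reference distance, Angstrom (default 1.78).
#' @param mixing_times ms; default the seven-point 50-350 ms series.
#' @param tau_sat saturation mixing time, ms (`Inf` = never saturates).
#' @param noise_cv coefficient of variation of multiplicative cross-peak
#'   noise (0 = noiseless).
#' @param seed integer seed.
#' @param diagonal_integral absolute diagonal integral (arbitrary units).
#' @return list: `table` ([noesy_table()]), `truth` (data.frame with
#'   per-pair `sigma` and `r`, reference pair included), `sigma_ref`,
#'   `r_ref`.
#' @export
simulate_buildup_curves <- function(true_distances, sigma_ref = 2e-4,
                                    r_ref = 1.78,
                                    mixing_times = seq(50, 350, by = 50),
                                    tau_sat = Inf, noise_cv = 0, seed = 1,
                                    diagonal_integral = 1e6) {
  if (is.numeric(true_distances) && !is.null(names(true_distances))) {
    ij <- strsplit(names(true_distances), "-", fixed = TRUE)
    true_distances <- data.frame(
      proton_i = vapply(ij, `[`, character(1), 1L),
      proton_j = vapply(ij, `[`, character(1), 2L),
      r = as.numeric(true_distances), stringsAsFactors = FALSE)
  }
  if (any(true_distances$r <= 0)) stop("distances must be positive")
  pairs <- rbind(data.frame(proton_i = "gemA", proton_j = "gemB", r = r_ref,
                            stringsAsFactors = FALSE),
                 true_distances)
  pairs$sigma <- sigma_ref * (r_ref / pairs$r)^6
  tau_eff <- pmin(mixing_times, tau_sat)
  cross <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    data.frame(proton_i = pairs$proton_i[p], proton_j = pairs$proton_j[p],
               mixing_time_ms = mixing_times,
               integral = pairs$sigma[p] * tau_eff * diagonal_integral,
               stringsAsFactors = FALSE)
  }))
  if (noise_cv > 0) {
    cross$integral <- with_fixture_seed(seed, "buildup_noise", {
      pmax(0, cross$integral *
             (1 + stats::rnorm(nrow(cross), sd = noise_cv)))
    })
  }
  protons <- unique(c(pairs$proton_i, pairs$proton_j))
  diagonal <- expand.grid(proton = protons, mixing_time_ms = mixing_times,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  diagonal$integral <- diagonal_integral
  list(table = noesy_table(cross, diagonal),
       truth = pairs, sigma_ref = sigma_ref, r_ref = r_ref)
}

#' Simulate an isotropic shielding table from known shifts
#'
#' Inverts the shift relation: `sigma = sigma_ref - delta (+ noise)`, so
#' a noiseless table round-trips through [shift_from_shielding()] to the
#' planted shifts exactly.
#'
#' @param true_shifts data.frame with columns `conformer_id`,
#'   `atom_label`, `delta` (ppm).
#' @param sigma_ref reference shielding, ppm.
#' @param noise Gaussian noise sd on sigma, ppm (0 = noiseless).
#' @param seed integer seed.
#' @return list: `table` ([shielding_table()]), `truth` (the input).
#' @export
simulate_shielding_tables <- function(true_shifts, sigma_ref = 31.8,
                                      noise = 0, seed = 1) {
  sigma <- sigma_ref - true_shifts$delta
  if (noise > 0)
    sigma <- sigma + with_fixture_seed(seed, "shielding_noise",
                                       stats::rnorm(length(sigma), sd = noise))
  list(table = shielding_table(
         data.frame(conformer_id = true_shifts$conformer_id,
                    atom_label = true_shifts$atom_label,
                    sigma = sigma, stringsAsFactors = FALSE),
         sigma_ref = sigma_ref),
       truth = true_shifts)
}
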