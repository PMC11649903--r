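# Shared fixtures and independent oracles. Oracles are deliberately
# written from first principles, not by calling the package internals.

# generating truth used throughout: hydrolysis, glycerol attack and a
# small autoubiquitination pathway
paper_params <- function() kinetic_params(k1 = 0.015, k2 = 3.8e-4,
                                          k3 = 0.002, E2L0 = 1)

chase_times <- function() seq(0, 120, by = 10)

# minimal frame builder
quick_frame <- function(atom, resid, resno, chain, elem, x, y, z) {
  md_frame(data.frame(atom = atom, resid = resid, resno = resno,
                      chain = chain, elem = elem, x = x, y = y, z = z,
                      stringsAsFactors = FALSE))
}

# a donor(N-H)...acceptor(O) trio with ideal H-bond geometry plus spectators
hbond_frame <- function(da = 2.83) {
  quick_frame(atom = c("N", "H", "O", "CA", "CA"),
              resid = c("ALA", "ALA", "SER", "ALA", "SER"),
              resno = c(1L, 1L, 2L, 1L, 2L), chain = "A",
              elem = c("N", "H", "O", "C", "C"),
              x = c(0, 0.98, da, -1.4, da + 1.4),
              y = c(0, 0.1, 0.6, 0.2, 1.0), z = 0)
}

# random polar frame for contact property tests: N/O heavies with some
# hydrogens sprinkled near the nitrogens
random_polar_frame <- function(seed, n_res = 8, box = 8) {
  set.seed(seed)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    base <- runif(3, -box / 2, box / 2)
    hpos <- base + stats::rnorm(3, 0, 0.4)
    hpos <- base + (hpos - base) / sqrt(sum((hpos - base)^2)) * 1.0
    data.frame(atom = c("N", "H1", "O"),
               resid = "XXX", resno = i, chain = "A",
               elem = c("N", "H", "O"),
               x = c(base[1], hpos[1], base[1] + runif(1, -2, 2)),
               y = c(base[2], hpos[2], base[2] + runif(1, -2, 2)),
               z = c(base[3], hpos[3], base[3] + runif(1, -2, 2)),
               stringsAsFactors = FALSE)
  }))
  md_frame(atoms)
}

# rigid-body transform of a frame (rotation from a seeded QR, translation)
rigid_transform <- function(frame, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- stats::runif(3, -20, 20)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(Q)
  fr <- frame
  fr$x <- xyz[, 1] + shift[1]
  fr$y <- xyz[, 2] + shift[2]
  fr$z <- xyz[, 3] + shift[3]
  md_frame(fr, frame_index = attr(frame, "frame_index"))
}

# ---- independent geometric oracles --------------------------------------

cross_o <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# point-plane signed distance with explicit cross-product normal,
# oriented by the reference point
oracle_plane_offset <- function(p_plane1, p_plane2, p_plane3, probe, ref) {
  n <- cross_o(p_plane2 - p_plane1, p_plane3 - p_plane1)
  n <- n / sqrt(sum(n^2))
  if (sum(n * (ref - p_plane1)) < 0) n <- -n
  sum(n * (probe - p_plane1))
}

# law-of-cosines vertex angle from the three side lengths
oracle_angle_lawcos <- function(p1, vertex, p2) {
  a <- sqrt(sum((p1 - vertex)^2))
  b <- sqrt(sum((p2 - vertex)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  acos(min(1, max(-1, (a^2 + b^2 - cc^2) / (2 * a * b)))) * 180 / pi
}

# dihedral by rotating the central bond onto z and reading the 2D angle
# between the projected substituents
oracle_dihedral_project <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  ez <- b2 / sqrt(sum(b2^2))
  aux <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- aux - sum(aux * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- cross_o(ez, ex)
  u <- p1 - p2; v <- p4 - p3
  u2 <- c(sum(u * ex), sum(u * ey))
  v2 <- c(sum(v * ex), sum(v * ey))
  # dihedral = CCW angle from projected (p1 - p2) to projected (p4 - p3)
  # in the right-handed frame whose z axis is the central bond
  ang <- (atan2(v2[2], v2[1]) - atan2(u2[2], u2[1])) * 180 / pi
  ang <- ((ang %% 360) + 360) %% 360
  if (ang > 180) ang - 360 else ang
}

# all-pairs brute-force H-bond scan (distance and minimum-angle criteria)
oracle_hbonds <- function(frame, donor_idx, acceptor_idx,
                          dh = 1.2, da_max = 3.0, ang_min = 150) {
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  h_idx <- which(frame$elem == "H")
  found <- character(0)
  for (d in donor_idx) for (a in acceptor_idx) {
    if (a == d) next
    if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > da_max) next
    for (h in h_idx) {
      if (sqrt(sum((xyz[d, ] - xyz[h, ])^2)) > dh) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= ang_min)
        found <- c(found, paste(d, h, a))
    }
  }
  sort(found)
}

# brute-force COM salt-bridge scan over explicit group index lists
oracle_salt_bridges <- function(frame, cations, anions, cutoff = 5) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  com <- function(idx) {
    m <- masses[frame$elem[idx]]
    m[is.na(m)] <- 12.011
    colSums(as.matrix(frame[idx, c("x", "y", "z")]) * m) / sum(m)
  }
  found <- character(0)
  for (i in names(cations)) for (j in names(anions)) {
    d <- sqrt(sum((com(cations[[i]]) - com(anions[[j]]))^2))
    if (d <= cutoff) found <- c(found, paste(i, j))
  }
  sort(found)
}

# exact in-sphere grid point count for the anchored pocket grid
oracle_sphere_count <- function(radius, spacing) {
  kmax <- floor(radius / spacing)
  ks <- seq(-kmax, kmax)
  g <- expand.grid(i = ks, j = ks, k = ks)
  sum((g$i^2 + g$j^2 + g$k^2) * spacing^2 <= radius^2 + 1e-9)
}
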