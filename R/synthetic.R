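#' Additive Gaussian noise model for densitometry-scale signals
#'
#' Noise on fractions is additive and unclipped by default, mimicking
#' densitometry scatter that can push values slightly outside \[0, 1\];
#' clipping is available.
#'
#' @param sigma Gaussian SD on the fraction scale (>= 0).
#' @param seed Integer master seed; every generator derives its own
#'   substream from it, so adding a generator does not perturb existing
#'   streams.
#' @param clip Clip generated signals to \[0, 1\].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.02, seed = 1L, clip = FALSE) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(sigma = sigma, seed = as.integer(seed),
                 clip = isTRUE(clip)),
            class = "noise_model")
}

# deterministic substream seed below 2^31
.substream <- function(seed, tag, i = 0L) {
  v <- utf8ToInt(tag)
  h <- sum(v * seq_along(v))
  as.integer((as.double(seed) %% 2147483629 * 69621 + h * 1013 +
                i * 7919) %% 2147483629)
}

#' Generate a synthetic chase design with known ground truth
#'
#' Simulates the paired discharge experiment: one time course per
#' nucleophile concentration, each the closed-form observed mono-band
#' signal plus i.i.d. Gaussian densitometry noise. The generating
#' parameters are embedded in the course labels for traceability.
#'
#' @param truth A [kinetic_params] holding the generating constants.
#' @param nus Nucleophile concentrations, mM (one course each).
#' @param times Sampling times, min.
#' @param noise A [noise_model].
#' @return A [chase_design].
#' @examples
#' gen_chase(kinetic_params(0.015, 3.8e-4, 0.002), c(0, 250),
#'           seq(0, 120, 10), noise_model(sigma = 0.02, seed = 1))
#' @export
gen_chase <- function(truth, nus, times,
                      noise = noise_model(sigma = 0, seed = 1L)) {
  stopifnot(inherits(truth, "kinetic_params"),
            inherits(noise, "noise_model"), is.numeric(nus),
            length(nus) >= 1L)
  courses <- lapply(seq_along(nus), function(i) {
    mu <- closed_form_species(truth, nus[i], times)
    y <- mu$E2L + mu$E2Ub
    if (noise$sigma > 0) {
      set.seed(.substream(noise$seed, "chase", i))
      y <- y + stats::rnorm(length(y), 0, noise$sigma)
    }
    if (noise$clip) y <- pmin(pmax(y, 0), 1)
    time_course(times, y, nu = nus[i], observable = "mono_band",
                label = sprintf(
                  "sim k1=%g k2=%g k3=%g E2L0=%g nu=%g sigma=%g seed=%d",
                  truth$k1, truth$k2, truth$k3, truth$E2L0, nus[i],
                  noise$sigma, noise$seed))
  })
  chase_design(courses)
}

#' Generate synthetic gel lanes from known modified fractions
#'
#' Emulates substrate-ubiquitination gel quantification: per time point
#' an untreated lane with `modified_total = fraction * scale +
#' background` and `unmodified = (1 - fraction) * scale`, optionally a
#' NaOH-treated twin in which only the resistant proportion of the
#' modification survives, and a no-ATP background lane. With zero noise
#' the densitometry pipeline recovers the input fractions exactly, and
#' the NaOH twins reproduce the prescribed resistant proportion.
#'
#' @param fractions Modified fractions, one per time point, in \[0, 1\].
#' @param times Sampling times, min (defaults to 0, 1, 2, ...).
#' @param scale Arbitrary intensity scale of the total substrate signal.
#' @param background Additive background intensity on the modified
#'   signal (>= 0).
#' @param noise A [noise_model]; `sigma` acts on the fraction scale and
#'   is applied to band intensities as `sigma * scale`.
#' @param naoh_resistant Optional scalar in \[0, 1\]: proportion of the
#'   modification that is NaOH-resistant; adds treated twin lanes.
#' @return List of [lane_quant] objects (plus one `no_ATP` lane when
#'   `background > 0`).
#' @export
gen_lane_table <- function(fractions, times = seq_along(fractions) - 1,
                           scale = 1000, background = 0,
                           noise = noise_model(sigma = 0, seed = 1L),
                           naoh_resistant = NULL) {
  stopifnot(is.numeric(fractions), all(fractions >= 0 & fractions <= 1),
            length(times) == length(fractions), scale > 0)
  if (!is.numeric(background) || background < 0)
    stop("background must be a non-negative intensity")
  if (!is.null(naoh_resistant))
    stopifnot(naoh_resistant >= 0, naoh_resistant <= 1)
  jitter_int <- function(x, i) {
    if (noise$sigma == 0) return(x)
    set.seed(.substream(noise$seed, "lanes", i))
    pmax(x + stats::rnorm(length(x), 0, noise$sigma * scale), 0)
  }
  lanes <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    ints <- jitter_int(c(unmodified = (1 - f) * scale,
                         modified_total = f * scale + background), i)
    lanes[[length(lanes) + 1L]] <-
      lane_quant(sprintf("t%02d", i), ints, treatment = "none",
                 time_min = times[i])
    if (!is.null(naoh_resistant)) {
      fr <- naoh_resistant * f
      ints_n <- jitter_int(c(unmodified = (1 - fr) * scale,
                             modified_total = fr * scale + background),
                           i + 1000L)
      lanes[[length(lanes) + 1L]] <-
        lane_quant(sprintf("t%02d_NaOH", i), ints_n, treatment = "NaOH",
                   time_min = times[i])
    }
  }
  if (background > 0)
    lanes[[length(lanes) + 1L]] <-
      lane_quant("noATP", c(unmodified = scale,
                            modified_total = background),
                 treatment = "no_ATP", time_min = NA_real_)
  lanes
}

#' Specification of a toy thioester-site frame
#'
#' @param offset Target signed plane offset of the His nitrogen, A.
#' @param angle Target orientation angle, degrees, in \[0, 180\].
#' @param n_decoys Number of random decoy carbon atoms.
#' @param box Edge length of the decoy box, A; `|offset|` must not
#'   exceed it.
#' @param seed Integer seed for decoy placement.
#' @return An object of class `toy_geometry_spec`.
#' @export
toy_geometry_spec <- function(offset = 3, angle = 120, n_decoys = 20,
                              box = 20, seed = 1L) {
  stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset),
            is.numeric(angle), length(angle) == 1L,
            is.numeric(n_decoys), n_decoys >= 0,
            is.numeric(box), box > 0)
  if (angle < 0 || angle > 180)
    stop("infeasible geometry: orientation angle must lie in [0, 180]")
  if (abs(offset) > box)
    stop(sprintf(
      "infeasible geometry: |offset| = %g exceeds the box size %g",
      abs(offset), box))
  structure(list(offset = offset, angle = angle,
                 n_decoys = as.integer(n_decoys), box = box,
                 seed = as.integer(seed)),
            class = "toy_geometry_spec")
}

# imidazole ring vertex masses (NE2 at vertex 0, then CD2, CG, ND1, CE1)
.ring_atoms <- c("NE2", "CD2", "CG", "ND1", "CE1")
.ring_elems <- c("N", "C", "C", "N", "C")

#' Generate a toy thioester-site frame with prescribed geometry
#'
#' Builds a minimal coordinate frame whose measured signed plane offset
#' and orientation angle equal the spec targets exactly (accounting for
#' the mass-weighted ring center): the Sgamma/C/O plane atoms, a
#' regular-pentagon imidazole proxy with the epsilon nitrogen as the
#' probe vertex, a cavity reference atom on the positive side of the
#' plane, and seeded random decoy atoms kept clear of the site.
#'
#' @param spec A [toy_geometry_spec].
#' @return A [md_frame] (valid for [write_frames_pdb()]).
#' @export
gen_thioester_frame <- function(spec) {
  stopifnot(inherits(spec, "toy_geometry_spec"))
  sg <- c(0, 0, 0)
  cc <- c(1.80, 0, 0)                  # thioester carbonyl carbon
  oo <- c(2.35, 1.10, 0)               # carbonyl oxygen; plane z = 0
  cav <- c(0, 0, 6)                    # solvent-cavity side: +z
  d <- spec$offset
  ne <- c(3.2, 1.2, d)                 # probe: lateral position arbitrary

  # ring center placed so that the MASS-WEIGHTED ring COM subtends the
  # target angle at NE2 relative to the carbonyl carbon
  theta <- spec$angle * pi / 180
  r_ring <- 1.16
  mass <- .mass_of(.ring_elems)
  k <- 0:4
  delta1 <- sum(mass * cos(2 * pi * k / 5)) / sum(mass)
  delta2 <- sum(mass * sin(2 * pi * k / 5)) / sum(mass)
  psi <- atan2(delta2, delta1 - 1)
  alpha <- theta - psi

  b <- cc - ne
  f1 <- b / .vnorm(b)
  aux <- if (abs(f1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  f2 <- .cross3(f1, aux); f2 <- f2 / .vnorm(f2)
  e1 <- cos(alpha) * f1 + sin(alpha) * f2
  e2 <- -sin(alpha) * f1 + cos(alpha) * f2
  center <- ne - r_ring * e1
  verts <- t(vapply(k, function(kk)
    center + r_ring * (cos(2 * pi * kk / 5) * e1 +
                         sin(2 * pi * kk / 5) * e2), numeric(3L)))

  atoms <- data.frame(
    atom = c("SG", "C", "O", .ring_atoms, "O"),
    resid = c("CYS", "GLY", "GLY", rep("HIS", 5L), "HOH"),
    resno = c(87L, 76L, 76L, rep(94L, 5L), 500L),
    chain = c("A", "B", "B", rep("A", 5L), "W"),
    elem = c("S", "C", "O", .ring_elems, "O"),
    tautomer = c(NA, NA, NA, rep("delta", 5L), NA),
    x = c(sg[1L], cc[1L], oo[1L], verts[, 1L], cav[1L]),
    y = c(sg[2L], cc[2L], oo[2L], verts[, 2L], cav[2L]),
    z = c(sg[3L], cc[3L], oo[3L], verts[, 3L], cav[3L]),
    stringsAsFactors = FALSE)
  # vertex 0 of the pentagon is NE2 = the probe, exactly
  atoms[atoms$atom == "NE2" & atoms$resid == "HIS", c("x", "y", "z")] <-
    as.list(ne)

  if (spec$n_decoys > 0) {
    set.seed(.substream(spec$seed, "decoys"))
    site <- as.matrix(atoms[, c("x", "y", "z")])
    placed <- 0L
    coords <- matrix(NA_real_, spec$n_decoys, 3L)
    guard <- 0L
    while (placed < spec$n_decoys && guard < 10000L) {
      guard <- guard + 1L
      p <- stats::runif(3L, -spec$box / 2, spec$box / 2)
      if (min(sqrt(colSums((t(site) - p)^2))) > 3) {
        placed <- placed + 1L
        coords[placed, ] <- p
        site <- rbind(site, p)
      }
    }
    if (placed < spec$n_decoys)
      stop("could not place decoys clear of the site; enlarge the box")
    atoms <- rbind(atoms, data.frame(
      atom = "C", resid = "DUM", resno = 200L + seq_len(placed),
      chain = "D", elem = "C", tautomer = NA_character_,
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE))
  }
  md_frame(atoms)
}

#' Canonical site selectors of a toy thioester frame
#'
#' @return A [thioester_site] matching [gen_thioester_frame()] output.
#' @export
toy_site <- function() {
  thioester_site(sg = "A:87:SG", carbonyl_c = "B:76:C",
                 carbonyl_o = "B:76:O", ne = "A:94:NE2",
                 ring = paste0("A:94:", .ring_atoms),
                 cavity_ref = "W:500:O")
}

#' Generate a fluctuating ensemble about a base frame
#'
#' Adds i.i.d. Gaussian displacements (per-atom sigma) to each atom in
#' each frame. An optional scripted contact schedule switches a
#' donor-acceptor contact on or off per frame with exactly known
#' frequency: in "off" frames the acceptor atom is displaced along the
#' donor-to-acceptor direction; contact atoms are exempt from jitter so
#' the schedule is honored exactly.
#'
#' @param base A [md_frame].
#' @param sigma Scalar or per-atom vector of displacement SDs, A.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param contact Optional list with `donor`, `acceptor` (selectors),
#'   `present` (logical vector of length `n_frames`), and optional
#'   `off_displacement` (A, default 5).
#' @return List of [md_frame] objects.
#' @export
gen_fluctuating_ensemble <- function(base, sigma, n_frames, seed = 1L,
                                     contact = NULL) {
  stopifnot(inherits(base, "md_frame"), n_frames >= 2L)
  natoms <- nrow(base)
  if (length(sigma) == 1L) sigma <- rep(sigma, natoms)
  stopifnot(length(sigma) == natoms, all(sigma >= 0))
  fixed <- integer(0)
  if (!is.null(contact)) {
    stopifnot(all(c("donor", "acceptor", "present") %in% names(contact)),
              length(contact$present) == n_frames)
    di <- .resolve_atom(base, contact$donor)
    ai <- .resolve_atom(base, contact$acceptor)
    offd <- if (is.null(contact$off_displacement)) 5 else
      contact$off_displacement
    dir <- as.numeric(base[ai, c("x", "y", "z")]) -
      as.numeric(base[di, c("x", "y", "z")])
    dir <- dir / .vnorm(dir)
    h_near <- which(base$elem == "H")
    if (length(h_near)) {
      dh <- sqrt(colSums((t(as.matrix(base[h_near, c("x", "y", "z")])) -
                            as.numeric(base[di, c("x", "y", "z")]))^2))
      fixed <- c(di, ai, h_near[dh <= 1.2])
    } else fixed <- c(di, ai)
  }
  set.seed(.substream(seed, "ensemble"))
  jitter_sigma <- sigma
  jitter_sigma[fixed] <- 0
  lapply(seq_len(n_frames), function(m) {
    fr <- base
    disp <- matrix(stats::rnorm(3L * natoms), natoms, 3L) * jitter_sigma
    fr$x <- fr$x + disp[, 1L]
    fr$y <- fr$y + disp[, 2L]
    fr$z <- fr$z + disp[, 3L]
    if (!is.null(contact) && !contact$present[m]) {
      ai <- .resolve_atom(base, contact$acceptor)
      offd <- if (is.null(contact$off_displacement)) 5 else
        contact$off_displacement
      fr[ai, c("x", "y", "z")] <- fr[ai, c("x", "y", "z")] + offd * dir
    }
    md_frame(fr, frame_index = m)
  })
}
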