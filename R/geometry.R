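.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(v) sqrt(sum(v * v))

#' Atom selectors for the thioester site
#'
#' Identifies the atoms entering the thioester-plane analyses: the
#' active-site cysteine Sgamma, the carbonyl C and O of ubiquitin's
#' C-terminal glycine (the three atoms spanning the thioester plane),
#' the catalytic histidine's unprotonated epsilon nitrogen (the probe),
#' the five imidazole ring atoms, and a reference atom on the solvent
#' cavity side that fixes the positive direction of the plane normal.
#'
#' @param sg,carbonyl_c,carbonyl_o,ne `"chain:resno:atom"` selectors
#'   for Sgamma, Gly C, Gly O and the His epsilon nitrogen.
#' @param ring Character vector of 5 selectors for the imidazole ring
#'   atoms (CG, ND1, CD2, CE1, NE2).
#' @param cavity_ref Selector of an atom on the solvent-cavity side of
#'   the plane.
#' @return An object of class `thioester_site`.
#' @export
thioester_site <- function(sg, carbonyl_c, carbonyl_o, ne, ring,
                           cavity_ref) {
  stopifnot(is.character(sg), is.character(carbonyl_c),
            is.character(carbonyl_o), is.character(ne),
            is.character(ring), is.character(cavity_ref))
  if (length(ring) != 5L)
    stop("ring must name exactly five imidazole atoms")
  structure(list(sg = sg, carbonyl_c = carbonyl_c,
                 carbonyl_o = carbonyl_o, ne = ne, ring = ring,
                 cavity_ref = cavity_ref),
            class = "thioester_site")
}

.site_coords <- function(frame, site) {
  list(sg = .atom_xyz(frame, .resolve_atom(frame, site$sg))[1L, ],
       c = .atom_xyz(frame, .resolve_atom(frame, site$carbonyl_c))[1L, ],
       o = .atom_xyz(frame, .resolve_atom(frame, site$carbonyl_o))[1L, ],
       ne = .atom_xyz(frame, .resolve_atom(frame, site$ne))[1L, ],
       ring = .atom_xyz(frame, vapply(site$ring, function(s)
         .resolve_atom(frame, s), integer(1L))),
       cav = .atom_xyz(frame, .resolve_atom(frame, site$cavity_ref))[1L, ])
}

#' Signed distance of the His nitrogen from the thioester plane
#'
#' Coordinates are centered on the cysteine Sgamma; the plane through
#' Sgamma, the Gly carbonyl C and the Gly carbonyl O defines a unit
#' normal, oriented so that the cavity reference atom lies on the
#' positive side. The returned value is the dot product of that normal
#' with the centered His epsilon-nitrogen position: positive offsets
#' mean the epsilon nitrogen faces the solvent cavity.
#'
#' @param frame A [md_frame].
#' @param site A [thioester_site].
#' @return Signed offset in Angstrom.
#' @export
signed_plane_offset <- function(frame, site) {
  sc <- .site_coords(frame, site)
  v1 <- sc$c - sc$sg
  v2 <- sc$o - sc$sg
  n <- .cross3(v1, v2)
  nn <- .vnorm(n)
  if (nn < 1e-9 * max(.vnorm(v1), .vnorm(v2), 1))
    stop("plane atoms (Sgamma, C, O) are collinear: plane undefined")
  n <- n / nn
  if (sum(n * (sc$cav - sc$sg)) < 0) n <- -n
  sum(n * (sc$ne - sc$sg))
}

#' Orientation angle of the imidazole ring at the His nitrogen
#'
#' The angle with vertex at the His epsilon nitrogen, between the center
#' of mass of the five imidazole ring atoms and the Gly carbonyl carbon.
#' Values near 180 degrees mean the ring points directly away from the
#' carbonyl; small values mean the ring leans onto it.
#'
#' @inheritParams signed_plane_offset
#' @return Angle in degrees, in \[0, 180\].
#' @export
orientation_angle <- function(frame, site) {
  sc <- .site_coords(frame, site)
  ring_idx <- vapply(site$ring, function(s) .resolve_atom(frame, s),
                     integer(1L))
  m <- .mass_of(frame$elem[ring_idx])
  com <- colSums(sc$ring * m) / sum(m)
  a <- com - sc$ne
  b <- sc$c - sc$ne
  na <- .vnorm(a); nb <- .vnorm(b)
  if (na < 1e-9 || nb < 1e-9)
    stop("coincident points: orientation angle undefined")
  cosang <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Classify frames as compatible with general base catalysis
#'
#' A frame supports base catalysis when the unprotonated His nitrogen
#' sits close to the thioester plane on the attack side (around 3
#' Angstrom away) with the imidazole oriented toward the carbonyl. The
#' default window accepts `|offset| <= max_abs_offset` and an
#' orientation angle within `angle_range`; both are tunable, and no
#' particular window is canonical.
#'
#' @param offset Signed plane offsets, Angstrom (vectorized).
#' @param angle Orientation angles, degrees (vectorized).
#' @param max_abs_offset Maximum |offset| in Angstrom (default 3.5).
#' @param angle_range Two-element inclusive angle window in degrees.
#' @return Logical vector, one flag per frame.
#' @export
classify_base_catalysis <- function(offset, angle, max_abs_offset = 3.5,
                                    angle_range = c(90, 180)) {
  stopifnot(is.numeric(offset), is.numeric(angle),
            length(offset) == length(angle),
            length(angle_range) == 2L, max_abs_offset > 0)
  abs(offset) <= max_abs_offset &
    angle >= angle_range[1L] & angle <= angle_range[2L]
}

# ---- contacts ------------------------------------------------------------

#' Geometric criteria for hydrogen bonds and salt bridges
#'
#' Defaults: a hydrogen belongs to a donor heavy atom when it lies
#' within `dh_covalent` (1.2 A); a hydrogen bond requires
#' donor-acceptor distance at most `da_cutoff` (3.0 A) and a
#' donor-hydrogen-acceptor angle of at least `dha_angle` (150 degrees,
#' near-linear). `angle_mode = "literal_maximum"` instead treats
#' `dha_angle` as an upper bound. A salt bridge requires the
#' centers of mass of the two charged groups to be within
#' `salt_bridge_cutoff` (5 A).
#'
#' @param dh_covalent Donor-hydrogen covalent identification cutoff, A.
#' @param da_cutoff Donor-acceptor distance cutoff, A.
#' @param dha_angle D-H-A angle threshold, degrees, in (0, 180].
#' @param angle_mode `"minimum"` (default) or `"literal_maximum"`.
#' @param salt_bridge_cutoff COM-COM ion-pair cutoff, A.
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(dh_covalent = 1.2, da_cutoff = 3.0,
                             dha_angle = 150,
                             angle_mode = c("minimum", "literal_maximum"),
                             salt_bridge_cutoff = 5.0) {
  angle_mode <- match.arg(angle_mode)
  stopifnot(dh_covalent > 0, da_cutoff > 0, salt_bridge_cutoff > 0,
            dha_angle > 0, dha_angle <= 180)
  structure(list(dh_covalent = dh_covalent, da_cutoff = da_cutoff,
                 dha_angle = dha_angle, angle_mode = angle_mode,
                 salt_bridge_cutoff = salt_bridge_cutoff),
            class = "contact_criteria")
}

.angle_deg <- function(p1, vertex, p2) {
  a <- p1 - vertex; b <- p2 - vertex
  na <- .vnorm(a); nb <- .vnorm(b)
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

.atom_tag <- function(frame, idx) {
  paste(frame$chain[idx], frame$resno[idx], frame$atom[idx], sep = ":")
}

# core H-bond scan over donor/acceptor row indices
.hbond_scan <- function(frame, donor_idx, acceptor_idx, criteria) {
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  h_idx <- which(frame$elem == "H")
  out <- list()
  for (d in donor_idx) {
    if (length(h_idx)) {
      dh <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[d, ])^2))
      hs <- h_idx[dh <= criteria$dh_covalent]
    } else hs <- integer(0)
    if (!length(hs)) {
      warning(sprintf("donor %s has no covalent hydrogen; skipped",
                      .atom_tag(frame, d)))
      next
    }
    for (a in acceptor_idx) {
      if (a == d) next
      da <- .vnorm(xyz[a, ] - xyz[d, ])
      if (da > criteria$da_cutoff) next
      for (h in hs) {
        ang <- .angle_deg(xyz[d, ], xyz[h, ], xyz[a, ])
        ok <- if (criteria$angle_mode == "minimum") ang >= criteria$dha_angle
              else ang <= criteria$dha_angle
        if (isTRUE(ok))
          out[[length(out) + 1L]] <- data.frame(
            donor = .atom_tag(frame, d), hydrogen = .atom_tag(frame, h),
            acceptor = .atom_tag(frame, a), distance = da, angle = ang,
            donor_resno = frame$resno[d], acceptor_resno = frame$resno[a],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = character(0), hydrogen = character(0),
                      acceptor = character(0), distance = numeric(0),
                      angle = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$donor_resno, df$acceptor_resno, df$donor,
                 df$acceptor, df$hydrogen), ]
  rownames(df) <- NULL
  df[, c("donor", "hydrogen", "acceptor", "distance", "angle")]
}

#' Detect hydrogen bonds in a frame
#'
#' Scans the given donor and acceptor atoms for pairs satisfying the
#' distance and angle criteria. Hydrogens are assigned to donors by the
#' covalent cutoff; donors without any hydrogen are skipped with a
#' warning. Output rows are deterministically ordered by donor then
#' acceptor residue.
#'
#' @param frame A [md_frame] (hydrogens present).
#' @param donors,acceptors Character vectors of `"chain:resno:atom"`
#'   selectors naming donor heavy atoms and acceptor atoms.
#' @param criteria A [contact_criteria].
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance` (A), `angle` (degrees).
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criteria = contact_criteria()) {
  stopifnot(inherits(frame, "md_frame"),
            inherits(criteria, "contact_criteria"))
  donor_idx <- vapply(donors, function(s) .resolve_atom(frame, s),
                      integer(1L))
  acceptor_idx <- vapply(acceptors, function(s) .resolve_atom(frame, s),
                         integer(1L))
  .hbond_scan(frame, donor_idx, acceptor_idx, criteria)
}

#' Standard charged-group definitions for salt-bridge analysis
#'
#' Builds the charged side-chain moieties present in a frame: Arg
#' guanidinium (CZ, NH1, NH2), Lys ammonium (NZ) as cations; Asp
#' (CG, OD1, OD2) and Glu (CD, OE1, OE2) carboxylates as anions.
#'
#' @param frame A [md_frame].
#' @return List with `cations` and `anions`, each a named list of atom
#'   row-index vectors (names `chain:resno:RESID`).
#' @export
charged_groups <- function(frame) {
  defs <- list(ARG = list(sign = "cation", atoms = c("CZ", "NH1", "NH2")),
               LYS = list(sign = "cation", atoms = "NZ"),
               ASP = list(sign = "anion", atoms = c("CG", "OD1", "OD2")),
               GLU = list(sign = "anion", atoms = c("CD", "OE1", "OE2")))
  cations <- list(); anions <- list()
  res <- unique(frame[, c("chain", "resno", "resid")])
  for (i in seq_len(nrow(res))) {
    def <- defs[[res$resid[i]]]
    if (is.null(def)) next
    idx <- which(frame$chain == res$chain[i] &
                 frame$resno == res$resno[i] &
                 frame$atom %in% def$atoms)
    if (!length(idx)) next
    nm <- paste(res$chain[i], res$resno[i], res$resid[i], sep = ":")
    if (def$sign == "cation") cations[[nm]] <- idx else anions[[nm]] <- idx
  }
  list(cations = cations, anions = anions)
}

.group_com <- function(frame, idx) {
  m <- .mass_of(frame$elem[idx])
  colSums(.atom_xyz(frame, idx) * m) / sum(m)
}

#' Detect salt bridges in a frame
#'
#' A salt bridge is called when the mass-weighted centers of the two
#' charged groups are within the COM cutoff (default 5 A).
#'
#' @param frame A [md_frame].
#' @param cations,anions Named lists of atom row-index vectors (as from
#'   [charged_groups()]), or `NULL` to derive them automatically.
#' @param criteria A [contact_criteria].
#' @return Data frame with `cation`, `anion`, `distance` (A), ordered
#'   by group name.
#' @export
detect_salt_bridges <- function(frame, cations = NULL, anions = NULL,
                                criteria = contact_criteria()) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(cations) || is.null(anions)) {
    cg <- charged_groups(frame)
    if (is.null(cations)) cations <- cg$cations
    if (is.null(anions)) anions <- cg$anions
  }
  if (!length(cations) || !length(anions))
    stop("empty charged-group definitions: no cations or no anions")
  ccom <- t(vapply(cations, function(ix) .group_com(frame, ix),
                   numeric(3L)))
  acom <- t(vapply(anions, function(ix) .group_com(frame, ix),
                   numeric(3L)))
  out <- list()
  for (i in seq_len(nrow(ccom)))
    for (j in seq_len(nrow(acom))) {
      d <- .vnorm(ccom[i, ] - acom[j, ])
      if (d <= criteria$salt_bridge_cutoff)
        out[[length(out) + 1L]] <- data.frame(
          cation = rownames(ccom)[i], anion = rownames(acom)[j],
          distance = d, stringsAsFactors = FALSE)
    }
  if (!length(out))
    return(data.frame(cation = character(0), anion = character(0),
                      distance = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$cation, df$anion), ]
  rownames(df) <- NULL
  df
}

# polar heavy atoms of a residue; donors are those with a covalent H
.residue_polar <- function(frame, res_idx, criteria) {
  polar <- res_idx[frame$elem[res_idx] %in% c("N", "O", "S")]
  if (!length(polar)) return(list(donors = integer(0),
                                  acceptors = integer(0)))
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  h_idx <- which(frame$elem == "H")
  has_h <- vapply(polar, function(d) {
    if (!length(h_idx)) return(FALSE)
    any(sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[d, ])^2)) <=
          criteria$dh_covalent)
  }, logical(1L))
  list(donors = polar[has_h], acceptors = polar)
}

#' Interaction frequencies between residue pairs across an ensemble
#'
#' For each requested residue pair, the fraction of frames in which the
#' pair forms a donor-to-acceptor hydrogen bond (`DA`, donor in the
#' first residue), an acceptor-to-donor bond (`AD`), or a salt bridge
#' (`SB`). Donors/acceptors are the residues' polar heavy atoms
#' (N/O/S), donors requiring a covalently attached hydrogen.
#'
#' @param frames List of [md_frame] objects (>= 1).
#' @param pairs Data frame with columns `res1`, `res2` holding
#'   `"chain:resno"` selectors.
#' @param criteria A [contact_criteria].
#' @return Data frame with `res1`, `res2`, `DA`, `AD`, `SB`
#'   frequencies in \[0, 1\].
#' @export
interaction_frequencies <- function(frames, pairs,
                                    criteria = contact_criteria()) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            is.data.frame(pairs), all(c("res1", "res2") %in% names(pairs)))
  for (sel in unique(c(pairs$res1, pairs$res2)))
    .resolve_residue(frames[[1L]], sel)        # reject absent residues
  counts <- matrix(0, nrow(pairs), 3L,
                   dimnames = list(NULL, c("DA", "AD", "SB")))
  for (fr in frames) {
    for (i in seq_len(nrow(pairs))) {
      i1 <- .resolve_residue(fr, pairs$res1[i])
      i2 <- .resolve_residue(fr, pairs$res2[i])
      p1 <- .residue_polar(fr, i1, criteria)
      p2 <- .residue_polar(fr, i2, criteria)
      da <- length(p1$donors) && length(p2$acceptors) &&
        nrow(suppressWarnings(
          .hbond_scan(fr, p1$donors, p2$acceptors, criteria))) > 0
      ad <- length(p2$donors) && length(p1$acceptors) &&
        nrow(suppressWarnings(
          .hbond_scan(fr, p2$donors, p1$acceptors, criteria))) > 0
      cg <- charged_groups(fr)
      tag1 <- paste0("^", pairs$res1[i], ":")
      tag2 <- paste0("^", pairs$res2[i], ":")
      pick <- function(groups, tag)
        groups[grepl(tag, names(groups))]
      sb <- FALSE
      c1 <- pick(cg$cations, tag1); a2 <- pick(cg$anions, tag2)
      c2 <- pick(cg$cations, tag2); a1 <- pick(cg$anions, tag1)
      if ((length(c1) && length(a2)) || (length(c2) && length(a1))) {
        sbdf <- detect_salt_bridges(fr,
          cations = c(c1, c2)[lengths(c(c1, c2)) > 0],
          anions = c(a1, a2)[lengths(c(a1, a2)) > 0],
          criteria = criteria)
        ok1 <- grepl(tag1, sbdf$cation) & grepl(tag2, sbdf$anion)
        ok2 <- grepl(tag2, sbdf$cation) & grepl(tag1, sbdf$anion)
        sb <- any(ok1 | ok2)
      }
      counts[i, ] <- counts[i, ] + c(da, ad, sb)
    }
  }
  data.frame(res1 = pairs$res1, res2 = pairs$res2,
             DA = counts[, "DA"] / length(frames),
             AD = counts[, "AD"] / length(frames),
             SB = counts[, "SB"] / length(frames))
}

# ---- dihedrals -----------------------------------------------------------

#' Signed dihedral angle over four points
#'
#' IUPAC convention: 0 for cis (eclipsed), 180 for trans, sign by the
#' right-hand rule about the central bond; range (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- .vnorm(b2)
  if (nb2 < 1e-12 || .vnorm(n1) < 1e-12 || .vnorm(n2) < 1e-12)
    stop("degenerate dihedral: collinear or coincident atoms")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Side-chain chi1/chi2 dihedrals of a residue
#'
#' `chi1` over N-CA-CB-CG and `chi2` over CA-CB-CG-(Ndelta) as used for
#' the catalytic histidine (for His, `chi2_atom = "ND1"`).
#'
#' @param frame A [md_frame].
#' @param residue `"chain:resno"` selector.
#' @param chi2_atom Name of the fourth chi2 atom (default `"ND1"`).
#' @return Named numeric vector `c(chi1, chi2)` in degrees, (-180, 180].
#' @export
sidechain_dihedrals <- function(frame, residue, chi2_atom = "ND1") {
  idx <- .resolve_residue(frame, residue)
  get1 <- function(name) {
    i <- idx[frame$atom[idx] == name]
    if (length(i) != 1L)
      stop(sprintf("residue %s: atom '%s' missing or ambiguous",
                   residue, name))
    as.numeric(frame[i, c("x", "y", "z")])
  }
  n <- get1("N"); ca <- get1("CA"); cb <- get1("CB"); cg <- get1("CG")
  nd <- get1(chi2_atom)
  c(chi1 = dihedral_angle(n, ca, cb, cg),
    chi2 = dihedral_angle(ca, cb, cg, nd))
}

# ---- RMSF ----------------------------------------------------------------

.frame_key <- function(frame)
  paste(frame$chain, frame$resno, frame$atom, sep = ":")

#' Per-residue root mean square fluctuation after superposition
#'
#' Each frame is least-squares superposed onto the first frame using the
#' fit selection (Kabsch algorithm via [bio3d::fit.xyz()]); the
#' per-atom RMSF about the ensemble mean position is then averaged
#' within each residue over the measure selection.
#'
#' @param frames List of >= 2 [md_frame] objects with identical atom
#'   sets.
#' @param fit_sel Character selectors (`"chain:resno:atom"`) of the
#'   atoms used for superposition; default: all CA atoms.
#' @param measure_sel Selectors of the atoms entering the RMSF; default:
#'   all atoms.
#' @param superpose Set `FALSE` for pre-aligned ensembles.
#' @return Data frame with `chain`, `resno`, `resid`, `rmsf` (A).
#' @export
per_residue_rmsf <- function(frames, fit_sel = NULL, measure_sel = NULL,
                             superpose = TRUE) {
  stopifnot(is.list(frames))
  if (length(frames) < 2L) stop("RMSF needs at least 2 frames")
  ref <- frames[[1L]]
  key0 <- .frame_key(ref)
  xyz <- matrix(NA_real_, length(frames), 3L * nrow(ref))
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    keym <- .frame_key(fr)
    ord <- match(key0, keym)
    if (anyNA(ord) || nrow(fr) != nrow(ref))
      stop(sprintf("frame %d atom selection does not match frame 1", m))
    xyz[m, ] <- as.vector(t(as.matrix(fr[ord, c("x", "y", "z")])))
  }
  if (superpose) {
    fit_rows <- if (is.null(fit_sel)) which(ref$atom == "CA") else
      vapply(fit_sel, function(s) .resolve_atom(ref, s), integer(1L))
    if (length(fit_rows) < 3L)
      stop("superposition needs at least 3 fit atoms")
    inds <- bio3d::atom2xyz(fit_rows)
    xyz <- bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz,
                          fixed.inds = inds, mobile.inds = inds)
  }
  mean_xyz <- colMeans(xyz)
  dev2 <- sweep(xyz, 2L, mean_xyz)^2
  natoms <- nrow(ref)
  atom_msf <- vapply(seq_len(natoms), function(i)
    mean(rowSums(dev2[, (3L * i - 2L):(3L * i), drop = FALSE])),
    numeric(1L))
  atom_rmsf <- sqrt(atom_msf)
  meas_rows <- if (is.null(measure_sel)) seq_len(natoms) else
    vapply(measure_sel, function(s) .resolve_atom(ref, s), integer(1L))
  res <- unique(ref[meas_rows, c("chain", "resno", "resid")])
  res$rmsf <- vapply(seq_len(nrow(res)), function(i) {
    rows <- meas_rows[ref$chain[meas_rows] == res$chain[i] &
                        ref$resno[meas_rows] == res$resno[i]]
    mean(atom_rmsf[rows])
  }, numeric(1L))
  rownames(res) <- NULL
  res
}

# ---- per-frame report ----------------------------------------------------

#' Per-frame geometric observables of the thioester site
#'
#' Evaluates the signed plane offset, the imidazole orientation angle
#' and the base-catalysis compatibility flag for every frame, plus the
#' pocket volume when a [pocket_spec] is supplied.
#'
#' @param frames List of [md_frame] objects.
#' @param site A [thioester_site].
#' @param pocket Optional [pocket_spec].
#' @param max_abs_offset,angle_range Passed to
#'   [classify_base_catalysis()].
#' @return Data frame with columns `frame`, `offset_A`, `angle_deg`,
#'   `compatible` (and `volume_A3` when `pocket` is given); suitable
#'   for `write.csv`.
#' @export
geometry_report <- function(frames, site, pocket = NULL,
                            max_abs_offset = 3.5,
                            angle_range = c(90, 180)) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  off <- vapply(frames, signed_plane_offset, numeric(1L), site = site)
  ang <- vapply(frames, orientation_angle, numeric(1L), site = site)
  out <- data.frame(frame = seq_along(frames), offset_A = off,
                    angle_deg = ang,
                    compatible = classify_base_catalysis(
                      off, ang, max_abs_offset, angle_range))
  if (!is.null(pocket))
    out$volume_A3 <- vapply(frames, function(fr)
      pocket_volume(fr, pocket)$volume, numeric(1L))
  out
}
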