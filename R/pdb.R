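#' @importFrom utils head
NULL

# monoisotopic-average atomic masses for COM computations
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                  ZN = 65.38, MG = 24.305, NA. = 22.99, CL = 35.45)

.mass_of <- function(elem) {
  m <- .atomic_mass[toupper(elem)]
  m[is.na(m)] <- 12.011
  unname(m)
}

# His residue-name dialects: delta-protonated (NE2 unprotonated) vs
# epsilon-protonated (ND1 unprotonated) vs doubly protonated
.his_dialects <- c(HID = "delta", HSD = "delta",
                   HIE = "epsilon", HSE = "epsilon",
                   HIP = "both", HSP = "both", HIS = "unspecified")

.infer_element <- function(name) {
  stripped <- gsub("[0-9'\"]", "", trimws(name))
  two <- toupper(substr(stripped, 1L, 2L))
  one <- toupper(substr(stripped, 1L, 1L))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE"), two,
         ifelse(one %in% c("C", "N", "O", "S", "H", "P", "F"), one, "C"))
}

#' A single coordinate frame of a structure ensemble
#'
#' @param atoms Data frame with columns `atom` (name), `resid` (residue
#'   name), `resno`, `chain`, `elem`, `x`, `y`, `z` (and optionally
#'   `tautomer` for histidines). Coordinates in Angstrom.
#' @param frame_index Index of the frame within its ensemble.
#' @return A data frame of class `md_frame`.
#' @export
md_frame <- function(atoms, frame_index = 1L) {
  need <- c("atom", "resid", "resno", "chain", "elem", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("frame atoms lack column(s): ",
         paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate atom key within frame: ", key[duplicated(key)][1L])
  if (!"tautomer" %in% names(atoms)) atoms$tautomer <- NA_character_
  structure(as.data.frame(atoms), frame_index = frame_index,
            class = c("md_frame", "data.frame"))
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("Coordinate frame %s: %d atoms, %d residues\n",
              as.character(attr(x, "frame_index")), nrow(x),
              length(unique(paste(x$chain, x$resno)))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

# resolve "chain:resno:atom" selectors to row indices of a frame
.resolve_atom <- function(frame, sel, multiple = FALSE) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("atom selector must be 'chain:resno:atomname', got '", sel, "'")
  idx <- which(frame$chain == parts[1L] &
               frame$resno == as.integer(parts[2L]) &
               frame$atom == parts[3L])
  if (length(idx) == 0L) stop("selector '", sel, "' matches no atom")
  if (length(idx) > 1L && !multiple)
    stop("selector '", sel, "' matches ", length(idx), " atoms")
  idx
}

.resolve_residue <- function(frame, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("residue selector must be 'chain:resno', got '", sel, "'")
  idx <- which(frame$chain == parts[1L] & frame$resno == as.integer(parts[2L]))
  if (length(idx) == 0L) stop("residue '", sel, "' not found")
  idx
}

.atom_xyz <- function(frame, idx) {
  as.matrix(frame[idx, c("x", "y", "z"), drop = FALSE])
}

#' Read a (multi-model) PDB file as a list of frames
#'
#' Uses [bio3d::read.pdb()]; each MODEL becomes one frame (a
#' single-model file yields one frame), model order defining frame
#' order. Elements come from PDB columns 77-78 with an atom-name
#' heuristic as fallback; His tautomer dialects (HID/HIE/HIP and
#' HSD/HSE/HSP) are normalized to residue name HIS with the protonation
#' recorded in the `tautomer` column.
#'
#' @param path Path to a PDB file (coordinates in Angstrom).
#' @return List of [md_frame] objects.
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  noelem <- is.na(elem) | !nzchar(trimws(elem))
  elem[noelem] <- .infer_element(at$elety[noelem])
  elem <- toupper(trimws(elem))
  resid <- at$resid
  taut <- rep(NA_character_, nrow(at))
  ish <- resid %in% names(.his_dialects)
  taut[ish] <- .his_dialects[resid[ish]]
  resid[ish] <- "HIS"
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    md_frame(data.frame(atom = at$elety, resid = resid, resno = at$resno,
                        chain = chain, elem = elem, tautomer = taut,
                        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                        stringsAsFactors = FALSE),
             frame_index = m)
  })
}

#' Write frames as a multi-model PDB file
#'
#' Standard fixed-column PDB ATOM records (coordinates to 0.001
#' Angstrom), one MODEL/ENDMDL block per frame; the inverse of
#' [read_ensemble_pdb()] up to coordinate rounding.
#'
#' @param frames A [md_frame] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    # re-emit His tautomers in the AMBER-style dialect so the
    # protonation state survives a write/read round trip
    ish <- fr$resid == "HIS" & !is.na(fr$tautomer)
    fr$resid[ish] <- c(delta = "HID", epsilon = "HIE",
                       both = "HIP")[fr$tautomer[ish]]
    fr$resid[is.na(fr$resid)] <- "HIS"
    name4 <- ifelse(nchar(fr$atom) >= 4L, substr(fr$atom, 1L, 4L),
                    sprintf(" %-3s", fr$atom))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(fr)), name4, substr(fr$resid, 1L, 3L),
      substr(as.character(fr$chain), 1L, 1L), as.integer(fr$resno),
      fr$x, fr$y, fr$z, 1, 0, fr$elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Name of the unprotonated histidine ring nitrogen
#'
#' For a delta-protonated His (HID/HSD) the unprotonated nitrogen is
#' NE2; for an epsilon-protonated His (HIE/HSE) it is ND1.
#'
#' @param tautomer `"delta"`, `"epsilon"`, or the raw residue-name
#'   dialect (HID/HIE/HSD/HSE).
#' @return `"NE2"` or `"ND1"`.
#' @export
his_unprotonated_nitrogen <- function(tautomer) {
  if (tautomer %in% names(.his_dialects))
    tautomer <- .his_dialects[[tautomer]]
  switch(tautomer,
         delta = "NE2",
         epsilon = "ND1",
         stop("tautomer must resolve to 'delta' or 'epsilon', got '",
              tautomer, "'"))
}
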