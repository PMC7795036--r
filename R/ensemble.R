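#' Structure ensembles
#'
#' A `StructureEnsemble` holds an ordered set of conformations of one
#' receptor, harmonized to the residues common to every frame.  Analyses in
#' this package (the activation variable, distance-fluctuation couplings,
#' site scoring) all operate on this container.
#'
#' Fields:
#' \describe{
#'   \item{residues}{data.frame of the common residues, in frame-1 order:
#'     `id`, `chain`, `number`, `insert`, `name` (3-letter).}
#'   \item{xyz}{numeric array `n_residues x 3 x n_frames` of C-alpha
#'     coordinates in Angstrom.}
#'   \item{frames}{data.frame with one row per conformation: `label`,
#'     `source`, `state` (`"inactive"`, `"active"` or `"unknown"`).}
#'   \item{atoms}{optional list, one data.frame per frame of all heavy atoms
#'     of the common residues (`id`, `elety`, `x`, `y`, `z`); used for
#'     pocket-residue assignment.  `NULL` for C-alpha-only ensembles, in
#'     which case assignment falls back to C-alpha positions.}
#' }
#'
#' @param residues,xyz,frames,atoms see Description.
#' @return an object of class `StructureEnsemble`.
#' @export
new_structure_ensemble <- function(residues, xyz, frames, atoms = NULL) {
  stopifnot(is.data.frame(residues), length(dim(xyz)) == 3L,
            dim(xyz)[1] == nrow(residues), dim(xyz)[2] == 3L,
            dim(xyz)[3] == nrow(frames))
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (anyDuplicated(residues$id))
    stop("duplicate residue ids within a conformation")
  if (!is.null(atoms)) stopifnot(length(atoms) == nrow(frames))
  structure(list(residues = residues, xyz = xyz,
                 frames = frames, atoms = atoms),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  st <- table(x$frames$state)
  cat("StructureEnsemble:", nrow(x$frames), "frames,",
      nrow(x$residues), "common residues\n")
  cat("  chains:", paste(unique(x$residues$chain), collapse = ", "), "\n")
  cat("  states:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$frames$rmsd))
    cat("  superposed (per-frame RMSD available)\n")
  invisible(x)
}

#' Number of frames / residues of an ensemble
#' @param ensemble a `StructureEnsemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$frames)

#' @rdname n_frames
#' @export
n_residues <- function(ensemble) nrow(ensemble$residues)

# ---- parsing ---------------------------------------------------------------

# altloc rule: keep highest occupancy; ties resolved toward altloc "A".
# hydrogens dropped; only polymer (ATOM) records contribute residues.
.clean_atoms <- function(atom) {
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  elesy <- trimws(ifelse(is.na(atom$elesy), "", atom$elesy))
  h <- elesy == "H" | (elesy == "" & grepl("^[0-9]*H", trimws(atom$elety)))
  atom <- atom[!h, , drop = FALSE]
  if (nrow(atom) == 0L) return(atom)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  alt <- ifelse(is.na(atom$alt), "A", atom$alt)
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "|")
  ord <- order(key, -occ, alt)
  keep <- ord[!duplicated(key[ord])]
  atom[sort(keep), , drop = FALSE]   # original file order preserved
}

# one parsed model -> conformation: residue table + C-alpha + heavy atoms
.make_conformation <- function(atom, xyz_row, label, source,
                               chain_filter, ranges) {
  atom$x <- xyz_row[seq(1, length(xyz_row), 3)]
  atom$y <- xyz_row[seq(2, length(xyz_row), 3)]
  atom$z <- xyz_row[seq(3, length(xyz_row), 3)]
  atom <- .clean_atoms(atom)
  if (!is.null(chain_filter)) {
    atom <- atom[atom$chain %in% chain_filter, , drop = FALSE]
    if (nrow(atom) == 0L)
      stop("chain '", chain_filter, "' selects no atoms in ", source)
  }
  atom <- atom[in_ranges(atom$resno, ranges), , drop = FALSE]
  if (nrow(atom) == 0L) stop("no atoms retained from ", source)
  ins <- ifelse(is.na(atom$insert), "", atom$insert)
  atom$rid <- residue_id(atom$chain, atom$resno, ins)
  ca <- atom[atom$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$rid), , drop = FALSE]
  residues <- data.frame(id = ca$rid, chain = ca$chain, number = ca$resno,
                         insert = ifelse(is.na(ca$insert), "", ca$insert),
                         name = ca$resid, stringsAsFactors = FALSE)
  list(label = label, source = source, residues = residues,
       ca = cbind(ca$x, ca$y, ca$z),
       all_ids = unique(atom$rid),
       atoms = data.frame(id = atom$rid, elety = atom$elety,
                          x = atom$x, y = atom$y, z = atom$z,
                          stringsAsFactors = FALSE))
}

.parse_pdb_conformations <- function(file, chain_filter, ranges) {
  reader <- if (grepl("\\.cif$", file, ignore.case = TRUE))
    function(f) bio3d::read.cif(f, verbose = FALSE)
  else
    function(f) bio3d::read.pdb(f, multi = TRUE, rm.alt = FALSE,
                                verbose = FALSE)
  pdb <- tryCatch(reader(file),
    error = function(e) stop("cannot parse structure file '", file, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("cannot parse structure file '", file, "': no atom records",
         call. = FALSE)
  xyzm <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  nm <- nrow(xyzm)
  lapply(seq_len(nm), function(m) {
    lab <- if (nm > 1L) paste0(basename(file), "#", m) else basename(file)
    .make_conformation(pdb$atom, as.numeric(xyzm[m, ]), lab, file,
                       chain_filter, ranges)
  })
}

.parse_traj_conformations <- function(traj, top, chain_filter, ranges) {
  pdb <- tryCatch(
    bio3d::read.pdb(top, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse topology '", top, "': ",
                             conditionMessage(e), call. = FALSE))
  xyz <- tryCatch(
    bio3d::read.dcd(traj, verbose = FALSE),
    error = function(e) stop("cannot parse trajectory '", traj, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(xyz) != 3L * nrow(pdb$atom))
    stop("trajectory '", traj, "' atom count does not match topology")
  lapply(seq_len(nrow(xyz)), function(m)
    .make_conformation(pdb$atom, as.numeric(xyz[m, ]),
                       paste0(basename(traj), "#", m), traj,
                       chain_filter, ranges))
}

#' Load and harmonize a conformational ensemble
#'
#' Reads an ensemble from (a) a directory of PDB files, (b) one or more PDB
#' files (single- or multi-MODEL), or (c) a DCD trajectory with a PDB
#' topology, and harmonizes the frames to their common residue set.
#' Residues are matched across frames by chain, author number and insertion
#' code; no sequence alignment or renumbering is attempted.  Residues
#' lacking a C-alpha in any frame are dropped from the common set with a
#' warning.  Hydrogens are ignored; for duplicated altloc atoms the highest
#' occupancy (ties toward altloc A) is kept; HETATM records never enter the
#' residue set.
#'
#' @param sources a directory path, a character vector of structure files,
#'   or `list(trajectory = "x.dcd", topology = "top.pdb")`.
#' @param chain optional chain label; selects exactly that polymer chain.
#' @param residues optional inclusive author-number ranges, as
#'   `"32-227,267-342"` or a list of `c(lo, hi)` pairs.
#' @param state optional per-frame conformational-state tags
#'   (`"inactive"`/`"active"`/`"unknown"`), recycled to the frame count.
#' @return a [new_structure_ensemble()] object.
#' @examples
#' \dontrun{
#' ens <- load_ensemble("pdbs/", chain = "A", residues = "32-227,267-342")
#' }
#' @export
load_ensemble <- function(sources, chain = NULL, residues = NULL,
                          state = "unknown") {
  ranges <- parse_residue_ranges(residues)
  confs <-
    if (is.list(sources) && !is.null(sources$trajectory)) {
      .parse_traj_conformations(sources$trajectory, sources$topology,
                                chain, ranges)
    } else {
      sources <- as.character(sources)
      if (length(sources) == 1L && dir.exists(sources))
        sources <- sort(list.files(sources, pattern = "\\.(pdb|ent|cif)$",
                                   full.names = TRUE, ignore.case = TRUE))
      if (length(sources) == 0L) stop("no structure files found")
      unlist(lapply(sources, .parse_pdb_conformations, chain, ranges),
             recursive = FALSE)
    }
  if (length(confs) < 3L)
    warning("fewer than 3 conformations loaded; ",
            "correlation analysis requires at least 3 frames")

  common <- Reduce(intersect, lapply(confs, function(cf) cf$residues$id))
  present_all <- Reduce(intersect, lapply(confs, function(cf) cf$all_ids))
  no_ca <- setdiff(present_all, common)
  if (length(no_ca) > 0L)
    warning("dropped ", length(no_ca),
            " residue(s) lacking a C-alpha in at least one frame: ",
            paste(utils::head(no_ca, 5), collapse = ", "),
            if (length(no_ca) > 5) " ...")
  if (length(common) == 0L) stop("no common residues across conformations")

  res <- confs[[1]]$residues
  res <- res[match(common, res$id), , drop = FALSE]
  rownames(res) <- NULL
  xyz <- array(NA_real_, c(length(common), 3L, length(confs)))
  atoms <- vector("list", length(confs))
  for (f in seq_along(confs)) {
    cf <- confs[[f]]
    xyz[, , f] <- cf$ca[match(common, cf$residues$id), , drop = FALSE]
    atoms[[f]] <- cf$atoms[cf$atoms$id %in% common, , drop = FALSE]
  }
  frames <- data.frame(
    label = vapply(confs, `[[`, "", "label"),
    source = vapply(confs, `[[`, "", "source"),
    state = rep_len(state, length(confs)),
    stringsAsFactors = FALSE)
  new_structure_ensemble(res, xyz, frames, atoms)
}

# ---- superposition ---------------------------------------------------------

# optimal least-squares rotation (Kabsch, SVD form); returns the transform
# mapping P onto Q: P %*% R + t
kabsch_transform <- function(P, Q) {
  if (nrow(P) < 3L) stop("superposition underdetermined")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  if (s$d[2] < max(s$d[1], 1) * 1e-10)
    stop("superposition underdetermined")   # collinear point set
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cq - as.numeric(cp %*% R))
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Rigid-body least-squares superposition (Kabsch) on the common-residue
#' C-alpha coordinates.  Heavy-atom coordinates, when present, receive the
#' same transform, so pocket dummy-atom assignment stays consistent.  The
#' reference frame is left unchanged.  Per-frame C-alpha RMSD to the
#' reference after superposition is stored in `frames$rmsd`.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param reference frame index of the reference conformation.
#' @return the superposed ensemble.
#' @export
superpose_ensemble <- function(ensemble, reference = 1L) {
  nf <- n_frames(ensemble)
  stopifnot(reference >= 1L, reference <= nf)
  if (n_residues(ensemble) < 3L) stop("superposition underdetermined")
  Q <- ensemble$xyz[, , reference]
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    if (f == reference) { rmsd[f] <- 0; next }
    P <- ensemble$xyz[, , f]
    tr <- kabsch_transform(P, Q)
    Pf <- P %*% tr$R + rep(tr$t, each = nrow(P))
    ensemble$xyz[, , f] <- Pf
    rmsd[f] <- sqrt(mean(rowSums((Pf - Q)^2)))
    if (!is.null(ensemble$atoms)) {
      at <- ensemble$atoms[[f]]
      m <- as.matrix(at[, c("x", "y", "z")]) %*% tr$R +
        rep(tr$t, each = nrow(at))
      ensemble$atoms[[f]][, c("x", "y", "z")] <- m
    }
  }
  ensemble$frames$rmsd <- rmsd
  ensemble
}

#' Concatenate two ensembles
#'
#' Frames of `a` followed by frames of `b`, harmonized to the intersection
#' of their residue sets; per-frame provenance and state tags are kept.
#' Used to pool harmonic trajectories generated from inactive and active
#' conformations into one mixed ensemble.
#'
#' @param a,b `StructureEnsemble` objects.
#' @return the concatenated `StructureEnsemble`.
#' @export
concatenate_ensembles <- function(a, b) {
  common <- intersect(a$residues$id, b$residues$id)
  if (length(common) == 0L)
    stop("ensembles share no residues; cannot concatenate")
  ia <- match(common, a$residues$id); ib <- match(common, b$residues$id)
  res <- a$residues[ia, , drop = FALSE]; rownames(res) <- NULL
  xyz <- array(NA_real_, c(length(common), 3L, n_frames(a) + n_frames(b)))
  xyz[, , seq_len(n_frames(a))] <- a$xyz[ia, , , drop = FALSE]
  xyz[, , n_frames(a) + seq_len(n_frames(b))] <- b$xyz[ib, , , drop = FALSE]
  sub_atoms <- function(lst) {
    if (is.null(lst)) return(NULL)
    lapply(lst, function(at) at[at$id %in% common, , drop = FALSE])
  }
  atoms <- if (is.null(a$atoms) && is.null(b$atoms)) NULL else {
    aa <- sub_atoms(a$atoms); bb <- sub_atoms(b$atoms)
    if (is.null(aa)) aa <- rep(list(NULL), n_frames(a))
    if (is.null(bb)) bb <- rep(list(NULL), n_frames(b))
    c(aa, bb)
  }
  fa <- a$frames; fb <- b$frames
  keep <- c("label", "source", "state")
  frames <- rbind(fa[keep], fb[keep])
  rownames(frames) <- NULL
  new_structure_ensemble(res, xyz, frames, atoms)
}

#' Write an ensemble as a multi-MODEL PDB (C-alpha trace)
#'
#' @param ensemble a `StructureEnsemble`.
#' @param file output path.
#' @param b optional per-residue B-factor column (e.g. a site coupling
#'   score for visualization), recycled over frames.
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, file, b = NULL) {
  res <- ensemble$residues
  nf <- n_frames(ensemble)
  xyz <- t(vapply(seq_len(nf),
                  function(f) as.numeric(t(ensemble$xyz[, , f])),
                  numeric(3L * nrow(res))))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = res$number, resid = res$name,
                   chain = res$chain,
                   insert = ifelse(res$insert == "", NA, res$insert),
                   elety = rep("CA", nrow(res)),
                   b = if (is.null(b)) rep(0, nrow(res)) else b)
  invisible(file)
}
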