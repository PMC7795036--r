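#' Site definitions
#'
#' A `site_definition` is a labeled residue set to be scored for coupling
#' to the activation variable: `site_label`, `residues` (canonical ids),
#' `presence_fraction` (fraction of ensemble frames in which the pocket was
#' detected; 1 by definition for user-supplied residue lists) and `origin`
#' (`"pocket_cloud"` or `"residue_list"`).
#'
#' @param site_label label.
#' @param residues character vector of residue ids (deduplicated).
#' @param presence_fraction in `[0, 1]`.
#' @param origin provenance tag.
#' @return an object of class `site_definition`.
#' @export
site_definition <- function(site_label, residues, presence_fraction = 1,
                            origin = "residue_list") {
  residues <- unique(as.character(residues))
  stopifnot(length(residues) >= 1L,
            presence_fraction >= 0, presence_fraction <= 1)
  structure(list(site_label = as.character(site_label), residues = residues,
                 presence_fraction = presence_fraction, origin = origin),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat("site '", x$site_label, "': ", length(x$residues), " residues (",
      x$origin, ", presence ", sprintf("%.2f", x$presence_fraction),
      ")\n", sep = "")
  invisible(x)
}

# ---- pocket dummy-atom clouds ----------------------------------------------

# fixed-column PDB record fields for STP dummy atoms; the dialect has a
# varying atom count per MODEL, so a dedicated line parser is used.
.parse_stp_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom <- grepl("^(ATOM  |HETATM)", lines)
  stp <- atom & trimws(substr(lines, 18, 20)) == "STP"
  list(
    stp = which(stp),
    n_skipped = sum(atom & !stp),
    pocket = suppressWarnings(as.integer(substr(lines[stp], 23, 26))),
    xyz = cbind(as.numeric(substr(lines[stp], 31, 38)),
                as.numeric(substr(lines[stp], 39, 46)),
                as.numeric(substr(lines[stp], 47, 54))))
}

#' Parse fpocket/Mdpocket dummy-atom output into per-pocket point clouds
#'
#' Dummy atoms are ATOM/HETATM records with residue name `STP`; the pocket
#' index sits in the residue-number field.  Input is either one multi-MODEL
#' file (one MODEL per ensemble frame) or a vector of files, one per frame.
#' Non-STP atom records are ignored (their count is reported in a warning).
#'
#' @param paths one multi-MODEL file or one file per frame.
#' @param n_frames expected ensemble frame count; frames with no dummy
#'   atoms for a pocket get an empty point list (pocket absent).
#' @return list of `pocket_cloud` objects: `site_label`, `frames` (list of
#'   k x 3 coordinate matrices), `source`, `presence_fraction`.
#' @export
parse_pocket_output <- function(paths, n_frames = NULL) {
  per_frame <- list()   # frame -> parsed STP table
  if (length(paths) == 1L) {
    lines <- readLines(paths)
    starts <- grep("^MODEL", lines)
    n_skipped <- 0L
    if (length(starts) == 0L) {
      p <- .parse_stp_lines(lines)
      per_frame[[1]] <- p; n_skipped <- p$n_skipped
    } else {
      ends <- c(starts[-1] - 1L, length(lines))
      for (m in seq_along(starts)) {
        p <- .parse_stp_lines(lines[starts[m]:ends[m]])
        per_frame[[m]] <- p; n_skipped <- n_skipped + p$n_skipped
      }
    }
  } else {
    n_skipped <- 0L
    for (m in seq_along(paths)) {
      p <- .parse_stp_lines(readLines(paths[m]))
      per_frame[[m]] <- p; n_skipped <- n_skipped + p$n_skipped
    }
  }
  if (n_skipped > 0L)
    warning("ignored ", n_skipped, " non-STP atom record(s) in pocket input")
  nf <- if (is.null(n_frames)) length(per_frame) else n_frames
  if (length(per_frame) > nf)
    stop("pocket input has more frames (", length(per_frame),
         ") than the ensemble (", nf, ")")
  labels <- sort(unique(unlist(lapply(per_frame, `[[`, "pocket"))))
  if (length(labels) == 0L) stop("no pocket dummy atoms in input")
  lapply(labels, function(lb) {
    frames <- lapply(seq_len(nf), function(m) {
      if (m > length(per_frame)) return(matrix(numeric(0), 0, 3))
      p <- per_frame[[m]]
      p$xyz[p$pocket == lb, , drop = FALSE]
    })
    structure(list(site_label = as.character(lb), frames = frames,
                   source = paste(basename(paths), collapse = ","),
                   presence_fraction =
                     mean(vapply(frames, nrow, 1L) > 0L)),
              class = "pocket_cloud")
  })
}

#' Write pocket clouds in the fpocket/Mdpocket dummy-atom dialect
#'
#' One MODEL per frame; STP HETATM records with the pocket index in the
#' residue-number field.  Round-trips through [parse_pocket_output()] to
#' PDB coordinate precision (1e-3 Angstrom).
#'
#' @param clouds list of `pocket_cloud` objects (equal frame counts).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pocket_pdb <- function(clouds, file) {
  nf <- length(clouds[[1]]$frames)
  stopifnot(all(vapply(clouds, function(cl) length(cl$frames), 1L) == nf))
  con <- file(file, "w")
  on.exit(close(con))
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (cl in clouds) {
      pts <- cl$frames[[m]]
      if (nrow(pts) == 0L) next
      for (k in seq_len(nrow(pts))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "HETATM%5d  O   STP  %4d    %8.3f%8.3f%8.3f  0.00  0.00",
          serial, as.integer(cl$site_label),
          pts[k, 1], pts[k, 2], pts[k, 3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Retain pockets detected in a sufficient fraction of frames
#'
#' A pocket is kept when it is present (has at least one dummy atom) in at
#' least `min_fraction` of the frames — inclusive, so a pocket present in
#' exactly 40% of frames survives the default rule.
#'
#' @param clouds list of `pocket_cloud` objects.
#' @param min_fraction retention threshold in (0, 1].
#' @return the retained clouds.
#' @export
presence_filter <- function(clouds, min_fraction = 0.40) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  keep <- vapply(clouds, `[[`, 1, "presence_fraction") >= min_fraction
  clouds[keep]
}

# ---- neighbor search -------------------------------------------------------

# grid (cell-list) neighbor query: for each row of A, is any row of B
# within `cutoff` (inclusive)?  Cells of edge `cutoff`; only the 27
# neighboring cells of a point can contain a match.
grid_any_within <- function(A, B, cutoff) {
  if (nrow(B) == 0L || nrow(A) == 0L) return(rep(FALSE, nrow(A)))
  cellB <- floor(sweep(B, 2, rep(cutoff, 3), "/"))
  keyB <- paste(cellB[, 1], cellB[, 2], cellB[, 3])
  binB <- split(seq_len(nrow(B)), keyB)
  cellA <- floor(sweep(A, 2, rep(cutoff, 3), "/"))
  out <- rep(FALSE, nrow(A))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (a in seq_len(nrow(A))) {
    neigh <- sweep(off, 2, cellA[a, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    cand <- unlist(binB[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- (B[cand, 1] - A[a, 1])^2 + (B[cand, 2] - A[a, 2])^2 +
      (B[cand, 3] - A[a, 3])^2
    out[a] <- any(d2 <= cut2)
  }
  out
}

# heavy-atom table of one frame; C-alpha fallback for coordinate-only
# ensembles
.frame_atoms <- function(ensemble, f) {
  if (!is.null(ensemble$atoms) && !is.null(ensemble$atoms[[f]]))
    return(ensemble$atoms[[f]])
  data.frame(id = ensemble$residues$id, elety = "CA",
             x = ensemble$xyz[, 1, f], y = ensemble$xyz[, 2, f],
             z = ensemble$xyz[, 3, f], stringsAsFactors = FALSE)
}

#' Assign residues to a pocket from its dummy-atom cloud
#'
#' A residue belongs to the site if, in at least one frame, any of its
#' heavy atoms lies within `cutoff` (inclusive) of any dummy atom of that
#' frame; the result is the union over frames (restrict with
#' `assignment_frames` to reproduce single-frame assignment).  The ensemble
#' must be superposed into the same frame of reference as the pocket
#' cloud.
#'
#' @param cloud a `pocket_cloud`.
#' @param ensemble a superposed `StructureEnsemble`.
#' @param cutoff Angstrom (default 4.0).
#' @param assignment_frames optional frame indices to restrict the union.
#' @return a [site_definition()] with origin `"pocket_cloud"`.
#' @export
assign_site_residues <- function(cloud, ensemble, cutoff = 4.0,
                                 assignment_frames = NULL) {
  stopifnot(cutoff > 0)
  frames <- seq_len(n_frames(ensemble))
  if (!is.null(assignment_frames)) frames <- assignment_frames
  if (length(cloud$frames) != n_frames(ensemble))
    stop("pocket cloud frame count does not match ensemble")
  hit_ids <- character(0)
  any_points <- FALSE
  for (f in frames) {
    pts <- cloud$frames[[f]]
    if (nrow(pts) == 0L) next
    any_points <- TRUE
    at <- .frame_atoms(ensemble, f)
    hits <- grid_any_within(as.matrix(at[, c("x", "y", "z")]), pts, cutoff)
    hit_ids <- union(hit_ids, unique(at$id[hits]))
  }
  if (!any_points)
    stop("pocket '", cloud$site_label, "' has no dummy atoms in the ",
         "requested frames")
  if (length(hit_ids) == 0L)
    stop("pocket '", cloud$site_label, "' assigns no residues at cutoff ",
         cutoff, " A")
  ord <- match(hit_ids, ensemble$residues$id)
  hit_ids <- hit_ids[order(ord)]
  site_definition(cloud$site_label, hit_ids,
                  presence_fraction = cloud$presence_fraction,
                  origin = "pocket_cloud")
}

#' Filter a site list
#'
#' Drops sites overlapping the orthosteric residue set (overlap fraction of
#' the smaller set at or above `max_overlap`, default 0.5) and sites whose
#' label appears in `exclude`.  Surface-versus-buried disposition is not
#' computed automatically; use `exclude` (or curate upstream) for buried
#' pockets.
#'
#' @param sites list of `site_definition` objects.
#' @param orthosteric_residues optional character vector of residue ids.
#' @param exclude optional site labels to drop.
#' @param max_overlap overlap fraction (of the smaller set) at which a
#'   site is considered orthosteric.
#' @return the filtered list.
#' @export
filter_sites <- function(sites, orthosteric_residues = NULL, exclude = NULL,
                         max_overlap = 0.5) {
  keep <- vapply(sites, function(s) {
    if (!is.null(exclude) && s$site_label %in% exclude) return(FALSE)
    if (!is.null(orthosteric_residues)) {
      ov <- length(intersect(s$residues, orthosteric_residues)) /
        min(length(s$residues), length(orthosteric_residues))
      if (ov >= max_overlap) return(FALSE)
    }
    TRUE
  }, TRUE)
  sites[keep]
}

#' Load site residue lists from a file
#'
#' Accepts JSON (`{"Site4": ["A:131", ...], ...}`) or plain text
#' (`Site4: A:131,A:141,...`; a bare number is resolved against the
#' ensemble's single chain).  Residues absent from the ensemble are
#' dropped with a per-site warning; duplicates are deduplicated.
#'
#' @param path input file.
#' @param ensemble a `StructureEnsemble` used to validate the residues.
#' @return list of `site_definition` objects (origin `"residue_list"`,
#'   presence fraction 1).
#' @export
load_site_lists <- function(path, ensemble) {
  txt <- readLines(path, warn = FALSE)
  raw <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
    parts <- strsplit(txt, ":", fixed = FALSE)
    lab <- vapply(strsplit(txt, ":"), function(p) trimws(p[1]), "")
    body <- sub("^[^:]*:", "", txt)
    stats::setNames(lapply(body, function(b)
      trimws(strsplit(b, ",", fixed = TRUE)[[1]])), lab)
  }
  chains <- unique(ensemble$residues$chain)
  lapply(names(raw), function(lb) {
    ids <- as.character(unlist(raw[[lb]]))
    bare <- grepl("^-?[0-9]+[A-Za-z]?$", ids)
    if (any(bare)) {
      if (length(chains) != 1L)
        stop("site '", lb, "' uses bare residue numbers but the ensemble ",
             "has ", length(chains), " chains; use chain:number ids")
      ids[bare] <- paste0(chains, ":", ids[bare])
    }
    ids <- unique(ids)
    missing <- setdiff(ids, ensemble$residues$id)
    if (length(missing) > 0L) {
      warning("site '", lb, "': dropped ", length(missing),
              " residue(s) absent from the ensemble: ",
              paste(utils::head(missing, 5), collapse = ", "))
      ids <- setdiff(ids, missing)
    }
    if (length(ids) == 0L)
      stop("site '", lb, "' has no residues present in the ensemble")
    site_definition(lb, ids, presence_fraction = 1,
                    origin = "residue_list")
  })
}

#' Write site residue lists (JSON)
#'
#' @param sites list of `site_definition` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_site_lists <- function(sites, file) {
  out <- stats::setNames(lapply(sites, `[[`, "residues"),
                         vapply(sites, `[[`, "", "site_label"))
  jsonlite::write_json(out, file, pretty = TRUE)
  invisible(file)
}
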