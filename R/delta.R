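#' Anchor residues defining the activation variable
#'
#' The collective activation variable is the difference of two inter-helix
#' C-alpha distances, `delta = d1 - d2`, where `d1` spans TM2-TM6 and `d2`
#' spans TM3-TM7.  Large delta marks active-like conformations (outward
#' TM6, inward TM3/TM7); inactive structures show low or negative delta.
#'
#' Built-in presets carry the author-numbered anchors for three receptors:
#'
#' | preset    | class | TM2  | TM6  | TM3  | TM7  |
#' |-----------|-------|------|------|------|------|
#' | `beta2AR` | A     | Y70  | G276 | C125 | I325 |
#' | `GCGR`    | B     | A175 | L347 | L243 | V398 |
#' | `M2`      | A     | Y60  | L390 | L115 | C439 |
#'
#' Generic GPCRdb positions (2x41/6x38/3x44/7x52 for class A; 6x33/7x51 for
#' class B) are recorded for reference but are never resolved against an
#' external service; custom receptors must supply explicit anchors.
#'
#' @param tm2,tm6,tm3,tm7 canonical residue ids (see [residue_id()]).
#' @param receptor_class `"A"`, `"B"` or `"custom"`.
#' @return an object of class `delta_spec`.
#' @export
delta_spec <- function(tm2, tm6, tm3, tm7, receptor_class = "custom") {
  anchors <- c(tm2 = tm2, tm6 = tm6, tm3 = tm3, tm7 = tm7)
  if (anyDuplicated(anchors))
    stop("the four anchor residues must be distinct")
  structure(list(anchors = anchors, receptor_class = receptor_class),
            class = "delta_spec")
}

#' @export
print.delta_spec <- function(x, ...) {
  cat("delta_spec (class ", x$receptor_class, "): d1 = ",
      x$anchors["tm2"], " <-> ", x$anchors["tm6"], ",  d2 = ",
      x$anchors["tm3"], " <-> ", x$anchors["tm7"], "\n", sep = "")
  invisible(x)
}

DELTA_PRESETS <- list(
  beta2AR = list(class = "A", numbers = c(tm2 = 70, tm6 = 276, tm3 = 125, tm7 = 325),
                 aa = c(tm2 = "Y", tm6 = "G", tm3 = "C", tm7 = "I"),
                 gpcrdb = c("2x41", "6x38", "3x44", "7x52")),
  GCGR    = list(class = "B", numbers = c(tm2 = 175, tm6 = 347, tm3 = 243, tm7 = 398),
                 aa = c(tm2 = "A", tm6 = "L", tm3 = "L", tm7 = "V"),
                 gpcrdb = c("2x41", "6x33", "3x44", "7x51")),
  M2      = list(class = "A", numbers = c(tm2 = 60, tm6 = 390, tm3 = 115, tm7 = 439),
                 aa = c(tm2 = "Y", tm6 = "L", tm3 = "L", tm7 = "C"),
                 gpcrdb = c("2x41", "6x38", "3x44", "7x52"))
)

#' Resolve a receptor preset (or explicit anchors) against an ensemble
#'
#' For a preset, the four author residue numbers are looked up in the
#' ensemble's common residues (an absent anchor is an error naming the
#' residue; a residue-name mismatch with the preset's expected amino acid
#' is a warning).  Explicit anchors are verified for presence only.
#'
#' @param preset `"beta2AR"`, `"GCGR"`, `"M2"`, or `NULL` when `anchors`
#'   is given.
#' @param ensemble a `StructureEnsemble`.
#' @param anchors four explicit residue ids, ordered (tm2, tm6, tm3, tm7).
#' @return a [delta_spec()].
#' @export
resolve_delta_spec <- function(preset = NULL, ensemble, anchors = NULL) {
  res <- ensemble$residues
  if (!is.null(anchors)) {
    stopifnot(length(anchors) == 4L)
    missing <- setdiff(anchors, res$id)
    if (length(missing) > 0L)
      stop("anchor residue(s) absent from ensemble: ",
           paste(missing, collapse = ", "))
    return(delta_spec(anchors[1], anchors[2], anchors[3], anchors[4]))
  }
  if (is.null(preset) || !preset %in% names(DELTA_PRESETS))
    stop("unknown preset; use one of ",
         paste(names(DELTA_PRESETS), collapse = ", "),
         " or supply explicit anchors")
  p <- DELTA_PRESETS[[preset]]
  ids <- character(4); names(ids) <- names(p$numbers)
  for (k in names(p$numbers)) {
    hit <- which(res$number == p$numbers[[k]] & res$insert == "")
    if (length(hit) == 0L)
      stop("preset '", preset, "' anchor residue ", p$numbers[[k]],
           " (", k, ") absent from ensemble")
    if (length(hit) > 1L)
      stop("anchor residue number ", p$numbers[[k]],
           " is ambiguous across chains; filter to one chain")
    expected <- AA1TO3[[p$aa[[k]]]]
    if (!is.na(res$name[hit]) && res$name[hit] != expected)
      warning("preset '", preset, "' expects ", expected, " at residue ",
              p$numbers[[k]], " but ensemble has ", res$name[hit])
    ids[k] <- res$id[hit]
  }
  sp <- delta_spec(ids[["tm2"]], ids[["tm6"]], ids[["tm3"]], ids[["tm7"]],
                   receptor_class = p$class)
  sp$gpcrdb <- p$gpcrdb
  sp
}

#' Compute the activation variable per frame
#'
#' `d1` is the C-alpha distance between the TM2 and TM6 anchors, `d2`
#' between the TM3 and TM7 anchors; `delta = d1 - d2`, all in Angstrom.
#'
#' @param ensemble a `StructureEnsemble`.
#' @param spec a [delta_spec()] whose anchors are present in the ensemble.
#' @return a data.frame of class `delta_series` with columns `frame`,
#'   `d1`, `d2`, `delta`; the spec is kept as attribute `"spec"`.
#' @export
compute_delta <- function(ensemble, spec) {
  stopifnot(inherits(spec, "delta_spec"))
  idx <- match(spec$anchors, ensemble$residues$id)
  if (anyNA(idx))
    stop("anchor residue(s) absent from ensemble: ",
         paste(spec$anchors[is.na(idx)], collapse = ", "))
  pdist <- function(i, j) {
    a <- matrix(ensemble$xyz[i, , ], nrow = 3L)  # 3 x n_frames
    b <- matrix(ensemble$xyz[j, , ], nrow = 3L)
    sqrt(colSums((a - b)^2))
  }
  d1 <- pdist(idx[1], idx[2])
  d2 <- pdist(idx[3], idx[4])
  out <- data.frame(frame = ensemble$frames$label,
                    d1 = d1, d2 = d2, delta = d1 - d2,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  class(out) <- c("delta_series", "data.frame")
  out
}

#' Classify conformational state from the activation variable
#'
#' `"active"` when `delta > active_threshold`, `"inactive"` when
#' `delta < inactive_threshold`, otherwise `"intermediate"`.  The default
#' thresholds (8 and 0 Angstrom) reflect the separation observed between
#' experimental beta2AR structures; they are reporting aids only and never
#' enter the coupling computation.
#'
#' @param series a `delta_series` (or numeric vector of delta values).
#' @param active_threshold,inactive_threshold Angstrom.
#' @return character vector of per-frame state labels.
#' @export
classify_state <- function(series, active_threshold = 8,
                           inactive_threshold = 0) {
  stopifnot(active_threshold > inactive_threshold)
  d <- if (is.data.frame(series)) series$delta else as.numeric(series)
  ifelse(d > active_threshold, "active",
         ifelse(d < inactive_threshold, "inactive", "intermediate"))
}

#' Write a per-frame activation-variable table
#'
#' Tab-separated columns: frame label, d1, d2, delta, state.
#'
#' @param series a `delta_series`.
#' @param file output path.
#' @param ... passed to [classify_state()].
#' @return `file`, invisibly.
#' @export
write_delta_table <- function(series, file, ...) {
  out <- cbind(series, state = classify_state(series, ...))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
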