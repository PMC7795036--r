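#' Per-frame inter-residue C-alpha distance series
#'
#' Computes the Euclidean C-alpha distance between requested residue pairs
#' in every frame.  Pairs are stored in canonical order (first residue
#' before the second in common-residue order).
#'
#' @param ensemble a `StructureEnsemble`.
#' @param pairs `NULL` for all unordered pairs, or a two-column matrix /
#'   data.frame of residue ids.
#' @return list of class `distance_series`: `pairs` (data.frame `i`, `j`)
#'   and `values` (matrix `n_frames x n_pairs`, Angstrom).
#' @export
compute_distance_series <- function(ensemble, pairs = NULL) {
  ids <- ensemble$residues$id
  n <- length(ids)
  nf <- n_frames(ensemble)
  if (is.null(pairs)) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ii <- ij[, 1]; jj <- ij[, 2]
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    ii <- match(pairs[, 1], ids); jj <- match(pairs[, 2], ids)
    if (anyNA(ii) || anyNA(jj))
      stop("pair references residue(s) outside the common residue set: ",
           paste(unique(pairs[is.na(ii) | is.na(jj)]), collapse = ", "))
    if (any(ii == jj)) stop("pair with identical residues requested")
    swap <- ii > jj
    tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  }
  vals <- matrix(NA_real_, nf, length(ii))
  for (f in seq_len(nf)) {
    X <- ensemble$xyz[, , f]
    vals[f, ] <- sqrt(rowSums((X[ii, , drop = FALSE] -
                                 X[jj, , drop = FALSE])^2))
  }
  structure(list(pairs = data.frame(i = ids[ii], j = ids[jj],
                                    stringsAsFactors = FALSE),
                 values = vals),
            class = "distance_series")
}

#' Correlation matrix between inter-residue distances and the activation
#' variable
#'
#' For every unordered residue pair (i, j), the Pearson correlation between
#' the per-frame C-alpha distance d_ij and the activation variable delta is
#' computed over the ensemble, giving a symmetric residue-by-residue
#' coupling matrix.  Entries whose distance series has zero variance are
#' undefined: they are flagged invalid (`NA` in `c`, `FALSE` in `valid`)
#' and contribute zero to downstream site sums while remaining in the pair
#' count.  All frames carry equal weight.
#'
#' @param ensemble a `StructureEnsemble` with at least 3 frames.
#' @param delta a `delta_series` from [compute_delta()] (or a numeric
#'   vector of per-frame values); must vary over the ensemble.
#' @param residues optional subset of residue ids to restrict the matrix to
#'   (e.g. the union of site residues).
#' @return list of class `coupling_matrix`: `residues` (data.frame),
#'   `c` (symmetric correlation matrix, `NA` where invalid), `valid`
#'   (logical matrix), `n_frames`, `n_invalid`.
#' @export
compute_coupling_matrix <- function(ensemble, delta, residues = NULL) {
  d <- if (is.data.frame(delta)) delta$delta else as.numeric(delta)
  nf <- n_frames(ensemble)
  if (nf < 3L) stop("at least 3 frames are required for correlations")
  if (length(d) != nf)
    stop("delta series length (", length(d), ") does not match frame count (",
         nf, ")")
  if (stats::sd(d) == 0)
    stop("collective variable constant over ensemble")
  sub <- ensemble
  if (!is.null(residues)) {
    idx <- match(residues, ensemble$residues$id)
    if (anyNA(idx))
      stop("residue(s) absent from ensemble: ",
           paste(residues[is.na(idx)], collapse = ", "))
    sub <- ensemble
    sub$residues <- ensemble$residues[idx, , drop = FALSE]
    sub$xyz <- ensemble$xyz[idx, , , drop = FALSE]
  }
  n <- n_residues(sub)
  ds <- compute_distance_series(sub)
  r <- suppressWarnings(as.numeric(stats::cor(ds$values, d)))
  ok <- !is.na(r)

  cm <- matrix(NA_real_, n, n,
               dimnames = list(sub$residues$id, sub$residues$id))
  vm <- matrix(FALSE, n, n, dimnames = dimnames(cm))
  # upper.tri(arr.ind) order used in compute_distance_series is column-major,
  # the same order in which upper-tri assignment fills a matrix
  cm[upper.tri(cm)] <- r
  vm[upper.tri(vm)] <- ok
  cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
  vm[lower.tri(vm)] <- t(vm)[lower.tri(vm)]
  structure(list(residues = sub$residues, c = cm, valid = vm,
                 n_frames = nf, n_invalid = sum(!ok)),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("coupling_matrix:", nrow(x$c), "residues,", x$n_frames, "frames")
  if (x$n_invalid > 0) cat(",", x$n_invalid, "invalid entries")
  cat("\n")
  v <- abs(x$c[upper.tri(x$c)])
  cat(sprintf("  |c|: mean %.3f, max %.3f\n",
              mean(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Mask of strong couplings
#'
#' `TRUE` where the coupling is valid and `|c|` strictly exceeds the
#' threshold (default 0.75, the visualization cutoff used for coupling-map
#' figures).
#'
#' @param matrix a `coupling_matrix`.
#' @param threshold strict absolute-correlation cutoff in (0, 1).
#' @return logical matrix.
#' @export
strong_coupling_mask <- function(matrix, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  m <- abs(matrix$c) > threshold & matrix$valid
  m[is.na(m)] <- FALSE
  m
}

#' Site coupling score
#'
#' The coupling of a site with N residues is the mean absolute correlation
#' over its N(N-1)/2 internal residue pairs:
#' `C_site = 2/(N(N-1)) * sum_{i<j} |c_ij|`.  Invalid (zero-variance)
#' entries contribute zero but stay in the denominator.  The pair with the
#' largest |c| is recorded as `top_pair`.
#'
#' @param matrix a `coupling_matrix` covering the site's residues.
#' @param site a `site_definition` (see [assign_site_residues()] /
#'   [load_site_lists()]) or a character vector of residue ids; a site
#'   needs at least 2 residues.
#' @param label site label when `site` is a plain residue vector.
#' @return list of class `site_coupling`: `site_label`, `residues`,
#'   `submatrix`, `c_site`, `n_pairs`, `top_pair` (`i`, `j`, `c`).
#' @export
compute_csite <- function(matrix, site, label = NULL) {
  if (inherits(site, "site_definition")) {
    ids <- site$residues
    if (is.null(label)) label <- site$site_label
  } else {
    ids <- as.character(site)
    if (is.null(label)) label <- "site"
  }
  ids <- unique(ids)
  if (length(ids) < 2L)
    stop("site '", label, "' too small to score (needs >= 2 residues)")
  idx <- match(ids, rownames(matrix$c))
  if (anyNA(idx))
    stop("site '", label, "' references residue(s) outside the coupling ",
         "matrix: ", paste(ids[is.na(idx)], collapse = ", "))
  sub <- matrix$c[idx, idx, drop = FALSE]
  subv <- matrix$valid[idx, idx, drop = FALSE]
  ut <- upper.tri(sub)
  vals <- ifelse(subv[ut], abs(sub[ut]), 0)
  n_pairs <- sum(ut)
  top <- NULL
  if (any(subv[ut])) {
    score <- ifelse(subv & ut, abs(sub), -Inf)
    k <- arrayInd(which.max(score), dim(score))
    top <- list(i = ids[k[1]], j = ids[k[2]], c = sub[k])
  }
  structure(list(site_label = label, residues = ids, submatrix = sub,
                 c_site = sum(vals) / n_pairs, n_pairs = n_pairs,
                 top_pair = top),
            class = "site_coupling")
}

#' Rank sites by coupling strength
#'
#' Sites are ordered by descending `C_site` (ties broken by ascending site
#' label); the unweighted arithmetic mean of the listed scores is computed,
#' and each site is flagged `above_mean` when its score strictly exceeds
#' that mean — the reporting rule under which known allosteric sites
#' cluster at the top of published rankings.  Comparison uses unrounded
#' values by default; `rounded = TRUE` compares two-decimal values as a
#' printed table would.
#'
#' @param scores a list of `site_coupling` objects, or a named numeric
#'   vector of C_site values (names are the site labels).
#' @param rounded compare rounded (2-decimal) values against the rounded
#'   mean instead of full-precision values.
#' @return data.frame of class `site_ranking`, ordered by rank, with
#'   columns `site_label`, `n_residues`, `c_site`, `rank`, `above_mean`,
#'   `top_pair_i`, `top_pair_j`, `top_pair_c`; the ranking mean is kept as
#'   attribute `"mean_c_site"`.
#' @examples
#' rank_sites(c(site4 = 0.76, site3 = 0.61, site7 = 0.60, site6 = 0.59,
#'              site5 = 0.50, site2 = 0.49, site8 = 0.44, site9 = 0.33,
#'              site1 = 0.31))
#' @export
rank_sites <- function(scores, rounded = FALSE) {
  if (is.numeric(scores)) {
    if (is.null(names(scores)) || anyDuplicated(names(scores)))
      stop("numeric scores must carry unique site labels as names")
    df <- data.frame(site_label = names(scores), n_residues = NA_integer_,
                     c_site = as.numeric(scores),
                     top_pair_i = NA_character_, top_pair_j = NA_character_,
                     top_pair_c = NA_real_, stringsAsFactors = FALSE)
  } else {
    stopifnot(length(scores) >= 1L,
              all(vapply(scores, inherits, TRUE, "site_coupling")))
    labs <- vapply(scores, `[[`, "", "site_label")
    if (anyDuplicated(labs)) stop("site labels must be unique")
    df <- data.frame(
      site_label = labs,
      n_residues = vapply(scores, function(s) length(s$residues), 1L),
      c_site = vapply(scores, `[[`, 1, "c_site"),
      top_pair_i = vapply(scores, function(s)
        if (is.null(s$top_pair)) NA_character_ else s$top_pair$i, ""),
      top_pair_j = vapply(scores, function(s)
        if (is.null(s$top_pair)) NA_character_ else s$top_pair$j, ""),
      top_pair_c = vapply(scores, function(s)
        if (is.null(s$top_pair)) NA_real_ else s$top_pair$c, 1),
      stringsAsFactors = FALSE)
  }
  mean_c <- mean(df$c_site)
  cmp <- if (rounded) round(df$c_site, 2) else df$c_site
  cmp_mean <- if (rounded) round(mean_c, 2) else mean_c
  df$above_mean <- cmp > cmp_mean
  ord <- order(-df$c_site, df$site_label)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("site_label", "n_residues", "c_site", "rank", "above_mean",
               "top_pair_i", "top_pair_j", "top_pair_c")]
  attr(df, "mean_c_site") <- mean_c
  class(df) <- c("site_ranking", "data.frame")
  df
}

#' @export
print.site_ranking <- function(x, ...) {
  cat("site ranking (mean C_site = ",
      sprintf("%.2f", attr(x, "mean_c_site")), "):\n", sep = "")
  out <- data.frame(rank = x$rank, site = x$site_label,
                    C_site = sprintf("%.2f", x$c_site),
                    above_mean = ifelse(x$above_mean, "*", ""))
  print(out, row.names = FALSE)
  invisible(x)
}

# ---- exports ---------------------------------------------------------------

#' Export a coupling matrix
#'
#' `"wide"` writes the square matrix with residue-id header row and column;
#' `"long"` writes one row per unordered pair (`res_i`, `res_j`, `c`,
#' `valid`); `"strong"` writes the wide matrix with entries blanked where
#' `|c|` does not exceed `threshold` (the coupling-map figure analog).
#'
#' @param matrix a `coupling_matrix`.
#' @param file output path.
#' @param format `"wide"`, `"long"` or `"strong"`.
#' @param threshold strict cutoff used by `"strong"`.
#' @return `file`, invisibly.
#' @export
export_coupling_matrix <- function(matrix, file,
                                   format = c("wide", "long", "strong"),
                                   threshold = 0.75) {
  format <- match.arg(format)
  if (format == "long") {
    ut <- which(upper.tri(matrix$c), arr.ind = TRUE)
    df <- data.frame(res_i = rownames(matrix$c)[ut[, 1]],
                     res_j = colnames(matrix$c)[ut[, 2]],
                     c = matrix$c[ut], valid = matrix$valid[ut])
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(file))
  }
  m <- matrix$c
  out <- matrix(sprintf("%.6f", m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  out[is.na(m)] <- ""
  diag(out) <- ""
  if (format == "strong") out[!strong_coupling_mask(matrix, threshold)] <- ""
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(file)
}

#' Export a site ranking as TSV or JSON
#'
#' @param ranking a `site_ranking`.
#' @param file output path.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
export_ranking <- function(ranking, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(ranking), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(mean_c_site = attr(ranking, "mean_c_site"),
           sites = as.data.frame(ranking)),
      file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(file)
}
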