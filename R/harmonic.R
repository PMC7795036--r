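#' Build a C-alpha anisotropic elastic network model
#'
#' Every pair of C-alpha atoms within `cutoff` is connected by a Hookean
#' spring of uniform stiffness `gamma`; the 3N x 3N Hessian is assembled
#' from the standard anisotropic-network super-blocks
#' `-gamma * (r r^T) / |r|^2` and diagonalized.  A connected,
#' non-collinear network has exactly six zero-frequency (rigid-body)
#' modes; all remaining eigenvalues are positive.  This coarse-grained
#' network is a deliberately simple surrogate for all-atom force-field
#' normal modes: it reproduces low-frequency collective motions, not local
#' chemistry.
#'
#' @param x a `StructureEnsemble` (one frame selected via `frame`) or an
#'   `n x 3` C-alpha coordinate matrix.
#' @param frame frame index when `x` is an ensemble.
#' @param cutoff interaction cutoff in Angstrom (default 13, standard ANM
#'   practice).
#' @param gamma uniform spring constant (arbitrary energy/A^2 units).
#' @return list of class `enm_model`: `residues`, `ref_xyz`, `cutoff`,
#'   `gamma`, `values` (ascending eigenvalues), `vectors` (orthonormal
#'   columns), `n_zero_modes`.
#' @export
build_enm <- function(x, frame = 1L, cutoff = 13, gamma = 1) {
  if (inherits(x, "StructureEnsemble")) {
    residues <- x$residues
    xyz <- x$xyz[, , frame]
  } else {
    xyz <- as.matrix(x)
    stopifnot(ncol(xyz) == 3L)
    residues <- data.frame(id = residue_id("A", seq_len(nrow(xyz))),
                           chain = "A", number = seq_len(nrow(xyz)),
                           insert = "", name = "ALA",
                           stringsAsFactors = FALSE)
  }
  n <- nrow(xyz)
  if (n < 2L) stop("at least 2 particles are required")
  dmat <- as.matrix(stats::dist(xyz))
  contact <- dmat <= cutoff & dmat > 0

  # connectivity (breadth-first search over the contact graph)
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(contact[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("elastic network disconnected at cutoff ", cutoff,
         " A; increase the cutoff")

  H <- matrix(0, 3L * n, 3L * n)
  pairs <- which(contact & upper.tri(contact), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- xyz[j, ] - xyz[i, ]
    blk <- -gamma * tcrossprod(r) / sum(r^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_len(3L * n))                  # ascending
  values <- pmax(eig$values[ord], 0)
  vectors <- eig$vectors[, ord, drop = FALSE]
  tol <- max(values) * 1e-8
  structure(list(residues = residues, ref_xyz = xyz, cutoff = cutoff,
                 gamma = gamma, values = values, vectors = vectors,
                 n_zero_modes = sum(values < tol)),
            class = "enm_model")
}

#' @export
print.enm_model <- function(x, ...) {
  cat("enm_model:", nrow(x$ref_xyz), "C-alpha nodes, cutoff",
      x$cutoff, "A,", x$n_zero_modes, "zero modes\n")
  nz <- x$values[x$values >= max(x$values) * 1e-8]
  cat(sprintf("  nonzero eigenvalues: %.4g .. %.4g\n", min(nz), max(nz)))
  invisible(x)
}

#' Generate a harmonic conformational ensemble from network modes
#'
#' Each frame displaces the reference structure along a random linear
#' combination of the `n_modes` lowest-frequency nonzero modes.  Mode
#' amplitudes are drawn independently per frame with variance
#' `temperature_scale / lambda_k` (equipartition over the harmonic wells),
#' so soft modes dominate; `amplitude = "sinusoid"` instead sweeps each
#' mode deterministically over one period with the same per-mode variance
#' (the oscillatory convention of classical NMA trajectory writers).
#'
#' @param model an `enm_model`.
#' @param n_frames number of frames (>= 2).
#' @param n_modes how many nonzero modes to combine; `NULL` uses
#'   `min(100, available)`.  Requesting more than available is an error.
#' @param temperature_scale multiplies every per-mode variance; 0 returns
#'   copies of the reference.
#' @param seed optional RNG seed for reproducible ensembles.
#' @param amplitude `"gaussian"` or `"sinusoid"`.
#' @param state conformational-state tag stored on every frame.
#' @return a `StructureEnsemble` (C-alpha only) with attributes
#'   `modes_used`, `amplitude_rule`, `seed`.
#' @export
generate_harmonic_trajectory <- function(model, n_frames, n_modes = NULL,
                                         temperature_scale = 1, seed = NULL,
                                         amplitude = c("gaussian", "sinusoid"),
                                         state = "unknown") {
  amplitude <- match.arg(amplitude)
  stopifnot(inherits(model, "enm_model"), n_frames >= 2L)
  avail <- length(model$values) - model$n_zero_modes
  if (is.null(n_modes)) n_modes <- min(100L, avail)
  if (n_modes > avail)
    stop("requested ", n_modes, " modes but only ", avail,
         " nonzero modes are available")
  modes <- model$n_zero_modes + seq_len(n_modes)
  lambda <- model$values[modes]
  sdk <- sqrt(temperature_scale / lambda)
  if (!is.null(seed)) set.seed(seed)
  A <- if (amplitude == "gaussian") {
    matrix(stats::rnorm(n_frames * n_modes), n_frames, n_modes) *
      rep(sdk, each = n_frames)
  } else {
    phase <- 2 * pi * (seq_len(n_modes) - 1) / n_modes
    t(vapply(seq_len(n_frames), function(f)
      sqrt(2) * sdk * sin(2 * pi * f / n_frames + phase),
      numeric(n_modes)))
  }
  disp <- model$vectors[, modes, drop = FALSE] %*% t(A)  # 3N x n_frames
  n <- nrow(model$ref_xyz)
  xyz <- array(NA_real_, c(n, 3L, n_frames))
  ref <- as.numeric(t(model$ref_xyz))
  for (f in seq_len(n_frames))
    xyz[, , f] <- matrix(ref + disp[, f], ncol = 3L, byrow = TRUE)
  frames <- data.frame(label = paste0(state, "_", seq_len(n_frames)),
                       source = "harmonic", state = state,
                       stringsAsFactors = FALSE)
  ens <- new_structure_ensemble(model$residues, xyz, frames)
  attr(ens, "modes_used") <- n_modes
  attr(ens, "amplitude_rule") <- amplitude
  attr(ens, "seed") <- seed
  ens
}

#' Two-state harmonic ensemble
#'
#' Builds an elastic network for the inactive and (optionally) the active
#' conformation, generates a harmonic trajectory from each, and
#' concatenates them into one mixed ensemble — the desk-scale analog of
#' pooling normal-mode trajectories of both conformational states so the
#' activation transition dominates the distance fluctuations.  With
#' `active = NULL` a single-state ensemble is returned (the
#' "inactive-only" experiment).
#'
#' @param inactive,active `StructureEnsemble`s (frame 1 used) or `n x 3`
#'   C-alpha matrices sharing a residue universe.
#' @param n_frames_per_state frames generated per state.
#' @param cutoff,gamma elastic-network parameters (see [build_enm()]).
#' @param n_modes,temperature_scale,amplitude
#'   see [generate_harmonic_trajectory()].
#' @param seed RNG seed; the active-state trajectory uses `seed + 1`.
#' @return a `StructureEnsemble` with state tags `"inactive"`/`"active"`.
#' @export
make_two_state_harmonic_ensemble <- function(inactive, active = NULL,
                                             n_frames_per_state = 500L,
                                             cutoff = 13, gamma = 1,
                                             n_modes = NULL,
                                             temperature_scale = 1,
                                             seed = NULL,
                                             amplitude = "gaussian") {
  gen <- function(x, st, sd) {
    m <- build_enm(x, cutoff = cutoff, gamma = gamma)
    generate_harmonic_trajectory(m, n_frames = n_frames_per_state,
                                 n_modes = n_modes,
                                 temperature_scale = temperature_scale,
                                 seed = sd, amplitude = amplitude,
                                 state = st)
  }
  ei <- gen(inactive, "inactive", seed)
  if (is.null(active)) return(ei)
  ea <- gen(active, "active", if (is.null(seed)) NULL else seed + 1L)
  concatenate_ensembles(ei, ea)
}
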