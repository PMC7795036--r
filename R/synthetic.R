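#' Specification of a synthetic two-state toy receptor
#'
#' Defines an idealized C-alpha helical bundle (default: 7 helices on a
#' circle, mimicking a 7TM receptor's topology at the level of distance
#' statistics only) together with a planted activation signal:
#' a latent per-frame activation coordinate lambda (0 = inactive,
#' 1 = active) moves the TM6 anchor outward and the TM3/TM7 anchors toward
#' each other so that the activation variable changes by exactly
#' `activation_gap` between the pure states, and displaces the residues of
#' one "coupled" site radially outward from the bundle axis so that every
#' internal pair distance of that site is a deterministic, near-linear
#' function of lambda whose mean rate is calibrated to `coupling_slope`
#' Angstrom per Angstrom of activation-variable change.  Decoy sites
#' receive only the i.i.d. Gaussian coordinate
#' noise shared by all residues.  Everything is deterministic given
#' `seed`.
#'
#' @param n_helices,residues_per_helix bundle topology.
#' @param activation_gap difference in the activation variable between
#'   pure active and pure inactive geometry, Angstrom (> 0).
#' @param noise_sigma standard deviation of the per-coordinate Gaussian
#'   noise, Angstrom (>= 0).
#' @param n_frames_per_state frames per pure state.
#' @param n_intermediate_frames frames with lambda drawn uniformly in
#'   (0, 1); 0 by default (experimental ensembles are effectively
#'   bimodal).
#' @param coupling_slope mean site-internal distance change (Angstrom) per
#'   Angstrom of change in the activation variable, for the coupled site.
#' @param anchor_helices which helices carry the TM2/TM6/TM3/TM7 anchors
#'   (mid-helix residue of each).
#' @param coupled_site,decoy_sites residue index vectors (global indices
#'   into the bundle); `NULL` picks defaults disjoint from the anchors.
#' @param bundle_radius,helix_radius,rise,twist ideal-helix geometry:
#'   spoke circle radius, helix radius (A), rise per residue (A) and twist
#'   per residue (degrees).
#' @param seed RNG seed.
#' @return list of class `toy_receptor_spec`.
#' @export
toy_receptor_spec <- function(n_helices = 7L, residues_per_helix = 10L,
                              activation_gap = 8, noise_sigma = 0.2,
                              n_frames_per_state = 50L,
                              n_intermediate_frames = 0L,
                              coupling_slope = 1,
                              anchor_helices = c(tm2 = 2L, tm6 = 6L,
                                                 tm3 = 3L, tm7 = 7L),
                              coupled_site = NULL, decoy_sites = NULL,
                              bundle_radius = 11, helix_radius = 2.3,
                              rise = 1.5, twist = 100, seed = 1L) {
  stopifnot(activation_gap > 0, noise_sigma >= 0, n_helices >= 4L,
            residues_per_helix >= 3L, n_frames_per_state >= 1L)
  rph <- as.integer(residues_per_helix)
  mid <- as.integer(ceiling(rph / 2))
  gidx <- function(h, r) (h - 1L) * rph + r
  anchors <- vapply(anchor_helices, gidx, 1L, r = mid)
  if (is.null(coupled_site))
    coupled_site <- c(gidx(4L, mid + c(-1L, 0L, 1L)),
                      gidx(5L, mid + c(-1L, 0L, 1L)))
  if (is.null(decoy_sites))
    decoy_sites <- list(
      decoy1 = c(gidx(1L, c(2L, 3L, 4L)), gidx(2L, rph - c(2L, 1L, 0L))),
      decoy2 = c(gidx(6L, c(1L, 2L, 3L)), gidx(7L, rph - c(2L, 1L, 0L))))
  if (length(decoy_sites) > 0L && is.null(names(decoy_sites)))
    names(decoy_sites) <- paste0("decoy", seq_along(decoy_sites))
  site_res <- c(coupled_site, unlist(decoy_sites))
  if (any(anchors %in% site_res))
    stop("coupled/decoy sites must be disjoint from the anchor residues")
  nres <- n_helices * rph
  if (any(site_res < 1L | site_res > nres) || anyDuplicated(site_res))
    stop("invalid or overlapping site residue indices")
  structure(list(n_helices = as.integer(n_helices),
                 residues_per_helix = rph,
                 activation_gap = activation_gap,
                 noise_sigma = noise_sigma,
                 n_frames_per_state = as.integer(n_frames_per_state),
                 n_intermediate_frames = as.integer(n_intermediate_frames),
                 coupling_slope = coupling_slope,
                 anchors = anchors, coupled_site = coupled_site,
                 decoy_sites = decoy_sites,
                 bundle_radius = bundle_radius,
                 helix_radius = helix_radius, rise = rise, twist = twist,
                 seed = as.integer(seed)),
            class = "toy_receptor_spec")
}

# ideal C-alpha trace of the bundle: one vertical helix per spoke
.toy_base_coords <- function(spec) {
  rph <- spec$residues_per_helix
  coords <- matrix(NA_real_, spec$n_helices * rph, 3L)
  for (h in seq_len(spec$n_helices)) {
    th <- 2 * pi * (h - 1) / spec$n_helices
    cx <- spec$bundle_radius * cos(th)
    cy <- spec$bundle_radius * sin(th)
    k <- seq_len(rph)
    ang <- (k - 1) * spec$twist * pi / 180 + th
    coords[(h - 1) * rph + k, ] <- cbind(
      cx + spec$helix_radius * cos(ang),
      cy + spec$helix_radius * sin(ang),
      (k - 1) * spec$rise - (rph - 1) * spec$rise / 2)
  }
  coords
}

#' Generate a synthetic two-state toy ensemble with known ground truth
#'
#' See [toy_receptor_spec()] for the construction.  Frames are ordered
#' inactive block, active block, then any intermediate frames.  Frames in
#' which any inter-residue C-alpha distance falls below 1 Angstrom have
#' their noise redrawn (at most 10 attempts per frame, then an error);
#' determinism under a fixed seed is preserved because redraws consume the
#' same RNG stream.
#'
#' @param spec a `toy_receptor_spec`.
#' @return list with elements `ensemble` (a `StructureEnsemble`) and
#'   `truth`: per-frame `lambda`, the anchor ids, a [delta_spec()], the
#'   site definitions (`sites`, coupled first), and the generator
#'   parameters.
#' @export
generate_toy_ensemble <- function(spec) {
  stopifnot(inherits(spec, "toy_receptor_spec"))
  base <- .toy_base_coords(spec)
  n <- nrow(base)
  ids <- residue_id("A", seq_len(n))
  residues <- data.frame(id = ids, chain = "A", number = seq_len(n),
                         insert = "", name = "ALA",
                         stringsAsFactors = FALSE)
  a <- spec$anchors
  g <- spec$activation_gap
  u1 <- base[a["tm6"], ] - base[a["tm2"], ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- base[a["tm7"], ] - base[a["tm3"], ]; u2 <- u2 / sqrt(sum(u2^2))
  d2_0 <- sqrt(sum((base[a["tm7"], ] - base[a["tm3"], ])^2))
  if (d2_0 <= g / 2)
    stop("activation gap too large for the bundle geometry (d2 would ",
         "collapse); increase bundle_radius or reduce activation_gap")
  cs <- spec$coupled_site
  # coupled-site deformation: each site residue moves radially outward
  # from the bundle axis (fixed per-residue direction, so every internal
  # distance is a deterministic, near-linear function of lambda and the
  # motion points into empty space outside the bundle, never toward other
  # residues).  The displacement magnitude is calibrated so the mean
  # internal pair distance changes by exactly coupling_slope Angstrom per
  # Angstrom of activation-variable change.
  rdir <- base[cs, , drop = FALSE]
  rdir[, 3] <- 0
  rdir <- rdir / sqrt(rowSums(rdir^2))
  site_shift <- function(M, amount) M + amount * rdir
  d0m <- mean(stats::dist(base[cs, , drop = FALSE]))
  mean_gain <- function(m)
    mean(stats::dist(site_shift(base[cs, , drop = FALSE], m))) - d0m
  site_amp <- if (spec$coupling_slope == 0) 0 else
    stats::uniroot(function(m) mean_gain(m) - spec$coupling_slope * g,
                   c(0, 200), tol = 1e-10)$root

  set.seed(spec$seed)
  lambda <- c(rep(0, spec$n_frames_per_state),
              rep(1, spec$n_frames_per_state),
              if (spec$n_intermediate_frames > 0L)
                stats::runif(spec$n_intermediate_frames))
  nf <- length(lambda)
  xyz <- array(NA_real_, c(n, 3L, nf))
  redraws <- 0L
  for (f in seq_len(nf)) {
    lam <- lambda[f]
    det_coords <- base
    det_coords[a["tm6"], ] <- det_coords[a["tm6"], ] + (g / 2) * lam * u1
    det_coords[a["tm7"], ] <- det_coords[a["tm7"], ] - (g / 4) * lam * u2
    det_coords[a["tm3"], ] <- det_coords[a["tm3"], ] + (g / 4) * lam * u2
    det_coords[cs, ] <- site_shift(det_coords[cs, , drop = FALSE],
                                   site_amp * lam)
    for (attempt in seq_len(10L)) {
      fr <- det_coords + matrix(stats::rnorm(3L * n, 0, spec$noise_sigma),
                                n, 3L)
      if (min(stats::dist(fr)) >= 1) break
      redraws <- redraws + 1L
      if (attempt == 10L)
        stop("persistent inter-residue collisions (< 1 A) in frame ", f,
             "; reduce noise_sigma")
    }
    xyz[, , f] <- fr
  }
  if (redraws > 0L)
    warning("redrew noise for ", redraws,
            " frame attempt(s) after inter-residue collisions")
  state <- ifelse(lambda == 0, "inactive",
                  ifelse(lambda == 1, "active", "intermediate"))
  frames <- data.frame(label = paste0(state, "_", seq_len(nf)),
                       source = "synthetic", state = state,
                       stringsAsFactors = FALSE)
  ens <- new_structure_ensemble(residues, xyz, frames)
  sites <- c(list(site_definition("coupled", ids[cs])),
             lapply(names(spec$decoy_sites), function(lb)
               site_definition(lb, ids[spec$decoy_sites[[lb]]])))
  truth <- list(lambda = lambda,
                anchors = stats::setNames(ids[a], names(a)),
                delta_spec = delta_spec(ids[a["tm2"]], ids[a["tm6"]],
                                        ids[a["tm3"]], ids[a["tm7"]]),
                sites = sites, expected_top = "coupled",
                activation_gap = g, coupling_slope = spec$coupling_slope,
                noise_sigma = spec$noise_sigma, seed = spec$seed)
  list(ensemble = ens, truth = truth)
}

#' Write a self-contained fixture bundle to disk
#'
#' Files written: `ensemble.pdb` (multi-MODEL C-alpha trace),
#' `sites.json` (site residue lists), `ground_truth.json` (per-frame
#' lambda, anchors, expected top site, generator parameters) and
#' `pockets.pdb` (a synthetic dummy-atom cloud per site in the
#' fpocket/Mdpocket dialect, built from per-frame site centroids, which
#' exercises the pocket parser and residue-assignment path).
#'
#' @param toy result of [generate_toy_ensemble()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(toy, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- toy$ensemble
  paths <- c(ensemble = file.path(out_dir, "ensemble.pdb"),
             sites = file.path(out_dir, "sites.json"),
             truth = file.path(out_dir, "ground_truth.json"),
             pockets = file.path(out_dir, "pockets.pdb"))
  write_ensemble_pdb(ens, paths[["ensemble"]])
  write_site_lists(toy$truth$sites, paths[["sites"]])
  jsonlite::write_json(
    list(lambda = toy$truth$lambda,
         anchors = as.list(toy$truth$anchors),
         expected_top = toy$truth$expected_top,
         activation_gap = toy$truth$activation_gap,
         coupling_slope = toy$truth$coupling_slope,
         noise_sigma = toy$truth$noise_sigma,
         seed = toy$truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1))
  clouds <- lapply(seq_along(toy$truth$sites), function(s) {
    site <- toy$truth$sites[[s]]
    idx <- match(site$residues, ens$residues$id)
    frames <- lapply(seq_len(n_frames(ens)), function(f) {
      ctr <- colMeans(ens$xyz[idx, , f, drop = FALSE][, , 1])
      sweep(offs, 2, ctr, "+")
    })
    structure(list(site_label = as.character(s), frames = frames,
                   source = "synthetic", presence_fraction = 1),
              class = "pocket_cloud")
  })
  write_pocket_pdb(clouds, paths[["pockets"]])
  invisible(paths)
}
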