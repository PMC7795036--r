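# Independent brute-force oracles and small fixture builders.  Everything
# here is deliberately written the slow, obvious way, independent of the
# package's vectorized implementations.

# textbook two-pass Pearson correlation
pearson_twopass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# all-pairs Euclidean distance matrix by explicit loops
brute_distance_matrix <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

# full pipeline oracle: distances -> Pearson vs delta -> mean |c| of a site
brute_site_coupling <- function(xyz_array, delta, site_idx) {
  n <- length(site_idx)
  total <- 0; npair <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- vapply(seq_len(dim(xyz_array)[3]), function(f)
        sqrt(sum((xyz_array[site_idx[a], , f] -
                    xyz_array[site_idx[b], , f])^2)), numeric(1))
      npair <- npair + 1
      if (stats::sd(d) > 0) total <- total + abs(pearson_twopass(d, delta))
    }
  }
  total / npair
}

# Horn's closed-form quaternion superposition; returns the optimal RMSD of
# P onto Q (independent of the package's SVD-based Kabsch)
quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P0, Q0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  mu <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * mu) / nrow(P)
  sqrt(max(msd, 0))
}

# all-pairs assignment oracle: ids of residues with any atom within cutoff
# (inclusive) of any dummy point
brute_assign <- function(atom_xyz, atom_ids, dummy_xyz, cutoff) {
  hits <- character(0)
  for (a in seq_len(nrow(atom_xyz))) {
    for (b in seq_len(nrow(dummy_xyz))) {
      if (sqrt(sum((atom_xyz[a, ] - dummy_xyz[b, ])^2)) <= cutoff) {
        hits <- c(hits, atom_ids[a])
        break
      }
    }
  }
  unique(hits)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small random ensemble: jittered copies of a random base structure
random_ensemble <- function(n_res = 6, n_frames = 5, seed = 1,
                            spread = 10, jitter = 0.5) {
  set.seed(seed)
  base <- matrix(stats::runif(n_res * 3, 0, spread), n_res, 3)
  xyz <- array(NA_real_, c(n_res, 3, n_frames))
  for (f in seq_len(n_frames))
    xyz[, , f] <- base + matrix(stats::rnorm(n_res * 3, 0, jitter), n_res, 3)
  residues <- data.frame(id = residue_id("A", seq_len(n_res)),
                         chain = "A", number = seq_len(n_res), insert = "",
                         name = "ALA", stringsAsFactors = FALSE)
  frames <- data.frame(label = paste0("f", seq_len(n_frames)),
                       source = "synthetic", state = "unknown",
                       stringsAsFactors = FALSE)
  new_structure_ensemble(residues, xyz, frames)
}

# hand-built coupling_matrix from an explicit symmetric matrix
fake_coupling_matrix <- function(cmat, valid = NULL) {
  n <- nrow(cmat)
  ids <- residue_id("A", seq_len(n))
  dimnames(cmat) <- list(ids, ids)
  if (is.null(valid)) valid <- !is.na(cmat)
  diag(valid) <- FALSE
  dimnames(valid) <- dimnames(cmat)
  structure(list(residues = data.frame(id = ids, chain = "A",
                                       number = seq_len(n), insert = "",
                                       name = "ALA",
                                       stringsAsFactors = FALSE),
                 c = cmat, valid = valid, n_frames = NA_integer_,
                 n_invalid = sum(!valid[upper.tri(valid)])),
            class = "coupling_matrix")
}

# write a single-model PDB with the given residue numbers (chain A, CA only)
write_test_pdb <- function(file, resno, coords, chain = "A",
                           resid = "ALA") {
  bio3d::write.pdb(file = file, xyz = as.numeric(t(coords)),
                   resno = resno, chain = rep(chain, length(resno)),
                   resid = rep(resid, length.out = length(resno)),
                   elety = rep("CA", length(resno)))
}
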