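test_that("distance series match brute-force distances", {
  # fixed 3-4-5 geometry gives a constant 5 A series
  ens <- random_ensemble(n_res = 2, n_frames = 4, seed = 1, jitter = 0)
  ens$xyz[1, , ] <- 0
  ens$xyz[2, , ] <- c(3, 4, 0)
  ds <- compute_distance_series(ens)
  expect_equal(as.numeric(ds$values), rep(5, 4))

  # random ensembles: every entry equals the brute-force matrix
  ens <- random_ensemble(n_res = 6, n_frames = 5, seed = 2)
  ds <- compute_distance_series(ens)
  for (f in 1:5) {
    D <- brute_distance_matrix(ens$xyz[, , f])
    for (p in seq_len(nrow(ds$pairs))) {
      i <- match(ds$pairs$i[p], ens$residues$id)
      j <- match(ds$pairs$j[p], ens$residues$id)
      expect_equal(ds$values[f, p], D[i, j], tolerance = 1e-10)
    }
  }

  # self-pairs and unknown residues are rejected
  expect_error(compute_distance_series(ens, cbind("A:1", "A:1")),
               "identical")
  expect_error(compute_distance_series(ens, cbind("A:1", "Z:9")),
               "outside")
})

test_that("perfect linear distance-delta dependence gives c of exactly +-1", {
  nf <- 10
  delta <- seq(-3, 6, length.out = nf)
  ens <- random_ensemble(n_res = 3, n_frames = nf, seed = 3, jitter = 0)
  ens$xyz[, , ] <- 0
  ens$xyz[2, 1, ] <- 2 * delta + 7     # d(1,2) = 2*delta + 7
  ens$xyz[3, 2, ] <- -delta + 100      # d(1,3) = -delta + 100
  cm <- compute_coupling_matrix(ens, delta)
  expect_equal(cm$c["A:1", "A:2"], 1.0)
  expect_equal(cm$c["A:1", "A:3"], -1.0)
})

test_that("coupling entries match a two-pass Pearson oracle", {
  ens <- random_ensemble(n_res = 6, n_frames = 20, seed = 4)
  set.seed(5)
  delta <- rnorm(20)
  cm <- compute_coupling_matrix(ens, delta)
  ids <- ens$residues$id
  for (i in 1:5) for (j in (i + 1):6) {
    d <- vapply(1:20, function(f)
      sqrt(sum((ens$xyz[i, , f] - ens$xyz[j, , f])^2)), numeric(1))
    expect_equal(cm$c[ids[i], ids[j]], pearson_twopass(d, delta),
                 tolerance = 1e-10)
  }
  expect_true(isSymmetric(cm$c))
  expect_true(all(abs(cm$c[upper.tri(cm$c)]) <= 1))
})

test_that("zero-variance distances are flagged invalid, constant delta errors", {
  ens <- random_ensemble(n_res = 4, n_frames = 8, seed = 6)
  ens$xyz[1, , ] <- 0          # residues 1 and 2 never move:
  ens$xyz[2, , ] <- c(3, 0, 0) # d(1,2) has zero variance
  cm <- compute_coupling_matrix(ens, rnorm(8))
  expect_false(cm$valid["A:1", "A:2"])
  expect_true(is.na(cm$c["A:1", "A:2"]))
  expect_equal(cm$n_invalid, 1)
  # invalid entries contribute zero but stay in the pair count
  cs <- compute_csite(cm, c("A:1", "A:2", "A:3"))
  manual <- (0 + abs(cm$c["A:1", "A:3"]) + abs(cm$c["A:2", "A:3"])) / 3
  expect_equal(cs$c_site, manual)
  expect_error(compute_coupling_matrix(ens, rep(1, 8)),
               "constant over ensemble")
  expect_error(compute_coupling_matrix(ens, rnorm(7)), "frame count")
})

test_that("coupling matrix is invariant to rigid motion, frame order and duplication", {
  toy <- generate_toy_ensemble(toy_receptor_spec(
    residues_per_helix = 7, n_frames_per_state = 10, seed = 7))
  ens <- toy$ensemble
  dl <- compute_delta(ens, toy$truth$delta_spec)
  cm <- compute_coupling_matrix(ens, dl)

  # per-frame random rigid motions
  set.seed(8)
  moved <- ens
  for (f in seq_len(n_frames(ens)))
    moved$xyz[, , f] <- ens$xyz[, , f] %*% random_rotation() +
      rep(rnorm(3, 0, 20), each = n_residues(ens))
  cm_moved <- compute_coupling_matrix(moved, compute_delta(moved, toy$truth$delta_spec))
  expect_lt(max(abs(cm_moved$c - cm$c), na.rm = TRUE), 1e-9)

  # frame permutation (together with delta)
  perm <- sample(n_frames(ens))
  pens <- ens; pens$xyz <- ens$xyz[, , perm]; pens$frames <- ens$frames[perm, ]
  cm_perm <- compute_coupling_matrix(pens, dl$delta[perm])
  expect_equal(cm_perm$c, cm$c)

  # duplication
  dup <- concatenate_ensembles(ens, ens)
  cm_dup <- compute_coupling_matrix(dup, c(dl$delta, dl$delta))
  expect_lt(max(abs(cm_dup$c - cm$c), na.rm = TRUE), 1e-12)
})

test_that("strong-coupling mask uses a strict threshold on valid entries", {
  cm <- fake_coupling_matrix(rbind(c(NA, 0.76, 0.75),
                                   c(0.76, NA, -0.80),
                                   c(0.75, -0.80, NA)))
  m <- strong_coupling_mask(cm)
  expect_true(m["A:1", "A:2"])     # 0.76 > 0.75
  expect_false(m["A:1", "A:3"])    # 0.75 is not strict
  expect_true(m["A:2", "A:3"])     # |-0.80|
  expect_false(any(strong_coupling_mask(fake_coupling_matrix(
    matrix(0, 3, 3)))))
  expect_error(strong_coupling_mask(cm, threshold = 0))
})

test_that("site scores follow the mean-absolute-coupling formula", {
  cm <- fake_coupling_matrix(rbind(c(NA, 0.9, -0.6),
                                   c(0.9, NA, 0.3),
                                   c(-0.6, 0.3, NA)))
  cs <- compute_csite(cm, c("A:1", "A:2", "A:3"))
  expect_equal(cs$c_site, 0.6)
  expect_equal(cs$n_pairs, 3)
  expect_equal(cs$top_pair$i, "A:1")
  expect_equal(cs$top_pair$j, "A:2")
  expect_equal(cs$top_pair$c, 0.9)
  expect_true(all(abs(cs$submatrix[upper.tri(cs$submatrix)]) <=
                    abs(cs$top_pair$c)))

  # N = 2 site: the score is |c| of its single pair
  expect_equal(compute_csite(cm, c("A:1", "A:3"))$c_site, 0.6)
  # too-small site is an error
  expect_error(compute_csite(cm, "A:1"), "too small")
})

test_that("a constant-coupling site scores exactly |c|", {
  set.seed(9)
  for (N in 2:10) {
    cval <- runif(1, -1, 1)
    M <- matrix(cval, N, N); diag(M) <- NA
    cm <- fake_coupling_matrix(M)
    expect_equal(compute_csite(cm, residue_id("A", 1:N))$c_site, abs(cval))
  }
})

test_that("a union site is not the mean of its parts (cross-pairs count)", {
  # two 2-residue sites with internal couplings 0.9 and 0.5; all cross
  # couplings zero -> union score is pulled far below the part-mean
  M <- matrix(0, 4, 4); diag(M) <- NA
  M[1, 2] <- M[2, 1] <- 0.9
  M[3, 4] <- M[4, 3] <- 0.5
  cm <- fake_coupling_matrix(M)
  a <- compute_csite(cm, c("A:1", "A:2"))$c_site
  b <- compute_csite(cm, c("A:3", "A:4"))$c_site
  u <- compute_csite(cm, residue_id("A", 1:4))$c_site
  expect_equal(u, (0.9 + 0.5) / 6)
  expect_false(isTRUE(all.equal(u, mean(c(a, b)))))
})

test_that("ranking reproduces the printed nine-site arithmetic", {
  scores <- c(site4 = 0.76, site3 = 0.61, site7 = 0.60, site6 = 0.59,
              site5 = 0.50, site2 = 0.49, site8 = 0.44, site9 = 0.33,
              site1 = 0.31)
  r <- rank_sites(scores)
  expect_equal(r$site_label,
               paste0("site", c(4, 3, 7, 6, 5, 2, 8, 9, 1)))
  expect_equal(round(attr(r, "mean_c_site"), 2), 0.51)
  expect_setequal(r$site_label[r$above_mean],
                  c("site4", "site3", "site7", "site6"))
  expect_equal(r$rank, 1:9)
})

test_that("ranking handles single sites, ties and duplicate labels", {
  one <- rank_sites(c(only = 0.5))
  expect_equal(one$rank, 1)
  expect_false(one$above_mean)      # equal to the mean, strict rule
  tie <- rank_sites(c(b = 0.4, a = 0.4, c = 0.6))
  expect_equal(tie$site_label, c("c", "a", "b"))
  expect_error(rank_sites(c(a = 1, a = 2)), "unique")
})

test_that("exports round-trip through files", {
  toy <- generate_toy_ensemble(toy_receptor_spec(
    residues_per_helix = 7, n_frames_per_state = 5, seed = 11))
  cm <- compute_coupling_matrix(toy$ensemble,
                                compute_delta(toy$ensemble, toy$truth$delta_spec))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  export_coupling_matrix(cm, f1, "long")
  tab <- read.delim(f1)
  expect_equal(nrow(tab), choose(n_residues(toy$ensemble), 2))
  i1 <- match(tab$res_i[1], rownames(cm$c)); j1 <- match(tab$res_j[1], colnames(cm$c))
  expect_equal(tab$c[1], cm$c[i1, j1], tolerance = 1e-6)

  r <- rank_sites(lapply(toy$truth$sites, compute_csite, matrix = cm))
  f2 <- withr::local_tempfile(fileext = ".json")
  export_ranking(r, f2, "json")
  back <- jsonlite::fromJSON(f2)
  expect_equal(back$mean_c_site, attr(r, "mean_c_site"))
  expect_equal(back$sites$site_label, r$site_label)
})
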