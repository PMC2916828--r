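# Branch-and-bound search: seeds, extension, maxima, invariants.

simple_rep <- function() {
  parse_representation(c("def ALA CA", "def GLY CA", "def VAL CA",
                         "ALA GLY VAL"))
}

test_that("seed_pairs enumerates allowed unit pairs deterministically", {
  rep <- rep_preset("coarse_ca")
  a <- make_ps(matrix(rnorm(9), ncol = 3), c("ALA", "SER", "TRP"))
  b <- make_ps(matrix(rnorm(6), ncol = 3), c("GLY", "LYS"))
  s <- seed_pairs(a, b, rep)
  expect_equal(nrow(s), 6L)   # 3 x 2 product under the any-any rule
  expect_equal(s$unit_a, rep(1:3, each = 2))
  expect_equal(s$unit_b, rep(1:2, 3))

  # disjoint alphabets under identity-only rules: no seeds
  rep2 <- parse_representation(c("def ALA CA", "def GLY CA", "ALA", "GLY"))
  a2 <- make_ps(matrix(rnorm(6), ncol = 3), c("ALA", "ALA"))
  b2 <- make_ps(matrix(rnorm(3), ncol = 3), "GLY")
  expect_equal(nrow(seed_pairs(a2, b2, rep2)), 0L)

  # ALA+GLY vs VAL under the three-way rule: 2 seeds
  a3 <- make_ps(matrix(rnorm(6), ncol = 3), c("ALA", "GLY"))
  b3 <- make_ps(matrix(rnorm(3), ncol = 3), "VAL")
  expect_equal(nrow(seed_pairs(a3, b3, simple_rep())), 2L)
})

test_that("self-comparison returns the full-length identity match at rmsd 0", {
  rep <- rep_preset("coarse_ca")
  m <- make_structure(5, seed = 31)
  ps <- build_pseudoatoms(m, rep)
  mm <- find_matches(ps, ps, rep, search_params())
  expect_gte(nrow(mm), 1L)
  expect_equal(mm$size_units[[1]], 5L)
  expect_lt(min(mm$rmsd), 1e-6)
  ident <- vapply(seq_len(nrow(mm)), function(i) {
    all(mm$pairs[[i]]$unit_a == mm$pairs[[i]]$unit_b)
  }, TRUE)
  expect_true(any(ident))
})

test_that("zero threshold on noisy data leaves only trivial matches", {
  rep <- rep_preset("coarse_ca")
  set.seed(5)
  a <- make_ps(matrix(rnorm(15, sd = 5), ncol = 3), rep("ALA", 5))
  b <- make_ps(matrix(rnorm(15, sd = 5), ncol = 3), rep("ALA", 5))
  mm <- find_matches(a, b, rep, search_params(rmsd_threshold = 1e-9,
                                              min_report_size = 1))
  # generic point clouds: no 2-point correspondence has rmsd ~ 0
  expect_equal(unique(mm$size_units), 1L)
})

test_that("a planted congruent subset is the unique maximum at noise 0", {
  rep <- rep_preset("ca_centroid_blosum")
  pm <- plant_motif(k = 4, sigma = 0, decoys = 10, seed = 8)
  pa <- suppressWarnings(build_pseudoatoms(pm$a, rep))
  pb <- suppressWarnings(build_pseudoatoms(pm$b, rep))
  mm <- find_matches(pa, pb, rep, search_params())
  expect_gte(nrow(mm), 1L)
  expect_true(recovered_truth(mm, pm$truth))
  # the noiseless planted correspondence itself superimposes exactly
  ua <- vapply(pm$truth$resno_a, function(r) pa$unit[pa$resno == r][1], 0L)
  ub <- vapply(pm$truth$resno_b, function(r) pb$unit[pb$resno == r][1], 0L)
  r0 <- rmsd_under_correspondence(pa, pb, tibble::tibble(unit_a = ua, unit_b = ub), rep)
  expect_lt(r0, 1e-6)
})

test_that("small instances equal the brute-force oracle exactly", {
  rep <- simple_rep()
  fails <- 0
  for (sd in 1:25) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    a <- suppressWarnings(make_structure(na, alphabet = c("ALA", "GLY", "VAL"),
                                         seed = sd * 2, box = 10))
    b <- suppressWarnings(make_structure(nb, alphabet = c("ALA", "GLY", "VAL"),
                                         seed = sd * 2 + 1, box = 10))
    pa <- build_pseudoatoms(a, rep)
    pb <- build_pseudoatoms(b, rep)
    cands <- seed_pairs(pa, pb, rep)
    A <- as.matrix(pa[, c("x", "y", "z")])
    B <- as.matrix(pb[, c("x", "y", "z")])
    o <- oracle_find_matches(cands, A, B, 0.7)
    mm <- find_matches(pa, pb, rep, search_params(min_report_size = 1))
    expect_equal(nrow(mm), length(o$sols), info = paste("seed", sd))
    if (nrow(mm) > 0) {
      expect_true(all(mm$size_units == o$best), info = paste("seed", sd))
      expect_equal(sort(mm$rmsd), sort(o$rmsds), tolerance = 1e-8,
                   info = paste("seed", sd))
      got <- sort(vapply(seq_len(nrow(mm)), function(i) {
        pair_set_key(mm$pairs[[i]]$unit_a, mm$pairs[[i]]$unit_b)
      }, ""))
      want <- sort(vapply(o$sols, function(s) {
        pair_set_key(cands$unit_a[s], cands$unit_b[s])
      }, ""))
      expect_equal(got, want, info = paste("seed", sd))
    }
  }
})

test_that("search is symmetric, rigid-invariant and order-independent", {
  rep <- rep_preset("ca_centroid_blosum")
  pm <- plant_motif(k = 5, sigma = 0.05, decoys = 8, seed = 77)
  pa <- suppressWarnings(build_pseudoatoms(pm$a, rep))
  pb <- suppressWarnings(build_pseudoatoms(pm$b, rep))
  fwd <- find_matches(pa, pb, rep, search_params())
  bwd <- find_matches(pb, pa, rep, search_params())
  expect_equal(fwd$size_units, bwd$size_units)
  expect_equal(sort(fwd$rmsd), sort(bwd$rmsd), tolerance = 1e-6)
  fk <- sort(vapply(seq_len(nrow(fwd)), function(i)
    pair_set_key(fwd$pairs[[i]]$resno_a, fwd$pairs[[i]]$resno_b), ""))
  bk <- sort(vapply(seq_len(nrow(bwd)), function(i)
    pair_set_key(bwd$pairs[[i]]$resno_b, bwd$pairs[[i]]$resno_a), ""))
  expect_equal(fk, bk)

  # rigid motion of either input leaves sizes and rmsds unchanged
  R <- structmatch:::random_rotation()
  pa2 <- rigid_transform_ps(pa, R, c(11, -4, 2))
  moved <- find_matches(pa2, pb, rep, search_params())
  expect_equal(moved$size_units, fwd$size_units)
  expect_equal(sort(moved$rmsd), sort(fwd$rmsd), tolerance = 1e-6)

  # permuting residue order changes nothing but labels
  perm <- sample(nrow(pa))
  pa3 <- pa[perm, ]
  pa3$unit <- match(pa3$unit, unique(pa3$unit))
  fwd3 <- find_matches(pa3, pb, rep, search_params())
  expect_equal(fwd3$size_units, fwd$size_units)
  expect_equal(sort(fwd3$rmsd), sort(fwd$rmsd), tolerance = 1e-6)
})

test_that("maximum match size is non-decreasing in the threshold", {
  rep <- rep_preset("ca_centroid_blosum")
  pm <- plant_motif(k = 6, sigma = 0.15, decoys = 10, seed = 21)
  pa <- suppressWarnings(build_pseudoatoms(pm$a, rep))
  pb <- suppressWarnings(build_pseudoatoms(pm$b, rep))
  sizes <- vapply(c(0.2, 0.4, 0.7, 1.0), function(t) {
    mm <- find_matches(pa, pb, rep, search_params(rmsd_threshold = t,
                                                  min_report_size = 1))
    if (nrow(mm) == 0L) 0L else mm$size_units[[1]]
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("empty inputs yield empty results; tiny node budgets error", {
  rep <- rep_preset("coarse_ca")
  m <- make_structure(5, seed = 41)
  ps <- build_pseudoatoms(m, rep)
  empty <- ps[0, ]
  expect_equal(nrow(find_matches(empty, ps, rep, search_params())), 0L)
  expect_error(
    find_matches(ps, ps, rep, search_params(node_budget = 10)),
    "node budget")
})

test_that("matches below min_report_size are suppressed", {
  rep <- rep_preset("coarse_ca")
  set.seed(9)
  a <- make_ps(matrix(rnorm(9, sd = 6), ncol = 3), rep("ALA", 3))
  b <- make_ps(matrix(rnorm(9, sd = 6), ncol = 3), rep("ALA", 3))
  all_m <- find_matches(a, b, rep, search_params(rmsd_threshold = 0.3,
                                                 min_report_size = 1))
  best <- if (nrow(all_m)) all_m$size_units[[1]] else 0L
  gated <- find_matches(a, b, rep, search_params(rmsd_threshold = 0.3,
                                                 min_report_size = best + 1L))
  expect_equal(nrow(gated), 0L)
})
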