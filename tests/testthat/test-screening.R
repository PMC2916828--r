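# Screening: ranking, background filter, ligand-proximity validation, AUC.

make_target_file <- function(model) {
  p <- tempfile(fileext = ".pdb")
  write_pdb(model, p)
  p
}

test_that("screening a probe against its own source puts self on top", {
  rep <- rep_preset("ca_centroid_blosum")
  m <- make_structure(10, seed = 50)
  p <- make_target_file(m)
  probe <- suppressWarnings(build_pseudoatoms(m, rep))
  decoy_paths <- vapply(51:53, function(sd)
    make_target_file(make_structure(10, seed = sd)), "")
  hits <- screen(probe, c(p, decoy_paths), rep, search_params())
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$path[[1]], p)
  expect_equal(hits$size_units[[1]], 10L)
  expect_lt(hits$rmsd[[1]], 0.01)  # file coordinates carry 3 decimals
})

test_that("targets with no equivalent residues produce no hits", {
  rep <- parse_representation(c("def TRP CA", "TRP"))
  probe <- make_ps(matrix(rnorm(9), ncol = 3), rep("TRP", 3))
  t1 <- make_target_file(make_structure(6, alphabet = "ALA", seed = 60))
  hits <- screen(probe, t1, rep, search_params(min_report_size = 1))
  expect_equal(nrow(hits), 0L)
})

test_that("planted targets outrank decoys and the ranking is order-independent", {
  rep <- rep_preset("ca_centroid_blosum")
  pm0 <- plant_motif(k = 6, sigma = 0.05, decoys = 6, seed = 70)
  probe <- suppressWarnings(
    build_pseudoatoms(pm0$a, rep, resno = pm0$truth$resno_a))
  # both structures of the pair carry the motif; decoy-only targets do not
  planted <- c(make_target_file(pm0$a), make_target_file(pm0$b))
  decoys <- vapply(81:90, function(sd)
    make_target_file(make_structure(12, seed = sd)), "")
  paths <- c(decoys[1:5], planted, decoys[6:10])
  hits <- screen(probe, paths, rep, search_params(min_report_size = 3))
  top <- hits$path[seq_len(2)]
  expect_true(all(top %in% planted))

  # permuting target order never changes the ranked table
  hits2 <- screen(probe, rev(paths), rep, search_params(min_report_size = 3))
  expect_equal(hits$target_id, hits2$target_id)
  expect_equal(hits$rmsd, hits2$rmsd)
})

test_that("filter_background drops strictly smaller hits, keeping order", {
  h <- tibble::tibble(target_id = letters[1:5], path = letters[1:5],
                      chain = "A", size_units = c(7L, 5L, 3L, 3L, 3L),
                      size_pseudoatoms = c(7L, 5L, 3L, 3L, 3L),
                      rmsd = c(0.5, 0.4, 0.1, 0.2, 0.3),
                      pairs = replicate(5, NULL),
                      validated = NA, min_ligand_distance = NA_real_,
                      status = "ok")
  f <- filter_background(h, 4)
  expect_equal(f$size_units, c(7L, 5L))
  expect_equal(filter_background(h, 1)$target_id, h$target_id)
  all3 <- filter_background(h, 3)
  expect_equal(nrow(all3), 5L)  # boundary: equal sizes survive
})

test_that("proximity validation is strict at the cutoff", {
  rep <- rep_preset("coarse_ca")
  for (d in c(4.4, 4.5, 4.6)) {
    m <- make_structure(4, alphabet = "ALA", seed = 90)
    m <- make_ligand_complex(m, anchor_resno = 2, distance = d,
                             ligand_name = "PO4", element = "P", seed = 91)
    ps <- build_pseudoatoms(m, rep)
    mm <- find_matches(ps, ps, rep, search_params())
    hit <- list(pairs = mm$pairs[1])
    v <- proximity_validate(hit, m, element = "P", cutoff = 4.5)
    expect_equal(v$distance, d, tolerance = 1e-6)
    expect_equal(v$validated, d < 4.5, info = paste("distance", d))
  }
  # element filter mismatch and missing ligands both yield Inf / FALSE
  m <- make_structure(4, alphabet = "ALA", seed = 90)
  ps <- build_pseudoatoms(m, rep)
  mm <- find_matches(ps, ps, rep, search_params())
  hit <- list(pairs = mm$pairs[1])
  v0 <- proximity_validate(hit, m, element = "P", cutoff = 4.5)
  expect_false(v0$validated)
  expect_equal(v0$distance, Inf)
  m2 <- make_ligand_complex(m, anchor_resno = 2, distance = 3,
                            ligand_name = "MG", element = "MG", seed = 92)
  v2 <- proximity_validate(hit, m2, element = "P", cutoff = 4.5)
  expect_false(v2$validated)
})

test_that("roc_auc equals exhaustive pair counting on all short sequences", {
  expect_equal(roc_auc(c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  for (n in 2:8) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    for (i in seq_len(nrow(grid))) {
      labs <- as.logical(grid[i, ])
      if (all(labs) || !any(labs)) {
        expect_error(roc_auc(labs), "undefined AUC")
      } else {
        expect_equal(roc_auc(labs), auc_by_counting(labs), info = paste(labs, collapse = ","))
      }
    }
  }
  # perfect and anti-perfect rankings
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(c(FALSE, FALSE, TRUE, TRUE)), 0.0)
  # midrank ties via scores
  expect_equal(roc_auc(c(TRUE, FALSE), scores = c(1, 1)), 0.5)
  expect_equal(roc_auc(c(TRUE, FALSE, TRUE, FALSE), scores = c(2, 2, 1, 1)),
               auc_by_counting(c(TRUE, FALSE, TRUE, FALSE), c(2, 2, 1, 1)))
})

test_that("validate_hits fills validation columns from target models", {
  rep <- rep_preset("coarse_ca")
  m <- make_structure(5, alphabet = "ALA", seed = 95)
  m <- make_ligand_complex(m, anchor_resno = 1, distance = 4.0,
                           ligand_name = "PO4", element = "P", seed = 96)
  p <- make_target_file(m)
  probe <- build_pseudoatoms(m, rep)
  hits <- screen(probe, p, rep, search_params())
  hits <- validate_hits(hits, element = "P", cutoff = 4.5)
  expect_true(hits$validated[[1]])
  expect_equal(hits$min_ligand_distance[[1]], 4.0, tolerance = 1e-3)
})
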