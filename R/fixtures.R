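# Synthetic PDB-like structures: random packed residues with plausible atom
# names, planted-motif structure pairs with known ground truth, and ligand
# complexes for proximity validation.  Geometrically plausible only - no
# stereochemistry - which is all the search layer can see.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_unit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

# rejection-sample n points in a cubic box with a minimum pairwise distance
pack_points <- function(n, box, min_dist = 3.5, existing = NULL,
                        max_tries = 2000L * n) {
  pts <- existing
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf("packing failure: placed %d of %d points in box %.1f A",
                   placed, n, box))
    }
    cand <- stats::runif(3L, 0, box)
    ok <- is.null(pts) ||
      all(rowSums(sweep(pts, 2L, cand)^2) >= min_dist^2)
    if (ok) {
      pts <- rbind(pts, cand)
      placed <- placed + 1L
    }
  }
  utils::tail(pts, n)
}

# idealized atoms for one residue given its CA position: backbone N, C, O at
# fixed bond lengths in random directions, side-chain atoms chained from CB
residue_atoms <- function(resname, ca) {
  sc <- SIDECHAIN_ATOMS[[resname]]
  names <- c("N", "CA", "C", "O", sc)
  coords <- matrix(NA_real_, nrow = length(names), ncol = 3L)
  coords[2L, ] <- ca
  coords[1L, ] <- ca + 1.46 * random_unit()
  coords[3L, ] <- ca + 1.52 * random_unit()
  coords[4L, ] <- coords[3L, ] + 1.23 * random_unit()
  if (length(sc)) {
    prev <- ca
    for (k in seq_along(sc)) {
      coords[4L + k, ] <- prev + 1.52 * random_unit()
      prev <- coords[4L + k, ]
    }
  }
  elem <- substr(gsub("[0-9]", "", names), 1L, 1L)
  tibble::tibble(atom = names, element = elem,
                 x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

build_model_atoms <- function(resnames, ca_pts, chain = "A",
                              resno = seq_along(resnames)) {
  rows <- lapply(seq_along(resnames), function(i) {
    at <- residue_atoms(resnames[[i]], ca_pts[i, ])
    tibble::tibble(chain = chain, resno = as.integer(resno[[i]]), icode = "",
                   resname = resnames[[i]], atom = at$atom,
                   element = at$element, altloc = "", occupancy = 1,
                   hetero = FALSE, ligand = FALSE,
                   x = at$x, y = at$y, z = at$z)
  })
  dplyr::bind_rows(rows)
}

#' Generate a random synthetic structure
#'
#' Residues get plausible backbone and side-chain atom names; C-alpha
#' positions are packed in a cubic box with a minimum inter-residue distance
#' of 3.5 Angstrom.  Deterministic for a given seed.
#'
#' @param n_residues number of residues (>= 1).
#' @param alphabet residue names to draw from.
#' @param seed integer RNG seed.
#' @param box box edge in Angstrom; default scales with `n_residues` to a
#'   protein-like point density (about 125 cubic Angstrom per residue).
#' @param id structure identifier.
#' @return A `structure_model`.
#' @export
make_structure <- function(n_residues, alphabet = AA_STANDARD, seed = 1L,
                           box = NULL, id = sprintf("synth%03d", seed)) {
  stopifnot(n_residues >= 1)
  if (is.null(box)) box <- max(8, (125 * n_residues)^(1 / 3))
  local_seed(seed, {
    resnames <- sample(alphabet, n_residues, replace = TRUE)
    pts <- pack_points(n_residues, box)
    new_structure_model(id, build_model_atoms(resnames, pts))
  })
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2), nrow = 3L, byrow = TRUE)
}

#' Plant a shared structural motif in two synthetic structures
#'
#' The same `k`-residue motif is embedded among decoy residues in two
#' structures; the copy in structure B is perturbed by isotropic Gaussian
#' coordinate noise of standard deviation `sigma` and the whole of B is
#' subjected to a random proper rigid motion.  The ground-truth residue
#' correspondence is returned for recovery scoring.
#'
#' @param k motif size in residues.
#' @param sigma isotropic noise standard deviation in Angstrom.
#' @param decoys number of decoy residues added to each structure.
#' @param seed integer RNG seed.
#' @param alphabet residue names for motif and decoys.
#' @param box box edge for the full structures; default as in
#'   [make_structure()] for `k + decoys` residues.
#' @return List with `a`, `b` (structure models), `truth` (tibble with
#'   `resno_a`, `resno_b`) and `transform` (the rigid motion applied to B).
#' @export
plant_motif <- function(k = 8L, sigma = 0.1, decoys = 30L, seed = 1L,
                        alphabet = AA_STANDARD, box = NULL) {
  stopifnot(k >= 1, sigma >= 0, decoys >= 0)
  n <- k + decoys
  if (is.null(box)) box <- max(8, (125 * n)^(1 / 3))
  local_seed(seed, {
    motif_names <- sample(alphabet, k, replace = TRUE)
    motif_box <- max(6, (125 * k)^(1 / 3))
    motif <- pack_points(k, motif_box)
    shift_a <- (box - motif_box) / 2
    motif_ca <- sweep(motif, 2L, shift_a, "+")
    # the motif's full-atom geometry is built once and shared by both copies
    motif_atoms <- build_model_atoms(motif_names, motif_ca)

    # structure A: motif in the box centre, decoys packed around it
    pts_a <- pack_points(decoys, box, existing = motif_ca)
    decoy_names_a <- sample(alphabet, decoys, replace = TRUE)
    atoms_a <- dplyr::bind_rows(
      motif_atoms,
      build_model_atoms(decoy_names_a, pts_a, resno = k + seq_len(decoys)))

    # structure B: every motif atom perturbed by isotropic noise, fresh
    # decoys, residue order scrambled, then a global rigid motion (which
    # leaves all internal geometry unchanged)
    motif_atoms_b <- motif_atoms
    nm <- nrow(motif_atoms_b)
    motif_atoms_b$x <- motif_atoms_b$x + stats::rnorm(nm, sd = sigma)
    motif_atoms_b$y <- motif_atoms_b$y + stats::rnorm(nm, sd = sigma)
    motif_atoms_b$z <- motif_atoms_b$z + stats::rnorm(nm, sd = sigma)
    motif_ca_b <- as.matrix(
      motif_atoms_b[motif_atoms_b$atom == "CA", c("x", "y", "z")])
    pts_b <- pack_points(decoys, box, existing = motif_ca_b)
    decoy_names_b <- sample(alphabet, decoys, replace = TRUE)
    ord <- sample.int(n)  # new residue numbers: old residue i becomes ord[i]
    motif_atoms_b$resno <- as.integer(ord[motif_atoms_b$resno])
    decoy_atoms_b <- build_model_atoms(decoy_names_b, pts_b,
                                       resno = ord[k + seq_len(decoys)])
    atoms_b <- dplyr::bind_rows(motif_atoms_b, decoy_atoms_b)
    atoms_b <- dplyr::arrange(atoms_b, .data$resno)
    R <- random_rotation()
    tr <- stats::runif(3L, -20, 20)
    model_b <- transform_model(new_structure_model("plantB", atoms_b), R, tr)

    truth <- tibble::tibble(resno_a = seq_len(k), resno_b = ord[seq_len(k)])
    list(a = new_structure_model("plantA", atoms_a), b = model_b,
         truth = truth, transform = list(rotation = R, translation = tr))
  })
}

#' Add a single-atom ligand to a synthetic structure
#'
#' Places a hetero residue with one atom of the given element at the stated
#' distance from the first atom of the anchor residue, in a direction that
#' avoids clashes (< 1 Angstrom) with existing atoms.
#'
#' @param model a `structure_model`.
#' @param anchor_resno author residue number of the anchor residue.
#' @param distance distance in Angstrom from the anchor's first atom.
#' @param ligand_name 3-letter hetero residue name.
#' @param element element symbol of the ligand atom.
#' @param chain chain of the anchor residue.
#' @param seed RNG seed for the direction search.
#' @return The model with the ligand appended.
#' @export
make_ligand_complex <- function(model, anchor_resno, distance,
                                ligand_name = "PO4", element = "P",
                                chain = NULL, seed = 1L) {
  atoms <- model$atoms
  if (is.null(chain)) chain <- atoms$chain[[1]]
  anchor <- atoms[atoms$chain == chain & atoms$resno == anchor_resno &
                    !atoms$ligand, ]
  if (nrow(anchor) == 0L) {
    stop(sprintf("anchor residue %s:%d not found", chain, anchor_resno))
  }
  a0 <- as.numeric(anchor[1L, c("x", "y", "z")])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  # prefer directions where the anchor's first atom is also the nearest
  # protein atom (so the stated distance is exactly the minimum distance);
  # fall back to any clash-free direction for buried anchors
  pos <- local_seed(seed, {
    found <- NULL
    for (try in 1:2000) {
      cand <- a0 + distance * as.numeric(random_unit())
      d <- sqrt(rowSums(sweep(xyz, 2L, cand)^2))
      if (all(d >= min(1.0, distance)) && sum(d < distance - 1e-9) == 0L) {
        found <- cand
        break
      }
    }
    if (is.null(found)) {
      for (try in 1:2000) {
        cand <- a0 + distance * as.numeric(random_unit())
        d <- sqrt(rowSums(sweep(xyz, 2L, cand)^2))
        if (all(d >= 1.0)) {
          found <- cand
          break
        }
      }
    }
    found
  })
  if (is.null(pos)) {
    stop("could not place ligand atom without a clash within 1 Angstrom")
  }
  lig <- tibble::tibble(chain = chain,
                        resno = max(atoms$resno) + 1L, icode = "",
                        resname = ligand_name, atom = toupper(element),
                        element = toupper(element), altloc = "",
                        occupancy = 1, hetero = TRUE, ligand = TRUE,
                        x = pos[[1]], y = pos[[2]], z = pos[[3]])
  new_structure_model(model$id, dplyr::bind_rows(atoms, lig))
}
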