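# Projection of a selected structure into a pseudoatom set according to a
# representation: each resolvable residue yields pseudoatoms per recipe,
# grouped into match units (whole residue, or single point in
# independent-atom mode).

#' Geometric centroid of a set of coordinates
#'
#' @param coords numeric matrix (n x 3) or data frame with `x`, `y`, `z`.
#' @return Length-3 numeric vector: the arithmetic mean per axis.
#' @examples
#' centroid(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
centroid <- function(coords) {
  m <- as_xyz_matrix(coords)
  if (nrow(m) == 0L) stop("centroid of an empty coordinate set")
  colMeans(m)
}

as_xyz_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[, c("x", "y", "z")])
  } else {
    m <- as.matrix(coords)
    if (is.null(dim(m)) || ncol(m) == 1L) m <- matrix(m, ncol = 3L, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 3L)
  m
}

#' Project a structure into a pseudoatom set
#'
#' For each selected polymer residue whose name resolves to a definition
#' (exactly, or through the `*` wildcard), every recipe of that definition
#' yields pseudoatoms:
#' * a single-atom recipe yields one pseudoatom if the atom is present in the
#'   coordinates, none otherwise;
#' * a pattern recipe (`\STR`) yields one pseudoatom per atom whose name
#'   contains the pattern (hydrogens only if the pattern names them);
#' * a centroid recipe yields one pseudoatom at the mean of the atoms that
#'   are present (a warning is issued when some are missing; the pseudoatom
#'   is skipped only if none are present).
#'
#' Residues yielding zero pseudoatoms are dropped with a warning.  In grouped
#' mode one match unit holds all of a residue's pseudoatoms; in
#' independent-atom mode each pseudoatom is its own unit.
#'
#' @param model a [read_pdb()] structure model.
#' @param rep a [parse_representation()] object.
#' @param chain,resno optional selection (see [select_residues()]).
#' @return A `pseudoatom_set`: tibble with one row per pseudoatom (columns
#'   `unit`, `chain`, `resno`, `icode`, `resname`, `recipe`, `src_recipe`,
#'   `x`, `y`, `z`) and attributes `mode`, `rep_id` and `source`.
#' @export
build_pseudoatoms <- function(model, rep, chain = NULL, resno = NULL) {
  stopifnot(inherits(model, "structure_model"), inherits(rep, "representation"))
  sel <- select_residues(model, chain = chain, resno = resno)
  atoms <- polymer_atoms(sel)

  res_tbl <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$icode,
                             .data$resname)
  rows <- vector("list", nrow(res_tbl))
  dropped <- character(0)
  for (i in seq_len(nrow(res_tbl))) {
    rr <- res_tbl[i, ]
    def <- resolve_def(rr$resname, rep)
    if (is.null(def)) next
    ra <- atoms[atoms$chain == rr$chain & atoms$resno == rr$resno &
                  atoms$icode == rr$icode, ]
    ps <- residue_pseudoatoms(ra, def, rr)
    if (is.null(ps)) {
      dropped <- c(dropped, sprintf("%s:%s:%d%s", rr$chain, rr$resname,
                                    rr$resno, rr$icode))
      next
    }
    rows[[i]] <- ps
  }
  out <- dplyr::bind_rows(rows)
  if (length(dropped)) {
    warning(sprintf("dropped %d residue(s) yielding no pseudoatoms: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (nrow(out) == 0L) {
    out <- tibble::tibble(chain = character(), resno = integer(),
                          icode = character(), resname = character(),
                          recipe = character(), src_recipe = character(),
                          x = double(), y = double(), z = double())
  }
  mode <- if (rep$independent_atoms) "independent" else "grouped"
  if (mode == "independent") {
    out$unit <- seq_len(nrow(out))
  } else {
    key <- paste(out$chain, out$resno, out$icode, sep = "\r")
    out$unit <- match(key, unique(key))
  }
  out <- dplyr::relocate(out, "unit")
  structure(out,
            mode = mode, rep_id = rep$id,
            source = list(id = model$id, chain = chain, resno = resno),
            class = c("pseudoatom_set", class(tibble::tibble())))
}

residue_pseudoatoms <- function(ra, def, rr) {
  ps <- list()
  for (rc in def$recipes) {
    if (rc$type == "atom") {
      hit <- which(ra$atom == rc$atom)
      if (length(hit) >= 1L) {
        ps[[length(ps) + 1L]] <- pseudo_row(rr, rc$name, rc$name,
                                            ra[hit[[1]], c("x", "y", "z")])
      }
    } else if (rc$type == "pattern") {
      hit <- which(grepl(rc$pattern, ra$atom, fixed = TRUE))
      for (h in hit) {
        ps[[length(ps) + 1L]] <- pseudo_row(rr, ra$atom[[h]], rc$name,
                                            ra[h, c("x", "y", "z")])
      }
    } else { # centroid
      hit <- which(ra$atom %in% rc$atoms)
      if (length(hit) >= 1L) {
        if (length(hit) < length(rc$atoms)) {
          warning(sprintf(
            "%s:%s:%d%s: centroid '%s' averaged over %d of %d atoms",
            rr$chain, rr$resname, rr$resno, rr$icode, rc$name,
            length(hit), length(rc$atoms)), call. = FALSE)
        }
        cc <- centroid(ra[hit, c("x", "y", "z")])
        ps[[length(ps) + 1L]] <- pseudo_row(
          rr, rc$name, rc$name,
          tibble::tibble(x = cc[[1]], y = cc[[2]], z = cc[[3]]))
      }
    }
  }
  if (length(ps) == 0L) return(NULL)
  dplyr::bind_rows(ps)
}

pseudo_row <- function(rr, recipe, src_recipe, xyz) {
  tibble::tibble(chain = rr$chain, resno = rr$resno, icode = rr$icode,
                 resname = rr$resname, recipe = recipe,
                 src_recipe = src_recipe,
                 x = xyz$x[[1]], y = xyz$y[[1]], z = xyz$z[[1]])
}

#' @export
print.pseudoatom_set <- function(x, ...) {
  cat(sprintf("<pseudoatom_set: %d pseudoatoms, %d units, %s mode, rep '%s'>\n",
              nrow(x), n_units(x), attr(x, "mode"), attr(x, "rep_id")))
  NextMethod()
}

n_units <- function(set) length(unique(set$unit))

#' Dump a pseudoatom set as PDB HETATM records (debug aid)
#'
#' @param set a [build_pseudoatoms()] set.
#' @param path output path, or `NULL` to just return the lines.
#' @return PDB lines, invisibly.
#' @export
dump_pseudoatoms <- function(set, path = NULL) {
  lines <- sprintf(
    "HETATM%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(set)), substr(sprintf("PS%d", set$unit), 1, 4), "",
    substr(set$resname, 1, 3), set$chain, set$resno,
    ifelse(nzchar(set$icode), set$icode, " "),
    set$x, set$y, set$z, 1, 0, "X")
  if (!is.null(path)) writeLines(c(lines, "END"), path)
  invisible(lines)
}
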