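# PDB structure input: read coordinate files (via bio3d), apply chain /
# residue selections, expose ligand heteroatoms for proximity validation.

WATER_NAMES <- c("HOH", "WAT", "DOD")

#' Read a PDB coordinate file
#'
#' Only the first model of a multi-model file is used.  For atoms with
#' alternate locations the highest-occupancy conformer is kept (ties broken
#' in favour of a blank altloc, then `'A'`, then alphabetically).  Hydrogens
#' are retained; the representation decides whether they are used.  HETATM
#' residues are routed to the ligand set unless they look like polymer
#' residues (modified amino acids carrying N, CA and C backbone atoms).
#' Water is never a ligand.
#'
#' @param path path to a PDB-format file.
#' @param id structure identifier; defaults to the file name without
#'   extension.
#' @return A `structure_model`: list with `id` and `atoms`, a tibble with one
#'   row per atom (columns `chain`, `resno`, `icode`, `resname`, `atom`,
#'   `element`, `altloc`, `occupancy`, `hetero`, `ligand`, `x`, `y`, `z`).
#' @export
read_pdb <- function(path, id = sub("\\.(pdb|ent)$", "", basename(path),
                                    ignore.case = TRUE)) {
  if (!file.exists(path)) stop(sprintf("cannot read structure file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  # first model only
  endm <- which(trimws(lines) == "ENDMDL")
  if (length(endm) > 0L) lines <- lines[seq_len(endm[[1]] - 1L)]
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    stop(sprintf("no coordinate records in '%s'", path))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE, hex = TRUE)
  a <- pdb$atom

  element <- toupper(trimws(a$elesy))
  miss <- is.na(element) | !nzchar(element)
  if (any(miss)) {
    element[miss] <- suppressWarnings(
      vapply(a$elety[miss], function(e) {
        tryCatch(bio3d::atom2ele(e), error = function(...) {
          toupper(substr(gsub("[0-9']", "", trimws(e)), 1L, 1L))
        })
      }, "")
    )
  }

  atoms <- tibble::tibble(
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = toupper(trimws(a$resid)),
    atom = toupper(trimws(a$elety)),
    element = element,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    hetero = a$type == "HETATM",
    x = a$x, y = a$y, z = a$z
  )

  # altloc: keep the highest-occupancy conformer per atom site (preserving
  # file order otherwise)
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$resname,
                    .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()

  # a HETATM residue is polymer-like (modified amino acid) if it carries the
  # N, CA, C backbone; everything else non-water is a ligand
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$resname) |>
    dplyr::mutate(
      ligand = any(.data$hetero) &&
        !(.data$resname[1] %in% WATER_NAMES) &&
        !all(c("N", "CA", "C") %in% .data$atom)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode, .data$.ord)
  atoms$.ord <- NULL

  # water is neither polymer nor ligand for our purposes, but keep the atoms
  new_structure_model(id, atoms)
}

new_structure_model <- function(id, atoms) {
  structure(list(id = id, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  pol <- polymer_atoms(x)
  lig <- ligand_residues(x)
  cat(sprintf("<structure_model '%s'>\n", x$id))
  cat(sprintf("  %d atoms, %d polymer residues in chain(s) %s, %d ligand residue(s)\n",
              nrow(x$atoms),
              nrow(dplyr::distinct(pol, .data$chain, .data$resno, .data$icode)),
              paste(unique(pol$chain), collapse = ","),
              nrow(lig)))
  invisible(x)
}

polymer_atoms <- function(model) {
  dplyr::filter(model$atoms, !.data$ligand, !.data$resname %in% WATER_NAMES)
}

ligand_residues <- function(model) {
  model$atoms |>
    dplyr::filter(.data$ligand) |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$resname)
}

#' List the atoms of bound ligands
#'
#' Water is excluded.  With an `element` filter only atoms of that element
#' are returned (e.g. `"P"` for phosphorus-proximity validation).
#'
#' @param model a [read_pdb()] structure model.
#' @param element optional element symbol filter.
#' @return Tibble of ligand atoms (possibly empty).
#' @export
ligand_atoms <- function(model, element = NULL) {
  out <- dplyr::filter(model$atoms, .data$ligand)
  if (!is.null(element)) {
    el <- toupper(element)
    out <- dplyr::filter(out, .data$element == .env$el)
  }
  out
}

#' Restrict a structure model to a chain and residue subset
#'
#' Ligand atoms are always retained (they are needed for proximity
#' validation); the selection applies to polymer residues.
#'
#' @param model a [read_pdb()] structure model.
#' @param chain chain identifier, or `NULL` for all chains.
#' @param resno integer vector of author residue numbers, or `NULL` for the
#'   whole chain.
#' @return A filtered `structure_model`.
#' @export
select_residues <- function(model, chain = NULL, resno = NULL) {
  atoms <- model$atoms
  keep <- !atoms$ligand
  if (!is.null(chain)) {
    if (!chain %in% atoms$chain) {
      stop(sprintf("unknown chain '%s' in structure '%s'", chain, model$id))
    }
    keep <- keep & atoms$chain == chain
  }
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  new_structure_model(model$id, dplyr::filter(atoms, keep | .data$ligand))
}

#' Read a structure/selection list file
#'
#' One selection per line: `structure_path [chain [resid_ranges]]`, where
#' `resid_ranges` is a comma-separated list of single residue numbers or
#' inclusive ranges (`10-20,25`).  An omitted chain means all chains; an
#' omitted range means the whole chain.
#'
#' @param path path to the list file.
#' @return Tibble with columns `path`, `chain` (`NA` = all chains) and
#'   `resno` (list column of integer vectors; `NULL` = whole chain).
#' @export
read_selection_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    resno <- if (length(toks) >= 3L) list(parse_ranges(toks[[3]], i)) else list(NULL)
    tibble::tibble(path = toks[[1]],
                   chain = if (length(toks) >= 2L) toks[[2]] else NA_character_,
                   resno = resno)
  })
  dplyr::bind_rows(rows)
}

parse_ranges <- function(txt, line) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^(-?[0-9]+)(-([0-9]+))?$", p))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("selection line %d: malformed residue range '%s'", line, p))
    }
    if (nzchar(m[[3]])) {
      out <- c(out, as.integer(m[[2]]):as.integer(m[[4]]))
    } else {
      out <- c(out, as.integer(m[[2]]))
    }
  }
  sort(unique(out))
}

#' Expand selections with unspecified chains into one selection per chain
#'
#' Reads each referenced structure (once) to discover its chains; errors on
#' unknown chains.
#'
#' @param selections a [read_selection_list()] tibble.
#' @return list with `selections` (expanded tibble, plus a `target_id`
#'   column) and `models` (named list of loaded models keyed by path).
#' @export
resolve_selections <- function(selections) {
  models <- list()
  rows <- list()
  for (i in seq_len(nrow(selections))) {
    p <- selections$path[[i]]
    if (is.null(models[[p]])) models[[p]] <- read_pdb(p)
    model <- models[[p]]
    chains <- unique(polymer_atoms(model)$chain)
    ch <- selections$chain[[i]]
    use <- if (is.na(ch)) chains else {
      if (!ch %in% chains) {
        stop(sprintf("unknown chain '%s' in structure '%s'", ch, model$id))
      }
      ch
    }
    for (cc in use) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = p, chain = cc, resno = selections$resno[i],
        target_id = paste0(model$id, "_", cc))
    }
  }
  list(selections = dplyr::bind_rows(rows), models = models)
}

#' Write a structure model as PDB-format text
#'
#' @param model a `structure_model`.
#' @param path output file path; `NULL` returns the lines invisibly writing
#'   nothing.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  name4 <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom), a$atom)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)), name4, "",
    a$resname, a$chain, a$resno, ifelse(nzchar(a$icode), a$icode, " "),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Apply a rigid transformation to a structure model
#'
#' @param model a `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @return The transformed model.
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(rotation), 2L, translation, "+")
  atoms <- model$atoms
  atoms$x <- new[, 1]; atoms$y <- new[, 2]; atoms$z <- new[, 3]
  new_structure_model(model$id, atoms)
}
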