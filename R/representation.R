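# Residue-definition language: parse "def" statements, equivalence rules and
# mode directives into a validated representation object, and resolve which
# definition / pairing rules apply to a residue at match time.

#' Parse a residue-definition file
#'
#' The representation language is line oriented.  Recognised statements:
#'
#' * `def RES item [item ...]` — defines the pseudoatoms representing residue
#'   `RES` (a 3-letter code, or `*` meaning "any residue without a more
#'   specific definition").  Each `item` is one of
#'     - a plain PDB atom name (`CA`, `OG1`, ...): one pseudoatom at that atom;
#'     - `avg(A1,A2,...):name` — a named pseudoatom at the geometric centroid
#'       of the listed atoms (the `:name` suffix is optional; an automatic
#'       name is assigned when absent);
#'     - `\STR` — one pseudoatom per atom whose name contains `STR`.
#'   Items may be separated by whitespace or `;` (so `\N;\O` is two items).
#' * an equivalence rule: a whitespace-separated list of members, each
#'   `RES`, `RES.ATOM` or `RES.(A,B,...)`; all members of a rule may be
#'   matched with one another, their selected pseudoatoms paired in the order
#'   written.  A member without a selector uses all pseudoatoms of its
#'   definition.
#' * `mode independent` / `mode grouped` — whether each pseudoatom is an
#'   independently matchable unit, or all pseudoatoms of a residue move
#'   together (the default).
#' * `#` starts a comment; blank lines are ignored.
#'
#' Residue and atom names are case-insensitive and stored upper-case.
#'
#' @param text character vector: lines (or a single string with embedded
#'   newlines) of a residue-definition file.
#' @param id identifier stored on the returned object (used in downstream
#'   provenance columns).
#' @return An object of class `representation`: a list with elements `defs`
#'   (named list of residue definitions), `rules` (list of equivalence
#'   rules), `independent_atoms` (logical) and `id`.
#' @examples
#' rep <- parse_representation(c("def SER CA CB", "def ALA CA", "SER ALA"))
#' resolve_def("SER", rep)
#' @export
parse_representation <- function(text, id = "representation") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  defs <- list()
  rules <- list()
  mode <- "grouped"
  mode_seen <- FALSE

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    kw <- tolower(toks[[1]])
    if (kw == "def") {
      if (length(toks) < 3L) {
        stop(sprintf("line %d: 'def' needs a residue name and at least one item", i))
      }
      res <- toupper(toks[[2]])
      if (!is.null(defs[[res]])) {
        stop(sprintf("line %d: duplicate definition for residue '%s'", i, res))
      }
      items <- unlist(lapply(toks[-(1:2)], split_items))
      recipes <- vector("list", length(items))
      for (k in seq_along(items)) {
        recipes[[k]] <- parse_recipe(items[[k]], k, i)
      }
      nms <- vapply(recipes, `[[`, "", "name")
      if (anyDuplicated(nms)) {
        stop(sprintf("line %d: duplicate pseudoatom name '%s' in residue '%s'",
                     i, nms[duplicated(nms)][1], res))
      }
      defs[[res]] <- list(residue = res, recipes = recipes, line = i)
    } else if (kw == "mode") {
      if (length(toks) != 2L || !tolower(toks[[2]]) %in% c("independent", "grouped")) {
        stop(sprintf("line %d: mode must be 'independent' or 'grouped'", i))
      }
      mode <- tolower(toks[[2]])
      mode_seen <- TRUE
    } else {
      members <- lapply(toks, parse_member, line = i)
      if (length(members) < 1L) next
      rules[[length(rules) + 1L]] <- list(members = members, line = i)
    }
  }

  if (length(defs) == 0L) stop("no residue definitions")

  rep <- structure(
    list(defs = defs, rules = rules,
         independent_atoms = identical(mode, "independent"),
         id = id),
    class = "representation"
  )
  validate_representation(rep)
  rep
}

# split a raw token on ';' unless it contains parentheses (avg(...) keeps
# its commas; a ';' never legally occurs inside parens)
split_items <- function(tok) {
  if (grepl("(", tok, fixed = TRUE)) tok else strsplit(tok, ";", fixed = TRUE)[[1]]
}

parse_recipe <- function(item, k, line) {
  if (grepl("^avg\\(", item, ignore.case = TRUE)) {
    m <- regmatches(item, regexec("^[Aa][Vv][Gg]\\(([^)]*)\\)(:(\\S+))?$", item))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("line %d: malformed centroid item '%s'", line, item))
    }
    atoms <- toupper(trimws(strsplit(m[[2]], "[,;]")[[1]]))
    atoms <- atoms[nzchar(atoms)]
    if (length(atoms) == 0L) {
      stop(sprintf("line %d: centroid item '%s' lists no atoms", line, item))
    }
    name <- if (nzchar(m[[4]])) toupper(m[[4]]) else sprintf("CEN%d", k)
    list(name = name, type = "centroid", atoms = atoms)
  } else if (startsWith(item, "\\")) {
    pat <- toupper(substring(item, 2L))
    if (!nzchar(pat)) {
      stop(sprintf("line %d: empty '\\' pattern", line))
    }
    list(name = paste0("\\", pat), type = "pattern", pattern = pat)
  } else {
    if (grepl("[(),:]", item)) {
      stop(sprintf("line %d: malformed item '%s'", line, item))
    }
    list(name = toupper(item), type = "atom", atom = toupper(item))
  }
}

parse_member <- function(tok, line) {
  m <- regmatches(tok, regexec("^([A-Za-z0-9*]+)(\\.(.+))?$", tok))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("line %d: malformed equivalence member '%s'", line, tok))
  }
  res <- toupper(m[[2]])
  sel <- m[[4]]
  if (!nzchar(sel)) {
    return(list(residue = res, recipes = NULL))
  }
  sel <- gsub("^\\(|\\)$", "", sel)
  recs <- toupper(trimws(strsplit(sel, "[,;]")[[1]]))
  recs <- recs[nzchar(recs)]
  if (length(recs) == 0L) {
    stop(sprintf("line %d: empty fragment selector in '%s'", line, tok))
  }
  list(residue = res, recipes = recs)
}

validate_representation <- function(rep) {
  # member references and fragment-length consistency
  for (rule in rep$rules) {
    lens <- base::rep(NA_integer_, length(rule$members))
    for (j in seq_along(rule$members)) {
      mb <- rule$members[[j]]
      def <- resolve_def(mb$residue, rep)
      if (mb$residue != "*" && is.null(def)) {
        stop(sprintf("line %d: equivalence references undefined residue '%s'",
                     rule$line, mb$residue))
      }
      if (!is.null(mb$recipes)) {
        if (!is.null(def)) {
          known <- vapply(def$recipes, `[[`, "", "name")
          bad <- setdiff(mb$recipes, known)
          if (length(bad)) {
            stop(sprintf("line %d: undefined pseudoatom '%s' for residue '%s'",
                         rule$line, bad[[1]], mb$residue))
          }
        }
        lens[[j]] <- length(mb$recipes)
      } else if (!is.null(def)) {
        lens[[j]] <- length(def$recipes)
      }
    }
    known_lens <- unique(lens[!is.na(lens)])
    if (length(known_lens) > 1L) {
      stop(sprintf("line %d: mismatched fragment counts in equivalence (%s)",
                   rule$line, paste(known_lens, collapse = " vs ")))
    }
  }
  invisible(rep)
}

#' Resolve the definition that applies to a residue
#'
#' Returns the exact-name definition when present, else the `*` wildcard
#' definition when present, else `NULL` (the residue is excluded from the
#' representation).
#'
#' @param residue_name 3-letter residue code (case-insensitive).
#' @param rep a [parse_representation()] object.
#' @return A residue definition (list with `residue` and `recipes`) or `NULL`.
#' @export
resolve_def <- function(residue_name, rep) {
  stopifnot(inherits(rep, "representation"))
  res <- toupper(residue_name)
  if (!is.null(rep$defs[[res]])) return(rep$defs[[res]])
  rep$defs[["*"]]
}

member_matches <- function(member, residue, rep) {
  if (member$residue == "*") {
    !is.null(resolve_def(residue, rep))
  } else {
    identical(member$residue, toupper(residue))
  }
}

member_fragments <- function(member, residue, rep) {
  if (!is.null(member$recipes)) return(member$recipes)
  def <- resolve_def(residue, rep)
  if (is.null(def)) return(NULL)
  vapply(def$recipes, `[[`, "", "name")
}

#' Enumerate the allowed recipe pairings between two residues
#'
#' A pairing exists only if some equivalence rule links the two residue names
#' (a rule member may match via the `*` wildcard; a residue listed once in a
#' rule may match itself).  For each applicable rule, the selected fragments
#' of the two members are paired positionally, in the order they are written.
#' Members whose fragment lists have different lengths yield no pairing.
#'
#' @param res_a,res_b residue names (3-letter codes).
#' @param rep a [parse_representation()] object.
#' @return A list of correspondences, each a list with character vectors `a`
#'   and `b` of equal length (recipe names, paired positionally).  Empty list
#'   if no rule links the residues.
#' @examples
#' rep <- parse_representation(c("def ALA CA", "def GLY CA", "def VAL CA",
#'                               "ALA GLY VAL"))
#' allowed_pairings("ALA", "VAL", rep)
#' @export
allowed_pairings <- function(res_a, res_b, rep) {
  stopifnot(inherits(rep, "representation"))
  res_a <- toupper(res_a)
  res_b <- toupper(res_b)
  if (is.null(resolve_def(res_a, rep)) || is.null(resolve_def(res_b, rep))) {
    return(list())
  }
  out <- list()
  seen <- character(0)
  for (rule in rep$rules) {
    ms <- rule$members
    ia <- which(vapply(ms, member_matches, TRUE, residue = res_a, rep = rep))
    ib <- which(vapply(ms, member_matches, TRUE, residue = res_b, rep = rep))
    for (i in ia) {
      fa <- member_fragments(ms[[i]], res_a, rep)
      if (is.null(fa)) next
      for (j in ib) {
        fb <- member_fragments(ms[[j]], res_b, rep)
        if (is.null(fb) || length(fa) != length(fb)) next
        key <- paste(paste(fa, collapse = ","), paste(fb, collapse = ","), sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- list(a = fa, b = fb)
      }
    }
  }
  out
}

#' Serialize a representation back to definition-file text
#'
#' Re-parsing the output yields an equivalent representation (same
#' definitions, rules and mode).
#'
#' @param rep a [parse_representation()] object.
#' @return Character vector of lines.
#' @export
format_representation <- function(rep) {
  stopifnot(inherits(rep, "representation"))
  out <- character(0)
  out <- c(out, paste("mode", if (rep$independent_atoms) "independent" else "grouped"))
  for (def in rep$defs) {
    items <- vapply(def$recipes, function(r) {
      switch(r$type,
        atom = r$atom,
        pattern = paste0("\\", r$pattern),
        centroid = sprintf("avg(%s):%s", paste(r$atoms, collapse = ","), r$name)
      )
    }, "")
    out <- c(out, paste("def", def$residue, paste(items, collapse = " ")))
  }
  for (rule in rep$rules) {
    mems <- vapply(rule$members, function(mb) {
      if (is.null(mb$recipes)) mb$residue
      else sprintf("%s.(%s)", mb$residue, paste(mb$recipes, collapse = ","))
    }, "")
    out <- c(out, paste(mems, collapse = " "))
  }
  out
}

#' Write a representation to a file
#' @param rep a [parse_representation()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_representation <- function(rep, path) {
  writeLines(format_representation(rep), path)
  invisible(path)
}

#' @export
print.representation <- function(x, ...) {
  cat(sprintf("<representation '%s'>\n", x$id))
  cat(sprintf("  %d residue definition(s), %d equivalence rule(s), mode %s\n",
              length(x$defs), length(x$rules),
              if (x$independent_atoms) "independent" else "grouped"))
  invisible(x)
}

#' Load a bundled representation preset
#'
#' Three presets ship with the package:
#' * `"coarse_ca"` — every residue is its C-alpha; any residue matches any
#'   other.
#' * `"ca_centroid_blosum"` — C-alpha plus the geometric centroid of the
#'   side-chain heavy atoms; residues match only if their BLOSUM62
#'   substitution score is at least -1 (glycine, lacking a side chain, is
#'   paired on C-alpha only).
#' * `"chemgroups"` — side-chain chemical-group pseudoatoms (hydroxyls,
#'   carboxylates, amide groups, ring centroids, ...) in independent-atom
#'   mode, with no main-chain matches.
#'
#' @param name one of `"coarse_ca"`, `"ca_centroid_blosum"`, `"chemgroups"`.
#' @return A [parse_representation()] object.
#' @export
rep_preset <- function(name = c("coarse_ca", "ca_centroid_blosum", "chemgroups")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".rep"),
                      package = "structmatch", mustWork = TRUE)
  parse_representation(readLines(path), id = name)
}

#' Read a representation from a file
#' @param path path to a residue-definition file.
#' @param id identifier for the returned object; defaults to the file name.
#' @return A [parse_representation()] object.
#' @export
read_representation <- function(path, id = basename(path)) {
  parse_representation(readLines(path), id = id)
}
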