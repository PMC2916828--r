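# Branch-and-bound enumeration of all maximum-size unit correspondences
# between two pseudoatom sets under an RMSD threshold.  Matches start from
# all admissible single-unit pairings and grow depth-first; a partial match
# is extended only while its own optimal rmsd stays below the threshold.

#' Search parameters
#'
#' @param rmsd_threshold RMSD threshold in Angstrom (must be > 0); a partial
#'   correspondence is kept only while its optimal rmsd does not exceed it.
#' @param min_report_size smallest match size (in units) worth reporting.
#' @param max_solutions cap on the number of tied maximum-size matches kept.
#' @param node_budget maximum number of explored search-tree nodes before the
#'   search aborts with an error.
#' @return A list of class `search_params`.
#' @export
search_params <- function(rmsd_threshold = 0.7, min_report_size = 3L,
                          max_solutions = 1000L, node_budget = 1e8) {
  stopifnot(rmsd_threshold > 0, min_report_size >= 1)
  structure(list(rmsd_threshold = rmsd_threshold,
                 min_report_size = as.integer(min_report_size),
                 max_solutions = as.integer(max_solutions),
                 node_budget = node_budget),
            class = "search_params")
}

# instantiate the recipe-level correspondences between two units on the
# pseudoatoms actually present; returns a list of list(ia, ib) index vectors
# (positions within the unit's rows), deduplicated
instantiate_pairings <- function(unit_a, unit_b, rep, corrs = NULL) {
  if (is.null(corrs)) {
    corrs <- allowed_pairings(unit_a$resname[[1]], unit_b$resname[[1]], rep)
  }
  out <- list()
  seen <- character(0)
  for (corr in corrs) {
    ia <- integer(0)
    ib <- integer(0)
    for (k in seq_along(corr$a)) {
      ra <- which(unit_a$src_recipe == corr$a[[k]])
      rb <- which(unit_b$src_recipe == corr$b[[k]])
      if (length(ra) == 0L || length(rb) == 0L) next
      if (length(ra) == 1L && length(rb) == 1L) {
        ia <- c(ia, ra)
        ib <- c(ib, rb)
      } else {
        # pattern recipes in grouped mode: pair atoms of equal name
        common <- sort(intersect(unit_a$recipe[ra], unit_b$recipe[rb]))
        for (nm in common) {
          ia <- c(ia, ra[match(nm, unit_a$recipe[ra])])
          ib <- c(ib, rb[match(nm, unit_b$recipe[rb])])
        }
      }
    }
    if (length(ia) == 0L) next
    key <- paste(paste(ia, collapse = ","), paste(ib, collapse = ","), sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(ia = ia, ib = ib)
  }
  out
}

#' Enumerate all admissible single-unit seed pairings
#'
#' One seed per (unit of `set_a`, unit of `set_b`, recipe correspondence)
#' triple allowed by [allowed_pairings()], in deterministic order (`set_a`
#' unit major, `set_b` unit minor, correspondence last).
#'
#' @param set_a,set_b [build_pseudoatoms()] sets built with the same
#'   representation.
#' @param rep the shared [parse_representation()] object.
#' @return Tibble with columns `unit_a`, `unit_b`, `ia`, `ib` (list columns
#'   of global pseudoatom row indices, paired positionally) and `n_points`.
#' @export
seed_pairs <- function(set_a, set_b, rep) {
  units_a <- split(seq_len(nrow(set_a)), set_a$unit)
  units_b <- split(seq_len(nrow(set_b)), set_b$unit)
  ord_a <- order(as.integer(names(units_a)))
  ord_b <- order(as.integer(names(units_b)))
  corr_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (ka in ord_a) {
    ra <- units_a[[ka]]
    ua <- as.integer(names(units_a)[[ka]])
    sub_a <- set_a[ra, ]
    for (kb in ord_b) {
      rb <- units_b[[kb]]
      ub <- as.integer(names(units_b)[[kb]])
      sub_b <- set_b[rb, ]
      key <- paste(sub_a$resname[[1]], sub_b$resname[[1]], sep = "|")
      corrs <- corr_cache[[key]]
      if (is.null(corrs)) {
        corrs <- allowed_pairings(sub_a$resname[[1]], sub_b$resname[[1]], rep)
        corr_cache[[key]] <- corrs
      }
      if (length(corrs) == 0L) next
      inst <- instantiate_pairings(sub_a, sub_b, rep, corrs = corrs)
      for (pp in inst) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          unit_a = ua, unit_b = ub,
          ia = list(ra[pp$ia]), ib = list(rb[pp$ib]),
          n_points = length(pp$ia))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(unit_a = integer(), unit_b = integer(),
                          ia = list(), ib = list(), n_points = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Find all maximum-size structural matches between two pseudoatom sets
#'
#' Branch-and-bound search: every admissible single-unit pairing is extended
#' depth-first with further unit pairs; an extension survives only if the
#' optimal rmsd of its pseudoatoms stays at or below the threshold.  All
#' matches of maximum size (in units) are returned, deduplicated by their
#' unordered pair-set and sorted by rmsd (ties: lexicographic pair order).
#'
#' @inheritParams seed_pairs
#' @param params a [search_params()] object.
#' @return A `match_set` tibble with one row per maximum match: `size_units`,
#'   `size_pseudoatoms`, `rmsd`, `pairs` (list of tibbles describing the
#'   paired residues) and `superposition` (list of
#'   [optimal_superposition()] objects mapping `set_b` onto `set_a`).
#'   Attributes: `params`, `n_nodes`, `rep_id`.
#' @export
find_matches <- function(set_a, set_b, rep, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  cands <- seed_pairs(set_a, set_b, rep)
  if (nrow(cands) == 0L || nrow(set_a) == 0L || nrow(set_b) == 0L) {
    return(empty_match_set(params, 0))
  }
  A <- as.matrix(set_a[, c("x", "y", "z")])
  B <- as.matrix(set_b[, c("x", "y", "z")])
  res <- cpp_find_matches(
    A, B,
    as.integer(cands$unit_a), as.integer(cands$unit_b),
    lapply(cands$ia, function(v) as.integer(v - 1L)),
    lapply(cands$ib, function(v) as.integer(v - 1L)),
    params$rmsd_threshold, params$max_solutions, params$node_budget)
  if (isTRUE(res$budget_exceeded)) {
    stop(sprintf("node budget exceeded (%g nodes explored); raise node_budget or tighten the representation/threshold",
                 res$n_nodes))
  }
  if (res$best_size < params$min_report_size || length(res$sets) == 0L) {
    return(empty_match_set(params, res$n_nodes))
  }
  rows <- lapply(seq_along(res$sets), function(i) {
    ids <- res$sets[[i]]
    cc <- cands[ids, ]
    ia <- unlist(cc$ia)
    ib <- unlist(cc$ib)
    sup <- optimal_superposition(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
    pairs <- tibble::tibble(
      unit_a = cc$unit_a, unit_b = cc$unit_b,
      chain_a = set_a$chain[vapply(cc$ia, `[[`, 0L, 1L)],
      resno_a = set_a$resno[vapply(cc$ia, `[[`, 0L, 1L)],
      icode_a = set_a$icode[vapply(cc$ia, `[[`, 0L, 1L)],
      resname_a = set_a$resname[vapply(cc$ia, `[[`, 0L, 1L)],
      chain_b = set_b$chain[vapply(cc$ib, `[[`, 0L, 1L)],
      resno_b = set_b$resno[vapply(cc$ib, `[[`, 0L, 1L)],
      icode_b = set_b$icode[vapply(cc$ib, `[[`, 0L, 1L)],
      resname_b = set_b$resname[vapply(cc$ib, `[[`, 0L, 1L)],
      n_points = cc$n_points)
    tibble::tibble(size_units = nrow(cc),
                   size_pseudoatoms = length(ia),
                   rmsd = sup$rmsd,
                   pairs = list(pairs),
                   superposition = list(sup),
                   pair_key = paste(sort(paste0(cc$unit_a, ":", cc$unit_b)),
                                    collapse = ";"))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$rmsd, .data$pair_key)
  out$pair_key <- NULL
  structure(out, params = params, n_nodes = res$n_nodes, rep_id = rep$id,
            class = c("match_set", class(tibble::tibble())))
}

empty_match_set <- function(params, n_nodes) {
  structure(
    tibble::tibble(size_units = integer(), size_pseudoatoms = integer(),
                   rmsd = double(), pairs = list(), superposition = list()),
    params = params, n_nodes = n_nodes,
    class = c("match_set", class(tibble::tibble())))
}

#' @export
print.match_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<match_set: no matches at or above min_report_size>\n")
  } else {
    cat(sprintf("<match_set: %d maximum match(es) of %d unit(s), best rmsd %.3f A>\n",
                nrow(x), x$size_units[[1]], min(x$rmsd)))
  }
  NextMethod()
}
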