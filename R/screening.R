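# Database screening: scan a probe pseudoatom set against many target
# chains, rank hits by size then rmsd, validate by ligand proximity and
# score rankings by ROC AUC.

#' Screen a probe motif against a list of target selections
#'
#' Each target selection is loaded, projected with the same representation as
#' the probe, and searched with [find_matches()]; the best (maximum-size,
#' lowest-rmsd) match becomes one hit.  Targets with no match at or above
#' `min_report_size` yield no hit.  Unreadable targets and targets exceeding
#' the node budget are flagged in the `status` column and never abort the
#' screen.  Results are deterministic and independent of target order: hits
#' are ranked by size (descending), rmsd (ascending), then target id.
#'
#' @param probe a [build_pseudoatoms()] set.
#' @param targets a [read_selection_list()] tibble (columns `path`, `chain`,
#'   `resno`), or a character vector of PDB paths.
#' @param rep the [parse_representation()] used for the probe.
#' @param params a [search_params()] object.
#' @return A `screening_hits` tibble: `target_id`, `path`, `chain`,
#'   `size_units`, `size_pseudoatoms`, `rmsd`, `pairs` (list), `validated`
#'   (NA until [validate_hits()]), `min_ligand_distance`, `status`.
#' @export
screen <- function(probe, targets, rep, params = search_params()) {
  if (is.character(targets)) {
    targets <- tibble::tibble(path = targets, chain = NA_character_,
                              resno = list(NULL))
  }
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    sel <- targets[i, ]
    expanded <- tryCatch(resolve_selections(sel), error = function(e) e)
    if (inherits(expanded, "error")) {
      rows[[length(rows) + 1L]] <- hit_row(
        target_id = paste0(basename(sel$path), ":?"), path = sel$path,
        chain = NA_character_, status = conditionMessage(expanded))
      next
    }
    model <- expanded$models[[sel$path]]
    for (j in seq_len(nrow(expanded$selections))) {
      es <- expanded$selections[j, ]
      hit <- tryCatch({
        tset <- suppressWarnings(build_pseudoatoms(
          model, rep, chain = es$chain, resno = es$resno[[1]]))
        ms <- find_matches(probe, tset, rep, params)
        if (nrow(ms) == 0L) NULL else ms[1L, ]
      }, error = function(e) e)
      if (is.null(hit)) next
      if (inherits(hit, "error")) {
        st <- if (grepl("node budget", conditionMessage(hit)))
          "node_budget_exceeded" else conditionMessage(hit)
        rows[[length(rows) + 1L]] <- hit_row(
          target_id = es$target_id, path = es$path, chain = es$chain,
          status = st)
        next
      }
      rows[[length(rows) + 1L]] <- hit_row(
        target_id = es$target_id, path = es$path, chain = es$chain,
        size_units = hit$size_units, size_pseudoatoms = hit$size_pseudoatoms,
        rmsd = hit$rmsd, pairs = hit$pairs, status = "ok")
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else hit_row()[0L, ]
  out <- rank_hits(out)
  structure(out, params = params,
            class = c("screening_hits", class(tibble::tibble())))
}

hit_row <- function(target_id = character(), path = character(),
                    chain = character(), size_units = NA_integer_,
                    size_pseudoatoms = NA_integer_, rmsd = NA_real_,
                    pairs = list(NULL), status = character()) {
  n <- max(length(target_id), 0L)
  tibble::tibble(target_id = target_id, path = path, chain = chain,
                 size_units = rep(as.integer(size_units), n),
                 size_pseudoatoms = rep(as.integer(size_pseudoatoms), n),
                 rmsd = rep(as.numeric(rmsd), n),
                 pairs = rep(pairs, n),
                 validated = rep(NA, n),
                 min_ligand_distance = rep(NA_real_, n),
                 status = status)
}

rank_hits <- function(hits) {
  dplyr::arrange(hits, dplyr::desc(.data$size_units), .data$rmsd,
                 .data$target_id)
}

#' Discard background-noise hits below a size cutoff
#'
#' Hits with `size_units < min_size` are removed (the filter is strict
#' less-than: hits exactly at `min_size` survive).  Surviving hits keep
#' their order.
#'
#' @param hits a [screen()] result.
#' @param min_size smallest match size (units) regarded as signal.
#' @return The filtered hits.
#' @export
filter_background <- function(hits, min_size) {
  dplyr::filter(hits, !is.na(.data$size_units), .data$size_units >= min_size)
}

#' Validate one hit by ligand proximity
#'
#' A hit is validated if any atom of a matched target residue lies strictly
#' closer than `cutoff` to a qualifying ligand atom (water never qualifies;
#' an `element` filter restricts ligand atoms, e.g. `"P"` for phosphorus).
#'
#' @param hit one row of a [screen()] result (or any list/row with a `pairs`
#'   tibble carrying `chain_b`/`resno_b`/`icode_b`).
#' @param model the target [read_pdb()] model, with its ligands.
#' @param element ligand element symbol filter, or `NULL` for any element.
#' @param cutoff proximity cutoff in Angstrom (default 4.5; comparison is
#'   strict `<`).
#' @return List with `validated` (logical) and `distance` (minimum residue
#'   atom to ligand atom distance; `Inf` when the model has no qualifying
#'   ligand atoms).
#' @export
proximity_validate <- function(hit, model, element = "P", cutoff = 4.5) {
  pairs <- if (is.data.frame(hit)) hit$pairs[[1]] else hit[["pairs"]][[1]]
  lig <- ligand_atoms(model, element = element)
  if (nrow(lig) == 0L) {
    return(list(validated = FALSE, distance = Inf))
  }
  keys <- paste(pairs$chain_b, pairs$resno_b, pairs$icode_b, sep = "\r")
  atoms <- model$atoms
  res_atoms <- atoms[paste(atoms$chain, atoms$resno, atoms$icode,
                           sep = "\r") %in% keys & !atoms$ligand, ]
  if (nrow(res_atoms) == 0L) {
    return(list(validated = FALSE, distance = Inf))
  }
  d2 <- outer(res_atoms$x, lig$x, "-")^2 +
    outer(res_atoms$y, lig$y, "-")^2 +
    outer(res_atoms$z, lig$z, "-")^2
  dmin <- sqrt(min(d2))
  list(validated = dmin < cutoff, distance = dmin)
}

#' Validate all hits of a screen by ligand proximity
#'
#' @param hits a [screen()] result.
#' @inheritParams proximity_validate
#' @return `hits` with `validated` and `min_ligand_distance` filled in.
#' @export
validate_hits <- function(hits, element = "P", cutoff = 4.5) {
  models <- list()
  for (i in seq_len(nrow(hits))) {
    if (is.null(hits$pairs[[i]])) next
    p <- hits$path[[i]]
    if (is.null(models[[p]])) models[[p]] <- read_pdb(p)
    v <- proximity_validate(hits[i, ], models[[p]], element = element,
                            cutoff = cutoff)
    hits$validated[[i]] <- v$validated
    hits$min_ligand_distance[[i]] <- v$distance
  }
  hits
}

#' Area under the ROC curve of a ranked labelling
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with tied scores sharing the midrank.
#' With `scores = NULL` the input order is the ranking, best first, with no
#' ties.
#'
#' @param labels logical vector (`TRUE` = positive), ordered best-first when
#'   `scores` is `NULL`.
#' @param scores optional numeric ranking scores (higher = better); ties
#'   share the midrank.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
roc_auc <- function(labels, scores = NULL) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0L || N == 0L) stop("undefined AUC: need at least one positive and one negative")
  if (is.null(scores)) scores <- rev(seq_along(labels))
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)  # midranks
  (sum(r[labels]) - P * (P + 1) / 2) / (P * N)
}

#' Write a hit table as TSV
#'
#' Columns: target_id, size_units, size_pseudoatoms, rmsd, validated,
#' min_ligand_distance, paired residue list (`chain:resname:resno(icode)`
#' pairs joined by `;`).
#'
#' @param hits a [screen()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- dplyr::mutate(
    tibble::as_tibble(hits),
    residues = vapply(.data$pairs, function(p) {
      if (is.null(p)) return("")
      paste(sprintf("%s:%s:%d%s=%s:%s:%d%s",
                    p$chain_a, p$resname_a, p$resno_a, p$icode_a,
                    p$chain_b, p$resname_b, p$resno_b, p$icode_b),
            collapse = ";")
    }, ""))
  flat <- flat[, c("target_id", "size_units", "size_pseudoatoms", "rmsd",
                   "validated", "min_ligand_distance", "status", "residues")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
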