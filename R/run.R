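# High-level front ends wiring the modules together: one-vs-one comparison
# with report output, and one-vs-many screening with a TSV hit table.  The
# command-line wrapper in inst/cli/structmatch.R is a thin shell over these.

#' Compare one probe selection against one target selection
#'
#' Reads both structures, projects them with the representation, runs
#' [find_matches()] and optionally writes a human-readable report, a
#' machine-readable TSV (one row per maximum match) and a PDB of the target
#' superposed onto the probe via the best match.
#'
#' @param probe,target either paths to PDB files or single-row selection
#'   tibbles as from [read_selection_list()].
#' @param rep a [parse_representation()] object, or a path to a
#'   residue-definition file.
#' @param params a [search_params()] object.
#' @param out optional path for the TSV match table.
#' @param report optional path for the human-readable report (use `""` for
#'   stdout).
#' @param superposed_pdb optional path: target coordinates transformed onto
#'   the probe frame by the best match.
#' @return The [find_matches()] result, invisibly when any output path is
#'   given.
#' @export
run_compare <- function(probe, target, rep, params = search_params(),
                        out = NULL, report = NULL, superposed_pdb = NULL) {
  if (is.character(rep)) rep <- read_representation(rep)
  ps <- load_selection(probe)
  ts <- load_selection(target)
  probe_set <- build_pseudoatoms(ps$model, rep, chain = ps$chain,
                                 resno = ps$resno)
  target_set <- build_pseudoatoms(ts$model, rep, chain = ts$chain,
                                  resno = ts$resno)
  matches <- find_matches(probe_set, target_set, rep, params)

  if (!is.null(report)) {
    lines <- compare_report(matches, ps$model$id, ts$model$id, params)
    if (identical(report, "")) cat(lines, sep = "\n") else writeLines(lines, report)
  }
  if (!is.null(out)) write_matches_tsv(matches, out)
  if (!is.null(superposed_pdb) && nrow(matches) > 0L) {
    sup <- matches$superposition[[1]]
    # the superposition maps target (b) onto probe (a)
    write_pdb(transform_model(ts$model, sup$rotation, sup$translation),
              superposed_pdb)
  }
  if (is.null(out) && is.null(report) && is.null(superposed_pdb)) matches
  else invisible(matches)
}

load_selection <- function(x) {
  if (is.character(x)) {
    return(list(model = read_pdb(x), chain = NULL, resno = NULL))
  }
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  model <- read_pdb(x$path[[1]])
  ch <- x$chain[[1]]
  list(model = model, chain = if (is.na(ch)) NULL else ch,
       resno = x$resno[[1]])
}

compare_report <- function(matches, probe_id, target_id, params) {
  head <- c(sprintf("probe:  %s", probe_id),
            sprintf("target: %s", target_id),
            sprintf("rmsd threshold: %.3f A; min report size: %d units",
                    params$rmsd_threshold, params$min_report_size),
            sprintf("maximum matches found: %d", nrow(matches)))
  if (nrow(matches) == 0L) return(c(head, "no match at or above the minimum size"))
  body <- unlist(lapply(seq_len(nrow(matches)), function(i) {
    p <- matches$pairs[[i]]
    c(sprintf("match %d: %d units / %d pseudoatoms, rmsd %.3f A", i,
              matches$size_units[[i]], matches$size_pseudoatoms[[i]],
              matches$rmsd[[i]]),
      sprintf("  %s:%s:%d%s = %s:%s:%d%s",
              p$chain_a, p$resname_a, p$resno_a, p$icode_a,
              p$chain_b, p$resname_b, p$resno_b, p$icode_b))
  }))
  c(head, body)
}

#' Write a match table as TSV (one row per maximum match)
#' @param matches a [find_matches()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  flat <- tibble::tibble(
    match = seq_len(nrow(matches)),
    size_units = matches$size_units,
    size_pseudoatoms = matches$size_pseudoatoms,
    rmsd = matches$rmsd,
    residues = vapply(matches$pairs, function(p) {
      paste(sprintf("%s:%s:%d%s=%s:%s:%d%s",
                    p$chain_a, p$resname_a, p$resno_a, p$icode_a,
                    p$chain_b, p$resname_b, p$resno_b, p$icode_b),
            collapse = ";")
    }, ""))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen a probe selection against a target list and write the hit table
#'
#' @param probe probe selection (path or single-row selection tibble).
#' @param targets a selection-list file path, or a [read_selection_list()]
#'   tibble.
#' @param rep representation object or definition-file path.
#' @param params a [search_params()] object.
#' @param out optional TSV output path for the hit table.
#' @param validate_element optional element symbol: when given, hits are
#'   validated by ligand proximity (cutoff `validate_cutoff`).
#' @param validate_cutoff proximity cutoff in Angstrom.
#' @return The [screen()] hits (invisibly when `out` is given).
#' @export
run_screen <- function(probe, targets, rep, params = search_params(),
                       out = NULL, validate_element = NULL,
                       validate_cutoff = 4.5) {
  if (is.character(rep)) rep <- read_representation(rep)
  if (is.character(targets)) targets <- read_selection_list(targets)
  ps <- load_selection(probe)
  probe_set <- build_pseudoatoms(ps$model, rep, chain = ps$chain,
                                 resno = ps$resno)
  hits <- screen(probe_set, targets, rep, params)
  if (!is.null(validate_element)) {
    hits <- validate_hits(hits, element = validate_element,
                          cutoff = validate_cutoff)
  }
  if (!is.null(out)) {
    write_hits_tsv(hits, out)
    message(sprintf("%d hit(s); size distribution: %s", nrow(hits),
                    paste(utils::capture.output(print(table(hits$size_units))),
                          collapse = " ")))
    return(invisible(hits))
  }
  hits
}
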