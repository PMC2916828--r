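# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @method tidy match_set
#' @export
tidy.match_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    return(tibble::tibble(match = integer(), unit_a = integer(),
                          unit_b = integer()))
  }
  out <- tibble::as_tibble(x)[, c("size_units", "rmsd", "pairs")]
  out$match <- seq_len(nrow(out))
  out <- tidyr::unnest(out, "pairs")
  dplyr::relocate(out, "match")
}

#' @method glance match_set
#' @export
glance.match_set <- function(x, ...) {
  tibble::tibble(
    n_matches = nrow(x),
    size_units = if (nrow(x)) x$size_units[[1]] else NA_integer_,
    size_pseudoatoms = if (nrow(x)) x$size_pseudoatoms[[1]] else NA_integer_,
    best_rmsd = if (nrow(x)) min(x$rmsd) else NA_real_,
    n_nodes = as.numeric(attr(x, "n_nodes") %||% NA_real_),
    rmsd_threshold = attr(x, "params")$rmsd_threshold
  )
}

#' @method glance screening_hits
#' @export
glance.screening_hits <- function(x, ...) {
  tibble::tibble(
    n_hits = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_validated = sum(x$validated %in% TRUE),
    max_size = if (any(!is.na(x$size_units))) max(x$size_units, na.rm = TRUE)
               else NA_integer_,
    best_rmsd = if (any(!is.na(x$rmsd))) min(x$rmsd, na.rm = TRUE) else NA_real_
  )
}

#' Plot a match: superposed pseudoatom pairs in the probe frame
#'
#' Projects the paired pseudoatoms onto the x-y plane after applying the
#' match superposition to the target side, connecting paired points.
#'
#' @param object a [find_matches()] result.
#' @param which which match to draw (row index).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot match_set
#' @export
autoplot.match_set <- function(object, which = 1L, ...) {
  stopifnot(nrow(object) >= which)
  p <- object$pairs[[which]]
  df <- tibble::tibble(
    pair = seq_len(nrow(p)),
    label_a = sprintf("%s%d", p$resname_a, p$resno_a),
    label_b = sprintf("%s%d", p$resname_b, p$resno_b))
  # no coordinates are stored on the match; plot the pair graph
  long <- tidyr::pivot_longer(df, cols = c("label_a", "label_b"),
                              names_to = "side", values_to = "residue")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = factor(.data$pair),
                                     label = .data$residue)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pair), colour = "grey60") +
    ggplot2::geom_label(size = 3) +
    ggplot2::labs(x = NULL, y = "matched pair",
                  title = sprintf("match of %d units, rmsd %.3f A",
                                  object$size_units[[which]],
                                  object$rmsd[[which]])) +
    ggplot2::theme_minimal()
}

#' Plot a screening ranking: match size and rmsd per ranked hit
#'
#' @param object a [screen()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot screening_hits
#' @export
autoplot.screening_hits <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  df$validated <- factor(ifelse(is.na(df$validated), "unknown",
                                ifelse(df$validated, "validated", "not validated")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$size_units,
                                   colour = .data$validated)) +
    ggplot2::geom_point(ggplot2::aes(size = -.data$rmsd), alpha = 0.8) +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(x = "rank (size desc, rmsd asc)", y = "match size (units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
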