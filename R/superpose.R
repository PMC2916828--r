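# Optimal rigid superposition (quaternion method).  The key matrix is built
# from the cross-covariance of the centred point sets; its largest eigenvalue
# gives the minimal rmsd and the corresponding eigenvector the optimal
# proper-rotation quaternion, so reflections are excluded by construction.

#' Optimal rigid superposition between two ordered point lists
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation of `R %*% b + t` from `a`, with the
#' correspondence taken positionally (point i of `points_b` onto point i of
#' `points_a`).  Reflections are never returned.  RMSD is unweighted:
#' `sqrt(sum(|a_i - (R b_i + t)|^2) / n)`.
#'
#' @param points_a,points_b n x 3 coordinate matrices (or data frames with
#'   `x`, `y`, `z` columns), equal `n >= 1`.
#' @return An object of class `superposition`: list with `rotation` (3x3,
#'   determinant +1), `translation` (length 3), `rmsd` and `n`.
#' @examples
#' a <- matrix(rnorm(15), ncol = 3)
#' s <- optimal_superposition(a, a)
#' s$rmsd  # 0
#' @export
optimal_superposition <- function(points_a, points_b) {
  A <- as_xyz_matrix(points_a)
  B <- as_xyz_matrix(points_b)
  if (nrow(A) != nrow(B)) stop("point lists differ in length")
  if (nrow(A) == 0L) stop("empty point lists")
  if (!all(is.finite(A)) || !all(is.finite(B))) stop("non-finite coordinates")
  res <- cpp_superpose(A, B)
  structure(list(rotation = res$rotation,
                 translation = as.numeric(res$translation),
                 rmsd = res$rmsd, n = nrow(A)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: n = %d, rmsd = %.4f A>\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a [optimal_superposition()] object.
#' @param points n x 3 matrix (the "b" frame).
#' @return Transformed n x 3 matrix in the "a" frame.
#' @export
apply_superposition <- function(sup, points) {
  m <- as_xyz_matrix(points)
  sweep(m %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' @method tidy superposition
#' @export
tidy.superposition <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("rotation[", rep(1:3, 3), ",", rep(1:3, each = 3), "]"),
             paste0("translation[", 1:3, "]")),
    estimate = c(as.numeric(x$rotation), x$translation)
  )
}

#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n = x$n,
                 det_rotation = det(x$rotation))
}

#' RMSD of two pseudoatom sets under a given unit correspondence
#'
#' Expands each unit pair into its paired pseudoatoms (first admissible
#' recipe correspondence under `rep`), flattens them in pairing order and
#' delegates to [optimal_superposition()].
#'
#' @param set_a,set_b [build_pseudoatoms()] sets.
#' @param pairs data frame with columns `unit_a`, `unit_b` (unit ids in
#'   `set_a` / `set_b`).
#' @param rep the shared [parse_representation()] object.
#' @return RMSD in Angstrom.
#' @export
rmsd_under_correspondence <- function(set_a, set_b, pairs, rep) {
  idx <- correspondence_points(set_a, set_b, pairs, rep)
  if (nrow(idx) == 0L) stop("correspondence pairs no pseudoatoms")
  A <- as.matrix(set_a[idx$ia, c("x", "y", "z")])
  B <- as.matrix(set_b[idx$ib, c("x", "y", "z")])
  optimal_superposition(A, B)$rmsd
}

# expand unit pairs into pseudoatom row indices using the first admissible
# instantiated pairing per unit pair
correspondence_points <- function(set_a, set_b, pairs, rep) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ua <- pairs$unit_a[[i]]
    ub <- pairs$unit_b[[i]]
    ra <- which(set_a$unit == ua)
    rb <- which(set_b$unit == ub)
    inst <- instantiate_pairings(set_a[ra, ], set_b[rb, ], rep)
    if (length(inst) == 0L) {
      stop(sprintf("no admissible pairing for units %s and %s", ua, ub))
    }
    out[[i]] <- tibble::tibble(ia = ra[inst[[1]]$ia], ib = rb[inst[[1]]$ib])
  }
  dplyr::bind_rows(out)
}
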