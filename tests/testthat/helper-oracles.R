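# Independent oracles and small fixture builders used across the suite.

# Kabsch SVD superposition, written independently of the package's
# quaternion path: rotate B onto A, reflections corrected via the sign of
# det(V U')
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = ca - as.vector(R %*% cb),
       rmsd = sqrt(sum((Ac - Bc %*% t(R))^2) / nrow(A)))
}

kabsch_rmsd <- function(A, B) kabsch_superpose(A, B)$rmsd

# Brute-force reference for the search: enumerate candidate subsets through
# their ascending-id growth chain, requiring every link to superimpose under
# the threshold (the same completion rule the package implements), with the
# rmsd computed by the independent Kabsch oracle.  Returns all maxima.
oracle_find_matches <- function(cands, A, B, threshold) {
  nc <- nrow(cands)
  env <- new.env()
  env$best <- 0L
  env$sols <- list()
  env$rmsds <- numeric(0)
  rec <- function(cur, last, usedA, usedB) {
    for (c in seq_len(nc)) {
      if (c <= last) next
      if (cands$unit_a[[c]] %in% usedA || cands$unit_b[[c]] %in% usedB) next
      ia <- unlist(cands$ia[c(cur, c)])
      ib <- unlist(cands$ib[c(cur, c)])
      r <- kabsch_rmsd(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
      if (r > threshold) next
      S <- c(cur, c)
      if (length(S) > env$best) {
        env$best <- length(S)
        env$sols <- list()
        env$rmsds <- numeric(0)
      }
      if (length(S) == env$best) {
        env$sols[[length(env$sols) + 1L]] <- S
        env$rmsds <- c(env$rmsds, r)
      }
      rec(S, c, c(usedA, cands$unit_a[[c]]), c(usedB, cands$unit_b[[c]]))
    }
  }
  if (nc > 0) rec(integer(0), 0L, integer(0), integer(0))
  env
}

# canonical key for a match's unordered pair-set
pair_set_key <- function(unit_a, unit_b) {
  paste(sort(paste0(unit_a, ":", unit_b)), collapse = ";")
}

# raw single-point pseudoatom set (one CA unit per residue) without going
# through a structure model
make_ps <- function(coords, resnames, chain = "A") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  structure(
    tibble::tibble(unit = seq_len(n), chain = chain, resno = seq_len(n),
                   icode = "", resname = resnames, recipe = "CA",
                   src_recipe = "CA", x = coords[, 1], y = coords[, 2],
                   z = coords[, 3]),
    mode = "grouped", rep_id = "raw", source = list(id = "raw"),
    class = c("pseudoatom_set", class(tibble::tibble())))
}

# exhaustive concordant-pair AUC (midrank ties) for label/score vectors
auc_by_counting <- function(labels, scores = NULL) {
  if (is.null(scores)) scores <- rev(seq_along(labels))
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# does any returned maximum contain all ground-truth pairs?
recovered_truth <- function(matches, truth) {
  if (nrow(matches) == 0L) return(FALSE)
  for (i in seq_len(nrow(matches))) {
    p <- matches$pairs[[i]]
    got <- paste(p$resno_a, p$resno_b)
    want <- paste(truth$resno_a, truth$resno_b)
    if (all(want %in% got)) return(TRUE)
  }
  FALSE
}

rigid_transform_ps <- function(set, R, tr) {
  xyz <- as.matrix(set[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(R), 2, tr, "+")
  set$x <- new[, 1]
  set$y <- new[, 2]
  set$z <- new[, 3]
  set
}
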