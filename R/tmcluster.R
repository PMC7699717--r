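#' Kabsch superposition
#'
#' Least-squares optimal proper rotation and translation of `P` onto `Q`
#' with positional correspondence. Reflections are corrected: if the naive
#' SVD solution is improper, the smallest singular direction is flipped so
#' the returned rotation has determinant +1.
#'
#' @param P,Q numeric n x 3 matrices (n >= 3) of corresponding points.
#' @return A `superposition`: list with `rotation` (3 x 3, proper
#'   orthonormal), `translation` (length-3, so that `Q ~ P %*% t(R) + t`),
#'   `rmsd` (angstroms) and `degenerate` (TRUE when the point set is
#'   rank-deficient, e.g. collinear).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- unclass(as.matrix(P)); Q <- unclass(as.matrix(Q))
  if (nrow(P) != nrow(Q)) stop("point sets differ in size", call. = FALSE)
  if (nrow(P) < 3) stop("need at least 3 points", call. = FALSE)
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  H <- crossprod(Pc, Qc)                    # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transl <- as.numeric(cQ - R %*% cP)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  degenerate <- s$d[2] < 1e-8 * max(s$d[1], 1e-300)
  structure(list(rotation = R, translation = transl, rmsd = rmsd,
                 degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A%s\n", x$rmsd,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

# Apply a superposition to an n x 3 matrix.
apply_superposition <- function(sup, P) {
  sweep(unclass(as.matrix(P)) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 angstrom — the
#' clamp matters for peptides, which are mostly shorter than the formula's
#' L = 15 pole.
#'
#' @param L normalising length in residues.
#' @return d0 in angstroms.
#' @export
tm_d0 <- function(L) {
  raw <- 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8
  max(0.5, raw)
}

#' TM-score between two C-alpha traces
#'
#' Heuristic maximisation of `(1/L_norm) * sum 1/(1 + (d_i/d0)^2)` over
#' residue correspondences, normalised by `L_norm = min(L_a, L_b)` so the
#' score is symmetric and suitable for undirected fold clustering. Scores
#' of 0.5 and above indicate the same fold topology.
#'
#' The search seeds correspondences by gapless threading of the shorter
#' trace at every offset of the longer one, then iterates (at most
#' `max_iter` rounds per seed): superpose on the currently aligned pairs,
#' recompute inter-residue distances, and realign by dynamic programming
#' with pair score `1/(1 + (d/d0)^2)` and gap penalty `gap`. Iteration
#' stops when the aligned pair set repeats; the best-scoring correspondence
#' over all seeds is returned. Arguments are ordered internally so the
#' result is independent of argument order.
#'
#' @param a,b `ca_trace` objects (or L x 3 matrices), L >= 3 each.
#' @param gap gap penalty of the realignment DP.
#' @param max_iter iteration cap per seed.
#' @return A `tm_score_result`: list with `score`, `d0`, `L_norm`,
#'   `aligned_pairs` (m x 2 matrix of 0-based indices into `a` and `b`)
#'   and `superposition`.
#' @export
tm_score <- function(a, b, gap = -0.6, max_iter = 20) {
  A <- unclass(as.matrix(a)); B <- unclass(as.matrix(b))
  if (nrow(A) < 3 || nrow(B) < 3) {
    stop("trace too short for superposition", call. = FALSE)
  }
  swapped <- nrow(A) > nrow(B)
  if (swapped) { tmp <- A; A <- B; B <- tmp }      # A is the shorter
  La <- nrow(A); Lb <- nrow(B)
  L_norm <- La
  d0 <- tm_d0(L_norm)
  d0sq <- d0^2

  score_pairs <- function(pairs) {
    # superpose on the pairs, return score and the superposition
    sup <- kabsch_superpose(A[pairs[, 1], , drop = FALSE],
                            B[pairs[, 2], , drop = FALSE])
    At <- apply_superposition(sup, A)
    dsq <- rowSums((At[pairs[, 1], , drop = FALSE] -
                    B[pairs[, 2], , drop = FALSE])^2)
    list(score = sum(1 / (1 + dsq / d0sq)) / L_norm, sup = sup, At = At)
  }

  best <- list(score = -Inf, pairs = NULL, sup = NULL)
  offsets <- 0:(Lb - La)
  for (off in offsets) {
    pairs <- cbind(seq_len(La), seq_len(La) + off)
    seen <- character(0)
    for (iter in seq_len(max_iter)) {
      key <- paste(pairs[, 1], pairs[, 2], collapse = ",")
      if (key %in% seen) break
      seen <- c(seen, key)
      sc <- score_pairs(pairs)
      if (sc$score > best$score) {
        best <- list(score = sc$score, pairs = pairs, sup = sc$sup)
      }
      # realign under the current superposition
      D <- outer(rowSums(sc$At^2), rowSums(B^2), `+`) -
        2 * sc$At %*% t(B)
      S <- 1 / (1 + pmax(D, 0) / d0sq)
      aln <- cpp_nw_matrix(S, gap)
      if (length(aln$ai) < 3) break
      pairs <- cbind(aln$ai, aln$bi)
    }
  }

  pairs0 <- best$pairs - 1L                        # 0-based
  if (swapped) pairs0 <- pairs0[, c(2, 1), drop = FALSE]
  structure(list(score = min(best$score, 1), d0 = d0, L_norm = L_norm,
                 aligned_pairs = pairs0, superposition = best$sup),
            class = "tm_score_result")
}

#' @export
print.tm_score_result <- function(x, ...) {
  cat(sprintf("tm_score: %.4f (d0 %.2f A, L_norm %d, %d aligned pairs)\n",
              x$score, x$d0, x$L_norm, nrow(x$aligned_pairs)))
  invisible(x)
}

#' Group structures into fold clusters by TM-score
#'
#' Greedy leader clustering at the topology cutoff: structures are visited
#' by decreasing length (ties: id order); each joins the first leader with
#' TM-score >= `cutoff`, otherwise founds a new cluster. Clusters are then
#' renumbered 1..K by decreasing size (ties: smallest member id first).
#'
#' @param traces named list of `ca_trace` objects.
#' @param cutoff TM-score threshold, default 0.5.
#' @param ... passed to [tm_score()].
#' @return A `fold_clustering`: list with `cluster_of` (named integer map
#'   structure id -> cluster index) and `cutoff`.
#' @export
cluster_structures <- function(traces, cutoff = 0.5, ...) {
  if (length(traces) == 0) stop("no traces", call. = FALSE)
  ids <- names(traces)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("traces must be a named list", call. = FALSE)
  }
  lens <- vapply(traces, nrow, integer(1))
  ord <- order(-lens, ids)
  leaders <- integer(0)                    # indices into ord'd list
  member_of <- integer(length(ord))        # provisional cluster per visit
  for (k in seq_along(ord)) {
    placed <- 0L
    for (li in seq_along(leaders)) {
      s <- tm_score(traces[[ord[leaders[li]]]], traces[[ord[k]]], ...)
      if (s$score >= cutoff) { placed <- li; break }
    }
    if (placed == 0L) {
      leaders <- c(leaders, k)
      placed <- length(leaders)
    }
    member_of[k] <- placed
  }
  # renumber by decreasing size, ties by smallest member id
  sizes <- tabulate(member_of, nbins = length(leaders))
  min_id <- vapply(seq_along(leaders), function(ci) {
    min(ids[ord][member_of == ci])
  }, character(1))
  new_order <- order(-sizes, min_id)
  renumber <- match(seq_along(leaders), new_order)
  cluster_of <- setNames(renumber[member_of], ids[ord])[ids]
  structure(list(cluster_of = cluster_of, cutoff = cutoff),
            class = "fold_clustering")
}

#' @export
print.fold_clustering <- function(x, ...) {
  k <- max(x$cluster_of)
  cat(sprintf("fold_clustering: %d structures in %d clusters (cutoff %g)\n",
              length(x$cluster_of), k, x$cutoff))
  invisible(x)
}
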