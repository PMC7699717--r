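# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths of the package functions they check.

# Enumerate every global alignment of a and b; return the maximum score
# and, over all score-optimal alignments, the attainable match counts.
brute_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ac) && j > length(bc)) {
      return(matrix(c(0, 0), 1))           # (score, nmatch)
    }
    out <- NULL
    if (i <= length(ac) && j <= length(bc)) {
      sub <- rec(i + 1, j + 1)
      s <- if (ac[i] == bc[j]) c(match, 1) else c(mismatch, 0)
      out <- rbind(out, sweep(sub, 2, s, `+`))
    }
    if (i <= length(ac)) {
      sub <- rec(i + 1, j)
      out <- rbind(out, sweep(sub, 2, c(gap, 0), `+`))
    }
    if (j <= length(bc)) {
      sub <- rec(i, j + 1)
      out <- rbind(out, sweep(sub, 2, c(gap, 0), `+`))
    }
    unique(out)
  }
  all_aln <- rec(1, 1)
  best <- max(all_aln[, 1])
  list(score = best, nmatch = sort(unique(all_aln[all_aln[, 1] == best, 2])))
}

# Exhaustive hypergeometric tail: enumerate all C(N, n) samples of a
# population whose first M elements are marked; fraction with >= m marked.
enum_hypergeom_tail <- function(N, M, n, m) {
  if (m == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  marked <- colSums(subsets <= M)
  mean(marked >= m)
}

# Step-up BH written directly from its definition.
stepup_bh <- function(p) {
  k <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(k)
  for (i in seq_len(k)) {
    q[i] <- min(1, min(ps[i:k] * k / (i:k)))
  }
  out <- numeric(k)
  out[ord] <- q
  out
}

# Coarse-to-fine grid search over rotations (ZYZ Euler angles) for the
# minimum RMSD superposition of P onto Q (centroids matched).
grid_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  rmsd_at <- function(a, b, c) {
    sqrt(mean(rowSums((Pc %*% t(rot(a, b, c)) - Qc)^2)))
  }
  centre <- c(0, pi / 2, 0)
  width <- pi
  best <- c(Inf, centre)
  for (pass in 1:6) {
    grid <- seq(-width, width, length.out = 9)
    for (a in centre[1] + grid) for (b in centre[2] + grid)
      for (c in centre[3] + grid) {
        r <- rmsd_at(a, b, c)
        if (r < best[1]) best <- c(r, a, b, c)
      }
    centre <- best[2:4]
    width <- width / 4
  }
  best[1]
}
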