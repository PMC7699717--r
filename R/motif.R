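#' Star alignment against the longest sequence
#'
#' Anchor-based multiple alignment: the longest sequence (ties broken by
#' id) is the anchor; every other sequence is globally aligned to it with
#' the clustering scoring (match +1, mismatch 0, gap -1), and the
#' anchor-relative insertions are merged into common columns. Adequate for
#' the short, family-homogeneous peptide sets that enrichment produces.
#'
#' @param seqs named character vector of at least two sequences.
#' @param config a [cluster_config()] giving the alignment scoring.
#' @return A `star_alignment`: list with `anchor_id`, `rows` (named
#'   character vector of equal-length gapped sequences, gap = `-`) and
#'   `n_columns`.
#' @export
star_align <- function(seqs, config = cluster_config()) {
  seqs <- unlist(as.list(seqs))
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  ord <- order(-nchar(seqs), names(seqs))
  anchor_id <- names(seqs)[ord[1]]
  anchor <- seqs[[anchor_id]]
  La <- nchar(anchor)
  others <- setdiff(names(seqs), anchor_id)

  # pairwise alignments to the anchor; slot k = insertions before anchor
  # position k (slot La+1 = after the anchor)
  alns <- lapply(others, function(id) {
    r <- cpp_nw_seq(anchor, seqs[[id]], config$match, config$mismatch,
                    config$gap)
    cbind(r$ai, r$bi)
  })
  names(alns) <- others

  ins <- integer(La + 1)
  slot_runs <- lapply(others, function(id) {
    pairs <- alns[[id]]
    Lb <- nchar(seqs[[id]])
    runs <- vector("list", La + 1)
    bounds_a <- c(0L, pairs[, 1], La + 1L)
    bounds_b <- c(0L, pairs[, 2], NA)
    for (g in seq_len(length(bounds_a) - 1)) {
      lo <- bounds_b[g]
      hi <- if (g == length(bounds_a) - 1) Lb + 1L else bounds_b[g + 1]
      if (hi - lo > 1) {
        slot <- bounds_a[g] + 1L
        runs[[slot]] <- (lo + 1L):(hi - 1L)
      }
    }
    runs
  })
  names(slot_runs) <- others
  for (runs in slot_runs) {
    ins <- pmax(ins, vapply(runs, length, integer(1)))
  }

  # column layout: [ins slot k][anchor col k] for k = 1..La, then slot La+1
  n_columns <- La + sum(ins)
  slot_start <- cumsum(c(1L, ins[seq_len(La)] + 1L))  # start col of slot k
  anchor_col <- slot_start[seq_len(La)] + ins[seq_len(La)]

  rows <- list()
  anchor_row <- rep("-", n_columns)
  anchor_row[anchor_col] <- strsplit(anchor, "")[[1]]
  rows[[anchor_id]] <- paste(anchor_row, collapse = "")

  for (id in others) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    row <- rep("-", n_columns)
    pairs <- alns[[id]]
    row[anchor_col[pairs[, 1]]] <- chars[pairs[, 2]]
    runs <- slot_runs[[id]]
    for (k in seq_len(La + 1)) {
      run <- runs[[k]]
      if (length(run)) {
        row[slot_start[k] + seq_along(run) - 1L] <- chars[run]
      }
    }
    rows[[id]] <- paste(row, collapse = "")
  }
  rows <- unlist(rows[names(seqs)])

  structure(list(anchor_id = anchor_id, rows = rows,
                 n_columns = n_columns),
            class = "star_alignment")
}

#' @export
print.star_alignment <- function(x, ...) {
  cat(sprintf("star_alignment: %d rows x %d columns (anchor %s)\n",
              length(x$rows), x$n_columns, x$anchor_id))
  invisible(x)
}

#' Per-column conservation summary of an alignment
#'
#' Computes per-column residue frequencies (gaps excluded from the
#' denominator), information content in bits (`log2(20)` minus the Shannon
#' entropy of the residue distribution) and a consensus string: a column
#' shows its modal residue when that residue's frequency reaches
#' `min_freq` among covering rows and at least `min_coverage` of the rows
#' cover the column; otherwise `.`.
#'
#' @param aln a [star_align()] result.
#' @param min_freq modal-residue frequency needed for conservation.
#' @param min_coverage minimum fraction of rows covering the column.
#' @return A `motif_summary`: list with `table` (one row per column:
#'   `column`, `coverage`, `modal_residue`, `modal_freq`,
#'   `information_bits`, `consensus_char`) and `consensus` (the string).
#' @export
consensus_motif <- function(aln, min_freq = 0.5, min_coverage = 0.5) {
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  nr <- nrow(mat)
  tab <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    coverage <- length(res) / nr
    if (length(res) == 0) {
      return(data.frame(column = j, coverage = 0,
                        modal_residue = NA_character_, modal_freq = 0,
                        information_bits = 0, consensus_char = ".",
                        stringsAsFactors = FALSE))
    }
    freq <- table(res) / length(res)
    modal <- names(freq)[which.max(freq)]         # ties: alphabetical
    modal_freq <- max(freq)
    info <- log2(20) + sum(freq * log2(freq))
    conserved <- modal_freq >= min_freq && coverage >= min_coverage
    data.frame(column = j, coverage = coverage, modal_residue = modal,
               modal_freq = as.numeric(modal_freq),
               information_bits = max(info, 0),
               consensus_char = if (conserved) modal else ".",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  structure(list(table = tab,
                 consensus = paste(tab$consensus_char, collapse = "")),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("motif_summary:", x$consensus, "\n")
  invisible(x)
}
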