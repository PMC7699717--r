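#' Clustering configuration
#'
#' @param thresholds identity thresholds swept when building representative
#'   sets; fractions in (0, 1], default 100% down to 40% in steps of 10%.
#' @param match,mismatch,gap alignment scoring used to measure identity:
#'   match reward, mismatch score and linear gap penalty.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(thresholds = c(1.00, 0.90, 0.80, 0.70, 0.60,
                                          0.50, 0.40),
                           match = 1, mismatch = 0, gap = -1) {
  thresholds <- sort(unique(as.numeric(thresholds)), decreasing = TRUE)
  if (any(thresholds <= 0) || any(thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(thresholds = thresholds, match = match,
                 mismatch = mismatch, gap = gap),
            class = "cluster_config")
}

#' Pairwise sequence identity
#'
#' Identity between two sequences under a global alignment that maximises
#' the configured score (match +1, mismatch 0, linear gap -1 by default).
#' The identity is the number of identical aligned residue pairs divided by
#' the length of the shorter sequence, so a perfect substring scores 1.
#'
#' @param a,b non-empty sequences.
#' @param config a [cluster_config()].
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_identity("KWKLF", "KWKLF")
pairwise_identity <- function(a, b, config = cluster_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (a == b) return(1)
  res <- cpp_nw_seq(a, b, config$match, config$mismatch, config$gap)
  res$nmatch / min(nchar(a), nchar(b))
}

#' Greedy sequence-identity clustering
#'
#' Leader clustering: peptides are visited in order of decreasing length
#' (ties broken by id); a peptide joins the first existing representative
#' with identity >= `threshold`, otherwise it founds a new cluster. The
#' procedure is deterministic for a fixed input.
#'
#' @param dataset an [amp_dataset()].
#' @param threshold identity fraction in (0, 1].
#' @param config a [cluster_config()] giving the alignment scoring.
#' @return A `cluster_assignment`: list with `threshold`,
#'   `representative_of` (named character map member id -> representative
#'   id) and `representatives` (ids in founding order).
#' @export
greedy_cluster <- function(dataset, threshold, config = cluster_config()) {
  p <- dataset$peptides
  if (nrow(p) == 0) stop("empty dataset", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(p$sequence), p$id)
  ids <- p$id[ord]
  seqs <- p$sequence[ord]

  rep_ids <- character(0)
  rep_seqs <- character(0)
  assign <- character(length(ids))
  for (k in seq_along(ids)) {
    joined <- NA_character_
    for (r in seq_along(rep_ids)) {
      if (pairwise_identity(seqs[k], rep_seqs[r], config) >= threshold) {
        joined <- rep_ids[r]
        break
      }
    }
    if (is.na(joined)) {
      rep_ids <- c(rep_ids, ids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
      joined <- ids[k]
    }
    assign[k] <- joined
  }
  structure(list(threshold = threshold,
                 representative_of = setNames(assign, ids),
                 representatives = rep_ids),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d members -> %d representatives at T=%g\n",
              length(x$representative_of), length(x$representatives),
              x$threshold))
  invisible(x)
}

#' Build representative sets over a threshold sweep
#'
#' Runs [greedy_cluster()] at every configured threshold and reduces the
#' dataset to the representatives. Each representative keeps its own
#' record unmodified (annotations are not unioned over cluster members).
#'
#' @param dataset an [amp_dataset()].
#' @param config a [cluster_config()].
#' @return List with `datasets` (named by percent threshold, e.g. `"100"`)
#'   and `assignments` (the matching `cluster_assignment`s).
#' @export
representative_sweep <- function(dataset, config = cluster_config()) {
  datasets <- list()
  assignments <- list()
  for (t in config$thresholds) {
    label <- sprintf("%g", t * 100)
    asg <- greedy_cluster(dataset, t, config)
    prov <- dataset$provenance
    prov$identity_threshold <- t
    datasets[[label]] <- subset_dataset(dataset, asg$representatives, prov)
    assignments[[label]] <- asg
  }
  list(datasets = datasets, assignments = assignments)
}
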