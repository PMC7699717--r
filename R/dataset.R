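#' Construct a peptide dataset
#'
#' The central container: one row per peptide with its sequence, activity
#' set, optional structural labels (at most one per scheme) and an optional
#' path to a C-alpha coordinate file. Invariants enforced: unique ids,
#' non-empty uppercase sequences, non-empty validated activity sets.
#'
#' @param peptides a data.frame with columns `id`, `sequence`, `activities`
#'   (a list column of character vectors) and optionally `cath_class`,
#'   `cath_arch`, `scop_class`, `scop_fold`, `tm_cluster`, `trace_path`.
#'   Missing structural columns are added as `NA`.
#' @param provenance free-form list of metadata (source, threshold, seed).
#' @return An object of class `amp_dataset`: a list with elements
#'   `peptides` (the validated data.frame) and `provenance`.
#' @export
#' @examples
#' d <- amp_dataset(data.frame(id = "p1", sequence = "KWKLFKK",
#'                             activities = I(list("G"))))
#' d
amp_dataset <- function(peptides, provenance = list()) {
  stopifnot(is.data.frame(peptides))
  need <- c("id", "sequence", "activities")
  miss <- setdiff(need, names(peptides))
  if (length(miss)) stop("missing peptide columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  opt <- c("cath_class", "cath_arch", "scop_class", "scop_fold",
           "tm_cluster", "trace_path")
  for (col in opt) {
    if (!col %in% names(peptides)) peptides[[col]] <- NA_character_
    peptides[[col]] <- as.character(peptides[[col]])
    blank <- !is.na(peptides[[col]]) & !nzchar(trimws(peptides[[col]]))
    peptides[[col]][blank] <- NA_character_
  }
  peptides$id <- as.character(peptides$id)
  peptides$sequence <- toupper(as.character(peptides$sequence))
  rownames(peptides) <- NULL

  dup <- peptides$id[duplicated(peptides$id)]
  if (length(dup)) stop("duplicate id: ", dup[1], call. = FALSE)
  if (any(!nzchar(peptides$sequence))) {
    stop("empty sequence for peptide ",
         peptides$id[!nzchar(peptides$sequence)][1], call. = FALSE)
  }
  acts <- peptides$activities
  if (!is.list(acts)) acts <- as.list(acts)
  acts <- lapply(seq_along(acts), function(i) {
    a <- unique(as.character(acts[[i]]))
    if (length(a) == 0 || all(is.na(a))) {
      stop("empty activity set: ", peptides$id[i], call. = FALSE)
    }
    vapply(a, normalize_activity, character(1), USE.NAMES = FALSE)
  })
  peptides$activities <- I(acts)

  # arch/fold labels require (or tolerate) a known first level; "*" stands
  # for an unspecified class
  bad <- !is.na(peptides$cath_arch) & is.na(peptides$cath_class)
  peptides$cath_class[bad] <- "*"
  bad <- !is.na(peptides$scop_fold) & is.na(peptides$scop_class)
  peptides$scop_class[bad] <- "*"

  structure(list(peptides = peptides, provenance = provenance),
            class = "amp_dataset")
}

#' @export
print.amp_dataset <- function(x, ...) {
  p <- x$peptides
  cat("amp_dataset:", nrow(p), "peptides\n")
  act <- sort(table(unlist(p$activities)), decreasing = TRUE)
  cat("  activities:",
      paste(sprintf("%s=%d", names(act), act), collapse = " "), "\n")
  for (s in c("CATH", "SCOP", "TM")) {
    cat(sprintf("  %s-annotated: %d\n", s, sum(scheme_annotated(x, s))))
  }
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance), unlist(lapply(x$provenance, format)),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of peptides in a dataset
#' @param dataset an `amp_dataset`.
#' @return Integer count.
#' @export
n_peptides <- function(dataset) nrow(dataset$peptides)

#' Which peptides carry a structural label under a scheme?
#'
#' @param dataset an `amp_dataset`.
#' @param scheme one of `"CATH"`, `"SCOP"`, `"TM"`.
#' @return Logical vector, one element per peptide.
#' @export
scheme_annotated <- function(dataset, scheme) {
  p <- dataset$peptides
  switch(match.arg(scheme, c("CATH", "SCOP", "TM")),
         CATH = !is.na(p$cath_class),
         SCOP = !is.na(p$scop_class),
         TM   = !is.na(p$tm_cluster))
}

# Per-peptide structural category key under (scheme, level); NA when the
# peptide carries no label at that level. Level-2 keys are "level1|level2".
# TM has a single level (the cluster id).
peptide_categories <- function(dataset, scheme, level = 1) {
  scheme <- match.arg(scheme, c("CATH", "SCOP", "TM"))
  p <- dataset$peptides
  if (scheme == "TM") return(p$tm_cluster)
  l1 <- if (scheme == "CATH") p$cath_class else p$scop_class
  if (level == 1) return(l1)
  l2 <- if (scheme == "CATH") p$cath_arch else p$scop_fold
  ifelse(is.na(l2), NA_character_, paste(l1, l2, sep = "|"))
}

# Split a category key back into (level1, level2) for reporting.
split_category_key <- function(key, scheme, level) {
  if (scheme == "TM" || level == 1) {
    return(data.frame(level1 = key, level2 = "*",
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(level1 = vapply(parts, `[`, character(1), 1),
             level2 = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Which peptides carry a given activity?
#' @param dataset an `amp_dataset`.
#' @param activity a canonical activity code.
#' @return Logical vector, one element per peptide.
#' @export
has_activity <- function(dataset, activity) {
  activity <- normalize_activity(activity)
  vapply(dataset$peptides$activities, function(a) activity %in% a, logical(1))
}

#' Subset a dataset by peptide id
#' @param dataset an `amp_dataset`.
#' @param ids character vector of peptide ids to keep (order respected).
#' @param provenance replacement provenance; default keeps the old one.
#' @return An `amp_dataset` with only the requested peptides.
#' @export
subset_dataset <- function(dataset, ids, provenance = dataset$provenance) {
  idx <- match(ids, dataset$peptides$id)
  if (anyNA(idx)) stop("unknown peptide id: ", ids[is.na(idx)][1],
                       call. = FALSE)
  amp_dataset(dataset$peptides[idx, , drop = FALSE], provenance)
}
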