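#' Read peptide sequences from FASTA
#'
#' Sequences are uppercased and order is preserved. Ids are the header text
#' up to the first whitespace. Non-standard residue letters (B, J, O, U, X,
#' Z) are retained but reported in a warning.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of uppercase sequences (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id: ", dup[1], call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  odd <- grepl("[BJOUXZ]", seqs)
  if (any(odd)) {
    warning("non-standard residues (B/J/O/U/X/Z) in: ",
            paste(ids[odd], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

ANNOTATION_COLUMNS <- c("peptide_id", "activities", "cath_class",
                        "cath_arch", "scop_class", "scop_fold",
                        "tm_cluster", "trace_path")

#' Read an annotation table and join it with sequences
#'
#' The table is tab-separated with header columns `peptide_id`,
#' `activities` (a `;`-separated activity set) and six optional columns:
#' `cath_class`, `cath_arch`, `scop_class`, `scop_fold`, `tm_cluster`,
#' `trace_path`. Blank structural cells mean "no label under that scheme".
#'
#' @param path path to the TSV.
#' @param sequences named character vector as returned by [read_fasta()];
#'   every annotated peptide must have a sequence.
#' @return An [amp_dataset()].
#' @export
read_annotations <- function(path, sequences) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  if (!all(c("peptide_id", "activities") %in% names(tab))) {
    stop("annotation table must have peptide_id and activities columns",
         call. = FALSE)
  }
  for (col in ANNOTATION_COLUMNS) {
    if (!col %in% names(tab)) tab[[col]] <- ""
  }
  idx <- match(tab$peptide_id, names(sequences))
  if (anyNA(idx)) {
    stop("no sequence for peptide: ", tab$peptide_id[is.na(idx)][1],
         call. = FALSE)
  }
  acts <- lapply(seq_len(nrow(tab)), function(i) {
    parse_activities(tab$activities[i], id = tab$peptide_id[i])
  })
  blank_na <- function(x) ifelse(nzchar(trimws(x)), trimws(x), NA_character_)
  peptides <- data.frame(id = tab$peptide_id,
                         sequence = unname(sequences[idx]),
                         stringsAsFactors = FALSE)
  peptides$activities <- I(acts)
  for (col in ANNOTATION_COLUMNS[-(1:2)]) {
    peptides[[col]] <- blank_na(tab[[col]])
  }
  amp_dataset(peptides, provenance = list(source = path))
}

#' Write a dataset's annotation table
#'
#' Inverse of [read_annotations()]: a write-then-read round trip
#' reproduces ids, activity sets and structural labels exactly.
#'
#' @param dataset an `amp_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(dataset, path) {
  p <- dataset$peptides
  out <- data.frame(
    peptide_id = p$id,
    activities = vapply(p$activities, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  for (col in ANNOTATION_COLUMNS[-(1:2)]) {
    out[[col]] <- ifelse(is.na(p[[col]]), "", p[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a C-alpha trace from a PDB-format file
#'
#' Uses the first model only; keeps CA `ATOM` records with blank or `'A'`
#' alternate-location codes; orders residues by residue number with
#' insertion codes after their base number.
#'
#' @param path path to a PDB-format coordinate file.
#' @param chain chain identifier; default is the first chain encountered.
#' @return A `ca_trace`: a numeric L x 3 matrix of coordinates in
#'   angstroms with attribute `id` (the file's base name).
#' @export
read_ca_trace <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms in ", path, call. = FALSE)
  if (is.null(chain)) {
    chain <- at$chain[1]
  } else if (!chain %in% at$chain) {
    stop("chain ", chain, " not found in ", path, call. = FALSE)
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  at <- at[order(at$resno, ins), , drop = FALSE]
  coords <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("non-finite coordinates in ", path,
                                    call. = FALSE)
  ca_trace(coords, id = tools::file_path_sans_ext(basename(path)))
}

#' Construct a C-alpha trace
#'
#' @param coords numeric L x 3 matrix of coordinates (angstroms).
#' @param id optional identifier.
#' @return A `ca_trace` object.
#' @export
ca_trace <- function(coords, id = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 1) {
    stop("coords must be an L x 3 matrix with L >= 1", call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  dimnames(coords) <- NULL
  structure(coords, class = c("ca_trace", "matrix"), id = id)
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("ca_trace:", nrow(x), "residues",
      if (!is.null(attr(x, "id"))) paste0("(", attr(x, "id"), ")"), "\n")
  invisible(x)
}

trace_length <- function(trace) nrow(trace)

#' Write a C-alpha trace as minimal PDB ATOM records
#'
#' Emits one CA `ATOM` line per residue (GLY, chain A), sufficient for
#' [read_ca_trace()] round trips and external structure viewers.
#'
#' @param trace a `ca_trace` or L x 3 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(trace, path) {
  coords <- unclass(trace)
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), seq_len(nrow(coords)),
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
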