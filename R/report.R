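#' Render the arrow matrix as a summary table
#'
#' One row per (scheme, level1, level2, activity) that qualifies by the
#' `min_table` original-count filter, one column per identity threshold;
#' arrows are encoded `"->"` (function enriched in structure), `"<-"`
#' (structure enriched in function), `"<->"` (mutual) and `"."` (neither).
#' Level-1 rows carry `"*"` in the `level2` column (all structures of the
#' class). Activities are shown in display form (`G+`, `G-`).
#'
#' @param mutual arrow rows from [enrichment_sweep()] or
#'   [mutual_classify()].
#' @param config an [enrich_config()]; rows below `min_table` original
#'   members are suppressed.
#' @param drop_empty drop rows whose arrows are all `"."` (default TRUE,
#'   matching a summary table of significant relationships only).
#' @return data.frame with columns `scheme`, `level1`, `level2`,
#'   `activity` and one character column per threshold (percent labels).
#' @export
render_arrow_matrix <- function(mutual, config = enrich_config(),
                                drop_empty = TRUE) {
  m <- mutual[mutual$qualifies_table, , drop = FALSE]
  thr <- sort(unique(m$threshold), decreasing = TRUE)
  labels <- sprintf("%g", thr * 100)
  keys <- unique(m[, c("scheme", "level1", "level2", "activity")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- m$scheme == k$scheme & m$level1 == k$level1 &
      m$level2 == k$level2 & m$activity == k$activity
    arrows <- setNames(rep(".", length(thr)), labels)
    got <- m[sel, c("threshold", "arrow")]
    arrows[sprintf("%g", got$threshold * 100)] <- got$arrow
    out <- data.frame(scheme = k$scheme, level1 = k$level1,
                      level2 = k$level2,
                      activity = activity_display(k$activity),
                      stringsAsFactors = FALSE)
    for (lb in labels) out[[lb]] <- arrows[[lb]]
    out
  })
  out <- do.call(rbind, rows)
  if (drop_empty) {
    any_sig <- apply(out[, labels, drop = FALSE], 1,
                     function(r) any(r != "."))
    out <- out[any_sig, , drop = FALSE]
  }
  ord <- order(out$scheme, out$level1, out$level2, out$activity)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category activity count tables
#'
#' For each scheme, level and category: the number of peptides in the
#' category (the "potential maximum" bar of a count plot) and the count
#' carrying each activity.
#'
#' @param dataset an [amp_dataset()].
#' @param schemes schemes to tabulate; default all with labels.
#' @return data.frame with `scheme`, `level`, `level1`, `level2`,
#'   `n_category` and one count column per activity code.
#' @export
count_tables <- function(dataset, schemes = NULL) {
  if (is.null(schemes)) {
    schemes <- c("CATH", "SCOP", "TM")
    schemes <- schemes[vapply(schemes, function(s)
      any(scheme_annotated(dataset, s)), logical(1))]
  }
  acts <- activity_codes()
  act_mat <- matrix(FALSE, n_peptides(dataset), length(acts),
                    dimnames = list(NULL, acts))
  for (f in acts) act_mat[, f] <- has_activity(dataset, f)
  rows <- list()
  for (scheme in schemes) {
    for (lv in if (scheme == "TM") 1 else c(1, 2)) {
      cat_key <- peptide_categories(dataset, scheme, lv)
      for (s in sort(unique(cat_key[!is.na(cat_key)]))) {
        in_s <- !is.na(cat_key) & cat_key == s
        splt <- split_category_key(s, scheme, lv)
        row <- data.frame(scheme = scheme, level = lv,
                          level1 = splt$level1, level2 = splt$level2,
                          n_category = sum(in_s),
                          stringsAsFactors = FALSE)
        for (f in acts) row[[f]] <- sum(in_s & act_mat[, f])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full enrichment pipeline and write its artifacts
#'
#' End-to-end orchestration: build representative sets at every threshold,
#' run both enrichment directions per scheme and level, classify mutual
#' arrows, and write per-threshold TSVs (representative annotations, test
#' rows, count tables), the arrow matrix, the cluster membership table and
#' a run log recording every configuration value. Output is deterministic:
#' rerunning with an identical input and configuration reproduces every
#' file byte for byte.
#'
#' @param dataset an [amp_dataset()] (alternatively give `fasta` and
#'   `annotations` paths).
#' @param out_dir output directory, created if absent.
#' @param fasta,annotations input paths, used when `dataset` is `NULL`.
#' @param cluster_cfg a [cluster_config()].
#' @param enrich_cfg an [enrich_config()].
#' @param schemes schemes to analyse; default all with labels.
#' @param force overwrite an existing non-empty `out_dir` (default FALSE).
#' @return Invisibly, a list with `sweep` (representative sets and
#'   assignments), `results`, `mutual` and `arrow_matrix`.
#' @export
run_pipeline <- function(dataset = NULL, out_dir,
                         fasta = NULL, annotations = NULL,
                         cluster_cfg = cluster_config(),
                         enrich_cfg = enrich_config(),
                         schemes = NULL, force = FALSE) {
  if (is.null(dataset)) {
    if (is.null(fasta) || is.null(annotations)) {
      stop("give either a dataset or fasta + annotations paths",
           call. = FALSE)
    }
    dataset <- read_annotations(annotations, read_fasta(fasta))
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory not empty (use force = TRUE): ", out_dir,
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sw <- representative_sweep(dataset, cluster_cfg)
  en <- enrichment_sweep(dataset, sw$datasets, schemes, enrich_cfg)
  arrows <- render_arrow_matrix(en$mutual, enrich_cfg)

  members <- do.call(rbind, lapply(names(sw$assignments), function(lb) {
    a <- sw$assignments[[lb]]
    data.frame(member_id = names(a$representative_of),
               representative_id = unname(a$representative_of),
               threshold = lb, stringsAsFactors = FALSE)
  }))
  write_tsv(members, file.path(out_dir, "cluster_membership.tsv"))
  for (lb in names(sw$datasets)) {
    write_annotations(sw$datasets[[lb]],
                      file.path(out_dir,
                                sprintf("representatives_%s.tsv", lb)))
    write_tsv(count_tables(sw$datasets[[lb]], schemes),
              file.path(out_dir, sprintf("counts_%s.tsv", lb)))
  }
  write_tsv(format_numeric(en$results),
            file.path(out_dir, "enrichment_results.tsv"))
  write_tsv(format_numeric(en$mutual),
            file.path(out_dir, "mutual_arrows.tsv"))
  write_tsv(arrows, file.path(out_dir, "arrow_matrix.tsv"))

  log_lines <- c(
    sprintf("peptides\t%d", n_peptides(dataset)),
    sprintf("thresholds\t%s",
            paste(cluster_cfg$thresholds, collapse = ",")),
    sprintf("alignment\tmatch=%g mismatch=%g gap=%g",
            cluster_cfg$match, cluster_cfg$mismatch, cluster_cfg$gap),
    sprintf("alpha\t%g", enrich_cfg$alpha),
    sprintf("Q\t%g", enrich_cfg$Q),
    sprintf("min_category\t%d", enrich_cfg$min_category),
    sprintf("min_table\t%d", enrich_cfg$min_table),
    vapply(split(en$results,
                 paste(en$results$scheme, en$results$level,
                       en$results$direction, en$results$threshold,
                       sep = "/")),
           function(g) sprintf("bh_family\t%s/%d/%s/%g\t%d",
                               g$scheme[1], g$level[1], g$direction[1],
                               g$threshold[1], nrow(g)),
           character(1), USE.NAMES = FALSE))
  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))

  invisible(list(sweep = sw, results = en$results, mutual = en$mutual,
                 arrow_matrix = arrows))
}

# Fixed-width formatting of p/q columns so TSV output is byte-stable
# across platforms.
format_numeric <- function(df) {
  for (col in intersect(c("p", "q", "q_fun", "q_struct"), names(df))) {
    df[[col]] <- sprintf("%.6e", df[[col]])
  }
  df
}
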