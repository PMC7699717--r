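#' Enrichment configuration
#'
#' @param alpha raw significance level for a single test (default 0.05).
#' @param Q false-discovery-rate level for the BH-adjusted calls and the
#'   arrow matrix (default 0.05).
#' @param min_category minimum number of original (unclustered) peptides a
#'   structural category needs before it is tested (default 5).
#' @param min_table minimum number of original peptides a category needs to
#'   enter the summary arrow table (default 10; must be >= `min_category`).
#' @return An `enrich_config` list.
#' @export
enrich_config <- function(alpha = 0.05, Q = 0.05, min_category = 5,
                          min_table = 10) {
  if (alpha <= 0 || alpha >= 1 || Q <= 0 || Q >= 1) {
    stop("alpha and Q must lie in (0, 1)", call. = FALSE)
  }
  if (min_table < min_category) {
    stop("min_table must be >= min_category", call. = FALSE)
  }
  structure(list(alpha = alpha, Q = Q, min_category = min_category,
                 min_table = min_table),
            class = "enrich_config")
}

#' Upper hypergeometric tail
#'
#' Probability of observing at least `m` marked objects in a sample of `n`
#' drawn without replacement from a population of `N` objects of which `M`
#' are marked:
#' `P = sum_{i=m}^{min(n, M)} C(M, i) C(N-M, n-i) / C(N, n)`.
#' Computed in log space (log-gamma binomials, log-sum-exp) for stability.
#'
#' @param N population size.
#' @param M marked objects in the population.
#' @param n sample size.
#' @param m marked objects in the sample.
#' @return The tail probability in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(20, 6, 7, 4)
hypergeom_tail <- function(N, M, n, m) {
  vals <- c(N = N, M = M, n = n, m = m)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (M > N) stop("M exceeds N", call. = FALSE)
  if (n > N) stop("n exceeds N", call. = FALSE)
  if (m > min(M, n)) stop("m exceeds min(M, n)", call. = FALSE)
  if (m == 0) return(1)
  i <- m:min(n, M)
  logp <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  mx <- max(logp)
  min(exp(mx + log(sum(exp(logp - mx)))), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) k / j` capped at 1, returned in the input
#' order (a thin validating wrapper around [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same order and length as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

# Shared driver for both enrichment directions. Emits one row per
# (category, activity) for every category with >= min_category members in
# the original dataset, then BH-adjusts jointly across the emitted rows
# (the test family = one {scheme, level, direction, threshold} batch).
enrichment_direction <- function(reps, original, scheme, level, config,
                                 direction, threshold = NA_real_) {
  scheme <- match.arg(scheme, c("CATH", "SCOP", "TM"))
  orig_cat <- peptide_categories(original, scheme, level)
  if (all(is.na(orig_cat))) {
    stop("no ", scheme, " labels in the dataset", call. = FALSE)
  }
  counts <- table(orig_cat)
  cats <- names(counts)[counts >= config$min_category]
  if (length(cats) == 0) return(empty_enrichment())

  rep_cat <- peptide_categories(reps, scheme, level)
  annotated <- !is.na(peptide_categories(reps, scheme, 1))
  acts <- activity_codes()
  act_mat <- matrix(FALSE, n_peptides(reps), length(acts),
                    dimnames = list(NULL, acts))
  for (f in acts) act_mat[, f] <- has_activity(reps, f)

  rows <- list()
  for (s in cats) {
    in_s <- !is.na(rep_cat) & rep_cat == s
    for (f in acts) {
      with_f <- act_mat[, f]
      if (direction == "function-in-structure") {
        N <- n_peptides(reps)          # every peptide has >= 1 activity
        M <- sum(with_f)
        n <- sum(in_s)
        m <- sum(in_s & with_f)
      } else {
        N <- sum(annotated)
        M <- sum(in_s)
        n <- sum(with_f & annotated)
        m <- sum(in_s & with_f)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, level = level, key = s, activity = f,
        direction = direction, N = N, M = M, n = n, m = m,
        n_original = as.integer(counts[[s]]),
        p = hypergeom_tail(N, M, n, m),
        threshold = threshold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  lv <- split_category_key(out$key, scheme, level)
  out$level1 <- lv$level1
  out$level2 <- lv$level2
  out[, c("scheme", "level", "level1", "level2", "key", "activity",
          "direction", "N", "M", "n", "m", "n_original", "p", "q",
          "threshold")]
}

empty_enrichment <- function() {
  data.frame(scheme = character(0), level = integer(0),
             level1 = character(0), level2 = character(0),
             key = character(0), activity = character(0),
             direction = character(0), N = integer(0), M = integer(0),
             n = integer(0), m = integer(0), n_original = integer(0),
             p = numeric(0), q = numeric(0), threshold = numeric(0),
             stringsAsFactors = FALSE)
}

#' Functional enrichment: activities within a structural category
#'
#' For each structural category `s` (with at least `min_category` members
#' in the original, unclustered dataset) and each of the seven activities
#' `f`: the population is every representative (all carry at least one
#' activity, structural annotation not required), `M` counts those with
#' `f`, the sample is the representatives in `s`, and `m` counts sample
#' members with `f`. BH adjustment is applied jointly across all
#' (category, activity) tests of the batch.
#'
#' @param reps representative [amp_dataset()] at one identity threshold.
#' @param original the unclustered dataset (category-size filter).
#' @param scheme `"CATH"`, `"SCOP"` or `"TM"`.
#' @param level 1 (class) or 2 (architecture/fold); ignored for TM.
#' @param config an [enrich_config()].
#' @param threshold identity threshold recorded in the result rows.
#' @return data.frame of test rows with counts `N, M, n, m`, `p` and `q`.
#' @export
functional_enrichment <- function(reps, original, scheme, level = 1,
                                  config = enrich_config(),
                                  threshold = NA_real_) {
  enrichment_direction(reps, original, scheme, level, config,
                       "function-in-structure", threshold)
}

#' Structural enrichment: a category within an activity's peptides
#'
#' The mirror direction: the population is the representatives annotated
#' under the scheme, `M` counts those in category `s`, the sample is the
#' scheme-annotated representatives with activity `f`, and `m` counts
#' sample members in `s`. Same category-size filter and BH batching as
#' [functional_enrichment()].
#'
#' @inheritParams functional_enrichment
#' @return data.frame of test rows.
#' @export
structural_enrichment <- function(reps, original, scheme, level = 1,
                                  config = enrich_config(),
                                  threshold = NA_real_) {
  enrichment_direction(reps, original, scheme, level, config,
                       "structure-in-function", threshold)
}

#' Classify mutual enrichment arrows
#'
#' Joins the two directions on (scheme, level, category, activity,
#' threshold) and assigns: `<->` when both BH-adjusted q-values fall below
#' `Q`, `->` when only the functional direction does, `<-` when only the
#' structural direction does, `.` otherwise. Categories below `min_table`
#' original members are kept but flagged `qualifies_table = FALSE` so the
#' summary view can suppress them.
#'
#' @param res_fun result of [functional_enrichment()].
#' @param res_struct result of [structural_enrichment()] on the same
#'   representatives.
#' @param config an [enrich_config()].
#' @return data.frame with one arrow row per joined test pair.
#' @export
mutual_classify <- function(res_fun, res_struct, config = enrich_config()) {
  if (!setequal(unique(res_fun$threshold), unique(res_struct$threshold))) {
    stop("mismatched thresholds between directions", call. = FALSE)
  }
  keycols <- c("scheme", "level", "level1", "level2", "key", "activity",
               "threshold")
  a <- res_fun[, c(keycols, "n_original", "q")]
  names(a)[names(a) == "q"] <- "q_fun"
  b <- res_struct[, c(keycols, "q")]
  names(b)[names(b) == "q"] <- "q_struct"
  m <- merge(a, b, by = keycols, sort = FALSE)
  sigA <- m$q_fun < config$Q
  sigB <- m$q_struct < config$Q
  m$arrow <- ifelse(sigA & sigB, "<->",
                    ifelse(sigA, "->", ifelse(sigB, "<-", ".")))
  m$qualifies_table <- m$n_original >= config$min_table
  m[order(m$scheme, m$level, m$key, m$activity), , drop = FALSE]
}

#' Run both enrichment directions across the threshold sweep
#'
#' For every representative set, scheme and level, computes both
#' enrichment directions and the mutual arrows. CATH and SCOP are analysed
#' at levels 1 and 2 (the level-1 rows are the `"*"` aggregation rows of
#' the summary table); TM has a single level.
#'
#' @param original the unclustered [amp_dataset()].
#' @param rep_sets named list of representative datasets (names are
#'   percent thresholds), as produced by [representative_sweep()].
#' @param schemes schemes to analyse; defaults to those with any labels.
#' @param config an [enrich_config()].
#' @return List with `results` (all directional test rows) and `mutual`
#'   (all arrow rows).
#' @export
enrichment_sweep <- function(original, rep_sets, schemes = NULL,
                             config = enrich_config()) {
  if (is.null(schemes)) {
    schemes <- c("CATH", "SCOP", "TM")
    schemes <- schemes[vapply(schemes, function(s)
      any(scheme_annotated(original, s)), logical(1))]
  }
  if (length(schemes) == 0) stop("no structural labels present",
                                 call. = FALSE)
  results <- list()
  mutual <- list()
  for (label in names(rep_sets)) {
    thr <- as.numeric(label) / 100
    reps <- rep_sets[[label]]
    for (scheme in schemes) {
      levels <- if (scheme == "TM") 1 else c(1, 2)
      for (lv in levels) {
        rf <- functional_enrichment(reps, original, scheme, lv, config, thr)
        rs <- structural_enrichment(reps, original, scheme, lv, config, thr)
        if (nrow(rf) == 0) next
        results[[length(results) + 1L]] <- rbind(rf, rs)
        mutual[[length(mutual) + 1L]] <- mutual_classify(rf, rs, config)
      }
    }
  }
  list(results = do.call(rbind, results), mutual = do.call(rbind, mutual))
}
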