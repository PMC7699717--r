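AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

default_categories <- function() {
  list(
    TM = setNames(rep(1, 6), as.character(1:6)),
    CATH = setNames(rep(1, 3),
                    c("Mainly Alpha|Orthogonal Bundle",
                      "Alpha Beta|2-Layer Sandwich",
                      "Mainly Beta|Beta Barrel")),
    SCOP = setNames(rep(1, 3),
                    c("Small proteins|Knottins",
                      "All alpha|Saposin-like",
                      "Alpha and beta|IL8-like")))
}

#' Configuration of the synthetic AMP generator
#'
#' Describes a population of peptide families with tunable within-family
#' identity, per-scheme structural categories, independent per-activity
#' base prevalences, and optional planted structure-function associations
#' of configurable lift: for peptides in the planted category,
#' `P(activity | category) = min(1, lift * prevalence)`.
#'
#' @param n_families number of sequence families.
#' @param family_size peptides per family; a single value or a
#'   `c(min, max)` range sampled per family.
#' @param seq_length `c(min, max)` range of family seed-sequence lengths.
#' @param mutation_rate per-residue substitution probability applied to
#'   each family member relative to the family seed sequence.
#' @param categories per-scheme named weight vectors; names are category
#'   labels (two-level labels as `"level1|level2"`, TM cluster ids as
#'   plain text). Each family draws one category per scheme.
#' @param allocation `NULL`, or a per-scheme named integer vector of
#'   family counts (summing to `n_families`); when given for a scheme,
#'   families are assigned to its categories deterministically in index
#'   order instead of by sampling, fixing the category sizes exactly.
#' @param base_prevalence named vector of activity prevalences in (0, 1),
#'   one per activity code. Defaults reflect the antibacterial-dominated
#'   composition of AMP databases.
#' @param planted `NULL` or a data.frame with columns `scheme`,
#'   `category`, `activity`, `lift` (lift >= 1).
#' @param motif optional conserved pattern (e.g. `"C..C..G"`); letter
#'   positions are injected into the seed of each family in
#'   `motif_families` and protected from mutation; `.` positions are free.
#' @param motif_families family indices receiving the motif.
#' @param trace_templates `NULL`, or a named map from TM category to a
#'   [make_trace()] template (`"helix"`, `"hairpin"`, `"extended"`); when
#'   given, every peptide receives a noisy template trace.
#' @param noise_sigma per-coordinate Gaussian noise of the traces, in
#'   angstroms.
#' @param seed integer RNG seed (mandatory).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_families = 30,
                             family_size = 10,
                             seq_length = c(15, 60),
                             mutation_rate = 0.1,
                             categories = default_categories(),
                             allocation = NULL,
                             base_prevalence = c(G = 0.5, Gpos = 0.3,
                                                 Gneg = 0.3, F = 0.2,
                                                 V = 0.1, P = 0.05,
                                                 C = 0.1),
                             planted = NULL,
                             motif = NULL,
                             motif_families = integer(0),
                             trace_templates = NULL,
                             noise_sigma = 0.5,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_families >= 1, mutation_rate >= 0, mutation_rate < 1,
            length(seq_length) %in% c(1, 2))
  if (length(seq_length) == 1) seq_length <- rep(seq_length, 2)
  if (length(family_size) == 1) family_size <- rep(family_size, 2)
  if (!setequal(names(base_prevalence), activity_codes())) {
    stop("base_prevalence must name all seven activity codes",
         call. = FALSE)
  }
  if (any(base_prevalence <= 0) || any(base_prevalence >= 1)) {
    stop("prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(allocation)) {
    for (scheme in names(allocation)) {
      if (sum(allocation[[scheme]]) != n_families) {
        stop("allocation for ", scheme, " must sum to n_families",
             call. = FALSE)
      }
    }
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("scheme", "category", "activity", "lift") %in%
                    names(planted)))
    if (any(planted$lift < 1)) stop("lift must be >= 1", call. = FALSE)
    planted$activity <- vapply(planted$activity, normalize_activity,
                               character(1))
    over <- planted$lift * base_prevalence[planted$activity] > 1
    if (any(over)) {
      warning("lift * prevalence exceeds 1 for ",
              paste(planted$activity[over], collapse = ", "),
              "; capping at 1", call. = FALSE)
    }
  }
  structure(list(n_families = n_families, family_size = family_size,
                 seq_length = seq_length, mutation_rate = mutation_rate,
                 categories = categories, allocation = allocation,
                 base_prevalence = base_prevalence, planted = planted,
                 motif = motif, motif_families = motif_families,
                 trace_templates = trace_templates,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Uniform draw from lo:hi that is safe when lo == hi (sample() would
# otherwise treat the scalar as 1:n).
sample_range <- function(lo, hi) {
  if (lo == hi) lo else sample(lo:hi, 1)
}

# P(activity) for one peptide given its family's categories.
activity_probs <- function(config, fam_cats) {
  pr <- config$base_prevalence[activity_codes()]
  names(pr) <- activity_codes()
  pl <- config$planted
  if (!is.null(pl)) {
    for (k in seq_len(nrow(pl))) {
      if (identical(fam_cats[[pl$scheme[k]]], pl$category[k])) {
        f <- pl$activity[k]
        pr[f] <- min(1, pl$lift[k] * pr[f])
      }
    }
  }
  pr
}

#' Generate a synthetic annotated AMP dataset
#'
#' Each family gets a random seed sequence, one structural category per
#' scheme, and `family_size` members mutated at `mutation_rate`;
#' activities are drawn independently per peptide from the (possibly
#' lifted) prevalences, and a peptide whose draw comes up empty receives
#' the highest-prevalence activity so every record satisfies the
#' non-empty-activities invariant. The RNG is split deterministically per
#' family, so adding families does not perturb earlier ones. Byte-identical
#' output for identical config and seed.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (an [amp_dataset()]), `truth` (list with
#'   `family_of`, `category_of`, `planted`) and `traces` (named list of
#'   `ca_trace`, empty unless `trace_templates` is set).
#' @export
generate_amp_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  fam_seeds <- sample.int(2^31 - 2, config$n_families)
  top_prev <- names(which.max(config$base_prevalence))

  rows <- list()
  traces <- list()
  family_of <- character(0)
  category_of <- list()
  for (fam in seq_len(config$n_families)) {
    set.seed(fam_seeds[fam])
    len <- sample_range(config$seq_length[1], config$seq_length[2])
    fam_cats <- lapply(names(config$categories), function(scheme) {
      w <- config$categories[[scheme]]
      alloc <- config$allocation[[scheme]]
      if (!is.null(alloc)) {
        rep(names(alloc), alloc)[fam]
      } else {
        names(w)[sample.int(length(w), 1, prob = w / sum(w))]
      }
    })
    names(fam_cats) <- names(config$categories)
    seed_seq <- sample(AA20, len, replace = TRUE)
    locked <- logical(len)
    if (!is.null(config$motif) && fam %in% config$motif_families) {
      pat <- strsplit(config$motif, "")[[1]]
      start <- min(3L, max(1L, len - length(pat) + 1L))
      if (start + length(pat) - 1L > len) {
        stop("motif longer than family sequence", call. = FALSE)
      }
      at <- start + seq_along(pat) - 1L
      fixed <- pat != "."
      seed_seq[at[fixed]] <- pat[fixed]
      locked[at[fixed]] <- TRUE
    }
    size <- sample_range(config$family_size[1], config$family_size[2])
    pr <- activity_probs(config, fam_cats)
    cath <- scop <- c(NA_character_, NA_character_)
    if (!is.null(fam_cats$CATH)) {
      cath <- strsplit(fam_cats$CATH, "|", fixed = TRUE)[[1]][1:2]
    }
    if (!is.null(fam_cats$SCOP)) {
      scop <- strsplit(fam_cats$SCOP, "|", fixed = TRUE)[[1]][1:2]
    }
    for (i in seq_len(size)) {
      id <- sprintf("fam%03d_p%02d", fam, i)
      s <- seed_seq
      mut <- runif(len) < config$mutation_rate & !locked
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(old) {
          sample(setdiff(AA20, old), 1)
        }, character(1))
      }
      acts <- activity_codes()[runif(7) < pr]
      if (length(acts) == 0) acts <- top_prev
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, sequence = paste(s, collapse = ""),
        cath_class = cath[1], cath_arch = cath[2],
        scop_class = scop[1], scop_fold = scop[2],
        tm_cluster = if (is.null(fam_cats$TM)) NA_character_ else
          fam_cats$TM,
        trace_path = NA_character_, stringsAsFactors = FALSE)
      rows[[length(rows)]]$activities <- I(list(acts))
      family_of[id] <- fam
      if (!is.null(config$trace_templates) && !is.null(fam_cats$TM)) {
        tmpl <- config$trace_templates[[fam_cats$TM]]
        if (!is.null(tmpl)) {
          traces[[id]] <- make_trace(tmpl, len, config$noise_sigma,
                                     seed = sample.int(2^31 - 2, 1))
        }
      }
    }
    category_of[[as.character(fam)]] <- fam_cats
  }
  peptides <- do.call(rbind, rows)
  dataset <- amp_dataset(peptides,
                         provenance = list(source = "synthetic",
                                           seed = config$seed))
  list(dataset = dataset,
       truth = list(family_of = family_of, category_of = category_of,
                    planted = config$planted),
       traces = traces)
}

#' Generate an idealised C-alpha trace
#'
#' Templates: `"helix"` is an ideal alpha-helix curve (1.5 angstrom rise
#' per residue, 100 degree turn, 2.3 angstrom radius); `"hairpin"` is two
#' antiparallel strands (3.4 angstrom rise) joined by a 4-residue turn;
#' `"extended"` is a straight chain with 3.5 angstrom spacing. Optional
#' i.i.d. Gaussian noise is added per coordinate.
#'
#' @param template `"helix"`, `"hairpin"` or `"extended"`.
#' @param length number of residues (>= 3).
#' @param noise_sigma per-coordinate noise standard deviation, angstroms.
#' @param seed optional seed for the noise (local to this call).
#' @return A `ca_trace`.
#' @export
#' @examples
#' make_trace("helix", 30)
make_trace <- function(template = c("helix", "hairpin", "extended"),
                       length, noise_sigma = 0, seed = NULL) {
  template <- match.arg(template)
  if (length < 3) stop("length must be >= 3", call. = FALSE)
  i <- seq_len(length) - 1
  coords <- switch(template,
    helix = {
      theta <- i * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    },
    hairpin = {
      n_turn <- 4L
      n1 <- (length - n_turn) %/% 2
      n2 <- length - n_turn - n1
      sep <- 4.8
      up <- cbind(rep(0, n1), 0, (seq_len(n1) - 1) * 3.4)
      ztop <- (n1 - 1) * 3.4
      phi <- pi * seq_len(n_turn) / (n_turn + 1)
      turn <- cbind(sep / 2 - sep / 2 * cos(phi), 0,
                    ztop + 1.7 * sin(phi))
      down <- cbind(rep(sep, n2), 0, ztop - (seq_len(n2) - 1) * 3.4)
      rbind(up, turn, down)
    },
    extended = cbind(3.5 * i, 0, 0))
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    coords <- coords + matrix(stats::rnorm(3 * length, 0, noise_sigma),
                              ncol = 3)
  }
  ca_trace(coords, id = template)
}
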