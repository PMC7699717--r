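# Deterministic toy datasets built in code.

# Distinct fixed-length sequence for index i (base-20 encoding over the
# standard amino-acid alphabet).
toy_seq <- function(i, len = 12) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  digits <- integer(len)
  x <- i
  for (k in seq_len(len)) {
    digits[k] <- x %% 20
    x <- x %/% 20
  }
  paste(aa[digits + 1], collapse = "")
}

# Dataset of n peptides: the first `in_s` sit in TM cluster "1" (the rest
# in cluster "2"); peptides listed in `f_ids` carry activity F, everyone
# carries G. Optionally only the first `annotated` peptides get a TM label.
toy_dataset <- function(n, in_s, f_ids, annotated = n) {
  acts <- lapply(seq_len(n), function(i) {
    if (i %in% f_ids) c("G", "F") else "G"
  })
  tm <- rep(NA_character_, n)
  tm[seq_len(annotated)] <- ifelse(seq_len(annotated) <= in_s, "1", "2")
  df <- data.frame(id = sprintf("p%03d", seq_len(n)),
                   sequence = vapply(seq_len(n), toy_seq, character(1)),
                   tm_cluster = tm, stringsAsFactors = FALSE)
  df$activities <- I(acts)
  amp_dataset(df)
}

# Small random dataset for clustering property tests.
random_dataset <- function(seed, n_families = 5, family_size = c(3, 6),
                           mutation_rate = 0.1, seq_length = c(15, 40)) {
  generate_amp_dataset(synthetic_config(
    n_families = n_families, family_size = family_size,
    seq_length = seq_length, mutation_rate = mutation_rate,
    seed = seed))$dataset
}

# Study conditions for the error-control simulations: 300 peptides in 30
# families labelled with 6 TM clusters; optionally one planted
# (cluster "1", antifungal) association with the given lift, the planted
# cluster sized ~40 of 300.
null_config <- function(seed, lift = NULL) {
  planted <- NULL
  allocation <- NULL
  weights <- setNames(rep(5, 6), as.character(1:6))
  if (!is.null(lift)) {
    planted <- data.frame(scheme = "TM", category = "1", activity = "F",
                          lift = lift)
    # fix the planted category at 4 families x 10 peptides = 40 of 300
    allocation <- list(TM = setNames(c(4, 6, 5, 5, 5, 5),
                                     as.character(1:6)))
  }
  synthetic_config(n_families = 30, family_size = 10,
                   seq_length = c(15, 40), mutation_rate = 0.1,
                   categories = list(TM = weights),
                   allocation = allocation,
                   base_prevalence = c(G = 0.5, Gpos = 0.3, Gneg = 0.3,
                                       F = 0.1, V = 0.1, P = 0.05,
                                       C = 0.1),
                   planted = planted, seed = seed)
}

# Both enrichment directions plus arrows on a dataset treated as its own
# representative set (the 100% identity column).
arrows_on_dataset <- function(dataset, config = enrich_config()) {
  rf <- functional_enrichment(dataset, dataset, "TM", 1, config, 1)
  rs <- structural_enrichment(dataset, dataset, "TM", 1, config, 1)
  mutual_classify(rf, rs, config)
}
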