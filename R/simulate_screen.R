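#' Assign ground-truth survival weights to library variants
#'
#' Builds the effect map used by the selection simulator. A survival weight
#' `w` is the per-round fitness of a variant in the toxin-clearance assay:
#' `w = 1` is wild-type-equivalent activity, `w > 1` enhanced, `w < 1`
#' impaired, `w = 0` inactive. Nonsense variants always get `w = 0` (a
#' truncated nuclease cannot clear the toxin plasmid) and synonymous
#' variants always get `w = 1`. Missense variants are assigned in
#' amino-acid-substitution groups — every codon encoding of the same
#' substitution shares one weight, since selection acts on the protein.
#'
#' Class weights default to a discrete effect ladder: beneficial
#' `w = effect_scale`, deleterious `w = 1 / effect_scale`, null `w = 0`,
#' neutral `w = 1`. With `continuous = TRUE`, beneficial and deleterious
#' weights are instead drawn log-uniformly from `(1, effect_scale]` and
#' `[1/effect_scale, 1)`, which gives an untied ground truth for
#' rank-recovery checks.
#'
#' @param variants Variant tibble from [enumerate_nnk_variants()].
#' @param frac_beneficial,frac_deleterious,frac_null Fractions of missense
#'   amino-acid substitutions assigned to each non-neutral class; the
#'   remainder is neutral. Must lie in `[0, 1]` and sum to at most 1.
#' @param effect_scale Weight of the beneficial class (and reciprocal of
#'   the deleterious class). Must be > 1.
#' @param continuous Draw class weights from continuous ranges instead of
#'   the discrete ladder.
#' @param seed Integer seed; the assignment is reproducible under it.
#' @return A tibble `variant_id`, `aa_id`, `class`, `w`, including a
#'   `"WT"` row with `w = 1`.
#' @export
assign_effects <- function(variants,
                           frac_beneficial = 0.10,
                           frac_deleterious = 0.15,
                           frac_null = 0.05,
                           effect_scale = 2,
                           continuous = FALSE,
                           seed = 1L) {
  fr <- c(frac_beneficial, frac_deleterious, frac_null)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (!is.finite(effect_scale) || effect_scale <= 1) {
    stop("effect_scale must be > 1", call. = FALSE)
  }

  mis_groups <- sort(unique(variants$aa_id[variants$consequence == "missense"]))
  n <- length(mis_groups)
  n_ben <- round(frac_beneficial * n)
  n_del <- round(frac_deleterious * n)
  n_null <- round(frac_null * n)

  group_tbl <- with_seed(seed, {
    cls <- rep("neutral", n)
    idx <- sample.int(n)
    cls[idx[seq_len(n_ben)]] <- "beneficial"
    cls[idx[n_ben + seq_len(n_del)]] <- "deleterious"
    cls[idx[n_ben + n_del + seq_len(n_null)]] <- "null"
    w <- rep(1, n)
    if (continuous) {
      w[cls == "beneficial"] <-
        exp(runif(sum(cls == "beneficial"), 0, log(effect_scale)))
      w[cls == "deleterious"] <-
        exp(runif(sum(cls == "deleterious"), -log(effect_scale), 0))
    } else {
      w[cls == "beneficial"] <- effect_scale
      w[cls == "deleterious"] <- 1 / effect_scale
    }
    w[cls == "null"] <- 0
    tibble::tibble(aa_id = mis_groups, class = cls, w = w)
  })

  out <- tibble::tibble(
    variant_id = variants$id,
    aa_id = variants$aa_id,
    consequence = variants$consequence
  )
  out <- dplyr::left_join(out, group_tbl, by = "aa_id")
  out$class[out$consequence == "synonymous"] <- "synonymous"
  out$w[out$consequence == "synonymous"] <- 1
  out$class[out$consequence == "nonsense"] <- "nonsense"
  out$w[out$consequence == "nonsense"] <- 0
  out$consequence <- NULL
  dplyr::bind_rows(
    out,
    tibble::tibble(variant_id = "WT", aa_id = "WT", class = "wt", w = 1)
  )
}

#' Simulate multi-round survival selection
#'
#' Deterministic expectation dynamics of iterative plating under selection:
#' each round multiplies every variant's frequency by its survival weight
#' and renormalizes, so after `t` rounds a variant's relative abundance has
#' grown by `w^t` against the library mean. Sequencing noise is added
#' separately by [simulate_counts()].
#'
#' @param initial_freqs Named numeric vector of starting frequencies
#'   (must sum to 1 within 1e-9, all non-negative).
#' @param effects Effect map from [assign_effects()] (or any tibble with
#'   `variant_id`, `w`); every variant in `initial_freqs` must have a weight.
#' @param n_rounds Number of selection rounds.
#' @return A `selection_trajectory`: list with `rounds` (list of
#'   `n_rounds + 1` named frequency vectors, element 1 being the input
#'   library) and `n_rounds`.
#' @export
simulate_selection <- function(initial_freqs, effects, n_rounds = 4L) {
  stopifnot(n_rounds >= 1L, !is.null(names(initial_freqs)))
  if (any(initial_freqs < 0) || abs(sum(initial_freqs) - 1) > 1e-9) {
    stop("initial frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  w <- setNames(effects$w, effects$variant_id)[names(initial_freqs)]
  if (anyNA(w) || any(!is.finite(w)) || any(w < 0)) {
    stop("every variant needs a finite non-negative survival weight",
         call. = FALSE)
  }
  rounds <- vector("list", n_rounds + 1L)
  rounds[[1]] <- initial_freqs
  f <- initial_freqs
  for (t in seq_len(n_rounds)) {
    tot <- sum(f * w)
    if (tot <= 0) {
      stop("degenerate selection: total survival weight is zero at round ",
           t, call. = FALSE)
    }
    f <- f * w / tot
    rounds[[t + 1L]] <- f
  }
  structure(list(rounds = rounds, n_rounds = n_rounds),
            class = "selection_trajectory")
}

#' @export
print.selection_trajectory <- function(x, ...) {
  cat("<selection_trajectory> ", x$n_rounds, " rounds, ",
      length(x$rounds[[1]]), " variants\n", sep = "")
  invisible(x)
}

#' Draw sequencing counts from a frequency table
#'
#' One multinomial draw of `depth` reads over the variant frequencies —
#' the sampling noise of sequencing a selection-round library.
#'
#' @param freqs Named non-negative numeric vector summing to 1.
#' @param depth Total read count (non-negative integer).
#' @param seed Optional integer seed for reproducibility.
#' @return Named integer vector of counts, same names as `freqs`.
#' @export
simulate_counts <- function(freqs, depth, seed = NULL) {
  stopifnot(length(depth) == 1L, depth >= 0, !is.null(names(freqs)))
  if (depth == 0) {
    return(setNames(integer(length(freqs)), names(freqs)))
  }
  with_seed(seed, {
    setNames(as.integer(rmultinom(1L, size = depth, prob = freqs)),
             names(freqs))
  })
}

#' Simulate a complete saturation-mutagenesis selection screen
#'
#' End-to-end generator for the bacterial survival screen: builds a random
#' reference CDS, enumerates its NNK single-codon library, assigns
#' ground-truth survival weights, runs the deterministic selection
#' dynamics, and sequences the requested rounds for each replicate with
#' multinomial noise. Replicates share the expected trajectory (the
#' biology is deterministic in expectation) and differ by independent
#' sequencing draws; an optional binomial bottleneck between rounds can be
#' switched on to add transformation-efficiency variance per replicate.
#'
#' @param n_codons Number of codons in the generated reference (first is ATG).
#' @param n_rounds Selection rounds (default 4).
#' @param sequenced_rounds Which rounds are sequenced (default 3 and 4).
#' @param depth Reads per sequenced sample.
#' @param n_replicates Biological replicates.
#' @param bottleneck Optional integer: if set, each replicate resamples the
#'   library down to this many cells (binomial) after every round before
#'   continuing, as a transformation-efficiency bottleneck. Default off.
#' @param seed Integer seed (forked deterministically across stages).
#' @inheritParams assign_effects
#' @return A list with `reference`, `variants`, `effects`, `trajectory`
#'   (replicate 1's expectation trajectory), and `counts`: a long tibble
#'   `variant_id`, `round`, `replicate`, `sample`, `count`.
#' @export
simulate_screen <- function(n_codons = 300L,
                            n_rounds = 4L,
                            sequenced_rounds = c(3L, 4L),
                            depth = 1e6,
                            n_replicates = 3L,
                            frac_beneficial = 0.10,
                            frac_deleterious = 0.15,
                            frac_null = 0.05,
                            effect_scale = 2,
                            continuous = FALSE,
                            bottleneck = NULL,
                            seed = 1L) {
  stopifnot(n_codons >= 2L, all(sequenced_rounds <= n_rounds))
  reference <- random_reference(n_codons, seed = fork_seed(seed, "reference"))
  variants <- enumerate_nnk_variants(reference)
  effects <- assign_effects(
    variants,
    frac_beneficial = frac_beneficial, frac_deleterious = frac_deleterious,
    frac_null = frac_null, effect_scale = effect_scale,
    continuous = continuous, seed = fork_seed(seed, "effects")
  )

  ids <- c(variants$id, "WT")
  f0 <- setNames(rep(1 / length(ids), length(ids)), ids)
  traj <- simulate_selection(f0, effects, n_rounds = n_rounds)

  counts <- list()
  for (r in seq_len(n_replicates)) {
    rounds <- if (is.null(bottleneck)) {
      traj$rounds
    } else {
      bottlenecked_rounds(f0, effects, n_rounds, bottleneck,
                          seed = fork_seed(seed, paste0("bottleneck", r)))
    }
    for (rd in sequenced_rounds) {
      cnt <- simulate_counts(rounds[[rd + 1L]], depth,
                             seed = fork_seed(seed, paste0("seq", r, "_", rd)))
      counts[[length(counts) + 1L]] <- tibble::tibble(
        variant_id = names(cnt), round = rd, replicate = r,
        sample = paste0("r", rd, "_rep", r), count = unname(cnt)
      )
    }
  }

  list(reference = reference, variants = variants, effects = effects,
       trajectory = traj, counts = dplyr::bind_rows(counts))
}

## Internal: expectation update interleaved with a binomial bottleneck of
## `size` cells per round (per-replicate stochastic trajectory).
bottlenecked_rounds <- function(f0, effects, n_rounds, size, seed) {
  w <- setNames(effects$w, effects$variant_id)[names(f0)]
  with_seed(seed, {
    rounds <- vector("list", n_rounds + 1L)
    rounds[[1]] <- f0
    f <- f0
    for (t in seq_len(n_rounds)) {
      f <- f * w / sum(f * w)
      cells <- rmultinom(1L, size = size, prob = f)[, 1]
      f <- cells / sum(cells)
      rounds[[t + 1L]] <- setNames(f, names(f0))
    }
    rounds
  })
}

#' Generate a random reference CDS
#'
#' ATG followed by `n_codons - 1` codons drawn uniformly from the 61 sense
#' codons (no internal stops by construction).
#'
#' @param n_codons Total codon count including the start.
#' @param seed Integer seed.
#' @return A [reference_cds()].
#' @export
random_reference <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 1L)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sense <- gsub("U", "T", sense)
  body <- with_seed(seed, sample(sense, n_codons - 1L, replace = TRUE))
  reference_cds(paste(c("ATG", body), collapse = ""),
                id = paste0("synthetic_", n_codons, "aa"))
}

#' Emit simulated amplicon reads for a sequenced library
#'
#' Turns a count table into full-length reads of the mutant CDS, with an
#' optional uniform per-base substitution error, for exercising the
#' FASTQ-driven variant-calling path. All reads get a flat quality string.
#'
#' @param counts Named integer vector (variant id -> read count) as from
#'   [simulate_counts()]; ids must come from `variants` or be `"WT"`.
#' @param reference A [reference_cds()].
#' @param variants Variant tibble from [enumerate_nnk_variants()].
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param quality Flat PHRED quality character (default `"I"`, Q40).
#' @param seed Integer seed.
#' @return Tibble `read_id`, `seq`, `qual`.
#' @export
simulate_reads <- function(counts, reference, variants,
                           error_rate = 0.001, quality = "I", seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  keep <- counts > 0
  ids <- rep(names(counts)[keep], counts[keep])
  var_idx <- match(ids, variants$id)

  seqs <- vapply(seq_along(ids), function(i) {
    if (ids[i] == "WT") return(reference$nt_seq)
    v <- variants[var_idx[i], ]
    codons <- reference$codons
    codons[v$codon_index] <- v$obs_codon
    paste(codons, collapse = "")
  }, character(1))

  if (error_rate > 0) {
    seqs <- with_seed(seed, {
      vapply(seqs, mutate_uniform, character(1), rate = error_rate,
             USE.NAMES = FALSE)
    })
  }
  tibble::tibble(
    read_id = sprintf("read%06d_%s", seq_along(ids), gsub("[/*]", "x", ids)),
    seq = seqs,
    qual = strrep(quality, nchar(reference$nt_seq))
  )
}

## Internal: uniform per-base substitution errors.
mutate_uniform <- function(seq, rate) {
  n <- nchar(seq)
  hits <- which(runif(n) < rate)
  if (length(hits) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in hits) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}
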