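#' Pseudocounted variant frequencies per sample
#'
#' `f(v) = (c(v) + alpha) / (N + alpha * V)` where `N` is the sample total
#' and `V` the number of table rows, so each sample's frequencies sum to 1
#' for any `alpha >= 0`.
#'
#' @param counts Long tibble `variant_id`, `sample`, `count`.
#' @param alpha Pseudocount (default 0.5).
#' @return Input tibble with an added `freq` column.
#' @export
variant_frequencies <- function(counts, alpha = 0.5) {
  stopifnot(alpha >= 0)
  out <- dplyr::group_by(counts, .data$sample)
  out <- dplyr::mutate(
    out,
    freq = (.data$count + alpha) /
      (sum(.data$count) + alpha * dplyr::n())
  )
  if (any(!is.finite(out$freq))) {
    stop("degenerate sample: zero total and zero pseudocount", call. = FALSE)
  }
  dplyr::ungroup(out)
}

#' Raw log enrichment between two sequenced rounds
#'
#' The phenotype score before centering: the natural log of the
#' pseudocounted frequency ratio of a variant between the pre and post
#' selection rounds,
#' `s = ln(((c_post + a) / (N_post + a V)) / ((c_pre + a) / (N_pre + a V)))`.
#' Vectorized over variants.
#'
#' @param c_pre,c_post Variant counts in the pre / post round.
#' @param n_pre,n_post Sample totals in the pre / post round.
#' @param alpha Pseudocount.
#' @param n_variants Number of table rows `V` (pseudocount mass scaling).
#' @return Numeric vector of scores in natural-log units.
#' @export
#' @examples
#' raw_enrichment(100, 1e4, 200, 1e4, alpha = 0, n_variants = 100)  # log(2)
raw_enrichment <- function(c_pre, n_pre, c_post, n_post,
                           alpha = 0.5, n_variants) {
  if (any(n_pre <= 0) || any(n_post <= 0)) {
    stop("sample totals must be positive", call. = FALSE)
  }
  log((c_post + alpha) / (n_post + alpha * n_variants)) -
    log((c_pre + alpha) / (n_pre + alpha * n_variants))
}

#' Center raw scores on the synonymous median
#'
#' Synonymous variants are expected to be neutral, so the median raw score
#' of the synonymous variants passing the count filter defines the zero
#' point of each replicate: `z = s - median(s[synonymous & passing])`.
#' By construction the centered synonymous median is exactly 0, and the
#' centering is invariant to any constant shift of the replicate's raw
#' scores (library composition drift between rounds).
#'
#' @param s Raw scores for one replicate.
#' @param is_anchor Logical: synonymous variants passing the count filter.
#' @param min_anchors Minimum anchors required (default 10); with fewer,
#'   no centering is applied and the result is flagged.
#' @return List: `z` (centered scores), `offset` (subtracted median),
#'   `centered` (logical).
#' @export
synonymous_center <- function(s, is_anchor, min_anchors = 10L) {
  stopifnot(length(s) == length(is_anchor))
  n_anchor <- sum(is_anchor, na.rm = TRUE)
  if (n_anchor < min_anchors) {
    warning("only ", n_anchor, " synonymous anchors pass the count filter; ",
            "scores left uncentered", call. = FALSE)
    return(list(z = s, offset = 0, centered = FALSE))
  }
  offset <- median(s[is_anchor])
  list(z = s - offset, offset = offset, centered = TRUE)
}

#' Count filter for enrichment scoring
#'
#' A variant passes in a replicate iff its summed counts across that
#' replicate's sequenced rounds reach `min_count`; the boundary is
#' inclusive (exactly `min_count` passes). The global pass requires
#' passing in every replicate.
#'
#' @param counts Long tibble `variant_id`, `round`, `replicate`, `count`.
#' @param min_count Minimum summed count (default 50).
#' @return Tibble `variant_id`, `replicate`, `pass`, plus `pass_all` per
#'   variant.
#' @export
apply_count_filter <- function(counts, min_count = 50L) {
  per_rep <- dplyr::summarise(
    dplyr::group_by(counts, .data$variant_id, .data$replicate),
    pass = sum(.data$count) >= min_count, .groups = "drop"
  )
  dplyr::mutate(
    dplyr::group_by(per_rep, .data$variant_id),
    pass_all = all(.data$pass)
  ) |> dplyr::ungroup()
}

#' Combine replicate scores into a phenotype call
#'
#' @param z Numeric vector of centered scores, one per replicate (`NA` =
#'   replicate missing).
#' @param n_required Number of replicates a positive call requires
#'   (default: all supplied).
#' @return List: `mean_score` (arithmetic mean of available scores) and
#'   `is_positive` (`TRUE` iff every required replicate is present and
#'   strictly positive).
#' @export
#' @examples
#' aggregate_replicates(c(0.5, 0.2, 0.1))  # mean 0.267, positive
#' aggregate_replicates(c(0.5, -0.1, 0.3)) # not positive
aggregate_replicates <- function(z, n_required = length(z)) {
  if (all(is.na(z))) stop("no replicate scores available", call. = FALSE)
  list(
    mean_score = mean(z, na.rm = TRUE),
    is_positive = sum(!is.na(z)) >= n_required && all(z > 0, na.rm = FALSE)
  )
}

#' Score a selection screen
#'
#' The main enrichment pipeline: completes the count table over the full
#' library, optionally aggregates to amino-acid resolution, computes each
#' replicate's raw log enrichment between the pre and post rounds
#' ([raw_enrichment()]), applies the count filter ([apply_count_filter()]),
#' centers on the synonymous median ([synonymous_center()]), and combines
#' replicates ([aggregate_replicates()]).
#'
#' Scoring runs at amino-acid level by default, matching residue-level
#' reporting of hits (missense/nonsense rows pooled over codon encodings;
#' synonymous rows kept at codon resolution as centering anchors).
#'
#' @param counts Long tibble `variant_id`, `round`, `replicate`, `count`.
#' @param variants Variant tibble from [enumerate_nnk_variants()].
#' @param round_pre,round_post Rounds whose frequency ratio defines the
#'   score (defaults 3 and 4, the sequenced rounds).
#' @param alpha Pseudocount (default 0.5).
#' @param min_count Count-filter threshold (default 50, inclusive, applied
#'   to each replicate's sum over sequenced rounds).
#' @param level `"aa"` (default) or `"codon"`.
#' @param min_anchors Minimum synonymous anchors for centering.
#' @return A tibble of enrichment records, one row per variant:
#'   `variant_id`, `consequence`, `codon_index`, wide `s_rep*` / `z_rep*` /
#'   `pass_rep*` columns, `mean_score`, `n_replicates_passing`,
#'   `passes_count_filter`, `is_positive`. Attribute `centering` stores the
#'   per-replicate offsets.
#' @export
score_enrichment <- function(counts, variants,
                             round_pre = 3L, round_post = 4L,
                             alpha = 0.5, min_count = 50L,
                             level = c("aa", "codon"),
                             min_anchors = 10L) {
  level <- match.arg(level)
  stopifnot(all(c("variant_id", "round", "replicate", "count") %in%
                  names(counts)))
  counts <- dplyr::filter(counts, .data$round %in% c(round_pre, round_post))
  if (nrow(counts) == 0L) {
    stop("no counts for the requested rounds", call. = FALSE)
  }

  if (level == "aa") {
    counts$sample <- paste0("r", counts$round, "_rep", counts$replicate)
    agg <- aggregate_to_aa(counts[c("variant_id", "sample", "count")],
                           variants)
    agg$round <- as.integer(sub("^r(\\d+)_rep\\d+$", "\\1", agg$sample))
    agg$replicate <- as.integer(sub("^r\\d+_rep(\\d+)$", "\\1", agg$sample))
    counts <- agg[c("variant_id", "round", "replicate", "count")]
    lib_ids <- unique(c(
      ifelse(variants$consequence %in% c("missense", "nonsense"),
             variants$aa_id, variants$id),
      "WT"
    ))
    cons_map <- c(
      setNames(variants$consequence,
               ifelse(variants$consequence %in% c("missense", "nonsense"),
                      variants$aa_id, variants$id)),
      WT = "wt"
    )
  } else {
    lib_ids <- c(variants$id, "WT")
    cons_map <- c(setNames(variants$consequence, variants$id), WT = "wt")
  }

  full <- tidyr::complete(
    counts[c("variant_id", "round", "replicate", "count")],
    variant_id = lib_ids,
    round = c(round_pre, round_post),
    replicate = unique(counts$replicate),
    fill = list(count = 0L)
  )

  wide <- tidyr::pivot_wider(full, names_from = "round",
                             values_from = "count", names_prefix = "c_")
  c_pre <- wide[[paste0("c_", round_pre)]]
  c_post <- wide[[paste0("c_", round_post)]]
  wide$consequence <- unname(cons_map[wide$variant_id])

  per_rep <- dplyr::group_by(
    tibble::tibble(
      variant_id = wide$variant_id, replicate = wide$replicate,
      consequence = wide$consequence, c_pre = c_pre, c_post = c_post
    ),
    .data$replicate
  )
  per_rep <- dplyr::mutate(
    per_rep,
    s = raw_enrichment(.data$c_pre, sum(.data$c_pre),
                       .data$c_post, sum(.data$c_post),
                       alpha = alpha, n_variants = dplyr::n()),
    pass = (.data$c_pre + .data$c_post) >= min_count
  )
  per_rep <- dplyr::ungroup(per_rep)

  centering <- list()
  per_rep$z <- NA_real_
  for (r in unique(per_rep$replicate)) {
    i <- per_rep$replicate == r
    cen <- synonymous_center(
      per_rep$s[i],
      per_rep$consequence[i] == "synonymous" & per_rep$pass[i],
      min_anchors = min_anchors
    )
    per_rep$z[i] <- cen$z
    centering[[as.character(r)]] <- cen[c("offset", "centered")]
  }

  reps <- sort(unique(per_rep$replicate))
  rec <- tidyr::pivot_wider(
    per_rep[c("variant_id", "consequence", "replicate", "s", "z", "pass")],
    names_from = "replicate", values_from = c("s", "z", "pass"),
    names_glue = "{.value}_rep{replicate}"
  )
  zmat <- as.matrix(rec[paste0("z_rep", reps)])
  pmat <- as.matrix(rec[paste0("pass_rep", reps)])
  rec$mean_score <- rowMeans(zmat)
  rec$n_replicates_passing <- rowSums(pmat)
  rec$passes_count_filter <- rowSums(pmat) == length(reps)
  rec$is_positive <- rec$passes_count_filter & rowSums(zmat > 0) == length(reps)
  rec$codon_index <- suppressWarnings(
    as.integer(gsub("[^0-9]", "", aa_id(rec$variant_id)))
  )
  rec <- dplyr::relocate(rec, "variant_id", "consequence", "codon_index")
  attr(rec, "centering") <- centering
  rec
}

#' Rank positive hits
#'
#' Keeps records that pass the count filter and are positive in every
#' replicate, sorted by mean score, descending — the screen's hit list.
#'
#' @param records Record tibble from [score_enrichment()].
#' @return The filtered, sorted tibble.
#' @export
call_hits <- function(records) {
  hits <- dplyr::filter(records, .data$passes_count_filter, .data$is_positive)
  dplyr::arrange(hits, dplyr::desc(.data$mean_score))
}

#' Restrict hits to an annotated interface
#'
#' Prioritizes hits whose residue lies on a user-supplied set of interface
#' residues (e.g. the DNA/R-loop binding interface derived from a
#' structure), preserving the ranking.
#'
#' @param hits Hit tibble from [call_hits()].
#' @param interface_residues Integer vector of 1-based residue indices.
#' @return The filtered tibble (empty, with a warning, if the annotation
#'   is empty).
#' @export
prioritize_interface <- function(hits, interface_residues) {
  if (length(interface_residues) == 0L) {
    warning("empty interface annotation; returning no hits", call. = FALSE)
    return(hits[0, ])
  }
  dplyr::filter(hits, .data$codon_index %in% interface_residues)
}
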