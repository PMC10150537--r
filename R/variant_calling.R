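#' Call the codon-level variant carried by an amplicon read
#'
#' Codon-by-codon comparison against the reference CDS, enforcing the
#' one-codon-change library design: reads identical to the reference are
#' called `"WT"`, reads differing in exactly one codon yield that codon
#' variant, and everything else is rejected with a reason
#' (`multi_codon`, `length_mismatch`, or `ambiguous_base` for reads
#' containing N). No alignment is attempted — the library is
#' substitution-only by construction, so length changes are rejections,
#' not indels.
#'
#' @param read_seq Read sequence (A/C/G/T/N) covering the full CDS window.
#' @param reference A [reference_cds()].
#' @param max_codon_changes Maximum differing codons accepted (default 1;
#'   raise only for diagnostics — multi-codon reads then return all
#'   differing codons).
#' @return A list: `status` (`"wt"`, `"variant"`, or `"rejected"`),
#'   `variant` (tibble of called codon variants, `NULL` otherwise), and
#'   `reason` (rejection reason or `NA`).
#' @export
#' @examples
#' ref <- reference_cds("ATGGCT")
#' call_codon_variants("ATGGAT", ref)$variant$id   # "A2D/GAT"
call_codon_variants <- function(read_seq, reference, max_codon_changes = 1L) {
  stopifnot(inherits(reference, "reference_cds"))
  read_seq <- toupper(read_seq)
  if (grepl("[^ACGTN]", read_seq)) {
    stop("read contains non-ACGTN characters", call. = FALSE)
  }
  reject <- function(reason) {
    list(status = "rejected", variant = NULL, reason = reason)
  }
  if (nchar(read_seq) != nchar(reference$nt_seq)) {
    return(reject("length_mismatch"))
  }
  if (grepl("N", read_seq, fixed = TRUE)) {
    return(reject("ambiguous_base"))
  }
  n <- reference$n_codons
  read_codons <- substring(read_seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  diff <- which(read_codons != reference$codons)
  if (length(diff) == 0L) {
    return(list(status = "wt", variant = NULL, reason = NA_character_))
  }
  if (length(diff) > max_codon_changes) {
    return(reject("multi_codon"))
  }
  wt_aa <- strsplit(reference$aa_seq, "")[[1]][diff]
  obs_aa <- translate_codon(read_codons[diff])
  var <- tibble::tibble(
    codon_index = diff,
    wt_codon = reference$codons[diff],
    obs_codon = read_codons[diff],
    wt_aa = wt_aa,
    obs_aa = obs_aa,
    consequence = classify_substitution(reference$codons[diff],
                                        read_codons[diff]),
    id = variant_id(wt_aa, diff, obs_aa, read_codons[diff])
  )
  list(status = "variant", variant = var, reason = NA_character_)
}

#' Call variants for a vector of reads
#'
#' Vectorized wrapper around the single-read caller.
#'
#' @param reads Character vector of read sequences.
#' @param reference A [reference_cds()].
#' @inheritParams call_codon_variants
#' @return Tibble with one row per read: `read`, `status`, `variant_id`
#'   (`"WT"` for wild-type reads, `NA` for rejections), `consequence`,
#'   `reason`.
#' @export
call_reads <- function(reads, reference, max_codon_changes = 1L) {
  calls <- lapply(reads, call_codon_variants, reference = reference,
                  max_codon_changes = max_codon_changes)
  tibble::tibble(
    read = seq_along(reads),
    status = vapply(calls, `[[`, character(1), "status"),
    variant_id = vapply(calls, function(x) {
      if (x$status == "wt") "WT"
      else if (x$status == "variant") x$variant$id[1]
      else NA_character_
    }, character(1)),
    consequence = vapply(calls, function(x) {
      if (x$status == "variant") x$variant$consequence[1] else NA_character_
    }, character(1)),
    reason = vapply(calls, `[[`, character(1), "reason")
  )
}

#' Mean-quality filter for FASTQ records
#'
#' @param qual PHRED+33 quality string(s).
#' @param min_mean_q Minimum mean quality; the boundary is inclusive
#'   (a read at exactly the threshold passes). Default 25.
#' @return Logical vector, `TRUE` = pass.
#' @export
quality_filter <- function(qual, min_mean_q = 25) {
  if (any(nchar(qual) == 0L)) stop("empty quality string", call. = FALSE)
  vapply(qual, function(q) {
    mean(utf8ToInt(q) - 33L) >= min_mean_q
  }, logical(1), USE.NAMES = FALSE)
}

#' Tabulate variant calls into a count table
#'
#' @param calls Tibble from [call_reads()] plus a `sample` column.
#' @param all_variants Optional character vector of library variant ids;
#'   if given, the table is completed with zero rows so every library
#'   member appears in every sample.
#' @return A list: `counts` (long tibble `variant_id`, `sample`, `count`)
#'   and `rejections` (tibble `sample`, `reason`, `n`). Accepted plus
#'   rejected reads add up to the input reads per sample.
#' @export
tabulate_calls <- function(calls, all_variants = NULL) {
  stopifnot("sample" %in% names(calls))
  acc <- dplyr::filter(calls, .data$status != "rejected")
  counts <- dplyr::count(acc, .data$sample, .data$variant_id, name = "count")
  counts <- dplyr::select(counts, "variant_id", "sample", "count")
  if (!is.null(all_variants)) {
    ids <- union(all_variants, "WT")
    counts <- tidyr::complete(
      counts,
      variant_id = ids,
      sample = unique(calls$sample),
      fill = list(count = 0L)
    )
  }
  rej <- dplyr::count(dplyr::filter(calls, .data$status == "rejected"),
                      .data$sample, .data$reason, name = "n")
  list(counts = counts, rejections = rej)
}

#' Aggregate a codon-level count table to amino-acid level
#'
#' Missense and nonsense rows are summed over the synonymous codon
#' encodings of the same amino-acid substitution (id `"R182V"`);
#' synonymous rows and the `"WT"` row are kept at codon resolution, since
#' collapsing them would erase the substitution. Per-sample totals are
#' conserved.
#'
#' @param counts Long count tibble (`variant_id`, `sample`, `count`).
#' @param variants Variant tibble from [enumerate_nnk_variants()] giving
#'   each id's consequence.
#' @return Long count tibble with aggregated `variant_id`s.
#' @export
aggregate_to_aa <- function(counts, variants) {
  cons <- setNames(variants$consequence, variants$id)[counts$variant_id]
  agg_id <- ifelse(!is.na(cons) & cons %in% c("missense", "nonsense"),
                   aa_id(counts$variant_id), counts$variant_id)
  out <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(counts, variant_id = agg_id),
      .data$variant_id, .data$sample
    ),
    count = sum(.data$count), .groups = "drop"
  )
  extra <- setdiff(names(counts), c("variant_id", "sample", "count"))
  if (length(extra)) {
    key <- dplyr::distinct(
      dplyr::mutate(counts, variant_id = agg_id),
      dplyr::across(dplyr::all_of(c("variant_id", "sample", extra)))
    )
    key <- dplyr::distinct(key, .data$variant_id, .data$sample,
                           .keep_all = TRUE)
    out <- dplyr::left_join(out, key, by = c("variant_id", "sample"))
  }
  out
}

#' Count variants directly from FASTQ files
#'
#' Convenience path from reads on disk to a count table: parse, quality
#' filter, call, tabulate.
#'
#' @param fastq_paths Named character vector of FASTQ paths; names are the
#'   sample labels.
#' @param reference A [reference_cds()].
#' @param min_mean_q Mean-quality threshold (inclusive).
#' @param all_variants Optional library ids for zero-completion.
#' @return As [tabulate_calls()], plus `n_quality_failed` per sample.
#' @export
count_fastq <- function(fastq_paths, reference, min_mean_q = 25,
                        all_variants = NULL) {
  stopifnot(!is.null(names(fastq_paths)))
  all_calls <- lapply(names(fastq_paths), function(smp) {
    rec <- read_fastq(fastq_paths[[smp]])
    keep <- quality_filter(rec$qual, min_mean_q)
    calls <- call_reads(rec$seq[keep], reference)
    calls$sample <- smp
    attr(calls, "n_quality_failed") <- sum(!keep)
    calls
  })
  nqf <- setNames(
    vapply(all_calls, function(x) attr(x, "n_quality_failed"), integer(1)),
    names(fastq_paths)
  )
  out <- tabulate_calls(dplyr::bind_rows(all_calls), all_variants)
  out$n_quality_failed <- nqf
  out
}
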