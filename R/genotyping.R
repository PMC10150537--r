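#' Default genotype-calling thresholds
#'
#' All frequency cutoffs of the diploid genotype classifier in one place:
#' `t_wt` (minimum WT fraction for a wild-type call), `t_hom` (minimum
#' single-allele fraction for a homozygous call), `t_wt_low` (maximum WT
#' fraction compatible with a biallelic call), `t_allele` (minimum
#' frequency for a "major" allele), `mono_lo`/`mono_hi` (WT band of a
#' monoallelic call), `min_depth` (minimum read depth for any call).
#'
#' @return Named list of thresholds.
#' @export
genotype_thresholds <- function() {
  list(t_wt = 0.95, t_hom = 0.90, t_wt_low = 0.05,
       t_allele = 0.35, mono_lo = 0.35, mono_hi = 0.65,
       min_depth = 100L)
}

#' Classify a diploid plant's editing outcome
#'
#' Decision rules over an allele-frequency table, with `w` the wild-type
#' allele fraction and "major" mutant alleles those at frequency >=
#' `t_allele`:
#'
#' * `WT` if `w >= t_wt`;
#' * `biallelic_homozygous` if one mutant allele >= `t_hom` and
#'   `w < t_wt_low` (both chromosomes carry the identical edit);
#' * `biallelic_heterozygous` if two distinct major mutant alleles and
#'   `w < t_wt_low`;
#' * `monoallelic` if `mono_lo <= w <= mono_hi` with exactly one major
#'   mutant allele (one edited chromosome, one wild type);
#' * `chimeric` otherwise (mosaic mixtures, e.g. three substantial
#'   alleles or an intermediate WT fraction).
#'
#' Tables below `min_depth` reads get a `no_call`.
#'
#' @param alleles Tibble for one plant/target: columns `allele`
#'   (descriptor; `"WT"` marks the unedited allele, mutant descriptors
#'   like `"del5"`, `"ins1"`, `"sub"`), `freq` (summing to 1 within 0.01),
#'   and optionally `depth`.
#' @param thresholds List from [genotype_thresholds()] (any subset
#'   overridable).
#' @return List: `class`, `wt_fraction`, `indel_frequency`
#'   (`1 - wt_fraction`), `major_alleles`.
#' @export
#' @examples
#' classify_genotype(tibble::tibble(allele = c("del5", "del3"),
#'                                  freq = c(0.52, 0.48)))$class
classify_genotype <- function(alleles, thresholds = genotype_thresholds()) {
  th <- utils::modifyList(genotype_thresholds(), thresholds)
  if (abs(sum(alleles$freq) - 1) > 0.01) {
    stop("allele frequencies must sum to 1 (within 0.01)", call. = FALSE)
  }
  depth <- if ("depth" %in% names(alleles)) alleles$depth[1] else Inf
  if (depth < th$min_depth) {
    return(list(class = "no_call", wt_fraction = NA_real_,
                indel_frequency = NA_real_, major_alleles = character(0)))
  }
  w <- sum(alleles$freq[alleles$allele == "WT"])
  mut <- alleles[alleles$allele != "WT", ]
  majors <- mut$allele[mut$freq >= th$t_allele]

  class <- if (w >= th$t_wt) {
    "WT"
  } else if (w < th$t_wt_low && any(mut$freq >= th$t_hom)) {
    "biallelic_homozygous"
  } else if (w < th$t_wt_low && length(unique(majors)) == 2L) {
    "biallelic_heterozygous"
  } else if (w >= th$mono_lo && w <= th$mono_hi &&
             length(unique(majors)) == 1L) {
    "monoallelic"
  } else {
    "chimeric"
  }
  list(class = class, wt_fraction = w, indel_frequency = 1 - w,
       major_alleles = unique(majors))
}

#' Classify every plant in a long allele table
#'
#' @param allele_tables Long tibble: `plant_id`, `target_id`, `allele`,
#'   `freq`, optionally `depth`.
#' @param thresholds As [classify_genotype()].
#' @return Tibble `plant_id`, `target_id`, `class`, `wt_fraction`,
#'   `indel_frequency`.
#' @export
classify_genotypes <- function(allele_tables,
                               thresholds = genotype_thresholds()) {
  grp <- dplyr::group_split(
    dplyr::group_by(allele_tables, .data$plant_id, .data$target_id)
  )
  dplyr::bind_rows(lapply(grp, function(g) {
    call <- classify_genotype(g, thresholds)
    tibble::tibble(
      plant_id = g$plant_id[1], target_id = g$target_id[1],
      class = call$class, wt_fraction = call$wt_fraction,
      indel_frequency = call$indel_frequency
    )
  }))
}

#' Per-target editing summary
#'
#' The statistics reported for T0 populations: percentage of edited
#' plants, percentage with biallelic edits (homozygous + heterozygous),
#' homozygous rate over all called plants (e.g. 6 of 12 homozygous plants
#' = 50%), and the deletion-size range over mutant alleles of edited
#' plants.
#'
#' @param calls Tibble from [classify_genotypes()].
#' @param allele_tables The long allele table the calls came from (for
#'   deletion sizes; descriptors `del<n>` are parsed).
#' @param t_allele Minimum allele frequency for inclusion in the deletion
#'   range.
#' @return Tibble, one row per `target_id`: `n_plants`, `pct_edited`,
#'   `pct_biallelic`, `pct_homozygous`, `del_min`, `del_max`.
#' @export
summarize_targets <- function(calls, allele_tables, t_allele = 0.35) {
  called <- dplyr::filter(calls, .data$class != "no_call")
  per_target <- dplyr::summarise(
    dplyr::group_by(called, .data$target_id),
    n_plants = dplyr::n(),
    pct_edited = 100 * mean(.data$class != "WT"),
    pct_biallelic = 100 * mean(.data$class %in%
      c("biallelic_homozygous", "biallelic_heterozygous")),
    pct_homozygous = 100 * mean(.data$class == "biallelic_homozygous"),
    .groups = "drop"
  )

  edited <- dplyr::semi_join(
    allele_tables,
    dplyr::filter(called, .data$class != "WT"),
    by = c("plant_id", "target_id")
  )
  dels <- dplyr::filter(
    edited, grepl("^del\\d+", .data$allele), .data$freq >= t_allele
  )
  dels$del_size <- as.integer(sub("^del(\\d+).*$", "\\1", dels$allele))
  dels <- dels[!is.na(dels$del_size), ]
  if (nrow(dels) == 0L) {
    per_target$del_min <- NA_integer_
    per_target$del_max <- NA_integer_
    return(per_target)
  }
  del_rng <- dplyr::summarise(
    dplyr::group_by(dels, .data$target_id),
    del_min = min(.data$del_size), del_max = max(.data$del_size),
    .groups = "drop"
  )
  dplyr::left_join(per_target, del_rng, by = "target_id")
}

#' Call alleles from amplicon reads
#'
#' Minimal indel-aware allele caller for synthetic fixtures: each read is
#' globally aligned to the reference amplicon (match +1, mismatch -1, gap
#' open -4, gap extend -1) and keyed by its indel pattern within
#' `window` bp of the cut site; allele frequencies are read shares.
#' Production data from external amplicon callers enters the pipeline as
#' the same allele-table contract.
#'
#' @param reads Character vector of read sequences.
#' @param reference_amplicon Reference amplicon sequence.
#' @param cut_site 1-based position of the expected cut site (default:
#'   amplicon midpoint).
#' @param window Half-width of the window around the cut site within
#'   which indels define alleles (default 20 bp).
#' @return Tibble `allele`, `n_reads`, `freq`, `depth`; descriptors are
#'   `"WT"`, `"del<n>"`, `"ins<n>"`, `"sub"` (mismatch-only), compound
#'   patterns joined by `+`.
#' @export
call_alleles_from_reads <- function(reads, reference_amplicon,
                                    cut_site = NULL, window = 20L) {
  if (length(reads) == 0L) stop("no reads covering the window", call. = FALSE)
  reference_amplicon <- toupper(reference_amplicon)
  if (is.null(cut_site)) cut_site <- round(nchar(reference_amplicon) / 2)
  lo <- cut_site - window
  hi <- cut_site + window

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  descr <- vapply(unique(reads), function(rd) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(rd)),
      Biostrings::DNAString(reference_amplicon),
      type = "global", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 1
    )
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

    # walk the alignment columns, recording indel runs in reference
    # coordinates; only events overlapping the cut-site window count
    events <- character(0)
    ref_pos <- 0L
    i <- 1L
    while (i <= length(pat)) {
      if (sub[i] != "-" && pat[i] != "-") {
        ref_pos <- ref_pos + 1L
        i <- i + 1L
      } else if (pat[i] == "-") {          # gap in read = deletion
        len <- 0L
        start <- ref_pos + 1L
        while (i <= length(pat) && pat[i] == "-") {
          len <- len + 1L; ref_pos <- ref_pos + 1L; i <- i + 1L
        }
        if (start <= hi && (start + len - 1L) >= lo) {
          events <- c(events, paste0("del", len))
        }
      } else {                             # gap in reference = insertion
        len <- 0L
        while (i <= length(pat) && sub[i] == "-") {
          len <- len + 1L; i <- i + 1L
        }
        if (ref_pos >= lo - 1L && ref_pos <= hi) {
          events <- c(events, paste0("ins", len))
        }
      }
    }
    if (length(events)) {
      paste(events, collapse = "+")
    } else if (toupper(rd) == reference_amplicon) {
      "WT"
    } else {
      "sub"
    }
  }, character(1))

  tab <- table(descr[match(reads, unique(reads))])
  tibble::tibble(
    allele = names(tab),
    n_reads = as.integer(tab),
    freq = as.integer(tab) / length(reads),
    depth = length(reads)
  )
}
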