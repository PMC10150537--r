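#' The 32 NNK degenerate codons
#'
#' NNK codons have any base (N) at the first two positions and G or T (K) at
#' the third. The set encodes all 20 amino acids plus a single stop (TAG),
#' which is why NNK primers are the standard choice for one-codon saturation
#' mutagenesis libraries.
#'
#' @return Character vector of the 32 NNK codons, alphabetically ordered.
#' @export
#' @examples
#' length(nnk_codons())            # 32
#' sum(translate_codon(nnk_codons()) == "*")  # 1 (TAG)
nnk_codons <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = c("G", "T"), b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$b1, grid$b2, grid$b3))
}

#' Translate codons with the standard genetic code
#'
#' @param codon Character vector of 3-mer DNA codons.
#' @return Character vector of one-letter amino acids, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  stopifnot(is.character(codon))
  if (any(nchar(codon) != 3L)) {
    stop("codons must be 3-mers", call. = FALSE)
  }
  aa <- unname(Biostrings::GENETIC_CODE[toupper(codon)])
  if (anyNA(aa)) {
    stop("invalid codon(s): ",
         paste(unique(codon[is.na(aa)]), collapse = ", "), call. = FALSE)
  }
  aa
}

#' Construct and validate a reference coding sequence
#'
#' The reference CDS is the scaffold every codon of which is randomized in
#' the saturation-mutagenesis library. It must start with ATG, have length
#' divisible by three, and contain no internal stop codon.
#'
#' @param nt_seq DNA string (A/C/G/T) of the coding sequence.
#' @param id Sequence identifier.
#' @return An object of class `reference_cds`: a list with `id`, `nt_seq`,
#'   `aa_seq` (standard-genetic-code translation), `codons` (character
#'   vector), and `n_codons`.
#' @export
#' @examples
#' ref <- reference_cds("ATGGCTAAA", id = "toy")
#' ref$aa_seq   # "MAK"
reference_cds <- function(nt_seq, id = "reference") {
  nt_seq <- toupper(as.character(nt_seq))
  if (nchar(nt_seq) == 0L || nchar(nt_seq) %% 3L != 0L) {
    stop("reference length must be a positive multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", nt_seq)) {
    stop("reference may only contain A/C/G/T", call. = FALSE)
  }
  codons <- substring(nt_seq, seq(1, nchar(nt_seq), 3), seq(3, nchar(nt_seq), 3))
  if (codons[1] != "ATG") {
    stop("reference must begin with ATG", call. = FALSE)
  }
  aa <- translate_codon(codons)
  if (any(aa[-length(aa)] == "*")) {
    stop("reference contains an internal stop codon", call. = FALSE)
  }
  structure(
    list(id = id, nt_seq = nt_seq, aa_seq = paste(aa, collapse = ""),
         codons = codons, n_codons = length(codons)),
    class = "reference_cds"
  )
}

#' @export
print.reference_cds <- function(x, ...) {
  cat("<reference_cds> ", x$id, ": ", x$n_codons, " codons (",
      nchar(x$nt_seq), " nt)\n", sep = "")
  invisible(x)
}

#' Classify a codon substitution
#'
#' @param wt_codon,obs_codon Distinct valid codons (vectorized).
#' @return `"synonymous"`, `"missense"`, or `"nonsense"` per element.
#'   Synonymous means the amino acid is unchanged; nonsense means the
#'   observed codon is a stop.
#' @export
#' @examples
#' classify_substitution("GCT", "GCC")  # synonymous
#' classify_substitution("TGG", "TAG")  # nonsense
#' classify_substitution("GGA", "AGA")  # missense (G -> R)
classify_substitution <- function(wt_codon, obs_codon) {
  if (any(wt_codon == obs_codon)) {
    stop("wt_codon and obs_codon must differ", call. = FALSE)
  }
  wt_aa <- translate_codon(wt_codon)
  obs_aa <- translate_codon(obs_codon)
  dplyr::case_when(
    obs_aa == "*" & wt_aa != "*" ~ "nonsense",
    obs_aa == wt_aa ~ "synonymous",
    TRUE ~ "missense"
  )
}

## Internal: canonical variant id, e.g. "A2D/GAT". The amino-acid-level id
## ("A2D") is the prefix before the slash; synonymous ids keep the codon so
## distinct encodings remain distinguishable.
variant_id <- function(wt_aa, codon_index, obs_aa, obs_codon) {
  paste0(wt_aa, codon_index, obs_aa, "/", obs_codon)
}

#' Amino-acid-level id of codon-variant ids
#'
#' Strips the codon suffix from canonical ids (`"A2D/GAT"` -> `"A2D"`).
#' Synonymous and WT rows are left untouched by aggregation, but the bare
#' aa id is still well defined for them.
#'
#' @param id Character vector of variant ids.
#' @return Character vector of amino-acid-level ids.
#' @export
aa_id <- function(id) sub("/.*$", "", id)

#' Enumerate all NNK single-codon variants of a reference CDS
#'
#' Every codon position is replaced, one at a time, by each of the 32 NNK
#' codons (minus the wild-type codon where it is itself NNK-encodable),
#' mirroring a saturation-mutagenesis library in which each clone carries
#' exactly one codon change.
#'
#' @param reference A [reference_cds()].
#' @return A tibble with one row per variant: `id`, `codon_index` (1-based),
#'   `wt_codon`, `obs_codon`, `wt_aa`, `obs_aa`, `consequence`
#'   (synonymous / missense / nonsense), and `aa_id`.
#' @export
#' @examples
#' nrow(enumerate_nnk_variants(reference_cds("ATG")))  # 31
enumerate_nnk_variants <- function(reference) {
  stopifnot(inherits(reference, "reference_cds"))
  nnk <- nnk_codons()
  nnk_aa <- translate_codon(nnk)
  wt_aa <- strsplit(reference$aa_seq, "")[[1]]

  per_pos <- lapply(seq_len(reference$n_codons), function(i) {
    obs <- nnk[nnk != reference$codons[i]]
    tibble::tibble(
      codon_index = i,
      wt_codon = reference$codons[i],
      obs_codon = obs,
      wt_aa = wt_aa[i],
      obs_aa = nnk_aa[nnk != reference$codons[i]]
    )
  })
  out <- dplyr::bind_rows(per_pos)
  out$consequence <- dplyr::case_when(
    out$obs_aa == "*" ~ "nonsense",
    out$obs_aa == out$wt_aa ~ "synonymous",
    TRUE ~ "missense"
  )
  out$id <- variant_id(out$wt_aa, out$codon_index, out$obs_aa, out$obs_codon)
  out$aa_id <- aa_id(out$id)
  dplyr::relocate(out, "id")
}
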