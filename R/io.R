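#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Tibble `id`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(x), seq = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble `id`, `seq` (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), seq = unname(seqs))
  }
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (PHRED+33)
#'
#' @param path FASTQ file.
#' @return Tibble `id`, `seq`, `qual`. Malformed records (e.g. a quality
#'   string shorter than its sequence) raise a parse error.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", path, " has ", length(lines),
         " non-empty lines (not a multiple of 4)", call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  ids <- lines[idx]
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(ids, "@") | !startsWith(lines[idx + 2L], "+"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ record at line ", (bad_hdr[1] - 1L) * 4L + 1L,
         call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("FASTQ record ", bad[1], " (line ", (bad[1] - 1L) * 4L + 1L,
         "): sequence and quality lengths differ", call. = FALSE)
  }
  tibble::tibble(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

#' Write reads to FASTQ (PHRED+33)
#'
#' @param reads Tibble with `seq`, `qual`, and an id column (`id` or
#'   `read_id`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  id <- if ("id" %in% names(reads)) reads$id else reads$read_id
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  writeLines(
    as.vector(rbind(paste0("@", id), reads$seq, "+", reads$qual)),
    path
  )
  invisible(path)
}

#' Read a TSV table with schema checking
#'
#' Skips `#`-prefixed header comments; errors name the first missing
#' required column.
#'
#' @param path TSV file.
#' @param required Character vector of required column names.
#' @return Tibble.
#' @export
read_tsv_table <- function(path, required = character(0)) {
  x <- read.delim(path, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("column '", missing[1], "' missing from ", path, call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Write a TSV table deterministically
#'
#' Rows are written in their current order, numeric columns formatted to
#' 6 significant digits, and a header comment records the tool version
#' and a digest of the run configuration, so identical inputs yield
#' byte-identical files.
#'
#' @param x Data frame.
#' @param path Output file.
#' @param config_digest Optional digest string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, config_digest = NULL) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      x[[j]] <- formatC(x[[j]], digits = 6, format = "g")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(
    "# casdms ", as.character(packageVersion("casdms")),
    if (!is.null(config_digest)) paste0(" config=", config_digest) else ""
  ), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Internal: stable digest of a configuration list (no external deps:
## sum/product hash over the serialized bytes).
config_digest <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 251)) %% .Machine$integer.max)
}
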