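#' Ground truth for the specificity assays
#'
#' Bundles a target site with an additive mismatch-penalty matrix (kT
#' units, exactly 0 at the target base of every position) and a cleavage
#' rate scale, for simulating bound/unbound and cleaved/mock libraries.
#'
#' @param target_seq Target DNA string.
#' @param energy_matrix Optional L x 4 penalty matrix (columns A, C, G, T);
#'   if omitted, penalties are drawn uniformly from `penalty_range`.
#' @param cleavage_rate_scale Dimensionless first-order cleavage extent of
#'   the perfect-match sequence (`k*t`); default 2.
#' @param mu Chemical-potential offset of the binding reaction, in kT
#'   (default 0; positive values push the library toward saturation).
#' @param penalty_range Range for randomly drawn penalties (kT).
#' @param seed Seed for random penalties.
#' @return A `spec_truth` object.
#' @export
spec_truth <- function(target_seq, energy_matrix = NULL,
                       cleavage_rate_scale = 2, mu = 0,
                       penalty_range = c(0.25, 3), seed = 1L) {
  target_seq <- toupper(target_seq)
  L <- nchar(target_seq)
  bases <- c("A", "C", "G", "T")
  tchars <- strsplit(target_seq, "")[[1]]
  if (is.null(energy_matrix)) {
    energy_matrix <- with_seed(seed, {
      m <- matrix(runif(4 * L, penalty_range[1], penalty_range[2]),
                  nrow = L, ncol = 4, dimnames = list(seq_len(L), bases))
      m[cbind(seq_len(L), match(tchars, bases))] <- 0
      m
    })
  }
  stopifnot(nrow(energy_matrix) == L, ncol(energy_matrix) == 4L)
  tgt_idx <- cbind(seq_len(L), match(tchars, bases))
  if (any(energy_matrix[tgt_idx] != 0)) {
    stop("penalty at the target base must be exactly 0", call. = FALSE)
  }
  if (any(!is.finite(energy_matrix))) {
    stop("penalties must be finite", call. = FALSE)
  }
  if (cleavage_rate_scale <= 0) {
    stop("cleavage_rate_scale must be positive", call. = FALSE)
  }
  dimnames(energy_matrix) <- list(seq_len(L), bases)
  structure(
    list(target_seq = target_seq, energy_matrix = energy_matrix,
         cleavage_rate_scale = cleavage_rate_scale, mu = mu),
    class = "spec_truth"
  )
}

#' @export
print.spec_truth <- function(x, ...) {
  cat("<spec_truth> ", nchar(x$target_seq), "-nt target ", x$target_seq,
      ", k*t = ", x$cleavage_rate_scale, ", mu = ", x$mu, " kT\n", sep = "")
  invisible(x)
}

#' Additive mismatch energies of library sequences
#'
#' `ddG(s) = sum over mismatched positions of the penalty of the
#' substituted base` — 0 for the perfect match.
#'
#' @param truth A [spec_truth()].
#' @param seqs Character vector of sequences (target length).
#' @return Numeric vector of energies (kT).
#' @export
truth_energies <- function(truth, seqs) {
  ann <- mismatch_annotation(seqs, truth$target_seq)
  bases <- colnames(truth$energy_matrix)
  vapply(ann, function(a) {
    if (nrow(a) == 0L) return(0)
    sum(truth$energy_matrix[cbind(a$pos, match(a$base, bases))])
  }, numeric(1))
}

#' Simulate Spec-seq and SEAM-seq count libraries
#'
#' From a known energy model, computes each library member's occupancy
#' under a logistic (Fermi) binding isotherm,
#' `p_b(s) = 1 / (1 + exp(ddG(s) - mu))`, and its survival of nuclease
#' treatment under first-order kinetics with an Arrhenius-type rate,
#' `surv(s) = exp(-k*t * exp(-ddG(s)))`, then draws multinomial counts
#' for the four fractions: bound and unbound (occupancy-partitioned) and
#' cleaved-surviving and mock (the mock is the unselected library).
#'
#' With `analytic = TRUE` the expected (real-valued) counts are returned
#' instead of multinomial draws — the infinite-depth limit used for
#' round-trip identifiability checks.
#'
#' @param truth A [spec_truth()].
#' @param library Character vector of library sequences (should include
#'   the target), or a tibble with a `seq` column.
#' @param depths Named list/vector of per-fraction depths
#'   (`bound`, `unbound`, `cleaved`, `mock`).
#' @param input_freqs Optional library composition (default uniform).
#' @param analytic Return expected counts instead of sampling.
#' @param seed Integer seed.
#' @return Tibble `seq`, `n_mismatch`, `ddG_true`, `bound`, `unbound`,
#'   `cleaved`, `mock`.
#' @export
simulate_specseq <- function(truth, library,
                             depths = c(bound = 1e6, unbound = 1e6,
                                        cleaved = 1e6, mock = 1e6),
                             input_freqs = NULL, analytic = FALSE,
                             seed = 1L) {
  seqs <- if (is.data.frame(library)) library$seq else library
  ddG <- truth_energies(truth, seqs)
  f <- if (is.null(input_freqs)) rep(1 / length(seqs), length(seqs)) else {
    input_freqs / sum(input_freqs)
  }

  p_b <- 1 / (1 + exp(ddG - truth$mu))
  surv <- exp(-truth$cleavage_rate_scale * exp(-ddG))

  frac <- list(
    bound = f * p_b,
    unbound = f * (1 - p_b),
    cleaved = f * surv,
    mock = f
  )
  frac <- lapply(frac, function(x) x / sum(x))

  draw <- function(name) {
    if (analytic) {
      frac[[name]] * depths[[name]]
    } else {
      with_seed(fork_seed(seed, name), {
        as.numeric(rmultinom(1L, size = depths[[name]], prob = frac[[name]]))
      })
    }
  }
  tibble::tibble(
    seq = seqs,
    n_mismatch = vapply(mismatch_annotation(seqs, truth$target_seq),
                        nrow, integer(1)),
    ddG_true = ddG,
    bound = draw("bound"),
    unbound = draw("unbound"),
    cleaved = draw("cleaved"),
    mock = draw("mock")
  )
}
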