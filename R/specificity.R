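#' Enumerate a mismatch library around a target site
#'
#' All sequences within Hamming distance `K` of the target (exhaustive
#' mode; `sum_{k<=K} choose(L,k) * 3^k` members including the target), or
#' the target plus a per-distance-class uniform sample without replacement
#' (sampled mode, for sites where exhaustive enumeration is impractical).
#'
#' @param target Target DNA string (protospacer, optionally with the PAM
#'   window). Positions are 1-based from the PAM-proximal end.
#' @param K Maximum number of mismatches (default 4).
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param quota_per_k Sequences drawn per distance class in sampled mode;
#'   clipped with a warning when it exceeds the class size.
#' @param seed Seed for sampled mode.
#' @return Tibble `seq`, `n_mismatch`; attribute `target`.
#' @export
#' @examples
#' nrow(enumerate_mismatch_library("ACGT", K = 1))  # 13
#' nrow(enumerate_mismatch_library("ACGT", K = 2))  # 67
enumerate_mismatch_library <- function(target, K = 4L,
                                       mode = c("exhaustive", "sampled"),
                                       quota_per_k = 500L, seed = 1L) {
  mode <- match.arg(mode)
  target <- toupper(target)
  if (nchar(target) == 0L || grepl("[^ACGT]", target)) {
    stop("target must be a non-empty A/C/G/T string", call. = FALSE)
  }
  L <- nchar(target)
  K <- min(K, L)
  tchars <- strsplit(target, "")[[1]]
  bases <- c("A", "C", "G", "T")

  make_seq <- function(pos, subs) {
    x <- tchars
    x[pos] <- subs
    paste(x, collapse = "")
  }

  out <- list(tibble::tibble(seq = target, n_mismatch = 0L))
  for (k in seq_len(K)) {
    pos_sets <- combn(L, k, simplify = FALSE)
    class_size <- length(pos_sets) * 3^k
    if (mode == "exhaustive") {
      seqs <- unlist(lapply(pos_sets, function(p) {
        alt <- lapply(p, function(i) setdiff(bases, tchars[i]))
        grid <- do.call(expand.grid,
                        c(alt, list(stringsAsFactors = FALSE)))
        apply(grid, 1L, function(row) make_seq(p, unname(row)))
      }))
    } else {
      quota <- quota_per_k
      if (quota > class_size) {
        warning("quota_per_k (", quota_per_k, ") exceeds class size (",
                class_size, ") at k = ", k, "; clipped", call. = FALSE)
        quota <- class_size
      }
      seqs <- with_seed(fork_seed(seed, paste0("k", k)), {
        picked <- character(0)
        while (length(picked) < quota) {
          p <- pos_sets[[sample.int(length(pos_sets), 1L)]]
          subs <- vapply(p, function(i) {
            sample(setdiff(bases, tchars[i]), 1L)
          }, character(1))
          picked <- unique(c(picked, make_seq(p, subs)))
        }
        picked
      })
    }
    out[[k + 1L]] <- tibble::tibble(seq = seqs, n_mismatch = k)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "target") <- target
  res
}

## Internal: per-sequence mismatch annotation against a target.
## Returns a list of data.frames with columns pos, base.
mismatch_annotation <- function(seqs, target) {
  L <- nchar(target)
  if (any(nchar(seqs) != L)) {
    stop("library sequences must match the target length", call. = FALSE)
  }
  tmat <- strsplit(target, "")[[1]]
  smat <- matrix(unlist(strsplit(seqs, "")), ncol = L, byrow = TRUE)
  lapply(seq_along(seqs), function(i) {
    pos <- which(smat[i, ] != tmat)
    data.frame(pos = pos, base = smat[i, pos])
  })
}

#' Relative binding energies from bound/unbound counts
#'
#' The Spec-seq estimator: with `b` and `u` the bound- and unbound-fraction
#' counts, `ddG(s) = -ln(((b_s+a)/(u_s+a)) / ((b_ref+a)/(u_ref+a)))` in kT
#' units, anchored so the perfect-match reference is exactly 0. Any
#' sequence-independent partitioning constants (chemical potential, gel
#' recovery, sequencing depth) cancel in the double ratio.
#'
#' @param counts Tibble `seq`, `bound`, `unbound` (counts may be
#'   non-integer, e.g. analytic expected frequencies).
#' @param reference_seq The perfect-match sequence; must be present.
#' @param alpha Pseudocount (default 0.5).
#' @return Tibble `seq`, `ddG`.
#' @export
binding_energy <- function(counts, reference_seq, alpha = 0.5) {
  stopifnot(all(c("seq", "bound", "unbound") %in% names(counts)))
  i_ref <- match(reference_seq, counts$seq)
  if (is.na(i_ref)) {
    stop("reference sequence absent from the count table", call. = FALSE)
  }
  lodds <- log(counts$bound + alpha) - log(counts$unbound + alpha)
  tibble::tibble(seq = counts$seq, ddG = -(lodds - lodds[i_ref]))
}

#' Cleavage depletion scores from cleaved/mock counts
#'
#' The SEAM-seq estimator: with `m` the mock counts (totals `M`) and `c`
#' the counts surviving nuclease treatment (totals `C`),
#' `d(s) = ln(((m_s+a)/M) / ((c_s+a)/C))` minus the same quantity for the
#' reference. Higher `d` = more efficiently cleaved (more depleted from
#' the surviving pool); `d(reference) = 0`; sequences cut more poorly than
#' the reference score negative.
#'
#' @param counts Tibble `seq`, `cleaved`, `mock`.
#' @inheritParams binding_energy
#' @return Tibble `seq`, `d`.
#' @export
cleavage_score <- function(counts, reference_seq, alpha = 0.5) {
  stopifnot(all(c("seq", "cleaved", "mock") %in% names(counts)))
  if (sum(counts$mock) <= 0) {
    stop("mock totals must be positive", call. = FALSE)
  }
  i_ref <- match(reference_seq, counts$seq)
  if (is.na(i_ref)) {
    stop("reference sequence absent from the count table", call. = FALSE)
  }
  M <- sum(counts$mock)
  C <- sum(counts$cleaved)
  d <- log((counts$mock + alpha) / M) - log((counts$cleaved + alpha) / C)
  tibble::tibble(seq = counts$seq, d = d - d[i_ref])
}

#' Fit an additive position-by-base energy matrix
#'
#' Weighted least-squares fit of the additive mismatch model
#' `score(s) = sum over mismatched positions i of eps[i, s_i]`,
#' anchored at 0 for the target base at every position. Each parameter is
#' one (position, non-target base) penalty; parameters never observed in
#' the library are reported as `NA`, not zero. Observation weights default
#' to an inverse-variance proxy (harmonic mean of the two fraction counts)
#' when the score table carries counts, else 1.
#'
#' @param scores Tibble with `seq` and a score column (`ddG` or `d`).
#' @param target Target sequence (the zero anchor).
#' @param score_col Name of the score column (default: `"ddG"` if present,
#'   else `"d"`).
#' @param weights Optional numeric observation weights.
#' @param assay `"binding"` or `"cleavage"`; for cleavage the fitted
#'   penalties are the negated depletion scores, so that a positive
#'   penalty always means "mismatch impairs activity".
#' @return An `energy_model`: list with `target_seq`, `epsilon`
#'   (L x 4 matrix, kT units, exact zeros at target bases, `NA` where
#'   unobserved), `assay`, and `diagnostics` (`rmse`, `n_obs`, `n_par`).
#' @export
fit_energy_model <- function(scores, target, score_col = NULL,
                             weights = NULL,
                             assay = c("binding", "cleavage")) {
  assay <- match.arg(assay)
  if (is.null(score_col)) {
    score_col <- if ("ddG" %in% names(scores)) "ddG" else "d"
  }
  stopifnot(score_col %in% names(scores))
  target <- toupper(target)
  L <- nchar(target)
  bases <- c("A", "C", "G", "T")
  tchars <- strsplit(target, "")[[1]]

  y <- scores[[score_col]]
  if (assay == "cleavage") y <- -y
  ann <- mismatch_annotation(scores$seq, target)

  par_names <- as.vector(outer(seq_len(L), bases, function(i, b) {
    paste0(i, ":", b)
  }))
  free <- !(par_names %in% paste0(seq_len(L), ":", rep(tchars, 4)))
  par_names <- par_names[free]

  X <- matrix(0, nrow = length(y), ncol = length(par_names),
              dimnames = list(NULL, par_names))
  for (i in seq_along(ann)) {
    if (nrow(ann[[i]])) {
      X[i, paste0(ann[[i]]$pos, ":", ann[[i]]$base)] <- 1
    }
  }

  observed <- colSums(X) > 0
  if (is.null(weights)) {
    weights <- if (all(c("bound", "unbound") %in% names(scores))) {
      2 / (1 / (scores$bound + 0.5) + 1 / (scores$unbound + 0.5))
    } else if (all(c("cleaved", "mock") %in% names(scores))) {
      2 / (1 / (scores$cleaved + 0.5) + 1 / (scores$mock + 0.5))
    } else {
      rep(1, length(y))
    }
  }

  fit <- lm.wfit(X[, observed, drop = FALSE], y, w = weights)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    stop("rank-deficient design; unidentifiable parameters: ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "), call. = FALSE)
  }

  eps <- matrix(NA_real_, nrow = L, ncol = 4,
                dimnames = list(seq_len(L), bases))
  eps[cbind(seq_len(L), match(tchars, bases))] <- 0
  obs_names <- colnames(X)[observed]
  pos <- as.integer(sub(":.*", "", obs_names))
  bas <- sub(".*:", "", obs_names)
  eps[cbind(pos, match(bas, bases))] <- unname(coefs)

  resid <- y - X[, observed, drop = FALSE] %*% coefs
  structure(
    list(
      target_seq = target,
      epsilon = eps,
      assay = assay,
      diagnostics = list(
        rmse = sqrt(sum(weights * resid^2) / sum(weights)),
        n_obs = length(y),
        n_par = sum(observed)
      )
    ),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", x$assay, " assay, ", nchar(x$target_seq),
      "-nt target ", x$target_seq, "\n", sep = "")
  cat("  ", x$diagnostics$n_par, " penalties from ", x$diagnostics$n_obs,
      " sequences; weighted RMSE ",
      format(x$diagnostics$rmse, digits = 3), " kT\n", sep = "")
  invisible(x)
}

#' Mean absolute error between two energy matrices
#'
#' Compared over parameters observed in both models (target-base zeros
#' excluded).
#'
#' @param model An `energy_model` (or bare matrix).
#' @param truth An `energy_model`, `spec_truth`, or bare matrix.
#' @return Mean absolute difference in kT.
#' @export
energy_mae <- function(model, truth) {
  get_eps <- function(x) {
    if (is.matrix(x)) x
    else if (inherits(x, "spec_truth")) x$energy_matrix
    else x$epsilon
  }
  m1 <- get_eps(model)
  m2 <- get_eps(truth)
  keep <- !is.na(m1) & !is.na(m2) & (m1 != 0 | m2 != 0)
  mean(abs(m1[keep] - m2[keep]))
}

#' Pearson concordance between replicate score sets
#'
#' @param scores_rep1,scores_rep2 Tibbles with `seq` and a shared score
#'   column (`ddG` or `d`).
#' @return List: `r` (Pearson correlation over shared sequences), `n`.
#' @export
replicate_correlation <- function(scores_rep1, scores_rep2) {
  col <- intersect(c("ddG", "d"), names(scores_rep1))[1]
  shared <- intersect(scores_rep1$seq, scores_rep2$seq)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared sequences between replicates", call. = FALSE)
  }
  x <- scores_rep1[[col]][match(shared, scores_rep1$seq)]
  y <- scores_rep2[[col]][match(shared, scores_rep2$seq)]
  list(r = cor(x, y), n = length(shared))
}

#' Convert an energy matrix to Boltzmann base weights
#'
#' Per position, `p[i, b]` is proportional to `exp(-eps[i, b])`; rows sum
#' to 1. Positions with missing (unobserved) penalties are rendered
#' uniform and flagged. Also reports each position's information content
#' (`2 - H(p)` bits), the letter-height scale of a motif logo.
#'
#' @param model An `energy_model` (or `spec_truth`).
#' @return List: `pwm` (L x 4 probability matrix), `info` (bits per
#'   position), `incomplete` (logical per position).
#' @export
energy_to_logo <- function(model) {
  eps <- if (inherits(model, "spec_truth")) model$energy_matrix else {
    model$epsilon
  }
  incomplete <- apply(eps, 1L, anyNA)
  pwm <- t(apply(eps, 1L, function(row) {
    if (anyNA(row)) return(rep(0.25, 4))
    w <- exp(-row)
    w / sum(w)
  }))
  dimnames(pwm) <- dimnames(eps)
  h <- -rowSums(ifelse(pwm > 0, pwm * log2(pwm), 0))
  list(pwm = pwm, info = 2 - h, incomplete = incomplete)
}

#' Plot an energy model as a motif logo
#'
#' Information-content-scaled stacked letters per position (PAM-proximal
#' position 1 on the left), built from [energy_to_logo()].
#'
#' @param model An `energy_model`.
#' @return A ggplot object.
#' @export
plot_energy_logo <- function(model) {
  logo <- energy_to_logo(model)
  L <- nrow(logo$pwm)
  df <- do.call(rbind, lapply(seq_len(L), function(i) {
    h <- logo$pwm[i, ] * logo$info[i]
    ord <- order(h)
    data.frame(pos = i, base = colnames(logo$pwm)[ord], height = h[ord],
               ymin = cumsum(c(0, h[ord]))[seq_len(4)],
               ymax = cumsum(h[ord]))
  }))
  df <- df[df$height > 1e-9, ]
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$pos - 0.45, xmax = .data$pos + 0.45,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$base),
      alpha = 0.25
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$pos, y = (.data$ymin + .data$ymax) / 2,
                   label = .data$base, colour = .data$base,
                   size = .data$height),
      fontface = "bold", show.legend = FALSE
    ) +
    ggplot2::scale_size(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = seq_len(L)) +
    ggplot2::labs(x = "position (PAM-proximal = 1)",
                  y = "information (bits)",
                  title = paste0(model$assay, " specificity logo")) +
    ggplot2::theme_minimal()
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm L x 4 probability matrix (columns A, C, G, T).
#' @param path Output file.
#' @param name Motif name.
#' @param nsites Nominal site count recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif1", nsites = 20L) {
  stopifnot(ncol(pwm) == 4L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            nrow(pwm), nsites)
  ), con)
  writeLines(apply(pwm, 1L, function(row) {
    paste(sprintf("%.6f", row), collapse = " ")
  }), con)
  invisible(path)
}
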