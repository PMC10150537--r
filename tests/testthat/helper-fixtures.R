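# Shared fixtures, all built in code.

tiny_ref <- function() reference_cds("ATGGCTAAA", id = "tiny")

# Independent brute-force oracle: every sequence of length L within
# Hamming distance K of `target`, by exhaustive scan of all 4^L strings.
hamming_ball_bruteforce <- function(target, K) {
  L <- nchar(target)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), L), list(stringsAsFactors = FALSE)))
  tchars <- strsplit(target, "")[[1]]
  dist <- rowSums(t(t(as.matrix(grid)) != tchars) * 1)
  apply(grid[dist <= K, , drop = FALSE], 1, paste, collapse = "")
}

# Independent scalar oracle for the log-enrichment score: explicit
# frequency computation, one variant at a time.
enrichment_oracle <- function(c_pre, n_pre, c_post, n_post, alpha, V) {
  f_pre <- (c_pre + alpha) / (n_pre + alpha * V)
  f_post <- (c_post + alpha) / (n_post + alpha * V)
  log(f_post / f_pre)
}

# Long count tibble for hand-specified per-round counts:
# counts_by_round[[round_name]] named vectors per replicate.
make_counts <- function(variant_ids, rounds, replicates, count_fun) {
  out <- list()
  for (r in replicates) {
    for (rd in rounds) {
      out[[length(out) + 1L]] <- tibble::tibble(
        variant_id = variant_ids, round = rd, replicate = r,
        count = count_fun(variant_ids, rd, r)
      )
    }
  }
  dplyr::bind_rows(out)
}
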