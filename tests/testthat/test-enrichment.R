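test_that("pseudocounted frequencies normalize for any alpha", {
  counts <- tibble::tibble(
    variant_id = c("A", "B", "C"), sample = "s1", count = c(2L, 3L, 5L)
  )
  f0 <- variant_frequencies(counts, alpha = 0)
  expect_equal(f0$freq, c(0.2, 0.3, 0.5))
  for (alpha in c(0, 0.5, 2)) {
    f <- variant_frequencies(counts, alpha = alpha)
    expect_lt(abs(sum(f$freq) - 1), 1e-12)
  }
  zero <- variant_frequencies(
    tibble::tibble(variant_id = c("A", "B"), sample = "s", count = c(0L, 9L)),
    alpha = 0.5
  )
  expect_gt(zero$freq[1], 0)
})

test_that("raw enrichment matches closed forms and is monotone", {
  expect_equal(raw_enrichment(100, 1e4, 200, 1e4, alpha = 0,
                              n_variants = 100), log(2))
  expect_equal(raw_enrichment(123, 5e3, 123, 5e3, alpha = 0.5,
                              n_variants = 50), 0)
  # dropout guarded by the pseudocount: ln(0.5 / 50.5)
  expect_equal(
    raw_enrichment(50, 1e4, 0, 1e4, alpha = 0.5, n_variants = 100),
    log(0.5 / 50.5),
    tolerance = 1e-12
  )
  s <- raw_enrichment(100, 1e4, c(50, 100, 200, 400), 1e4,
                      alpha = 0.5, n_variants = 100)
  expect_true(all(diff(s) > 0))
  expect_error(raw_enrichment(1, 0, 1, 10, 0.5, 10), "positive")
})

test_that("vectorized scoring equals the scalar oracle on random tables", {
  set.seed(99)
  for (i in 1:100) {
    V <- sample(5:50, 1)
    c_pre <- rpois(V, lambda = sample(1:200, 1))
    c_post <- rpois(V, lambda = sample(1:200, 1))
    alpha <- sample(c(0, 0.5, 1), 1)
    n_pre <- sum(c_pre) + sample(0:100, 1)
    n_post <- sum(c_post) + sample(0:100, 1)
    got <- raw_enrichment(c_pre, n_pre, c_post, n_post, alpha, V)
    want <- vapply(seq_len(V), function(j) {
      enrichment_oracle(c_pre[j], n_pre, c_post[j], n_post, alpha, V)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("synonymous centering zeroes the anchor median and is shift-invariant", {
  s <- c(-0.1, 0, 0.1, 0.5, 1.2, rnorm(20))
  anchors <- c(rep(TRUE, 3), rep(FALSE, 2), rep(TRUE, 10), rep(FALSE, 10))
  cen <- synonymous_center(s, anchors)
  expect_true(cen$centered)
  expect_identical(median(cen$z[anchors]), 0)
  shifted <- synonymous_center(s + 0.3, anchors)
  expect_equal(shifted$z, cen$z)

  expect_warning(
    few <- synonymous_center(s, c(rep(TRUE, 3), rep(FALSE, 22))),
    "anchors"
  )
  expect_false(few$centered)
  expect_equal(few$z, s)
})

test_that("the count filter is an inclusive per-replicate sum", {
  counts <- make_counts(c("v1", "v2", "v3"), rounds = 3:4, replicates = 1:2,
    count_fun = function(ids, rd, r) {
      # v1: 30 + 20 = 50 (boundary), v2: 25 + 24 = 49, v3: plenty
      c(if (rd == 3) 30L else 20L, if (rd == 3) 25L else 24L, 500L)
    })
  flt <- apply_count_filter(counts, min_count = 50)
  expect_true(all(flt$pass[flt$variant_id == "v1"]))
  expect_false(any(flt$pass[flt$variant_id == "v2"]))
  expect_true(all(flt$pass_all[flt$variant_id == "v3"]))
  all_pass <- apply_count_filter(counts, min_count = 0)
  expect_true(all(all_pass$pass))
})

test_that("replicate aggregation requires strict positivity everywhere", {
  a <- aggregate_replicates(c(0.5, 0.2, 0.1))
  expect_equal(a$mean_score, 0.8 / 3)
  expect_true(a$is_positive)
  expect_false(aggregate_replicates(c(0.5, -0.1, 0.3))$is_positive)
  expect_false(aggregate_replicates(c(0, 0, 0))$is_positive)
  expect_error(aggregate_replicates(c(NA_real_, NA_real_)), "no replicate")
})

test_that("screen scoring centers synonymous scores and flags hits", {
  scr <- simulate_screen(n_codons = 40, depth = 3e5, seed = 17)
  rec <- score_enrichment(scr$counts, scr$variants)

  # per-replicate synonymous medians are exactly zero among passing anchors
  for (r in 1:3) {
    anchor <- rec$consequence == "synonymous" & rec[[paste0("pass_rep", r)]]
    expect_equal(median(rec[[paste0("z_rep", r)]][anchor]), 0)
  }

  hits <- call_hits(rec)
  expect_true(all(hits$is_positive))
  expect_true(all(hits$passes_count_filter))
  expect_true(!is.unsorted(rev(hits$mean_score)))
  expect_true(all(hits$variant_id %in% rec$variant_id))

  # codon-level scoring keeps codon resolution
  rec_codon <- score_enrichment(scr$counts, scr$variants, level = "codon")
  expect_gt(nrow(rec_codon), nrow(rec))
  expect_true(all(grepl("/", rec_codon$variant_id) |
                    rec_codon$variant_id == "WT"))
})

test_that("interface prioritization filters by residue index", {
  hits <- tibble::tibble(
    variant_id = c("G146R", "R182V", "E795Q", "K900T"),
    codon_index = c(146L, 182L, 795L, 900L),
    mean_score = c(2, 1.5, 1, 0.5),
    passes_count_filter = TRUE, is_positive = TRUE
  )
  kept <- prioritize_interface(hits, c(146L, 182L, 795L))
  expect_identical(nrow(kept), 3L)
  expect_identical(kept$variant_id, c("G146R", "R182V", "E795Q"))
  expect_identical(prioritize_interface(hits, hits$codon_index), hits)
  expect_identical(nrow(prioritize_interface(hits, c(7L, 8L))), 0L)
  expect_warning(none <- prioritize_interface(hits, integer(0)), "empty")
  expect_identical(nrow(none), 0L)
})

test_that("mean scores recover a continuous effect ladder by rank", {
  scr <- simulate_screen(n_codons = 100, depth = 1e6, continuous = TRUE,
                         frac_beneficial = 0.3, frac_deleterious = 0.3,
                         frac_null = 0, seed = 5)
  rec <- score_enrichment(scr$counts, scr$variants)
  eff <- dplyr::distinct(scr$effects, aa_id, .keep_all = TRUE)
  m <- dplyr::inner_join(rec, eff, by = c("variant_id" = "aa_id"))
  m <- m[m$passes_count_filter & m$w > 0 & m$class != "synonymous", ]
  expect_gt(nrow(m), 500)
  expect_gt(cor(log(m$w), m$mean_score, method = "spearman"), 0.9)
})
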