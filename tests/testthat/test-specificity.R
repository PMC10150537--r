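test_that("mismatch-library enumeration matches brute-force Hamming balls", {
  expect_identical(nrow(enumerate_mismatch_library("ACGT", K = 1)), 13L)
  expect_identical(nrow(enumerate_mismatch_library("ACGT", K = 2)), 67L)
  lib0 <- enumerate_mismatch_library("ACGTAC", K = 0)
  expect_identical(lib0$seq, "ACGTAC")

  for (target in c("ACGT", "TTGACA")) {
    for (K in 0:2) {
      lib <- enumerate_mismatch_library(target, K = K)
      oracle <- hamming_ball_bruteforce(target, K)
      expect_setequal(lib$seq, oracle)
      # closed-form size
      L <- nchar(target)
      expect_identical(nrow(lib),
                       as.integer(sum(choose(L, 0:K) * 3^(0:K))))
    }
  }
})

test_that("sampled libraries honor quotas and clip oversized ones", {
  lib <- enumerate_mismatch_library("ACGTACGTACGT", K = 3, mode = "sampled",
                                    quota_per_k = 10, seed = 2)
  expect_identical(nrow(lib), 31L)  # target + 3 x 10
  expect_false(anyDuplicated(lib$seq) > 0)
  # annotated distances are correct
  tchars <- strsplit("ACGTACGTACGT", "")[[1]]
  d <- vapply(strsplit(lib$seq, ""), function(s) sum(s != tchars),
              integer(1))
  expect_identical(d, lib$n_mismatch)
  expect_warning(
    clipped <- enumerate_mismatch_library("ACGT", K = 1, mode = "sampled",
                                          quota_per_k = 99),
    "clipped"
  )
  expect_identical(nrow(clipped), 13L)
})

test_that("binding energies are anchored, scale-invariant double ratios", {
  cts <- tibble::tibble(
    seq = c("AAAA", "AAAT", "AATT"),
    bound = c(100, 50, 100),
    unbound = c(100, 200, 100)
  )
  ddG <- binding_energy(cts, "AAAA", alpha = 0)
  expect_equal(ddG$ddG[1], 0)
  expect_equal(ddG$ddG[2], log(4))
  expect_equal(ddG$ddG[3], 0)
  halved <- dplyr::mutate(cts, bound = bound / 2, unbound = unbound / 2)
  expect_equal(binding_energy(halved, "AAAA", alpha = 0)$ddG, ddG$ddG)
  expect_error(binding_energy(cts, "GGGG"), "reference")
})

test_that("cleavage depletion scores follow the stated sign convention", {
  cts <- tibble::tibble(
    seq = c("AAAA", "AAAT", "AATT"),
    mock = c(100, 100, 100),
    cleaved = c(100, 10, 400)
  )
  d <- cleavage_score(cts, "AAAA", alpha = 0)
  expect_equal(d$d[1], 0)
  expect_equal(d$d[2], log(10))   # strongly depleted = efficiently cleaved
  expect_lt(d$d[3], 0)            # enriched in the surviving pool
  expect_error(cleavage_score(cts, "TTTT"), "reference")
})

test_that("the additive fit is exact on single-mismatch designs", {
  target <- "ACGTAC"
  lib <- enumerate_mismatch_library(target, K = 1)
  truth <- spec_truth(target, seed = 3)
  scores <- tibble::tibble(seq = lib$seq,
                           ddG = truth_energies(truth, lib$seq))
  fit <- fit_energy_model(scores, target)
  # one observation per parameter: every penalty equals its variant's score
  expect_lt(energy_mae(fit, truth), 1e-10)
  expect_true(all(fit$epsilon[cbind(
    seq_len(6), match(strsplit(target, "")[[1]], c("A", "C", "G", "T"))
  )] == 0))
})

test_that("unobserved parameters are missing, not zero, and logos flag them", {
  target <- "ACGT"
  lib <- enumerate_mismatch_library(target, K = 1)
  keep <- lib$seq[substr(lib$seq, 1, 1) != "G"]  # never observe 1:G
  truth <- spec_truth(target, seed = 9)
  scores <- tibble::tibble(seq = keep, ddG = truth_energies(truth, keep))
  fit <- fit_energy_model(scores, target)
  expect_true(is.na(fit$epsilon["1", "G"]))
  logo <- energy_to_logo(fit)
  expect_true(logo$incomplete[1])
  expect_equal(unname(logo$pwm[1, ]), rep(0.25, 4))
})

test_that("simulated occupancies are monotone in the mismatch penalty", {
  target <- "ACGTACGT"
  eps <- matrix(0, 8, 4, dimnames = list(1:8, c("A", "C", "G", "T")))
  eps[1, "C"] <- 2   # 2 kT mismatch
  eps[2, "G"] <- 4   # 4 kT mismatch
  for (mu in c(-2, 0, 2)) {
    truth <- spec_truth(target, energy_matrix = eps, mu = mu)
    lib <- c(target, "CCGTACGT", "AGGTACGT")
    cts <- simulate_specseq(truth, lib, analytic = TRUE)
    expect_equal(cts$ddG_true, c(0, 2, 4))
    frac_bound <- cts$bound / (cts$bound + cts$unbound)
    expect_gt(frac_bound[2], frac_bound[3])
    expect_gt(frac_bound[1], frac_bound[2])
  }
})

test_that("fitting simulated data recovers the generating energies", {
  target <- "ACGTTGCA"
  truth <- spec_truth(target, seed = 31)
  lib <- enumerate_mismatch_library(target, K = 2)

  # analytic limit: recovery to numerical precision
  cts <- simulate_specseq(truth, lib, analytic = TRUE)
  ddG <- binding_energy(cts, target, alpha = 0)
  fit <- fit_energy_model(cbind(ddG, cts[c("bound", "unbound")]), target)
  expect_lt(energy_mae(fit, truth), 1e-6)

  # multinomial noise at moderate depth
  cts2 <- simulate_specseq(truth, lib,
                           depths = c(bound = 3e5, unbound = 3e5,
                                      cleaved = 3e5, mock = 3e5),
                           seed = 7)
  ddG2 <- binding_energy(cts2, target)
  fit2 <- fit_energy_model(cbind(ddG2, cts2[c("bound", "unbound")]), target)
  expect_lt(energy_mae(fit2, truth), 0.1)

  # cleavage scores order sequences by their mismatch load even though the
  # kinetic link is not exactly additive
  d <- cleavage_score(cts, target, alpha = 0)
  expect_equal(d$d[cts$n_mismatch == 0], 0)
  expect_gt(min(d$d[cts$n_mismatch == 0]) + 1e-9,
            max(d$d[cts$n_mismatch == 2]))
  cfit <- fit_energy_model(cbind(d, cts[c("cleaved", "mock")]), target,
                           assay = "cleavage")
  expect_true(all(cfit$epsilon >= -1e-9, na.rm = TRUE))
})

test_that("replicate concordance behaves at the limits", {
  s1 <- tibble::tibble(seq = c("A", "C", "G", "T"), ddG = c(0, 1, 2, 3))
  expect_equal(replicate_correlation(s1, s1)$r, 1)
  s2 <- dplyr::mutate(s1, ddG = -ddG)
  expect_equal(replicate_correlation(s1, s2)$r, -1)
  expect_identical(replicate_correlation(s1, s1)$n, 4L)
  expect_error(
    replicate_correlation(s1[1:2, ], s1[1:2, ]), "shared"
  )
})

test_that("logo weights are normalized Boltzmann probabilities", {
  target <- "ACGT"
  eps <- matrix(0, 4, 4, dimnames = list(1:4, c("A", "C", "G", "T")))
  eps[2, c("A", "G", "T")] <- 10  # near-certain target base
  model <- structure(
    list(target_seq = target, epsilon = eps, assay = "binding",
         diagnostics = list(rmse = 0, n_obs = 0, n_par = 12)),
    class = "energy_model"
  )
  logo <- energy_to_logo(model)
  expect_true(all(abs(rowSums(logo$pwm) - 1) < 1e-12))
  # all-zero position: uniform, zero information
  expect_equal(unname(logo$pwm[1, ]), rep(0.25, 4))
  expect_equal(logo$info[[1]], 0)
  # dominant target base: p ~ 1, information ~ 2 bits
  expect_gt(logo$pwm[2, "C"], 0.999)
  expect_gt(logo$info[[2]], 1.99)

  p <- plot_energy_logo(model)
  expect_s3_class(p, "ggplot")
})

test_that("MEME export round-trips the probability matrix", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.25, 0.25, 0.25, 0.25), nrow = 2, byrow = TRUE,
                dimnames = list(1:2, c("A", "C", "G", "T")))
  tmp <- tempfile(fileext = ".meme")
  write_meme(pwm, tmp, name = "test_motif")
  lines <- readLines(tmp)
  expect_true(any(grepl("MOTIF test_motif", lines)))
  expect_true(any(grepl("w= 2", lines)))
  rows <- utils::tail(lines, 2)
  back <- do.call(rbind, lapply(strsplit(rows, " "), as.numeric))
  expect_equal(back, unname(pwm), tolerance = 1e-6)
})
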