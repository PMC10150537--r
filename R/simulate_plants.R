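#' Simulate diploid T0-plant allele mixtures
#'
#' Generates ground-truth-labelled allele-frequency tables for the
#' genotype classifier. Each plant is drawn into an editing class from
#' `profile` and given the corresponding diploid allele mixture:
#'
#' * `WT` — a single wild-type allele at frequency 1;
#' * `monoallelic` — WT and one mutant allele at 0.5 each;
#' * `biallelic_homozygous` — one mutant allele at ~0.98 (residual WT
#'   reads model low-level contamination);
#' * `biallelic_heterozygous` — two distinct mutant alleles at 0.5 each;
#' * `chimeric` — a mosaic of WT and two mutant alleles at intermediate
#'   frequencies (0.2 / 0.45 / 0.35).
#'
#' Observed frequencies are multinomial draws at `read_depth`, so every
#' table carries realistic sampling noise. `chimeric_noise` adds a
#' low-frequency somatic allele to that fraction of non-chimeric plants.
#' Mutant alleles are deletions of 3-14 bp (descriptor `del<n>`) or 1-bp
#' insertions, the typical outcome spectrum of a staggered-cut nuclease.
#'
#' @param n_plants Number of plants.
#' @param profile Named numeric vector of class proportions over the five
#'   classes (missing classes = 0); normalized internally.
#' @param target_id Target label.
#' @param read_depth Reads per plant (default 2000).
#' @param chimeric_noise Fraction of a low-frequency (0.10) noise allele
#'   added to non-chimeric plants (default 0 = none).
#' @param seed Integer seed.
#' @return List: `alleles` (long tibble `plant_id`, `target_id`,
#'   `allele`, `freq`, `depth`) and `truth` (tibble `plant_id`,
#'   `true_class`).
#' @export
simulate_plant_alleles <- function(n_plants = 120L,
                                   profile = c(WT = 0.2,
                                               monoallelic = 0.2,
                                               biallelic_heterozygous = 0.2,
                                               biallelic_homozygous = 0.2,
                                               chimeric = 0.2),
                                   target_id = "target1",
                                   read_depth = 2000L,
                                   chimeric_noise = 0,
                                   seed = 1L) {
  classes <- c("WT", "monoallelic", "biallelic_heterozygous",
               "biallelic_homozygous", "chimeric")
  prof <- setNames(rep(0, 5), classes)
  prof[names(profile)] <- profile
  if (sum(prof) <= 0) stop("profile must give positive proportions",
                           call. = FALSE)
  prof <- prof / sum(prof)

  with_seed(seed, {
    true_class <- sample(classes, n_plants, replace = TRUE, prob = prof)
    mutant_pool <- c(paste0("del", 3:14), "ins1")

    tables <- lapply(seq_len(n_plants), function(i) {
      muts <- sample(mutant_pool, 2L)
      mix <- switch(true_class[i],
        WT = c(WT = 1),
        monoallelic = setNames(c(0.5, 0.5), c("WT", muts[1])),
        biallelic_homozygous = setNames(c(0.02, 0.98), c("WT", muts[1])),
        biallelic_heterozygous = setNames(c(0.5, 0.5), muts),
        chimeric = setNames(c(0.2, 0.45, 0.35), c("WT", muts[1], muts[2]))
      )
      if (chimeric_noise > 0 && true_class[i] != "chimeric" &&
          runif(1) < chimeric_noise) {
        extra <- sample(setdiff(mutant_pool, names(mix)), 1L)
        mix <- c(mix * 0.9, setNames(0.1, extra))
      }
      obs <- rmultinom(1L, size = read_depth, prob = mix)[, 1]
      obs <- obs[obs > 0]
      tibble::tibble(
        plant_id = sprintf("plant%03d", i),
        target_id = target_id,
        allele = names(obs),
        freq = as.numeric(obs) / sum(obs),
        depth = read_depth
      )
    })

    list(
      alleles = dplyr::bind_rows(tables),
      truth = tibble::tibble(plant_id = sprintf("plant%03d", seq_len(n_plants)),
                             true_class = true_class)
    )
  })
}
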