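test_that("genotype decision rules classify the canonical patterns", {
  tbl <- function(allele, freq) tibble::tibble(allele = allele, freq = freq)
  expect_identical(classify_genotype(tbl("WT", 1))$class, "WT")
  expect_identical(
    classify_genotype(tbl(c("del5", "del3"), c(0.52, 0.48)))$class,
    "biallelic_heterozygous"
  )
  expect_identical(
    classify_genotype(tbl(c("WT", "ins1"), c(0.5, 0.5)))$class,
    "monoallelic"
  )
  expect_identical(
    classify_genotype(tbl(c("del7", "WT"), c(0.97, 0.03)))$class,
    "biallelic_homozygous"
  )
  # residual class: mosaic patterns
  expect_identical(
    classify_genotype(tbl(c("WT", "del4", "del9"), c(0.2, 0.45, 0.35)))$class,
    "chimeric"
  )
  expect_identical(
    classify_genotype(tbl(c("WT", "del4"), c(0.15, 0.85)))$class,
    "chimeric"
  )
  # indel frequency is 1 - WT fraction
  call <- classify_genotype(tbl(c("WT", "ins1"), c(0.5, 0.5)))
  expect_equal(call$indel_frequency, 0.5)
  # low depth -> no call
  low <- classify_genotype(
    tibble::tibble(allele = "WT", freq = 1, depth = 50L)
  )
  expect_identical(low$class, "no_call")
  expect_error(classify_genotype(tbl(c("WT", "del2"), c(0.6, 0.6))),
               "sum to 1")
})

test_that("classification is total and deterministic", {
  sim <- simulate_plant_alleles(n_plants = 50, seed = 4)
  calls <- classify_genotypes(sim$alleles)
  expect_identical(nrow(calls), 50L)
  expect_true(all(calls$class %in% c(
    "WT", "monoallelic", "biallelic_heterozygous",
    "biallelic_homozygous", "chimeric"
  )))
  expect_identical(classify_genotypes(sim$alleles), calls)
})

test_that("target summaries reproduce the reported rate arithmetic", {
  # 12 plants: 6 homozygous + 6 heterozygous -> 100% biallelic, 50% homozygous
  calls <- tibble::tibble(
    plant_id = sprintf("p%02d", 1:12), target_id = "siteA",
    class = rep(c("biallelic_homozygous", "biallelic_heterozygous"), 6)
  )
  alleles <- tibble::tibble(
    plant_id = rep(calls$plant_id, each = 2), target_id = "siteA",
    allele = rep(c("del3", "del14"), 12), freq = 0.5, depth = 1000L
  )
  s <- summarize_targets(calls, alleles)
  expect_equal(s$pct_biallelic, 100)
  expect_equal(s$pct_homozygous, 50)
  expect_equal(s$pct_edited, 100)
  expect_identical(c(s$del_min, s$del_max), c(3L, 14L))

  # 10 of 12 homozygous -> 83.33%
  calls2 <- dplyr::mutate(calls, class = c(
    rep("biallelic_homozygous", 10), rep("biallelic_heterozygous", 2)
  ))
  s2 <- summarize_targets(calls2, alleles)
  expect_equal(s2$pct_homozygous, 1000 / 12)

  # all WT -> nothing edited, empty deletion range
  calls3 <- dplyr::mutate(calls, class = "WT")
  s3 <- summarize_targets(calls3, alleles)
  expect_equal(s3$pct_edited, 0)
  expect_true(is.na(s3$del_min))
})

test_that("profile extremes generate the promised allele mixtures", {
  wt <- simulate_plant_alleles(n_plants = 10, profile = c(WT = 1), seed = 2)
  expect_true(all(wt$alleles$allele == "WT"))
  expect_true(all(wt$alleles$freq == 1))

  hom <- simulate_plant_alleles(
    n_plants = 10, profile = c(biallelic_homozygous = 1), seed = 2
  )
  top <- dplyr::slice_max(dplyr::group_by(hom$alleles, plant_id), freq,
                          n = 1)
  expect_true(all(top$allele != "WT"))
  expect_true(all(top$freq > 0.9))
})

test_that("the classifier recovers simulated ground-truth labels", {
  sim <- simulate_plant_alleles(n_plants = 60, chimeric_noise = 0, seed = 13)
  calls <- classify_genotypes(sim$alleles)
  agree <- calls$class[match(sim$truth$plant_id, calls$plant_id)] ==
    sim$truth$true_class
  expect_gte(mean(agree), 0.95)
})

test_that("the bundled allele caller keys reads by indel pattern", {
  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
  expect_error(call_alleles_from_reads(character(0), ref), "no reads")

  wt_only <- call_alleles_from_reads(rep(ref, 5), ref)
  expect_identical(wt_only$allele, "WT")
  expect_equal(wt_only$freq, 1)

  # 60/40 mixture with a 5-bp deletion at the midpoint
  del5 <- paste0(substr(ref, 1, 37), substr(ref, 43, 80))
  mix <- call_alleles_from_reads(c(rep(ref, 60), rep(del5, 40)), ref)
  expect_equal(mix$freq[mix$allele == "WT"], 0.6)
  expect_equal(mix$freq[mix$allele == "del5"], 0.4)

  # insertion at the cut site
  ins2 <- paste0(substr(ref, 1, 40), "GG", substr(ref, 41, 80))
  ins <- call_alleles_from_reads(rep(ins2, 3), ref)
  expect_identical(ins$allele, "ins2")
})
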