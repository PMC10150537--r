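## Recognized configuration keys per pipeline, used for schema validation.
.config_schema <- list(
  common = c("pipeline", "seed", "out_dir"),
  screen = c("n_codons", "n_rounds", "sequenced_rounds", "depth",
             "n_replicates", "frac_beneficial", "frac_deleterious",
             "frac_null", "effect_scale", "round_pre", "round_post",
             "alpha", "min_count", "level"),
  specseq = c("target", "K", "library_mode", "quota_per_k", "depth",
              "cleavage_rate_scale", "mu", "alpha"),
  plants = c("n_plants", "profile", "read_depth", "chimeric_noise",
             "target_id")
)

#' Validate a run configuration
#'
#' Checks the configuration (a list, or a YAML file path) against the
#' published schema before any stage runs: the pipeline name must be one
#' of `screen`, `specseq`, `plants`; `seed` and `out_dir` are required;
#' unknown keys are rejected.
#'
#' @param config List or path to a YAML file.
#' @return The validated configuration list (invisibly usable).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  if (is.null(config$pipeline) ||
      !config$pipeline %in% c("screen", "specseq", "plants")) {
    stop("config$pipeline must be one of screen/specseq/plants",
         call. = FALSE)
  }
  for (key in c("seed", "out_dir")) {
    if (is.null(config[[key]])) {
      stop("config is missing required key '", key, "'", call. = FALSE)
    }
  }
  allowed <- c(.config_schema$common, .config_schema[[config$pipeline]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config
}

## Internal: append a structured event to the run log.
log_event <- function(log, stage, event, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event, ...)
  c(log, list(entry))
}

#' Run a pipeline end to end from a configuration
#'
#' Executes the stages of the requested pipeline in dependency order and
#' writes all artifacts plus a structured JSON run log to `out_dir`.
#' Identical configurations (including `seed`) produce byte-identical
#' TSV outputs.
#'
#' Pipelines:
#' * `screen` — simulate the NNK selection screen, tabulate counts, score
#'   enrichment, call hits; writes `counts.tsv`, `scores.tsv`,
#'   `effects.tsv`, `reference.fasta`, `summary.json`.
#' * `specseq` — simulate bound/unbound and cleaved/mock libraries from a
#'   random ground-truth energy model, fit both models; writes
#'   `specseq_counts.tsv`, `binding_energy.tsv`, `cleavage_energy.tsv`,
#'   `binding_model.meme`, `summary.json`.
#' * `plants` — simulate T0 allele tables, classify, summarize; writes
#'   `alleles.tsv`, `genotype_calls.tsv`, `target_summary.tsv`,
#'   `summary.json`.
#'
#' @param config List or YAML path; see [validate_config()].
#' @return Invisibly, a list of the pipeline's main in-memory results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # digest covers the analysis parameters, not the output location
  digest <- config_digest(config[setdiff(names(config), "out_dir")])
  log <- list()
  log <- log_event(log, config$pipeline, "begin", config_digest = digest)

  getp <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  out <- switch(config$pipeline,
    screen = {
      scr <- simulate_screen(
        n_codons = getp("n_codons", 300L),
        n_rounds = getp("n_rounds", 4L),
        sequenced_rounds = unlist(getp("sequenced_rounds", c(3L, 4L))),
        depth = getp("depth", 1e6),
        n_replicates = getp("n_replicates", 3L),
        frac_beneficial = getp("frac_beneficial", 0.10),
        frac_deleterious = getp("frac_deleterious", 0.15),
        frac_null = getp("frac_null", 0.05),
        effect_scale = getp("effect_scale", 2),
        seed = config$seed
      )
      log <- log_event(log, "simulate_screen", "done",
                       n_variants = nrow(scr$variants),
                       n_counts = nrow(scr$counts))
      records <- score_enrichment(
        scr$counts, scr$variants,
        round_pre = getp("round_pre", 3L),
        round_post = getp("round_post", 4L),
        alpha = getp("alpha", 0.5),
        min_count = getp("min_count", 50L),
        level = getp("level", "aa")
      )
      hits <- call_hits(records)
      write_fasta(
        tibble::tibble(id = scr$reference$id, seq = scr$reference$nt_seq),
        file.path(config$out_dir, "reference.fasta")
      )
      write_tsv_table(scr$counts, file.path(config$out_dir, "counts.tsv"),
                      digest)
      write_tsv_table(scr$effects, file.path(config$out_dir, "effects.tsv"),
                      digest)
      write_tsv_table(records, file.path(config$out_dir, "scores.tsv"),
                      digest)
      summary <- list(
        n_variants = nrow(scr$variants),
        n_records = nrow(records),
        n_passing = sum(records$passes_count_filter),
        n_hits = nrow(hits),
        n_synonymous_anchors =
          sum(records$consequence == "synonymous" &
                records$passes_count_filter, na.rm = TRUE)
      )
      log <- log_event(log, "enrich", "done", n_hits = nrow(hits))
      list(screen = scr, records = records, hits = hits, summary = summary)
    },
    specseq = {
      target <- getp("target", "TTTACGCAGTCGATCGTAGCTAGC")
      truth <- spec_truth(
        target,
        cleavage_rate_scale = getp("cleavage_rate_scale", 2),
        mu = getp("mu", 0),
        seed = fork_seed(config$seed, "truth")
      )
      lib <- enumerate_mismatch_library(
        target, K = getp("K", 2L),
        mode = getp("library_mode", "exhaustive"),
        quota_per_k = getp("quota_per_k", 500L),
        seed = fork_seed(config$seed, "library")
      )
      depth <- getp("depth", 1e6)
      counts <- simulate_specseq(
        truth, lib,
        depths = c(bound = depth, unbound = depth,
                   cleaved = depth, mock = depth),
        seed = fork_seed(config$seed, "counts")
      )
      ddG <- binding_energy(counts, target, alpha = getp("alpha", 0.5))
      dd <- cleavage_score(counts, target, alpha = getp("alpha", 0.5))
      bind_model <- fit_energy_model(cbind(ddG, counts[c("bound", "unbound")]),
                                     target, assay = "binding")
      cleave_model <- fit_energy_model(cbind(dd, counts[c("cleaved", "mock")]),
                                       target, assay = "cleavage")
      write_tsv_table(counts, file.path(config$out_dir, "specseq_counts.tsv"),
                      digest)
      write_tsv_table(as.data.frame(bind_model$epsilon),
                      file.path(config$out_dir, "binding_energy.tsv"), digest)
      write_tsv_table(as.data.frame(cleave_model$epsilon),
                      file.path(config$out_dir, "cleavage_energy.tsv"), digest)
      write_meme(energy_to_logo(bind_model)$pwm,
                 file.path(config$out_dir, "binding_model.meme"),
                 name = "binding")
      summary <- list(
        n_library = nrow(lib),
        binding_rmse = bind_model$diagnostics$rmse,
        binding_mae_vs_truth = energy_mae(bind_model, truth)
      )
      log <- log_event(log, "specseq", "done", n_library = nrow(lib))
      list(truth = truth, counts = counts, binding_model = bind_model,
           cleavage_model = cleave_model, summary = summary)
    },
    plants = {
      sim <- simulate_plant_alleles(
        n_plants = getp("n_plants", 120L),
        profile = unlist(getp("profile", c(
          WT = 0.2, monoallelic = 0.2, biallelic_heterozygous = 0.2,
          biallelic_homozygous = 0.2, chimeric = 0.2
        ))),
        target_id = getp("target_id", "target1"),
        read_depth = getp("read_depth", 2000L),
        chimeric_noise = getp("chimeric_noise", 0),
        seed = config$seed
      )
      calls <- classify_genotypes(sim$alleles)
      summ <- summarize_targets(calls, sim$alleles)
      write_tsv_table(sim$alleles, file.path(config$out_dir, "alleles.tsv"),
                      digest)
      write_tsv_table(calls,
                      file.path(config$out_dir, "genotype_calls.tsv"), digest)
      write_tsv_table(summ,
                      file.path(config$out_dir, "target_summary.tsv"), digest)
      recovery <- mean(
        calls$class[match(sim$truth$plant_id, calls$plant_id)] ==
          sim$truth$true_class
      )
      summary <- list(n_plants = nrow(sim$truth), label_recovery = recovery)
      log <- log_event(log, "plants", "done", n_plants = nrow(sim$truth))
      list(sim = sim, calls = calls, target_summary = summ,
           summary = summary)
    }
  )

  log <- log_event(log, config$pipeline, "end")
  jsonlite::write_json(out$summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
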