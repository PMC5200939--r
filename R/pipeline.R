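#' Build and validate a pipeline run configuration
#'
#' Accepts a nested list or a YAML file path and validates every threshold
#' before any work is done. See [demo_config()] for the full shape.
#'
#' @param x list or YAML path.
#' @return validated `run_config` list.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(reference = "builtin", seed = 1L, identity_threshold = 70,
                   hec_threshold = 0.01, case_group = "T1D", subset = "CD4",
                   pcr = NULL, pcr_series = NULL)
  for (nm in names(defaults)) if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  if (is.null(x$out_dir)) stop("config must name an out_dir")
  if (is.null(x$cohort) || !length(x$cohort)) stop("config must define a cohort")
  check_fraction(x$hec_threshold, "hec_threshold", open = TRUE)
  if (x$identity_threshold < 0 || x$identity_threshold > 100)
    stop("identity_threshold must lie in [0, 100]")
  if (is.null(x$sequencing) || is.null(x$sequencing$n_reads))
    stop("config must define sequencing$n_reads")
  for (g in names(x$cohort)) {
    arm <- x$cohort[[g]]
    if (is.null(arm$n_samples) || arm$n_samples < 1)
      stop("cohort arm '", g, "' needs n_samples >= 1")
    do.call(repertoire_model, arm$model)   # validates abundance parameters
  }
  structure(x, class = "run_config")
}

#' Demo configuration for a full simulated cohort run
#'
#' The packaged end-to-end demo: a 9 T1D / 4 T2D / 6 control CD4 cohort over
#' the built-in toy reference, with T1D samples in the HEC-dominated regime
#' (22 expanded clones holding 77% of reads) and the other arms near-even.
#' Problem sizes (clones and reads per sample) are kept small so the demo
#' runs in seconds; scale them up through the returned list.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_reads reads per sample.
#' @param n_clones_case,n_clones_ctrl clone richness per arm.
#' @return a validated [run_config()].
#' @export
demo_config <- function(out_dir, seed = 1L, n_reads = 1500L,
                        n_clones_case = 120L, n_clones_ctrl = 200L) {
  run_config(list(
    out_dir = out_dir, seed = seed,
    cohort = list(
      T1D = list(n_samples = 9L,
                 model = list(n_clones = n_clones_case,
                              abundance_mode = "hec_dominated",
                              n_expanded = 22L, expanded_mass = 0.77,
                              lognormal_sigma = 1)),
      T2D = list(n_samples = 4L,
                 model = list(n_clones = n_clones_ctrl,
                              abundance_mode = "even_lognormal",
                              lognormal_sigma = 1)),
      control = list(n_samples = 6L,
                     model = list(n_clones = n_clones_ctrl,
                                  abundance_mode = "even_lognormal",
                                  lognormal_sigma = 1))),
    sequencing = list(n_reads = n_reads, error_rate = 0, paired = FALSE)))
}

load_reference <- function(reference) {
  if (identical(reference, "builtin")) return(builtin_toy_reference())
  load_germline(reference$fasta, reference$anchors)
}

#' Simulate an annotated cohort
#'
#' Draws one ground-truthed repertoire per sample, samples sequencing reads,
#' annotates them against the reference and builds clonotype tables. Read
#' accounting (total, aligned, identity-passing, productive) is logged per
#' sample via `message()`.
#'
#' @param config a [run_config()].
#' @param db a [germline_db()].
#' @return list with `samples` (list of `repertoire_sample`), `truths`
#'   (per-sample truth tables) and `log` (read-accounting tibble).
#' @export
simulate_cohort <- function(config, db) {
  seq_model <- do.call(sequencing_model, config$sequencing)
  pcr <- if (!is.null(config$pcr)) do.call(pcr_model, config$pcr)
  samples <- list(); truths <- list(); logs <- list()
  idx <- 0L
  for (g in names(config$cohort)) {
    arm <- config$cohort[[g]]
    for (i in seq_len(arm$n_samples)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g, i)
      truth <- simulate_repertoire(do.call(repertoire_model, arm$model), db)
      sim <- simulate_reads(truth, seq_model, pcr)
      reads <- if (seq_model$paired)
        merge_pairs(tibble(read_id = sim$reads$read_id, sequence = sim$reads$sequence1,
                           quality = strrep("I", nchar(sim$reads$sequence1))),
                    tibble(read_id = sim$reads$read_id, sequence = sim$reads$sequence2,
                           quality = strrep("I", nchar(sim$reads$sequence2))))
      else sim$reads
      ann <- annotate_reads(reads, db, identity_threshold = config$identity_threshold)
      kept <- filter_by_identity(ann, config$identity_threshold)
      samples[[sid]] <- build_clonotypes(kept, sample_id = sid, group = g,
                                         subset = config$subset)
      truths[[sid]] <- truth
      logs[[sid]] <- tibble(sample_id = sid, group = g,
                            n_reads = nrow(ann),
                            n_aligned = sum(!is.na(ann$v_call) & !is.na(ann$j_call)),
                            n_pass_identity = sum(ann$pass_filter),
                            n_productive = sum(ann$productive & ann$pass_filter,
                                               na.rm = TRUE))
      message(sprintf("[tcrep] %s: %d reads, %d aligned, %d pass identity >= %g, %d productive",
                      sid, logs[[sid]]$n_reads, logs[[sid]]$n_aligned,
                      logs[[sid]]$n_pass_identity, config$identity_threshold,
                      logs[[sid]]$n_productive))
    }
  }
  list(samples = samples, truths = truths, log = bind_rows(logs))
}

usage_table <- function(profiles, gene) {
  mat <- t(vapply(profiles, function(p) p[[paste0(gene, "_usage")]],
                  numeric(length(profiles[[1]][[paste0(gene, "_usage")]]))))
  cbind(tibble(sample_id = vapply(profiles, function(p) p$sample_id, "")),
        as_tibble(as.data.frame(mat, check.names = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> annotate -> clonotype -> diversity -> usage ->
#' sharing -> cohort comparison (plus PCR-bias estimation when a
#' `pcr_series` block is configured) and writes every stage artifact, with a
#' manifest recording the package version, seed and config hash, to
#' `config$out_dir`. Identical config and seed reproduce byte-identical
#' tables.
#'
#' @param config a [run_config()] (or list/YAML path coercible to one).
#' @return invisibly, a list of in-memory stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  db <- load_reference(config$reference)
  out <- function(f) file.path(config$out_dir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("simulate+annotate", simulate_cohort(config, db))
  samples <- cohort$samples
  write_clonotypes(samples, out("clonotypes.tsv"))
  write_tsv_plain(cohort$log, out("read_accounting.tsv"))

  div <- stage("diversity", cohort_diversity(samples, threshold = config$hec_threshold))
  write_tsv_plain(div, out("diversity.tsv"))

  profiles <- stage("usage", lapply(samples, usage_profile, db = db))
  write_tsv_plain(usage_table(profiles, "v"), out("usage_v.tsv"))
  write_tsv_plain(usage_table(profiles, "j"), out("usage_j.tsv"))
  vj <- lapply(samples, vj_matrix, db = db)
  vj_long <- bind_rows(lapply(vj, function(x)
    cbind(tibble(sample_id = x$sample_id),
          as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE,
                                        responseName = "fraction")))))
  names(vj_long)[names(vj_long) %in% c("Var1", "Var2")] <- c("v_family", "j_family")
  write_tsv_plain(vj_long, out("vj_combinations.tsv"))
  spec_long <- bind_rows(lapply(names(samples), function(sid)
    cbind(tibble(sample_id = sid), spectratype(samples[[sid]]))))
  write_tsv_plain(spec_long, out("spectratype.tsv"))
  corr <- stage("usage", usage_correlation(profiles, "v"))

  shares <- stage("sharing", share_matrix(samples, config$case_group,
                                          config$hec_threshold))
  write_share_matrix(shares, out("sharing.tsv"))
  jsonlite::write_json(sharing_summary(shares), out("sharing_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  comparisons <- stage("cohort_stats", compare_groups(div))
  write_tsv_plain(comparisons, out("comparisons.tsv"))

  bias <- NULL
  if (!is.null(config$pcr_series)) {
    ps <- config$pcr_series
    bias <- stage("pcr_bias", {
      truth <- cohort$truths[[1]]
      series <- simulate_cycle_series(truth, cycles = ps$cycles,
                                      depths = ps$depths %||% 2e5,
                                      per_cycle_bias_sigma = ps$per_cycle_bias_sigma %||% 0.076)
      estimate_bias(series, min(ps$cycles), max(ps$cycles))
    })
    jsonlite::write_json(bias[c("c1", "c2", "k", "per_cycle_bias", "n_clones")],
                         out("pcr_bias.json"), auto_unbox = TRUE, digits = NA)
  }

  cfg_path <- out("config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(tool = "tcrep",
                   version = as.character(utils::packageVersion("tcrep")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(samples = samples, diversity = div, profiles = profiles,
                 correlation = corr, sharing = shares, comparisons = comparisons,
                 pcr_bias = bias, out_dir = config$out_dir))
}
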