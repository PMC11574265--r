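# Orchestration: a full stage-resolved analysis run from a config, with
# echoed configuration, input checksums, and machine-readable outputs.

#' Load a run configuration
#'
#' A run configuration describes a complete analysis: the CDS FASTA, one or
#' more stages (each with an expression TSV, an anticodon-count TSV and
#' optionally a dwell-time TSV), an optional decay time-course, an output
#' directory, and analysis options.
#'
#' @param path YAML config file with top-level keys `cds_fasta`, `stages`
#'   (named list; each stage: `expression`, `anticodon_counts`, optional
#'   `dwell_times`, optional `count_sample` column name), optional
#'   `time_course`, optional `repertoire` (TSV override), `out_dir`, and
#'   optional `options` (`top_fraction`, `t0_min_tpm`, `alpha`, `csc_mode`,
#'   `floor_zero`, `seed`).
#' @param overrides named list merged over the file values (flags beat
#'   file).
#' @return A `run_config` list.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  as_run_config(cfg)
}

#' @rdname load_run_config
#' @param cfg a plain list with the same fields as the YAML file.
#' @export
as_run_config <- function(cfg) {
  defaults <- list(top_fraction = 0.05, t0_min_tpm = 10, alpha = 0.05,
                   csc_mode = "frequency", floor_zero = FALSE, seed = 1L)
  cfg$options <- utils::modifyList(defaults, cfg$options %||% list())
  for (field in c("cds_fasta", "stages", "out_dir")) {
    if (is.null(cfg[[field]])) {
      stop("config error: missing field '", field, "'")
    }
  }
  if (length(cfg$stages) == 0L || is.null(names(cfg$stages))) {
    stop("config error: 'stages' must be a named list")
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_inputs_exist <- function(cfg) {
  paths <- c(cfg$cds_fasta, cfg$time_course, cfg$repertoire,
             unlist(lapply(cfg$stages, function(s) {
               c(s$expression, s$anticodon_counts, s$dwell_times)
             })))
  paths <- paths[!vapply(paths, is.null, logical(1))]
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("config error: input files not found: ",
         paste(missing, collapse = ", "))
  }
  unlist(paths)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stage-resolved analysis
#'
#' Produces, per stage: proportional codon usage, demand/supply table, CAI
#' and etAI weights, transcript scores (CAI, etAI and, when dwell times are
#' given, decoding rate), and the Watson-Crick vs wobble dwell-time
#' comparison. Across stages: the codon-usage CV table and a Fisher-z
#' comparison of the etAI-decoding-rate correlations. When a time-course is
#' configured: half-lives, the CSC table, and (if transcript groups are
#' given) class-content comparisons. A `summary.json` and a `run_log.txt`
#' with input MD5 checksums are always written, and the effective config is
#' echoed to `config_used.yaml`.
#'
#' @param config a `run_config` (or a list coerced with [as_run_config()]).
#' @return The output directory path, invisibly; the summary list as the
#'   `summary` attribute.
#' @export
run_stage_analysis <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  inputs <- check_inputs_exist(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  opts <- config$options

  log_lines <- c(
    sprintf("codonopt run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "input checksums:",
    sprintf("  %s  %s", tools::md5sum(inputs), inputs)
  )
  yaml::write_yaml(unclass(config), file.path(out, "config_used.yaml"))

  repertoire <- if (!is.null(config$repertoire)) {
    read_repertoire(config$repertoire)
  } else {
    default_repertoire()
  }
  map <- build_decoding_map(repertoire)
  cds_all <- read_cds_fasta(config$cds_fasta)
  n_invalid <- sum(!vapply(cds_all, `[[`, logical(1), "valid"))
  cds_set <- valid_cds(cds_all, warn = FALSE)
  log_lines <- c(log_lines, sprintf("CDS: %d records, %d invalid dropped",
                                    length(cds_all), n_invalid))

  summary <- list(
    n_cds = length(cds_set), n_invalid_cds = n_invalid,
    n_wobble_pairs = nrow(map$wobble_pairs), stages = list()
  )

  usage_by_stage <- list()
  scores_by_stage <- list()
  for (stage in names(config$stages)) {
    s <- config$stages[[stage]]
    sdir <- file.path(out, stage)
    dir.create(sdir, showWarnings = FALSE)

    tpm_tab <- read_expression(s$expression)
    tpm <- rowMeans(tpm_tab)
    counts_tab <- read_anticodon_counts(s$anticodon_counts)
    profile <- trna_proportions(rowMeans(counts_tab), label = stage)

    usage <- weighted_codon_usage(cds_set, tpm, stage = stage)
    usage_by_stage[[stage]] <- usage$usage
    write_tsv(data.frame(codon = names(usage$usage),
                         usage = unname(usage$usage)),
              file.path(sdir, "usage.tsv"))

    ds <- demand_supply(usage, profile, map)
    write_tsv(ds, file.path(sdir, "demand_supply.tsv"))

    cai <- cai_weights(cds_set, tpm, top_fraction = opts$top_fraction)
    etai <- etai_weights(profile, map, floor_zero = opts$floor_zero)
    write_weights(cai, file.path(sdir, "weights_cai.tsv"))
    write_weights(etai, file.path(sdir, "weights_etai.tsv"))

    rates <- NULL
    if (!is.null(s$dwell_times)) {
      dt <- read_dwell_times(s$dwell_times)
      rates <- decoding_rates(dt)
      wob <- wobble_vs_wc_dt(dt, map)
      write_tsv(wob$pairs, file.path(sdir, "wobble_dt_pairs.tsv"))
      summary$stages[[stage]]$wobble_vs_wc_p <- wob$test$p
    }
    scored <- transcript_scores(cds_set, cai = cai, etai = etai,
                                rates = rates)
    scores_by_stage[[stage]] <- scored
    write_tsv(scored, file.path(sdir, "scores.tsv"))

    summary$stages[[stage]]$n_expressed <- sum(tpm > 0)
    summary$stages[[stage]]$cai_reference <- cai$reference_label
    log_lines <- c(log_lines, sprintf("stage %s: %d expressed transcripts",
                                      stage, sum(tpm > 0)))
  }

  if (length(usage_by_stage) >= 2L) {
    cv <- cross_stage_cv(usage_by_stage)
    write_tsv(cv, file.path(out, "usage_cv.tsv"))
    summary$usage_cv_range <- range(cv$cv_percent, na.rm = TRUE)

    with_rates <- Filter(function(s) "decoding_rate" %in% names(s),
                         scores_by_stage)
    if (length(with_rates) >= 2L) {
      s1 <- with_rates[[1L]]
      s2 <- with_rates[[2L]]
      cmp <- fisher_z_compare(
        stats::cor(s1$etai, s1$decoding_rate), nrow(s1),
        stats::cor(s2$etai, s2$decoding_rate), nrow(s2)
      )
      cmp$stage1 <- names(with_rates)[[1L]]
      cmp$stage2 <- names(with_rates)[[2L]]
      summary$etai_rate_correlation_comparison <- cmp
    }
  }

  if (!is.null(config$time_course)) {
    tc <- read_time_course(config$time_course)
    hl <- fit_half_lives(tc, t0_min_tpm = opts$t0_min_tpm,
                         alpha = opts$alpha)
    write_tsv(hl, file.path(out, "half_lives.tsv"))
    summary$n_retained <- sum(hl$status == "retained")
    csc <- compute_csc(cds_set, hl, alpha = opts$alpha,
                       mode = opts$csc_mode)
    write_tsv(as.data.frame(csc), file.path(out, "csc.tsv"))
    summary$csc_classes <- as.list(table(csc$class))

    if (!is.null(config$groups)) {
      groups_tab <- utils::read.delim(config$groups,
                                      stringsAsFactors = FALSE)
      groups <- stats::setNames(groups_tab$group, groups_tab$transcript_id)
      groups <- groups[names(groups) %in% names(cds_set)]
      cc <- transcript_class_codon_content(cds_set, csc, groups)
      write_tsv(cc$content, file.path(out, "class_content.tsv"))
      if (!is.null(cc$tests)) {
        write_tsv(cc$tests, file.path(out, "class_content_tests.tsv"))
      }
    }
  }

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(structure(out, summary = summary))
}
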