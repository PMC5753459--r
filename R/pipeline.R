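# End-to-end orchestration: channels -> filters -> concordance ->
# inspection-set selection -> classification -> evaluation; plus the IGV
# batch-script emitter and the run summary.

#' Pipeline configuration
#'
#' A single serializable source of truth for a run. `fixture_dir` must hold a
#' fixture manifest as written by [write_fixture()] (the same layout works
#' for real data prepared in that shape).
#'
#' @param fixture_dir Directory containing `manifest.tsv` and the input
#'   files.
#' @param out_dir Output directory.
#' @param seed Integer seed (drives only the inspection-set sampling).
#' @param params A [classifier_params()].
#' @param strategies Named character vector of strategy expressions.
#' @param max_singletons Per-channel singleton cap for the inspection set.
#' @param vs_p_max VarScan somatic p-value threshold.
#' @param rescue_flags MuTect failure reasons eligible for rescue.
#' @param keep_classes Functional classes retained by the annotation filter.
#' @param lenient Lenient annotation lookup (retain unannotated with
#'   warning).
#' @param collapse_rule Per-locus collapse of per-sample labels
#'   (see [collapse_labels()]).
#' @param labels_file Optional TSV of external per-locus verdicts (columns
#'   `chrom`, `pos`, `ref`, `alt`, `label`); when given, the rule-based
#'   classifier is bypassed and these human labels are used unchanged.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture_dir, out_dir, seed,
                            params = classifier_params(),
                            strategies = default_strategies(),
                            max_singletons = 50L,
                            vs_p_max = 1e-6,
                            rescue_flags = "nearby_gap_events",
                            keep_classes = KEEP_FUNC_CLASSES,
                            lenient = FALSE,
                            collapse_rule = "any_valid",
                            labels_file = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every key of [pipeline_config()] may appear in the file; `params` is a
#' mapping of [classifier_params()] overrides and `strategies` a mapping of
#' name -> expression.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- do.call(classifier_params, y$params)
  if (!is.null(y$strategies)) y$strategies <- unlist(y$strategies)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

load_manifest <- function(fixture_dir) {
  path <- file.path(fixture_dir, "manifest.tsv")
  if (!file.exists(path)) {
    abort_typed(paste("no manifest.tsv under", fixture_dir),
                "ionsomatic_io_error")
  }
  m <- read_tsv_stable(path)
  m$abs <- file.path(fixture_dir, m$path)
  m
}

stage_log <- function(log, stage, n_in, n_out, note = "") {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note, stringsAsFactors = FALSE))
}

#' Run the full somatic-identification pipeline
#'
#' Executes, in order: channel construction (IR ingestion, TVC tumor/normal
#' subtraction for PM, MuTect call-stats rescue for MG, VarScan p-value
#' filtering for VS), population and functional annotation filters,
#' concordance-matrix construction, inspection-set selection, per-sample
#' classification (or ingestion of external labels), extrapolation and
#' strategy evaluation. All stage outputs are written as TSVs under
#' `out_dir` together with a run log (seeds and parameters; no timestamps, so
#' identical config + seed reproduces identical bytes) and an output
#' manifest with checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `channels` (filtered calls per channel),
#'   `matrix`, `inspection`, `labels` (collapsed), `labels_by_sample`,
#'   `extrapolation`, `strategy_table`, `stage_log`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  manifest <- load_manifest(config$fixture_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(stage = character(), n_in = integer(), n_out = integer(),
                    note = character(), stringsAsFactors = FALSE)

  pick <- function(kind) manifest[manifest$kind == kind, , drop = FALSE]

  # --- channel construction -------------------------------------------------
  load_rows <- function(rows, caller) {
    out <- lapply(seq_len(nrow(rows)), function(i) {
      load_vcf_calls(rows$abs[i], caller, rows$sample[i], rows$patient[i])
    })
    dplyr::bind_rows(out)
  }
  ir <- load_rows(pick("ir_vcf"), "IR")

  tvc_t_rows <- pick("tvc_tumor_vcf")
  tvc_n_rows <- pick("tvc_normal_vcf")
  pm <- dplyr::bind_rows(lapply(seq_len(nrow(tvc_t_rows)), function(i) {
    tumor <- load_vcf_calls(tvc_t_rows$abs[i], "TVC", tvc_t_rows$sample[i],
                            tvc_t_rows$patient[i])
    n_row <- tvc_n_rows[tvc_n_rows$patient == tvc_t_rows$patient[i], ,
                        drop = FALSE]
    normal <- load_vcf_calls(n_row$abs[1], "TVC", n_row$sample[1],
                             n_row$patient[1])
    pm_subtract(tumor, normal)
  }))

  mg <- dplyr::bind_rows(lapply(seq_len(nrow(pick("mg_callstats"))),
    function(i) {
      row <- pick("mg_callstats")[i, ]
      mutect_rescue(read_callstats(row$abs), config$rescue_flags,
                    sample = row$sample, patient = row$patient)
    }))

  vs_raw <- load_rows(pick("vs_vcf"), "VS")
  vs <- varscan_somatic_filter(vs_raw, config$vs_p_max)
  log <- stage_log(log, "channel_VS_pfilter", nrow(vs_raw), nrow(vs))

  channels <- list(IR = ir, MG = mg, PM = pm, VS = vs)
  for (ch in names(channels)) {
    log <- stage_log(log, paste0("channel_", ch), NA, nrow(channels[[ch]]))
  }

  # --- annotation filters ---------------------------------------------------
  ann <- read_annotations(pick("annotations")$abs[1])
  channels <- lapply(channels, function(calls) {
    n0 <- nrow(calls)
    calls <- apply_population_filter(calls, ann, lenient = config$lenient)
    apply_functional_filter(calls, ann, keep_classes = config$keep_classes,
                            lenient = config$lenient)
  })
  for (ch in names(channels)) {
    log <- stage_log(log, paste0("filtered_", ch), NA, nrow(channels[[ch]]))
  }

  # --- concordance and inspection ------------------------------------------
  cmat <- build_concordance(channels, callers = names(channels))
  inspection <- select_inspection_set(cmat, config$max_singletons,
                                      seed = config$seed)
  log <- stage_log(log, "inspection_set", nrow(cmat$loci),
                   length(inspection$ids))

  # --- labels ---------------------------------------------------------------
  all_calls <- dplyr::bind_rows(channels)
  inspected_calls <- all_calls[all_calls$id %in% inspection$ids, ,
                               drop = FALSE]
  if (!is.null(config$labels_file)) {
    ext <- read_tsv_stable(config$labels_file)
    ext$id <- variant_id(ext$chrom, ext$pos, ext$ref, ext$alt)
    labels <- tibble::tibble(id = ext$id, label = ext$label,
                             valid = ext$label == "valid")
    labels_by_sample <- NULL
  } else {
    evidence <- read_evidence(pick("evidence")$abs[1])
    reference <- Biostrings::readDNAStringSet(pick("reference")$abs[1])
    names(reference) <- sub("\\s.*$", "", names(reference))
    labels_by_sample <- classify_all(inspected_calls, evidence, reference,
                                     config$params)
    labels <- collapse_labels(labels_by_sample, config$collapse_rule)
  }
  log <- stage_log(log, "classified", length(inspection$ids), nrow(labels))

  # --- evaluation -----------------------------------------------------------
  strat <- evaluate_strategies(cmat, labels, inspection$ids,
                               config$strategies)
  report <- attr(strat, "extrapolation")

  # --- outputs --------------------------------------------------------------
  out <- function(rel) file.path(config$out_dir, rel)
  for (ch in names(channels)) {
    write_tsv_stable(channels[[ch]], out(paste0("calls_", ch, ".tsv")))
  }
  write_tsv_stable(venn_counts(cmat), out("venn_counts.tsv"))
  write_tsv_stable(
    tibble::tibble(id = inspection$ids,
                   multi_caller = inspection$ids %in% inspection$multi_ids),
    out("inspection_set.tsv"))
  write_tsv_stable(inspection$sampling_log, out("inspection_sampling.tsv"))
  write_tsv_stable(labels, out("labels.tsv"))
  if (!is.null(labels_by_sample)) {
    write_tsv_stable(labels_by_sample, out("labels_by_sample.tsv"))
  }
  write_tsv_stable(report$strata, out("extrapolation_strata.tsv"))
  write_tsv_stable(format_strategy_table(strat), out("strategy_results.tsv"))
  write_tsv_stable(log, out("stage_log.tsv"))

  run_log <- c(
    "ionsomatic run log",
    sprintf("seed: %s", format(config$seed)),
    sprintf("max_singletons: %d", config$max_singletons),
    sprintf("vs_p_max: %g", config$vs_p_max),
    sprintf("rescue_flags: %s", paste(config$rescue_flags, collapse = ",")),
    sprintf("keep_classes: %s", paste(config$keep_classes, collapse = ",")),
    sprintf("collapse_rule: %s", config$collapse_rule),
    sprintf("classifier: %s",
            paste(names(config$params), unlist(config$params), sep = "=",
                  collapse = " ")),
    sprintf("V_hat: %d", attr(strat, "V_hat")),
    sprintf("n_inspected: %d", attr(strat, "n_total_inspected"))
  )
  writeLines(run_log, out("run_log.txt"))

  files <- sort(list.files(config$out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.tsv")
  out_manifest <- tibble::tibble(
    path = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  write_tsv_stable(out_manifest, out("manifest.tsv"))

  invisible(list(channels = channels, matrix = cmat, inspection = inspection,
                 labels = labels, labels_by_sample = labels_by_sample,
                 extrapolation = report, strategy_table = strat,
                 stage_log = log, out_dir = config$out_dir))
}

#' Summarize a pipeline run as plain text
#'
#' Counts at each stage, the Venn breakdown, the classifier reason histogram
#' and the formatted strategy table.
#'
#' @param run The list returned by [run_pipeline()].
#' @return A character vector of report lines.
#' @export
summarize_run <- function(run) {
  lines <- c("== ionsomatic run summary ==", "", "-- stages --")
  lines <- c(lines, sprintf("%-22s in=%-6s out=%-6s", run$stage_log$stage,
                            ifelse(is.na(run$stage_log$n_in), "-",
                                   run$stage_log$n_in),
                            run$stage_log$n_out))
  vc <- venn_counts(run$matrix)
  vc <- vc[vc$n > 0L, , drop = FALSE]
  lines <- c(lines, "", "-- caller signatures (nonzero cells) --",
             sprintf("%-16s %d", vc$signature, vc$n))
  if (!is.null(run$labels_by_sample)) {
    s <- attr(run$labels_by_sample, "summary")
    lines <- c(lines, "", "-- labels --",
               sprintf("%-14s %d", names(s$labels), as.integer(s$labels)),
               "", "-- reasons --",
               sprintf("%-14s %d", names(s$reasons), as.integer(s$reasons)))
  }
  ft <- format_strategy_table(run$strategy_table)
  lines <- c(lines, "", "-- strategies --",
             sprintf("%-24s C=%-5d v=%-4d PPV=%s (SE %s, n=%d) Sens=%s (SE %s)",
                     ft$name, run$strategy_table$C, run$strategy_table$v_hat,
                     ft$ppv, ft$ppv_se, run$strategy_table$n_inspected,
                     ft$sens, ft$sens_se))
  lines
}

#' Emit an IGV batch script for visual review
#'
#' Writes the control script that automates inspection: for each variant,
#' start a fresh session, load every carrying sample's alignments plus the
#' matched normal, jump to the locus, sort reads by base, collapse tracks and
#' snapshot to `<chrom>_<pos>_<ref>_<alt>.png`. Variants are ordered by locus
#' only and neither file names nor ordering carry any caller identity, so
#' reviewers stay blinded to which method(s) called each variant.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` and `samples`
#'   (list column, or comma-joined string, of carrying sample ids).
#' @param alignment_paths Named character vector: sample id -> alignment file
#'   path.
#' @param normal_of Named character vector: tumor sample id -> matched normal
#'   sample id.
#' @param out_path File to write.
#' @param snapshot_dir Snapshot directory line for the script header.
#' @return The script lines, invisibly (also written to `out_path`).
#' @export
render_igv_batch <- function(variants, alignment_paths, normal_of, out_path,
                             snapshot_dir = "snapshots") {
  lines <- c("snapshotDirectory " %+% snapshot_dir, "genome reference.fa")
  if (nrow(variants)) {
    ord <- order_variant_keys(variants$chrom, variants$pos, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    snap_names <- character(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      samples <- if (is.list(variants$samples)) v$samples[[1]] else
        strsplit(v$samples, ",", fixed = TRUE)[[1]]
      if (!length(samples)) {
        abort_typed(sprintf("variant %s has no carrying sample",
                            variant_id(v$chrom, v$pos, v$ref, v$alt)),
                    "ionsomatic_bad_igv_input")
      }
      normals <- unique(normal_of[samples])
      tracks <- unique(c(samples, normals))
      missing <- tracks[!tracks %in% names(alignment_paths)]
      if (length(missing)) {
        abort_typed(paste("no alignment path for sample(s):",
                          paste(missing, collapse = ", ")),
                    "ionsomatic_bad_igv_input")
      }
      snap_names[i] <- sprintf("%s_%d_%s_%s.png", v$chrom, v$pos, v$ref,
                               v$alt)
      lines <- c(lines,
                 "new",
                 paste("load", alignment_paths[tracks]),
                 sprintf("goto %s:%d", v$chrom, v$pos),
                 "sort base",
                 "collapse",
                 paste("snapshot", snap_names[i]))
    }
    if (anyDuplicated(snap_names)) {
      abort_typed("duplicate snapshot names", "ionsomatic_bad_igv_input")
    }
  }
  writeLines(lines, out_path)
  invisible(lines)
}

`%+%` <- function(a, b) paste0(a, b)
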