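# Orchestration: simulate -> methylome -> dmr -> somatic -> enrich under a
# single config, with a manifest of stage outputs (md5 checksums) and a
# report reproducing the study-style summary tables plus ground-truth
# recovery metrics.

#' Pipeline configuration
#'
#' Bundles per-stage parameter blocks and the run directory. `seed`
#' overrides the simulation seed so one number controls the whole run.
#' When `"simulate"` is not among the stages, `inputs` must name existing
#' files (`genome`, `genes`, `control_cx`, `treated_cx`, `pathways`, plus
#' `mucosa`/`muscularis` VCF vectors).
#'
#' @param outdir run directory (created by [run_pipeline()]).
#' @param sim a [sim_config()].
#' @param dmr a [dmr_config()].
#' @param filters list with `min_mq`, `min_depth` for [filter_variants()].
#' @param enrichment list with `method`, `q_cutoff` and `zone`
#'   (`"all"`, `"up2k"`, `"body"` or `"down2k"`).
#' @param stages character vector of stages to run, in dependency order.
#' @param inputs named list of input paths for runs without the simulate
#'   stage.
#' @param seed optional integer overriding `sim$seed`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            sim = sim_config(),
                            dmr = dmr_config(),
                            filters = list(min_mq = 20, min_depth = 4),
                            enrichment = list(method = "BH",
                                              q_cutoff = 0.05,
                                              zone = "all"),
                            stages = c("simulate", "methylome", "dmr",
                                       "somatic", "enrich"),
                            inputs = list(),
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  known <- c("simulate", "methylome", "dmr", "somatic", "enrich")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- list(outdir = outdir, sim = sim, dmr = dmr, filters = filters,
              enrichment = enrichment, stages = stages, inputs = inputs)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] arguments; `sim` and `dmr` blocks
#' are passed to [sim_config()] / [dmr_config()].
#'
#' @param path YAML file.
#' @param outdir optional override of the configured run directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list(outdir = outdir %||% y$outdir %||% "inflammeth_run")
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$dmr)) args$dmr <- do.call(dmr_config, y$dmr)
  for (k in c("filters", "enrichment", "stages", "inputs", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

manifest_add <- function(run_dir, stage, files) {
  files <- files[file.exists(files)]
  if (length(files) == 0) return(invisible())
  df <- data.frame(stage = stage,
                   file = sub(paste0("^", run_dir, "/?"), "", files),
                   md5 = unname(tools::md5sum(files)),
                   stringsAsFactors = FALSE)
  path <- file.path(run_dir, "manifest.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(path),
                     append = file.exists(path))
  invisible(df)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order inside `outdir`:
#' `simulate` writes the synthetic scenario; `methylome` flags methylated
#' sites and writes summary/density/context-matrix/metagene tables for both
#' samples; `dmr` calls DMRs between control and treated; `somatic` runs
#' the paired variant analysis per mouse; `enrich` assigns DMRs to gene
#' zones and tests pathway enrichment. Each stage appends its outputs and
#' their md5 checksums to `manifest.tsv`; rerunning with the same
#' configuration reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_dir <- config$outdir
  stages <- config$stages
  # validate before any stage runs
  if (!"simulate" %in% stages) {
    need <- c("genome", "genes", "control_cx", "treated_cx")
    if ("somatic" %in% stages) need <- c(need, "mucosa", "muscularis")
    if ("enrich" %in% stages) need <- c(need, "pathways")
    for (k in need) {
      paths <- unlist(config$inputs[[k]])
      if (is.null(paths) || !all(file.exists(paths))) {
        stop("validation: missing input '", k,
             "' while the simulate stage is disabled", call. = FALSE)
      }
    }
  }
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(run_dir, "manifest.tsv"))

  sim_dir <- file.path(run_dir, "sim")
  state <- list()
  if ("simulate" %in% stages) {
    state$sim <- run_stage("simulate", simulate_all(config$sim,
                                                    outdir = sim_dir))
    manifest_add(run_dir, "simulate",
                 list.files(sim_dir, full.names = TRUE))
  } else {
    state$sim <- run_stage("load_inputs", list(
      genome = Biostrings::readDNAStringSet(config$inputs$genome),
      genes = read_gene_bed(config$inputs$genes),
      methylomes = list(control = read_cx_report(config$inputs$control_cx),
                        treated = read_cx_report(config$inputs$treated_cx)),
      pathways = if (!is.null(config$inputs$pathways))
        read_pathway_map(config$inputs$pathways) else NULL,
      truth = NULL))
    names(state$sim$genome) <- sub("\\s.*$", "", names(state$sim$genome))
  }

  if ("methylome" %in% stages) {
    run_stage("methylome", {
      mdir <- file.path(run_dir, "methylome")
      dir.create(mdir, showWarnings = FALSE)
      cl <- Biostrings::width(state$sim$genome)
      names(cl) <- names(state$sim$genome)
      for (nm in c("control", "treated")) {
        flagged <- call_methylated_sites(
          state$sim$methylomes[[nm]], error_rate = config$dmr$error_rate,
          alpha = config$dmr$alpha,
          min_coverage = config$dmr$min_call_coverage)
        state$flagged[[nm]] <- flagged
        sm <- summarize_methylome(flagged)
        utils::write.table(sm$contexts,
                           file.path(mdir, paste0(nm, "_mc_ratio.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(sm$chroms,
                           file.path(mdir, paste0(nm, "_chrom_level.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dens <- chromosome_density(flagged, window = 1000L,
                                   chrom_lengths = cl)
        utils::write.table(dens,
                           file.path(mdir, paste0(nm, "_mc_density.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cm <- context_matrix_9bp(state$sim$genome, flagged)
        utils::write.table(round(cm$mcg, 4),
                           file.path(mdir, paste0(nm, "_mcg_context9.tsv")),
                           sep = "\t", quote = FALSE)
        prof <- metagene_profile(flagged, state$sim$genes)
        utils::write.table(as.data.frame(prof),
                           file.path(mdir, paste0(nm, "_metagene.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      manifest_add(run_dir, "methylome",
                   list.files(mdir, full.names = TRUE))
    })
  }

  if ("dmr" %in% stages) {
    run_stage("dmr", {
      ddir <- file.path(run_dir, "dmr")
      dir.create(ddir, showWarnings = FALSE)
      a <- state$flagged$control %||% state$sim$methylomes$control
      b <- state$flagged$treated %||% state$sim$methylomes$treated
      dmrs <- call_dmrs(a, b, cfg = config$dmr)
      state$dmrs <- dmrs
      utils::write.table(dmrs, file.path(ddir, "dmrs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_dmr_bed(dmrs, file.path(ddir, "dmrs.bed"))
      rej <- attr(dmrs, "rejections")
      utils::write.table(
        data.frame(reason = names(rej), n = as.integer(rej)),
        file.path(ddir, "rejections.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      manifest_add(run_dir, "dmr", list.files(ddir, full.names = TRUE))
    })
  }

  if ("somatic" %in% stages) {
    run_stage("somatic", {
      sdir <- file.path(run_dir, "somatic")
      dir.create(sdir, showWarnings = FALSE)
      if ("simulate" %in% stages) {
        n_mice <- config$sim$n_mice
        muc_paths <- file.path(sim_dir, sprintf("mucosa_%d.vcf",
                                                seq_len(n_mice)))
        mus_paths <- file.path(sim_dir, sprintf("muscularis_%d.vcf",
                                                seq_len(n_mice)))
      } else {
        muc_paths <- unlist(config$inputs$mucosa)
        mus_paths <- unlist(config$inputs$muscularis)
      }
      summaries <- list()
      gene_sets <- list()
      for (m in seq_along(muc_paths)) {
        muc <- filter_variants(read_variants(muc_paths[m]),
                               min_mq = config$filters$min_mq,
                               min_depth = config$filters$min_depth)
        mus <- filter_variants(read_variants(mus_paths[m]),
                               min_mq = config$filters$min_mq,
                               min_depth = config$filters$min_depth)
        som <- subtract_germline(muc, mus)
        sid <- sprintf("mouse%d", m)
        summaries[[m]] <- summarize_sample(som, sid, n_total = nrow(muc))
        ga <- assign_genes(som, state$sim$genes)
        gene_sets[[sid]] <- ga$gene_set
        write_variant_vcf(som, file.path(sdir, sprintf("somatic_%d.vcf", m)),
                          state$sim$genome)
      }
      summary_df <- do.call(rbind, summaries)
      utils::write.table(summary_df, file.path(sdir, "sample_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      shared <- if (length(gene_sets) >= 2) intersect_gene_sets(gene_sets)
                else unlist(gene_sets)
      writeLines(shared, file.path(sdir, "shared_genes.txt"))
      state$somatic <- list(summaries = summary_df, gene_sets = gene_sets,
                             shared_genes = shared)
      manifest_add(run_dir, "somatic", list.files(sdir, full.names = TRUE))
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", {
      edir <- file.path(run_dir, "enrich")
      dir.create(edir, showWarnings = FALSE)
      dmrs <- state$dmrs
      if (is.null(dmrs)) {
        stop("the enrich stage needs the dmr stage (or its outputs)")
      }
      assign <- assign_dmr_genes(dmrs, state$sim$genes)
      utils::write.table(assign$assignments,
                         file.path(edir, "dmr_gene_zones.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      pmap <- state$sim$pathways
      background <- unique(state$sim$genes$gene_id)
      zone <- config$enrichment$zone %||% "all"
      hit <- if (zone == "all") {
        sort(unique(unlist(assign$zone_genes)))
      } else {
        assign$zone_genes[[zone]]
      }
      enr <- adjust_q(hypergeometric_enrich(hit, pmap, background),
                      method = config$enrichment$method %||% "BH",
                      q_cutoff = config$enrichment$q_cutoff %||% 0.05)
      utils::write.table(enr, file.path(edir, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      state$enrichment <- enr
      manifest_add(run_dir, "enrich", list.files(edir, full.names = TRUE))
    })
  }
  invisible(run_dir)
}

interval_overlap_any <- function(q_start, q_end, s_start, s_end) {
  vapply(seq_along(q_start), function(i)
    any(q_start[i] <= s_end & q_end[i] >= s_start), TRUE)
}

# Sensitivity/precision of called DMRs against planted truth, by >= 1 bp
# interval overlap within the same chromosome and context.
dmr_recovery <- function(called, truth, context = NULL) {
  if (!is.null(context)) {
    called <- called[called$context == context, , drop = FALSE]
    truth <- truth[truth$context == context, , drop = FALSE]
  }
  if (nrow(truth) == 0) {
    return(data.frame(context = context %||% "all", n_planted = 0L,
                      n_called = nrow(called), sensitivity = NA_real_,
                      precision = NA_real_))
  }
  sens_hits <- 0L
  for (i in seq_len(nrow(truth))) {
    sub <- called[called$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(sub) > 0 &&
        any(truth$start[i] <= sub$end & truth$end[i] >= sub$start)) {
      sens_hits <- sens_hits + 1L
    }
  }
  prec_hits <- 0L
  for (i in seq_len(nrow(called))) {
    sub <- truth[truth$chrom == called$chrom[i], , drop = FALSE]
    if (nrow(sub) > 0 &&
        any(called$start[i] <= sub$end & called$end[i] >= sub$start)) {
      prec_hits <- prec_hits + 1L
    }
  }
  data.frame(context = context %||% "all",
             n_planted = nrow(truth), n_called = nrow(called),
             sensitivity = sens_hits / nrow(truth),
             precision = if (nrow(called) > 0) prec_hits / nrow(called)
                         else NA_real_)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `run_dir` and writes `report.md` plus
#' recovery tables: per-sample variant summaries (counts and the
#' allele-frequency SUM), the mC-type ratio table, DMR counts per context
#' and zone, the top enriched pathways, and — when the run was simulated —
#' ground-truth recovery metrics (DMR sensitivity/precision per context and
#' somatic key recovery per mouse). Regenerating the report from the same
#' run directory reproduces identical content.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return list with the report tables, invisibly; `report.md` and
#'   `recovery.tsv` are written into `run_dir`.
#' @export
pipeline_report <- function(run_dir) {
  need <- c("manifest.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    stop("incomplete run; missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd <- function(p) if (file.exists(file.path(run_dir, p)))
    utils::read.table(file.path(run_dir, p), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  out <- list()
  lines <- c("# inflammeth run report", "")

  out$variant_summary <- rd("somatic/sample_summary.tsv")
  if (!is.null(out$variant_summary)) {
    lines <- c(lines, "## Somatic variants per sample", "",
               paste(capture.output(print(out$variant_summary,
                                          row.names = FALSE)),
                     collapse = "\n"), "")
    shared <- readLines(file.path(run_dir, "somatic/shared_genes.txt"))
    shared <- shared[nzchar(shared)]
    out$shared_genes <- shared
    lines <- c(lines, sprintf("Shared mutated genes across samples: %d",
                              length(shared)), "")
  }

  out$mc_ratio <- rd("methylome/control_mc_ratio.tsv")
  if (!is.null(out$mc_ratio)) {
    lines <- c(lines, "## mC-type ratios (control)", "",
               paste(capture.output(print(out$mc_ratio, row.names = FALSE)),
                     collapse = "\n"), "")
  }

  dmrs <- rd("dmr/dmrs.tsv")
  if (!is.null(dmrs)) {
    out$dmr_counts <- as.data.frame(table(context = dmrs$context),
                                    stringsAsFactors = FALSE)
    lines <- c(lines, "## DMR counts per context", "",
               paste(capture.output(print(out$dmr_counts,
                                          row.names = FALSE)),
                     collapse = "\n"), "")
    zones <- rd("enrich/dmr_gene_zones.tsv")
    if (!is.null(zones)) {
      out$dmr_zone_counts <- as.data.frame(table(zone = zones$zone),
                                           stringsAsFactors = FALSE)
      lines <- c(lines, "## DMR-gene zone assignments", "",
                 paste(capture.output(print(out$dmr_zone_counts,
                                            row.names = FALSE)),
                       collapse = "\n"), "")
    }
  }

  enr <- rd("enrich/enrichment.tsv")
  if (!is.null(enr)) {
    out$top_pathways <- head(enr, 20)
    lines <- c(lines, "## Top enriched pathways", "",
               paste(capture.output(print(out$top_pathways,
                                          row.names = FALSE)),
                     collapse = "\n"), "")
  }

  truth_dmrs <- rd("sim/truth_dmrs.tsv")
  if (!is.null(truth_dmrs) && !is.null(dmrs)) {
    rec <- do.call(rbind, lapply(c("CG", "CHG", "CHH"), function(cx)
      dmr_recovery(dmrs, truth_dmrs, context = cx)))
    out$dmr_recovery <- rec
    lines <- c(lines, "## Planted-DMR recovery", "",
               paste(capture.output(print(rec, row.names = FALSE)),
                     collapse = "\n"), "")
    utils::write.table(rec, file.path(run_dir, "recovery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  truth_var <- rd("sim/truth_variants.tsv")
  if (!is.null(truth_var) && !is.null(out$variant_summary)) {
    recs <- lapply(sort(unique(truth_var$mouse)), function(m) {
      som_path <- file.path(run_dir, sprintf("somatic/somatic_%d.vcf", m))
      if (!file.exists(som_path)) return(NULL)
      called <- variant_key(read_variants(som_path))
      tv <- truth_var[truth_var$mouse == m, , drop = FALSE]
      som_true <- tv$key[tv$class == "somatic"]
      sub <- tv$key[tv$class == "sub_threshold"]
      expected <- setdiff(som_true, sub)
      data.frame(mouse = m,
                 n_true_somatic = length(som_true),
                 n_expected_after_filters = length(expected),
                 n_called = length(called),
                 n_recovered = length(intersect(called, expected)),
                 exact = setequal(called, expected))
    })
    out$somatic_recovery <- do.call(rbind, recs)
    if (!is.null(out$somatic_recovery)) {
      lines <- c(lines, "## Somatic key recovery", "",
                 paste(capture.output(print(out$somatic_recovery,
                                            row.names = FALSE)),
                       collapse = "\n"), "")
    }
  }

  writeLines(lines, file.path(run_dir, "report.md"))
  invisible(out)
}
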