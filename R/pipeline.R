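#' Default pipeline configuration
#'
#' Every knob defaults to the published study value where one exists: QC
#' call-rate thresholds 0.90, 31 autosomes, ROH calibration alpha 0.05 with
#' 15-SNP windows (one heterozygous and one missing call allowed, 100 kb/SNP
#' density, 500 kb gap), LD pairs from 1 kb to 50 Mb, consensus sharing
#' thresholds \{0.20, 0.25, 0.30, 0.40, 0.45\}, 99th-percentile islands and
#' 1e5 gene-drop rounds.
#'
#' @param out_dir Output directory for the report bundle.
#' @return A nested list; write it with [yaml::write_yaml()] to use as a
#'   config file.
#' @export
default_config <- function(out_dir = "rohdiv_out") {
  list(
    input = list(plink_prefix = NULL, pedigree = NULL, annotation = NULL),
    simulate = list(enabled = TRUE, seed = 1L),
    qc = list(min_call_rate_snp = 0.90, min_call_rate_sample = 0.90,
              autosomes_only = TRUE, autosomes = 1:31),
    roh = list(alpha = 0.05, window_snps = 15L, max_het_in_window = 1L,
               max_missing_in_window = 1L, min_density_kb_per_snp = 100,
               max_gap_kb = 500, window_hit_fraction = 0.05),
    gene_drop = list(rounds = 1e5, seed = 1L),
    ld = list(min_bp = 1e3, max_bp = 50e6, correct_n = FALSE),
    islands = list(consensus_thresholds = c(0.20, 0.25, 0.30, 0.40, 0.45),
                   percentile = 99, max_bridge = 0L),
    out_dir = out_dir)
}

# shallow-merge user config over defaults
merge_config <- function(user, base = default_config()) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
      merge_config(user[[k]], base[[k]]) else user[[k]]
  }
  base
}

#' Run the full diversity analysis
#'
#' Orchestrates the stages end to end: load (or simulate) genotypes and
#' pedigree, quality control, ROH calibration and detection, genomic
#' inbreeding coefficients, pedigree coefficients (skipped gracefully when
#' no pedigree is available), LD-based and ROH-based effective population
#' size, and consensus-ROH / island mapping. Each stage writes its tables
#' into `out_dir` as it completes, so a failing stage leaves the earlier
#' outputs in place, and the error names the stage. A JSON provenance
#' record (package version, seeds, parameters) is written alongside.
#'
#' @param config A config list as from [default_config()], or the path to a
#'   YAML file with the same structure. Omitted entries take their defaults.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  stage("input", {
    if (!is.null(cfg$input$plink_prefix)) {
      res$gm <- read_plink(cfg$input$plink_prefix)
      res$ped <- if (!is.null(cfg$input$pedigree))
        read_pedigree(cfg$input$pedigree)
    } else if (isTRUE(cfg$simulate$enabled)) {
      sim_args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
      sim <- simulate_population(do.call(sim_config, sim_args))
      res$gm <- sim$gm
      res$ped <- sim$ped
      res$truth <- sim$truth
    } else stop("no input: set input$plink_prefix or simulate$enabled")
  })

  stage("qc", {
    qc <- apply_qc(res$gm, cfg$qc$min_call_rate_snp,
                   cfg$qc$min_call_rate_sample, cfg$qc$autosomes_only,
                   cfg$qc$autosomes)
    res$gm <- qc$gm
    res$qc_report <- qc$report
    write_qc_report(qc$report, out("qc_report.tsv"))
  })

  stage("roh", {
    sm <- summarize_genotypes(res$gm)
    res$summary <- sm
    cal <- min_snp_count(cfg$roh$alpha, sm$mean_heterozygosity,
                         n_markers(res$gm), n_samples(res$gm),
                         mean_spacing_kb = sm$mean_spacing_bp / 1000)
    res$roh_params <- roh_params(
      window_snps = cfg$roh$window_snps,
      max_het_in_window = cfg$roh$max_het_in_window,
      max_missing_in_window = cfg$roh$max_missing_in_window,
      min_snps_in_roh = cal$min_snps,
      min_length_kb = cal$min_length_kb,
      min_density_kb_per_snp = cfg$roh$min_density_kb_per_snp,
      max_gap_kb = cfg$roh$max_gap_kb,
      window_hit_fraction = cfg$roh$window_hit_fraction)
    res$segments <- detect_roh(res$gm, res$roh_params)
    write_segments_tsv(res$segments, out("roh_segments.tsv"), res$roh_params)
    res$roh_stats <- per_individual_stats(res$segments, res$gm$samples)
    utils::write.table(res$roh_stats, out("roh_per_individual.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$length_classes <- classify_lengths(res$segments)
    utils::write.table(res$length_classes, out("roh_length_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  stage("genomic_inbreeding", {
    ge_mean <- if (!is.null(res$ped)) {
      ge <- equivalent_generations(res$ped)
      mean(ge[res$gm$samples[res$gm$samples %in% names(ge)]], na.rm = TRUE)
    } else NULL
    L_auto <- res$summary$covered_length_bp
    tab <- f_roh_table(res$segments, res$gm$samples, L_auto,
                       ge_pedigree = if (!is.null(ge_mean) && ge_mean > 1)
                         ge_mean)
    tab$f_hom <- unname(f_hom(res$gm))
    tab$f_is <- unname(f_is(res$gm))
    tab <- cbind(tab, f_hat(res$gm)[, -1])
    res$genomic_coef <- tab
    utils::write.table(tab, out("genomic_inbreeding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(coef_summary(tab), out("genomic_inbreeding_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(res$ped)) {
    stage("pedigree", {
      res$pedigree_coef <- pedigree_inbreeding(
        res$ped, rounds = cfg$gene_drop$rounds, seed = cfg$gene_drop$seed)
      utils::write.table(res$pedigree_coef, out("pedigree_inbreeding.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  } else message("no pedigree available; pedigree stage skipped")

  stage("popsize", {
    res$ld_bins <- ld_ne(res$gm, min_bp = cfg$ld$min_bp,
                         max_bp = cfg$ld$max_bp, correct_n = cfg$ld$correct_n)
    utils::write.table(res$ld_bins, out("ne_trajectory.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fr <- res$genomic_coef
    means <- c(mean(fr$f_roh), mean(fr$f_roh_gt_4), mean(fr$f_roh_gt_8),
               mean(fr$f_roh_gt_16), mean(fr$f_roh_gt_32))
    res$ne_roh <- ne_from_roh_means(pmin(means, 1 - 1e-12))
    utils::write.table(res$ne_roh, out("ne_from_roh.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  stage("islands", {
    res$incidence <- roh_incidence(res$segments, res$gm$map, n_samples(res$gm))
    cons <- lapply(cfg$islands$consensus_thresholds, function(t)
      consensus_roh(res$incidence, t))
    res$consensus <- do.call(rbind, cons)
    res$islands <- percentile_islands(res$incidence, cfg$islands$percentile,
                                      cfg$islands$max_bridge)
    regions <- rbind(res$consensus, res$islands)
    regions <- annotate_regions(regions, cfg$input$annotation)
    res$regions <- regions
    write_regions_tsv(regions, out("roh_regions.tsv"))
    write_regions_bed(regions, out("roh_regions.bed"))
  })

  stage("provenance", {
    prov <- list(
      package = "rohdiv",
      version = as.character(utils::packageVersion("rohdiv")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seeds = list(simulate = cfg$simulate$seed,
                   gene_drop = cfg$gene_drop$seed),
      parameters = cfg[setdiff(names(cfg), "out_dir")],
      n_samples = n_samples(res$gm), n_markers = n_markers(res$gm))
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  })

  invisible(res)
}
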