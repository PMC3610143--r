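# Run configuration and the end-to-end pipeline: simulate -> build
# reference -> filter -> map -> differential expression -> enrichment ->
# qPCR, with provenance-stamped reports.

#' Default run configuration
#'
#' One nested list drives every stage: synthetic-data parameters,
#' filtering/mapping/DE/enrichment thresholds and the master seed. It
#' round-trips losslessly through YAML ([read_config()] /
#' [write_config()]).
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(
      n_genes = 2000L, n1 = 200000L, n2 = 319000L,
      n_de = 200L, log2fc = 3, error_rate = 0.001,
      adaptor_frac = 0.002, lowq_frac = 0.005,
      mito_frac = 5e-04, genome_frac = 0.005,
      abund_sdlog = 1.5, min_expected = 25,
      length_range = c(200L, 600L), catg_sites_range = c(1L, 3L),
      shared_tag_fraction = 0.01,
      mito_length = 8000L, nuclear_length = 40000L,
      n_terms = 50L, term_size_range = c(10L, 100L),
      enriched_odds_ratio = 8),
    thresholds = list(
      min_quality = 10, max_mismatch = 1L,
      p_max = 0.001, fdr_max = 0.001, lfc_min = 2,
      q_max = 0.05, zero_floor = 0.01),
    adaptors = DEFAULT_ADAPTOR,
    priority = c("unigene", "cdna", "tc", "predicted"),
    qpcr = list(n_validation_genes = 8L, reference = "RPS20",
                n_animals = 3L, n_tech = 3L)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param file path to the YAML file.
#' @param config a `run_config` list.
#' @return `read_config` the configuration; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' MD5 hash of a configuration
#'
#' Stamped into every report so outputs can be traced to the exact
#' configuration that produced them.
#'
#' @param config a `run_config`.
#' @return character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic two-library workflow
#'
#' Executes, in order: synthetic-data generation, reference tag library
#' construction, raw-tag filtering (both libraries), the mapping cascade,
#' copy-number/saturation summaries, two-library differential expression,
#' GO/pathway enrichment of the significant genes, and qPCR validation
#' math on a synthetic Ct table for a panel of significant genes. All
#' reports are written under `outdir` as tab-separated files stamped with
#' the configuration hash; a provenance log records versions, seeds and
#' thresholds.
#'
#' @param config a `run_config`, see [default_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with every intermediate object (truth,
#'   transcriptome, reference, clean libraries, ledgers, mapping results,
#'   DE table, enrichment table, qPCR table).
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- list(config = hash, seed = config$seed)
  syn <- config$synthetic
  thr <- config$thresholds
  out <- function(f) file.path(outdir, f)

  truth <- run_stage("simulate", synthetic_truth(
    n_genes = syn$n_genes, n1 = syn$n1, n2 = syn$n2, n_de = syn$n_de,
    log2fc = syn$log2fc, error_rate = syn$error_rate,
    adaptor_frac = syn$adaptor_frac, lowq_frac = syn$lowq_frac,
    mito_frac = syn$mito_frac, genome_frac = syn$genome_frac,
    abund_sdlog = syn$abund_sdlog, min_expected = syn$min_expected,
    seed = config$seed))
  txome <- run_stage("simulate", generate_transcriptome(
    n_genes = syn$n_genes, length_range = syn$length_range,
    catg_sites_range = syn$catg_sites_range,
    shared_tag_fraction = syn$shared_tag_fraction, seed = config$seed))
  genomes <- run_stage("simulate", generate_genomes(
    mito_length = syn$mito_length, nuclear_length = syn$nuclear_length,
    seed = config$seed))
  libs <- run_stage("simulate", simulate_libraries(truth, txome, genomes))

  records <- transcript_records(names(txome$sequences), txome$sequences,
                                source = config$priority[1], priority = 1L)
  ref <- run_stage("build-reference", build_reference_library(records))
  write_reference_library(ref, out("reference_library.tsv"), meta)

  filt1 <- run_stage("filter", filter_raw_tags(
    libs$reads1, adaptor_seqs = config$adaptors,
    min_quality = thr$min_quality))
  filt2 <- run_stage("filter", filter_raw_tags(
    libs$reads2, adaptor_seqs = config$adaptors,
    min_quality = thr$min_quality))

  map1 <- run_stage("map", map_library(filt1$clean, ref,
                                       mito = genomes$mito,
                                       genome = genomes$nuclear,
                                       max_mismatch = thr$max_mismatch))
  map2 <- run_stage("map", map_library(filt2$clean, ref,
                                       mito = genomes$mito,
                                       genome = genomes$nuclear,
                                       max_mismatch = thr$max_mismatch))

  # Table-1-style census per library: ledger, copy-number bins, mapping
  census <- rbind(
    data.frame(library = "lib1", row = c("Raw Data", "Low Quality Tag",
                                         "Adaptors", "Tag CopyNum <2",
                                         "Clean Tags"),
               total_tags = c(filt1$ledger$n_raw, filt1$ledger$n_low_quality,
                              filt1$ledger$n_adaptor, filt1$ledger$n_singleton,
                              filt1$ledger$n_clean),
               stringsAsFactors = FALSE),
    data.frame(library = "lib2", row = c("Raw Data", "Low Quality Tag",
                                         "Adaptors", "Tag CopyNum <2",
                                         "Clean Tags"),
               total_tags = c(filt2$ledger$n_raw, filt2$ledger$n_low_quality,
                              filt2$ledger$n_adaptor, filt2$ledger$n_singleton,
                              filt2$ledger$n_clean),
               stringsAsFactors = FALSE))
  write_report(census, out("library_census.tsv"), meta)
  cn <- rbind(cbind(library = "lib1", copy_number_distribution(filt1$clean)),
              cbind(library = "lib2", copy_number_distribution(filt2$clean)))
  write_report(cn, out("copy_number.tsv"), meta)
  write_report(cbind(library = "lib1", map1$summary$pct),
               out("mapping_summary_lib1.tsv"), meta)
  write_report(cbind(library = "lib2", map2$summary$pct),
               out("mapping_summary_lib2.tsv"), meta)

  resolver <- stats::setNames(txome$metadata$gene_id,
                              txome$metadata$rank1_tag)
  sat1 <- run_stage("saturation", saturation_analysis(
    libs$reads1, step = max(1L, length(libs$reads1) %/% 20L),
    resolver = resolver, seed = config$seed))
  write_report(as.data.frame(sat1), out("saturation_lib1.tsv"), meta)

  pos1 <- tag_position_profile(map1$annotations)
  write_report(pos1$histogram, out("tag_positions_lib1.tsv"), meta)
  write_report(antisense_report(map1$annotations),
               out("antisense_lib1.tsv"), meta)

  a <- library_counts("lib1", map1$gene_counts, filt1$clean$total_clean)
  b <- library_counts("lib2", map2$gene_counts, filt2$clean$total_clean)
  de <- run_stage("de", call_de(a, b, p_max = thr$p_max,
                                fdr_max = thr$fdr_max,
                                lfc_min = thr$lfc_min,
                                zero_floor = thr$zero_floor))
  write_report(as.data.frame(de), out("de_table.tsv"), meta)

  sig <- de$gene_id[de$significant]
  background <- de$gene_id
  ann <- run_stage("enrich", generate_annotations(
    genes = truth$genes, n_terms = syn$n_terms,
    term_size_range = syn$term_size_range,
    enriched = if (length(sig)) list(genes = sig,
                                     odds_ratio = syn$enriched_odds_ratio)
               else NULL,
    seed = config$seed))
  keep <- ann$membership$gene_id %in% background
  enr <- run_stage("enrich", hypergeom_enrich(
    sig, background, ann$membership[keep, , drop = FALSE], ann$info,
    q_max = thr$q_max))
  write_report(enr, out("enrichment.tsv"), meta)

  qp <- NULL
  if (length(sig) >= 1L) {
    panel <- utils::head(sig, config$qpcr$n_validation_genes)
    ratios <- stats::setNames(de$tpm_a[match(panel, de$gene_id)] /
                                de$tpm_b[match(panel, de$gene_id)], panel)
    ct <- run_stage("qpcr", generate_ct_table(
      ratios, groups = c("lib1", "lib2"),
      n_animals = config$qpcr$n_animals, n_tech = config$qpcr$n_tech,
      reference = config$qpcr$reference, seed = config$seed))
    qp <- run_stage("qpcr", qpcr_panel(ct, panel,
                                       reference = config$qpcr$reference,
                                       group_a = "lib1", group_b = "lib2"))
    write_report(qp, out("qpcr_validation.tsv"), meta)
    write_report(concordance_table(qp, de), out("qpcr_concordance.tsv"),
                 meta)
  }

  log_lines <- c(
    paste0("config_hash: ", hash),
    paste0("seed: ", config$seed),
    paste0("package: tagdge ",
           as.character(utils::packageVersion("tagdge"))),
    paste0("R: ", R.version.string),
    paste0("thresholds: ", paste(names(thr), unlist(thr), sep = "=",
                                 collapse = " ")),
    paste0("n_significant: ", length(sig)))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(config = config, hash = hash, truth = truth,
                 transcriptome = txome, genomes = genomes,
                 reference = ref, filter1 = filt1, filter2 = filt2,
                 map1 = map1, map2 = map2, saturation1 = sat1,
                 de = de, enrichment = enr, qpcr = qp))
}
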