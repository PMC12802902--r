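# Orchestration: run the full workflow (simulate -> build database ->
# digest/classify -> filter -> PTM/readthrough/missing summaries ->
# expression integration) from one configuration, writing machine-readable
# TSVs and a human-readable summary. Every stage is a pure function of its
# inputs and the configuration; identical runs produce identical output
# trees.

#' Default pipeline configuration
#'
#' Combines the synthetic-data generator settings with the analysis tunables
#' (start-codon set, uORF length floor, junction window, coverage threshold,
#' correlation and enrichment settings). Configurations can be written
#' to / read from YAML for one-file provenance of a run.
#'
#' @param synthetic a [synthetic_config()].
#' @param start_codons permitted TIS/uORF start codons.
#' @param min_uorf_aa uORF length floor (aa).
#' @param window_nt junction window half-width (nt).
#' @param coverage_threshold fragment-ion coverage threshold.
#' @param min_joint_fraction joint-coverage rule for correlation.
#' @param p_cutoff,lfc_cutoff enrichment thresholds.
#' @param cpm_floor expression prefilter floor.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            start_codons = default_start_codons(),
                            min_uorf_aa = 6, window_nt = 96,
                            coverage_threshold = 0.5,
                            min_joint_fraction = 0.25,
                            p_cutoff = 0.01, lfc_cutoff = 1,
                            cpm_floor = 0.01) {
  structure(list(
    synthetic = synthetic, start_codons = start_codons,
    min_uorf_aa = min_uorf_aa, window_nt = window_nt,
    coverage_threshold = coverage_threshold,
    min_joint_fraction = min_joint_fraction,
    p_cutoff = p_cutoff, lfc_cutoff = lfc_cutoff, cpm_floor = cpm_floor
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return a `pipeline_config` (reader) or `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, raw$synthetic %||% list())
  raw$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), raw))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$synthetic <- unclass(out$synthetic)
  yaml::write_yaml(out, path)
  invisible(path)
}

write_tsv_with_header <- function(df, path, config) {
  hash <- substr(rlang_hash(config), 1, 12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# proteomapr %s seed=%d config=%s",
                     as.character(utils::packageVersion("proteomapr")),
                     config$synthetic$seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Small stable hash of the configuration (provenance stamp in output
# headers): sum-based rolling hash over the serialized fields.
rlang_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline on the synthetic bundle
#'
#' Simulates the input bundle, builds the custom database, classifies the
#' diagnostic peptides, filters PSMs by fragment-ion coverage, produces the
#' PTM landscape summaries, the readthrough plausibility table and the
#' missing-protein report, and integrates the expression matrices. All
#' tables are written under `outdir` together with `summary.txt`, which
#' includes a planted-event recovery line.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return list with every intermediate result, invisibly.
#' @export
run_all <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inputs_dir <- file.path(outdir, "inputs")
  syn <- config$synthetic

  log_info("stage simulate: generating synthetic bundle (seed ", syn$seed, ")")
  bundle <- simulate_bundle(syn, inputs_dir)
  truth <- bundle$truth

  log_info("stage build-db: building the custom protein database")
  entries <- build_custom_db(
    bundle$genome$transcripts, bundle$genome$novel_transcripts,
    start_codons = config$start_codons, min_uorf_aa = config$min_uorf_aa,
    window_nt = config$window_nt
  )
  write_database(entries, file.path(outdir, "database.fasta"))
  write_entry_manifest(entries, file.path(outdir, "database_manifest.tsv"))
  cat_counts <- table(entries$category)

  log_info("stage classify: classifying diagnostic peptides")
  diag_peptides <- c(
    tis = DIAG_TIS_PEPTIDE, uorf = DIAG_UORF_PEPTIDE,
    junction = DIAG_JUNCTION_PEPTIDE, readthrough = DIAG_READTHROUGH_PEPTIDE
  )
  classified <- classify_peptides(unname(diag_peptides), entries, entries)
  write_tsv_with_header(classified, file.path(outdir, "diagnostic_peptides.tsv"),
                        config)

  log_info("stage filter-psms: fragment-ion coverage filter")
  filt <- coverage_filter(bundle$psms, config$coverage_threshold)
  write_tsv_with_header(filt$kept, file.path(outdir, "psms_kept.tsv"), config)
  write_tsv_with_header(filt$rejected, file.path(outdir, "psms_rejected.tsv"),
                        config)

  log_info("stage ptm-summary: site frequencies and per-protein summaries")
  registry <- ptm_registry()
  kept <- classify_modifications(filt$kept, registry)
  sf <- site_frequency(kept, registry)
  pps <- protein_ptm_summary(kept, registry)
  write_tsv_with_header(sf$by_residue, file.path(outdir, "ptm_site_frequency.tsv"),
                        config)
  write_tsv_with_header(pps$summary, file.path(outdir, "protein_ptm_summary.tsv"),
                        config)

  log_info("stage readthrough-classify: single-substitution plausibility")
  rt <- readthrough_plausibility(kept)
  write_tsv_with_header(rt$kept, file.path(outdir, "readthrough_kept.tsv"),
                        config)

  log_info("stage missing-report: missing-protein evidence")
  missing <- missing_protein_report(kept, bundle$pe_levels, entries)
  write_tsv_with_header(missing, file.path(outdir, "missing_proteins.tsv"),
                        config)

  log_info("stage correlate: mRNA-protein integration")
  prot_avg <- average_replicates(bundle$protein)
  gene_cor <- correlate_genes(bundle$mrna, prot_avg,
                              min_joint_fraction = config$min_joint_fraction)
  sample_cor <- correlate_samples(bundle$mrna, prot_avg)
  write_tsv_with_header(gene_cor$results, file.path(outdir, "gene_correlation.tsv"),
                        config)
  write_tsv_with_header(sample_cor, file.path(outdir, "sample_correlation.tsv"),
                        config)

  log_info("stage call-enriched: cell-type enrichment")
  enrich <- call_enriched(bundle$mrna, bundle$groups,
                          cpm_floor = config$cpm_floor,
                          p_cutoff = config$p_cutoff,
                          lfc_cutoff = config$lfc_cutoff)
  write_tsv_with_header(enrich[enrich$enriched, , drop = FALSE],
                        file.path(outdir, "enriched_genes.tsv"), config)

  recovery <- recovery_report(entries, truth, min_uorf_aa = config$min_uorf_aa)
  summary_lines <- c(
    sprintf("proteomapr run (seed %d)", syn$seed),
    "",
    "database entries per category:",
    sprintf("  %-16s %d", names(cat_counts), as.integer(cat_counts)),
    "",
    sprintf("planted-event recovery: %.1f%% (%d/%d events)",
            100 * recovery$fraction, recovery$n_recovered, recovery$n_planted),
    "",
    sprintf("diagnostic peptides: %s",
            paste(sprintf("%s=%s", classified$peptide, classified$category),
                  collapse = ", ")),
    "",
    sprintf("PSMs kept by coverage filter: %d / %d", nrow(filt$kept),
            nrow(bundle$psms)),
    sprintf("distinct modified sites: %d (biological %d, post-isolation %d)",
            nrow(sf$sites), sf$class_totals[["biological"]],
            sf$class_totals[["post_isolation"]]),
    sprintf("proteins with biological PTMs: %d", nrow(pps$summary)),
    sprintf("readthrough events kept (single substitution): %d / %d",
            nrow(rt$kept), nrow(rt$kept) + nrow(rt$rejected)),
    sprintf("missing proteins reported: %d", nrow(missing)),
    "",
    sprintf("gene-level correlation: mean %.3f over %d genes (%.0f%% positive)",
            gene_cor$summary$mean_coefficient, gene_cor$summary$n_included,
            100 * gene_cor$summary$fraction_positive),
    sprintf("sample-level correlation: mean %.3f",
            mean(sample_cor$coefficient, na.rm = TRUE)),
    sprintf("enriched gene calls: %d", sum(enrich$enriched))
  )
  writeLines(summary_lines, file.path(outdir, "summary.txt"))

  invisible(list(
    bundle = bundle, entries = entries, classified = classified,
    filtered = filt, site_frequency = sf, protein_summary = pps,
    readthrough = rt, missing = missing, gene_correlation = gene_cor,
    sample_correlation = sample_cor, enrichment = enrich,
    recovery = recovery
  ))
}

#' Compare built database entries against the planted-event ledger
#'
#' Checks that every planted TIS extension, uORF at or above the length
#' floor, readthrough tract (all 20 variants) and novel junction is present
#' with the expected sequence, and that no unplanned entries exist beyond
#' the combinatorially implied ones (uORF entries arising from in-frame
#' planted TIS codons).
#'
#' @param entries built database entries.
#' @param truth generator ledger.
#' @param min_uorf_aa uORF length floor used at build time.
#' @return list with `n_planted`, `n_recovered`, `fraction`, `exact`
#'   (logical: no missing and no spurious entries) and per-category detail.
#' @export
recovery_report <- function(entries, truth, min_uorf_aa = 6) {
  detail <- list()
  ok_pair <- function(found, expected) {
    list(n_planted = nrow(expected), n_recovered = sum(
      paste(expected$transcript_id, expected$sequence) %in%
        paste(found$transcript_id, found$sequence)),
      n_extra = sum(!paste(found$transcript_id, found$sequence) %in%
                      paste(expected$transcript_id, expected$sequence)))
  }
  empty <- data.frame(transcript_id = character(), sequence = character())

  tis_found <- entries[entries$category == "nterm_extension",
                       c("transcript_id", "sequence")]
  detail$tis <- ok_pair(tis_found, truth$tis %||% empty)

  uorf_exp <- truth$uorfs
  if (!is.null(uorf_exp)) {
    uorf_exp <- uorf_exp[!uorf_exp$below_min &
                           uorf_exp$length_aa >= min_uorf_aa, , drop = FALSE]
  }
  uorf_exp <- rbind(
    if (is.null(uorf_exp)) empty else uorf_exp[, c("transcript_id", "sequence")],
    if (is.null(truth$implied_uorfs)) empty else
      truth$implied_uorfs[, c("transcript_id", "sequence")]
  )
  uorf_found <- entries[entries$category == "uorf",
                        c("transcript_id", "sequence")]
  detail$uorf <- ok_pair(uorf_found, uorf_exp)

  rt_found <- entries[entries$category == "readthrough", , drop = FALSE]
  rt_exp <- truth$readthrough %||% empty
  n_rt_exp <- if (nrow(rt_exp)) nrow(rt_exp) * 20L else 0L
  rt_ok <- 0L
  if (nrow(rt_exp)) {
    canon <- entries[entries$category == "canonical", ]
    prot_of <- setNames(canon$sequence, canon$transcript_id)
    for (r in seq_len(nrow(rt_exp))) {
      tid <- rt_exp$transcript_id[r]
      sub <- rt_found[rt_found$transcript_id == tid, , drop = FALSE]
      expect_seqs <- paste0(prot_of[[tid]], AA20, rt_exp$extension[r])
      rt_ok <- rt_ok + sum(expect_seqs %in% sub$sequence)
    }
  }
  detail$readthrough <- list(n_planted = n_rt_exp, n_recovered = rt_ok,
                             n_extra = nrow(rt_found) - rt_ok)

  junc_found <- entries[entries$category == "junction", , drop = FALSE]
  junc_exp <- truth$junctions
  n_j_exp <- if (is.null(junc_exp)) 0L else nrow(junc_exp)
  j_ok <- 0L
  if (n_j_exp > 0) {
    for (r in seq_len(n_j_exp)) {
      sub <- junc_found[junc_found$transcript_id ==
                          junc_exp$novel_transcript_id[r], , drop = FALSE]
      j_ok <- j_ok + as.integer(nrow(sub) == 1 &&
                                  grepl(junc_exp$insert_peptide[r],
                                        sub$sequence, fixed = TRUE))
    }
  }
  detail$junction <- list(n_planted = n_j_exp, n_recovered = j_ok,
                          n_extra = nrow(junc_found) - j_ok)

  n_planted <- sum(vapply(detail, `[[`, numeric(1), "n_planted"))
  n_recovered <- sum(vapply(detail, `[[`, numeric(1), "n_recovered"))
  n_extra <- sum(vapply(detail, `[[`, numeric(1), "n_extra"))
  list(n_planted = n_planted, n_recovered = n_recovered,
       fraction = if (n_planted == 0) 1 else n_recovered / n_planted,
       exact = n_recovered == n_planted && n_extra == 0, detail = detail)
}
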