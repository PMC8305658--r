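# End-to-end orchestration: ingest -> prefilter -> score -> triage ->
# segregate -> report, with structured stage-count logging.

#' Run the full prioritization and co-segregation pipeline
#'
#' Reads a pedigree, a VCF and the five-predictor annotation table, keeps
#' consequence classes of interest, computes ensemble scores, triages
#' candidates, evaluates per-family co-segregation for every triaged variant
#' carried in a family, and writes the report files. Stage counts (variants
#' in, after prefilter, after triage, candidate families/genes) are logged
#' as one JSON line per stage and are non-increasing through the filtering
#' stages.
#'
#' @param ped_path Extended PED file (see [read_pedigree()]).
#' @param vcf_path VCF with germline genotypes.
#' @param annotation_path Annotation TSV (see [read_annotation_table()]).
#' @param out_dir Output directory for report files (created).
#' @param config A [triage_config()].
#' @param phenotype A [phenotype_spec()] used for the candidate verdicts.
#' @param rule A [penetrance_rule()].
#' @param validation_counts_path Optional validation-counts TSV (see
#'   [validation_cohorts_from_counts()]) for prevalence reporting.
#' @param curation_path Optional curated-labels TSV (gene, hgvs_c, hgvs_p,
#'   mutation_type, significance, maf_label).
#' @param keep_promoter Passed to [prefilter_nonsynonymous()].
#' @return List of class `fpc_pipeline_result` with elements `cohort`,
#'   `genotypes`, `annotation`, `scored`, `triaged`, `segregation` (data
#'   frame over family x triaged carried variant), `candidates` (per-family
#'   passing summaries from [count_cosegregating_candidates()]),
#'   `candidate_families`, `candidate_genes`, `prevalence`, `summary_table`,
#'   `stage_counts`, `paths`.
#' @export
run_pipeline <- function(ped_path, vcf_path, annotation_path, out_dir,
                         config = triage_config(),
                         phenotype = phenotype_spec(),
                         rule = penetrance_rule(),
                         validation_counts_path = NULL,
                         curation_path = NULL,
                         keep_promoter = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "stage_counts.json")
  log_lines <- character(0)
  log_stage <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    log_lines <<- c(log_lines,
                    jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
  }

  cohort <- read_pedigree(ped_path)
  log_stage("pedigree", families = length(cohort$families),
            individuals = nrow(cohort_members(cohort)))
  gset <- read_vcf_genotypes(vcf_path, cohort)
  annot <- read_annotation_table(annotation_path)
  miss <- setdiff(gset$variants$variant_id, annot$variant_id)
  if (length(miss) > 0) {
    warn_fpc("%d VCF variant(s) missing from the annotation table are dropped",
             length(miss))
  }
  annot <- annot[annot$variant_id %in% gset$variants$variant_id, ,
                 drop = FALSE]
  log_stage("variants_in", n = nrow(annot))

  kept <- prefilter_nonsynonymous(annot, keep_promoter = keep_promoter)
  log_stage("after_prefilter", n = nrow(kept))

  scored <- total_score(kept, config)
  carriers <- carrier_families(gset, cohort)
  triaged <- triage(scored, carriers, config)
  log_stage("after_triage", n = nrow(triaged))

  seg_rows <- list()
  candidates <- list()
  for (fid in names(cohort$families)) {
    fam <- cohort$families[[fid]]
    cc <- count_cosegregating_candidates(fam, gset, triaged, phenotype, rule)
    candidates[[fid]] <- cc
    if (nrow(cc$results) == 0) next
    for (i in seq_len(nrow(cc$results))) {
      v <- cc$results$variant_id[i]
      ids <- fam$members$individual_id
      g <- gset$genotypes[v, ids]
      names(g) <- ids
      res <- evaluate_segregation(fam, g, phenotype, rule)
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        family_id = fid,
        gene = cc$results$gene[i],
        variant = v,
        phenotype = phenotype$name,
        verdict = res$verdict,
        affected_carriers = res$affected_carriers,
        affected_genotyped = res$affected_genotyped,
        affected_noncarriers = res$affected_noncarriers,
        unaffected_carriers = res$unaffected_carriers,
        exemption_ages = paste(
          ifelse(is.na(res$exemptions$age_years), ".",
                 res$exemptions$age_years), collapse = ";"),
        notes = paste(res$notes, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  segregation <- if (length(seg_rows) == 0) {
    data.frame(family_id = character(0), gene = character(0),
               variant = character(0), phenotype = character(0),
               verdict = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, seg_rows)
  }
  segregation <- segregation[order(segregation$family_id, segregation$gene,
                                   segregation$variant, method = "radix"), ,
                             drop = FALSE]
  rownames(segregation) <- NULL

  n_passing <- vapply(candidates, `[[`, integer(1), "n_passing")
  candidate_families <- names(candidates)[n_passing > 0]
  candidate_genes <- sort(unique(unlist(lapply(candidates, `[[`, "genes"))))
  log_stage("candidates", families = length(candidate_families),
            genes = length(candidate_genes))

  prevalence <- list()
  if (!is.null(validation_counts_path)) {
    counts <- utils::read.delim(validation_counts_path,
                                stringsAsFactors = FALSE,
                                colClasses = "character")
    counts$families_tested <- as.integer(counts$families_tested)
    merged <- validation_cohorts_from_counts(counts)
    prevalence <- lapply(merged, family_prevalence)
  }
  curation <- if (!is.null(curation_path)) {
    utils::read.delim(curation_path, stringsAsFactors = FALSE)
  } else NULL

  passing <- segregation[segregation$verdict %in%
                           c("complete", "incomplete_penetrance"), ,
                         drop = FALSE]
  cand_tab <- if (nrow(passing) == 0) {
    data.frame(gene = character(0), variant_id = character(0),
               family_ids = character(0), family_type = character(0),
               segregates = logical(0), af_band = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(passing, paste(passing$gene,
                                               passing$variant)),
      function(sub) {
        fams <- sort(unique(sub$family_id))
        data.frame(
          gene = sub$gene[1],
          variant_id = sub$variant[1],
          family_ids = paste(fams, collapse = ";"),
          family_type = paste(unique(vapply(fams, function(f)
            cohort$families[[f]]$family_type, character(1))), collapse = ";"),
          segregates = TRUE,
          af_band = annot$af_band[match(sub$variant[1], annot$variant_id)],
          stringsAsFactors = FALSE)
      }))
  }
  summary_table <- build_summary_table(cand_tab, prevalence, curation)

  paths <- list(
    scored = file.path(out_dir, "scored_variants.tsv"),
    triaged = file.path(out_dir, "triaged_variants.tsv"),
    segregation = file.path(out_dir, "segregation_report.tsv"),
    summary = file.path(out_dir, "summary_table.tsv"),
    stage_counts = log_path
  )
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  scored_out <- scored[order(scored$chrom, scored$pos, scored$ref,
                             scored$alt, method = "radix"), , drop = FALSE]
  write_tsv(scored_out, paths$scored)
  write_tsv(triaged, paths$triaged)
  write_tsv(segregation, paths$segregation)
  write_tsv(summary_table, paths$summary)
  writeLines(log_lines, log_path)
  if (length(prevalence) > 0) {
    paths$prevalence <- file.path(out_dir, "prevalence.json")
    write_prevalence_json(prevalence, paths$prevalence)
  }

  structure(list(cohort = cohort, genotypes = gset, annotation = annot,
                 scored = scored, triaged = triaged,
                 segregation = segregation, candidates = candidates,
                 candidate_families = candidate_families,
                 candidate_genes = candidate_genes,
                 prevalence = prevalence, summary_table = summary_table,
                 stage_counts = list(
                   variants_in = nrow(annot),
                   after_prefilter = nrow(kept),
                   after_triage = nrow(triaged),
                   candidate_families = length(candidate_families),
                   candidate_genes = length(candidate_genes)),
                 paths = paths),
            class = "fpc_pipeline_result")
}

#' @export
print.fpc_pipeline_result <- function(x, ...) {
  sc <- x$stage_counts
  cat(sprintf(paste0(
    "<fpc_pipeline_result>\n",
    "  families: %d\n",
    "  variants in / after prefilter / after triage: %d / %d / %d\n",
    "  candidate families: %d (%s)\n",
    "  candidate genes: %d (%s)\n"),
    length(x$cohort$families), sc$variants_in, sc$after_prefilter,
    sc$after_triage, sc$candidate_families,
    paste(x$candidate_families, collapse = ", "),
    sc$candidate_genes, paste(x$candidate_genes, collapse = ", ")))
  invisible(x)
}
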