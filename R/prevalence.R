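# Cross-cohort carrier-family counting and prevalence reporting.

#' Validation cohort for one gene variant
#'
#' Records how many families were tested for a variant and which of them
#' carried it.
#'
#' @param gene Gene symbol.
#' @param variant Variant key string (see [variant_key()]), or `NA`.
#' @param families_tested Positive integer.
#' @param carrier_families Character vector of carrier family ids (must not
#'   exceed `families_tested`).
#' @return List of class `validation_cohort`.
#' @export
validation_cohort <- function(gene, variant = NA_character_, families_tested,
                              carrier_families = character(0)) {
  families_tested <- as.integer(families_tested)
  carrier_families <- unique(as.character(carrier_families))
  if (families_tested < 1) stop_fpc("families_tested must be positive")
  if (length(carrier_families) > families_tested) {
    stop_fpc("more carrier families than families tested for %s", gene)
  }
  structure(list(gene = as.character(gene), variant = variant,
                 families_tested = families_tested,
                 carrier_families = carrier_families),
            class = "validation_cohort")
}

#' Carrier-family prevalence
#'
#' Percentage of tested families carrying the variant, rounded to one decimal
#' (round-half-even, R's default).
#'
#' @param cohort A [validation_cohort()].
#' @return List of class `prevalence_record`: `gene`, `variant`, `numerator`,
#'   `denominator`, `percent`.
#' @export
family_prevalence <- function(cohort) {
  if (cohort$families_tested == 0) stop_fpc("denominator is zero")
  num <- length(cohort$carrier_families)
  den <- cohort$families_tested
  structure(list(gene = cohort$gene, variant = cohort$variant,
                 numerator = num, denominator = den,
                 percent = round(100 * num / den, 1)),
            class = "prevalence_record")
}

#' Display label for a prevalence percentage
#'
#' One decimal with a trailing `.0` suppressed, matching the reporting style
#' `8.7%` / `2%`.
#'
#' @param percent Numeric percentage.
#' @return Character label.
#' @export
percent_label <- function(percent) {
  x <- round(percent, 1)
  ifelse(x == round(x), sprintf("%d%%", as.integer(round(x))),
         sprintf("%.1f%%", x))
}

#' Merge validation cohorts
#'
#' Sums the tested-family counts and unions the carrier sets of an initial
#' cohort and its extensions (e.g. additional Sanger-sequenced families).
#' Extensions must test disjoint families: an overlap between carrier sets
#' is an error.
#'
#' @param initial A [validation_cohort()].
#' @param extensions List of further `validation_cohort`s for the same gene.
#' @return A merged [validation_cohort()].
#' @export
merge_cohorts <- function(initial, extensions = list()) {
  if (inherits(extensions, "validation_cohort")) extensions <- list(extensions)
  out <- initial
  for (ext in extensions) {
    overlap <- intersect(out$carrier_families, ext$carrier_families)
    if (length(overlap) > 0) {
      stop_fpc("overlapping family id(s) between cohorts: %s",
               paste(overlap, collapse = ", "))
    }
    out <- validation_cohort(
      gene = out$gene,
      variant = out$variant,
      families_tested = out$families_tested + ext$families_tested,
      carrier_families = c(out$carrier_families, ext$carrier_families))
  }
  out
}

#' Build the summary table of findings
#'
#' One row per (gene, variant): family ids and type, HGVS strings, mutation
#' type, curated significance label (pass-through input, never computed),
#' segregation yes/no, carrier-family fraction, population AF and band.
#' Column order is fixed and the table serializes to TSV.
#'
#' @param candidates Data frame with one row per passing (gene, variant) and
#'   columns `gene`, `variant_id`, `family_ids` (semicolon-joined),
#'   `family_type`, `segregates` (logical).
#' @param prevalence Named list of [family_prevalence()] records keyed by
#'   gene (optional; genes without a record get `NA` fractions).
#' @param curation Optional data frame with columns `gene`, `hgvs_c`,
#'   `hgvs_p`, `mutation_type`, `significance`, `maf_label` carrying the
#'   curated labels.
#' @return Data frame with columns `gene, family_ids, family_type, variant,
#'   hgvs_c, hgvs_p, mutation_type, significance, segregation,
#'   families_with_variant, maf, af_band`.
#' @export
build_summary_table <- function(candidates, prevalence = list(),
                                curation = NULL) {
  cols <- c("gene", "family_ids", "family_type", "variant", "hgvs_c",
            "hgvs_p", "mutation_type", "significance", "segregation",
            "families_with_variant", "maf", "af_band")
  if (nrow(candidates) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), character(0), simplify = FALSE), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    gene <- candidates$gene[i]
    cur <- if (!is.null(curation) && gene %in% curation$gene) {
      curation[match(gene, curation$gene), ]
    } else NULL
    prev <- prevalence[[gene]]
    data.frame(
      gene = gene,
      family_ids = candidates$family_ids[i],
      family_type = candidates$family_type[i],
      variant = candidates$variant_id[i],
      hgvs_c = if (!is.null(cur)) cur$hgvs_c else NA_character_,
      hgvs_p = if (!is.null(cur)) cur$hgvs_p else NA_character_,
      mutation_type = if (!is.null(cur)) cur$mutation_type else NA_character_,
      significance = if (!is.null(cur)) cur$significance else NA_character_,
      segregation = ifelse(isTRUE(candidates$segregates[i]), "yes", "no"),
      families_with_variant = if (!is.null(prev)) {
        sprintf("%d/%d", prev$numerator, prev$denominator)
      } else NA_character_,
      maf = if (!is.null(cur)) cur$maf_label else NA_character_,
      af_band = if ("af_band" %in% names(candidates)) {
        candidates$af_band[i]
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$variant, method = "radix"), cols,
             drop = FALSE]
  out <- out[!duplicated(paste(out$gene, out$variant)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export prevalence records as JSON
#'
#' @param records List of [family_prevalence()] records.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_prevalence_json <- function(records, path) {
  payload <- lapply(records, function(r) {
    list(gene = r$gene, variant = r$variant, numerator = r$numerator,
         denominator = r$denominator, percent = r$percent,
         label = percent_label(r$percent))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
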