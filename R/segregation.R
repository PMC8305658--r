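# Per-family co-segregation verdicts with the complete/incomplete-penetrance
# distinction, phenotype-specific evaluation, and Mendelian-consistency QC.

#' Phenotype specification for segregation
#'
#' Defines which phenotype tokens count as "affected" when a variant is
#' evaluated. The default is pancreatic disease: PDAC or its high-grade
#' precursor lesions (PanIN2/3).
#'
#' @param name Label for the specification.
#' @param targets Non-empty subset of [phenotype_tokens()].
#' @return List of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name = "pancreatic_disease",
                           targets = c("PDAC", "precursor_high_grade")) {
  targets <- unique(as.character(targets))
  if (length(targets) == 0) stop_fpc("phenotype_spec needs >= 1 target")
  check_phenotypes(targets, where = name)
  structure(list(name = as.character(name), targets = targets),
            class = "phenotype_spec")
}

#' Penetrance rule for segregation verdicts
#'
#' By default, unaffected carriers never fail a variant (incomplete
#' penetrance); they are listed as exemptions with their ages, annotated
#' `elderly_carrier` at or above the exemption age threshold and
#' `young_carrier` below it. `max_affected_noncarriers` controls how many
#' affected non-carriers (phenocopies) are tolerated before the variant
#' fails.
#'
#' @param allow_unaffected_carriers Logical (default TRUE).
#' @param exemption_age_threshold Years (default 65, the median FPC onset
#'   age); only annotates exemptions, never changes the verdict.
#' @param max_affected_noncarriers Integer (default 0).
#' @return List of class `penetrance_rule`.
#' @export
penetrance_rule <- function(allow_unaffected_carriers = TRUE,
                            exemption_age_threshold = 65,
                            max_affected_noncarriers = 0) {
  stopifnot(exemption_age_threshold >= 0, max_affected_noncarriers >= 0)
  structure(list(allow_unaffected_carriers = isTRUE(allow_unaffected_carriers),
                 exemption_age_threshold = as.numeric(exemption_age_threshold),
                 max_affected_noncarriers = as.integer(max_affected_noncarriers)),
            class = "penetrance_rule")
}

#' Evaluate co-segregation of a variant in one family
#'
#' Counts only individuals with a non-missing germline genotype. The variant
#' fails when more than `max_affected_noncarriers` genotyped target-phenotype
#' individuals are hom_ref (or when no genotyped affected exist, note
#' `no_informative_affected`). Otherwise the verdict is `complete` when no
#' genotyped unaffected member carries the variant, and
#' `incomplete_penetrance` when unaffected carriers exist and the rule allows
#' them (each listed as an exemption with age annotation). Members whose only
#' phenotypes fall outside the target set count as unaffected for this
#' evaluation but keep their phenotypes for cross-phenotype analyses.
#'
#' @param family An [fpc_family()].
#' @param genotypes Named character vector (`hom_ref`/`het`/`hom_alt`/`NA`)
#'   keyed by individual id; a key absent from the family is an error.
#' @param phenotype A [phenotype_spec()].
#' @param rule A [penetrance_rule()].
#' @return List of class `segregation_result` with fields `family_id`,
#'   `phenotype`, `verdict`, `affected_carriers`, `affected_genotyped`,
#'   `affected_noncarriers`, `unaffected_carriers`,
#'   `exempted_unaffected_carriers`, `exemptions` (data frame
#'   `individual_id, age_years, tag`), `notes`.
#' @export
evaluate_segregation <- function(family, genotypes,
                                 phenotype = phenotype_spec(),
                                 rule = penetrance_rule()) {
  m <- family$members
  unknown <- setdiff(names(genotypes), m$individual_id)
  if (length(unknown) > 0) {
    stop_fpc("genotype(s) for unknown individual(s) in family %s: %s",
             family$family_id, paste(unknown, collapse = ", "))
  }
  gt <- genotypes[m$individual_id]
  names(gt) <- m$individual_id
  counted <- !is.na(gt)
  is_target <- vapply(m$phenotypes, function(p)
    has_any_phenotype(p, phenotype$targets), logical(1))
  carrier <- counted & (gt == "het" | gt == "hom_alt")
  affected <- counted & is_target
  unaffected <- counted & !is_target
  notes <- character(0)

  aff_gt <- sum(affected)
  aff_car <- sum(affected & carrier)
  aff_non <- sum(affected & !carrier)
  unaff_car <- sum(unaffected & carrier)
  if (sum(carrier) == 0 && aff_gt > 0) notes <- c(notes, "no_carriers")

  exemptions <- data.frame(individual_id = character(0),
                           age_years = numeric(0), tag = character(0),
                           stringsAsFactors = FALSE)
  if (aff_gt == 0) {
    verdict <- "fails"
    notes <- c(notes, "no_informative_affected")
  } else if (aff_non > rule$max_affected_noncarriers) {
    verdict <- "fails"
  } else if (unaff_car == 0) {
    verdict <- "complete"
  } else if (rule$allow_unaffected_carriers) {
    verdict <- "incomplete_penetrance"
    idx <- which(unaffected & carrier)
    idx <- idx[order(m$individual_id[idx])] # invariant to member row order
    exemptions <- data.frame(
      individual_id = m$individual_id[idx],
      age_years = m$age_years[idx],
      tag = ifelse(is.na(m$age_years[idx]), "unknown_age",
                   ifelse(m$age_years[idx] >= rule$exemption_age_threshold,
                          "elderly_carrier", "young_carrier")),
      stringsAsFactors = FALSE
    )
  } else {
    verdict <- "fails"
    notes <- c(notes, "unaffected_carriers_disallowed")
  }
  structure(list(
    family_id = family$family_id,
    phenotype = phenotype$name,
    verdict = verdict,
    affected_carriers = aff_car,
    affected_genotyped = aff_gt,
    affected_noncarriers = aff_non,
    unaffected_carriers = unaff_car,
    exempted_unaffected_carriers = nrow(exemptions),
    exemptions = exemptions,
    notes = notes
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> family %s, %s: %s (%d/%d affected carry; %d unaffected carriers%s)\n",
    x$family_id, x$phenotype, x$verdict, x$affected_carriers,
    x$affected_genotyped, x$unaffected_carriers,
    if (length(x$notes) > 0) paste0("; ", paste(x$notes, collapse = ",")) else ""))
  invisible(x)
}

#' Evaluate a variant against several phenotype definitions
#'
#' A variant may fail one phenotype and pass another (e.g. a variant tracking
#' breast cancer rather than pancreatic disease in the same family).
#'
#' @param family An [fpc_family()].
#' @param genotypes Named genotype vector as in [evaluate_segregation()].
#' @param phenotypes List of [phenotype_spec()] with distinct names.
#' @param rule A [penetrance_rule()].
#' @return Named list of `segregation_result`, keyed by phenotype name.
#' @export
evaluate_cross_phenotype <- function(family, genotypes, phenotypes,
                                     rule = penetrance_rule()) {
  nms <- vapply(phenotypes, function(p) p$name, character(1))
  if (anyDuplicated(nms)) stop_fpc("phenotype specs must be disjointly named")
  stats::setNames(
    lapply(phenotypes, function(p)
      evaluate_segregation(family, genotypes, p, rule)),
    nms)
}

#' Mendelian-consistency check
#'
#' Flags genotype configurations impossible under Mendelian transmission:
#' a child carrying the alternate allele while both parents are genotyped
#' hom_ref, and a hom_alt child with a genotyped hom_ref parent (who cannot
#' transmit the alternate allele). A child with an ungenotyped parent is
#' never flagged (transmission cannot be excluded).
#'
#' @param family An [fpc_family()].
#' @param genotypes Named genotype vector as in [evaluate_segregation()].
#' @return Data frame `individual_id, violation` (zero rows when consistent).
#' @export
mendelian_consistency <- function(family, genotypes) {
  m <- family$members
  gt <- genotypes[m$individual_id]
  names(gt) <- m$individual_id
  out <- list()
  for (i in seq_len(nrow(m))) {
    g <- gt[[i]]
    if (is.na(g) || g == "hom_ref") next
    fa <- m$father_id[i]; mo <- m$mother_id[i]
    g_fa <- if (!is.na(fa)) gt[[fa]] else NA_character_
    g_mo <- if (!is.na(mo)) gt[[mo]] else NA_character_
    both_ref <- !is.na(g_fa) && !is.na(g_mo) &&
      g_fa == "hom_ref" && g_mo == "hom_ref"
    if (both_ref) {
      out[[length(out) + 1L]] <- data.frame(
        individual_id = m$individual_id[i],
        violation = "alt_allele_with_both_parents_hom_ref",
        stringsAsFactors = FALSE)
      next
    }
    if (g == "hom_alt" &&
        ((!is.na(g_fa) && g_fa == "hom_ref") ||
         (!is.na(g_mo) && g_mo == "hom_ref"))) {
      out[[length(out) + 1L]] <- data.frame(
        individual_id = m$individual_id[i],
        violation = "hom_alt_with_hom_ref_parent",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(individual_id = character(0), violation = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count co-segregating triaged candidates in a family
#'
#' Evaluates every triaged variant carried by at least one genotyped member
#' of the family and counts those whose verdict is `complete` or
#' `incomplete_penetrance`.
#'
#' @param family An [fpc_family()].
#' @param gset An `fpc_genotypes` object covering the family's members.
#' @param triaged Data frame from [triage()] (needs `variant_id` and `gene`).
#' @param phenotype A [phenotype_spec()].
#' @param rule A [penetrance_rule()].
#' @return List with `n_passing` (integer), `genes` (sorted unique symbols of
#'   passing variants) and `results` (data frame `variant_id, gene, verdict`).
#' @export
count_cosegregating_candidates <- function(family, gset, triaged,
                                           phenotype = phenotype_spec(),
                                           rule = penetrance_rule()) {
  fam_ids <- intersect(family$members$individual_id, colnames(gset$genotypes))
  rows <- list()
  for (v in triaged$variant_id) {
    if (!(v %in% rownames(gset$genotypes))) next
    g <- gset$genotypes[v, fam_ids]
    names(g) <- fam_ids
    if (!any(g %in% c("het", "hom_alt"))) next # variant absent from family
    res <- evaluate_segregation(family, g, phenotype, rule)
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = v,
      gene = triaged$gene[match(v, triaged$variant_id)],
      verdict = res$verdict,
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows) == 0) {
    data.frame(variant_id = character(0), gene = character(0),
               verdict = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  passing <- results$verdict %in% c("complete", "incomplete_penetrance")
  list(n_passing = sum(passing),
       genes = sort(unique(results$gene[passing])),
       results = results)
}
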