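# Ensemble "total score" over five in-silico predictors and the three-tier
# candidate triage (high score; risk gene with sub-threshold CADD; recurrence
# across families).

PREDICTORS <- c("sift", "polyphen2", "mutation_taster", "provean", "cadd")

#' Bundled FPC risk-gene list
#'
#' Reads the editable risk-gene list shipped with the package (one symbol per
#' line, `#` comments allowed).
#'
#' @param path Optional path to an alternative list file.
#' @return Character vector of gene symbols.
#' @export
default_risk_genes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fpc_risk_genes.txt",
                                package = "fpcseg")
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Triage configuration
#'
#' @param high_score_threshold Damaging votes needed for the high-score tier
#'   (default 4 of 5 — strict majority-plus; the study does not print its
#'   numeric cutoff).
#' @param risk_genes Gene symbols for the risk-gene tier.
#' @param recurrence_min_families Minimum carrier families for the recurrence
#'   tier.
#' @param cadd_high_cutoff CADD phred treated as a damaging vote; the
#'   risk-gene tier captures risk-gene variants *below* this cutoff.
#' @param polyphen_possibly_counts Should PolyPhen-2 "possibly_damaging"
#'   count as damaging (default TRUE, the D/P convention)?
#' @param min_informative Minimum informative predictors for the unanimity
#'   rule: a variant assessable by fewer than `high_score_threshold`
#'   predictors (e.g. promoter or splice-site variants, outside the scope of
#'   the protein-substitution tools) still reaches the high-score tier when
#'   all of its informative predictors vote damaging and at least
#'   `min_informative` are informative.
#' @return List of class `triage_config`.
#' @export
triage_config <- function(high_score_threshold = 4,
                          risk_genes = default_risk_genes(),
                          recurrence_min_families = 2,
                          cadd_high_cutoff = 20,
                          polyphen_possibly_counts = TRUE,
                          min_informative = 2) {
  stopifnot(high_score_threshold >= 0, recurrence_min_families >= 1,
            cadd_high_cutoff > 0, min_informative >= 1)
  structure(list(high_score_threshold = as.integer(high_score_threshold),
                 risk_genes = as.character(risk_genes),
                 recurrence_min_families = as.integer(recurrence_min_families),
                 cadd_high_cutoff = as.numeric(cadd_high_cutoff),
                 polyphen_possibly_counts = isTRUE(polyphen_possibly_counts),
                 min_informative = as.integer(min_informative)),
            class = "triage_config")
}

#' Read triage and penetrance settings from a YAML file
#'
#' Recognized keys: `high_score_threshold`, `cadd_high_cutoff`,
#' `recurrence_min_families`, `polyphen_possibly_counts`, `min_informative`,
#' `risk_genes` (inline list or a `risk_genes_file` path), and a `penetrance`
#' block with `allow_unaffected_carriers`, `exemption_age_threshold`,
#' `max_affected_noncarriers`.
#'
#' @param path YAML file.
#' @return List with elements `triage` ([triage_config()]) and `rule`
#'   ([penetrance_rule()]).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  risk <- if (!is.null(cfg$risk_genes_file)) {
    default_risk_genes(cfg$risk_genes_file)
  } else if (!is.null(cfg$risk_genes)) {
    as.character(unlist(cfg$risk_genes))
  } else {
    default_risk_genes()
  }
  triage <- triage_config(
    high_score_threshold = cfg$high_score_threshold %||% 4,
    risk_genes = risk,
    recurrence_min_families = cfg$recurrence_min_families %||% 2,
    cadd_high_cutoff = cfg$cadd_high_cutoff %||% 20,
    polyphen_possibly_counts = cfg$polyphen_possibly_counts %||% TRUE,
    min_informative = cfg$min_informative %||% 2
  )
  pen <- cfg$penetrance %||% list()
  rule <- penetrance_rule(
    allow_unaffected_carriers = pen$allow_unaffected_carriers %||% TRUE,
    exemption_age_threshold = pen$exemption_age_threshold %||% 65,
    max_affected_noncarriers = pen$max_affected_noncarriers %||% 0
  )
  list(triage = triage, rule = rule)
}

#' Per-predictor damaging vote
#'
#' Maps one predictor's call to `damaging` / `benign` / `missing`:
#' SIFT deleterious, PolyPhen-2 probably (and by default possibly) damaging,
#' either MutationTaster disease-causing class, PROVEAN deleterious, and CADD
#' phred at or above `cadd_high_cutoff` vote damaging.
#'
#' @param calls One-row data frame (or list) with fields `sift`, `polyphen2`,
#'   `mutation_taster`, `provean`, `cadd_phred`; vectors are supported and
#'   give vectorized votes.
#' @param predictor One of `"sift"`, `"polyphen2"`, `"mutation_taster"`,
#'   `"provean"`, `"cadd"`.
#' @param config A [triage_config()].
#' @return Character vector of votes.
#' @export
damaging_vote <- function(calls, predictor, config = triage_config()) {
  if (!(predictor %in% PREDICTORS)) {
    stop_fpc("unknown predictor '%s'", predictor)
  }
  vote <- function(x, damaging_set) {
    ifelse(is.na(x), "missing",
           ifelse(x %in% damaging_set, "damaging", "benign"))
  }
  switch(predictor,
    sift = vote(calls$sift, "deleterious"),
    polyphen2 = {
      dmg <- if (config$polyphen_possibly_counts) {
        c("probably_damaging", "possibly_damaging")
      } else "probably_damaging"
      vote(calls$polyphen2, dmg)
    },
    mutation_taster = vote(calls$mutation_taster,
                           c("disease_causing_automatic", "disease_causing")),
    provean = vote(calls$provean, "deleterious"),
    cadd = ifelse(is.na(calls$cadd_phred), "missing",
                  ifelse(calls$cadd_phred >= config$cadd_high_cutoff,
                         "damaging", "benign"))
  )
}

#' Ensemble total score
#'
#' Adds up the damaging votes of the five predictors; `n_informative` counts
#' the non-missing votes (so `total_score <= n_informative <= 5`).
#'
#' @param calls Data frame with the predictor call columns (any number of
#'   rows).
#' @param config A [triage_config()].
#' @return `calls` with appended columns `vote_sift`, `vote_polyphen2`,
#'   `vote_mutation_taster`, `vote_provean`, `vote_cadd`, `total_score`,
#'   `n_informative`.
#' @export
total_score <- function(calls, config = triage_config()) {
  votes <- vapply(PREDICTORS, function(p) damaging_vote(calls, p, config),
                  character(nrow(as.data.frame(calls))))
  votes <- matrix(votes, ncol = length(PREDICTORS),
                  dimnames = list(NULL, PREDICTORS))
  out <- as.data.frame(calls, stringsAsFactors = FALSE)
  for (p in PREDICTORS) out[[paste0("vote_", p)]] <- votes[, p]
  out$total_score <- as.integer(rowSums(votes == "damaging"))
  out$n_informative <- as.integer(rowSums(votes != "missing"))
  out
}

#' Pre-filter to consequence classes of interest
#'
#' Retains missense and splice-site variants (the exonic focus of the
#' analysis) and, by default, promoter variants; synonymous and other
#' consequences are dropped.
#'
#' @param variants Data frame with a `consequence` column.
#' @param keep_promoter Retain promoter variants (default TRUE)?
#' @return The retained subset of `variants`.
#' @export
prefilter_nonsynonymous <- function(variants, keep_promoter = TRUE) {
  keep <- c("missense", "splice_site", if (keep_promoter) "promoter")
  variants[variants$consequence %in% keep, , drop = FALSE]
}

#' Three-tier candidate triage
#'
#' Applies the study's candidate-retention rules to scored variants:
#' \describe{
#'   \item{T1_high_score}{`total_score >= high_score_threshold`, or the
#'     unanimity rule for variants with fewer informative predictors than the
#'     threshold (see [triage_config()]).}
#'   \item{T2_risk_gene}{gene in the risk-gene list with
#'     `cadd_phred < cadd_high_cutoff` — risk-gene variants the high-score
#'     tier would miss.}
#'   \item{T3_recurrent}{high-scoring (as T1) and carried by at least
#'     `recurrence_min_families` families (families, not carriers, are
#'     counted).}
#' }
#' Variants reaching no tier are dropped. Output order is deterministic
#' (chrom, pos, ref, alt).
#'
#' @param scored Data frame from [total_score()] with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `cadd_phred`, `total_score`,
#'   `n_informative`.
#' @param carriers Data frame `variant_id, family_id` listing, for each
#'   variant, the families with at least one carrier.
#' @param config A [triage_config()].
#' @return Data frame of retained variants with logical tier columns
#'   `T1_high_score`, `T2_risk_gene`, `T3_recurrent`, a semicolon-joined
#'   `tiers` label, and `families_with_variant` (integer count) plus
#'   `family_ids` (semicolon-joined).
#' @export
triage <- function(scored, carriers, config = triage_config()) {
  carriers <- unique(carriers[, c("variant_id", "family_id")])
  fam_sets <- split(carriers$family_id, carriers$variant_id)
  n_fam <- vapply(fam_sets, length, integer(1))
  nf <- unname(n_fam[match(scored$variant_id, names(fam_sets))])
  nf[is.na(nf)] <- 0L
  high <- scored$total_score >= config$high_score_threshold |
    (scored$n_informative < config$high_score_threshold &
       scored$n_informative >= config$min_informative &
       scored$total_score == scored$n_informative)
  t1 <- high
  t2 <- scored$gene %in% config$risk_genes &
    !is.na(scored$cadd_phred) &
    scored$cadd_phred < config$cadd_high_cutoff
  t3 <- high & nf >= config$recurrence_min_families
  keep <- t1 | t2 | t3
  out <- scored[keep, , drop = FALSE]
  out$T1_high_score <- t1[keep]
  out$T2_risk_gene <- t2[keep]
  out$T3_recurrent <- t3[keep]
  out$tiers <- apply(cbind(ifelse(out$T1_high_score, "T1_high_score", NA),
                           ifelse(out$T2_risk_gene, "T2_risk_gene", NA),
                           ifelse(out$T3_recurrent, "T3_recurrent", NA)),
                     1, function(x) paste(stats::na.omit(x), collapse = ";"))
  out$families_with_variant <- nf[keep]
  out$family_ids <- vapply(out$variant_id, function(v) {
    fams <- fam_sets[[v]]
    if (is.null(fams)) "" else paste(sort(fams), collapse = ";")
  }, character(1))
  out <- out[order(out$chrom, out$pos, out$ref, out$alt, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Carrier families per variant
#'
#' Derives the `variant_id, family_id` carriage table used by [triage()] from
#' a genotype set and its cohort (a family carries a variant when at least
#' one genotyped member is het or hom_alt).
#'
#' @param gset An `fpc_genotypes` object.
#' @param cohort The matching [fpc_cohort()].
#' @return Data frame `variant_id, family_id`.
#' @export
carrier_families <- function(gset, cohort) {
  members <- cohort_members(cohort)
  fam_of <- stats::setNames(members$family_id, members$individual_id)
  ids <- colnames(gset$genotypes)
  res <- list()
  for (fam in unique(fam_of)) {
    cols <- ids[!is.na(fam_of[ids]) & fam_of[ids] == fam]
    if (length(cols) == 0) next
    sub <- gset$genotypes[, cols, drop = FALSE]
    carried <- rownames(sub)[rowSums(sub == "het" | sub == "hom_alt",
                                     na.rm = TRUE) > 0]
    if (length(carried) > 0) {
      res[[fam]] <- data.frame(variant_id = carried, family_id = fam,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(variant_id = character(0), family_id = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
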