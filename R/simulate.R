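# Seeded synthetic cohort generator: multi-generation pedigrees, dominant
# gene-drop with age-dependent penetrance, background variants at realistic
# allele frequencies, and predictor calls correlated with true
# deleteriousness. Stands in for registry data so the whole pipeline is
# testable offline.

#' Simulation configuration
#'
#' Defaults emulate the sequenced registry families: three-generation
#' pedigrees ascertained for at least three pancreatic-affected genotyped
#' members, a dominant founder variant with incomplete age-dependent
#' penetrance (median onset 65 years, range 42-78), background variants at
#' rare-to-low allele frequencies, and in-silico predictor calls that are
#' damaging at high rate for the planted variant and low rate otherwise.
#'
#' @param n_families Number of families.
#' @param generations Pedigree depth (>= 2; default 3).
#' @param mean_sibship Mean children per couple (>= 1; sibship is
#'   1 + Poisson(`mean_sibship` - 1), so the mean is exact and every couple
#'   has a child).
#' @param causal_fraction Fraction of families given a planted dominant
#'   founder variant (the first `round(causal_fraction * n_families)`
#'   families).
#' @param penetrance_by_target_age Probability that a carrier who has reached
#'   their sampled onset age is affected (default 0.8).
#' @param onset_age_median,onset_age_range Onset-age distribution: normal
#'   with this median and sd `diff(range)/6`, truncated to the range.
#' @param phenocopy_rate Probability that a non-carrier develops the target
#'   phenotype; gated through the same onset-age distribution (sporadic PDAC
#'   is late-onset).
#' @param n_background_variants Shared background variant sites.
#' @param background_af_shape1,background_af_shape2 Beta parameters for
#'   background population allele frequencies (defaults give mostly rare to
#'   low-frequency variants).
#' @param predictor_damaging_rate_causal,predictor_damaging_rate_background
#'   Per-predictor damaging-vote probabilities for planted and background
#'   variants.
#' @param genotyping_missingness Probability that a member has no usable
#'   blood DNA (their genotypes are missing).
#' @param risk_gene_fraction Probability that a planted variant is placed in
#'   a gene from `risk_genes` (the study's candidate set included the risk
#'   genes ATM and POLQ, roughly 2 of 7).
#' @param risk_genes Risk-gene symbols used for planted-gene placement.
#' @param generation_ages Mean current age per generation (extended by -26
#'   years per extra generation when `generations` exceeds its length).
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 15,
                              generations = 3,
                              mean_sibship = 2.5,
                              causal_fraction = 1,
                              penetrance_by_target_age = 0.8,
                              onset_age_median = 65,
                              onset_age_range = c(42, 78),
                              phenocopy_rate = 0.01,
                              n_background_variants = 200,
                              background_af_shape1 = 0.5,
                              background_af_shape2 = 35,
                              predictor_damaging_rate_causal = 0.9,
                              predictor_damaging_rate_background = 0.1,
                              genotyping_missingness = 0.05,
                              risk_gene_fraction = 0.3,
                              risk_genes = default_risk_genes(),
                              generation_ages = c(88, 66, 40),
                              seed = 1L) {
  stopifnot(generations >= 2, mean_sibship >= 1,
            causal_fraction >= 0, causal_fraction <= 1,
            penetrance_by_target_age >= 0, penetrance_by_target_age <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            genotyping_missingness >= 0, genotyping_missingness <= 1,
            risk_gene_fraction >= 0, risk_gene_fraction <= 1,
            length(onset_age_range) == 2,
            onset_age_range[1] <= onset_age_median,
            onset_age_median <= onset_age_range[2])
  if (generations > length(generation_ages)) {
    extra <- seq_len(generations - length(generation_ages))
    generation_ages <- c(generation_ages,
                         generation_ages[length(generation_ages)] - 26 * extra)
  }
  structure(as.list(environment()), class = "simulation_config")
}

# Truncated-normal onset ages: median onset_age_median, sd = range/6,
# truncated to onset_age_range (inverse-CDF sampling).
sample_onset_ages <- function(n, config) {
  lo <- config$onset_age_range[1]
  hi <- config$onset_age_range[2]
  mu <- config$onset_age_median
  sdev <- (hi - lo) / 6
  p_lo <- stats::pnorm(lo, mu, sdev)
  p_hi <- stats::pnorm(hi, mu, sdev)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mu, sdev)
}

#' Simulate one multi-generation pedigree
#'
#' Founder couple at the top; every lineage member below the last generation
#' marries an unrelated founder spouse and has 1 + Poisson(`mean_sibship` -
#' 1) children. Ages decrease by generation around `generation_ages` (sd 4
#' years); first-generation members are flagged deceased. Members lack blood
#' DNA with probability `genotyping_missingness`. Phenotypes are left empty
#' (see [assign_phenotypes()]). Uses the session RNG; seed via
#' [simulate_cohort()] or `set.seed()` for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param family_id Family id; member ids are prefixed with it so that
#'   cohort-wide ids stay unique.
#' @return An [fpc_family()].
#' @export
simulate_pedigree <- function(config, family_id = "SIM-1") {
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("%s_%02d", family_id, counter)
  }
  age_of <- function(g) {
    max(1, round(stats::rnorm(1, config$generation_ages[g], 4)))
  }
  rows <- list()
  add <- function(id, father, mother, sex, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = id, father_id = father, mother_id = mother, sex = sex,
      phenotypes = "", age_years = age_of(gen), age_kind = "current",
      has_blood_dna = stats::runif(1) >= config$genotyping_missingness,
      has_tumor_dna = FALSE, deceased = gen == 1L,
      generation = gen, stringsAsFactors = FALSE)
  }
  f1 <- next_id(); f2 <- next_id()
  add(f1, NA_character_, NA_character_, "male", 1L)
  add(f2, NA_character_, NA_character_, "female", 1L)
  frontier <- list(list(father = f1, mother = f2, gen = 1L))
  while (length(frontier) > 0) {
    couple <- frontier[[1]]
    frontier <- frontier[-1]
    n_child <- 1L + stats::rpois(1, config$mean_sibship - 1)
    for (k in seq_len(n_child)) {
      child <- next_id()
      child_sex <- if (stats::runif(1) < 0.5) "male" else "female"
      add(child, couple$father, couple$mother, child_sex, couple$gen + 1L)
      if (couple$gen + 1L < config$generations) {
        spouse <- next_id()
        spouse_sex <- if (child_sex == "male") "female" else "male"
        add(spouse, NA_character_, NA_character_, spouse_sex, couple$gen + 1L)
        frontier[[length(frontier) + 1L]] <-
          list(father = if (child_sex == "male") child else spouse,
               mother = if (child_sex == "male") spouse else child,
               gen = couple$gen + 1L)
      }
    }
  }
  members <- do.call(rbind, rows)
  generation <- members$generation
  members$generation <- NULL
  fam <- fpc_family(family_id, members)
  attr(fam, "generation") <- stats::setNames(generation, members$individual_id)
  fam
}

#' Drop one variant through a pedigree
#'
#' The designated founder is heterozygous; every child of a carrier parent
#' inherits the alternate allele from that parent with probability 1/2,
#' independently. All other founders are hom_ref, so non-descendants stay
#' hom_ref and the output is always Mendelian-consistent.
#'
#' @param family An [fpc_family()] (members ordered parents-before-children,
#'   as produced by [simulate_pedigree()]).
#' @param founder_carrier Id of the carrier founder, or `NA` for a variant
#'   absent from the family.
#' @return Named character vector of genotypes for every member.
#' @export
gene_drop <- function(family, founder_carrier = NA_character_) {
  m <- family$members
  founder_dosage <- stats::setNames(integer(nrow(m)), m$individual_id)
  if (!is.na(founder_carrier)) {
    if (!(founder_carrier %in% m$individual_id)) {
      stop_fpc("founder '%s' not in family %s", founder_carrier,
               family$family_id)
    }
    founder_dosage[founder_carrier] <- 1L
  }
  dosage <- gene_drop_matrix(family, matrix(founder_dosage, nrow = 1,
                                            dimnames = list(NULL, m$individual_id)))
  stats::setNames(GENOTYPE_LEVELS[dosage[1, ] + 1L], m$individual_id)
}

# Drop many variants at once. founder_dosage: variants x members matrix of
# alt-allele dosages for founders (members with any recorded parent are
# overwritten by transmission). Members must be ordered parents-first.
gene_drop_matrix <- function(family, founder_dosage) {
  m <- family$members
  v <- nrow(founder_dosage)
  dosage <- founder_dosage[, m$individual_id, drop = FALSE]
  for (i in seq_len(nrow(m))) {
    fa <- m$father_id[i]; mo <- m$mother_id[i]
    if (is.na(fa) && is.na(mo)) next
    from_fa <- if (!is.na(fa)) {
      stats::rbinom(v, 1L, dosage[, fa] / 2)
    } else integer(v)
    from_mo <- if (!is.na(mo)) {
      stats::rbinom(v, 1L, dosage[, mo] / 2)
    } else integer(v)
    dosage[, i] <- from_fa + from_mo
  }
  dosage
}

#' Assign phenotypes given genotypes
#'
#' A carrier whose age has reached their sampled onset age becomes affected
#' with probability `penetrance_by_target_age` (PDAC with probability 0.75,
#' otherwise a high-grade precursor lesion). A non-carrier becomes a
#' phenocopy (PDAC) with probability `phenocopy_rate`, gated through the
#' same onset-age distribution. Affected members get `age_kind`
#' `"at_diagnosis"`.
#'
#' @param family An [fpc_family()].
#' @param genotypes Named genotype vector for the planted variant (e.g. from
#'   [gene_drop()]).
#' @param config A [simulation_config()].
#' @return The family with phenotypes filled in.
#' @export
assign_phenotypes <- function(family, genotypes, config) {
  m <- family$members
  gt <- genotypes[m$individual_id]
  carrier <- !is.na(gt) & gt %in% c("het", "hom_alt")
  n <- nrow(m)
  onset <- sample_onset_ages(n, config)
  reached <- !is.na(m$age_years) & m$age_years >= onset
  u <- stats::runif(n)
  affected <- (carrier & reached & u < config$penetrance_by_target_age) |
    (!carrier & reached & u < config$phenocopy_rate)
  pheno_type <- ifelse(stats::runif(n) < 0.75, "PDAC", "precursor_high_grade")
  m$phenotypes[affected] <- pheno_type[affected]
  m$age_kind[affected] <- "at_diagnosis"
  m$age_years[affected] <- pmin(m$age_years[affected],
                                round(onset[affected]))
  family$members <- m
  family
}

#' Simulate predictor annotations
#'
#' Builds the per-variant annotation table for planted and background
#' variants: each predictor votes damaging with
#' `predictor_damaging_rate_causal` for planted variants and
#' `predictor_damaging_rate_background` otherwise; CADD is drawn above or
#' below the 20 cutoff with the same rates. Background allele frequencies
#' come from the configured Beta distribution; planted variants are forced
#' rare. Planted variants are placed in a risk gene with probability
#' `risk_gene_fraction`.
#'
#' @param keys Data frame `variant_id, chrom, pos, ref, alt` (as in
#'   `fpc_genotypes$variants`).
#' @param causal_ids Variant ids of planted variants.
#' @param config A [simulation_config()].
#' @return Annotation data frame in the layout of [read_annotation_table()].
#' @export
simulate_annotations <- function(keys, causal_ids, config) {
  n <- nrow(keys)
  if (n == 0) {
    return(data.frame(
      variant_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), gene = character(0),
      consequence = character(0), hgvs_c = character(0),
      hgvs_p = character(0), sift = character(0), polyphen2 = character(0),
      mutation_taster = character(0), provean = character(0),
      cadd_phred = numeric(0), population_af = numeric(0),
      af_band = character(0), band_imputed = logical(0),
      stringsAsFactors = FALSE))
  }
  causal <- keys$variant_id %in% causal_ids
  rate <- ifelse(causal, config$predictor_damaging_rate_causal,
                 config$predictor_damaging_rate_background)
  draw <- function(dmg_val, ben_val) {
    ifelse(stats::runif(n) < rate, dmg_val, ben_val)
  }
  cadd_dmg <- stats::runif(n, 20, 40)
  cadd_ben <- stats::runif(n, 0, 19.9)
  af <- stats::rbeta(n, config$background_af_shape1,
                     config$background_af_shape2)
  af[causal] <- stats::runif(sum(causal), 1e-6, 1e-3)
  gene <- sprintf("GENE%04d", seq_len(n))
  n_risk <- sum(causal)
  if (n_risk > 0 && length(config$risk_genes) > 0) {
    use_risk <- stats::runif(n_risk) < config$risk_gene_fraction
    gene[causal][use_risk] <- sample(config$risk_genes, sum(use_risk),
                                     replace = TRUE)
  }
  band <- af_band(af)
  data.frame(
    variant_id = keys$variant_id,
    chrom = keys$chrom, pos = keys$pos, ref = keys$ref, alt = keys$alt,
    gene = gene,
    consequence = "missense",
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    sift = draw("deleterious", "tolerated"),
    polyphen2 = draw("probably_damaging", "benign"),
    mutation_taster = draw("disease_causing", "polymorphism"),
    provean = draw("deleterious", "neutral"),
    cadd_phred = ifelse(stats::runif(n) < rate, cadd_dmg, cadd_ben),
    population_af = af,
    af_band = as.character(band),
    band_imputed = attr(band, "band_imputed"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort
#'
#' Generates `n_families` pedigrees; the first
#' `round(causal_fraction * n_families)` get a planted dominant founder
#' variant and are rejection-sampled (up to `max_tries` redraws) until at
#' least three affected and two unaffected members carry usable blood DNA —
#' the registry's own ascertainment regime. Background variants are shared
#' sites whose founder genotypes are drawn from their population allele
#' frequencies and dropped through each pedigree, so Mendelian consistency
#' holds for every variant. Genotypes are reported only for members with
#' blood DNA.
#'
#' @param config A [simulation_config()]; `config$seed` seeds all
#'   randomness.
#' @param max_tries Ascertainment redraw limit per causal family.
#' @return List of class `fpc_simulation`: `cohort` ([fpc_cohort()]),
#'   `genotypes` (`fpc_genotypes`), `annotation` (data frame), `truth`
#'   (named list family id -> planted variant id or `NA`), `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), max_tries = 200) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_causal <- round(config$causal_fraction * config$n_families)
  fam_ids <- sprintf("SIM-%03d", seq_len(config$n_families))

  bg_n <- config$n_background_variants
  bg_keys <- if (bg_n > 0) {
    # positions sampled without replacement so keys are unique
    sprintf("%d:%d:A:G", sample(1:22, bg_n, replace = TRUE),
            1000000L + sample.int(49000000L, bg_n))
  } else character(0)
  bg_af <- stats::rbeta(bg_n, config$background_af_shape1,
                        config$background_af_shape2)

  families <- list()
  geno_cols <- list()
  truth <- stats::setNames(vector("list", config$n_families), fam_ids)
  causal_keys <- character(0)

  for (i in seq_len(config$n_families)) {
    fid <- fam_ids[i]
    causal <- i <= n_causal
    planted_key <- if (causal) {
      sprintf("%d:%d:C:T", (i %% 22L) + 1L, 100000L + i)
    } else NA_character_
    tries <- 0L
    repeat {
      tries <- tries + 1L
      fam <- simulate_pedigree(config, fid)
      planted_gt <- if (causal) {
        gene_drop(fam, fam$members$individual_id[1])
      } else {
        stats::setNames(rep("hom_ref", nrow(fam$members)),
                        fam$members$individual_id)
      }
      fam <- assign_phenotypes(fam, planted_gt, config)
      if (!causal) break
      ok <- with(fam$members, {
        aff <- vapply(phenotypes, function(p)
          has_any_phenotype(p, c("PDAC", "precursor_high_grade")), logical(1))
        unaff <- vapply(phenotypes, is_unaffected, logical(1))
        carrier_aff <- aff & planted_gt[individual_id] %in% c("het", "hom_alt")
        sum(carrier_aff & has_blood_dna) >= 3 && sum(unaff & has_blood_dna) >= 2
      })
      if (ok || tries >= max_tries) {
        if (!ok) warn_fpc("family %s: ascertainment not met after %d tries",
                          fid, max_tries)
        break
      }
    }
    m <- fam$members
    ids <- m$individual_id
    # background founder dosages from population AF, then gene drop
    is_founder <- is.na(m$father_id) & is.na(m$mother_id)
    founder_dosage <- matrix(0L, nrow = bg_n, ncol = length(ids),
                             dimnames = list(bg_keys, ids))
    if (bg_n > 0 && any(is_founder)) {
      nf <- sum(is_founder)
      founder_dosage[, is_founder] <-
        matrix(stats::rbinom(bg_n * nf, 2L, rep(bg_af, nf)), nrow = bg_n)
    }
    bg_dosage <- if (bg_n > 0) gene_drop_matrix(fam, founder_dosage) else
      founder_dosage
    gmat <- matrix(NA_character_, nrow = bg_n + 1L, ncol = length(ids),
                   dimnames = list(c(bg_keys, "planted"), ids))
    if (bg_n > 0) gmat[bg_keys, ] <- GENOTYPE_LEVELS[bg_dosage + 1L]
    gmat["planted", ] <- planted_gt[ids]
    gmat[, !m$has_blood_dna] <- NA_character_
    if (causal) {
      rownames(gmat)[bg_n + 1L] <- planted_key
      truth[[fid]] <- planted_key
      causal_keys <- c(causal_keys, planted_key)
      geno_cols[[fid]] <- gmat
    } else {
      truth[[fid]] <- NA_character_
      geno_cols[[fid]] <- gmat[seq_len(bg_n), , drop = FALSE]
    }
    families[[fid]] <- fam
  }

  all_keys <- c(bg_keys, causal_keys)
  all_ids <- unlist(lapply(geno_cols, colnames), use.names = FALSE)
  gmat_all <- matrix(NA_character_, nrow = length(all_keys),
                     ncol = length(all_ids),
                     dimnames = list(all_keys, all_ids))
  for (fid in names(geno_cols)) {
    gmat_all[rownames(geno_cols[[fid]]), colnames(geno_cols[[fid]])] <-
      geno_cols[[fid]]
  }
  gset <- structure(list(variants = parse_variant_key(all_keys),
                         genotypes = gmat_all),
                    class = "fpc_genotypes")
  annotation <- simulate_annotations(gset$variants, causal_keys, config)
  # background AFs in the annotation are the generating frequencies
  annotation$population_af[match(bg_keys, annotation$variant_id)] <- bg_af
  band <- af_band(annotation$population_af)
  annotation$af_band <- as.character(band)
  annotation$band_imputed <- attr(band, "band_imputed")

  structure(list(cohort = fpc_cohort(unname(families), label = "simulated"),
                 genotypes = gset,
                 annotation = annotation,
                 truth = truth,
                 config = config),
            class = "fpc_simulation")
}

#' Write a simulated cohort to disk
#'
#' Emits the extended PED file, a plain-text VCF, the annotation TSV and a
#' truth JSON; all re-readable by the package's I/O functions with a
#' lossless round trip.
#'
#' @param sim An `fpc_simulation` from [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pedigree = file.path(out_dir, "cohort.ped"),
    vcf = file.path(out_dir, "cohort.vcf"),
    annotation = file.path(out_dir, "annotation.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_pedigree(sim$cohort, paths$pedigree)
  write_vcf_genotypes(sim$genotypes, paths$vcf)
  write_annotation_table(sim$annotation, paths$annotation)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(paths)
}

#' Planted-variant recovery
#'
#' For each causal family, checks whether the planted variant survives
#' scoring, triage and co-segregation (verdict `complete` or
#' `incomplete_penetrance`) — the end-to-end sensitivity of the pipeline
#' under the simulation's study conditions.
#'
#' @param sim An `fpc_simulation`.
#' @param config A [triage_config()].
#' @param phenotype A [phenotype_spec()].
#' @param rule A [penetrance_rule()].
#' @return List with `n_causal`, `n_recovered`, `fraction`, and a logical
#'   vector `recovered` keyed by family id.
#' @export
planted_recovery <- function(sim, config = triage_config(),
                             phenotype = phenotype_spec(),
                             rule = penetrance_rule()) {
  scored <- total_score(sim$annotation, config)
  carriers <- carrier_families(sim$genotypes, sim$cohort)
  triaged <- triage(scored, carriers, config)
  causal_fams <- names(sim$truth)[!is.na(unlist(sim$truth))]
  recovered <- stats::setNames(logical(length(causal_fams)), causal_fams)
  for (fid in causal_fams) {
    key <- sim$truth[[fid]]
    if (!(key %in% triaged$variant_id)) next
    fam <- sim$cohort$families[[fid]]
    ids <- fam$members$individual_id
    g <- sim$genotypes$genotypes[key, ids]
    names(g) <- ids
    res <- evaluate_segregation(fam, g, phenotype, rule)
    recovered[fid] <- res$verdict %in% c("complete", "incomplete_penetrance")
  }
  list(n_causal = length(causal_fams),
       n_recovered = sum(recovered),
       fraction = if (length(causal_fams) > 0) mean(recovered) else NA_real_,
       recovered = recovered)
}
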