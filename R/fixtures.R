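# Machine-readable study fixtures: the candidate-gene families encoded from
# the published per-family narratives (genotype and phenotype are encoded
# only for individuals the text characterizes), plus synthetic candidate-free
# filler families so the bundle holds the full set of 15 sequenced families.
# Validation-cohort counts and curated variant labels mirror the published
# summary table.

FIXTURE_VARIANTS <- function() {
  df <- data.frame(
    chrom = c("11", "10", "14", "1", "3", "10", "17", "3",
              "7", "9", "2", "5", "8"),
    pos = c(108200000L, 104263000L, 45650000L, 57800000L, 121200000L,
            93670000L, 61700000L, 128622922L,
            130020000L, 35074000L, 5000000L, 1200000L, 2500000L),
    ref = c("G", "C", "C", "G", "C", "G", "T", "G",
            "C", "G", "C", "A", "T"),
    alt = c("T", "T", "G", "A", "A", "A", "C", "A",
            "T", "A", "T", "C", "G"),
    gene = c("ATM", "SUFU", "FANCM", "DAB1", "POLQ", "FGFBP3", "MAP3K3",
             "ACAD9", "CPA1", "FANCG", "BGSYN1", "BGMIS1", "BGMIS2"),
    consequence = c("missense", "promoter", "missense", "splice_site",
                    "missense", "missense", "missense", "missense",
                    "missense", "missense", "synonymous", "missense",
                    "missense"),
    hgvs_c = c("c.5385G>T", "c.-8C>T", "c.4375C>G", "c.786+1G>A",
               "c.4141C>A", "c.724G>A", "c.1511T>C", "c.976G>A",
               NA, NA, NA, NA, NA),
    hgvs_p = c("p.(W1795C)", NA, "p.(P1459A)", NA, "p.(P1381T)",
               "p.(A242T)", "p.(I504T)", "p.(A326T)", NA, NA, NA, NA, NA),
    sift = c("deleterious", NA, "deleterious", NA, "tolerated",
             "deleterious", "deleterious", "deleterious",
             "deleterious", "deleterious", NA, "deleterious", "deleterious"),
    polyphen2 = c("possibly_damaging", NA, "probably_damaging", NA, "benign",
                  "probably_damaging", "probably_damaging",
                  "probably_damaging", "probably_damaging",
                  "possibly_damaging", NA, "benign", "probably_damaging"),
    mutation_taster = c("disease_causing", "disease_causing_automatic",
                        "disease_causing", "disease_causing_automatic",
                        "disease_causing", "disease_causing",
                        "disease_causing", "disease_causing",
                        "disease_causing", "polymorphism", NA,
                        "polymorphism", "disease_causing"),
    provean = c("neutral", NA, "deleterious", NA, "neutral", "deleterious",
                "deleterious", "neutral", "deleterious", "neutral", NA,
                "neutral", "neutral"),
    cadd_phred = c(18.5, 20.5, 24.1, 34.0, 15.2, 25.8, 27.5, 22.1,
                   28.3, 14.0, 2.1, 8.4, 12.0),
    population_af = c(NA, 0.000024, 0.0002, 0.00001, 0.015, 0.000004,
                      0.00001, 0.0152, 0.0005, 0.002, 0.01, 0.004, 0.0008),
    stringsAsFactors = FALSE
  )
  df$variant_id <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  band <- af_band(df$population_af)
  df$af_band <- as.character(band)
  df$band_imputed <- attr(band, "band_imputed")
  df[, c("variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
         "hgvs_c", "hgvs_p", "sift", "polyphen2", "mutation_taster",
         "provean", "cadd_phred", "population_af", "af_band", "band_imputed")]
}

# One family's members, with ids prefixed for cohort-wide uniqueness.
fixture_family_0382 <- function() {
  p <- function(x) paste0("0382_", x)
  members <- rbind(
    pedigree_members(p("GF"), sex = "male", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("GM"), sex = "female", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("FA"), father_id = p("GF"), mother_id = p("GM"),
                     sex = "male", phenotypes = "PDAC", age_years = 70,
                     age_kind = "at_death", has_blood_dna = FALSE,
                     deceased = TRUE),
    pedigree_members(p("UN"), father_id = p("GF"), mother_id = p("GM"),
                     sex = "male", phenotypes = "PDAC", age_years = 74,
                     age_kind = "at_death", has_blood_dna = FALSE,
                     deceased = TRUE),
    pedigree_members(p("MO"), sex = "female", phenotypes = "PDAC",
                     age_years = 68, age_kind = "at_diagnosis",
                     has_blood_dna = FALSE, has_tumor_dna = TRUE),
    pedigree_members(p("IX"), father_id = p("FA"), mother_id = p("MO"),
                     sex = "male", phenotypes = "PDAC", age_years = 48,
                     age_kind = "at_diagnosis"),
    pedigree_members(p("SP"), sex = "female", has_blood_dna = FALSE),
    pedigree_members(p("SON"), father_id = p("IX"), mother_id = p("SP"),
                     sex = "male", age_years = 22, age_kind = "current"),
    pedigree_members(p("DAU"), father_id = p("IX"), mother_id = p("SP"),
                     sex = "female", phenotypes = "leukemia",
                     has_blood_dna = FALSE, deceased = TRUE)
  )
  fam <- fpc_family("02-5-0382", members)
  list(family = fam, het = list(ATM = p(c("IX", "SON"))))
}

fixture_family_67 <- function() {
  p <- function(x) paste0("67_", x)
  gen2 <- function(id, sex, pheno, age, kind = "at_diagnosis") {
    pedigree_members(p(id), father_id = p("GF1"), mother_id = p("GM1"),
                     sex = sex, phenotypes = pheno, age_years = age,
                     age_kind = kind)
  }
  members <- rbind(
    pedigree_members(p("GF1"), sex = "male", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("GM1"), sex = "female", deceased = TRUE,
                     has_blood_dna = FALSE),
    gen2("P1", "male", "PDAC", 72),
    gen2("P2", "female", "PDAC", 69),
    gen2("P3", "male", "PDAC", 74),
    gen2("L1", "female", "precursor_high_grade", 63),
    gen2("L2", "male", "precursor_high_grade", 66),
    gen2("L3", "female", "precursor_high_grade", 61),
    gen2("L4", "female", "breast_cancer;precursor_high_grade", 58),
    gen2("E1", "female", "", 84, kind = "current"),
    gen2("E2", "male", "", 87, kind = "current"),
    gen2("E3", "female", "", 90, kind = "current"),
    pedigree_members(p("S2"), sex = "male", has_blood_dna = FALSE),
    pedigree_members(p(c("B1", "B2", "B3", "B4")), father_id = p("S2"),
                     mother_id = p("P2"), sex = "female",
                     phenotypes = "breast_cancer",
                     age_years = c(45, 48, 51, 54),
                     age_kind = "at_diagnosis")
  )
  fam <- fpc_family("25-5-67", members, family_type = "FPC_breast")
  list(family = fam,
       het = list(
         SUFU = p(c("P1", "P2", "P3", "L1", "L2", "L3", "L4",
                    "E1", "E2", "E3")),
         FANCM = p(c("B1", "B2", "B3", "B4"))))
}

fixture_family_44 <- function() {
  p <- function(x) paste0("44_", x)
  gen2 <- function(id, sex, pheno, age, kind) {
    pedigree_members(p(id), father_id = p("GF"), mother_id = p("GM"),
                     sex = sex, phenotypes = pheno, age_years = age,
                     age_kind = kind)
  }
  members <- rbind(
    pedigree_members(p("GF"), sex = "male", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("GM"), sex = "female", deceased = TRUE,
                     has_blood_dna = FALSE),
    gen2("A1", "male", "PDAC", 65, "at_diagnosis"),
    gen2("A2", "female", "PDAC", 61, "at_diagnosis"),
    gen2("A3", "male", "PDAC", 70, "at_diagnosis"),
    gen2("HO1", "female", "", 78, "current"),
    gen2("HO2", "male", "", 81, "current"),
    pedigree_members(p("SA1"), sex = "female", has_blood_dna = FALSE),
    pedigree_members(p("SA2"), sex = "male", has_blood_dna = FALSE),
    pedigree_members(p("M1"), father_id = p("A1"), mother_id = p("SA1"),
                     sex = "male", phenotypes = "melanoma", age_years = 34,
                     age_kind = "at_diagnosis"),
    pedigree_members(p("HY1"), father_id = p("A1"), mother_id = p("SA1"),
                     sex = "female", age_years = 35, age_kind = "current"),
    pedigree_members(p("H42"), father_id = p("SA2"), mother_id = p("A2"),
                     sex = "male", age_years = 42, age_kind = "current"),
    pedigree_members(p("HY2"), father_id = p("SA2"), mother_id = p("A2"),
                     sex = "male", age_years = 38, age_kind = "current")
  )
  fam <- fpc_family("25-9-44", members, family_type = "PCMS")
  core <- p(c("A1", "A2", "A3", "M1"))
  list(family = fam,
       het = list(
         DAB1 = core,
         POLQ = c(core, p("H42")),
         FGFBP3 = c(core, p(c("HO1", "HO2")))))
}

fixture_family_46 <- function() {
  p <- function(x) paste0("46_", x)
  members <- rbind(
    pedigree_members(p("C1"), sex = "male", phenotypes = "PDAC",
                     age_years = 66, age_kind = "at_diagnosis",
                     has_tumor_dna = TRUE),
    pedigree_members(p("C2"), sex = "female",
                     phenotypes = "precursor_high_grade", age_years = 58,
                     age_kind = "at_diagnosis"),
    pedigree_members(p("U1"), sex = "female", age_years = 48,
                     age_kind = "current"),
    pedigree_members(p("U2"), sex = "male", age_years = 52,
                     age_kind = "current"),
    pedigree_members(p("U3"), sex = "female", age_years = 75,
                     age_kind = "current"),
    pedigree_members(p("U4"), father_id = p("C1"), sex = "female",
                     age_years = 39, age_kind = "current"),
    pedigree_members(p("U5"), mother_id = p("C2"), sex = "male",
                     age_years = 33, age_kind = "current")
  )
  fam <- fpc_family("25-4-46", members)
  list(family = fam,
       het = list(
         MAP3K3 = p(c("C1", "C2")),
         ACAD9 = p(c("C1", "C2", "U1", "U2"))))
}

# Small two-generation ACAD9 validation families.
fixture_family_acad9 <- function(family_id, prefix, phenos, ages,
                                 het_members) {
  p <- function(x) paste0(prefix, "_", x)
  members <- rbind(
    pedigree_members(p("GP1"), sex = "male", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("GP2"), sex = "female", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p(c("A1", "A2", "U1", "U2")),
                     father_id = p("GP1"), mother_id = p("GP2"),
                     sex = c("male", "female", "male", "female"),
                     phenotypes = c(phenos, "", ""),
                     age_years = ages,
                     age_kind = c("at_diagnosis", "at_diagnosis",
                                  "current", "current"))
  )
  fam <- fpc_family(family_id, members)
  list(family = fam, het = list(ACAD9 = p(het_members)))
}

# Synthetic candidate-free filler family (labelled synthetic in the
# manifest); `het` maps gene -> carrier short-ids.
fixture_family_filler <- function(k, het = list()) {
  prefix <- sprintf("F%02d", k)
  p <- function(x) paste0(prefix, "_", x)
  members <- rbind(
    pedigree_members(p("GP1"), sex = "male", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p("GP2"), sex = "female", deceased = TRUE,
                     has_blood_dna = FALSE),
    pedigree_members(p(c("A1", "A2", "A3", "U1", "U2")),
                     father_id = p("GP1"), mother_id = p("GP2"),
                     sex = c("male", "female", "male", "female", "male"),
                     phenotypes = c("PDAC", "PDAC", "PDAC", "", ""),
                     age_years = c(66, 69, 72, 61, 58),
                     age_kind = c("at_diagnosis", "at_diagnosis",
                                  "at_diagnosis", "current", "current"),
                     has_blood_dna = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                     deceased = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  )
  fam <- fpc_family(sprintf("25-F%02d", k), members)
  list(family = fam, het = lapply(het, p))
}

fixture_validation_counts <- function() {
  data.frame(
    gene = c("ATM", "ATM", "SUFU", "DAB1", "DAB1", "POLQ", "POLQ",
             "FGFBP3", "FGFBP3", "MAP3K3", "MAP3K3", "ACAD9", "ACAD9"),
    cohort = c("wgs_families", "sanger_extension",
               "wgs_families",
               "pcms_families", "fpc_families",
               "wgs_families", "sanger_extension",
               "wgs_families", "sanger_extension",
               "wgs_families", "sanger_extension",
               "wgs_families", "sanger_extension"),
    families_tested = c(15L, 21L, 15L, 32L, 17L, 15L, 14L, 15L, 14L,
                        15L, 14L, 15L, 31L),
    carrier_families = c("02-5-0382", ".", "25-5-67", "25-9-44", ".",
                         "25-9-44", ".", "25-9-44", ".", "25-4-46", ".",
                         "25-4-46;25-1-91;25-9-113", "25-2-209"),
    stringsAsFactors = FALSE
  )
}

fixture_curation <- function() {
  data.frame(
    gene = c("ATM", "SUFU", "DAB1", "POLQ", "FGFBP3", "MAP3K3", "ACAD9"),
    hgvs_c = c("c.5385G>T", "c.-8C>T", "c.786+1G>A", "c.4141C>A",
               "c.724G>A", "c.1511T>C", "c.976G>A"),
    hgvs_p = c("p.(W1795C)", ".", ".", "p.(P1381T)", "p.(A242T)",
               "p.(I504T)", "p.(A326T)"),
    mutation_type = c("missense", "promoter variant", "splice site",
                      "missense", "missense", "missense", "missense"),
    significance = c("deleterious", "pathogenic", "pathogenic", "VUS",
                     "deleterious", "deleterious", "VUS"),
    maf_label = c("n.a.", "0.000024", "0.00001", "0.015/0.025", "0.000004",
                  "0.00001", "0.0152/0.0219"),
    stringsAsFactors = FALSE
  )
}

#' Build the encoded study-fixture bundle
#'
#' Assembles the 15 sequenced families as machine-readable fixtures — the
#' four narrative candidate families (ATM; SUFU + FANCM; DAB1 + POLQ +
#' FGFBP3; MAP3K3 + ACAD9), three further ACAD9-carrier families, and eight
#' synthetic candidate-free filler families — together with the cohort VCF,
#' the five-predictor annotation table, validation-cohort counts and curated
#' variant labels. Files are written in the package's standard formats and
#' re-read by the I/O modules; the manifest marks which families are
#' synthetic fillers.
#'
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return List with `dir`, `paths` (named file paths), and the in-memory
#'   objects `cohort`, `genotypes`, `annotation`, `validation_counts`,
#'   `curation`.
#' @export
build_paper_fixtures <- function(dir = tempfile("fpc_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- c(
    list(fixture_family_0382(), fixture_family_67(), fixture_family_44(),
         fixture_family_46(),
         fixture_family_acad9("25-1-91", "91", c("PDAC", "PDAC"),
                              c(67, 71, 63, 59), c("A1", "A2")),
         fixture_family_acad9("25-9-113", "113",
                              c("PDAC", "precursor_high_grade"),
                              c(64, 60, 60, 66), c("A1", "A2", "U1")),
         fixture_family_acad9("25-2-209", "209", c("PDAC", "PDAC"),
                              c(69, 73, 55, 70), c("A1", "A2", "U1"))),
    list(fixture_family_filler(1, list(CPA1 = "A1")),
         fixture_family_filler(2, list(FANCG = "A1")),
         fixture_family_filler(3, list(BGSYN1 = "A1", BGMIS1 = "A1")),
         fixture_family_filler(4, list(BGMIS1 = "A2")),
         fixture_family_filler(5, list(BGMIS2 = c("A1", "U1")))),
    lapply(6:8, fixture_family_filler)
  )
  cohort <- fpc_cohort(lapply(specs, `[[`, "family"), label = "study_fixtures")
  annotation <- FIXTURE_VARIANTS()

  members <- cohort_members(cohort)
  genotyped <- members$individual_id[members$has_blood_dna]
  gmat <- matrix(NA_character_, nrow = nrow(annotation),
                 ncol = nrow(members),
                 dimnames = list(annotation$variant_id, members$individual_id))
  gmat[, genotyped] <- "hom_ref"
  key_of <- stats::setNames(annotation$variant_id, annotation$gene)
  for (spec in specs) {
    for (gene in names(spec$het)) {
      gmat[key_of[[gene]], spec$het[[gene]]] <- "het"
    }
  }
  gset <- structure(list(variants = parse_variant_key(annotation$variant_id),
                         genotypes = gmat),
                    class = "fpc_genotypes")

  validation <- fixture_validation_counts()
  curation <- fixture_curation()
  paths <- list(
    pedigree = file.path(dir, "families.ped"),
    vcf = file.path(dir, "genotypes.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    validation_counts = file.path(dir, "validation_counts.tsv"),
    curation = file.path(dir, "curation.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_pedigree(cohort, paths$pedigree)
  write_vcf_genotypes(gset, paths$vcf)
  write_annotation_table(annotation, paths$annotation)
  utils::write.table(validation, paths$validation_counts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(curation, paths$curation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fillers <- grep("^25-F", names(cohort$families), value = TRUE)
  jsonlite::write_json(
    list(families = names(cohort$families),
         synthetic_fillers = fillers,
         note = "filler families are synthetic stand-ins; narrative families encode only individuals characterized in the study text"),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  list(dir = dir, paths = paths, cohort = cohort, genotypes = gset,
       annotation = annotation, validation_counts = validation,
       curation = curation)
}

#' Validation cohorts from a counts table
#'
#' Turns the `validation_counts.tsv` layout (gene, cohort, families_tested,
#' semicolon-joined carrier families, `.` for none) into merged
#' [validation_cohort()] objects, one per gene, merging rows in table order
#' via [merge_cohorts()].
#'
#' @param counts Data frame as written by [build_paper_fixtures()].
#' @return Named list of merged `validation_cohort`s keyed by gene.
#' @export
validation_cohorts_from_counts <- function(counts) {
  out <- list()
  for (gene in unique(counts$gene)) {
    rows <- counts[counts$gene == gene, , drop = FALSE]
    cohorts <- lapply(seq_len(nrow(rows)), function(i) {
      carriers <- rows$carrier_families[i]
      carriers <- if (carriers == "." || carriers == "") character(0) else
        strsplit(carriers, ";", fixed = TRUE)[[1]]
      validation_cohort(gene, families_tested = rows$families_tested[i],
                        carrier_families = carriers)
    })
    out[[gene]] <- merge_cohorts(cohorts[[1]], cohorts[-1])
  }
  out
}
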