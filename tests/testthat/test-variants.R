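vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

two_sample_cohort <- function() {
  fpc_cohort(list(fpc_family("V1", pedigree_members(
    c("s1", "s2"), sex = c("male", "female")))))
}

test_that("a single het call is read from a VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(c("s1", "s2")),
               "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0"), path)
  g <- read_vcf_genotypes(path, two_sample_cohort())
  expect_equal(nrow(g$variants), 1)
  expect_equal(g$variants$variant_id, "1:100:A:G")
  expect_equal(unname(g$genotypes["1:100:A:G", c("s1", "s2")]),
               c("het", "hom_ref"))
})

test_that("multiallelic records split per alt and a 1/2 sample is het for both", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(c("s1", "s2")),
               "2\t500\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t2/2"), path)
  g <- read_vcf_genotypes(path, two_sample_cohort())
  expect_equal(sort(g$variants$variant_id), c("2:500:A:G", "2:500:A:T"))
  expect_equal(unname(g$genotypes["2:500:A:G", "s1"]), "het")
  expect_equal(unname(g$genotypes["2:500:A:T", "s1"]), "het")
  expect_equal(unname(g$genotypes["2:500:A:T", "s2"]), "hom_alt")
  expect_equal(unname(g$genotypes["2:500:A:G", "s2"]), "hom_ref")
})

test_that("splitting multiallelic sites conserves per-sample alt dosage", {
  set.seed(5)
  dosage_of <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (rep in 1:10) {
    n_alt <- sample(2:3, 1)
    alleles1 <- sample(0:n_alt, 2, replace = TRUE)
    alleles2 <- sample(0:n_alt, 2, replace = TRUE)
    rec <- sprintf("3\t%d\t.\tA\t%s\t.\tPASS\t.\tGT\t%s\t%s",
                   1000 + rep,
                   paste(c("C", "G", "T")[seq_len(n_alt)], collapse = ","),
                   paste(alleles1, collapse = "/"),
                   paste(alleles2, collapse = "/"))
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(vcf_header(c("s1", "s2")), rec), path)
    g <- read_vcf_genotypes(path, two_sample_cohort())
    expect_equal(nrow(g$variants), n_alt)
    expect_equal(sum(dosage_of[g$genotypes[, "s1"]]), sum(alleles1 > 0))
    expect_equal(sum(dosage_of[g$genotypes[, "s2"]]), sum(alleles2 > 0))
  }
})

test_that("VCF write/read round trip preserves keys and genotype maps", {
  set.seed(15)
  n <- 100
  ids <- sprintf("s%02d", 1:6)
  cohort <- fpc_cohort(list(fpc_family("V2", pedigree_members(
    ids, sex = "unknown"))))
  keys <- sprintf("%d:%d:%s:%s", sample(1:22, n, replace = TRUE),
                  sample.int(1e6, n), "A",
                  sample(c("C", "G", "T"), n, replace = TRUE))
  keys <- unique(keys)
  gmat <- matrix(sample(c("hom_ref", "het", "hom_alt", NA), length(keys) * 6,
                        replace = TRUE),
                 nrow = length(keys), dimnames = list(keys, ids))
  gset <- structure(list(variants = fpcseg:::parse_variant_key(keys),
                         genotypes = gmat), class = "fpc_genotypes")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_genotypes(gset, path)
  back <- read_vcf_genotypes(path, cohort)
  expect_setequal(back$variants$variant_id, keys)
  expect_equal(back$genotypes[keys, ids], gmat)
})

test_that("unknown VCF samples are skipped with a warning, or error when strict", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(c("s1", "ghost")),
               "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1"), path)
  cohort <- two_sample_cohort()
  expect_warning(g <- read_vcf_genotypes(path, cohort), "ghost")
  expect_equal(unname(g$genotypes["1:100:A:G", "s1"]), "het")
  expect_error(read_vcf_genotypes(path, cohort, strict = TRUE), "ghost")
})

test_that("variant keys reduce alleles to minimal representation", {
  expect_equal(variant_key("1", 100, "TC", "GC"), "1:100:T:G") # shared suffix
  expect_equal(variant_key("1", 100, "AT", "AC"), "1:101:T:C") # shared prefix
  expect_equal(variant_key("1", 100, "ATG", "A"), "1:100:ATG:A") # indel kept
  expect_error(variant_key("1", 100, "A", "A"), "differ")
  expect_error(variant_key("1", 0, "A", "C"), ">= 1")
})

test_that("annotation table parsing matches a naive line-splitting oracle", {
  set.seed(25)
  n <- 50
  annot <- data.frame(
    variant_id = NA, chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e7, n), ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE),
    gene = sprintf("G%03d", 1:n),
    consequence = sample(c("missense", "splice_site", "promoter",
                           "synonymous", "other"), n, replace = TRUE),
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    stringsAsFactors = FALSE)
  annot <- cbind(annot[-1], random_calls(n)[c("sift", "polyphen2",
                                              "mutation_taster", "provean",
                                              "cadd_phred")])
  annot$population_af <- ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.06))
  annot$variant_id <- variant_key(annot$chrom, annot$pos, annot$ref, annot$alt)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(annot, path)
  parsed <- read_annotation_table(path)

  # naive oracle: split each line on tabs and decode independently
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  for (i in seq_len(n)) {
    f <- stats::setNames(strsplit(lines[i + 1], "\t")[[1]], header)
    row <- parsed[parsed$chrom == f["chrom"] &
                    parsed$pos == as.integer(f["pos"]) &
                    parsed$alt == f["alt"], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$gene, unname(f["gene"]))
    sift_want <- c(D = "deleterious", T = "tolerated", "." = NA)[[f[["sift"]]]]
    expect_equal(row$sift, sift_want)
    cadd_want <- if (f[["cadd_phred"]] == ".") NA_real_ else
      as.numeric(f[["cadd_phred"]])
    expect_equal(row$cadd_phred, cadd_want)
    af_want <- if (f[["population_af"]] == ".") NA_real_ else
      as.numeric(f[["population_af"]])
    expect_equal(row$population_af, af_want, tolerance = 1e-9)
  }
})

test_that("annotation table errors and warnings are specific", {
  header <- paste(c("chrom", "pos", "ref", "alt", "gene", "consequence",
                    "hgvs_c", "hgvs_p", "sift", "polyphen2",
                    "mutation_taster", "provean", "cadd_phred",
                    "population_af"), collapse = "\t")
  row1 <- "1\t100\tA\tG\tGX\tmissense\t.\t.\tD\tD\tD\tD\t25\t0.001"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(header, row1, row1), path)
  expect_error(read_annotation_table(path), "duplicate")

  writeLines(c(header,
               "1\t100\tA\tG\tGX\tmissense\t.\t.\tD\tD\tD\tD\toops\t0.001"),
             path)
  expect_error(read_annotation_table(path), "row 1.*cadd")

  writeLines(c(header,
               "1\t100\tA\tG\tGX\tmissense\t.\t.\tZ\tD\tD\tD\t20.5\t."),
             path)
  expect_warning(tab <- read_annotation_table(path), "unknown sift")
  expect_true(is.na(tab$sift))
  expect_equal(tab$cadd_phred, 20.5)
  expect_true(tab$band_imputed)

  # CADD-only row: every categorical predictor missing
  writeLines(c(header,
               "1\t100\tA\tG\tGX\tpromoter\t.\t.\t.\t.\t.\t.\t20.5\t."),
             path)
  tab <- read_annotation_table(path)
  expect_equal(tab$cadd_phred, 20.5)
  expect_true(all(is.na(c(tab$sift, tab$polyphen2, tab$mutation_taster,
                          tab$provean))))
})

test_that("allele-frequency bands use the 1% and 5% boundaries", {
  expect_equal(as.character(af_band(0.0152)), "low_frequency")
  expect_equal(as.character(af_band(0.000024)), "rare")
  expect_equal(as.character(af_band(0.05)), "common")   # boundary
  expect_equal(as.character(af_band(0.01)), "low_frequency") # boundary
  expect_equal(as.character(af_band(0.0099999)), "rare")
  b <- af_band(c(NA, 0.2))
  expect_equal(as.character(b), c("rare", "common"))
  expect_equal(attr(b, "band_imputed"), c(TRUE, FALSE))
  expect_error(af_band(1.2), "outside")
  expect_error(af_band(-0.1), "outside")
})
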