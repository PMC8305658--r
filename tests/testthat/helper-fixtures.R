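# Shared test fixtures, built in code.

# The study-fixture bundle is expensive enough to build once per test run.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_paper_fixtures()
    cache
  }
})

# Named genotype vector for one fixture variant in one family.
fixture_genotypes <- function(bundle, family_id, gene) {
  fam <- bundle$cohort$families[[family_id]]
  key <- bundle$annotation$variant_id[match(gene, bundle$annotation$gene)]
  ids <- fam$members$individual_id
  g <- bundle$genotypes$genotypes[key, ids]
  names(g) <- ids
  g
}

# A small nuclear family with `n_aff` affected and `n_unaff` unaffected
# genotyped children plus ungenotyped founder parents.
nuclear_family <- function(n_aff, n_unaff, family_id = "T1", ages = 70) {
  kids <- sprintf("K%02d", seq_len(n_aff + n_unaff))
  members <- rbind(
    pedigree_members("FA", sex = "male", has_blood_dna = FALSE),
    pedigree_members("MO", sex = "female", has_blood_dna = FALSE),
    pedigree_members(kids, father_id = "FA", mother_id = "MO",
                     sex = rep_len(c("male", "female"), length(kids)),
                     phenotypes = c(rep("PDAC", n_aff), rep("", n_unaff)),
                     age_years = ages)
  )
  fpc_family(family_id, members)
}

# Random pedigree-like family for property tests: founders plus randomly
# attached children (guaranteed acyclic because parents precede children).
random_family <- function(n, family_id = "R1") {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  ids <- sprintf("I%02d", seq_len(n))
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) < 0.7) {
      males <- which(sex[seq_len(i - 1)] == "male")
      females <- which(sex[seq_len(i - 1)] == "female")
      if (length(males) > 0 && length(females) > 0) {
        father[i] <- ids[males[sample.int(length(males), 1)]]
        mother[i] <- ids[females[sample.int(length(females), 1)]]
      }
    }
  }
  phen <- ifelse(stats::runif(n) < 0.3, "PDAC",
                 ifelse(stats::runif(n) < 0.1, "breast_cancer", ""))
  fpc_family(family_id, pedigree_members(
    ids, father_id = father, mother_id = mother, sex = sex,
    phenotypes = phen, age_years = sample(20:90, n, replace = TRUE),
    has_blood_dna = stats::runif(n) < 0.8))
}

# Random predictor-call table for scoring tests.
random_calls <- function(n) {
  pick <- function(vals) {
    v <- vals[sample.int(length(vals) + 1, n, replace = TRUE)]
    v # index beyond length gives NA
  }
  data.frame(
    sift = pick(c("deleterious", "tolerated")),
    polyphen2 = pick(c("probably_damaging", "possibly_damaging", "benign")),
    mutation_taster = pick(c("disease_causing_automatic", "disease_causing",
                             "polymorphism")),
    provean = pick(c("deleterious", "neutral")),
    cadd_phred = ifelse(stats::runif(n) < 0.2, NA_real_,
                        stats::runif(n, 0, 40)),
    stringsAsFactors = FALSE
  )
}
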