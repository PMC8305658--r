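test_that("ped6 trio parses into one family with one affected member", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("T1 FA 0 0 1 1",
               "T1 MO 0 0 2 1",
               "T1 CH FA MO 1 2"), path)
  cohort <- read_pedigree(path, dialect = "ped6")
  expect_length(cohort$families, 1)
  fam <- cohort$families[["T1"]]
  expect_equal(nrow(fam$members), 3)
  expect_equal(sum(fam$members$phenotypes == "PDAC"), 1)
  expect_equal(fam$members$father_id[3], "FA")
})

test_that("the MAP3K3/ACAD9 family fixture has 7 genotyped members, 2 pancreatic-affected", {
  fx <- fixture_bundle()
  cohort <- read_pedigree(fx$paths$pedigree)
  fam <- cohort$families[["25-4-46"]]
  expect_equal(nrow(fam$members), 7)
  expect_true(all(fam$members$has_blood_dna))
  n_panc <- sum(vapply(fam$members$phenotypes, function(p)
    any(strsplit(p, ";")[[1]] %in% c("PDAC", "precursor_high_grade")),
    logical(1)))
  expect_equal(n_panc, 2)
})

test_that("extended PED write/read round trip is lossless", {
  set.seed(11)
  for (rep in 1:3) {
    fam <- simulate_pedigree(simulation_config(seed = NULL),
                             family_id = sprintf("RT-%d", rep))
    cohort <- fpc_cohort(list(fam), label = "rt")
    path <- withr::local_tempfile(fileext = ".ped")
    write_pedigree(cohort, path)
    back <- read_pedigree(path)
    m1 <- fam$members[order(fam$members$individual_id), ]
    m2 <- back$families[[fam$family_id]]$members
    m2 <- m2[order(m2$individual_id), ]
    rownames(m1) <- rownames(m2) <- NULL
    expect_equal(m2, m1)
    expect_equal(back$families[[fam$family_id]]$family_type, fam$family_type)
  }
})

test_that("parse errors name the offending line and cycles are rejected", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c(paste(c("family_id", "individual_id", "father_id", "mother_id",
                       "sex", "phenotypes", "age_years", "age_kind",
                       "blood_dna", "tumor_dna", "deceased", "family_type"),
                     collapse = "\t"),
               "F1\tA\t0\t0\t1\t.\t.\t.\t1\t0\t0\tFPC",
               "F1\tB\tNOPE\t0\t1\t.\t.\t.\t1\t0\t0\tFPC"), path)
  expect_error(read_pedigree(path), "line 3.*NOPE")

  expect_error(
    fpc_family("C1", pedigree_members(
      c("A", "B"), father_id = c("B", "A"), sex = "male")),
    "cycle")
  expect_error(
    fpc_family("S1", pedigree_members(
      c("A", "B"), father_id = c(NA, "A"), sex = c("female", "male"))),
    "not recorded as male")
})

test_that("first-degree relatives are parents, children and full siblings only", {
  trio <- nuclear_family(1, 0)
  expect_setequal(first_degree_relatives(trio, "K01"), c("FA", "MO"))

  # founder with spouse and three children: children only
  fam <- fpc_family("F2", rbind(
    pedigree_members("P1", sex = "male"),
    pedigree_members("P2", sex = "female"),
    pedigree_members(c("C1", "C2", "C3"), father_id = "P1",
                     mother_id = "P2", sex = "female")))
  expect_setequal(first_degree_relatives(fam, "P1"), c("C1", "C2", "C3"))

  # half-siblings (only one shared parent) are excluded
  half <- fpc_family("F3", rbind(
    pedigree_members("P1", sex = "male"),
    pedigree_members(c("M1", "M2"), sex = "female"),
    pedigree_members("C1", father_id = "P1", mother_id = "M1", sex = "male"),
    pedigree_members("C2", father_id = "P1", mother_id = "M2", sex = "male")))
  expect_false("C2" %in% first_degree_relatives(half, "C1"))

  expect_error(first_degree_relatives(trio, "nobody"), "not found")
})

test_that("first_degree_relatives matches brute-force enumeration and is symmetric", {
  set.seed(21)
  for (rep in 1:5) {
    fam <- random_family(20, sprintf("R%d", rep))
    m <- fam$members
    ids <- m$individual_id
    brute <- function(id) {
      i <- match(id, ids)
      rel <- character(0)
      for (j in seq_along(ids)) {
        if (j == i) next
        parent_of_i <- ids[j] %in% c(m$father_id[i], m$mother_id[i])
        child_of_i <- !is.na(m$father_id[j]) && m$father_id[j] == id ||
          !is.na(m$mother_id[j]) && m$mother_id[j] == id
        full_sib <- !is.na(m$father_id[i]) && !is.na(m$mother_id[i]) &&
          !is.na(m$father_id[j]) && !is.na(m$mother_id[j]) &&
          m$father_id[i] == m$father_id[j] && m$mother_id[i] == m$mother_id[j]
        if (parent_of_i || child_of_i || full_sib) rel <- c(rel, ids[j])
      }
      sort(unique(rel))
    }
    fdr <- lapply(ids, function(id) first_degree_relatives(fam, id))
    names(fdr) <- ids
    for (id in ids) expect_equal(fdr[[id]], brute(id))
    # symmetry: b in FDR(a) <=> a in FDR(b)
    for (a in ids) for (b in fdr[[a]]) expect_true(a %in% fdr[[b]])
  }
})

test_that("FPC definition requires a first-degree pair of PDAC cases", {
  fam <- fpc_family("D1", rbind(
    pedigree_members("FA", sex = "male", phenotypes = "PDAC"),
    pedigree_members("MO", sex = "female"),
    pedigree_members("SON", father_id = "FA", mother_id = "MO",
                     sex = "male", phenotypes = "PDAC")))
  expect_true(meets_fpc_definition(fam))

  # two affected first cousins only: not first-degree
  cousins <- fpc_family("D2", rbind(
    pedigree_members(c("GF"), sex = "male"),
    pedigree_members(c("GM"), sex = "female"),
    pedigree_members(c("U1", "U2"), father_id = "GF", mother_id = "GM",
                     sex = "male"),
    pedigree_members(c("W1", "W2"), sex = "female"),
    pedigree_members("C1", father_id = "U1", mother_id = "W1",
                     sex = "male", phenotypes = "PDAC"),
    pedigree_members("C2", father_id = "U2", mother_id = "W2",
                     sex = "male", phenotypes = "PDAC")))
  expect_false(meets_fpc_definition(cousins))

  single <- nuclear_family(1, 2)
  expect_false(meets_fpc_definition(single))
})

test_that("FPC definition is monotone under adding PDAC phenotypes", {
  set.seed(31)
  for (rep in 1:20) {
    fam <- random_family(12)
    before <- meets_fpc_definition(fam)
    i <- sample.int(12, 1)
    ph <- fam$members$phenotypes[i]
    fam$members$phenotypes[i] <-
      if (ph == "") "PDAC" else paste(sort(unique(c(strsplit(ph, ";")[[1]],
                                                    "PDAC"))), collapse = ";")
    after <- meets_fpc_definition(fam)
    expect_true(!before || after)
  }
})

test_that("sequencing inclusion verdicts match an independent re-count", {
  # worked example: 3 PDAC (2 with blood DNA) + 2 unaffected with DNA
  fam <- fpc_family("W1", rbind(
    pedigree_members("FA", sex = "male", phenotypes = "PDAC",
                     has_blood_dna = FALSE),
    pedigree_members("MO", sex = "female"),
    pedigree_members(c("A1", "A2"), father_id = "FA", mother_id = "MO",
                     sex = "male", phenotypes = "PDAC"),
    pedigree_members("U1", father_id = "FA", mother_id = "MO",
                     sex = "female")))
  res <- meets_wgs_inclusion(fam)
  expect_true(res$eligible)
  expect_length(res$reasons, 0)

  two <- nuclear_family(2, 3)
  res2 <- meets_wgs_inclusion(two)
  expect_false(res2$eligible)
  expect_true("affected_count<3" %in% res2$reasons)

  flagged <- fpc_family("W2", fam$members,
                        known_predisposition_mutation = TRUE)
  expect_false(meets_wgs_inclusion(flagged)$eligible)

  set.seed(41)
  for (rep in 1:200) {
    rf <- random_family(sample(4:15, 1))
    got <- meets_wgs_inclusion(rf)
    m <- rf$members
    has <- function(p, tok) tok %in% strsplit(p, ";")[[1]]
    pdac <- vapply(m$phenotypes, has, logical(1), "PDAC")
    aff <- pdac | vapply(m$phenotypes, has, logical(1), "precursor_high_grade")
    unaff <- m$phenotypes == ""
    want <- sum(pdac) >= 3 && sum(aff & m$has_blood_dna) >= 2 &&
      sum(unaff & m$has_blood_dna) >= 2
    expect_identical(got$eligible, want)
  }
})
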