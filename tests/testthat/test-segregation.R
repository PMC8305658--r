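test_that("the SUFU family shows incomplete penetrance with three elderly exemptions", {
  fx <- fixture_bundle()
  fam <- fx$cohort$families[["25-5-67"]]
  g <- fixture_genotypes(fx, "25-5-67", "SUFU")
  res <- evaluate_segregation(fam, g)
  expect_equal(res$verdict, "incomplete_penetrance")
  expect_equal(res$affected_carriers, 7)
  expect_equal(res$affected_genotyped, 7)
  expect_equal(res$exempted_unaffected_carriers, 3)
  expect_setequal(res$exemptions$age_years, c(84, 87, 90))
  expect_true(all(res$exemptions$tag == "elderly_carrier"))
})

test_that("the FANCM variant fails pancreatic segregation but tracks breast cancer", {
  fx <- fixture_bundle()
  fam <- fx$cohort$families[["25-5-67"]]
  g <- fixture_genotypes(fx, "25-5-67", "FANCM")
  res <- evaluate_cross_phenotype(
    fam, g,
    phenotypes = list(phenotype_spec(),
                      phenotype_spec("breast_cancer", "breast_cancer")),
    rule = penetrance_rule(max_affected_noncarriers = 1))
  expect_equal(res$pancreatic_disease$verdict, "fails")
  expect_equal(res$breast_cancer$affected_carriers, 4)
  expect_equal(res$breast_cancer$affected_genotyped, 5)
  expect_equal(res$breast_cancer$unaffected_carriers, 0)
  expect_false(res$breast_cancer$verdict == "fails")
  # under the default zero-phenocopy rule even breast segregation fails
  strict <- evaluate_segregation(fam, g,
                                 phenotype_spec("breast_cancer",
                                                "breast_cancer"))
  expect_equal(strict$verdict, "fails")
})

test_that("the MAP3K3 family segregates completely", {
  fx <- fixture_bundle()
  fam <- fx$cohort$families[["25-4-46"]]
  res <- evaluate_segregation(fam, fixture_genotypes(fx, "25-4-46", "MAP3K3"))
  expect_equal(res$verdict, "complete")
  expect_equal(res$affected_carriers, 2)
  expect_equal(res$unaffected_carriers, 0)
})

test_that("degenerate segregation inputs produce verdicts with notes", {
  fam <- nuclear_family(1, 2)
  kids <- grep("^K", fam$members$individual_id, value = TRUE)
  # single affected non-carrier
  g <- stats::setNames(c("hom_ref", "het", "hom_ref"), kids)
  expect_equal(evaluate_segregation(fam, g)$verdict, "fails")
  # carried by nobody
  g0 <- stats::setNames(rep("hom_ref", 3), kids)
  r0 <- evaluate_segregation(fam, g0)
  expect_equal(r0$verdict, "fails")
  expect_true("no_carriers" %in% r0$notes)
  # no genotyped affected
  g1 <- stats::setNames(c(NA, "het", "hom_ref"), kids)
  r1 <- evaluate_segregation(fam, g1)
  expect_equal(r1$verdict, "fails")
  expect_true("no_informative_affected" %in% r1$notes)
  # unknown individual
  expect_error(evaluate_segregation(fam, c(ghost = "het")), "unknown")
})

test_that("ungenotyped members never change a segregation result", {
  set.seed(201)
  for (rep in 1:10) {
    fam <- nuclear_family(sample(1:3, 1), sample(1:4, 1),
                          ages = sample(30:90, 1))
    kids <- grep("^K", fam$members$individual_id, value = TRUE)
    g <- stats::setNames(sample(c("hom_ref", "het"), length(kids),
                                replace = TRUE), kids)
    before <- evaluate_segregation(fam, g)
    fam2 <- fam
    fam2$members <- rbind(fam$members, pedigree_members(
      "EXTRA", father_id = "FA", mother_id = "MO", sex = "male",
      phenotypes = sample(c("", "PDAC"), 1)))
    after <- evaluate_segregation(fam2, g)
    before$family_id <- after$family_id <- NULL
    expect_equal(after, before)
  }
})

test_that("disallowing unaffected carriers restricts verdicts to complete/fails", {
  set.seed(211)
  strict <- penetrance_rule(allow_unaffected_carriers = FALSE)
  for (rep in 1:20) {
    fam <- nuclear_family(sample(1:3, 1), sample(1:4, 1))
    kids <- grep("^K", fam$members$individual_id, value = TRUE)
    g <- stats::setNames(sample(c("hom_ref", "het", NA), length(kids),
                                replace = TRUE), kids)
    res_default <- evaluate_segregation(fam, g)
    res_strict <- evaluate_segregation(fam, g, rule = strict)
    expect_true(res_strict$verdict %in% c("complete", "fails"))
    if (res_default$verdict == "complete") {
      expect_equal(res_strict$verdict, "complete")
    }
  }
})

test_that("probability of a complete verdict under random carriage matches the closed form", {
  # exhaustive enumeration over all 2^(a+u) het assignments
  for (sizes in list(c(1, 2), c(2, 3), c(3, 4), c(4, 6))) {
    a <- sizes[1]; u <- sizes[2]
    fam <- nuclear_family(a, u, ages = 75)
    kids <- grep("^K", fam$members$individual_id, value = TRUE)
    n <- a + u
    n_complete <- 0L
    for (mask in 0:(2^n - 1)) {
      carrier <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      g <- stats::setNames(ifelse(carrier, "het", "hom_ref"), kids)
      res <- evaluate_segregation(fam, g)
      if (res$verdict == "complete") n_complete <- n_complete + 1L
    }
    expect_equal(n_complete / 2^n, 0.5^a * 0.5^u)
    expect_equal(n_complete, 1L) # only the perfectly co-segregating pattern
  }
})

test_that("Mendelian-consistency flags impossible trios only", {
  fam <- nuclear_family(1, 0)
  # het child of two hom_ref parents
  fam2 <- fam
  fam2$members$has_blood_dna <- TRUE
  v <- mendelian_consistency(fam2, c(FA = "hom_ref", MO = "hom_ref",
                                     K01 = "het"))
  expect_equal(nrow(v), 1)
  expect_equal(v$individual_id, "K01")
  # one parent ungenotyped: cannot exclude transmission
  v2 <- mendelian_consistency(fam2, c(FA = "hom_ref", K01 = "het"))
  expect_equal(nrow(v2), 0)
  # hom_alt child with one hom_ref parent is impossible even if the other
  # parent is unknown
  v3 <- mendelian_consistency(fam2, c(FA = "hom_ref", K01 = "hom_alt"))
  expect_equal(nrow(v3), 1)
  # consistent transmission
  v4 <- mendelian_consistency(fam2, c(FA = "het", MO = "hom_ref",
                                      K01 = "het"))
  expect_equal(nrow(v4), 0)
})

test_that("candidate counting matches per-variant brute force", {
  fx <- fixture_bundle()
  fam <- fx$cohort$families[["25-9-44"]]
  scored <- total_score(fx$annotation)
  carriers <- carrier_families(fx$genotypes, fx$cohort)
  triaged <- triage(scored, carriers)
  cc <- count_cosegregating_candidates(fam, fx$genotypes, triaged)
  expect_equal(cc$n_passing, 3)
  expect_equal(cc$genes, c("DAB1", "FGFBP3", "POLQ"))

  # family with no triaged variants
  empty_fam <- fx$cohort$families[["25-F06"]]
  cc0 <- count_cosegregating_candidates(empty_fam, fx$genotypes, triaged)
  expect_equal(cc0$n_passing, 0)

  # randomized brute force: loop variants, evaluate, count
  set.seed(221)
  for (rep in 1:5) {
    fam_r <- nuclear_family(2, 3)
    kids <- grep("^K", fam_r$members$individual_id, value = TRUE)
    keys <- sprintf("9:%d:A:G", 1:12 * 100)
    gmat <- matrix(sample(c("hom_ref", "het", NA), 12 * 5, replace = TRUE,
                          prob = c(0.5, 0.4, 0.1)),
                   nrow = 12, dimnames = list(keys, kids))
    gset <- structure(list(variants = fpcseg:::parse_variant_key(keys),
                           genotypes = gmat), class = "fpc_genotypes")
    tri <- data.frame(variant_id = keys, gene = sprintf("G%02d", 1:12),
                      stringsAsFactors = FALSE)
    got <- count_cosegregating_candidates(fam_r, gset, tri)
    want <- 0L
    for (k in keys) {
      g <- gmat[k, ]
      names(g) <- kids
      if (!any(g %in% c("het", "hom_alt"))) next
      if (evaluate_segregation(fam_r, g)$verdict != "fails") want <- want + 1L
    }
    expect_equal(got$n_passing, want)
  }
})
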