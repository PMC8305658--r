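# Pedigree data model, PED-dialect I/O, relationship queries, and the
# family-eligibility filters used by the FPC study design.

PED_EXTENDED_COLUMNS <- c("family_id", "individual_id", "father_id", "mother_id",
                          "sex", "phenotypes", "age_years", "age_kind",
                          "blood_dna", "tumor_dna", "deceased", "family_type")

AGE_KINDS <- c("current", "at_diagnosis", "at_death", "missing")

#' Construct a pedigree member table
#'
#' Builds the canonical members data frame used inside [fpc_family()]. Each
#' argument is recycled to the length of `individual_id`.
#'
#' @param individual_id Character ids, unique within the family.
#' @param father_id,mother_id Character ids or `NA` when unknown.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param phenotypes Semicolon-joined phenotype tokens (see
#'   [phenotype_tokens()]); `""` means unaffected.
#' @param age_years Nonnegative age (current, or at diagnosis/death as flagged
#'   by `age_kind`), `NA` when unknown.
#' @param age_kind One of `"current"`, `"at_diagnosis"`, `"at_death"`,
#'   `"missing"`.
#' @param has_blood_dna,has_tumor_dna,deceased Logicals.
#' @return A data frame with one row per individual.
#' @export
pedigree_members <- function(individual_id,
                             father_id = NA_character_,
                             mother_id = NA_character_,
                             sex = "unknown",
                             phenotypes = "",
                             age_years = NA_real_,
                             age_kind = "missing",
                             has_blood_dna = TRUE,
                             has_tumor_dna = FALSE,
                             deceased = FALSE) {
  n <- length(individual_id)
  out <- data.frame(
    individual_id = as.character(individual_id),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(as.character(sex), n),
    phenotypes = rep_len(as.character(phenotypes), n),
    age_years = rep_len(as.numeric(age_years), n),
    age_kind = rep_len(as.character(age_kind), n),
    has_blood_dna = rep_len(as.logical(has_blood_dna), n),
    has_tumor_dna = rep_len(as.logical(has_tumor_dna), n),
    deceased = rep_len(as.logical(deceased), n),
    stringsAsFactors = FALSE
  )
  out
}

#' Family (pedigree) object
#'
#' A family is a pedigree graph over its members plus study-level metadata:
#' the family type and whether a deleterious BRCA1/2, CDKN2A or PALB2 germline
#' mutation was identified in earlier testing (an input flag, never computed
#' here).
#'
#' @param family_id Family identifier, e.g. `"25-9-44"`.
#' @param members Data frame as returned by [pedigree_members()].
#' @param family_type One of `"FPC"`, `"FPC_breast"`, `"PCMS"`, `"other"`.
#' @param known_predisposition_mutation Logical; `TRUE` when prior testing
#'   identified a deleterious mutation in an established predisposition gene.
#' @return An object of class `fpc_family`.
#' @export
fpc_family <- function(family_id, members, family_type = "FPC",
                       known_predisposition_mutation = FALSE) {
  fam <- structure(
    list(family_id = as.character(family_id),
         family_type = match.arg(family_type,
                                 c("FPC", "FPC_breast", "PCMS", "other")),
         known_predisposition_mutation = isTRUE(known_predisposition_mutation),
         members = members),
    class = "fpc_family"
  )
  validate_family(fam)
  fam
}

#' Validate family invariants
#'
#' Checks id uniqueness, parent-reference resolution, parent sexes, phenotype
#' vocabulary, and pedigree acyclicity (no individual is its own ancestor).
#'
#' @param family An `fpc_family`.
#' @return The family, invisibly; errors on violation.
#' @export
validate_family <- function(family) {
  m <- family$members
  if (anyDuplicated(m$individual_id)) {
    stop_fpc("family %s: duplicated individual_id(s): %s", family$family_id,
             paste(unique(m$individual_id[duplicated(m$individual_id)]),
                   collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    refs <- m[[col]]
    bad <- !is.na(refs) & !(refs %in% m$individual_id)
    if (any(bad)) {
      stop_fpc("family %s: unresolved %s reference(s): %s", family$family_id,
               col, paste(unique(refs[bad]), collapse = ", "))
    }
  }
  sex_of <- stats::setNames(m$sex, m$individual_id)
  fa <- m$father_id[!is.na(m$father_id)]
  if (any(sex_of[fa] != "male")) {
    stop_fpc("family %s: father(s) not recorded as male: %s", family$family_id,
             paste(unique(fa[sex_of[fa] != "male"]), collapse = ", "))
  }
  mo <- m$mother_id[!is.na(m$mother_id)]
  if (any(sex_of[mo] != "female")) {
    stop_fpc("family %s: mother(s) not recorded as female: %s",
             family$family_id,
             paste(unique(mo[sex_of[mo] != "female"]), collapse = ", "))
  }
  for (p in m$phenotypes) check_phenotypes(split_phenotypes(p))
  bad_age <- !is.na(m$age_years) & m$age_years < 0
  if (any(bad_age)) stop_fpc("family %s: negative age_years", family$family_id)
  if (!all(m$age_kind %in% AGE_KINDS)) {
    stop_fpc("family %s: invalid age_kind value(s)", family$family_id)
  }
  # acyclicity: climb ancestors from every member; a pedigree with n members
  # has ancestor chains of length < n unless there is a cycle
  parent_of <- stats::setNames(
    lapply(seq_len(nrow(m)),
           function(i) stats::na.omit(c(m$father_id[i], m$mother_id[i]))),
    m$individual_id)
  n <- nrow(m)
  for (id in m$individual_id) {
    frontier <- parent_of[[id]]
    depth <- 0L
    while (length(frontier) > 0) {
      depth <- depth + 1L
      if (id %in% frontier || depth > n) {
        stop_fpc("family %s: pedigree cycle involving individual %s",
                 family$family_id, id)
      }
      frontier <- unique(unlist(parent_of[frontier], use.names = FALSE))
    }
  }
  invisible(family)
}

#' Cohort of families
#'
#' @param families List of [fpc_family()] objects.
#' @param label Optional cohort label.
#' @return An object of class `fpc_cohort`; `families` is a named list keyed
#'   by family id.
#' @export
fpc_cohort <- function(families, label = "") {
  ids <- vapply(families, function(f) f$family_id, character(1))
  if (anyDuplicated(ids)) {
    stop_fpc("duplicated family_id(s) in cohort: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(label = as.character(label),
                 families = stats::setNames(families, ids)),
            class = "fpc_cohort")
}

#' @export
print.fpc_family <- function(x, ...) {
  n_aff <- sum(vapply(x$members$phenotypes, function(p)
    has_any_phenotype(p, c("PDAC", "precursor_high_grade")), logical(1)))
  cat(sprintf("<fpc_family> %s (%s): %d members, %d pancreatic-affected\n",
              x$family_id, x$family_type, nrow(x$members), n_aff))
  invisible(x)
}

#' @export
print.fpc_cohort <- function(x, ...) {
  cat(sprintf("<fpc_cohort> %s: %d families, %d individuals\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$families),
              sum(vapply(x$families, function(f) nrow(f$members), integer(1)))))
  invisible(x)
}

#' All members of a cohort as one table
#'
#' @param cohort An `fpc_cohort`.
#' @return Data frame with a `family_id` column prepended to the member fields.
#' @export
cohort_members <- function(cohort) {
  do.call(rbind, lapply(unname(cohort$families), function(f) {
    cbind(data.frame(family_id = rep(f$family_id, nrow(f$members)),
                     stringsAsFactors = FALSE),
          f$members,
          data.frame(family_type = rep(f$family_type, nrow(f$members)),
                     stringsAsFactors = FALSE))
  }))
}

## ---- PED I/O -------------------------------------------------------------

#' Read a pedigree file
#'
#' Two dialects are supported. `"ped6"` is the standard 6-column linkage PED
#' file (family, individual, father, mother, sex, status) where status 2 is
#' read as PDAC-affected and anything else as unaffected. `"ped_extended"` is
#' a tab-separated dialect with a mandatory header and columns
#' `family_id individual_id father_id mother_id sex phenotypes age_years
#' age_kind blood_dna tumor_dna deceased`; `phenotypes` holds semicolon-joined
#' tokens. Missing parents are coded `0` (PED convention) and other missing
#' values `.`.
#'
#' @param path File path (UTF-8, whitespace/tab delimited).
#' @param dialect `"ped_extended"` (default) or `"ped6"`.
#' @param label Cohort label.
#' @return An [fpc_cohort()].
#' @export
read_pedigree <- function(path, dialect = c("ped_extended", "ped6"),
                          label = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fpc("pedigree file not found: %s", path)
  if (dialect == "ped6") {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character", comment.char = "#")
    if (ncol(raw) != 6) {
      stop_fpc("ped6 file must have 6 columns, found %d", ncol(raw))
    }
    names(raw) <- c("family_id", "individual_id", "father_id", "mother_id",
                    "sex", "status")
    df <- data.frame(
      family_id = raw$family_id,
      individual_id = raw$individual_id,
      father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
      mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
      sex = c("1" = "male", "2" = "female")[raw$sex],
      phenotypes = ifelse(raw$status == "2", "PDAC", ""),
      age_years = NA_real_,
      age_kind = "missing",
      has_blood_dna = TRUE,
      has_tumor_dna = FALSE,
      deceased = FALSE,
      stringsAsFactors = FALSE
    )
    df$sex[is.na(df$sex)] <- "unknown"
    df$line <- seq_len(nrow(df)) # no header line
  } else {
    raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = NULL)
    if (!("family_type" %in% names(raw))) raw$family_type <- "FPC"
    missing_cols <- setdiff(PED_EXTENDED_COLUMNS, names(raw))
    if (length(missing_cols) > 0) {
      stop_fpc("ped_extended file %s lacks column(s): %s", path,
               paste(missing_cols, collapse = ", "))
    }
    dot_na <- function(x) ifelse(x == ".", NA_character_, x)
    df <- data.frame(
      family_id = raw$family_id,
      individual_id = raw$individual_id,
      father_id = ifelse(raw$father_id == "0", NA_character_, raw$father_id),
      mother_id = ifelse(raw$mother_id == "0", NA_character_, raw$mother_id),
      sex = c("1" = "male", "2" = "female", "0" = "unknown")[raw$sex],
      phenotypes = ifelse(raw$phenotypes == ".", "", raw$phenotypes),
      age_years = suppressWarnings(as.numeric(dot_na(raw$age_years))),
      age_kind = ifelse(raw$age_kind == ".", "missing", raw$age_kind),
      has_blood_dna = dot_na(raw$blood_dna) == "1",
      has_tumor_dna = dot_na(raw$tumor_dna) == "1",
      deceased = dot_na(raw$deceased) == "1",
      family_type = raw$family_type,
      stringsAsFactors = FALSE
    )
    df$sex[is.na(df$sex)] <- "unknown"
    df$line <- seq_len(nrow(df)) + 1L # account for header line
  }
  # structured parse check: every parent reference must resolve within family
  families <- lapply(split(df, df$family_id), function(sub) {
    for (col in c("father_id", "mother_id")) {
      refs <- sub[[col]]
      bad <- which(!is.na(refs) & !(refs %in% sub$individual_id))
      if (length(bad) > 0) {
        stop_fpc("%s line %d: %s '%s' of individual '%s' not found in family %s",
                 path, sub$line[bad[1]], sub("_id$", "", col),
                 refs[bad[1]], sub$individual_id[bad[1]], sub$family_id[1])
      }
    }
    fam_id <- sub$family_id[1]
    fam_type <- if ("family_type" %in% names(sub)) sub$family_type[1] else "FPC"
    sub$family_id <- NULL
    sub$line <- NULL
    sub$family_type <- NULL
    rownames(sub) <- NULL
    fpc_family(fam_id, sub, family_type = fam_type)
  })
  # preserve file order of first appearance rather than split()'s sorting
  order_ids <- unique(df$family_id)
  fpc_cohort(families[order_ids], label = label)
}

#' Write a cohort in the extended PED dialect
#'
#' Inverse of [read_pedigree()] for `dialect = "ped_extended"`; the round trip
#' is lossless for all member fields.
#'
#' @param cohort An `fpc_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(cohort, path) {
  df <- cohort_members(cohort)
  if (is.null(df)) {
    df <- cbind(data.frame(family_id = character(0)),
                pedigree_members(character(0)),
                data.frame(family_type = character(0)))
  }
  out <- data.frame(
    family_id = df$family_id,
    individual_id = df$individual_id,
    father_id = ifelse(is.na(df$father_id), "0", df$father_id),
    mother_id = ifelse(is.na(df$mother_id), "0", df$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[df$sex],
    phenotypes = ifelse(df$phenotypes == "", ".", df$phenotypes),
    age_years = ifelse(is.na(df$age_years), ".",
                       format(df$age_years, trim = TRUE, scientific = FALSE)),
    age_kind = ifelse(df$age_kind == "missing", ".", df$age_kind),
    blood_dna = ifelse(df$has_blood_dna, "1", "0"),
    tumor_dna = ifelse(df$has_tumor_dna, "1", "0"),
    deceased = ifelse(df$deceased, "1", "0"),
    family_type = df$family_type,
    stringsAsFactors = FALSE
  )
  names(out) <- PED_EXTENDED_COLUMNS
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## ---- relationship queries and eligibility --------------------------------

#' First-degree relatives of an individual
#'
#' Parents, children, and full siblings (both parents shared and known).
#' Spouses and half-siblings are not first-degree relatives.
#'
#' @param family An `fpc_family`.
#' @param individual_id Member id.
#' @return Character vector of member ids (possibly empty), sorted.
#' @export
first_degree_relatives <- function(family, individual_id) {
  m <- family$members
  i <- match(individual_id, m$individual_id)
  if (is.na(i)) {
    stop_fpc("individual '%s' not found in family %s", individual_id,
             family$family_id)
  }
  parents <- stats::na.omit(c(m$father_id[i], m$mother_id[i]))
  children <- m$individual_id[
    (!is.na(m$father_id) & m$father_id == individual_id) |
    (!is.na(m$mother_id) & m$mother_id == individual_id)]
  sibs <- character(0)
  if (length(parents) == 2) {
    full <- !is.na(m$father_id) & !is.na(m$mother_id) &
      m$father_id == m$father_id[i] & m$mother_id == m$mother_id[i]
    sibs <- setdiff(m$individual_id[full], individual_id)
  }
  sort(unique(c(as.character(parents), children, sibs)))
}

#' Does a family meet the clinical FPC definition?
#'
#' TRUE iff some pair of PDAC-affected members are first-degree relatives of
#' each other ("two or more first-degree relatives with a confirmed diagnosis
#' of PDAC").
#'
#' @param family An `fpc_family`.
#' @return Logical scalar.
#' @export
meets_fpc_definition <- function(family) {
  m <- family$members
  pdac <- m$individual_id[vapply(m$phenotypes, function(p)
    has_any_phenotype(p, "PDAC"), logical(1))]
  if (length(pdac) < 2) return(FALSE)
  for (id in pdac) {
    if (length(intersect(first_degree_relatives(family, id), pdac)) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

#' Sequencing-study inclusion criteria
#'
#' A family is eligible when it has at least 3 PDAC-affected members, blood
#' DNA from at least two pancreatic-affected (PDAC or high-grade precursor)
#' and two unaffected members, and no previously identified deleterious
#' mutation in an established predisposition gene (the
#' `known_predisposition_mutation` input flag).
#'
#' @param family An `fpc_family`.
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
meets_wgs_inclusion <- function(family) {
  m <- family$members
  pdac_n <- sum(vapply(m$phenotypes, function(p)
    has_any_phenotype(p, "PDAC"), logical(1)))
  aff <- vapply(m$phenotypes, function(p)
    has_any_phenotype(p, c("PDAC", "precursor_high_grade")), logical(1))
  unaff <- vapply(m$phenotypes, is_unaffected, logical(1))
  reasons <- character(0)
  if (pdac_n < 3) reasons <- c(reasons, "affected_count<3")
  if (sum(aff & m$has_blood_dna) < 2) {
    reasons <- c(reasons, "affected_with_blood_dna<2")
  }
  if (sum(unaff & m$has_blood_dna) < 2) {
    reasons <- c(reasons, "unaffected_with_blood_dna<2")
  }
  if (family$known_predisposition_mutation) {
    reasons <- c(reasons, "known_predisposition_mutation")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}
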