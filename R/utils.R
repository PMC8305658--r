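# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phenotype vocabulary
#'
#' Closed set of phenotype tokens used throughout the package. An individual
#' with an empty phenotype set is unaffected.
#'
#' @return Character vector of valid phenotype tokens.
#' @export
phenotype_tokens <- function() {
  c("PDAC", "precursor_high_grade", "breast_cancer", "melanoma",
    "leukemia", "other_cancer")
}

# Split a semicolon-joined phenotype string into a character vector.
# "" and "." mean unaffected (empty set).
split_phenotypes <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(character(0))
  sort(unique(strsplit(x, ";", fixed = TRUE)[[1]]))
}

# Join a phenotype vector back to canonical string form (sorted, unique).
join_phenotypes <- function(x) {
  if (length(x) == 0) return("")
  paste(sort(unique(x)), collapse = ";")
}

check_phenotypes <- function(x, where = "phenotypes") {
  bad <- setdiff(x, phenotype_tokens())
  if (length(bad) > 0) {
    stop(sprintf("unknown phenotype token(s) in %s: %s",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Does this member row carry any of the target phenotypes?
has_any_phenotype <- function(pheno_string, targets) {
  length(intersect(split_phenotypes(pheno_string), targets)) > 0
}

is_unaffected <- function(pheno_string) {
  length(split_phenotypes(pheno_string)) == 0
}

stop_fpc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fpc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
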