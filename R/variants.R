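# Variant and genotype I/O plus ingestion of the five-predictor annotation
# table (frozen output of external annotation tools; running those tools is
# out of scope).

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt")

SIFT_LEVELS <- c("deleterious", "tolerated")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign")
MT_LEVELS <- c("disease_causing_automatic", "disease_causing", "polymorphism")
PROVEAN_LEVELS <- c("deleterious", "neutral")
CONSEQUENCE_LEVELS <- c("missense", "splice_site", "promoter", "synonymous",
                        "other")

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` identity string after reducing alleles to
#' their minimal representation (shared suffix, then shared prefix, trimmed
#' with position adjustment) so VCF records and annotation rows key
#' identically.
#'
#' @param chrom Chromosome string.
#' @param pos 1-based position.
#' @param ref,alt Allele strings (uppercased; `ref != alt`).
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (any(pos < 1, na.rm = TRUE)) stop_fpc("variant position must be >= 1")
  if (any(ref == alt)) stop_fpc("ref and alt alleles must differ")
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    if (grepl("[^ACGT]", r) || grepl("[^ACGT]", a)) next # symbolic alleles
    # trim shared suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim shared prefix, advancing pos
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  sprintf("%s:%d:%s:%s", chrom, pos, ref, alt)
}

parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    variant_id = key,
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE
  )
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) and returns per-variant genotype
#' calls for the individuals of `cohort`. Multiallelic records are split into
#' one variant per alternate allele; a sample's genotype against each alt is
#' the count of that alt among its called alleles (so a `1/2` sample is `het`
#' for both alts), which conserves summed alt dosages across the split.
#'
#' @param path VCF file.
#' @param cohort An [fpc_cohort()] whose member ids match the VCF sample
#'   names. Ids must be unique across the cohort.
#' @param strict If `TRUE`, a VCF sample absent from the cohort is an error;
#'   otherwise it is skipped with a warning.
#' @return Object of class `fpc_genotypes`: list with `variants` (data frame
#'   `variant_id, chrom, pos, ref, alt`) and `genotypes` (character matrix,
#'   variants x individuals, values `hom_ref`/`het`/`hom_alt`/`NA`).
#' @export
read_vcf_genotypes <- function(path, cohort, strict = FALSE) {
  if (!file.exists(path)) stop_fpc("VCF file not found: %s", path)
  members <- cohort_members(cohort)
  ids <- members$individual_id
  if (anyDuplicated(ids)) {
    stop_fpc("individual id(s) duplicated across families (VCF sample names must be cohort-unique): %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_genotypes(ids))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  unknown <- setdiff(samples, ids)
  if (length(unknown) > 0) {
    if (strict) {
      stop_fpc("VCF sample(s) absent from cohort: %s",
               paste(unknown, collapse = ", "))
    }
    warn_fpc("skipping VCF sample(s) absent from cohort: %s",
             paste(unknown, collapse = ", "))
    samples <- setdiff(samples, unknown)
  }
  rows <- list()
  gts <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- lapply(gt_raw[r, samples], function(g) {
      if (is.na(g)) return(NULL)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == ".")) return(NULL)
      as.integer(a)
    })
    for (k in seq_along(alts)) {
      key <- variant_key(fix[r, "CHROM"], as.integer(fix[r, "POS"]),
                         fix[r, "REF"], alts[k])
      dosage <- vapply(alleles, function(a) {
        if (is.null(a)) return(NA_integer_)
        sum(a == k)
      }, integer(1))
      rows[[length(rows) + 1L]] <- key
      gts[[length(gts) + 1L]] <-
        ifelse(is.na(dosage), NA_character_, GENOTYPE_LEVELS[dosage + 1L])
    }
  }
  keys <- unlist(rows)
  if (anyDuplicated(keys)) {
    stop_fpc("duplicate variant key(s) after normalization: %s",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  mat <- matrix(NA_character_, nrow = length(keys), ncol = length(ids),
                dimnames = list(keys, ids))
  if (length(samples) > 0) {
    mat[, samples] <- do.call(rbind, gts)
  }
  structure(list(variants = parse_variant_key(keys), genotypes = mat),
            class = "fpc_genotypes")
}

empty_genotypes <- function(ids) {
  structure(list(
    variants = parse_variant_key(character(0)),
    genotypes = matrix(NA_character_, nrow = 0, ncol = length(ids),
                       dimnames = list(NULL, ids))),
    class = "fpc_genotypes")
}

#' @export
print.fpc_genotypes <- function(x, ...) {
  cat(sprintf("<fpc_genotypes> %d variants x %d individuals\n",
              nrow(x$variants), ncol(x$genotypes)))
  invisible(x)
}

#' Write genotypes as a plain-text VCF
#'
#' Minimal VCF 4.2 writer (GT field only), the inverse of
#' [read_vcf_genotypes()] for biallelic records.
#'
#' @param gset An `fpc_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gset, path) {
  v <- gset$variants
  samples <- colnames(gset$genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  ord <- order(v$chrom, v$pos, v$ref, v$alt, method = "radix")
  body <- vapply(ord, function(i) {
    g <- gset$genotypes[i, ]
    gt <- ifelse(is.na(g), "./.", code[g])
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Default predictor code maps
#'
#' Maps the single-letter codes used in annotation tables (the dbNSFP/ANNOVAR
#' convention) to the package's categorical calls. Override entries to match
#' other annotation exports (e.g. a different PolyPhen-2 model).
#'
#' @return Named list of named character vectors, one per predictor.
#' @export
default_code_maps <- function() {
  list(
    sift = c(D = "deleterious", T = "tolerated"),
    polyphen2 = c(D = "probably_damaging", P = "possibly_damaging",
                  B = "benign"),
    mutation_taster = c(A = "disease_causing_automatic", D = "disease_causing",
                        N = "polymorphism", P = "polymorphism"),
    provean = c(D = "deleterious", N = "neutral")
  )
}

#' Read the per-variant annotation table
#'
#' Tab-separated table with header columns `chrom pos ref alt gene consequence
#' hgvs_c hgvs_p sift polyphen2 mutation_taster provean cadd_phred
#' population_af`. Predictor columns carry single-letter codes (see
#' [default_code_maps()]); `.` denotes missing. Unknown codes are normalized
#' to missing with a warning; duplicate variant keys and unparseable CADD or
#' allele-frequency values are errors naming the offending row.
#'
#' @param path Annotation TSV.
#' @param code_maps Code maps, as [default_code_maps()].
#' @return Data frame keyed by `variant_id`, with normalized predictor calls,
#'   `cadd_phred`, `population_af`, plus `af_band` and `band_imputed` (TRUE
#'   when the band was assigned by the missing-AF convention).
#' @export
read_annotation_table <- function(path, code_maps = default_code_maps()) {
  if (!file.exists(path)) stop_fpc("annotation table not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "hgvs_c", "hgvs_p", "sift", "polyphen2", "mutation_taster",
                "provean", "cadd_phred", "population_af")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_fpc("annotation table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  key <- if (n > 0) {
    variant_key(raw$chrom, as.integer(raw$pos), raw$ref, raw$alt)
  } else character(0)
  if (anyDuplicated(key)) {
    stop_fpc("duplicate variant key(s) in annotation table: %s",
             paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  decode <- function(col, map) {
    out <- rep(NA_character_, n)
    known <- raw[[col]] %in% names(map)
    out[known] <- unname(map[raw[[col]][known]])
    odd <- !known & raw[[col]] != "."
    if (any(odd)) {
      warn_fpc("annotation table: unknown %s code(s) treated as missing: %s",
               col, paste(unique(raw[[col]][odd]), collapse = ", "))
    }
    out
  }
  num_col <- function(col, lo = -Inf, hi = Inf) {
    out <- rep(NA_real_, n)
    present <- raw[[col]] != "."
    val <- suppressWarnings(as.numeric(raw[[col]][present]))
    if (anyNA(val)) {
      bad_row <- which(present)[which(is.na(val))[1]]
      stop_fpc("annotation table row %d: malformed %s value '%s'",
               bad_row, col, raw[[col]][bad_row])
    }
    if (any(val < lo | val > hi)) {
      bad_row <- which(present)[which(val < lo | val > hi)[1]]
      stop_fpc("annotation table row %d: %s out of range", bad_row, col)
    }
    out[present] <- val
    out
  }
  cons <- raw$consequence
  odd_cons <- !(cons %in% CONSEQUENCE_LEVELS)
  if (any(odd_cons)) {
    warn_fpc("annotation table: unknown consequence value(s) set to 'other': %s",
             paste(unique(cons[odd_cons]), collapse = ", "))
    cons[odd_cons] <- "other"
  }
  af <- num_col("population_af", 0, 1)
  band <- af_band(af)
  out <- data.frame(
    variant_id = key,
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    ref = toupper(raw$ref),
    alt = toupper(raw$alt),
    gene = raw$gene,
    consequence = cons,
    hgvs_c = ifelse(raw$hgvs_c == ".", NA_character_, raw$hgvs_c),
    hgvs_p = ifelse(raw$hgvs_p == ".", NA_character_, raw$hgvs_p),
    sift = decode("sift", code_maps$sift),
    polyphen2 = decode("polyphen2", code_maps$polyphen2),
    mutation_taster = decode("mutation_taster", code_maps$mutation_taster),
    provean = decode("provean", code_maps$provean),
    cadd_phred = num_col("cadd_phred", 0, Inf),
    population_af = af,
    af_band = as.character(band),
    band_imputed = attr(band, "band_imputed"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]; categorical calls are re-encoded to
#' the single-letter codes of `code_maps`.
#'
#' @param annot Data frame in the layout returned by
#'   [read_annotation_table()].
#' @param path Output TSV path.
#' @param code_maps Code maps, as [default_code_maps()].
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annot, path,
                                   code_maps = default_code_maps()) {
  encode <- function(x, map) {
    rev_map <- stats::setNames(names(map), unname(map))
    ifelse(is.na(x), ".", rev_map[x])
  }
  fmt_num <- function(x) {
    ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE,
                                 digits = 10))
  }
  out <- data.frame(
    chrom = annot$chrom,
    pos = annot$pos,
    ref = annot$ref,
    alt = annot$alt,
    gene = annot$gene,
    consequence = annot$consequence,
    hgvs_c = ifelse(is.na(annot$hgvs_c), ".", annot$hgvs_c),
    hgvs_p = ifelse(is.na(annot$hgvs_p), ".", annot$hgvs_p),
    sift = encode(annot$sift, code_maps$sift),
    polyphen2 = encode(annot$polyphen2, code_maps$polyphen2),
    mutation_taster = encode(annot$mutation_taster, code_maps$mutation_taster),
    provean = encode(annot$provean, code_maps$provean),
    cadd_phred = fmt_num(annot$cadd_phred),
    population_af = fmt_num(annot$population_af),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Allele-frequency band
#'
#' Classifies population allele frequencies into the bands used for reporting:
#' rare (< 1%), low_frequency (1-5%, lower-inclusive) and common (>= 5%).
#' Missing frequencies are banded `rare` by convention and flagged via the
#' `band_imputed` attribute (novel variants are near-absent from reference
#' panels).
#'
#' @param af Numeric vector of allele frequencies in \[0, 1\] (NA allowed).
#' @return Character vector of bands with attribute `band_imputed` (logical
#'   vector, TRUE where `af` was missing).
#' @export
af_band <- function(af) {
  af <- as.numeric(af)
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop_fpc("allele frequency outside [0, 1]")
  }
  band <- ifelse(is.na(af), "rare",
          ifelse(af < 0.01, "rare",
          ifelse(af < 0.05, "low_frequency", "common")))
  attr(band, "band_imputed") <- is.na(af)
  band
}
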