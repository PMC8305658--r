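---
title: "Methods: variant triage and co-segregation in FPC pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage and co-segregation in FPC pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpcseg)
```

## Scope and model

`fpcseg` implements the analysis stage of a family-based rare-variant
study of familial pancreatic cancer (FPC): given pedigrees with rich
phenotypes, germline genotypes, and a frozen table of in-silico predictor
calls, it scores variants, triages candidates, and renders per-family
co-segregation verdicts under an autosomal-dominant model with incomplete,
age-dependent penetrance. Upstream steps — alignment, variant calling,
running the annotation tools — are deliberately out of scope; their output
is consumed as data, which keeps every analysis fully reproducible offline.

Affectedness is phenotype-set based. The default target set is
*pancreatic disease* = {PDAC, high-grade precursor lesion (PanIN2/3)}:
precursor carriers count as affected because in screened high-risk
families these lesions are the observable expression of the same
predisposition. Members whose only phenotypes fall outside the target set
(a breast-cancer case when evaluating pancreatic disease) count as
unaffected *for that evaluation* but keep their phenotypes, so the same
variant can be evaluated against several phenotype definitions
(`evaluate_cross_phenotype()`); this is how a variant can fail pancreatic
segregation yet track breast cancer in the same family.

## Pedigree model and PED dialect

Standard 6-column PED encodes only a binary status, which cannot express
"precursor lesion" vs "breast cancer" — distinctions the segregation rule
needs. The extended dialect adds fixed, headered columns: semicolon-joined
phenotype tokens, age with an `age_kind` qualifier (current, at diagnosis,
at death), blood/tumor DNA availability, a deceased flag, and the family
type (FPC, FPC-breast, PCMS). Missing parents are `0` (PED convention),
other missing values `.`. The writer inverts the reader exactly; the
round-trip identity is property-tested.

Relationship queries follow conventional clinical-genetics usage:
first-degree relatives are parents, children and *full* siblings — both
parents shared and known. Half-siblings are excluded; the source material
for this design never needed the distinction, so the conservative
definition was chosen. The clinical FPC criterion is then "some pair of
PDAC cases are first-degree relatives of each other", and the
sequencing-eligibility check (≥ 3 PDAC cases, blood DNA from ≥ 2 affected
and ≥ 2 unaffected, no previously identified predisposition-gene mutation)
takes the prior-mutation status as an input flag — it was established by
earlier testing, not computed here. `run_pipeline()` reports eligibility
rather than enforcing it, because encoded fixture families list only the
individuals the study text characterizes and may understate the real
family's case count.

Tumor-tissue genotypes are carried as availability flags but never
substitute for germline calls in segregation: a wild-type tumor read is a
note, not a non-carrier. Obligate-carrier inference for ungenotyped
ancestors is deliberately not performed; unavailable individuals are
simply uninformative, and `affected_genotyped` is reported so callers can
impose stricter requirements.

## Variant identity and annotation

Variants are keyed `chrom:pos:ref:alt` after reducing alleles to minimal
representation (shared suffix, then shared prefix trimmed with position
adjustment), so VCF records and annotation rows key identically.
Left-alignment against a reference genome is not attempted — no interface
in the package takes a FASTA, and minimal representation suffices to match
the package's own I/O. Multiallelic VCF records are split one variant per
alternate allele with genotypes recoded as the count of that allele, which
conserves summed alt dosages (property-tested).

Predictor calls arrive as single-letter codes in the dbNSFP/ANNOVAR
convention, normalized through a configurable code map (`default_code_maps()`)
because different exports differ, e.g. in the PolyPhen-2 model used.
Unknown codes become missing with a warning; malformed numeric fields are
hard errors naming the row. Missing population frequencies are banded
`rare` but flagged `band_imputed`: genuinely novel variants are near-absent
from reference panels, and silently treating them as common would invert
their meaning. Band boundaries are exact: rare < 1%, low-frequency 1–5%
(lower-inclusive), common ≥ 5%.

## Ensemble score and triage

The total score adds one point per damaging vote over SIFT, PolyPhen-2
(possibly-damaging counts by default, the D/P convention), MutationTaster
(either disease-causing class), PROVEAN, and CADD (phred ≥
`cadd_high_cutoff`, default 20). Alongside the score, `n_informative`
counts non-missing votes.

Triage retains a variant on any of three grounds:

* **T1, high score** — `total_score ≥ high_score_threshold`. The threshold
  defaults to 4 of 5, a strict majority-plus; it is config-exposed because
  reasonable studies differ. T1 additionally admits variants with *fewer
  informative predictors than the threshold* when all informative
  predictors (at least `min_informative`, default 2) vote damaging. This
  unanimity rule exists because promoter and splice-site variants are
  outside the scope of the protein-substitution tools: a regulatory
  variant scoreable only by MutationTaster and CADD can never reach 4
  votes, yet two-of-two damaging is the strongest statement the evidence
  admits. Without it, tiering would structurally exclude whole consequence
  classes that the analysis intends to keep (the consequence prefilter
  deliberately retains splice-site and, by default, promoter variants).
* **T2, risk gene** — gene in a configurable FPC risk-gene list *and*
  CADD < 20: these are exactly the risk-gene variants T1 would miss. The
  shipped list seeds established predisposition genes and
  previously reported low-frequency FPC candidates; it is a plain text
  file, one symbol per line, meant to be edited.
* **T3, recurrence** — high-scoring (as T1) and carried by at least
  `recurrence_min_families` families. Families are counted, not carriers,
  since within-family recurrence is just transmission.

Variants reaching no tier are dropped; output order is a fixed sort on
(chrom, pos, ref, alt) so results are invariant to input row order.

## Segregation verdicts

Only individuals with a non-missing germline genotype are counted. With
`a` genotyped affected and `u` genotyped unaffected members:

* *fails* — more than `max_affected_noncarriers` (default 0) affected
  members are hom_ref, or no genotyped affected exist
  (`no_informative_affected`);
* *complete* — otherwise, when no unaffected member carries the variant;
* *incomplete_penetrance* — otherwise, when unaffected carriers exist and
  the rule allows them (default yes).

Unaffected carriers never fail a variant by default: in a late-onset,
incompletely penetrant disease, a healthy carrier is expected — whether an
elderly escapee or someone simply too young to be affected. The
`exemption_age_threshold` (default 65 years, the median onset age) only
*annotates* each exemption as `elderly_carrier` or `young_carrier`; it
never changes the verdict, because both kinds of healthy carrier are
compatible with a causal dominant variant. Setting
`allow_unaffected_carriers = FALSE` collapses verdicts to complete/fails
without disturbing complete results (property-tested).

Under independent Bernoulli(1/2) carriage, exactly one of the
2^(a+u) genotype patterns yields a complete verdict, so the completeness
probability is (1/2)^a · (1/2)^u; the test suite verifies this by
exhaustive enumeration for a + u ≤ 10, which doubles as a correctness
oracle for the engine's counting.

A Mendelian-consistency check (`mendelian_consistency()`) guards fixtures
and simulator output: it flags alt alleles whose genotyped parents are
both hom_ref, and hom_alt children with any genotyped hom_ref parent. A
child with an ungenotyped parent is never flagged — transmission cannot be
excluded.

## Prevalence reporting

Carrier-family prevalence is `numerator/denominator` as a percentage
rounded half-even to one decimal (R's default rounding); display labels
suppress a trailing `.0` (`8.7%`, but `2%`), matching the reporting style
of family studies. Cohort merges sum denominators and union carrier sets,
and refuse overlapping carrier ids — double-counting a family across a
discovery and a validation cohort is the main bookkeeping hazard here.

## The encoded fixture bundle

`build_paper_fixtures()` reconstructs the study's 15 sequenced families as
data: four narrative candidate families (ATM; SUFU + FANCM; DAB1 + POLQ +
FGFBP3; MAP3K3 + ACAD9), three further ACAD9-carrier families, and eight
synthetic candidate-free fillers, plus two triaged-but-non-segregating
variants (CPA1, FANCG) so the elimination path is exercised. Fixture
pedigrees encode only individuals the study text characterizes —
figure-only individuals are omitted because pedigree figures are not
machine-readable — and the manifest marks the fillers as synthetic.

One curation point deserves note: the published account is arithmetically
ambiguous about whether the fourth ACAD9 family was among the 15 sequenced
families or found in the Sanger extension. The bundle encodes all four
ACAD9 families among the sequenced 15 (giving 7 candidate families, as the
study reports), while the validation-count table follows the printed
prevalence arithmetic (3 carriers among 15 sequenced + 1 among 31
extension families = 4/46, 8.7%). The two sub-fixtures serve different
computations and are deliberately not forced to agree.

## The synthetic cohort generator

`simulate_cohort()` emulates the study regime so that pipeline sensitivity
and specificity can be measured against known truth. Design choices, all
fixed before any acceptance measurement:

* **Pedigree shape.** Three generations; every couple has
  1 + Poisson(mean_sibship − 1) children (mean exactly `mean_sibship`,
  default 2.5, and never zero — a childless branch would not be in a
  registry pedigree). Generation mean ages default to 88/66/40 years
  (sd 4): a registry family ascertained today has elderly founders, a
  sibship around retirement age, and adult grandchildren.
* **Inheritance.** The planted variant enters as a heterozygous founder
  and gene-drops with transmission probability 1/2 per carrier parent.
  Background variants are shared sites whose founder genotypes are drawn
  from Beta(0.5, 35) population frequencies (mostly rare to
  low-frequency) and then gene-dropped, so *every* variant is
  Mendelian-consistent by construction — site-independent per-person
  sampling would violate the QC oracle.
* **Penetrance.** Onset ages are normal (median 65, sd = range/6)
  truncated to 42–78 years. A carrier who has reached their onset age is
  affected with probability 0.8 (PDAC 3:1 over precursor lesions).
  Phenocopies occur in non-carriers at rate 0.01, gated through the same
  onset distribution because sporadic PDAC is equally late-onset; an
  ungated phenocopy rate would seed implausible 40-year-old sporadic
  cases.
* **Ascertainment.** Causal families are rejection-sampled until at least
  three affected and two unaffected members have usable blood DNA — the
  registry's own inclusion regime. Sampling conditions on the planted
  variant's carrier cluster, i.e. the generator emulates families in
  which the planted variant explains the aggregation; non-causal families
  are not ascertained (a phenocopy-only cluster of three is vanishingly
  rare and the null cohort is meant to be null).
* **Annotations.** Each predictor votes damaging with probability 0.9 for
  the planted variant and 0.1 for background variants, independently;
  CADD falls above/below 20 at the same rates. Planted variants are
  forced rare and placed in a configured risk gene with probability 0.3
  (about the proportion of risk-gene candidates among the study's seven).
* **Missingness.** Members lack blood DNA with probability 0.05; their
  genotypes are absent everywhere.

All randomness flows from the single `seed`; identical configurations
produce byte-identical output files.

What the generator does *not* emulate: linkage and haplotype structure
(sites are dropped independently), X-linked or recessive models,
de-novo mutation, somatic genotypes, and age-cohort effects on
availability. Passing tests on simulated cohorts therefore demonstrate the
pipeline's logic and calibration under the dominant-founder model, not
robustness to every real-data pathology.

### Expected sensitivity under the defaults

The end-to-end recovery of a planted variant is capped by the triage
stage: with five independent damaging votes at rate 0.9 and a high-score
threshold of 4, the probability a planted variant is triaged is
P(Bin(5, 0.9) ≥ 4) = 0.9185 (0.9529 when a risk gene admits the T2
rescue), and genotyped phenocopies remove a few further percent at the
segregation stage. The expected recovery fraction under the default
configuration is therefore ≈ 0.90–0.93 with a sampling sd of ≈ 0.02 over
200 families — a quantity that sits by construction near the 90%
sensitivity gate the test suite applies, and the measured value at any
given seed can fall on either side of it. The suite reports the measured
fraction rather than adjusting the generator toward the gate.

## Numerical and determinism choices

* Rounding is half-even throughout (R default); percentages are computed
  on the full fraction and rounded once, at one decimal.
* All output tables have fixed column orders and fixed sorts; JSON is
  written with stable field order and no timestamps, so equal inputs give
  byte-identical reports.
* Degenerate inputs are defined rather than accidental: empty cohorts
  write valid header-only files; a variant carried by nobody fails with
  note `no_carriers`; a family with no genotyped affected fails with
  `no_informative_affected`; a high-score threshold of 0 retains every
  scored variant.
* Problem sizes in the test suite were chosen to make binomial
  tolerances meaningful at interactive runtimes: 10^4 transmissions for
  the gene-drop check (99% CI half-width ≈ 1.3%), 10^4 random call
  profiles for the scoring oracle, exhaustive enumeration up to 2^10
  genotype patterns for the segregation closed form, and 200 causal
  families for the recovery estimate.

## Known limitations

Kinship is computed only to first degree; consanguinity beyond the
acyclicity check is unmodelled. Co-segregation is a filter, not a
statistic — no Bayes-factor or likelihood-based co-segregation evidence is
produced, so a "complete" verdict in a small family is weak evidence (the
closed form above quantifies exactly how weak). The risk-gene list and all
significance labels are curated inputs; the package never computes
pathogenicity from external evidence.
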