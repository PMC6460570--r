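# Synthetic cohort generator: genotypes in Hardy-Weinberg proportions with a
# realistic minor-allele-frequency spectrum, ATC-coded prescriptions, ICD10-coded
# adverse-drug-effect (ADE) diagnoses drawn from a logistic model with planted
# variant-by-drug effects, self-reports, and a covariate table. Every planted
# parameter is recorded in a truth table so downstream estimators can be tested
# for parameter recovery without access-controlled biobank data.

# MAF bin edges used throughout the package (half-open, lower-inclusive).
.MAF_BINS <- data.frame(
  bin = c("MAF<0.05%", "0.05%<=MAF<0.5%", "0.5%<=MAF<1%", "1%<=MAF<5%", "MAF>5%"),
  lo  = c(0,      5e-4, 5e-3, 1e-2, 5e-2),
  hi  = c(5e-4,   5e-3, 1e-2, 5e-2, 0.5 + 1e-12),
  stringsAsFactors = FALSE
)

#' MAF bin labels
#'
#' The five minor-allele-frequency bins used to summarise variant spectra
#' (half-open, lower-inclusive): `<0.05%`, `0.05–0.5%`, `0.5–1%`, `1–5%`,
#' `>5%`.
#'
#' @return Character vector of bin labels, rarest first.
#' @export
maf_bin_labels <- function() .MAF_BINS$bin

#' Define a planted variant-by-drug effect
#'
#' Describes a true log-odds-ratio linking one variant's genotype to ADE risk
#' among persons prescribed drugs in one ATC level-4 group. Used by
#' [generate_cohort()] and recorded in its truth table.
#'
#' @param variant_id Variant identifier (must exist in the generated cohort).
#' @param atc4 Five-character ATC level-4 group the effect acts within.
#' @param log_or True log odds ratio per effect-allele unit.
#' @param model `"additive"` (per-allele, dosage 0/1/2) or `"carrier"`
#'   (any alt allele vs none).
#' @param maf Optional minor allele frequency to force for this variant
#'   (otherwise drawn from the spectrum).
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(variant_id, atc4, log_or,
                           model = c("additive", "carrier"), maf = NULL) {
  model <- match.arg(model)
  .assert(is.numeric(log_or) && length(log_or) == 1L, "log_or must be a single number")
  structure(list(variant_id = as.character(variant_id), atc4 = as.character(atc4),
                 log_or = log_or, model = model, maf = maf),
            class = "planted_effect")
}

#' Specify a synthetic pharmacogenomic cohort
#'
#' Collects the parameters of the generator: cohort size, variant panel and
#' its MAF spectrum, number of ATC level-4 drug groups, prescription and ADE
#' rates, planted effects, and the RNG seed. Defaults for the MAF spectrum
#' follow the observed spectrum of candidate-pharmacogene variants
#' (55.2/21.7/3.4/7.2/12.5 percent across the five bins, rarest first).
#'
#' @param n_persons,n_variants Cohort and variant-panel sizes (positive).
#' @param maf_spectrum Mixture weights over the five MAF bins (rarest first);
#'   must sum to 1.
#' @param maf Optional numeric vector of per-variant MAFs overriding the
#'   spectrum draw (length `n_variants`).
#' @param n_drugs Number of ATC level-4 groups to simulate.
#' @param prescription_rate Per-person, per-drug Bernoulli probability of at
#'   least one prescription.
#' @param base_ade_rate Baseline ADE probability among persons with any
#'   prescription.
#' @param background_ade_rate Drug-independent ADE probability applied to all
#'   persons (emulates disease processes mimicking ADEs).
#' @param self_report_rate Per-person probability of a self-reported ADE.
#' @param noise_dx_rate Per-person probability of an unrelated (non-ADE)
#'   diagnosis record.
#' @param missing_rate Per-genotype missingness probability.
#' @param planted_effects List of [planted_effect()] objects.
#' @param covariate_effects Named list of true covariate log-odds effects on
#'   ADE risk: `sex`, `age` (per year), `bmi` (per unit), `pc` (per unit of
#'   each of PC1-PC4), `platform`. Terms are centred at the covariate
#'   generating means, so `base_ade_rate` is the rate for an average person.
#' @param seed Integer RNG seed; identical seeds give byte-identical outputs.
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(n_persons, n_variants,
                        maf_spectrum = c(0.552, 0.217, 0.034, 0.072, 0.125),
                        maf = NULL,
                        n_drugs = 10,
                        prescription_rate = 0.2,
                        base_ade_rate = 0.05,
                        background_ade_rate = 0.001,
                        self_report_rate = 0.002,
                        noise_dx_rate = 0.05,
                        missing_rate = 0,
                        planted_effects = list(),
                        covariate_effects = list(sex = 0.2, age = 0.01,
                                                 bmi = 0.02, pc = 0.05,
                                                 platform = 0.1),
                        seed = 1L) {
  .assert(n_persons >= 1 && n_variants >= 1,
          "n_persons and n_variants must both be at least 1")
  .assert(length(maf_spectrum) == 5L && abs(sum(maf_spectrum) - 1) < 1e-8,
          "maf_spectrum must be 5 mixture weights summing to 1")
  probs <- c(prescription_rate, base_ade_rate, background_ade_rate,
             self_report_rate, noise_dx_rate, missing_rate)
  .assert(all(probs >= 0 & probs <= 1), "all rates must be probabilities in [0,1]")
  if (!is.null(maf)) {
    .assert(length(maf) == n_variants && all(maf > 0 & maf <= 0.5),
            "maf overrides must have length n_variants with values in (0, 0.5]")
  }
  if (inherits(planted_effects, "planted_effect")) planted_effects <- list(planted_effects)
  .assert(all(vapply(planted_effects, inherits, logical(1), "planted_effect")),
          "planted_effects must be a list of planted_effect objects")
  structure(list(n_persons = as.integer(n_persons), n_variants = as.integer(n_variants),
                 maf_spectrum = maf_spectrum, maf = maf, n_drugs = as.integer(n_drugs),
                 prescription_rate = prescription_rate, base_ade_rate = base_ade_rate,
                 background_ade_rate = background_ade_rate,
                 self_report_rate = self_report_rate, noise_dx_rate = noise_dx_rate,
                 missing_rate = missing_rate, planted_effects = planted_effects,
                 covariate_effects = covariate_effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic supply of ATC level-4 codes
.atc4_codes <- function(n) {
  anat <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")
  g <- expand.grid(a = anat, t = sprintf("%02d", 1:20),
                   p = LETTERS[1:10], c = LETTERS[1:10],
                   stringsAsFactors = FALSE)
  codes <- paste0(g$a, g$t, g$p, g$c)
  .assert(n <= length(codes), "too many drug groups requested (max %d)", length(codes))
  codes[seq_len(n)]
}

.draw_mafs <- function(spec) {
  if (!is.null(spec$maf)) return(spec$maf)
  bin <- sample.int(5L, spec$n_variants, replace = TRUE, prob = spec$maf_spectrum)
  lo <- .MAF_BINS$lo[bin]
  hi <- pmin(.MAF_BINS$hi[bin], 0.5)
  # keep the rarest bin above the resolution of the cohort
  lo[bin == 1L] <- min(1 / (2 * spec$n_persons), 4.9e-4)
  runif(spec$n_variants, lo, hi)
}

#' Generate a synthetic cohort with planted pharmacogenomic effects
#'
#' Draws genotypes in Hardy-Weinberg proportions at MAFs sampled from the
#' spectrum in `spec`, covariates (sex ~ Bernoulli(0.5), age ~ U(18, 90),
#' BMI ~ N(26, 4), PC1-PC4 ~ N(0, 1), platform WGS/chip), per-drug
#' prescriptions, and ADE diagnoses. ADE status among prescribed persons
#' follows a logistic model
#' `logit P(ADE) = logit(base_ade_rate) + sum(beta_planted * g) + covariate terms`;
#' a small drug-independent background rate and self-reports are added on top.
#' ICD10 codes for ADE events are drawn uniformly from the supplied code list.
#' Dates are uniform over January 2004 to August 2015.
#'
#' @param spec A [cohort_spec()].
#' @param codelist An [ade_codelist()] supplying ICD10 codes and the
#'   12 diagnostic groups; defaults to the bundled synthetic example list.
#' @param out_dir Optional directory; when given, [write_cohort()] writes
#'   VCF/TSV/JSON files there (byte-identical for identical seeds).
#' @return A `pharm_cohort` list: `genotypes` (person x variant dosage matrix,
#'   NA = missing), `variants`, `covariates`, `prescriptions`, `diagnoses`,
#'   `self_reports` tibbles, and `truth` (planted parameters).
#' @export
generate_cohort <- function(spec, codelist = ade_codelist_example(), out_dir = NULL) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(spec$seed)
  n <- spec$n_persons
  m <- spec$n_variants
  persons <- sprintf("P%05d", seq_len(n))
  vids <- sprintf("v%04d", seq_len(m))

  mafs <- .draw_mafs(spec)
  # forced MAFs for planted variants declared with maf=
  for (pe in spec$planted_effects) {
    .assert(pe$variant_id %in% vids,
            "planted effect names unknown variant '%s'", pe$variant_id)
    if (!is.null(pe$maf)) mafs[match(pe$variant_id, vids)] <- pe$maf
  }

  geno <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n,
                 dimnames = list(persons, vids))
  if (spec$missing_rate > 0) {
    geno[runif(n * m) < spec$missing_rate] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variants <- tibble::tibble(chrom = "1", pos = 10000L * seq_len(m), id = vids,
                             ref = ref, alt = unname(alt), maf = mafs)

  covariates <- tibble::tibble(
    person_id = persons,
    sex = rbinom(n, 1L, 0.5),
    age = runif(n, 18, 90),
    bmi = rnorm(n, 26, 4),
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n),
    platform = ifelse(runif(n) < 0.15, "WGS", "chip")
  )

  atc4 <- .atc4_codes(spec$n_drugs)
  for (pe in spec$planted_effects) {
    .assert(pe$atc4 %in% atc4,
            "planted effect targets drug group '%s' that is not prescribed in this cohort",
            pe$atc4)
  }
  rx_flags <- matrix(runif(n * spec$n_drugs) < spec$prescription_rate,
                     nrow = n, dimnames = list(persons, atc4))
  date0 <- as.Date("2004-01-01")
  n_days <- as.integer(as.Date("2015-08-31") - date0)
  rx_idx <- which(rx_flags, arr.ind = TRUE)
  prescriptions <- tibble::tibble(
    person_id = persons[rx_idx[, 1L]],
    atc = paste0(atc4[rx_idx[, 2L]], "01"),
    date = date0 + sample.int(n_days, nrow(rx_idx), replace = TRUE)
  )
  prescriptions <- prescriptions[order(prescriptions$person_id, prescriptions$atc), ]

  # linear predictor of the ADE logistic model among prescribed persons;
  # covariate terms are centred at their generating means so base_ade_rate is
  # the baseline probability for an average person
  ce <- spec$covariate_effects
  lp <- qlogis(spec$base_ade_rate) +
    ce$sex * (covariates$sex - 0.5) +
    ce$age * (covariates$age - 54) +
    ce$bmi * (covariates$bmi - 26) +
    ce$pc * (covariates$PC1 + covariates$PC2 + covariates$PC3 + covariates$PC4) +
    ce$platform * ((covariates$platform == "WGS") - 0.15)
  for (pe in spec$planted_effects) {
    g <- geno[, pe$variant_id]
    g[is.na(g)] <- 0L
    if (pe$model == "carrier") g <- as.integer(g > 0L)
    lp <- lp + pe$log_or * g * rx_flags[, pe$atc4]
  }
  prescribed_any <- rowSums(rx_flags) > 0L
  ade <- prescribed_any & (runif(n) < plogis(lp))
  ade_bg <- runif(n) < spec$background_ade_rate

  ade_persons <- persons[ade | ade_bg]
  diagnoses <- tibble::tibble(person_id = character(), icd10 = character(),
                              date = as.Date(character()),
                              physician_confirmed = logical(), source = character())
  if (length(ade_persons) > 0L) {
    codes <- sample(codelist$codes, length(ade_persons), replace = TRUE)
    diagnoses <- tibble::tibble(
      person_id = ade_persons,
      icd10 = codes,
      date = date0 + sample.int(n_days, length(ade_persons), replace = TRUE),
      physician_confirmed = TRUE,
      source = "ehr"
    )
  }
  noise <- runif(n) < spec$noise_dx_rate
  if (any(noise)) {
    noise_codes <- c("I10", "E11.9", "J06.9", "K21.9", "M54.5")
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      person_id = persons[noise],
      icd10 = sample(noise_codes, sum(noise), replace = TRUE),
      date = date0 + sample.int(n_days, sum(noise), replace = TRUE),
      physician_confirmed = FALSE,
      source = "ehr"
    ))
  }
  diagnoses <- diagnoses[order(diagnoses$person_id, diagnoses$icd10), ]

  sr <- runif(n) < spec$self_report_rate
  self_reports <- tibble::tibble(
    person_id = persons[sr],
    description = "self-reported adverse drug reaction",
    date = if (any(sr)) date0 + sample.int(n_days, sum(sr), replace = TRUE) else as.Date(character())
  )

  truth <- list(
    seed = spec$seed,
    base_ade_rate = spec$base_ade_rate,
    background_ade_rate = spec$background_ade_rate,
    covariate_effects = ce,
    maf = stats::setNames(mafs, vids),
    planted_effects = lapply(spec$planted_effects, function(pe) {
      list(variant_id = pe$variant_id, atc4 = pe$atc4,
           log_or = pe$log_or, model = pe$model)
    })
  )

  cohort <- structure(list(genotypes = geno, variants = variants,
                           covariates = covariates, prescriptions = prescriptions,
                           diagnoses = diagnoses, self_reports = self_reports,
                           truth = truth, spec = spec),
                      class = "pharm_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.pharm_cohort <- function(x, ...) {
  cat(sprintf(
    "pharm_cohort: %d persons x %d variants, %d drug groups, %d Rx rows, %d dx rows, %d planted effect(s)\n",
    nrow(x$genotypes), ncol(x$genotypes), x$spec$n_drugs,
    nrow(x$prescriptions), nrow(x$diagnoses), length(x$truth$planted_effects)))
  invisible(x)
}

#' Generate a pair of variants in linkage disequilibrium
#'
#' Samples diploid genotypes at two loci from the two-locus haplotype
#' distribution whose allele frequencies are `maf` and whose squared
#' correlation is `r2` (positive-D convention). Used to exercise conditional
#' association analysis on correlated variants.
#'
#' @param n Number of diploid persons (realised r-squared is within about 0.05
#'   of target for n of 5000 or more).
#' @param maf Length-2 vector of minor allele frequencies, each in (0, 0.5].
#' @param r2 Target squared correlation between the two dosage columns, in
#'   \[0, 1\]. Infeasible targets for the given MAFs raise an error naming the
#'   attainable bound.
#' @param seed Integer RNG seed.
#' @return Integer matrix with `n` rows and columns `g1`, `g2` (dosages 0/1/2).
#' @export
generate_ld_pair <- function(n, maf = c(0.3, 0.3), r2 = 0.8, seed = 1L) {
  .assert(r2 >= 0 && r2 <= 1, "r2 must be in [0,1]")
  .assert(length(maf) == 2L && all(maf > 0 & maf <= 0.5),
          "maf must be two frequencies in (0, 0.5]")
  p <- maf[1]; q <- maf[2]
  denom <- sqrt(p * (1 - p) * q * (1 - q))
  d_max <- min(p * (1 - q), q * (1 - p))
  r2_max <- (d_max / denom)^2
  .assert(r2 <= r2_max + 1e-12,
          "r2 = %.3f infeasible for MAFs (%.3f, %.3f); maximum attainable r2 = %.3f",
          r2, p, q, r2_max)
  D <- sqrt(r2) * denom
  # haplotype frequencies (minor alleles coded 1)
  f <- c(`11` = p * q + D, `10` = p * (1 - q) - D,
         `01` = (1 - p) * q - D, `00` = (1 - p) * (1 - q) + D)
  f <- pmax(f, 0); f <- f / sum(f)
  set.seed(seed)
  hap <- sample.int(4L, 2L * n, replace = TRUE, prob = f)
  a1 <- c(1L, 1L, 0L, 0L)[hap]  # allele at locus 1 per haplotype
  a2 <- c(1L, 0L, 1L, 0L)[hap]
  g1 <- a1[seq_len(n)] + a1[n + seq_len(n)]
  g2 <- a2[seq_len(n)] + a2[n + seq_len(n)]
  cbind(g1 = g1, g2 = g2)
}

#' Empirical squared genotype correlation
#'
#' @param g1,g2 Dosage vectors.
#' @return Squared Pearson correlation.
#' @export
empirical_r2 <- function(g1, g2) stats::cor(g1, g2)^2
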