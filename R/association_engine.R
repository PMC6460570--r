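# The statistical core: crude 2x2 odds ratios with Woolf confidence intervals,
# covariate-adjusted logistic association (additive dosage or carrier coding),
# the candidate-variant scan with its inclusion filters and skip accounting,
# conditional adjustment for known variants, the genome-wide scan, and the
# drug-independent (prescription-free) group test.

#' Crude odds ratio from a 2x2 table
#'
#' Computes OR = (a*d)/(b*c) with Woolf's log-method confidence interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a two-sided Wald p.
#' Cell layout: `a` = ADE & carrier, `b` = ADE & non-carrier, `c` = no-ADE &
#' carrier, `d` = no-ADE & non-carrier.
#'
#' @param a,b,c,d Non-negative counts. `a` may also be a length-4 vector or
#'   2x2 matrix (`rbind(c(a, b), c(c, d))`).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to every cell
#'   (required to score tables with zero cells).
#' @param conf_level Confidence level, default 0.95.
#' @return List with `or`, `ci95` (lo, hi), `p`, `log_or`, `se`, `status`
#'   (`"ok"` or `"zero_cell"`).
#' @export
crude_or <- function(a, b = NULL, c = NULL, d = NULL, haldane = FALSE,
                     conf_level = 0.95) {
  if (is.null(b)) {
    cells <- as.numeric(t(a))
    .assert(length(cells) == 4L, "expected a 2x2 table")
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  }
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  .assert(all(c(a, b, c, d) >= 0) && sum(a, b, c, d) >= 1,
          "counts must be non-negative with at least one observation")
  if (any(c(a, b, c, d) == 0)) {
    if (!haldane) {
      return(list(or = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                  log_or = NA_real_, se = NA_real_, status = "zero_cell"))
    }
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci95 = exp(log_or + c(-1, 1) * z * se),
       p = 2 * pnorm(-abs(log_or / se)),
       log_or = log_or, se = se, status = "ok")
}

# numeric covariate design from the covariate table, constant columns dropped
.design_frame <- function(covariates, persons) {
  if (is.null(covariates)) return(NULL)
  idx <- match(persons, covariates$person_id)
  .assert(!anyNA(idx), "persons missing from covariate table")
  cv <- covariates[idx, , drop = FALSE]
  X <- data.frame(sex = as.numeric(cv$sex), age = cv$age, bmi = cv$bmi,
                  PC1 = cv$PC1, PC2 = cv$PC2, PC3 = cv$PC3, PC4 = cv$PC4,
                  platform = as.numeric(cv$platform == "WGS"))
  X[, vapply(X, function(x) stats::var(x) > 0, logical(1)), drop = FALSE]
}

.empty_result <- function(variant = NA_character_, cohort = NA_character_,
                          n = NA_integer_, status = "ok") {
  tibble::tibble(variant = variant, cohort = cohort, n = n,
                 a = NA_integer_, b = NA_integer_, c = NA_integer_,
                 d = NA_integer_, beta = NA_real_, or = NA_real_,
                 lo = NA_real_, hi = NA_real_, p = NA_real_,
                 conditional_p = NA_real_, status = status)
}

#' Covariate-adjusted logistic association fit
#'
#' Maximum-likelihood logistic regression of case status on genotype
#' (additive 0/1/2 dosage or carrier 0/1 coding) plus covariates, fitted by
#' iteratively reweighted least squares (epsilon 1e-10, at most 100
#' iterations), reporting the Wald test of the genotype term. The carrier
#' collapse of the data is reported as a 2x2 table alongside.
#'
#' @param y Logical or 0/1 case flags.
#' @param g Genotype dosages (0/1/2); `NA` rows are dropped.
#' @param covariates Optional covariate table (columns `person_id`, `sex`,
#'   `age`, `bmi`, `PC1`-`PC4`, `platform`) aligned by `persons`.
#' @param persons Person ids aligned with `y`/`g` (needed with `covariates`).
#' @param coding `"additive"` or `"carrier"`.
#' @param conditioning Optional matrix/vector of conditioning-variant dosages
#'   (columns are added as covariates); perfect collinearity with `g` yields
#'   status `"collinear"`.
#' @param variant,cohort Labels carried into the result.
#' @return One-row tibble (`variant`, `cohort`, `n`, 2x2 cells `a`-`d`,
#'   `beta`, `or`, `lo`, `hi`, `p`, `conditional_p`, `status`). Non-`"ok"`
#'   statuses: `skipped:too_few_cases`, `skipped:no_carriers` (constant
#'   genotype), `separated` (|beta| > 15), `nonconverged`, `collinear`.
#' @export
fit_logistic <- function(y, g, covariates = NULL, persons = NULL,
                         coding = c("additive", "carrier"),
                         conditioning = NULL,
                         variant = NA_character_, cohort = NA_character_) {
  coding <- match.arg(coding)
  y <- as.integer(y)
  g <- as.numeric(g)
  if (!is.null(conditioning)) conditioning <- as.matrix(conditioning)
  keep <- !is.na(y) & !is.na(g)
  if (!is.null(conditioning)) keep <- keep & stats::complete.cases(conditioning)
  y <- y[keep]; g <- g[keep]
  if (!is.null(persons)) persons <- persons[keep]
  if (!is.null(conditioning)) conditioning <- conditioning[keep, , drop = FALSE]
  n <- length(y)
  if (coding == "carrier") g <- as.numeric(g > 0)

  carrier <- g > 0
  tab <- c(a = sum(y == 1L & carrier), b = sum(y == 1L & !carrier),
           c = sum(y == 0L & carrier), d = sum(y == 0L & !carrier))
  res <- .empty_result(variant, cohort, n)
  res[, c("a", "b", "c", "d")] <- as.list(as.integer(tab))

  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    res$status <- "skipped:too_few_cases"
    return(res)
  }
  if (stats::var(g) == 0) {
    res$status <- "skipped:no_carriers"
    return(res)
  }
  df <- data.frame(y = y, g = g)
  if (!is.null(conditioning)) {
    r2 <- apply(conditioning, 2L, function(x) {
      if (stats::var(x) == 0) 0 else stats::cor(g, x)^2
    })
    if (any(r2 >= 1 - 1e-12)) {
      res$status <- "collinear"
      return(res)
    }
    colnames(conditioning) <- paste0("cond", seq_len(ncol(conditioning)))
    df <- cbind(df, conditioning)
  }
  if (!is.null(covariates)) {
    .assert(!is.null(persons), "persons ids are required with a covariate table")
    X <- .design_frame(covariates, persons)
    if (!is.null(X) && ncol(X) > 0L) df <- cbind(df, X)
  }
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                              control = list(epsilon = 1e-10, maxit = 100)))
  beta <- coef(fit)["g"]
  if (is.na(beta)) {
    res$status <- "collinear"
    return(res)
  }
  if (abs(beta) > 15) {
    res$status <- "separated"
    return(res)
  }
  if (!fit$converged) {
    res$status <- "nonconverged"
    return(res)
  }
  se <- sqrt(diag(vcov(fit))["g"])
  res$beta <- unname(beta)
  res$or <- exp(res$beta)
  res$lo <- exp(res$beta - 1.96 * se)
  res$hi <- exp(res$beta + 1.96 * se)
  res$p <- unname(2 * pnorm(-abs(beta / se)))
  res
}

#' Conditional adjustment for known variants
#'
#' Refits an association adding the dosages of known variants as covariates
#' and returns the Wald p of the index variant (the post-conditional p).
#'
#' @inheritParams fit_logistic
#' @param known Matrix (or vector) of conditioning-variant dosages aligned
#'   with `y`.
#' @return One-row tibble as [fit_logistic()], with `conditional_p` set; the
#'   unconditional fit's `p` is preserved in `p`.
#' @export
conditional_test <- function(y, g, known, covariates = NULL, persons = NULL,
                             coding = "additive",
                             variant = NA_character_, cohort = NA_character_) {
  base <- fit_logistic(y, g, covariates, persons, coding,
                       variant = variant, cohort = cohort)
  cond <- fit_logistic(y, g, covariates, persons, coding,
                       conditioning = known, variant = variant, cohort = cohort)
  base$conditional_p <- cond$p
  if (cond$status != "ok") base$status <- cond$status
  base
}

# persons prescribed any drug matching the (possibly full-length) ATC prefix
.prescribed_persons <- function(prescriptions, atc_prefix) {
  unique(as.character(
    prescriptions$person_id[startsWith(prescriptions$atc, atc_prefix)]))
}

#' Candidate pharmacogene variant scan
#'
#' Tests every (variant, drug) pair implied by the gene-drug map at gene
#' level (all map drugs of the variant's gene), with the inclusion filters:
#' the variant must segregate in the cohort, the drug must have prescriptions
#' and at least one ADE among prescribed persons, at least one carrier must
#' be prescribed, and at least `min_prescribed` persons (default 500) must be
#' prescribed. Each skip reason is tallied in the `"tally"` attribute.
#' Persons with missing genotype at the tested variant are dropped from that
#' test only. Nominal significance is flagged at p < 0.05.
#'
#' @param genotypes Person x variant dosage matrix.
#' @param variant_genes Named character vector variant id -> gene.
#' @param map A [gene_drug_map()].
#' @param prescriptions Tibble `person_id`, `atc`.
#' @param phenotypes `ade_phenotypes` or tibble `person_id`, `is_case`.
#' @param covariates Optional covariate table.
#' @param min_prescribed Minimum prescribed persons per pair (default 500).
#' @param coding Genotype coding for single variants (default additive).
#' @return Tibble of association results, one row per tested pair, with a
#'   `significant` flag; skip statuses recorded per pair and tallied in
#'   `attr(, "tally")`.
#' @export
candidate_scan <- function(genotypes, variant_genes, map, prescriptions,
                           phenotypes, covariates = NULL,
                           min_prescribed = 500, coding = "additive") {
  phen <- if (inherits(phenotypes, "ade_phenotypes")) phenotypes$phenotypes else phenotypes
  case_ids <- phen$person_id[phen$is_case]
  lt_label <- sprintf("skipped:lt_%d", min_prescribed)
  rows <- list()
  for (v in names(variant_genes)) {
    gene <- variant_genes[[v]]
    atcs <- sort(unique(map$atc[map$gene == gene]))
    for (atc in atcs) {
      label <- function(status, n = NA_integer_) {
        r <- .empty_result(v, atc, n, status)
        r$gene <- gene
        r
      }
      if (!v %in% colnames(genotypes) ||
          sum(genotypes[, v], na.rm = TRUE) == 0) {
        rows[[length(rows) + 1L]] <- label("skipped:variant_absent")
        next
      }
      prescribed <- .prescribed_persons(prescriptions, atc)
      prescribed <- intersect(prescribed, rownames(genotypes))
      if (length(prescribed) == 0L) {
        rows[[length(rows) + 1L]] <- label("skipped:no_prescriptions")
        next
      }
      g <- genotypes[prescribed, v]
      ok <- !is.na(g)
      prescribed <- prescribed[ok]; g <- g[ok]
      y <- prescribed %in% case_ids
      if (sum(y) == 0L) {
        rows[[length(rows) + 1L]] <- label("skipped:no_ade", length(prescribed))
        next
      }
      if (sum(g > 0) == 0L) {
        rows[[length(rows) + 1L]] <- label("skipped:no_carriers", length(prescribed))
        next
      }
      if (length(prescribed) < min_prescribed) {
        rows[[length(rows) + 1L]] <- label(lt_label, length(prescribed))
        next
      }
      r <- fit_logistic(y, g, covariates, prescribed, coding,
                        variant = v, cohort = atc)
      r$gene <- gene
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out <- out[, c("variant", "gene", setdiff(names(out), c("variant", "gene")))]
    out$significant <- !is.na(out$p) & out$p < 0.05
  }
  attr(out, "tally") <- if (nrow(out) > 0L) table(out$status) else table(character())
  out
}

#' Genome-wide scan across drug cohorts
#'
#' For each drug-exposure cohort, fits the additive logistic model to every
#' variant with minor allele frequency of at least `maf_min` (computed on
#' non-missing calls), and extracts the subset below the suggestive
#' significance threshold. Cohorts lacking both cases and controls are
#' skipped with a warning.
#'
#' @param genotypes Person x variant dosage matrix.
#' @param cohorts Output of [build_cohorts()].
#' @param phenotypes `ade_phenotypes` or tibble `person_id`, `is_case`.
#' @param covariates Optional covariate table.
#' @param maf_min MAF inclusion threshold (default 0.01).
#' @param p_suggestive Suggestive threshold (default 1e-6).
#' @return List with `results` (all tests) and `suggestive` (subset with
#'   p < `p_suggestive`).
#' @export
genome_scan <- function(genotypes, cohorts, phenotypes, covariates = NULL,
                        maf_min = 0.01, p_suggestive = 1e-6) {
  phen <- if (inherits(phenotypes, "ade_phenotypes")) phenotypes$phenotypes else phenotypes
  case_ids <- phen$person_id[phen$is_case]
  mafs <- apply(genotypes, 2L, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    af <- sum(g) / (2 * length(g))
    min(af, 1 - af)
  })
  test_vars <- colnames(genotypes)[!is.na(mafs) & mafs >= maf_min]
  rows <- list()
  for (i in seq_len(nrow(cohorts))) {
    persons <- intersect(cohorts$persons[[i]], rownames(genotypes))
    y <- persons %in% case_ids
    if (sum(y) == 0L || sum(!y) == 0L) {
      warning(sprintf("cohort %s has no %s; skipped", cohorts$atc4[i],
                      if (sum(y) == 0L) "cases" else "controls"), call. = FALSE)
      next
    }
    for (v in test_vars) {
      rows[[length(rows) + 1L]] <-
        fit_logistic(y, genotypes[persons, v], covariates, persons,
                     coding = "additive", variant = v, cohort = cohorts$atc4[i])
    }
  }
  results <- if (length(rows) > 0L) dplyr::bind_rows(rows) else .empty_result()[0L, ]
  list(results = results,
       suggestive = results[!is.na(results$p) & results$p < p_suggestive, ,
                            drop = FALSE])
}

#' Drug-independent diagnostic-group association test
#'
#' Tests a variant against membership in one diagnostic group regardless of
#' drug intake: cases are persons with any ADE event in the group, controls
#' are persons with no ADE at all (persons with ADEs only in other groups are
#' excluded). Used to check whether a within-cohort signal is a disease
#' association rather than a drug response.
#'
#' @param g Named dosage vector (names are person ids).
#' @param phenotypes An `ade_phenotypes` object.
#' @param group Diagnostic group label.
#' @param covariates Optional covariate table.
#' @param coding Genotype coding, default additive.
#' @return One-row tibble as [fit_logistic()].
#' @export
drug_independent_test <- function(g, phenotypes, group, covariates = NULL,
                                  coding = "additive") {
  .assert(inherits(phenotypes, "ade_phenotypes"), "phenotypes must come from extract_ades()")
  groups <- group_ades(phenotypes)
  cases <- unique(groups$person_id[groups$group == group])
  cases <- intersect(cases, names(g))
  .assert(length(cases) > 0L, "diagnostic group '%s' has no cases", group)
  controls <- intersect(
    phenotypes$phenotypes$person_id[!phenotypes$phenotypes$is_case], names(g))
  persons <- c(cases, controls)
  fit_logistic(persons %in% cases, g[persons], covariates, persons, coding,
               cohort = paste0("group:", group))
}
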