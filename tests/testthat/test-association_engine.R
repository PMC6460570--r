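test_that("crude odds ratios reproduce published-style 2x2 tables and closed forms", {
  # validated carrier/non-carrier tables for known gene-drug pairs
  slc22a1 <- crude_or(52, 139, 236, 961)
  expect_equal(slc22a1$or, (52 * 961) / (139 * 236), tolerance = 1e-12)
  expect_equal(round(slc22a1$or, 1), 1.5)
  expect_lt(slc22a1$p, 0.05)
  adrb1 <- crude_or(11, 8, 49, 129)
  expect_equal(round(adrb1$or, 1), 3.6)
  # symmetric table
  expect_equal(crude_or(1, 1, 1, 1)$or, 1)
  # 2x2 matrix input
  expect_equal(crude_or(rbind(c(52, 139), c(236, 961)))$or, slc22a1$or)
})

test_that("zero cells give a zero_cell status unless the Haldane correction is enabled", {
  z <- crude_or(0, 10, 5, 20)
  expect_equal(z$status, "zero_cell")
  expect_true(is.na(z$or))
  h <- crude_or(0, 10, 5, 20, haldane = TRUE)
  expect_equal(h$status, "ok")
  expect_equal(h$or, (0.5 * 20.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("a covariate-free carrier fit reproduces the closed-form 2x2 OR", {
  set.seed(91)
  tables <- cbind(a = sample(5:60, 20, TRUE), b = sample(5:200, 20, TRUE),
                  c = sample(5:200, 20, TRUE), d = sample(50:900, 20, TRUE))
  tables <- rbind(tables, c(52, 139, 236, 961))
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    dat <- expand_2x2(tb[1], tb[2], tb[3], tb[4])
    fit <- fit_logistic(dat$y, dat$g, coding = "carrier")
    oracle <- crude_or(tb[1], tb[2], tb[3], tb[4])
    expect_equal(fit$or, oracle$or, tolerance = 1e-6)
    expect_equal(unname(c(fit$a, fit$b, fit$c, fit$d)), unname(tb))
  }
})

test_that("null genotype-phenotype data yields a non-significant fit", {
  set.seed(92)
  g <- rbinom(2000, 2, 0.3)
  y <- rbinom(2000, 1, 0.1)
  r <- fit_logistic(y, g)
  expect_equal(r$status, "ok")
  expect_gt(r$p, 0.05)
})

test_that("degenerate fits are reported via status, not bogus estimates", {
  # constant genotype
  expect_equal(fit_logistic(rep(c(0, 1), 20), rep(0, 40))$status,
               "skipped:no_carriers")
  # too few cases
  expect_equal(fit_logistic(c(1, rep(0, 20)), rbinom(21, 2, 0.4))$status,
               "skipped:too_few_cases")
  # perfect separation
  g <- c(rep(1, 20), rep(0, 80))
  expect_equal(fit_logistic(g, g)$status, "separated")
})

test_that("adding an all-zero covariate leaves the genotype estimate untouched", {
  set.seed(93)
  g <- rbinom(1500, 2, 0.25)
  y <- rbinom(1500, 1, plogis(-2 + 0.4 * g))
  plain <- fit_logistic(y, g)
  zeroed <- conditional_test(y, g, known = rep(0, 1500))
  expect_equal(zeroed$beta, plain$beta, tolerance = 1e-8)
})

test_that("the candidate scan applies the published inclusion filters with a skip tally", {
  persons <- sprintf("p%03d", 1:700)
  cases <- persons[1:50]
  geno <- matrix(0L, nrow = 700, ncol = 6,
                 dimnames = list(persons, c("vA", "vB", "vC", "vD", "vE", "vF")))
  set.seed(94)
  geno[, "vB"] <- rbinom(700, 2, 0.2)
  geno[, "vC"] <- rbinom(700, 2, 0.2)
  geno[601:700, "vD"] <- 1L                      # carriers never prescribed
  geno[, "vE"] <- rbinom(700, 2, 0.2)
  geno[, "vF"] <- rbinom(700, 2, 0.2)
  variant_genes <- c(vA = "GA", vB = "GB", vC = "GC", vD = "GD", vE = "GE",
                     vF = "GF")
  map <- gene_drug_map(
    gene = c("GA", "GB", "GC", "GD", "GE", "GF"),
    atc = c("A01AA01", "B02BB01", "C03CC01", "D04DD01", "E05EE01", "F06FF01"))
  rx <- tibble::tibble(
    person_id = c(persons[1:600],            # A01AA01: vA absent from cohort
                  persons[51:650],           # C03CC01: prescribed but ADE-free
                  persons[1:600],            # D04DD01: no carriers among prescribed
                  persons[1:499],            # E05EE01: below the 500 filter
                  persons[1:600]),           # F06FF01: testable
    atc = rep(c("A01AA01", "C03CC01", "D04DD01", "E05EE01", "F06FF01"),
              c(600, 600, 600, 499, 600)))
  phen <- tibble::tibble(person_id = persons, is_case = persons %in% cases)
  res <- candidate_scan(geno, variant_genes, map, rx, phen,
                        min_prescribed = 500)
  status_by_variant <- setNames(res$status, res$variant)
  expect_equal(status_by_variant[["vA"]], "skipped:variant_absent")
  expect_equal(status_by_variant[["vB"]], "skipped:no_prescriptions")
  expect_equal(status_by_variant[["vC"]], "skipped:no_ade")
  expect_equal(status_by_variant[["vD"]], "skipped:no_carriers")
  expect_equal(status_by_variant[["vE"]], "skipped:lt_500")
  expect_equal(status_by_variant[["vF"]], "ok")
  tally <- attr(res, "tally")
  expect_equal(sort(as.integer(tally)), rep(1L, 6))
  expect_equal(res$n[res$variant == "vE"], 499L)
})

test_that("scan results are invariant to person and variant ordering", {
  set.seed(95)
  persons <- sprintf("p%03d", 1:600)
  geno <- matrix(rbinom(600 * 3, 2, 0.3), nrow = 600,
                 dimnames = list(persons, c("v1", "v2", "v3")))
  rx <- tibble::tibble(person_id = persons, atc = "A01AA01")
  phen <- tibble::tibble(person_id = persons,
                         is_case = runif(600) < 0.15)
  vg <- c(v1 = "G1", v2 = "G1", v3 = "G2")
  map <- gene_drug_map(gene = c("G1", "G2"), atc = c("A01AA01", "A01AA01"))
  base <- candidate_scan(geno, vg, map, rx, phen, min_prescribed = 100)
  perm <- sample(600)
  scram <- candidate_scan(geno[perm, c("v3", "v1", "v2")],
                          vg[c("v3", "v1", "v2")], map,
                          rx[sample(600), ], phen[sample(600), ],
                          min_prescribed = 100)
  key <- function(x) x[order(x$variant, x$cohort), c("variant", "cohort", "beta", "p")]
  expect_equal(key(scram), key(base), tolerance = 1e-10)
})

test_that("conditioning on an independent variant barely moves the p-value", {
  set.seed(96)
  n <- 6000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-2 + log(1.6) * g1))
  r <- conditional_test(y, g1, known = g2)
  expect_equal(r$status, "ok")
  expect_lt(abs(log(r$conditional_p / r$p)), 0.5)
})

test_that("conditioning on the variant itself is reported as collinear", {
  set.seed(97)
  g <- rbinom(500, 2, 0.3)
  y <- rbinom(500, 1, 0.2)
  expect_equal(conditional_test(y, g, known = g)$status, "collinear")
})

test_that("conditioning on the causal LD partner attenuates the index signal", {
  pair <- generate_ld_pair(5000, c(0.3, 0.3), r2 = 0.8, seed = 98)
  set.seed(98)
  y <- rbinom(5000, 1, plogis(-2.2 + log(2) * pair[, "g2"]))
  r <- conditional_test(y, pair[, "g1"], known = pair[, "g2"])
  expect_lt(r$p, 0.05)                 # index shows a marginal signal via LD
  expect_gt(r$conditional_p, r$p)      # which conditioning absorbs
})

test_that("the genome scan filters on MAF and flags planted effects as suggestive", {
  set.seed(99)
  n <- 4000
  persons <- sprintf("p%04d", 1:n)
  rare <- c(rep(1L, 14), rep(0L, n - 14))            # MAF 0.00175 < 1%
  causal <- rbinom(n, 2, 0.2)
  nullv <- rbinom(n, 2, 0.3)
  geno <- cbind(v_rare = rare, v_causal = causal, v_null = nullv)
  rownames(geno) <- persons
  y <- rbinom(n, 1, plogis(qlogis(0.1) + log(3) * causal))
  phen <- tibble::tibble(person_id = persons, is_case = y == 1L)
  rx <- tibble::tibble(person_id = persons, atc = "M01AC01")
  cohorts <- build_cohorts(rx, phen, min_prescribed = 1000)
  scan <- genome_scan(geno, cohorts, phen, maf_min = 0.01, p_suggestive = 1e-6)
  expect_false("v_rare" %in% scan$results$variant)
  expect_true(all(c("v_causal", "v_null") %in% scan$results$variant))
  expect_true("v_causal" %in% scan$suggestive$variant)
  expect_false("v_null" %in% scan$suggestive$variant)
})

test_that("cohorts lacking cases are skipped by the genome scan with a warning", {
  persons <- sprintf("p%03d", 1:200)
  geno <- matrix(rbinom(200, 2, 0.3), ncol = 1,
                 dimnames = list(persons, "v1"))
  phen <- tibble::tibble(person_id = persons, is_case = FALSE)
  cohorts <- build_cohorts(tibble::tibble(person_id = persons, atc = "A01AA01"),
                           phen, min_prescribed = 10)
  expect_warning(scan <- genome_scan(geno, cohorts, phen), "no cases")
  expect_equal(nrow(scan$results), 0L)
})

test_that("the drug-independent group test uses prescription-free cases and clean controls", {
  spec <- cohort_spec(8000, 1, maf = 0.3, n_drugs = 2, prescription_rate = 0.4,
                      base_ade_rate = 0.08, background_ade_rate = 0.01,
                      planted_effects = planted_effect("v0001", "A01AA", log(3)),
                      seed = 100)
  co <- generate_cohort(spec)
  phen <- extract_ades(co$diagnoses, co$self_reports, ade_codelist_example(),
                       persons = co$covariates$person_id)
  expect_error(drug_independent_test(co$genotypes[, 1], phen, "no_such_group"),
               "no cases")
  # within-cohort signal
  prescribed <- unique(co$prescriptions$person_id[startsWith(co$prescriptions$atc, "A01AA")])
  y <- prescribed %in% phen$phenotypes$person_id[phen$phenotypes$is_case]
  in_cohort <- fit_logistic(y, co$genotypes[prescribed, 1], co$covariates, prescribed)
  # drug-independent test in the single busiest group is attenuated
  grp <- group_ades(phen)
  busiest <- names(sort(table(grp$group), decreasing = TRUE))[1]
  indep <- drug_independent_test(co$genotypes[, 1], phen, busiest, co$covariates)
  expect_equal(indep$status, "ok")
  expect_gt(indep$p, in_cohort$p)
})
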