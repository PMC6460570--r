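# Replication stage: refine genome-scan hits by diagnostic group, gate
# replication p-values with a Bonferroni correction, and combine discovery and
# replication evidence with the directional Stouffer (sum-of-z) method.

#' Refine a hit by diagnostic group
#'
#' Refits the association within a drug cohort once per diagnostic group,
#' with cases = cohort persons having an ADE event in that group and
#' controls = cohort persons with no ADE at all (persons with ADEs only in
#' other groups are excluded). Groups with fewer than two cases are skipped.
#' The group minimising the p-value is returned; ties break towards the
#' larger case count, then lexicographically.
#'
#' @param g Named dosage vector over persons.
#' @param phenotypes An `ade_phenotypes` object.
#' @param cohort_persons Person ids of the drug-exposure cohort.
#' @param covariates Optional covariate table.
#' @param coding Genotype coding, default additive.
#' @param variant,cohort Labels carried into the result.
#' @return List with `best_group`, `p_discovery`, `direction` (sign of beta),
#'   and `by_group` (tibble of per-group fits).
#' @export
refine_by_group <- function(g, phenotypes, cohort_persons, covariates = NULL,
                            coding = "additive", variant = NA_character_,
                            cohort = NA_character_) {
  .assert(inherits(phenotypes, "ade_phenotypes"), "phenotypes must come from extract_ades()")
  groups_tab <- group_ades(phenotypes)
  phen <- phenotypes$phenotypes
  cohort_persons <- intersect(cohort_persons, names(g))
  controls <- intersect(cohort_persons, phen$person_id[!phen$is_case])
  rows <- list()
  for (grp in phenotypes$codelist$groups) {
    cases <- intersect(cohort_persons,
                       groups_tab$person_id[groups_tab$group == grp])
    if (length(cases) < 2L) next
    persons <- c(cases, controls)
    r <- fit_logistic(persons %in% cases, g[persons], covariates, persons,
                      coding, variant = variant, cohort = cohort)
    r$group <- grp
    r$n_cases <- length(cases)
    rows[[length(rows) + 1L]] <- r
  }
  .assert(length(rows) > 0L, "no diagnostic group has at least 2 cases in this cohort")
  by_group <- dplyr::bind_rows(rows)
  eligible <- by_group[by_group$status == "ok" & !is.na(by_group$p), , drop = FALSE]
  .assert(nrow(eligible) > 0L, "no diagnostic group yielded a valid fit")
  ord <- order(eligible$p, -eligible$n_cases, eligible$group)
  best <- eligible[ord[1L], ]
  list(best_group = best$group, p_discovery = best$p,
       direction = sign(best$beta), by_group = by_group)
}

#' Bonferroni gate for replication tests
#'
#' Passes a p-value when `p < alpha / m` with `m` the number of tests (with
#' the defaults and five tests, the threshold is exactly 0.01).
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param alpha Family-wise level, default 0.05.
#' @return Logical vector of pass flags; the threshold is attached as
#'   `attr(, "threshold")`.
#' @export
bonferroni_gate <- function(p_values, alpha = 0.05) {
  .assert(length(p_values) > 0L, "empty p-value list")
  .assert(all(p_values > 0 & p_values <= 1), "p-values must be in (0, 1]")
  thr <- alpha / length(p_values)
  structure(p_values < thr, threshold = thr)
}

#' Sum-of-z (Stouffer) p-value combination
#'
#' Combines per-cohort evidence as `z_i = qnorm(1 - p_one_i) * sign_i`,
#' `z_combined = sum(z_i) / sqrt(k)` (unweighted). Two-sided inputs are
#' converted to one-sided via `p/2` with the effect direction, the standard
#' directional Stouffer construction.
#'
#' @param p Vector of p-values in (0, 1).
#' @param direction Optional vector of effect signs (+1/-1). Required when
#'   `input = "two_sided"`; defaults to all +1 for one-sided input.
#' @param input `"one_sided"` (default) or `"two_sided"`.
#' @return List with `z` (per-cohort), `z_combined`, `p_one`, `p_two`, `k`.
#' @export
sum_of_z <- function(p, direction = NULL, input = c("one_sided", "two_sided")) {
  input <- match.arg(input)
  .assert(all(p > 0 & p < 1), "p-values must be strictly inside (0, 1)")
  k <- length(p)
  .assert(k >= 1L, "at least one p-value is required")
  if (input == "two_sided") {
    .assert(!is.null(direction), "two-sided input needs effect directions")
    p_one <- p / 2
    sgn <- sign(direction)
  } else {
    p_one <- p
    sgn <- if (is.null(direction)) rep(1, k) else sign(direction)
  }
  z <- qnorm(1 - p_one) * sgn
  z_comb <- sum(z) / sqrt(k)
  list(z = z, z_combined = z_comb,
       p_one = pnorm(-z_comb), p_two = 2 * pnorm(-abs(z_comb)), k = k)
}

#' Replicate suggestive hits in an independent cohort
#'
#' For each suggestive discovery association, refines the discovery phenotype
#' by diagnostic group, refits the variant in the replication cohort (within
#' the same ATC-4 drug cohort, refined-group cases vs ADE-free controls)
#' using the reduced replication covariate set (age, BMI, sex), applies the
#' Bonferroni gate across hits, and combines discovery and replication with
#' the directional sum-of-z method.
#'
#' @param suggestive Suggestive subset from [genome_scan()].
#' @param rep_cohort A `pharm_cohort` for the replication sample.
#' @param rep_phen `ade_phenotypes` of the replication sample.
#' @param discovery Optional list passing the discovery `cohort`
#'   (`pharm_cohort`) and `phenotypes` to refine discovery groups; when
#'   omitted, the unrefined discovery p is combined.
#' @param alpha,m_tests Bonferroni parameters (defaults 0.05 and the number
#'   of hits).
#' @return Tibble: one row per hit with discovery/replication p, direction,
#'   Bonferroni pass flag, and meta-analysis z and p.
#' @export
replicate_hits <- function(suggestive, rep_cohort, rep_phen, discovery = NULL,
                           alpha = 0.05, m_tests = nrow(suggestive)) {
  .assert(nrow(suggestive) > 0L, "no suggestive hits to replicate")
  rep_cov <- rep_cohort$covariates
  rep_cov$PC1 <- rep_cov$PC2 <- rep_cov$PC3 <- rep_cov$PC4 <- 0
  rep_cov$platform <- "chip"  # reduced replication covariate set: age, BMI, sex
  rows <- list()
  for (i in seq_len(nrow(suggestive))) {
    v <- suggestive$variant[i]; atc4 <- suggestive$cohort[i]
    p_d <- suggestive$p[i]; dir_d <- sign(suggestive$beta[i])
    best_group <- NA_character_
    if (!is.null(discovery)) {
      disc_persons <- .prescribed_persons(discovery$cohort$prescriptions, atc4)
      ref <- refine_by_group(discovery$cohort$genotypes[, v],
                             discovery$phenotypes, disc_persons,
                             discovery$cohort$covariates,
                             variant = v, cohort = atc4)
      best_group <- ref$best_group
      p_d <- ref$p_discovery
      dir_d <- ref$direction
    }
    rep_persons <- .prescribed_persons(rep_cohort$prescriptions, atc4)
    rep_persons <- intersect(rep_persons, rownames(rep_cohort$genotypes))
    g <- rep_cohort$genotypes[rep_persons, v]
    if (!is.na(best_group)) {
      groups_tab <- group_ades(rep_phen)
      cases <- intersect(rep_persons,
                         groups_tab$person_id[groups_tab$group == best_group])
      controls <- intersect(rep_persons,
                            rep_phen$phenotypes$person_id[!rep_phen$phenotypes$is_case])
      persons <- c(cases, controls)
      r <- fit_logistic(persons %in% cases, rep_cohort$genotypes[persons, v],
                        rep_cov, persons, variant = v, cohort = atc4)
    } else {
      y <- rep_persons %in% rep_phen$phenotypes$person_id[rep_phen$phenotypes$is_case]
      r <- fit_logistic(y, g, rep_cov, rep_persons, variant = v, cohort = atc4)
    }
    meta <- if (r$status == "ok") {
      sum_of_z(c(p_d, r$p), direction = c(dir_d, sign(r$beta)),
               input = "two_sided")
    } else list(z_combined = NA_real_, p_one = NA_real_, p_two = NA_real_)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variant = v, cohort = atc4, best_group = best_group,
      p_discovery = p_d, direction_discovery = dir_d,
      p_replication = r$p, direction_replication = sign(r$beta),
      n_replication = r$n, status_replication = r$status,
      z_meta = meta$z_combined, p_meta_one = meta$p_one, p_meta_two = meta$p_two)
  }
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p_replication)
  out$bonferroni_pass <- FALSE
  if (any(ok)) {
    out$bonferroni_pass[ok] <- out$p_replication[ok] < alpha / m_tests
  }
  out
}
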