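# Shared readers/writers and the pipeline orchestrator. Coordinates are VCF
# 1-based closed internally; BED input is converted at the boundary.

.ATC_RE <- "^[A-Z][0-9]{2}[A-Z]{2}([0-9]{2})?$"
.ICD10_RE <- "^[A-Z][0-9]{2}(\\.?[0-9A-Z]{1,3})?$"

.read_tsv <- function(path, ...) readr::read_tsv(path, show_col_types = FALSE,
                                                 progress = FALSE, ...)

#' Write a genotype matrix as VCF 4.2
#'
#' Minimal deterministic writer (GT field only, diploid, unphased). Identical
#' inputs produce byte-identical files, which the reproducibility guarantees
#' of [generate_cohort()] rely on.
#'
#' @param genotypes Person x variant dosage matrix (0/1/2, NA = missing) with
#'   dimnames.
#' @param variants Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt` in
#'   column order of `genotypes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  .assert(ncol(genotypes) == nrow(variants), "genotypes/variants dimension mismatch")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(variants), ncol = nrow(genotypes))
  dm <- t(genotypes)  # variants x persons
  ok <- !is.na(dm)
  gt[ok] <- gt_code[as.character(dm[ok])]
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Parses GT fields into alt-allele dosages (0/1/2, NA for missing), phased or
#' unphased.
#'
#' @param path VCF path (plain or gzipped).
#' @return List with `genotypes` (person x variant dosage matrix) and
#'   `variants` (tibble: chrom, pos, id, ref, alt).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(dos) <- ids
  list(genotypes = t(dos),
       variants = tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                                 id = ids, ref = fix$REF, alt = fix$ALT))
}

#' Write a synthetic cohort to disk
#'
#' Writes `genotypes.vcf`, `prescriptions.tsv`, `diagnoses.tsv`,
#' `self_reports.tsv`, `covariates.tsv`, and `truth.json` into `dir`.
#' Outputs are byte-identical for identical cohorts.
#'
#' @param cohort A `pharm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  .assert(inherits(cohort, "pharm_cohort"), "cohort must be a pharm_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort$genotypes, cohort$variants, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(cohort$prescriptions, file.path(dir, "prescriptions.tsv"), progress = FALSE)
  readr::write_tsv(cohort$diagnoses, file.path(dir, "diagnoses.tsv"), progress = FALSE)
  readr::write_tsv(cohort$self_reports, file.path(dir, "self_reports.tsv"), progress = FALSE)
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"), progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Validate pipeline input files
#'
#' Report-only structural checks: VCF header and GT FORMAT presence, ATC and
#' ICD10 code grammar, covariate-table completeness.
#'
#' @param vcf,prescriptions,diagnoses,covariates Optional file paths; `NULL`
#'   entries are not checked.
#' @return Tibble with columns `severity` (`"error"`/`"warning"`), `input`,
#'   `message`. Zero rows means all checks passed.
#' @export
validate_inputs <- function(vcf = NULL, prescriptions = NULL, diagnoses = NULL,
                            covariates = NULL) {
  out <- list()
  note <- function(severity, input, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(severity = severity, input = input,
                                               message = message)
  }
  for (p in c(vcf, prescriptions, diagnoses, covariates)) {
    if (!file.exists(p)) note("error", p, "file does not exist")
  }
  if (!is.null(vcf) && file.exists(vcf)) {
    head_lines <- readLines(vcf, n = 200L)
    if (!any(grepl("^##fileformat=VCF", head_lines)))
      note("error", vcf, "missing ##fileformat VCF header")
    if (!any(grepl("^##FORMAT=<ID=GT", head_lines)))
      note("error", vcf, "no GT FORMAT declaration in header")
  }
  if (!is.null(prescriptions) && file.exists(prescriptions)) {
    rx <- .read_tsv(prescriptions)
    missing_cols <- setdiff(c("person_id", "atc", "date"), names(rx))
    if (length(missing_cols) > 0L) {
      note("error", prescriptions,
           paste("missing columns:", paste(missing_cols, collapse = ", ")))
    } else {
      bad <- unique(rx$atc[!grepl(.ATC_RE, rx$atc)])
      if (length(bad) > 0L)
        note("error", prescriptions,
             paste("ATC codes violating grammar:", paste(head(bad, 5L), collapse = ", ")))
    }
  }
  if (!is.null(diagnoses) && file.exists(diagnoses)) {
    dx <- .read_tsv(diagnoses)
    if (!"icd10" %in% names(dx)) {
      note("error", diagnoses, "missing columns: icd10")
    } else {
      bad <- unique(dx$icd10[!grepl(.ICD10_RE, dx$icd10)])
      if (length(bad) > 0L)
        note("warning", diagnoses,
             paste("ICD10 codes violating grammar (will be skipped):",
                   paste(head(bad, 5L), collapse = ", ")))
    }
  }
  if (!is.null(covariates) && file.exists(covariates)) {
    cv <- .read_tsv(covariates)
    need <- c("person_id", "sex", "age", "bmi", "PC1", "PC2", "PC3", "PC4", "platform")
    missing_cols <- setdiff(need, names(cv))
    if (length(missing_cols) > 0L)
      note("error", covariates,
           paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if ("person_id" %in% names(cv) && anyDuplicated(cv$person_id) > 0L)
      note("error", covariates, "duplicate person ids")
  }
  if (length(out) == 0L)
    return(tibble::tibble(severity = character(), input = character(),
                          message = character()))
  dplyr::bind_rows(out)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate, phenotype, link, assoc (candidate scan), gwas, and
#' replicate stages on a synthetic cohort, writing stage outputs and a
#' provenance manifest (package version, seed, thresholds, input-file hashes)
#' under `out_dir`. Reruns with the same config reproduce identical outputs.
#' The replicate stage runs only when a `replication_spec` is supplied (an
#' independent cohort drawn with a different seed); otherwise it is recorded
#' as skipped in the manifest.
#'
#' @param spec A [cohort_spec()] for the simulated discovery cohort.
#' @param out_dir Output directory.
#' @param map Optional gene-drug map tibble (`gene`, `variant_id`, `atc`,
#'   `level`) enabling the candidate scan stage.
#' @param variant_genes Optional named vector variant id -> gene (required
#'   with `map`).
#' @param replication_spec Optional [cohort_spec()] for the replication stage.
#' @param codelist ADE code list, default bundled example.
#' @param min_prescribed Minimum distinct prescribed persons per ATC-4 cohort
#'   (genome-wide stage), default 1000.
#' @param min_participants Minimum prescribed persons per candidate pair,
#'   default 500.
#' @param maf_min Genome-scan MAF filter, default 0.01.
#' @param p_suggestive Suggestive significance threshold, default 1e-6.
#' @param alpha,m_tests Replication Bonferroni parameters, defaults 0.05 and 5.
#' @return Invisibly, a list with the manifest and the per-stage results.
#' @export
run_pipeline <- function(spec, out_dir, map = NULL, variant_genes = NULL,
                         replication_spec = NULL,
                         codelist = ade_codelist_example(),
                         min_prescribed = 1000, min_participants = 500,
                         maf_min = 0.01, p_suggestive = 1e-6,
                         alpha = 0.05, m_tests = 5) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "phenotype", "link", "assoc", "gwas", "replicate")
  status <- stats::setNames(rep("skipped", length(stages)), stages)
  results <- list()

  data_dir <- file.path(out_dir, "data")
  cohort <- generate_cohort(spec, codelist = codelist, out_dir = data_dir)
  status["simulate"] <- "done"

  phen <- extract_ades(cohort$diagnoses, cohort$self_reports, codelist,
                       persons = cohort$covariates$person_id)
  readr::write_tsv(phen$phenotypes, file.path(out_dir, "phenotypes.tsv"), progress = FALSE)
  results$phenotypes <- phen
  status["phenotype"] <- "done"

  cohorts <- build_cohorts(cohort$prescriptions, phen,
                           min_prescribed = min_prescribed)
  readr::write_tsv(
    tibble::tibble(atc4 = cohorts$atc4, n_prescribed = cohorts$n_prescribed,
                   n_cases = vapply(cohorts$cases, length, integer(1)),
                   n_controls = vapply(cohorts$controls, length, integer(1))),
    file.path(out_dir, "cohorts.tsv"), progress = FALSE)
  results$cohorts <- cohorts
  status["link"] <- "done"

  if (!is.null(map)) {
    .assert(!is.null(variant_genes), "variant_genes is required with map")
    scan <- candidate_scan(cohort$genotypes, variant_genes, map,
                           cohort$prescriptions, phen, cohort$covariates,
                           min_prescribed = min_participants)
    readr::write_tsv(scan, file.path(out_dir, "candidate_scan.tsv"), progress = FALSE)
    results$candidate_scan <- scan
    status["assoc"] <- "done"
    flows <- triad_overlap(cohort$genotypes, variant_genes,
                           cohort$prescriptions, phen, map)
    readr::write_tsv(flows, file.path(out_dir, "triad_flows.tsv"), progress = FALSE)
    write_sankey_json(flows, file.path(out_dir, "triad_sankey.json"))
    results$flows <- flows
  }

  gwas <- genome_scan(cohort$genotypes, cohorts, phen, cohort$covariates,
                      maf_min = maf_min, p_suggestive = p_suggestive)
  readr::write_tsv(gwas$results, file.path(out_dir, "gwas.tsv"), progress = FALSE)
  results$gwas <- gwas
  status["gwas"] <- "done"

  if (!is.null(replication_spec) && nrow(gwas$suggestive) > 0L) {
    rep_cohort <- generate_cohort(replication_spec, codelist = codelist)
    rep_phen <- extract_ades(rep_cohort$diagnoses, rep_cohort$self_reports,
                             codelist, persons = rep_cohort$covariates$person_id)
    meta <- replicate_hits(gwas$suggestive, rep_cohort, rep_phen,
                           alpha = alpha, m_tests = m_tests)
    readr::write_tsv(meta, file.path(out_dir, "replication.tsv"), progress = FALSE)
    results$replication <- meta
    status["replicate"] <- "done"
  }

  data_files <- list.files(data_dir, full.names = TRUE)
  manifest <- list(
    package = "pharmscan",
    version = as.character(utils::packageVersion("pharmscan")),
    seed = spec$seed,
    thresholds = list(min_prescribed = min_prescribed,
                      min_participants = min_participants, maf_min = maf_min,
                      p_suggestive = p_suggestive, alpha = alpha,
                      m_tests = m_tests),
    stages = lapply(stages, function(s) list(name = s, status = unname(status[s]))),
    inputs = as.list(stats::setNames(unname(tools::md5sum(data_files)),
                                     basename(data_files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}

#' Read transcript models from a GFF3 file
#'
#' Builds [transcript_model()] objects from `mRNA`/`transcript`, `exon`, and
#' `CDS` features linked by `Parent` attributes. The gene symbol is taken
#' from the transcript's `gene` attribute when present, else its `ID`.
#'
#' @param path GFF3 path.
#' @return Named list of `transcript_model` objects (by transcript ID).
#' @export
read_transcript_models <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$type <- as.character(gr$type)
  first_chr <- function(x) vapply(x, function(v) as.character(v)[1], character(1))
  tx_rows <- gr[gr$type %in% c("mRNA", "transcript"), , drop = FALSE]
  .assert(nrow(tx_rows) > 0L, "no mRNA/transcript features in %s", path)
  out <- list()
  for (i in seq_len(nrow(tx_rows))) {
    id <- tx_rows$ID[i]
    parent <- if ("Parent" %in% names(gr)) first_chr(gr$Parent) else rep(NA_character_, nrow(gr))
    exons <- gr[gr$type == "exon" & parent == id, c("start", "end"), drop = FALSE]
    cds <- gr[gr$type == "CDS" & parent == id, c("start", "end"), drop = FALSE]
    .assert(nrow(exons) > 0L && nrow(cds) > 0L,
            "transcript %s lacks exon or CDS features", id)
    gene <- if ("gene" %in% names(tx_rows) && !is.na(tx_rows$gene[i])) tx_rows$gene[i] else id
    out[[id]] <- transcript_model(gene, as.character(tx_rows$seqnames[i]),
                                  as.character(tx_rows$strand[i]), exons, cds)
  }
  out
}

#' Read BED intervals as 1-based closed coordinates
#'
#' Converts the 0-based half-open BED convention at the I/O boundary, e.g.
#' for ChIP-seq masks passed to [scan_promoter()].
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
read_bed_intervals <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "bed"))
  tibble::tibble(chrom = as.character(gr$seqnames),
                 start = as.integer(gr$start), end = as.integer(gr$end))
}
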