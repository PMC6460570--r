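# Drug-exposure cohorts and gene-drug-ADE linkage. Drugs are grouped at ATC
# level 4 (first five characters); a cohort keeps the distinct persons with any
# prescription in the group, split into cases (any ADE) and controls.

#' Construct or read a gene-drug association map
#'
#' PharmGKB-style rows linking genes (optionally via a specific variant or
#' star allele) to drugs with a level of evidence.
#'
#' @param gene,variant_id,atc,level Equal-length vectors; `level` must use the
#'   vocabulary 1A/1B/2A/2B/3/4.
#' @return Tibble of class `gene_drug_map`.
#' @export
gene_drug_map <- function(gene, variant_id = NA_character_, atc, level = "3") {
  lv <- as.character(level)
  .assert(all(lv %in% c("1A", "1B", "2A", "2B", "3", "4")),
          "level of evidence must be one of 1A, 1B, 2A, 2B, 3, 4")
  .assert(all(grepl(.ATC_RE, atc)), "ATC codes violating grammar: %s",
          paste(unique(atc[!grepl(.ATC_RE, atc)]), collapse = ", "))
  out <- tibble::tibble(gene = as.character(gene),
                        variant_id = as.character(variant_id),
                        atc = as.character(atc), level = lv)
  class(out) <- c("gene_drug_map", class(out))
  out
}

#' @rdname gene_drug_map
#' @param path TSV with columns `gene`, `variant_id`, `atc`, `level`.
#' @export
read_gene_drug_map <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("gene", "atc", "level") %in% names(tab)),
          "gene-drug map needs columns gene, atc, level")
  gene_drug_map(tab$gene,
                variant_id = if ("variant_id" %in% names(tab)) tab$variant_id else NA,
                atc = tab$atc, level = tab$level)
}

# ATC level-4 prefix; rejects codes shorter than 5 characters
.atc4 <- function(atc) {
  .assert(all(nchar(atc) >= 5L & grepl(.ATC_RE, atc)),
          "ATC codes shorter than 5 characters or violating grammar: %s",
          paste(unique(atc[nchar(atc) < 5L | !grepl(.ATC_RE, atc)]), collapse = ", "))
  substr(atc, 1L, 5L)
}

#' Build drug-exposure cohorts at ATC level 4
#'
#' Groups prescriptions by the five-character ATC level-4 prefix, counts each
#' person once per group regardless of refills, keeps groups with at least
#' `min_prescribed` distinct persons, and labels prescribed persons as cases
#' (any ADE) or controls.
#'
#' @param prescriptions Tibble with columns `person_id`, `atc`.
#' @param phenotypes An `ade_phenotypes` object from [extract_ades()] (or a
#'   tibble with `person_id`, `is_case`).
#' @param min_prescribed Minimum distinct prescribed persons per retained
#'   group (default 1000).
#' @return Tibble with one row per retained cohort: `atc4`, `n_prescribed`,
#'   and list-columns `persons`, `cases`, `controls`.
#' @export
build_cohorts <- function(prescriptions, phenotypes, min_prescribed = 1000) {
  phen <- if (inherits(phenotypes, "ade_phenotypes")) phenotypes$phenotypes else phenotypes
  empty <- tibble::tibble(atc4 = character(), n_prescribed = integer(),
                          persons = list(), cases = list(), controls = list())
  if (nrow(prescriptions) == 0L) return(empty)
  grp <- .atc4(prescriptions$atc)
  case_ids <- phen$person_id[phen$is_case]
  by_grp <- split(as.character(prescriptions$person_id), grp)
  rows <- lapply(sort(names(by_grp)), function(g) {
    persons <- sort(unique(by_grp[[g]]))
    if (length(persons) < min_prescribed) return(NULL)
    cases <- persons[persons %in% case_ids]
    controls <- setdiff(persons, cases)
    tibble::tibble(atc4 = g, n_prescribed = length(persons),
                   persons = list(persons), cases = list(cases),
                   controls = list(controls))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  dplyr::bind_rows(rows)
}

#' Flag carriers of a multi-variant allele
#'
#' A person carries the allele if any defining variant is heterozygous or
#' homozygous (dosage at least 1). Persons missing at every defining site are
#' flagged `NA`.
#'
#' @param genotypes Person x variant dosage matrix.
#' @param allele_def Character vector of defining variant ids (columns of
#'   `genotypes`).
#' @return Named logical vector over persons.
#' @export
assign_allele_carriers <- function(genotypes, allele_def) {
  .assert(length(allele_def) > 0L, "allele definition is empty")
  missing_vars <- setdiff(allele_def, colnames(genotypes))
  .assert(length(missing_vars) == 0L, "defining variants absent from genotypes: %s",
          paste(missing_vars, collapse = ", "))
  g <- genotypes[, allele_def, drop = FALSE]
  carrier <- rowSums(g >= 1L, na.rm = TRUE) > 0L
  carrier[rowSums(!is.na(g)) == 0L] <- NA
  carrier
}

#' Gene-drug-ADE triad overlap counts
#'
#' For every (gene, drug) pair in the map, counts persons carrying any
#' qualifying variant of the gene, persons prescribed the drug, persons with
#' an ADE, and the three-way intersection. Rows whose three-way count falls
#' below `min_n` are flagged `suppressed` for plot export but retained in the
#' table. Gene-to-drug linkage is at gene level: all map drugs of a variant's
#' gene count.
#'
#' @param genotypes Person x variant dosage matrix.
#' @param variant_genes Named character vector mapping variant id to gene.
#' @param prescriptions Tibble `person_id`, `atc`.
#' @param phenotypes `ade_phenotypes` or tibble with `person_id`, `is_case`.
#' @param map A [gene_drug_map()].
#' @param min_n Suppression threshold for the flow export (default 10).
#' @return Tibble: `gene`, `atc`, `n_carrier`, `n_prescribed`, `n_ade`,
#'   `n_triad`, `suppressed`.
#' @export
triad_overlap <- function(genotypes, variant_genes, prescriptions, phenotypes,
                          map, min_n = 10) {
  phen <- if (inherits(phenotypes, "ade_phenotypes")) phenotypes$phenotypes else phenotypes
  case_ids <- phen$person_id[phen$is_case]
  pairs <- dplyr::distinct(tibble::tibble(gene = map$gene, atc = map$atc))
  rx_person <- as.character(prescriptions$person_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    gene <- pairs$gene[i]; atc <- pairs$atc[i]
    vids <- intersect(names(variant_genes)[variant_genes == gene],
                      colnames(genotypes))
    carriers <- if (length(vids) > 0L) {
      flags <- assign_allele_carriers(genotypes, vids)
      names(flags)[!is.na(flags) & flags]
    } else character()
    prescribed <- unique(rx_person[startsWith(prescriptions$atc, atc)])
    triad <- length(intersect(intersect(carriers, prescribed), case_ids))
    tibble::tibble(gene = gene, atc = atc,
                   n_carrier = length(carriers),
                   n_prescribed = length(prescribed),
                   n_ade = length(case_ids),
                   n_triad = triad,
                   suppressed = triad < min_n)
  })
  dplyr::bind_rows(rows)
}

#' Export triad flows as Sankey-ready JSON
#'
#' Writes a nodes/links JSON for standard Sankey plotting tools, dropping
#' suppressed rows.
#'
#' @param flows Output of [triad_overlap()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sankey_json <- function(flows, path) {
  keep <- flows[!flows$suppressed, , drop = FALSE]
  genes <- unique(keep$gene)
  drugs <- unique(keep$atc)
  nodes <- c(genes, drugs, "ADE")
  links <- list()
  for (i in seq_len(nrow(keep))) {
    gi <- match(keep$gene[i], nodes) - 1L
    di <- match(keep$atc[i], nodes) - 1L
    links[[length(links) + 1L]] <- list(source = gi, target = di,
                                        value = keep$n_triad[i])
    links[[length(links) + 1L]] <- list(source = di,
                                        target = length(nodes) - 1L,
                                        value = keep$n_triad[i])
  }
  jsonlite::write_json(list(nodes = lapply(nodes, function(n) list(name = n)),
                            links = links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
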