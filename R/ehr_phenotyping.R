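# ADE phenotyping from EHR-style diagnosis tables. A diagnosis is an ADE event
# when its ICD10 code prefix-matches a configurable code list and, for codes
# whose description does not tie them to drugs directly, a physician
# confirmation flag is set (modelling manual chart review). Self-reported ADEs
# are always included. Events are mapped to 12 diagnostic groups defined by the
# leading pathophysiological mechanism and affected organ system.

.norm_icd10 <- function(x) gsub("\\.", "", toupper(trimws(x)))
.ICD10_NORM_RE <- "^[A-Z][0-9]{2}[0-9A-Z]{0,3}$"

#' Construct an ADE code list
#'
#' @param codes Character vector of ICD10 code prefixes that define possible
#'   adverse-drug-effect diagnoses (e.g. `"L23.3"`, or `"M60"` to match any
#'   M60.x).
#' @param requires_confirmation Subset of `codes` that only count as ADE
#'   events when the diagnosis record carries `physician_confirmed = TRUE`.
#' @param group_map Named character vector mapping every code in `codes` to
#'   its diagnostic group.
#' @return An `ade_codelist`.
#' @export
ade_codelist <- function(codes, requires_confirmation = character(), group_map) {
  codes <- as.character(codes)
  .assert(!anyDuplicated(codes), "duplicate codes in code list")
  .assert(all(requires_confirmation %in% codes),
          "requires_confirmation must be a subset of codes")
  .assert(all(codes %in% names(group_map)),
          "every code needs a diagnostic group; missing: %s",
          paste(setdiff(codes, names(group_map)), collapse = ", "))
  bad <- codes[!grepl(.ICD10_NORM_RE, .norm_icd10(codes))]
  .assert(length(bad) == 0L, "malformed ICD10 codes in list: %s",
          paste(bad, collapse = ", "))
  structure(list(codes = codes,
                 requires_confirmation = as.character(requires_confirmation),
                 group_map = group_map[codes],
                 groups = sort(unique(unname(group_map[codes])))),
            class = "ade_codelist")
}

#' Read an ADE code list from a TSV config
#'
#' Expects columns `code`, `group`, `requires_confirmation` (logical).
#'
#' @param path TSV path.
#' @return An [ade_codelist()].
#' @export
read_ade_codelist <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("code", "group", "requires_confirmation") %in% names(tab)),
          "code list config needs columns code, group, requires_confirmation")
  ade_codelist(tab$code,
               requires_confirmation = tab$code[tab$requires_confirmation],
               group_map = stats::setNames(tab$group, tab$code))
}

#' Bundled synthetic example ADE code list
#'
#' A synthetic, editable example configuration of 79 ICD10 codes for possible
#' drug-induced diagnoses, regrouped into 12 diagnostic groups, with
#' per-code confirmation requirements. It is a plausible stand-in assembled
#' from public ICD10 drug-induced codes, not the access-controlled study
#' list; replace it with your own config for real analyses.
#'
#' @return An [ade_codelist()].
#' @export
ade_codelist_example <- function() {
  read_ade_codelist(system.file("extdata", "ade_codes_synthetic.tsv",
                                package = "pharmscan", mustWork = TRUE))
}

# longest code-list prefix matching each normalized record code; NA if none
.match_code <- function(norm_records, codelist) {
  norm_list <- .norm_icd10(codelist$codes)
  ord <- order(nchar(norm_list), decreasing = TRUE)
  norm_list <- norm_list[ord]
  orig <- codelist$codes[ord]
  out <- rep(NA_character_, length(norm_records))
  for (i in seq_along(norm_list)) {
    hit <- is.na(out) & startsWith(norm_records, norm_list[i])
    out[hit] <- orig[i]
  }
  out
}

#' Extract ADE phenotypes from diagnoses and self-reports
#'
#' A diagnosis record becomes an ADE event when its ICD10 code prefix-matches
#' the code list and, if the matched code requires confirmation, the record is
#' physician-confirmed. Every self-report becomes an event with source
#' `"self_report"`. Records with malformed ICD10 codes are skipped with a
#' warning (the count is kept in the returned object).
#'
#' @param diagnoses Tibble with columns `person_id`, `icd10`,
#'   `physician_confirmed` (logical; missing column treated as all-FALSE), and
#'   optionally `date`.
#' @param self_reports Optional tibble with `person_id` and optionally `code`,
#'   `date`.
#' @param codelist An [ade_codelist()].
#' @param persons Optional character vector giving the full person universe,
#'   so that persons without events appear as non-cases.
#' @return An `ade_phenotypes` object: list with `phenotypes` (tibble
#'   `person_id`, `is_case`, `n_events`), `events` (tibble `person_id`,
#'   `code`, `group`, `date`, `source`), and `n_skipped`.
#' @export
extract_ades <- function(diagnoses, self_reports = NULL, codelist,
                         persons = NULL) {
  .assert(inherits(codelist, "ade_codelist"), "codelist must be an ade_codelist")
  .assert(all(c("person_id", "icd10") %in% names(diagnoses)),
          "diagnoses needs columns person_id, icd10")
  confirmed <- if ("physician_confirmed" %in% names(diagnoses)) {
    !is.na(diagnoses$physician_confirmed) & diagnoses$physician_confirmed
  } else rep(FALSE, nrow(diagnoses))
  dates <- if ("date" %in% names(diagnoses)) diagnoses$date else rep(as.Date(NA), nrow(diagnoses))

  norm <- .norm_icd10(diagnoses$icd10)
  malformed <- !grepl(.ICD10_NORM_RE, norm)
  n_skipped <- sum(malformed)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d diagnosis record(s) with malformed ICD10 codes",
                    n_skipped), call. = FALSE)
  }
  matched <- .match_code(norm, codelist)
  matched[malformed] <- NA_character_
  needs_conf <- matched %in% codelist$requires_confirmation
  is_event <- !is.na(matched) & (!needs_conf | confirmed)

  events <- tibble::tibble(
    person_id = as.character(diagnoses$person_id[is_event]),
    code = diagnoses$icd10[is_event],
    group = unname(codelist$group_map[matched[is_event]]),
    date = dates[is_event],
    source = "ehr"
  )
  if (!is.null(self_reports) && nrow(self_reports) > 0L) {
    sr_code <- if ("code" %in% names(self_reports)) as.character(self_reports$code) else rep(NA_character_, nrow(self_reports))
    sr_match <- ifelse(is.na(sr_code), NA_character_,
                       .match_code(.norm_icd10(sr_code), codelist))
    events <- dplyr::bind_rows(events, tibble::tibble(
      person_id = as.character(self_reports$person_id),
      code = sr_code,
      group = ifelse(is.na(sr_match), NA_character_,
                     unname(codelist$group_map[sr_match])),
      date = if ("date" %in% names(self_reports)) self_reports$date else rep(as.Date(NA), nrow(self_reports)),
      source = "self_report"
    ))
  }
  events <- events[order(events$person_id, events$source, events$code), ]

  universe <- sort(unique(c(as.character(persons),
                            as.character(diagnoses$person_id),
                            events$person_id)))
  counts <- table(events$person_id)
  phenotypes <- tibble::tibble(
    person_id = universe,
    n_events = as.integer(ifelse(universe %in% names(counts),
                                 counts[universe], 0L)),
    is_case = universe %in% events$person_id
  )[, c("person_id", "is_case", "n_events")]
  structure(list(phenotypes = phenotypes, events = events,
                 n_skipped = n_skipped, codelist = codelist),
            class = "ade_phenotypes")
}

#' @export
print.ade_phenotypes <- function(x, ...) {
  cat(sprintf("ade_phenotypes: %d persons, %d cases, %d events (%d skipped records)\n",
              nrow(x$phenotypes), sum(x$phenotypes$is_case), nrow(x$events),
              x$n_skipped))
  invisible(x)
}

#' Map ADE phenotypes to diagnostic groups
#'
#' Returns, for each case, the distinct diagnostic groups implied by their
#' events under the code list's 12-group mapping. Self-report events without
#' a mappable code carry no group and are excluded here.
#'
#' @param phenotypes An `ade_phenotypes` object from [extract_ades()].
#' @param codelist An [ade_codelist()]; defaults to the one used in
#'   extraction.
#' @return Tibble with columns `person_id`, `group` (one row per distinct
#'   pair).
#' @export
group_ades <- function(phenotypes, codelist = phenotypes$codelist) {
  .assert(inherits(phenotypes, "ade_phenotypes"), "phenotypes must come from extract_ades()")
  ev <- phenotypes$events
  ehr <- ev[ev$source == "ehr", ]
  unmapped <- unique(ehr$code[is.na(ehr$group)])
  .assert(length(unmapped) == 0L, "events with codes missing from group map: %s",
          paste(unmapped, collapse = ", "))
  keep <- !is.na(ev$group)
  dplyr::distinct(tibble::tibble(person_id = ev$person_id[keep],
                                 group = ev$group[keep]))
}
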