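# k-mer copy-number proxy for segmental-duplication genes. Diagnostic k-mers
# (unique genome-wide, inside the target region) are counted in sequencing
# reads and normalised against k-mers from a copy-number-2 control region:
# cn = 2 * median(diagnostic counts) / median(control counts).

# canonical form: lexicographic minimum of a k-mer and its reverse complement
.canonical <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

.as_seqs <- function(x, format = "fasta") {
  if (inherits(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(Biostrings::readDNAStringSet(x, format = format))
  }
  Biostrings::DNAStringSet(toupper(x))
}

# all k-mers of one contig with start positions
.contig_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build a diagnostic k-mer panel for a target region
#'
#' Enumerates all k-mers of the reference in canonical form (lexicographic
#' minimum of the k-mer and its reverse complement) and retains, for the
#' target and control regions, only k-mers occurring exactly once
#' genome-wide with that occurrence inside the region. The control region
#' must be disjoint from the target and is assumed to carry copy number 2.
#'
#' @param reference Named character vector, `DNAStringSet`, or FASTA path.
#' @param region,control Lists `list(chrom, start, end)` (1-based closed).
#' @param k k-mer length, default 25.
#' @return A `kmer_panel`: list with `k`, `kmers` (diagnostic), and
#'   `control_kmers`.
#' @export
build_panel <- function(reference, region, control, k = 25L) {
  seqs <- .as_seqs(reference)
  .assert(!is.null(names(seqs)), "reference contigs must be named")
  .assert(region$chrom %in% names(seqs) && control$chrom %in% names(seqs),
          "region/control chromosome not in reference")
  same_chrom <- region$chrom == control$chrom
  if (same_chrom && region$start <= control$end && control$start <= region$end) {
    .fail("target and control regions overlap; they must be disjoint")
  }
  .assert(k <= region$end - region$start + 1L, "k exceeds the region length")

  tally <- new.env(hash = TRUE)
  where <- list()
  for (chrom in names(seqs)) {
    km <- .contig_kmers(toupper(as.character(seqs[[chrom]])), k)
    if (length(km) == 0L) next
    can <- .canonical(km)
    cnt <- table(can)
    for (nm in names(cnt)) {
      tally[[nm]] <- (if (is.null(tally[[nm]])) 0L else tally[[nm]]) + cnt[[nm]]
    }
    where[[chrom]] <- can
  }
  pick_unique <- function(reg) {
    can <- where[[reg$chrom]]
    starts <- seq_along(can)
    inside <- starts >= reg$start & (starts + k - 1L) <= reg$end
    cand <- unique(can[inside])
    cand[vapply(cand, function(nm) tally[[nm]] == 1L, logical(1))]
  }
  diagnostic <- pick_unique(region)
  .assert(length(diagnostic) > 0L,
          "no region k-mer is unique genome-wide; try a larger k")
  ctrl <- pick_unique(control)
  .assert(length(ctrl) > 0L,
          "no control k-mer is unique genome-wide; try a larger k")
  structure(list(k = as.integer(k), kmers = diagnostic, control_kmers = ctrl),
            class = "kmer_panel")
}

#' Simulate uniform reads from a set of haplotype sequences
#'
#' Toy read generator for validating the copy-number estimator: reads of
#' fixed length drawn uniformly (position and strand) from each haplotype,
#' error-free.
#'
#' @param haplotypes Character vector of haplotype sequences (a diploid
#'   individual passes two).
#' @param coverage Total depth summed over haplotypes (each haplotype gets
#'   `coverage / length(haplotypes)`).
#' @param read_length Read length, default 100.
#' @param seed RNG seed.
#' @return `DNAStringSet` of reads.
#' @export
simulate_reads <- function(haplotypes, coverage = 30, read_length = 100L,
                           seed = 1L) {
  set.seed(seed)
  per_hap <- coverage / length(haplotypes)
  reads <- character()
  for (h in haplotypes) {
    h <- toupper(h)
    n <- nchar(h)
    if (n < read_length) next
    n_reads <- max(1L, round(per_hap * n / read_length))
    starts <- sample.int(n - read_length + 1L, n_reads, replace = TRUE)
    r <- substring(h, starts, starts + read_length - 1L)
    flip <- runif(n_reads) < 0.5
    if (any(flip)) {
      r[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(r[flip])))
    }
    reads <- c(reads, r)
  }
  Biostrings::DNAStringSet(reads)
}

#' Estimate region copy number from reads and a k-mer panel
#'
#' Counts occurrences of the panel's canonical k-mers in the reads (both
#' strands) and returns
#' `cn = 2 * median(diagnostic counts) / median(control counts)`.
#' Diagnostic counts below 10% of the control median are treated as absent
#' (sequencing-error tolerance).
#'
#' @param reads `DNAStringSet`, character vector of reads, or FASTQ path.
#' @param panel A `kmer_panel` from [build_panel()].
#' @param person_id Optional sample label carried into the result.
#' @return List: `person_id`, `cn`, `cn_rounded`, and the per-k-mer count
#'   medians `median_diag`, `median_ctrl`.
#' @export
estimate_cn <- function(reads, panel, person_id = NA_character_) {
  .assert(inherits(panel, "kmer_panel"), "panel must come from build_panel()")
  reads <- .as_seqs(reads, format = "fastq")
  .assert(length(reads) > 0L, "no reads supplied")
  all_kmers <- c(panel$kmers, panel$control_kmers)
  pd <- Biostrings::PDict(all_kmers)
  fwd <- Biostrings::vcountPDict(pd, reads, collapse = 1L)
  rev <- Biostrings::vcountPDict(pd, Biostrings::reverseComplement(reads),
                                 collapse = 1L)
  counts <- fwd + rev
  n_diag <- length(panel$kmers)
  diag_counts <- counts[seq_len(n_diag)]
  ctrl_counts <- counts[n_diag + seq_along(panel$control_kmers)]
  med_ctrl <- median(ctrl_counts)
  .assert(med_ctrl > 0, "control k-mer median is zero; insufficient coverage")
  diag_counts[diag_counts < 0.1 * med_ctrl] <- 0
  med_diag <- median(diag_counts)
  cn <- 2 * med_diag / med_ctrl
  list(person_id = person_id, cn = cn, cn_rounded = as.integer(round(cn)),
       median_diag = med_diag, median_ctrl = med_ctrl)
}

#' Squared Pearson correlation between paired copy-number call sets
#'
#' @param cnv_a,cnv_b Paired numeric vectors (n >= 3) from two independent
#'   CNV callers.
#' @return Squared Pearson correlation (R-squared).
#' @export
correlate_estimates <- function(cnv_a, cnv_b) {
  .assert(length(cnv_a) == length(cnv_b), "vectors must be paired")
  .assert(length(cnv_a) >= 3L, "need at least 3 paired estimates")
  .assert(stats::var(cnv_a) > 0 && stats::var(cnv_b) > 0,
          "zero variance in one of the call sets")
  stats::cor(cnv_a, cnv_b)^2
}
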