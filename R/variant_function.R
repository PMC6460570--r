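# Functional classification of candidate-pharmacogene variants.
#
# Loss-of-function rules (MacArthur-style): stop-gain SNVs, frameshift indels
# in the CDS, and essential splice-site changes (the 2 intronic bases flanking
# each exon). Candidate LoF calls are excluded when the alternate allele is the
# ancestral allele or when the variant lies in the 3'-most 5% of the spliced
# transcript. Remaining coding SNVs that change the encoded amino acid are
# missense. Promoter impact is assessed by scanning the 5-kb region upstream of
# the transcription start site with TRANSFAC-style position weight matrices
# using Match-style matrix/core similarity scores.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
.comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Construct a variant record
#'
#' @param chrom,pos Chromosome and 1-based position.
#' @param ref,alt Reference and alternate alleles (VCF conventions; indels
#'   anchored).
#' @param id Variant identifier (rsID or `"."`).
#' @return A `variant_record` list.
#' @export
variant_record <- function(chrom, pos, ref, alt, id = ".") {
  .assert(pos >= 1, "pos must be 1-based positive")
  .assert(ref != alt, "ref and alt must differ")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = toupper(ref), alt = toupper(alt), id = id),
            class = "variant_record")
}

#' Construct a transcript model
#'
#' @param gene Gene symbol.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with `start`, `end` (1-based closed, genomic
#'   ascending, non-overlapping).
#' @param cds Data frame like `exons`; must lie within exons and have total
#'   length divisible by 3.
#' @param tss Transcription start site; defaults to the 5' transcript end.
#' @return A `transcript_model` list with `transcript_length` precomputed.
#' @export
transcript_model <- function(gene, chrom, strand, exons, cds, tss = NULL) {
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  exons <- exons[order(exons$start), c("start", "end")]
  cds <- cds[order(cds$start), c("start", "end")]
  .assert(all(exons$end >= exons$start), "malformed exon intervals")
  if (nrow(exons) > 1L) {
    .assert(all(exons$start[-1L] > exons$end[-nrow(exons)]),
            "exons must be non-overlapping and sorted")
  }
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, logical(1))
  .assert(all(in_exon), "CDS intervals must lie within exons")
  cds_len <- sum(cds$end - cds$start + 1L)
  .assert(cds_len %% 3L == 0L, "CDS length (%d) not divisible by 3", cds_len)
  if (is.null(tss)) tss <- if (strand == "+") min(exons$start) else max(exons$end)
  structure(list(gene = gene, chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds, tss = as.integer(tss),
                 transcript_length = sum(exons$end - exons$start + 1L)),
            class = "transcript_model")
}

# 5'->3' spliced coordinate of a genomic position within a set of intervals;
# NA when the position falls outside them
.interval_coord <- function(intervals, strand, gpos) {
  hit <- which(gpos >= intervals$start & gpos <= intervals$end)
  if (length(hit) == 0L) return(NA_integer_)
  widths <- intervals$end - intervals$start + 1L
  if (strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (gpos - intervals$start[hit]) + 1L
  } else {
    after <- if (hit < nrow(intervals)) sum(widths[seq(hit + 1L, nrow(intervals))]) else 0L
    after + (intervals$end[hit] - gpos) + 1L
  }
}

# coding-strand CDS sequence
.cds_seq <- function(t, seq) {
  parts <- substring(seq, t$cds$start, t$cds$end)
  s <- toupper(paste(parts, collapse = ""))
  if (t$strand == "-") .revcomp(s) else s
}

# genomic positions of the 2 intronic bases flanking every exon
.splice_positions <- function(t) {
  if (nrow(t$exons) < 2L) return(integer())
  donors <- t$exons$end[-nrow(t$exons)]
  acceptors <- t$exons$start[-1L]
  sort(unique(c(donors + 1L, donors + 2L, acceptors - 2L, acceptors - 1L)))
}

# spliced-transcript fraction of a variant (intronic variants use the nearest
# exon boundary); measures how far 3' along the mature transcript it lies
.tx_fraction <- function(t, gpos) {
  coord <- .interval_coord(t$exons, t$strand, gpos)
  if (is.na(coord)) {
    boundary <- c(t$exons$start, t$exons$end)
    nearest <- boundary[which.min(abs(boundary - gpos))]
    coord <- .interval_coord(t$exons, t$strand, nearest)
  }
  coord / t$transcript_length
}

.call <- function(v, t, category, reason = NA_character_) {
  tibble::tibble(variant_id = v$id, gene = t$gene, category = category,
                 excluded_reason = reason)
}

.is_snv <- function(v) nchar(v$ref) == 1L && nchar(v$alt) == 1L &&
  v$ref %in% .BASES && v$alt %in% .BASES

# ref/alt codons of a coding SNV, or NULL if outside the CDS
.codon_change <- function(v, t, seq) {
  cpos <- .interval_coord(t$cds, t$strand, v$pos)
  if (is.na(cpos)) return(NULL)
  cds <- .cds_seq(t, seq)
  codon_i <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  old <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_coding <- if (t$strand == "-") .comp_base(v$alt) else v$alt
  new <- old
  substr(new, within, within) <- alt_coding
  list(old = old, new = new)
}

#' Classify a variant against loss-of-function rules
#'
#' Stop-gain: an SNV converting a CDS codon to TAA/TAG/TGA. Frameshift: an
#' indel overlapping the CDS whose length change is not a multiple of 3.
#' Essential splice: a change hitting the 2 intronic bases flanking an exon.
#' Candidate LoF calls are excluded (category `"none"` with a reason) when
#' the alternate allele equals the ancestral allele or the variant lies in
#' the 3'-most 5% of the spliced transcript.
#'
#' @param v A [variant_record()].
#' @param t A [transcript_model()] on the same contig.
#' @param seq Contig sequence (character or `DNAString`) in plus-strand
#'   orientation, needed for codon lookup.
#' @param ancestral Optional ancestral allele (e.g. from a VCF `AA` INFO key).
#' @return One-row tibble: `variant_id`, `gene`, `category`,
#'   `excluded_reason`.
#' @export
classify_lof <- function(v, t, seq, ancestral = NA_character_) {
  seq <- toupper(as.character(seq))
  category <- "none"
  if (.is_snv(v)) {
    .assert(substr(seq, v$pos, v$pos) == v$ref,
            "reference mismatch at %s:%d (expected %s, sequence has %s)",
            v$chrom, v$pos, v$ref, substr(seq, v$pos, v$pos))
    cc <- .codon_change(v, t, seq)
    if (!is.null(cc) && !(cc$old %in% .STOPS) && cc$new %in% .STOPS) {
      category <- "stop_gain"
    } else if (v$pos %in% .splice_positions(t)) {
      category <- "essential_splice"
    }
  } else {
    span <- v$pos:(v$pos + max(nchar(v$ref), 1L) - 1L)
    len_shift <- abs(nchar(v$alt) - nchar(v$ref))
    in_cds <- any(vapply(seq_len(nrow(t$cds)), function(i) {
      any(span >= t$cds$start[i] & span <= t$cds$end[i])
    }, logical(1)))
    if (in_cds && len_shift %% 3L != 0L) {
      category <- "frameshift"
    } else if (any(span %in% .splice_positions(t))) {
      category <- "essential_splice"
    }
  }
  if (category == "none") return(.call(v, t, "none"))
  if (!is.na(ancestral) && toupper(ancestral) == v$alt) {
    return(.call(v, t, "none", "ancestral_allele"))
  }
  if (.tx_fraction(t, v$pos) > 0.95) {
    return(.call(v, t, "none", "last_5_percent"))
  }
  .call(v, t, category)
}

#' Classify a coding SNV as missense
#'
#' Missense when the codon change alters the encoded amino acid and the
#' variant is not loss-of-function (stop-gain takes precedence). Synonymous
#' changes and non-SNVs return `"none"`.
#'
#' @inheritParams classify_lof
#' @return One-row tibble as [classify_lof()].
#' @export
classify_missense <- function(v, t, seq) {
  seq <- toupper(as.character(seq))
  if (!.is_snv(v)) return(.call(v, t, "none"))
  cc <- .codon_change(v, t, seq)
  if (is.null(cc)) return(.call(v, t, "none"))
  if (!(cc$old %in% .STOPS) && cc$new %in% .STOPS) return(.call(v, t, "stop_gain"))
  code <- Biostrings::GENETIC_CODE
  if (cc$old %in% .STOPS) return(.call(v, t, "none"))
  if (code[[cc$old]] != code[[cc$new]]) return(.call(v, t, "missense"))
  .call(v, t, "none")
}

#' Full functional classification of one variant
#'
#' Applies the loss-of-function rules first (including exclusions), then the
#' missense rule. Promoter (TFBS) classification is separate; see
#' [scan_promoter()].
#'
#' @inheritParams classify_lof
#' @return One-row tibble as [classify_lof()].
#' @export
classify_variant <- function(v, t, seq, ancestral = NA_character_) {
  lof <- classify_lof(v, t, seq, ancestral)
  if (lof$category != "none" || !is.na(lof$excluded_reason)) return(lof)
  classify_missense(v, t, seq)
}

# ---------------------------------------------------------------------------
# Position weight matrices and Match-style promoter scanning

#' Construct a position weight matrix
#'
#' Accepts per-position counts or frequencies over A/C/G/T; columns are
#' normalised to sum to 1. The information content of position i is
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))`; the core is the `core_length`
#' consecutive positions of maximal summed information (leftmost on ties).
#'
#' @param name Matrix name.
#' @param mat 4 x L matrix with rownames A/C/G/T (or L x 4 with such
#'   colnames).
#' @param core_length Core width, default 5 (clipped to the matrix length).
#' @return A `pwm` object with `mat`, `info`, `core_start`, `core_length`.
#' @export
pwm <- function(name, mat, core_length = 5L) {
  mat <- as.matrix(mat)
  if (!is.null(colnames(mat)) && all(.BASES %in% colnames(mat))) {
    mat <- t(mat[, .BASES, drop = FALSE])
  }
  .assert(nrow(mat) == 4L, "PWM must have 4 base rows")
  if (is.null(rownames(mat))) rownames(mat) <- .BASES
  mat <- mat[.BASES, , drop = FALSE]
  .assert(all(mat >= 0) && all(colSums(mat) > 0),
          "PWM columns must have non-negative entries with positive sums")
  f <- sweep(mat, 2L, colSums(mat), "/")
  info <- apply(f, 2L, function(col) sum(ifelse(col > 0, col * log(4 * col), 0)))
  L <- ncol(f)
  core_length <- min(as.integer(core_length), L)
  .assert(core_length >= 1L, "core_length must be at least 1")
  if (core_length == L) {
    core_start <- 1L
  } else {
    sums <- vapply(seq_len(L - core_length + 1L),
                   function(s) sum(info[s:(s + core_length - 1L)]), numeric(1))
    core_start <- which.max(sums)  # leftmost on ties
  }
  structure(list(name = name, mat = f, info = info,
                 core_start = as.integer(core_start),
                 core_length = core_length),
            class = "pwm")
}

# Match similarity scores for all ungapped windows of one strand of `chars`
# (integer base codes, NA for ambiguous). Returns tibble(offset, css, mss).
.scan_one_strand <- function(p, codes) {
  L <- ncol(p$mat)
  n <- length(codes)
  if (n < L) return(tibble::tibble(offset = integer(), css = numeric(),
                                   mss = numeric()))
  W <- sweep(p$mat, 2L, p$info, "*")  # I(i) * f(i, b)
  core_cols <- p$core_start:(p$core_start + p$core_length - 1L)
  score_range <- function(cols) {
    lo <- sum(p$info[cols] * apply(p$mat[, cols, drop = FALSE], 2L, min))
    hi <- sum(p$info[cols] * apply(p$mat[, cols, drop = FALSE], 2L, max))
    c(lo, hi)
  }
  full_rng <- score_range(seq_len(L))
  core_rng <- score_range(core_cols)
  offs <- seq_len(n - L + 1L)
  idx <- outer(offs, seq_len(L) - 1L, "+")      # offsets x L base positions
  bmat <- matrix(codes[idx], nrow = length(offs))
  valid <- rowSums(is.na(bmat)) == 0L
  norm_score <- function(cur, rng) {
    if (rng[2] - rng[1] <= .Machine$double.eps) return(rep(1, length(cur)))
    (cur - rng[1]) / (rng[2] - rng[1])
  }
  cur_full <- rep(NA_real_, length(offs))
  cur_core <- rep(NA_real_, length(offs))
  if (any(valid)) {
    bv <- bmat[valid, , drop = FALSE]
    pick <- function(cols) {
      sub <- bv[, cols, drop = FALSE]
      rowSums(matrix(W[cbind(as.vector(sub),
                             rep(cols, each = nrow(sub)))],
                     nrow = nrow(sub)))
    }
    cur_full[valid] <- pick(seq_len(L))
    cur_core[valid] <- pick(core_cols)
  }
  tibble::tibble(offset = offs,
                 css = ifelse(valid, norm_score(cur_core, core_rng), NA_real_),
                 mss = ifelse(valid, norm_score(cur_full, full_rng), NA_real_))
}

#' Scan a sequence for transcription-factor binding sites
#'
#' Match-style PWM scan: every window on both strands is scored with the
#' information-weighted similarity `(sum I(i) f(i, b_i) - Min)/(Max - Min)`,
#' once over the whole matrix (matrix similarity, mss) and once over the
#' high-information core (core similarity, css). A window is a hit when
#' `css >= css_cut` and `mss >= mss_cut`. Windows containing non-ACGT bases
#' are skipped. `offset` is always the 1-based start of the window on the
#' plus strand.
#'
#' @param seq Sequence to scan (character or `DNAString`), e.g. a 5-kb
#'   promoter region upstream of a gene's transcription start site.
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param mss_cut,css_cut Score cut-offs in \[0, 1\] (defaults 0.95 and 0.90).
#' @param chip_mask Optional data frame of 1-based closed intervals
#'   (`start`, `end`) in `seq` coordinates (e.g. liver ChIP-seq peaks); when
#'   supplied, only hits overlapping a mask interval are retained.
#' @return Tibble: `pwm`, `offset`, `strand`, `css`, `mss`.
#' @export
scan_promoter <- function(seq, pwms, mss_cut = 0.95, css_cut = 0.90,
                          chip_mask = NULL) {
  .assert(mss_cut >= 0 && mss_cut <= 1 && css_cut >= 0 && css_cut <= 1,
          "cut-offs must be in [0, 1]")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  fwd_codes <- match(strsplit(seq, "")[[1]], .BASES)
  rev_codes <- match(strsplit(.revcomp(seq), "")[[1]], .BASES)
  out <- list()
  for (p in pwms) {
    L <- ncol(p$mat)
    fwd <- .scan_one_strand(p, fwd_codes)
    fwd$strand <- "+"
    rev <- .scan_one_strand(p, rev_codes)
    rev$offset <- n - (rev$offset + L - 1L) + 1L  # plus-strand window start
    rev$strand <- "-"
    hits <- dplyr::bind_rows(fwd, rev)
    hits <- hits[!is.na(hits$mss) & hits$css >= css_cut & hits$mss >= mss_cut, ]
    if (nrow(hits) > 0L) {
      hits$pwm <- p$name
      out[[length(out) + 1L]] <-
        hits[order(hits$offset, hits$strand),
             c("pwm", "offset", "strand", "css", "mss")]
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(pwm = character(), offset = integer(),
                          strand = character(), css = numeric(),
                          mss = numeric()))
  }
  hits <- dplyr::bind_rows(out)
  if (!is.null(chip_mask) && nrow(hits) > 0L) {
    L_by <- vapply(pwms, function(p) ncol(p$mat), integer(1))
    names(L_by) <- vapply(pwms, function(p) p$name, character(1))
    keep <- vapply(seq_len(nrow(hits)), function(i) {
      s <- hits$offset[i]; e <- s + L_by[[hits$pwm[i]]] - 1L
      any(e >= chip_mask$start & s <= chip_mask$end)
    }, logical(1))
    hits <- hits[keep, ]
  }
  hits
}

#' Promoter window upstream of a transcription start site
#'
#' The 1-based closed interval covering `width` bases immediately upstream of
#' the TSS on the transcript strand, clipped at the contig start.
#'
#' @param t A [transcript_model()].
#' @param width Window width, default 5000.
#' @param contig_length Optional contig length for 3' clipping on the minus
#'   strand.
#' @return Integer vector `c(start, end)` in plus-strand coordinates.
#' @export
promoter_window <- function(t, width = 5000L, contig_length = NULL) {
  if (t$strand == "+") {
    c(max(1L, t$tss - width), max(1L, t$tss - 1L))
  } else {
    end <- t$tss + width
    if (!is.null(contig_length)) end <- min(end, contig_length)
    c(t$tss + 1L, end)
  }
}

#' Read a TRANSFAC-format matrix library
#'
#' Parses `DE`/`ID`/`NA` names and `P0`/`PO` count blocks; records are
#' separated by `//`.
#'
#' @param path Path to the TRANSFAC file.
#' @param core_length Core width passed to [pwm()].
#' @return List of `pwm` objects.
#' @export
read_transfac <- function(path, core_length = 5L) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (length(rec) == 0L) next
    name_line <- c(grep("^DE\\s+", rec, value = TRUE),
                   grep("^NA\\s+", rec, value = TRUE),
                   grep("^ID\\s+", rec, value = TRUE))
    header <- grep("^P[O0]\\s+", rec)
    if (length(header) == 0L) next
    cols <- strsplit(trimws(sub("^P[O0]\\s+", "", rec[header[1L]])), "\\s+")[[1]]
    .assert(all(.BASES %in% toupper(cols)), "P0 header must list A C G T")
    rows <- grep("^[0-9]+\\s", rec, value = TRUE)
    .assert(length(rows) > 0L, "TRANSFAC record without matrix rows")
    vals <- t(vapply(strsplit(trimws(rows), "\\s+"), function(x) {
      as.numeric(x[2:5])
    }, numeric(4)))
    colnames(vals) <- toupper(cols)[1:4]
    name <- if (length(name_line) > 0L) {
      trimws(sub("^(DE|ID|NA)\\s+", "", name_line[1L]))
    } else sprintf("matrix%03d", length(out) + 1L)
    out[[length(out) + 1L]] <- pwm(name, vals, core_length)
  }
  .assert(length(out) > 0L, "no TRANSFAC records found in %s", path)
  out
}

# ---------------------------------------------------------------------------
# Per-variant frequency statistics and novelty tagging

#' Per-variant allele statistics
#'
#' Minor allele count, frequency, call rate, and frequency bin (half-open,
#' lower-inclusive) from diploid dosages.
#'
#' @param dosages Vector of 0/1/2 dosages, NA for missing.
#' @return List: `ac` (minor allele count), `maf`, `call_rate`, `bin`, and
#'   `ac_bin` (`"AC=1"`/`"AC=2"` or NA).
#' @export
variant_stats <- function(dosages) {
  n_all <- length(dosages)
  dosages <- dosages[!is.na(dosages)]
  .assert(length(dosages) > 0L, "all genotypes missing")
  .assert(all(dosages %in% 0:2), "dosages must be 0, 1, or 2")
  alleles <- 2L * length(dosages)
  ac_alt <- sum(dosages)
  ac <- min(ac_alt, alleles - ac_alt)
  maf <- ac / alleles
  list(ac = as.integer(ac), maf = maf,
       call_rate = length(dosages) / n_all,
       bin = maf_bin(maf),
       ac_bin = if (ac %in% 1:2) sprintf("AC=%d", ac) else NA_character_)
}

#' Assign MAFs to frequency bins
#'
#' @param maf Numeric vector of minor allele frequencies in \[0, 0.5\].
#' @return Character vector of bin labels (see [maf_bin_labels()]).
#' @export
maf_bin <- function(maf) {
  .assert(all(maf >= 0 & maf <= 0.5), "MAF must be in [0, 0.5]")
  .MAF_BINS$bin[findInterval(maf, .MAF_BINS$lo)]
}

#' Tag variants as novel or known against a catalogue
#'
#' A variant is novel only when both its (chrom, pos, ref, alt) key and its
#' id are absent from the catalogue.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, `id`.
#' @param known Catalogue tibble with the same columns (ids `"."` ignored).
#' @return `variants` with an added `novelty` column (`"novel"`/`"known"`).
#' @export
tag_novelty <- function(variants, known) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  known_keys <- if (nrow(known) > 0L) key(known) else character()
  known_ids <- if (nrow(known) > 0L) setdiff(known$id, c(".", NA)) else character()
  variants$novelty <- ifelse(
    key(variants) %in% known_keys |
      (!variants$id %in% c(".", NA) & variants$id %in% known_ids),
    "known", "novel")
  variants
}
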