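# Shared fixtures and independent oracles used across the suite.

# deterministic random DNA string
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# A two-exon plus-strand transcript on an 800 bp contig with controlled
# codons written into the CDS. Exons 101-220 and 301-520; CDS 131-220 and
# 301-450 (240 bp = 80 codons).
toy_gene <- function(seed = 3) {
  contig <- random_dna(800, seed)
  # plant known codons at the CDS start: ATG CAA GCT AAA ...
  substr(contig, 131, 142) <- "ATGCAAGCTAAA"
  tx <- transcript_model("GENE1", "1", "+",
                         exons = data.frame(start = c(101, 301), end = c(220, 520)),
                         cds = data.frame(start = c(131, 301), end = c(220, 450)))
  list(contig = contig, tx = tx)
}

# mirror a plus-strand fixture onto the minus strand: reverse-complement the
# contig and flip all coordinates
mirror_fixture <- function(contig, tx, v) {
  n <- nchar(contig)
  flip <- function(iv) data.frame(start = n - iv$end + 1L, end = n - iv$start + 1L)
  tx2 <- transcript_model(tx$gene, tx$chrom, if (tx$strand == "+") "-" else "+",
                          exons = flip(tx$exons), cds = flip(tx$cds),
                          tss = n - tx$tss + 1L)
  v2 <- variant_record(v$chrom, n - v$pos + 1L,
                       chartr("ACGT", "TGCA", v$ref),
                       chartr("ACGT", "TGCA", v$alt), v$id)
  list(contig = rc_chr(contig), tx = tx2, v = v2)
}

# independent brute-force Match scorer: explicit per-offset loops, scores
# recomputed from frequencies from first principles
bf_scan <- function(seq, p, mss_cut, css_cut) {
  f <- p$mat
  L <- ncol(f)
  info <- vapply(seq_len(L), function(i) {
    sum(vapply(1:4, function(b) if (f[b, i] > 0) f[b, i] * log(4 * f[b, i]) else 0,
               numeric(1)))
  }, numeric(1))
  core <- p$core_start:(p$core_start + p$core_length - 1L)
  score <- function(window, cols) {
    cur <- 0; lo <- 0; hi <- 0
    for (j in seq_along(cols)) {
      i <- cols[j]
      b <- match(substr(window, j, j), c("A", "C", "G", "T"))
      if (is.na(b)) return(NA_real_)
      cur <- cur + info[i] * f[b, i]
      lo <- lo + info[i] * min(f[, i])
      hi <- hi + info[i] * max(f[, i])
    }
    if (hi - lo <= .Machine$double.eps) return(1)
    (cur - lo) / (hi - lo)
  }
  rows <- list()
  for (off in seq_len(nchar(seq) - L + 1L)) {
    w <- substr(seq, off, off + L - 1L)
    for (strand in c("+", "-")) {
      ww <- if (strand == "-") rc_chr(w) else w
      mss <- score(ww, seq_len(L))
      if (is.na(mss)) next
      css <- score(substr(ww, core[1], core[length(core)]), core)
      if (css >= css_cut && mss >= mss_cut) {
        rows[[length(rows) + 1L]] <- data.frame(pwm = p$name, offset = off,
                                                strand = strand, css = css,
                                                mss = mss)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pwm = character(), offset = integer(),
                      strand = character(), css = numeric(), mss = numeric()))
  }
  do.call(rbind, rows)
}

random_pwm <- function(seed, L = 8, name = paste0("M", seed)) {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * L, 0.6), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm(name, m)
}

# expand a 2x2 carrier table into individual-level case/carrier vectors
expand_2x2 <- function(a, b, c, d) {
  list(y = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
       g = rep(c(1, 0, 1, 0), times = c(a, b, c, d)))
}

# minimal codelist used where the bundled 79-code list would be overkill
mini_codelist <- function() {
  ade_codelist(c("L23.3", "M60", "G72.0", "D59"),
               requires_confirmation = "M60",
               group_map = c("L23.3" = "dermatologic", "M60" = "myopathy",
                             "G72.0" = "myopathy", "D59" = "hematologic"))
}
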