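test_that("loss-of-function rules call stop-gain, frameshift, and splice variants", {
  fx <- toy_gene()
  # CAA codon at 134-136: C>T at its first base makes TAA mid-CDS
  stop_v <- variant_record("1", 134, "C", "T")
  expect_equal(classify_lof(stop_v, fx$tx, fx$contig)$category, "stop_gain")
  # 2-bp deletion inside the CDS (about 30% along the transcript)
  del_v <- variant_record("1", 199, substr(fx$contig, 199, 201),
                          substr(fx$contig, 199, 199))
  expect_equal(classify_lof(del_v, fx$tx, fx$contig)$category, "frameshift")
  # in-frame 3-bp deletion is not a frameshift
  del3 <- variant_record("1", 199, substr(fx$contig, 199, 202),
                         substr(fx$contig, 199, 199))
  expect_equal(classify_lof(del3, fx$tx, fx$contig)$category, "none")
  # the two intronic bases at each intron end are essential splice sites
  for (pos in c(221, 222, 299, 300)) {
    ref <- substr(fx$contig, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    sv <- variant_record("1", pos, ref, alt)
    expect_equal(classify_lof(sv, fx$tx, fx$contig)$category, "essential_splice")
  }
  # 3 bases into the intron is no longer essential
  deep <- variant_record("1", 223, substr(fx$contig, 223, 223),
                         setdiff(c("A", "C", "G", "T"), substr(fx$contig, 223, 223))[1])
  expect_equal(classify_lof(deep, fx$tx, fx$contig)$category, "none")
})

test_that("ancestral-allele and last-5-percent exclusions apply to LoF candidates", {
  fx <- toy_gene()
  stop_v <- variant_record("1", 134, "C", "T")
  exc <- classify_lof(stop_v, fx$tx, fx$contig, ancestral = "T")
  expect_equal(exc$category, "none")
  expect_equal(exc$excluded_reason, "ancestral_allele")

  # single-exon gene whose CDS reaches the transcript end; a stop-gain at 97%
  # of the spliced length is excluded
  contig <- random_dna(600, seed = 9)
  substr(contig, 101, 103) <- "ATG"
  substr(contig, 389, 391) <- "CAA"
  tx <- transcript_model("GENE2", "1", "+",
                         exons = data.frame(start = 101, end = 400),
                         cds = data.frame(start = 101, end = 400))
  late <- variant_record("1", 389, "C", "T")
  res <- classify_lof(late, tx, contig)
  expect_equal(res$category, "none")
  expect_equal(res$excluded_reason, "last_5_percent")
  # the same change earlier in the transcript is kept
  substr(contig, 200, 202) <- "CAA"
  early <- variant_record("1", 200, "C", "T")
  expect_equal(classify_lof(early, tx, contig)$category, "stop_gain")
})

test_that("missense calls require an amino-acid change and yield to stop-gain", {
  fx <- toy_gene()
  # GCT codon at 137-139: C>T at second base gives GTT (Ala -> Val)
  expect_equal(classify_missense(variant_record("1", 138, "C", "T"),
                                 fx$tx, fx$contig)$category, "missense")
  # GCT -> GCC is synonymous
  expect_equal(classify_missense(variant_record("1", 139, "T", "C"),
                                 fx$tx, fx$contig)$category, "none")
  # stop-gain takes precedence over missense
  expect_equal(classify_missense(variant_record("1", 134, "C", "T"),
                                 fx$tx, fx$contig)$category, "stop_gain")
  # indels are not missense candidates
  del_v <- variant_record("1", 199, substr(fx$contig, 199, 201),
                          substr(fx$contig, 199, 199))
  expect_equal(classify_missense(del_v, fx$tx, fx$contig)$category, "none")
})

test_that("classification matches a genetic-code oracle for every SNV of the planted codons", {
  fx <- toy_gene()
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  # codons planted at CDS starts 134 (CAA), 137 (GCT), 140 (AAA)
  for (codon_start in c(134L, 137L, 140L)) {
    old <- substr(fx$contig, codon_start, codon_start + 2L)
    for (within in 0:2) {
      pos <- codon_start + within
      ref <- substr(fx$contig, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        new <- old
        substr(new, within + 1L, within + 1L) <- alt
        expected <- if (new %in% stops) "stop_gain"
                    else if (code[[old]] != code[[new]]) "missense"
                    else "none"
        got <- classify_variant(variant_record("1", pos, ref, alt), fx$tx, fx$contig)
        expect_equal(got$category, expected,
                     info = sprintf("%s>%s at %d", old, new, pos))
      }
    }
  }
})

test_that("classification is invariant under reverse-complementing the locus", {
  fx <- toy_gene()
  set.seed(17)
  positions <- c(134L, 138L, 139L, 199L, 221L, 300L,
                 sample(131:450, 12))
  for (pos in positions) {
    ref <- substr(fx$contig, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- variant_record("1", pos, ref, alt)
      fwd <- classify_variant(v, fx$tx, fx$contig)
      mir <- mirror_fixture(fx$contig, fx$tx, v)
      rev <- classify_variant(mir$v, mir$tx, mir$contig)
      expect_equal(rev$category, fwd$category, info = sprintf("pos %d alt %s", pos, alt))
      expect_equal(rev$excluded_reason, fwd$excluded_reason)
    }
  }
})

test_that("variant statistics compute allele counts, MAF, call rate, and bins", {
  s <- variant_stats(c(0, 1, 2))
  expect_equal(s$ac, 3L)
  expect_equal(s$maf, 0.5)
  expect_equal(s$call_rate, 1)

  s1 <- variant_stats(c(1L, rep(0L, 1119)))
  expect_equal(s1$ac, 1L)
  expect_equal(s1$maf, 1 / 2240, tolerance = 1e-12)
  expect_equal(s1$bin, "MAF<0.05%")
  expect_equal(s1$ac_bin, "AC=1")

  # MAF is computed on the minor allele even when alt is the major allele
  s_flip <- variant_stats(c(2, 2, 2, 1))
  expect_equal(s_flip$ac, 1L)
  expect_lte(s_flip$maf, 0.5)

  sm <- variant_stats(c(0, 1, NA, NA))
  expect_equal(sm$call_rate, 0.5)
  expect_error(variant_stats(c(NA_integer_, NA_integer_)), "all genotypes missing")

  # boundary behaviour: lower-inclusive bins
  expect_equal(maf_bin(c(0.05, 0.01, 0.005, 5e-4, 4.9e-4)),
               c("MAF>5%", "1%<=MAF<5%", "0.5%<=MAF<1%", "0.05%<=MAF<0.5%",
                 "MAF<0.05%"))
})

test_that("bin tallies over a drawn fixture match an independent cut() oracle", {
  set.seed(23)
  mafs <- runif(20, 1e-4, 0.5)
  got <- table(factor(maf_bin(mafs), levels = maf_bin_labels()))
  oracle <- table(cut(mafs, breaks = c(0, 5e-4, 5e-3, 1e-2, 5e-2, 0.51),
                      right = FALSE, labels = maf_bin_labels()))
  expect_equal(as.integer(got), as.integer(oracle))
})

test_that("novelty tagging requires both the variant key and the id to be unknown", {
  vars <- tibble::tibble(chrom = "1", pos = 1:10 * 100L, ref = "A", alt = "G",
                         id = c(paste0("rs", 1:5), rep(".", 5)))
  known <- vars[c(1, 2), ]
  # catalogue entry matched by key at a different id, and by id at a different position
  known <- rbind(known, tibble::tibble(chrom = "1", pos = 300L, ref = "A",
                                       alt = "G", id = "rsX"),
                 tibble::tibble(chrom = "2", pos = 999L, ref = "T", alt = "C",
                                id = "rs4"))
  tagged <- tag_novelty(vars, known)
  expect_equal(sum(tagged$novelty == "novel"), 6)
  expect_equal(tagged$novelty[1:4], rep("known", 4))
  # empty catalogue: everything is novel
  all_novel <- tag_novelty(vars, known[0, ])
  expect_true(all(all_novel$novelty == "novel"))
})

test_that("a consensus-only PWM scores its consensus 1.0 on either strand", {
  m <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("T", "G", "A", "C", "T", "G")
  for (i in seq_along(cons)) m[cons[i], i] <- 1
  p <- pwm("toy", m)
  s <- paste0("AAAAA", paste(cons, collapse = ""), "CCCCC")
  hits <- scan_promoter(s, p, mss_cut = 0.95, css_cut = 0.9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 6L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mss, 1)
  expect_equal(hits$css, 1)
  rc_hits <- scan_promoter(rc_chr(s), p, mss_cut = 0.95, css_cut = 0.9)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$mss, 1)
})

test_that("windows containing N are skipped and short sequences yield no hits", {
  p <- random_pwm(1, L = 6)
  expect_equal(nrow(scan_promoter("ACG", p)), 0L)
  with_n <- paste0("ACGTN", random_dna(30, 2))
  hits <- scan_promoter(with_n, p, mss_cut = 0, css_cut = 0)
  # every window covering position 5 is absent
  expect_false(any(hits$offset %in% 1:5 & hits$strand == "+"))
})

test_that("the PWM scanner agrees exactly with a brute-force scorer", {
  for (seed in 1:10) {
    p <- random_pwm(seed, L = sample(5:10, 1))
    s <- random_dna(120, seed + 100)
    cuts <- c(mss = runif(1, 0.5, 0.9), css = runif(1, 0.5, 0.9))
    got <- as.data.frame(scan_promoter(s, p, cuts["mss"], cuts["css"]))
    want <- bf_scan(s, p, cuts["mss"], cuts["css"])
    got <- got[order(got$offset, got$strand), ]
    want <- want[order(want$offset, want$strand), ]
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got) > 0) {
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mss, want$mss, tolerance = 1e-12)
      expect_equal(got$css, want$css, tolerance = 1e-12)
    }
  }
})

test_that("an optional ChIP mask restricts hits to overlapping intervals", {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in 1:4) m[c("T", "G", "A", "C")[i], i] <- 1
  p <- pwm("mask_test", m)
  s <- paste0("TGAC", random_dna(20, 4), "TGAC")  # hits at offsets 1 and 25
  free <- scan_promoter(s, p, 0.99, 0.99)
  expect_true(all(c(1L, 25L) %in% free$offset))
  masked <- scan_promoter(s, p, 0.99, 0.99,
                          chip_mask = data.frame(start = 20, end = 28))
  expect_true(all(masked$offset == 25L))
})

test_that("the promoter window covers 5 kb upstream of the TSS on the transcript strand", {
  fx <- toy_gene()  # plus strand, TSS at 101
  expect_equal(promoter_window(fx$tx, width = 5000), c(1L, 100L))
  expect_equal(promoter_window(fx$tx, width = 50), c(51L, 100L))
  minus <- mirror_fixture(fx$contig, fx$tx, variant_record("1", 134, "C", "T"))
  w <- promoter_window(minus$tx, width = 50, contig_length = 800L)
  expect_equal(w, c(minus$tx$tss + 1L, minus$tx$tss + 50L))
})

test_that("TRANSFAC matrix libraries are parsed into normalised PWMs", {
  path <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c(
    "VV  TRANSFAC-like example",
    "//",
    "ID  M00001",
    "DE  toy_factor",
    "P0      A      C      G      T",
    "01      6      0      0      0      A",
    "02      0      5      1      0      C",
    "03      0      0      6      0      G",
    "04      2      2      1      1      N",
    "05      0      0      0      6      T",
    "06      6      0      0      0      A",
    "XX",
    "//"
  ), path)
  lib <- read_transfac(path)
  expect_length(lib, 1L)
  p <- lib[[1]]
  expect_equal(p$name, "toy_factor")
  expect_equal(ncol(p$mat), 6L)
  expect_equal(unname(colSums(p$mat)), rep(1, 6))
  expect_equal(unname(p$mat["C", 2]), 5 / 6)
  # uninformative position contributes no information
  expect_lt(p$info[4], p$info[1])
  hits <- scan_promoter("GGACGATAGG", p, 0.9, 0.9)
  expect_true(any(hits$offset == 3L & hits$strand == "+"))
})
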