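test_that("promoter extraction uses 0-based half-open windows on both strands", {
  # hand-built chromosome: position g (0-based) holds a known base pattern
  withr::with_seed(1, chrom <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))
  genome <- c(chr1 = chrom)
  sub0 <- function(from, to) substr(chrom, from + 1, to)   # 0-based half-open

  plus <- extract_promoters(genome, tibble::tibble(chrom = "chr1", tss = 1000,
                                                   strand = "+", gene = "gp"),
                            upstream = 10, downstream = 2)
  expect_equal(nchar(plus$sequence), 13)
  expect_equal(plus$sequence, sub0(990, 1003))
  # position -10 is genomic base 990, position 0 the TSS base 1000
  expect_equal(substr(plus$sequence, 1, 1), sub0(990, 991))
  expect_equal(substr(plus$sequence, 11, 11), sub0(1000, 1001))

  minus <- extract_promoters(genome, tibble::tibble(chrom = "chr1", tss = 1000,
                                                    strand = "-", gene = "gm"),
                             upstream = 2, downstream = 2)
  rc <- motifnet:::revcomp_chr(sub0(998, 1003))
  expect_equal(minus$sequence, rc)
  # position 0 reads the complement of genomic base 1000
  expect_equal(substr(minus$sequence, 3, 3),
               motifnet:::revcomp_chr(sub0(1000, 1001)))

  # the narrow-promoter configuration: 1000 upstream, nothing downstream
  narrow <- extract_promoters(genome, tibble::tibble(chrom = "chr1", tss = 1500,
                                                     strand = "+", gene = "gn"),
                              upstream = 1000, downstream = 0)
  expect_equal(nchar(narrow$sequence), 1001)

  expect_error(extract_promoters(genome,
                                 tibble::tibble(chrom = "chrX", tss = 5, strand = "+", gene = "bad"),
                                 10, 0), "chrX")
  expect_error(extract_promoters(genome, tibble::tibble(chrom = character(0),
                                                        tss = integer(0),
                                                        strand = character(0),
                                                        gene = character(0)), 10, 0),
               "zero genes")
  # running off the chromosome start pads with N and warns
  expect_warning(tr <- extract_promoters(genome,
                                         tibble::tibble(chrom = "chr1", tss = 3,
                                                        strand = "+", gene = "gt"),
                                         upstream = 10, downstream = 0), "truncated")
  expect_equal(substr(tr$sequence, 1, 7), "NNNNNNN")
})

test_that("soft-masked and N bases are excluded from the free mask", {
  p <- hand_promoters("ACgtNCA", upstream = 3, downstream = 3)
  expect_equal(as.vector(free_matrix_of(p)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("masked FASTA round-trips a promoter set", {
  p <- quiet(generate_promoters(6, 40, 5, mask_fraction = 0.3, seed = 2))
  f <- withr::local_tempfile(fileext = ".fa")
  write_promoters_fasta(p, f)
  p2 <- read_promoters_fasta(f)
  expect_identical(p2$sequence, p$sequence)
  expect_identical(promoter_upstream(p2), promoter_upstream(p))
  expect_identical(promoter_downstream(p2), promoter_downstream(p))
})

test_that("gene models parse from BED6 and GTF", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t990\t1200\tgA\t0\t+", "chr1\t800\t1001\tgB\t0\t-"), bed)
  gm <- read_gene_models(bed)
  expect_equal(gm$tss, c(990, 1000))
  expect_equal(gm$gene, c("gA", "gB"))

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\tgene\t991\t1200\t.\t+\t.\tgene_id \"gA\"; gene_name \"A\";",
               "chr1\tsrc\tgene\t801\t1001\t.\t-\t.\tgene_id \"gB\";"), gtf)
  gm2 <- read_gene_models(gtf)
  expect_equal(gm2$tss, c(990, 1000))
  expect_equal(gm2$gene, c("gA", "gB"))
})

test_that("JASPAR count matrices normalise with pseudocounts and background", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0000.1 TOY",
               "A [ 100  0 ]",
               "C [ 0  100 ]",
               "G [ 0  0 ]",
               "T [ 0  0 ]"), f)
  pwm <- load_jaspar_pwm(f, pseudocount = 0)
  expect_equal(pwm$id, "MA0000.1")
  expect_equal(pwm$prob[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwm$consensus, "AC")

  # uniform counts against a uniform background: all log-odds are zero
  u <- pwm_from_counts(matrix(25, 4, 3), pseudocount = 0)
  expect_true(all(u$log_odds == 0))
  # probability columns always sum to 1
  t1 <- toy_pwm()
  expect_true(all(abs(colSums(t1$prob) - 1) < 1e-9))

  # multi-motif files: select by JASPAR-style identifier
  multi <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0079.3 SP1",
               "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]",
               ">MA0060.1 NFYA",
               "A [ 0 10 ]", "C [ 10 0 ]", "G [ 0 0 ]", "T [ 0 0 ]"), multi)
  second <- load_jaspar_pwm(multi, id = "MA0060.1", pseudocount = 0)
  expect_equal(second$consensus, "CA")
  expect_equal(load_jaspar_pwm(multi)$id, "MA0079.3")
  expect_error(load_jaspar_pwm(multi, id = "MA9999.9"), "not found")

  # the shipped synthetic CCAAT-box example parses
  shipped <- load_jaspar_pwm(system.file("extdata", "ccaat_box_synthetic.pfm",
                                         package = "motifnet"))
  expect_equal(shipped$width, 6)
  expect_equal(substr(shipped$consensus, 1, 5), "CCAAT")

  bad <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 X", "A [ 1 x ]", "C [ 1 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"), bad)
  expect_error(load_jaspar_pwm(bad), "non-numeric")
})

test_that("score thresholds reproduce exact tail probabilities", {
  # width-2 PWM with a unique top word: at pvalue 1/16 under a uniform
  # background the threshold is exactly the maximum dinucleotide score
  pwm <- pwm_from_counts(matrix(c(10, 2, 3, 1,
                                  9, 4, 2, 1), 4, 2), pseudocount = 0.5)
  thr <- pwm_score_threshold(pwm, pvalue = 1 / 16)
  all_words <- as.matrix(expand.grid(1:4, 1:4))
  scores <- pwm$log_odds[cbind(all_words[, 1], 1)] + pwm$log_odds[cbind(all_words[, 2], 2)]
  expect_equal(thr, max(scores), tolerance = 0.011)
  expect_equal(mean(scores >= thr - 0.011), 1 / 16)  # only the top word passes
  expect_equal(mean(scores > thr + 0.011), 0)

  # pvalue 1: everything passes
  expect_lte(pwm_score_threshold(pwm, pvalue = 1), min(scores))

  # width-4: DP tail matches enumeration over all 256 words
  p4 <- toy_pwm(width = 4)
  thr4 <- pwm_score_threshold(p4, pvalue = 0.05)
  words <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  s4 <- rowSums(matrix(p4$log_odds[cbind(as.vector(words),
                                         rep(1:4, each = nrow(words)))], nrow(words)))
  expect_lte(mean(s4 >= thr4), 0.05)
  # smallest such threshold: the next achievable word score below already
  # admits too much tail mass
  prev <- max(s4[s4 < thr4 - 0.011])
  expect_gt(mean(s4 >= prev), 0.05)

  expect_error(pwm_score_threshold(p4, pvalue = 0), "pvalue")
  expect_warning(pwm_score_threshold(ccaat_pwm(), pvalue = 1e-9), "achievable")
})

test_that("scanning finds both strands, respects masks, and mirrors under revcomp", {
  pwm <- ccaat_pwm()
  s <- paste0(strrep("A", 20), "CCAAT", strrep("G", 30), "ATTGG", strrep("T", 40))
  p <- hand_promoters(s, upstream = 60, downstream = 39)
  hits <- scan_promoters(p, pwm, threshold = 9.9)
  expect_equal(nrow(hits), 2)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(plus$anchor, 20 - 60)          # CCAAT starts at string pos 21
  expect_equal(minus$anchor, 55 - 60)         # ATTGG = revcomp(CCAAT) at pos 56
  expect_equal(hits$distance, abs(hits$anchor))

  # a hit fully inside a masked block disappears
  s_masked <- paste0(strrep("A", 20), "ccaat", strrep("G", 30), "ATTGG", strrep("T", 40))
  pm <- hand_promoters(s_masked, upstream = 60, downstream = 39)
  hm <- scan_promoters(pm, pwm, threshold = 9.9)
  expect_equal(hm$strand, "-")

  # mirror property: scanning the reverse complement swaps strands and anchors
  prc <- hand_promoters(motifnet:::revcomp_chr(s), upstream = 39, downstream = 60)
  hrc <- scan_promoters(prc, pwm, threshold = 9.9)
  expect_setequal(-(hrc$anchor + pwm$width - 1), hits$anchor)
  expect_setequal(hrc$strand, c("+", "-")[match(hits$strand, c("-", "+"))])

  # hit count is monotone non-increasing in the threshold
  p2 <- quiet(generate_promoters(20, 300, 0, 0, seed = 6))
  t2 <- toy_pwm()
  counts <- vapply(c(-2, 0, 1, 2, 4), function(th)
    nrow(scan_promoters(p2, t2, threshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # PWM wider than the promoter: empty result with a warning
  expect_warning(none <- scan_promoters(hand_promoters("ACGT", 3, 0),
                                        toy_pwm(width = 6), threshold = 0),
                 "wider")
  expect_equal(nrow(none), 0)
})
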