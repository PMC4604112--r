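test_that("translated search finds a planted exact in-frame copy", {
  set.seed(10)
  q <- rand_prot(310)
  orf <- chemorep:::.reverse_translate(q)
  genome <- c(scf1 = paste0(rand_dna(2000), orf, rand_dna(2000)))
  hits <- translated_search(genome, c(q1 = q), evalue_cutoff = 1e-20)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$strand, "+")
  expect_equal(hits$end0 - hits$start0, 930L)   # 310 aa exactly
  expect_equal(hits$start0, 2000L)
  ## raw score equals the full-DP oracle on the translated frame
  expect_equal(hits$raw_score, oracle_sw_protein(q, q))
})

test_that("e-value cutoff excludes weak similarities, per oracle statistics", {
  set.seed(11)
  q <- rand_prot(300)
  ## plant only a short (28 aa) exact fragment: too little score for 1e-20
  frag <- substr(q, 100, 127)
  genome <- c(scf1 = paste0(rand_dna(1500), chemorep:::.reverse_translate(frag),
                            rand_dna(1500)))
  sch <- scoring_scheme()
  oracle_S <- oracle_sw_protein(frag, q)
  m <- sum((nchar(genome) - 0:2) %/% 3) * 2   # both strands
  n <- nchar(q)
  oracle_E <- sch$K * m * n * exp(-sch$lambda * oracle_S)
  expect_gt(oracle_E, 1e-20)
  hits <- translated_search(genome, c(q1 = q), evalue_cutoff = 1e-20)
  expect_equal(nrow(hits), 0L)
  ## the same fragment is reported at a permissive cutoff
  hits2 <- translated_search(genome, c(q1 = q), evalue_cutoff = 1e-3)
  expect_gte(nrow(hits2), 1L)
})

test_that("strand mirror: searching the reverse-complemented genome flips hits", {
  set.seed(12)
  q <- rand_prot(150)
  genome <- c(s = paste0(rand_dna(800), chemorep:::.reverse_translate(q),
                         rand_dna(700)))
  L <- nchar(genome[[1]])
  h1 <- translated_search(genome, c(q = q), evalue_cutoff = 1e-10)
  h2 <- translated_search(c(s = revcomp(genome[[1]])), c(q = q),
                          evalue_cutoff = 1e-10)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(L - h1$end0), sort(h2$start0))
  expect_equal(sort(L - h1$start0), sort(h2$end0))
  expect_true(all(h1$strand != h2$strand[order(L - h2$end0)]))
})

test_that("e-values decrease strictly as raw score increases", {
  set.seed(13)
  q <- rand_prot(200)
  mut <- chemorep:::.mutate_protein(q, 0.25)
  genome <- c(s = paste0(rand_dna(500), chemorep:::.reverse_translate(q),
                         rand_dna(500), chemorep:::.reverse_translate(mut),
                         rand_dna(500)))
  hits <- translated_search(genome, c(q = q), evalue_cutoff = 1e-5)
  expect_gte(nrow(hits), 2L)
  o <- order(hits$raw_score, decreasing = TRUE)
  expect_true(all(diff(hits$evalue[o]) > 0 | diff(hits$raw_score[o]) == 0))
})

test_that("nucleotide search handles strands, divergence, short queries", {
  set.seed(14)
  exon <- rand_dna(500)
  genome <- c(scf = paste0(rand_dna(1200), revcomp(exon), rand_dna(1200)))
  hits <- nucleotide_search(genome, c(e1 = exon))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$identity, 1.0)
  expect_equal(c(hits$start0, hits$end0), c(1200L, 1700L))

  ## 5% substitutions: still found, identity in [0.90, 1.00]
  mut <- strsplit(exon, "")[[1]]
  pos <- sample(500, 25)
  for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1)
  genome2 <- c(scf = paste0(rand_dna(1000), paste(mut, collapse = ""),
                            rand_dna(1000)))
  h2 <- nucleotide_search(genome2, c(e1 = exon))
  expect_equal(nrow(h2), 1L)
  expect_gte(h2$identity, 0.90)
  expect_lte(h2$identity, 1.0)

  ## queries shorter than the seed are skipped with a warning
  expect_warning(h3 <- nucleotide_search(genome, c(tiny = "ACGTACGT")),
                 "seed length")
  expect_equal(nrow(h3), 0L)
})

test_that("merge_hits merges same-orientation overlaps transitively", {
  h <- function(s, e, strand, q = "q") data.frame(
    query_id = q, seq_id = "scf1", start0 = s, end0 = e, strand = strand,
    frame = 0L, raw_score = 100L, bitscore = 50, evalue = 1e-30,
    identity = 0.9, qstart0 = 0L, qend0 = 10L, stringsAsFactors = FALSE)
  m <- merge_hits(rbind(h(100, 200, "+"), h(150, 300, "+")), "fam")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start0, m$end0), c(100L, 300L))

  ## opposite strands never merge
  m2 <- merge_hits(rbind(h(100, 200, "+"), h(150, 300, "-")), "fam")
  expect_equal(nrow(m2), 2L)

  ## single hit: locus equals its interval
  m3 <- merge_hits(h(10, 50, "+"), "fam")
  expect_equal(c(m3$start0, m3$end0), c(10L, 50L))

  ## idempotent and order-independent; transitive chains collapse
  hh <- rbind(h(0, 100, "+"), h(90, 190, "+"), h(180, 280, "+"),
              h(400, 500, "-"))
  a <- merge_hits(hh, "fam")
  b <- merge_hits(hh[sample(nrow(hh)), ], "fam")
  expect_equal(a[, c("start0", "end0", "strand")],
               b[, c("start0", "end0", "strand")])
  expect_equal(nrow(a), 2L)
  ## per (scaffold, strand) the merged intervals are pairwise disjoint
  plus <- a[a$strand == "+", ]
  expect_true(all(plus$start0[-1] >= head(plus$end0, -1)))
})

test_that("reciprocal filter keeps family loci and discards impostors", {
  set.seed(15)
  fam <- small_family()
  other <- make_gpcr_family(n_refs = 4L, length_aa = 260L, seed = 99L,
                            family = "other")
  gene_fam <- chemorep:::.reverse_translate(
    chemorep:::.mutate_protein(fam$ancestor, 0.1))
  gene_other <- chemorep:::.reverse_translate(
    chemorep:::.mutate_protein(other$ancestor, 0.1))
  genome <- c(s1 = paste0(rand_dna(500), gene_fam, rand_dna(500),
                          gene_other, rand_dna(500)))
  loci <- data.frame(
    locus_id = c("L1", "L2"), family = "tfam", seq_id = "s1",
    start0 = c(500L, 500L + nchar(gene_fam) + 500L),
    end0 = c(500L + nchar(gene_fam),
             500L + nchar(gene_fam) + 500L + nchar(gene_other)),
    strand = "+", stringsAsFactors = FALSE)
  proteome <- c(fam$refs, other$refs)
  res <- reciprocal_filter(loci, genome, proteome, names(fam$refs))
  expect_equal(res$kept$locus_id, "L1")
  expect_equal(res$discarded$locus_id, "L2")
  expect_true(res$discarded$best_ref %in% names(other$refs))
  expect_equal(res$discarded$reason, "best_hit_not_in_family")

  ## empty input
  empty <- reciprocal_filter(loci[0, ], genome, proteome, names(fam$refs))
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$discarded), 0L)
})

test_that("the 12-column tabular adapter maps coordinates and strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tscf1\t95.5\t100\t4\t1\t1\t100\t201\t300\t1e-30\t180.2",
               "q2\tscf1\t88.0\t90\t10\t0\t5\t94\t900\t811\t1e-20\t120.0"),
             f)
  h <- read_tabular_hits(f)
  expect_equal(h$start0, c(200L, 810L))
  expect_equal(h$end0, c(300L, 900L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$identity, c(0.955, 0.88))
})
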