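locus_row <- function(seq_id, start0, end0, strand = "+", id = "L1",
                      family = "tfam") {
  data.frame(locus_id = id, family = family, seq_id = seq_id,
             start0 = as.integer(start0), end0 = as.integer(end0),
             strand = strand, stringsAsFactors = FALSE)
}

## a clean planted intact gene and its coordinates, from the shared world
intact_case <- function() {
  w <- small_world()
  tr <- w$planted$truth
  row <- tr[tr$label == "intact", ][1, ]
  list(w = w, row = row)
}

test_that("reconstruct_cds recovers the planted ORF, with and without extension", {
  ic <- intact_case()
  w <- ic$w; row <- ic$row
  planted <- substr(w$planted$genome[[row$seq_id]], row$start0 + 1, row$end0)
  if (row$strand == "-") planted <- revcomp(planted)

  ## locus spanning the full ORF: zero extension, CDS = planted ORF
  m <- reconstruct_cds(locus_row(row$seq_id, row$start0, row$end0, row$strand),
                       w$fam$profile, w$planted$genome)
  expect_true(m$has_start && m$has_stop)
  expect_equal(m$cds, planted)

  ## locus starting 30 bp downstream of the ATG: 5' extension recovers it
  if (row$strand == "+") {
    lr <- locus_row(row$seq_id, row$start0 + 30, row$end0, row$strand)
  } else {
    lr <- locus_row(row$seq_id, row$start0, row$end0 - 30, row$strand)
  }
  m2 <- reconstruct_cds(lr, w$fam$profile, w$planted$genome)
  expect_true(m2$has_start)
  expect_equal(m2$cds, planted)
  expect_gte(m2$ext5_used, 30L)
})

test_that("a gene cut at a scaffold boundary lacks its start or stop", {
  w <- small_world()
  tr <- w$planted$truth
  rows <- tr[tr$label == "truncated", ]
  expect_gte(nrow(rows), 1L)
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, ]
    m <- reconstruct_cds(locus_row(row$seq_id, row$start0, row$end0,
                                   row$strand),
                         w$fam$profile, w$planted$genome)
    d <- detect_disruptions(m, w$fam$profile)
    if (row$mutation == "missing_start") {
      expect_false(m$has_start)
      expect_true(m$clip5)
      expect_true("missing_start" %in% d$kind)
    } else {
      expect_false(m$has_stop)
      expect_true(m$clip3)
      expect_true("missing_stop" %in% d$kind)
    }
    expect_false(any(d$kind %in% chemorep:::PSEUDOGENIZING))
  }
})

test_that("detect_disruptions finds constructed stops and frameshifts", {
  ic <- intact_case()
  w <- ic$w; row <- ic$row
  planted <- substr(w$planted$genome[[row$seq_id]], row$start0 + 1, row$end0)
  if (row$strand == "-") planted <- revcomp(planted)

  ## unmutated planted CDS: no disruptions at all
  m0 <- reconstruct_cds(locus_row(row$seq_id, row$start0, row$end0, row$strand),
                        w$fam$profile, w$planted$genome)
  d0 <- detect_disruptions(m0, w$fam$profile)
  expect_equal(nrow(d0), 0L)

  mini_genome <- function(orf) c(chr = paste0(strrep("ACGT", 500), orf,
                                              strrep("TGCA", 500)))
  run <- function(orf) {
    g <- mini_genome(orf)
    m <- reconstruct_cds(locus_row("chr", 2000, 2000 + nchar(orf)),
                         w$fam$profile, g)
    detect_disruptions(m, w$fam$profile)
  }

  ## TGA swapped in at codon 150
  mut <- planted
  substr(mut, 448, 450) <- "TGA"
  d1 <- run(mut)
  expect_true("premature_stop" %in% d1$kind)
  ps <- d1[d1$kind == "premature_stop", ]
  expect_equal(ps$cds_pos, 448L)
  expect_match(ps$detail, "consensus position 150")

  ## 1-bp deletion at CDS position 88
  mut2 <- paste0(substr(planted, 1, 87), substr(planted, 89, nchar(planted)))
  d2 <- run(mut2)
  fs <- d2[d2$kind == "frameshift_indel", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$detail, "1-bp deletion")
  expect_lt(abs(fs$cds_pos - 88L), 6L)  # indel position within placement slack
})

test_that("TM coverage distinguishes complete from partial segment loss", {
  ic <- intact_case()
  w <- ic$w; row <- ic$row
  prof <- w$fam$profile
  planted <- substr(w$planted$genome[[row$seq_id]], row$start0 + 1, row$end0)
  if (row$strand == "-") planted <- revcomp(planted)
  mini <- function(orf) c(chr = paste0(strrep("ACGT", 500), orf,
                                       strrep("TGCA", 500)))
  model_of <- function(orf) reconstruct_cds(
    locus_row("chr", 2000, 2000 + nchar(orf)), prof, mini(orf))

  tm0 <- tm_coverage(model_of(planted), prof)
  expect_equal(tm0$coverage, rep(1, 7))
  expect_false(any(tm0$missing))

  ## delete the whole TM3-encoding block
  rng <- prof$tm_consensus[[3]]
  cut <- paste0(substr(planted, 1, 3 * (rng[1] - 1)),
                substr(planted, 3 * rng[2] + 1, nchar(planted)))
  tm3 <- tm_coverage(model_of(cut), prof)
  ## at most gap-placement jitter (<= 2 boundary columns) may appear covered
  expect_lte(tm3$coverage[3], 2 / 24)
  expect_true(tm3$missing[3])
  expect_true(all(tm3$coverage[-3] > 0))

  ## delete only half of TM5: reduced coverage but NOT completely missing
  rng5 <- prof$tm_consensus[[5]]
  half <- floor((rng5[2] - rng5[1] + 1) / 2)
  cut5 <- paste0(substr(planted, 1, 3 * (rng5[1] - 1)),
                 substr(planted, 3 * (rng5[1] - 1 + half) + 1, nchar(planted)))
  tm5 <- tm_coverage(model_of(cut5), prof)
  expect_lt(tm5$coverage[5], 0.75)
  expect_gt(tm5$coverage[5], 0.25)
  expect_false(tm5$missing[5])
})

test_that("classification rules: pseudogenization dominates, edges rescue", {
  d <- function(...) {
    kinds <- c(...)
    data.frame(kind = kinds, cds_pos = rep(NA_integer_, length(kinds)),
               genome_start0 = rep(NA_integer_, length(kinds)),
               genome_end0 = rep(NA_integer_, length(kinds)),
               detail = rep("", length(kinds)), stringsAsFactors = FALSE)
  }
  none <- d(character(0))
  ## premature stop near a scaffold edge is still a pseudogene
  expect_equal(classify_gene(d("premature_stop", "missing_stop"), TRUE),
               "pseudogene")
  ## missing start near an edge, no other disruption: truncated
  expect_equal(classify_gene(d("missing_start"), TRUE), "truncated")
  ## missing start with intact flanking sequence: pseudogene
  expect_equal(classify_gene(d("missing_start"), FALSE), "pseudogene")
  expect_equal(classify_gene(none, FALSE), "intact")
  expect_equal(classify_gene(d("missing_tm"), FALSE), "pseudogene")
})

test_that("planted labels are recovered and summarized; trichotomy holds", {
  w <- small_world()
  calls <- small_calls()
  cmp <- match_truth(calls, w$planted$truth)
  expect_true(all(cmp$called == cmp$planted))
  expect_true(all(calls$label %in% c("intact", "truncated", "pseudogene")))

  s <- summarize_repertoire(calls)
  expect_equal(s$intact, sum(w$planted$truth$label == "intact"))
  expect_equal(s$pseudogene, sum(w$planted$truth$label == "pseudogene"))
  expect_equal(s$truncated, sum(w$planted$truth$label == "truncated"))
  expect_equal(s$total, s$intact + s$truncated + s$pseudogene)

  ## per-call invariants: label matches its recorded disruptions
  for (i in seq_len(nrow(calls))) {
    kinds <- strsplit(calls$disruption_kinds[i], ",")[[1]]
    if (calls$label[i] == "intact") expect_equal(length(kinds), 0L)
    if (calls$label[i] == "pseudogene")
      expect_gte(length(kinds), 1L)
    if (calls$label[i] == "truncated") {
      expect_true(all(kinds %in% c("missing_start", "missing_stop")))
      expect_gte(length(kinds), 1L)
    }
  }
  expect_equal(nrow(summarize_repertoire(calls[0, ])), 0L)
})

test_that("adding a premature stop to an intact gene always pseudogenizes", {
  w <- small_world()
  calls <- small_calls()
  intact <- calls[calls$label == "intact", ]
  prof <- w$fam$profile
  set.seed(20)
  for (i in seq_len(min(3L, nrow(intact)))) {
    cds <- intact$cds[i]
    cd <- sample(50:250, 1)
    substr(cds, 3 * cd - 2, 3 * cd) <- "TGA"
    g <- c(chr = paste0(strrep("GTCA", 500), cds, strrep("CATG", 500)))
    m <- reconstruct_cds(locus_row("chr", 2000, 2000 + nchar(cds)), prof, g)
    dd <- detect_disruptions(m, prof)
    expect_equal(classify_gene(dd, FALSE), "pseudogene")
  }
})

test_that("gene calls export to GFF3 with 1-based coordinates", {
  calls <- small_calls()
  f <- withr::local_tempfile(fileext = ".gff3")
  write_calls_gff3(calls, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(length(lines), nrow(calls) + 1L)
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[4]), calls$start0[1] + 1L)
  expect_equal(as.integer(first[5]), calls$end0[1])
})
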