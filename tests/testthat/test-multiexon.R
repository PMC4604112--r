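test_that("exon mapping is self-consistent on the source locus", {
  pm <- plant_multiexon(n_exons = 6L, seed = 31L)
  pres <- map_exons(pm$reference, pm$model, source_genome = pm$reference)
  expect_true(all(pres$status == "found"))
  expect_equal(pres$start0, pm$model$ref_intervals[, 1])
  expect_equal(pres$end0, pm$model$ref_intervals[, 2])
  expect_true(all(pres$strand == "+"))
  expect_equal(pres$order_index, 1:6)
  expect_equal(length(detect_inversion(pres)), 0L)
})

test_that("deleted exons are detected and confirmed as deleted", {
  ## 13-exon gene losing exons 5, 9, 10, 11
  pm <- plant_multiexon(n_exons = 13L, delete_exons = c(5L, 9L, 10L, 11L),
                        seed = 32L)
  pres <- map_exons(pm$target, pm$model, source_genome = pm$reference)
  expect_equal(sort(pres$exon[pres$status == "absent"]), c(5L, 9L, 10L, 11L))
  expect_true(all(pres$status[-c(5, 9, 10, 11)] == "found"))
  v <- confirm_deletion(pm$target, pres, pm$model)
  expect_equal(sort(v$exon), c(5L, 9L, 10L, 11L))
  expect_true(all(v$verdict == "deleted"))

  ## additionally losing exons 1 and 2
  pm2 <- plant_multiexon(n_exons = 13L,
                         delete_exons = c(1L, 2L, 5L, 9L, 10L, 11L),
                         seed = 32L)
  pres2 <- map_exons(pm2$target, pm2$model, source_genome = pm2$reference)
  expect_equal(sort(pres2$exon[pres2$status == "absent"]),
               c(1L, 2L, 5L, 9L, 10L, 11L))
  v2 <- confirm_deletion(pm2$target, pres2, pm2$model)
  ## exons 1-2 have no upstream found flank: unresolved, not "deleted"
  expect_equal(v2$verdict[v2$exon %in% c(1L, 2L)], rep("unresolved", 2))
  expect_equal(v2$verdict[v2$exon %in% c(5L, 9L, 10L, 11L)],
               rep("deleted", 4))
})

test_that("an intervening assembly gap blocks the deletion verdict", {
  pm <- plant_multiexon(n_exons = 6L, seed = 33L)
  ## replace exon 3 (plus a margin) with a 500-bp N run
  iv <- pm$model$ref_intervals
  target <- pm$reference[[1]]
  target <- paste0(substr(target, 1, iv[3, 1] - 100),
                   strrep("N", 500),
                   substr(target, iv[3, 2] + 100, nchar(target)))
  pres <- map_exons(c(t = target), pm$model, source_genome = pm$reference)
  expect_true(pres$status[3] == "absent")
  v <- confirm_deletion(c(t = target), pres, pm$model)
  expect_equal(v$verdict[v$exon == 3L], "assembly_gap")
})

test_that("dot plots show self-identity diagonals and transpose symmetry", {
  set.seed(34)
  a <- rand_dna(5000)
  dp <- compute_dotplot(a, a, mesh = 1000)
  expect_equal(dim(dp$grid), c(5L, 5L))
  expect_true(all(diag(dp$grid) == 100))
  b <- rand_dna(4000)
  ab <- compute_dotplot(a, b, mesh = 1000)
  ba <- compute_dotplot(b, a, mesh = 1000)
  expect_equal(ab$grid, t(ba$grid))
  ## unrelated sequences: almost all cells weak
  expect_gt(mean(ab$grid < 50), 0.95)
  expect_error(compute_dotplot(a, b, mesh = 0), class = "chemorep_config_error")
  ## an inverted segment still lights up (reverse-complement orientation)
  inv <- paste0(substr(a, 1, 2000), revcomp(substr(a, 2001, 3000)),
                substr(a, 3001, 5000))
  dpi <- compute_dotplot(a, inv, mesh = 1000)
  expect_equal(dpi$grid[3, 3], 100)
})

test_that("inversions are recovered from strand and order reversal", {
  pm <- plant_multiexon(n_exons = 6L, invert_exons = c(4L, 5L), seed = 35L)
  pres <- map_exons(pm$target, pm$model, source_genome = pm$reference)
  expect_true(all(pres$status == "found"))
  ev <- detect_inversion(pres)
  expect_equal(length(ev), 1L)
  expect_equal(ev[[1]]$exons, c(4L, 5L))

  ## single found exon: orientation indeterminate, no events
  one <- pres[pres$exon == 1, ]
  expect_equal(length(detect_inversion(one)), 0L)
})

test_that("exon boundaries snap to GT..AG within the shift window", {
  ## controlled locus: exon tails/heads and intron interior are G-free, so
  ## the only GT / AG near each junction is the genuine splice site
  set.seed(36)
  e1 <- paste0(rand_dna(180), strrep("C", 20))
  e2 <- paste0(strrep("C", 20), rand_dna(160), strrep("C", 20))
  e3 <- paste0(strrep("C", 20), rand_dna(180))
  intron <- function() paste0("GT", strrep("CA", 100), "AG")
  target <- paste0(e1, intron(), e2, intron(), e3)
  s1 <- 0L; en1 <- nchar(e1)
  s2 <- en1 + 204L; en2 <- s2 + nchar(e2)
  s3 <- en2 + 204L; en3 <- s3 + nchar(e3)
  pres <- data.frame(exon = 1:3, status = "found", seq_id = "t",
                     start0 = c(s1, s2, s3), end0 = c(en1, en2, en3),
                     strand = "+", order_index = 1:3,
                     stringsAsFactors = FALSE)
  ## knock placements off by 4 bp, as homology placement would
  off <- pres
  off$end0[1] <- off$end0[1] - 4L
  off$start0[2] <- off$start0[2] + 4L
  fixed <- annotate_exon_boundaries(target, off)
  expect_equal(fixed$end0[1], pres$end0[1])
  expect_equal(fixed$start0[2], pres$start0[2])
  expect_true(fixed$donor_canonical[1])
  expect_true(fixed$acceptor_canonical[2])
  ## untouched boundaries stay put
  expect_equal(fixed$end0[2], pres$end0[2])
  expect_equal(fixed$start0[3], pres$start0[3])

  ## a non-canonical intron is flagged and left as placed
  seq2 <- target
  substr(seq2, en2 + 1, en2 + 2) <- "CC"   # break the second donor site
  fixed2 <- annotate_exon_boundaries(seq2, pres)
  expect_false(fixed2$donor_canonical[2])
  expect_equal(fixed2$end0[2], pres$end0[2])
})

test_that("shared disrupting mutations are reported in reference coordinates", {
  set.seed(37)
  ## reference CDS long enough to carry events at positions 643 and 658-660
  n_codon <- 240L
  ref <- chemorep:::.reverse_translate(rand_prot(n_codon))
  ## distinct bases around position 643: unambiguous deletion placement
  substr(ref, 640, 645) <- "GCATGC"
  mk_target <- function(del_at = NA, stop_codon = NA) {
    s <- ref
    if (!is.na(stop_codon))
      substr(s, 3 * stop_codon - 2, 3 * stop_codon) <- "TGA"
    if (!is.na(del_at))
      s <- paste0(substr(s, 1, del_at - 1), substr(s, del_at + 1, nchar(s)))
    s
  }
  targets <- c(cet1 = mk_target(643, 220), cet2 = mk_target(643, 220),
               cet3 = mk_target(643, 220), outgroup = ref)
  res <- annotate_disruptions_vs_reference(targets, ref,
                                           group = c("cet1", "cet2", "cet3"))
  expect_equal(nrow(res$events[res$events$target == "outgroup", ]), 0L)
  sh <- res$shared
  expect_equal(nrow(sh), 2L)
  del <- sh[sh$kind == "deletion", ]
  expect_equal(del$ref_pos, 643L)
  expect_equal(del$length, 1L)
  stp <- sh[sh$kind == "stop_gain", ]
  expect_equal(c(stp$ref_pos, stp$ref_end), c(658L, 660L))

  ## a private mutation is not shared
  targets2 <- c(targets, cet4 = mk_target(643, NA))
  res2 <- annotate_disruptions_vs_reference(
    targets2, ref, group = c("cet1", "cet2", "cet3", "cet4"))
  expect_equal(res2$shared$kind, "deletion")
  expect_equal(res2$shared$ref_pos, 643L)
})

test_that("in-silico PCR reproduces planted products with degenerate primers", {
  fwd <- "AGGTGGACAGAGATCTGARAG"     # one R (A/G) degeneracy
  rev <- "TATAAAAGATGAAAATGTGTAGGAT"
  fwd_site <- sub("R", "A", fwd)     # R matching A at zero cost
  spacer <- 299 - nchar(fwd) - nchar(rev)
  set.seed(38)
  template <- c(t1 = paste0(rand_dna(150), fwd_site, rand_dna(spacer),
                            revcomp(rev), rand_dna(150)))
  amp <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length, 299L)
  expect_equal(amp$fwd_mm + amp$rev_mm, 0L)

  ## no reverse site, no product
  t2 <- c(t2 = paste0(rand_dna(150), fwd_site, rand_dna(400)))
  expect_equal(nrow(insilico_pcr(t2, fwd, rev)), 0L)

  ## products beyond max_product are suppressed
  t3 <- c(t3 = paste0(rand_dna(50), fwd_site, rand_dna(6000),
                      revcomp(rev), rand_dna(50)))
  expect_equal(nrow(insilico_pcr(t3, fwd, rev)), 0L)
})
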