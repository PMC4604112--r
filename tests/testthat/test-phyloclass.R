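test_that("Poisson-corrected distances follow the closed form", {
  msa <- c(a = "MKLVSTAGHE", b = "MKLVSTAGHE")
  expect_error(protein_distance(msa), "30")   # too few shared columns
  set.seed(40)
  s <- rand_prot(300)
  sm <- strsplit(s, "")[[1]]
  pos <- sample(300, 30)
  for (p in pos) sm[p] <- sample(setdiff(strsplit(
    "ARNDCQEGHILKMFPSTWYV", "")[[1]], sm[p]), 1)
  d <- protein_distance(c(a = s, b = paste(sm, collapse = ""), c = s))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], -log(1 - 0.1), tolerance = 1e-12)
  expect_true(isSymmetric(unname(d)))
  ## no shared columns at all
  expect_error(protein_distance(c(a = paste0(strrep("-", 40), "MKLV"),
                                  b = paste0("MKLV", strrep("-", 40)))))
})

test_that("neighbor joining is exact on additive matrices", {
  ## hand-built additive matrix for the tree ((A:1,B:2):1,(C:3,D:1):0)
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- build_nj(d)
  expect_s3_class(tr, "phylo")
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d),
                                                           colnames(d)]),
               unname(d), tolerance = 1e-9)
  ## A and B must be sisters
  expect_equal(length(ape::getMRCA(tr, c("A", "B"))), 1L)

  ## 3 taxa: unique topology, branch lengths solve the three-point equations
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- build_nj(d3)
  cp <- as.matrix(ape::cophenetic.phylo(t3))
  expect_equal(unname(cp[c("x", "y", "z"), c("x", "y", "z")]), unname(d3),
               tolerance = 1e-9)

  ## identical taxa pair up as sisters
  d4 <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  t4 <- build_nj(d4)
  expect_equal(as.matrix(ape::cophenetic.phylo(t4))["p", "q"], 0)

  ## non-symmetric input refused
  dbad <- d; dbad[1, 2] <- 99
  expect_error(build_nj(dbad), class = "chemorep_config_error")
})

test_that("tree classification assigns classes by clade then nearest leaf", {
  set.seed(41)
  ancI <- rand_prot(300); ancII <- rand_prot(300)
  mut <- function(s, d) chemorep:::.mutate_protein(s, d)
  refs <- c(setNames(lapply(1:4, function(i) mut(ancI, 0.1)),
                     paste0("I", 1:4)),
            setNames(lapply(1:4, function(i) mut(ancII, 0.1)),
                     paste0("II", 1:4)))
  labels <- setNames(rep(c("classI", "classII"), each = 4), names(refs))
  ## a query identical to a class I reference
  msa <- c(unlist(refs), query = refs[["I1"]])
  tr <- build_nj(protein_distance(msa))
  res <- classify_by_tree(tr, labels, "query")
  expect_equal(res$assigned_class, "classI")

  ## constructed exact tie: the query's smallest reference-containing clade
  ## holds one leaf of each class at identical distance, so the clade rule
  ## cannot decide and the nearest-leaf fallback warns and picks class II
  taxa <- c("a1", "b1", "q", "a2", "b2")
  dt <- matrix(c(0.0, 0.2, 0.7, 1.7, 1.7,
                 0.2, 0.0, 0.7, 1.7, 1.7,
                 0.7, 0.7, 0.0, 1.7, 1.7,
                 1.7, 1.7, 1.7, 0.0, 0.2,
                 1.7, 1.7, 1.7, 0.2, 0.0), 5, 5,
               dimnames = list(taxa, taxa))
  tt <- build_nj(dt)
  tie_labels <- c(a1 = "classI", a2 = "classI",
                  b1 = "classII", b2 = "classII")
  expect_warning(res2 <- classify_by_tree(tt, tie_labels, "q"),
                 "equidistant")
  expect_equal(res2$assigned_class, "classII")
  expect_equal(res2$method, "nearest")

  ## leaf-order permutation cannot change the assignment
  perm <- sample(length(msa))
  tr2 <- build_nj(protein_distance(msa[perm]))
  expect_equal(classify_by_tree(tr2, labels, "query")$assigned_class,
               "classI")
})

test_that("truncated fragments are placed one by one, order-independently", {
  set.seed(42)
  ancI <- rand_prot(300); ancII <- rand_prot(300)
  mut <- function(s, d) chemorep:::.mutate_protein(s, d)
  ref_msa <- c(setNames(vapply(1:4, function(i) mut(ancI, 0.1), ""),
                        paste0("I", 1:4)),
               setNames(vapply(1:4, function(i) mut(ancII, 0.1), ""),
                        paste0("II", 1:4)))
  labels <- setNames(rep(c("classI", "classII"), each = 4), names(ref_msa))
  gene <- mut(ancII, 0.1)
  frags <- c(f_nterm = substr(gene, 1, 150), f_cterm = substr(gene, 151, 300))
  r1 <- place_one_by_one(frags, ref_msa, labels)
  r2 <- place_one_by_one(rev(frags), ref_msa, labels)
  expect_equal(r1$assigned_class, c("classII", "classII"))
  expect_equal(r2[order(r2$query_id), "assigned_class"],
               r1[order(r1$query_id), "assigned_class"])

  ## a C-terminal fragment of a class I sequence goes to class I
  fragI <- c(tail_frag = substr(mut(ancI, 0.05), 230, 300))
  expect_equal(place_one_by_one(fragI, ref_msa, labels)$assigned_class,
               "classI")

  ## too-short fragments are left unassigned; empty input gives empty output
  tiny <- c(tiny = substr(gene, 1, 20))
  expect_equal(place_one_by_one(tiny, ref_msa, labels)$method, "unassigned")
  expect_equal(nrow(place_one_by_one(character(0), ref_msa, labels)), 0L)
})

test_that("Nei-Gojobori dN/dS matches hand-counted oracles", {
  ## identical sequences
  r0 <- dnds_nei_gojobori("ATGAAACCC", "ATGAAACCC")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))

  ## synonymous-only third-position change: dN = 0, dS > 0, omega = 0
  a1 <- "ATGCCCGGGACT"
  b1 <- "ATGCCAGGGACT"
  r1 <- dnds_nei_gojobori(a1, b1)
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_equal(r1$omega, 0)

  ## 9-codon pair, every count frozen from a hand-worked pathway tally:
  ## diffs: AAA>AAG (syn), CCC>CCA (syn), TTT>TTC (syn), GAA>GAT (nonsyn)
  ## per-codon synonymous sites: ATG 0, AAA 1/3, CCC 1, GGG 1, TTT 1/3,
  ## CTG 4/3, GAA 1/3, TAC 1/3, CGT 1  (identical totals for both strands
  ## of the comparison), so S = 17/3 and N = 27 - 17/3 = 64/3
  a2 <- "ATGAAACCCGGGTTTCTGGAATACCGT"
  b2 <- "ATGAAGCCAGGGTTCCTGGATTACCGT"
  r2 <- dnds_nei_gojobori(a2, b2)
  expect_equal(r2$sd, 3)
  expect_equal(r2$nd, 1)
  expect_equal(r2$S_sites, 17 / 3, tolerance = 1e-12)
  expect_equal(r2$N_sites, 64 / 3, tolerance = 1e-12)
  expect_equal(r2$dS, -0.75 * log(1 - 4 * (3 / (17 / 3)) / 3),
               tolerance = 1e-12)
  expect_equal(r2$dN, -0.75 * log(1 - 4 * (1 / (64 / 3)) / 3),
               tolerance = 1e-12)
  expect_equal(r2$omega, r2$dN / r2$dS)

  ## contract violations
  expect_error(dnds_nei_gojobori("ATGAA", "ATGAA"),
               class = "chemorep_config_error")
  expect_error(dnds_nei_gojobori("ATGTAAGGG", "ATGTAAGGG"),
               class = "chemorep_config_error")
  expect_error(dnds_nei_gojobori("ATGAAA", "ATG"),
               class = "chemorep_config_error")
})

test_that("omega is calibrated: ~1 under neutrality, <1 under purifying", {
  set.seed(43)
  evolve <- function(cds, n_events, accept_nonsyn) {
    nts <- c("A", "C", "G", "T")
    done <- 0
    while (done < n_events) {
      p <- sample(nchar(cds), 1)
      cd <- (p - 1) %/% 3 + 1
      old_codon <- substr(cds, 3 * cd - 2, 3 * cd)
      new <- cds
      substr(new, p, p) <- sample(setdiff(nts, substr(cds, p, p)), 1)
      new_codon <- substr(new, 3 * cd - 2, 3 * cd)
      if (chemorep:::.CODON_TABLE[new_codon] == "*") next
      syn <- chemorep:::.CODON_TABLE[new_codon] ==
        chemorep:::.CODON_TABLE[old_codon]
      if (syn || runif(1) < accept_nonsyn) {
        cds <- new
        done <- done + 1
      }
    }
    cds
  }
  ## neutral: all changes accepted, large gene
  base <- chemorep:::.reverse_translate(rand_prot(500))
  omegas <- vapply(1:5, function(i) {
    a <- evolve(base, 60, 1)
    b <- evolve(base, 60, 1)
    dnds_nei_gojobori(a, b)$omega
  }, numeric(1))
  expect_gt(mean(omegas), 0.8)
  expect_lt(mean(omegas), 1.25)

  ## purifying: nonsynonymous changes accepted at 0.1x
  base2 <- chemorep:::.reverse_translate(rand_prot(300))
  om2 <- vapply(1:10, function(i) {
    a <- evolve(base2, 40, 0.1)
    b <- evolve(base2, 40, 0.1)
    dnds_nei_gojobori(a, b)$omega
  }, numeric(1))
  expect_gte(mean(om2 < 1), 0.9)
})
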