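## shared fixtures, built once per run and memoized

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_family <- function() memo("small_family", function()
  make_gpcr_family(n_refs = 4L, length_aa = 260L, divergence = 0.1,
                   seed = 42L, family = "tfam"))

## one small family planted sparsely: fast enough for per-module tests
small_world <- function() memo("small_world", function() {
  fam <- small_family()
  spec <- plant_spec("tfam", n_intact = 4L, n_pseudo = 4L, n_truncated = 2L,
                     pseudo_mutation_mix = c(premature_stop = 0.25,
                                             frameshift_1bp = 0.25,
                                             frameshift_2bp = 0.25,
                                             tm_deletion = 0.25))
  pl <- plant_genome(list(spec), list(fam),
                     scaffold_lengths = rep(14000L, 4L), seed = 7L)
  list(fam = fam, planted = pl)
})

small_calls <- function() memo("small_calls", function() {
  w <- small_world()
  hits <- translated_search(w$planted$genome, w$fam$refs)
  loci <- merge_hits(hits, "tfam")
  call_genes(loci, w$fam$profile, w$planted$genome)
})

## independent full-DP local alignment oracle (Biostrings)
oracle_sw_protein <- function(a, b, gap_open = 11, gap_extend = 1) {
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE))
}

## random sequences
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
rand_prot <- function(n) paste(sample(strsplit(
  "ARNDCQEGHILKMFPSTWYV", "")[[1]], n, TRUE), collapse = "")

## match calls against a planted truth table; returns per-truth-row labels
match_truth <- function(calls, truth) {
  truth <- truth[truth$label != "gap", , drop = FALSE]
  got <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ov <- calls$seq_id == truth$seq_id[i] &
      calls$start0 < truth$end0[i] & calls$end0 > truth$start0[i] &
      calls$family == truth$family[i]
    got[i] <- if (any(ov)) calls$label[which(ov)[1L]] else "missed"
  }
  data.frame(planted = truth$label, called = got,
             stringsAsFactors = FALSE)
}
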