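## synthetic: seeded genome / gene-family simulator with planted truth -----
##
## The generator states the world the pipeline is tested against: scaffolded
## genomes carrying planted 7-TM GPCR genes (intact), pseudogenized copies
## (one premature stop, 1-2 bp frameshifting indel, or whole-TM deletion
## each), truncated copies split at scaffold ends, and N-gap runs, over an
## i.i.d. uniform intergenic background.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")
## hydrophobic-leaning alphabet for transmembrane stretches
AA_TM <- c("A","C","F","G","I","L","M","S","T","V","W","Y")

## standard-code codon table grouped by amino acid (no stop codons)
.codons_by_aa <- local({
  aa <- .CODON_TABLE
  split(names(aa)[aa != "*"], aa[aa != "*"])
})

.rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = "")

## reverse-translate a protein with uniformly drawn synonymous codons
.reverse_translate <- function(prot) {
  aa <- strsplit(prot, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- .codons_by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

## Poisson substitution of a protein at `divergence` subs/site; position 1
## (the initiator methionine) is held fixed
.mutate_protein <- function(prot, divergence) {
  aa <- strsplit(prot, "")[[1]]
  n_sub <- stats::rpois(1L, divergence * length(aa))
  if (n_sub > 0L && length(aa) > 1L) {
    pos <- sample(2:length(aa), min(n_sub, length(aa) - 1L))
    for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  }
  paste(aa, collapse = "")
}

#' Simulate a 7-TM GPCR family and its profile
#'
#' Draws a random ancestor protein with seven designated transmembrane
#' segments (hydrophobic-leaning composition) starting with methionine, then
#' simulates reference members by Poisson substitutions at the stated
#' divergence. The returned profile carries the TM column ranges, so planted
#' TM deletions are checkable downstream.
#'
#' @param n_refs Number of reference sequences (>= 4).
#' @param length_aa Ancestor length in residues (>= 250; default 310, a
#'   typical chemosensory GPCR length).
#' @param divergence Expected substitutions/site from the ancestor
#'   (default 0.1).
#' @param seed Integer seed.
#' @param family Family name.
#' @return `list(refs = <named character>, profile = <family_profile>,
#'   ancestor = <character>)`.
#' @export
make_gpcr_family <- function(n_refs = 6L, length_aa = 310L, divergence = 0.1,
                             seed = 1L, family = "fam") {
  stopifnot(length_aa >= 250L, n_refs >= 4L, divergence >= 0, divergence <= 0.5)
  set.seed(seed)
  ## seven TM segments of ~24 residues spread over the chain, GPCR-style
  tm_starts <- round(length_aa * c(0.08, 0.19, 0.30, 0.43, 0.56, 0.74, 0.86))
  tm_len <- 24L
  aa <- sample(AA20, length_aa, replace = TRUE)
  aa[1L] <- "M"
  for (s in tm_starts) {
    idx <- s:(s + tm_len - 1L)
    aa[idx] <- sample(AA_TM, tm_len, replace = TRUE)
  }
  ancestor <- paste(aa, collapse = "")
  refs <- setNames(
    vapply(seq_len(n_refs), function(i) .mutate_protein(ancestor, divergence),
           character(1)),
    sprintf("%s_ref%02d", family, seq_len(n_refs)))
  tm_segments <- lapply(tm_starts, function(s) c(s, s + tm_len - 1L))
  profile <- family_profile(refs, tm_segments, family = family)
  list(refs = refs, profile = profile, ancestor = ancestor)
}

#' Specification of what to plant in a synthetic genome
#'
#' @param family Family name.
#' @param n_intact,n_pseudo,n_truncated Planted counts per label (defaults
#'   10 / 5 / 2).
#' @param pseudo_mutation_mix Named proportions over `premature_stop`,
#'   `frameshift_1bp`, `frameshift_2bp`, `tm_deletion` (must sum to 1).
#' @param divergence Substitutions/site of each planted gene from the family
#'   ancestor (default 0.1).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(family, n_intact = 10L, n_pseudo = 5L,
                       n_truncated = 2L,
                       pseudo_mutation_mix = c(premature_stop = 0.4,
                                               frameshift_1bp = 0.3,
                                               frameshift_2bp = 0.1,
                                               tm_deletion = 0.2),
                       divergence = 0.1) {
  stopifnot(n_intact >= 0, n_pseudo >= 0, n_truncated >= 0,
            abs(sum(pseudo_mutation_mix) - 1) < 1e-9,
            divergence >= 0, divergence <= 0.5)
  structure(list(family = family, n_intact = as.integer(n_intact),
                 n_pseudo = as.integer(n_pseudo),
                 n_truncated = as.integer(n_truncated),
                 pseudo_mutation_mix = pseudo_mutation_mix,
                 divergence = divergence),
            class = "plant_spec")
}

## one pseudogenizing edit; returns list(orf, kind, detail, cds_pos)
.pseudogenize <- function(orf, kind, profile) {
  n_codon <- nchar(orf) %/% 3L - 1L            # exclude the stop codon
  mid <- max(2L, round(n_codon * 0.2)):min(n_codon - 1L, round(n_codon * 0.8))
  if (kind == "premature_stop") {
    cd <- sample(mid, 1L)
    repeat {
      stop_cd <- sample(STOP_CODONS, 1L)
      if (substr(orf, 3L * cd - 2L, 3L * cd) != stop_cd) break
    }
    substr(orf, 3L * cd - 2L, 3L * cd) <- stop_cd
    list(orf = orf, kind = "premature_stop",
         detail = sprintf("%s at codon %d", stop_cd, cd), cds_pos = 3L * cd - 2L)
  } else if (kind %in% c("frameshift_1bp", "frameshift_2bp")) {
    nbp <- if (kind == "frameshift_1bp") 1L else 2L
    pos <- sample(3L * mid, 1L)                # nt position inside coding span
    if (stats::runif(1) < 0.5) {
      orf2 <- paste0(substr(orf, 1L, pos - nbp), substr(orf, pos + 1L, nchar(orf)))
      detail <- sprintf("%d-bp deletion", nbp)
    } else {
      ins <- .rand_dna(nbp)
      orf2 <- paste0(substr(orf, 1L, pos), ins, substr(orf, pos + 1L, nchar(orf)))
      detail <- sprintf("%d-bp insertion", nbp)
    }
    list(orf = orf2, kind = "frameshift_indel", detail = detail, cds_pos = pos)
  } else { # tm_deletion
    s <- sample.int(7L, 1L)
    rng <- profile$tm_consensus[[s]]
    nt_lo <- 3L * (rng[1] - 1L) + 1L
    nt_hi <- 3L * rng[2]
    orf2 <- paste0(substr(orf, 1L, nt_lo - 1L), substr(orf, nt_hi + 1L, nchar(orf)))
    list(orf = orf2, kind = "missing_tm", detail = sprintf("TM%d absent", s),
         cds_pos = nt_lo)
  }
}

#' Plant gene families in a synthetic scaffolded genome
#'
#' Intact genes are complete ORFs (ATG ... stop) of freshly diverged family
#' members; pseudogenes carry exactly one disruptive mutation drawn from the
#' spec's mix; truncated genes are intact ORFs split at a scaffold boundary
#' (start- or stop-side removed). Intergenic background is i.i.d. uniform
#' nucleotides with optional N-gap runs. A truth table records every planted
#' element with coordinates that slice the genome back to the planted
#' sequence exactly.
#'
#' @param specs A `plant_spec` or list of them (one per family).
#' @param families Matching list of [make_gpcr_family()] results.
#' @param scaffold_lengths Integer vector (default eight 30-kb scaffolds).
#' @param gap_spec `list(n = <gaps>, length = <run length>)` (default 4 runs
#'   of 300 N, the size a draft-assembly scaffolder typically leaves).
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param spacing Minimum distance between planted elements and to scaffold
#'   interiors (default 1500 bp).
#' @return `list(genome = <named character>, truth = <data.frame>)`.
#' @export
plant_genome <- function(specs, families, scaffold_lengths = rep(30000L, 8L),
                         gap_spec = list(n = 4L, length = 300L), seed = 1L,
                         spacing = 1500L) {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  if (!is.null(families$profile)) families <- list(families)
  stopifnot(length(specs) == length(families))
  set.seed(seed)
  n_scaf <- length(scaffold_lengths)
  scaf_ids <- sprintf("scaffold%02d", seq_len(n_scaf))
  genome <- setNames(vapply(scaffold_lengths, .rand_dna, character(1)), scaf_ids)
  truth <- list()
  ## per-scaffold occupied intervals (gene bodies + spacing)
  occupied <- setNames(rep(list(data.frame(lo = integer(), hi = integer())),
                           n_scaf), scaf_ids)
  reserve <- function(sc, lo, hi) {
    occupied[[sc]] <<- rbind(occupied[[sc]], data.frame(lo = lo, hi = hi))
  }
  free_slot <- function(len, margin) {
    for (try in seq_len(400L)) {
      sc <- sample(scaf_ids, 1L)
      L <- nchar(genome[[sc]])
      if (L - 2L * margin - len <= 0L) next
      lo <- sample.int(L - 2L * margin - len, 1L) + margin
      hi <- lo + len
      occ <- occupied[[sc]]
      if (nrow(occ) == 0L || all(hi + spacing <= occ$lo | lo >= occ$hi + spacing)) {
        reserve(sc, lo, hi)
        return(list(sc = sc, lo = lo, hi = hi))
      }
    }
    runtime_error("could not place a planted element; genome too small for spec")
  }
  insert_seq <- function(sc, lo, s) {
    substr(genome[[sc]], lo + 1L, lo + nchar(s)) <<- s
  }
  total_planted <- 0L
  edge_slots <- expand.grid(sc = scaf_ids, side = c("start", "end"),
                            stringsAsFactors = FALSE)
  edge_slots <- edge_slots[sample.int(nrow(edge_slots)), ]
  edge_used <- 0L
  for (fi in seq_along(specs)) {
    spec <- specs[[fi]]
    fam <- families[[fi]]
    new_orf <- function() {
      prot <- .mutate_protein(fam$ancestor, spec$divergence)
      paste0(.reverse_translate(prot), sample(STOP_CODONS, 1L))
    }
    plant_one <- function(label, orf, kind = NA, detail = NA, cds_pos = NA) {
      slot <- free_slot(nchar(orf), spacing)
      strand <- sample(c("+", "-"), 1L)
      s <- if (strand == "+") orf else revcomp(orf)
      insert_seq(slot$sc, slot$lo, s)
      total_planted <<- total_planted + nchar(orf)
      truth[[length(truth) + 1L]] <<- data.frame(
        family = spec$family, label = label, seq_id = slot$sc,
        start0 = slot$lo, end0 = slot$hi, strand = strand,
        mutation = kind, detail = detail, cds_pos = cds_pos,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(spec$n_intact)) plant_one("intact", new_orf())
    for (i in seq_len(spec$n_pseudo)) {
      kind <- sample(names(spec$pseudo_mutation_mix), 1L,
                     prob = spec$pseudo_mutation_mix)
      ed <- .pseudogenize(new_orf(), kind, fam$profile)
      plant_one("pseudogene", ed$orf, ed$kind, ed$detail, ed$cds_pos)
    }
    for (i in seq_len(spec$n_truncated)) {
      edge_used <- edge_used + 1L
      if (edge_used > nrow(edge_slots))
        runtime_error("not enough scaffold edges for truncated genes")
      slot <- edge_slots[edge_used, ]
      orf <- new_orf()
      keep <- round(nchar(orf) * stats::runif(1, 0.45, 0.7) / 3) * 3L
      L <- nchar(genome[[slot$sc]])
      if (slot$side == "start") {
        ## 3' part of a + strand gene survives at the scaffold start
        frag <- substr(orf, nchar(orf) - keep + 1L, nchar(orf))
        insert_seq(slot$sc, 0L, frag)
        reserve(slot$sc, 0L, nchar(frag))
        truth[[length(truth) + 1L]] <- data.frame(
          family = spec$family, label = "truncated", seq_id = slot$sc,
          start0 = 0L, end0 = nchar(frag), strand = "+",
          mutation = "missing_start", detail = "5' end beyond scaffold start",
          cds_pos = NA_integer_, stringsAsFactors = FALSE)
      } else {
        ## 5' part of a + strand gene survives at the scaffold end
        frag <- substr(orf, 1L, keep)
        insert_seq(slot$sc, L - nchar(frag), frag)
        reserve(slot$sc, L - nchar(frag), L)
        truth[[length(truth) + 1L]] <- data.frame(
          family = spec$family, label = "truncated", seq_id = slot$sc,
          start0 = L - nchar(frag), end0 = L, strand = "+",
          mutation = "missing_stop", detail = "3' end beyond scaffold end",
          cds_pos = NA_integer_, stringsAsFactors = FALSE)
      }
      total_planted <- total_planted + keep
    }
  }
  if (total_planted >= 0.8 * sum(scaffold_lengths))
    runtime_error("planted length exceeds 80% of genome length")
  ## N-gap runs in unoccupied background, away from planted elements
  if (gap_spec$n > 0L) {
    for (g in seq_len(gap_spec$n)) {
      slot <- free_slot(gap_spec$length, spacing)
      insert_seq(slot$sc, slot$lo,
                 paste(rep("N", gap_spec$length), collapse = ""))
      truth[[length(truth) + 1L]] <- data.frame(
        family = "gap", label = "gap", seq_id = slot$sc,
        start0 = slot$lo, end0 = slot$hi, strand = "+",
        mutation = NA_character_, detail = sprintf("%d N", gap_spec$length),
        cds_pos = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Plant a multi-exon gene and an edited target copy
#'
#' Builds a reference locus of `n_exons` exons separated by introns with
#' canonical GT..AG ends, then a target locus in which specified exons are
#' excised or a contiguous exon block is reverse-complemented in place
#' (taking its introns with it) - the deletion and inversion scenarios seen
#' when a marker gene decays in a genome comparison.
#'
#' @param n_exons Number of exons.
#' @param exon_lengths Integer vector (recycled; default 180 bp).
#' @param intron_lengths Integer vector (recycled; default 900 bp).
#' @param delete_exons Integer vector of exon numbers to excise.
#' @param invert_exons Integer vector of consecutive exon numbers to invert.
#' @param seed Integer seed.
#' @return `list(reference, target, model = <exon_model>, truth)`.
#' @export
plant_multiexon <- function(n_exons = 13L, exon_lengths = 180L,
                            intron_lengths = 900L, delete_exons = integer(),
                            invert_exons = integer(), seed = 1L) {
  stopifnot(n_exons >= 2L)
  if (length(intersect(delete_exons, invert_exons)) > 0L)
    config_error("cannot delete and invert the same exon")
  if (length(invert_exons) > 0L &&
      !identical(as.integer(invert_exons),
                 seq(min(invert_exons), max(invert_exons))))
    config_error("inverted exons must be consecutive")
  bad <- setdiff(c(delete_exons, invert_exons), seq_len(n_exons))
  if (length(bad) > 0L)
    config_error(sprintf("edit references nonexistent exon(s): %s",
                         paste(bad, collapse = ", ")))
  set.seed(seed)
  exon_lengths <- rep_len(as.integer(exon_lengths), n_exons)
  intron_lengths <- rep_len(as.integer(intron_lengths), n_exons - 1L)
  exons <- lapply(exon_lengths, .rand_dna)
  introns <- lapply(intron_lengths, function(n) {
    s <- .rand_dna(n)
    substr(s, 1L, 2L) <- "GT"
    substr(s, n - 1L, n) <- "AG"
    s
  })
  flank5 <- .rand_dna(1000L); flank3 <- .rand_dna(1000L)
  parts <- character(0); coords <- integer(0)
  pos <- nchar(flank5)
  ref_intervals <- matrix(0L, n_exons, 2L,
                          dimnames = list(NULL, c("start0", "end0")))
  parts <- flank5
  for (e in seq_len(n_exons)) {
    ref_intervals[e, ] <- c(pos, pos + exon_lengths[e])
    parts <- c(parts, exons[[e]])
    pos <- pos + exon_lengths[e]
    if (e < n_exons) {
      parts <- c(parts, introns[[e]])
      pos <- pos + intron_lengths[e]
    }
  }
  parts <- c(parts, flank3)
  reference <- paste(parts, collapse = "")
  ## target: apply edits on the unit list (exon/intron alternation)
  units <- vector("list", 2L * n_exons - 1L)
  for (e in seq_len(n_exons)) units[[2L * e - 1L]] <- exons[[e]]
  for (e in seq_len(n_exons - 1L)) units[[2L * e]] <- introns[[e]]
  keep <- rep(TRUE, length(units))
  for (e in delete_exons) keep[2L * e - 1L] <- FALSE
  if (length(invert_exons) > 0L) {
    lo <- 2L * min(invert_exons) - 1L
    hi <- 2L * max(invert_exons) - 1L
    block <- paste(unlist(units[lo:hi]), collapse = "")
    units[[lo]] <- revcomp(block)
    if (hi > lo) keep[(lo + 1L):hi] <- FALSE
  }
  target <- paste(c(flank5, unlist(units[keep]), flank3), collapse = "")
  model <- exon_model("synthetic_gene",
                      setNames(vapply(exons, identity, character(1)),
                               sprintf("exon%02d", seq_len(n_exons))),
                      ref_intervals)
  truth <- list(deleted = sort(as.integer(delete_exons)),
                inverted = sort(as.integer(invert_exons)))
  list(reference = c(ref_locus = reference),
       target = c(target_locus = target),
       model = model, truth = truth)
}

#' Default synthetic world: three planted GPCR families
#'
#' Three independent 7-TM families, each planted with 10 intact, 5
#' pseudogenized and 2 truncated copies (the default [plant_spec()]), on
#' eight 30-kb scaffolds with four 300-bp N-gap runs.
#'
#' @param seed Integer seed.
#' @return `list(families, specs, planted)` where `planted` is the
#'   [plant_genome()] result.
#' @export
default_synthetic_world <- function(seed = 1L) {
  fams <- lapply(1:3, function(i)
    make_gpcr_family(seed = seed * 17L + i, family = sprintf("fam%d", i)))
  specs <- lapply(1:3, function(i) plant_spec(sprintf("fam%d", i)))
  planted <- plant_genome(specs, fams, seed = seed)
  list(families = fams, specs = specs, planted = planted)
}
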