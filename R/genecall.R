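## genecall: CDS reconstruction and intact / truncated / pseudogene calls --
##
## A candidate locus is aligned, frameshift-aware, against the family profile
## consensus. Premature stop codons, frameshifting indels and complete loss
## of a transmembrane segment pseudogenize a locus; candidates lacking a
## start/stop codon solely because the scaffold is cut nearby are truncated.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build a gene-family profile
#'
#' A profile is a curated reference alignment of intact family members plus
#' the seven transmembrane (TM1..TM7) column ranges of that alignment. The
#' majority-rule consensus (gap-majority columns dropped) anchors CDS
#' reconstruction; TM ranges are carried over to consensus coordinates so
#' that "completely lacks a TM region" is a testable condition.
#'
#' @param msa Named character vector of aligned protein sequences (equal
#'   lengths; `-` for gaps).
#' @param tm_segments List of 7 integer pairs `c(start, end)` (1-based
#'   inclusive MSA columns), ordered and non-overlapping.
#' @param family Family name.
#' @return An object of class `family_profile`.
#' @export
family_profile <- function(msa, tm_segments, family = "family") {
  msa <- .as_named_chr(msa)
  w <- unique(nchar(msa))
  if (length(w) != 1L) config_error("profile MSA sequences must be aligned")
  if (length(tm_segments) != 7L) config_error("exactly 7 TM segments required")
  seg <- do.call(rbind, lapply(tm_segments, as.integer))
  if (any(diff(as.vector(t(seg))) < 0))
    config_error("TM segments must be ordered and non-overlapping")
  mat <- do.call(rbind, strsplit(msa, ""))
  for (i in seq_along(msa)) {
    for (s in seq_len(7L)) {
      if (all(mat[i, seg[s, 1]:seg[s, 2]] == "-"))
        config_error(sprintf("reference %s lacks TM%d entirely", names(msa)[i], s))
    }
  }
  cons_col <- apply(mat, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  })
  keep <- cons_col != "-"
  consensus <- paste(cons_col[keep], collapse = "")
  colmap <- cumsum(keep)           # MSA column -> consensus position
  tm_cons <- lapply(seq_len(7L), function(s) {
    cols <- seg[s, 1]:seg[s, 2]
    cols <- cols[keep[cols]]
    c(min(colmap[cols]), max(colmap[cols]))
  })
  structure(list(family = family, msa = msa, consensus = consensus,
                 consensus_len = nchar(consensus), tm_consensus = tm_cons),
            class = "family_profile")
}

## residue code of the codon ending at each 0-based window position
.aa_at_codes <- function(window) {
  m <- nchar(window)
  xcode <- match("X", PROT_ALPHABET) - 1L
  aa_at <- rep.int(xcode, m)
  for (f in 0:2) {
    P <- translate_frame(window, f, "+")
    if (nchar(P) == 0L) next
    cf <- prot_codes(P)
    aa_at[f + 3L * seq_along(cf)] <- cf
  }
  aa_at
}

## map a 0-based half-open window interval to forward scaffold coordinates
.win2genome <- function(a, b, w0, w1, strand) {
  if (strand == "+") c(w0 + a, w0 + b) else c(w1 - b, w1 - a)
}

#' Reconstruct a candidate CDS against a family profile
#'
#' The genomic window around the locus (extended by up to `extension_limit`
#' bases on each side, clipped at scaffold ends) is aligned to the profile
#' consensus with a frameshift-aware protein-to-DNA alignment. Initiation
#' and termination codons are then sought codon-wise outside the aligned
#' core, mirroring the 5'/3' extension used when annotating receptor loci.
#'
#' @param locus One row of a candidate-locus data.frame (`seq_id`, `start0`,
#'   `end0`, `strand`).
#' @param profile A [family_profile()].
#' @param genome Named character vector or `DNAStringSet`.
#' @param extension_limit Maximum extension distance in bp (default 500).
#' @param fs_penalty,fs_penalty2 Frameshift penalties for +-1 / +-2 nt codons.
#' @return A list of class `cds_model`: alignment path and score, aligned
#'   consensus span, CDS (with genomic coordinates), conceptual protein,
#'   start/stop status, scaffold-edge flags and extension distances used.
#' @export
reconstruct_cds <- function(locus, profile, genome, extension_limit = 500L,
                            fs_penalty = 12L, fs_penalty2 = 15L) {
  genome <- .as_named_chr(genome)
  scaf <- genome[[locus$seq_id]]
  if (is.null(scaf)) runtime_error(sprintf("scaffold %s not in genome", locus$seq_id))
  L <- nchar(scaf)
  w0 <- max(0L, locus$start0 - extension_limit)
  w1 <- min(L, locus$end0 + extension_limit)
  window <- substr(scaf, w0 + 1L, w1)
  clip_left <- (locus$start0 - extension_limit) < 0L
  clip_right <- (locus$end0 + extension_limit) > L
  if (locus$strand == "-") {
    window <- revcomp(window)
    clip5 <- clip_right; clip3 <- clip_left
  } else {
    clip5 <- clip_left; clip3 <- clip_right
  }
  scheme <- scoring_scheme()
  pc <- prot_codes(profile$consensus)
  aa_at <- .aa_at_codes(window)
  aln <- cpp_fs_align(pc, aa_at, scheme$prot_matrix, scheme$gap_open,
                      scheme$gap_extend, fs_penalty, fs_penalty2)
  c1 <- aln$prot_start; c2 <- aln$prot_end
  wA <- aln$dna_start; wB <- aln$dna_end   # 0-based half-open in window
  m <- nchar(window)
  start_tol <- 5L; stop_tol <- 5L
  ## initiation codon: only credible if the alignment reached the consensus
  ## N-terminus; scan upstream codon-wise until ATG, a stop, or window start
  has_start <- FALSE; cds_start <- wA
  if (c1 <= start_tol) {
    pos <- wA
    repeat {
      if (pos < 0L) break
      codon <- substr(window, pos + 1L, pos + 3L)
      if (codon == "ATG") { has_start <- TRUE; cds_start <- pos; break }
      if (pos < wA && codon %in% STOP_CODONS) break
      pos <- pos - 3L
    }
  }
  ## termination codon downstream of the aligned core
  has_stop <- FALSE; cds_end <- wB
  if (c2 >= profile$consensus_len - stop_tol) {
    pos <- wB
    while (pos + 3L <= m) {
      codon <- substr(window, pos + 1L, pos + 3L)
      if (codon %in% STOP_CODONS) { has_stop <- TRUE; cds_end <- pos + 3L; break }
      pos <- pos + 3L
    }
  }
  path <- aln$path
  cds <- substr(window, cds_start + 1L, cds_end)
  ## conceptual protein read along the alignment path
  aa <- character(0)
  if (nrow(path) > 0L) {
    cod <- path[, "op"] == 1L
    aa <- vapply(which(cod), function(r) {
      if (path[r, "ntlen"] >= 3L) {
        a <- .CODON_TABLE[substr(window, path[r, "dna_end"] - 2L,
                                 path[r, "dna_end"])]
        if (is.na(a)) "X" else unname(a)
      } else "X"
    }, character(1))
  }
  g_cds <- .win2genome(cds_start, cds_end, w0, w1, locus$strand)
  structure(list(locus = locus, window_start0 = w0, window_end0 = w1,
                 strand = locus$strand, window = window,
                 score = aln$score, path = path,
                 cons_start = c1, cons_end = c2,
                 aln_w_start = wA, aln_w_end = wB,
                 has_start = has_start, has_stop = has_stop,
                 cds_w_start = cds_start, cds_w_end = cds_end,
                 cds = cds, protein = paste(aa, collapse = ""),
                 cds_g_start0 = g_cds[1], cds_g_end0 = g_cds[2],
                 clip5 = clip5, clip3 = clip3,
                 ext5_used = max(0L, (if (locus$strand == "+")
                   locus$start0 - (w0 + cds_start) else
                     (w1 - cds_start) - locus$end0)),
                 ext3_used = max(0L, (if (locus$strand == "+")
                   (w0 + cds_end) - locus$end0 else
                     locus$start0 - (w1 - cds_end)))),
            class = "cds_model")
}

#' Transmembrane-segment coverage of a reconstructed gene model
#'
#' Coverage of each TM segment is the fraction of its consensus positions
#' aligned to a genomic codon. A segment counts as *completely missing* only
#' when its coverage is zero **and** it lies inside the aligned consensus
#' span: segments beyond an alignment that stops at a scaffold edge are a
#' truncation question, not a deletion.
#'
#' @param model A `cds_model` from [reconstruct_cds()].
#' @param profile The [family_profile()] used for reconstruction.
#' @return data.frame with `segment`, `coverage`, `in_span`, `missing`.
#' @export
tm_coverage <- function(model, profile) {
  path <- model$path
  covered <- if (nrow(path) > 0L) path[path[, "op"] == 1L, "prot_pos"] else integer(0)
  ## drop isolated single-residue anchors: a lone high-scoring residue inside
  ## a long deletion is alignment noise, not evidence the segment is present
  if (length(covered) > 2L) {
    covered <- sort(unique(covered))
    iso <- !(covered - 1L) %in% covered & !(covered + 1L) %in% covered
    covered <- covered[!iso]
  }
  res <- lapply(seq_len(7L), function(s) {
    rng <- profile$tm_consensus[[s]][1]:profile$tm_consensus[[s]][2]
    cov <- mean(rng %in% covered)
    ## a deletion gap exactly the segment's size can slide by a column or two
    ## when flank and segment residues happen to tie; judge "completely
    ## missing" on the segment interior so gap-placement jitter cannot turn
    ## a whole-segment deletion into token coverage
    interior <- if (length(rng) > 6L) rng[c(-1L, -2L, -(length(rng) - 1L),
                                            -length(rng))] else rng
    int_cov <- mean(interior %in% covered)
    in_span <- all(rng >= model$cons_start & rng <= model$cons_end)
    data.frame(segment = paste0("TM", s), coverage = cov, in_span = in_span,
               missing = (int_cov == 0) && cov <= 2 / length(rng) && in_span)
  })
  do.call(rbind, res)
}

#' Detect disrupting mutations in a reconstructed gene model
#'
#' Premature stop codons (in-frame stop strictly before the profile-aligned
#' terminus), frameshifting indels (codons of non-3 length on the alignment
#' path), completely missing TM segments, and missing initiation/termination
#' codons, each positioned in both CDS and genomic coordinates.
#'
#' @inheritParams tm_coverage
#' @return A data.frame with `kind`, `cds_pos` (1-based within the
#'   reconstructed CDS, `NA` where not applicable), `genome_start0`,
#'   `genome_end0`, `detail`.
#' @export
detect_disruptions <- function(model, profile) {
  out <- list()
  path <- model$path
  add <- function(kind, w_lo, w_hi, detail) {
    g <- if (!is.na(w_lo))
      .win2genome(w_lo, w_hi, model$window_start0, model$window_end0,
                  model$strand) else c(NA_integer_, NA_integer_)
    out[[length(out) + 1L]] <<- data.frame(
      kind = kind,
      cds_pos = if (!is.na(w_lo)) w_lo - model$cds_w_start + 1L else NA_integer_,
      genome_start0 = g[1], genome_end0 = g[2], detail = detail,
      stringsAsFactors = FALSE)
  }
  if (nrow(path) > 0L) {
    for (r in seq_len(nrow(path))) {
      if (path[r, "op"] != 1L) next
      ntlen <- path[r, "ntlen"]
      dend <- path[r, "dna_end"]
      if (ntlen != 3L) {
        detail <- switch(as.character(ntlen),
                         "1" = "2-bp deletion", "2" = "1-bp deletion",
                         "4" = "1-bp insertion", "5" = "2-bp insertion")
        add("frameshift_indel", dend - ntlen, dend, detail)
      } else {
        codon <- substr(model$window, dend - 2L, dend)
        if (codon %in% STOP_CODONS)
          add("premature_stop", dend - 3L, dend,
              sprintf("%s at consensus position %d", codon, path[r, "prot_pos"]))
      }
    }
  }
  tm <- tm_coverage(model, profile)
  for (s in which(tm$missing))
    add("missing_tm", NA_integer_, NA_integer_, sprintf("TM%d absent", s))
  if (!model$has_start)
    add("missing_start", NA_integer_, NA_integer_,
        if (model$clip5) "no ATG found; window clipped at scaffold edge"
        else "no ATG found within extension limit")
  if (!model$has_stop)
    add("missing_stop", NA_integer_, NA_integer_,
        if (model$clip3) "no stop codon found; window clipped at scaffold edge"
        else "no stop codon found within extension limit")
  if (length(out) == 0L)
    return(data.frame(kind = character(), cds_pos = integer(),
                      genome_start0 = integer(), genome_end0 = integer(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

PSEUDOGENIZING <- c("premature_stop", "frameshift_indel", "missing_tm")

#' Classify a candidate locus as intact, truncated or pseudogene
#'
#' Pseudogene if any premature stop, frameshifting indel or completely
#' missing TM segment is present (pseudogenization dominates truncation).
#' Otherwise, a candidate missing its start and/or stop codon is *truncated*
#' when the locus lies within `edge_window` of a scaffold end or an assembly
#' gap (the fragmented-scaffold situation), and a *pseudogene* when it does
#' not: with intact flanking sequence, an unfindable start/stop is itself a
#' disruption. A candidate with a complete ORF is intact.
#'
#' @param disruptions A data.frame from [detect_disruptions()].
#' @param edge_context `TRUE` when the locus is within `edge_window` of a
#'   scaffold end or an N-gap of at least `gap_min` bases.
#' @return One of `"intact"`, `"truncated"`, `"pseudogene"`.
#' @export
classify_gene <- function(disruptions, edge_context) {
  if (any(disruptions$kind %in% PSEUDOGENIZING)) return("pseudogene")
  missing_ends <- any(disruptions$kind %in% c("missing_start", "missing_stop"))
  if (missing_ends) {
    if (edge_context) "truncated" else "pseudogene"
  } else "intact"
}

## distance from locus to nearest scaffold end or qualifying N-gap
.edge_context <- function(locus, scaf_len, gap_runs, edge_window = 1000L,
                          gap_min = 100L) {
  d_end <- min(locus$start0, scaf_len - locus$end0)
  d_gap <- Inf
  if (nrow(gap_runs) > 0L) {
    g <- gap_runs[gap_runs$length >= gap_min, , drop = FALSE]
    if (nrow(g) > 0L)
      d_gap <- min(pmax(0L, pmax(g$start0 - locus$end0,
                                 locus$start0 - g$end0)))
  }
  min(d_end, d_gap) <= edge_window
}

#' Call genes at candidate loci
#'
#' Runs [reconstruct_cds()], [detect_disruptions()] and [classify_gene()]
#' over a table of candidate loci.
#'
#' @param loci Candidate loci (from [merge_hits()] / [reciprocal_filter()]).
#' @param profile A [family_profile()].
#' @param genome Named character vector or `DNAStringSet`.
#' @param extension_limit,edge_window,gap_min Tuning parameters (bp; defaults
#'   500 / 1000 / 100).
#' @return A data.frame of gene calls (one row per locus: label, CDS and
#'   protein sequences, genomic CDS coordinates, collapsed disruption kinds)
#'   with per-locus models and disruption tables in `attr(x, "details")`.
#' @export
call_genes <- function(loci, profile, genome, extension_limit = 500L,
                       edge_window = 1000L, gap_min = 100L) {
  genome <- .as_named_chr(genome)
  gap_cache <- lapply(genome, find_gap_runs, min_len = gap_min)
  rows <- list(); details <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, , drop = FALSE]
    model <- reconstruct_cds(locus, profile, genome, extension_limit)
    disr <- detect_disruptions(model, profile)
    edge <- .edge_context(locus, nchar(genome[[locus$seq_id]]),
                          gap_cache[[locus$seq_id]], edge_window, gap_min) ||
      model$clip5 || model$clip3
    label <- classify_gene(disr, edge)
    rows[[i]] <- data.frame(
      locus_id = locus$locus_id, family = locus$family,
      seq_id = locus$seq_id, start0 = locus$start0, end0 = locus$end0,
      strand = locus$strand, label = label,
      cds_start0 = model$cds_g_start0, cds_end0 = model$cds_g_end0,
      n_disruptions = nrow(disr),
      disruption_kinds = paste(disr$kind, collapse = ","),
      cds = model$cds, protein = model$protein,
      stringsAsFactors = FALSE)
    details[[locus$locus_id]] <- list(model = model, disruptions = disr,
                                      edge_context = edge)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), family = character(),
               seq_id = character(), start0 = integer(), end0 = integer(),
               strand = character(), label = character(),
               cds_start0 = integer(), cds_end0 = integer(),
               n_disruptions = integer(), disruption_kinds = character(),
               cds = character(), protein = character(),
               stringsAsFactors = FALSE)
  attr(out, "details") <- details
  out
}

#' Summarize a gene-call table into per-family repertoire counts
#'
#' @param calls A gene-call data.frame from [call_genes()].
#' @return data.frame with columns `family`, `intact`, `truncated`,
#'   `pseudogene`, `total`.
#' @export
summarize_repertoire <- function(calls) {
  fams <- unique(calls$family)
  out <- do.call(rbind, lapply(fams, function(f) {
    x <- calls[calls$family == f, ]
    data.frame(family = f,
               intact = sum(x$label == "intact"),
               truncated = sum(x$label == "truncated"),
               pseudogene = sum(x$label == "pseudogene"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(family = character(), intact = integer(),
                      truncated = integer(), pseudogene = integer())
  out$total <- out$intact + out$truncated + out$pseudogene
  out
}

#' Write gene calls as GFF3
#'
#' One `gene` feature per call (1-based inclusive coordinates) with the
#' label and disruption kinds in the attribute column.
#'
#' @param calls A gene-call data.frame.
#' @param path Output path.
#' @export
write_calls_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  if (nrow(calls) > 0L) {
    attrs <- sprintf("ID=%s;family=%s;label=%s;disruptions=%s",
                     calls$locus_id, calls$family, calls$label,
                     ifelse(calls$disruption_kinds == "", ".",
                            calls$disruption_kinds))
    lines <- c(lines, sprintf("%s\tchemorep\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              calls$seq_id, calls$start0 + 1L, calls$end0,
                              calls$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
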