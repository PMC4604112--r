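## multiexon: exon presence/absence, deletion confirmation, dot plots,
## inversion detection, splice-aware boundaries, reference-coordinate
## disruption annotation, and in-silico PCR --------------------------------

#' Multi-exon reference gene model
#'
#' @param gene_id Gene name.
#' @param exons Named character vector of per-exon nucleotide sequences,
#'   ordered 1..n.
#' @param ref_intervals Two-column integer matrix (`start0`, `end0`) of the
#'   exon positions on the reference locus (0-based half-open, ordered,
#'   non-overlapping).
#' @return An object of class `exon_model`.
#' @export
exon_model <- function(gene_id, exons, ref_intervals) {
  n <- length(exons)
  stopifnot(n >= 1L, nrow(ref_intervals) == n)
  ri <- apply(ref_intervals, 2L, as.integer)
  if (n > 1L && any(ri[-1L, 1L] < ri[-n, 2L]))
    config_error("reference exon intervals must be ordered and non-overlapping")
  structure(list(gene_id = gene_id, exons = .as_named_chr(exons),
                 ref_intervals = ri, n_exons = n),
            class = "exon_model")
}

#' Map the exons of a reference gene onto a target genome
#'
#' Each exon is used as a nucleotide query against the target; the best
#' placement is kept. When `source_genome` (the genome or locus the model
#' came from) is given, each placement is checked reciprocally: the target
#' sequence is searched back against the source and discarded as
#' `ambiguous` unless its best hit overlaps the exon's own reference
#' interval. Exons shorter than 20 bp are flagged unmappable (`ambiguous`).
#'
#' @param genome Target genome (named character vector or `DNAStringSet`).
#' @param model An [exon_model()].
#' @param evalue_cutoff E-value threshold (default `1e-20`).
#' @param source_genome Optional source genome/locus for the reciprocal
#'   check; its first sequence must carry the model's reference intervals.
#' @param scheme A [scoring_scheme()].
#' @return A data.frame of class `exon_presence`: `exon`, `status`
#'   (`found`/`absent`/`ambiguous`), placement coordinates, `strand`,
#'   `order_index` (rank of the placement along the target).
#' @export
map_exons <- function(genome, model, evalue_cutoff = 1e-20,
                      source_genome = NULL, scheme = scoring_scheme()) {
  genome <- .as_named_chr(genome)
  rows <- list()
  for (e in seq_len(model$n_exons)) {
    exon_seq <- model$exons[[e]]
    if (nchar(exon_seq) < 20L) {
      warning(sprintf("exon %d shorter than 20 bp; unmappable", e))
      rows[[e]] <- data.frame(exon = e, status = "ambiguous",
                              seq_id = NA_character_, start0 = NA_integer_,
                              end0 = NA_integer_, strand = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    hits <- nucleotide_search(genome, setNames(exon_seq, names(model$exons)[e]),
                              scheme, evalue_cutoff)
    if (nrow(hits) == 0L) {
      rows[[e]] <- data.frame(exon = e, status = "absent",
                              seq_id = NA_character_, start0 = NA_integer_,
                              end0 = NA_integer_, strand = NA_character_,
                              stringsAsFactors = FALSE)
      next
    }
    best <- hits[which.max(hits$bitscore), ]
    status <- "found"
    if (!is.null(source_genome)) {
      src <- .as_named_chr(source_genome)
      placed <- substr(genome[[best$seq_id]], best$start0 + 1L, best$end0)
      if (best$strand == "-") placed <- revcomp(placed)
      back <- nucleotide_search(src, c(placed_seq = placed), scheme,
                                evalue_cutoff)
      ok <- FALSE
      if (nrow(back) > 0L) {
        bb <- back[which.max(back$bitscore), ]
        ri <- model$ref_intervals[e, ]
        ok <- bb$seq_id == names(src)[1L] &&
          bb$start0 < ri[2L] && bb$end0 > ri[1L]
      }
      if (!ok) status <- "ambiguous"
    }
    rows[[e]] <- data.frame(exon = e, status = status,
                            seq_id = best$seq_id, start0 = best$start0,
                            end0 = best$end0, strand = best$strand,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$order_index <- NA_integer_
  found <- out$status == "found"
  out$order_index[found] <- rank(out$start0[found], ties.method = "first")
  class(out) <- c("exon_presence", class(out))
  out
}

#' Confirm whether absent exons are genuinely deleted
#'
#' For each absent exon the nearest found flanking exons are compared: the
#' exon is `deleted` when the flank-to-flank distance on the target is
#' shorter than the reference distance minus `tolerance` times the missing
#' exon length(s) and no assembly gap (N-run of at least `gap_min`)
#' intervenes; an intervening N-run gives `assembly_gap`; anything else,
#' including an absent flank, is `unresolved`.
#'
#' @param genome Target genome.
#' @param presence An `exon_presence` map from [map_exons()].
#' @param model The [exon_model()].
#' @param tolerance Fraction of the missing exon length subtracted from the
#'   reference distance before comparison (default 0.5).
#' @param gap_min Minimum N-run length treated as an assembly gap (default
#'   100).
#' @return data.frame `exon`, `verdict` (`deleted`/`assembly_gap`/
#'   `unresolved`), `target_dist`, `ref_dist`, `missing_len`.
#' @export
confirm_deletion <- function(genome, presence, model, tolerance = 0.5,
                             gap_min = 100L) {
  genome <- .as_named_chr(genome)
  absent <- presence$exon[presence$status == "absent"]
  out <- list()
  for (e in absent) {
    lower <- presence[presence$exon < e & presence$status == "found", ]
    upper <- presence[presence$exon > e & presence$status == "found", ]
    if (nrow(lower) == 0L || nrow(upper) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        exon = e, verdict = "unresolved", target_dist = NA_integer_,
        ref_dist = NA_integer_, missing_len = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    lo <- lower[which.max(lower$exon), ]
    hi <- upper[which.min(upper$exon), ]
    between <- (lo$exon + 1L):(hi$exon - 1L)
    missing_len <- sum(nchar(model$exons[between]))
    ref_dist <- model$ref_intervals[hi$exon, 1L] -
      model$ref_intervals[lo$exon, 2L]
    if (lo$seq_id != hi$seq_id) {
      verdict <- "unresolved"; target_dist <- NA_integer_
    } else {
      a <- min(lo$end0, hi$end0); b <- max(lo$start0, hi$start0)
      target_dist <- max(0L, b - a)
      span <- substr(genome[[lo$seq_id]], a + 1L, b)
      gaps <- find_gap_runs(span, min_len = gap_min)
      if (nrow(gaps) > 0L) verdict <- "assembly_gap"
      else if (target_dist < ref_dist - tolerance * missing_len)
        verdict <- "deleted"
      else verdict <- "unresolved"
    }
    out[[length(out) + 1L]] <- data.frame(
      exon = e, verdict = verdict, target_dist = target_dist,
      ref_dist = ref_dist, missing_len = missing_len,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(exon = integer(), verdict = character(),
                      target_dist = integer(), ref_dist = integer(),
                      missing_len = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Windowed-identity dot plot of two sequences
#'
#' The two sequences are cut into `mesh`-bp windows; each cell holds the
#' percent identity of the best exact-12-mer chain between the window pair,
#' taking the better of the forward and reverse-complement orientations (so
#' inversions show up as anti-diagonal signal). 0 when no 12-mer is shared.
#'
#' @param seq_a,seq_b Single sequences (character scalars, possibly named).
#' @param mesh Window size in bp (1000 or 10000 in typical locus-scale
#'   figures).
#' @param k Exact-match word size for the cell statistic (default 12).
#' @return An object of class `dotplot`: `grid` (rows = `seq_a` windows,
#'   columns = `seq_b` windows, values 0-100), window starts, `mesh`.
#' @export
compute_dotplot <- function(seq_a, seq_b, mesh = 1000L, k = 12L) {
  if (mesh <= 0L) config_error("mesh must be positive")
  a <- as.character(seq_a)[1L]; b <- as.character(seq_b)[1L]
  if (nchar(a) < mesh || nchar(b) < mesh)
    config_error("both sequences must be at least one mesh long")
  astarts <- seq(0L, nchar(a) - 1L, by = mesh)
  bstarts <- seq(0L, nchar(b) - 1L, by = mesh)
  awin <- lapply(astarts, function(s) nuc_codes(substr(a, s + 1L,
                                                       min(s + mesh, nchar(a)))))
  bwin_chr <- lapply(bstarts, function(s) substr(b, s + 1L,
                                                 min(s + mesh, nchar(b))))
  bwin <- lapply(bwin_chr, nuc_codes)
  bwin_rc <- lapply(bwin_chr, function(s) nuc_codes(revcomp(s)))
  grid <- matrix(0, length(astarts), length(bstarts))
  for (i in seq_along(astarts)) {
    for (j in seq_along(bstarts)) {
      grid[i, j] <- max(cpp_window_identity(awin[[i]], bwin[[j]], k),
                        cpp_window_identity(awin[[i]], bwin_rc[[j]], k))
    }
  }
  structure(list(grid = grid, a_starts = astarts, b_starts = bstarts,
                 mesh = as.integer(mesh), k = as.integer(k)),
            class = "dotplot")
}

#' Write a dot plot as a TSV grid
#'
#' @param dp A [compute_dotplot()] result.
#' @param path Output path.
#' @export
write_dotplot_tsv <- function(dp, path) {
  g <- round(dp$grid, 1)
  dimnames(g) <- list(dp$a_starts, dp$b_starts)
  utils::write.table(g, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Detect genomic inversions from an exon presence map
#'
#' Maximal runs of two or more consecutive found exons whose strand is
#' opposite to the majority strand and whose order along the target is
#' reversed are reported as inversion events.
#'
#' @param presence An `exon_presence` map from [map_exons()].
#' @return A list of inversion events, each `list(exons = <integer vector>)`.
#' @export
detect_inversion <- function(presence) {
  f <- presence[presence$status == "found", ]
  if (nrow(f) < 2L) return(list())
  f <- f[order(f$exon), ]
  strands <- table(f$strand)
  majority <- names(strands)[which.max(strands)]
  minority <- f$strand != majority
  runs <- rle(minority)
  events <- list()
  at <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r] || runs$lengths[r] < 2L) next
    idx <- at[r]:(at[r + 1L] - 1L)
    block <- f[idx, ]
    if (any(diff(block$exon) != 1L)) next       # must be consecutive exons
    if (all(diff(block$order_index) < 0L))      # reversed order on target
      events[[length(events) + 1L]] <- list(exons = block$exon)
  }
  events
}

#' Refine homology-placed exon boundaries to canonical splice sites
#'
#' Adjusts internal exon boundaries within `max_shift` bp so that each
#' intron begins `GT` and ends `AG` where attainable; boundaries with no
#' canonical solution are left as placed and flagged. Exon count never
#' changes. Only collinear plus-strand placements are adjusted.
#'
#' @param target Target sequence carrying the placements (character scalar).
#' @param presence An `exon_presence` map whose found exons lie on `target`'s
#'   plus strand.
#' @param max_shift Maximum boundary adjustment in bp (default 15).
#' @return The presence map with refined `start0`/`end0` plus logical
#'   columns `donor_canonical`, `acceptor_canonical`.
#' @export
annotate_exon_boundaries <- function(target, presence, max_shift = 15L) {
  target <- as.character(target)[1L]
  out <- as.data.frame(presence)
  out$donor_canonical <- NA
  out$acceptor_canonical <- NA
  f <- which(out$status == "found")
  if (length(f) < 2L) return(out)
  if (any(out$strand[f] != "+")) {
    warning("non-plus-strand placements left unadjusted")
    return(out)
  }
  f <- f[order(out$start0[f])]
  shifts <- c(0L, as.vector(rbind(seq_len(max_shift), -seq_len(max_shift))))
  for (i in seq_len(length(f) - 1L)) {
    up <- f[i]; dn <- f[i + 1L]
    ## donor: intron must start GT right after the upstream exon end
    don <- NA
    for (d in shifts) {
      p <- out$end0[up] + d
      if (substr(target, p + 1L, p + 2L) == "GT") { don <- d; break }
    }
    if (!is.na(don)) { out$end0[up] <- out$end0[up] + don
                       out$donor_canonical[up] <- TRUE
    } else out$donor_canonical[up] <- FALSE
    ## acceptor: intron must end AG right before the downstream exon start
    acc <- NA
    for (d in shifts) {
      p <- out$start0[dn] + d
      if (p >= 2L && substr(target, p - 1L, p) == "AG") { acc <- d; break }
    }
    if (!is.na(acc)) { out$start0[dn] <- out$start0[dn] + acc
                       out$acceptor_canonical[dn] <- TRUE
    } else out$acceptor_canonical[dn] <- FALSE
  }
  out
}

#' Annotate disruptions of target sequences in reference coordinates
#'
#' Aligns each homologous target to a reference sequence (whose 1-based
#' positions define the coordinate system, e.g. a reference CDS) and reports
#' per-target deletions, insertions and stop-gain codons at reference
#' positions. Events carried by *every* member of a named group at identical
#' reference coordinates are summarized as shared events.
#'
#' @param targets Named character vector of target sequences.
#' @param reference Reference sequence (character scalar); positions are
#'   1-based along this sequence, codons read from position 1.
#' @param group Optional character vector of target names forming the clade
#'   whose shared events are wanted (default: all targets).
#' @param min_identity Targets aligning below this identity are excluded
#'   with a warning (default 0.4).
#' @return `list(events = <per-target data.frame>, shared = <data.frame>)`;
#'   events have `target`, `kind` (`deletion`/`insertion`/`stop_gain`),
#'   `ref_pos`, `ref_end`, `length`, `detail`.
#' @export
annotate_disruptions_vs_reference <- function(targets, reference,
                                              group = NULL,
                                              min_identity = 0.4) {
  targets <- .as_named_chr(targets)
  reference <- as.character(reference)[1L]
  if (is.null(group)) group <- names(targets)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  events <- list()
  kept <- character(0)
  for (tn in names(targets)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(targets[[tn]]), Biostrings::DNAString(reference),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ident <- mean(pat == sub & sub != "-")
    if (ident < min_identity) {
      warning(sprintf("target %s aligns below %.0f%% identity; excluded",
                      tn, 100 * min_identity))
      next
    }
    kept <- c(kept, tn)
    refpos <- cumsum(sub != "-")    # reference position at each column
    ## deletions: runs of '-' in the target
    r <- rle(pat == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      p0 <- refpos[starts[i]]
      events[[length(events) + 1L]] <- data.frame(
        target = tn, kind = "deletion", ref_pos = p0,
        ref_end = refpos[ends[i]], length = r$lengths[i],
        detail = sprintf("%d-bp deletion", r$lengths[i]),
        stringsAsFactors = FALSE)
    }
    ## insertions: runs of '-' in the reference
    r <- rle(sub == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      p0 <- if (starts[i] > 1L) refpos[starts[i] - 1L] else 0L
      events[[length(events) + 1L]] <- data.frame(
        target = tn, kind = "insertion", ref_pos = p0, ref_end = p0,
        length = r$lengths[i],
        detail = sprintf("%d-bp insertion after position %d", r$lengths[i], p0),
        stringsAsFactors = FALSE)
    }
    ## stop gains in the reference codon frame
    n_codon <- nchar(reference) %/% 3L
    for (cd in seq_len(n_codon)) {
      cols <- which(refpos %in% (3L * cd - 2L):(3L * cd) & sub != "-")
      if (length(cols) != 3L) next
      tgt_codon <- paste(pat[cols], collapse = "")
      ref_codon <- paste(sub[cols], collapse = "")
      if (tgt_codon %in% STOP_CODONS && !(ref_codon %in% STOP_CODONS)) {
        events[[length(events) + 1L]] <- data.frame(
          target = tn, kind = "stop_gain", ref_pos = 3L * cd - 2L,
          ref_end = 3L * cd, length = 3L,
          detail = sprintf("premature stop codon at positions %d-%d",
                           3L * cd - 2L, 3L * cd),
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(target = character(), kind = character(), ref_pos = integer(),
               ref_end = integer(), length = integer(), detail = character(),
               stringsAsFactors = FALSE)
  grp <- intersect(group, kept)
  shared <- ev[0, c("kind", "ref_pos", "ref_end", "length", "detail")]
  if (length(grp) > 0L) {
    gev <- ev[ev$target %in% grp, , drop = FALSE]
    key <- paste(gev$kind, gev$ref_pos, gev$length)
    tab <- table(key[!duplicated(paste(gev$target, key))])
    shared_keys <- names(tab)[tab == length(grp)]
    shared <- unique(gev[paste(gev$kind, gev$ref_pos, gev$length) %in%
                           shared_keys,
                         c("kind", "ref_pos", "ref_end", "length", "detail")])
    rownames(shared) <- NULL
  }
  list(events = ev, shared = shared)
}

#' In-silico PCR with degenerate primers
#'
#' Finds all primer-site pairs on opposite strands facing inward within
#' `max_product` bp and reports the amplicons (primer-inclusive length).
#' IUPAC degenerate positions in the primers match their expansion set at
#' zero cost; template letters are taken literally.
#'
#' @param templates Named character vector or `DNAStringSet`.
#' @param fwd,rev Primer sequences 5'->3' (character scalars; IUPAC codes
#'   allowed).
#' @param max_mismatch Maximum mismatches per primer site (default 0).
#' @param max_product Maximum product length in bp (default 5000).
#' @return data.frame `template_id`, `start0`, `end0`, `length`,
#'   `fwd_strand`, `fwd_mm`, `rev_mm`.
#' @export
insilico_pcr <- function(templates, fwd, rev, max_mismatch = 0L,
                         max_product = 5000L) {
  templates <- .as_named_chr(templates)
  fixed <- c(pattern = FALSE, subject = TRUE)
  site_hits <- function(primer, subject) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subject,
                                  max.mismatch = max_mismatch, fixed = fixed)
    if (length(m) == 0L)
      return(data.frame(start0 = integer(), end0 = integer(), mm = integer()))
    mm <- Biostrings::neditAt(Biostrings::DNAString(primer), subject,
                              at = BiocGenerics::start(m), fixed = fixed)
    data.frame(start0 = BiocGenerics::start(m) - 1L,
               end0 = BiocGenerics::end(m), mm = mm)
  }
  out <- list()
  for (tid in names(templates)) {
    subject <- Biostrings::DNAString(templates[[tid]])
    for (orient in c("fwd_plus", "rev_plus")) {
      left <- if (orient == "fwd_plus") fwd else rev
      right <- if (orient == "fwd_plus") rev else fwd
      ls <- site_hits(left, subject)
      rs <- site_hits(as.character(revcomp(right)), subject)
      for (i in seq_len(nrow(ls))) {
        for (j in seq_len(nrow(rs))) {
          if (rs$start0[j] < ls$end0[i]) next   # must face inward
          len <- rs$end0[j] - ls$start0[i]
          if (len > max_product) next
          out[[length(out) + 1L]] <- data.frame(
            template_id = tid, start0 = ls$start0[i], end0 = rs$end0[j],
            length = len, fwd_strand = if (orient == "fwd_plus") "+" else "-",
            fwd_mm = if (orient == "fwd_plus") ls$mm[i] else rs$mm[j],
            rev_mm = if (orient == "fwd_plus") rs$mm[j] else ls$mm[i],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(template_id = character(), start0 = integer(),
                      end0 = integer(), length = integer(),
                      fwd_strand = character(), fwd_mm = integer(),
                      rev_mm = integer(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
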