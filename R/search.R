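## search: translated / nucleotide homology search with Karlin-Altschul
## e-values, hit merging, and reciprocal best-hit family filtering ----------

#' Scoring scheme for homology searches
#'
#' Bundles the substitution scoring and the Karlin-Altschul statistical
#' parameters used to convert raw local-alignment scores into bit scores and
#' e-values (`E = K * m * n * exp(-lambda * S)`). Defaults are the published
#' gapped constants for BLOSUM62 with gap open 11 / extend 1 (protein) and
#' match +1 / mismatch -2 (nucleotide).
#'
#' @param matrix_name Protein substitution matrix name (a Biostrings data
#'   set; default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties (protein); a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for the protein scheme.
#' @param nuc_match,nuc_mismatch Nucleotide match/mismatch scores.
#' @param nuc_gap_open,nuc_gap_extend Nucleotide gap penalties.
#' @param nuc_lambda,nuc_K Karlin-Altschul parameters for the nucleotide
#'   scheme.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62",
                           gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041,
                           nuc_match = 1L, nuc_mismatch = -2L,
                           nuc_gap_open = 5L, nuc_gap_extend = 2L,
                           nuc_lambda = 1.28, nuc_K = 0.46) {
  stopifnot(lambda > 0, K > 0, is.finite(lambda), is.finite(K),
            gap_extend <= gap_open, nuc_match > 0, nuc_mismatch < 0)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  full <- e[[matrix_name]]
  if (!all(PROT_ALPHABET %in% rownames(full)))
    config_error(sprintf("matrix %s lacks required residues", matrix_name))
  pm <- full[PROT_ALPHABET, PROT_ALPHABET]
  storage.mode(pm) <- "integer"
  nm <- matrix(as.integer(nuc_mismatch), 5L, 5L,
               dimnames = list(NUC_ALPHABET, NUC_ALPHABET))
  diag(nm)[1:4] <- as.integer(nuc_match)
  nm["N", ] <- as.integer(nuc_mismatch)
  nm[, "N"] <- as.integer(nuc_mismatch)
  structure(list(matrix_name = matrix_name, prot_matrix = pm,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 nuc_matrix = nm, nuc_match = as.integer(nuc_match),
                 nuc_mismatch = as.integer(nuc_mismatch),
                 nuc_gap_open = as.integer(nuc_gap_open),
                 nuc_gap_extend = as.integer(nuc_gap_extend),
                 nuc_lambda = nuc_lambda, nuc_K = nuc_K),
            class = "scoring_scheme")
}

.as_named_chr <- function(x) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x
  } else setNames(as.character(x), names(x))
}

empty_hits <- function() {
  data.frame(query_id = character(), seq_id = character(), start0 = integer(),
             end0 = integer(), strand = character(), frame = integer(),
             raw_score = integer(), bitscore = numeric(), evalue = numeric(),
             identity = numeric(), qstart0 = integer(), qend0 = integer(),
             stringsAsFactors = FALSE)
}

## numeric k-mer keys over an integer code vector; NA where the window
## contains a code >= bad_from (X/stop for protein, N for nucleotide)
.kmer_keys <- function(codes, k, base, bad_from) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  bad <- codes >= bad_from
  keys <- numeric(n - k + 1L)
  anybad <- logical(n - k + 1L)
  for (i in seq_len(k)) {
    seg <- codes[i:(n - k + i)]
    keys <- keys * base + seg
    anybad <- anybad | bad[i:(n - k + i)]
  }
  keys[anybad] <- NA_real_
  keys
}

## cluster seed pairs (qpos, tpos; 0-based) by diagonal bands; each cluster
## carries its candidate target window [lo, hi) and all member seeds (the
## triage stage extends every member, so one spurious off-diagonal seed
## cannot sink a genuine cluster)
.seed_clusters <- function(qpos, tpos, qlen, tlen, k, band = 32L, join = 200L,
                           pad = NULL) {
  if (is.null(pad)) pad <- qlen + 16L
  o <- order(tpos - qpos, tpos)
  qpos <- qpos[o]; tpos <- tpos[o]
  dg <- tpos - qpos
  cl <- cumsum(c(TRUE, diff(dg) > band | diff(tpos) > join))
  lapply(split(seq_along(cl), cl), function(ix) {
    list(lo = max(0L, min(tpos[ix]) - pad),
         hi = min(tlen, max(tpos[ix]) + k + pad),
         qpos = qpos[ix], tpos = tpos[ix])
  })
}

## best ungapped X-drop extension over every seed of each cluster
.cluster_ext <- function(clusters, qc, tc, sub, k, xdrop) {
  all_q <- unlist(lapply(clusters, `[[`, "qpos"))
  all_t <- unlist(lapply(clusters, `[[`, "tpos"))
  ext <- cpp_ungapped_extend(qc, tc, sub, all_q, all_t, k, xdrop)
  vapply(split(ext, rep(seq_along(clusters),
                        vapply(clusters, function(cl) length(cl$qpos), 0L))),
         max, numeric(1))
}

.merge_windows <- function(w) {
  if (is.null(w) || nrow(w) == 0L) return(w)
  w <- w[order(w[, "lo"]), , drop = FALSE]
  out <- list(w[1L, ])
  for (i in seq_len(nrow(w))[-1L]) {
    last <- out[[length(out)]]
    if (w[i, "lo"] <= last["hi"]) {
      last["hi"] <- max(last["hi"], w[i, "hi"])
      out[[length(out)]] <- last
    } else out[[length(out) + 1L]] <- w[i, ]
  }
  do.call(rbind, out)
}

## iterative best-local-alignment with masking, so several genes inside one
## candidate window are each reported
.window_hits <- function(qcodes, tcodes, submat, gap_open, gap_extend,
                         lambda, K, mn, cutoff, mask_code, max_iter = 16L,
                         min_leftover = 150L) {
  out <- list()
  tw <- tcodes
  masked <- 0L
  for (it in seq_len(max_iter)) {
    r <- cpp_sw_local(qcodes, tw, submat, gap_open, gap_extend)
    if (r$score <= 0L) break
    ev <- K * mn * exp(-lambda * r$score)
    if (ev >= cutoff) break
    out[[length(out) + 1L]] <- r
    tw[r$b_start:r$b_end] <- mask_code
    masked <- masked + (r$b_end - r$b_start + 1L)
    ## another reportable alignment needs room to live in
    if (length(tw) - masked < min_leftover) break
  }
  out
}

#' Translated homology search (TBLASTN-like)
#'
#' Seed-and-extend search of protein queries against all six reading frames
#' of a nucleotide genome: exact protein k-mer seeds, ungapped X-drop
#' extension, then full gapped local alignment inside candidate windows.
#' E-values use Karlin-Altschul statistics with `m` = total translated
#' residues searched and `n` = total query residues; only hits with
#' `evalue < evalue_cutoff` are returned, sorted by scaffold and start.
#'
#' @param genome Named character vector or `DNAStringSet` of scaffolds.
#' @param queries Named character vector or `AAStringSet` of protein queries.
#' @param scheme A [scoring_scheme()].
#' @param evalue_cutoff E-value threshold (default `1e-20`, the olfactory
#'   receptor screening cutoff; taste-gene screens conventionally use
#'   `1e-5`).
#' @param seed_len Exact-match protein seed length (default 4).
#' @param min_ungapped Minimum ungapped X-drop extension score for a seed
#'   cluster to be aligned (default 25).
#' @param xdrop X-drop parameter for the ungapped stage (default 20).
#' @return A data.frame of hits with 0-based half-open genomic coordinates
#'   (`start0`, `end0`), strand, frame, raw score, bit score, e-value,
#'   identity fraction and query span (`qstart0`, `qend0`).
#' @export
translated_search <- function(genome, queries, scheme = scoring_scheme(),
                              evalue_cutoff = 1e-20, seed_len = 4L,
                              min_ungapped = 25L, xdrop = 20L) {
  stopifnot(evalue_cutoff > 0)
  genome <- .as_named_chr(genome)
  queries <- .as_named_chr(queries)
  if (length(genome) == 0L || length(queries) == 0L)
    config_error("genome and queries must be non-empty")
  short <- nchar(queries) < seed_len
  if (any(short)) {
    warning(sprintf("query shorter than seed length skipped: %s",
                    paste(names(queries)[short], collapse = ", ")))
    queries <- queries[!short]
  }
  if (length(queries) == 0L) return(empty_hits())
  sub <- scheme$prot_matrix
  xcode <- match("X", PROT_ALPHABET) - 1L
  qcodes <- lapply(queries, prot_codes)
  qkeys <- lapply(qcodes, .kmer_keys, k = seed_len, base = 24, bad_from = 22L)
  qtabs <- lapply(qkeys, function(kk) split(which(!is.na(kk)) - 1L, kk[!is.na(kk)]))
  qvals <- lapply(qtabs, function(qt) as.numeric(names(qt)))
  m_total <- sum(vapply(nchar(genome), function(L)
    sum((L - 0:2) %/% 3L), numeric(1)))
  n_total <- sum(nchar(queries))
  mn <- m_total * n_total
  hits <- list()
  for (sid in names(genome)) {
    L <- nchar(genome[[sid]])
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") genome[[sid]] else revcomp(genome[[sid]])
      for (f in 0:2) {
        P <- translate_frame(oriented, f, "+")
        np <- nchar(P)
        if (np < seed_len) next
        tcodes <- prot_codes(P)
        tkeys <- .kmer_keys(tcodes, seed_len, 24, 22L)
        for (qi in seq_along(queries)) {
          qtab <- qtabs[[qi]]
          if (length(qtab) == 0L) next
          sel <- which(!is.na(match(tkeys, qvals[[qi]])))
          if (length(sel) == 0L) next
          qp_list <- qtab[match(tkeys[sel], qvals[[qi]])]
          tpos <- rep.int(sel - 1L, lengths(qp_list))
          qpos <- unlist(qp_list, use.names = FALSE)
          cls <- .seed_clusters(qpos, tpos, length(qcodes[[qi]]), np, seed_len,
                                pad = 64L)
          ext <- .cluster_ext(cls, qcodes[[qi]], tcodes, sub, seed_len, xdrop)
          cls <- cls[ext >= min_ungapped]
          if (length(cls) == 0L) next
          wins <- .merge_windows(do.call(rbind, lapply(cls, function(cl)
            c(lo = cl$lo, hi = cl$hi))))
          for (w in seq_len(nrow(wins))) {
            lo <- wins[w, "lo"]; hi <- wins[w, "hi"]
            res <- .window_hits(qcodes[[qi]], tcodes[(lo + 1L):hi], sub,
                                scheme$gap_open, scheme$gap_extend,
                                scheme$lambda, scheme$K, mn, evalue_cutoff,
                                xcode)
            for (r in res) {
              p_lo <- lo + r$b_start - 1L   # 0-based aa on oriented frame
              p_hi <- lo + r$b_end          # exclusive
              nt_lo <- f + 3L * p_lo
              nt_hi <- f + 3L * p_hi
              if (strand == "+") {
                g_lo <- nt_lo; g_hi <- nt_hi
              } else {
                g_lo <- L - nt_hi; g_hi <- L - nt_lo
              }
              hits[[length(hits) + 1L]] <- data.frame(
                query_id = names(queries)[qi], seq_id = sid,
                start0 = g_lo, end0 = g_hi, strand = strand, frame = f,
                raw_score = r$score,
                bitscore = (scheme$lambda * r$score - log(scheme$K)) / log(2),
                evalue = scheme$K * mn * exp(-scheme$lambda * r$score),
                identity = r$n_ident / r$n_col,
                qstart0 = r$a_start - 1L, qend0 = r$a_end,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$seq_id, out$start0), , drop = FALSE]
}

#' Nucleotide homology search (BLASTN-like)
#'
#' As [translated_search()] but with exact nucleotide k-mer seeds (default
#' 11), match/mismatch scoring and both strands. `m` is the total target
#' length and `n` the total query length.
#'
#' @inheritParams translated_search
#' @param queries Named character vector or `DNAStringSet` of nucleotide
#'   queries.
#' @param seed_len Exact-match nucleotide seed length (default 11).
#' @return A data.frame of hits (see [translated_search()]); `frame` is `NA`.
#' @export
nucleotide_search <- function(genome, queries, scheme = scoring_scheme(),
                              evalue_cutoff = 1e-20, seed_len = 11L,
                              min_ungapped = 16L, xdrop = 20L) {
  stopifnot(evalue_cutoff > 0)
  genome <- .as_named_chr(genome)
  queries <- .as_named_chr(queries)
  if (length(genome) == 0L || length(queries) == 0L)
    config_error("genome and queries must be non-empty")
  short <- nchar(queries) < seed_len
  if (any(short)) {
    warning(sprintf("query shorter than seed length skipped: %s",
                    paste(names(queries)[short], collapse = ", ")))
    queries <- queries[!short]
  }
  if (length(queries) == 0L) return(empty_hits())
  sub <- scheme$nuc_matrix
  ncode <- 4L
  m_total <- sum(nchar(genome))
  n_total <- sum(nchar(queries))
  mn <- m_total * n_total
  hits <- list()
  for (sid in names(genome)) {
    tcodes <- nuc_codes(genome[[sid]])
    tkeys <- .kmer_keys(tcodes, seed_len, 5, 4L)
    for (qi in seq_along(queries)) {
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
        qc <- nuc_codes(qseq)
        qk <- .kmer_keys(qc, seed_len, 5, 4L)
        qtab <- split(which(!is.na(qk)) - 1L, qk[!is.na(qk)])
        if (length(qtab) == 0L) next
        qv <- as.numeric(names(qtab))
        sel <- which(!is.na(match(tkeys, qv)))
        if (length(sel) == 0L) next
        qp_list <- qtab[match(tkeys[sel], qv)]
        tpos <- rep.int(sel - 1L, lengths(qp_list))
        qpos <- unlist(qp_list, use.names = FALSE)
        cls <- .seed_clusters(qpos, tpos, length(qc), length(tcodes), seed_len,
                              band = 64L, join = 400L)
        ext <- .cluster_ext(cls, qc, tcodes, sub, seed_len, xdrop)
        cls <- cls[ext >= min_ungapped]
        if (length(cls) == 0L) next
        wins <- .merge_windows(do.call(rbind, lapply(cls, function(cl)
          c(lo = cl$lo, hi = cl$hi))))
        for (w in seq_len(nrow(wins))) {
          lo <- wins[w, "lo"]; hi <- wins[w, "hi"]
          res <- .window_hits(qc, tcodes[(lo + 1L):hi], sub,
                              scheme$nuc_gap_open, scheme$nuc_gap_extend,
                              scheme$nuc_lambda, scheme$nuc_K, mn,
                              evalue_cutoff, ncode)
          for (r in res) {
            g_lo <- lo + r$b_start - 1L
            g_hi <- lo + r$b_end
            qlen <- length(qc)
            qs <- if (strand == "+") r$a_start - 1L else qlen - r$a_end
            qe <- if (strand == "+") r$a_end else qlen - (r$a_start - 1L)
            hits[[length(hits) + 1L]] <- data.frame(
              query_id = names(queries)[qi], seq_id = sid,
              start0 = g_lo, end0 = g_hi, strand = strand, frame = NA_integer_,
              raw_score = r$score,
              bitscore = (scheme$nuc_lambda * r$score - log(scheme$nuc_K)) / log(2),
              evalue = scheme$nuc_K * mn * exp(-scheme$nuc_lambda * r$score),
              identity = r$n_ident / r$n_col,
              qstart0 = qs, qend0 = qe,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$seq_id, out$start0), , drop = FALSE]
}

#' Merge overlapping same-orientation hits into candidate loci
#'
#' Hits on the same scaffold and strand whose intervals overlap by at least
#' one base are transitively merged; hits on opposite strands are never
#' merged. The operation is idempotent and order-independent.
#'
#' @param hits A hit data.frame from one family search.
#' @param family Family label recorded on each locus.
#' @return A data.frame of candidate loci (`locus_id`, `family`, `seq_id`,
#'   `start0`, `end0`, `strand`, `n_hits`, `best_bitscore`, `best_query`)
#'   with the supporting hits in the list-column `hits`.
#' @export
merge_hits <- function(hits, family = "family") {
  cols <- c("locus_id", "family", "seq_id", "start0", "end0", "strand",
            "n_hits", "best_bitscore", "best_query")
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.frame(locus_id = character(), family = character(),
                      seq_id = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      n_hits = integer(), best_bitscore = numeric(),
                      best_query = character(), stringsAsFactors = FALSE)
    out$hits <- list()
    return(out)
  }
  hits <- hits[order(hits$seq_id, hits$strand, hits$start0, hits$end0), ,
               drop = FALSE]
  key <- paste(hits$seq_id, hits$strand)
  loci <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    grp <- integer(nrow(h))
    grp[1L] <- 1L
    hi <- h$end0[1L]
    for (i in seq_len(nrow(h))[-1L]) {
      if (h$start0[i] < hi) {       # >= 1 bp overlap
        grp[i] <- grp[i - 1L]
        hi <- max(hi, h$end0[i])
      } else {
        grp[i] <- grp[i - 1L] + 1L
        hi <- h$end0[i]
      }
    }
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      b <- which.max(hh$bitscore)
      loci[[length(loci) + 1L]] <- list(
        family = family, seq_id = hh$seq_id[1L],
        start0 = min(hh$start0), end0 = max(hh$end0),
        strand = hh$strand[1L], n_hits = nrow(hh),
        best_bitscore = hh$bitscore[b], best_query = hh$query_id[b],
        hits = hh)
    }
  }
  out <- data.frame(
    family = vapply(loci, `[[`, "", "family"),
    seq_id = vapply(loci, `[[`, "", "seq_id"),
    start0 = as.integer(vapply(loci, `[[`, 0, "start0")),
    end0 = as.integer(vapply(loci, `[[`, 0, "end0")),
    strand = vapply(loci, `[[`, "", "strand"),
    n_hits = as.integer(vapply(loci, `[[`, 0, "n_hits")),
    best_bitscore = vapply(loci, `[[`, 0, "best_bitscore"),
    best_query = vapply(loci, `[[`, "", "best_query"),
    stringsAsFactors = FALSE)
  ord <- order(out$seq_id, out$start0)
  out <- out[ord, , drop = FALSE]
  out$locus_id <- sprintf("%s_locus%03d", family, seq_len(nrow(out)))
  out$hits <- lapply(loci, `[[`, "hits")[ord]
  rownames(out) <- NULL
  out[, c(cols, "hits")]
}

#' Reciprocal best-hit family filter
#'
#' Each candidate locus is excised from the genome, translated in the three
#' reading frames of its own orientation, and scored against a reference
#' proteome by gapped local alignment. The locus is kept only if the
#' top-scoring reference protein belongs to the target family; bit-score
#' ties are resolved permissively (kept if any tied top hit is a family
#' member).
#'
#' @param loci Candidate loci from [merge_hits()].
#' @param genome Named character vector or `DNAStringSet` of scaffolds.
#' @param reference_proteome Named character vector or `AAStringSet`.
#' @param family_member_ids Character vector of reference ids belonging to
#'   the family.
#' @param scheme A [scoring_scheme()].
#' @return `list(kept = <loci>, discarded = <loci with best_ref/reason>)`.
#' @export
reciprocal_filter <- function(loci, genome, reference_proteome,
                              family_member_ids, scheme = scoring_scheme()) {
  genome <- .as_named_chr(genome)
  refs <- .as_named_chr(reference_proteome)
  if (nrow(loci) == 0L)
    return(list(kept = loci, discarded = cbind(loci[0, , drop = FALSE],
                                               best_ref = character(),
                                               reason = character())))
  ref_codes <- lapply(refs, prot_codes)
  ## 4-mer key sets per reference: cheap prescreen so only plausible
  ## locus/reference pairs are aligned
  ref_keys <- lapply(ref_codes, function(rc)
    unique(.kmer_keys(rc, 4L, 24, 22L)))
  sub <- scheme$prot_matrix
  keep <- logical(nrow(loci))
  best_ref <- character(nrow(loci))
  reason <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    s <- substr(genome[[loci$seq_id[i]]], loci$start0[i] + 1L, loci$end0[i])
    if (loci$strand[i] == "-") s <- revcomp(s)
    frames <- lapply(0:2, function(f) prot_codes(translate_frame(s, f, "+")))
    frame_keys <- lapply(frames, function(fc)
      unique(.kmer_keys(fc, 4L, 24, 22L)))
    scores <- vapply(seq_along(ref_codes), function(ri) {
      rc <- ref_codes[[ri]]
      max(vapply(seq_along(frames), function(fi) {
        fc <- frames[[fi]]
        if (length(fc) == 0L) return(0L)
        if (sum(frame_keys[[fi]] %in% ref_keys[[ri]], na.rm = TRUE) < 2L)
          return(0L)
        cpp_sw_local(fc, rc, sub, scheme$gap_open, scheme$gap_extend)$score
      }, integer(1)))
    }, integer(1))
    names(scores) <- names(refs)
    if (all(scores <= 0L)) {
      keep[i] <- FALSE
      best_ref[i] <- NA_character_
      reason[i] <- "no_reference_hit"
      next
    }
    top <- names(scores)[scores == max(scores)]
    keep[i] <- any(top %in% family_member_ids)
    best_ref[i] <- top[1L]
    reason[i] <- if (keep[i]) "" else "best_hit_not_in_family"
  }
  discarded <- loci[!keep, , drop = FALSE]
  if (nrow(discarded) > 0L) {
    discarded$best_ref <- best_ref[!keep]
    discarded$reason <- reason[!keep]
  } else {
    discarded$best_ref <- character(0)
    discarded$reason <- character(0)
  }
  list(kept = loci[keep, , drop = FALSE], discarded = discarded)
}

#' Read standard 12-column tabular search output
#'
#' Adapter for plugging an external search engine into the pipeline: parses
#' the conventional 12-column tabular format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore; 1-based inclusive coordinates, minus-strand hits
#' with sstart > send) into the internal hit table.
#'
#' @param path Path to a tab-separated file with the 12 standard columns.
#' @return A hit data.frame as produced by [translated_search()] (raw scores
#'   and frames are `NA`).
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) config_error(sprintf("hit file not found: %s", path))
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tb) != 12L)
    config_error("expected 12 tab-separated columns of tabular search output")
  names(tb) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  minus <- tb$sstart > tb$send
  data.frame(query_id = tb$qseqid, seq_id = tb$sseqid,
             start0 = ifelse(minus, tb$send, tb$sstart) - 1L,
             end0 = ifelse(minus, tb$sstart, tb$send),
             strand = ifelse(minus, "-", "+"), frame = NA_integer_,
             raw_score = NA_integer_, bitscore = tb$bitscore,
             evalue = tb$evalue, identity = tb$pident / 100,
             qstart0 = tb$qstart - 1L, qend0 = tb$qend,
             stringsAsFactors = FALSE)
}

#' Write a hit table as TSV (1-based coordinates)
#'
#' @param hits A hit data.frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(query = hits$query_id, scaffold = hits$seq_id,
                    start = hits$start0 + 1L, end = hits$end0,
                    strand = hits$strand, frame = hits$frame,
                    score = hits$raw_score, bitscore = round(hits$bitscore, 2),
                    evalue = signif(hits$evalue, 3),
                    identity = round(hits$identity, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
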