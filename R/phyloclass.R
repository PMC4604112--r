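## phyloclass: distance trees for class I/II assignment, one-by-one
## placement of truncated genes, and pairwise dN/dS -------------------------

#' Poisson-corrected protein distance matrix
#'
#' Pairwise distances `d = -ln(1 - p)` over the columns where both
#' sequences are ungapped, with `p` the mismatch fraction. Saturated pairs
#' (`p >= 0.95`) are capped at `p = 0.95` with a warning; pairs sharing
#' fewer than 30 columns are an error.
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param min_shared Minimum shared ungapped columns per pair (default 30).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(msa, min_shared = 30L) {
  msa <- .as_named_chr(msa)
  if (length(msa) < 2L) config_error("need at least two sequences")
  if (length(unique(nchar(msa))) != 1L)
    config_error("sequences must be aligned to equal length")
  mat <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- mat[i, ] != "-" & mat[j, ] != "-"
      ns <- sum(shared)
      if (ns < min_shared)
        runtime_error(sprintf(
          "pair %s / %s shares only %d aligned columns (need >= %d)",
          names(msa)[i], names(msa)[j], ns, min_shared))
      p <- mean(mat[i, shared] != mat[j, shared])
      if (p >= 0.95) {
        warning(sprintf("pair %s / %s is saturated (p = %.2f); capped",
                        names(msa)[i], names(msa)[j], p))
        p <- 0.95
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (exact on additive matrices). Negative branch
#' lengths arising from noise are clamped to zero.
#'
#' @param d Symmetric distance matrix with taxon names.
#' @return An unrooted `phylo` tree.
#' @export
build_nj <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) config_error("need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    config_error("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## tip labels reachable from `node` without stepping back through `parent`,
## on an unrooted tree given as an adjacency list
.tips_away <- function(adj, tree, node, parent) {
  ntip <- length(tree$tip.label)
  out <- character(0)
  stack <- list(c(node, parent))
  while (length(stack) > 0L) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur[1] <= ntip) out <- c(out, tree$tip.label[cur[1]])
    for (nb in adj[[cur[1]]]) {
      if (nb != cur[2]) stack[[length(stack) + 1L]] <- c(nb, cur[1])
    }
  }
  out
}

#' Classify a query leaf as class I or class II on a reference tree
#'
#' The tree is rooted on the edge holding the midpoint of the longest
#' path between a class I and a class II reference (the inter-class stem in
#' a two-deep-clade topology). If the smallest clade containing the query
#' and at least one reference contains references of only one class, that
#' class is assigned (`method = "clade"`); otherwise the class of the
#' nearest labeled leaf by patristic distance is used
#' (`method = "nearest"`), with ties broken toward class II (mammalian ORs
#' are overwhelmingly class II) with a warning.
#'
#' @param tree A `phylo` tree containing the query and labeled references.
#' @param reference_labels Named character vector mapping reference tip
#'   labels to `"classI"` / `"classII"` (or other two-level labels such as
#'   TAAR subtypes; with more than two labels only nearest-leaf assignment
#'   is used).
#' @param query_id Tip label of the query.
#' @return data.frame `query_id`, `assigned_class`, `support` (patristic
#'   distance to the nearest reference of the assigned class), `method`.
#' @export
classify_by_tree <- function(tree, reference_labels, query_id) {
  stopifnot(query_id %in% tree$tip.label)
  refs <- intersect(names(reference_labels), tree$tip.label)
  labs <- reference_labels[refs]
  classes <- unique(labs)
  if (length(classes) < 2L)
    config_error("references of at least two classes are required")
  pat <- ape::cophenetic.phylo(tree)
  method <- "nearest"; assigned <- NA_character_
  if (length(classes) == 2L) {
    ## the edge holding the midpoint of the longest inter-class path plays
    ## the root: clades are read away from it, never across it
    d_ic <- pat[refs[labs == classes[1L]], refs[labs == classes[2L]],
                drop = FALSE]
    w <- which(d_ic == max(d_ic), arr.ind = TRUE)[1L, ]
    from <- rownames(d_ic)[w[1L]]; to <- colnames(d_ic)[w[2L]]
    np <- ape::nodepath(tree, which(tree$tip.label == from),
                        which(tree$tip.label == to))
    half <- max(d_ic) / 2
    acc <- 0
    stem <- c(np[1L], np[2L])
    for (s in seq_len(length(np) - 1L)) {
      e <- which((tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1L]) |
                   (tree$edge[, 2] == np[s] & tree$edge[, 1] == np[s + 1L]))
      acc <- acc + tree$edge.length[e]
      if (acc >= half) { stem <- c(np[s], np[s + 1L]); break }
    }
    ## adjacency list of the unrooted tree
    nnode <- max(tree$edge)
    adj <- vector("list", nnode)
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    ## which stem endpoint is on the query's side?
    qi <- which(tree$tip.label == query_id)
    side_u <- .tips_away(adj, tree, stem[1L], stem[2L])
    if (query_id %in% side_u) { top <- stem[1L]; beyond <- stem[2L] }
    else { top <- stem[2L]; beyond <- stem[1L] }
    ## parent pointers from the stem endpoint downward
    parent <- rep(NA_integer_, nnode)
    parent[top] <- -1L   # virtual root on the stem edge
    stack <- top
    blocked <- beyond
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in adj[[cur]]) {
        if (is.na(parent[nb]) && nb != blocked && !(cur == top && nb == beyond)) {
          parent[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
    ## ancestor walk: smallest clade containing the query and >= 1 reference
    node <- qi
    repeat {
      node <- parent[node]
      if (is.na(node) || node == -1L) break
      tips <- .tips_away(adj, tree, node,
                         if (parent[node] == -1L) beyond else parent[node])
      in_clade <- intersect(tips, refs)
      if (length(in_clade) > 0L) {
        cl <- unique(labs[in_clade])
        if (length(cl) == 1L) { assigned <- cl; method <- "clade" }
        break
      }
    }
  }
  if (is.na(assigned)) {
    dq <- pat[query_id, refs]
    best <- min(dq)
    top <- unique(labs[names(dq)[dq <= best + 1e-12]])
    if (length(top) > 1L) {
      warning(sprintf("query %s equidistant between classes; assigned classII",
                      query_id))
      assigned <- if ("classII" %in% top) "classII" else top[1L]
    } else assigned <- top
    method <- "nearest"
  }
  support <- min(pat[query_id, refs[labs == assigned]])
  data.frame(query_id = query_id, assigned_class = unname(assigned),
             support = support, method = method, stringsAsFactors = FALSE)
}

## align a query to its best-matching reference row and spread its residues
## over the MSA columns (NA where uncovered). Threading through the closest
## reference, not a pooled consensus, keeps deep inter-class divergence from
## contaminating the anchor.
.thread_to_msa <- function(query, ref_mat, scheme) {
  n_col <- ncol(ref_mat)
  qc <- prot_codes(query)
  ungapped <- apply(ref_mat, 1, function(r) paste(r[r != "-"], collapse = ""))
  scores <- vapply(ungapped, function(r)
    cpp_sw_local(qc, prot_codes(r), scheme$prot_matrix, scheme$gap_open,
                 scheme$gap_extend)$score, integer(1))
  best <- which.max(scores)
  if (scores[best] <= 0L) return(rep(NA_character_, n_col))
  anchor <- ungapped[[best]]
  r <- cpp_sw_local(qc, prot_codes(anchor), scheme$prot_matrix,
                    scheme$gap_open, scheme$gap_extend)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(substr(query, r$a_start, r$a_end)),
    Biostrings::AAString(substr(anchor, r$b_start, r$b_end)),
    type = "global", substitutionMatrix = scheme$prot_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ## ungapped anchor position -> MSA column
  pos2col <- which(ref_mat[best, ] != "-")
  out <- rep(NA_character_, n_col)
  apos <- r$b_start - 1L
  for (col in seq_along(sub)) {
    if (sub[col] != "-") {
      apos <- apos + 1L
      if (pat[col] != "-") out[pos2col[apos]] <- pat[col]
    }
  }
  out
}

#' Place truncated queries on a reference tree one by one
#'
#' Each query is aligned independently to the reference alignment's
#' consensus; distances to the references are computed on the query's
#' covered columns only, a neighbor-joining tree of references plus the one
#' query is built, and [classify_by_tree()] is applied. Queries never
#' influence each other's assignment, so the result is order-independent.
#'
#' @param queries Named character vector of (possibly fragmentary) protein
#'   queries.
#' @param reference_msa Named character vector of aligned reference
#'   proteins.
#' @param reference_labels Named class labels for the references.
#' @param min_columns Queries covering fewer aligned columns are left
#'   unassigned (default 30).
#' @param scheme A [scoring_scheme()].
#' @return data.frame with one row per query (`assigned_class` is `NA` for
#'   queries below the column threshold).
#' @export
place_one_by_one <- function(queries, reference_msa, reference_labels,
                             min_columns = 30L, scheme = scoring_scheme()) {
  if (length(queries) == 0L)
    return(data.frame(query_id = character(), assigned_class = character(),
                      support = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  queries <- .as_named_chr(queries)
  reference_msa <- .as_named_chr(reference_msa)
  ref_mat <- do.call(rbind, strsplit(reference_msa, ""))
  ref_d <- suppressWarnings(
    protein_distance(setNames(apply(ref_mat, 1, paste, collapse = ""),
                              names(reference_msa))))
  out <- list()
  for (qn in names(queries)) {
    threaded <- .thread_to_msa(queries[[qn]], ref_mat, scheme)
    covered <- which(!is.na(threaded))
    if (length(covered) < min_columns) {
      out[[length(out) + 1L]] <- data.frame(
        query_id = qn, assigned_class = NA_character_, support = NA_real_,
        method = "unassigned", stringsAsFactors = FALSE)
      next
    }
    n <- length(reference_msa)
    d <- matrix(0, n + 1L, n + 1L,
                dimnames = list(c(names(reference_msa), qn),
                                c(names(reference_msa), qn)))
    d[seq_len(n), seq_len(n)] <- ref_d
    for (i in seq_len(n)) {
      ref_res <- ref_mat[i, covered]
      ok <- ref_res != "-"
      p <- if (sum(ok) > 0L) mean(threaded[covered[ok]] != ref_res[ok]) else 0.95
      p <- min(p, 0.95)
      d[i, n + 1L] <- d[n + 1L, i] <- -log(1 - p)
    }
    tr <- build_nj(d)
    out[[length(out) + 1L]] <- classify_by_tree(tr, reference_labels, qn)
  }
  do.call(rbind, out)
}

## --- Nei-Gojobori pairwise dN/dS ------------------------------------------

.NG_TABLE <- local({
  list(codons = names(.CODON_TABLE), aa = .CODON_TABLE)
})

## fraction of synonymous sites of one codon (changes to stop codons count
## as nonsynonymous; stop codons themselves contribute no sites)
.syn_sites <- function(codon) {
  aa <- .NG_TABLE$aa[[codon]]
  if (aa == "*") return(c(S = 0, N = 0))
  S <- 0
  for (pos in 1:3) {
    for (nt in c("T", "C", "A", "G")) {
      if (nt == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (.NG_TABLE$aa[[alt]] == aa) S <- S + 1 / 3
    }
  }
  c(S = S, N = 3 - S)
}

## synonymous/nonsynonymous differences between two codons, averaged over
## all mutational pathways that avoid stop codons (all pathways if every
## pathway passes through a stop)
.codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    pm <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(pm(v[-i]), function(rest) c(v[i], rest))))
    pm(pos)
  }
  eval_path <- function(order) {
    cur <- c1; sd <- 0; nd_ <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- .NG_TABLE$aa[[cur]]; a2 <- .NG_TABLE$aa[[nxt]]
      if (a2 == "*" || a1 == "*") blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd_, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, eval_path, numeric(3))
  ok <- res["blocked", ] == 0
  if (any(ok)) res <- res[, ok, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

#' Pairwise dN/dS by the Nei-Gojobori pathway method
#'
#' Counts synonymous and nonsynonymous sites and differences per the
#' classic pathway-averaging rules (changes to stop codons count as
#' nonsynonymous; pathways through stop codons are excluded from averaging
#' when an unblocked pathway exists), applies the Jukes-Cantor correction,
#' and returns `omega = dN/dS` (undefined, `NA`, when `dS = 0`).
#'
#' @param cds_a,cds_b In-frame, gap-free, equal-length codon sequences with
#'   no internal stop codons.
#' @return `list(dN, dS, omega, pN, pS, S_sites, N_sites, sd, nd)`.
#' @export
dnds_nei_gojobori <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a)[1L]); b <- toupper(as.character(cds_b)[1L])
  if (nchar(a) != nchar(b)) config_error("sequences must be equal length")
  if (nchar(a) %% 3L != 0L) config_error("length must be a multiple of 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    config_error("sequences must be gap-free ACGT")
  n_codon <- nchar(a) %/% 3L
  ca <- substring(a, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  cb <- substring(b, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  if (any(.NG_TABLE$aa[ca] == "*") || any(.NG_TABLE$aa[cb] == "*"))
    config_error("internal stop codon in input")
  ## vapply returns a 2 x n matrix; rows S then N
  sites_a <- vapply(ca, .syn_sites, numeric(2))
  sites_b <- vapply(cb, .syn_sites, numeric(2))
  S <- (sum(sites_a["S", ]) + sum(sites_b["S", ])) / 2
  N <- (sum(sites_a["N", ]) + sum(sites_b["N", ])) / 2
  diffs <- vapply(seq_len(n_codon), function(i) .codon_diffs(ca[i], cb[i]),
                  numeric(2))
  sd_ <- sum(diffs["sd", ]); nd_ <- sum(diffs["nd", ])
  pS <- if (S > 0) sd_ / S else 0
  pN <- if (N > 0) nd_ / N else 0
  jc <- function(p) {
    if (p >= 0.75) runtime_error("substitution fraction saturated (p >= 3/4)")
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  list(dN = dN, dS = dS, omega = if (dS > 0) dN / dS else NA_real_,
       pN = pN, pS = pS, S_sites = S, N_sites = N, sd = sd_, nd = nd_)
}
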