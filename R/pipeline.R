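## cli_pipeline: end-to-end orchestration, config validation, reports ------

#' Validate and normalize a repertoire-run configuration
#'
#' A config is a list with `genome` (path or named character vector),
#' `families` (list of `list(name, queries, profile, evalue)` where
#' `queries` is a FASTA path or named character vector and `profile` a
#' [family_profile()]), and optional `thresholds`
#' (`extension_limit`, `edge_window`, `gap_min`), `out_dir`, `seed`.
#' Per-family e-values default to `1e-20` (single-exon olfactory screen);
#' taste-gene screens conventionally use `1e-5`.
#'
#' @param config A list as above.
#' @return The normalized config (sequences loaded, defaults filled in).
#' @export
validate_config <- function(config) {
  if (!is.list(config)) config_error("config must be a list")
  if (is.null(config$genome)) config_error("config$genome is required")
  if (is.character(config$genome) && is.null(names(config$genome)) &&
      length(config$genome) == 1L) {
    if (!file.exists(config$genome))
      config_error(sprintf("genome path does not exist: %s", config$genome))
    config$genome <- read_fasta(config$genome, "nuc")
  }
  config$genome <- .as_named_chr(config$genome)
  if (is.null(config$families)) config$families <- list()
  config$families <- lapply(config$families, function(f) {
    if (is.null(f$name)) config_error("each family needs a name")
    if (is.character(f$queries) && is.null(names(f$queries)) &&
        length(f$queries) == 1L) {
      if (!file.exists(f$queries))
        config_error(sprintf("query path does not exist: %s", f$queries))
      f$queries <- read_fasta(f$queries, "prot")
    }
    f$queries <- .as_named_chr(f$queries)
    if (!inherits(f$profile, "family_profile"))
      config_error(sprintf("family %s needs a family_profile", f$name))
    if (is.null(f$evalue)) f$evalue <- 1e-20
    if (f$evalue <= 0) config_error("evalue threshold must be positive")
    f
  })
  th <- config$thresholds
  if (is.null(th)) th <- list()
  th$extension_limit <- th$extension_limit %||% 500L
  th$edge_window <- th$edge_window %||% 1000L
  th$gap_min <- th$gap_min %||% 100L
  if (any(unlist(th) <= 0)) config_error("thresholds must be positive")
  config$thresholds <- th
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mine the chemosensory-gene repertoire of one genome
#'
#' Runs, per family: translated search, same-orientation hit merging,
#' cross-family overlap resolution (higher best bit score wins), reciprocal
#' best-hit filtering against the pooled family queries, CDS reconstruction,
#' and intact/truncated/pseudogene classification; then summarizes counts
#' per family. Deterministic given the config. Every candidate that leaves
#' the pipeline is recorded in the discard log with a reason.
#'
#' @param config A config for [validate_config()].
#' @return `list(summary, calls, loci, discarded, log)`; when
#'   `config$out_dir` is set, also writes `calls.tsv`, `calls.gff3`,
#'   `summary.tsv`, `cds.fasta`, `protein.fasta` and `discard.log` there.
#' @export
run_repertoire <- function(config) {
  config <- validate_config(config)
  genome <- config$genome
  scheme <- scoring_scheme()
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  ## pooled reference proteome for the reciprocal check: all family queries
  proteome <- character(0); member_ids <- list()
  for (f in config$families) {
    proteome <- c(proteome, f$queries)
    member_ids[[f$name]] <- names(f$queries)
  }
  all_loci <- list()
  for (f in config$families) {
    hits <- translated_search(genome, f$queries, scheme, f$evalue)
    loci <- merge_hits(hits, family = f$name)
    note("family %s: %d hits merged into %d candidate loci",
         f$name, nrow(hits), nrow(loci))
    all_loci[[f$name]] <- loci
  }
  loci <- do.call(rbind, c(all_loci, list(make.row.names = FALSE)))
  discarded <- list()
  if (!is.null(loci) && nrow(loci) > 1L) {
    ## cross-family overlap: keep the family with the higher best bitscore
    drop <- rep(FALSE, nrow(loci))
    for (i in seq_len(nrow(loci) - 1L)) {
      for (j in (i + 1L):nrow(loci)) {
        if (drop[i] || drop[j]) next
        if (loci$family[i] == loci$family[j]) next
        if (loci$seq_id[i] != loci$seq_id[j]) next
        if (loci$start0[i] < loci$end0[j] && loci$start0[j] < loci$end0[i]) {
          loser <- if (loci$best_bitscore[i] >= loci$best_bitscore[j]) j else i
          drop[loser] <- TRUE
          note("locus %s dropped: overlaps %s with lower bitscore",
               loci$locus_id[loser],
               loci$locus_id[if (loser == i) j else i])
          d <- loci[loser, , drop = FALSE]
          d$reason <- "cross_family_overlap"
          discarded[[length(discarded) + 1L]] <- d
        }
      }
    }
    loci <- loci[!drop, , drop = FALSE]
  }
  calls_list <- list()
  if (!is.null(loci)) {
    for (f in config$families) {
      fl <- loci[loci$family == f$name, , drop = FALSE]
      if (nrow(fl) == 0L) next
      rf <- reciprocal_filter(fl, genome, proteome, member_ids[[f$name]],
                              scheme)
      if (nrow(rf$discarded) > 0L) {
        for (r in seq_len(nrow(rf$discarded)))
          note("locus %s discarded: best hit %s not in family %s",
               rf$discarded$locus_id[r], rf$discarded$best_ref[r], f$name)
        d <- rf$discarded
        d$reason <- paste0("reciprocal:", d$reason)
        discarded[[length(discarded) + 1L]] <-
          d[, c(setdiff(names(loci), "hits"), "reason"), drop = FALSE]
      }
      if (nrow(rf$kept) == 0L) next
      calls <- call_genes(rf$kept, f$profile, genome,
                          config$thresholds$extension_limit,
                          config$thresholds$edge_window,
                          config$thresholds$gap_min)
      for (r in seq_len(nrow(calls)))
        note("locus %s classified %s (%s)", calls$locus_id[r],
             calls$label[r],
             ifelse(calls$disruption_kinds[r] == "", "no disruptions",
                    calls$disruption_kinds[r]))
      calls_list[[f$name]] <- calls
    }
  }
  calls <- if (length(calls_list))
    do.call(rbind, c(lapply(calls_list, function(x) { attr(x, "details") <- NULL; x }),
                     list(make.row.names = FALSE)))
  else
    data.frame(locus_id = character(), family = character(),
               seq_id = character(), start0 = integer(), end0 = integer(),
               strand = character(), label = character(),
               cds_start0 = integer(), cds_end0 = integer(),
               n_disruptions = integer(), disruption_kinds = character(),
               cds = character(), protein = character(),
               stringsAsFactors = FALSE)
  summary <- summarize_repertoire(calls)
  discarded <- if (length(discarded))
    do.call(rbind, c(lapply(discarded, function(d)
      d[, intersect(names(d), c(setdiff(names(loci), "hits"), "reason")),
        drop = FALSE]), list(make.row.names = FALSE)))
  else NULL
  res <- list(summary = summary, calls = calls, loci = loci,
              discarded = discarded, log = log_lines)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    utils::write.table(calls[, setdiff(names(calls), c("cds", "protein"))],
                       file.path(od, "calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_calls_gff3(calls, file.path(od, "calls.gff3"))
    utils::write.table(summary, file.path(od, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(calls) > 0L) {
      write_fasta(setNames(calls$cds, calls$locus_id),
                  file.path(od, "cds.fasta"))
      prot <- calls$protein[nchar(calls$protein) > 0L]
      if (length(prot) > 0L)
        write_fasta(setNames(prot, calls$locus_id[nchar(calls$protein) > 0L]),
                    file.path(od, "protein.fasta"))
    }
    writeLines(log_lines, file.path(od, "discard.log"))
  }
  res
}

#' Audit a multi-exon gene in a target genome
#'
#' Maps the model's exons onto the target (with reciprocal checking against
#' the reference locus), confirms deletions, detects inversions, and
#' computes a reference-vs-target dot plot of the scaffold carrying most
#' found exons.
#'
#' @param target Target genome (named character vector or `DNAStringSet`).
#' @param model An [exon_model()].
#' @param reference Named character vector holding the reference locus (the
#'   model's coordinate owner) as its first sequence.
#' @param evalue_cutoff E-value threshold (default `1e-20`).
#' @param mesh Dot-plot mesh in bp (default 1000).
#' @param out_dir Optional output directory (`presence.tsv`,
#'   `verdicts.tsv`, `dotplot.tsv`, `dotplot.png`).
#' @return `list(presence, verdicts, inversions, dotplot)`.
#' @export
run_multiexon_audit <- function(target, model, reference,
                                evalue_cutoff = 1e-20, mesh = 1000L,
                                out_dir = NULL) {
  target <- .as_named_chr(target)
  reference <- .as_named_chr(reference)
  presence <- map_exons(target, model, evalue_cutoff,
                        source_genome = reference)
  verdicts <- confirm_deletion(target, presence, model)
  inversions <- detect_inversion(presence)
  found <- presence[presence$status == "found", ]
  dp <- NULL
  if (nrow(found) > 0L) {
    sc <- names(sort(table(found$seq_id), decreasing = TRUE))[1L]
    if (nchar(reference[[1L]]) >= mesh && nchar(target[[sc]]) >= mesh)
      dp <- compute_dotplot(reference[[1L]], target[[sc]], mesh)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(presence),
                       file.path(out_dir, "presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(verdicts, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dp)) {
      write_dotplot_tsv(dp, file.path(out_dir, "dotplot.tsv"))
      grDevices::png(file.path(out_dir, "dotplot.png"), 640, 640)
      plot(dp)
      grDevices::dev.off()
    }
  }
  list(presence = presence, verdicts = verdicts, inversions = inversions,
       dotplot = dp)
}

#' @export
plot.dotplot <- function(x, ...) {
  graphics::image(x = x$a_starts + x$mesh / 2, y = x$b_starts + x$mesh / 2,
                  z = x$grid, zlim = c(0, 100),
                  col = grDevices::hcl.colors(32, "viridis"),
                  xlab = "sequence A (bp)", ylab = "sequence B (bp)", ...)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `chemorep` Rscript front end
#' (`inst/cli/chemorep.R`). Subcommands: `mine`, `audit`, `simulate`,
#' `dotplot`, `pcr`. Returns the process exit status: 0 success, 1 runtime
#' failure, 2 configuration error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      config_error("usage: chemorep <mine|audit|simulate|dotplot|pcr> ...")
    cmd <- args[[1L]]
    opts <- .parse_kv(args[-1L])
    switch(cmd,
      mine = .cli_mine(opts),
      audit = .cli_audit(opts),
      simulate = .cli_simulate(opts),
      dotplot = .cli_dotplot(opts),
      pcr = .cli_pcr(opts),
      config_error(sprintf("unknown subcommand: %s", cmd)))
    0L
  },
  chemorep_config_error = function(e) { message("config error: ",
                                               conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

.parse_kv <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) config_error(sprintf("unexpected argument: %s", a))
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      config_error(sprintf("missing value for --%s", key))
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

.req <- function(opts, key) {
  if (is.null(opts[[key]])) config_error(sprintf("--%s is required", key))
  opts[[key]]
}

.cli_simulate <- function(opts) {
  out <- .req(opts, "out")
  seed <- as.integer(opts$seed %||% 1L)
  sim <- default_synthetic_world(seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$planted$genome, file.path(out, "genome.fasta"))
  utils::write.table(sim$planted$truth, file.path(out, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.cli_mine <- function(opts) {
  cfg_path <- .req(opts, "config")
  if (!file.exists(cfg_path))
    config_error(sprintf("config file not found: %s", cfg_path))
  raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  fams <- lapply(seq_len(nrow(raw$families)), function(i) {
    fr <- raw$families[i, ]
    msa <- read_fasta(fr$profile_msa, "prot")
    tm <- matrix(unlist(raw$families$tm_segments[[i]]), ncol = 2L,
                 byrow = TRUE)
    list(name = fr$name, queries = fr$queries,
         profile = family_profile(.as_named_chr(msa),
                                  lapply(seq_len(7L), function(s) tm[s, ]),
                                  family = fr$name),
         evalue = fr$evalue %||% 1e-20)
  })
  cfg <- list(genome = opts$genome %||% raw$genome, families = fams,
              thresholds = raw$thresholds, out_dir = .req(opts, "out"))
  run_repertoire(cfg)
  invisible(NULL)
}

.cli_audit <- function(opts) {
  ref <- read_fasta(.req(opts, "reference"), "nuc")
  tgt <- read_fasta(.req(opts, "genome"), "nuc")
  exons <- read_fasta(.req(opts, "exons"), "nuc")
  coords <- utils::read.table(.req(opts, "exon-coords"), header = TRUE)
  model <- exon_model(opts$gene %||% "gene", .as_named_chr(exons),
                      as.matrix(coords[, c("start0", "end0")]))
  run_multiexon_audit(tgt, model, ref, out_dir = .req(opts, "out"))
  invisible(NULL)
}

.cli_dotplot <- function(opts) {
  a <- read_fasta(.req(opts, "a"), "nuc")
  b <- read_fasta(.req(opts, "b"), "nuc")
  dp <- compute_dotplot(.as_named_chr(a)[[1L]], .as_named_chr(b)[[1L]],
                        as.integer(opts$mesh %||% 1000L))
  write_dotplot_tsv(dp, .req(opts, "out"))
  invisible(NULL)
}

.cli_pcr <- function(opts) {
  tmpl <- read_fasta(.req(opts, "template"), "nuc")
  amp <- insilico_pcr(tmpl, .req(opts, "fwd"), .req(opts, "rev"),
                      as.integer(opts[["max-mismatch"]] %||% 0L))
  utils::write.table(amp, .req(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
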