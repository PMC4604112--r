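## seqcore: sequence and interval primitives -------------------------------
##
## Internal convention: all coordinates are 0-based half-open [start, end);
## the report layer (GFF3/TSV writers) converts to 1-based inclusive.

#' Read a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file. Record ids are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the description. Nucleotide residues are normalized to the five-letter
#' alphabet `{A,C,G,T,N}`: lowercase is uppercased and any other character
#' (IUPAC ambiguity codes, gaps) is mapped to `N` with a warning. Draft
#' assemblies routinely contain ambiguity codes, so they are tolerated rather
#' than rejected.
#'
#' @param path Path to a FASTA file.
#' @param type `"nuc"` for nucleotide (the default), `"prot"` for protein.
#' @return A [Biostrings::DNAStringSet] (or [Biostrings::AAStringSet] for
#'   `type = "prot"`) with record descriptions in `metadata(x)$description`.
#' @export
read_fasta <- function(path, type = c("nuc", "prot")) {
  type <- match.arg(type)
  if (!file.exists(path)) config_error(sprintf("FASTA file not found: %s", path))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) config_error(
                    sprintf("not a well-formed FASTA file: %s (%s)",
                            path, conditionMessage(e))))
  if (length(raw) == 0L) config_error(sprintf("FASTA file has no records: %s", path))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) config_error("FASTA record with empty id")
  if (anyDuplicated(ids))
    config_error(sprintf("duplicate FASTA id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) config_error("empty FASTA record")
  if (type == "nuc") {
    norm <- normalize_nuc(seqs)
    out <- Biostrings::DNAStringSet(norm)
  } else {
    norm <- gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", seqs)
    if (!identical(norm, seqs)) warning("non-standard amino acid letters mapped to X")
    out <- Biostrings::AAStringSet(norm)
  }
  names(out) <- ids
  S4Vectors::metadata(out)$description <- setNames(desc, ids)
  out
}

## map anything outside {A,C,G,T,N} to N (after uppercasing)
normalize_nuc <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%d sequence(s) contained non-ACGTN characters; mapped to N",
                    sum(bad)))
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Write sequences as FASTA
#'
#' @param x A named character vector, `DNAStringSet` or `AAStringSet`.
#' @param path Output path.
#' @param width Line-wrap column (default 60).
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    lines <- unlist(lapply(names(x), function(id) {
      s <- x[[id]]
      c(paste0(">", id),
        substring(s, seq(1L, nchar(s), width),
                  pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))))
    }))
    writeLines(lines, path)
  } else {
    Biostrings::writeXStringSet(x, path, width = width)
  }
  invisible(path)
}

#' Reverse complement
#'
#' `N` maps to `N`; `revcomp(revcomp(x))` is the identity.
#'
#' @param x A character vector of nucleotide sequences, or a `DNAStringSet`.
#' @return Same type as the input.
#' @export
revcomp <- function(x) {
  if (is.character(x)) {
    if (any(nchar(x) == 0L)) stop("cannot reverse-complement an empty sequence")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    if (any(Biostrings::width(x) == 0L))
      stop("cannot reverse-complement an empty sequence")
    Biostrings::reverseComplement(x)
  }
}

#' Translate one reading frame
#'
#' Standard genetic code; stop codons are rendered `*` and any codon
#' containing `N` becomes `X`. For `strand = "-"` the reverse complement is
#' translated, so `translate_frame(x, f, "-")` equals
#' `translate_frame(revcomp(x), f, "+")`.
#'
#' @param x A single nucleotide sequence (character scalar or `DNAString`).
#' @param frame Integer offset 0, 1 or 2.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar of amino acids (possibly empty).
#' @export
translate_frame <- function(x, frame = 0L, strand = "+") {
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  s <- as.character(x)
  if (strand == "-") s <- revcomp(s)
  n <- nchar(s)
  n_codon <- (n - frame) %/% 3L
  if (n_codon <= 0L) return("")
  starts <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
  aa <- .CODON_TABLE[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}


#' Find runs of assembly gap characters (N)
#'
#' Maximal runs of `N` of at least `min_len` bases, reported in 0-based
#' half-open coordinates sorted by start. Used as evidence when deciding
#' whether a gene candidate is truncated by a fragmented scaffold.
#'
#' @param x A single nucleotide sequence (character scalar or `DNAString`).
#' @param min_len Minimum run length (>= 1).
#' @param seq_id Optional scaffold id recorded in the output.
#' @return A data.frame with columns `seq_id`, `start0`, `end0`, `length`.
#' @export
find_gap_runs <- function(x, min_len = 1L, seq_id = NA_character_) {
  stopifnot(min_len >= 1L)
  s <- as.character(x)
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1L) {
    return(data.frame(seq_id = character(), start0 = integer(),
                      end0 = integer(), length = integer()))
  }
  len <- attr(m, "match.length")
  keep <- len >= min_len
  data.frame(seq_id = rep(seq_id, sum(keep)),
             start0 = as.integer(m[keep] - 1L),
             end0 = as.integer(m[keep] - 1L + len[keep]),
             length = as.integer(len[keep]))
}

## ---- integer encodings shared with the C++ aligners ----------------------

PROT_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                   "P","S","T","W","Y","V","B","Z","X","*")
NUC_ALPHABET <- c("A", "C", "G", "T", "N")

.lookup <- function(alphabet, default) {
  tab <- rep.int(default, 127L)
  tab[utf8ToInt(paste(alphabet, collapse = ""))] <- seq_along(alphabet) - 1L
  tab
}
.PROT_LOOKUP <- .lookup(PROT_ALPHABET, 22L) # unknown -> X
.NUC_LOOKUP <- .lookup(NUC_ALPHABET, 4L)    # unknown -> N

prot_codes <- function(s) .PROT_LOOKUP[utf8ToInt(s)]
nuc_codes <- function(s) .NUC_LOOKUP[utf8ToInt(s)]

## 0-based half-open interval helper
interval_df <- function(seq_id, start0, end0, strand = "+") {
  stopifnot(all(start0 >= 0L), all(end0 > start0))
  data.frame(seq_id = seq_id, start0 = as.integer(start0),
             end0 = as.integer(end0), strand = strand,
             stringsAsFactors = FALSE)
}
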