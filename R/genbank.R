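# Minimal GenBank-style flat-file reader: LOCUS length, CDS/tRNA/rRNA
# features with plain or complement() locations, /gene and /product
# qualifiers, and the ORIGIN sequence block. Everything else is ignored.

#' Parse a minimal GenBank-style flat file
#'
#' Supports the subset needed for accession-based checks: the `LOCUS` line
#' (molecule length and circular flag), `CDS`/`tRNA`/`rRNA` features with
#' locations `a..b` or `complement(a..b)` (mapped to the N strand), `/gene`
#' and `/product` qualifiers normalized through [canonical_gene_label()],
#' and the `ORIGIN` sequence block. Features whose name cannot be mapped to
#' the canonical vocabulary are skipped with a warning; `join()` locations
#' are rejected (origin-spanning features are unsupported).
#'
#' @param file path to a flat file, or its content as a single string with
#'   newlines.
#' @param genome_id identifier; defaults to the LOCUS name.
#' @return a [mito_annotation()] (with sequence when an ORIGIN block is
#'   present).
#' @export
read_genbank_lite <- function(file, genome_id = NULL) {
  lines <- if (grepl("\n", file, fixed = TRUE))
    strsplit(file, "\n", fixed = TRUE)[[1]] else readLines(file)

  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  bp_at <- which(toks == "bp")
  glen <- if (length(bp_at)) suppressWarnings(as.integer(toks[bp_at[1] - 1]))
          else suppressWarnings(as.integer(toks[3]))
  if (is.na(glen)) stop("cannot read molecule length from LOCUS line")
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  if (is.null(genome_id)) genome_id <- if (length(toks) >= 2) toks[2] else "genome"

  # cut out the FEATURES block
  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- if (length(fend)) min(fend) else length(lines) + 1L
  feats <- if (length(fstart) && fend - 1L >= fstart[1] + 1L)
    lines[(fstart[1] + 1L):(fend - 1L)] else character(0)

  keys <- c("CDS", "tRNA", "rRNA")
  recs <- list()
  cur <- NULL
  flush <- function(cur) { if (!is.null(cur)) recs[[length(recs) + 1]] <<- cur }
  for (ln in feats) {
    key_m <- regmatches(ln, regexec("^ {1,10}([A-Za-z_']+) +(.+)$", ln))[[1]]
    is_new <- length(key_m) == 3 && !grepl("^ {12}", ln)
    if (is_new) {
      flush(cur)
      cur <- if (key_m[2] %in% keys)
        list(key = key_m[2], location = trimws(key_m[3]), quals = character(0))
      else NULL
    } else if (!is.null(cur)) {
      q <- regmatches(ln, regexec("^ +/([a-z_]+)=\"?([^\"]*)\"?", ln))[[1]]
      if (length(q) == 3) cur$quals[q[2]] <- q[3]
      else cur$location <- paste0(cur$location, trimws(ln))  # wrapped location
    }
  }
  flush(cur)

  rows <- list()
  for (r in recs) {
    loc <- gsub("[[:space:]<>]", "", r$location)
    strand <- "J"
    if (grepl("^complement\\(", loc)) {
      strand <- "N"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order", loc))
      stop("join()/order() locations are not supported (feature ", r$key,
           " ", r$location, ")")
    m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
    if (length(m) != 3) {
      warning("unparseable location '", r$location, "' for ", r$key,
              "; feature skipped")
      next
    }
    nm <- unname(r$quals["gene"])
    if (is.na(nm)) nm <- unname(r$quals["product"])
    if (is.na(nm)) {
      warning(r$key, " feature at ", loc, " has no /gene or /product; skipped")
      next
    }
    lab <- canonical_gene_label(nm)
    if (is.na(lab)) {
      warning("cannot map ", r$key, " name '", nm,
              "' to the canonical vocabulary; feature skipped")
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(name = lab, start = as.integer(m[2]), end = as.integer(m[3]),
                 strand = strand, label = lab, stringsAsFactors = FALSE)
  }
  genes <- if (length(rows)) do.call(rbind, rows)
           else data.frame(name = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    oend <- grep("^//", lines)
    oend <- if (length(oend)) min(oend[oend > ostart[1]]) else length(lines) + 1L
    if (oend > ostart[1] + 1) {
      block <- lines[seq(ostart[1] + 1L, oend - 1L)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
      if (!nzchar(seq)) seq <- NULL
    }
  }
  mito_annotation(genes, genome_id = genome_id, genome_length = glen,
                  circular = circular, sequence = seq)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as plain character
#' vectors named by record id. Written sequences wrap at 70 columns.
#'
#' @param file path to a FASTA file.
#' @return `read_fasta()`: named character vector of upper-case sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, file, width = 70L)
  invisible(file)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (IUPAC letters).
#' @return reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}
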