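# Annotation containers and IO: Table-1-style TSV dialect, a minimal
# GenBank-style flat-file reader, coordinate/size/spacer validation, and
# circular intergenic spacer computation.
#
# Coordinates are 1-based, fully closed. Strands are written "+"/"-" on disk
# and held as "J"/"N" (majority/minority strand) internally.

.tsv_columns <- c("gene", "start", "end", "strand", "start_codon",
                  "stop_codon", "size", "intergenic")

#' Construct a mitogenome annotation
#'
#' @param genes data.frame with columns `name` (label as given), `start`,
#'   `end` (1-based, closed), `strand` (`"J"`/`"N"`), and optionally
#'   `start_codon`, `stop_codon`, `declared_size`, `declared_intergenic`.
#' @param genome_id identifier for the genome.
#' @param genome_length total length in nucleotides; defaults to `max(end)`.
#' @param circular is the molecule circular? (animal mitogenomes are).
#' @param sequence optional J-strand nucleotide string of length
#'   `genome_length`.
#' @param complete declare the 37-gene complement complete (checked by
#'   [validate_annotation()]).
#' @return object of class `mito_annotation`: a list with fields `genome_id`,
#'   `genome_length`, `circular`, `complete`, `genes` (sorted by `start`,
#'   with canonical `label` and `gene_class` columns added) and `sequence`.
#' @export
mito_annotation <- function(genes, genome_id = "genome",
                            genome_length = NULL, circular = TRUE,
                            sequence = NULL, complete = FALSE) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) > 0) {
    for (col in c("name", "start", "end", "strand"))
      if (is.null(genes[[col]])) stop("genes is missing column '", col, "'")
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    if (anyNA(genes$start) || anyNA(genes$end))
      stop("non-integer coordinate in annotation")
    if (any(genes$start > genes$end))
      stop("start > end for gene(s): ",
           paste(genes$name[genes$start > genes$end], collapse = ", "),
           " (origin-spanning features are not supported)")
    if (any(genes$start < 1)) stop("coordinates must be >= 1")
    genes$strand <- .norm_strand(genes$strand)
    if (is.null(genes$label)) genes$label <- canonical_gene_label(genes$name)
    if (is.null(genes$gene_class)) genes$gene_class <- gene_class_of(genes$label)
    for (col in c("start_codon", "stop_codon"))
      if (is.null(genes[[col]])) genes[[col]] <- NA_character_
    for (col in c("declared_size", "declared_intergenic"))
      if (is.null(genes[[col]])) genes[[col]] <- NA_integer_
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
    dup <- genes$label[!is.na(genes$label)]
    if (anyDuplicated(dup))
      stop("duplicate gene label(s): ",
           paste(unique(dup[duplicated(dup)]), collapse = ", "))
  }
  if (is.null(genome_length)) {
    if (nrow(genes) == 0) stop("genome_length required for an empty annotation")
    genome_length <- max(genes$end)
  }
  genome_length <- as.integer(genome_length)
  if (nrow(genes) > 0 && max(genes$end) > genome_length)
    stop("gene end beyond genome_length")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != genome_length)
      stop("sequence length (", nchar(sequence),
           ") != genome_length (", genome_length, ")")
  }
  structure(list(genome_id = genome_id,
                 genome_length = genome_length,
                 circular = isTRUE(circular),
                 complete = isTRUE(complete),
                 genes = genes,
                 sequence = sequence),
            class = "mito_annotation")
}

.norm_strand <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% c("+", "J", "j"), "J",
                ifelse(x %in% c("-", "N", "n"), "N", NA_character_))
  if (anyNA(out)) stop("unknown strand symbol: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("mito_annotation '%s': %d genes, %s bp%s%s\n",
              x$genome_id, nrow(x$genes),
              format(x$genome_length, big.mark = ","),
              if (x$circular) ", circular" else ", linear",
              if (!is.null(x$sequence)) ", with sequence" else ""))
  if (nrow(x$genes) > 0) {
    cls <- table(factor(x$genes$gene_class, levels = c("PCG", "tRNA", "rRNA")))
    cat(sprintf("  %d PCG, %d tRNA, %d rRNA; %d on N strand\n",
                cls[["PCG"]], cls[["tRNA"]], cls[["rRNA"]],
                sum(x$genes$strand == "N")))
  }
  invisible(x)
}

#' Parse a Table-style annotation TSV
#'
#' Reads the 8-column dialect `gene, start, end, strand, start_codon,
#' stop_codon, size, intergenic` (tab-separated, `+`/`-` strands, empty codon
#' cells for RNA genes, negative intergenic = overlap with the next gene).
#'
#' @param file path to a TSV file, or its content as a single string
#'   containing newlines.
#' @param genome_id identifier; defaults to the file base name.
#' @param genome_length override the genome length (default: max `end`).
#' @param circular treat the genome as circular.
#' @param complete declare the 37-gene complement complete.
#' @return a [mito_annotation()].
#' @export
read_annotation_tsv <- function(file, genome_id = NULL, genome_length = NULL,
                                circular = TRUE, complete = FALSE) {
  is_content <- grepl("\n", file, fixed = TRUE)
  if (is.null(genome_id))
    genome_id <- if (is_content) "genome" else
      sub("\\.[^.]*$", "", basename(file))
  con <- if (is_content) textConnection(file) else file
  tab <- read.delim(con, header = TRUE, sep = "\t",
                    colClasses = "character", strip.white = TRUE,
                    blank.lines.skip = TRUE)
  names(tab) <- tolower(names(tab))
  missing_cols <- setdiff(.tsv_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("annotation TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("no genes in annotation table")
  num <- function(col, what) {
    x <- suppressWarnings(as.integer(tab[[col]]))
    bad <- is.na(x) & nzchar(tab[[col]])
    if (any(bad)) stop("unparseable ", what, " for gene(s): ",
                       paste(tab$gene[bad], collapse = ", "))
    x
  }
  genes <- data.frame(name = tab$gene,
                      start = num("start", "start"),
                      end = num("end", "end"),
                      strand = tab$strand,
                      start_codon = ifelse(nzchar(tab$start_codon),
                                           tab$start_codon, NA_character_),
                      stop_codon = ifelse(nzchar(tab$stop_codon),
                                          tab$stop_codon, NA_character_),
                      declared_size = num("size", "size"),
                      declared_intergenic = num("intergenic", "intergenic"),
                      stringsAsFactors = FALSE)
  if (anyNA(genes$start) || anyNA(genes$end))
    stop("missing coordinate in annotation table")
  lab <- canonical_gene_label(genes$name)
  if (anyNA(lab))
    stop("unknown gene label(s): ",
         paste(genes$name[is.na(lab)], collapse = ", "))
  genes$label <- lab
  mito_annotation(genes, genome_id = genome_id,
                  genome_length = genome_length, circular = circular,
                  complete = complete)
}

#' Write an annotation back to the TSV dialect
#'
#' Inverse of [read_annotation_tsv()]: for an annotation that came from the
#' TSV dialect the written cells are identical to the input cells.
#'
#' @param ann a [mito_annotation()].
#' @param file output path, or `NULL` to return the lines invisibly.
#' @return invisibly, the character vector of lines written.
#' @export
write_annotation_tsv <- function(ann, file = NULL) {
  stopifnot(inherits(ann, "mito_annotation"))
  g <- ann$genes
  cell <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- c(paste(.tsv_columns, collapse = "\t"),
             paste(g$name, g$start, g$end,
                   ifelse(g$strand == "J", "+", "-"),
                   cell(g$start_codon), cell(g$stop_codon),
                   cell(g$declared_size), cell(g$declared_intergenic),
                   sep = "\t"))
  if (!is.null(file)) writeLines(lines, file, sep = "\n")
  invisible(lines)
}

#' Circular intergenic spacers
#'
#' For genes sorted by start, the spacer after gene *i* is
#' `start[i+1] - end[i] - 1`; negative values are overlaps. On a circular
#' genome the last gene wraps to the first:
#' `(genome_length - end[last]) + (start[first] - 1)`. The largest positive
#' spacer is the putative A+T-rich (control) region.
#'
#' @param ann a [mito_annotation()].
#' @return data.frame with columns `gene`, `next_gene`, `gap`, plus an
#'   attribute `largest` (row index of the largest positive gap).
#' @export
#' @examples
#' tsv <- system.file("extdata", "sinentomon_annotation.tsv",
#'                    package = "mitoarch")
#' sp <- compute_spacers(read_annotation_tsv(tsv))
#' sp[which.max(sp$gap), ]   # the 993-bp A+T-rich region, nad6 -> cob
compute_spacers <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  g <- ann$genes
  if (nrow(g) == 0) stop("empty annotation")
  n <- nrow(g)
  if (n == 1 && !ann$circular)
    return(data.frame(gene = character(0), next_gene = character(0),
                      gap = integer(0)))
  nxt <- c(seq_len(n)[-1], 1L)
  gap <- g$start[nxt] - g$end - 1L
  gap[n] <- (ann$genome_length - g$end[n]) + (g$start[1] - 1L)
  out <- data.frame(gene = g$name, next_gene = g$name[nxt], gap = gap,
                    stringsAsFactors = FALSE)
  if (!ann$circular) out <- out[-n, , drop = FALSE]
  pos <- which(out$gap > 0)
  attr(out, "largest") <- if (length(pos)) pos[which.max(out$gap[pos])] else NA_integer_
  out
}

#' Largest non-coding region of an annotation
#'
#' @param ann a [mito_annotation()].
#' @return list with `after` (gene name), `before` (next gene), `start`,
#'   `end` (1-based coordinates of the spacer) and `length`; `NULL` if the
#'   annotation has no positive spacer.
#' @export
largest_spacer <- function(ann) {
  sp <- compute_spacers(ann)
  i <- attr(sp, "largest")
  if (is.na(i)) return(NULL)
  g <- ann$genes
  j <- match(sp$gene[i], g$name)
  st <- g$end[j] + 1L
  list(after = sp$gene[i], before = sp$next_gene[i],
       start = st, end = st + sp$gap[i] - 1L, length = sp$gap[i])
}

#' Validate an annotation against its own declared columns
#'
#' Checks, in order: declared size vs `end - start + 1`; declared intergenic
#' vs the computed circular spacers (the wrap cell of the last gene uses the
#' circular convention and is flagged when the table disagrees); strand/class
#' consistency of the label; and 37-gene completeness when the annotation is
#' declared complete. Violations are returned as data, not raised.
#'
#' @param ann a [mito_annotation()].
#' @return data.frame with columns `gene`, `type`, `declared`, `computed`,
#'   `detail`; zero rows iff the annotation is fully self-consistent.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "mito_annotation"))
  g <- ann$genes
  v <- list()
  add <- function(gene, type, declared, computed, detail) {
    v[[length(v) + 1]] <<- data.frame(gene = gene, type = type,
                                      declared = as.character(declared),
                                      computed = as.character(computed),
                                      detail = detail,
                                      stringsAsFactors = FALSE)
  }
  if (nrow(g) > 0) {
    size <- g$end - g$start + 1L
    bad <- which(!is.na(g$declared_size) & g$declared_size != size)
    for (i in bad)
      add(g$name[i], "size_mismatch", g$declared_size[i], size[i],
          "declared size != end - start + 1")
    sp <- compute_spacers(ann)
    if (nrow(sp) > 0) {
      idx <- match(sp$gene, g$name)
      decl <- g$declared_intergenic[idx]
      bad <- which(!is.na(decl) & decl != sp$gap)
      for (i in bad) {
        wrap <- ann$circular && i == nrow(sp)
        add(sp$gene[i], if (wrap) "wrap_intergenic_mismatch"
                        else "intergenic_mismatch",
            decl[i], sp$gap[i],
            if (wrap)
              "declared intergenic of the origin-wrapping spacer disagrees with the circular convention (L - end) + (start_1 - 1)"
            else "declared intergenic != next start - end - 1")
      }
    }
    bad <- which(is.na(g$label))
    for (i in bad)
      add(g$name[i], "unknown_label", g$name[i], NA,
          "name not in the 37-gene vocabulary")
    implied <- gene_class_of(g$label)
    bad <- which(!is.na(g$label) & !is.na(g$gene_class) &
                   implied != g$gene_class)
    for (i in bad)
      add(g$name[i], "class_mismatch", g$gene_class[i], implied[i],
          "gene_class does not match the label prefix")
    is_pcg <- !is.na(g$gene_class) & g$gene_class == "PCG"
    bad <- which(!is_pcg & (!is.na(g$start_codon) | !is.na(g$stop_codon)))
    for (i in bad)
      add(g$name[i], "codon_on_rna_gene",
          paste(stats::na.omit(c(g$start_codon[i], g$stop_codon[i])),
                collapse = "/"),
          NA, "RNA gene carries start/stop codon cells")
  }
  if (ann$complete) {
    missing <- setdiff(mito_gene_labels(), g$label)
    for (m in missing)
      add(m, "missing_gene", "present", "absent",
          "annotation declared complete but gene absent")
  }
  if (length(v) == 0)
    return(data.frame(gene = character(0), type = character(0),
                      declared = character(0), computed = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}
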