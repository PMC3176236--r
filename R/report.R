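# Per-genome report orchestration: annotation validation -> spacers ->
# composition (with sequence) -> gene-order classification and comparison ->
# control-region repeats (with sequence) -> per-tRNA cloverleaf fits (with
# sequence). Sections whose inputs are missing are skipped, not faked.

#' Run the full per-genome analysis report
#'
#' @param annotation a [mito_annotation()], or a path to an annotation TSV
#'   or GenBank-style flat file (`.gb`/`.gbk`/`.genbank` extension selects
#'   the flat-file reader).
#' @param sequence optional nucleotide string, path to a FASTA file, or
#'   `NULL`; ignored when the annotation already carries a sequence.
#' @param references ground-pattern names to compare the gene order against.
#' @param tdrl_blocks passed to [compare_orders()] for each reference;
#'   `NULL` tests the observed span of the reference's `trnI..trnY` block.
#' @param out_dir optional directory; when given, each section is written as
#'   JSON/TSV and the bundle records the paths.
#' @return object of class `report_bundle` with sections `validation`,
#'   `spacers`, `largest_spacer`, `composition`, `order` (classification +
#'   one `rearrangement_report` per reference), `repeats`, `trna`, `paths`.
#' @export
run_report <- function(annotation, sequence = NULL,
                       references = c("arthropod", "pancrustacean"),
                       tdrl_blocks = NULL, out_dir = NULL) {
  ann <- if (inherits(annotation, "mito_annotation")) annotation
         else if (grepl("\\.(gb|gbk|genbank)$", annotation, ignore.case = TRUE))
           read_genbank_lite(annotation)
         else read_annotation_tsv(annotation)
  if (is.null(ann$sequence) && !is.null(sequence)) {
    seq <- if (file.exists(sequence)) read_fasta(sequence)[[1]]
           else toupper(sequence)
    ann <- mito_annotation(ann$genes, genome_id = ann$genome_id,
                           genome_length = max(ann$genome_length, nchar(seq)),
                           circular = ann$circular, sequence = seq,
                           complete = ann$complete)
  }

  bundle <- list(genome_id = ann$genome_id,
                 validation = validate_annotation(ann),
                 spacers = compute_spacers(ann),
                 largest_spacer = largest_spacer(ann),
                 composition = NULL, order = NULL, repeats = NULL,
                 trna = NULL, paths = character(0))

  ord <- extract_signed_order(ann)
  cls <- classify_trnl2_pattern(ord)
  comparisons <- list()
  for (ref_name in references) {
    ref <- ground_pattern(ref_name)
    if (setequal(ord$labels, ref$labels)) {
      blocks <- tdrl_blocks
      if (is.null(blocks))
        blocks <- list(.observed_span(ord, ref, "trnI", "trnY"))
      comparisons[[ref_name]] <- compare_orders(ord, ref,
                                                tdrl_blocks = blocks)
    }
  }
  bundle$order <- list(order = ord, classification = cls,
                       comparisons = comparisons)

  if (!is.null(ann$sequence)) {
    bundle$composition <- per_gene_composition(ann)
    ls <- bundle$largest_spacer
    if (!is.null(ls) && ls$length >= 10) {
      window <- substr(ann$sequence, ls$start, ls$end)
      bundle$repeats <- find_tandem_repeats(window)
      for (i in seq_along(bundle$repeats)) {
        bundle$repeats[[i]]$start <- bundle$repeats[[i]]$start + ls$start - 1L
        bundle$repeats[[i]]$end <- bundle$repeats[[i]]$end + ls$start - 1L
      }
    }
    tg <- ann$genes[!is.na(ann$genes$gene_class) &
                      ann$genes$gene_class == "tRNA", , drop = FALSE]
    fits <- list()
    for (i in seq_len(nrow(tg))) {
      s <- substr(ann$sequence, tg$start[i], tg$end[i])
      if (tg$strand[i] == "N") s <- revcomp(s)
      fits[[tg$label[i]]] <- if (nchar(s) >= 50 && nchar(s) <= 75)
        fit_cloverleaf(s) else NULL
    }
    bundle$trna <- fits
  }

  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) bundle <- .write_bundle(bundle, out_dir)
  bundle
}

# the contiguous stretch of `ord` spanned by the genes that lie between
# `from` and `to` (inclusive) in the reference reading
.observed_span <- function(ord, ref, from, to) {
  i <- match(from, ref$labels); j <- match(to, ref$labels)
  n <- length(ref$labels)
  idx <- if (i <= j) i:j else c(i:n, 1:j)
  ref$labels[idx]
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(name, obj) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    paths[[name]] <<- p
  }
  wr("validation", bundle$validation)
  wr("spacers", bundle$spacers)
  wr("order", list(
    order = format(bundle$order$order),
    classification = bundle$order$classification,
    comparisons = lapply(bundle$order$comparisons, unclass)))
  if (!is.null(bundle$composition)) {
    p <- file.path(out_dir, "composition.tsv")
    write.table(bundle$composition, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[["composition"]] <- p
  }
  if (!is.null(bundle$repeats)) wr("repeats", lapply(bundle$repeats, unclass))
  if (!is.null(bundle$trna))
    wr("trna", lapply(bundle$trna, function(f) if (is.null(f)) NULL else
      list(arms = as.list(f$arms), score = f$score,
           truncation = classify_truncation(f), structure = f$structure)))
  bundle$paths <- paths
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle for '%s'\n", x$genome_id))
  cat(sprintf("  validation: %d violation(s)\n", nrow(x$validation)))
  if (!is.null(x$largest_spacer))
    cat(sprintf("  largest spacer: %d nt (%s -> %s)\n",
                x$largest_spacer$length, x$largest_spacer$after,
                x$largest_spacer$before))
  cat(sprintf("  trnL2 pattern: %s\n", x$order$classification$classification))
  for (nm in names(x$order$comparisons))
    cat(sprintf("  vs %s: %d breakpoints, %d inverted block(s)\n", nm,
                x$order$comparisons[[nm]]$breakpoints,
                length(x$order$comparisons[[nm]]$inverted_blocks)))
  if (!is.null(x$repeats) && length(x$repeats))
    print(x$repeats)
  if (!is.null(x$trna)) {
    tr <- vapply(x$trna, function(f)
      if (is.null(f)) NA_character_ else classify_truncation(f), "")
    cat(sprintf("  tRNAs fitted: %d (%d lacking T arm, %d lacking D arm)\n",
                sum(!is.na(tr)),
                sum(tr %in% c("lacks_T_arm", "lacks_D_and_T_arms")),
                sum(tr %in% c("lacks_D_arm", "lacks_D_and_T_arms"))))
  }
  invisible(x)
}
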