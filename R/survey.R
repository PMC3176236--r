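# Multi-genome junction-pattern survey: classify each annotated mitogenome
# by its trnL2 junction pattern and aggregate conformance ratios per taxon
# group. Partial (junction-only) records, e.g. a sequenced cox1/cox2
# amplicon, are first-class inputs: flags whose genes are absent stay NA and
# drop out of that pattern's denominator.

#' Classify a collection of mitogenomes by junction pattern
#'
#' @param annotations list of [mito_annotation()] objects (or
#'   `signed_gene_order` objects).
#' @param groups character vector of taxon-group labels, one per annotation
#'   (caller-supplied metadata, not inferred taxonomy).
#' @param genome_ids optional identifiers; defaults to annotation ids.
#' @return object of class `junction_survey`: list with `records`
#'   (data.frame: one row per genome with classification and the four
#'   junction flags) and `ratios` (data.frame per group x pattern:
#'   `n_conforming`, `n_total`; groups ordered by name; genomes whose flag
#'   is NA are excluded from that pattern's total).
#' @export
#' @examples
#' anns <- replicate(3, ground_pattern("pancrustacean"), simplify = FALSE)
#' classify_collection(anns, groups = rep("Insecta", 3))$ratios
classify_collection <- function(annotations, groups, genome_ids = NULL) {
  stopifnot(length(annotations) == length(groups))
  if (is.null(genome_ids))
    genome_ids <- vapply(seq_along(annotations), function(i) {
      a <- annotations[[i]]
      if (inherits(a, "mito_annotation")) a$genome_id
      else paste0("genome_", i)
    }, "")
  rows <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    ord <- if (inherits(a, "signed_gene_order")) a else extract_signed_order(a)
    cl <- tryCatch(classify_trnl2_pattern(ord),
                   error = function(e) list(
                     classification = "unclassifiable",
                     junctions = list(cox1_trnL2_cox2 = NA, cox1_cox2 = NA,
                                      rrnL_trnL1_nad1 = NA,
                                      rrnL_trnL1_trnL2_nad1 = NA)))
    data.frame(genome_id = genome_ids[i], taxon_group = groups[i],
               classification = cl$classification,
               cox1_trnL2_cox2 = .na_lgl(cl$junctions$cox1_trnL2_cox2),
               cox1_cox2 = .na_lgl(cl$junctions$cox1_cox2),
               rrnL_trnL1_nad1 = .na_lgl(cl$junctions$rrnL_trnL1_nad1),
               rrnL_trnL1_trnL2_nad1 =
                 .na_lgl(cl$junctions$rrnL_trnL1_trnL2_nad1),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  patterns <- c("cox1_trnL2_cox2", "cox1_cox2", "rrnL_trnL1_nad1",
                "rrnL_trnL1_trnL2_nad1")
  grp <- sort(unique(records$taxon_group))
  ratios <- do.call(rbind, lapply(grp, function(g) {
    sub <- records[records$taxon_group == g, , drop = FALSE]
    do.call(rbind, lapply(patterns, function(p) {
      flags <- sub[[p]]
      data.frame(taxon_group = g, pattern = p,
                 n_conforming = sum(flags, na.rm = TRUE),
                 n_total = sum(!is.na(flags)),
                 n_unclassifiable = sum(is.na(flags)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(ratios) <- NULL
  structure(list(records = records, ratios = ratios),
            class = "junction_survey")
}

.na_lgl <- function(x) if (is.null(x) || is.na(x)) NA else isTRUE(x)

#' @export
print.junction_survey <- function(x, ...) {
  cat(sprintf("junction_survey: %d genomes, %d group(s)\n",
              nrow(x$records), length(unique(x$records$taxon_group))))
  r <- x$ratios[x$ratios$n_total > 0, , drop = FALSE]
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-12s %-22s %d/%d\n", r$taxon_group[i], r$pattern[i],
                r$n_conforming[i], r$n_total[i]))
  invisible(x)
}

#' Run a survey from annotation files and a manifest
#'
#' @param manifest path to a TSV with columns `genome_id`, `group`, `file`
#'   (annotation TSV path, relative to the manifest's directory unless
#'   absolute).
#' @return a `junction_survey` (see [classify_collection()]).
#' @export
survey_from_files <- function(manifest) {
  man <- read.delim(manifest, sep = "\t", colClasses = "character")
  need <- c("genome_id", "group", "file")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  anns <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    read_annotation_tsv(f, genome_id = man$genome_id[i])
  })
  classify_collection(anns, man$group, man$genome_id)
}
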