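# Nucleotide composition and strand-asymmetry statistics, computed on the
# J-strand (majority strand) throughout. AT-skew = (A - T)/(A + T),
# GC-skew = (G - C)/(G + C); both are antisymmetric under the corresponding
# base exchange and negate under reverse complementation.

#' Base counts of a nucleotide string
#'
#' @param seq nucleotide string; case-insensitive. IUPAC letters other than
#'   A/C/G/T are tallied under `other`.
#' @return named integer vector `A, C, G, T, other` (all zero for `""`).
#' @export
#' @examples
#' base_counts("TTTTGTTAAA")   # A=3 C=0 G=1 T=6
base_counts <- function(seq) {
  seq <- toupper(as.character(seq))
  if (is.na(seq) || !nzchar(seq))
    return(c(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = c("A", "C", "G", "T")))
  out <- c(A = unname(tab[["A"]]), C = unname(tab[["C"]]),
           G = unname(tab[["G"]]), T = unname(tab[["T"]]))
  c(out, other = length(ch) - sum(out))
}

#' Strand-asymmetry statistics from base counts
#'
#' Computes AT content `(A+T)/(A+C+G+T)`, AT-skew `(A-T)/(A+T)` and GC-skew
#' `(G-C)/(G+C)`. Counts may be raw tallies or proportions (as printed in a
#' paper); the formulas are scale-free. A zero denominator yields `NA` with
#' the corresponding flag set instead of a division blow-up. Values are kept
#' at full precision; rounding belongs to presentation.
#'
#' @param counts named numeric vector with elements `A`, `C`, `G`, `T`
#'   (anything else, e.g. `other`, is ignored), or a sequence string.
#' @param region_name label carried into the report.
#' @return object of class `skew_report`: list with `region_name`, `counts`,
#'   `at_content`, `at_skew`, `gc_skew`, `undefined` (character vector naming
#'   any skew whose denominator was zero).
#' @export
#' @examples
#' r <- skew_stats(c(A = 0.252, C = 0.073, G = 0.151, T = 0.524))
#' round(r$at_skew, 3)   # -0.351
skew_stats <- function(counts, region_name = "region") {
  if (is.character(counts) && length(counts) == 1 && is.null(names(counts)))
    counts <- base_counts(counts)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(counts)))
    stop("counts must have named elements A, C, G, T")
  a <- as.numeric(counts[["A"]]); cc <- as.numeric(counts[["C"]])
  g <- as.numeric(counts[["G"]]); t <- as.numeric(counts[["T"]])
  if (any(c(a, cc, g, t) < 0)) stop("negative counts")
  tot <- a + cc + g + t
  undefined <- character(0)
  at_content <- if (tot > 0) (a + t) / tot else {
    undefined <- c(undefined, "at_content"); NA_real_
  }
  at_skew <- if (a + t > 0) (a - t) / (a + t) else {
    undefined <- c(undefined, "at_skew"); NA_real_
  }
  gc_skew <- if (g + cc > 0) (g - cc) / (g + cc) else {
    undefined <- c(undefined, "gc_skew"); NA_real_
  }
  structure(list(region_name = region_name,
                 counts = c(A = a, C = cc, G = g, T = t),
                 at_content = at_content, at_skew = at_skew,
                 gc_skew = gc_skew, undefined = undefined),
            class = "skew_report")
}

#' @export
print.skew_report <- function(x, digits = 3, ...) {
  cat(sprintf("skew_report '%s'\n", x$region_name))
  cat(sprintf("  A=%g C=%g G=%g T=%g\n", x$counts[["A"]], x$counts[["C"]],
              x$counts[["G"]], x$counts[["T"]]))
  fmt <- function(v) if (is.na(v)) "undefined" else
    formatC(round(v, digits), format = "f", digits = digits)
  cat(sprintf("  AT content %s  AT-skew %s  GC-skew %s\n",
              fmt(x$at_content), fmt(x$at_skew), fmt(x$gc_skew)))
  invisible(x)
}

#' Per-gene composition table
#'
#' One row per protein-coding and rRNA gene (the 15-gene set of a standard
#' per-gene skew panel) plus a whole-genome row, computed on the J-strand
#' substring of each gene regardless of its coding strand. Set
#' `coding_strand = TRUE` to reverse-complement N-strand genes first (off by
#' default: majority-strand values are the comparable convention).
#'
#' @param ann a [mito_annotation()] carrying its sequence.
#' @param classes gene classes to include (default PCG and rRNA).
#' @param coding_strand compute on the coding strand instead of the J-strand.
#' @return data.frame with columns `region`, `A`, `C`, `G`, `T`, `length`,
#'   `at_content`, `at_skew`, `gc_skew`.
#' @export
per_gene_composition <- function(ann, classes = c("PCG", "rRNA"),
                                 coding_strand = FALSE) {
  stopifnot(inherits(ann, "mito_annotation"))
  if (is.null(ann$sequence)) stop("annotation has no sequence")
  g <- ann$genes[!is.na(ann$genes$gene_class) &
                   ann$genes$gene_class %in% classes, , drop = FALSE]
  if (nrow(g) > 0 && any(g$end > nchar(ann$sequence)))
    stop("gene beyond sequence bounds")
  one <- function(name, seq) {
    r <- skew_stats(base_counts(seq), region_name = name)
    data.frame(region = name,
               A = r$counts[["A"]], C = r$counts[["C"]],
               G = r$counts[["G"]], T = r$counts[["T"]],
               length = nchar(seq), at_content = r$at_content,
               at_skew = r$at_skew, gc_skew = r$gc_skew,
               stringsAsFactors = FALSE)
  }
  rows <- list(one("whole_genome", ann$sequence))
  for (i in seq_len(nrow(g))) {
    s <- substr(ann$sequence, g$start[i], g$end[i])
    if (coding_strand && g$strand[i] == "N") s <- revcomp(s)
    rows[[length(rows) + 1]] <- one(g$label[i], s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Longest homopolymer run
#'
#' @param seq nucleotide string.
#' @param base single letter to search for (case-insensitive).
#' @return integer length of the longest run of `base` (0 if absent).
#' @export
#' @examples
#' longest_run("TTATTT", "T")   # 3
longest_run <- function(seq, base) {
  seq <- toupper(as.character(seq)); base <- toupper(base)
  stopifnot(nchar(base) == 1)
  if (!nzchar(seq)) return(0L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  hits <- r$lengths[r$values == base]
  if (length(hits)) max(hits) else 0L
}

#' Codon usage of a coding sequence
#'
#' Counts the 64 codons over the in-frame triplets of `cds`; a trailing
#' partial codon (1 or 2 nt, the signature of the incomplete mitochondrial
#' stop codons written `T--` / `TA-`) is reported separately rather than
#' silently dropped. Triplets containing non-ACGT letters count under
#' `other`.
#'
#' @param cds coding sequence on its coding strand.
#' @return list with `codons` (named integer vector of 64 counts), `other`
#'   (count of ambiguous triplets), and `partial` (trailing partial codon,
#'   `""` if none).
#' @export
codon_usage <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  n_full <- n %/% 3L
  partial <- if (n %% 3L) substr(cds, 3L * n_full + 1L, n) else ""
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  counts <- setNames(integer(64), sort(all64))
  other <- 0L
  if (n_full > 0) {
    starts <- 3L * (seq_len(n_full) - 1L) + 1L
    cods <- substring(cds, starts, starts + 2L)
    known <- cods %in% names(counts)
    tab <- table(cods[known])
    counts[names(tab)] <- as.integer(tab)
    other <- sum(!known)
  }
  list(codons = counts, other = other, partial = partial)
}
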