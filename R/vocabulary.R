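# Canonical gene vocabulary of the 37-gene animal mitogenome and the synonym
# maps used to normalize annotation-table and GenBank-style labels onto it.

#' Canonical mitochondrial gene labels
#'
#' The 37-gene complement of a typical animal (bilaterian) mitochondrial
#' genome: 13 protein-coding genes, 22 tRNAs and 2 rRNAs. The two leucine and
#' two serine tRNAs are disambiguated as `trnL1` (anticodon uag, CUN codons),
#' `trnL2` (uaa, UUR), `trnS1` (gcu, AGN) and `trnS2` (uga, UCN).
#'
#' @param class one of `"all"`, `"PCG"`, `"tRNA"`, `"rRNA"`.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' length(mito_gene_labels())        # 37
#' mito_gene_labels("rRNA")
mito_gene_labels <- function(class = c("all", "PCG", "tRNA", "rRNA")) {
  class <- match.arg(class)
  pcg <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
           "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
  trna <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
            "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
            "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
  rrna <- c("rrnS", "rrnL")
  switch(class,
         all  = c(pcg, trna, rrna),
         PCG  = pcg,
         tRNA = trna,
         rRNA = rrna)
}

#' Gene class implied by a canonical label
#'
#' @param label canonical label(s), e.g. `"cox1"`, `"trnL2"`, `"rrnS"`.
#' @return character vector in `{"PCG","tRNA","rRNA"}` (`NA` for unknown).
#' @export
gene_class_of <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label %in% mito_gene_labels("PCG")]  <- "PCG"
  out[label %in% mito_gene_labels("tRNA")] <- "tRNA"
  out[label %in% mito_gene_labels("rRNA")] <- "rRNA"
  out
}

# one-letter amino acid -> canonical tRNA label stem (Leu/Ser handled apart)
.aa3 <- c(Ala = "trnA", Cys = "trnC", Asp = "trnD", Glu = "trnE", Phe = "trnF",
          Gly = "trnG", His = "trnH", Ile = "trnI", Lys = "trnK", Met = "trnM",
          Asn = "trnN", Pro = "trnP", Gln = "trnQ", Arg = "trnR", Thr = "trnT",
          Val = "trnV", Trp = "trnW", Tyr = "trnY")

#' Canonicalize a gene label
#'
#' Maps annotation-table and GenBank-style names onto the canonical
#' vocabulary: `trnX-abc` anticodon-suffixed names (with `trnL-uaa` -> trnL2,
#' `trnL-uag` -> trnL1, `trnS-gcu` -> trnS1, `trnS-uga` -> trnS2), upper-case
#' gene symbols (`COX1`, `COI`, `ND4L`, `CYTB`, `ATP8`, `12S`/`16S`), and
#' `tRNA-Xxx` product names, using codon-family suffixes `(UUR)/(CUN)` and
#' `(AGN)/(UCN)` to separate the leucine and serine paralogs.
#'
#' @param name character vector of labels as found in input files.
#' @return canonical labels; `NA` where the name cannot be mapped.
#' @export
#' @examples
#' canonical_gene_label(c("trnL-uaa", "tRNA-Phe", "COI", "l-rRNA"))
canonical_gene_label <- function(name) {
  vapply(as.character(name), .canonical_one, character(1), USE.NAMES = FALSE)
}

.canonical_one <- function(nm) {
  if (is.na(nm) || !nzchar(nm)) return(NA_character_)
  raw <- trimws(nm)
  # already canonical
  if (raw %in% mito_gene_labels()) return(raw)
  low <- tolower(raw)

  # tRNA-Xxx product names (GenBank-lite); checked before the anticodon
  # dialect because "trna-ugc" (trnA + anticodon) and "trna-phe" (product)
  # collide case-insensitively -- a valid amino-acid code decides
  if (grepl("^trna[-_ ]", low)) {
    m <- regmatches(low, regexec("^trna[-_ ]([a-z]{3})", low))[[1]]
    if (length(m) == 2L) {
      aa3 <- paste0(toupper(substr(m[2], 1, 1)), substr(m[2], 2, 3))
      if (aa3 == "Leu") {
        if (grepl("uur|l2", low)) return("trnL2")
        if (grepl("cun|l1", low)) return("trnL1")
        return(NA_character_)
      }
      if (aa3 == "Ser") {
        if (grepl("agn|s1", low)) return("trnS1")
        if (grepl("ucn|s2", low)) return("trnS2")
        return(NA_character_)
      }
      if (aa3 %in% names(.aa3)) return(unname(.aa3[aa3]))
      # not an amino-acid code: fall through to the anticodon dialect
    }
  }

  # trnX-anticodon dialect (Table-1 style)
  if (grepl("^trn", low)) {
    m <- regmatches(low, regexec("^trn([a-z])(?:[-_]?([acgu]{3}))?", low))[[1]]
    if (length(m) == 3L && nzchar(m[2])) {
      aa <- toupper(m[2]); ac <- m[3]
      if (aa == "L") {
        if (identical(ac, "uaa")) return("trnL2")
        if (identical(ac, "uag")) return("trnL1")
        if (grepl("l1", low)) return("trnL1")
        if (grepl("l2", low)) return("trnL2")
        return(NA_character_)
      }
      if (aa == "S") {
        if (identical(ac, "gcu")) return("trnS1")
        if (identical(ac, "uga")) return("trnS2")
        if (grepl("s1", low)) return("trnS1")
        if (grepl("s2", low)) return("trnS2")
        return(NA_character_)
      }
      cand <- paste0("trn", aa)
      if (cand %in% mito_gene_labels("tRNA")) return(cand)
    }
    return(NA_character_)
  }

  # gene symbols and rRNA products
  syn <- c(
    "coi" = "cox1", "coii" = "cox2", "coiii" = "cox3",
    "cox1" = "cox1", "cox2" = "cox2", "cox3" = "cox3",
    "co1" = "cox1", "co2" = "cox2", "co3" = "cox3",
    "cytb" = "cob", "cob" = "cob", "cyt b" = "cob",
    "atp6" = "atp6", "atp8" = "atp8", "atpase6" = "atp6", "atpase8" = "atp8",
    "nd1" = "nad1", "nd2" = "nad2", "nd3" = "nad3", "nd4" = "nad4",
    "nd4l" = "nad4L", "nd5" = "nad5", "nd6" = "nad6",
    "nad1" = "nad1", "nad2" = "nad2", "nad3" = "nad3", "nad4" = "nad4",
    "nad4l" = "nad4L", "nad5" = "nad5", "nad6" = "nad6",
    "rrns" = "rrnS", "rrnl" = "rrnL",
    "s-rrna" = "rrnS", "l-rrna" = "rrnL",
    "12s" = "rrnS", "16s" = "rrnL",
    "12s rrna" = "rrnS", "16s rrna" = "rrnL",
    "12s ribosomal rna" = "rrnS", "16s ribosomal rna" = "rrnL",
    "small subunit ribosomal rna" = "rrnS",
    "large subunit ribosomal rna" = "rrnL")
  # long product names for the PCGs
  if (grepl("cytochrome c oxidase subunit", low)) {
    if (grepl("iii|3", low)) return("cox3")
    if (grepl("ii|2", low)) return("cox2")
    return("cox1")
  }
  if (grepl("cytochrome b", low)) return("cob")
  if (grepl("nadh dehydrogenase subunit", low)) {
    if (grepl("4l", low)) return("nad4L")
    n <- regmatches(low, regexec("([1-6])", low))[[1]]
    if (length(n) == 2L) return(paste0("nad", n[2]))
    return(NA_character_)
  }
  if (grepl("atp synthase", low)) {
    if (grepl("8", low)) return("atp8")
    if (grepl("6", low)) return("atp6")
    return(NA_character_)
  }
  if (low %in% names(syn)) return(unname(syn[[low]]))
  NA_character_
}
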