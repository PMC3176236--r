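# One-step tandem-duplication-random-loss (TDRL) feasibility.
#
# In a TDRL event a contiguous block is duplicated in tandem and one copy of
# each gene is then lost. The surviving genes read: those retained in the
# first copy, in ancestral order, followed by those retained in the second
# copy, in ancestral order. A block order is therefore reachable in ONE such
# event iff its sequence of ancestral indices splits into an increasing
# prefix followed by an increasing suffix -- equivalently, it has at most one
# descent. TDRL never flips coding strands, so any orientation mismatch is
# an immediate refusal.

#' One-step TDRL feasibility of an observed block order
#'
#' @param reference_block a [signed_gene_order()] or character vector giving
#'   the ancestral (pre-duplication) gene order of the block.
#' @param observed_block the observed order over the same label set (same
#'   type as `reference_block`).
#' @param reference_orientation,observed_orientation orientations aligned
#'   with the label vectors when character input is used (default all `"J"`).
#' @return list with `feasible` (flag), `witness` (when feasible: list of
#'   the two retained-copy label subsequences, the second empty when the
#'   observed order equals the reference), `index_sequence` (observed
#'   positions mapped to reference indices), and `reason` (when infeasible).
#' @export
#' @examples
#' ref <- c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY")
#' obs <- c("trnI", "nad2", "trnY", "trnQ", "trnM", "trnW", "trnC")
#' tdrl_feasible(ref, obs)$witness
tdrl_feasible <- function(reference_block, observed_block,
                          reference_orientation = NULL,
                          observed_orientation = NULL) {
  unpack <- function(x, orient) {
    if (inherits(x, "signed_gene_order"))
      list(labels = x$labels, orientation = x$orientation)
    else
      list(labels = as.character(x),
           orientation = .norm_strand(rep_len(
             if (is.null(orient)) "J" else orient, length(x))))
  }
  ref <- unpack(reference_block, reference_orientation)
  obs <- unpack(observed_block, observed_orientation)
  if (!setequal(ref$labels, obs$labels))
    stop("label sets differ between reference and observed block")
  if (anyDuplicated(ref$labels) || anyDuplicated(obs$labels))
    stop("duplicate labels in block")

  idx <- match(obs$labels, ref$labels)
  out <- list(feasible = FALSE, witness = NULL, index_sequence = idx,
              reason = NULL)

  mism <- obs$orientation != ref$orientation[idx]
  if (any(mism)) {
    out$reason <- paste0("orientation mismatch for ",
                         paste(obs$labels[mism], collapse = ", "),
                         "; TDRL never flips strands")
    return(out)
  }

  descents <- which(diff(idx) < 0)
  if (length(descents) > 1) {
    out$reason <- sprintf(
      "index sequence has %d descents; a single duplication-loss event allows at most one",
      length(descents))
    return(out)
  }
  cut <- if (length(descents) == 0) length(idx) else descents[1]
  out$feasible <- TRUE
  out$witness <- list(copy1 = obs$labels[seq_len(cut)],
                      copy2 = if (cut < length(idx))
                        obs$labels[(cut + 1):length(idx)] else character(0))
  out
}

#' Displaced genes relative to a reference order
#'
#' Labels that do not conserve both circular neighbors (labels only,
#' orientation ignored) with respect to the reference.
#'
#' @param order,reference [signed_gene_order()] objects over the same label
#'   set.
#' @return character vector of displaced labels, in `order` reading.
#' @export
displaced_genes <- function(order, reference) {
  stopifnot(inherits(order, "signed_gene_order"),
            inherits(reference, "signed_gene_order"))
  if (!setequal(order$labels, reference$labels)) stop("label sets differ")
  n <- length(order$labels)
  if (n < 3) return(character(0))
  nbrs <- function(x) {
    m <- length(x$labels)
    lapply(seq_len(m), function(i) {
      sort(c(x$labels[((i - 2L) %% m) + 1L], x$labels[(i %% m) + 1L]))
    })
  }
  a <- nbrs(order)
  b <- nbrs(reference)
  names(b) <- reference$labels
  keep <- vapply(seq_len(n), function(i) {
    identical(a[[i]], b[[order$labels[i]]])
  }, logical(1))
  order$labels[!keep]
}

#' Full rearrangement report of an order against a reference
#'
#' Combines breakpoint counting, inverted-block/strand-flip detection,
#' neighbor-conservation (displaced genes) and, when `tdrl_blocks` are
#' given, one-step TDRL feasibility for each named block.
#'
#' @param order,reference [signed_gene_order()] objects over the same label
#'   set.
#' @param tdrl_blocks optional list of character vectors; each is a set of
#'   labels forming a contiguous block of `reference` whose observed
#'   arrangement is tested with [tdrl_feasible()].
#' @return object of class `rearrangement_report`.
#' @export
compare_orders <- function(order, reference, tdrl_blocks = NULL) {
  inv <- find_inverted_blocks(order, reference)
  res <- list(breakpoints = breakpoint_count(order, reference),
              inverted_blocks = inv$blocks,
              strand_flips = inv$strand_flips,
              displaced = displaced_genes(order, reference),
              tdrl_results = list())
  for (blk in tdrl_blocks) {
    sub_ref <- .subset_order(reference, blk)
    sub_obs <- .subset_order(order, blk)
    res$tdrl_results[[paste(blk, collapse = "-")]] <-
      tdrl_feasible(sub_ref, sub_obs)
  }
  structure(res, class = "rearrangement_report")
}

# restrict an order to `labels`, keeping circular reading; the subsequence is
# linearized starting at the member following the largest gap of excluded
# genes (for contiguous blocks this is the block's natural start).
.subset_order <- function(order, labels) {
  n <- length(order$labels)
  keep <- order$labels %in% labels
  if (!any(keep)) stop("none of the labels occur in the order")
  idx <- which(keep)
  if (length(idx) == n) {
    start <- 1L
  } else {
    gaps <- diff(c(idx, idx[1] + n))      # circular gaps between members
    start_i <- which.max(gaps)            # largest excluded stretch follows
    start <- (start_i %% length(idx)) + 1L
  }
  ordering <- c(idx[seq(start, length(idx))],
                if (start > 1) idx[seq_len(start - 1L)])
  structure(list(labels = order$labels[ordering],
                 orientation = order$orientation[ordering],
                 anchor = order$labels[ordering][1]),
            class = "signed_gene_order")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat("rearrangement_report\n")
  cat(sprintf("  breakpoints: %d\n", x$breakpoints))
  if (length(x$inverted_blocks))
    for (b in x$inverted_blocks)
      cat("  inverted block: [", paste(b, collapse = ", "), "]\n")
  else cat("  inverted blocks: none\n")
  cat("  strand flips:", if (length(x$strand_flips))
    paste(x$strand_flips, collapse = ", ") else "none", "\n")
  cat("  displaced:", if (length(x$displaced))
    paste(x$displaced, collapse = ", ") else "none", "\n")
  for (nm in names(x$tdrl_results)) {
    r <- x$tdrl_results[[nm]]
    cat(sprintf("  TDRL[%s]: %s\n", nm,
                if (r$feasible) "feasible" else paste("infeasible:", r$reason)))
  }
  invisible(x)
}
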