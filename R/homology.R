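# Sequence homology: affine-gap global alignment (BLOSUM62) standing in for
# an external BLAST step, and homologue selection over a complex corpus.

#' Globally align two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (BLOSUM62,
#' gap open 11, gap extend 1) via \pkg{Biostrings}. Identity is the fraction
#' of identical columns over aligned (non-gap) columns.
#'
#' @param seq_a,seq_b one-letter amino-acid strings (non-empty; nonstandard
#'   residues as \code{"X"}).
#' @return List with \code{identity} (percent), \code{n_aligned} (non-gap
#'   columns) and \code{map}, a two-column matrix of aligned sequence
#'   positions (1-based, strictly increasing in both columns).
#' @examples
#' align_pair("ACDEFGHIKL", "ACDEFGHIKL")$identity  # 100
#' @export
align_pair <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("align_pair: empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gi <- ap != "-"
  gj <- as_ != "-"
  both <- gi & gj
  pos_a <- cumsum(gi)
  pos_b <- cumsum(gj)
  n_aligned <- sum(both)
  identity <- if (n_aligned) 100 * sum(ap[both] == as_[both]) / n_aligned else 0
  list(identity = identity, n_aligned = n_aligned,
       map = cbind(a = pos_a[both], b = pos_b[both]))
}

#' Select homologous target complexes for a reference chain
#'
#' Aligns the reference chain against every chain of every other complex in
#' the corpus and keeps, per target complex, the best-identity chain whose
#' identity reaches \code{min_identity} over at least \code{min_aligned}
#' aligned residues. The reference complex itself is excluded from its own
#' target list.
#'
#' @param reference an \code{lsr_complex} (the complex holding the reference
#'   ligand).
#' @param ref_chain chain id of the reference chain.
#' @param corpus list of \code{lsr_complex}.
#' @param min_identity minimum percent sequence identity (default 90).
#' @param min_aligned minimum aligned (non-gap) columns (default 50).
#' @return List of \code{lsr_homologue} objects: reference/target (entry,
#'   chain), \code{identity}, and \code{residue_map} (data frame of aligned
#'   reference/target residue numbers, strictly increasing in both columns).
#' @export
select_homologues <- function(reference, ref_chain, corpus,
                              min_identity = 90, min_aligned = 50) {
  stopifnot(inherits(reference, "lsr_complex"))
  ref_seq <- extract_sequence(reference, ref_chain)
  ref_res <- chain_residues(reference, ref_chain)
  out <- list()
  for (target in corpus) {
    if (identical(target$entry_id, reference$entry_id)) next
    best <- NULL
    for (ch in unique(target$atoms$chain)) {
      tseq <- extract_sequence(target, ch)
      if (!nzchar(tseq)) next
      al <- align_pair(ref_seq, tseq)
      if (al$n_aligned < min_aligned || al$identity < min_identity) next
      if (is.null(best) || al$identity > best$identity) {
        tres <- chain_residues(target, ch)
        best <- structure(list(
          reference = c(entry = reference$entry_id, chain = ref_chain),
          target = c(entry = target$entry_id, chain = ch),
          identity = al$identity,
          residue_map = data.frame(ref_resno = ref_res$resno[al$map[, "a"]],
                                   target_resno = tres$resno[al$map[, "b"]])),
          class = "lsr_homologue")
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  out
}

#' @export
print.lsr_homologue <- function(x, ...) {
  cat(sprintf("<lsr_homologue %s/%s -> %s/%s> identity %.1f%%, %d mapped residues\n",
              x$reference["entry"], x$reference["chain"],
              x$target["entry"], x$target["chain"], x$identity,
              nrow(x$residue_map)))
  invisible(x)
}
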