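# SMILES-composition categories: every fragment maps to exactly one label
# from a controlled vocabulary built from its heavy-element set and
# ring/no-ring status, e.g. "cycle C+O+N", "C+O", "F", "cycle other".

.ELEMENT_PRIORITY <- c("C", "O", "N", "S", "P", "F", "Cl", "Br", "I", "B")

element_set_name <- function(elements) {
  els <- unique(elements)
  pri <- match(els, .ELEMENT_PRIORITY)
  pri[is.na(pri)] <- length(.ELEMENT_PRIORITY) + rank(els[is.na(pri)])
  paste(els[order(pri)], collapse = "+")
}

#' Default category vocabulary
#'
#' The predefined cyclic and acyclic element-set names. Any fragment whose
#' element set is not listed falls into \code{"cycle other"} or
#' \code{"acyclic other"}; single-heavy-atom fragments are labelled by their
#' element symbol. The vocabulary is configuration: extend or shrink it to
#' control how fine the categorization is.
#'
#' @return List with character vectors \code{cyclic} and \code{acyclic}.
#' @export
category_vocab <- function() {
  list(
    cyclic = c("C", "C+O", "C+N", "C+S", "C+O+N", "C+O+S", "C+N+S"),
    acyclic = c("C", "C+O", "C+N", "C+S", "C+O+N", "C+O+S", "N+O")
  )
}

#' Assign the composition category of a fragment SMILES
#'
#' @param smiles fragment SMILES (wildcard attachment atoms \code{"*"} are
#'   ignored).
#' @param vocab vocabulary as returned by \code{\link{category_vocab}}.
#' @return Category label string.
#' @examples
#' assign_category("c1ccncc1")   # "cycle C+N"
#' assign_category("[F]")        # "F"
#' @export
assign_category <- function(smiles, vocab = category_vocab()) {
  g <- smiles_to_graph(smiles)
  if (is.null(g))
    stop(sprintf("assign_category: unparseable SMILES \"%s\"", smiles))
  heavy <- which(g$atoms$element != "*")
  if (!length(heavy)) stop("assign_category: no heavy atoms")
  if (length(heavy) == 1L) return(g$atoms$element[heavy])
  b <- g$bonds[g$bonds$i %in% heavy & g$bonds$j %in% heavy, , drop = FALSE]
  ncomp <- length(graph_components(nrow(g$atoms), b, heavy))
  cyclic <- has_cycle(length(heavy), b, ncomp)
  set <- element_set_name(g$atoms$element[heavy])
  if (cyclic) {
    if (set %in% vocab$cyclic) paste("cycle", set) else "cycle other"
  } else {
    if (set %in% vocab$acyclic) set else "acyclic other"
  }
}

#' Tabulate categories over a fragment set
#'
#' @param smiles_list character vector of fragment SMILES.
#' @param vocab vocabulary as returned by \code{\link{category_vocab}}.
#' @return Data frame (category, count), descending by count; the counts
#'   always sum to \code{length(smiles_list)}.
#' @export
category_table <- function(smiles_list, vocab = category_vocab()) {
  labs <- vapply(smiles_list, assign_category, "", vocab = vocab,
                 USE.NAMES = FALSE)
  tb <- sort(table(labs), decreasing = TRUE)
  data.frame(category = names(tb), count = as.integer(tb),
             stringsAsFactors = FALSE)
}
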