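# Fragment queries: SMILES with attachment markers ("[R]" or "*") and
# subgraph matching of the query core against perceived ligand graphs.

#' Parse a fragment query SMILES
#'
#' The attachment point -- the vertex where the queried moiety connects to
#' the rest of a ligand -- may be written \code{"[R]"} (as sketched in
#' fragment editors) or as the SMILES wildcard \code{"*"}. Attachment atoms
#' must be terminal (degree 1).
#'
#' @param smiles query SMILES, e.g. \code{"Oc1cccc([R])c1O"} for a
#'   3-substituted catechol.
#' @return An object of class \code{lsr_query}: atom table (\code{element},
#'   \code{aromatic}, \code{is_attachment}), bond table, \code{core}
#'   (indices of non-attachment atoms) and \code{attachment_count}.
#' @examples
#' q <- parse_fragment_query("Oc1cccc([R])c1O")
#' length(q$core)        # 8 core atoms: 6 ring C + 2 O
#' q$attachment_count    # 1
#' @export
parse_fragment_query <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("parse_fragment_query: empty query")
  smiles <- trimws(smiles)
  norm <- gsub("\\[R[0-9]*\\]", "*", smiles)

  # cheap structural lint so malformed input names the offending token
  unbal <- function(s, open, close) {
    v <- strsplit(s, "")[[1]]
    sum(v == open) != sum(v == close)
  }
  if (unbal(norm, "(", ")"))
    stop(sprintf("parse_fragment_query: unbalanced '(' in \"%s\"", smiles))
  if (unbal(norm, "[", "]"))
    stop(sprintf("parse_fragment_query: unbalanced '[' in \"%s\"", smiles))

  g <- smiles_to_graph(norm)
  if (is.null(g))
    stop(sprintf("parse_fragment_query: unparseable SMILES \"%s\"", smiles))

  is_att <- g$atoms$element == "*"
  deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = nrow(g$atoms))
  if (any(is_att & deg != 1L))
    stop("parse_fragment_query: attachment atoms must be terminal (degree 1)")

  structure(list(
    smiles = smiles,
    atoms = data.frame(element = g$atoms$element, aromatic = g$aromatic,
                       is_attachment = is_att, stringsAsFactors = FALSE),
    bonds = g$bonds,
    core = which(!is_att),
    attachment_count = sum(is_att)), class = "lsr_query")
}

#' @export
print.lsr_query <- function(x, ...) {
  cat(sprintf("<lsr_query \"%s\"> %d core atoms, %d attachment point(s)\n",
              x$smiles, length(x$core), x$attachment_count))
  invisible(x)
}

bond_class <- function(order) ifelse(order == "ar", "ar", "sigma")

#' Find all matches of a query core in a ligand
#'
#' Subgraph (monomorphism) matching of the query's core atoms against a
#' perceived ligand graph. Atoms are compatible when element and aromaticity
#' agree; bonds when both are aromatic or both are not. Each attachment
#' wildcard requires the matched neighbour atom to carry at least one ligand
#' substituent outside the matched core (the wildcard matches any heavy
#' atom). Matches covering the same ligand atom set (symmetry duplicates)
#' are collapsed to one.
#'
#' @param ligand a perceived \code{lsr_ligand}.
#' @param query an \code{lsr_query}.
#' @return List of integer vectors; each maps query core atom k to a ligand
#'   atom index. Empty list when there is no match.
#' @export
match_substructure <- function(ligand, query) {
  stopifnot(inherits(ligand, "lsr_ligand"), inherits(query, "lsr_query"))
  if (!isTRUE(ligand$perceived))
    stop("match_substructure: ligand graph not perceived; call perceive_ligand_graph()")

  core <- query$core
  nq <- length(core)
  nl <- nrow(ligand$atoms)
  if (nq == 0L || nl < nq) return(list())

  # query core graph in core-local indexing
  qel <- query$atoms$element[core]
  qar <- query$atoms$aromatic[core]
  qmap <- match(seq_len(nrow(query$atoms)), core)
  qb <- query$bonds
  in_core <- !is.na(qmap[qb$i]) & !is.na(qmap[qb$j])
  qbonds <- data.frame(i = qmap[qb$i[in_core]], j = qmap[qb$j[in_core]],
                       cls = bond_class(qb$order[in_core]),
                       stringsAsFactors = FALSE)
  # attachment demand per core atom
  att_demand <- integer(nq)
  for (k in which(!in_core)) {
    end <- c(qb$i[k], qb$j[k])
    cn <- end[!query$atoms$is_attachment[end]]
    att_demand[qmap[cn]] <- att_demand[qmap[cn]] + 1L
  }

  lel <- ligand$atoms$element
  lar <- ligand$aromatic
  ladj <- vector("list", nl)
  lcls <- matrix(NA_character_, nl, nl)
  for (k in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[k]; j <- ligand$bonds$j[k]
    ladj[[i]] <- c(ladj[[i]], j); ladj[[j]] <- c(ladj[[j]], i)
    lcls[i, j] <- lcls[j, i] <- bond_class(ligand$bonds$order[k])
  }
  ldeg <- lengths(ladj)

  qadj <- vector("list", nq)
  qcls <- matrix(NA_character_, nq, nq)
  for (k in seq_len(nrow(qbonds))) {
    i <- qbonds$i[k]; j <- qbonds$j[k]
    qadj[[i]] <- c(qadj[[i]], j); qadj[[j]] <- c(qadj[[j]], i)
    qcls[i, j] <- qcls[j, i] <- qbonds$cls[k]
  }
  qdeg <- lengths(qadj)

  # visit order: BFS from the most-connected core atom keeps the search tight
  ord <- integer(0)
  remaining <- seq_len(nq)
  while (length(remaining)) {
    comp_seed <- remaining[order(-qdeg[remaining])][1]
    queue <- comp_seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% ord) next
      ord <- c(ord, v)
      nb <- setdiff(qadj[[v]], ord)
      queue <- c(queue, nb[order(-qdeg[nb])])
    }
    remaining <- setdiff(remaining, ord)
  }

  results <- list()
  assign_vec <- integer(nq)     # query k -> ligand atom
  used <- logical(nl)

  compatible <- function(k, a) {
    if (lel[a] != qel[k] || lar[a] != qar[k]) return(FALSE)
    if (ldeg[a] < qdeg[k] + att_demand[k]) return(FALSE)
    TRUE
  }

  backtrack <- function(pos) {
    if (pos > nq) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    k <- ord[pos]
    prev <- ord[seq_len(pos - 1L)]
    anchored <- intersect(qadj[[k]], prev)
    cand <- if (length(anchored)) {
      Reduce(intersect, lapply(anchored, function(p) ladj[[assign_vec[p]]]))
    } else which(vapply(seq_len(nl), function(a) compatible(k, a), TRUE))
    for (a in cand) {
      if (used[a] || !compatible(k, a)) next
      ok <- TRUE
      for (p in anchored)
        if (!identical(qcls[k, p], lcls[a, assign_vec[p]])) { ok <- FALSE; break }
      if (!ok) next
      assign_vec[k] <<- a; used[a] <<- TRUE
      backtrack(pos + 1L)
      used[a] <<- FALSE
    }
    invisible(NULL)
  }
  backtrack(1L)

  if (!length(results)) return(list())
  # attachment feasibility: matched neighbour must have enough outside bonds
  keep <- vapply(results, function(m) {
    for (k in which(att_demand > 0L)) {
      outside <- setdiff(ladj[[m[k]]], m)
      if (length(outside) < att_demand[k]) return(FALSE)
    }
    TRUE
  }, TRUE)
  results <- results[keep]
  # collapse symmetry duplicates (same atom set)
  sets <- vapply(results, function(m) paste(sort(m), collapse = ","), "")
  results[!duplicated(sets)]
}
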