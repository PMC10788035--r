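# End-to-end orchestration: query -> reference hits -> homologues ->
# superposition -> probe capture -> fitness filter -> dedup -> categories /
# clustering. Stage counts are logged via message() since result counts are
# the pipeline's natural diagnostics.

#' Search configuration
#'
#' Aggregates every tunable of the pipeline.
#'
#' @param probe_radius probe-sphere radius, Angstrom (default 2.5).
#' @param fitness_threshold acceptance threshold on the combined
#'   shape/electrostatics score (default 0.2).
#' @param min_identity minimum percent sequence identity for homologue
#'   selection (default 90).
#' @param min_aligned minimum aligned residues (default 50).
#' @param min_atoms minimum heavy atoms of an organic fragment (default 3;
#'   metal ions are exempt).
#' @param fingerprint a \code{\link{fingerprint_config}}.
#' @param fitness a \code{\link{fitness_config}} (its threshold is taken
#'   from \code{fitness_threshold}).
#' @param cluster_algorithm algorithm tuned over k for the post-processing
#'   step (default \code{"kmeans"}).
#' @param min_cluster_n smallest fragment count for which clustering is
#'   attempted (default 8).
#' @param seed integer seed driving every stochastic step.
#' @return Object of class \code{search_config}.
#' @export
search_config <- function(probe_radius = 2.5, fitness_threshold = 0.2,
                          min_identity = 90, min_aligned = 50, min_atoms = 3,
                          fingerprint = fingerprint_config(),
                          fitness = fitness_config(threshold = fitness_threshold),
                          cluster_algorithm = "kmeans", min_cluster_n = 8,
                          seed = 1) {
  stopifnot(probe_radius > 0, fitness_threshold >= 0, fitness_threshold <= 1,
            min_identity >= 0, min_identity <= 100, min_atoms >= 1)
  fitness$threshold <- fitness_threshold
  structure(list(probe_radius = probe_radius,
                 fitness_threshold = fitness_threshold,
                 min_identity = min_identity, min_aligned = min_aligned,
                 min_atoms = min_atoms, fingerprint = fingerprint,
                 fitness = fitness, cluster_algorithm = cluster_algorithm,
                 min_cluster_n = min_cluster_n, seed = as.integer(seed)),
            class = "search_config")
}

load_corpus <- function(corpus) {
  if (is.character(corpus)) {
    paths <- corpus
    if (length(paths) == 1L && dir.exists(paths))
      paths <- sort(list.files(paths, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE, ignore.case = TRUE))
    if (!length(paths)) stop("run_search: no PDB files in corpus")
    lapply(paths, function(p)
      parse_structure(paste(readLines(p, warn = FALSE), collapse = "\n"),
                      entry_id = toupper(sub("\\.[^.]*$", "", basename(p)))))
  } else if (all(vapply(corpus, inherits, TRUE, what = "lsr_complex"))) {
    corpus
  } else stop("run_search: corpus must be paths or a list of lsr_complex")
}

# reference fragment: the matched query-core atoms of the reference ligand,
# induced as a single fragment (no min_atoms filter; it is connected by
# construction of the query).
reference_fragment <- function(ligand, match_idx) {
  fr <- induce_fragments(ligand, match_idx, min_atoms = 1)
  sizes <- vapply(fr, function(f) nrow(f$atoms), 0L)
  fr[[which.max(sizes)]]
}

#' Run the full local-structural-replacement search
#'
#' Executes the whole pipeline for one fragment query over a corpus of
#' complexes: reference-ligand identification by substructure match,
#' homologue selection by global sequence alignment, least-squares
#' superposition, probe-sphere capture at the matched reference-fragment
#' atoms, fragment induction and SMILES generation, shape+ESP fitness
#' filtering at the configured threshold, global deduplication,
#' categorization and (when enough fragments survive) fingerprint
#' clustering with tuned k plus a PCA embedding.
#'
#' @param query query SMILES with \code{"[R]"}/\code{"*"} attachment
#'   markers, or an \code{lsr_query}.
#' @param corpus directory path, vector of PDB paths, or list of
#'   \code{lsr_complex}.
#' @param config a \code{\link{search_config}}.
#' @return Object of class \code{lsr_result}: \code{table} (ranked data
#'   frame of SMILES, fitness components, category, cluster, provenance),
#'   \code{fragments} (the \code{lsr_fragment} list), \code{counts} (per
#'   stage), \code{clustering} (\code{lsr_tuning} or NULL), \code{embedding}
#'   (PCA scores or NULL), \code{reference} (entry/het/SMILES of the
#'   reference moiety).
#' @export
run_search <- function(query, corpus, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  complexes <- load_corpus(corpus)
  if (!length(complexes)) stop("run_search: empty corpus")
  q <- if (inherits(query, "lsr_query")) query else parse_fragment_query(query)
  counts <- list(parsed = length(complexes), reference_hits = 0L,
                 homologues = 0L, captured = 0L, post_threshold = 0L,
                 post_dedup = 0L)
  message(sprintf("[1/6] parsed %d complexes", counts$parsed))

  # perceive every ligand graph once
  complexes <- lapply(complexes, function(cx) {
    cx$ligands <- lapply(cx$ligands, perceive_ligand_graph)
    cx
  })

  # reference hits: ligands containing the query core
  hits <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    for (lig in cx$ligands) {
      for (m in match_substructure(lig, q))
        hits[[length(hits) + 1L]] <- list(complex = ci, ligand = lig,
                                          match = m)
    }
  }
  counts$reference_hits <- length(hits)
  message(sprintf("[2/6] %d reference ligand match(es)", length(hits)))
  if (!length(hits)) {
    message("no reference ligand contains the query; nothing to search")
    return(empty_result(q, counts))
  }

  all_frags <- list()
  ref_info <- NULL
  for (h in hits) {
    ref_cx <- complexes[[h$complex]]
    ref_lig <- h$ligand
    ref_frag <- reference_fragment(ref_lig, h$match)
    ref_frag <- fragment_to_smiles(ref_frag)
    if (is.null(ref_info))
      ref_info <- list(entry = ref_cx$entry_id, het = ref_lig$het_code,
                       smiles = ref_frag$smiles)
    ref_chain <- if (ref_lig$chain %in% ref_cx$atoms$chain) ref_lig$chain
      else names(sort(table(ref_cx$atoms$chain), decreasing = TRUE))[1]
    homs <- select_homologues(ref_cx, ref_chain, complexes,
                              min_identity = config$min_identity,
                              min_aligned = config$min_aligned)
    counts$homologues <- counts$homologues + length(homs)
    probes <- probe_set(
      as.matrix(ref_lig$atoms[h$match, c("x", "y", "z")]),
      radius = config$probe_radius)
    for (hp in homs) {
      tgt <- complexes[[match(hp$target["entry"],
                              vapply(complexes, `[[`, "", "entry_id"))]]
      sup <- superpose_by_mapping(tgt, ref_cx, hp)
      for (lig in sup$ligands) {
        cap <- capture_atoms(probes, lig)
        counts$captured <- counts$captured + length(cap)
        frs <- induce_fragments(lig, cap, min_atoms = config$min_atoms)
        for (fr in frs) {
          fr <- fragment_to_smiles(fr)
          fr$fitness <- score_fragment(fr, ref_frag, config$fitness)
          fr$provenance <- data.frame(
            ref_entry = ref_cx$entry_id, ref_het = ref_lig$het_code,
            target_entry = sup$entry_id, target_het = lig$het_code,
            stringsAsFactors = FALSE)
          all_frags[[length(all_frags) + 1L]] <- fr
        }
      }
    }
  }
  message(sprintf("[3/6] %d homologue pair(s); %d atoms captured; %d raw fragment(s)",
                  counts$homologues, counts$captured, length(all_frags)))
  if (counts$homologues == 0L)
    warning("run_search: no homologue above the identity threshold")

  kept <- filter_rank(all_frags, config$fitness)
  counts$post_threshold <- length(kept)
  kept <- deduplicate(kept)
  counts$post_dedup <- length(kept)
  message(sprintf("[4/6] %d fragment(s) >= threshold %.2f; %d after dedup",
                  counts$post_threshold, config$fitness$threshold,
                  counts$post_dedup))

  if (!length(kept)) return(empty_result(q, counts, ref_info))

  smiles <- vapply(kept, `[[`, "", "smiles")
  self_flag <- !is.null(ref_info) & smiles == ref_info$smiles
  category <- vapply(smiles, function(s)
    tryCatch(assign_category(s), error = function(e) "unclassified"), "",
    USE.NAMES = FALSE)

  clustering <- NULL; embedding <- NULL
  cluster_lab <- rep(NA_integer_, length(kept))
  if (length(kept) >= config$min_cluster_n) {
    fps <- suppressMessages(fingerprint_set(smiles, config$fingerprint))
    if (nrow(fps) >= config$min_cluster_n) {
      clustering <- tune_clusters(fps, config$cluster_algorithm,
                                  seed = config$seed)
      embedding <- pca_embed(fps, dims = 2)
      cluster_lab <- clustering$best$labels[match(smiles, rownames(fps))]
      message(sprintf("[5/6] clustering (%s): k = %d, silhouette %.3f",
                      config$cluster_algorithm, clustering$best$k,
                      clustering$best$silhouette))
    }
  } else {
    message(sprintf("[5/6] clustering skipped (%d < %d fragments)",
                    length(kept), config$min_cluster_n))
  }

  tab <- data.frame(
    smiles = smiles,
    fitness = vapply(kept, function(f) f$fitness$combined, 0),
    shape = vapply(kept, function(f) f$fitness$shape, 0),
    esp = vapply(kept, function(f) f$fitness$esp, 0),
    n_atoms = vapply(kept, function(f) nrow(f$atoms), 0L),
    attachments = vapply(kept, function(f) f$attachment_count, 0L),
    category = category,
    cluster = cluster_lab,
    self_replacement = self_flag,
    ref_entry = vapply(kept, function(f) f$provenance$ref_entry[1], ""),
    ref_het = vapply(kept, function(f) f$provenance$ref_het[1], ""),
    target_entry = vapply(kept, function(f)
      paste(unique(f$provenance$target_entry), collapse = ";"), ""),
    target_het = vapply(kept, function(f)
      paste(unique(f$provenance$target_het), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  message(sprintf("[6/6] done: %d replacement idea(s)", nrow(tab)))

  structure(list(query = q, table = tab, fragments = kept, counts = counts,
                 clustering = clustering, embedding = embedding,
                 reference = ref_info, config = config),
            class = "lsr_result")
}

empty_result <- function(q, counts, ref_info = NULL) {
  structure(list(query = q,
                 table = data.frame(smiles = character(0),
                                    fitness = numeric(0)),
                 fragments = list(), counts = counts, clustering = NULL,
                 embedding = NULL, reference = ref_info, config = NULL),
            class = "lsr_result")
}

#' @export
print.lsr_result <- function(x, ...) {
  cat(sprintf("<lsr_result \"%s\"> %d replacement idea(s)\n",
              x$query$smiles, nrow(x$table)))
  cn <- x$counts
  cat(sprintf("  stages: %d parsed | %d reference hits | %d homologues | %d captured atoms | %d >= threshold | %d unique\n",
              cn$parsed, cn$reference_hits, cn$homologues, cn$captured,
              cn$post_threshold, cn$post_dedup))
  if (nrow(x$table))
    print(utils::head(x$table[, c("smiles", "fitness", "category",
                                  "self_replacement")], 10))
  invisible(x)
}

#' @export
summary.lsr_result <- function(object, ...) {
  print(object)
  if (nrow(object$table)) {
    cat("\ncategories:\n")
    print(table(object$table$category))
    if (!is.null(object$clustering)) print(object$clustering)
  }
  invisible(object)
}

#' Write a result bundle to disk
#'
#' Emits \code{results.csv} and \code{results.json} (the ranked table plus
#' stage counts), \code{fragments.sdf} (3D fragments), and when clustering
#' ran, \code{tuning_curves.csv}, \code{embedding.csv} and
#' \code{clustering.png} / \code{tuning.png}.
#'
#' @param result an \code{lsr_result}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "lsr_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$table, file.path(dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(query = result$query$smiles, counts = result$counts,
         reference = result$reference, results = result$table),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (length(result$fragments))
    write_fragments_sdf(result$fragments, file.path(dir, "fragments.sdf"))
  if (!is.null(result$clustering)) {
    utils::write.csv(result$clustering$curves,
                     file.path(dir, "tuning_curves.csv"), row.names = FALSE)
    grDevices::png(file.path(dir, "tuning.png"), width = 900, height = 450)
    plot(result$clustering)
    grDevices::dev.off()
  }
  if (!is.null(result$embedding)) {
    emb <- cbind(as.data.frame(result$embedding),
                 smiles = result$table$smiles,
                 cluster = result$table$cluster)
    utils::write.csv(emb, file.path(dir, "embedding.csv"), row.names = FALSE)
    grDevices::png(file.path(dir, "clustering.png"), width = 600, height = 600)
    plot(result$embedding[, 1], result$embedding[, 2],
         col = (result$table$cluster %% 8) + 1, pch = 19,
         xlab = "PC1", ylab = "PC2",
         main = "replacement ideas, PCA of 2048-bit fingerprints")
    grDevices::dev.off()
  }
  invisible(dir)
}
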