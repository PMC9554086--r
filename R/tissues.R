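.clonotypeKey <- function(v, j, cdr3) paste(v, j, cdr3, sep = "|")

#' Track labelled clonotypes across one subject's samples
#'
#' Builds a matrix of log10 relative abundance for every labelled clonotype
#' found in at least one of the subject's repertoires (rows) across the
#' samples (columns, named `tissue.fraction`). Absence is encoded as -6,
#' the same convention as [burden()].
#'
#' @param reps list of [Repertoire-class] objects, all sharing one
#'   `subject_id` (>= 2 samples).
#' @param label class label (default `"CAIT"`).
#' @param rules classification rules.
#' @return numeric matrix, rows named `V|J|CDR3`, columns per sample.
#' @export
trackSubject <- function(reps, label = "CAIT", rules = defaultRules()) {
  if (length(reps) < 2L)
    stop("need at least 2 repertoires of the same subject")
  subjects <- vapply(reps, subjectID, character(1))
  if (length(unique(subjects)) != 1L)
    stop("all repertoires must belong to one subject; found: ",
         paste(unique(subjects), collapse = ", "))
  hits <- lapply(reps, function(rep) {
    cl <- clonotypes(rep)
    cl[classifyClonotypes(rep, rules) == label, , drop = FALSE]
  })
  keys <- sort(unique(unlist(lapply(hits, function(h)
    .clonotypeKey(h$v_gene, h$j_gene, h$cdr3_aa)))))
  cols <- make.unique(vapply(reps, function(r)
    paste(tissue(r), cellFraction(r), sep = "."), character(1)))
  m <- matrix(-6, nrow = length(keys), ncol = length(reps),
              dimnames = list(keys, cols))
  for (i in seq_along(reps)) {
    h <- hits[[i]]
    if (nrow(h))
      m[.clonotypeKey(h$v_gene, h$j_gene, h$cdr3_aa), i] <- log10(h$frequency)
  }
  m
}

#' Clonotype sharing network and publicity table
#'
#' One node per (sample, labelled clonotype) occurrence, carrying the
#' clonotype key, sample, subject, cohort and within-sample abundance;
#' nodes of the same subject are connected so each subject forms one
#' cluster. The publicity table counts, for every clonotype, the number of
#' distinct subjects carrying it (so multi-tissue subjects are not double
#' counted).
#'
#' @param reps list of [Repertoire-class] objects.
#' @param label class label (default `"CAIT"`).
#' @param rules classification rules.
#' @return list with elements `graph` (an [igraph::igraph] object) and
#'   `publicity` (data.frame `clonotype`, `n_subjects`).
#' @export
sharingNetwork <- function(reps, label = "CAIT", rules = defaultRules()) {
  rows <- data.table::rbindlist(lapply(reps, function(rep) {
    cl <- clonotypes(rep)
    hit <- cl[classifyClonotypes(rep, rules) == label, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(clonotype = .clonotypeKey(hit$v_gene, hit$j_gene, hit$cdr3_aa),
               sample_id = sampleID(rep), subject_id = subjectID(rep),
               cohort = cohort(rep), abundance = hit$frequency)
  }))
  if (!nrow(rows)) {
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                publicity = data.frame(clonotype = character(),
                                       n_subjects = integer())))
  }
  rows <- data.table::setDF(rows)
  g <- igraph::make_empty_graph(n = nrow(rows), directed = FALSE)
  igraph::V(g)$name      <- paste(rows$sample_id, rows$clonotype, sep = ":")
  igraph::V(g)$clonotype <- rows$clonotype
  igraph::V(g)$sample    <- rows$sample_id
  igraph::V(g)$subject   <- rows$subject_id
  igraph::V(g)$cohort    <- rows$cohort
  igraph::V(g)$size      <- rows$abundance
  # connect nodes within a subject so each subject forms one cluster
  for (idx in split(seq_len(nrow(rows)), rows$subject_id)) {
    if (length(idx) > 1L)
      g <- igraph::add_edges(g, as.vector(combn(idx, 2)))
  }
  pub <- data.table::as.data.table(rows)[, .(n_subjects = length(unique(subject_id))),
                                         by = clonotype]
  data.table::setorder(pub, -n_subjects, clonotype)
  list(graph = g, publicity = data.table::setDF(pub))
}

#' Count bulk individuals carrying given beta chains
#'
#' Exact-match presence counting of TRB chains (V gene, J gene, CDR3)
#' against bulk repertoire collections, at the subject level. Used to check
#' whether beta chains paired with semi-invariant alpha chains are private
#' to single individuals.
#'
#' @param beta_chains data.frame with columns `v_gene`, `j_gene`, `cdr3_aa`.
#' @param bulk_reps list of [Repertoire-class] objects (one or more
#'   collections, flattened).
#' @return the input data.frame plus `n_subjects`, the number of distinct
#'   bulk subjects carrying each chain.
#' @export
betaPrivacy <- function(beta_chains, bulk_reps) {
  keys <- .clonotypeKey(stripAllele(beta_chains$v_gene),
                        stripAllele(beta_chains$j_gene),
                        beta_chains$cdr3_aa)
  carriers <- lapply(bulk_reps, function(rep) {
    cl <- clonotypes(rep)
    cl <- cl[cl$chain == "TRB", , drop = FALSE]
    unique(.clonotypeKey(cl$v_gene, cl$j_gene, cl$cdr3_aa))
  })
  subjects <- vapply(bulk_reps, subjectID, character(1))
  counts <- vapply(keys, function(k) {
    length(unique(subjects[vapply(carriers, function(ck) k %in% ck, logical(1))]))
  }, integer(1))
  out <- beta_chains
  out$n_subjects <- unname(counts)
  out
}

#' Write a sharing network as GraphML
#'
#' @param network list returned by [sharingNetwork()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
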