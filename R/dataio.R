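# Readers/writers for the three input formats (association TSV, miRNA FASTA,
# disease-hierarchy edge TSV) and the two output formats (ranked-prediction
# CSV, evaluation-report JSON). All text is UTF-8; '#' comment lines and blank
# lines are ignored in the TSV readers.

#' Construct an association table
#'
#' An association table holds experimentally supported (miRNA, disease) pairs,
#' the positive examples for link prediction. Duplicate pairs are collapsed.
#'
#' @param mirna character vector of miRNA identifiers.
#' @param disease character vector of disease identifiers, same length.
#' @param source_tag short free-text label recording where the pairs came from.
#' @return A data.frame of class `mda_associations` with columns `mirna` and
#'   `disease` and attribute `source_tag`.
#' @export
association_table <- function(mirna, disease, source_tag = "user") {
  mirna <- as.character(mirna)
  disease <- as.character(disease)
  if (length(mirna) != length(disease)) {
    stop("`mirna` and `disease` must have the same length")
  }
  if (any(!nzchar(mirna)) || any(!nzchar(disease))) {
    stop("association ids must be non-empty strings")
  }
  key <- paste(mirna, disease, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(mirna = mirna[keep], disease = disease[keep],
                    stringsAsFactors = FALSE)
  attr(out, "source_tag") <- source_tag
  attr(out, "n_duplicates_dropped") <- sum(!keep)
  class(out) <- c("mda_associations", "data.frame")
  out
}

#' Read a miRNA-disease association table from a TSV file
#'
#' Each non-comment line must carry at least two tab- or whitespace-separated
#' fields: miRNA id, disease id. Duplicate pairs are collapsed and the number
#' dropped is reported via [message()] and stored as an attribute.
#'
#' @param path path to the TSV file.
#' @param exclude optional character vector of miRNA ids to drop (e.g. ids
#'   flagged as unreliable upstream); the number of pairs removed is logged.
#' @return An `mda_associations` table (see [association_table()]).
#' @export
read_associations <- function(path, exclude = NULL) {
  lines <- read_text_lines(path)
  if (nrow(lines) == 0L) {
    stop("association file is empty: ", path)
  }
  fields <- strsplit(lines$text, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed association line %d in %s: need >= 2 fields",
                 lines$lineno[bad[1L]], path))
  }
  mirna <- vapply(fields, `[[`, "", 1L)
  disease <- vapply(fields, `[[`, "", 2L)
  if (!is.null(exclude)) {
    drop <- mirna %in% exclude
    if (any(drop)) {
      message(sum(drop), " association(s) removed by miRNA exclusion list")
    }
    mirna <- mirna[!drop]
    disease <- disease[!drop]
    if (length(mirna) == 0L) stop("no associations left after exclusion")
  }
  out <- association_table(mirna, disease, source_tag = basename(path))
  ndup <- attr(out, "n_duplicates_dropped")
  if (ndup > 0L) message(ndup, " duplicate association(s) collapsed")
  out
}

#' Read miRNA sequences from a FASTA file
#'
#' The id is the header token up to the first whitespace. Sequences are
#' uppercased and DNA-style T is normalized to U; any character outside
#' A/C/G/U/T is an error naming the offending record, as are duplicate ids.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of RNA sequences (alphabet ACGU).
#' @export
read_mirna_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "AA") # raw characters, no translation
  ids <- vapply(recs, function(r) attr(r, "name"), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(vapply(recs, as.character, ""))
  names(seqs) <- ids
  bad <- grepl("[^ACGUT]", seqs)
  if (any(bad)) {
    stop("record '", ids[bad][1L], "' contains characters outside ACGUT")
  }
  if (any(!nzchar(seqs))) {
    stop("record '", ids[!nzchar(seqs)][1L], "' has an empty sequence")
  }
  chartr("T", "U", seqs)
}

#' Construct a disease hierarchy (rooted DAG)
#'
#' The hierarchy is given as child -> parent edges, MeSH-style. It must be
#' acyclic and free of self-edges; roots are the nodes with no parent.
#'
#' @param child,parent character vectors of equal length, one edge per entry.
#' @return An object of class `disease_dag`: list with `edges` (data.frame),
#'   `nodes` (sorted ids), `roots`, and `parents` (named list id -> parent ids).
#' @export
disease_dag <- function(child, parent) {
  child <- as.character(child)
  parent <- as.character(parent)
  if (length(child) != length(parent)) stop("child/parent length mismatch")
  if (length(child) == 0L) stop("hierarchy has no edges")
  if (any(child == parent)) {
    stop("self-edge on node '", child[child == parent][1L], "'")
  }
  edges <- unique(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE))
  nodes <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  if (!igraph::is_dag(g)) {
    stop("hierarchy contains a cycle: ", format_one_cycle(edges))
  }
  parents <- split(edges$parent, edges$child)
  roots <- setdiff(nodes, edges$child)
  structure(list(edges = edges, nodes = nodes, roots = sort(roots),
                 parents = parents),
            class = "disease_dag")
}

# Peel nodes that cannot lie on a cycle, then walk the remainder to print one.
format_one_cycle <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  repeat {
    live <- edges$child %in% nodes & edges$parent %in% nodes
    edges <- edges[live, , drop = FALSE]
    # a node never appearing as child (no outgoing child->parent edge) or
    # never as parent (no incoming) cannot be on a directed cycle
    keep <- nodes %in% edges$child & nodes %in% edges$parent
    if (all(keep)) break
    nodes <- nodes[keep]
    if (length(nodes) == 0L) return("<none>")
  }
  # every remaining node has an outgoing edge within the remainder: walk it
  start <- nodes[1L]
  path <- start
  cur <- start
  repeat {
    cur <- edges$parent[edges$child == cur][1L]
    if (cur %in% path) {
      cyc <- c(path[seq(match(cur, path), length(path))], cur)
      return(paste(cyc, collapse = " -> "))
    }
    path <- c(path, cur)
  }
}

#' Read a disease hierarchy from a child-parent TSV file
#'
#' @param path path to a two-column (child, parent) TSV.
#' @return A `disease_dag` object; see [disease_dag()].
#' @export
read_disease_dag <- function(path) {
  lines <- read_text_lines(path)
  if (nrow(lines) == 0L) stop("hierarchy file is empty: ", path)
  fields <- strsplit(lines$text, "[\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed hierarchy line %d in %s: need 2 fields",
                 lines$lineno[bad[1L]], path))
  }
  disease_dag(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("Disease hierarchy:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", length(x$roots), "root(s)\n")
  invisible(x)
}

#' @export
print.mda_associations <- function(x, ...) {
  cat("Association table:", nrow(x), "pairs,",
      length(unique(x$mirna)), "miRNAs,",
      length(unique(x$disease)), "diseases",
      sprintf("(source: %s)\n", attr(x, "source_tag")))
  NextMethod()
}

#' Write an association table as TSV
#' @param assoc an `mda_associations` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  write.table(assoc[, c("mirna", "disease")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Write a disease hierarchy as a child-parent TSV
#' @param dag a `disease_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_dag <- function(dag, path) {
  write.table(dag$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write ranked predictions as CSV
#'
#' Columns are (rank, mirna_id, disease_id, score); scores are non-increasing.
#'
#' @param ranked a `ranked_predictions` object from [rank_candidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_predictions"))
  n <- nrow(ranked$entries)
  df <- data.frame(rank = seq_len(n),
                   mirna_id = ranked$entries$mirna,
                   disease_id = rep(ranked$disease, n),
                   score = ranked$entries$score)
  if (n == 0L) {
    df <- data.frame(rank = integer(), mirna_id = character(),
                     disease_id = character(), score = numeric())
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ranked predictions back from CSV
#' @param path CSV written by [write_predictions()].
#' @return data.frame with rank, mirna_id, disease_id, score.
#' @export
read_predictions <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write an evaluation report as JSON
#'
#' Serializes per-fold scalar metrics plus the mean and standard deviation of
#' each indicator, and the run configuration used, mirroring the usual layout
#' of cross-validation result tables.
#'
#' @param report an `mdanet_cv` evaluation report.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mdanet_cv"))
  scalars <- c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr")
  per_fold <- lapply(report$per_fold, function(m) as.list(unclass(m)[scalars]))
  payload <- list(
    per_fold = per_fold,
    mean = as.list(report$mean[scalars]),
    sd = as.list(report$sd[scalars]),
    k = report$k,
    mode = report$mode,
    config = report$config,
    config_hash = report$config_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON path.
#' @return list with `per_fold`, `mean`, `sd`, `k`, `mode`, `config`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# -- internal helpers ---------------------------------------------------------

# Returns data.frame(text, lineno) of non-blank, non-comment lines.
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(raw)) & !grepl("^\\s*#", raw)
  out <- data.frame(text = trimws(raw[keep]), lineno = which(keep),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out[0, ])
  out
}

#' Build the deterministic node index of an attributed network
#'
#' miRNAs sorted lexicographically occupy positions 1..m, diseases sorted
#' lexicographically occupy m+1..m+d, so results never depend on input order.
#'
#' @param mirna_ids,disease_ids character vectors of ids (any order).
#' @return list with `mirnas`, `diseases` (sorted), `m`, `d`, and `nodes`
#'   (the concatenated index).
#' @export
node_index <- function(mirna_ids, disease_ids) {
  mirnas <- sort(unique(as.character(mirna_ids)))
  diseases <- sort(unique(as.character(disease_ids)))
  overlap <- intersect(mirnas, diseases)
  if (length(overlap) > 0L) {
    stop("id used both as miRNA and disease: ", overlap[1L])
  }
  list(mirnas = mirnas, diseases = diseases,
       m = length(mirnas), d = length(diseases),
       nodes = c(mirnas, diseases))
}

# Check association ids against the attribute-bearing universe; error by
# default, optionally drop pairs whose ids carry no attributes.
check_association_ids <- function(assoc, mirna_ids, disease_ids,
                                  allow_missing = FALSE) {
  ok <- assoc$mirna %in% mirna_ids & assoc$disease %in% disease_ids
  if (all(ok)) return(assoc)
  if (!allow_missing) {
    bad <- assoc[!ok, ][1L, ]
    stop("association (", bad$mirna, ", ", bad$disease,
         ") uses an id with no sequence/hierarchy attributes; ",
         "set allow_missing = TRUE to drop such pairs")
  }
  message(sum(!ok), " association(s) dropped: ids without attributes")
  out <- assoc[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no associations left after dropping")
  attr(out, "source_tag") <- attr(assoc, "source_tag")
  class(out) <- class(assoc)
  out
}
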