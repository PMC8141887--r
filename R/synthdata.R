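# Planted-partition generator: miRNAs and diseases are assigned to groups
# round-robin; associations are dense within groups and sparse across; each
# group shares a sequence motif; the disease hierarchy is a rooted tree whose
# subtrees are the groups. All randomness flows from one seed, split into
# per-component sub-streams so changing one field perturbs only its component.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a desk-scale miRNA-disease corpus: ~22-nt sequences, five
#' latent disease groups, within-group association probability far above the
#' cross-group one so that there is recoverable signal.
#'
#' @param n_mirnas,n_diseases numbers of miRNA and disease nodes.
#' @param n_groups number of planted groups; must not exceed
#'   `min(n_mirnas, n_diseases)`.
#' @param p_in,p_out association probability within / across groups;
#'   `0 <= p_out < p_in <= 1`.
#' @param seq_len sequence length in nucleotides.
#' @param motif_len length of the group motif implanted in each sequence.
#' @param mutation_rate per-base probability that an implanted motif base is
#'   replaced by a random base.
#' @param dag_branching arity of the disease hierarchy tree.
#' @param seed integer seed; fully determines the output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_mirnas = 200L, n_diseases = 100L, n_groups = 5L,
                         p_in = 0.3, p_out = 0.01, seq_len = 22L,
                         motif_len = 8L, mutation_rate = 0.1,
                         dag_branching = 3L, seed = 7L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_diseases = as.integer(n_diseases),
              n_groups = as.integer(n_groups),
              p_in = p_in, p_out = p_out,
              seq_len = as.integer(seq_len),
              motif_len = as.integer(motif_len),
              mutation_rate = mutation_rate,
              dag_branching = as.integer(dag_branching),
              seed = as.integer(seed))
  if (cfg$n_mirnas < 1L || cfg$n_diseases < 1L) stop("need >= 1 node per side")
  if (!(cfg$p_out >= 0 && cfg$p_out < cfg$p_in && cfg$p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (cfg$n_groups < 1L || cfg$n_groups > min(cfg$n_mirnas, cfg$n_diseases)) {
    stop("n_groups must be in [1, min(n_mirnas, n_diseases)]")
  }
  if (cfg$motif_len > cfg$seq_len) stop("motif_len must be <= seq_len")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (cfg$dag_branching < 2L) stop("dag_branching must be >= 2")
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a self-contained synthetic miRNA-disease dataset
#'
#' Produces the three pipeline inputs (association table, sequence set,
#' disease hierarchy) plus the planted group truth. Group structure is
#' expressed three ways so structure and attributes carry correlated signal:
#' associations are Bernoulli(`p_in`) within a group and Bernoulli(`p_out`)
#' across; each group's miRNAs share a mutated copy of a group motif; and the
#' hierarchy places each group's diseases under a private subtree, so
#' same-group diseases share a deeper ancestor than cross-group ones.
#'
#' @param cfg a [synth_config()].
#' @return list with `associations` (`mda_associations`), `sequences` (named
#'   character vector), `dag` (`disease_dag`), and `truth` (data.frame with
#'   id, type, group). Isolated node ids are attached to the association table
#'   as attribute `isolated`.
#' @export
simulate_mda_data <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L) # sequences, dag, edges

  width <- function(n) max(2L, nchar(as.character(n)))
  mirnas <- sprintf(paste0("mir-%0", width(cfg$n_mirnas), "d"),
                    seq_len(cfg$n_mirnas))
  diseases <- sprintf(paste0("disease-%0", width(cfg$n_diseases), "d"),
                      seq_len(cfg$n_diseases))
  m_group <- ((seq_len(cfg$n_mirnas) - 1L) %% cfg$n_groups) + 1L
  d_group <- ((seq_len(cfg$n_diseases) - 1L) %% cfg$n_groups) + 1L

  sequences <- synth_sequences(mirnas, m_group, cfg, sub[1L])
  dag <- synth_dag(diseases, d_group, cfg$dag_branching)
  assoc <- synth_associations(mirnas, diseases, m_group, d_group, cfg, sub[3L])

  truth <- data.frame(
    id = c(mirnas, diseases),
    type = rep(c("mirna", "disease"), c(cfg$n_mirnas, cfg$n_diseases)),
    group = c(m_group, d_group),
    stringsAsFactors = FALSE)

  list(associations = assoc, sequences = sequences, dag = dag, truth = truth)
}

synth_sequences <- function(mirnas, m_group, cfg, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "U")
  n_groups <- max(m_group)
  motifs <- replicate(n_groups,
                      paste(sample(bases, cfg$motif_len, replace = TRUE),
                            collapse = ""))
  seqs <- vapply(seq_along(mirnas), function(i) {
    s <- sample(bases, cfg$seq_len, replace = TRUE)
    motif <- strsplit(motifs[m_group[i]], "")[[1L]]
    mut <- runif(cfg$motif_len) < cfg$mutation_rate
    if (any(mut)) motif[mut] <- sample(bases, sum(mut), replace = TRUE)
    pos <- sample.int(cfg$seq_len - cfg$motif_len + 1L, 1L)
    s[pos:(pos + cfg$motif_len - 1L)] <- motif
    paste(s, collapse = "")
  }, "")
  names(seqs) <- mirnas
  seqs
}

# Deterministic rooted tree: each group's diseases are leaves of a private
# b-ary subtree; subtree roots hang under the global root.
synth_dag <- function(diseases, d_group, branching) {
  child <- character(0)
  parent <- character(0)
  for (g in sort(unique(d_group))) {
    level <- diseases[d_group == g]
    depth <- 0L
    while (length(level) > 1L) {
      depth <- depth + 1L
      chunks <- split(level, ceiling(seq_along(level) / branching))
      ups <- sprintf("grp%02d_l%d_%03d", g, depth, seq_along(chunks))
      for (k in seq_along(chunks)) {
        child <- c(child, chunks[[k]])
        parent <- c(parent, rep(ups[k], length(chunks[[k]])))
      }
      level <- ups
    }
    child <- c(child, level)
    parent <- c(parent, "ROOT")
  }
  disease_dag(child, parent)
}

synth_associations <- function(mirnas, diseases, m_group, d_group, cfg, seed) {
  set.seed(seed)
  same <- outer(m_group, d_group, `==`)
  prob <- ifelse(same, cfg$p_in, cfg$p_out)
  hit <- matrix(runif(length(prob)) < prob, nrow = length(mirnas))
  idx <- which(hit, arr.ind = TRUE)
  assoc <- association_table(mirnas[idx[, 1L]], diseases[idx[, 2L]],
                             source_tag = "synthetic")
  linked <- unique(c(assoc$mirna, assoc$disease))
  attr(assoc, "isolated") <- setdiff(c(mirnas, diseases), linked)
  attr(assoc, "within_group") <- same[idx]
  assoc
}

#' Write a synthetic dataset to a directory in the pipeline input formats
#'
#' @param data result of [simulate_mda_data()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Writes `associations.tsv`, `sequences.fasta`,
#'   `hierarchy.tsv` and `truth.csv`.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(data$associations, file.path(dir, "associations.tsv"))
  write_mirna_fasta(data$sequences, file.path(dir, "sequences.fasta"))
  write_disease_dag(data$dag, file.path(dir, "hierarchy.tsv"))
  write.csv(data$truth, file.path(dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}
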