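#' Read miRNA sequences from FASTA
#'
#' DNA-style thymine is normalised to uracil so miRBase-mixed conventions
#' compare cleanly.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("T", "U", seqs)
  stats::setNames(seqs, sub("\\s.*$", "", names(ss)))
}

#' Read a disease DAG forest from a TSV edge table
#'
#' Expected columns: `child`, `parent`, `root_disease`. Rows are grouped by
#' root disease; a row with an empty parent declares the bare node.
#'
#' @param path TSV file; `lambda` semantic contribution factor.
#' @return named list of [disease_dag()].
#' @export
read_dag_table <- function(path, lambda = 0.5) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("child", "parent", "root_disease")
  if (!all(need %in% names(df)))
    stop("DAG table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$root_disease), function(x) {
    root <- unique(x$root_disease)
    real <- x[nzchar(x$parent), , drop = FALSE]
    nodes <- unique(c(root, real$child, real$parent))
    edges <- if (nrow(real)) cbind(real$parent, real$child) else NULL
    disease_dag(root, nodes, edges, lambda = lambda)
  })
  out[order(names(out))]
}

#' Read a (signed) miRNA-disease association TSV
#'
#' Columns `mirna`, `disease` and optionally `k` (0 = up-, 1 =
#' down-regulation; missing column defaults to 0).
#'
#' @param path TSV file.
#' @export
read_association_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("mirna", "disease") %in% names(df)))
    stop("association table needs mirna/disease columns")
  df$k <- if ("k" %in% names(df)) as.integer(df$k) else 0L
  validate_association_table(df)
}

#' Persist / load a similarity matrix as TSV
#'
#' Header row and first column carry the entity ids.
#'
#' @param s similarity matrix with dimnames; `path` TSV file.
#' @export
write_similarity <- function(s, path) {
  df <- data.frame(id = rownames(s), s, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  check_similarity(m)
  m
}
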