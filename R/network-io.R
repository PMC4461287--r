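#' Signed directed regulatory network
#'
#' Container for a prior-knowledge network (PKN) or any of its subnetworks:
#' a set of gene identifiers plus signed directed edges. Gene identifiers are
#' opaque, case-sensitive strings (no symbol normalization). Self-loops are
#' permitted, and an activating and an inhibiting edge between the same pair
#' of genes may coexist (dual regulation). Duplicate (source, target, sign)
#' triples are collapsed.
#'
#' @param edges data.frame with columns `from`, `sign`, `to`; `sign` is `+1`
#'   for activation, `-1` for inhibition.
#' @param nodes optional character vector of node names; defaults to the union
#'   of edge endpoints. Extra isolated nodes may be listed here.
#' @return An object of class `signed_digraph`: a list with components
#'   `nodes` (sorted character vector) and `edges` (data.frame `from`, `sign`,
#'   `to`, deduplicated and sorted canonically).
#' @examples
#' net <- signed_digraph(data.frame(from = "A", sign = 1, to = "B"))
#' n_edges(net)
#' @export
signed_digraph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), sign = integer(), to = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "sign", "to") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      sign = as.integer(edges$sign),
                      to   = as.character(edges$to),
                      stringsAsFactors = FALSE)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 (activation) or -1 (inhibition)")
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  if (nrow(edges)) {
    edges <- edges[!duplicated(edge_keys_df(edges)), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

edge_keys_df <- function(edges) {
  if (!nrow(edges)) return(character())
  paste0(edges$from, "\t", ifelse(edges$sign > 0, "+", "-"), "\t", edges$to)
}

#' Canonical edge keys of a network
#'
#' One string per edge, `"source<TAB>sign<TAB>target"`, in canonical order.
#' Used for edge-set comparison, frequency bookkeeping and tie-breaking.
#' @param net a `signed_digraph`
#' @return character vector of edge keys
#' @export
edge_keys <- function(net) edge_keys_df(net$edges)

#' Number of edges in a network
#' @param net a `signed_digraph`
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

#' Stable identity hash of a network's edge set
#'
#' Concatenation of the sorted edge keys; two subnetworks of the same PKN are
#' equal iff their hashes are equal. Lexicographic order on hashes is the
#' deterministic last-resort tie-break in selection.
#' @param net a `signed_digraph`
#' @return single string
#' @export
net_hash <- function(net) paste(sort(edge_keys(net)), collapse = ";")

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("signed_digraph: %d nodes, %d edges (%d activating, %d inhibiting)\n",
              length(x$nodes), n_edges(x), sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

.effect_tokens <- c(
  "activate" = 1L, "+" = 1L, "1" = 1L,
  "inhibit" = -1L, "-" = -1L, "-1" = -1L
)

#' Read a signed network from a SIF-like TSV file
#'
#' Each non-comment line is `source<TAB>effect<TAB>target`, with effect one of
#' `activate`, `inhibit`, `+`, `-`, `1`, `-1` (case-insensitive). Lines
#' beginning with `#` and blank lines are ignored. Duplicate triples collapse
#' to one edge. UTF-8; Unix or Windows line endings.
#'
#' Exports of published supplementary interaction tables (one sheet per
#' network, source/effect/target columns) can be saved in this format from any
#' spreadsheet program.
#'
#' @param path file path
#' @return a [signed_digraph()]
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(signed_digraph())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 idx[bad[1]], path))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  eff <- .effect_tokens[tolower(trimws(m[, 2]))]
  if (anyNA(eff))
    stop(sprintf("unknown effect token '%s' on line %d in %s",
                 m[which(is.na(eff))[1], 2], idx[which(is.na(eff))[1]], path))
  signed_digraph(data.frame(from = trimws(m[, 1]), sign = unname(eff),
                            to = trimws(m[, 3]), stringsAsFactors = FALSE))
}

#' Write a signed network as SIF-like TSV
#'
#' Inverse of [read_network()]: `source<TAB>activate|inhibit<TAB>target`.
#' @param net a `signed_digraph`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  lines <- paste0(net$edges$from, "\t",
                  ifelse(net$edges$sign > 0, "activate", "inhibit"), "\t",
                  net$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' Booleanized phenotype set
#'
#' Ordered collection of named Boolean state vectors over a shared gene
#' universe: the training data for contextualization. Each column is one
#' stable phenotype; each row one gene, with 1 = active/up-regulated and
#' 0 = inactive/down-regulated.
#'
#' @param states 0/1 matrix, genes in rows (rownames required), phenotypes in
#'   columns (colnames required).
#' @return object of class `phenotype_set`
#' @export
phenotype_set <- function(states) {
  states <- as.matrix(states)
  if (is.null(colnames(states)) || (nrow(states) > 0 && is.null(rownames(states))))
    stop("phenotype matrix needs gene rownames and phenotype colnames")
  if (nrow(states) == 0 && is.null(rownames(states))) rownames(states) <- character()
  if (anyDuplicated(rownames(states))) stop("duplicate gene in phenotype set")
  if (!all(states %in% c(0, 1))) stop("phenotype states must be 0 or 1")
  storage.mode(states) <- "integer"
  structure(list(states = states), class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d genes x %d phenotypes (%s)\n",
              nrow(x$states), ncol(x$states),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Genes covered by a phenotype set
#' @param ps a `phenotype_set`
#' @return character vector of gene names
#' @export
ph_genes <- function(ps) rownames(ps$states)

#' Number of phenotypes in a set
#' @param ps a `phenotype_set`
#' @return integer
#' @export
n_phenotypes <- function(ps) ncol(ps$states)

#' Extract one phenotype as a named 0/1 vector
#' @param ps a `phenotype_set`
#' @param which column index or phenotype name
#' @return named integer vector over the set's genes
#' @export
get_phenotype <- function(ps, which) {
  v <- ps$states[, which]
  stats::setNames(as.integer(v), rownames(ps$states))
}

#' Read a Booleanized phenotype table
#'
#' TSV with header `gene<TAB>name1<TAB>name2...`; one phenotype per state
#' column, in column order; cells strictly 0 or 1.
#' @param path file path
#' @return a [phenotype_set()]
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("phenotype table needs a gene column plus >= 1 state column")
  if (anyDuplicated(tab[[1]])) stop("duplicate gene row in ", path)
  st <- as.matrix(tab[, -1, drop = FALSE])
  if (!all(st %in% c("0", "1")))
    stop("non-Boolean cell in phenotype table ", path, " (states must be 0/1)")
  m <- matrix(as.integer(st), nrow = nrow(st),
              dimnames = list(tab[[1]], colnames(st)))
  phenotype_set(m)
}

#' Write a phenotype set as TSV
#' @param ps a `phenotype_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(ps, path) {
  tab <- data.frame(gene = rownames(ps$states), ps$states,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an initial/final phenotype pair from a differential gene list
#'
#' Converts a two-condition comparison into two Booleanized phenotypes:
#' up-regulated genes are 0 in the initial condition and 1 in the final one;
#' down-regulated genes the opposite. The two phenotypes are therefore bitwise
#' complements over the listed genes.
#'
#' @param up_genes character vector of up-regulated genes
#' @param down_genes character vector of down-regulated genes
#' @return a [phenotype_set()] with phenotypes `initial` and `final`
#' @export
booleanize_differential <- function(up_genes, down_genes) {
  up_genes <- as.character(up_genes); down_genes <- as.character(down_genes)
  overlap <- intersect(up_genes, down_genes)
  if (length(overlap))
    stop("gene(s) in both up and down lists: ", paste(overlap, collapse = ", "))
  genes <- c(up_genes, down_genes)
  ini <- c(rep(0L, length(up_genes)), rep(1L, length(down_genes)))
  m <- cbind(initial = ini, final = 1L - ini)
  rownames(m) <- genes
  phenotype_set(m)
}
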