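# Over-representation analysis of miRNA target genes against user-supplied
# pathway collections (GMT). One hypergeometric engine covers any collection
# (GO, KEGG, Reactome, ... are just different GMT inputs).

#' Read a two-column miRNA-to-gene target map
#'
#' TSV with columns `mirna_id`, `gene` (validated interactions). Gene symbols
#' are uppercased; miRNAs with no genes are dropped.
#'
#' @param path TSV path
#' @return named list: miRNA id -> character vector of unique gene symbols
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene") %in% names(df)))
    stop("target map must contain columns: mirna_id, gene")
  df <- df[!is.na(df$gene) & nzchar(df$gene), , drop = FALSE]
  sp <- split(toupper(df$gene), df$mirna_id)
  lapply(sp, unique)
}

#' Read GMT pathway gene sets
#'
#' Thin wrapper over [fgsea::gmtPathways()] with gene symbols uppercased.
#'
#' @param path GMT file path
#' @return named list of gene vectors
#' @export
read_gmt <- function(path) {
  lapply(fgsea::gmtPathways(path), function(g) unique(toupper(g)))
}

#' Union of target genes over a set of miRNAs
#'
#' @param mirnas miRNA ids (e.g. the significant set from a comparison)
#' @param target_map named list from [read_target_map()]
#' @return list: `genes` (character union), `unmapped` (miRNAs absent from
#'   the map, also reported via `message`)
#' @export
map_targets <- function(mirnas, target_map) {
  unmapped <- setdiff(mirnas, names(target_map))
  if (length(unmapped))
    message(length(unmapped), " miRNA(s) absent from the target map: ",
            paste(utils::head(unmapped, 10), collapse = ", "))
  genes <- sort(unique(unlist(target_map[intersect(mirnas,
                                                   names(target_map))])))
  list(genes = genes, unmapped = unmapped)
}

#' Hypergeometric over-representation test
#'
#' For each pathway, tests whether the query gene set overlaps it more than
#' expected by chance within the universe: with N universe genes, K pathway
#' genes, n query genes and k overlapping, p = P(X >= k) for
#' X ~ Hypergeometric(N, K, n). Pathways are intersected with the universe
#' first (empty ones are skipped); p-values are BH-adjusted across the
#' pathways actually tested. By default the universe is the set of genes
#' reachable by the assay's target map, not all pathway genes.
#'
#' @param query character vector of query genes (must be within `universe`)
#' @param pathways named list of gene vectors (e.g. [read_gmt()])
#' @param universe character vector of background genes
#' @return data.frame sorted by `fdr` then `p_value`: `pathway`, `k`, `K`,
#'   `n`, `N`, `p_value`, `fdr`
#' @export
ora_test <- function(query, pathways, universe) {
  universe <- unique(universe)
  query <- unique(query)
  out_of_universe <- setdiff(query, universe)
  if (length(out_of_universe))
    stop(length(out_of_universe), " query gene(s) outside the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    K <- length(pw)
    if (K == 0) return(NULL)
    k <- length(intersect(query, pw))
    # upper tail P(X >= k); phyper is P(X <= q), so q = k - 1, upper tail
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$fdr, res$p_value), , drop = FALSE]
}
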