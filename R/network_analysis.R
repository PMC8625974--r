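#' Typed ceRNA gene network
#'
#' Builds the undirected lncRNA/miRNA/mRNA graph from a triplet table.
#' Every triplet contributes a sponge edge (lncRNA-miRNA) and a target edge
#' (miRNA-mRNA); duplicate edges are collapsed. The triplet table is kept
#' inside the object because subnetwork extraction is triplet-based.
#'
#' @param triplets data.frame with columns `lnc_id`, `mirna_id`, `mrna_id`.
#' @return list of class `gene_network` with `nodes` (id, type), `edges`
#'   (from, to, kind) and `triplets`.
#' @export
gene_network <- function(triplets) {
  need <- c("lnc_id", "mirna_id", "mrna_id")
  miss <- setdiff(need, names(triplets))
  if (length(miss))
    stop("triplet table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  triplets <- as.data.frame(triplets)[, need]
  triplets[] <- lapply(triplets, as.character)
  ids <- c(triplets$lnc_id, triplets$mirna_id, triplets$mrna_id)
  types <- rep(c("lncRNA", "miRNA", "mRNA"), each = nrow(triplets))
  keep <- !duplicated(ids)
  clash <- tapply(types, ids, function(t) length(unique(t)) > 1L)
  if (any(clash))
    stop("id(s) used with more than one node class: ",
         paste(names(clash)[clash], collapse = ", "), call. = FALSE)
  nodes <- data.frame(id = ids[keep], type = types[keep],
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- rbind(
    data.frame(from = triplets$lnc_id, to = triplets$mirna_id,
               kind = rep("sponge", nrow(triplets)), stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               kind = rep("target", nrow(triplets)), stringsAsFactors = FALSE))
  if (nrow(edges) && any(edges$from == edges$to))
    stop("self-loop edge(s) in triplet table", call. = FALSE)
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  edges <- edges[order(edges$kind, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(triplets) <- NULL
  structure(list(nodes = nodes, edges = edges, triplets = triplets),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes (%s), %d edges, %d triplets\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$type)[unique(x$nodes$type)],
                            unique(x$nodes$type)), collapse = ", "),
              nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' Connectivity degree of every node
#'
#' Degree = number of distinct incident edges in the union graph of sponge
#' and target edges (not triplet multiplicity). Satisfies the handshake
#' lemma: the degrees sum to twice the edge count.
#'
#' @param net a [gene_network()].
#' @return named integer vector, one entry per node.
#' @export
node_degrees <- function(net) {
  if (!nrow(net$nodes)) return(stats::setNames(integer(0), character(0)))
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$id))
  stats::setNames(as.integer(deg), names(deg))
}

#' Hub lncRNAs by connectivity degree
#'
#' lncRNA nodes ranked by degree (descending), ties broken lexicographically
#' by id; the first `top_k` are the hubs. If fewer lncRNAs exist, all are
#' returned with a warning.
#'
#' @param net a [gene_network()].
#' @param top_k number of hubs (default 5).
#' @return character vector of lncRNA ids, best first.
#' @export
hub_lncrnas <- function(net, top_k = 5L) {
  lncs <- net$nodes$id[net$nodes$type == "lncRNA"]
  deg <- node_degrees(net)[lncs]
  ord <- order(-deg, lncs)
  ranked <- lncs[ord]
  if (length(ranked) < top_k) {
    warning(sprintf("only %d lncRNA node(s) available (top_k = %d)",
                    length(ranked), top_k))
    return(ranked)
  }
  ranked[seq_len(top_k)]
}

#' Extract a triplet-based subnetwork
#'
#' `hub_triplets` keeps every triplet whose lncRNA is in `seed_nodes`;
#' `mirna_filter` keeps every triplet whose miRNA is in `seed_nodes`.
#'
#' @param net a [gene_network()].
#' @param seed_nodes character vector of node ids present in the network.
#' @param mode `"hub_triplets"` or `"mirna_filter"`.
#' @return a [gene_network()].
#' @export
extract_subnetwork <- function(net, seed_nodes,
                               mode = c("hub_triplets", "mirna_filter")) {
  mode <- match.arg(mode)
  miss <- setdiff(seed_nodes, net$nodes$id)
  if (length(miss))
    stop("seed node(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- if (mode == "hub_triplets") net$triplets$lnc_id %in% seed_nodes
          else net$triplets$mirna_id %in% seed_nodes
  gene_network(net$triplets[keep, , drop = FALSE])
}

#' Hypergeometric over-representation of annotation sets
#'
#' For each set: k = |query in set|, K = |set in universe|, n = |query|,
#' N = |universe|; p from [hypergeom_sf()], BH-adjusted across sets,
#' sorted by p (ties by set id).
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param annotation named list of character vectors ([read_annotation_sets()]).
#' @param universe character vector of background gene ids.
#' @return data.frame `set_id`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
enrich_sets <- function(query, annotation, universe) {
  universe <- unique(universe)
  query <- unique(query)
  out_of <- setdiff(query, universe)
  if (length(out_of))
    stop("query gene(s) outside universe: ", paste(out_of, collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation), function(id) {
    members <- intersect(unique(annotation[[id]]), universe)
    k <- length(intersect(query, members))
    data.frame(set_id = id, k = k, K = length(members), n = n, N = N,
               p = hypergeom_sf(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
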