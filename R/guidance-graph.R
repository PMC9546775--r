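#' Genomic feature table
#'
#' Builds a validated table of genomic features in BED-style 0-based,
#' half-open coordinates. GTF-derived genes (1-based, inclusive) must be
#' converted on read; [read_gtf_genes()] does this.
#'
#' @param id Character vector of unique feature identifiers.
#' @param chrom Chromosome names.
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @param strand One of `"+"`, `"-"`, `"."` per feature.
#' @param kind Feature kind, e.g. `"gene"`, `"peak"`, `"methylation-site"`.
#' @return A `data.frame` with class `"genomic_features"`.
#' @export
genomic_features <- function(id, chrom, start, end, strand = ".",
                             kind = "other") {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(id)),
                   kind = rep_len(as.character(kind), length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("genomic_features: duplicated feature ids")
  if (any(df$start >= df$end))
    stop("genomic_features: malformed intervals (need start < end)")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("genomic_features: strand must be '+', '-' or '.'")
  class(df) <- c("genomic_features", "data.frame")
  df
}

#' Power-law genomic distance weight
#'
#' Chromatin-contact-probability-style weight `(d + 1)^-0.75` for a genomic
#' distance `d` in kilobases. Equals 1 at `d = 0` and decreases
#' monotonically.
#'
#' @param d Non-negative genomic distance(s) in kb.
#' @param exponent Positive decay exponent (default 0.75).
#' @return Weights in (0, 1].
#' @examples
#' power_law_weight(c(0, 1, 150))
#' @export
power_law_weight <- function(d, exponent = 0.75) {
  if (any(d < 0)) stop("power_law_weight: distance must be non-negative")
  (d + 1)^(-exponent)
}

#' Guidance graph over multi-omics feature spaces
#'
#' A signed, weighted multigraph whose vertices are the features of all
#' omics layers and whose edges encode prior regulatory interactions.
#' Every vertex carries a positive self-loop of weight 1 (added here if
#' absent); weights must lie in (0, 1] and signs in \{-1, +1\}. Parallel
#' edges between the same pair are allowed when they carry distinct
#' evidence tags.
#'
#' @param vertices Character vector of vertex ids, or a data.frame with
#'   columns `id` and optionally `layer`.
#' @param edges Data.frame with columns `i`, `j` (vertex ids), `sign`,
#'   `weight` and optionally `tag` (default `"prior"`). Undirected;
#'   self-loops need not be listed.
#' @return An object of class `"guidance_graph"` with elements `vertices`
#'   (data.frame: id, layer) and `edges` (data.frame: i, j, sign, weight,
#'   tag; includes the self-loops).
#' @export
guidance_graph <- function(vertices, edges = NULL) {
  if (is.data.frame(vertices)) {
    vdf <- data.frame(id = as.character(vertices$id),
                      layer = if ("layer" %in% names(vertices))
                        as.character(vertices$layer) else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    vdf <- data.frame(id = as.character(vertices), layer = NA_character_,
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(vdf$id)) stop("guidance_graph: duplicated vertex ids")
  if (is.null(edges) || nrow(edges) == 0) {
    edf <- data.frame(i = character(), j = character(), sign = numeric(),
                      weight = numeric(), tag = character(),
                      stringsAsFactors = FALSE)
  } else {
    edf <- data.frame(i = as.character(edges$i), j = as.character(edges$j),
                      sign = as.numeric(edges$sign),
                      weight = as.numeric(edges$weight),
                      tag = if ("tag" %in% names(edges))
                        as.character(edges$tag) else "prior",
                      stringsAsFactors = FALSE)
  }
  bad <- setdiff(c(edf$i, edf$j), vdf$id)
  if (length(bad)) stop("guidance_graph: edges reference unknown vertices: ",
                        paste(head(bad, 5), collapse = ", "))
  if (nrow(edf) && (any(edf$weight <= 0) || any(edf$weight > 1)))
    stop("guidance_graph: edge weights must lie in (0, 1]")
  if (nrow(edf) && !all(edf$sign %in% c(-1, 1)))
    stop("guidance_graph: edge signs must be -1 or +1")
  # drop caller-provided self-loops, then add the canonical ones
  edf <- edf[edf$i != edf$j, , drop = FALSE]
  loops <- data.frame(i = vdf$id, j = vdf$id, sign = 1, weight = 1,
                      tag = "self-loop", stringsAsFactors = FALSE)
  g <- list(vertices = vdf, edges = rbind(edf, loops))
  rownames(g$edges) <- NULL
  class(g) <- "guidance_graph"
  g
}

#' @export
print.guidance_graph <- function(x, ...) {
  ns <- sum(x$edges$i == x$edges$j)
  cat("Guidance graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges) - ns, "edges (+", ns, "self-loops)\n")
  if (!all(is.na(x$vertices$layer))) {
    tab <- table(x$vertices$layer, useNA = "ifany")
    cat("  vertex layers:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# non-self-loop edges
cross_edges <- function(g) g$edges[g$edges$i != g$edges$j, , drop = FALSE]

# Strand-aware promoter interval: `upstream` bp ahead of the TSS.
promoter_intervals <- function(genes, upstream = 2000) {
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$end, pmax(0L, genes$start - upstream))
  end <- ifelse(minus, genes$end + upstream, genes$start)
  # a 0-length promoter (gene starting at coordinate 0 on '+') stays valid
  end <- pmax(end, start)
  data.frame(id = genes$id, chrom = genes$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

# All overlapping pairs between two half-open interval sets (same chrom).
# Returns indices into a and b. Quadratic per chromosome; fine at the
# feature counts this package targets.
interval_overlap_pairs <- function(a, b) {
  out_a <- integer(0); out_b <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    if (!length(ia) || !length(ib)) next
    hit <- outer(a$start[ia], b$end[ib], `<`) &
      outer(a$end[ia], b$start[ib], `>`)
    w <- which(hit, arr.ind = TRUE)
    out_a <- c(out_a, ia[w[, 1]]); out_b <- c(out_b, ib[w[, 2]])
  }
  list(a = out_a, b = out_b)
}

# Gap in bp between half-open intervals (0 when overlapping or touching).
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(pmax(b_start - a_end, a_start - b_end), 0)
}

#' Overlap-based guidance graph between genes and peaks
#'
#' Connects each peak to every gene whose gene body or proximal promoter
#' (strand-aware `promoter_upstream_bp` upstream of the TSS) it overlaps,
#' with a positive edge of weight 1. Intervals are half-open, so touching
#' intervals do not overlap.
#'
#' @param genes,peaks [genomic_features()] tables; gene strands must be
#'   known for the promoter definition.
#' @param promoter_upstream_bp Promoter length upstream of the TSS (bp).
#' @return A [guidance_graph()] whose vertices are all genes and peaks
#'   (vertex layers `"gene"` / `"peak"`).
#' @export
build_overlap_graph <- function(genes, peaks, promoter_upstream_bp = 2000) {
  stopifnot(is.data.frame(genes), is.data.frame(peaks))
  prom <- promoter_intervals(genes, promoter_upstream_bp)
  ext <- data.frame(id = genes$id, chrom = genes$chrom,
                    start = pmin(genes$start, prom$start),
                    end = pmax(genes$end, prom$end))
  hits <- interval_overlap_pairs(peaks, ext)
  edges <- if (length(hits$a)) {
    unique(data.frame(i = peaks$id[hits$a], j = genes$id[hits$b],
                      sign = 1, weight = 1, tag = "overlap",
                      stringsAsFactors = FALSE))
  } else NULL
  vertices <- data.frame(id = c(genes$id, peaks$id),
                         layer = rep(c("gene", "peak"),
                                     c(nrow(genes), nrow(peaks))))
  guidance_graph(vertices, edges)
}

#' Window-based guidance graph with power-law distance weights
#'
#' Connects each peak to every gene whose proximal promoter lies within
#' `window_kb` of the peak, weighting the positive edge by
#' [power_law_weight()] of the closest-gap distance in kb (weight 1 when
#' peak and promoter overlap).
#'
#' @inheritParams build_overlap_graph
#' @param window_kb Maximum peak-to-promoter distance in kb.
#' @param decay_exponent Power-law decay exponent.
#' @return A [guidance_graph()].
#' @export
build_window_graph <- function(genes, peaks, window_kb = 150,
                               decay_exponent = 0.75,
                               promoter_upstream_bp = 2000) {
  prom <- promoter_intervals(genes, promoter_upstream_bp)
  edges <- NULL
  rows_i <- character(0); rows_j <- character(0); rows_w <- numeric(0)
  for (ch in intersect(unique(prom$chrom), unique(peaks$chrom))) {
    ig <- which(prom$chrom == ch); ip <- which(peaks$chrom == ch)
    gap <- interval_gap(
      outer(peaks$start[ip], rep(1, length(ig))),
      outer(peaks$end[ip], rep(1, length(ig))),
      outer(rep(1, length(ip)), prom$start[ig]),
      outer(rep(1, length(ip)), prom$end[ig]))
    d_kb <- gap / 1000
    w <- which(d_kb <= window_kb, arr.ind = TRUE)
    if (nrow(w)) {
      rows_i <- c(rows_i, peaks$id[ip[w[, 1]]])
      rows_j <- c(rows_j, prom$id[ig[w[, 2]]])
      rows_w <- c(rows_w, power_law_weight(d_kb[w], decay_exponent))
    }
  }
  if (length(rows_i))
    edges <- data.frame(i = rows_i, j = rows_j, sign = 1, weight = rows_w,
                        tag = "window", stringsAsFactors = FALSE)
  vertices <- data.frame(id = c(genes$id, peaks$id),
                         layer = rep(c("gene", "peak"),
                                     c(nrow(genes), nrow(peaks))))
  guidance_graph(vertices, edges)
}

#' Add evidence edges to a guidance graph
#'
#' Composes a base graph with additional evidence edge lists (e.g. pcHi-C
#' contacts, eQTL associations) into a multigraph: evidence edges keep
#' their own tags, and duplicate pairs under the same tag have their
#' weights summed and clipped to 1.
#'
#' @param base A [guidance_graph()].
#' @param evidence Data.frame with columns `i`, `j`, `weight`, `tag` and
#'   optionally `sign` (default +1).
#' @return A [guidance_graph()] multigraph.
#' @export
compose_evidence_graph <- function(base, evidence) {
  stopifnot(inherits(base, "guidance_graph"))
  if (is.null(evidence) || nrow(evidence) == 0) return(base)
  if (any(evidence$weight <= 0))
    stop("compose_evidence_graph: evidence weights must be positive")
  ev <- data.frame(i = as.character(evidence$i),
                   j = as.character(evidence$j),
                   sign = if ("sign" %in% names(evidence))
                     as.numeric(evidence$sign) else 1,
                   weight = as.numeric(evidence$weight),
                   tag = as.character(evidence$tag),
                   stringsAsFactors = FALSE)
  # canonical unordered pair key, then sum + clip per (pair, tag, sign)
  key <- paste(pmin(ev$i, ev$j), pmax(ev$i, ev$j), ev$tag, ev$sign)
  agg <- lapply(split(seq_len(nrow(ev)), key), function(idx) {
    r <- ev[idx[1], , drop = FALSE]
    r$weight <- min(1, sum(ev$weight[idx]))
    r
  })
  ev <- do.call(rbind, agg)
  vertices <- base$vertices
  new_v <- setdiff(c(ev$i, ev$j), vertices$id)
  if (length(new_v))
    vertices <- rbind(vertices, data.frame(id = new_v, layer = NA_character_))
  guidance_graph(vertices, rbind(cross_edges(base), ev))
}

#' Corrupt a guidance graph by edge replacement
#'
#' Removes a fraction of the non-self-loop edges uniformly at random and
#' replaces them with the same number of previously absent cross-layer
#' edges (sign +1, weight set to the median removed weight), preserving
#' the total edge count. Used for robustness experiments on the prior.
#'
#' @param g A [guidance_graph()] whose vertices carry layer labels.
#' @param rate Fraction of edges to replace, in \[0, 1\].
#' @param seed Integer seed; the corruption is deterministic given it.
#' @return A corrupted [guidance_graph()].
#' @export
corrupt_graph <- function(g, rate, seed = 1) {
  stopifnot(inherits(g, "guidance_graph"))
  if (rate < 0 || rate > 1) stop("corrupt_graph: rate must lie in [0, 1]")
  ce <- cross_edges(g)
  n_remove <- floor(rate * nrow(ce))
  if (n_remove == 0) return(g)
  if (all(is.na(g$vertices$layer)))
    stop("corrupt_graph: vertex layer labels are required")
  with_seed(seed, {
    rem <- sample.int(nrow(ce), n_remove)
    kept <- ce[-rem, , drop = FALSE]
    w_new <- median(ce$weight[rem])
    # sample absent cross-layer pairs
    existing <- unique(paste(pmin(ce$i, ce$j), pmax(ce$i, ce$j)))
    layers <- split(g$vertices$id, g$vertices$layer)
    if (length(layers) < 2)
      stop("corrupt_graph: need at least two vertex layers")
    pairs_i <- character(0); pairs_j <- character(0)
    got <- character(0)
    guard <- 0
    while (length(pairs_i) < n_remove && guard < 1000) {
      need <- n_remove - length(pairs_i)
      kl <- sample.int(length(layers), 2 * need, replace = TRUE)
      k2 <- vapply(kl, function(k) {
        others <- setdiff(seq_along(layers), k)
        if (length(others) == 1L) others else sample(others, 1)
      }, 1L)
      pick <- function(ids) ids[sample.int(length(ids), 1)]
      a <- vapply(kl, function(k) pick(layers[[k]]), "")
      b <- vapply(k2, function(k) pick(layers[[k]]), "")
      key <- paste(pmin(a, b), pmax(a, b))
      ok <- !(key %in% existing) & !(key %in% got) & !duplicated(key)
      take <- which(ok)[seq_len(min(need, sum(ok)))]
      pairs_i <- c(pairs_i, a[take]); pairs_j <- c(pairs_j, b[take])
      got <- c(got, key[take])
      guard <- guard + 1
    }
    if (length(pairs_i) < n_remove)
      stop("corrupt_graph: not enough absent cross-layer pairs to sample")
    added <- data.frame(i = pairs_i, j = pairs_j, sign = 1, weight = w_new,
                        tag = "corruption", stringsAsFactors = FALSE)
    guidance_graph(g$vertices, rbind(kept, added))
  })
}

#' Validate a guidance graph against its invariants
#'
#' Checks weight/sign ranges, self-loop presence, and (optionally) reports
#' layer features that have no cross-layer edge — these remain trainable
#' but receive no guidance.
#'
#' @param g A [guidance_graph()].
#' @param layers Optional list of [omics_layer()] objects whose features
#'   are checked for coverage.
#' @param error If `TRUE` (default), violations raise an error naming the
#'   offending edges; otherwise they are returned.
#' @return Invisibly, a list with `violations` (character) and
#'   `unguided` (feature ids without cross-layer edges).
#' @export
validate_graph <- function(g, layers = NULL, error = TRUE) {
  stopifnot(inherits(g, "guidance_graph"))
  e <- g$edges
  viol <- character(0)
  bad_w <- which(e$weight <= 0 | e$weight > 1)
  if (length(bad_w))
    viol <- c(viol, paste0("weight out of (0,1] on edge ", e$i[bad_w],
                           "--", e$j[bad_w]))
  bad_s <- which(!(e$sign %in% c(-1, 1)))
  if (length(bad_s))
    viol <- c(viol, paste0("sign not in {-1,+1} on edge ", e$i[bad_s],
                           "--", e$j[bad_s]))
  loops <- e$i[e$i == e$j]
  no_loop <- setdiff(g$vertices$id, loops)
  if (length(no_loop))
    viol <- c(viol, paste0("vertex without self-loop: ", no_loop))
  unguided <- character(0)
  if (!is.null(layers)) {
    ce <- cross_edges(g)
    linked <- unique(c(ce$i, ce$j))
    for (ly in layers)
      unguided <- c(unguided, setdiff(ly$features, linked))
  }
  if (length(viol) && error)
    stop("validate_graph: ", paste(head(viol, 10), collapse = "; "))
  invisible(list(violations = viol, unguided = unguided))
}

# Collapse the multigraph to a simple undirected graph for training:
# keep the maximum-weight edge per (unordered pair, sign).
collapse_graph <- function(g) {
  e <- g$edges
  key <- paste(pmin(e$i, e$j), pmax(e$i, e$j), e$sign)
  keep <- unlist(lapply(split(seq_len(nrow(e)), key), function(idx)
    idx[which.max(e$weight[idx])]), use.names = FALSE)
  e <- e[sort(keep), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# Signed, symmetrically normalised adjacency for the graph encoder.
# Parallel edges are summed then clipped to |a_ij| <= 1; normalisation by
# sqrt of total absolute incident weight on each side.
graph_adjacency <- function(g) {
  v <- g$vertices$id
  idx <- stats::setNames(seq_along(v), v)
  e <- g$edges
  ii <- idx[e$i]; jj <- idx[e$j]
  a <- Matrix::sparseMatrix(i = c(ii, jj[ii != jj]), j = c(jj, ii[ii != jj]),
                            x = c(e$sign * e$weight,
                                  (e$sign * e$weight)[ii != jj]),
                            dims = c(length(v), length(v)))
  a@x <- pmin(pmax(a@x, -1), 1)
  d <- Matrix::rowSums(abs(a))
  d[d == 0] <- 1
  s <- Matrix::Diagonal(x = 1 / sqrt(d))
  as(s %*% a %*% s, "generalMatrix")
}

#' Write / read a guidance graph as GraphML
#'
#' Serialises the multigraph with `weight`, `sign` and `tag` edge
#' attributes and a `layer` vertex attribute; the round-trip is lossless.
#'
#' @param g A [guidance_graph()].
#' @param path Output (input) file path.
#' @return `read_graphml` returns a [guidance_graph()].
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "guidance_graph"))
  e <- g$edges
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$weight, sign = e$sign,
               tag = e$tag),
    directed = FALSE,
    vertices = data.frame(name = g$vertices$id,
                          layer = ifelse(is.na(g$vertices$layer), "",
                                         g$vertices$layer)))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(ig, what = "edges")
  vd <- igraph::as_data_frame(ig, what = "vertices")
  layer <- if ("layer" %in% names(vd))
    ifelse(vd$layer == "", NA_character_, vd$layer) else NA_character_
  guidance_graph(
    data.frame(id = vd$name, layer = layer),
    data.frame(i = ed$from, j = ed$to, sign = ed$sign, weight = ed$weight,
               tag = ed$tag))
}
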