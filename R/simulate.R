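# Synthetic multi-omics generator with full ground truth. Emulates the
# generative assumptions of the integration model: a shared
# low-dimensional cell-state manifold sampled by several layers with
# distinct feature spaces, a planted bipartite regulatory graph with
# signed edges, NB counts with log-normal library sizes, ZILN
# methylation levels, optional batch effects and composition imbalance,
# and known ground-truth cell pairing.

#' Simulation configuration
#'
#' Defaults describe a two-layer RNA + ATAC design of moderate size with
#' five cell types and a planted peak--gene regulatory graph; a third
#' methylation (ZILN) layer is added when `n_methyl > 0`.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type Cells per type per layer; a vector (one entry
#'   per type) or a single number. All layers share the same cells
#'   (known pairing); use [make_unbalanced()] for composition imbalance.
#' @param n_genes,n_peaks,n_methyl Feature counts per layer (methylation
#'   features are gene-linked sites; 0 disables the third layer).
#' @param m_true Latent dimension of the true cell states.
#' @param edge_density Fraction of peaks (and methylation sites) carrying
#'   a planted regulatory link to a gene.
#' @param negative_frac Fraction of planted methylation edges; peak
#'   edges are positive, methylation edges negative (repressive).
#' @param decoy_frac Decoy (false) edges added to the guidance graph, as
#'   a fraction of the planted edge count.
#' @param type_sep Standard deviation of the type centroids (larger =
#'   better separated types).
#' @param state_noise Within-type cell-state noise standard deviation.
#' @param loading_noise Noise added to linked peak/methyl loadings
#'   relative to their gene loading.
#' @param nb_disp_range Range of the NB inverse dispersion per feature.
#' @param lib_meanlog,lib_sdlog Log-normal library size parameters
#'   (RNA; ATAC uses `lib_meanlog_atac`).
#' @param lib_meanlog_atac ATAC library size meanlog.
#' @param ziln_sigma_range,ziln_delta_range Ranges of the ZILN log-scale
#'   standard deviation and zero-inflation probability.
#' @param n_batches,batch_scale Number of batches per layer and the
#'   standard deviation of batch-specific logit offsets (0 = none).
#' @param centroids Optional explicit type-centroid matrix
#'   (`n_types` x `m_true`); drawn at random when `NULL`.
#' @param seed Integer seed; everything is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_types = 5, cells_per_type = 100, n_genes = 200,
                       n_peaks = 300, n_methyl = 0, m_true = 10,
                       edge_density = 0.8, negative_frac = 1,
                       decoy_frac = 0.5, type_sep = 1.2,
                       state_noise = 0.35, loading_noise = 0.35,
                       nb_disp_range = c(2, 8),
                       lib_meanlog = 8.5, lib_sdlog = 0.35,
                       lib_meanlog_atac = 8,
                       ziln_sigma_range = c(0.3, 0.6),
                       ziln_delta_range = c(0.2, 0.5),
                       n_batches = 1, batch_scale = 0, centroids = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_types >= 1, all(cells_per_type > 0), n_genes > 0,
            n_peaks > 0, m_true >= 2, edge_density > 0, edge_density <= 1,
            n_batches >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Draw NB counts row-wise: rates from softmax logits, scaled by library.
draw_nb_counts <- function(logits, libs, disp) {
  P <- softmax_rows(logits)
  mu <- P * libs
  cnt <- matrix(rnbinom(length(mu), size = rep(disp, each = nrow(mu)),
                        mu = as.vector(mu)), nrow(mu))
  cnt
}

#' Simulate a multi-layer single-cell dataset with ground truth
#'
#' Draws type centroids in `m_true` dimensions, cell states around them,
#' gene loadings at random, and peak / methylation loadings tied to
#' their planted partner gene's loading (negated for repressive
#' methylation edges). NB layers get counts from softmax rates times
#' log-normal library sizes; the methylation layer gets ZILN levels.
#' The guidance graph contains the planted edges plus decoys, and every
#' feature receives genomic coordinates consistent with the planted
#' links so that window-based graph construction can rediscover them.
#'
#' @param config A [sim_config()].
#' @return List with `layers` (named list of [omics_layer()]), `graph`
#'   (the [guidance_graph()] with planted + decoy edges), and `truth`
#'   (cell states, type/batch labels, loadings, planted and decoy edge
#'   tables, features with coordinates, and the cross-layer pairing).
#' @export
simulate_multiomics <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    cpt <- rep_len(cfg$cells_per_type, cfg$n_types)
    n_cells <- sum(cpt)
    types <- rep(seq_len(cfg$n_types), cpt)
    centroids <- cfg$centroids %||%
      matrix(rnorm(cfg$n_types * cfg$m_true, sd = cfg$type_sep),
             cfg$n_types)
    stopifnot(nrow(centroids) == cfg$n_types,
              ncol(centroids) == cfg$m_true)
    states <- centroids[types, , drop = FALSE] +
      matrix(rnorm(n_cells * cfg$m_true, sd = cfg$state_noise), n_cells)
    rownames(states) <- sprintf("cell%04d", seq_len(n_cells))

    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    peak_ids <- sprintf("peak%04d", seq_len(cfg$n_peaks))
    gene_load <- matrix(rnorm(cfg$n_genes * cfg$m_true), cfg$n_genes)
    rownames(gene_load) <- gene_ids

    # planted peak->gene links (positive regulation)
    n_link_p <- round(cfg$edge_density * cfg$n_peaks)
    linked_peaks <- sort(sample.int(cfg$n_peaks, n_link_p))
    peak_gene <- sample.int(cfg$n_genes, n_link_p, replace = TRUE)
    peak_load <- matrix(rnorm(cfg$n_peaks * cfg$m_true), cfg$n_peaks)
    peak_load[linked_peaks, ] <- gene_load[peak_gene, , drop = FALSE] +
      matrix(rnorm(n_link_p * cfg$m_true, sd = cfg$loading_noise), n_link_p)
    rownames(peak_load) <- peak_ids
    planted <- data.frame(i = peak_ids[linked_peaks],
                          j = gene_ids[peak_gene], sign = 1,
                          stringsAsFactors = FALSE)

    # methylation layer: gene-linked sites with negative (repressive) links
    met_ids <- character(0); met_load <- NULL
    if (cfg$n_methyl > 0) {
      met_ids <- sprintf("methyl%04d", seq_len(cfg$n_methyl))
      n_link_m <- round(cfg$edge_density * cfg$n_methyl)
      linked_met <- sort(sample.int(cfg$n_methyl, n_link_m))
      met_gene <- sample.int(cfg$n_genes, n_link_m, replace = TRUE)
      neg <- runif(n_link_m) < cfg$negative_frac
      met_load <- matrix(rnorm(cfg$n_methyl * cfg$m_true), cfg$n_methyl)
      met_load[linked_met, ] <-
        sweep(gene_load[met_gene, , drop = FALSE], 1,
              ifelse(neg, -1, 1), `*`) +
        matrix(rnorm(n_link_m * cfg$m_true, sd = cfg$loading_noise),
               n_link_m)
      rownames(met_load) <- met_ids
      planted <- rbind(planted,
                       data.frame(i = met_ids[linked_met],
                                  j = gene_ids[met_gene],
                                  sign = ifelse(neg, -1, 1)))
    }

    # batch structure shared across layers
    batches <- sample.int(cfg$n_batches, n_cells, replace = TRUE)

    make_nb_layer <- function(load, ids, name, meanlog) {
      logits <- tcrossprod(states, load)
      if (cfg$batch_scale > 0) {
        off <- matrix(rnorm(cfg$n_batches * length(ids),
                            sd = cfg$batch_scale), cfg$n_batches)
        logits <- logits + off[batches, , drop = FALSE]
      }
      libs <- rlnorm(n_cells, meanlog, cfg$lib_sdlog)
      disp <- runif(length(ids), cfg$nb_disp_range[1], cfg$nb_disp_range[2])
      cnt <- draw_nb_counts(logits, libs, disp)
      colnames(cnt) <- ids
      rownames(cnt) <- rownames(states)
      omics_layer(cnt, features = ids, family = "NB", name = name,
                  batches = batches)
    }
    layers <- list(rna = make_nb_layer(gene_load, gene_ids, "rna",
                                       cfg$lib_meanlog),
                   atac = make_nb_layer(peak_load, peak_ids, "atac",
                                        cfg$lib_meanlog_atac))
    if (cfg$n_methyl > 0) {
      muz <- tcrossprod(states, met_load) * 0.25
      if (cfg$batch_scale > 0) {
        off <- matrix(rnorm(cfg$n_batches * cfg$n_methyl,
                            sd = cfg$batch_scale), cfg$n_batches)
        muz <- muz + off[batches, , drop = FALSE]
      }
      sig <- runif(cfg$n_methyl, cfg$ziln_sigma_range[1],
                   cfg$ziln_sigma_range[2])
      del <- runif(cfg$n_methyl, cfg$ziln_delta_range[1],
                   cfg$ziln_delta_range[2])
      lev <- exp(muz + matrix(rnorm(n_cells * cfg$n_methyl), n_cells) %*%
                   diag(sig, cfg$n_methyl))
      zero <- matrix(runif(n_cells * cfg$n_methyl), n_cells) <
        rep(del, each = n_cells)
      lev[zero] <- 0
      colnames(lev) <- met_ids
      rownames(lev) <- rownames(states)
      layers$methyl <- omics_layer(lev, features = met_ids,
                                   family = "ZILN", name = "methyl",
                                   batches = batches)
    }

    # genomic coordinates consistent with the planted links: genes laid
    # out on a chromosome; linked peaks placed near their gene's TSS
    gene_start <- seq(100000, by = 200000, length.out = cfg$n_genes)
    features <- genomic_features(
      id = gene_ids, chrom = "chr1", start = gene_start,
      end = gene_start + 20000, strand = "+", kind = "gene")
    peak_start <- integer(cfg$n_peaks)
    peak_start[linked_peaks] <- gene_start[peak_gene] +
      sample(c(-30000:-5000, 1000:15000), n_link_p, replace = TRUE)
    unlinked <- setdiff(seq_len(cfg$n_peaks), linked_peaks)
    # decoys dropped into gene deserts beyond the gene array
    peak_start[unlinked] <- max(gene_start) + 5e6 +
      sample.int(5e6, length(unlinked))
    peak_feat <- genomic_features(
      id = peak_ids, chrom = "chr1", start = peak_start,
      end = peak_start + 500, strand = ".", kind = "peak")
    features <- rbind(features, peak_feat)

    # guidance graph: planted edges plus decoy edges over unlinked pairs
    n_decoy <- round(cfg$decoy_frac * nrow(planted))
    planted_key <- paste(planted$i, planted$j)
    all_src <- c(peak_ids, met_ids)
    decoys <- data.frame(i = character(0), j = character(0),
                         sign = numeric(0))
    guard <- 0
    while (nrow(decoys) < n_decoy && guard < 50) {
      need <- n_decoy - nrow(decoys)
      di <- sample(all_src, 2 * need, replace = TRUE)
      dj <- sample(gene_ids, 2 * need, replace = TRUE)
      key <- paste(di, dj)
      ok <- !(key %in% planted_key) & !duplicated(key) &
        !(key %in% paste(decoys$i, decoys$j))
      take <- which(ok)[seq_len(min(need, sum(ok)))]
      decoys <- rbind(decoys, data.frame(i = di[take], j = dj[take],
                                         sign = 1))
      guard <- guard + 1
    }
    vertices <- data.frame(
      id = c(gene_ids, peak_ids, met_ids),
      layer = c(rep("rna", cfg$n_genes), rep("atac", cfg$n_peaks),
                rep("methyl", length(met_ids))))
    edges <- rbind(
      data.frame(i = planted$i, j = planted$j, sign = planted$sign,
                 weight = 1, tag = "planted"),
      if (nrow(decoys)) data.frame(i = decoys$i, j = decoys$j,
                                   sign = decoys$sign, weight = 1,
                                   tag = "decoy"))
    graph <- guidance_graph(vertices, edges)

    truth <- list(states = states, types = types, batches = batches,
                  gene_loadings = gene_load, peak_loadings = peak_load,
                  methyl_loadings = met_load,
                  planted_edges = planted, decoy_edges = decoys,
                  features = features,
                  pairing = stats::setNames(seq_len(n_cells),
                                            rownames(states)))
    list(layers = layers, graph = graph, truth = truth)
  })
}

#' Impose unbalanced cell-type compositions
#'
#' Removes a stated fraction of each type's cells from each layer
#' (independently sampled), pruning the ground-truth pairing
#' accordingly. Used to exercise the balanced adversarial alignment.
#'
#' @param sim Output of [simulate_multiomics()].
#' @param drop Named list: for each layer name, a numeric vector of
#'   per-type drop fractions in \[0, 1\] (recycled over types).
#' @param seed Integer seed.
#' @return The modified simulation (layers subsetted, truth carrying
#'   per-layer `kept` index vectors; `pairing` reduced to cells
#'   surviving in all layers).
#' @export
make_unbalanced <- function(sim, drop, seed = 1) {
  stopifnot(is.list(drop))
  with_seed(seed, {
    kept <- list()
    for (nm in names(sim$layers)) {
      fr <- rep_len(drop[[nm]] %||% 0, max(sim$truth$types))
      if (any(fr < 0 | fr > 1))
        stop("make_unbalanced: drop fractions must lie in [0, 1]")
      keep <- unlist(lapply(seq_along(fr), function(ty) {
        idx <- which(sim$truth$types == ty)
        n_drop <- round(fr[ty] * length(idx))
        if (n_drop == 0) idx else sort(sample(idx, length(idx) - n_drop))
      }))
      keep <- sort(keep)
      if (length(keep) == 0)
        stop("make_unbalanced: dropping emptied layer '", nm, "'")
      ly <- sim$layers[[nm]]
      ly$X <- ly$X[keep, , drop = FALSE]
      ly$batches <- ly$batches[keep]
      ly$reduced <- NULL; ly$reduction <- NULL
      sim$layers[[nm]] <- ly
      kept[[nm]] <- keep
    }
    sim$truth$kept <- kept
    common <- Reduce(intersect, kept)
    sim$truth$pairing <- sim$truth$pairing[common]
    sim
  })
}

#' A pair of datasets with no shared cell states
#'
#' Generates two simulations representing inconsistent "tissues": the
#' second dataset's type centroids are drawn inside the orthogonal
#' complement of the first dataset's centroid span, so every
#' cross-dataset centroid cosine similarity is essentially zero (always
#' below 0.3). Used to exercise the over-integration diagnostic.
#'
#' @param configA,configB Two [sim_config()]s (seeds may coincide; the
#'   second is internally offset). Requires
#'   `m_true > n_types` of `configA` so the complement is non-trivial.
#' @return List with `simA`, `simB`.
#' @export
mismatched_pair <- function(configA = sim_config(),
                            configB = sim_config()) {
  if (identical(configA$seed, configB$seed))
    configB$seed <- child_seed(configB$seed, 999)
  simA <- simulate_multiomics(configA)
  centA <- rowsum(simA$truth$states, simA$truth$types) /
    as.vector(table(simA$truth$types))
  qa <- qr(t(centA))
  rk <- qa$rank
  if (rk >= configA$m_true)
    stop("mismatched_pair: need m_true > n_types to host disjoint states")
  Qfull <- qr.Q(qa, complete = TRUE)
  Qc <- Qfull[, (rk + 1):configA$m_true, drop = FALSE] # complement basis
  configB$centroids <- with_seed(child_seed(configB$seed, 5), {
    R <- matrix(rnorm(configB$n_types * ncol(Qc), sd = configB$type_sep),
                configB$n_types)
    R %*% t(Qc) * sqrt(configB$m_true / ncol(Qc))
  })
  simB <- simulate_multiomics(configB)
  centB <- rowsum(simB$truth$states, simB$truth$types) /
    as.vector(table(simB$truth$types))
  cs <- tcrossprod(l2_normalize_rows(centA), l2_normalize_rows(centB))
  if (max(abs(cs)) >= 0.3)
    stop("mismatched_pair: residual centroid similarity too high")
  list(simA = simA, simB = simB)
}
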