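#' Default bone-marrow lineage tree for the synthetic scenario
#'
#' Fifteen cell types arranged as a rooted tree: the hematopoietic branches
#' (erythroid, megakaryocyte, granulocyte, monocyte, basophil, B and T
#' lymphoid) radiate from an HSPC root, and the vascular niche types
#' (endothelial cells, pericytes) hang off the root as a separate branch so
#' the graph stays connected. Megakaryocytes and endothelial cells are, in
#' the default scenario, exclusive to the source species; immature B cells
#' exclusive to the target species.
#'
#' @return A `lineage_tree`.
#' @export
bone_marrow_tree <- function() {
  edges <- rbind(
    c("HSPC", "Erythroblast"),
    c("HSPC", "Megakaryocyte"),
    c("HSPC", "Myeloblast"),
    c("Myeloblast", "Myelocyte"),
    c("Myelocyte", "Neutrophil"),
    c("HSPC", "Monoblast"),
    c("Monoblast", "Monocyte"),
    c("HSPC", "Basophil"),
    c("HSPC", "ProB"),
    c("ProB", "PreB"),
    c("PreB", "ImmatureB"),
    c("HSPC", "Tlymphocyte"),
    c("HSPC", "Endothelial"),
    c("Endothelial", "Pericyte")
  )
  lineage_tree(unique(c(edges)), edges)
}

#' Simulation configuration for a paired two-species dataset
#'
#' Defines the generative model: every cell type carries a program of
#' class-defining genes with high expression probability, inherited along the
#' lineage tree with per-edge mutation (so adjacent types share more program
#' genes than distant ones); all other genes fire at a low background
#' probability drawn from a baseline prior whose mean is `base_expr_prob`.
#' Pre-binarization counts are zero-truncated negative binomial, so the
#' probability that a gene is detected at all in a cell of class k is exactly
#' the class's per-gene probability while count magnitudes remain
#' overdispersed and class/gene specific.
#'
#' Cross-species divergence: for a fraction `divergence[k]` of genes the
#' target-species probability is resampled from the baseline prior, erasing
#' any program membership of those genes in the target. Within-class
#' heterogeneity: with probability `heterogeneity[k]` a cell is drawn from
#' the profile of the class's tree neighbour (parent, or first child for the
#' root) instead of its own — a two-component mixture emulating, e.g., the
#' heterogeneous HSPC pool.
#'
#' @param n_genes Number of orthologous genes simulated.
#' @param classes Character vector of class names (must be nodes of `tree`).
#' @param tree A `lineage_tree` covering `classes`.
#' @param abundance_source,abundance_target Named abundance vectors over the
#'   classes present in each species; each sums to 1.
#' @param exclusive_source,exclusive_target Classes present in only one
#'   species.
#' @param base_expr_prob Mean background (non-program) expression
#'   probability; controls sparsity.
#' @param program_size Number of class-defining genes per class.
#' @param program_mutation Fraction of program genes replaced along each tree
#'   edge.
#' @param divergence Named per-class fraction of genes whose target-species
#'   probability is resampled (0 = fully conserved).
#' @param heterogeneity Named per-class mixture weight of the neighbour
#'   component.
#' @param ambiguous_fraction Fraction of ortholog pairs given an extra
#'   one-to-many entry in the ortholog table.
#' @param n_cells_source,n_cells_target Cells per species.
#' @param count_mean Mean scale of expressed (non-zero) counts.
#' @param count_dispersion Negative binomial size parameter.
#' @param seed Integer seed; one seed drives reproducible per-species
#'   substreams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       classes,
                       tree,
                       abundance_source,
                       abundance_target,
                       exclusive_source = character(0),
                       exclusive_target = character(0),
                       base_expr_prob = 0.031,
                       program_size = 40,
                       program_mutation = 0.3,
                       divergence = stats::setNames(rep(0, length(classes)), classes),
                       heterogeneity = stats::setNames(rep(0, length(classes)), classes),
                       ambiguous_fraction = 0.05,
                       n_cells_source = 3000,
                       n_cells_target = 2000,
                       count_mean = 2,
                       count_dispersion = 1,
                       seed = 1L) {
  stopifnot(inherits(tree, "lineage_tree"))
  classes <- as.character(classes)
  if (!all(classes %in% tree$nodes)) {
    stop("configuration error: tree does not cover all classes: ",
         paste(setdiff(classes, tree$nodes), collapse = ", "))
  }
  src_classes <- setdiff(classes, exclusive_target)
  tgt_classes <- setdiff(classes, exclusive_source)
  check_abund <- function(ab, present, what) {
    if (!all(sort(names(ab)) == sort(present))) {
      stop("configuration error: ", what,
           " abundance must name exactly the present classes")
    }
    if (abs(sum(ab) - 1) > 1e-9) {
      stop("configuration error: ", what, " abundances must sum to 1")
    }
    if (any(ab <= 0)) stop("configuration error: ", what, " abundances must be > 0")
  }
  check_abund(abundance_source, src_classes, "source")
  check_abund(abundance_target, tgt_classes, "target")
  fill_named <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- stats::setNames(rep(x, length(classes)), classes)
      else if (length(x) == length(classes)) names(x) <- classes
      else stop(what, " must be named by class")
    }
    out <- stats::setNames(rep(0, length(classes)), classes)
    out[names(x)] <- x
    if (any(out < 0 | out > 1)) stop(what, " must lie in [0, 1]")
    out
  }
  divergence <- fill_named(divergence, "divergence")
  heterogeneity <- fill_named(heterogeneity, "heterogeneity")
  stopifnot(n_genes >= 1, program_size >= 1, program_size <= n_genes,
            base_expr_prob > 0, base_expr_prob < 1,
            program_mutation >= 0, program_mutation <= 1,
            ambiguous_fraction >= 0, ambiguous_fraction < 1,
            n_cells_source >= 1, n_cells_target >= 1,
            count_mean > 0, count_dispersion > 0)
  structure(list(
    n_genes = as.integer(n_genes), classes = classes, tree = tree,
    abundance_source = abundance_source, abundance_target = abundance_target,
    exclusive_source = exclusive_source, exclusive_target = exclusive_target,
    base_expr_prob = base_expr_prob, program_size = as.integer(program_size),
    program_mutation = program_mutation, divergence = divergence,
    heterogeneity = heterogeneity, ambiguous_fraction = ambiguous_fraction,
    n_cells_source = as.integer(n_cells_source),
    n_cells_target = as.integer(n_cells_target),
    count_mean = count_mean, count_dispersion = count_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default paired-species scenario
#'
#' Fourteen source classes (two of them source-exclusive: megakaryocytes and
#' endothelial cells), thirteen target classes including a target-exclusive
#' immature-B-like type, imbalanced abundances with a rare HSPC root, mild
#' divergence for most types, strong divergence for the B-lymphoid branch,
#' and heterogeneity plus divergence for HSPCs and monoblasts. These defaults
#' reproduce the qualitative structure the analysis assumes: conserved
#' homogeneous types, conserved heterogeneous types, divergent homogeneous
#' types, and divergent heterogeneous types.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, ...) {
  tree <- bone_marrow_tree()
  ab_src <- c(Erythroblast = 0.22, Neutrophil = 0.14, Myelocyte = 0.12,
              Monocyte = 0.10, Myeloblast = 0.08, Monoblast = 0.07,
              ProB = 0.06, PreB = 0.06, Tlymphocyte = 0.05, Basophil = 0.02,
              Megakaryocyte = 0.02, Pericyte = 0.02, Endothelial = 0.02,
              HSPC = 0.02)
  ab_tgt <- c(Erythroblast = 0.20, Neutrophil = 0.14, Myelocyte = 0.12,
              Monocyte = 0.10, Myeloblast = 0.08, Monoblast = 0.07,
              ProB = 0.06, PreB = 0.06, ImmatureB = 0.06, Tlymphocyte = 0.05,
              Basophil = 0.02, Pericyte = 0.02, HSPC = 0.02)
  divergence <- c(Erythroblast = 0.02, Tlymphocyte = 0.02, Neutrophil = 0.05,
                  Myelocyte = 0.05, Myeloblast = 0.05, Monocyte = 0.05,
                  Basophil = 0.05, Pericyte = 0.05, Megakaryocyte = 0.05,
                  Endothelial = 0.05, ProB = 0.45, PreB = 0.45,
                  ImmatureB = 0.50, Monoblast = 0.45, HSPC = 0.35)
  heterogeneity <- c(HSPC = 0.35, Monoblast = 0.30, Myelocyte = 0.15)
  args <- list(classes = tree$nodes, tree = tree,
               abundance_source = ab_src, abundance_target = ab_tgt,
               exclusive_source = c("Megakaryocyte", "Endothelial"),
               exclusive_target = "ImmatureB",
               divergence = divergence, heterogeneity = heterogeneity,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Engineered four-group validation scenario
#'
#' A five-class scenario (a root plus four leaves) constructed so that each
#' leaf realizes one of the four learning-curve archetypes: `Conserved` —
#' fully conserved and homogeneous (high initial F1, no improvement);
#' `ConsHet` — conserved but strongly heterogeneous (moderate initial
#' deficit that re-training cannot remove); `DivHom` — strongly divergent
#' but homogeneous (low initial F1, large improvement on re-training);
#' `DivHet` — divergent and dominated by a root-like mixture component (low
#' initial F1 that barely improves).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
four_group_config <- function(seed = 1L, ...) {
  edges <- rbind(c("Root", "Conserved"), c("Root", "ConsHet"),
                 c("Root", "DivHom"), c("Root", "DivHet"))
  tree <- lineage_tree(unique(c(edges)), edges)
  ab <- c(Root = 0.2, Conserved = 0.2, ConsHet = 0.2, DivHom = 0.2,
          DivHet = 0.2)
  args <- list(n_genes = 600, classes = tree$nodes, tree = tree,
               abundance_source = ab, abundance_target = ab,
               program_mutation = 1,
               divergence = c(DivHom = 1, DivHet = 1),
               heterogeneity = c(ConsHet = 0.3, DivHet = 0.95),
               ambiguous_fraction = 0,
               n_cells_source = 1500, n_cells_target = 1500,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

#' Calibrate the background expression probability to a target sparsity
#'
#' Solves, in expectation, for the baseline-prior mean that makes the
#' realized fraction of zero entries in the binarized matrix equal
#' `target_zero_fraction`: with a program fraction f and mean program
#' probability p_prog, expected expressed fraction is
#' (1-f)·base + f·p_prog.
#'
#' @param config A `sim_config`.
#' @param target_zero_fraction Desired zero fraction, e.g. 0.94.
#' @return The config with `base_expr_prob` replaced.
#' @export
calibrate_sparsity <- function(config, target_zero_fraction) {
  stopifnot(inherits(config, "sim_config"),
            target_zero_fraction > 0, target_zero_fraction < 1)
  f <- config$program_size / config$n_genes
  p_prog <- mean(c(0.55, 0.95))  # mean of the program-probability prior
  base <- ((1 - target_zero_fraction) - f * p_prog) / (1 - f)
  if (base <= 0 || base >= 1) {
    stop("target sparsity unreachable with ", config$program_size,
         " program genes of ", config$n_genes)
  }
  config$base_expr_prob <- base
  config
}

# Draw background probabilities from the baseline prior (mean = base).
rbaseline <- function(n, base, shape1 = 2) {
  stats::rbeta(n, shape1, shape1 * (1 - base) / base)
}

# Build per-class gene programs by inheritance along the tree and the
# per-class probability matrix for one species.
build_truth <- function(config) {
  G <- config$n_genes
  tree <- config$tree
  classes <- config$classes
  root <- setdiff(tree$nodes, tree$edges[, "child"])
  programs <- vector("list", length(classes))
  names(programs) <- classes
  programs[[root]] <- sample.int(G, config$program_size)
  # breadth-first inheritance
  queue <- root
  while (length(queue)) {
    parent <- queue[1]; queue <- queue[-1]
    children <- tree$edges[tree$edges[, "parent"] == parent, "child"]
    for (ch in children) {
      prog <- programs[[parent]]
      pool <- setdiff(seq_len(G), prog)
      n_mut <- min(round(config$program_mutation * length(prog)), length(pool))
      if (n_mut > 0) {
        drop <- sample(seq_along(prog), n_mut)
        fresh <- sample(pool, n_mut)
        prog <- c(prog[-drop], fresh)
      }
      programs[[ch]] <- prog
      queue <- c(queue, ch)
    }
  }
  p <- matrix(rbaseline(length(classes) * G, config$base_expr_prob),
              nrow = length(classes), dimnames = list(classes, NULL))
  for (k in classes) {
    p[k, programs[[k]]] <- stats::runif(config$program_size, 0.55, 0.95)
  }
  list(p = p, programs = programs)
}

# Mixing partner for the heterogeneity component: parent, or first child for
# the root.
mix_partner <- function(tree, class) {
  parent <- tree$edges[tree$edges[, "child"] == class, "parent"]
  if (length(parent)) return(parent[1])
  tree$edges[tree$edges[, "parent"] == class, "child"][1]
}

# Sample a cells x genes count matrix for one species.
# p: classes x genes probability matrix (pure component profiles).
sample_species <- function(p, config, present, abundance, n_cells) {
  G <- config$n_genes
  counts_per_class <- stats::rmultinom(1, n_cells, abundance[present])[, 1]
  if (any(counts_per_class == 0)) {
    stop("configuration error: zero cells drawn for present class(es): ",
         paste(present[counts_per_class == 0], collapse = ", "),
         " (increase n_cells)")
  }
  labels <- rep(present, counts_per_class)
  size <- config$count_dispersion
  mat <- matrix(0L, nrow = n_cells, ncol = G)
  row0 <- 0L
  for (k in present) {
    nk <- counts_per_class[[k]]
    h <- config$heterogeneity[[k]]
    comp <- if (h > 0) {
      stats::runif(nk) < h
    } else rep(FALSE, nk)
    partner <- if (any(comp)) mix_partner(config$tree, k)
    for (component in unique(comp)) {
      rows <- which(comp == component)
      pv <- if (component) p[partner, ] else p[k, ]
      n_r <- length(rows)
      expressed <- matrix(stats::runif(n_r * G) < rep(pv, each = n_r),
                          nrow = n_r)
      idx <- which(expressed)
      if (length(idx)) {
        gene <- ((idx - 1L) %/% n_r) + 1L
        # zero-truncated NB: mean scales with the gene's detection prob
        mu <- config$count_mean * (0.5 + pv[gene])
        p0 <- stats::dnbinom(0, size = size, mu = mu)
        u <- stats::runif(length(idx), min = p0, max = 1)
        cnt <- stats::qnbinom(u, size = size, mu = mu)
        block <- matrix(0L, nrow = n_r, ncol = G)
        block[idx] <- as.integer(pmax(cnt, 1L))
        mat[row0 + rows, ] <- block
      }
    }
    row0 <- row0 + nk
  }
  list(counts = mat, labels = labels)
}

#' Generate a paired two-species synthetic dataset
#'
#' Draws source- and target-species cell x gene count matrices with class
#' labels, the lineage tree, an ortholog table (with a configurable fraction
#' of ambiguous entries), and the generating truth (per-class expected
#' detection-probability profiles and the program gene sets). The same seed
#' yields bit-identical output; source and target use independent RNG
#' substreams derived from it.
#'
#' @param config A `sim_config`.
#' @return An object of class `synthetic_pair` with elements `source`,
#'   `target` (each: `counts` cells x genes, `labels`, `gene_names`,
#'   `barcodes`), `tree`, `orthologs` (data.frame source_gene, target_gene)
#'   and `truth` (`p_source`, `p_target` expected profiles in `[0,1]`,
#'   `programs`).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  G <- config$n_genes
  src_classes <- setdiff(config$classes, config$exclusive_target)
  tgt_classes <- setdiff(config$classes, config$exclusive_source)

  set.seed(sub_seeds[1])
  truth <- build_truth(config)
  p_src <- truth$p

  # target profiles: conserved copy, then per-class resampling of a
  # `divergence[k]` fraction of genes from the baseline prior
  p_tgt <- p_src
  for (k in config$classes) {
    dv <- config$divergence[[k]]
    if (dv > 0) {
      n_dv <- round(dv * G)
      sel <- sample.int(G, n_dv)
      p_tgt[k, sel] <- rbaseline(n_dv, config$base_expr_prob)
    }
  }

  set.seed(sub_seeds[2])
  src <- sample_species(p_src, config, src_classes,
                        config$abundance_source, config$n_cells_source)
  set.seed(sub_seeds[3])
  tgt <- sample_species(p_tgt, config, tgt_classes,
                        config$abundance_target, config$n_cells_target)

  src_genes <- sprintf("mGene%04d", seq_len(G))
  tgt_genes <- sprintf("hGENE%04d", seq_len(G))
  dimnames(src$counts) <- list(sprintf("mCELL%05d", seq_len(nrow(src$counts))),
                               src_genes)
  dimnames(tgt$counts) <- list(sprintf("hCELL%05d", seq_len(nrow(tgt$counts))),
                               tgt_genes)

  set.seed(sub_seeds[4])
  orth <- data.frame(source_gene = src_genes, target_gene = tgt_genes,
                     stringsAsFactors = FALSE)
  n_amb <- round(config$ambiguous_fraction * G)
  if (n_amb > 0) {
    amb <- sample.int(G, n_amb)
    half <- amb[seq_len(ceiling(n_amb / 2))]
    rest <- setdiff(amb, half)
    extra <- rbind(
      data.frame(source_gene = src_genes[half],
                 target_gene = sprintf("hGENEx%04d", half),
                 stringsAsFactors = FALSE),
      data.frame(source_gene = sprintf("mGenex%04d", rest),
                 target_gene = tgt_genes[rest],
                 stringsAsFactors = FALSE)
    )
    orth <- rbind(orth, extra)
  }

  # expected (mixture) profiles define the truth matrices
  expected_profile <- function(p, present) {
    out <- p[present, , drop = FALSE]
    for (k in present) {
      h <- config$heterogeneity[[k]]
      if (h > 0) out[k, ] <- (1 - h) * p[k, ] + h * p[mix_partner(config$tree, k), ]
    }
    out
  }

  structure(list(
    source = list(counts = src$counts, labels = src$labels,
                  gene_names = src_genes,
                  barcodes = rownames(src$counts), species = "source"),
    target = list(counts = tgt$counts, labels = tgt$labels,
                  gene_names = tgt_genes,
                  barcodes = rownames(tgt$counts), species = "target"),
    tree = config$tree,
    orthologs = orth,
    truth = list(p_source = expected_profile(p_src, src_classes),
                 p_target = expected_profile(p_tgt, tgt_classes),
                 programs = truth$programs,
                 gene_names_source = src_genes,
                 gene_names_target = tgt_genes),
    config = config
  ), class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("synthetic_pair: %d source cells, %d target cells, %d genes\n",
              nrow(x$source$counts), nrow(x$target$counts),
              x$config$n_genes))
  invisible(x)
}

#' Write a synthetic pair to disk
#'
#' Emits, per species, a MatrixMarket matrix (genes x cells), gene names,
#' barcodes and labels as TSV, plus the lineage tree as JSON and the ortholog
#' table as TSV. A round-trip through [read_species_dataset()] reproduces the
#' count values exactly.
#'
#' @param pair A `synthetic_pair`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written (the manifest), invisibly
#'   checked to be complete.
#' @export
write_dataset <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_pair"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("cannot write to directory: ", dir)
  }
  manifest <- character(0)
  for (sp in c("source", "target")) {
    d <- pair[[sp]]
    mm <- file.path(dir, paste0(sp, "_matrix.mtx"))
    Matrix::writeMM(Matrix::Matrix(t(d$counts), sparse = TRUE), mm)
    utils::write.table(data.frame(gene = d$gene_names),
                       file.path(dir, paste0(sp, "_genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(data.frame(barcode = d$barcodes),
                       file.path(dir, paste0(sp, "_barcodes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(data.frame(barcode = d$barcodes, label = d$labels),
                       file.path(dir, paste0(sp, "_labels.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
    manifest <- c(manifest, paste0(sp, c("_matrix.mtx", "_genes.tsv",
                                         "_barcodes.tsv", "_labels.tsv")))
  }
  write_tree_json(pair$tree, file.path(dir, "tree.json"))
  utils::write.table(pair$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, "tree.json", "orthologs.tsv")
  missing <- manifest[!file.exists(file.path(dir, manifest))]
  if (length(missing)) stop("failed to write: ", paste(missing, collapse = ", "))
  manifest
}

#' Read one species of a written dataset
#'
#' @param dir Directory written by [write_dataset()].
#' @param species `"source"` or `"target"`.
#' @return List with `counts` (cells x genes, base matrix), `labels`,
#'   `gene_names`, `barcodes`.
#' @export
read_species_dataset <- function(dir, species = c("source", "target")) {
  species <- match.arg(species)
  pre <- function(s) file.path(dir, paste0(species, s))
  m <- as.matrix(Matrix::readMM(pre("_matrix.mtx")))
  genes <- readLines(pre("_genes.tsv"))
  barcodes <- readLines(pre("_barcodes.tsv"))
  labels <- utils::read.table(pre("_labels.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  counts <- t(m)
  dimnames(counts) <- list(barcodes, genes)
  storage.mode(counts) <- "integer"
  list(counts = counts, labels = labels$label, gene_names = genes,
       barcodes = barcodes, species = species)
}

#' Read an ortholog table from TSV
#'
#' @param path TSV with columns `source_gene`, `target_gene`.
#' @return data.frame with those two columns.
#' @export
read_orthologs <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("source_gene", "target_gene") %in% names(x))) {
    stop("ortholog table needs columns source_gene, target_gene: ", path)
  }
  x[, c("source_gene", "target_gene")]
}
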